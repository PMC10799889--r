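# Gene-signature scoring with expression-matched control genes, and the
# exhaustion / cytotoxicity profiling of T cells with empirical background
# cutoffs derived from reference (non-exhausted / non-cytotoxic)
# populations.

#' Built-in marker panels
#'
#' The exhaustion panel is `CTLA4, HAVCR2, LAG3, PDCD1, TIGIT` with the
#' non-exhausted CD4 populations (`CD4 SOCS3+`, `CD4 naive`) as statistical
#' background; the cytotoxicity panel is `PRF1, IFNG, GNLY, NKG7, GZMK,
#' GZMB, GZMA, CST7, TNFSF10` with all CD4+ T cells as background.
#'
#' @return named list of panels; each panel is a list with `genes`,
#'   `reference` (labels or a regex), and `reference_mode` (`"exact"` or
#'   `"pattern"`).
#' @export
default_panels <- function() {
  list(
    exhausted = list(
      genes = c("CTLA4", "HAVCR2", "LAG3", "PDCD1", "TIGIT"),
      reference = c("CD4 SOCS3+", "CD4 naive"),
      reference_mode = "exact"),
    cytotoxic = list(
      genes = c("PRF1", "IFNG", "GNLY", "NKG7", "GZMK", "GZMB", "GZMA",
                "CST7", "TNFSF10"),
      reference = "^CD4",
      reference_mode = "pattern"))
}

#' Read marker panels from a YAML config
#'
#' Flat mapping of panel name to a list with `genes` and optionally
#' `reference` / `reference_mode`; see the bundled
#' `system.file("extdata", "panels.yaml", package = "tmedyn")`.
#'
#' @param path YAML file path.
#' @return named list of panels as in [default_panels()].
#' @export
read_panels <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) {
    if (is.character(p)) p <- list(genes = p)
    p$reference_mode <- p$reference_mode %||% "exact"
    p
  })
}

#' Score cells for a gene signature with binned control genes
#'
#' The score of a cell is the mean log-normalized expression of the
#' signature genes minus the mean expression of control genes. Controls are
#' sampled (seeded, `n_ctrl` per signature gene, without replacement within
#' a bin) from expression bins: all genes are ranked by their mean
#' expression across cells and split into `n_bins` equal-frequency bins,
#' and each signature gene draws its controls from its own bin, excluding
#' signature genes. This cancels the depth/expression-level component of
#' the signature mean.
#'
#' @param matrix log-normalized [count_matrix()].
#' @param genes signature gene symbols.
#' @param n_bins number of expression bins.
#' @param n_ctrl control genes sampled per signature gene.
#' @param seed integer seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
score_signature <- function(matrix, genes, n_bins = 25, n_ctrl = 50, seed = 0) {
  if (matrix$state != "lognorm")
    stop_fmt("score_signature requires a log-normalized matrix (state = %s)",
             matrix$state)
  m <- matrix$counts
  present <- intersect(genes, rownames(m))
  if (length(present) == 0)
    stop_fmt("none of the signature genes are present in the matrix: %s",
             paste(genes, collapse = ", "))
  if (length(present) < length(genes))
    warn_fmt("signature gene(s) absent from the matrix skipped: %s",
             paste(setdiff(genes, present), collapse = ", "))
  gene_means <- Matrix::rowMeans(m)
  n_genes <- length(gene_means)
  ranks <- rank(gene_means, ties.method = "min")
  bins <- ceiling(ranks * n_bins / n_genes)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      cand <- setdiff(names(bins)[bins == bins[[g]]], genes)
      if (length(cand) == 0) return(character(0))
      sample(cand, min(n_ctrl, length(cand)))
    })))
  })
  sig_mean <- Matrix::colMeans(m[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl) > 0) Matrix::colMeans(m[ctrl, , drop = FALSE]) else 0
  score <- sig_mean - ctrl_mean
  names(score) <- colnames(m)
  score
}

#' Background score cutoff from reference cells
#'
#' The empirical quantile at `level` of the pooled reference-population
#' scores; a one-tailed test at the 99% level corresponds to
#' `level = 0.99`. Scores above the cutoff are flagged positive.
#'
#' @param ref_scores numeric scores of the reference (background) cells.
#' @param level quantile level in `(0, 1)`.
#' @return scalar cutoff.
#' @export
background_cutoff <- function(ref_scores, level = 0.99) {
  ref_scores <- ref_scores[is.finite(ref_scores)]
  if (length(ref_scores) == 0)
    stop_fmt("empty reference score set")
  if (length(ref_scores) < 100)
    warn_fmt("fewer than 100 reference cells (%d); the cutoff may be unstable",
             length(ref_scores))
  unname(stats::quantile(ref_scores, probs = level, type = 7))
}

reference_cells <- function(cells, panel) {
  if (is.null(cells$subtype)) stop_fmt("cell table has no 'subtype' column")
  mode <- panel$reference_mode %||% "exact"
  if (mode == "pattern") {
    sel <- !is.na(cells$subtype) & grepl(panel$reference, cells$subtype)
  } else {
    sel <- !is.na(cells$subtype) & cells$subtype %in% panel$reference
  }
  if (!any(sel))
    stop_fmt("reference population absent from cohort (panel reference: %s)",
             paste(panel$reference, collapse = ", "))
  cells$cell_id[sel]
}

#' Exhaustion and cytotoxicity profile of T cells
#'
#' Scores every cell for both panels, derives the background cutoff from
#' each panel's reference population, and summarizes scores per subtype and
#' timepoint with a two-sided Mann-Whitney (Wilcoxon rank-sum) pre-vs-post
#' comparison.
#'
#' @param matrix log-normalized [count_matrix()].
#' @param cells cell table (with `subtype`).
#' @param panels list of two panels as in [default_panels()].
#' @param level one-tailed background level for the cutoff.
#' @param seed control-gene sampling seed.
#' @return list with `scores` (cell_id, panel, score, above_cutoff),
#'   `cutoffs`, `summary` (per subtype x timepoint n and median), and
#'   `tests` (per subtype Mann-Whitney p-values).
#' @export
exhaustion_cytotoxicity_profile <- function(matrix, cells,
                                            panels = default_panels(),
                                            level = 0.99, seed = 0) {
  df <- as.data.frame(cells)
  df <- df[df$cell_id %in% colnames(matrix$counts), , drop = FALSE]
  score_rows <- list(); cutoffs <- list(); summaries <- list(); tests <- list()
  for (nm in names(panels)) {
    panel <- panels[[nm]]
    sc <- score_signature(matrix, panel$genes, seed = seed)
    ref <- reference_cells(df, panel)
    cut <- background_cutoff(sc[ref], level = level)
    cutoffs[[nm]] <- cut
    score_rows[[nm]] <- data.frame(cell_id = names(sc), panel = nm,
                                   score = unname(sc),
                                   above_cutoff = unname(sc > cut),
                                   stringsAsFactors = FALSE)
    s <- sc[df$cell_id]
    labeled <- !is.na(df$subtype)
    for (st in sort(unique(df$subtype[labeled]))) {
      for (tp in c("pre", "post")) {
        sel <- labeled & df$subtype == st & df$timepoint == tp
        if (!any(sel)) next
        summaries[[length(summaries) + 1]] <- data.frame(
          panel = nm, subtype = st, timepoint = tp, n = sum(sel),
          median_score = stats::median(s[sel]),
          frac_above = mean(s[sel] > cut), stringsAsFactors = FALSE)
      }
      pre <- s[labeled & df$subtype == st & df$timepoint == "pre"]
      post <- s[labeled & df$subtype == st & df$timepoint == "post"]
      if (length(pre) > 0 && length(post) > 0) {
        p <- suppressWarnings(stats::wilcox.test(pre, post)$p.value)
        tests[[length(tests) + 1]] <- data.frame(
          panel = nm, subtype = st, n_pre = length(pre), n_post = length(post),
          mann_whitney_p = p, stringsAsFactors = FALSE)
      }
    }
  }
  list(scores = do.call(rbind, score_rows),
       cutoffs = unlist(cutoffs),
       summary = do.call(rbind, summaries),
       tests = do.call(rbind, tests))
}

#' Mean functional signature scores per myeloid subtype
#'
#' Scores every cell for each functional panel (e.g. M1, M2, angiogenesis,
#' phagocytosis, anti-/pro-inflammatory) and averages scores within each
#' myeloid subtype.
#'
#' @param matrix log-normalized [count_matrix()].
#' @param cells cell table; only cells with `major_type %in% major_types`
#'   enter the summary.
#' @param panels named list of gene vectors (or panel lists with `genes`).
#' @param major_types major-type labels delimiting the myeloid compartment.
#' @param seed control-gene sampling seed.
#' @return numeric matrix, subtypes x panels, of mean scores.
#' @export
myeloid_function_scores <- function(matrix, cells, panels,
                                    major_types = "Myeloid", seed = 0) {
  df <- as.data.frame(cells)
  df <- df[df$major_type %in% major_types & !is.na(df$subtype), , drop = FALSE]
  if (nrow(df) == 0) stop_fmt("no cells in the myeloid compartment")
  subtypes <- sort(unique(df$subtype))
  out <- matrix(NA_real_, length(subtypes), length(panels),
                dimnames = list(subtypes, names(panels)))
  for (nm in names(panels)) {
    genes <- if (is.list(panels[[nm]])) panels[[nm]]$genes else panels[[nm]]
    sc <- score_signature(matrix, genes, seed = seed)
    s <- sc[df$cell_id]
    out[, nm] <- vapply(subtypes, function(st) mean(s[df$subtype == st]), numeric(1))
  }
  out
}
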
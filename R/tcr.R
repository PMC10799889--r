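# TCR clonotype dynamics. A clonotype is a cluster of T cells sharing
# identical CDR3 nucleotide sequences; clone IDs are taken as given from
# the upstream V(D)J pipeline. Expansion/contraction is a per-clone
# two-sided Fisher's exact test of the clone's share of the patient's
# repertoire before vs after therapy.

#' Read per-cell clonotype assignments
#'
#' @param path CSV with columns `cell_id`, `clone_id` and optionally
#'   `chain_count` (dual-IR cells have 2).
#' @return data.frame of assignments.
#' @export
read_clonotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "clone_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop_fmt("clonotype table is missing column(s): %s", paste(missing, collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  df$clone_id <- as.character(df$clone_id)
  df
}

#' Build per-patient clonotype count tables
#'
#' Tallies, per patient and clone, the number of cells at each timepoint.
#' Cells without an identified immune receptor (`has_ir = FALSE`) are
#' excluded with a warning even if a clone row exists; dual-IR cells are
#' retained. Totals are the IR-positive cells of the same patient and
#' timepoint.
#'
#' @param cells cell table.
#' @param clonotypes assignments from [read_clonotypes()].
#' @return object of class `"clonotype_counts"`: a list with `counts`
#'   (patient_id, clone_id, count_pre, count_post, total_pre, total_post)
#'   and `cells` (the merged cell-level records with subtype labels).
#' @export
build_clonotype_counts <- function(cells, clonotypes) {
  df <- as.data.frame(cells)
  unknown <- setdiff(clonotypes$cell_id, df$cell_id)
  if (length(unknown) > 0)
    stop_fmt("clonotype assignment(s) for unknown cell(s): %s",
             paste(utils::head(unknown, 5), collapse = ", "))
  m <- merge(clonotypes, df, by = "cell_id")
  if (!is.null(m$has_ir)) {
    no_ir <- !m$has_ir
    if (any(no_ir)) {
      warn_fmt("%d clone assignment(s) for cells without an identified immune receptor excluded",
               sum(no_ir))
      m <- m[!no_ir, , drop = FALSE]
    }
  }
  if (nrow(m) == 0) stop_fmt("no IR-positive cells with clonotype assignments")
  key <- interaction(m$patient_id, m$clone_id, drop = TRUE, sep = "\r")
  cnt <- function(tp) {
    tapply(m$timepoint == tp, key, sum)
  }
  pre <- cnt("pre"); post <- cnt("post")
  ids <- do.call(rbind, strsplit(names(pre), "\r", fixed = TRUE))
  counts <- data.frame(patient_id = ids[, 1], clone_id = ids[, 2],
                       count_pre = as.integer(pre), count_post = as.integer(post),
                       stringsAsFactors = FALSE)
  tot <- stats::aggregate(cbind(count_pre, count_post) ~ patient_id, data = counts, FUN = sum)
  counts$total_pre <- tot$count_pre[match(counts$patient_id, tot$patient_id)]
  counts$total_post <- tot$count_post[match(counts$patient_id, tot$patient_id)]
  counts <- counts[order(counts$patient_id, counts$clone_id), ]
  rownames(counts) <- NULL
  structure(list(counts = counts, cells = m), class = "clonotype_counts")
}

#' @export
print.clonotype_counts <- function(x, ...) {
  cat(sprintf("<clonotype_counts> %d clones, %d patients, %d cells\n",
              nrow(x$counts), length(unique(x$counts$patient_id)), nrow(x$cells)))
  invisible(x)
}

#' Classify clonotype expansion and contraction
#'
#' For each clone, a 2x2 table `[[count_pre, total_pre - count_pre],
#' [count_post, total_post - count_post]]` is tested with a two-sided
#' Fisher's exact test. Clones with `p < alpha` and cross-product odds
#' ratio `OR > 1` are `contracted`; `p < alpha` with `OR < 1` are
#' `expanded` (clones absent before therapy -- "novel", `OR = 0` -- fall
#' here and are merged into `expanded`); all other clones are `unchange`.
#'
#' @param ct a [build_clonotype_counts()] object (or its `counts` data.frame).
#' @param alpha significance threshold on the raw Fisher p-value.
#' @param p_adjust apply Benjamini-Hochberg correction before thresholding
#'   (off by default: each clone is thresholded on its raw p-value).
#' @return data.frame: `patient_id`, `clone_id`, counts, `odds_ratio`
#'   (cross-product, with 0 and `Inf` permitted), `fisher_p`, `label`.
#' @export
classify_clonotype_change <- function(ct, alpha = 0.05, p_adjust = FALSE) {
  counts <- if (inherits(ct, "clonotype_counts")) ct$counts else ct
  if (any(counts$total_pre <= 0 | counts$total_post <= 0)) {
    bad <- unique(counts$patient_id[counts$total_pre <= 0 | counts$total_post <= 0])
    stop_fmt("patient(s) with an empty repertoire at one timepoint: %s",
             paste(bad, collapse = ", "))
  }
  a <- counts$count_pre; c_ <- counts$count_post
  b <- counts$total_pre - a; d <- counts$total_post - c_
  if (any(a + c_ == 0))
    stop_fmt("clone(s) absent at both timepoints")
  or <- ifelse(a == 0, 0,
        ifelse(c_ == 0, Inf, (a * d) / (b * c_)))
  or[a > 0 & c_ > 0 & b == 0] <- Inf
  p <- vapply(seq_len(nrow(counts)), function(i) {
    stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  p_thr <- if (p_adjust) stats::p.adjust(p, method = "BH") else p
  label <- ifelse(p_thr < alpha & or > 1, "contracted",
           ifelse(p_thr < alpha & or < 1, "expanded", "unchange"))
  data.frame(patient_id = counts$patient_id, clone_id = counts$clone_id,
             count_pre = a, count_post = c_,
             total_pre = counts$total_pre, total_post = counts$total_post,
             odds_ratio = or, fisher_p = p, label = label,
             stringsAsFactors = FALSE)
}

# Compartment from a subtype label by prefix patterns (default CD8/CD4).
compartment_of <- function(subtype, compartments = c(CD8 = "^CD8", CD4 = "^CD4")) {
  out <- rep(NA_character_, length(subtype))
  for (nm in names(compartments)) {
    hit <- !is.na(subtype) & grepl(compartments[[nm]], subtype)
    out[is.na(out) & hit] <- nm
  }
  out
}

#' Unique / clonal / shared clone classes per patient and compartment
#'
#' `unique` = a clone represented by exactly one cell in the patient;
#' `clonal` = two or more cells confined to a single timepoint;
#' `shared` = present at both timepoints regardless of size. Percentages
#' are over clones within each compartment and sum to 100.
#'
#' @param ct a [build_clonotype_counts()] object.
#' @param compartments named character vector of regex patterns mapping
#'   subtype labels to compartments.
#' @return data.frame: `patient_id`, `compartment`, `class`, `n_clones`,
#'   `percent`.
#' @export
sharing_classes <- function(ct, compartments = c(CD8 = "^CD8", CD4 = "^CD4")) {
  cells <- ct$cells
  cells$compartment <- compartment_of(cells$subtype, compartments)
  cells <- cells[!is.na(cells$compartment), , drop = FALSE]
  out <- list()
  for (pat in sort(unique(cells$patient_id))) {
    for (comp in names(compartments)) {
      sub <- cells[cells$patient_id == pat & cells$compartment == comp, , drop = FALSE]
      if (nrow(sub) == 0) {
        warn_fmt("patient %s has no %s clones; omitted", pat, comp)
        next
      }
      n_cells <- tapply(rep(1L, nrow(sub)), sub$clone_id, sum)
      tp_n <- tapply(sub$timepoint, sub$clone_id, function(z) length(unique(z)))
      cls <- ifelse(tp_n == 2, "shared",
             ifelse(n_cells >= 2, "clonal", "unique"))
      tab <- table(factor(cls, levels = c("unique", "clonal", "shared")))
      out[[length(out) + 1]] <- data.frame(
        patient_id = pat, compartment = comp, class = names(tab),
        n_clones = as.integer(tab), percent = 100 * as.integer(tab) / sum(tab),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' D50 repertoire diversity
#'
#' The minimum percentage of distinct clonotypes whose cumulative abundance
#' accounts for at least half of the total cells: abundances are sorted
#' descending (ties broken by clone ID for determinism), `k` is the
#' smallest number of clones reaching half the total, and
#' `D50 = 100 * k / n_clones`. Lower values mean a more clonal repertoire.
#'
#' @param abundances (optionally named) positive clone abundances.
#' @return D50 percentage in `(0, 100]`.
#' @export
d50 <- function(abundances) {
  if (length(abundances) == 0) stop_fmt("D50 undefined for an empty group")
  if (any(abundances < 0)) stop_fmt("abundances must be nonnegative")
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0) stop_fmt("D50 undefined: all abundances zero")
  nm <- names(abundances) %||% as.character(seq_along(abundances))
  o <- order(-abundances, nm)
  cum <- cumsum(abundances[o])
  k <- unname(which(cum >= sum(abundances) / 2)[1])
  100 * k / length(abundances)
}

#' D50 per group of a clonotype table
#'
#' @param ct a [build_clonotype_counts()] object.
#' @param by grouping of cells: `"patient"`, `"patient_timepoint"`, or
#'   `"subtype"`.
#' @return data.frame: `group`, `n_clones`, `d50`.
#' @export
d50_table <- function(ct, by = c("patient", "patient_timepoint", "subtype")) {
  by <- match.arg(by)
  cells <- ct$cells
  grp <- switch(by,
    patient = cells$patient_id,
    patient_timepoint = paste(cells$patient_id, cells$timepoint, sep = "/"),
    subtype = cells$subtype)
  keep <- !is.na(grp)
  cells <- cells[keep, ]; grp <- grp[keep]
  res <- lapply(sort(unique(grp)), function(g) {
    ab <- tapply(rep(1L, sum(grp == g)), cells$clone_id[grp == g], sum)
    data.frame(group = g, n_clones = length(ab), d50 = d50(ab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise clonal similarity across subtypes
#'
#' Jaccard index of the clone-ID sets observed in each pair of subtypes.
#'
#' @param ct a [build_clonotype_counts()] object.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
subtype_clonal_similarity <- function(ct) {
  cells <- ct$cells[!is.na(ct$cells$subtype), , drop = FALSE]
  subtypes <- sort(unique(cells$subtype))
  sets <- lapply(subtypes, function(s) unique(cells$clone_id[cells$subtype == s]))
  names(sets) <- subtypes
  n <- length(subtypes)
  sim <- matrix(0, n, n, dimnames = list(subtypes, subtypes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- length(union(sets[[i]], sets[[j]]))
    sim[i, j] <- if (u == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / u
  }
  diag(sim) <- ifelse(lengths(sets) == 0, 0, 1)
  if (any(lengths(sets) == 0))
    warn_fmt("subtype(s) with no clones assigned similarity 0 by convention")
  sim
}

#' Subtype composition of each patient's most abundant clones
#'
#' @param ct a [build_clonotype_counts()] object.
#' @param k number of top clones per patient (ties broken lexicographically
#'   by clone ID); patients with fewer clones return all of them.
#' @return data.frame: `patient_id`, `rank`, `clone_id`, `n_cells`,
#'   `subtype`, `n_cells_subtype`.
#' @export
top_clone_subtype_map <- function(ct, k = 5) {
  cells <- ct$cells
  out <- list()
  for (pat in sort(unique(cells$patient_id))) {
    sub <- cells[cells$patient_id == pat, , drop = FALSE]
    ab <- tapply(rep(1L, nrow(sub)), sub$clone_id, sum)
    o <- order(-ab, names(ab))
    top <- names(ab)[o][seq_len(min(k, length(ab)))]
    for (r in seq_along(top)) {
      cl <- top[r]
      st <- table(sub$subtype[sub$clone_id == cl], useNA = "no")
      out[[length(out) + 1]] <- data.frame(
        patient_id = pat, rank = r, clone_id = cl, n_cells = as.integer(ab[cl]),
        subtype = names(st), n_cells_subtype = as.integer(st),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Association between clonal expansion and tumor response
#'
#' Per patient, computes the proportion of compartment cells (default CD8)
#' carrying clonotypes with a given classification label, and fits the
#' signed regression index against tumor change.
#'
#' @param ct a [build_clonotype_counts()] object.
#' @param classification output of [classify_clonotype_change()].
#' @param sizes tumor-size table.
#' @param status clone label whose carrier proportion is the predictor
#'   (`"expanded"` or `"contracted"`).
#' @param compartment_pattern regex selecting subtype labels of the
#'   compartment.
#' @return one-row data.frame from [fit_index()].
#' @export
expansion_response_association <- function(ct, classification, sizes,
                                           status = c("expanded", "contracted"),
                                           compartment_pattern = "^CD8") {
  status <- match.arg(status)
  cells <- ct$cells
  cells <- cells[!is.na(cells$subtype) & grepl(compartment_pattern, cells$subtype), , drop = FALSE]
  if (nrow(cells) == 0) stop_fmt("no cells match the compartment pattern")
  key <- paste(classification$patient_id, classification$clone_id, sep = "\r")
  lab <- classification$label[match(paste(cells$patient_id, cells$clone_id, sep = "\r"), key)]
  patients <- sort(unique(cells$patient_id))
  x <- vapply(patients, function(p) {
    sel <- cells$patient_id == p
    mean(lab[sel] == status, na.rm = TRUE)
  }, numeric(1))
  y <- sizes$tumor_change[match(patients, sizes$patient_id)]
  fit_index(x, y, feature = paste0(status, "_carrier_proportion"))
}
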
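# Cohort-level pipeline: runs the enabled stages in dependency order on a
# fixture directory (cells.tsv + MatrixMarket triplet + clonotypes.csv +
# tumor_sizes.tsv, optionally bulk TSVs), writes per-stage TSVs and a
# summary.json, and serializes its configuration for reproducibility.

PIPELINE_STAGES <- c("composition", "indices", "tcr", "scores", "lr", "bulk")

#' Pipeline run configuration
#'
#' @param input_dir directory holding `cells.tsv`, `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `clonotypes.csv`, `tumor_sizes.tsv`.
#' @param out_dir output directory.
#' @param stages stages to run, a subset of
#'   `c("composition", "indices", "tcr", "scores", "lr", "bulk")`.
#' @param do_qc apply [qc_filter()] before normalization.
#' @param qc a [qc_thresholds()] object.
#' @param alpha Fisher significance threshold for clonotype classes.
#' @param quantile_level background-cutoff level for signature scores.
#' @param expr_threshold,spec_threshold,detection_threshold ligand-receptor
#'   edge filters (CPM / weight / detection rate).
#' @param lr_pairs path to a two-column TSV (`ligand`, `receptor`); required
#'   for the `lr` stage.
#' @param bulk_expr,bulk_clinical paths for the `bulk` stage.
#' @param bulk_numerator,bulk_denominator names of the bulk marker sets
#'   whose score ratio is median-split for survival.
#' @param seed seed for control-gene sampling.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input_dir, out_dir,
                       stages = c("composition", "indices", "tcr", "scores"),
                       do_qc = TRUE, qc = qc_thresholds(),
                       alpha = 0.05, quantile_level = 0.99,
                       expr_threshold = 10, spec_threshold = 0.1,
                       detection_threshold = 0.20,
                       lr_pairs = NULL, bulk_expr = NULL, bulk_clinical = NULL,
                       bulk_numerator = "CD8_GZMK",
                       bulk_denominator = "CD8_proliferating",
                       seed = 0L) {
  if (length(setdiff(stages, PIPELINE_STAGES)) > 0)
    stop_fmt("unknown stage(s): %s",
             paste(setdiff(stages, PIPELINE_STAGES), collapse = ", "))
  structure(mget(names(formals(run_config))[names(formals(run_config)) != "..."]),
            class = "run_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `stages` is comma-separated; numeric
#' and logical values are coerced. Unknown keys are rejected.
#'
#' @param path config file path.
#' @param ... overrides taking precedence over the file.
#' @return a [run_config()] list.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(z) paste(z[-1], collapse = "="), character(1)))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    stop_fmt("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  if (!is.null(args$stages)) args$stages <- trimws(strsplit(args$stages, ",")[[1]])
  for (k in intersect(names(args), c("alpha", "quantile_level", "expr_threshold",
                                     "spec_threshold", "detection_threshold", "seed")))
    args[[k]] <- as.numeric(args[[k]])
  if (!is.null(args$do_qc)) args$do_qc <- as.logical(args$do_qc)
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Executes the enabled stages in dependency order (I/O and QC, then
#' composition, regression indices, TCR dynamics, signature scores,
#' ligand-receptor specificity, bulk validation), writes one TSV per
#' output table plus `summary.json` and the serialized `config.json` into
#' `config$out_dir`.
#'
#' @param config a [run_config()] list.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- config
  cfg_json$qc <- unclass(config$qc)
  jsonlite::write_json(cfg_json[setdiff(names(cfg_json), "")],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  summary <- list(package_version = as.character(utils::packageVersion("tmedyn")),
                  seed = config$seed)

  cells <- read_cell_table(file.path(config$input_dir, "cells.tsv"))
  sizes <- read_tumor_sizes(file.path(config$input_dir, "tumor_sizes.tsv"))
  mat <- read_counts_mtx(file.path(config$input_dir, "matrix.mtx"),
                         file.path(config$input_dir, "features.tsv"),
                         file.path(config$input_dir, "barcodes.tsv"))
  if (isTRUE(config$do_qc)) {
    qcres <- qc_filter(mat, cells, config$qc)
    mat <- qcres$matrix
    cells <- as_cell_table(qcres$cells)
    summary$qc <- qcres$report
  }
  summary$n_cells <- nrow(cells)
  summary$n_genes <- nrow(mat$counts)

  pm <- proportion_matrix(cells, level = "major_type")

  if ("composition" %in% config$stages) {
    props <- data.frame(sample_id = rownames(pm), as.data.frame(unclass(pm)),
                        check.names = FALSE)
    write_tsv(props, file.path(config$out_dir, "proportions.tsv"))
    enr <- enrichment_table(cells, level = "major_type")
    write_tsv(enr, file.path(config$out_dir, "enrichment_scores.tsv"))
    sl <- slocc_table(cells, level = "major_type")
    write_tsv(sl, file.path(config$out_dir, "slocc.tsv"))
    summary$composition <- list(
      n_types = ncol(pm),
      max_enrichment = list(label = enr$label[which.max(enr$score)],
                            score = max(enr$score)),
      max_slocc = list(label = sl$label[which.max(sl$slocc)],
                       slocc = max(sl$slocc)))
  }

  if ("indices" %in% config$stages) {
    pi_tab <- predictive_index(pm, sizes)
    ti_tab <- therapeutic_index(pm, sizes)
    idx <- rbind(pi_tab, ti_tab)
    write_tsv(idx, file.path(config$out_dir, "indices.tsv"))
    summary$indices <- list(
      n_features = nrow(pi_tab),
      n_significant = sum(idx$wald_p < 0.05, na.rm = TRUE),
      pi = stats::setNames(as.list(pi_tab$index), pi_tab$feature),
      ti = stats::setNames(as.list(ti_tab$index), ti_tab$feature))
  }

  if ("tcr" %in% config$stages) {
    clones <- read_clonotypes(file.path(config$input_dir, "clonotypes.csv"))
    clones <- clones[clones$cell_id %in% cells$cell_id, , drop = FALSE]
    ct <- build_clonotype_counts(cells, clones)
    cls <- classify_clonotype_change(ct, alpha = config$alpha)
    write_tsv(cls, file.path(config$out_dir, "clonotype_classes.tsv"))
    sh <- sharing_classes(ct)
    write_tsv(sh, file.path(config$out_dir, "sharing.tsv"))
    dd <- d50_table(ct, by = "patient_timepoint")
    write_tsv(dd, file.path(config$out_dir, "d50.tsv"))
    sim <- subtype_clonal_similarity(ct)
    write_tsv(data.frame(subtype = rownames(sim), as.data.frame(sim),
                         check.names = FALSE),
              file.path(config$out_dir, "similarity.tsv"))
    summary$tcr <- list(
      n_clones = nrow(cls),
      class_counts = as.list(table(cls$label)),
      d50 = stats::setNames(as.list(dd$d50), dd$group))
  }

  if ("scores" %in% config$stages) {
    logm <- normalize_counts(mat, "lognorm")
    prof <- exhaustion_cytotoxicity_profile(logm, cells,
                                            level = config$quantile_level,
                                            seed = config$seed)
    write_tsv(prof$scores, file.path(config$out_dir, "scores.tsv"))
    write_tsv(prof$summary, file.path(config$out_dir, "score_summary.tsv"))
    summary$scores <- list(
      cutoffs = as.list(prof$cutoffs),
      n_above = as.list(tapply(prof$scores$above_cutoff, prof$scores$panel, sum)))
  }

  if ("lr" %in% config$stages) {
    if (is.null(config$lr_pairs))
      stop_fmt("stage 'lr' requires a ligand-receptor pair catalog (lr_pairs)")
    pairs <- utils::read.delim(config$lr_pairs, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    cpm <- normalize_counts(mat, "cpm")
    means <- mean_expression_by_type(cpm, cells)
    edges <- compute_lr_edges(means, pairs)
    filt <- filter_edges(edges,
                         expr_threshold = config$expr_threshold,
                         spec_threshold = config$spec_threshold,
                         detection_threshold = config$detection_threshold)
    ret <- filt$retained
    if (nrow(ret) > 0) ret$reason <- ""
    rej <- filt$rejected
    out_edges <- if (nrow(ret) > 0 && nrow(rej) > 0) rbind(ret, rej)
      else if (nrow(ret) > 0) ret else rej
    write_tsv(out_edges, file.path(config$out_dir, "edges.tsv"))
    summary$lr <- list(n_edges = nrow(edges),
                       n_retained = nrow(filt$retained),
                       n_rejected = nrow(filt$rejected))
  }

  if ("bulk" %in% config$stages) {
    if (is.null(config$bulk_expr) || is.null(config$bulk_clinical))
      stop_fmt("stage 'bulk' requires bulk_expr and bulk_clinical paths")
    expr <- read_bulk_expression(config$bulk_expr)
    clin <- read_clinical(config$bulk_clinical)
    markers <- default_bulk_markers()
    scores <- lapply(markers, function(m) celltype_score(expr, m))
    sc_df <- data.frame(sample_id = colnames(expr),
                        do.call(cbind, scores), check.names = FALSE)
    write_tsv(sc_df, file.path(config$out_dir, "bulk_scores.tsv"))
    surv <- ratio_split_survival(scores[[config$bulk_numerator]],
                                 scores[[config$bulk_denominator]], clin)
    write_tsv(data.frame(statistic = surv$chisq, p = surv$p_value,
                         n_high = surv$n_high, n_low = surv$n_low),
              file.path(config$out_dir, "survival.tsv"))
    summary$bulk <- list(
      ratio = paste(config$bulk_numerator, config$bulk_denominator, sep = "/"),
      logrank_chisq = surv$chisq, logrank_p = surv$p_value,
      n_high = surv$n_high, n_low = surv$n_low)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
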
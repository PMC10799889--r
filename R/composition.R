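# Cell-type composition: per-sample proportion matrices, the pre/post
# enrichment score, sample-level cluster occupancy (SLOCC), and the paired
# Wilcoxon test on per-patient proportion changes.

#' Per-sample cell-type proportion matrix
#'
#' Rows are samples, columns are labels at the requested level. The
#' denominator of a row is every cell of its scope: the whole sample under
#' `scope = "all_cells"`, or the parent compartment (e.g. CD8 subtypes over
#' all cells of the `compartment` major type in the sample) under
#' `scope = "parent_compartment"`. Rows sum to 1 whenever every cell of the
#' scope carries a label at the requested level.
#'
#' @param cells a cell table.
#' @param level `"major_type"` or `"subtype"`.
#' @param scope denominator scope, `"all_cells"` or `"parent_compartment"`.
#' @param compartment major-type label delimiting the parent compartment
#'   (required when `level = "subtype"` and `scope = "parent_compartment"`).
#' @return numeric matrix (samples x labels) with attributes `patient_id`,
#'   `timepoint`, `denominator` (per-row cell counts), `scope`, and `level`;
#'   class `"proportion_matrix"`.
#' @export
proportion_matrix <- function(cells,
                              level = c("major_type", "subtype"),
                              scope = c("all_cells", "parent_compartment"),
                              compartment = NULL) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  df <- as.data.frame(cells)
  pool <- df
  if (level == "subtype") {
    if (is.null(df$subtype)) stop_fmt("cell table has no 'subtype' column")
    if (scope == "parent_compartment") {
      if (is.null(compartment))
        stop_fmt("scope = 'parent_compartment' requires a 'compartment' major type")
      pool <- df[df$major_type == compartment, , drop = FALSE]
    } else {
      pool <- df
    }
    pool <- pool[!is.na(pool$subtype) & pool$subtype != "", , drop = FALSE]
    lab <- pool$subtype
  } else {
    lab <- pool$major_type
  }
  if (nrow(pool) == 0) stop_fmt("no cells in the requested scope")
  samples <- sort(unique(df$sample_id))
  labels <- sort(unique(lab))
  tab <- table(factor(pool$sample_id, levels = samples), factor(lab, levels = labels))
  counts <- matrix(as.numeric(tab), nrow = length(samples),
                   dimnames = list(samples, labels))
  # denominator: every cell of the scope's pool, labeled or not -- the whole
  # sample under all_cells, the parent compartment otherwise
  denom_pool <- if (level == "subtype" && scope == "parent_compartment") {
    df[df$major_type == compartment, , drop = FALSE]
  } else df
  denom <- as.numeric(table(factor(denom_pool$sample_id, levels = samples)))
  names(denom) <- samples
  empty <- samples[denom == 0]
  if (length(empty) > 0)
    stop_fmt("sample(s) with zero cells in scope: %s", paste(empty, collapse = ", "))
  pm <- counts / denom
  meta <- unique(df[, c("sample_id", "patient_id", "timepoint")])
  meta <- meta[match(samples, meta$sample_id), ]
  structure(pm,
            patient_id = meta$patient_id,
            timepoint = meta$timepoint,
            denominator = denom,
            scope = scope, level = level,
            class = c("proportion_matrix", "matrix"))
}

# Rows of a proportion matrix for one timepoint, re-keyed by patient.
pm_by_patient <- function(pm, timepoint) {
  tp <- attr(pm, "timepoint")
  pat <- attr(pm, "patient_id")
  if (is.null(tp) || is.null(pat))
    stop_fmt("expected a proportion_matrix with patient/timepoint attributes")
  sel <- tp == timepoint
  if (!any(sel)) stop_fmt("no samples at timepoint '%s'", timepoint)
  out <- unclass(pm)[sel, , drop = FALSE]
  rownames(out) <- pat[sel]
  out
}

#' Pre/post enrichment score of a cell type
#'
#' Measures how far a cell type's pre-treatment share departs from its
#' pooled pre+post share:
#' `|1 - (pre/Npre) / ((pre + post) / (Npre + Npost))|`.
#' It is 0 when the pre and post proportions are equal, and 1 when the cell
#' type is absent before treatment.
#'
#' @param pre,post cell-type cell counts in the pooled pre / post samples.
#' @param Npre,Npost total cell counts in the pre / post groups.
#' @return nonnegative numeric vector (vectorized over inputs).
#' @export
enrichment_score <- function(pre, Npre, post, Npost) {
  if (any(Npre <= 0) || any(Npost <= 0))
    stop_fmt("Npre and Npost must be positive")
  if (any(pre + post <= 0))
    stop_fmt("enrichment score undefined when pre + post = 0")
  abs(1 - (pre / Npre) / ((pre + post) / (Npre + Npost)))
}

#' Enrichment scores for every cell type in a cohort
#'
#' Pools cells over all pre samples and all post samples and evaluates
#' [enrichment_score()] per label.
#'
#' @param cells cell table.
#' @param level `"major_type"` or `"subtype"`.
#' @return data.frame: `label`, `pre`, `post`, `Npre`, `Npost`, `score`.
#' @export
enrichment_table <- function(cells, level = c("major_type", "subtype")) {
  level <- match.arg(level)
  df <- as.data.frame(cells)
  lab <- df[[level]]
  keep <- !is.na(lab) & lab != ""
  df <- df[keep, ]; lab <- lab[keep]
  Npre <- sum(df$timepoint == "pre")
  Npost <- sum(df$timepoint == "post")
  labels <- sort(unique(lab))
  pre <- sapply(labels, function(l) sum(lab == l & df$timepoint == "pre"))
  post <- sapply(labels, function(l) sum(lab == l & df$timepoint == "post"))
  data.frame(label = labels, pre = pre, post = post, Npre = Npre, Npost = Npost,
             score = enrichment_score(pre, Npre, post, Npost),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample-level occupancy of a cell cluster (SLOCC)
#'
#' The largest single-sample share of a cluster's cells:
#' `max(counts) / sum(counts)`. A value near 1 means the cluster is
#' essentially private to one sample; `1/n_samples` means a uniform spread.
#'
#' @param counts nonnegative per-sample cell counts of one cluster.
#' @return occupancy value in `(0, 1]`.
#' @export
slocc <- function(counts) {
  if (any(counts < 0)) stop_fmt("SLOCC counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop_fmt("SLOCC undefined for an all-zero cluster")
  max(counts) / tot
}

#' SLOCC for every cluster of a cohort
#'
#' @param cells cell table.
#' @param level `"major_type"` or `"subtype"`.
#' @return data.frame: `label`, `slocc`, `top_sample`.
#' @export
slocc_table <- function(cells, level = c("major_type", "subtype")) {
  level <- match.arg(level)
  df <- as.data.frame(cells)
  lab <- df[[level]]
  keep <- !is.na(lab) & lab != ""
  df <- df[keep, ]; lab <- lab[keep]
  labels <- sort(unique(lab))
  res <- lapply(labels, function(l) {
    counts <- table(df$sample_id[lab == l])
    data.frame(label = l, slocc = slocc(as.numeric(counts)),
               top_sample = names(counts)[which.max(counts)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Paired Wilcoxon test on pre/post proportions of one label
#'
#' Two-sided Wilcoxon signed-rank test on per-patient (post - pre)
#' proportion differences. Patients lacking either timepoint are excluded
#' with a warning; if every difference is zero the test is degenerate and
#' `p = 1` is reported.
#'
#' @param pm a [proportion_matrix()] with both timepoints.
#' @param label column (cell-type label) to test.
#' @return list: `label`, `n_pairs`, `statistic`, `p_value`, `differences`.
#' @export
paired_proportion_test <- function(pm, label) {
  if (!label %in% colnames(pm))
    stop_fmt("label '%s' not present in the proportion matrix", label)
  pre <- pm_by_patient(pm, "pre")[, label]
  post <- pm_by_patient(pm, "post")[, label]
  common <- intersect(names(pre), names(post))
  dropped <- setdiff(union(names(pre), names(post)), common)
  if (length(dropped) > 0)
    warn_fmt("unpaired patient(s) excluded: %s", paste(dropped, collapse = ", "))
  if (length(common) < 2)
    stop_fmt("paired test requires at least 2 complete pre/post pairs")
  d <- post[common] - pre[common]
  if (all(d == 0)) {
    return(list(label = label, n_pairs = length(d), statistic = 0, p_value = 1,
                differences = d))
  }
  wt <- suppressWarnings(stats::wilcox.test(post[common], pre[common],
                                            paired = TRUE, alternative = "two.sided"))
  list(label = label, n_pairs = length(d),
       statistic = unname(wt$statistic), p_value = wt$p.value, differences = d)
}
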
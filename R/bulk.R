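# Bulk-cohort validation: marker-averaged cell-type scores, score-on-score
# regression, and overall-survival comparison between median-split
# score-ratio groups.

#' Built-in bulk marker sets for the key subtypes
#'
#' Marker averages represent a cell type's level in a bulk RNA-seq sample:
#' CD5L+ macrophages (`CD5L, SLC40A1, FCGR3A, MARCO, SEPP1`), CD8 GZMK+
#' (`GZMK, GZMA, ITM2C, TNFSF9`), CD8 GZMB+ (`GZMB, RGS1, RBPJ, CTSD`), and
#' proliferating CD8 (`STMN1, TYMS, MKI67, TUBB`).
#'
#' @return named list of marker-gene vectors.
#' @export
default_bulk_markers <- function() {
  list(
    Macro_CD5L = c("CD5L", "SLC40A1", "FCGR3A", "MARCO", "SEPP1"),
    CD8_GZMK = c("GZMK", "GZMA", "ITM2C", "TNFSF9"),
    CD8_GZMB = c("GZMB", "RGS1", "RBPJ", "CTSD"),
    CD8_proliferating = c("STMN1", "TYMS", "MKI67", "TUBB"))
}

#' Read a bulk expression matrix (genes x samples) from TSV
#'
#' @param path TSV whose first column is the gene symbol and remaining
#'   columns are samples. Values are assumed already normalized (e.g.
#'   TPM-like); set `log1p = TRUE` to log-transform on load.
#' @param log1p apply `log1p` to the values.
#' @return numeric matrix, genes x samples.
#' @export
read_bulk_expression <- function(path, log1p = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (log1p) m <- log1p(m)
  m
}

#' Read a clinical survival table
#'
#' @param path TSV with columns `sample_id`, `os_months`, `os_event`
#'   (event indicator 0/1).
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_months", "os_event")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop_fmt("clinical table is missing column(s): %s", paste(missing, collapse = ", "))
  if (any(df$os_months <= 0)) stop_fmt("survival times must be positive")
  if (!all(df$os_event %in% c(0, 1))) stop_fmt("os_event must be 0 or 1")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Marker-averaged cell-type score per bulk sample
#'
#' The arithmetic mean of the marker genes' expression in each sample;
#' markers absent from the matrix are skipped with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param markers marker gene symbols.
#' @return named numeric vector of per-sample scores.
#' @export
celltype_score <- function(expr, markers) {
  present <- intersect(markers, rownames(expr))
  if (length(present) == 0)
    stop_fmt("no marker genes present in the expression matrix: %s",
             paste(markers, collapse = ", "))
  if (length(present) < length(markers))
    warn_fmt("marker gene(s) absent from the matrix skipped: %s",
             paste(setdiff(markers, present), collapse = ", "))
  colMeans(expr[present, , drop = FALSE])
}

#' Single-variable regression between two cell-type scores
#'
#' OLS fit of `y` on `x` with the two-sided t-test on the slope
#' (`n - 2` df); used to quantify coordinated dynamics between cell types
#' in bulk cohorts.
#'
#' @param x,y named per-sample score vectors (matched on names when both
#'   are named).
#' @return one-row data.frame: `n`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `degenerate`.
#' @export
score_regression <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  fi <- fit_index(x, y, feature = "score_regression")
  data.frame(n = fi$n, slope = fi$slope,
             intercept = mean(y[is.finite(x) & is.finite(y)]) -
               fi$slope * mean(x[is.finite(x) & is.finite(y)]),
             r_squared = fi$r_squared, p_value = fi$wald_p,
             degenerate = fi$degenerate)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each distinct event time the observed
#' minus expected events in group 1 are accumulated with the hypergeometric
#' variance, and `(O - E)^2 / V` is referred to a chi-squared distribution
#' with one degree of freedom (two-sided).
#'
#' @param time survival times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level grouping vector.
#' @return list: `chisq`, `p_value`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop_fmt("logrank_test requires exactly 2 groups")
  o <- order(time)
  time <- time[o]; event <- event[o]; g <- g[o]
  times <- unique(time[event == 1])
  O1 <- E1 <- V <- 0
  obs <- c(0, 0); expd <- c(0, 0)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == levels(g)[1])
    e1 <- d * n1 / n
    O1 <- O1 + d1
    E1 <- E1 + e1
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    obs <- obs + c(d1, d - d1)
    expd <- expd + c(e1, d - e1)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  list(chisq = chisq, p_value = p,
       observed = stats::setNames(obs, levels(g)),
       expected = stats::setNames(expd, levels(g)))
}

#' Survival comparison between median-split score-ratio groups
#'
#' Computes the per-sample ratio of two cell-type scores, splits the cohort
#' at the median ratio (ties assigned to the high group), and compares
#' overall survival between groups with the two-sided log-rank test. If
#' either score vector contains non-positive values (possible on log-scale
#' data), both are shifted by a common constant so all values are positive
#' before forming the ratio; the shift is reported.
#'
#' @param numerator,denominator named per-sample score vectors.
#' @param clinical data.frame from [read_clinical()].
#' @return list: `chisq`, `p_value`, `n_high`, `n_low`, `median_ratio`,
#'   `shift`, `groups` (per-sample assignment).
#' @export
ratio_split_survival <- function(numerator, denominator, clinical) {
  common <- Reduce(intersect, list(names(numerator), names(denominator),
                                   clinical$sample_id))
  if (length(common) < 4)
    stop_fmt("too few samples shared by scores and clinical data (%d)", length(common))
  num <- numerator[common]; den <- denominator[common]
  shift <- 0
  mn <- min(c(num, den))
  if (mn <= 0) {
    shift <- -mn + 1
    num <- num + shift; den <- den + shift
  }
  ratio <- num / den
  med <- stats::median(ratio)
  if (all(ratio == ratio[1]))
    stop_fmt("all score ratios identical; no median split possible")
  high <- ratio >= med
  cl <- clinical[match(common, clinical$sample_id), ]
  lr <- logrank_test(cl$os_months, cl$os_event,
                     factor(ifelse(high, "high", "low"), levels = c("high", "low")))
  list(chisq = lr$chisq, p_value = lr$p_value,
       n_high = sum(high), n_low = sum(!high),
       median_ratio = med, shift = shift,
       groups = stats::setNames(ifelse(high, "high", "low"), common))
}
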
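# Signed regression indices: the predictive index (Pi) regresses tumor-size
# change on a baseline cell-population feature, the therapeutic index (Ti)
# on the log10 post/pre proportion ratio. Both are summarized as
# -sign(slope) * R^2, so a positive index means the feature favors tumor
# shrinkage, and significance is the two-sided t (Wald) test on the OLS
# slope with n - 2 degrees of freedom.

#' Fit a univariate signed regression index
#'
#' Ordinary least-squares fit of `y` (relative tumor-size change, negative =
#' shrinkage) on `x` (a cell-population feature). The index is
#' `-sign(slope) * R^2`, lying in `[-1, 1]`; its significance is the
#' two-sided t-test on the slope with `n - 2` degrees of freedom.
#'
#' @param x numeric predictor vector (length >= 3, nonzero variance).
#' @param y numeric response vector (tumor change), same length.
#' @param feature label recorded in the result.
#' @return one-row data.frame: `feature`, `n`, `slope`, `r_squared`,
#'   `index`, `wald_p`, `degenerate`. Perfect fits report `wald_p = 0` with
#'   `degenerate = TRUE`; a constant `y` reports a zero slope and index with
#'   `wald_p = NA` and `degenerate = TRUE`.
#' @export
fit_index <- function(x, y, feature = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop_fmt("fit_index requires at least 3 complete observations (got %d)", n)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0)
    stop_fmt("predictor '%s' has zero variance", feature)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  if (syy == 0) {
    return(data.frame(feature = feature, n = n, slope = 0, r_squared = 0,
                      index = 0, wald_p = NA_real_, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  r2 <- sxy^2 / (sxx * syy)
  idx <- -sign(slope) * r2
  rss <- syy - slope * sxy
  degenerate <- rss <= 1e-12 * syy
  if (degenerate) {
    p <- 0
  } else {
    se <- sqrt(rss / ((n - 2) * sxx))
    p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  data.frame(feature = feature, n = n, slope = slope, r_squared = r2,
             index = idx, wald_p = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

# Shared scaffolding for Pi/Ti: match patients between a proportion matrix
# and the tumor-size table, fit per label, degrade gracefully on
# zero-variance features.
fit_index_by_label <- function(xmat, sizes, kind) {
  patients <- rownames(xmat)
  hit <- patients %in% sizes$patient_id
  if (!all(hit)) {
    warn_fmt("patient(s) without tumor-size data excluded: %s",
             paste(patients[!hit], collapse = ", "))
    xmat <- xmat[hit, , drop = FALSE]
    patients <- patients[hit]
  }
  y <- sizes$tumor_change[match(patients, sizes$patient_id)]
  res <- lapply(colnames(xmat), function(lab) {
    x <- xmat[, lab]
    if (length(unique(x)) < 2) {
      return(data.frame(feature = lab, n = length(x), slope = NA_real_,
                        r_squared = NA_real_, index = NA_real_,
                        wald_p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit_index(x, y, feature = lab)
  })
  out <- do.call(rbind, res)
  out$index_kind <- kind
  rownames(out) <- NULL
  out
}

#' Predictive index (Pi) per cell type
#'
#' Regresses tumor change on the *baseline* (pre-treatment) proportion of
#' each cell type. A positive Pi means a higher baseline proportion predicts
#' more tumor shrinkage.
#'
#' @param pm a [proportion_matrix()] (only its `pre` rows are used).
#' @param sizes tumor-size table from [read_tumor_sizes()]/[as_tumor_sizes()].
#' @return data.frame with one [fit_index()] row per cell-type label plus an
#'   `index_kind` column.
#' @export
predictive_index <- function(pm, sizes) {
  xm <- pm_by_patient(pm, "pre")
  fit_index_by_label(xm, sizes, kind = "Pi")
}

#' Therapeutic index (Ti) per cell type
#'
#' Regresses tumor change on `log10((post + eps) / (pre + eps))` of each
#' cell type's proportion. A positive Ti means an increasing proportion
#' under therapy predicts more tumor shrinkage.
#'
#' @param pm a [proportion_matrix()] containing both timepoints.
#' @param sizes tumor-size table.
#' @param pseudocount zero-proportion policy: `"half_min_nonzero"` (default)
#'   adds half the minimum nonzero proportion of that label when any zero
#'   occurs, `"none"` leaves zeros untouched (labels with zeros then yield
#'   non-finite ratios and are dropped from the fit).
#' @return data.frame as in [predictive_index()], plus attribute
#'   `"pseudocount"` recording the per-label epsilon applied.
#' @export
therapeutic_index <- function(pm, sizes,
                              pseudocount = c("half_min_nonzero", "none")) {
  pseudocount <- match.arg(pseudocount)
  pre <- pm_by_patient(pm, "pre")
  post <- pm_by_patient(pm, "post")
  common <- intersect(rownames(pre), rownames(post))
  if (length(common) < length(rownames(pre)) || length(common) < length(rownames(post)))
    warn_fmt("unpaired patient(s) excluded from Ti")
  pre <- pre[common, , drop = FALSE]
  post <- post[common, , drop = FALSE]
  eps_used <- stats::setNames(numeric(ncol(pre)), colnames(pre))
  lx <- pre
  for (lab in colnames(pre)) {
    p0 <- pre[, lab]; p1 <- post[, lab]
    eps <- 0
    if (pseudocount == "half_min_nonzero" && any(c(p0, p1) == 0)) {
      nz <- c(p0, p1)[c(p0, p1) > 0]
      eps <- if (length(nz) > 0) min(nz) / 2 else NA_real_
    }
    eps_used[lab] <- eps
    lx[, lab] <- log10((p1 + eps) / (p0 + eps))
  }
  out <- fit_index_by_label(lx, sizes, kind = "Ti")
  attr(out, "pseudocount") <- eps_used
  out
}

#' Predictive index on per-cell cluster signature scores
#'
#' For gene-expression meta-cluster signatures scored per cell, summarizes
#' each patient by the *median* baseline per-cell score and fits the
#' predictive index against tumor change.
#'
#' @param cell_scores data.frame with columns `cell_id`, `cluster`, `score`
#'   (per-cell signature scores, one row per cell x cluster).
#' @param cells cell table (to assign cells to patients and timepoints).
#' @param sizes tumor-size table.
#' @return data.frame with one [fit_index()] row per cluster.
#' @export
meta_cluster_pi <- function(cell_scores, cells, sizes) {
  m <- merge(cell_scores, as.data.frame(cells)[, c("cell_id", "patient_id", "timepoint")],
             by = "cell_id")
  m <- m[m$timepoint == "pre", , drop = FALSE]
  if (nrow(m) == 0) stop_fmt("no baseline (pre) cells with scores")
  med <- stats::aggregate(score ~ patient_id + cluster, data = m, FUN = stats::median)
  clusters <- sort(unique(med$cluster))
  patients <- sort(unique(med$patient_id))
  xm <- matrix(NA_real_, length(patients), length(clusters),
               dimnames = list(patients, clusters))
  xm[cbind(med$patient_id, med$cluster)] <- med$score
  keep <- rowSums(is.na(xm)) == 0
  if (!all(keep)) {
    warn_fmt("patient(s) without baseline scores excluded: %s",
             paste(patients[!keep], collapse = ", "))
    xm <- xm[keep, , drop = FALSE]
  }
  fit_index_by_label(xm, sizes, kind = "Pi")
}
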
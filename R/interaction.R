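# Ligand-receptor edge specificity. The weight of an edge from a sender to
# a receiver cell type is the product of the ligand's sender-type share and
# the receptor's receiver-type share of the cohort-wide mean expression, so
# the factors of each gene form a partition of unity over cell types.

#' Mean CPM and detection rate per cell type
#'
#' @param matrix CPM-normalized [count_matrix()].
#' @param cells cell table.
#' @param level grouping column of the cell table (default `"major_type"`).
#' @return list with `mean` (gene x type mean CPM), `detection` (gene x
#'   type fraction of cells with expression > 0), and `n_cells` per type.
#' @export
mean_expression_by_type <- function(matrix, cells, level = "major_type") {
  if (matrix$state != "cpm")
    stop_fmt("mean_expression_by_type requires a CPM matrix (state = %s)",
             matrix$state)
  df <- as.data.frame(cells)
  df <- df[df$cell_id %in% colnames(matrix$counts), , drop = FALSE]
  types <- sort(unique(df[[level]]))
  m <- matrix$counts[, df$cell_id, drop = FALSE]
  mean_mat <- sapply(types, function(tt) {
    sel <- df[[level]] == tt
    if (!any(sel)) stop_fmt("cell type '%s' has zero cells", tt)
    Matrix::rowMeans(m[, sel, drop = FALSE])
  })
  det_mat <- sapply(types, function(tt) {
    sel <- df[[level]] == tt
    Matrix::rowMeans(m[, sel, drop = FALSE] > 0)
  })
  n_cells <- vapply(types, function(tt) sum(df[[level]] == tt), integer(1))
  structure(list(mean = mean_mat, detection = det_mat, n_cells = n_cells),
            class = "mean_expression_by_type")
}

#' Specificity weight of one ligand-receptor edge
#'
#' `ligand_factor` is the sender type's share of the ligand's summed mean
#' expression over all types; `receptor_factor` analogously for the
#' receiver; the edge weight is their product.
#'
#' @param means a [mean_expression_by_type()] object.
#' @param ligand,receptor gene symbols.
#' @param sender,receiver cell-type labels.
#' @return one-row data.frame: genes, types, `ligand_factor`,
#'   `receptor_factor`, `weight`, per-type means and detection rates.
#' @export
specificity_weight <- function(means, ligand, receptor, sender, receiver) {
  M <- means$mean
  for (g in c(ligand, receptor)) {
    if (!g %in% rownames(M)) stop_fmt("gene '%s' not present in the matrix", g)
  }
  for (tt in c(sender, receiver)) {
    if (!tt %in% colnames(M)) stop_fmt("cell type '%s' unknown", tt)
  }
  lig_tot <- sum(M[ligand, ])
  rec_tot <- sum(M[receptor, ])
  if (lig_tot == 0) stop_fmt("ligand '%s' has zero mean expression in every type", ligand)
  if (rec_tot == 0) stop_fmt("receptor '%s' has zero mean expression in every type", receptor)
  lf <- M[ligand, sender] / lig_tot
  rf <- M[receptor, receiver] / rec_tot
  data.frame(ligand = ligand, receptor = receptor,
             sender = sender, receiver = receiver,
             ligand_factor = unname(lf), receptor_factor = unname(rf),
             weight = unname(lf * rf),
             ligand_mean = unname(M[ligand, sender]),
             receptor_mean = unname(M[receptor, receiver]),
             ligand_detection = unname(means$detection[ligand, sender]),
             receptor_detection = unname(means$detection[receptor, receiver]),
             stringsAsFactors = FALSE)
}

#' All sender-receiver edges for a ligand-receptor catalog
#'
#' @param means a [mean_expression_by_type()] object.
#' @param lr_pairs data.frame with columns `ligand`, `receptor` (pairs
#'   whose genes are absent from the matrix are skipped with a warning).
#' @param senders,receivers optional restrictions on the types considered.
#' @return data.frame of [specificity_weight()] rows.
#' @export
compute_lr_edges <- function(means, lr_pairs, senders = NULL, receivers = NULL) {
  types <- colnames(means$mean)
  senders <- senders %||% types
  receivers <- receivers %||% types
  out <- list()
  for (i in seq_len(nrow(lr_pairs))) {
    lig <- lr_pairs$ligand[i]; rec <- lr_pairs$receptor[i]
    if (!lig %in% rownames(means$mean) || !rec %in% rownames(means$mean)) {
      warn_fmt("ligand-receptor pair %s-%s skipped (gene absent)", lig, rec)
      next
    }
    if (sum(means$mean[lig, ]) == 0 || sum(means$mean[rec, ]) == 0) {
      warn_fmt("ligand-receptor pair %s-%s skipped (zero expression)", lig, rec)
      next
    }
    for (s in senders) for (r in receivers) {
      out[[length(out) + 1]] <- specificity_weight(means, lig, rec, s, r)
    }
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter ligand-receptor edges on expression, specificity, and detection
#'
#' Retains edges where the ligand mean in the sender and the receptor mean
#' in the receiver are both at or above `expr_threshold` (CPM), the edge
#' weight is *strictly above* `spec_threshold`, and both detection rates
#' are at or above `detection_threshold`. Every rejection is logged with
#' the failing rule(s).
#'
#' @param edges data.frame from [compute_lr_edges()].
#' @param expr_threshold minimum mean CPM (default 10).
#' @param spec_threshold specificity (weight) threshold (default 0.1,
#'   strict).
#' @param detection_threshold minimum detection rate (default 0.20).
#' @return list with `retained`, `rejected` (with a `reason` column), and
#'   the thresholds used.
#' @export
filter_edges <- function(edges, expr_threshold = 10, spec_threshold = 0.1,
                         detection_threshold = 0.20) {
  fail_expr <- edges$ligand_mean < expr_threshold | edges$receptor_mean < expr_threshold
  fail_spec <- !(edges$weight > spec_threshold)
  fail_det <- edges$ligand_detection < detection_threshold |
    edges$receptor_detection < detection_threshold
  reason <- mapply(function(e, s, d) {
    paste(c(if (e) "expression", if (s) "specificity", if (d) "detection"),
          collapse = "+")
  }, fail_expr, fail_spec, fail_det)
  keep <- !(fail_expr | fail_spec | fail_det)
  edges$passed_filters <- keep
  rejected <- edges[!keep, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!keep]
  list(retained = edges[keep, , drop = FALSE], rejected = rejected,
       thresholds = list(expression = expr_threshold,
                         specificity = spec_threshold,
                         detection = detection_threshold))
}
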
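# Synthetic paired pre/post cohorts with planted compositional, clonal,
# and expression structure. The generator is the package's testbed: the
# planted parameters are recorded in a ground-truth object so that every
# downstream statistic (Pi/Ti, Fisher expansion labels, signature-score
# shifts) can be checked for recovery without access to patient data.
#
# Generative model, per patient:
#   baseline composition  ~ Dirichlet(cell_type concentrations), sampled
#                           multinomially into cells_per_sample cells;
#   post composition      = baseline with the shifted type's weight
#                           multiplied by 10^r, r ~ N(0, sd), renormalized;
#   tumor change          = intercept
#                           + responder_slope * realized baseline proportion
#                             of the responder type
#                           + shifted_slope * realized log10 post/pre ratio
#                             of the shifted type
#                           + N(0, noise_sd).
# Tumor change is computed from the *realized* (sampled) proportions, so a
# noise-free configuration places the downstream regression exactly on a
# line and the signed index is +/-1 exactly.

#' Simulation parameters for a synthetic paired cohort
#'
#' Defaults describe an 8-patient paired pre/post cohort whose baseline
#' composition is centered on the major-lineage mix typical of treated
#' tumor biopsies, with a planted unfavorable association for the myeloid
#' baseline proportion and a planted favorable association for an
#' on-treatment T-cell increase.
#'
#' @param n_patients number of patients (each contributes a pre and a post
#'   sample).
#' @param cells_per_sample cells sampled per sample.
#' @param cell_types named positive Dirichlet concentrations of the major
#'   cell types.
#' @param responder_type cell type whose *baseline* proportion drives tumor
#'   change.
#' @param responder_slope planted slope of tumor change on the baseline
#'   responder proportion (positive = higher baseline proportion, more
#'   growth).
#' @param shifted_type cell type whose post/pre log10 proportion ratio
#'   drives tumor change.
#' @param shifted_slope planted slope of tumor change on that log-ratio.
#' @param shifted_logratio_sd standard deviation of the planted per-patient
#'   log10 shift.
#' @param intercept baseline mean tumor change.
#' @param tumor_change_noise_sd Gaussian noise on tumor change.
#' @param t_subtypes,myeloid_subtypes named concentration vectors of the
#'   subtype mixes within the T and myeloid compartments.
#' @param ir_rate fraction of T cells with an identified immune receptor.
#' @param dual_ir_rate fraction of IR-positive cells with two chains.
#' @param n_clones distinct clonotypes per patient.
#' @param clone_size_exponent Zipf exponent of the clone-size law (`Inf`
#'   collapses the repertoire to a single clone).
#' @param n_expanded_clones,n_contracted_clones planted clone counts.
#' @param expansion_fold,contraction_fold multiplicative change of the
#'   planted clones' post-timepoint sampling weight.
#' @param n_genes total genes in the simulated expression matrix.
#' @param signature_genes genes receiving the planted exhaustion shift.
#' @param control_genes unshifted genes generated at the same base rate
#'   (must be disjoint from `signature_genes`).
#' @param marker_base_rate Poisson base rate of signature/control/marker
#'   genes.
#' @param exhaustion_shift additive log-scale mean shift applied to
#'   signature genes in exhausted cells.
#' @param exhausted_subtype,exhausted_timepoint cells designated exhausted.
#' @param depth_sd log-scale standard deviation of per-cell depth factors.
#' @param seed integer; fully determines all generator output.
#' @return validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_patients = 8,
                       cells_per_sample = 2000,
                       cell_types = c(T = 39.1, Myeloid = 15.9, NK = 13.1,
                                      B = 11.2, Epithelial = 11.0,
                                      Fibroblast = 3.0, Neutrophil = 2.3,
                                      Endothelial = 2.0, Plasma = 1.3,
                                      pDC = 0.6, Mast = 0.35,
                                      Hepatocyte = 0.3) / 2,
                       responder_type = "Myeloid",
                       responder_slope = 1.5,
                       shifted_type = "T",
                       shifted_slope = -0.4,
                       shifted_logratio_sd = 0.25,
                       intercept = -0.2,
                       tumor_change_noise_sd = 0.1,
                       t_subtypes = c("CD8 GZMK+" = 14, "CD8 GZMB+" = 12,
                                      "CD8 proliferating" = 8,
                                      "CD8 KLRB1+" = 6, "CD4 naive" = 16,
                                      "CD4 SOCS3+" = 12, "CD4 Treg" = 8,
                                      "CD4 CXCL13+" = 6),
                       myeloid_subtypes = c("Macro CD5L+" = 10,
                                            "Macro GPNMB+" = 8,
                                            "Mono FCN1+" = 12,
                                            "DC CD1C+" = 5),
                       ir_rate = 0.9,
                       dual_ir_rate = 0.05,
                       n_clones = 200,
                       clone_size_exponent = 1.5,
                       n_expanded_clones = 6,
                       n_contracted_clones = 6,
                       expansion_fold = 8,
                       contraction_fold = 8,
                       n_genes = 1000,
                       signature_genes = c("CTLA4", "HAVCR2", "LAG3",
                                           "PDCD1", "TIGIT"),
                       control_genes = sprintf("CTRL%02d", 1:20),
                       marker_base_rate = 5,
                       exhaustion_shift = 1.0,
                       exhausted_subtype = "CD8 GZMB+",
                       exhausted_timepoint = "post",
                       depth_sd = 0.3,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(n_patients > 0, cells_per_sample > 0, n_clones > 0, n_genes > 0)
  if (is.null(names(cell_types)) || any(cell_types <= 0))
    stop_fmt("cell_types must be a named vector of positive concentrations")
  if (!responder_type %in% names(cell_types))
    stop_fmt("responder_type '%s' is not one of the cell types", responder_type)
  if (!shifted_type %in% names(cell_types))
    stop_fmt("shifted_type '%s' is not one of the cell types", shifted_type)
  if (n_expanded_clones + n_contracted_clones > n_clones)
    stop_fmt("more planted clones (%d) than distinct clones (%d)",
             n_expanded_clones + n_contracted_clones, n_clones)
  if (length(intersect(signature_genes, control_genes)) > 0)
    stop_fmt("signature and control gene lists must be disjoint")
  structure(p, class = "sim_params")
}

# Composition + tumor-change layer; draws from the current RNG stream.
sim_composition_ <- function(params) {
  K <- length(params$cell_types)
  types <- names(params$cell_types)
  patients <- sprintf("P%02d", seq_len(params$n_patients))
  counts_pre <- counts_post <- matrix(0L, params$n_patients, K,
                                      dimnames = list(patients, types))
  r_planted <- x_resp <- x_ratio <- tumor_change <- numeric(params$n_patients)
  for (i in seq_len(params$n_patients)) {
    p0 <- stats::setNames(rdirichlet1(params$cell_types), types)
    counts_pre[i, ] <- stats::rmultinom(1, params$cells_per_sample, p0)
    r <- stats::rnorm(1, 0, params$shifted_logratio_sd)
    r_planted[i] <- r
    w <- p0
    w[params$shifted_type] <- w[params$shifted_type] * 10^r
    w <- w / sum(w)
    counts_post[i, ] <- stats::rmultinom(1, params$cells_per_sample, w)
    pp <- counts_pre[i, ] / params$cells_per_sample
    qp <- counts_post[i, ] / params$cells_per_sample
    x_resp[i] <- pp[params$responder_type]
    x_ratio[i] <- if (pp[params$shifted_type] > 0 && qp[params$shifted_type] > 0)
      log10(qp[params$shifted_type] / pp[params$shifted_type]) else r
    tumor_change[i] <- params$intercept +
      params$responder_slope * x_resp[i] +
      params$shifted_slope * x_ratio[i] +
      if (params$tumor_change_noise_sd > 0)
        stats::rnorm(1, 0, params$tumor_change_noise_sd) else 0
  }
  size_pre <- stats::runif(params$n_patients, 30, 80)
  size_post <- pmax(size_pre * (1 + tumor_change), 0)
  tumor <- data.frame(patient_id = patients,
                      size_pre_mm = size_pre, size_post_mm = size_post,
                      tumor_change = tumor_change, stringsAsFactors = FALSE)
  truth <- list(responder_type = params$responder_type,
                responder_slope = params$responder_slope,
                shifted_type = params$shifted_type,
                shifted_slope = params$shifted_slope,
                intercept = params$intercept,
                noise_sd = params$tumor_change_noise_sd,
                baseline_responder_proportion = stats::setNames(x_resp, patients),
                shifted_logratio_realized = stats::setNames(x_ratio, patients),
                shifted_logratio_planted = stats::setNames(r_planted, patients))
  list(patients = patients, counts_pre = counts_pre, counts_post = counts_post,
       tumor = tumor, truth = truth)
}

#' Simulate the composition layer of a cohort
#'
#' Lightweight counterpart of [simulate_cohort()] that returns per-sample
#' cell-type *count matrices* instead of a per-cell table; used for
#' calibration studies where thousands of replicate cohorts are needed.
#'
#' @param params a [sim_params()] object.
#' @return list: `patients`, `counts_pre`, `counts_post` (patients x
#'   types), `tumor` (tumor-size table with `tumor_change`), `truth`.
#' @export
simulate_composition <- function(params) {
  with_seed(params$seed, sim_composition_(params))
}

#' Simulate a paired pre/post cohort
#'
#' Expands the composition layer into a per-cell table with subtype labels
#' within the T and myeloid compartments, plus a tumor-size table and the
#' ground-truth record of every planted effect.
#'
#' @param params a [sim_params()] object.
#' @return list: `cells` (a cell table), `tumor` (tumor-size table),
#'   `truth` (ground-truth list).
#' @export
simulate_cohort <- function(params) {
  with_seed(params$seed, {
    comp <- sim_composition_(params)
    types <- names(params$cell_types)
    t_probs <- params$t_subtypes / sum(params$t_subtypes)
    m_probs <- params$myeloid_subtypes / sum(params$myeloid_subtypes)
    rows <- list()
    for (i in seq_along(comp$patients)) {
      pat <- comp$patients[i]
      for (tp in c("pre", "post")) {
        counts <- if (tp == "pre") comp$counts_pre[i, ] else comp$counts_post[i, ]
        major <- rep(types, counts)
        n <- length(major)
        subtype <- rep(NA_character_, n)
        is_t <- major == "T"
        if (any(is_t))
          subtype[is_t] <- sample(names(t_probs), sum(is_t), replace = TRUE,
                                  prob = t_probs)
        is_m <- major == "Myeloid"
        if (any(is_m))
          subtype[is_m] <- sample(names(m_probs), sum(is_m), replace = TRUE,
                                  prob = m_probs)
        has_ir <- is_t & stats::runif(n) < params$ir_rate
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = sprintf("%s_%s_c%05d", pat, tp, seq_len(n)),
          patient_id = pat, timepoint = tp,
          sample_id = paste(pat, tp, sep = "_"),
          major_type = major, subtype = subtype, has_ir = has_ir,
          stringsAsFactors = FALSE)
      }
    }
    cells <- as_cell_table(do.call(rbind, rows))
    truth <- comp$truth
    truth$exhausted_cells <- cells$cell_id[
      !is.na(cells$subtype) &
        cells$subtype == params$exhausted_subtype &
        cells$timepoint == params$exhausted_timepoint]
    truth$exhaustion_shift <- params$exhaustion_shift
    list(cells = cells, tumor = comp$tumor, truth = truth)
  })
}

#' Simulate clonotype assignments for the T cells of a cohort
#'
#' Clone abundances follow a truncated discrete power law (Zipf) per
#' patient; planted expanded clones multiply their post-timepoint sampling
#' weight by `expansion_fold` and contracted clones divide theirs by
#' `contraction_fold`. Only IR-positive T cells receive assignments.
#'
#' @param params a [sim_params()] object.
#' @param cells cell table from [simulate_cohort()].
#' @return list: `assignments` (cell_id, clone_id, chain_count) and
#'   `truth` (patient_id, clone_id, status in expanded/contracted/neutral).
#' @export
simulate_clonotypes <- function(params, cells) {
  df <- as.data.frame(cells)
  tcell <- df[df$major_type == "T" & !is.na(df$has_ir) & df$has_ir, , drop = FALSE]
  if (nrow(tcell) == 0) stop_fmt("no IR-positive T cells to assign clonotypes to")
  with_seed(params$seed + 1L, {
    base_w <- if (is.infinite(params$clone_size_exponent)) {
      c(1, rep(0, params$n_clones - 1))
    } else {
      seq_len(params$n_clones)^(-params$clone_size_exponent)
    }
    assign_rows <- list(); truth_rows <- list()
    for (pat in sort(unique(tcell$patient_id))) {
      clone_ids <- sprintf("%s_clone%04d", pat, seq_len(params$n_clones))
      n_planted <- params$n_expanded_clones + params$n_contracted_clones
      status <- rep("neutral", params$n_clones)
      if (n_planted > 0) {
        planted <- sample(which(base_w > 0), min(n_planted, sum(base_w > 0)))
        status[planted[seq_len(min(params$n_expanded_clones, length(planted)))]] <- "expanded"
        if (length(planted) > params$n_expanded_clones)
          status[planted[(params$n_expanded_clones + 1):length(planted)]] <- "contracted"
      }
      w_pre <- base_w
      w_post <- base_w
      w_post[status == "expanded"] <- w_post[status == "expanded"] * params$expansion_fold
      w_post[status == "contracted"] <- w_post[status == "contracted"] / params$contraction_fold
      for (tp in c("pre", "post")) {
        sel <- tcell$patient_id == pat & tcell$timepoint == tp
        n <- sum(sel)
        if (n == 0) next
        w <- if (tp == "pre") w_pre else w_post
        idx <- sample.int(params$n_clones, n, replace = TRUE, prob = w)
        assign_rows[[length(assign_rows) + 1]] <- data.frame(
          cell_id = tcell$cell_id[sel], clone_id = clone_ids[idx],
          chain_count = 1L + (stats::runif(n) < params$dual_ir_rate),
          stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        patient_id = pat, clone_id = clone_ids, status = status,
        stringsAsFactors = FALSE)
    }
    list(assignments = do.call(rbind, assign_rows),
         truth = do.call(rbind, truth_rows))
  })
}

#' Simulate a count matrix with a planted exhaustion shift
#'
#' Counts follow a lognormal-Poisson model: gene base rates (lognormal for
#' filler genes, a fixed rate for signature/control/marker genes so their
#' expression bins match) times a lognormal per-cell depth factor.
#' Designated exhausted cells (see [sim_params()]) receive the planted
#' multiplicative shift `exp(exhaustion_shift)` on signature genes only.
#'
#' @param params a [sim_params()] object.
#' @param cells cell table.
#' @return list: `matrix` (raw [count_matrix()]) and `truth` (exhausted
#'   cell IDs and the planted shift).
#' @export
simulate_expression <- function(params, cells) {
  df <- as.data.frame(cells)
  with_seed(params$seed + 2L, {
    cyto <- c("PRF1", "IFNG", "GNLY", "NKG7", "GZMK", "GZMB", "GZMA",
              "CST7", "TNFSF10")
    mito <- c("MT-CO1", "MT-ND1", "MT-CYB")
    named <- unique(c(params$signature_genes, params$control_genes, cyto, mito))
    n_fill <- max(params$n_genes - length(named), 0)
    filler <- if (n_fill > 0) sprintf("GENE%04d", seq_len(n_fill)) else character(0)
    genes <- c(named, filler)
    lambda <- stats::setNames(rep(params$marker_base_rate, length(genes)), genes)
    lambda[mito] <- 1
    if (n_fill > 0)
      lambda[filler] <- stats::rlnorm(n_fill, meanlog = log(1.5), sdlog = 1.2)
    depth <- stats::rlnorm(nrow(df), meanlog = 0, sdlog = params$depth_sd)
    exhausted <- !is.na(df$subtype) &
      df$subtype == params$exhausted_subtype &
      df$timepoint == params$exhausted_timepoint
    sig_idx <- match(params$signature_genes, genes)
    blocks <- split(seq_len(nrow(df)), ceiling(seq_len(nrow(df)) / 2000))
    parts <- lapply(blocks, function(cols) {
      mu <- outer(lambda, depth[cols])
      shifted_cols <- which(exhausted[cols])
      if (length(shifted_cols) > 0)
        mu[sig_idx, shifted_cols] <- mu[sig_idx, shifted_cols] * exp(params$exhaustion_shift)
      cnt <- matrix(stats::rpois(length(mu), mu), nrow = length(genes))
      Matrix::Matrix(cnt, sparse = TRUE)
    })
    m <- do.call(cbind, parts)
    dimnames(m) <- list(genes, df$cell_id)
    list(matrix = count_matrix(m, state = "raw"),
         truth = list(exhausted_cells = df$cell_id[exhausted],
                      exhaustion_shift = params$exhaustion_shift,
                      gene_base_rates = lambda))
  })
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits `cells.tsv`, the `matrix.mtx`/`features.tsv`/`barcodes.tsv`
#' triplet, `clonotypes.csv`, `tumor_sizes.tsv`, and `ground_truth.json`.
#'
#' @param params a [sim_params()] object.
#' @param dir output directory (created if absent).
#' @return invisibly, the list of simulated objects.
#' @export
write_synthetic_cohort <- function(params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_cohort(params)
  clones <- simulate_clonotypes(params, sim$cells)
  expr <- simulate_expression(params, sim$cells)
  write_cell_table(sim$cells, file.path(dir, "cells.tsv"))
  write_counts_mtx(expr$matrix, dir)
  utils::write.csv(clones$assignments, file.path(dir, "clonotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(sim$tumor[, c("patient_id", "size_pre_mm", "size_post_mm")],
                     file.path(dir, "tumor_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(composition = sim$truth,
                clones = clones$truth,
                expression = list(
                  exhausted_cells = expr$truth$exhausted_cells,
                  exhaustion_shift = expr$truth$exhaustion_shift))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cells = sim$cells, tumor = sim$tumor, truth = truth,
                 clonotypes = clones$assignments, matrix = expr$matrix))
}
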
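# Fixture builders shared across test files. Everything is generated in
# code; no data files are read from disk.

# Minimal paired cohort table: n cells per sample for each patient.
make_cells <- function(n_patients = 2, n_per_sample = 4,
                       major_type = "T", subtype = NA_character_,
                       has_ir = TRUE) {
  rows <- list()
  for (p in sprintf("P%02d", seq_len(n_patients))) {
    for (tp in c("pre", "post")) {
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = sprintf("%s_%s_c%03d", p, tp, seq_len(n_per_sample)),
        patient_id = p, timepoint = tp, sample_id = paste(p, tp, sep = "_"),
        major_type = major_type, subtype = subtype, has_ir = has_ir,
        stringsAsFactors = FALSE)
    }
  }
  as_cell_table(do.call(rbind, rows))
}

# Dense count matrix from a plain matrix with names.
make_matrix <- function(m, state = "raw") {
  count_matrix(Matrix::Matrix(m, sparse = TRUE), state = state)
}

# A one-patient repertoire of n cells per timepoint, all one subtype.
make_repertoire_cells <- function(n = 1000, subtype = "CD8 GZMB+") {
  as_cell_table(data.frame(
    cell_id = sprintf("c%05d_%s", seq_len(2 * n), rep(c("pre", "post"), each = n)),
    patient_id = "P01", timepoint = rep(c("pre", "post"), each = n),
    sample_id = rep(c("P01_pre", "P01_post"), each = n),
    major_type = "T", subtype = subtype, has_ir = TRUE,
    stringsAsFactors = FALSE))
}

# Hand-built proportion_matrix object for tests that need exact values.
make_pm <- function(values, patients, timepoints) {
  structure(values,
            patient_id = patients, timepoint = timepoints,
            denominator = rep(1, nrow(values)),
            scope = "all_cells", level = "major_type",
            class = c("proportion_matrix", "matrix"))
}

# Small simulation defaults used when the full study-scale cohort is not
# needed by the test.
small_params <- function(...) {
  args <- list(...)
  defaults <- list(cells_per_sample = 300, n_genes = 400, n_clones = 60,
                   n_expanded_clones = 3, n_contracted_clones = 3)
  defaults[names(args)] <- args
  do.call(sim_params, defaults)
}

# A controlled log-normalized matrix where every gene in an expression bin
# shares one expression vector: any control draw then reproduces the
# signature mean exactly, so signature scores are identically zero.
make_binned_matrix <- function(n_bins = 5, genes_per_bin = 10, n_cells = 30) {
  levels <- seq(0.5, 3, length.out = n_bins)
  m <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    matrix(rep(levels[b] + seq_len(n_cells) / 100, each = genes_per_bin),
           nrow = genes_per_bin, byrow = FALSE)
  }))
  rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  make_matrix(m, state = "lognorm")
}

# Independent two-sided Fisher p oracle: exhaustive hypergeometric
# enumeration over the clone-cell margin (sums all outcomes no more
# probable than the observed one).
fisher_p_oracle <- function(count_pre, total_pre, count_post, total_post) {
  k <- count_pre + count_post
  d <- stats::dhyper(0:k, total_pre, total_post, k)
  sum(d[d <= d[count_pre + 1] * (1 + 1e-7)])
}
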
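test_that("simulation parameters are validated", {
  expect_error(sim_params(responder_type = "Unicorn"), "responder_type")
  expect_error(sim_params(shifted_type = "Unicorn"), "shifted_type")
  expect_error(sim_params(n_clones = 4, n_expanded_clones = 3,
                          n_contracted_clones = 3), "more planted clones")
  expect_error(sim_params(signature_genes = c("A", "B"),
                          control_genes = c("B", "C")), "disjoint")
})

test_that("the generator is fully determined by its seed", {
  p <- small_params(seed = 123)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(as.data.frame(a$cells), as.data.frame(b$cells))
  expect_identical(a$tumor, b$tumor)
  ca <- simulate_clonotypes(p, a$cells)
  cb <- simulate_clonotypes(p, b$cells)
  expect_identical(ca$assignments, cb$assignments)
  ea <- simulate_expression(p, a$cells)
  eb <- simulate_expression(p, b$cells)
  expect_identical(as.matrix(ea$matrix$counts), as.matrix(eb$matrix$counts))
  d <- simulate_cohort(small_params(seed = 124))
  expect_false(identical(a$tumor$tumor_change, d$tumor$tumor_change))
})

test_that("composition rows sum to the configured cells per sample", {
  p <- small_params(seed = 5)
  comp <- simulate_composition(p)
  expect_equal(unname(rowSums(comp$counts_pre)), rep(p$cells_per_sample, p$n_patients))
  expect_equal(unname(rowSums(comp$counts_post)), rep(p$cells_per_sample, p$n_patients))
  sim <- simulate_cohort(p)
  per_sample <- table(sim$cells$sample_id)
  expect_true(all(per_sample == p$cells_per_sample))
})

test_that("ground truth predicts the sign of every planted downstream statistic", {
  p <- sim_params(cells_per_sample = 800, responder_slope = 2,
                  shifted_slope = -0.5, tumor_change_noise_sd = 0.02, seed = 42)
  sim <- simulate_cohort(p)
  pm <- proportion_matrix(sim$cells, "major_type")
  pi_tab <- predictive_index(pm, sim$tumor)
  # positive planted slope (more growth) -> negative Pi
  expect_lt(pi_tab$index[pi_tab$feature == sim$truth$responder_type], 0)
  ti_tab <- therapeutic_index(pm, sim$tumor)
  # negative planted slope on the log-ratio -> positive Ti
  expect_gt(ti_tab$index[ti_tab$feature == sim$truth$shifted_type], 0)
})

test_that("neutral clone simulations keep pre/post abundances balanced", {
  cells <- make_repertoire_cells(n = 1000)
  p <- sim_params(n_clones = 50, n_expanded_clones = 0, n_contracted_clones = 0,
                  clone_size_exponent = 1.0, seed = 77)
  cl <- simulate_clonotypes(p, cells)
  ct <- build_clonotype_counts(cells, cl$assignments)
  big <- ct$counts[ct$counts$count_pre + ct$counts$count_post >= 50, ]
  ratio <- (big$count_post + 1) / (big$count_pre + 1)
  expect_true(all(ratio > 1 / 3 & ratio < 3))
  expect_true(all(cl$truth$status == "neutral"))

  # degenerate exponent: the whole repertoire is one clone
  pinf <- sim_params(n_clones = 50, n_expanded_clones = 0,
                     n_contracted_clones = 0, clone_size_exponent = Inf,
                     seed = 78)
  clinf <- simulate_clonotypes(pinf, cells)
  expect_equal(length(unique(clinf$assignments$clone_id)), 1)
})

test_that("a null expression shift leaves exhausted and other cells indistinguishable", {
  p <- small_params(cells_per_sample = 120, exhaustion_shift = 0, seed = 31)
  sim <- simulate_cohort(p)
  ex <- simulate_expression(p, sim$cells)
  logm <- normalize_counts(ex$matrix, "lognorm")
  sc <- score_signature(logm, p$signature_genes, seed = 1)
  hit <- names(sc) %in% ex$truth$exhausted_cells
  expect_lt(abs(mean(sc[hit]) - mean(sc[!hit])), 0.1)

  # the recovered gap grows monotonically with the planted shift
  gaps <- sapply(c(0.5, 1.5), function(s) {
    ps <- small_params(cells_per_sample = 120, exhaustion_shift = s, seed = 31)
    exs <- simulate_expression(ps, sim$cells)
    lg <- normalize_counts(exs$matrix, "lognorm")
    scs <- score_signature(lg, ps$signature_genes, seed = 1)
    h <- names(scs) %in% exs$truth$exhausted_cells
    mean(scs[h]) - mean(scs[!h])
  })
  expect_gt(gaps[1], 0.2)
  expect_gt(gaps[2], gaps[1])
})

test_that("the written fixture set round-trips through the readers", {
  dir <- withr::local_tempdir()
  p <- small_params(cells_per_sample = 100, seed = 55)
  sim <- write_synthetic_cohort(p, dir)
  expect_setequal(list.files(dir),
                  c("cells.tsv", "matrix.mtx", "features.tsv", "barcodes.tsv",
                    "clonotypes.csv", "tumor_sizes.tsv", "ground_truth.json"))
  cells <- read_cell_table(file.path(dir, "cells.tsv"))
  expect_equal(as.data.frame(cells), as.data.frame(sim$cells))
  mat <- read_counts_mtx(file.path(dir, "matrix.mtx"),
                         file.path(dir, "features.tsv"),
                         file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(mat$counts), as.matrix(sim$matrix$counts))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(truth$composition$responder_type, p$responder_type)
})
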
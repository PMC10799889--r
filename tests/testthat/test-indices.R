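test_that("fit_index reproduces the least-squares closed form", {
  # exact line y = 0.2 - 1.5 x: perfect anticorrelation
  r <- fit_index(c(0.1, 0.2, 0.3, 0.4), c(0.05, -0.10, -0.25, -0.40))
  expect_equal(r$slope, -1.5)
  expect_equal(r$r_squared, 1)
  expect_equal(r$index, 1)
  expect_true(r$degenerate)
  expect_equal(r$wald_p, 0)

  # worked example: slope -0.9, R^2 = Sxy^2/(Sxx Syy)
  r2 <- fit_index(c(0.10, 0.20, 0.30, 0.40), c(0.00, -0.10, -0.10, -0.30))
  expect_equal(r2$slope, -0.9)
  expect_equal(r2$r_squared, 0.2025 / 0.2375, tolerance = 1e-12)
  expect_equal(r2$index, 0.8526, tolerance = 1e-4)
  lmfit <- summary(lm(c(0.00, -0.10, -0.10, -0.30) ~ c(0.10, 0.20, 0.30, 0.40)))
  expect_equal(r2$wald_p, lmfit$coefficients[2, 4], tolerance = 1e-12)

  expect_error(fit_index(rep(0.2, 5), rnorm(5)), "zero variance")
  expect_error(fit_index(1:2, 1:2), "at least 3")
})

test_that("fit_index agrees with the reference OLS fit on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- fit_index(x, y)
    s <- summary(lm(y ~ x))
    expect_equal(got$slope, unname(s$coefficients[2, 1]), tolerance = 1e-10)
    expect_equal(got$r_squared, s$r.squared, tolerance = 1e-10)
    expect_equal(got$wald_p, unname(s$coefficients[2, 4]), tolerance = 1e-10)
    expect_true(abs(got$index) <= 1)
  }
})

test_that("the index is invariant to affine predictor rescaling and antisymmetric in y", {
  set.seed(5)
  x <- runif(8); y <- -x + rnorm(8, 0, 0.3)
  a <- fit_index(x, y)
  b <- fit_index(2.5 * x + 1, y)       # positive affine map of x
  expect_equal(a$index, b$index, tolerance = 1e-12)
  expect_equal(a$wald_p, b$wald_p, tolerance = 1e-12)
  cc <- fit_index(x, y + 0.7)          # shifting y
  expect_equal(a$index, cc$index, tolerance = 1e-12)
  d <- fit_index(x, -y)                # negating y flips the index only
  expect_equal(d$index, -a$index, tolerance = 1e-12)
  expect_equal(d$wald_p, a$wald_p, tolerance = 1e-12)
})

test_that("Pi on a noise-free planted cohort is exactly +1", {
  p <- sim_params(cells_per_sample = 500, responder_slope = -1,
                  shifted_slope = 0, tumor_change_noise_sd = 0, seed = 3)
  sim <- simulate_cohort(p)
  pm <- proportion_matrix(sim$cells, "major_type")
  tab <- predictive_index(pm, sim$tumor)
  row <- tab[tab$feature == p$responder_type, ]
  expect_equal(row$index, 1)
  expect_true(row$degenerate)
})

test_that("constant proportions degrade to a flagged degenerate result", {
  vals <- cbind(A = rep(0.3, 4), B = rep(0.7, 4))
  pm <- make_pm(vals, patients = sprintf("P%d", 1:4), timepoints = rep("pre", 4))
  sizes <- as_tumor_sizes(data.frame(patient_id = sprintf("P%d", 1:4),
                                     size_pre_mm = 50,
                                     size_post_mm = c(40, 45, 55, 60)))
  tab <- predictive_index(pm, sizes)
  expect_true(all(tab$degenerate))
  expect_true(all(is.na(tab$index)))
})

test_that("Ti uses exact log10 ratios and a pseudocount only for zeros", {
  # ratios (10, 1, 0.1) -> x = (1, 0, -1); y = (-0.5, 0, 0.5) -> Ti = +1
  vals <- rbind(c(0.05, 0.95), c(0.20, 0.80), c(0.50, 0.50),
                c(0.50, 0.50), c(0.20, 0.80), c(0.05, 0.95))
  colnames(vals) <- c("A", "B")
  pm <- make_pm(vals, patients = rep(c("P1", "P2", "P3"), 2),
                timepoints = rep(c("pre", "post"), each = 3))
  sizes <- as_tumor_sizes(data.frame(patient_id = c("P1", "P2", "P3"),
                                     size_pre_mm = 40,
                                     size_post_mm = c(20, 40, 60)))
  tab <- therapeutic_index(pm, sizes)
  rowA <- tab[tab$feature == "A", ]
  expect_equal(rowA$slope, -0.5)
  expect_equal(rowA$index, 1)
  expect_equal(unname(attr(tab, "pseudocount")["A"]), 0)

  # zero pre proportion: epsilon = half the minimum nonzero proportion
  vals0 <- vals; vals0[1, ] <- c(0, 1)
  pm0 <- make_pm(vals0, patients = rep(c("P1", "P2", "P3"), 2),
                 timepoints = rep(c("pre", "post"), each = 3))
  tab0 <- therapeutic_index(pm0, sizes)
  expect_true(all(is.finite(tab0$index)))
  expect_equal(unname(attr(tab0, "pseudocount")["A"]), 0.025)  # min nonzero 0.05 / 2
})

test_that("meta-cluster Pi uses patient medians and is robust to outlier cells", {
  cells <- make_cells(n_patients = 4, n_per_sample = 5, major_type = "Tumor")
  patients <- sprintf("P%02d", 1:4)
  base <- c(P01 = 0.1, P02 = 0.2, P03 = 0.3, P04 = 0.4)
  pre_cells <- cells[cells$timepoint == "pre", ]
  scores <- data.frame(cell_id = pre_cells$cell_id,
                       cluster = "C1",
                       score = base[pre_cells$patient_id],
                       stringsAsFactors = FALSE)
  sizes <- as_tumor_sizes(data.frame(
    patient_id = patients, size_pre_mm = 50,
    size_post_mm = 50 * (1 + (0.2 - 1.5 * base))))  # exact line
  tab <- meta_cluster_pi(scores, cells, sizes)
  expect_equal(tab$index, 1)

  # one wild cell per patient leaves the (odd-n) median unchanged
  scores2 <- scores
  scores2$score[match(unique(pre_cells$patient_id), pre_cells$patient_id)] <- 1e6
  tab2 <- meta_cluster_pi(scores2, cells, sizes)
  expect_equal(tab2$index, tab$index)
})
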
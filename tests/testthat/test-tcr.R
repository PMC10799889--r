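test_that("clonotype counting tallies cells and conserves totals", {
  cells <- make_repertoire_cells(n = 10)
  # clone K1: 3 pre + 7 post; the rest singletons
  assign <- data.frame(
    cell_id = cells$cell_id,
    clone_id = c(rep("K1", 3), sprintf("U%02d", 1:7),
                 rep("K1", 7), sprintf("V%02d", 1:3)),
    stringsAsFactors = FALSE)
  ct <- build_clonotype_counts(cells, assign)
  k1 <- ct$counts[ct$counts$clone_id == "K1", ]
  expect_equal(c(k1$count_pre, k1$count_post), c(3, 7))
  expect_equal(unique(ct$counts$total_pre), 10)
  expect_equal(unique(ct$counts$total_post), 10)
  expect_equal(sum(ct$counts$count_pre), 10)

  # cells without an immune receptor are excluded with a warning
  cells2 <- cells; cells2$has_ir[1] <- FALSE
  expect_warning(ct2 <- build_clonotype_counts(as_cell_table(cells2), assign),
                 "without an identified immune receptor")
  expect_equal(unique(ct2$counts$total_pre), 9)

  expect_error(build_clonotype_counts(cells, data.frame(cell_id = "nope",
                                                        clone_id = "K9")),
               "unknown cell")
})

test_that("Fisher classification follows the odds-ratio and p-value rules", {
  df <- data.frame(patient_id = "P", clone_id = c("a", "b", "c"),
                   count_pre = c(10, 0, 30), count_post = c(10, 15, 5),
                   total_pre = 1000, total_post = 1000,
                   stringsAsFactors = FALSE)
  cls <- classify_clonotype_change(df)
  expect_equal(cls$label, c("unchange", "expanded", "contracted"))
  expect_equal(cls$fisher_p[1], 1)
  expect_equal(cls$odds_ratio[2], 0)
  expect_equal(cls$odds_ratio[3], (30 * 995) / (970 * 5), tolerance = 1e-12)
  expect_lt(cls$fisher_p[2], 0.05)
  # p-values match the exact hypergeometric enumeration oracle
  for (i in 1:3) {
    expect_equal(cls$fisher_p[i],
                 fisher_p_oracle(df$count_pre[i], 1000, df$count_post[i], 1000),
                 tolerance = 1e-12)
  }
  expect_error(classify_clonotype_change(
    data.frame(patient_id = "P", clone_id = "z", count_pre = 0, count_post = 0,
               total_pre = 10, total_post = 10)), "absent at both")
})

test_that("swapping timepoints maps contracted to expanded and inverts the OR", {
  set.seed(21)
  df <- data.frame(patient_id = "P", clone_id = sprintf("k%03d", 1:100),
                   count_pre = rbinom(100, 30, 0.2),
                   count_post = rbinom(100, 30, 0.2),
                   total_pre = 800, total_post = 900)
  df <- df[df$count_pre + df$count_post > 0, ]
  fwd <- classify_clonotype_change(df)
  swapped <- data.frame(patient_id = df$patient_id, clone_id = df$clone_id,
                        count_pre = df$count_post, count_post = df$count_pre,
                        total_pre = df$total_post, total_post = df$total_pre)
  rev <- classify_clonotype_change(swapped)
  expect_equal(rev$fisher_p, fwd$fisher_p, tolerance = 1e-12)
  expect_equal(rev$odds_ratio, 1 / fwd$odds_ratio, tolerance = 1e-12)
  map <- c(contracted = "expanded", expanded = "contracted", unchange = "unchange")
  expect_equal(rev$label, unname(map[fwd$label]))
  expect_equal(sum(fwd$label %in% c("contracted", "expanded", "unchange")),
               nrow(fwd))
})

test_that("sharing classes partition clones into unique, clonal, and shared", {
  cells <- make_repertoire_cells(n = 6, subtype = "CD8 GZMK+")
  # 6 clones: 3 singletons, 2 one-timepoint multicell, 1 spanning both
  assign <- data.frame(
    cell_id = cells$cell_id,
    clone_id = c("s1", "s2", "m1", "m1", "m1", "x1",      # pre
                 "s3", "m2", "m2", "m2", "m2", "x1"),     # post
    stringsAsFactors = FALSE)
  ct <- build_clonotype_counts(cells, assign)
  expect_warning(sh <- sharing_classes(ct), "no CD4 clones")
  sh8 <- sh[sh$compartment == "CD8", ]
  expect_equal(sh8$percent[sh8$class == "unique"], 50)
  expect_equal(sh8$percent[sh8$class == "clonal"], 100 / 3, tolerance = 1e-9)
  expect_equal(sh8$percent[sh8$class == "shared"], 100 / 6, tolerance = 1e-9)
  expect_equal(sum(sh8$percent), 100)
})

test_that("D50 follows its definition with inclusive half-total and scale invariance", {
  expect_equal(d50(42), 100)
  expect_equal(d50(rep(10, 10)), 50)
  expect_equal(d50(c(50, 20, 10, 10, 5, 5)), 100 / 6, tolerance = 1e-9)
  expect_equal(round(d50(c(50, 20, 10, 10, 5, 5)), 2), 16.67)
  expect_equal(d50(3 * c(50, 20, 10, 10, 5, 5)), d50(c(50, 20, 10, 10, 5, 5)))
  expect_error(d50(numeric(0)), "empty")
})

test_that("clonal similarity is the Jaccard index of clone sets", {
  cells <- make_repertoire_cells(n = 4)
  cells$subtype <- rep(c("CD8 GZMB+", "CD8 GZMK+"), 4)
  # GZMB+ cells carry {a, b, c}; GZMK+ carry {b, c, d}
  assign <- data.frame(cell_id = cells$cell_id,
                       clone_id = c("a", "b", "b", "c", "c", "d", "a", "d"),
                       stringsAsFactors = FALSE)
  ct <- build_clonotype_counts(cells, assign)
  sim <- subtype_clonal_similarity(ct)
  expect_equal(sim["CD8 GZMB+", "CD8 GZMK+"], 0.5)
  expect_equal(diag(sim), c("CD8 GZMB+" = 1, "CD8 GZMK+" = 1))
  expect_equal(sim, t(sim))
})

test_that("top-clone maps rank by abundance with lexicographic tie-breaks", {
  cells <- make_repertoire_cells(n = 5)
  assign <- data.frame(cell_id = cells$cell_id,
                       clone_id = c("b", "b", "b", "a", "a",
                                    "a", "c", "c", "c", "c"),
                       stringsAsFactors = FALSE)
  ct <- build_clonotype_counts(cells, assign)
  top <- top_clone_subtype_map(ct, k = 5)
  expect_equal(length(unique(top$clone_id)), 3)   # fewer clones than k
  ranked <- unique(top[, c("rank", "clone_id")])
  expect_equal(ranked$clone_id[order(ranked$rank)], c("c", "a", "b"))
  # a and b tie at 3 cells: "a" precedes "b" lexicographically
  expect_equal(ranked$rank[ranked$clone_id == "a"], 2)
})

test_that("expansion-response association errors on a zero-variance predictor", {
  p <- small_params(n_expanded_clones = 0, n_contracted_clones = 0, seed = 12)
  sim <- simulate_cohort(p)
  cl <- simulate_clonotypes(p, sim$cells)
  ct <- build_clonotype_counts(sim$cells, cl$assignments)
  cls <- classify_clonotype_change(ct)
  cls$label <- "unchange"   # force zero expanded clones everywhere
  expect_error(expansion_response_association(ct, cls, sim$tumor), "zero variance")
})
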
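test_that("cell table parsing validates structure and round-trips", {
  cells <- make_cells(n_patients = 2, n_per_sample = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(cells, path)
  back <- read_cell_table(path)
  expect_equal(as.data.frame(back), as.data.frame(cells))
  expect_equal(nrow(back), 8)
  expect_equal(length(unique(back$patient_id)), 2)

  df <- as.data.frame(cells)
  expect_error(as_cell_table(df[, setdiff(names(df), "timepoint")]),
               "timepoint")
  dup <- rbind(df, df[1, ])
  expect_error(as_cell_table(dup), "duplicate cell_id")
  bad <- df; bad$timepoint[1] <- "baseline"
  expect_error(as_cell_table(bad), "unknown timepoint")
  multi <- df; multi$sample_id[1] <- "other_sample"
  expect_error(as_cell_table(multi), "multiple sample_ids")
})

test_that("MatrixMarket triplet reading recovers dense counts and mito fraction", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(5, 3), dims = c(3, 2))
  dir <- withr::local_tempdir()
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("GENE1", "GENE2", "GENE3"), file.path(dir, "features.tsv"))
  writeLines(c("cellA", "cellB"), file.path(dir, "barcodes.tsv"))
  cm <- read_counts_mtx(file.path(dir, "matrix.mtx"),
                        file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"))
  expect_equal(unname(as.matrix(cm$counts)),
               matrix(c(5, 0, 0, 0, 3, 0), nrow = 3))
  expect_equal(cm$state, "raw")

  writeLines(c("GENE1", "GENE2"), file.path(dir, "short.tsv"))
  expect_error(read_counts_mtx(file.path(dir, "matrix.mtx"),
                               file.path(dir, "short.tsv"),
                               file.path(dir, "barcodes.tsv")),
               "does not match matrix rows")

  # mito fraction: MT-CO1 = 8 of 100 total counts -> 0.08
  m2 <- matrix(c(8, 92), nrow = 2, dimnames = list(c("MT-CO1", "GENE1"), "c1"))
  cm2 <- make_matrix(m2)
  expect_equal(unname(cm2$mito_fraction["c1"]), 0.08)
})

test_that("QC removes cells below the detected-gene floor and above the mito ceiling", {
  # 1000 genes; vary detected genes and mito content per cell
  n_genes <- 1000
  genes <- c("MT-CO1", sprintf("G%03d", seq_len(n_genes - 1)))
  build_cell <- function(n_detected, mito_counts) {
    v <- numeric(n_genes)
    v[2:n_detected] <- 1           # detected non-mito genes
    v[1] <- mito_counts            # MT-CO1
    v
  }
  # cell1: 499 detected genes (fails floor); cell2: 500 (kept)
  # cell3: mito 0.081 of total (fails); cell4: mito 0.080 (kept)
  c1 <- build_cell(499, 1)
  c2 <- build_cell(500, 1)
  c3 <- numeric(n_genes); c3[2:920] <- 1; c3[1] <- 81   # total 1000, 8.1% mito
  c4 <- numeric(n_genes); c4[2:921] <- 1; c4[1] <- 80   # total 1000, 8.0% mito
  m <- cbind(c1, c2, c3, c4)
  rownames(m) <- genes; colnames(m) <- paste0("cell", 1:4)
  cm <- make_matrix(m)
  expect_equal(unname(cm$mito_fraction), c(1/499, 1/500, 0.081, 0.080))
  res <- qc_filter(cm, thresholds = qc_thresholds(min_cells_per_gene = 1))
  expect_setequal(colnames(res$matrix$counts), c("cell2", "cell4"))
  expect_equal(res$report$cells_removed_min_genes, 1)
  expect_equal(res$report$cells_removed_mito, 1)
})

test_that("QC filters cells then genes and is idempotent", {
  # 5 cells x 6 genes built so exactly 2 cells and 1 gene violate the rules
  thr <- qc_thresholds(min_genes_per_cell = 3, max_mito_fraction = 0.5,
                       max_features_per_cell = 5, min_cells_per_gene = 2)
  m <- rbind(
    G1 = c(1, 1, 1, 1, 0),
    G2 = c(1, 1, 1, 1, 1),
    G3 = c(1, 1, 1, 0, 1),
    G4 = c(0, 1, 1, 0, 0),
    G5 = c(0, 1, 1, 0, 1),
    G6 = c(0, 0, 1, 0, 0))   # detected in 1 retained cell -> dropped
  colnames(m) <- paste0("c", 1:5)
  # c4 detects 2 genes (< 3) -> removed; c3 detects 6 (> 5) -> removed
  cm <- make_matrix(m)
  res <- qc_filter(cm, thresholds = thr)
  expect_setequal(colnames(res$matrix$counts), c("c1", "c2", "c5"))
  expect_equal(res$report$cells_removed_total, 2)
  # G6 detected only in removed c3; G4 detected in 1 retained cell -> both out
  expect_setequal(rownames(res$matrix$counts), c("G1", "G2", "G3", "G5"))
  expect_equal(res$report$genes_removed, 2)

  twice <- qc_filter(res$matrix, thresholds = thr)
  expect_equal(as.matrix(twice$matrix$counts), as.matrix(res$matrix$counts))
  expect_equal(twice$report$cells_removed_total, 0)

  harsh <- qc_thresholds(min_genes_per_cell = 100)
  expect_error(qc_filter(cm, thresholds = harsh), "all cells removed")
})

test_that("normalization matches the closed forms and flags zero-total cells", {
  m <- matrix(c(10, 90, 0, 50, 50, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  cm <- make_matrix(m)
  cpm <- normalize_counts(cm, "cpm")
  expect_equal(unname(as.matrix(cpm$counts)[, "c1"]), c(1e5, 9e5, 0))
  expect_equal(unname(Matrix::colSums(cpm$counts)), c(1e6, 1e6), tolerance = 1e-6)
  ln <- normalize_counts(cm, "lognorm")
  expect_equal(unname(as.matrix(ln$counts)["A", "c1"]), log1p(1000))
  expect_equal(ln$state, "lognorm")

  mz <- m; mz[, 2] <- 0
  expect_error(normalize_counts(make_matrix(mz), "cpm"), "zero total")
  expect_error(normalize_counts(cpm, "cpm"), "requires a raw matrix")
})
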
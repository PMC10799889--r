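# Data model and I/O: per-cell metadata, 10x-style MatrixMarket counts,
# tumor-size tables, QC filtering, and per-cell normalization.

CELL_TABLE_REQUIRED <- c("cell_id", "patient_id", "timepoint", "sample_id", "major_type")

#' Validate and construct a cell table
#'
#' A cell table is a `data.frame` with one row per cell carrying the columns
#' `cell_id`, `patient_id`, `timepoint` (`"pre"` or `"post"`), `sample_id`,
#' `major_type`, and optionally `subtype` and `has_ir` (whether an immune
#' receptor was identified for the cell).
#'
#' @param df data.frame of per-cell metadata.
#' @return The validated data.frame with class `"cell_table"`.
#' @export
as_cell_table <- function(df) {
  missing <- setdiff(CELL_TABLE_REQUIRED, names(df))
  if (length(missing) > 0)
    stop_fmt("cell table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  df$patient_id <- as.character(df$patient_id)
  df$timepoint <- as.character(df$timepoint)
  df$sample_id <- as.character(df$sample_id)
  df$major_type <- as.character(df$major_type)
  if (!is.null(df$subtype)) df$subtype <- as.character(df$subtype)
  if (!is.null(df$has_ir)) df$has_ir <- as.logical(df$has_ir)
  bad_tp <- setdiff(unique(df$timepoint), c("pre", "post"))
  if (length(bad_tp) > 0)
    stop_fmt("unknown timepoint value(s): %s (must be 'pre' or 'post')",
             paste(bad_tp, collapse = ", "))
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup) > 0)
    stop_fmt("duplicate cell_id(s): %s", paste(utils::head(unique(dup), 5), collapse = ", "))
  # each (patient, timepoint) pair must map to a single sample
  key <- paste(df$patient_id, df$timepoint, sep = "\r")
  n_samp <- tapply(df$sample_id, key, function(s) length(unique(s)))
  if (any(n_samp > 1))
    stop_fmt("patient/timepoint pair mapped to multiple sample_ids: %s",
             paste(gsub("\r", "/", names(n_samp)[n_samp > 1]), collapse = ", "))
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Read a per-cell metadata table from TSV
#'
#' @param path path to a tab-separated file with a header row containing at
#'   least `cell_id`, `patient_id`, `timepoint`, `sample_id`, `major_type`.
#' @return A validated [as_cell_table()] data.frame.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!is.null(df$has_ir)) df$has_ir <- as.logical(df$has_ir)
  as_cell_table(df)
}

#' Write a cell table to TSV
#'
#' @param cells a cell table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(as.data.frame(cells), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tumor-size table
#'
#' Expects columns `patient_id`, `size_pre_mm`, `size_post_mm` (sums of
#' target-lesion diameters in mm). Tumor change is the relative change
#' `(post - pre) / pre`; negative values mean shrinkage.
#'
#' @param path tab-separated file path.
#' @return data.frame with an added `tumor_change` column.
#' @export
read_tumor_sizes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  as_tumor_sizes(df)
}

#' @rdname read_tumor_sizes
#' @param df data.frame with columns `patient_id`, `size_pre_mm`, `size_post_mm`.
#' @export
as_tumor_sizes <- function(df) {
  need <- c("patient_id", "size_pre_mm", "size_post_mm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop_fmt("tumor-size table is missing column(s): %s", paste(missing, collapse = ", "))
  if (any(df$size_pre_mm <= 0))
    stop_fmt("size_pre_mm must be positive for all patients")
  df$patient_id <- as.character(df$patient_id)
  df$tumor_change <- (df$size_post_mm - df$size_pre_mm) / df$size_pre_mm
  df
}

#' Construct a count matrix object
#'
#' Wraps a genes-by-cells sparse matrix together with its normalization
#' state and the per-cell mitochondrial count fraction.
#'
#' @param counts matrix or `Matrix` with gene symbols as rownames and cell
#'   barcodes as colnames.
#' @param state one of `"raw"`, `"cpm"`, `"lognorm"`.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes
#'   (human default `"MT-"`).
#' @param mito_fraction optional precomputed per-cell fraction; computed from
#'   `mito_prefix` when `state = "raw"` and not supplied.
#' @return An object of class `"count_matrix"` with elements `counts`,
#'   `state`, `mito_fraction`.
#' @export
count_matrix <- function(counts, state = c("raw", "cpm", "lognorm"),
                         mito_prefix = "MT-", mito_fraction = NULL) {
  state <- match.arg(state)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("count matrix must carry gene rownames and cell colnames")
  if (any(counts@x < 0))
    stop_fmt("count matrix contains negative entries")
  if (state == "raw" && any(counts@x != floor(counts@x)))
    stop_fmt("raw count matrix must contain integer counts")
  if (state == "raw" && is.null(mito_fraction)) {
    mito <- startsWith(rownames(counts), mito_prefix)
    tot <- Matrix::colSums(counts)
    mt <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
    mito_fraction <- ifelse(tot > 0, mt / tot, 0)
    names(mito_fraction) <- colnames(counts)
  }
  structure(list(counts = counts, state = state, mito_fraction = mito_fraction),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, state = %s\n",
              nrow(x$counts), ncol(x$counts), x$state))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read 10x-style MatrixMarket triplet counts
#'
#' @param matrix_path MatrixMarket coordinate file (genes x cells).
#' @param features_path one gene symbol per line (first column of a TSV).
#' @param barcodes_path one cell barcode per line.
#' @param mito_prefix mitochondrial gene-symbol prefix.
#' @return A raw [count_matrix()].
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path,
                            mito_prefix = "MT-") {
  m <- Matrix::readMM(matrix_path)
  features <- utils::read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (length(features) != nrow(m))
    stop_fmt("features list length (%d) does not match matrix rows (%d)",
             length(features), nrow(m))
  if (length(barcodes) != ncol(m))
    stop_fmt("barcodes list length (%d) does not match matrix columns (%d)",
             length(barcodes), ncol(m))
  dimnames(m) <- list(features, barcodes)
  count_matrix(m, state = "raw", mito_prefix = mito_prefix)
}

#' Write a count matrix as a MatrixMarket triplet with sidecar files
#'
#' @param matrix a [count_matrix()].
#' @param dir output directory; writes `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(matrix, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(matrix$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(matrix$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Quality-control thresholds
#'
#' Defaults follow common droplet-scRNA practice: cells with fewer than 500
#' detected genes, more than 8% mitochondrial counts, or more than 6000
#' detected genes are excluded; genes detected in fewer than 3 retained cells
#' are dropped.
#'
#' @param min_genes_per_cell minimum detected genes per cell (cells *below*
#'   this are removed; a cell with exactly this many is kept).
#' @param max_mito_fraction maximum mitochondrial count fraction (cells
#'   *strictly above* are removed).
#' @param max_features_per_cell maximum detected genes per cell (strictly
#'   above removed).
#' @param min_cells_per_gene minimum number of retained cells a gene must be
#'   detected in.
#' @return list of thresholds with class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_genes_per_cell = 500,
                          max_mito_fraction = 0.08,
                          max_features_per_cell = 6000,
                          min_cells_per_gene = 3) {
  stopifnot(min_genes_per_cell > 0, max_mito_fraction > 0,
            max_features_per_cell > 0, min_cells_per_gene > 0,
            min_genes_per_cell < max_features_per_cell)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 max_features_per_cell = max_features_per_cell,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

#' Filter cells and genes by quality-control thresholds
#'
#' Cell filters are applied first (detected-gene lower bound, mitochondrial
#' fraction, detected-gene upper bound, in that order), then genes detected
#' in fewer than `min_cells_per_gene` of the *retained* cells are removed.
#'
#' @param matrix raw [count_matrix()].
#' @param cells optional cell table restricted alongside the matrix.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with elements `matrix`, `cells` (or `NULL`), and `report`
#'   (cells/genes removed per rule).
#' @export
qc_filter <- function(matrix, cells = NULL, thresholds = qc_thresholds()) {
  if (matrix$state != "raw")
    stop_fmt("qc_filter requires a raw count matrix (state = %s)", matrix$state)
  m <- matrix$counts
  detected <- Matrix::colSums(m > 0)
  mito <- matrix$mito_fraction[colnames(m)]
  fail_min_genes <- detected < thresholds$min_genes_per_cell
  fail_mito <- mito > thresholds$max_mito_fraction
  fail_max_genes <- detected > thresholds$max_features_per_cell
  keep_cell <- !(fail_min_genes | fail_mito | fail_max_genes)
  if (!any(keep_cell))
    stop_fmt("all cells removed by QC filtering")
  m2 <- m[, keep_cell, drop = FALSE]
  gene_cells <- Matrix::rowSums(m2 > 0)
  keep_gene <- gene_cells >= thresholds$min_cells_per_gene
  m3 <- m2[keep_gene, , drop = FALSE]
  report <- list(
    n_cells_in = ncol(m), n_genes_in = nrow(m),
    cells_removed_min_genes = sum(fail_min_genes),
    cells_removed_mito = sum(fail_mito & !fail_min_genes),
    cells_removed_max_genes = sum(fail_max_genes & !fail_min_genes & !fail_mito),
    cells_removed_total = sum(!keep_cell),
    genes_removed = sum(!keep_gene),
    n_cells_out = ncol(m3), n_genes_out = nrow(m3))
  out_cells <- NULL
  if (!is.null(cells)) {
    out_cells <- cells[cells$cell_id %in% colnames(m3), , drop = FALSE]
    rownames(out_cells) <- NULL
  }
  out <- count_matrix(m3, state = "raw",
                      mito_fraction = matrix$mito_fraction[colnames(m3)])
  list(matrix = out, cells = out_cells, report = report)
}

#' Normalize a raw count matrix per cell
#'
#' `"cpm"` scales each cell to one million counts. `"lognorm"` is
#' `log1p(count * 1e4 / cell_total)`, i.e. log-normalization with a size
#' factor of 10,000.
#'
#' @param matrix raw [count_matrix()].
#' @param mode `"cpm"` or `"lognorm"`.
#' @return A [count_matrix()] in the requested state.
#' @export
normalize_counts <- function(matrix, mode = c("cpm", "lognorm")) {
  mode <- match.arg(mode)
  if (matrix$state != "raw")
    stop_fmt("normalize_counts requires a raw matrix (state = %s)", matrix$state)
  m <- matrix$counts
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop_fmt("cell(s) with zero total counts: %s",
             paste(utils::head(colnames(m)[totals == 0], 5), collapse = ", "))
  sf <- if (mode == "cpm") 1e6 else 1e4
  scaled <- m %*% Matrix::Diagonal(x = sf / totals)
  dimnames(scaled) <- dimnames(m)
  if (mode == "lognorm") scaled@x <- log1p(scaled@x)
  count_matrix(scaled, state = mode, mito_fraction = matrix$mito_fraction)
}
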
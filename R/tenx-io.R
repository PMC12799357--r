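#' Write a cohort as a 10x-style MatrixMarket bundle
#'
#' Writes `matrix.mtx` (features as rows, cells as columns), `barcodes.tsv`,
#' `features.tsv`, a `metadata.tsv` cell table (columns `barcode`,
#' `donor_id`, `age_years`, `cell_type`, `batch`) and, when ground-truth
#' senescent flags are present, `truth.tsv` (`barcode`, `senescent_true`).
#' All files are plain text; a round-trip through [read_tenx_bundle()]
#' reproduces the counts exactly.
#'
#' @param x a `SingleCellExperiment` with a `counts` assay, or a genes x
#'   cells count matrix (then `metadata` must be supplied).
#' @param out_dir output directory (created if needed).
#' @param metadata optional cell metadata data.frame; defaults to the
#'   `colData` of `x`.
#' @return `out_dir`, invisibly.
#' @export
write_tenx_bundle <- function(x, out_dir, metadata = NULL) {
  counts <- .get_counts(x)
  if (is.null(metadata)) {
    metadata <- if (is(x, "SummarizedExperiment")) .get_metadata_df(x) else
      stop("metadata required when 'x' is a bare matrix", call. = FALSE)
  }
  metadata <- as.data.frame(metadata)
  if (!"barcode" %in% names(metadata)) {
    stop("metadata lacks a 'barcode' column", call. = FALSE)
  }
  if (!identical(as.character(metadata$barcode), colnames(counts))) {
    stop("barcode mismatch between count matrix and metadata", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts, file.path(out_dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(out_dir, "barcodes.tsv"))
  feat <- data.frame(id = rownames(counts), name = rownames(counts),
                     type = "Gene Expression")
  utils::write.table(feat, file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cols <- intersect(c("barcode", "donor_id", "age_years", "cell_type", "batch"),
                    names(metadata))
  utils::write.table(metadata[, cols, drop = FALSE],
                     file.path(out_dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if ("senescent_true" %in% names(metadata)) {
    utils::write.table(metadata[, c("barcode", "senescent_true")],
                       file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Read a 10x-style MatrixMarket bundle
#'
#' Counterpart of [write_tenx_bundle()]: reads `matrix.mtx`,
#' `barcodes.tsv`, `features.tsv` and, if present, `metadata.tsv` and
#' `truth.tsv`, and assembles a `SingleCellExperiment` (genes x cells).
#'
#' @param dir directory holding the bundle.
#' @return a `SingleCellExperiment` with a `counts` assay; cell metadata
#'   columns appear in `colData` when `metadata.tsv` is present.
#' @export
read_tenx_bundle <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir, call. = FALSE)
  counts <- as(Matrix::readMM(mtx), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feat <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                            header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feat) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("bundle dimensions disagree with matrix.mtx", call. = FALSE)
  }
  dimnames(counts) <- list(feat[[1]], barcodes)
  cd <- DataFrame(barcode = barcodes, row.names = barcodes)
  meta_path <- file.path(dir, "metadata.tsv")
  if (file.exists(meta_path)) {
    md <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!identical(as.character(md$barcode), barcodes)) {
      stop("barcode mismatch between metadata.tsv and matrix", call. = FALSE)
    }
    cd <- DataFrame(md, row.names = barcodes)
  }
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    tr <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cd$senescent_true <- tr$senescent_true[match(barcodes, tr$barcode)]
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = DataFrame(gene_id = feat[[1]],
                        is_mito = startsWith(feat[[1]], "MT-"),
                        row.names = feat[[1]]))
}
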
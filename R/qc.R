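#' Per-cell quality-control metrics
#'
#' Computes, from raw counts only: the total UMI count, the number of
#' detected genes (count > 0) and the mitochondrial percentage (sum of
#' counts over `mito_genes` divided by the total, times 100; 0 for
#' zero-total cells).
#'
#' @param x a `SingleCellExperiment` or genes x cells count matrix.
#' @param mito_genes character vector of mitochondrial gene ids, or a
#'   single prefix string such as `"MT-"` (matched against rownames).
#'   Ids absent from the matrix raise a warning.
#' @return data.frame with columns `barcode`, `total`, `detected`,
#'   `mito_pct`.
#' @export
compute_qc_metrics <- function(x, mito_genes = "MT-") {
  counts <- .get_counts(x)
  if (length(mito_genes) == 1L && !mito_genes %in% rownames(counts)) {
    mito <- rownames(counts)[startsWith(rownames(counts), mito_genes)]
  } else {
    miss <- setdiff(mito_genes, rownames(counts))
    if (length(miss)) {
      warning(length(miss), " mitochondrial gene id(s) not in matrix: ",
              paste(utils::head(miss, 3), collapse = ", "))
    }
    mito <- intersect(mito_genes, rownames(counts))
  }
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito_sum <- if (length(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else
    numeric(ncol(counts))
  mito_pct <- ifelse(total > 0, 100 * mito_sum / total, 0)
  data.frame(barcode = colnames(counts), total = as.numeric(total),
             detected = as.numeric(detected), mito_pct = as.numeric(mito_pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' QC thresholds
#'
#' Thresholds for [filter_cells()]: an absolute minimum total UMI count,
#' MAD-count limits on log1p totals and log1p detected genes (two-sided,
#' unscaled MAD), and absolute plus MAD limits on the mitochondrial
#' percentage (MAD rule one-sided, high side only).
#'
#' @param min_total_umi minimum total UMI count per cell.
#' @param total_nmads,genes_nmads allowed deviation (in unscaled MADs on the
#'   log1p scale) for totals and detected genes.
#' @param mito_max_pct absolute mitochondrial ceiling in percent.
#' @param mito_nmads allowed upward deviation of the mitochondrial
#'   percentage, in unscaled MADs.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_total_umi = 500, total_nmads = 5,
                          genes_nmads = 5, mito_max_pct = 15, mito_nmads = 4) {
  thr <- list(min_total_umi = min_total_umi, total_nmads = total_nmads,
              genes_nmads = genes_nmads, mito_max_pct = mito_max_pct,
              mito_nmads = mito_nmads)
  for (f in names(thr)) .check(is.numeric(thr[[f]]) && thr[[f]] > 0, f, "must be positive")
  structure(thr, class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' A cell is kept iff it passes all of: total >= `min_total_umi`;
#' |log1p(total) - median| <= `total_nmads` * MAD; |log1p(detected) -
#' median| <= `genes_nmads` * MAD; mito_pct <= `mito_max_pct`; and
#' mito_pct - median <= `mito_nmads` * MAD (high side only). MADs are
#' unscaled and computed on the full input population. When a metric's MAD
#' is zero its MAD rule is dropped (absolute criteria only) with a warning.
#'
#' @param qc data.frame from [compute_qc_metrics()].
#' @param thresholds a [qc_thresholds()] object.
#' @return named logical keep-mask (TRUE = keep), one entry per cell.
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds()) {
  if (!nrow(qc)) stop("QC table is empty", call. = FALSE)
  thr <- thresholds
  lt <- log1p(qc$total)
  ld <- log1p(qc$detected)

  mad_rule <- function(x, nmads, metric, one_sided = FALSE) {
    m <- .mad_raw(x)
    if (m == 0) {
      warning("MAD of ", metric, " is zero; using absolute criteria only ",
              "for this metric", call. = FALSE)
      return(rep(TRUE, length(x)))
    }
    dev <- x - stats::median(x)
    if (one_sided) dev <= nmads * m else abs(dev) <= nmads * m
  }

  keep <- qc$total >= thr$min_total_umi &
    mad_rule(lt, thr$total_nmads, "log1p total UMI") &
    mad_rule(ld, thr$genes_nmads, "log1p detected genes") &
    qc$mito_pct <= thr$mito_max_pct &
    mad_rule(qc$mito_pct, thr$mito_nmads, "mitochondrial percent", one_sided = TRUE)
  stats::setNames(keep, qc$barcode)
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to sum to `target_sum` and stores
#' `log(1 + scaled)` (natural log) as a `logcounts` assay. Raw counts are
#' retained unchanged.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay; cells with a
#'   zero total are an error (filter first).
#' @param target_sum per-cell target library size before the log.
#' @return the input object with a `logcounts` assay added.
#' @export
normalize_log <- function(sce, target_sum = 1e4) {
  counts <- .get_counts(sce)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[which(totals == 0)]
    stop("cell(s) with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  scaled <- counts %*% Matrix::Diagonal(x = target_sum / totals)
  lc <- as(log1p(scaled), "CsparseMatrix")
  dimnames(lc) <- dimnames(counts)
  if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logcounts") <- lc
    sce
  } else {
    lc
  }
}
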
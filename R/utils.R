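# Internal helpers shared across modules.

#' @importFrom methods is as
#' @importFrom SummarizedExperiment assay assays colData rowData assayNames
#' @importFrom S4Vectors metadata DataFrame
NULL

# Extract a genes x cells count matrix from an SCE or a matrix-like object.
.get_counts <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!"counts" %in% assayNames(x)) {
      stop("object has no 'counts' assay", call. = FALSE)
    }
    m <- assay(x, "counts")
  } else {
    m <- x
  }
  if (is.null(dim(m)) || any(dim(m) == 0L)) {
    stop("count matrix is empty: no cells", call. = FALSE)
  }
  as(m, "CsparseMatrix")
}

.get_logcounts <- function(x) {
  if (!is(x, "SummarizedExperiment") || !"logcounts" %in% assayNames(x)) {
    stop("normalized 'logcounts' layer not found; run normalize_log() first",
         call. = FALSE)
  }
  as(assay(x, "logcounts"), "CsparseMatrix")
}

.get_metadata_df <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    md <- as.data.frame(colData(x))
    md$barcode <- colnames(x)
  } else {
    md <- as.data.frame(x)
  }
  need <- c("barcode", "donor_id", "age_years", "cell_type")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("cell metadata lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  md
}

# Unscaled MAD (constant = 1): median absolute deviation from the median.
.mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

# Population (ddof = 0) standard deviation.
.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Validation helper producing errors that name the offending field.
.check <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop("invalid '", field, "': ", msg, call. = FALSE)
  invisible(TRUE)
}
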
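#' Criteria for senescence-signature gene selection
#'
#' A gene enters a cell type's senescence signature when, among cells of
#' that type, its expressing-cell fraction is below `young_max_frac` in the
#' pooled young-donor group, lies strictly between `old_min_frac` and
#' `old_max_frac` in the pooled old-donor group, and either rises at least
#' `min_fold`-fold from young to old or increases by more than
#' `min_abs_diff` in absolute terms. "Expressing" means raw count > 0.
#'
#' @param young_max_frac maximum expressing fraction in young donors.
#' @param old_min_frac,old_max_frac open band for the old-donor expressing
#'   fraction.
#' @param min_fold minimum old/young fold change (satisfied by convention
#'   whenever the young fraction is exactly zero).
#' @param min_abs_diff absolute old-minus-young increase that the gene may
#'   satisfy instead of the fold rule (strict).
#' @param young_max_age,old_min_age donor-age cutoffs (years) assigning
#'   donors to the young and old groups.
#' @return list of class `signature_criteria`.
#' @export
signature_criteria <- function(young_max_frac = 0.05, old_min_frac = 0.01,
                               old_max_frac = 0.20, min_fold = 2.5,
                               min_abs_diff = 0.05, young_max_age = 30,
                               old_min_age = 55) {
  .check(young_max_frac >= 0 && young_max_frac < 1, "young_max_frac", "must lie in [0, 1)")
  .check(old_min_frac < old_max_frac, "old_min_frac", "must be below old_max_frac")
  .check(min_fold > 1, "min_fold", "must exceed 1")
  .check(min_abs_diff > 0, "min_abs_diff", "must be positive")
  .check(young_max_age < old_min_age, "young_max_age", "must be below old_min_age")
  structure(list(young_max_frac = young_max_frac, old_min_frac = old_min_frac,
                 old_max_frac = old_max_frac, min_fold = min_fold,
                 min_abs_diff = min_abs_diff, young_max_age = young_max_age,
                 old_min_age = old_min_age),
            class = "signature_criteria")
}

# Vectorized inclusion rule on young/old expressing fractions.
.signature_included <- function(p_y, p_o, criteria) {
  fold_ok <- ifelse(p_y > 0, p_o >= criteria$min_fold * p_y, TRUE)
  p_y < criteria$young_max_frac &
    p_o > criteria$old_min_frac & p_o < criteria$old_max_frac &
    (fold_ok | (p_o - p_y) > criteria$min_abs_diff)
}

#' Derive a cell-type-specific senescence signature
#'
#' Pools cells of `cell_type` from young donors (age <= `young_max_age`)
#' and from old donors (age >= `old_min_age`), computes per-gene
#' expressing-cell fractions (raw count > 0) in each pool, and applies the
#' selection rule of [signature_criteria()].
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay and `colData`
#'   columns `donor_id`, `age_years`, `cell_type`.
#' @param cell_type label of the cell population to derive the signature for.
#' @param criteria a [signature_criteria()] object.
#' @return data.frame of class `senescence_signature` with one row per gene
#'   (`gene`, `p_young`, `p_old`, `fold`, `abs_diff`, `included`) and
#'   attributes `cell_type`, `genes` (included gene ids), `criteria`,
#'   `n_young`, `n_old`. An empty signature raises a warning.
#' @export
derive_signature <- function(sce, cell_type, criteria = signature_criteria()) {
  counts <- .get_counts(sce)
  md <- .get_metadata_df(sce)
  is_type <- md$cell_type == cell_type
  young <- is_type & md$age_years <= criteria$young_max_age
  old <- is_type & md$age_years >= criteria$old_min_age
  if (!any(young)) {
    stop("no '", cell_type, "' cells from young donors (age <= ",
         criteria$young_max_age, ")", call. = FALSE)
  }
  if (!any(old)) {
    stop("no '", cell_type, "' cells from old donors (age >= ",
         criteria$old_min_age, ")", call. = FALSE)
  }
  p_y <- as.numeric(Matrix::rowSums(counts[, young, drop = FALSE] > 0)) / sum(young)
  p_o <- as.numeric(Matrix::rowSums(counts[, old, drop = FALSE] > 0)) / sum(old)
  inc <- .signature_included(p_y, p_o, criteria)
  sig <- data.frame(gene = rownames(counts), cell_type = cell_type,
                    p_young = p_y, p_old = p_o,
                    fold = ifelse(p_y > 0, p_o / p_y, Inf),
                    abs_diff = p_o - p_y, included = inc,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(inc)) {
    warning("empty senescence signature for cell type '", cell_type,
            "'; downstream scoring will be skipped", call. = FALSE)
  }
  structure(sig, class = c("senescence_signature", "data.frame"),
            cell_type = cell_type, genes = sig$gene[inc], criteria = criteria,
            n_young = sum(young), n_old = sum(old))
}

#' @export
print.senescence_signature <- function(x, ...) {
  cat("senescence signature for cell type '", attr(x, "cell_type"), "': ",
      length(attr(x, "genes")), " of ", nrow(x), " genes included (",
      attr(x, "n_young"), " young / ", attr(x, "n_old"), " old cells)\n",
      sep = "")
  invisible(x)
}

#' Per-cell senescence score
#'
#' Scores every cell of the signature's cell type as the unweighted mean,
#' over signature genes, of the per-gene z-scored log-normalized expression
#' (z computed within the scored cell population). Higher scores indicate
#' broader and stronger expression of the senescence signature. Genes with
#' zero variance contribute zero; signature genes absent from the matrix
#' are dropped with a warning (all absent is an error).
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay (see
#'   [normalize_log()]).
#' @param signature a [derive_signature()] result (or a character vector of
#'   gene ids, in which case `cell_type` must be given).
#' @param cell_type optional cell-type label override.
#' @return named numeric vector of scores for cells of the cell type.
#' @export
score_cells <- function(sce, signature, cell_type = NULL) {
  lc <- .get_logcounts(sce)
  md <- .get_metadata_df(sce)
  genes <- if (inherits(signature, "senescence_signature"))
    attr(signature, "genes") else as.character(signature)
  if (is.null(cell_type)) cell_type <- attr(signature, "cell_type")
  if (is.null(cell_type)) stop("cell_type must be supplied", call. = FALSE)
  if (!length(genes)) stop("signature is empty; nothing to score", call. = FALSE)
  present <- genes %in% rownames(lc)
  if (!any(present)) stop("no signature gene is present in the matrix", call. = FALSE)
  if (!all(present)) {
    warning(sum(!present), " signature gene(s) absent from the matrix; dropped",
            call. = FALSE)
    genes <- genes[present]
  }
  cells <- md$barcode[md$cell_type == cell_type]
  if (!length(cells)) stop("no cells of type '", cell_type, "'", call. = FALSE)
  expr <- as.matrix(Matrix::t(lc[genes, cells, drop = FALSE]))  # cells x genes
  mu <- colMeans(expr)
  sdv <- apply(expr, 2L, stats::sd)
  z <- sweep(expr, 2L, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sdv[nz], "/")
  z[, !nz] <- 0
  stats::setNames(rowMeans(z), cells)
}
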
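#' Criteria for differential-expression calls
#'
#' A gene passes for a target group when its BH FDR is below `fdr_max`, it
#' is detected (raw count > 0) in more than `min_frac_target` of the target
#' group's cells and in fewer than `max_frac_other` of the comparison
#' group's cells, and its mean log-normalized expression is higher in the
#' target group.
#'
#' @param fdr_max FDR ceiling.
#' @param min_frac_target minimum expressing fraction in the target group
#'   (strict).
#' @param max_frac_other maximum expressing fraction in the comparison
#'   group (strict).
#' @param young_max_age,old_min_age donor-age cutoffs (years) defining the
#'   young and old groups.
#' @param exact use exact Mann-Whitney enumeration for very small groups.
#' @return list of class `deg_criteria`.
#' @export
deg_criteria <- function(fdr_max = 0.01, min_frac_target = 0.10,
                         max_frac_other = 0.50, young_max_age = 30,
                         old_min_age = 55, exact = FALSE) {
  .check(fdr_max > 0 && fdr_max < 1, "fdr_max", "must lie in (0, 1)")
  .check(min_frac_target >= 0 && min_frac_target <= 1, "min_frac_target",
         "must lie in [0, 1]")
  .check(max_frac_other >= 0 && max_frac_other <= 1, "max_frac_other",
         "must lie in [0, 1]")
  .check(young_max_age < old_min_age, "young_max_age", "must be below old_min_age")
  structure(list(fdr_max = fdr_max, min_frac_target = min_frac_target,
                 max_frac_other = max_frac_other, young_max_age = young_max_age,
                 old_min_age = old_min_age, exact = exact),
            class = "deg_criteria")
}

#' Differential expression between old- and young-donor cells of a subset
#'
#' For every gene, runs the Mann-Whitney U test on log-normalized
#' expression between cells of `subset` from old donors (age >=
#' `old_min_age`) and young donors (age <= `young_max_age`), adjusts
#' p-values by Benjamini-Hochberg across genes, and evaluates the pass rule
#' of [deg_criteria()] once per direction (each age group in turn as the
#' target). Expressing fractions are computed on raw counts.
#'
#' @param sce a `SingleCellExperiment` with `counts` and `logcounts`
#'   assays and metadata columns `donor_id`, `age_years`, `cell_type`.
#' @param subset cell-type label to test within.
#' @param criteria a [deg_criteria()] object.
#' @return data.frame of class `deg_table`, two rows per gene (one per
#'   target group): `gene`, `subset`, `target`, `U`, `p`, `fdr`,
#'   `frac_target`, `frac_other`, `mean_target`, `mean_other`,
#'   `up_in_target`, `pass`.
#' @export
find_degs <- function(sce, subset, criteria = deg_criteria()) {
  counts <- .get_counts(sce)
  lc <- .get_logcounts(sce)
  md <- .get_metadata_df(sce)
  is_sub <- md$cell_type == subset
  old_cells <- md$barcode[is_sub & md$age_years >= criteria$old_min_age]
  young_cells <- md$barcode[is_sub & md$age_years <= criteria$young_max_age]
  if (!length(old_cells)) {
    stop("no '", subset, "' cells in the old group (age >= ",
         criteria$old_min_age, ")", call. = FALSE)
  }
  if (!length(young_cells)) {
    stop("no '", subset, "' cells in the young group (age <= ",
         criteria$young_max_age, ")", call. = FALSE)
  }
  cells <- c(old_cells, young_cells)
  grp_old <- seq_along(old_cells)
  expr <- as.matrix(Matrix::t(lc[, cells, drop = FALSE]))       # cells x genes
  raw <- Matrix::t(counts[, cells, drop = FALSE]) > 0
  n_o <- length(old_cells); n_y <- length(young_cells)

  frac_old <- as.numeric(Matrix::colSums(raw[grp_old, , drop = FALSE])) / n_o
  frac_young <- as.numeric(Matrix::colSums(raw[-grp_old, , drop = FALSE])) / n_y
  mean_old <- colMeans(expr[grp_old, , drop = FALSE])
  mean_young <- colMeans(expr[-grp_old, , drop = FALSE])

  stats_per_gene <- vapply(seq_len(ncol(expr)), function(g) {
    r <- mann_whitney_u(expr[grp_old, g], expr[-grp_old, g],
                        exact = criteria$exact)
    c(r$U, r$p)
  }, numeric(2))
  U <- stats_per_gene[1, ]
  p <- stats_per_gene[2, ]
  fdr <- bh_fdr(p)
  genes <- colnames(expr)

  mk <- function(target) {
    if (target == "old") {
      ft <- frac_old; fo <- frac_young; mt <- mean_old; mo <- mean_young
    } else {
      ft <- frac_young; fo <- frac_old; mt <- mean_young; mo <- mean_old
    }
    up <- mt > mo
    data.frame(gene = genes, subset = subset, target = target, U = U, p = p,
               fdr = fdr, frac_target = ft, frac_other = fo,
               mean_target = mt, mean_other = mo, up_in_target = up,
               pass = fdr < criteria$fdr_max & ft > criteria$min_frac_target &
                 fo < criteria$max_frac_other & up,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(rbind(mk("old"), mk("young")),
            class = c("deg_table", "data.frame"),
            n_old = n_o, n_young = n_y, criteria = criteria)
}
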
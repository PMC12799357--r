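#' Exclude donors with low cell counts for a cell type
#'
#' A donor is excluded when its cell count falls below
#' `mean - n_sd * SD` of the counts across all donors (population SD by
#' default). With zero spread nobody is excluded. The rule is one-sided:
#' only low counts are removed.
#'
#' @param counts named numeric per-donor cell counts (>= 3 donors).
#' @param n_sd number of standard deviations (default 2).
#' @param ddof 0 for population SD (default) or 1 for sample SD.
#' @return character vector of included donor ids, with the excluded ids
#'   in attribute `excluded`.
#' @export
exclude_low_count_samples <- function(counts, n_sd = 2, ddof = 0) {
  if (length(counts) < 3L) stop("need counts for at least 3 donors", call. = FALSE)
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  s <- if (ddof == 0) .sd_pop(counts) else stats::sd(counts)
  cutoff <- mean(counts) - n_sd * s
  keep <- if (s == 0) rep(TRUE, length(counts)) else counts >= cutoff
  structure(names(counts)[keep], excluded = names(counts)[!keep],
            cutoff = cutoff)
}

#' Donor-level T-subset composition table
#'
#' For each donor: cell counts of the T subsets, the total T pool and all
#' cells; subset proportions under both denominator conventions (the total
#' T-cell pool and the total cell count across all cell types); the
#' immunological indices Th/Tc, Treg/Tc and Treg/Th (NA when the
#' denominator subset is absent); per-cell-type counts for every cell type
#' present; and, when senescent calls are supplied, the pooled and
#' per-cell-type senescent fractions.
#'
#' @param metadata cell metadata (`barcode`, `donor_id`, `age_years`,
#'   `cell_type`) or a `SingleCellExperiment`.
#' @param calls optional `senescence_calls` data.frame (concatenated over
#'   cell types) used to add senescent fractions.
#' @param t_subsets labels of the T subsets of interest.
#' @param other_t_types additional labels counted toward the T pool but not
#'   reported as subsets.
#' @return data.frame of class `composition_table`, one row per donor:
#'   `donor_id`, `age_years`, `n_Th`/`n_Tc`/`n_Treg`, `n_T`, `n_cells`,
#'   `prop_<s>_of_T`, `prop_<s>_of_all`, `ratio_Th_Tc`, `ratio_Treg_Tc`,
#'   `ratio_Treg_Th`, `n_type_<type>` for every cell type, and (with
#'   `calls`) `sen_frac_pooled` and `sen_frac_<type>`.
#' @export
subset_proportions <- function(metadata, calls = NULL,
                               t_subsets = c("Th", "Tc", "Treg"),
                               other_t_types = character(0)) {
  md <- .get_metadata_df(metadata)
  missing_sub <- setdiff(t_subsets, unique(md$cell_type))
  if (length(missing_sub) == length(t_subsets)) {
    stop("none of the T-subset labels (", paste(t_subsets, collapse = ", "),
         ") occur in the metadata", call. = FALSE)
  }
  donors <- sort(unique(md$donor_id))
  tab <- table(factor(md$donor_id, donors), md$cell_type)
  out <- data.frame(donor_id = donors,
                    age_years = md$age_years[match(donors, md$donor_id)],
                    stringsAsFactors = FALSE)
  sub_counts <- sapply(t_subsets, function(s)
    if (s %in% colnames(tab)) as.numeric(tab[, s]) else numeric(length(donors)))
  sub_counts <- matrix(sub_counts, nrow = length(donors),
                       dimnames = list(donors, t_subsets))
  for (s in t_subsets) out[[paste0("n_", s)]] <- sub_counts[, s]
  t_pool <- union(t_subsets, other_t_types)
  out$n_T <- rowSums(tab[, intersect(t_pool, colnames(tab)), drop = FALSE])
  out$n_cells <- rowSums(tab)
  for (s in t_subsets) {
    out[[paste0("prop_", s, "_of_T")]] <-
      ifelse(out$n_T > 0, sub_counts[, s] / out$n_T, NA_real_)
    out[[paste0("prop_", s, "_of_all")]] <- sub_counts[, s] / out$n_cells
  }
  ratio <- function(a, b) ifelse(sub_counts[, b] > 0,
                                 sub_counts[, a] / sub_counts[, b], NA_real_)
  if (all(c("Th", "Tc") %in% t_subsets)) out$ratio_Th_Tc <- ratio("Th", "Tc")
  if (all(c("Treg", "Tc") %in% t_subsets)) out$ratio_Treg_Tc <- ratio("Treg", "Tc")
  if (all(c("Treg", "Th") %in% t_subsets)) out$ratio_Treg_Th <- ratio("Treg", "Th")
  for (ct in colnames(tab)) out[[paste0("n_type_", ct)]] <- as.numeric(tab[, ct])

  if (!is.null(calls)) {
    fr <- senescent_fractions(calls, md)
    pooled <- fr[fr$cell_type == "(all)", ]
    out$sen_frac_pooled <- pooled$fraction[match(donors, pooled$donor_id)]
    for (ct in setdiff(unique(fr$cell_type), "(all)")) {
      f <- fr[fr$cell_type == ct, ]
      out[[paste0("sen_frac_", ct)]] <- f$fraction[match(donors, f$donor_id)]
    }
  }
  structure(out, class = c("composition_table", "data.frame"))
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average (mid-) ranks for ties, Pearson correlation of the ranks, and a
#' two-sided p-value from the t distribution with n - 2 degrees of freedom.
#' Zero variance in either vector leaves rho undefined (`defined = FALSE`).
#'
#' @param x,y paired numeric vectors without missing values, length >= 4.
#' @return list with `rho`, `p`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: apply exclusions first", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

#' Bonferroni adjustment for a declared family of m tests
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param m family size (defaults to `length(pvals)`).
#' @return adjusted p-values `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, m * pvals)
}

#' Correlation scan of T-cell metrics against age and senescent burden
#'
#' Computes Spearman correlations between donor-level T-cell metrics
#' (subset proportions under both denominators and the immunological
#' indices) and targets (donor age, the pooled senescent fraction and
#' per-cell-type senescent fractions), with Bonferroni adjustment over the
#' scan as the declared family. Before each correlation the low-cell-count
#' exclusion rule ([exclude_low_count_samples()]) is applied to the donors:
#' T metrics are guarded by the total-T count and per-cell-type senescent
#' fraction targets by that cell type's count.
#'
#' @param composition a [subset_proportions()] table (with senescent
#'   fractions for burden targets).
#' @param metrics,targets column names to correlate; defaults cover the
#'   full scan.
#' @param exclude_low_counts apply the 2SD rule (default TRUE).
#' @param n_sd standard-deviation multiple for the exclusion rule.
#' @param min_donors pairs with fewer donors after exclusion are flagged
#'   `insufficient_n` and get NA statistics.
#' @return data.frame with one row per metric x target: `metric`, `target`,
#'   `n`, `rho`, `p`, `p_adj`, `m`, `excluded` (comma-separated donor ids),
#'   `defined`, `insufficient_n`.
#' @export
burden_association_scan <- function(composition,
                                    metrics = NULL, targets = NULL,
                                    exclude_low_counts = TRUE, n_sd = 2,
                                    min_donors = 4L) {
  comp <- as.data.frame(composition)
  if (is.null(metrics)) {
    metrics <- intersect(c("prop_Th_of_T", "prop_Tc_of_T", "prop_Treg_of_T",
                           "prop_Th_of_all", "prop_Tc_of_all", "prop_Treg_of_all",
                           "ratio_Th_Tc", "ratio_Treg_Tc", "ratio_Treg_Th"),
                         names(comp))
  }
  if (is.null(targets)) {
    targets <- intersect(c("age_years", "sen_frac_pooled",
                           grep("^sen_frac_(?!pooled)", names(comp),
                                value = TRUE, perl = TRUE)),
                         names(comp))
  }
  included_for <- function(var) {
    if (!exclude_low_counts) return(comp$donor_id)
    guard <- if (var %in% c("age_years")) NULL
      else if (startsWith(var, "sen_frac_") && var != "sen_frac_pooled")
        paste0("n_type_", sub("^sen_frac_", "", var))
      else "n_T"
    if (is.null(guard) || !guard %in% names(comp)) return(comp$donor_id)
    exclude_low_count_samples(stats::setNames(comp[[guard]], comp$donor_id),
                              n_sd = n_sd)
  }
  rows <- list()
  for (mt in metrics) for (tg in targets) {
    inc <- intersect(included_for(mt), included_for(tg))
    sub <- comp[comp$donor_id %in% inc, c("donor_id", mt, tg)]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    excluded <- setdiff(comp$donor_id, sub$donor_id)
    if (nrow(sub) < min_donors) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mt, target = tg, n = nrow(sub), rho = NA_real_, p = NA_real_,
        excluded = paste(excluded, collapse = ","), defined = FALSE,
        insufficient_n = TRUE, stringsAsFactors = FALSE)
      next
    }
    r <- spearman_cor(sub[[mt]], sub[[tg]])
    rows[[length(rows) + 1L]] <- data.frame(
      metric = mt, target = tg, n = r$n, rho = r$rho, p = r$p,
      excluded = paste(excluded, collapse = ","), defined = r$defined,
      insufficient_n = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$m <- nrow(out)
  out$p_adj <- bonferroni_adjust(out$p, m = out$m[1])
  out[, c("metric", "target", "n", "rho", "p", "p_adj", "m",
          "excluded", "defined", "insufficient_n")]
}
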
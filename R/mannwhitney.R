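#' Mann-Whitney U test (rank-sum), tie-aware
#'
#' Computes the U statistic of the first group from midranks and a
#' two-sided p-value from the normal approximation with tie correction and
#' continuity correction. With `exact = TRUE` and
#' `length(a) + length(b) <= max_exact_n` the p-value is obtained instead
#' by full enumeration of group assignments of the pooled values
#' (conditional on ties), as `2 * min(P(U <= u), P(U >= u))` capped at 1.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact request exact enumeration for small samples.
#' @param max_exact_n largest pooled size for which enumeration is allowed.
#' @return list with `U` (statistic of group `a`), `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact = FALSE, max_exact_n = 12L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (exact && N <= max_exact_n) {
    idx <- utils::combn(N, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  cc <- if (U == mu) 0 else 0.5
  z <- (U - mu - sign(U - mu) * cc) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment via [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
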
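#' Fit a one-dimensional Gaussian mixture to senescence scores
#'
#' Runs expectation-maximization for each candidate number of components,
#' restarting `n_init` times from seeded k-means++ initializations, and
#' selects K by the lowest BIC. Components are reported sorted by mean; a
#' fit whose means collapse onto each other is discarded in favour of the
#' next candidate K.
#'
#' @param scores numeric vector of per-cell scores (length >= `min_scores`,
#'   non-degenerate variance).
#' @param k_candidates candidate component counts (default 2 and 3).
#' @param seed integer seed for the restarts.
#' @param n_init number of EM restarts per K.
#' @param min_scores minimum number of scores required.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance, relative to `|loglik| + 1`.
#' @return list of class `senescence_gmm`: `k`, `weight`, `mean`, `var`
#'   (sorted by mean), `loglik`, `bic` (named per candidate K),
#'   `converged`, `n`, `seed`.
#' @export
fit_score_mixture <- function(scores, k_candidates = c(2L, 3L), seed = 1L,
                              n_init = 10L, min_scores = 50L,
                              max_iter = 300L, tol = 1e-6) {
  x <- as.numeric(scores)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < min_scores) {
    stop("need at least ", min_scores, " scores to fit a mixture; got ", n,
         call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("scores have zero variance; mixture fit is degenerate", call. = FALSE)
  }
  set.seed(seed)
  var_floor <- 1e-8 * stats::var(x)
  fits <- list()
  bics <- stats::setNames(rep(NA_real_, length(k_candidates)),
                          paste0("K", k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    best <- NULL
    for (r in seq_len(n_init)) {
      f <- .em_1d(x, k, max_iter, tol, var_floor)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    if (is.null(best)) next
    o <- order(best$mean)
    best$mean <- best$mean[o]; best$var <- best$var[o]; best$weight <- best$weight[o]
    # Collapsed components (indistinguishable means) invalidate the fit.
    if (any(diff(best$mean) < 1e-6 * stats::sd(x))) next
    npar <- 3 * k - 1
    bics[i] <- -2 * best$loglik + npar * log(n)
    best$k <- k
    fits[[paste0("K", k)]] <- best
  }
  if (!length(fits)) {
    stop("EM failed to produce a valid mixture for any candidate K ",
         "(n = ", n, ", sd = ", signif(stats::sd(x), 4), ")", call. = FALSE)
  }
  sel <- names(which.min(bics[names(fits)]))
  f <- fits[[sel]]
  structure(list(k = f$k, weight = f$weight, mean = f$mean, var = f$var,
                 loglik = f$loglik, bic = bics, converged = TRUE,
                 n = n, seed = seed),
            class = "senescence_gmm")
}

# One EM run for a K-component univariate normal mixture; returns NULL when
# the run degenerates (empty component).
.em_1d <- function(x, k, max_iter, tol, var_floor) {
  n <- length(x)
  mu <- .kmeanspp_1d(x, k)
  v <- rep(stats::var(x), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E step in log space for stability.
    lp <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sqrt(v[j]), log = TRUE),
      numeric(n))
    m <- apply(lp, 1L, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(weight = w, mean = mu, var = v, loglik = ll)
}

# k-means++ seeding in one dimension.
.kmeanspp_1d <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- vapply(x, function(xx) min((xx - centers[seq_len(j - 1L)])^2), numeric(1))
      if (sum(d2) == 0) {
        centers[j] <- x[sample.int(length(x), 1L)]
      } else {
        centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
      }
    }
  }
  centers + stats::rnorm(k, 0, 1e-6 * (stats::sd(x) + 1e-12))
}

#' Senescence decision threshold from a fitted mixture
#'
#' The threshold is the point between the means of the two rightmost
#' mixture components at which their weighted component densities are equal
#' (the posterior decision boundary restricted to that interval). When the
#' weighted densities do not cross inside the open inter-mean interval the
#' midpoint of the two means is returned with a warning.
#'
#' @param fit a [fit_score_mixture()] result with at least two components.
#' @return numeric threshold.
#' @export
senescence_threshold <- function(fit) {
  if (!inherits(fit, "senescence_gmm")) stop("not a 'senescence_gmm' fit", call. = FALSE)
  k <- fit$k
  if (k < 2L) stop("threshold needs at least two mixture components", call. = FALSE)
  i <- k - 1L; j <- k
  m1 <- fit$mean[i]; m2 <- fit$mean[j]
  g <- function(x) {
    log(fit$weight[i]) + stats::dnorm(x, m1, sqrt(fit$var[i]), log = TRUE) -
      log(fit$weight[j]) - stats::dnorm(x, m2, sqrt(fit$var[j]), log = TRUE)
  }
  eps <- 1e-9 * max(m2 - m1, 1)
  lo <- m1 + eps; hi <- m2 - eps
  if (g(lo) * g(hi) < 0) {
    stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  } else {
    warning("weighted component densities do not cross between the two ",
            "rightmost means; using their midpoint", call. = FALSE)
    (m1 + m2) / 2
  }
}

#' Call senescent cells from scores and a threshold
#'
#' A cell is senescent iff its score is strictly greater than the
#' threshold (a score exactly at the threshold is not senescent).
#'
#' @param scores named numeric per-cell scores (names are barcodes).
#' @param threshold decision threshold from [senescence_threshold()].
#' @param cell_type optional label stored with the calls.
#' @return data.frame of class `senescence_calls` with columns `barcode`,
#'   `cell_type`, `score`, `threshold`, `senescent`.
#' @export
call_senescent <- function(scores, threshold, cell_type = NA_character_) {
  structure(
    data.frame(barcode = if (is.null(names(scores)))
                 as.character(seq_along(scores)) else names(scores),
               cell_type = cell_type, score = as.numeric(scores),
               threshold = threshold,
               senescent = as.numeric(scores) > threshold,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("senescence_calls", "data.frame"))
}

#' Senescent-cell fractions per donor and cell type
#'
#' Joins calls to cell metadata by barcode and returns one row per donor x
#' cell type with the senescent fraction, plus one pooled row per donor
#' (`cell_type = "(all)"`) whose fraction is the senescent-count sum over
#' the cell-count sum across the called cell types.
#'
#' @param calls a `senescence_calls` data.frame (rows from several cell
#'   types may be concatenated with `rbind`).
#' @param metadata cell metadata (`barcode`, `donor_id`, `age_years`,
#'   `cell_type`) or a `SingleCellExperiment`.
#' @return data.frame with columns `donor_id`, `cell_type`, `age_years`,
#'   `n_cells`, `n_senescent`, `fraction`.
#' @export
senescent_fractions <- function(calls, metadata) {
  md <- .get_metadata_df(metadata)
  dat <- merge(as.data.frame(calls)[, c("barcode", "senescent")],
               md[, c("barcode", "donor_id", "age_years", "cell_type")],
               by = "barcode")
  if (!nrow(dat)) stop("no call barcodes match the metadata", call. = FALSE)
  per <- stats::aggregate(dat$senescent,
                          by = list(donor_id = dat$donor_id, cell_type = dat$cell_type),
                          FUN = function(z) c(n = length(z), k = sum(z)))
  per <- data.frame(donor_id = per$donor_id, cell_type = per$cell_type,
                    n_cells = per$x[, "n"], n_senescent = per$x[, "k"],
                    stringsAsFactors = FALSE)
  pooled <- stats::aggregate(dat$senescent, by = list(donor_id = dat$donor_id),
                             FUN = function(z) c(n = length(z), k = sum(z)))
  pooled <- data.frame(donor_id = pooled$donor_id, cell_type = "(all)",
                       n_cells = pooled$x[, "n"], n_senescent = pooled$x[, "k"],
                       stringsAsFactors = FALSE)
  out <- rbind(per, pooled)
  out$fraction <- out$n_senescent / out$n_cells
  ages <- md$age_years[match(out$donor_id, md$donor_id)]
  out <- data.frame(donor_id = out$donor_id, cell_type = out$cell_type,
                    age_years = ages, n_cells = out$n_cells,
                    n_senescent = out$n_senescent, fraction = out$fraction,
                    stringsAsFactors = FALSE)
  out[order(out$donor_id, out$cell_type), , drop = FALSE]
}
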
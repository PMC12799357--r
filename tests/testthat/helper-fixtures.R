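# Fixture builders and independent oracles used across the suite.
# The oracles deliberately re-derive every quantity from first principles
# (explicit loops, closed forms, enumeration) rather than calling package
# internals.

suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# Build a SingleCellExperiment from a dense genes x cells matrix and
# per-cell metadata vectors.
toy_sce <- function(counts, donor_id, age_years, cell_type,
                    barcodes = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(barcodes)) barcodes <- sprintf("cell%03d", seq_len(ncol(counts)))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(counts)))
  dimnames(counts) <- list(gene_ids, barcodes)
  SingleCellExperiment(
    assays = list(counts = as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(barcode = barcodes, donor_id = donor_id,
                                   age_years = age_years, cell_type = cell_type,
                                   batch = donor_id, row.names = barcodes))
}

# A small fast cohort configuration for unit tests.
small_config <- function(seed = 1, ...) {
  # baseline means raised so that ~300-gene cells still clear the 500-UMI cut
  sim_config(n_donors = 8, cell_types = c(Keratinocyte = 60, T = 80),
             n_genes = 300, program_size = 15, n_mito_genes = 3,
             baseline_expression = list(meanlog = log(1.2), sdlog = 1.5, size = 1),
             seed = seed, ...)
}

# Two-group (young/old) SCE in which chosen genes are expressed in an exact
# number of cells per group, so expressing fractions are exact.
frac_sce <- function(n_young = 50, n_old = 50, express_young, express_old) {
  genes <- names(express_young)
  m <- matrix(0, nrow = length(genes) + 1, ncol = n_young + n_old,
              dimnames = list(c(genes, "filler"), NULL))
  m["filler", ] <- 1   # keeps every cell nonzero
  for (g in genes) {
    if (express_young[g] > 0) m[g, seq_len(express_young[g])] <- 2
    if (express_old[g] > 0) m[g, n_young + seq_len(express_old[g])] <- 2
  }
  toy_sce(m, donor_id = rep(c("DY", "DO"), c(n_young, n_old)),
          age_years = rep(c(25, 70), c(n_young, n_old)),
          cell_type = "Tc", gene_ids = rownames(m))
}

# ---- independent oracles ---------------------------------------------------

# Spearman by explicit ranking and the Pearson product-moment formula on
# ranks, with the t-approximation p-value.
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i]); eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- num / den
  p <- if (abs(rho) >= 1) 0 else
    2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p = p)
}

# Mann-Whitney U by direct pair counting; exact two-sided p by enumerating
# every assignment of the pooled values to the first group.
oracle_mwu_exact <- function(a, b) {
  count_u <- function(aa, bb) {
    u <- 0
    for (x in aa) for (y in bb) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  U <- count_u(a, b)
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  Us <- apply(idx, 2, function(i) count_u(pool[i], pool[-i]))
  p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
  list(U = U, p = p)
}

# Benjamini-Hochberg by the step-up definition written out longhand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Hypergeometric upper tail by exhaustive enumeration of all draws of size
# n from a universe of size N containing K marked elements.
oracle_hyper_tail <- function(k, K, n, N) {
  idx <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(idx, 2, function(i) sum(i %in% marked)) >= k)
}

# Signature inclusion rule evaluated longhand per gene.
oracle_sig_include <- function(p_y, p_o, cr) {
  out <- logical(length(p_y))
  for (i in seq_along(p_y)) {
    young_ok <- p_y[i] < cr$young_max_frac
    old_ok <- p_o[i] > cr$old_min_frac && p_o[i] < cr$old_max_frac
    fold_ok <- if (p_y[i] == 0) TRUE else p_o[i] >= cr$min_fold * p_y[i]
    diff_ok <- (p_o[i] - p_y[i]) > cr$min_abs_diff
    out[i] <- young_ok && old_ok && (fold_ok || diff_ok)
  }
  out
}

# QC keep-mask evaluated longhand per cell (unscaled MAD on log1p totals and
# detected genes, two-sided; mito absolute + one-sided MAD).
oracle_qc_mask <- function(total, detected, mito, thr) {
  med_abs_dev <- function(v) stats::median(abs(v - stats::median(v)))
  lt <- log1p(total); ld <- log1p(detected)
  m_lt <- med_abs_dev(lt); m_ld <- med_abs_dev(ld); m_mi <- med_abs_dev(mito)
  keep <- logical(length(total))
  for (i in seq_along(total)) {
    ok <- total[i] >= thr$min_total_umi
    if (m_lt > 0) ok <- ok && abs(lt[i] - stats::median(lt)) <= thr$total_nmads * m_lt
    if (m_ld > 0) ok <- ok && abs(ld[i] - stats::median(ld)) <= thr$genes_nmads * m_ld
    ok <- ok && mito[i] <= thr$mito_max_pct
    if (m_mi > 0) ok <- ok && (mito[i] - stats::median(mito)) <= thr$mito_nmads * m_mi
    keep[i] <- ok
  }
  keep
}

# 2SD low-count exclusion by direct inequality.
oracle_low_count_included <- function(counts, n_sd = 2) {
  mu <- mean(counts)
  s <- sqrt(sum((counts - mu)^2) / length(counts))
  if (s == 0) rep(TRUE, length(counts)) else counts >= mu - n_sd * s
}
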
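test_that("signature selection follows the expressing-fraction criteria", {
  sce <- frac_sce(express_young = c(gIn = 1, gLowFold = 2, gTooYoung = 3),
                  express_old = c(gIn = 3, gLowFold = 4, gTooYoung = 5))
  sig <- derive_signature(sce, "Tc")
  inc <- setNames(sig$included, sig$gene)
  # p_y = 0.02, p_o = 0.06: fold 3 >= 2.5, 0.01 < 0.06 < 0.20, 0.02 < 0.05
  expect_true(inc[["gIn"]])
  # p_y = 0.04, p_o = 0.08: fold 2 < 2.5 and diff 0.04 <= 0.05
  expect_false(inc[["gLowFold"]])
  # p_y = 0.06 violates the young criterion regardless of fold
  expect_false(inc[["gTooYoung"]])
  expect_equal(attr(sig, "genes"), "gIn")
  expect_equal(sig$p_young[sig$gene == "gIn"], 0.02)
  expect_equal(sig$p_old[sig$gene == "gIn"], 0.06)
})

test_that("a never-expressed-in-young gene satisfies the fold rule by convention", {
  sce <- frac_sce(express_young = c(gZero = 0), express_old = c(gZero = 2))
  sig <- derive_signature(sce, "Tc")
  expect_true(sig$included[sig$gene == "gZero"])   # p_o = 0.04 > 0.01
  expect_equal(sig$fold[sig$gene == "gZero"], Inf)
})

test_that("signature inclusion matches the brute-force rule on random fractions", {
  set.seed(33)
  cr <- signature_criteria()
  for (rep in 1:6) {
    n_y <- sample(40:80, 1); n_o <- sample(40:80, 1)
    genes <- sprintf("g%03d", 1:80)
    ey <- setNames(rbinom(80, n_y, runif(80, 0, 0.12)), genes)
    eo <- setNames(rbinom(80, n_o, runif(80, 0, 0.3)), genes)
    sce <- frac_sce(n_y, n_o, ey, eo)
    sig <- suppressWarnings(derive_signature(sce, "Tc", cr))
    sig <- sig[sig$gene != "filler", ]
    want <- oracle_sig_include(ey[sig$gene] / n_y, eo[sig$gene] / n_o, cr)
    expect_identical(sig$included, want)
  }
})

test_that("signature derivation names the missing donor group", {
  sce <- frac_sce(express_young = c(g = 1), express_old = c(g = 3))
  old_only <- signature_criteria(young_max_age = 20, old_min_age = 55)
  expect_error(derive_signature(sce, "Tc", old_only), "young")
  young_only <- signature_criteria(young_max_age = 30, old_min_age = 80)
  expect_error(derive_signature(sce, "Tc", young_only), "old")
  expect_error(derive_signature(sce, "Keratinocyte"), "Keratinocyte")
})

test_that("scoring is deterministic and separates true senescent cells", {
  for (s in c(3, 14)) {
    sce <- simulate_cohort(small_config(seed = s))
    sce <- normalize_log(sce)
    sig <- derive_signature(sce, "Keratinocyte")
    sc1 <- score_cells(sce, sig)
    sc2 <- score_cells(sce, sig)
    expect_identical(sc1, sc2)
    truth <- sce$senescent_true[match(names(sc1), colnames(sce))]
    expect_gt(mean(sc1[truth]), mean(sc1[!truth]))
  }
})

test_that("cells expressing no signature gene score at or below the mean", {
  m <- matrix(0, nrow = 3, ncol = 40,
              dimnames = list(c("sig1", "sig2", "base"), NULL))
  m["base", ] <- 5
  m["sig1", 1:4] <- 6; m["sig2", 1:4] <- 4
  sce <- normalize_log(toy_sce(m, donor_id = "D1", age_years = 40,
                               cell_type = "Tc", gene_ids = rownames(m)))
  sc <- score_cells(sce, c("sig1", "sig2"), cell_type = "Tc")
  expect_true(all(sc[5:40] <= 0))
  expect_equal(unname(sc[5]), unname(sc[6]))   # identical cells, identical score
})

test_that("missing signature genes are dropped with a warning", {
  sce <- normalize_log(simulate_cohort(small_config(seed = 5)))
  sig_genes <- S4Vectors::metadata(sce)$truth$programs$Keratinocyte$genes
  expect_warning(sc <- score_cells(sce, c(sig_genes, "NOT_A_GENE"),
                                   cell_type = "Keratinocyte"), "absent")
  expect_error(score_cells(sce, c("NOPE1", "NOPE2"), cell_type = "Keratinocyte"),
               "no signature gene")
})

test_that("mixture fitting recovers a well-separated two-component mixture", {
  set.seed(2)
  x <- c(rnorm(1000, 0, 1), rnorm(1000, 6, 1))
  fit <- fit_score_mixture(x, seed = 1)
  expect_equal(fit$k, 2L)
  expect_lt(max(abs(fit$mean - c(0, 6))), 0.2)
  expect_lt(max(abs(fit$weight - 0.5)), 0.05)
  expect_true(fit$converged)
  expect_equal(sum(fit$weight), 1)
  expect_true(all(fit$var > 0))
  if (requireNamespace("mclust", quietly = TRUE)) {
    suppressPackageStartupMessages(require(mclust, quietly = TRUE))
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_lt(max(abs(sort(fit$mean) - sort(as.numeric(mc$parameters$mean)))), 0.05)
  }
})

test_that("degenerate score vectors are rejected", {
  expect_error(fit_score_mixture(rep(1, 200)), "zero variance")
  expect_error(fit_score_mixture(rnorm(10)), "at least 50")
})

test_that("a unimodal score distribution falls back to the inter-mean midpoint", {
  # On a single N(0,1) the two fitted components overlap heavily and their
  # weighted densities do not cross between the means, so the threshold is
  # the documented midpoint fallback (with a warning); the flagged fraction
  # is then bounded by the mass right of the lower mean, not a tiny tail.
  set.seed(5)
  x <- rnorm(2000)
  fit <- fit_score_mixture(x, seed = 3)
  expect_warning(thr <- senescence_threshold(fit), "midpoint")
  k <- fit$k
  expect_equal(thr, mean(fit$mean[(k - 1):k]))
  expect_lt(mean(x > thr), mean(x > fit$mean[k - 1]) + 1e-9)
})

test_that("the threshold sits at the weighted-density crossing", {
  mk_fit <- function(w, m, v) {
    structure(list(k = length(m), weight = w, mean = m, var = v,
                   loglik = NA, bic = NA, converged = TRUE, n = 1000, seed = 1),
              class = "senescence_gmm")
  }
  # equal weights, equal variances: the crossing is the midpoint
  expect_equal(senescence_threshold(mk_fit(c(.5, .5), c(0, 6), c(1, 1))), 3)
  # K = 3: only the two rightmost components matter
  expect_equal(senescence_threshold(mk_fit(c(.2, .4, .4), c(-3, 4, 8), c(1, 1, 1))), 6)
  # unequal weights: analytic root of the weighted-density equality
  thr <- senescence_threshold(mk_fit(c(.9, .1), c(0, 6), c(1, 1)))
  analytic <- (18 + log(9)) / 6   # solve .9 phi(x) = .1 phi(x - 6)
  expect_gt(thr, 3)
  expect_equal(thr, analytic, tolerance = 1e-9)
  expect_error(senescence_threshold(mk_fit(1, 0, 1)), "two")
})

test_that("threshold and calls are invariant under affine rescaling of scores", {
  set.seed(9)
  x <- c(rnorm(600, 0, 1), rnorm(200, 5, 1.3))
  a <- 2.5; b <- -7
  f1 <- fit_score_mixture(x, seed = 4)
  f2 <- fit_score_mixture(a * x + b, seed = 4)
  expect_equal(f2$k, f1$k)
  expect_equal(f2$mean, a * f1$mean + b, tolerance = 1e-3)
  t1 <- senescence_threshold(f1); t2 <- senescence_threshold(f2)
  expect_equal(t2, a * t1 + b, tolerance = 5e-3)
  expect_identical(call_senescent(a * x + b, t2)$senescent,
                   call_senescent(x, t1)$senescent)
})

test_that("calls use a strict inequality at the threshold", {
  calls <- call_senescent(c(a = 0.9, b = 1.0, c = 1.1), threshold = 1.0)
  expect_identical(calls$senescent, c(FALSE, FALSE, TRUE))
  none <- call_senescent(c(0.1, 0.2), threshold = 5)
  expect_equal(mean(none$senescent), 0)
})

test_that("senescent fractions aggregate correctly, with a pooled identity", {
  md <- data.frame(barcode = sprintf("c%03d", 1:160),
                   donor_id = rep(c("D1", "D2"), each = 80),
                   age_years = rep(c(25, 70), each = 80),
                   cell_type = rep(c("Th", "Tc"), 80))
  sen <- rep(FALSE, 160)
  sen[md$donor_id == "D1" & md$cell_type == "Th"][1:4] <- TRUE   # 4 of 40
  sen[md$donor_id == "D2"][1:10] <- TRUE
  calls <- data.frame(barcode = md$barcode, senescent = sen)
  fr <- senescent_fractions(calls, md)
  expect_equal(fr$fraction[fr$donor_id == "D1" & fr$cell_type == "Th"], 0.1)
  expect_equal(fr$fraction[fr$donor_id == "D1" & fr$cell_type == "Tc"], 0)
  pooled <- fr[fr$cell_type == "(all)", ]
  for (d in c("D1", "D2")) {
    per <- fr[fr$donor_id == d & fr$cell_type != "(all)", ]
    expect_equal(pooled$fraction[pooled$donor_id == d],
                 sum(per$n_senescent) / sum(per$n_cells))
  }
})
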
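test_that("mann-whitney reproduces the small exact example", {
  # a = (1,2), b = (3,4): U_a = 0; 6 assignments, two-sided exact p = 1/3
  r <- mann_whitney_u(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")
})

test_that("identical groups give the null U and p near 1", {
  a <- c(1, 2, 3, 4, 5)
  r <- mann_whitney_u(a, a)
  expect_equal(r$U, length(a)^2 / 2)
  expect_equal(r$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact p equals the enumeration oracle on random small instances", {
  set.seed(101)
  for (i in 1:120) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(1:5, na + nb, replace = TRUE)   # ties likely
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    got <- mann_whitney_u(a, b, exact = TRUE)
    want <- oracle_mwu_exact(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("the normal approximation matches the reference implementation", {
  set.seed(7)
  for (i in 1:40) {
    a <- rnorm(sample(15:40, 1)); b <- rnorm(sample(15:40, 1), 0.5)
    got <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    got <- bh_fdr(p)
    expect_equal(got, oracle_bh(p), tolerance = 1e-12)
    # monotone in the order of sorted p
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
})

# Small two-age-group cohort with hand-planted expression patterns.
deg_fixture <- function() {
  n_o <- 100; n_y <- 100
  set.seed(202)
  genes <- c("up_clean", "up_but_broad", "flat", "rare")
  m <- matrix(0, nrow = length(genes) + 1, ncol = n_o + n_y,
              dimnames = list(c(genes, "base"), NULL))
  m["base", ] <- 10
  old <- seq_len(n_o); young <- n_o + seq_len(n_y)
  m["up_clean", old[1:20]] <- 5                  # 20 % of old, 0 % of young
  m["up_but_broad", old] <- 4                    # up in old ...
  m["up_but_broad", young[1:60]] <- 2            # ... but 60 % of young express
  m["flat", c(old[1:30], young[1:30])] <- 3
  m["rare", old[1:5]] <- 8                       # only 5 % of old
  sce <- toy_sce(m, donor_id = rep(c("DO", "DY"), c(n_o, n_y)),
                 age_years = rep(c(70, 25), c(n_o, n_y)),
                 cell_type = "Treg", gene_ids = rownames(m))
  normalize_log(sce)
}

test_that("DEG pass flags apply all three criteria per direction", {
  degs <- find_degs(deg_fixture(), "Treg")
  old_rows <- degs[degs$target == "old", ]
  row <- function(g) old_rows[old_rows$gene == g, ]
  expect_true(row("up_clean")$pass)
  expect_lt(row("up_clean")$fdr, 0.01)
  expect_false(row("up_but_broad")$pass)         # comparison group at 60 % > 50 %
  expect_gte(row("up_but_broad")$frac_other, 0.5)
  expect_false(row("flat")$pass)                 # no signal
  expect_false(row("rare")$pass)                 # 5 % < 10 % target presence
  young_rows <- degs[degs$target == "young", ]
  expect_false(young_rows$pass[young_rows$gene == "up_clean"])
})

test_that("DEG errors name the subset and missing group", {
  sce <- deg_fixture()
  expect_error(find_degs(sce, "Tc"), "Tc")
  old_only <- sce[, sce$age_years >= 55]
  expect_error(find_degs(old_only, "Treg"), "young")
})

test_that("the pass set equals a brute-force three-rule evaluation", {
  sce <- normalize_log(simulate_cohort(small_config(seed = 23)))
  cr <- deg_criteria()
  degs <- find_degs(sce, "Th", cr)
  md <- as.data.frame(colData(sce))
  old <- colnames(sce)[md$cell_type == "Th" & md$age_years >= cr$old_min_age]
  young <- colnames(sce)[md$cell_type == "Th" & md$age_years <= cr$young_max_age]
  raw <- as.matrix(counts(sce)); lc <- as.matrix(assay(sce, "logcounts"))
  p_ref <- vapply(rownames(sce), function(g) suppressWarnings(
    stats::wilcox.test(lc[g, old], lc[g, young], exact = FALSE,
                       correct = TRUE)$p.value), numeric(1))
  p_ref[!is.finite(p_ref)] <- 1   # no variation carries no evidence
  fdr_ref <- setNames(oracle_bh(p_ref), names(p_ref))
  for (target in c("old", "young")) {
    tgt <- if (target == "old") old else young
    oth <- if (target == "old") young else old
    sub <- degs[degs$target == target, ]
    for (g in sample(rownames(sce), 60)) {
      ft <- mean(raw[g, tgt] > 0); fo <- mean(raw[g, oth] > 0)
      want <- fdr_ref[[g]] < cr$fdr_max && ft > cr$min_frac_target &&
        fo < cr$max_frac_other && mean(lc[g, tgt]) > mean(lc[g, oth])
      expect_equal(sub$pass[sub$gene == g], want)
      expect_equal(sub$frac_target[sub$gene == g], ft)
      expect_equal(sub$fdr[sub$gene == g], fdr_ref[[g]], tolerance = 1e-9)
    }
  }
})

test_that("planted old-specific program genes are recovered", {
  sce <- normalize_log(simulate_cohort(sim_config(
    n_donors = 12, age_range = c(20, 75), cell_types = c(T = 150),
    n_genes = 400, program_size = 25, f_young = 0.01, f_old = 0.35,
    expr_prob = 0.6, boost_mean = 3, seed = 31)))
  degs <- find_degs(sce, "Th")
  planted <- S4Vectors::metadata(sce)$truth$programs$Th$genes
  passed <- degs$gene[degs$target == "old" & degs$pass]
  expect_gte(mean(planted %in% passed), 0.8)
  null_genes <- setdiff(rownames(sce), planted)
  expect_lte(mean(null_genes %in% passed), 0.02)
})

test_that("hypergeometric ORA matches the closed-form tail", {
  # N = 10, K = 5, n = 4, k = 4: p = C(5,4) C(5,0) / C(10,4) = 5/210
  uni <- sprintf("g%02d", 1:10)
  sets <- list(s = uni[1:5])
  enr <- ora_hypergeometric(uni[1:4], uni, sets, min_size = 1, max_size = 100)
  expect_equal(enr$k, 4)
  expect_equal(enr$p, 5 / 210, tolerance = 1e-12)
  # a whole-universe set always gives p = 1
  enr2 <- ora_hypergeometric(uni[1:4], uni, list(all = uni),
                             min_size = 1, max_size = 100)
  expect_equal(enr2$p, 1)
})

test_that("ORA equals exhaustive enumeration on tiny universes", {
  set.seed(90)
  for (i in 1:40) {
    N <- sample(6:12, 1)
    uni <- sprintf("g%02d", seq_len(N))
    K <- sample(2:(N - 1), 1); n <- sample(2:(N - 1), 1)
    sets <- list(s = uni[seq_len(K)])
    query <- sample(uni, n)
    enr <- ora_hypergeometric(query, uni, sets, min_size = 1, max_size = 20)
    want <- oracle_hyper_tail(enr$k, K, n, N)
    expect_equal(enr$p, want, tolerance = 1e-10)
  }
})

test_that("ORA is invariant to gene relabelling and validates its inputs", {
  set.seed(3)
  uni <- sprintf("g%02d", 1:30)
  sets <- list(a = uni[1:12], b = uni[10:25])
  q <- uni[c(1:6, 20)]
  e1 <- ora_hypergeometric(q, uni, sets, min_size = 5, max_size = 50)
  perm <- setNames(sample(uni), uni)   # relabel every gene
  e2 <- ora_hypergeometric(unname(perm[q]), unname(perm[uni]),
                           lapply(sets, function(s) unname(perm[s])),
                           min_size = 5, max_size = 50)
  expect_equal(e1$p, e2$p)
  expect_equal(e1$k, e2$k)
  expect_warning(ora_hypergeometric(c(q, "alien"), uni, sets,
                                    min_size = 5, max_size = 50), "outside")
  expect_error(ora_hypergeometric(character(0), uni, sets), "empty query")
  # sets outside the size bounds are dropped
  e3 <- ora_hypergeometric(q, uni, c(sets, list(tiny = uni[1:2])),
                           min_size = 5, max_size = 50)
  expect_false("tiny" %in% e3$set)
})
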
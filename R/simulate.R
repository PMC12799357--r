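#' Configuration for a synthetic multi-donor skin scRNA-seq cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults describe a cohort of 32 donors spanning ages 18-76 with
#' keratinocytes, fibroblasts and a T-cell pool split into helper (Th),
#' cytotoxic (Tc) and regulatory (Treg) subsets, sparse negative-binomial
#' UMI counts, and one senescence program per cell type whose
#' expressing-cell fraction rises linearly with donor age.
#'
#' @param n_donors number of donors (>= 2).
#' @param age_range numeric length-2, youngest and oldest donor age in years.
#' @param cell_types named numeric vector of mean cells per donor for each
#'   top-level cell type. The entry named `"T"` is a pool that is split into
#'   `t_subsets`.
#' @param cell_type_dispersion negative-binomial size parameter for the
#'   cells-per-donor draw (larger = less dispersed).
#' @param t_subsets named numeric baseline proportions of the T pool for
#'   labels `Th`, `Tc`, `Treg`; must sum to 1.
#' @param n_genes number of non-mitochondrial genes.
#' @param n_mito_genes number of mitochondrial genes (features named
#'   `MT-1`, `MT-2`, ...), used to exercise the mitochondrial QC rule.
#' @param baseline_expression list with `meanlog`, `sdlog` (lognormal
#'   distribution of per-gene mean counts) and `size` (per-gene NB
#'   dispersion).
#' @param senescence_programs optional named list (one entry per terminal
#'   cell type) of lists with elements `genes`, `f_young`, `f_old`,
#'   `expr_prob`, `boost_mean`. When `NULL`, a disjoint program of
#'   `program_size` genes per terminal cell type is built with the shared
#'   `f_young`/`f_old`/`expr_prob`/`boost_mean` below.
#' @param program_size genes per auto-built senescence program.
#' @param f_young,f_old probability that a cell is senescent for a donor at
#'   the youngest / oldest age; interpolated linearly in age between them.
#'   Must satisfy `f_old > f_young >= 0`.
#' @param expr_prob probability that a given program gene is switched on in
#'   a senescent cell.
#' @param boost_mean mean UMI count of a switched-on program gene (counts
#'   are `1 + NB(boost_mean - 1)`, so switched-on genes are always detected).
#' @param program_background_rate expressing-cell fraction of program genes
#'   outside senescent cells (sets their baseline NB mean).
#' @param burden_composition_effect slope linking a donor's (age-expected,
#'   centred) senescent burden to Th/Treg proportions on the log scale of
#'   the subset weights: Treg is shifted up and Th down by
#'   `slope * centred_burden` before renormalization. 0 disables the effect.
#' @param batch_effect_sd standard deviation of the per-donor log-normal
#'   library size factor.
#' @param age_sampling `"even"` (evenly spaced ages, default) or
#'   `"uniform"` (random draws within `age_range`).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 32L,
                       age_range = c(18, 76),
                       cell_types = c(Keratinocyte = 120, Fibroblast = 80, T = 100),
                       cell_type_dispersion = 10,
                       t_subsets = c(Th = 0.45, Tc = 0.40, Treg = 0.15),
                       n_genes = 1000L,
                       n_mito_genes = 5L,
                       baseline_expression = list(meanlog = log(0.3), sdlog = 1.5, size = 1),
                       senescence_programs = NULL,
                       program_size = 30L,
                       f_young = 0.02,
                       f_old = 0.30,
                       expr_prob = 0.5,
                       boost_mean = 3,
                       program_background_rate = 0.01,
                       burden_composition_effect = 4,
                       batch_effect_sd = 0.1,
                       age_sampling = c("even", "uniform"),
                       seed = 1L) {
  age_sampling <- match.arg(age_sampling)
  cfg <- list(n_donors = as.integer(n_donors), age_range = as.numeric(age_range),
              cell_types = cell_types, cell_type_dispersion = cell_type_dispersion,
              t_subsets = t_subsets, n_genes = as.integer(n_genes),
              n_mito_genes = as.integer(n_mito_genes),
              baseline_expression = baseline_expression,
              senescence_programs = senescence_programs,
              program_size = as.integer(program_size),
              f_young = f_young, f_old = f_old, expr_prob = expr_prob,
              boost_mean = boost_mean,
              program_background_rate = program_background_rate,
              burden_composition_effect = burden_composition_effect,
              batch_effect_sd = batch_effect_sd, age_sampling = age_sampling,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  .check(config$n_donors >= 2L, "n_donors", "need at least 2 donors")
  .check(length(config$age_range) == 2L && config$age_range[1] < config$age_range[2],
         "age_range", "min age must be below max age")
  .check(length(config$cell_types) >= 1L && !is.null(names(config$cell_types)) &&
           all(nzchar(names(config$cell_types))) && all(config$cell_types > 0),
         "cell_types", "named positive mean cells-per-donor required")
  .check(all(config$t_subsets >= 0 & config$t_subsets <= 1),
         "t_subsets", "proportions must lie in [0, 1]")
  .check(abs(sum(config$t_subsets) - 1) < 1e-8,
         "t_subsets", "proportions of the T pool must sum to 1")
  .check(config$n_genes >= 1L, "n_genes", "need at least 1 gene")
  .check(config$n_mito_genes >= 0L, "n_mito_genes", "must be non-negative")
  progs <- .sim_programs(config)
  for (nm in names(progs)) {
    p <- progs[[nm]]
    .check(p$f_young >= 0 && p$f_old > p$f_young,
           "senescence_programs",
           sprintf("program '%s' needs f_old > f_young >= 0", nm))
    .check(p$f_old <= 1 && p$expr_prob >= 0 && p$expr_prob <= 1,
           "senescence_programs",
           sprintf("program '%s' proportions must lie in [0, 1]", nm))
  }
  .check(config$batch_effect_sd >= 0, "batch_effect_sd", "must be non-negative")
  .check(config$program_background_rate >= 0 && config$program_background_rate < 1,
         "program_background_rate", "must lie in [0, 1)")
  invisible(config)
}

# Terminal cell-type labels: the "T" pool expands into its subsets.
.terminal_types <- function(config) {
  tt <- names(config$cell_types)
  if ("T" %in% tt) tt <- c(setdiff(tt, "T"), names(config$t_subsets))
  tt
}

# Resolve the senescence program list, auto-building default programs
# (disjoint gene blocks, shared parameters) when none are supplied.
.sim_programs <- function(config) {
  if (!is.null(config$senescence_programs)) return(config$senescence_programs)
  types <- .terminal_types(config)
  n_needed <- length(types) * config$program_size
  if (n_needed > config$n_genes) {
    stop("invalid 'program_size': default programs need ", n_needed,
         " genes but n_genes = ", config$n_genes, call. = FALSE)
  }
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  progs <- vector("list", length(types))
  names(progs) <- types
  for (i in seq_along(types)) {
    idx <- ((i - 1L) * config$program_size + 1L):(i * config$program_size)
    progs[[i]] <- list(genes = gene_ids[idx],
                       f_young = config$f_young, f_old = config$f_old,
                       expr_prob = config$expr_prob,
                       boost_mean = config$boost_mean)
  }
  progs
}

#' Simulate a multi-donor scRNA-seq cohort with known senescence ground truth
#'
#' Draws donor ages across `age_range`, assigns each cell a donor, cell type
#' and latent senescent flag (Bernoulli with probability interpolating
#' `f_young` to `f_old` linearly in age), and emits sparse negative-binomial
#' UMI counts in which each senescence-program gene is switched on with
#' probability `expr_prob` in senescent cells (count `1 + NB(boost_mean - 1)`)
#' and detected at `program_background_rate` otherwise. T-subset proportions
#' may be tilted by the donor's senescent burden on the log-weight scale
#' (`burden_composition_effect`). The per-donor log-normal size factor
#' (`batch_effect_sd`) acts as a batch effect on all genes.
#'
#' @param config a [sim_config()] object.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (genes x cells), `colData` columns `donor_id`, `age_years`,
#'   `cell_type`, `batch` and the ground-truth flag `senescent_true`, and
#'   `metadata()` entries `truth` (donor-level true senescent fractions,
#'   true subset proportions, program gene lists, per-donor burden) and
#'   `config`.
#' @examples
#' sce <- simulate_cohort(sim_config(n_donors = 4, n_genes = 60,
#'                                   program_size = 10, seed = 1))
#' table(sce$cell_type)
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_d <- config$n_donors
  donors <- sprintf("D%02d", seq_len(n_d))
  ages <- switch(config$age_sampling,
                 even = seq(config$age_range[1], config$age_range[2], length.out = n_d),
                 uniform = sort(stats::runif(n_d, config$age_range[1], config$age_range[2])))
  size_factor <- exp(stats::rnorm(n_d, 0, config$batch_effect_sd))

  be <- config$baseline_expression
  n_g <- config$n_genes + config$n_mito_genes
  gene_ids <- c(sprintf("GENE%04d", seq_len(config$n_genes)),
                if (config$n_mito_genes > 0L) sprintf("MT-%d", seq_len(config$n_mito_genes)))
  mu_g <- stats::rlnorm(n_g, be$meanlog, be$sdlog)
  names(mu_g) <- gene_ids

  progs <- .sim_programs(config)
  prog_genes_all <- unique(unlist(lapply(progs, `[[`, "genes")))
  missing_pg <- setdiff(prog_genes_all, gene_ids)
  if (length(missing_pg)) {
    stop("invalid 'senescence_programs': unknown gene id(s) ",
         paste(utils::head(missing_pg, 3), collapse = ", "), call. = FALSE)
  }
  # Background NB mean giving P(count > 0) ~= program_background_rate at the
  # configured dispersion (solved for the size-1 geometric case, adequate for
  # the small rates used here).
  bg <- config$program_background_rate
  mu_g[prog_genes_all] <- bg / (1 - bg)

  # Age-linear senescent probability per terminal type.
  rel_age <- (ages - config$age_range[1]) / diff(config$age_range)
  types <- .terminal_types(config)
  p_sen <- sapply(types, function(tt) {
    pr <- progs[[tt]]
    if (is.null(pr)) rep(0, n_d) else pr$f_young + (pr$f_old - pr$f_young) * rel_age
  })
  p_sen <- matrix(p_sen, nrow = n_d, dimnames = list(donors, types))

  # Expected cells per donor per terminal type (for the burden expectation
  # and the composition tilt), before the stochastic count draw.
  exp_cells <- numeric(length(types))
  names(exp_cells) <- types
  for (tt in names(config$cell_types)) {
    if (tt == "T") {
      exp_cells[names(config$t_subsets)] <- config$cell_types[["T"]] * config$t_subsets
    } else {
      exp_cells[tt] <- config$cell_types[[tt]]
    }
  }
  burden <- as.numeric(p_sen %*% exp_cells / sum(exp_cells))
  names(burden) <- donors
  cburden <- burden - mean(burden)

  # Donor-specific T-subset proportions: burden tilt on the log-weight scale.
  slope <- config$burden_composition_effect
  subset_props <- t(vapply(seq_len(n_d), function(d) {
    eta <- log(config$t_subsets)
    if ("Treg" %in% names(eta)) eta["Treg"] <- eta["Treg"] + slope * cburden[d]
    if ("Th" %in% names(eta)) eta["Th"] <- eta["Th"] - slope * cburden[d]
    w <- exp(eta)
    w / sum(w)
  }, numeric(length(config$t_subsets))))
  dimnames(subset_props) <- list(donors, names(config$t_subsets))

  blocks <- vector("list", n_d)
  meta <- vector("list", n_d)
  for (d in seq_len(n_d)) {
    n_per_type <- stats::rnbinom(length(config$cell_types),
                                 mu = config$cell_types,
                                 size = config$cell_type_dispersion)
    names(n_per_type) <- names(config$cell_types)
    cell_type <- character(0)
    for (tt in names(n_per_type)) {
      if (tt == "T") {
        if (n_per_type[[tt]] > 0) {
          ns <- as.integer(stats::rmultinom(1, n_per_type[[tt]], subset_props[d, ]))
          cell_type <- c(cell_type, rep(colnames(subset_props), ns))
        }
      } else {
        cell_type <- c(cell_type, rep(tt, n_per_type[[tt]]))
      }
    }
    n_c <- length(cell_type)
    if (n_c == 0L) {
      blocks[[d]] <- NULL
      meta[[d]] <- NULL
      next
    }
    sen <- stats::rbinom(n_c, 1L, p_sen[d, cell_type]) == 1L
    m <- matrix(stats::rnbinom(n_g * n_c, mu = mu_g * size_factor[d], size = be$size),
                nrow = n_g, dimnames = list(gene_ids, NULL))
    # Overlay senescence-program expression in senescent cells.
    for (tt in unique(cell_type[sen])) {
      pr <- progs[[tt]]
      if (is.null(pr)) next
      cells <- which(sen & cell_type == tt)
      on <- matrix(stats::rbinom(length(pr$genes) * length(cells), 1L, pr$expr_prob) == 1L,
                   nrow = length(pr$genes))
      k <- sum(on)
      if (k > 0) {
        vals <- 1L + stats::rnbinom(k, mu = max(pr$boost_mean - 1, 1e-8), size = be$size)
        sub <- m[pr$genes, cells, drop = FALSE]
        sub[on] <- vals
        m[pr$genes, cells] <- sub
      }
    }
    blocks[[d]] <- methods::as(m, "CsparseMatrix")
    meta[[d]] <- data.frame(donor_id = donors[d], age_years = ages[d],
                            cell_type = cell_type, batch = donors[d],
                            senescent_true = sen,
                            stringsAsFactors = FALSE)
  }
  keep <- !vapply(blocks, is.null, logical(1))
  counts <- do.call(cbind, blocks[keep])
  cmeta <- do.call(rbind, meta[keep])
  cmeta$barcode <- sprintf("%s-%05d", cmeta$donor_id, stats::ave(
    seq_len(nrow(cmeta)), cmeta$donor_id, FUN = seq_along))
  colnames(counts) <- cmeta$barcode

  # Donor-level realized truth, consistent with the emitted cells.
  agg <- stats::aggregate(cmeta$senescent_true,
                          by = list(donor_id = cmeta$donor_id, cell_type = cmeta$cell_type),
                          FUN = function(z) c(frac = mean(z), n = length(z)))
  donor_frac <- data.frame(donor_id = agg$donor_id, cell_type = agg$cell_type,
                           true_fraction = agg$x[, "frac"], n_cells = agg$x[, "n"],
                           stringsAsFactors = FALSE)
  pooled <- stats::aggregate(cmeta$senescent_true, by = list(donor_id = cmeta$donor_id),
                             FUN = mean)
  truth <- list(donor_fraction = donor_frac,
                pooled_fraction = stats::setNames(pooled$x, pooled$donor_id),
                subset_proportions = subset_props,
                programs = progs,
                expected_burden = burden,
                donor_ages = stats::setNames(ages, donors))

  rd <- DataFrame(gene_id = gene_ids,
                  is_mito = startsWith(gene_ids, "MT-"),
                  program = NA_character_, row.names = gene_ids)
  for (tt in names(progs)) rd$program[gene_ids %in% progs[[tt]]$genes] <- tt

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cmeta[, c("barcode", "donor_id", "age_years",
                                  "cell_type", "batch", "senescent_true")],
                        row.names = cmeta$barcode),
    rowData = rd)
  S4Vectors::metadata(sce)$truth <- truth
  S4Vectors::metadata(sce)$config <- config
  sce
}
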
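#' Configuration for the end-to-end pipeline
#'
#' Collects the per-stage settings with the published defaults: the QC
#' thresholds (minimum 500 UMIs, 5 MADs on totals and detected genes, 15 %
#' mitochondrial ceiling with a 4 MAD rule), the library-size target of
#' 10,000 UMIs, the signature selection criteria (young < 5 %, old in
#' (1 %, 20 %), 2.5-fold or > 5 % absolute increase), mixture settings
#' (2 or 3 components), the DEG filters (FDR < 0.01, target > 10 %,
#' comparison < 50 %) and the ORA set-size bounds.
#'
#' @param qc a [qc_thresholds()] object.
#' @param target_sum normalization target library size.
#' @param mito_genes mitochondrial gene prefix or id vector.
#' @param signature a [signature_criteria()] object.
#' @param gmm_k,gmm_n_init,gmm_min_scores mixture candidate K values,
#'   restarts per K, and the minimum number of scores per cell type.
#' @param deg a [deg_criteria()] object.
#' @param deg_subsets cell-type labels tested for differential expression.
#' @param t_subsets T-subset labels used by the composition stage.
#' @param ora_min_size,ora_max_size gene-set size bounds for ORA.
#' @param gmt_file optional path to a GMT collection; when `NULL` the ORA
#'   stage is skipped.
#' @param exclude_barcodes optional barcodes removed before QC (e.g. an
#'   external doublet list).
#' @param min_cells_per_type cell types with fewer cells are skipped in the
#'   signature/calling stages.
#' @param seed global seed fanned out to the per-stage seeds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(), target_sum = 1e4,
                            mito_genes = "MT-",
                            signature = signature_criteria(),
                            gmm_k = c(2L, 3L), gmm_n_init = 10L,
                            gmm_min_scores = 50L,
                            deg = deg_criteria(),
                            deg_subsets = c("Th", "Tc", "Treg"),
                            t_subsets = c("Th", "Tc", "Treg"),
                            ora_min_size = 10L, ora_max_size = 500L,
                            gmt_file = NULL,
                            exclude_barcodes = NULL,
                            min_cells_per_type = 50L,
                            seed = 1L) {
  structure(list(qc = qc, target_sum = target_sum, mito_genes = mito_genes,
                 signature = signature, gmm_k = gmm_k, gmm_n_init = gmm_n_init,
                 gmm_min_scores = gmm_min_scores, deg = deg,
                 deg_subsets = deg_subsets, t_subsets = t_subsets,
                 ora_min_size = ora_min_size, ora_max_size = ora_max_size,
                 gmt_file = gmt_file, exclude_barcodes = exclude_barcodes,
                 min_cells_per_type = min_cells_per_type,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Deterministic per-stage seed derived from the global seed and a stage
# counter, kept within 32-bit integer range.
.stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 7919 * stage_index) %% .Machine$integer.max)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full senescence/composition pipeline
#'
#' Executes QC, normalization, signature derivation, per-cell scoring and
#' GMM-based senescent-cell calling for every sufficiently large cell type,
#' donor-level composition and correlation scans, differential expression
#' per T subset and (when a GMT collection is configured)
#' over-representation analysis. All result tables are written as TSV under
#' `out_dir` together with a JSON run manifest holding the configuration
#' hash, per-stage seeds, output checksums and collected warnings. A stage
#' failure aborts with the stage name and leaves a `FAILED` marker file.
#'
#' @param input a `SingleCellExperiment` (counts + cell metadata) or a path
#'   to a 10x-style bundle as written by [write_tenx_bundle()].
#' @param out_dir output directory.
#' @param config a [pipeline_config()] object.
#' @return the run manifest (list), invisibly; the same content is written
#'   to `manifest.json`.
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note("[", name, "] ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      writeLines(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  outputs <- character(0)

  sce <- stage("load", {
    if (is.character(input)) read_tenx_bundle(input) else input
  })
  if (!is.null(config$exclude_barcodes)) {
    sce <- sce[, !colnames(sce) %in% config$exclude_barcodes]
  }

  qc <- stage("qc", {
    qcm <- compute_qc_metrics(sce, config$mito_genes)
    keep <- filter_cells(qcm, config$qc)
    qcm$kept <- as.logical(keep)
    outputs <- c(outputs, .write_tsv(qcm, file.path(out_dir, "qc_report.tsv")))
    qcm
  })
  sce <- sce[, qc$kept]

  sce <- stage("normalize", normalize_log(sce, config$target_sum))
  md <- .get_metadata_df(sce)

  type_counts <- table(md$cell_type)
  types <- names(type_counts)[type_counts >= config$min_cells_per_type]
  skipped <- setdiff(names(type_counts), types)
  if (length(skipped)) {
    note("[signatures] skipped cell type(s) with fewer than ",
         config$min_cells_per_type, " cells: ", paste(skipped, collapse = ", "))
  }

  stage_i <- 0L
  seeds <- list()
  sig_tables <- list()
  call_tables <- list()
  for (ct in types) {
    stage_i <- stage_i + 1L
    sig <- stage(paste0("signature:", ct),
                 derive_signature(sce, ct, config$signature))
    sig_tables[[ct]] <- as.data.frame(sig)
    if (!length(attr(sig, "genes"))) {
      note("[signature:", ct, "] empty signature; scoring skipped")
      next
    }
    sc <- stage(paste0("score:", ct), score_cells(sce, sig))
    if (length(sc) < config$gmm_min_scores) {
      note("[call:", ct, "] fewer than ", config$gmm_min_scores,
           " scores; calling skipped")
      next
    }
    sd_seed <- .stage_seed(config$seed, stage_i)
    seeds[[paste0("gmm:", ct)]] <- sd_seed
    fit <- stage(paste0("gmm:", ct),
                 fit_score_mixture(sc, k_candidates = config$gmm_k,
                                   seed = sd_seed, n_init = config$gmm_n_init,
                                   min_scores = config$gmm_min_scores))
    thr <- stage(paste0("threshold:", ct), senescence_threshold(fit))
    call_tables[[ct]] <- call_senescent(sc, thr, cell_type = ct)
  }
  if (length(sig_tables)) {
    outputs <- c(outputs, .write_tsv(do.call(rbind, sig_tables),
                                    file.path(out_dir, "signatures.tsv")))
  }
  calls <- if (length(call_tables)) do.call(rbind, call_tables) else NULL
  if (!is.null(calls)) {
    outputs <- c(outputs, .write_tsv(calls, file.path(out_dir, "calls.tsv")))
    fr <- stage("fractions", senescent_fractions(calls, md))
    outputs <- c(outputs, .write_tsv(fr, file.path(out_dir, "senescent_fractions.tsv")))
  } else {
    note("[call] no cell type produced senescent calls")
  }

  comp <- stage("compose",
                subset_proportions(md, calls, t_subsets = config$t_subsets))
  outputs <- c(outputs, .write_tsv(comp, file.path(out_dir, "composition.tsv")))

  corr <- stage("correlate", burden_association_scan(comp))
  outputs <- c(outputs, .write_tsv(corr, file.path(out_dir, "correlations.tsv")))

  deg_tables <- list()
  for (ts in intersect(config$deg_subsets, types)) {
    tab <- stage(paste0("deg:", ts), tryCatch(
      find_degs(sce, ts, config$deg),
      error = function(e) { note("[deg:", ts, "] ", conditionMessage(e)); NULL }))
    if (!is.null(tab)) deg_tables[[ts]] <- as.data.frame(tab)
  }
  degs <- if (length(deg_tables)) do.call(rbind, deg_tables) else NULL
  if (!is.null(degs)) {
    outputs <- c(outputs, .write_tsv(degs, file.path(out_dir, "degs.tsv")))
  }

  if (!is.null(config$gmt_file) && !is.null(degs)) {
    enr <- stage("ora", {
      sets <- read_gmt(config$gmt_file)
      query <- unique(degs$gene[degs$pass])
      if (!length(query)) {
        note("[ora] no passing DEG; enrichment skipped")
        NULL
      } else {
        ora_hypergeometric(query, rownames(sce), sets,
                           min_size = config$ora_min_size,
                           max_size = config$ora_max_size)
      }
    })
    if (!is.null(enr)) {
      outputs <- c(outputs, .write_tsv(enr, file.path(out_dir, "enrichment.tsv")))
    }
  }

  cfg_file <- tempfile()
  writeLines(deparse(config), cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("senskin")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stage_seeds = seeds,
    n_cells_in = nrow(qc), n_cells_kept = sum(qc$kept),
    cell_types = as.list(type_counts),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    warnings = warnings_log)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
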
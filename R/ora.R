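#' Read gene sets in GMT format
#'
#' Thin wrapper around [fgsea::gmtPathways()]: tab-separated lines of
#' set name, description, then member gene ids.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under hypergeometric sampling from the universe:
#' `p = P(X >= k)` with `k` the overlap, `K` the set size within the
#' universe, `n` the query size and `N` the universe size, followed by
#' Benjamini-Hochberg adjustment across the tested sets. Sets are
#' intersected with the universe first and dropped when their intersected
#' size falls outside `[min_size, max_size]`. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query character vector of genes of interest (e.g. DEGs).
#' @param universe character vector of all assayed genes.
#' @param gene_sets named list of gene-id vectors (see [read_gmt()]).
#' @param min_size,max_size set-size bounds after intersection with the
#'   universe.
#' @return data.frame of class `enrichment_table`: `set`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `overlap` (comma-separated gene ids), sorted by p.
#' @export
ora_hypergeometric <- function(query, universe, gene_sets,
                               min_size = 10L, max_size = 500L) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query gene list", call. = FALSE)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
    if (!length(query)) stop("no query gene lies in the universe", call. = FALSE)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    if (K < min_size || K > max_size) return(NULL)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               overlap = paste(ov, collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), overlap = character(0),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_table", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  out <- out[order(out$p), c("set", "k", "K", "n", "N", "p", "p_adj", "overlap")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}
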
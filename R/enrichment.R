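# Hypergeometric over-representation analysis against user-supplied gene
# sets, plus the probe-to-gene bridge.

#' Map a probe set to its (deduplicated) gene list
#'
#' Union of the gene symbols of all probes matching the region filter,
#' deduplicated and sorted; the input for over-representation analysis.
#'
#' @param probe_ids character vector of probe ids.
#' @param manifest manifest data.frame (gene symbols `;`-separated in
#'   `genes`).
#' @param region optional region filter (`"promoter"`, `"gene_body"`,
#'   `"enhancer"`); `NULL` keeps all probes.
#' @return sorted character vector of gene symbols.
#' @export
probes_to_genes <- function(probe_ids, manifest, region = NULL) {
  m <- manifest[manifest$probe_id %in% probe_ids, , drop = FALSE]
  if (!is.null(region)) {
    region <- match.arg(region, REGIONS)
    m <- m[m[[region]], , drop = FALSE]
  }
  g <- unlist(strsplit(m$genes, ";", fixed = TRUE), use.names = FALSE)
  sort(unique(g[g != ""]))
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT (set id, description, member genes...); parsing
#' is delegated to `fgsea::gmtPathways`.
#'
#' @param path file path.
#' @return named list: set id -> character vector of gene symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability
#' P(X >= k) with X ~ Hypergeom(N, K, n), where N is the universe size, K
#' the set size, n the query size and k their overlap; BH adjustment across
#' sets. Query genes outside the universe are dropped (count reported via
#' message); gene sets are intersected with the universe, empty sets dropped
#' with a warning.
#'
#' @param query character vector of query gene symbols.
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param universe character vector of all eligible gene symbols (typically
#'   all genes on the harmonized manifest).
#' @return data.frame sorted by q then p: set_id, overlap (k), set_size (K),
#'   query_size (n), universe_size (N), gene_ratio (k/n), p, q.
#' @export
ora <- function(query, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop2("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  sets <- lapply(collection, intersect, universe)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped")
    sets <- sets[!empty]
  }
  N <- length(universe); n <- length(query)
  res <- data.frame(
    set_id = names(sets),
    overlap = vapply(sets, function(s) length(intersect(s, query)), integer(1)),
    set_size = lengths(sets),
    query_size = n, universe_size = N,
    stringsAsFactors = FALSE)
  res$gene_ratio <- if (n == 0) NA_real_ else res$overlap / n
  res$p <- stats::phyper(res$overlap - 1, res$set_size, N - res$set_size, n,
                         lower.tail = FALSE)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
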
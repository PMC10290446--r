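## Cross-species gene-set overlap: select genes near (motif-bearing) peaks,
## map orthologs, and test overlap with a reference list by the
## hypergeometric upper tail.

#' Genes lying near a peak set
#'
#' Gene ids whose span overlaps a peak or lies strictly less than
#' `maxDist` bp from the nearest peak (default 500 bp, the usual window for
#' peaks carrying a transcription-factor motif).
#'
#' @param genes Gene models (spans with a `gene_id` metadata column).
#' @param peaks Non-empty peak set.
#' @param maxDist Strict upper bound on the edge gap in bp.
#' @return Character vector of gene ids.
#' @export
genesNearPeaks <- function(genes, peaks, maxDist = 500) {
  if (length(genes) == 0L)
    return(character(0))
  mcols(genes)$gene_id[colocationFlag(genes, peaks, maxDist)]
}

#' Map gene ids through an ortholog table
#'
#' @param geneIds Character vector of source-species gene ids.
#' @param map Data frame with columns `source` and `target`; may be partial
#'   and many-to-many (duplicate pairs are an error).
#' @return List with `targets` (deduplicated target ids of all mapped
#'   sources) and `nDropped` (input ids with no mapping, silently dropped
#'   but counted).
#' @export
mapOrthologs <- function(geneIds, map) {
  stopifnot(is.data.frame(map), all(c("source", "target") %in% names(map)))
  if (anyDuplicated(map[c("source", "target")]))
    stop("duplicate ortholog pairs in the map")
  geneIds <- unique(geneIds)
  hit <- map$source %in% geneIds
  mapped <- unique(map$source[hit])
  list(targets = unique(map$target[hit]),
       nDropped = sum(!geneIds %in% mapped))
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= k) for the overlap `k` between a query list of size `n` and a
#' reference list of size `K` drawn from a universe of `N` genes. The
#' universe is a required explicit argument: overlap p-values are
#' meaningless without stating it, so it is never defaulted.
#'
#' @param N Universe size.
#' @param K Reference-list size.
#' @param n Query-list size.
#' @param k Observed overlap; must satisfy
#'   `0 <= k <= min(K, n) <= N`.
#' @return List `{N, K, n, k, p}` with the exact upper-tail probability
#'   (computed via the log-space hypergeometric tail, safe for large `N`).
#' @examples
#' hypergeometricOverlap(10, 5, 5, 5)$p  # 1/252
#' @export
hypergeometricOverlap <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
            length(k) == 1L)
  if (!(k >= 0 && k <= min(K, n) && K <= N && n <= N))
    stop("require 0 <= k <= min(K, n) <= N")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, p = p)
}

#' End-to-end ortholog overlap test
#'
#' Composition of [genesNearPeaks()], [mapOrthologs()] and
#' [hypergeometricOverlap()]: genes near `peaks` are mapped to the target
#' species and their overlap with `referenceIds` is tested against the
#' stated `universe`.
#'
#' @inheritParams genesNearPeaks
#' @param map Ortholog table (see [mapOrthologs()]).
#' @param referenceIds Target-species reference gene list.
#' @param universe Size of the target-species gene universe, or a character
#'   vector of universe ids (its length is used, and the overlap is
#'   restricted to it).
#' @return The [hypergeometricOverlap()] result, plus `nDropped`.
#' @export
orthologOverlapTest <- function(genes, peaks, map, referenceIds, universe,
                                maxDist = 500) {
  near <- genesNearPeaks(genes, peaks, maxDist)
  mapped <- mapOrthologs(near, map)
  targets <- mapped$targets
  referenceIds <- unique(referenceIds)
  if (is.character(universe)) {
    universe <- unique(universe)
    targets <- intersect(targets, universe)
    referenceIds <- intersect(referenceIds, universe)
    N <- length(universe)
  } else {
    N <- universe
  }
  res <- hypergeometricOverlap(N, length(referenceIds), length(targets),
                               length(intersect(targets, referenceIds)))
  res$nDropped <- mapped$nDropped
  res
}
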
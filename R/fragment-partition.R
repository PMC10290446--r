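## Fragment-length separation of the MN and SN fractions, binned coverage
## and replicate correlation.

#' Partition paired-end fragments by template length
#'
#' Splits fragments into the sub-nucleosomal fraction (template length
#' `<= snMax`), the mono-nucleosomal fraction (`mnMin` to `mnMax`) and a
#' discarded remainder. The defaults reproduce the standard insert-size
#' windows for sperm MNase-seq: SN up to 110 bp, MN 111-1000 bp, matching
#' the ~100 bp and ~147 bp fragment populations the digestion produces.
#'
#' @param fragments [GenomicRanges::GRanges] of mapped fragment spans
#'   (leftmost mate start to rightmost mate end); width is the template
#'   length.
#' @param snMax,mnMin,mnMax Inclusive bp bounds; must satisfy
#'   `snMax < mnMin <= mnMax`.
#' @return A [FractionPartition-class].
#' @examples
#' gt <- GenomeInfoDb::Seqinfo("chr1", 10000)
#' fr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 101, 201), width = c(100, 147, 1200)),
#'   seqinfo = gt)
#' partitionFragments(fr)
#' @export
partitionFragments <- function(fragments, snMax = 110L, mnMin = 111L,
                               mnMax = 1000L) {
  stopifnot(is(fragments, "GRanges"))
  snMax <- as.integer(snMax); mnMin <- as.integer(mnMin)
  mnMax <- as.integer(mnMax)
  if (!(snMax < mnMin && mnMin <= mnMax))
    stop("bounds must satisfy snMax < mnMin <= mnMax")
  w <- width(fragments)
  isSn <- w <= snMax
  isMn <- w >= mnMin & w <= mnMax
  new("FractionPartition",
      sn = fragments[isSn], mn = fragments[isMn],
      discarded = sum(!isSn & !isMn),
      bounds = c(snMax = snMax, mnMin = mnMin, mnMax = mnMax))
}

#' Fixed-width genome bins
#'
#' Tiles every chromosome of `genome` into consecutive `binSize`-bp bins
#' (the last bin of each chromosome may be short), in genome order.
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param binSize Bin width in bp (>= 1).
#' @return A [GenomicRanges::GRanges] of bins.
#' @export
genomeBins <- function(genome, binSize) {
  stopifnot(is(genome, "Seqinfo"), binSize >= 1)
  if (length(seqnames(genome)) == 0L)
    stop("genome table is empty")
  binSize <- as.integer(binSize)
  sl <- seqlengths(genome)
  per <- lapply(names(sl), function(cn) {
    st <- seq.int(1L, sl[[cn]], by = binSize)
    GRanges(cn, IRanges(st, pmin(st + binSize - 1L, sl[[cn]])),
            seqinfo = genome)
  })
  do.call(c, per)
}

#' Per-bin fragment counts along the genome
#'
#' Counts, for each genomic bin, the fragments overlapping it by at least
#' 1 bp (a fragment spanning several bins increments each of them).
#'
#' @inheritParams genomeBins
#' @param fragments Fragment spans ([GenomicRanges::GRanges]).
#' @return Integer vector with one count per bin, ordered as
#'   [genomeBins()].
#' @export
binnedCoverage <- function(fragments, genome, binSize) {
  stopifnot(is(fragments, "GRanges"))
  bins <- genomeBins(genome, binSize)
  countOverlaps(bins, fragments, ignore.strand = TRUE)
}

#' Pearson correlation of two binned coverage tracks
#'
#' Replicate-agreement statistic for coverage vectors. `skipZeros` drops
#' bins where both replicates are zero (uncovered genome); `removeOutliers`
#' additionally drops bins where either value exceeds its track's
#' median + `k` * MAD, a robust high-coverage artefact filter.
#'
#' @param v1,v2 Equal-length numeric count vectors.
#' @param skipZeros Drop bins that are zero in both tracks.
#' @param removeOutliers Apply the median + `k` * MAD filter.
#' @param k Outlier multiplier (default 200: only extreme pile-ups are
#'   removed).
#' @return Pearson r of the surviving bins (at least 2 required).
#' @export
coverageCorrelation <- function(v1, v2, skipZeros = TRUE,
                                removeOutliers = FALSE, k = 200) {
  stopifnot(is.numeric(v1), is.numeric(v2), length(v1) == length(v2))
  keep <- rep(TRUE, length(v1))
  if (skipZeros)
    keep <- keep & !(v1 == 0 & v2 == 0)
  if (removeOutliers) {
    lim1 <- stats::median(v1[keep]) + k * stats::mad(v1[keep])
    lim2 <- stats::median(v2[keep]) + k * stats::mad(v2[keep])
    keep <- keep & v1 <= lim1 & v2 <= lim2
  }
  if (sum(keep) < 2L)
    stop("fewer than 2 bins survive filtering")
  stats::cor(v1[keep], v2[keep])
}
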
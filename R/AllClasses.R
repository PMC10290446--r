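## S4 containers for the three central results: a fragment-length
## partition, a gene-feature catalog, and a permutation enrichment result.

setClassUnion("integerOrNumeric", c("integer", "numeric"))

#' FractionPartition: fragments split by template length
#'
#' Holds the sub-nucleosomal (SN) and mono-nucleosomal (MN) fragment
#' fractions produced by [partitionFragments()], together with the number of
#' discarded fragments and the length bounds used. The three parts always
#' partition the input: `length(sn) + length(mn) + discarded` equals the
#' input size.
#'
#' @slot sn,mn [GenomicRanges::GRanges] of fragments with template length
#'   `<= snMax` and in `[mnMin, mnMax]` respectively.
#' @slot discarded Number of fragments outside both windows.
#' @slot bounds Named integer vector `c(snMax, mnMin, mnMax)`.
#' @seealso [partitionFragments()], [snFraction()], [mnFraction()],
#'   [discardedCount()]
#' @export
setClass("FractionPartition",
         representation(sn = "GRanges", mn = "GRanges",
                        discarded = "integer", bounds = "integer"))

setValidity("FractionPartition", function(object) {
  b <- object@bounds
  if (length(b) != 3L || is.na(b["snMax"]) || is.na(b["mnMin"]) ||
      is.na(b["mnMax"]))
    return("bounds must be named c(snMax, mnMin, mnMax)")
  if (!(b["snMax"] < b["mnMin"] && b["mnMin"] <= b["mnMax"]))
    return("bounds must satisfy snMax < mnMin <= mnMax")
  if (object@discarded < 0L)
    return("discarded count must be non-negative")
  if (length(object@sn) && max(width(object@sn)) > b["snMax"])
    return("sn fraction contains fragments longer than snMax")
  if (length(object@mn) &&
      (min(width(object@mn)) < b["mnMin"] ||
       max(width(object@mn)) > b["mnMax"]))
    return("mn fraction contains fragments outside [mnMin, mnMax]")
  TRUE
})

#' FeatureCatalog: prioritised genomic feature classes
#'
#' A named set of feature interval classes (for gene annotation: TSS,
#' PROMOTER, UTR5, UTR3, CDS, INTRON) over a common genome, with a priority
#' order used to classify each peak into exactly one class; peaks hitting no
#' class fall into the background class (INTERGENIC by default). The same
#' container also serves single-class catalogs (e.g. a repeat family) for
#' planted-enrichment simulations.
#'
#' @slot features A [GenomicRanges::GRangesList], one element per class.
#' @slot genome The [GenomeInfoDb::Seqinfo] all features are bound to.
#' @slot priority Character vector: class names, highest priority first.
#' @slot background Name of the complement class.
#' @seealso [buildFeatureCatalog()], [featureCatalog()], [classifyPeaks()]
#' @export
setClass("FeatureCatalog",
         representation(features = "GRangesList", genome = "Seqinfo",
                        priority = "character", background = "character"))

setValidity("FeatureCatalog", function(object) {
  if (!setequal(object@priority, names(object@features)))
    return("priority must be a permutation of the feature class names")
  if (length(object@background) != 1L ||
      object@background %in% object@priority)
    return("background must be a single class name distinct from features")
  for (nm in names(object@features)) {
    gr <- object@features[[nm]]
    sl <- seqlengths(object@genome)[as.character(seqnames(gr))]
    if (length(gr) && (any(start(gr) < 1L) || any(end(gr) > sl)))
      return(sprintf("class '%s' has intervals outside the genome", nm))
  }
  TRUE
})

#' EnrichmentResult: one row of a permutation co-location report
#'
#' The outcome of [permutationTest()]: the observed overlap count, the full
#' vector of permutation overlap counts, the empirical two-sided p-value,
#' the fold change (observed / permutation mean) and the
#' enriched/depleted/none call.
#'
#' @slot observed Observed overlap count.
#' @slot permCounts Overlap counts of the `nPerms` shuffled replicates.
#' @slot pValue Empirical two-sided p-value (0 means "below 1/nPerms").
#' @slot foldChange Observed / mean of `permCounts` (`NA` if the mean is 0).
#' @slot label One of `"enriched"`, `"depleted"`, `"none"`.
#' @slot queryLabel,subjectLabel Free-text labels for reporting.
#' @slot seed Root seed of the shuffle stream (`NA` if unseeded).
#' @seealso [permutationTest()], [permSummary()], [enrichmentLabel()]
#' @export
setClass("EnrichmentResult",
         representation(observed = "integer", permCounts = "numeric",
                        pValue = "numeric", foldChange = "numeric",
                        label = "character", queryLabel = "character",
                        subjectLabel = "character",
                        seed = "integerOrNumeric"))

setValidity("EnrichmentResult", function(object) {
  if (length(object@permCounts) < 1L)
    return("permCounts must be non-empty")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  if (!is.na(object@foldChange) && object@foldChange < 0)
    return("foldChange must be non-negative")
  if (!object@label %in% c("enriched", "depleted", "none"))
    return("label must be enriched, depleted or none")
  TRUE
})
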
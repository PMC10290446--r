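## Accessors and show() methods for the S4 containers.

#' @describeIn FractionPartition-class SN-fraction fragments.
#' @param object A `FractionPartition`.
#' @export
snFraction <- function(object) {
  stopifnot(is(object, "FractionPartition"))
  object@sn
}

#' @describeIn FractionPartition-class MN-fraction fragments.
#' @export
mnFraction <- function(object) {
  stopifnot(is(object, "FractionPartition"))
  object@mn
}

#' @describeIn FractionPartition-class Number of discarded fragments.
#' @export
discardedCount <- function(object) {
  stopifnot(is(object, "FractionPartition"))
  object@discarded
}

setMethod("show", "FractionPartition", function(object) {
  b <- object@bounds
  n <- length(object@sn) + length(object@mn) + object@discarded
  cat("FractionPartition of", n, "fragments\n")
  cat(sprintf("  SN (width <= %d):        %d\n", b["snMax"],
              length(object@sn)))
  cat(sprintf("  MN (%d <= width <= %d): %d\n", b["mnMin"], b["mnMax"],
              length(object@mn)))
  cat(sprintf("  discarded:               %d\n", object@discarded))
})

#' Feature classes of a catalog
#'
#' @param object A [FeatureCatalog-class].
#' @return For `featureClasses()`, the class names in priority order with
#'   the background class appended; for `featureRegions()`, the
#'   [GenomicRanges::GRangesList] of feature intervals.
#' @export
featureClasses <- function(object) {
  stopifnot(is(object, "FeatureCatalog"))
  c(object@priority, object@background)
}

#' @rdname featureClasses
#' @export
featureRegions <- function(object) {
  stopifnot(is(object, "FeatureCatalog"))
  object@features
}

#' @rdname featureClasses
#' @export
catalogGenome <- function(object) {
  stopifnot(is(object, "FeatureCatalog"))
  object@genome
}

#' Intergenic (background) complement of a catalog
#'
#' The genome minus every catalogued feature interval: the regions a peak
#' must fall in to be classified as background.
#'
#' @param object A [FeatureCatalog-class].
#' @return A [GenomicRanges::GRanges].
#' @export
intergenicRegions <- function(object) {
  stopifnot(is(object, "FeatureCatalog"))
  covered <- reduce(unstrand(unlist(object@features, use.names = FALSE)))
  gaps <- gaps(covered)
  gaps[strand(gaps) == "*"]
}

setMethod("show", "FeatureCatalog", function(object) {
  cat("FeatureCatalog on", length(seqnames(object@genome)),
      "chromosome(s),",
      sum(as.numeric(seqlengths(object@genome))), "bp\n")
  cat("  priority:", paste(object@priority, collapse = " > "),
      ">", object@background, "(background)\n")
  n <- vapply(object@features, length, 0L)
  for (nm in object@priority)
    cat(sprintf("  %-10s %6d interval(s)\n", nm, n[[nm]]))
})

#' @describeIn EnrichmentResult-class Observed overlap count.
#' @param object An `EnrichmentResult`.
#' @export
observedCount <- function(object) {
  stopifnot(is(object, "EnrichmentResult"))
  object@observed
}

#' @describeIn EnrichmentResult-class Per-permutation overlap counts.
#' @export
permCounts <- function(object) {
  stopifnot(is(object, "EnrichmentResult"))
  object@permCounts
}

#' @describeIn EnrichmentResult-class Empirical two-sided p-value.
#' @export
empiricalP <- function(object) {
  stopifnot(is(object, "EnrichmentResult"))
  object@pValue
}

#' @describeIn EnrichmentResult-class Fold change (observed / perm mean).
#' @export
foldChange <- function(object) {
  stopifnot(is(object, "EnrichmentResult"))
  object@foldChange
}

#' @describeIn EnrichmentResult-class Enriched/depleted/none call.
#' @export
enrichmentLabel <- function(object) {
  stopifnot(is(object, "EnrichmentResult"))
  object@label
}

#' @describeIn EnrichmentResult-class Min/max/mean/SE summary of the
#'   permutation counts. The SE column follows the reporting convention of
#'   permutation co-location tables: the standard deviation of the
#'   permutation counts (set `sd = FALSE` for SD/sqrt(n)).
#' @param sd Report the standard deviation (default) rather than the
#'   standard error of the mean.
#' @export
permSummary <- function(object, sd = TRUE) {
  stopifnot(is(object, "EnrichmentResult"))
  x <- object@permCounts
  s <- stats::sd(x)
  if (length(x) == 1L) s <- 0
  c(min = min(x), max = max(x), mean = mean(x),
    se = if (sd) s else s / sqrt(length(x)))
}

#' One-row data frame in the co-location report schema
#'
#' Columns Feature, Real, Min, Max, Mean, SE, P, FC, Label: the layout of a
#' permutation co-location summary table.
#'
#' @param x An [EnrichmentResult-class].
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A one-row `data.frame`.
#' @method as.data.frame EnrichmentResult
#' @export
as.data.frame.EnrichmentResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  s <- permSummary(x)
  data.frame(Source = x@queryLabel, Feature = x@subjectLabel,
             Real = x@observed, Min = s[["min"]], Max = s[["max"]],
             Mean = s[["mean"]], SE = s[["se"]], P = x@pValue,
             FC = x@foldChange, Label = x@label,
             stringsAsFactors = FALSE)
}

setMethod("show", "EnrichmentResult", function(object) {
  s <- permSummary(object)
  cat("EnrichmentResult:", object@queryLabel, "vs", object@subjectLabel,
      "\n")
  cat(sprintf("  observed %d | perm min %g max %g mean %.2f SE %.2f (n=%d)\n",
              object@observed, s[["min"]], s[["max"]], s[["mean"]],
              s[["se"]], length(object@permCounts)))
  cat(sprintf("  P %s  FC %s  -> %s\n",
              formatPValue(object@pValue, length(object@permCounts)),
              ifelse(is.na(object@foldChange), "NA",
                     sprintf("%.2f", object@foldChange)),
              object@label))
})
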
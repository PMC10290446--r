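## The permutation co-location machinery: width-preserving randomisation of
## a region set, empirical two-sided p-value, fold change and the
## enriched/depleted call.

#' Evaluate code with a private RNG stream
#'
#' Seeds the RNG deterministically when `seed` is non-NULL and always
#' restores the caller's RNG state afterwards; the backbone of every
#' seeded operation in the package.
#'
#' @param seed Integer seed or `NULL` (leave the RNG untouched but still
#'   restore it).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
withSeed <- function(seed, code) {
  hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasOld) get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasOld) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

## Independent per-iteration sub-seeds derived from one root seed, so
## permutation results do not depend on execution order.
deriveSubSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

## Placement core shared by shuffleRegions() and the fast path inside
## permutationTest(): draws (chromosome index, start) for each width, with
## exactly the RNG call sequence of shuffleRegions(). `ownChromIdx` is used
## by same-chromosome placement.
.samplePlacement <- function(w, sl, placement, ownChromIdx = NULL) {
  n <- length(w)
  if (placement == "same-chromosome") {
    if (any(w > sl[ownChromIdx]))
      stop("interval wider than its own chromosome")
    chromIdx <- ownChromIdx
  } else {
    if (any(w > max(sl)))
      stop("interval wider than every chromosome")
    ## group widths by the set of chromosomes they fit on; within a group a
    ## single weighted draw places all intervals
    thresholds <- sort(unique(sl))
    grp <- findInterval(w, thresholds + 1L) + 1L  # first fitting length
    chromIdx <- integer(n)
    for (g in unique(grp)) {
      fits <- which(sl >= thresholds[g])
      idx <- grp == g
      chromIdx[idx] <- fits[sample.int(length(fits), sum(idx),
                                       replace = TRUE,
                                       prob = sl[fits])]
    }
  }
  L <- sl[chromIdx]
  list(chromIdx = chromIdx, start = 1 + floor(runif(n) * (L - w + 1)))
}

## Subject preprocessed for fast overlap counting: per-chromosome sorted
## disjoint intervals (union of the subject set).
.reduceSubject <- function(subject, sl) {
  red <- reduce(unstrand(subject), ignore.strand = TRUE)
  chrom <- as.character(seqnames(red))
  lapply(names(sl), function(cn) {
    sel <- chrom == cn
    list(starts = start(red)[sel], ends = end(red)[sel])
  })
}

## Number of query intervals overlapping the reduced subject, on raw
## vectors; equals countOverlapping(query, subject) by construction.
.fastCountQuery <- function(chromIdx, qs, qe, redSubject) {
  total <- 0L
  for (c in unique(chromIdx)) {
    sub <- redSubject[[c]]
    if (length(sub$starts) == 0L) next
    sel <- chromIdx == c
    idx <- findInterval(qe[sel], sub$starts)
    total <- total + sum(idx > 0L & sub$ends[pmax(idx, 1L)] >= qs[sel])
  }
  total
}

#' Width-preserving random placement of a region set
#'
#' Draws `length(regions)` intervals whose multiset of widths is exactly
#' that of the input, each placed uniformly at random wholly inside a
#' chromosome. Under genome-wide placement the chromosome is chosen with
#' probability proportional to its length among the chromosomes the
#' interval fits on; `"same-chromosome"` keeps each interval on its own
#' chromosome. Shuffled intervals may overlap one another, and optionally
#' an `exclude` set is avoided by rejection.
#'
#' @param regions [GenomicRanges::GRanges] to randomise.
#' @param genome [GenomeInfoDb::Seqinfo] defining the placement space;
#'   defaults to the regions' own.
#' @param placement `"genome-wide"` (default) or `"same-chromosome"`.
#' @param exclude Optional [GenomicRanges::GRanges]; placements overlapping
#'   it are redrawn (up to `maxTries` rounds).
#' @param maxTries Redraw rounds before giving up when `exclude` is set.
#' @return A [GenomicRanges::GRanges] with unstranded intervals; element
#'   `i` keeps the width of input element `i`.
#' @export
shuffleRegions <- function(regions, genome = seqinfo(regions),
                           placement = c("genome-wide", "same-chromosome"),
                           exclude = NULL, maxTries = 100L) {
  stopifnot(is(regions, "GRanges"), is(genome, "Seqinfo"))
  placement <- match.arg(placement)
  sl <- seqlengths(genome)
  if (length(sl) == 0L)
    stop("cannot shuffle on an empty genome table")
  w <- width(regions)
  n <- length(w)
  if (n == 0L)
    return(GRanges(seqinfo = genome))
  own <- if (placement == "same-chromosome")
    match(as.character(seqnames(regions)), names(sl))
  place <- .samplePlacement(w, sl, placement, own)
  out <- GRanges(names(sl)[place$chromIdx],
                 IRanges(place$start, width = w), seqinfo = genome)
  if (!is.null(exclude) && length(exclude)) {
    for (i in seq_len(maxTries)) {
      bad <- overlapsAny(out, exclude, ignore.strand = TRUE)
      if (!any(bad)) break
      out[bad] <- shuffleRegions(regions[bad], genome, placement)
    }
    if (any(overlapsAny(out, exclude, ignore.strand = TRUE)))
      stop("could not place all intervals outside the exclude set in ",
           maxTries, " tries")
  }
  out
}

#' Empirical two-sided permutation p-value
#'
#' The proportion of permutations whose overlap count deviates from the
#' permutation mean at least as much as the observed count does
#' (ties count towards p, the conservative choice). An observed count equal
#' to the mean gives p = 1; an observed count beyond every permutation
#' gives p = 0, conventionally reported as below `1/length(permCounts)`
#' (see [formatPValue()]).
#'
#' Two alternative estimators are provided: `"add-one"` returns
#' `(b + 1) / (n + 1)` and never reaches 0, and `"mid"` counts ties with
#' weight 1/2. Because overlap counts are discrete, the plain tie-inclusive
#' estimator is stochastically larger than uniform under the null; the
#' mid-p variant is its unbiased counterpart and is the right object for
#' calibration (uniformity) checks, while `"plain"` remains the reporting
#' default.
#'
#' @param observed Observed overlap count.
#' @param permCounts Non-empty numeric vector of permutation counts.
#' @param estimator `"plain"` (default), `"add-one"` or `"mid"`.
#' @return A p-value in `[0, 1]`.
#' @examples
#' computeEmpiricalP(10, 1:10)  # 0.2: only counts 1 and 10 deviate >= 4.5
#' @export
computeEmpiricalP <- function(observed, permCounts,
                              estimator = c("plain", "add-one", "mid")) {
  stopifnot(length(permCounts) >= 1L)
  estimator <- match.arg(estimator)
  m <- mean(permCounts)
  d <- abs(permCounts - m)
  o <- abs(observed - m)
  n <- length(permCounts)
  switch(estimator,
         plain = sum(d >= o - 1e-9) / n,
         `add-one` = (sum(d >= o - 1e-9) + 1) / (n + 1),
         mid = (sum(d > o + 1e-9) + 0.5 * sum(abs(d - o) <= 1e-9)) / n)
}

#' Format an empirical p-value for reporting
#'
#' A p of 0 only means the observed count fell beyond all permutations, so
#' it is printed as the resolution bound `"<1/nPerms"` (e.g. `"<0.001"` at
#' 1000 permutations).
#'
#' @param p P-value from [computeEmpiricalP()].
#' @param nPerms Number of permutations behind it.
#' @return A character scalar.
#' @export
formatPValue <- function(p, nPerms) {
  if (is.na(p)) return("NA")
  if (p == 0) sprintf("<%s", format(1 / nPerms, scientific = FALSE))
  else format(round(p, max(3L, ceiling(log10(nPerms)))),
              scientific = FALSE)
}

#' Fold change of observed over expected overlap
#'
#' @param observed Observed overlap count.
#' @param permMean Mean overlap count across permutations.
#' @return `observed / permMean`; `NA` with a warning when `permMean` is 0
#'   (no random placement ever hit the subject).
#' @examples
#' computeFoldChange(2793, 553.01)  # 5.05
#' @export
computeFoldChange <- function(observed, permMean) {
  if (permMean == 0) {
    warning("permutation mean is 0; fold change undefined")
    return(NA_real_)
  }
  observed / permMean
}

#' Enriched / depleted / none call
#'
#' A comparison is enriched when `p < pThresh` and `fc >= fcUp`, depleted
#' when `p < pThresh` and `fc <= fcDown`, otherwise none. Defaults are the
#' conventional permutation co-location thresholds p < 0.001 with
#' FC >= 1.5 (enrichment) or FC <= 0.66 (depletion).
#'
#' @param p Empirical p-value(s).
#' @param fc Fold change(s); `NA` gives `"none"`.
#' @param pThresh,fcUp,fcDown Positive thresholds, `fcDown < fcUp`.
#' @return Character vector of labels.
#' @export
classifyEnrichment <- function(p, fc, pThresh = 0.001, fcUp = 1.5,
                               fcDown = 0.66) {
  stopifnot(pThresh > 0, fcUp > 0, fcDown > 0, fcDown < fcUp)
  out <- rep("none", length(p))
  sig <- !is.na(p) & !is.na(fc) & p < pThresh
  out[sig & fc >= fcUp] <- "enriched"
  out[sig & fc <= fcDown] <- "depleted"
  out
}

#' Permutation co-location test of two region sets
#'
#' The central statistic of the analysis: the observed overlap count
#' ([countOverlapping()]) of `query` with `subject` is compared against
#' `nPerms` width-preserving random placements of the query
#' ([shuffleRegions()]). Each permutation uses an independent sub-stream
#' derived from `seed`, so results are reproducible and independent of
#' execution order.
#'
#' @param query,subject [GenomicRanges::GRanges] on the same genome.
#' @param genome Placement space; defaults to the query's `seqinfo`.
#' @param nPerms Number of permutations (default 1000).
#' @param seed Root seed; `NULL` uses (and advances) the session RNG.
#' @param placement,exclude Passed to [shuffleRegions()].
#' @param mode Overlap counting unit, see [countOverlapping()].
#' @param pThresh,fcUp,fcDown Call thresholds, see [classifyEnrichment()].
#' @param queryLabel,subjectLabel Labels carried into the result.
#' @return An [EnrichmentResult-class].
#' @examples
#' gt <- GenomeInfoDb::Seqinfo(c("chr1", "chr2"), c(1e6, 5e5))
#' set.seed(7)
#' q <- shuffleRegions(GenomicRanges::GRanges("chr1",
#'        IRanges::IRanges(1, width = rep(270, 50)), seqinfo = gt), gt)
#' s <- shuffleRegions(GenomicRanges::GRanges("chr1",
#'        IRanges::IRanges(1, width = rep(1000, 100)), seqinfo = gt), gt)
#' permutationTest(q, s, nPerms = 100, seed = 1)
#' @export
permutationTest <- function(query, subject, genome = seqinfo(query),
                            nPerms = 1000L, seed = NULL,
                            placement = "genome-wide", exclude = NULL,
                            mode = "query", pThresh = 0.001, fcUp = 1.5,
                            fcDown = 0.66, queryLabel = "query",
                            subjectLabel = "subject") {
  stopifnot(nPerms >= 1L)
  placement <- match.arg(placement, c("genome-wide", "same-chromosome"))
  checkSameGenome(query, subject)
  observed <- countOverlapping(query, subject, mode = mode)
  subSeeds <- if (is.null(seed))
    sample.int(.Machine$integer.max - 1L, nPerms)
  else deriveSubSeeds(seed, nPerms)
  sl <- seqlengths(genome)
  fastPath <- is.null(exclude) && mode == "query" && length(sl) > 0L
  if (fastPath) {
    ## identical RNG draws as shuffleRegions(), counted on raw vectors
    red <- .reduceSubject(subject, sl)
    w <- width(query)
    own <- if (placement == "same-chromosome")
      match(as.character(seqnames(query)), names(sl))
    perm <- vapply(seq_len(nPerms), function(i) {
      pl <- withSeed(subSeeds[i],
                     .samplePlacement(w, sl, placement, own))
      as.numeric(.fastCountQuery(pl$chromIdx, pl$start,
                                 pl$start + w - 1, red))
    }, numeric(1))
  } else {
    perm <- vapply(seq_len(nPerms), function(i) {
      shuffled <- withSeed(subSeeds[i],
                           shuffleRegions(query, genome,
                                          placement = placement,
                                          exclude = exclude))
      as.numeric(countOverlapping(shuffled, subject, mode = mode))
    }, numeric(1))
  }
  p <- computeEmpiricalP(observed, perm)
  fc <- computeFoldChange(observed, mean(perm))
  new("EnrichmentResult", observed = as.integer(observed),
      permCounts = perm, pValue = p, foldChange = fc,
      label = classifyEnrichment(p, fc, pThresh, fcUp, fcDown),
      queryLabel = queryLabel, subjectLabel = subjectLabel,
      seed = if (is.null(seed)) NA_integer_ else seed)
}
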
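## Integration of peak positions with gene-level RNA abundance: FPKM class
## binning, 5-kb co-location flags, class-vs-absent Fisher exact tests and
## Kruskal-Wallis on log2 abundance.

abundanceLevels <- c("absent", "low", "intermediate", "high")

#' Bin FPKM values into abundance classes
#'
#' Half-open bins: absent `[0, 1)`, low `[1, 10)`, intermediate
#' `[10, 100)`, high `[100, Inf)`.
#'
#' @param fpkm Non-negative numeric vector.
#' @return Factor with levels absent/low/intermediate/high.
#' @examples
#' binAbundance(c(0.5, 1, 10, 100))  # absent low intermediate high
#' @export
binAbundance <- function(fpkm) {
  stopifnot(is.numeric(fpkm))
  if (any(fpkm < 0, na.rm = TRUE))
    stop("negative FPKM")
  cut(fpkm, c(0, 1, 10, 100, Inf), right = FALSE,
      labels = abundanceLevels)
}

#' Peak-proximity flag for gene spans
#'
#' TRUE for genes whose span overlaps a peak or lies strictly less than
#' `maxDist` bp from the nearest peak (edge-gap distance; the conventional
#' "below 5 kb" co-location rule).
#'
#' @param genes Gene spans ([GenomicRanges::GRanges]).
#' @param peaks Non-empty peak set.
#' @param maxDist Strict upper bound on the gap in bp (default 5000).
#' @return Logical vector along `genes`; genes on peak-free chromosomes are
#'   FALSE.
#' @export
colocationFlag <- function(genes, peaks, maxDist = 5000) {
  if (length(peaks) == 0L)
    stop("empty peak set")
  closestDistance(genes, peaks) < maxDist
}

#' Gene abundance table with peak-proximity flags
#'
#' Joins gene models to an FPKM table, bins the abundance classes and adds
#' per-fraction co-location flags.
#'
#' @param genes Gene models (spans with `gene_id`).
#' @param fpkm Data frame with columns `gene_id` and `fpkm` (one row per
#'   gene).
#' @param peaks Named list of peak sets (e.g. `list(MN = ..., SN = ...)`);
#'   each adds a logical `near<NAME>` column.
#' @param maxDist Passed to [colocationFlag()].
#' @return Data frame: `gene_id`, `fpkm`, `class`, and one `near*` column
#'   per peak set.
#' @export
abundanceTable <- function(genes, fpkm, peaks = list(), maxDist = 5000) {
  stopifnot(is.data.frame(fpkm), all(c("gene_id", "fpkm") %in% names(fpkm)))
  if (anyDuplicated(fpkm$gene_id))
    stop("duplicate gene_id in the abundance table")
  idx <- match(mcols(genes)$gene_id, fpkm$gene_id)
  if (anyNA(idx))
    stop("gene(s) missing from the abundance table: ",
         mcols(genes)$gene_id[which(is.na(idx))[1L]])
  out <- data.frame(gene_id = mcols(genes)$gene_id,
                    fpkm = fpkm$fpkm[idx],
                    class = binAbundance(fpkm$fpkm[idx]),
                    stringsAsFactors = FALSE)
  for (nm in names(peaks))
    out[[paste0("near", nm)]] <- colocationFlag(genes, peaks[[nm]],
                                                maxDist)
  out
}

#' 2x2 contingency table of a focal abundance class against absent genes
#'
#' Rows: focal class, absent class; columns: near, far (per the proximity
#' flag). The construction behind the class-vs-absent Fisher tests.
#'
#' @param abundance Data frame from [abundanceTable()].
#' @param focalClass One of `"low"`, `"intermediate"`, `"high"`.
#' @param flagColumn Name of the logical proximity column (e.g.
#'   `"nearMN"`).
#' @return 2x2 integer matrix with informative dimnames.
#' @export
classContingency <- function(abundance, focalClass,
                             flagColumn = "nearMN") {
  stopifnot(is.data.frame(abundance),
            flagColumn %in% names(abundance))
  focalClass <- match.arg(focalClass, abundanceLevels[-1])
  near <- abundance[[flagColumn]]
  focal <- abundance$class == focalClass
  absent <- abundance$class == "absent"
  if (!any(focal)) stop("focal class '", focalClass, "' is empty")
  if (!any(absent)) stop("absent class is empty")
  m <- matrix(c(sum(focal & near), sum(focal & !near),
                sum(absent & near), sum(absent & !near)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c(focalClass, "absent"),
                              c("near", "far")))
  storage.mode(m) <- "integer"
  m
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact two-sided p by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table (the
#' convention of standard exact-test implementations, computed in log
#' space so counts of order 10^4 are safe).
#'
#' @param tab 2x2 non-negative integer matrix with positive margins.
#' @return The two-sided p-value.
#' @examples
#' fisherClassVsAbsent(matrix(c(2774, 3040, 4083, 8042), 2, byrow = TRUE))
#' @export
fisherClassVsAbsent <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a table margin is zero; the test is undefined")
  fisher.test(tab)$p.value
}

#' Class-vs-absent co-location report (one fraction)
#'
#' For each non-absent abundance class: near/far counts and the two-tailed
#' Fisher p against the absent class, plus the absent row itself.
#'
#' @inheritParams classContingency
#' @return Data frame with columns `class`, `near`, `far`, `p` (p is `NA`
#'   for the absent reference row).
#' @export
rnaColocationReport <- function(abundance, flagColumn = "nearMN") {
  near <- abundance[[flagColumn]]
  rows <- lapply(abundanceLevels, function(cl) {
    sel <- abundance$class == cl
    p <- if (cl == "absent" || !any(sel)) NA_real_
    else fisherClassVsAbsent(classContingency(abundance, cl, flagColumn))
    data.frame(class = cl, near = sum(sel & near), far = sum(sel & !near),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis comparison of log2-stabilised abundances
#'
#' Rank test across two or more groups of FPKM values, computed on
#' `log2(fpkm + 1)` (the pseudo-count matters only for display summaries;
#' the rank-based test is invariant to any common monotone transform).
#' When every pooled value is identical the statistic is 0 and p = 1.
#'
#' @param groups List of two or more numeric vectors, each of length >= 2.
#' @return List with elements `H` (tie-corrected statistic), `df` and `p`
#'   (chi-square approximation).
#' @export
kruskalWallisLog2 <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  x <- lapply(groups, function(g) log2(g + 1))
  pooled <- unlist(x, use.names = FALSE)
  if (length(unique(pooled)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- kruskal.test(x)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
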
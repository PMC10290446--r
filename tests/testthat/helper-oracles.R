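## Independent oracles used across the suite. These deliberately share no
## code with the implementation paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(GenomeInfoDb)
})

## O(n*m) double-loop overlap count: number of query intervals sharing
## >= 1 bp with any subject interval (1-based closed coordinates).
bruteCountOverlapping <- function(qChrom, qStart, qEnd,
                                  sChrom, sStart, sEnd) {
  n <- 0L
  for (i in seq_along(qStart)) {
    hit <- FALSE
    for (j in seq_along(sStart)) {
      if (qChrom[i] == sChrom[j] &&
          qStart[i] <= sEnd[j] && sStart[j] <= qEnd[i]) {
        hit <- TRUE
        break
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

## Two-sided Fisher p by direct enumeration of all tables with the
## observed margins, summing point probabilities <= that of the observed
## table (with the customary 1e-7 relative tolerance for ties).
fisherEnumP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  N <- r1 + r2
  x <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  pObs <- probs[x == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Upper-tail hypergeometric P(X >= k) by direct summation of the mass
## function.
hyperEnumP <- function(N, K, n, k) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

## Small random genome + random interval set generators for property
## tests.
randomGenomeTable <- function(nChrom = 3, minLen = 1000, maxLen = 100000) {
  Seqinfo(paste0("chr", seq_len(nChrom)),
          sample(minLen:maxLen, nChrom, replace = TRUE))
}

randomIntervalSet <- function(genome, n, maxWidth = 500) {
  sl <- seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  w <- pmin(w, sl[chrom])
  st <- 1L + floor(runif(n) * (sl[chrom] - w + 1))
  GRanges(chrom, IRanges(st, width = w), seqinfo = genome)
}

## Coordinate mirror within each chromosome: position x -> L - x + 1.
mirrorRegions <- function(gr) {
  sl <- seqlengths(seqinfo(gr))[as.character(seqnames(gr))]
  st <- sl - end(gr) + 1L
  en <- sl - start(gr) + 1L
  out <- GRanges(seqnames(gr), IRanges(st, en), seqinfo = seqinfo(gr))
  str <- as.character(strand(gr))
  strand(out) <- ifelse(str == "+", "-", ifelse(str == "-", "+", "*"))
  mcols(out) <- mcols(gr)
  names(out) <- names(gr)
  out
}

## Mirror full gene models (span, strand and all block columns).
mirrorGenes <- function(genes) {
  sl <- seqlengths(seqinfo(genes))[as.character(seqnames(genes))]
  mirrorBlocks <- function(irl) {
    as(lapply(seq_along(irl), function(i) {
      ir <- irl[[i]]
      rev(IRanges(sl[i] - end(ir) + 1L, sl[i] - start(ir) + 1L))
    }), "IRangesList")
  }
  out <- mirrorRegions(granges(genes))
  mcols(out) <- DataFrame(gene_id = mcols(genes)$gene_id,
                          exons = mirrorBlocks(mcols(genes)$exons),
                          cds = mirrorBlocks(mcols(genes)$cds),
                          utr5 = mirrorBlocks(mcols(genes)$utr5),
                          utr3 = mirrorBlocks(mcols(genes)$utr3),
                          introns = mirrorBlocks(mcols(genes)$introns))
  names(out) <- mcols(genes)$gene_id
  out
}

## Tiny deterministic genome shared by several unit tests.
tinyGenome <- function() Seqinfo(c("chr1", "chr2"), c(100000L, 50000L))

gr1 <- function(starts, ends, genome = tinyGenome(), chrom = "chr1",
                strand = "*") {
  GRanges(chrom, IRanges(starts, ends), strand = strand, seqinfo = genome)
}
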
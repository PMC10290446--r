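## Gene models, the prioritised feature catalog, single-class peak
## annotation and the TSS-centred signal matrix.

## Internal gene-model constructor. All coordinates 1-based closed (GRanges
## convention); exons as an IRangesList parallel to the genes.
.makeGeneModels <- function(geneId, chrom, strand, spanStart, spanEnd,
                            cdsStart, cdsEnd, exons, genome) {
  n <- length(geneId)
  stopifnot(length(chrom) == n, length(strand) == n, length(exons) == n)
  if (anyDuplicated(geneId))
    stop("duplicate gene_id: ", geneId[duplicated(geneId)][1L])
  span <- GRanges(chrom, IRanges(spanStart, spanEnd), strand = strand,
                  seqinfo = genome)
  sl <- seqlengths(genome)[chrom]
  if (any(spanStart < 1L) || any(spanEnd > sl))
    stop("gene span outside genome bounds: ",
         geneId[which(spanStart < 1L | spanEnd > sl)[1L]])
  exons <- as(exons, "IRangesList")
  cdsRegion <- IRanges(cdsStart, cdsEnd)
  cds <- utr5 <- utr3 <- introns <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- reduce(exons[[i]])
    if (min(start(ex)) < spanStart[i] || max(end(ex)) > spanEnd[i])
      stop("exon block outside gene span: ", geneId[i])
    cds[[i]] <- intersect(ex, cdsRegion[i])
    utr <- setdiff(ex, cdsRegion[i])
    left <- utr[end(utr) < cdsStart[i]]
    right <- utr[start(utr) > cdsEnd[i]]
    if (strand[i] == "+") {
      utr5[[i]] <- left; utr3[[i]] <- right
    } else {
      utr5[[i]] <- right; utr3[[i]] <- left
    }
    introns[[i]] <- setdiff(IRanges(spanStart[i], spanEnd[i]), ex)
  }
  mcols(span) <- DataFrame(gene_id = geneId,
                           exons = as(exons, "IRangesList"),
                           cds = as(cds, "IRangesList"),
                           utr5 = as(utr5, "IRangesList"),
                           utr3 = as(utr3, "IRangesList"),
                           introns = as(introns, "IRangesList"))
  names(span) <- geneId
  span
}

#' Read a simplified gene annotation table
#'
#' Parses the 8-column TSV gene dialect: `gene_id`, `chrom`, `strand`,
#' `span_start`, `span_end`, `cds_start`, `cds_end`, `exon_blocks`
#' (comma-separated `start-end` pairs). Coordinates on file are 0-based
#' half-open; 5'/3' UTR, CDS and intron blocks are derived from the exon
#' structure and the CDS extent, strand-aware.
#'
#' @param path Path to the TSV (header optional; detected from the first
#'   line).
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A [GenomicRanges::GRanges] of gene spans whose metadata columns
#'   carry `gene_id` and per-gene `exons`, `cds`, `utr5`, `utr3` and
#'   `introns` blocks as [IRanges::IRangesList] columns.
#' @export
readGeneTable <- function(path, genome) {
  stopifnot(file.exists(path), is(genome, "Seqinfo"))
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("gene_id", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE,
                   col.names = c("gene_id", "chrom", "strand", "span_start",
                                 "span_end", "cds_start", "cds_end",
                                 "exon_blocks"))
  blocks <- lapply(strsplit(df$exon_blocks, ","), function(b) {
    se <- do.call(rbind, strsplit(b, "-", fixed = TRUE))
    IRanges(as.integer(se[, 1]) + 1L, as.integer(se[, 2]))
  })
  .makeGeneModels(df$gene_id, df$chrom, df$strand,
                  df$span_start + 1L, df$span_end,
                  df$cds_start + 1L, df$cds_end, blocks, genome)
}

#' Write gene models in the simplified 8-column dialect
#'
#' Inverse of [readGeneTable()] (coordinates converted back to 0-based
#' half-open).
#'
#' @param genes Gene models as returned by [readGeneTable()] or
#'   [makeGenes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  ex <- mcols(genes)$exons
  cds <- mcols(genes)$cds
  blocks <- vapply(seq_along(genes), function(i)
    paste(sprintf("%d-%d", start(ex[[i]]) - 1L, end(ex[[i]])),
          collapse = ","), "")
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   span_start = start(genes) - 1L, span_end = end(genes),
                   cds_start = vapply(seq_along(genes), function(i)
                     min(start(cds[[i]])) - 1L, 0L),
                   cds_end = vapply(seq_along(genes), function(i)
                     max(end(cds[[i]])), 0L),
                   exon_blocks = blocks)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcription start positions of gene models
#'
#' @param genes Gene-model [GenomicRanges::GRanges].
#' @return Integer vector of 1-based TSS positions (span start on `+`
#'   strand, span end on `-` strand).
#' @export
tssPositions <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

## Lift an IRangesList column to a flat GRanges with per-gene seqnames and
## strand.
.liftBlocks <- function(genes, column) {
  irl <- mcols(genes)[[column]]
  n <- elementNROWS(irl)
  out <- GRanges(rep(seqnames(genes), n), unlist(irl, use.names = FALSE),
                 strand = rep(strand(genes), n),
                 seqinfo = seqinfo(genes))
  names(out) <- rep(mcols(genes)$gene_id, n)
  out
}

#' Build a prioritised gene-feature catalog
#'
#' Derives, for every gene, a 1-bp TSS site (optionally expanded by
#' `tssFlank` bp each side), a strand-aware promoter window of
#' `promoterLen` bp immediately upstream of (and excluding) the TSS base,
#' and the 5' UTR, 3' UTR, CDS and intron blocks, all clipped to chromosome
#' bounds. Peaks hitting none of these are intergenic.
#'
#' @param genes Gene models (see [readGeneTable()] / [makeGenes()]).
#' @param genome A [GenomeInfoDb::Seqinfo]; defaults to the genes' own.
#' @param promoterLen Promoter window length in bp upstream of the TSS
#'   (default 2000, the common promoter convention; reported feature counts
#'   depend on it, so it is exposed).
#' @param tssFlank Expansion of the TSS site by this many bp on each side
#'   (default 0: a single base).
#' @param priority Classification priority, highest first. The default puts
#'   the rarest, most specific features first so promoters cannot absorb
#'   TSS hits.
#' @return A [FeatureCatalog-class].
#' @examples
#' gt <- GenomeInfoDb::Seqinfo("chr1", 50000)
#' g <- makeGenes(simulationConfig(nGenes = 5, chromLengths = c(chr1 = 50000)),
#'                gt)
#' buildFeatureCatalog(g, gt)
#' @export
buildFeatureCatalog <- function(genes, genome = seqinfo(genes),
                                promoterLen = 2000L, tssFlank = 0L,
                                priority = c("TSS", "PROMOTER", "UTR5",
                                             "UTR3", "CDS", "INTRON")) {
  stopifnot(is(genes, "GRanges"), is(genome, "Seqinfo"), promoterLen >= 1)
  sl <- seqlengths(genome)[as.character(seqnames(genes))]
  if (any(start(genes) < 1L) || any(end(genes) > sl))
    stop("gene span outside genome bounds")
  tss <- tssPositions(genes)
  chrom <- as.character(seqnames(genes))
  str <- as.character(strand(genes))
  tssGr <- GRanges(chrom,
                   IRanges(pmax(tss - tssFlank, 1L),
                           pmin(tss + tssFlank, sl)),
                   strand = str, seqinfo = genome)
  names(tssGr) <- mcols(genes)$gene_id
  promStart <- ifelse(str == "+", tss - promoterLen, tss + 1L)
  promEnd <- ifelse(str == "+", tss - 1L, tss + promoterLen)
  promStart <- pmax(promStart, 1L)
  promEnd <- pmin(promEnd, sl)
  keep <- promStart <= promEnd  # promoter fully clipped away at chrom edge
  promGr <- GRanges(chrom[keep], IRanges(promStart[keep], promEnd[keep]),
                    strand = str[keep], seqinfo = genome)
  names(promGr) <- mcols(genes)$gene_id[keep]
  feats <- GRangesList(TSS = tssGr, PROMOTER = promGr,
                       UTR5 = .liftBlocks(genes, "utr5"),
                       UTR3 = .liftBlocks(genes, "utr3"),
                       CDS = .liftBlocks(genes, "cds"),
                       INTRON = .liftBlocks(genes, "introns"))
  new("FeatureCatalog", features = feats[priority], genome = genome,
      priority = priority, background = "INTERGENIC")
}

#' Assemble a catalog from arbitrary feature sets
#'
#' Generic constructor for non-gene catalogs, e.g. repeat families or a
#' single planted-enrichment target class.
#'
#' @param features Named [GenomicRanges::GRangesList] (or named list of
#'   `GRanges`), one element per class.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param priority Class priority, highest first (default: list order).
#' @param background Name of the complement class.
#' @return A [FeatureCatalog-class].
#' @export
featureCatalog <- function(features, genome,
                           priority = names(features),
                           background = "INTERGENIC") {
  features <- as(features, "GRangesList")
  new("FeatureCatalog", features = features[priority], genome = genome,
      priority = priority, background = background)
}

#' Classify peaks into exactly one feature class
#'
#' Each peak is assigned the highest-priority class whose intervals it
#' overlaps by at least 1 bp; peaks overlapping no class get the background
#' class. Classification is exhaustive and mutually exclusive, and does not
#' depend on the order of genes in the catalog.
#'
#' @param peaks [GenomicRanges::GRanges].
#' @param catalog A [FeatureCatalog-class].
#' @return Factor of length `length(peaks)` with levels
#'   `featureClasses(catalog)`.
#' @export
classifyPeaks <- function(peaks, catalog) {
  stopifnot(is(peaks, "GRanges"), is(catalog, "FeatureCatalog"))
  lv <- featureClasses(catalog)
  cls <- rep(catalog@background, length(peaks))
  unassigned <- rep(TRUE, length(peaks))
  for (nm in catalog@priority) {
    if (!any(unassigned)) break
    hit <- overlapsAny(peaks, catalog@features[[nm]], ignore.strand = TRUE)
    take <- unassigned & hit
    cls[take] <- nm
    unassigned[take] <- FALSE
  }
  factor(cls, levels = lv)
}

#' Class proportions of a peak set
#'
#' @inheritParams classifyPeaks
#' @return Named numeric vector of proportions over all feature classes
#'   (including the background class), summing to 1.
#' @export
summarizeClasses <- function(peaks, catalog) {
  if (length(peaks) == 0L)
    stop("empty peak set")
  tab <- table(classifyPeaks(peaks, catalog))
  setNames(as.vector(tab) / length(peaks), names(tab))
}

#' TSS-centred fragment signal matrix
#'
#' For every TSS in the catalog, counts the fragments overlapping each
#' `bin`-bp bin of the window `[tss - flank, tss + flank)`; rows of genes on
#' the `-` strand are reversed so that columns always read 5' to 3'. Genes
#' whose window extends past a chromosome end are dropped (with a message),
#' as are all-zero rows when `skipZeros`.
#'
#' @param fragments Fragment spans ([GenomicRanges::GRanges]).
#' @param catalog A [FeatureCatalog-class] with a `TSS` class (as built by
#'   [buildFeatureCatalog()]).
#' @param flank Half-window in bp (default 500); must be divisible by
#'   `bin`.
#' @param bin Bin width in bp.
#' @param skipZeros Drop genes with no signal anywhere in the window.
#' @return Numeric matrix, genes x bins, with gene ids as row names.
#' @export
tssSignalMatrix <- function(fragments, catalog, flank = 500L, bin = 10L,
                            skipZeros = FALSE) {
  stopifnot(is(fragments, "GRanges"), is(catalog, "FeatureCatalog"),
            "TSS" %in% names(catalog@features))
  flank <- as.integer(flank); bin <- as.integer(bin)
  if (flank %% bin != 0L)
    stop("flank must be divisible by bin")
  tssGr <- catalog@features$TSS
  tss <- start(resize(tssGr, 1L, fix = "center"))
  chrom <- as.character(seqnames(tssGr))
  str <- as.character(strand(tssGr))
  sl <- seqlengths(catalog@genome)[chrom]
  ## on the minus strand transcription runs towards lower coordinates, so
  ## the half-open window is [tss - flank + 1, tss + flank]: after the
  ## column flip the TSS base lands in the same column on both strands
  winStart <- ifelse(str == "-", tss - flank + 1L, tss - flank)
  inside <- winStart >= 1L & winStart + 2L * flank - 1L <= sl
  if (!any(inside))
    stop("no TSS window fits inside the genome bounds")
  if (any(!inside))
    message(sum(!inside), " TSS window(s) overhanging a chromosome end ",
            "dropped")
  winStart <- winStart[inside]; chrom <- chrom[inside]
  str <- str[inside]
  ids <- names(tssGr)[inside]
  nbin <- 2L * flank %/% bin
  starts <- rep(winStart, each = nbin) +
    bin * rep(seq_len(nbin) - 1L, length(winStart))
  bins <- GRanges(rep(chrom, each = nbin),
                  IRanges(starts, width = bin),
                  seqinfo = catalog@genome)
  counts <- countOverlaps(bins, fragments, ignore.strand = TRUE)
  mat <- matrix(counts, ncol = nbin, byrow = TRUE,
                dimnames = list(ids, NULL))
  neg <- str == "-"
  mat[neg, ] <- mat[neg, nbin:1, drop = FALSE]
  colnames(mat) <- sprintf("%+d", seq(-flank, flank - bin, by = bin))
  if (skipZeros)
    mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  mat
}
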
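## Core interval data model: genome tables, BED-like region I/O, overlap
## counting and edge-gap distances. Region sets are GRanges bound to a
## Seqinfo; files are BED convention (0-based half-open), memory is GRanges
## convention (1-based closed).

#' Read a chromosome-sizes table
#'
#' Parses a two-column `chrom.sizes` file (chromosome name, length in bp;
#' whitespace-delimited, `#` comments and blank lines skipped) into a
#' [GenomeInfoDb::Seqinfo] that defines the shuffle space for all
#' randomisations.
#'
#' @param path Path to the file. An empty file yields an empty `Seqinfo`
#'   (valid, but shuffling against it is an error).
#' @return A [GenomeInfoDb::Seqinfo].
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1 1000", "chr2 500"), tf)
#' gt <- readGenomeTable(tf)
#' sum(GenomeInfoDb::seqlengths(gt))  # 1500
#' @export
readGenomeTable <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(Seqinfo())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("genome table line ", lineno[which(nf < 2L)[1L]],
         ": expected 2 columns (name, length)")
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- is.na(len) | len < 1 | len != floor(len)
  if (any(bad))
    stop("genome table line ", lineno[which(bad)[1L]],
         ": length must be a positive integer")
  if (anyDuplicated(nm))
    stop("genome table line ", lineno[which(duplicated(nm))[1L]],
         ": duplicate chromosome '", nm[duplicated(nm)][1L], "'")
  Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Read a BED-like region file into a genome-bound GRanges
#'
#' Accepts BED3/BED6, tab- or space-delimited, with `#` comment lines.
#' Coordinates on file are 0-based half-open and are converted to GRanges
#' convention. Every interval is validated against `genome`; violations are
#' reported with their line number.
#'
#' @param path Path to the region file.
#' @param genome A [GenomeInfoDb::Seqinfo] the intervals must be valid
#'   against.
#' @param label Optional free-text label stored in `metadata(x)$label`.
#' @return A [GenomicRanges::GRanges] in input order, with `name` (column 4)
#'   as range names where present and strand from column 6 where present.
#' @seealso [writeRegionFile()] for the inverse operation.
#' @export
readRegionFile <- function(path, genome, label = NULL) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path),
            is(genome, "Seqinfo"))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    gr <- GRanges(seqinfo = genome)
  } else {
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("region file line ", lineno[which(nf < 3L)[1L]],
           ": expected at least 3 columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- is.na(start0) | is.na(end0) |
      start0 != floor(start0) | end0 != floor(end0)
    if (any(bad))
      stop("region file line ", lineno[which(bad)[1L]],
           ": non-integer coordinates")
    if (any(start0 < 0))
      stop("region file line ", lineno[which(start0 < 0)[1L]],
           ": negative start")
    if (any(start0 >= end0))
      stop("region file line ", lineno[which(start0 >= end0)[1L]],
           ": empty or inverted interval (start >= end)")
    unknown <- !(chrom %in% seqnames(genome))
    if (any(unknown))
      stop("region file line ", lineno[which(unknown)[1L]],
           ": unknown chromosome '", chrom[unknown][1L], "'")
    over <- end0 > seqlengths(genome)[chrom]
    if (any(over))
      stop("region file line ", lineno[which(over)[1L]],
           ": interval end exceeds chromosome length")
    nm <- ifelse(nf >= 4L, vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
    strand <- ifelse(nf >= 6L, vapply(fields, function(f)
      if (length(f) >= 6L) f[[6L]] else "*", ""), "*")
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                  seqinfo = genome)
    if (!all(is.na(nm)))
      names(gr) <- nm
  }
  if (!is.null(label))
    metadata(gr)$label <- label
  gr
}

#' Write a region set as BED6
#'
#' Inverse of [readRegionFile()]: coordinates are converted back to 0-based
#' half-open, the interval width is written in the score column, and `*`
#' strand becomes `.`. A write/read round trip reproduces coordinates and
#' order exactly.
#'
#' @param x A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRegionFile <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  nm <- names(x)
  if (is.null(nm)) nm <- rep(".", length(x))
  str <- as.character(strand(x))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x),
                   name = nm, score = width(x), strand = str)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

checkSameGenome <- function(query, subject) {
  sq <- seqinfo(query); ss <- seqinfo(subject)
  if (!identical(seqnames(sq), seqnames(ss)) ||
      !identical(seqlengths(sq), seqlengths(ss)))
    stop("query and subject are bound to different genomes")
  invisible(TRUE)
}

#' Count query intervals overlapping a subject set
#'
#' The co-location statistic of the permutation test: by default the number
#' of `query` intervals sharing at least 1 bp with at least one `subject`
#' interval, each query interval counted at most once. This makes fold
#' changes insensitive to fragmented subject annotations and keeps counts
#' bounded by the query size. `mode = "pairs"` counts overlapping
#' (query, subject) pairs instead.
#'
#' @param query,subject [GenomicRanges::GRanges] bound to the same genome.
#' @param mode `"query"` (default) or `"pairs"`.
#' @return A single non-negative integer. Strand is ignored.
#' @examples
#' gt <- GenomeInfoDb::Seqinfo("chr1", 100)
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 21), c(10, 30)),
#'                             seqinfo = gt)
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(6, 26, 51),
#'                             c(6, 40, 60)), seqinfo = gt)
#' countOverlapping(q, s)  # 2
#' @export
countOverlapping <- function(query, subject, mode = c("query", "pairs")) {
  stopifnot(is(query, "GRanges"), is(subject, "GRanges"))
  mode <- match.arg(mode)
  checkSameGenome(query, subject)
  if (mode == "query")
    sum(overlapsAny(query, subject, ignore.strand = TRUE))
  else
    length(findOverlaps(query, subject, ignore.strand = TRUE))
}

#' Edge-gap distance from intervals to the nearest subject interval
#'
#' For each interval in `x`, the minimum gap in bp between interval edges
#' and any `subject` interval on the same chromosome. Overlapping or
#' directly abutting intervals have distance 0; if the chromosome carries no
#' subject interval the distance is `Inf`.
#'
#' @param x Query intervals ([GenomicRanges::GRanges]).
#' @param subject Non-empty subject set.
#' @return Numeric vector, one distance per query interval.
#' @export
closestDistance <- function(x, subject) {
  stopifnot(is(x, "GRanges"), is(subject, "GRanges"))
  if (length(subject) == 0L)
    stop("subject region set is empty")
  hits <- distanceToNearest(x, subject, ignore.strand = TRUE)
  d <- rep(Inf, length(x))
  d[queryHits(hits)] <- mcols(hits)$distance
  d
}
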
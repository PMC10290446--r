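## Synthetic-data generator: genomes, gene models, peak sets with planted
## enrichment, abundance tables coupled to peak proximity, and paired-end
## fragment mixtures. Every generated object carries known ground truth so
## each pipeline stage can be validated without external data.

#' Simulation configuration
#'
#' Bundles all generator parameters with defaults that emulate the
#' statistical structure of a sperm MNase-seq study at desk scale: a 10-Mbp
#' genome, 500 genes, 2000 mono-nucleosomal (MN) peaks averaging 270 bp and
#' 300 sub-nucleosomal (SN) peaks averaging 141 bp, fragment template
#' lengths from a two-component normal mixture centred at 147 bp (MN) and
#' 95 bp (SN) with the MN component carrying ~90% of the mass, and a
#' log-normal FPKM distribution populating all four abundance classes
#' (absent/low/intermediate/high) in realistic proportions.
#'
#' @param seed Default seed for [simulateScenario()].
#' @param chromLengths Named integer vector of chromosome lengths in bp.
#' @param nGenes Number of non-overlapping gene models.
#' @param promoterLen Promoter window in bp.
#' @param spanMeanLog,spanSdLog,spanMin Log-normal gene-span widths (bp)
#'   and their floor.
#' @param exonLambda Mean of the Poisson exon-count excess (exons per gene
#'   = 1 + Poisson).
#' @param nPeaksMn,nPeaksSn Peak counts per fraction.
#' @param mnWidthMeanLog,mnWidthSdLog,snWidthMeanLog,snWidthSdLog
#'   Log-normal peak-width parameters; the defaults give mean widths of
#'   ~270 bp (MN) and ~141 bp (SN).
#' @param rho Named non-negative enrichment multipliers per feature class
#'   (classes not named get 1; empty means uniform placement).
#' @param beta Shift, in log2 FPKM units, added to genes lying within 5 kb
#'   of a peak (0 = abundance independent of peak proximity).
#' @param abundanceMeanLog2,abundanceSdLog2 Normal parameters of log2 FPKM.
#' @param fragMeans,fragSds Named (`MN`, `SN`) means and SDs in bp of the
#'   fragment template-length components.
#' @param mnWeight Mixture weight of the MN component.
#' @param nFragments Total fragments drawn by [makeFragments()].
#' @return A `SimulationConfig` (validated named list).
#' @export
simulationConfig <- function(seed = 1L,
                             chromLengths = c(chr1 = 4e6, chr2 = 3e6,
                                              chr3 = 2e6, chr4 = 1e6),
                             nGenes = 500L,
                             promoterLen = 2000L,
                             spanMeanLog = log(8000), spanSdLog = 0.5,
                             spanMin = 600L,
                             exonLambda = 4,
                             nPeaksMn = 2000L, nPeaksSn = 300L,
                             mnWidthMeanLog = log(270) - 0.35^2 / 2,
                             mnWidthSdLog = 0.35,
                             snWidthMeanLog = log(141) - 0.25^2 / 2,
                             snWidthSdLog = 0.25,
                             rho = numeric(0),
                             beta = 1,
                             abundanceMeanLog2 = -0.5,
                             abundanceSdLog2 = 4,
                             fragMeans = c(MN = 147, SN = 95),
                             fragSds = c(MN = 10, SN = 10),
                             mnWeight = 0.9,
                             nFragments = 20000L) {
  stopifnot(length(chromLengths) >= 0, all(chromLengths >= 1),
            nGenes >= 1, promoterLen >= 1, spanMin >= 1,
            nPeaksMn >= 0, nPeaksSn >= 0, all(rho >= 0),
            mnWeight >= 0, mnWeight <= 1, nFragments >= 0,
            all(c("MN", "SN") %in% names(fragMeans)),
            all(c("MN", "SN") %in% names(fragSds)))
  structure(list(seed = seed, chromLengths = chromLengths,
                 nGenes = as.integer(nGenes),
                 promoterLen = as.integer(promoterLen),
                 spanMeanLog = spanMeanLog, spanSdLog = spanSdLog,
                 spanMin = as.integer(spanMin), exonLambda = exonLambda,
                 nPeaksMn = as.integer(nPeaksMn),
                 nPeaksSn = as.integer(nPeaksSn),
                 mnWidthMeanLog = mnWidthMeanLog,
                 mnWidthSdLog = mnWidthSdLog,
                 snWidthMeanLog = snWidthMeanLog,
                 snWidthSdLog = snWidthSdLog,
                 rho = rho, beta = beta,
                 abundanceMeanLog2 = abundanceMeanLog2,
                 abundanceSdLog2 = abundanceSdLog2,
                 fragMeans = fragMeans, fragSds = fragSds,
                 mnWeight = mnWeight,
                 nFragments = as.integer(nFragments)),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:",
      sum(as.numeric(x$chromLengths)) / 1e6, "Mbp on",
      length(x$chromLengths), "chromosome(s);",
      x$nGenes, "genes;", x$nPeaksMn, "MN +", x$nPeaksSn, "SN peaks\n")
  if (length(x$rho))
    cat("  planted rho:",
        paste(sprintf("%s=%g", names(x$rho), x$rho), collapse = ", "),
        "\n")
  cat("  abundance coupling beta =", x$beta,
      "| fragment mixture", sprintf("%.0f/%.0f bp, MN weight %.2f",
                                    x$fragMeans[["MN"]],
                                    x$fragMeans[["SN"]], x$mnWeight),
      "\n")
  invisible(x)
}

#' Genome table of a simulation
#'
#' @param config A [simulationConfig()].
#' @return A [GenomeInfoDb::Seqinfo] with the configured chromosomes.
#' @export
makeGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(config$chromLengths) == 0L)
    stop("configuration has zero chromosomes")
  Seqinfo(seqnames = names(config$chromLengths),
          seqlengths = as.integer(config$chromLengths))
}

## log-normal widths, floored at 1 bp and capped
sampleWidths <- function(n, meanLog, sdLog, maxWidth = Inf) {
  pmin(pmax(round(rlnorm(n, meanLog, sdLog)), 1), maxWidth)
}

## genomic position of the j-th exonic base (1-based, left to right)
.exonicOffsetToGenomic <- function(exons, j) {
  cum <- cumsum(width(exons))
  i <- which(cum >= j)[1L]
  start(exons[i]) + (j - 1L) - if (i > 1L) cum[i - 1L] else 0L
}

#' Generate non-overlapping gene models
#'
#' Places `nGenes` genes with log-normal span widths, non-overlapping
#' within each chromosome (chromosomes receive genes in proportion to
#' their length). Each gene gets 1 + Poisson exons spanning the full gene
#' body, introns of at least 50 bp, and a CDS flanked by 5'/3' UTRs carved
#' from the exonic sequence; strands are balanced Bernoulli(1/2).
#'
#' @param config A [simulationConfig()].
#' @param genome [makeGenome()] output (or any compatible `Seqinfo`).
#' @param seed Optional seed for a private RNG stream.
#' @return Gene-model [GenomicRanges::GRanges] (see [readGeneTable()] for
#'   the metadata layout).
#' @export
makeGenes <- function(config, genome, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"), is(genome, "Seqinfo"))
  withSeed(seed, {
    sl <- seqlengths(genome)
    n <- config$nGenes
    chromOf <- sort(sample.int(length(sl), n, replace = TRUE,
                               prob = sl))
    w <- pmax(sampleWidths(n, config$spanMeanLog, config$spanSdLog),
              config$spanMin)
    geneId <- sprintf("gene%04d", seq_len(n))
    spanStart <- integer(n)
    for (ci in unique(chromOf)) {
      idx <- which(chromOf == ci)
      free <- sl[ci] - sum(w[idx])
      if (free < length(idx) + 1L)
        stop("genome too small for the requested gene count/geometry")
      shares <- diff(c(0, sort(runif(length(idx))), 1))
      gapsizes <- floor(shares * free)
      pos <- 1L
      for (j in seq_along(idx)) {
        pos <- pos + gapsizes[j]
        spanStart[idx[j]] <- pos
        pos <- pos + w[idx[j]]
      }
    }
    spanEnd <- spanStart + w - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    exons <- vector("list", n)
    cdsStart <- cdsEnd <- integer(n)
    for (i in seq_len(n)) {
      wi <- w[i]
      kMax <- max(1L, (wi - 100L) %/% 400L)
      k <- min(1L + rpois(1L, config$exonLambda), kMax, 8L)
      if (k == 1L) {
        ex <- IRanges(spanStart[i], spanEnd[i])
      } else {
        repeat {
          e <- pmax(round(rlnorm(k, log(180), 0.4)), 50L)
          if (sum(e) + 50L * (k - 1L) <= wi) break
          k <- k - 1L
          if (k == 1L) { e <- wi; break }
        }
        if (k == 1L) {
          ex <- IRanges(spanStart[i], spanEnd[i])
        } else {
          slack <- wi - sum(e) - 50L * (k - 1L)
          shares <- diff(c(0, sort(runif(k - 1L)), 1))
          intron <- 50L + floor(shares[seq_len(k - 1L)] * slack)
          starts <- spanStart[i] +
            cumsum(c(0L, e[-k] + intron))
          ex <- IRanges(starts, width = e)
          ## rounding slack goes to the last exon so the span is covered
          end(ex)[k] <- spanEnd[i]
        }
      }
      E <- sum(width(ex))
      u5 <- min(1L + rpois(1L, 100), (E - 3L) %/% 3L)
      u3 <- min(1L + rpois(1L, 150), (E - 3L - u5) %/% 2L)
      leftUTR <- if (strand[i] == "+") u5 else u3
      rightUTR <- if (strand[i] == "+") u3 else u5
      cdsStart[i] <- .exonicOffsetToGenomic(ex, leftUTR + 1L)
      cdsEnd[i] <- .exonicOffsetToGenomic(ex, E - rightUTR)
      exons[[i]] <- ex
    }
    .makeGeneModels(geneId, names(sl)[chromOf], strand, spanStart,
                    spanEnd, cdsStart, cdsEnd, exons, genome)
  })
}

#' Uniformly placed random regions
#'
#' Convenience wrapper over [shuffleRegions()]: `n` intervals with the
#' given widths placed uniformly at random (chromosome chosen proportional
#' to length), optionally avoiding an exclude set.
#'
#' @param n Number of intervals.
#' @param widths Width in bp, recycled to length `n`.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param exclude Optional regions to avoid (rejection).
#' @param seed Optional seed for a private RNG stream.
#' @return A [GenomicRanges::GRanges].
#' @export
randomRegions <- function(n, widths, genome, exclude = NULL, seed = NULL) {
  stopifnot(is(genome, "Seqinfo"), n >= 0)
  if (n == 0L)
    return(GRanges(seqinfo = genome))
  widths <- rep_len(widths, n)
  big <- names(seqlengths(genome))[which.max(seqlengths(genome))]
  template <- GRanges(big, IRanges(1L, width = pmin(widths,
                                                    max(seqlengths(genome)))),
                      seqinfo = genome)
  withSeed(seed, shuffleRegions(template, genome, exclude = exclude))
}

#' Plant peaks with a prescribed per-class enrichment
#'
#' Places `n` peaks by rejection sampling so that the expected rate at
#' which peaks classify into feature class `c` is `rho[c]` times the
#' uniform-placement rate, with the background class absorbing the
#' complement. `rho` of 1 everywhere reduces to uniform placement; values
#' above 1 plant enrichment, below 1 depletion, and the planted `rho` is
#' exactly the quantity a permutation fold change estimates.
#'
#' Uniform class rates are estimated once from `nCalibrate` uniform
#' placements with the same width distribution.
#'
#' @param n Number of peaks.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param catalog A [FeatureCatalog-class] defining the classes.
#' @param rho Named non-negative multipliers for (a subset of) the
#'   catalog's priority classes; unnamed classes default to 1.
#' @param widthMeanLog,widthSdLog Log-normal peak-width parameters.
#' @param seed Optional seed for a private RNG stream.
#' @param nCalibrate Uniform placements used to estimate class rates.
#' @return A [GenomicRanges::GRanges] of `n` peaks.
#' @export
plantPeaks <- function(n, genome, catalog, rho = numeric(0),
                       widthMeanLog = log(270) - 0.35^2 / 2,
                       widthSdLog = 0.35, seed = NULL,
                       nCalibrate = 20000L) {
  stopifnot(is(genome, "Seqinfo"), is(catalog, "FeatureCatalog"), n >= 0)
  bad <- setdiff(names(rho), catalog@priority)
  if (length(bad))
    stop("rho names not in the catalog: ", paste(bad, collapse = ", "))
  if (any(rho < 0)) stop("rho must be non-negative")
  withSeed(seed, {
    maxW <- max(seqlengths(genome))
    rhoFull <- setNames(rep(1, length(catalog@priority)),
                        catalog@priority)
    rhoFull[names(rho)] <- rho
    ## uniform class rates, estimated with the same width distribution
    calib <- randomRegions(nCalibrate,
                           sampleWidths(nCalibrate, widthMeanLog,
                                        widthSdLog, maxW), genome)
    u <- table(classifyPeaks(calib, catalog)) / nCalibrate
    u <- setNames(as.numeric(u), names(u))
    uBg <- u[[catalog@background]]
    focalMass <- sum(u[catalog@priority] * rhoFull)
    if (focalMass > 1)
      stop("infeasible rho: target class rates sum to ", round(focalMass, 3),
           " > 1")
    if (uBg <= 0 && focalMass < 1)
      stop("background class rate is 0; rho cannot be compensated")
    rhoBg <- if (uBg > 0) (1 - focalMass) / uBg else 0
    accept <- c(rhoFull, setNames(rhoBg, catalog@background))
    accept <- accept / max(accept)
    out <- GRanges(seqinfo = genome)
    while (length(out) < n) {
      m <- max(200L, ceiling((n - length(out)) / max(mean(accept), 0.05)))
      prop <- randomRegions(m, sampleWidths(m, widthMeanLog, widthSdLog,
                                            maxW), genome)
      keep <- runif(m) < accept[as.character(classifyPeaks(prop, catalog))]
      out <- c(out, prop[keep])
    }
    unname(out[seq_len(n)])
  })
}

#' Place repeat-like elements in intergenic space
#'
#' Random intervals avoiding an exclusion set (typically gene spans plus
#' promoters), emulating interspersed repeat annotations that sit mostly
#' outside genes.
#'
#' @param n Number of elements.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param avoid Regions the elements must not overlap.
#' @param widthMeanLog,widthSdLog Log-normal width parameters (default
#'   mean ~3 kbp, LINE-like).
#' @param seed Optional seed.
#' @return A [GenomicRanges::GRanges].
#' @export
makeRepeats <- function(n, genome, avoid = NULL,
                        widthMeanLog = log(3000) - 0.3^2 / 2,
                        widthSdLog = 0.3, seed = NULL) {
  withSeed(seed, {
    w <- sampleWidths(n, widthMeanLog, widthSdLog,
                      max(seqlengths(genome)))
    randomRegions(n, w, genome, exclude = avoid)
  })
}

#' Generate a gene abundance table coupled to peak proximity
#'
#' FPKM is log-normal (normal on the log2 scale); genes lying within 5 kb
#' of a peak receive an additive `beta` shift on the log2 scale before
#' exponentiation, so `beta = 0` makes abundance independent of peak
#' proximity and larger `beta` plants the co-location signal the Fisher
#' tests detect.
#'
#' @param config A [simulationConfig()].
#' @param genes Gene models.
#' @param peaks Peak set (a `GRanges`, or a list whose elements are
#'   combined).
#' @param beta Log2-scale shift; defaults to `config$beta`.
#' @param seed Optional seed.
#' @return Data frame `gene_id`, `fpkm`.
#' @export
makeAbundance <- function(config, genes, peaks, beta = config$beta,
                          seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"), beta >= 0)
  if (is.list(peaks))
    peaks <- do.call(c, lapply(peaks, granges))
  withSeed(seed, {
    n <- length(genes)
    log2fpkm <- rnorm(n, config$abundanceMeanLog2, config$abundanceSdLog2)
    if (length(peaks))
      log2fpkm <- log2fpkm + beta * colocationFlag(genes, peaks, 5000)
    data.frame(gene_id = mcols(genes)$gene_id, fpkm = 2^log2fpkm,
               stringsAsFactors = FALSE)
  })
}

#' Generate paired-end fragments around peaks
#'
#' Draws fragments centred uniformly within randomly chosen peaks of each
#' fraction, with template lengths from the configured two-component
#' normal mixture (MN component around 147 bp, SN around 95 bp). The true
#' component of every fragment is recorded in `mcols()$component`, so
#' [partitionFragments()] recovery can be scored exactly.
#'
#' @param config A [simulationConfig()].
#' @param peaksMn,peaksSn Peak sets the two components are centred in.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param nFragments Total fragments; defaults to `config$nFragments`.
#' @param seed Optional seed.
#' @return A [GenomicRanges::GRanges] with a `component` factor column.
#' @export
makeFragments <- function(config, peaksMn, peaksSn, genome,
                          nFragments = config$nFragments, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(seed, {
    nMn <- round(nFragments * config$mnWeight)
    nSn <- nFragments - nMn
    drawOne <- function(nf, peaks, component) {
      if (nf == 0L || length(peaks) == 0L)
        return(GRanges(seqinfo = genome))
      pk <- peaks[sample.int(length(peaks), nf, replace = TRUE)]
      center <- start(pk) + floor(runif(nf) * width(pk))
      len <- pmax(1L, round(rnorm(nf, config$fragMeans[[component]],
                                  config$fragSds[[component]])))
      L <- seqlengths(genome)[as.character(seqnames(pk))]
      len <- pmin(len, L)
      st <- pmin(pmax(center - len %/% 2L, 1L), L - len + 1L)
      gr <- GRanges(seqnames(pk), IRanges(st, width = len),
                    seqinfo = genome)
      mcols(gr)$component <- factor(component, levels = c("MN", "SN"))
      gr
    }
    c(drawOne(nMn, peaksMn, "MN"), drawOne(nSn, peaksSn, "SN"))
  })
}

#' Generate a complete synthetic scenario
#'
#' One call producing every input the pipeline consumes: genome, gene
#' models, feature catalog, MN/SN peak sets (with the configured planted
#' `rho`), abundance table (with the configured `beta`) and the fragment
#' mixture. Fully deterministic for a given `seed`.
#'
#' @param config A [simulationConfig()].
#' @param seed Root seed; defaults to `config$seed`.
#' @return Named list: `config`, `genome`, `genes`, `catalog`, `mnPeaks`,
#'   `snPeaks`, `abundance`, `fragments`.
#' @export
simulateScenario <- function(config = simulationConfig(),
                             seed = config$seed) {
  genome <- makeGenome(config)
  withSeed(seed, {
    genes <- makeGenes(config, genome)
    catalog <- buildFeatureCatalog(genes, genome,
                                   promoterLen = config$promoterLen)
    mnPeaks <- plantPeaks(config$nPeaksMn, genome, catalog,
                          rho = config$rho,
                          widthMeanLog = config$mnWidthMeanLog,
                          widthSdLog = config$mnWidthSdLog)
    snPeaks <- plantPeaks(config$nPeaksSn, genome, catalog,
                          rho = config$rho,
                          widthMeanLog = config$snWidthMeanLog,
                          widthSdLog = config$snWidthSdLog)
    abundance <- makeAbundance(config, genes, list(mnPeaks, snPeaks))
    fragments <- makeFragments(config, mnPeaks, snPeaks, genome)
    list(config = config, genome = genome, genes = genes,
         catalog = catalog, mnPeaks = mnPeaks, snPeaks = snPeaks,
         abundance = abundance, fragments = fragments)
  })
}
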
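## End-to-end orchestration: per-fraction permutation co-location reports,
## class proportions, RNA integration and the TSS matrix, written as TSVs
## with a reproducible run log.

#' Permutation co-location report over many subjects
#'
#' Runs [permutationTest()] for every (query, subject) pair with
#' deterministic per-pair sub-seeds derived from one root seed, and stacks
#' the results into the standard report schema (Source, Feature, Real,
#' Min, Max, Mean, SE, P, FC, Label).
#'
#' @param queries Named list of query region sets (e.g. MN and SN peaks).
#' @param subjects Named list of subject feature sets.
#' @param genome [GenomeInfoDb::Seqinfo] shuffle space.
#' @param nPerms,seed,pThresh,fcUp,fcDown Passed to [permutationTest()].
#' @return A `data.frame`, one row per pair; the `results` attribute keeps
#'   the full [EnrichmentResult-class] objects.
#' @export
enrichmentReport <- function(queries, subjects, genome, nPerms = 1000L,
                             seed = 1L, pThresh = 0.001, fcUp = 1.5,
                             fcDown = 0.66) {
  stopifnot(length(queries) >= 1L, length(subjects) >= 1L,
            !is.null(names(queries)), !is.null(names(subjects)))
  pairSeeds <- deriveSubSeeds(seed, length(queries) * length(subjects))
  results <- list()
  i <- 0L
  for (qn in names(queries)) for (sn in names(subjects)) {
    i <- i + 1L
    results[[paste(qn, sn, sep = ".")]] <-
      permutationTest(queries[[qn]], subjects[[sn]], genome,
                      nPerms = nPerms, seed = pairSeeds[i],
                      pThresh = pThresh, fcUp = fcUp, fcDown = fcDown,
                      queryLabel = qn, subjectLabel = sn)
  }
  df <- do.call(rbind, lapply(results, as.data.frame))
  rownames(df) <- NULL
  attr(df, "results") <- results
  df
}

## Table-2-style display formatting: means/SE/FC to 2 d.p., p as "<1/n"
## below resolution.
formatEnrichmentReport <- function(df, nPerms) {
  out <- df
  out$Mean <- sprintf("%.2f", df$Mean)
  out$SE <- sprintf("%.2f", df$SE)
  out$FC <- ifelse(is.na(df$FC), "NA", sprintf("%.2f", df$FC))
  out$P <- vapply(df$P, formatPValue, "", nPerms = nPerms)
  out
}

.writeTsv <- function(df, path, rownames = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = rownames, col.names = TRUE)
  path
}

#' Run the full co-location analysis
#'
#' Orchestrates every stage on in-memory inputs: builds the gene-feature
#' catalog, classifies peaks (class-proportion table), runs the
#' width-preserving permutation co-location test of each peak fraction
#' against every gene feature and extra subject set, integrates RNA
#' abundance (class-vs-absent Fisher tests and the Kruskal-Wallis
#' comparison of log2 abundances), computes the TSS-centred signal matrix
#' when fragments are supplied, and writes everything to `outdir` as TSV
#' plus a run log that echoes the configuration. Identical seeds give
#' byte-identical outputs.
#'
#' @param genome [GenomeInfoDb::Seqinfo].
#' @param genes Gene models.
#' @param mnPeaks,snPeaks Peak sets of the two fractions.
#' @param subjects Extra named subject sets (piRNA, circRNA, GWAS,
#'   repeats, lifted cross-species peaks, ...) tested alongside the gene
#'   features.
#' @param abundance Optional data frame `gene_id`, `fpkm`.
#' @param fragments Optional fragment spans for the TSS matrix.
#' @param outdir Output directory (created if needed).
#' @param nPerms,seed,pThresh,fcUp,fcDown Permutation-test settings.
#' @param promoterLen Promoter window for the catalog.
#' @param rnaMaxDist Proximity rule for the RNA integration (bp, strict
#'   `<`).
#' @param tssFlank,tssBin TSS matrix geometry.
#' @return Invisibly, a list with the computed tables (`enrichment`,
#'   `proportions`, `rna`, `kruskal`, `tssMatrix`) and the written file
#'   paths.
#' @export
runFullAnalysis <- function(genome, genes, mnPeaks, snPeaks,
                            subjects = list(), abundance = NULL,
                            fragments = NULL, outdir, nPerms = 1000L,
                            seed = 1L, pThresh = 0.001, fcUp = 1.5,
                            fcDown = 0.66, promoterLen = 2000L,
                            rnaMaxDist = 5000, tssFlank = 500L,
                            tssBin = 10L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fail <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  catalog <- tryCatch(
    buildFeatureCatalog(genes, genome, promoterLen = promoterLen),
    error = function(e) fail("feature catalog", e))

  queries <- list(MN = mnPeaks, SN = snPeaks)
  props <- tryCatch({
    p <- lapply(queries, summarizeClasses, catalog = catalog)
    data.frame(class = names(p$MN), MN = unname(p$MN),
               SN = unname(p$SN), stringsAsFactors = FALSE)
  }, error = function(e) fail("peak classification", e))
  files["proportions"] <- .writeTsv(props,
                                    file.path(outdir,
                                              "class_proportions.tsv"))

  featSubjects <- c(as.list(featureRegions(catalog)),
                    list(INTERGENIC = intergenicRegions(catalog)))
  allSubjects <- c(featSubjects, subjects)
  enr <- tryCatch(
    enrichmentReport(queries, allSubjects, genome, nPerms = nPerms,
                     seed = seed, pThresh = pThresh, fcUp = fcUp,
                     fcDown = fcDown),
    error = function(e) fail("permutation enrichment", e))
  files["enrichment_raw"] <- .writeTsv(enr,
                                       file.path(outdir,
                                                 "enrichment_raw.tsv"))
  files["enrichment"] <- .writeTsv(formatEnrichmentReport(enr, nPerms),
                                   file.path(outdir, "enrichment.tsv"))

  rna <- kw <- NULL
  if (!is.null(abundance)) {
    rna <- tryCatch({
      ab <- abundanceTable(genes, abundance, peaks = queries,
                           maxDist = rnaMaxDist)
      rbind(cbind(fraction = "MN",
                  rnaColocationReport(ab, "nearMN")),
            cbind(fraction = "SN",
                  rnaColocationReport(ab, "nearSN")))
    }, error = function(e) fail("rna colocation", e))
    files["rna"] <- .writeTsv(rna, file.path(outdir,
                                             "rna_colocation.tsv"))
    kw <- tryCatch({
      ab <- abundanceTable(genes, abundance, peaks = queries,
                           maxDist = rnaMaxDist)
      groups <- list(all = ab$fpkm, MN = ab$fpkm[ab$nearMN],
                     SN = ab$fpkm[ab$nearSN])
      groups <- groups[lengths(groups) >= 2L]
      res <- kruskalWallisLog2(groups)
      summ <- do.call(rbind, lapply(names(groups), function(g) {
        x <- log2(groups[[g]] + 1)
        q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
        data.frame(group = g, n = length(x), q1 = q[1], median = q[2],
                   q3 = q[3], stringsAsFactors = FALSE)
      }))
      list(test = res, summary = summ)
    }, error = function(e) fail("abundance comparison", e))
    files["abundance_summary"] <-
      .writeTsv(kw$summary, file.path(outdir, "abundance_summary.tsv"))
  }

  tssMat <- NULL
  if (!is.null(fragments)) {
    tssMat <- tryCatch(
      suppressMessages(tssSignalMatrix(fragments, catalog,
                                       flank = tssFlank, bin = tssBin)),
      error = function(e) fail("tss matrix", e))
    files["tss_matrix"] <- .writeTsv(as.data.frame(tssMat),
                                     file.path(outdir, "tss_matrix.tsv"),
                                     rownames = TRUE)
  }

  log <- c(sprintf("nucleoperm %s | R %s.%s",
                   as.character(packageVersion("nucleoperm")),
                   R.version$major, R.version$minor),
           sprintf("seed=%d nPerms=%d pThresh=%g fcUp=%g fcDown=%g",
                   seed, nPerms, pThresh, fcUp, fcDown),
           sprintf("promoterLen=%d rnaMaxDist=%g tssFlank=%d tssBin=%d",
                   promoterLen, rnaMaxDist, tssFlank, tssBin),
           sprintf("genome: %d chromosome(s), %.0f bp",
                   length(seqnames(genome)),
                   sum(as.numeric(seqlengths(genome)))),
           sprintf("genes=%d peaksMN=%d peaksSN=%d subjects=%s",
                   length(genes), length(mnPeaks), length(snPeaks),
                   paste(names(allSubjects), collapse = ",")),
           if (!is.null(kw))
             sprintf("kruskal-wallis: H=%.4f df=%d p=%.6g",
                     kw$test$H, kw$test$df, kw$test$p))
  writeLines(log, file.path(outdir, "run_log.txt"))
  files["log"] <- file.path(outdir, "run_log.txt")

  invisible(list(catalog = catalog, enrichment = enr,
                 proportions = props, rna = rna, kruskal = kw,
                 tssMatrix = tssMat, files = files))
}
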
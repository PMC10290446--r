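## Writes a gene-table TSV (0-based half-open dialect) and reads it back.
readGenes <- function(rows, genome) {
  tf <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(c(paste("gene_id", "chrom", "strand", "span_start",
                     "span_end", "cds_start", "cds_end", "exon_blocks",
                     sep = "\t"), rows), tf)
  readGeneTable(tf, genome)
}

test_that("catalog windows follow strand-aware promoter/TSS arithmetic", {
  gt <- tinyGenome()
  genes <- readGenes(c(
    "plus\tchr1\t+\t10000\t20000\t10200\t19800\t10000-20000",
    "minus\tchr1\t-\t30000\t40000\t30200\t39800\t30000-40000",
    "edge\tchr1\t+\t500\t3000\t600\t2900\t500-3000"), gt)
  cat <- buildFeatureCatalog(genes, gt)
  f <- featureRegions(cat)
  # plus-strand gene, file span [10000,20000): TSS base and 2-kb promoter
  expect_identical(start(f$TSS["plus"]), 10001L)
  expect_identical(width(f$TSS["plus"]), 1L)
  expect_identical(c(start(f$PROMOTER["plus"]), end(f$PROMOTER["plus"])),
                   c(8001L, 10000L))
  # minus-strand mirror: TSS at the span end, promoter downstream in
  # genomic coordinates
  expect_identical(start(f$TSS["minus"]), 40000L)
  expect_identical(c(start(f$PROMOTER["minus"]), end(f$PROMOTER["minus"])),
                   c(40001L, 42000L))
  # promoter overhanging the chromosome start is clipped at base 1
  expect_identical(c(start(f$PROMOTER["edge"]), end(f$PROMOTER["edge"])),
                   c(1L, 500L))
  # UTRs flank the CDS in transcription order
  expect_identical(c(start(f$UTR5["plus"]), end(f$UTR5["plus"])),
                   c(10001L, 10200L))
  expect_identical(c(start(f$UTR5["minus"]), end(f$UTR5["minus"])),
                   c(39801L, 40000L))
})

test_that("intron blocks are the span minus the exons", {
  gt <- tinyGenome()
  genes <- readGenes(
    "g\tchr1\t+\t1000\t9000\t1500\t8500\t1000-3000,4000-6000,7000-9000",
    gt)
  intr <- featureRegions(buildFeatureCatalog(genes, gt))$INTRON
  expect_identical(start(intr), c(3001L, 6001L))
  expect_identical(end(intr), c(4000L, 7000L))
})

test_that("peaks take the highest-priority overlapping class", {
  gt <- tinyGenome()
  genes <- readGenes(
    "g\tchr1\t+\t10000\t20000\t10300\t19700\t10000-12000,15000-20000",
    gt)
  cat <- buildFeatureCatalog(genes, gt)
  classify <- function(s, e) as.character(classifyPeaks(gr1(s, e), cat))
  expect_identical(classify(9950, 10050), "TSS")      # TSS beats promoter
  expect_identical(classify(9000, 9500), "PROMOTER")
  expect_identical(classify(10150, 10250), "UTR5")
  expect_identical(classify(11900, 12100), "CDS")     # CDS beats intron
  expect_identical(classify(13000, 13500), "INTRON")
  expect_identical(classify(50000, 50100), "INTERGENIC")
  # a custom priority putting INTRON above CDS flips the straddling peak
  cat2 <- buildFeatureCatalog(genes, gt,
                              priority = c("TSS", "PROMOTER", "UTR5",
                                           "UTR3", "INTRON", "CDS"))
  expect_identical(as.character(classifyPeaks(gr1(11900, 12100), cat2)),
                   "INTRON")
})

test_that("class proportions are exhaustive, sum to 1 and ignore gene order", {
  set.seed(21)
  cfg <- simulationConfig(nGenes = 60,
                          chromLengths = c(chr1 = 2e6, chr2 = 1e6))
  gt <- makeGenome(cfg)
  genes <- makeGenes(cfg, gt, seed = 8)
  cat <- buildFeatureCatalog(genes, gt)
  peaks <- randomRegions(400, 270, gt, seed = 9)
  pr <- summarizeClasses(peaks, cat)
  expect_equal(sum(pr), 1)
  expect_identical(names(pr), featureClasses(cat))
  catRev <- buildFeatureCatalog(rev(genes), gt)
  expect_equal(summarizeClasses(peaks, catRev), pr)
  expect_error(summarizeClasses(GRanges(seqinfo = gt), cat), "empty")
  # counts sum to the number of peaks
  expect_identical(sum(table(classifyPeaks(peaks, cat))), 400L)
})

test_that("classification is invariant under genome mirroring", {
  cfg <- simulationConfig(nGenes = 40,
                          chromLengths = c(chr1 = 2e6, chr2 = 1e6))
  gt <- makeGenome(cfg)
  genes <- makeGenes(cfg, gt, seed = 31)
  peaks <- randomRegions(300, 270, gt, seed = 32)
  pr <- summarizeClasses(peaks, buildFeatureCatalog(genes, gt))
  prM <- summarizeClasses(mirrorRegions(peaks),
                          buildFeatureCatalog(mirrorGenes(genes), gt))
  expect_equal(prM, pr)
})

test_that("TSS signal matrix geometry, orientation and filters", {
  gt <- tinyGenome()
  genes <- readGenes(c(
    "plus\tchr1\t+\t30000\t40000\t30200\t39800\t30000-40000",
    "minus\tchr1\t-\t60000\t70000\t60200\t69800\t60000-70000"), gt)
  cat <- buildFeatureCatalog(genes, gt)
  # one fragment spanning the whole chromosome -> constant matrix
  whole <- gr1(1, 100000)
  m <- tssSignalMatrix(whole, cat, flank = 500, bin = 10)
  expect_identical(dim(m), c(2L, 100L))
  expect_true(all(m == 1))
  expect_error(tssSignalMatrix(whole, cat, flank = 505, bin = 10),
               "divisible")
  # a fragment downstream of the plus TSS and its strand-mirror image
  # upstream of the minus TSS give identical row profiles
  fr <- gr1(c(30001 + 10, 70000 - 40), c(30001 + 40, 70000 - 10))
  m2 <- tssSignalMatrix(fr, cat, flank = 500, bin = 10)
  expect_gt(sum(m2["plus", ]), 0)
  expect_identical(m2["plus", ], m2["minus", ])
  # skipZeros drops silent genes
  frPlus <- gr1(30100, 30200)
  m3 <- tssSignalMatrix(frPlus, cat, flank = 500, bin = 10,
                        skipZeros = TRUE)
  expect_identical(rownames(m3), "plus")
})
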
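test_that("genome construction is configured and validated", {
  gt <- makeGenome(simulationConfig(chromLengths = c(a = 1e6, b = 1e6)))
  expect_identical(sum(as.numeric(seqlengths(gt))), 2e6)
  expect_identical(makeGenome(simulationConfig()),
                   makeGenome(simulationConfig()))
  expect_error(makeGenome(simulationConfig(chromLengths = numeric(0))),
               "zero chromosomes")
})

test_that("generated gene models satisfy every structural invariant", {
  cfg <- simulationConfig(nGenes = 120,
                          chromLengths = c(chr1 = 3e6, chr2 = 2e6))
  gt <- makeGenome(cfg)
  genes <- makeGenes(cfg, gt, seed = 7)
  expect_length(genes, 120)
  expect_identical(makeGenes(cfg, gt, seed = 7), genes)
  # non-overlapping spans within each chromosome
  expect_identical(length(reduce(granges(genes))), length(genes))
  mc <- mcols(genes)
  for (i in seq_along(genes)) {
    span <- IRanges(start(genes)[i], end(genes)[i])
    ex <- mc$exons[[i]]
    expect_true(all(start(ex) >= start(span) & end(ex) <= end(span)))
    # introns are exactly the span minus the exons
    expect_identical(mc$introns[[i]], setdiff(span, ex))
    # cds + utr blocks partition the exonic bases
    expect_identical(sum(width(mc$cds[[i]])) + sum(width(mc$utr5[[i]])) +
                       sum(width(mc$utr3[[i]])), sum(width(ex)))
    expect_gt(sum(width(mc$cds[[i]])), 0L)
  }
  # both strands represented, ratio compatible with Bernoulli(1/2)
  nPlus <- sum(strand(genes) == "+")
  expect_gt(nPlus, qbinom(0.0005, 120, 0.5))
  expect_lt(nPlus, qbinom(0.9995, 120, 0.5))
})

test_that("planted rho of 1 reduces to uniform placement", {
  cfg <- simulationConfig(nGenes = 100,
                          chromLengths = c(chr1 = 4e6, chr2 = 2e6))
  gt <- makeGenome(cfg)
  genes <- makeGenes(cfg, gt, seed = 19)
  cat <- buildFeatureCatalog(genes, gt)
  # family-wise null sanity: no enriched/depleted labels in >= 90% of runs
  feats <- featureRegions(cat)
  clean <- vapply(1:10, function(run) {
    pk <- plantPeaks(500, gt, cat, seed = 100 + run,
                     nCalibrate = 5000)
    labels <- vapply(names(feats), function(nm) {
      enrichmentLabel(permutationTest(pk, feats[[nm]], gt, nPerms = 200,
                                      seed = 200 + run))
    }, "")
    all(labels == "none")
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("planted enrichment and depletion are recovered end to end", {
  cfg <- simulationConfig(nGenes = 150,
                          chromLengths = c(chr1 = 6e6, chr2 = 4e6))
  gt <- makeGenome(cfg)
  genes <- makeGenes(cfg, gt, seed = 23)
  gcat <- buildFeatureCatalog(genes, gt)
  # repeat-like LINE features live in intergenic space, as in real genomes
  avoid <- c(granges(featureRegions(gcat)$PROMOTER), granges(genes))
  lines <- makeRepeats(250, gt, avoid = avoid, seed = 24)
  cat <- featureCatalog(c(as.list(featureRegions(gcat)[c("TSS",
                                                         "PROMOTER")]),
                          list(LINE = lines)), gt)
  rho <- c(TSS = 11, PROMOTER = 5, LINE = 0.5)
  feats <- featureRegions(cat)
  hits <- vapply(1:20, function(run) {
    pk <- plantPeaks(2000, gt, cat, rho = rho, seed = 300 + run,
                     nCalibrate = 10000)
    lab <- vapply(c("TSS", "PROMOTER", "LINE"), function(nm) {
      enrichmentLabel(permutationTest(pk, feats[[nm]], gt, nPerms = 200,
                                      seed = 400 + run))
    }, "")
    all(lab == c(TSS = "enriched", PROMOTER = "enriched",
                 LINE = "depleted"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("infeasible planting targets are rejected", {
  cfg <- simulationConfig(nGenes = 80,
                          chromLengths = c(chr1 = 2e6))
  gt <- makeGenome(cfg)
  cat <- buildFeatureCatalog(makeGenes(cfg, gt, seed = 3), gt)
  expect_error(plantPeaks(100, gt, cat, rho = c(INTRON = 50),
                          seed = 1, nCalibrate = 2000), "infeasible")
  expect_error(plantPeaks(100, gt, cat, rho = c(BOGUS = 2)), "not in")
})

test_that("abundance generator populates all classes and plants coupling", {
  cfg <- simulationConfig(nGenes = 2000,
                          chromLengths = c(chr1 = 2e7, chr2 = 2e7))
  gt <- makeGenome(cfg)
  genes <- makeGenes(cfg, gt, seed = 31)
  peaks <- randomRegions(1200, 270, gt, seed = 32)
  ab0 <- makeAbundance(cfg, genes, peaks, beta = 0, seed = 33)
  expect_true(all(table(binAbundance(ab0$fpkm)) > 0))
  # strong coupling: the class-vs-absent test sees it at 2000 genes
  ab2 <- makeAbundance(cfg, genes, peaks, beta = 2, seed = 33)
  tab <- abundanceTable(genes, ab2, peaks = list(MN = peaks))
  p <- fisherClassVsAbsent(classContingency(tab, "low", "nearMN"))
  expect_lt(p, 1e-4)
  # and beta = 0 gives no signal at the same seed
  tab0 <- abundanceTable(genes, ab0, peaks = list(MN = peaks))
  expect_gt(fisherClassVsAbsent(classContingency(tab0, "low", "nearMN")),
            0.001)
})

test_that("fragment mixtures separate cleanly at the 110/111 boundary", {
  cfg <- simulationConfig()
  sc <- simulateScenario(cfg, seed = 77)
  fr <- sc$fragments
  expect_length(fr, cfg$nFragments)
  expect_identical(makeFragments(cfg, sc$mnPeaks, sc$snPeaks, sc$genome,
                                 seed = 5),
                   makeFragments(cfg, sc$mnPeaks, sc$snPeaks, sc$genome,
                                 seed = 5))
  expect_length(makeFragments(cfg, sc$mnPeaks, sc$snPeaks, sc$genome,
                              nFragments = 0), 0)
  p <- partitionFragments(fr)
  predicted <- c(rep("SN", length(snFraction(p))),
                 rep("MN", length(mnFraction(p))))
  truth <- mcols(fr)$component
  inSn <- width(fr) <= 110
  agreement <- mean(ifelse(inSn, "SN", "MN") == as.character(truth))
  expect_gte(agreement, 0.95)
  # normal tail computation: misclassification across the boundary < 5%
  expect_lt(mean(truth == "MN" & inSn) + mean(truth == "SN" & !inSn),
            0.05)
})

test_that("generator output feeds every consumer without violation", {
  sc <- simulateScenario(simulationConfig(nGenes = 80,
                                          nPeaksMn = 200, nPeaksSn = 50,
                                          nFragments = 1000),
                         seed = 55)
  expect_true(validObject(sc$catalog))
  expect_s4_class(sc$mnPeaks, "GRanges")
  cls <- classifyPeaks(sc$mnPeaks, sc$catalog)
  expect_false(anyNA(cls))
  expect_identical(length(cls), length(sc$mnPeaks))
  expect_true(all(sc$abundance$fpkm >= 0))
  expect_identical(nrow(sc$abundance), length(sc$genes))
  p <- partitionFragments(sc$fragments)
  expect_identical(length(snFraction(p)) + length(mnFraction(p)) +
                     discardedCount(p), 1000L)
  # determinism of the whole scenario
  sc2 <- simulateScenario(simulationConfig(nGenes = 80,
                                           nPeaksMn = 200, nPeaksSn = 50,
                                           nFragments = 1000),
                          seed = 55)
  expect_identical(sc2$mnPeaks, sc$mnPeaks)
  expect_identical(sc2$abundance, sc$abundance)
})
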
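test_that("shuffles preserve widths, stay in bounds and are seeded", {
  set.seed(13)
  for (i in 1:25) {
    gt <- randomGenomeTable(sample(1:4, 1))
    rs <- randomIntervalSet(gt, sample.int(100, 1))
    sh <- shuffleRegions(rs, gt)
    expect_identical(width(sh), width(rs))
    sl <- seqlengths(gt)[as.character(seqnames(sh))]
    expect_true(all(start(sh) >= 1) && all(end(sh) <= sl))
  }
  gt <- Seqinfo("chr1", 1000L)
  tooWide <- GRanges("chr1", IRanges(1, 1000), seqinfo = gt)
  suppressWarnings(width(tooWide) <- 1001L)
  expect_error(suppressWarnings(shuffleRegions(tooWide, gt)),
               "wider than every chromosome")
  rs <- randomIntervalSet(tinyGenome(), 40)
  a <- withSeed(99, shuffleRegions(rs))
  b <- withSeed(99, shuffleRegions(rs))
  expect_identical(a, b)
})

test_that("same-chromosome placement and exclude sets are honoured", {
  gt <- tinyGenome()
  rs <- c(gr1(c(1, 50), c(270, 319)), gr1(1, 141, chrom = "chr2"))
  sh <- withSeed(4, shuffleRegions(rs, gt,
                                   placement = "same-chromosome"))
  expect_identical(as.character(seqnames(sh)),
                   as.character(seqnames(rs)))
  excl <- gr1(1, 90000)  # only [90001, 100000] of chr1 stays open
  sh2 <- withSeed(5, shuffleRegions(gr1(c(1, 1), c(100, 100)), gt,
                                    exclude = excl))
  expect_false(any(overlapsAny(sh2, excl)))
})

test_that("empirical p follows the two-sided deviation rule", {
  expect_equal(computeEmpiricalP(5.5, rep(5.5, 10)), 1)   # obs == mean
  expect_equal(computeEmpiricalP(10, 1:10), 0.2)          # {1, 10} qualify
  expect_equal(computeEmpiricalP(100, 1:10), 0)
  expect_equal(computeEmpiricalP(100, 1:10, estimator = "add-one"),
               1 / 11)
  # mid-p halves the tie mass: counts 1 and 10 both tie at deviation 4.5
  expect_equal(computeEmpiricalP(10, 1:10, estimator = "mid"),
               (0 + 0.5 * 2) / 10)
  expect_identical(formatPValue(0, 1000), "<0.001")
  expect_identical(formatPValue(0, 200), "<0.005")
})

test_that("fold change reproduces the reported arithmetic", {
  expect_equal(round(computeFoldChange(2793, 553.01), 2), 5.05)
  expect_equal(round(computeFoldChange(3826, 7889.53), 2), 0.48)
  expect_equal(computeFoldChange(50, 50), 1)
  expect_warning(fc0 <- computeFoldChange(5, 0), "undefined")
  expect_true(is.na(fc0))
})

test_that("enrichment calls apply both the p and FC thresholds", {
  expect_identical(classifyEnrichment(1e-4, 5.05), "enriched")
  expect_identical(classifyEnrichment(0.09, 1.10), "none")
  expect_identical(classifyEnrichment(1e-4, 0.47), "depleted")
  expect_identical(classifyEnrichment(1e-4, 1.2), "none")  # fc in between
  expect_identical(classifyEnrichment(0.5, 9.0), "none")   # p too large
  expect_identical(classifyEnrichment(c(1e-4, 0.5), c(2, 2)),
                   c("enriched", "none"))
  expect_error(classifyEnrichment(0.5, 1, fcUp = 0.5, fcDown = 0.9))
})

test_that("a saturating subject gives fc 1 and no call", {
  gt <- tinyGenome()
  q <- gr1(c(1000, 30000, 70000), c(1270, 30270, 70270))
  tiles <- genomeBins(gt, 5000)
  r <- permutationTest(q, tiles, gt, nPerms = 50, seed = 2)
  expect_identical(observedCount(r), 3L)
  expect_true(all(permCounts(r) == 3))
  expect_equal(foldChange(r), 1)
  expect_equal(empiricalP(r), 1)
  expect_identical(enrichmentLabel(r), "none")
})

test_that("permutation test equals the composition of its parts", {
  gt <- makeGenome(simulationConfig())
  q <- randomRegions(120, 270, gt, seed = 51)
  s <- randomRegions(80, 2000, gt, seed = 52)
  for (seed in c(1, 7, 3141)) {
    r <- permutationTest(q, s, gt, nPerms = 1, seed = seed)
    sub <- withSeed(seed, sample.int(.Machine$integer.max - 1L, 1))
    shuffled <- withSeed(sub, shuffleRegions(q, gt))
    expect_identical(permCounts(r),
                     as.numeric(countOverlapping(shuffled, s)))
    expect_identical(observedCount(r), countOverlapping(q, s))
  }
  # full determinism of the summary for a fixed root seed
  r1 <- permutationTest(q, s, gt, nPerms = 30, seed = 9)
  r2 <- permutationTest(q, s, gt, nPerms = 30, seed = 9)
  expect_identical(permCounts(r1), permCounts(r2))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("result objects expose a coherent summary", {
  gt <- makeGenome(simulationConfig())
  q <- randomRegions(100, 270, gt, seed = 61)
  s <- randomRegions(150, 2000, gt, seed = 62)
  r <- permutationTest(q, s, gt, nPerms = 40, seed = 8,
                       queryLabel = "MN", subjectLabel = "piRNA")
  sm <- permSummary(r)
  expect_true(sm[["min"]] <= sm[["mean"]] && sm[["mean"]] <= sm[["max"]])
  expect_equal(sm[["se"]], sd(permCounts(r)))
  expect_equal(permSummary(r, sd = FALSE)[["se"]],
               sd(permCounts(r)) / sqrt(40))
  df <- as.data.frame(r)
  expect_identical(df$Source, "MN")
  expect_identical(df$Feature, "piRNA")
  expect_equal(df$FC, observedCount(r) / mean(permCounts(r)))
  expect_output(show(r), "MN vs piRNA")
})

test_that("null fold changes centre on 1", {
  gt <- makeGenome(simulationConfig())
  subj <- randomRegions(120, 1500, gt, seed = 70)  # ~1.8% of the genome
  tmpl <- GRanges("chr1", IRanges(1, width = rep(270, 60)), seqinfo = gt)
  seeds <- withSeed(71, sample.int(1e8, 100))
  fcs <- vapply(seeds, function(s) {
    q <- withSeed(s, shuffleRegions(tmpl, gt))
    foldChange(permutationTest(q, subj, gt, nPerms = 60, seed = s + 1))
  }, numeric(1))
  expect_gt(mean(fcs), 0.8)
  expect_lt(mean(fcs), 1.2)
})
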
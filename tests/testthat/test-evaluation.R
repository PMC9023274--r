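library(IRanges)

test_that("binding-site coverage counts recovered reference nucleotides", {
  ref <- IRanges(10, 19)
  def <- 1:100
  expect_equal(bsc(10:12, ref, def), 0.3)
  expect_equal(bsc(1:100, ref, def), 1)
  expect_equal(bsc(integer(), ref, def), 0)
  # only defined reference positions enter the denominator
  expect_equal(bsc(10:12, ref, 5:14), 3 / 5)
  expect_error(bsc(1:5, IRanges(200, 210), def), "undefined")
})

test_that("normalized BSC divides by the defined called-set size", {
  def <- 1:100
  expect_equal(normalizedBsc(1:10, IRanges(1, 10), def), 1 / 10)
  # doubling called positions outside the reference halves the value
  expect_equal(normalizedBsc(1:20, IRanges(1, 10), def),
               normalizedBsc(1:10, IRanges(1, 10), def) / 2)
  expect_error(normalizedBsc(integer(), IRanges(1, 10), def), "no called")
})

test_that("Jaccard index is intersection over union of positions", {
  expect_equal(jaccardIndex(IRanges(1, 10), IRanges(6, 15)), 1 / 3)
  expect_equal(jaccardIndex(IRanges(1, 10), IRanges(1, 10)), 1)
  expect_equal(jaccardIndex(IRanges(1, 10), IRanges(50, 60)), 0)
  expect_error(jaccardIndex(IRanges(), IRanges()), "empty")
})

test_that("permutation p-values are bit-reproducible under a fixed seed", {
  case <- syntheticPair(genomeLength = 1500, nSites = 2, span = 90,
                        seed = 5)
  r1 <- shuffleTest(case$gRNA, case$protein, polarRequirement(),
                    case$planted, cutoff = -0.5, mode = "shuffle_CP",
                    profileKind = "pearson", n = 25, seed = 99)
  r2 <- shuffleTest(case$gRNA, case$protein, polarRequirement(),
                    case$planted, cutoff = -0.5, mode = "shuffle_CP",
                    profileKind = "pearson", n = 25, seed = 99)
  expect_identical(r1@nullBscs, r2@nullBscs)
  expect_identical(r1@pValue, r2@pValue)
  expect_equal(r1@pValue, mean(r1@nullBscs >= r1@nativeBsc - 1e-12))
})

test_that("an unbeatable native prediction yields p = 0", {
  # noise-free planted sites: the native profile covers the planted
  # reference almost perfectly while shuffled genomes cannot
  case <- syntheticPair(genomeLength = 1500, nSites = 2, span = 90,
                        noise = 0, seed = 8)
  r <- shuffleTest(case$gRNA, case$protein, case$scales, case$planted,
                   cutoff = -2, mode = "shuffle_gRNA",
                   profileKind = "energy", n = 50, seed = 1)
  expect_gt(r@nativeBsc, 0.2)
  expect_identical(r@pValue, 0)
})

test_that("BSC is monotone non-decreasing in a min-direction cutoff", {
  case <- syntheticPair(genomeLength = 2000, nSites = 2, span = 120,
                        seed = 13)
  mp <- slidingPearson(case$gRNA, case$protein, polarRequirement())
  def <- definedPositions(mp)
  cuts <- seq(-0.9, 0.6, by = 0.1)
  bscs <- vapply(cuts, function(ct)
    bsc(callSites(mp, ct), case$planted, def), numeric(1))
  expect_true(all(diff(bscs) >= 0))
  # a cutoff below the profile minimum calls nothing
  expect_equal(bsc(callSites(mp, -1.01), case$planted, def), 0)
})

test_that("bscCurve reports native BSC, null medians and p per cutoff", {
  case <- syntheticPair(genomeLength = 1500, nSites = 2, span = 90,
                        seed = 3)
  cuts <- c(-0.8, -0.5, -0.2)
  tab <- bscCurve(case$gRNA, case$protein, polarRequirement(),
                  case$planted, cutoffs = cuts, profileKind = "pearson",
                  n = 20, seed = 7)
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$native_bsc) >= 0))
  expect_true(all(tab$p_gRNA >= 0 & tab$p_gRNA <= 1))
  expect_true(all(tab$p_CP >= 0 & tab$p_CP <= 1))
  # shared shuffle set: rerunning reproduces the table exactly
  tab2 <- bscCurve(case$gRNA, case$protein, polarRequirement(),
                   case$planted, cutoffs = cuts, profileKind = "pearson",
                   n = 20, seed = 7)
  expect_identical(tab, tab2)
})

test_that("coverage-based references keep the top percentage and flanks", {
  cov <- c(rep(1, 90), rep(100, 10))
  r <- coverageReference(cov, topPct = 10)
  expect_identical(IRanges::start(r), 91L)
  expect_identical(IRanges::end(r), 100L)
  r2 <- coverageReference(cov, topPct = 10, flank = 5)
  expect_identical(IRanges::start(r2), 86L)
  expect_identical(IRanges::end(r2), 100L)
})
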
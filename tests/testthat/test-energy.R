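zeroScales <- function() {
  z <- setNames(rep(0, 20), AA20)
  fam <- lapply(c("A", "C", "G", "U"), function(b)
    affinityScale(paste0("Z", b), z, direction = "min"))
  names(fam) <- c("A", "C", "G", "U")
  fam
}

test_that("fragment energy is the affinity-weighted base-count sum", {
  fam <- zeroScales()
  expect_identical(fragmentEnergy("ACGUACGUA", 1, "KRM", fam), 0)

  vals <- setNames(rep(0, 20), AA20)
  valsA <- vals; valsA["K"] <- -1
  valsG <- vals; valsG["R"] <- -2
  fam$A <- affinityScale("A", valsA)
  fam$G <- affinityScale("G", valsG)
  expect_identical(fragmentEnergy("AAAGGG", 1, "KR", fam), -9)
  expect_error(fragmentEnergy("AAAGGG", 2, "KR", fam), "outside")

  # additivity over protein halves
  set.seed(77)
  g <- randomRna(120)
  p <- randomProtein(20)
  fam2 <- pairScaleFamily(polarRequirement())
  e <- fragmentEnergy(g, 7, p, fam2)
  eL <- fragmentEnergy(g, 7, substring(p, 1, 8), fam2)
  eR <- fragmentEnergy(g, 7 + 24, substring(p, 9, 20), fam2)
  expect_equal(e, eL + eR, tolerance = 1e-10)
})

test_that("energy profile matches the brute-force oracle", {
  set.seed(44)
  for (i in 1:4) {
    g <- randomRna(sample(250:500, 1))
    p <- randomProtein(sample(c(20, 33), 1))
    fam <- pairScaleFamily(polarRequirement())
    ep <- energyProfile(g, p, fam, smoothingWindow = 63)
    orc <- oracleEnergyProfile(g, p, fam, sw = 63)
    expect_equal(rawEnergy(ep), orc$raw, tolerance = 1e-9)
    expect_equal(profileValues(ep), orc$smoothed, tolerance = 1e-9)
    expect_equal(zScores(ep), orc$z, tolerance = 1e-9)
  }
})

test_that("energy margins: first/last (3N-1)/2 + 31 positions undefined (odd N)", {
  set.seed(9)
  L <- 1000L
  g <- randomRna(L)
  fam <- pairScaleFamily(polarRequirement())
  ep <- energyProfile(g, randomProtein(129), fam)
  expect_identical(firstDefined(ep), 225L)
  expect_identical(lastDefined(ep), L - 224L)
  epEven <- energyProfile(g, randomProtein(50), fam)
  expect_identical(firstDefined(epEven), 107L)  # 3N/2 + 31 + 1
  expect_identical(lastDefined(epEven), L - 106L)
})

test_that("z-scores have mean 0 and population sd 1 over defined positions", {
  set.seed(10)
  ep <- energyProfile(randomRna(800), randomProtein(41),
                      pairScaleFamily(polarRequirement()))
  z <- zScores(ep)
  z <- z[!is.na(z)]
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
})

test_that("a constant-composition genome gives a flat raw profile and no z", {
  ep <- energyProfile(strrep("A", 500), randomProtein(31),
                      pairScaleFamily(polarRequirement()))
  raw <- rawEnergy(ep)
  expect_equal(diff(range(raw[!is.na(raw)])), 0)
  expect_true(all(is.na(zScores(ep))))
})

test_that("fractional triplet content scales raw energy by 1/3 and leaves z unchanged", {
  set.seed(71)
  g <- randomRna(600)
  p <- randomProtein(33)
  fam <- pairScaleFamily(polarRequirement())
  famThird <- lapply(fam, function(s)
    affinityScale(s@name, scaleValues(s) / 3, direction = "min"))
  e1 <- energyProfile(g, p, fam)
  e3 <- energyProfile(g, p, famThird)
  expect_equal(rawEnergy(e3), rawEnergy(e1) / 3, tolerance = 1e-9)
  expect_equal(zScores(e3), zScores(e1), tolerance = 1e-9)
})

test_that("adding a constant to every scale shifts raw energy uniformly, z unchanged", {
  set.seed(72)
  g <- randomRna(600)
  p <- randomProtein(34)
  fam <- pairScaleFamily(polarRequirement())
  famShift <- lapply(fam, function(s)
    affinityScale(s@name, scaleValues(s) + 2.5, direction = "min"))
  e1 <- energyProfile(g, p, fam)
  e2 <- energyProfile(g, p, famShift)
  shift <- rawEnergy(e2) - rawEnergy(e1)
  expect_equal(diff(range(shift[!is.na(shift)])), 0, tolerance = 1e-9)
  expect_equal(zScores(e2), zScores(e1), tolerance = 1e-9)
})

test_that("region prediction thresholds inclusively and merges by the strict gap rule", {
  mkProfile <- function(v) new("EnergyProfile", seqId = "g", values = v,
                               window = 63L, unit = "nt", proteinId = "p",
                               raw = v, z = (v - mean(v, na.rm = TRUE)) /
                                 stats::sd(v, na.rm = TRUE),
                               nResidues = 11L)
  set.seed(20)
  n <- 300
  base <- runif(n, 1, 2)
  # two 12-nt runs at -1 separated by a 9-nt gap -> merged
  v <- base
  v[101:112] <- -1
  v[122:133] <- -1
  reg <- predictRegions(mkProfile(v), percentile = 7, mergeGap = 10)
  expect_identical(length(reg), 1L)
  expect_identical(IRanges::start(reg), 101L)
  expect_identical(IRanges::end(reg), 133L)
  # gap of exactly 10 -> kept separate
  v <- base
  v[101:112] <- -1
  v[123:134] <- -1
  reg <- predictRegions(mkProfile(v), percentile = 7, mergeGap = 10)
  expect_identical(length(reg), 2L)
  expect_identical(IRanges::start(reg), c(101L, 123L))

  expect_error(predictRegions(mkProfile(v), percentile = 0), "between 0 and 100")
  expect_error(predictRegions(mkProfile(v), percentile = 100), "between 0 and 100")
})

test_that("energy site calling thresholds z inclusively", {
  v <- rep(NA_real_, 400)
  z <- rep(NA_real_, 400)
  z[300:302] <- c(-1.5, -0.9, -2.0)
  ep <- new("EnergyProfile", seqId = "g", values = v, window = 63L,
            unit = "nt", proteinId = "p", raw = v, z = z, nResidues = 11L)
  expect_identical(callSites(ep, -1.3), c(300L, 302L))
  expect_length(callSites(ep, -3), 0L)
  expect_identical(callSites(ep, max(z, na.rm = TRUE)), c(300L, 301L, 302L))
})
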
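test_that("a density track built from the scale values correlates perfectly in frame", {
  # four residues with affinities 0, 1/3, 2/3, 1 under a toy scale;
  # triplets engineered to carry exactly those pyrimidine densities
  vals <- setNames(rep(0, 20), AA20)
  vals[c("A", "D", "G", "K")] <- c(0, 1/3, 2/3, 1)
  sc <- affinityScale("toy", vals)
  units <- c(A = "AAA", D = "CAA", G = "CCA", K = "CCC")
  set.seed(42)
  aa <- sample(c("A", "D", "G", "K"), 80, replace = TRUE)
  g <- paste(units[aa], collapse = "")
  mp <- slidingPearson(g, paste(aa, collapse = ""), sc, baseSet = c("C", "U"),
                       w = 5)
  nAa <- 80L
  inFrame <- 1L + 3L * (0:(nchar(g) / 3 - nAa))  # fragment starts, frame 0
  v <- profileValues(mp)
  centers <- inFrame + 3L * nAa %/% 2L  # even protein: straddle average
  r <- v[centers]
  expect_true(all(r[!is.na(r)] > 0.99))
})

test_that("match-profile margins follow the centre-assignment arithmetic", {
  set.seed(12)
  L <- 1000L
  g <- randomRna(L)
  sc <- polarRequirement()
  # odd protein length: (3N-1)/2 positions undefined on each side
  mpOdd <- slidingPearson(g, randomProtein(129), sc)
  expect_identical(firstDefined(mpOdd), 194L)
  expect_identical(lastDefined(mpOdd), L - 193L)
  # even protein length: 3N/2 on each side
  mpEven <- slidingPearson(g, randomProtein(60), sc)
  expect_identical(firstDefined(mpEven), 91L)
  expect_identical(lastDefined(mpEven), L - 90L)
})

test_that("sliding Pearson matches the brute-force oracle", {
  set.seed(33)
  for (i in 1:5) {
    g <- randomRna(sample(300:600, 1))
    p <- randomProtein(sample(c(25, 40, 61), 1))
    for (bs in list("A", c("C", "U"))) {
      mine <- profileValues(slidingPearson(g, p, polarRequirement(),
                                           baseSet = bs, w = 21))
      oracle <- oracleSlidingPearson(g, p, polarRequirement(), bs, w = 21)
      expect_equal(mine, oracle, tolerance = 1e-12)
    }
  }
})

test_that("zero-variance windows are undefined, not poisoning", {
  g <- strrep("A", 400)  # homopolymer: density track has zero variance
  mp <- slidingPearson(g, randomProtein(31), polarRequirement())
  expect_true(all(is.na(profileValues(mp))))
  expect_length(callSites(mp, cutoff = 0), 0L)
})

test_that("reversing both sequences mirrors the profile", {
  set.seed(14)
  g <- randomRna(500)
  p <- randomProtein(41)
  fwd <- profileValues(slidingPearson(g, p, polarRequirement()))
  revg <- paste(rev(strsplit(g, "")[[1]]), collapse = "")
  revp <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
  bwd <- profileValues(slidingPearson(revg, revp, polarRequirement()))
  expect_equal(bwd, rev(fwd), tolerance = 1e-12)
})

test_that("combined knowledge profile is R_G + R_C + R_U - R_A", {
  set.seed(55)
  g <- randomRna(420)
  p <- randomProtein(31)
  fam <- list(ADE = affinityScale("ADE", setNames(rnorm(20), AA20)),
              GUA = affinityScale("GUA", setNames(rnorm(20), AA20)),
              CYT = affinityScale("CYT", setNames(rnorm(20), AA20)),
              URA = affinityScale("URA", setNames(rnorm(20), AA20)))
  comb <- profileValues(combinedKnowledgeProfile(g, p, fam))
  parts <- mapply(function(nm, b) profileValues(
    slidingPearson(g, p, fam[[nm]], baseSet = b)),
    c("ADE", "GUA", "CYT", "URA"), c("A", "G", "C", "U"),
    SIMPLIFY = FALSE)
  expected <- parts[[2]] + parts[[3]] + parts[[4]] - parts[[1]]
  expect_equal(comb, expected, tolerance = 1e-12)
  expect_true(all(abs(comb[!is.na(comb)]) <= 4))
  expect_error(combinedKnowledgeProfile(g, p, fam[1:3]), "four")
})

test_that("site calling respects cutoff, direction and undefined positions", {
  v <- rep(NA_real_, 300)
  v[200:202] <- c(-0.7, -0.5, -0.65)
  mp <- new("MatchProfile", seqId = "g", values = v, window = 21L,
            unit = "nt", proteinId = "p", scaleName = "s",
            baseSet = c("C", "U"), direction = "min", nResidues = 31L)
  expect_identical(callSites(mp, -0.6), c(200L, 202L))
  expect_length(callSites(mp, -1), 0L)
  # max direction mirrors min on the negated profile
  mpNeg <- new("MatchProfile", seqId = "g", values = -v, window = 21L,
               unit = "nt", proteinId = "p", scaleName = "ADE",
               baseSet = "A", direction = "max", nResidues = 31L)
  expect_identical(callSites(mpNeg, 0.6), callSites(mp, -0.6))
})

test_that("a genome shorter than one fragment is an error", {
  expect_error(slidingPearson(randomRna(100), randomProtein(50),
                              polarRequirement()), "cannot host")
})
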
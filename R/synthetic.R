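#' Derive a four-base affinity-scale family from a single scale
#'
#' Builds synthetic knowledge-based-style scales for all four
#' nucleobases from one affinity scale: the centred scale values are
#' used as the affinity for every base in \code{baseSet} and their
#' negation for the complementary bases (signs flipped for a
#' \code{"max"}-direction input). Residues with strong affinity for the
#' target bases then contribute favourably (negatively) to the linear
#' interaction energy wherever those bases are enriched, so the energy
#' pipeline can be exercised without external scale files.
#'
#' @param scale An \linkS4class{AffinityScale}.
#' @param baseSet Target bases of the input scale (default pyrimidines).
#' @return Named list of four \linkS4class{AffinityScale}s keyed by
#'   base (\code{A,C,G,U}).
#' @export
pairScaleFamily <- function(scale, baseSet = c("C", "U")) {
  stopifnot(is(scale, "AffinityScale"))
  baseSet <- toupper(baseSet)
  v0 <- scaleValues(scale) - mean(scaleValues(scale))
  if (scaleDirection(scale) == "max") v0 <- -v0
  fam <- lapply(RNA_BASES, function(b)
    affinityScale(paste0("SYN_", b),
                  if (b %in% baseSet) v0 else -v0, direction = "min"))
  names(fam) <- RNA_BASES
  fam
}

.samplePlacements <- function(n, lo, hi, span, minGap, maxTries = 10000L) {
  if (n == 0L) return(integer())
  need <- n * span + (n - 1L) * (minGap + 1L)
  if (hi - lo + 1L < need)
    stop(sprintf("cannot place %d non-overlapping %d-nt sites in [%d, %d]",
                 n, span, lo, hi))
  for (i in seq_len(maxTries)) {
    st <- sort(sample.int(hi - lo - span + 2L, n) + lo - 1L)
    if (n == 1L || all(diff(st) >= span + minGap + 1L)) return(st)
  }
  stop("failed to place planted sites; relax the packing constraints")
}

#' Generate a seeded synthetic gRNA/CP pair with planted binding sites
#'
#' Draws a random protein and an i.i.d.-background genome, then plants
#' \code{nSites} copies of one realized binding motif, a region in
#' which the in-frame triplet density of \code{baseSet} linearly tracks
#' the negated per-residue affinity of the protein (plus Gaussian noise
#' on the density scale, rounded to the nearest realizable triplet
#' composition 0, 1/3, 2/3 or 1). Repeating one realization emulates
#' the multiple dispersed copies of a packaging-signal-like motif and
#' keeps the planted sites equally deep in the energy profile. Planted
#' regions are therefore anti-correlated with the protein's affinity
#' profile (matched profiles, negative sliding Pearson R) and form
#' minima of the interaction-energy profile under the accompanying
#' \code{\link{pairScaleFamily}} scales. Each planted region spans one
#' full protein fragment: \code{span} must equal 3 times the protein
#' length, and sites are placed inside the defined (non-margin) part of
#' the profiles, pairwise separated by more than \code{minGap}
#' nucleotides. Regeneration from the same parameters and seed is
#' bit-identical.
#'
#' @param genomeLength Genome length in nt (default 4000).
#' @param nSites Number of planted sites (default 4; 0 gives a pure
#'   background genome for null calibration).
#' @param span Planted-site span in nt, a multiple of 3 (default 150;
#'   the protein has span/3 residues).
#' @param noise Standard deviation of the Gaussian density noise
#'   (default 0.1).
#' @param scale Affinity scale of the planted anti-correlation (default
#'   \code{\link{polarRequirement}}).
#' @param baseSet Target bases (default pyrimidines).
#' @param baseFreqs Background base frequencies (A,C,G,U; default
#'   uniform).
#' @param minGap Minimum separation between planted sites (default 150).
#' @param proteinBias Compositional bias of the protein toward
#'   strong-affinity residues, in scale standard deviations (default
#'   0.7). Coat proteins are compositionally biased binders; a net
#'   attractive protein makes every fragment overlapping a planted
#'   high-density region score favourably, giving the funnel-shaped
#'   energy minimum characteristic of real packaging signals.
#' @param proteinSmoothing Window (residues) of the latent
#'   autocorrelation of the drawn protein's affinity profile (default
#'   9); clustered strong/weak stretches mirror the smooth affinity
#'   profiles of natural CPs.
#' @param seed Integer seed.
#' @return A list with elements \code{gRNA} (\code{RNAString}),
#'   \code{protein} (\code{AAString}), \code{planted} (\code{IRanges}),
#'   \code{scales} (four-base family) and \code{params}.
#' @export
#' @examples
#' case <- syntheticPair(seed = 7)
#' case$planted
syntheticPair <- function(genomeLength = 4000L, nSites = 4L, span = 150L,
                          noise = 0.1, scale = polarRequirement(),
                          baseSet = c("C", "U"),
                          baseFreqs = rep(0.25, 4), minGap = 150L,
                          proteinBias = 0.7, proteinSmoothing = 9L,
                          seed = 1L) {
  stopifnot(span %% 3L == 0L, span >= 9L, noise >= 0, genomeLength >= span)
  baseSet <- toupper(baseSet)
  nAa <- span %/% 3L
  set.seed(seed)
  # protein with an autocorrelated, attraction-biased affinity profile:
  # a smoothed latent curve sets the local target affinity, residues are
  # drawn around it (negative latent = strong affinity under the scale)
  sv <- scaleValues(scale)
  v0s <- (sv - mean(sv)) / stats::sd(sv)
  if (scaleDirection(scale) == "max") v0s <- -v0s
  hw <- max(1L, as.integer(proteinSmoothing))
  lat <- as.numeric(stats::filter(stats::rnorm(nAa + 2L * hw), rep(1, hw) / hw,
                                  sides = 2L))
  lat <- lat[hw + seq_len(nAa)]
  lat <- (lat - mean(lat)) / max(stats::sd(lat), 1e-12) - proteinBias
  aa <- vapply(seq_len(nAa), function(j)
    sample(AA_CODES, 1L, prob = stats::dnorm(v0s, lat[j], 0.6)), character(1L))
  v <- sv[aa]
  # target density anti-tracks affinity: strongest residues -> density 1
  rng <- range(scaleValues(scale))
  d <- if (scaleDirection(scale) == "min")
    (rng[2L] - v) / diff(rng) else (v - rng[1L]) / diff(rng)
  bg <- sample(RNA_BASES, genomeLength, replace = TRUE, prob = baseFreqs)
  # energy margin of the accompanying profiles, plus slack
  margin <- (3L * nAa) %/% 2L + 32L
  starts <- .samplePlacements(nSites, margin + 1L,
                              genomeLength - span - margin, span,
                              max(as.integer(minGap), 67L))
  others <- setdiff(RNA_BASES, baseSet)
  pIn <- baseFreqs[match(baseSet, RNA_BASES)]
  pOut <- baseFreqs[match(others, RNA_BASES)]
  # one realized motif, repeated at every site (tandem packaging-signal
  # analogue); noise is drawn once per case, on the density scale, then
  # rounded to the nearest realizable triplet composition
  if (nSites) {
    dd <- pmin(pmax(d + stats::rnorm(nAa, 0, noise), 0), 1)
    k <- as.integer(round(3 * dd))
    motif <- unlist(lapply(seq_len(nAa), function(j) {
      trip <- c(sample(baseSet, k[j], replace = TRUE, prob = pIn),
                sample(others, 3L - k[j], replace = TRUE, prob = pOut))
      trip[sample.int(3L)]
    }))
    # conserved background-like flanks, one smoothing half-window wide,
    # so that every copy's smoothed energy apex is identical
    guard <- 33L
    flank5 <- sample(RNA_BASES, guard, replace = TRUE, prob = baseFreqs)
    flank3 <- sample(RNA_BASES, guard, replace = TRUE, prob = baseFreqs)
    for (st in starts)
      bg[(st - guard):(st + span + guard - 1L)] <- c(flank5, motif, flank3)
  }
  list(gRNA = RNAString(paste(bg, collapse = "")),
       protein = AAString(paste(aa, collapse = "")),
       planted = if (nSites) IRanges(starts, starts + span - 1L) else IRanges(),
       scales = pairScaleFamily(scale, baseSet),
       params = list(genomeLength = as.integer(genomeLength),
                     nSites = as.integer(nSites), span = as.integer(span),
                     noise = noise, baseSet = baseSet,
                     baseFreqs = baseFreqs, minGap = as.integer(minGap),
                     proteinBias = proteinBias,
                     proteinSmoothing = as.integer(proteinSmoothing),
                     scale = scale@name, seed = as.integer(seed)))
}
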
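#' @importFrom IRanges IRanges reduce start end width
NULL

.affMatrix <- function(scales) {
  scales <- .baseKeyedScales(scales)
  vapply(scales, scaleValues, numeric(20L))  # 20 aa x 4 bases
}

#' Relative interaction energy of one gRNA fragment
#'
#' Aligns every residue of \code{protein} with one triplet of the gRNA
#' fragment starting at \code{start} and sums, over residues and over
#' the four nucleobases, the product of the residue's affinity for the
#' base and the base's count (0-3) in the aligned triplet. The result is
#' a dimensionless relative energy: only differences between fragments
#' are meaningful.
#'
#' @param gRNA Genome sequence.
#' @param start 1-based fragment start; the fragment spans
#'   \code{start .. start + 3*N - 1} for an N-residue protein.
#' @param protein CP sequence.
#' @param scales Four \linkS4class{AffinityScale}s keyed by base
#'   (\code{A,G,C,U}) or name (\code{ADE,GUA,CYT,URA}).
#' @return A single relative energy value.
#' @export
fragmentEnergy <- function(gRNA, start, protein, scales) {
  aff <- .affMatrix(scales)
  ch <- .seqChars(normalizeSequence(gRNA, "rna"))
  aa <- .seqChars(normalizeSequence(protein, "protein"))
  nAa <- length(aa)
  if (start < 1L || start + 3L * nAa - 1L > length(ch))
    stop(sprintf("fragment [%d, %d] outside genome of length %d",
                 start, start + 3L * nAa - 1L, length(ch)))
  e <- 0
  for (j in seq_len(nAa)) {
    trip <- ch[start + 3L * (j - 1L) + 0:2]
    for (b in RNA_BASES)
      e <- e + aff[aa[j], b] * sum(trip == b)
  }
  e
}

#' Relative gRNA/CP interaction-energy profile
#'
#' Slides the full protein along the genome in steps of one nucleotide,
#' computes the linearly additive relative interaction energy of each
#' fragment (\code{\link{fragmentEnergy}}), assigns it to the fragment's
#' central nucleotide (with the same straddling-average rule as profile
#' matching for even-length proteins), window-averages the resulting
#' track (63 nt by default) and standardizes the smoothed values to
#' z-scores over all defined positions. For an N-residue protein the
#' first and last (3N-1)/2 + (smoothingWindow-1)/2 positions (odd N; 3N/2
#' + (smoothingWindow-1)/2 for even N) are undefined.
#'
#' @inheritParams fragmentEnergy
#' @param smoothingWindow Odd window (nt) for the energy track
#'   (default 63).
#' @param dropInitiatorMet Drop a leading Met before profiling.
#' @param sdType \code{"population"} (divide by n; default) or
#'   \code{"sample"} for the z-score denominator.
#' @param genomeId,proteinId Identifiers stored in the result.
#' @return An \linkS4class{EnergyProfile} with slots \code{raw} (fragment
#'   energies at centres), \code{values} (smoothed) and \code{z}.
#' @export
energyProfile <- function(gRNA, protein, scales, smoothingWindow = 63L,
                          dropInitiatorMet = FALSE,
                          sdType = c("population", "sample"),
                          genomeId = "gRNA", proteinId = "CP") {
  sdType <- match.arg(sdType)
  aff <- .affMatrix(scales)
  rna <- normalizeSequence(gRNA, "rna")
  ch <- .seqChars(rna)
  aa <- .seqChars(normalizeSequence(protein, "protein"))
  if (dropInitiatorMet && aa[1L] == "M") aa <- aa[-1L]
  nAa <- length(aa)
  L <- length(ch)
  P <- .fragmentStarts(L, nAa)
  counts <- .tripletCounts(ch)                      # 4 x (L-2)
  perBase <- t(counts)                              # (L-2) x 4
  # residue-type tracks: v_t[i] = sum_b aff_b(t) * count_b(triplet i)
  types <- unique(aa)
  vt <- perBase %*% t(aff[types, RNA_BASES, drop = FALSE])  # (L-2) x types
  colnames(vt) <- types
  E <- numeric(P)
  p <- seq_len(P)
  for (j in seq_len(nAa))
    E <- E + vt[p + 3L * (j - 1L), aa[j]]
  raw <- .centerAssign(E, nAa, L)
  sw <- as.integer(smoothingWindow)
  def <- which(!is.na(raw))
  run <- seq.int(def[1L], def[length(def)])
  sm <- rep(NA_real_, L)
  sm[run] <- smoothStrided(raw[run], w = sw, stride = 1L)
  dsm <- sm[!is.na(sm)]
  mu <- mean(dsm)
  sigma <- if (sdType == "population")
    sqrt(mean((dsm - mu)^2)) else stats::sd(dsm)
  z <- if (is.finite(sigma) && sigma > 0) (sm - mu) / sigma else
    rep(NA_real_, L)
  new("EnergyProfile", seqId = genomeId, values = sm, window = sw,
      unit = "nt", proteinId = proteinId, raw = raw, z = z,
      nResidues = as.integer(nAa))
}

#' Predict binding regions from the lowest energy percentile
#'
#' Selects the genome positions whose smoothed relative interaction
#' energy lies at or below the given percentile of all defined values
#' (linear-interpolation quantile, ties included), collapses maximal
#' runs of selected positions into 1-based inclusive intervals and
#' merges intervals separated by fewer than \code{mergeGap} intervening
#' nucleotides (strictly; a gap of exactly \code{mergeGap} is kept
#' separate).
#'
#' @param profile An \linkS4class{EnergyProfile}.
#' @param percentile Percentage in (0, 100); 1 and 5 are the
#'   conventional report levels.
#' @param mergeGap Merge intervals separated by fewer than this many
#'   positions (default 10).
#' @return An \code{\link[IRanges]{IRanges}} with metadata columns
#'   \code{minZ} (minimum z-score inside each region) and \code{level}.
#' @export
predictRegions <- function(profile, percentile = 1, mergeGap = 10L) {
  stopifnot(is(profile, "EnergyProfile"))
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop("'percentile' must lie strictly between 0 and 100")
  v <- profile@values
  def <- which(!is.na(v))
  if (!length(def)) stop("profile has no defined values")
  thr <- quantile(v[def], percentile / 100, names = FALSE, type = 7)
  sel <- def[v[def] <= thr]
  if (!length(sel))
    return(IRanges())
  runs <- reduce(IRanges(sel, sel))
  merged <- reduce(runs, min.gapwidth = as.integer(mergeGap))
  minZ <- vapply(seq_along(merged), function(i)
    min(profile@z[seq.int(start(merged)[i], end(merged)[i])], na.rm = TRUE),
    numeric(1L))
  mcols(merged)$minZ <- minZ
  mcols(merged)$level <- percentile
  merged
}
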
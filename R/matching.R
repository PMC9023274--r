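#' @importFrom S4Vectors mcols mcols<-
NULL

# Pearson R between the fixed vector x (pre-centred) and every strided
# slice s[p + offs], p = 1..P, via BLAS.  Zero-variance windows -> NA.
.slideCor <- function(s, x, offs, P) {
  l <- length(x)
  x <- x - mean(x)
  Sxx <- sum(x * x)
  out <- rep(NA_real_, P)
  # windows whose variance is below numerical noise (far under the 1/w
  # quantum of smoothed density tracks) are degenerate: R undefined
  eps <- l * 1e-18
  if (l < 2L || Sxx <= eps) return(out)
  Y <- matrix(s[outer(seq_len(P), offs, "+")], nrow = P)
  Y <- Y - rowMeans(Y)
  Syy <- rowSums(Y * Y)
  Sxy <- as.numeric(Y %*% x)
  ok <- which(Syy > eps)
  out[ok] <- Sxy[ok] / sqrt(Sxx * Syy[ok])
  pmin(pmax(out, -1), 1, na.rm = FALSE)
}

# map per-fragment values (index = fragment start p) to genome positions:
# each fragment's value goes to its central nucleotide; for even-length
# fragments (even nResidues) position i averages the two fragments whose
# centres straddle it at i -/+ 0.5.
.centerAssign <- function(vals, nAa, L) {
  out <- rep(NA_real_, L)
  P <- length(vals)
  if (nAa %% 2L == 1L) {
    centers <- seq_len(P) + (3L * nAa - 1L) %/% 2L
    out[centers] <- vals
  } else if (P >= 2L) {
    pos <- seq_len(P - 1L) + 3L * nAa %/% 2L
    out[pos] <- (vals[seq_len(P - 1L)] + vals[seq.int(2L, P)]) / 2
  }
  out
}

.fragmentStarts <- function(L, nAa) {
  P <- L - 3L * nAa + 1L
  if (P < 1L)
    stop(sprintf(
      "genome of %d nt cannot host a single fragment of a %d-residue protein (%d nt)",
      L, nAa, 3L * nAa))
  P
}

#' Sliding Pearson comparison of gRNA density and CP affinity profiles
#'
#' Slides the smoothed nucleobase-affinity profile of \code{protein}
#' along the smoothed nucleobase-density profile of \code{gRNA} in steps
#' of one nucleotide, aligning each residue with one triplet, and
#' records at each offset the Pearson R between the two smoothed
#' profiles. The R of each gRNA fragment is assigned to its central
#' nucleotide; for proteins with an even number of residues each
#' position receives the mean of the two values belonging to the
#' half-integer centres straddling it. With window \code{w} and a
#' protein of N residues (smoothed profile length l = N - w + 1) the
#' first and last (3l-1)/2 + 3(w-1)/2 positions (odd l) are undefined.
#'
#' @param gRNA Genome sequence (string, \code{RNAString}; T is mapped
#'   to U).
#' @param protein CP sequence (string or \code{AAString}).
#' @param scale An \linkS4class{AffinityScale}.
#' @param baseSet Nucleobases whose triplet density is profiled
#'   (default pyrimidines \code{c("C","U")}).
#' @param w Odd smoothing window (residues/triplets; default 21).
#' @param dropInitiatorMet Drop a leading Met before profiling.
#' @param genomeId,proteinId Identifiers stored in the result.
#' @return A \linkS4class{MatchProfile}; undefined positions (margins
#'   and zero-variance windows) are \code{NA}.
#' @export
slidingPearson <- function(gRNA, protein, scale, baseSet = c("C", "U"),
                           w = 21L, dropInitiatorMet = FALSE,
                           genomeId = "gRNA", proteinId = "CP") {
  stopifnot(is(scale, "AffinityScale"))
  rna <- normalizeSequence(gRNA, "rna")
  prof <- affinityProfile(protein, scale, w = w,
                          dropInitiatorMet = dropInitiatorMet)
  x <- profileValues(prof)
  x <- x[!is.na(x)]
  nAa <- length(profileValues(prof))
  L <- length(rna)
  P <- .fragmentStarts(L, nAa)
  h <- (as.integer(w) - 1L) %/% 2L
  s <- smoothStrided(tripletDensity(rna, baseSet), w = w, stride = 3L)
  offs <- 3L * h + 3L * (seq_along(x) - 1L)
  R <- .slideCor(s, x, offs, P)
  new("MatchProfile", seqId = genomeId, values = .centerAssign(R, nAa, L),
      window = as.integer(w), unit = "nt", proteinId = proteinId,
      scaleName = scale@name, baseSet = toupper(baseSet),
      direction = scaleDirection(scale), nResidues = as.integer(nAa))
}

.KB_BASE <- c(ADE = "A", GUA = "G", CYT = "C", URA = "U")

# accept scales keyed by base (A/C/G/U) or by name (ADE/GUA/CYT/URA)
.baseKeyedScales <- function(scales) {
  stopifnot(is.list(scales))
  nm <- toupper(names(scales))
  nm[nm %in% names(.KB_BASE)] <- .KB_BASE[nm[nm %in% names(.KB_BASE)]]
  if (!setequal(nm, RNA_BASES))
    stop("need exactly four scales keyed by base (A/C/G/U) or by ",
         "name (ADE/GUA/CYT/URA); got: ", paste(names(scales), collapse = ", "))
  names(scales) <- nm
  for (sc in scales) stopifnot(is(sc, "AffinityScale"))
  scales[RNA_BASES]
}

#' Combined four-scale match profile
#'
#' Sums the per-position sliding Pearson R obtained for the four
#' knowledge-based nucleobase scales, with the adenine term subtracted
#' to honour its anti-matching convention:
#' combined = R_GUA + R_CYT + R_URA - R_ADE. Each scale is compared
#' against the density of its own base. Defined exactly where all four
#' constituent profiles are defined; strong binding regions appear as
#' minima of the combined profile.
#'
#' @inheritParams slidingPearson
#' @param scales List of four \linkS4class{AffinityScale}s keyed by base
#'   (\code{A,G,C,U}) or by name (\code{ADE,GUA,CYT,URA}).
#' @return A \linkS4class{MatchProfile} with \code{scaleName}
#'   \code{"combined"} and values in [-4, 4].
#' @export
combinedKnowledgeProfile <- function(gRNA, protein, scales, w = 21L,
                                     dropInitiatorMet = FALSE,
                                     genomeId = "gRNA", proteinId = "CP") {
  scales <- .baseKeyedScales(scales)
  parts <- lapply(RNA_BASES, function(b)
    profileValues(slidingPearson(gRNA, protein, scales[[b]], baseSet = b,
                                 w = w, dropInitiatorMet = dropInitiatorMet,
                                 genomeId = genomeId, proteinId = proteinId)))
  names(parts) <- RNA_BASES
  comb <- parts$G + parts$C + parts$U - parts$A
  tmpl <- slidingPearson(gRNA, protein, scales[["G"]], baseSet = "G", w = w,
                         dropInitiatorMet = dropInitiatorMet,
                         genomeId = genomeId, proteinId = proteinId)
  new("MatchProfile", seqId = genomeId, values = comb,
      window = as.integer(w), unit = "nt", proteinId = proteinId,
      scaleName = "combined", baseSet = RNA_BASES, direction = "min",
      nResidues = tmpl@nResidues)
}

#' Call predicted interaction sites from a profile
#'
#' Thresholds a profile into a set of predicted interaction-site
#' positions. For a \linkS4class{MatchProfile}, positions with
#' R <= cutoff are called when the scale direction is \code{"min"} and
#' R >= cutoff when it is \code{"max"} (adenine convention). For an
#' \linkS4class{EnergyProfile} the z-scores are thresholded at
#' z <= cutoff. Undefined positions are never called.
#'
#' @param profile A \linkS4class{MatchProfile} or
#'   \linkS4class{EnergyProfile}.
#' @param cutoff Finite threshold (Pearson R or z-score).
#' @param direction Optional override of the calling direction.
#' @return Sorted integer vector of 1-based genome positions.
#' @export
setGeneric("callSites",
           function(profile, cutoff, ...) standardGeneric("callSites"))

#' @rdname callSites
#' @export
setMethod("callSites", "MatchProfile",
  function(profile, cutoff, direction = NULL) {
    stopifnot(is.finite(cutoff))
    direction <- if (is.null(direction)) profile@direction else
      match.arg(direction, c("min", "max"))
    v <- profile@values
    hit <- if (direction == "min") v <= cutoff else v >= cutoff
    which(!is.na(v) & hit)
  })

#' @rdname callSites
#' @export
setMethod("callSites", "EnergyProfile",
  function(profile, cutoff) {
    stopifnot(is.finite(cutoff))
    z <- profile@z
    which(!is.na(z) & z <= cutoff)
  })
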
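#' @importFrom Biostrings RNAString AAString readBStringSet
NULL

.seqChars <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (length(x) == 1L) x <- strsplit(x, "")[[1L]]
  toupper(x)
}

#' Normalize a raw sequence string
#'
#' Uppercases, maps T to U for RNA, and rejects any character outside
#' the strict alphabet: ambiguity codes (N, R, Y, B, Z, X, ...) and
#' non-standard residues (selenocysteine U) are errors, mirroring the
#' exclusion of ambiguous records from genome-scale screens.
#'
#' @param raw A character string, \code{RNAString}/\code{DNAString} or
#'   \code{AAString}.
#' @param alphabet \code{"rna"} or \code{"protein"}.
#' @return An \code{RNAString} or \code{AAString}.
#' @export
#' @examples
#' normalizeSequence("acgt", "rna")     # ACGU
#' normalizeSequence("MASNF", "protein")
normalizeSequence <- function(raw, alphabet = c("rna", "protein")) {
  alphabet <- match.arg(alphabet)
  ch <- .seqChars(raw)
  if (!length(ch)) stop("empty sequence")
  if (alphabet == "rna") {
    ch[ch == "T"] <- "U"
    bad <- which(!ch %in% RNA_BASES)
    if (length(bad))
      stop(sprintf("ambiguous or invalid nucleotide '%s' at position %d",
                   ch[bad[1L]], bad[1L]))
    RNAString(paste(ch, collapse = ""))
  } else {
    bad <- which(!ch %in% AA_CODES)
    if (length(bad))
      stop(sprintf("ambiguous or non-standard residue '%s' at position %d",
                   ch[bad[1L]], bad[1L]))
    AAString(paste(ch, collapse = ""))
  }
}

#' Triplet nucleobase density along an RNA
#'
#' For every triplet start i (1-based, i = 1..L-2) the fraction of the
#' three nucleotides i, i+1, i+2 belonging to \code{baseSet}; values lie
#' in \{0, 1/3, 2/3, 1\}. This is the raw track underlying smoothed
#' nucleobase-density profiles.
#'
#' @param rna RNA sequence (string or \code{RNAString}, length >= 3).
#' @param baseSet Non-empty subset of \code{c("A","C","G","U")}.
#' @return Numeric vector of length L-2.
#' @export
#' @examples
#' tripletDensity("UUUAAA", c("C", "U"))  # 1, 2/3, 1/3, 0
tripletDensity <- function(rna, baseSet) {
  baseSet <- toupper(baseSet)
  if (!length(baseSet) || !all(baseSet %in% RNA_BASES))
    stop("'baseSet' must be a non-empty subset of A/C/G/U")
  ch <- .seqChars(rna)
  L <- length(ch)
  if (L < 3L) stop("RNA sequence must be at least 3 nt")
  ind <- as.numeric(ch %in% baseSet)
  (ind[1:(L - 2L)] + ind[2:(L - 1L)] + ind[3:L]) / 3
}

# per-base triplet counts (0..3), rows A/C/G/U, cols = triplet starts
.tripletCounts <- function(ch) {
  L <- length(ch)
  out <- matrix(0, nrow = 4L, ncol = L - 2L,
                dimnames = list(RNA_BASES, NULL))
  for (b in RNA_BASES) {
    ind <- as.numeric(ch == b)
    out[b, ] <- ind[1:(L - 2L)] + ind[2:(L - 1L)] + ind[3:L]
  }
  out
}

#' Strided window average of a raw track
#'
#' Smooths a raw per-unit track with a centred window of \code{w}
#' values taken every \code{stride} positions: the smoothed value at
#' position i is the mean of the raw values at
#' i - stride*(w-1)/2, ..., i, ..., i + stride*(w-1)/2, assigned to the
#' central position i. Positions where the window does not fully fit are
#' \code{NA}. For per-residue protein tracks \code{stride = 1}; for
#' per-triplet-start gRNA tracks \code{stride = 3}, so that the profile
#' at a nucleotide averages w in-frame, non-overlapping triplets centred
#' on the triplet starting there.
#'
#' @param track Numeric raw track.
#' @param w Odd positive window size (number of values averaged).
#' @param stride Positive integer step between averaged values.
#' @return Numeric vector of \code{length(track)} with \code{NA}
#'   margins of \code{stride*(w-1)/2} on each side.
#' @export
#' @examples
#' smoothStrided(1:5, w = 3)  # NA 2 3 4 NA
smoothStrided <- function(track, w, stride = 1L) {
  w <- as.integer(w); stride <- as.integer(stride)
  if (is.na(w) || w < 1L || w %% 2L == 0L)
    stop("'w' must be a positive odd integer")
  if (is.na(stride) || stride < 1L) stop("'stride' must be >= 1")
  n <- length(track)
  h <- (w - 1L) %/% 2L
  m <- stride * h
  if (n < 2L * m + 1L)
    stop(sprintf("track of length %d too short for w=%d, stride=%d", n, w, stride))
  if (w == 1L) return(as.numeric(track))
  core <- seq.int(m + 1L, n - m)
  acc <- numeric(length(core))
  for (k in seq.int(-h, h)) acc <- acc + track[core + stride * k]
  out <- rep(NA_real_, n)
  out[core] <- acc / w
  out
}

#' Smoothed nucleobase-affinity profile of a protein
#'
#' Maps each residue to its affinity under \code{scale} and smooths the
#' per-residue track with a centred window of \code{w} residues. With
#' \code{dropInitiatorMet = TRUE} the N-terminal methionine is removed
#' before profiling (mature-protein convention, e.g. the MS2 coat
#' protein whose initiator Met is absent from the mature chain).
#'
#' @param protein Protein sequence (string or \code{AAString}).
#' @param scale An \linkS4class{AffinityScale}.
#' @param w Odd smoothing window in residues (default 21).
#' @param dropInitiatorMet Drop a leading methionine before profiling.
#' @return A \linkS4class{PositionProfile} (unit "residue") whose first
#'   and last (w-1)/2 residues are undefined.
#' @export
affinityProfile <- function(protein, scale, w = 21L,
                            dropInitiatorMet = FALSE) {
  stopifnot(is(scale, "AffinityScale"))
  ch <- .seqChars(protein)
  if (dropInitiatorMet && length(ch) && ch[1L] == "M") ch <- ch[-1L]
  bad <- which(!ch %in% AA_CODES)
  if (length(bad))
    stop(sprintf("residue '%s' at position %d not covered by scale '%s'",
                 ch[bad[1L]], bad[1L], scale@name))
  vals <- smoothStrided(scaleValues(scale)[ch], w = w, stride = 1L)
  new("PositionProfile", seqId = "protein", values = vals,
      window = as.integer(w), unit = "residue")
}
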
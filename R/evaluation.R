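#' Permutation-test result for binding-site coverage
#'
#' @slot nativeBsc BSC of the native gRNA/CP pair at the tested cutoff.
#' @slot nullBscs Per-shuffle BSC values (full null vector, for audit).
#' @slot pValue Fraction of shuffles with BSC greater than or equal to
#'   the native value (no pseudocount; an empirical p of 0 is possible).
#' @slot nShuffles,mode,seed,cutoff Test metadata.
#' @export
setClass("PermutationResult",
  representation(nativeBsc = "numeric", nullBscs = "numeric",
                 pValue = "numeric", nShuffles = "integer",
                 mode = "character", seed = "integer", cutoff = "numeric"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@nullBscs) != object@nShuffles)
    msg <- c(msg, "length(nullBscs) != nShuffles")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue outside [0, 1]")
  if (!object@mode %in% c("shuffle_gRNA", "shuffle_CP"))
    msg <- c(msg, "mode must be shuffle_gRNA or shuffle_CP")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(paste0("PermutationResult (%s, n = %d, seed = %d)\n",
                     "  native BSC = %.4g at cutoff %.3g, P = %.4g\n"),
              object@mode, object@nShuffles, object@seed,
              object@nativeBsc, object@cutoff, object@pValue))
})

.rangePositions <- function(x) {
  if (is(x, "IRanges") || is(x, "IRangesList"))
    return(unique(unlist(lapply(seq_along(x), function(i)
      seq.int(start(x)[i], end(x)[i])))))
  if (is(x, "GRanges"))
    return(unique(unlist(mapply(seq.int, IRanges::start(x), IRanges::end(x),
                                SIMPLIFY = FALSE))))
  unique(as.integer(x))
}

#' Binding-site coverage (BSC)
#'
#' Fraction of reference binding-site nucleotides recovered by a
#' prediction, restricted to the genome positions for which the
#' theoretical profile is defined:
#' |called & reference & defined| / |reference & defined|.
#'
#' @param called Predicted positions (integer vector or
#'   \code{IRanges}).
#' @param reference Reference binding sites (\code{IRanges} or
#'   positions).
#' @param defined Positions carrying a defined profile value.
#' @return A fraction in [0, 1].
#' @export
bsc <- function(called, reference, defined) {
  ref <- intersect(.rangePositions(reference), .rangePositions(defined))
  if (!length(ref))
    stop("reference sites lie entirely outside the defined profile range; BSC undefined")
  length(intersect(.rangePositions(called), ref)) / length(ref)
}

#' BSC normalized by prediction size
#'
#' Divides the BSC by the number of called positions with a defined
#' profile value, making coverage comparable between predictions (e.g.
#' shuffle replicates) that call very different numbers of positions.
#'
#' @inheritParams bsc
#' @return \code{bsc / |called & defined|}.
#' @export
normalizedBsc <- function(called, reference, defined) {
  cd <- intersect(.rangePositions(called), .rangePositions(defined))
  if (!length(cd)) stop("no called positions with defined profile values")
  bsc(called, reference, defined) / length(cd)
}

#' Jaccard index of two genomic position sets
#'
#' Intersection over union of the nucleotide positions covered by two
#' interval sets on the same genome.
#'
#' @param a,b \code{IRanges} or integer position vectors.
#' @return A fraction in [0, 1].
#' @export
#' @examples
#' library(IRanges)
#' jaccardIndex(IRanges(1, 10), IRanges(6, 15))  # 1/3
jaccardIndex <- function(a, b) {
  pa <- .rangePositions(a); pb <- .rangePositions(b)
  u <- union(pa, pb)
  if (!length(u)) stop("both position sets are empty; Jaccard undefined")
  length(intersect(pa, pb)) / length(u)
}

# one thresholdable track per gRNA/protein pair: values + calling direction
.profileTrack <- function(gRNA, protein, scaleOrScales,
                          profileKind = c("pearson", "energy"),
                          baseSet = c("C", "U"), w = 21L,
                          smoothingWindow = 63L) {
  profileKind <- match.arg(profileKind)
  if (profileKind == "pearson") {
    p <- slidingPearson(gRNA, protein, scaleOrScales, baseSet = baseSet, w = w)
    list(values = p@values, direction = p@direction)
  } else {
    p <- energyProfile(gRNA, protein, scaleOrScales,
                       smoothingWindow = smoothingWindow)
    list(values = p@z, direction = "min")
  }
}

.callFromTrack <- function(track, cutoff) {
  v <- track$values
  hit <- if (track$direction == "min") v <= cutoff else v >= cutoff
  which(!is.na(v) & hit)
}

.shuffleChars <- function(ch) ch[sample.int(length(ch))]

#' Shuffled-sequence permutation test of binding-site coverage
#'
#' Recomputes the sliding Pearson or interaction-energy profile for
#' composition-preserving random re-orderings (Fisher-Yates shuffles) of
#' either the gRNA or the CP, calls sites at the same cutoff and
#' compares the native BSC against the shuffled null. The reported
#' p-value is the fraction of shuffles reaching a BSC greater than or
#' equal to the native one.
#'
#' @param gRNA,protein Native sequences.
#' @param scaleOrScales One \linkS4class{AffinityScale}
#'   (\code{profileKind = "pearson"}) or a four-scale list keyed by base
#'   (\code{profileKind = "energy"}).
#' @param reference Reference binding sites (\code{IRanges}).
#' @param cutoff Site-calling cutoff (Pearson R or z-score).
#' @param mode \code{"shuffle_gRNA"} or \code{"shuffle_CP"}.
#' @param profileKind \code{"pearson"} or \code{"energy"}.
#' @param n Number of shuffles (default 1000).
#' @param seed Integer seed; the test is bit-reproducible for a fixed
#'   seed.
#' @param statistic \code{"bsc"} (default) or \code{"normalized_bsc"}.
#' @param baseSet,w,smoothingWindow Profile parameters.
#' @param dropInitiatorMet Drop a leading Met from the native CP before
#'   the analysis (shuffles then permute the mature sequence).
#' @return A \linkS4class{PermutationResult}.
#' @export
shuffleTest <- function(gRNA, protein, scaleOrScales, reference, cutoff,
                        mode = c("shuffle_gRNA", "shuffle_CP"),
                        profileKind = c("pearson", "energy"),
                        n = 1000L, seed = 1L,
                        statistic = c("bsc", "normalized_bsc"),
                        baseSet = c("C", "U"), w = 21L,
                        smoothingWindow = 63L, dropInitiatorMet = FALSE) {
  mode <- match.arg(mode)
  profileKind <- match.arg(profileKind)
  statistic <- match.arg(statistic)
  if (n < 1L) stop("'n' must be >= 1")
  stat <- if (statistic == "bsc") bsc else normalizedBsc
  rnaCh <- .seqChars(normalizeSequence(gRNA, "rna"))
  aaCh <- .seqChars(normalizeSequence(protein, "protein"))
  if (dropInitiatorMet && aaCh[1L] == "M") aaCh <- aaCh[-1L]
  score <- function(rc, ac) {
    tr <- .profileTrack(paste(rc, collapse = ""), paste(ac, collapse = ""),
                        scaleOrScales, profileKind, baseSet, w,
                        smoothingWindow)
    stat(.callFromTrack(tr, cutoff), reference, which(!is.na(tr$values)))
  }
  native <- score(rnaCh, aaCh)
  set.seed(seed)
  nulls <- vapply(seq_len(n), function(i) {
    if (mode == "shuffle_gRNA") score(.shuffleChars(rnaCh), aaCh)
    else score(rnaCh, .shuffleChars(aaCh))
  }, numeric(1L))
  new("PermutationResult", nativeBsc = native, nullBscs = nulls,
      pValue = mean(nulls >= native - 1e-12), nShuffles = as.integer(n),
      mode = mode, seed = as.integer(seed), cutoff = as.numeric(cutoff))
}

#' BSC as a function of cutoff, with permutation p-values
#'
#' Evaluates the native BSC over a grid of site-calling cutoffs and, for
#' each requested shuffle mode, the median null BSC and the permutation
#' p-value. One seeded shuffle set is drawn per mode and reused across
#' all cutoffs (set \code{independentShuffles = TRUE} to redraw per
#' cutoff).
#'
#' @inheritParams shuffleTest
#' @param cutoffs Numeric vector of cutoffs.
#' @param modes Shuffle modes to evaluate.
#' @param independentShuffles Redraw the shuffle set for every cutoff.
#' @return A data.frame with one row per cutoff: native BSC, and per
#'   mode the median null BSC and p-value.
#' @export
bscCurve <- function(gRNA, protein, scaleOrScales, reference, cutoffs,
                     profileKind = c("pearson", "energy"),
                     modes = c("shuffle_gRNA", "shuffle_CP"),
                     n = 1000L, seed = 1L, baseSet = c("C", "U"), w = 21L,
                     smoothingWindow = 63L, dropInitiatorMet = FALSE,
                     independentShuffles = FALSE) {
  profileKind <- match.arg(profileKind)
  modes <- match.arg(modes, several.ok = TRUE)
  if (!length(cutoffs)) stop("'cutoffs' must be non-empty")
  rnaCh <- .seqChars(normalizeSequence(gRNA, "rna"))
  aaCh <- .seqChars(normalizeSequence(protein, "protein"))
  if (dropInitiatorMet && aaCh[1L] == "M") aaCh <- aaCh[-1L]
  track <- function(rc, ac)
    .profileTrack(paste(rc, collapse = ""), paste(ac, collapse = ""),
                  scaleOrScales, profileKind, baseSet, w, smoothingWindow)
  trackBsc <- function(tr, cutoff)
    bsc(.callFromTrack(tr, cutoff), reference, which(!is.na(tr$values)))
  nativeTr <- track(rnaCh, aaCh)
  out <- data.frame(cutoff = cutoffs,
                    native_bsc = vapply(cutoffs, function(ct)
                      trackBsc(nativeTr, ct), numeric(1L)))
  for (m in modes) {
    set.seed(seed)
    if (!independentShuffles) {
      nullTracks <- lapply(seq_len(n), function(i)
        if (m == "shuffle_gRNA") track(.shuffleChars(rnaCh), aaCh)
        else track(rnaCh, .shuffleChars(aaCh)))
      nullMat <- vapply(cutoffs, function(ct)
        vapply(nullTracks, trackBsc, numeric(1L), cutoff = ct), numeric(n))
    } else {
      nullMat <- vapply(cutoffs, function(ct)
        vapply(seq_len(n), function(i) {
          tr <- if (m == "shuffle_gRNA") track(.shuffleChars(rnaCh), aaCh)
                else track(rnaCh, .shuffleChars(aaCh))
          trackBsc(tr, ct)
        }, numeric(1L)), numeric(n))
    }
    nullMat <- matrix(nullMat, nrow = n)
    out[[paste0("median_null_bsc_", sub("shuffle_", "", m))]] <-
      apply(nullMat, 2L, stats::median)
    out[[paste0("p_", sub("shuffle_", "", m))]] <- vapply(
      seq_along(cutoffs), function(k)
        mean(nullMat[, k] >= out$native_bsc[k] - 1e-12), numeric(1L))
  }
  out
}

#' Build a reference interval set from per-position read coverage
#'
#' CLIP-style reference construction: the genome positions whose
#' coverage is in the top \code{topPct} percent are selected, optionally
#' extended by \code{flank} nucleotides on each side, and collapsed into
#' intervals.
#'
#' @param coverage Numeric per-position coverage vector, or a
#'   data.frame/path of a two-column TSV (position, coverage).
#' @param topPct Percentage of top-covered positions to keep.
#' @param flank Nucleotides added on both sides of each selected
#'   position before collapsing.
#' @return An \code{IRanges} of reference intervals (1-based inclusive),
#'   clipped to the genome.
#' @export
coverageReference <- function(coverage, topPct = 10, flank = 0L) {
  if (is.character(coverage))
    coverage <- utils::read.delim(coverage, header = FALSE)
  if (is.data.frame(coverage)) {
    v <- rep(0, max(coverage[[1L]]))
    v[coverage[[1L]]] <- coverage[[2L]]
    coverage <- v
  }
  if (topPct <= 0 || topPct > 100) stop("'topPct' must be in (0, 100]")
  thr <- quantile(coverage, 1 - topPct / 100, names = FALSE, type = 7)
  sel <- which(coverage >= thr)
  if (!length(sel)) return(IRanges())
  r <- IRanges(pmax(sel - flank, 1L), pmin(sel + flank, length(coverage)))
  reduce(r)
}
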
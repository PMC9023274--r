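#' @import methods
#' @importFrom stats cor quantile sd setNames
NULL

AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

RNA_BASES <- c("A", "C", "G", "U")

#' Nucleobase/amino-acid affinity scale
#'
#' One relative affinity value per standard amino acid for a single
#' nucleobase (or nucleobase mimetic). Lower values denote stronger
#' affinity; profile matching therefore looks for minima, except for
#' adenine-type scales which follow the opposite ("anti-matching")
#' convention and are matched at maxima.
#'
#' @slot name Short scale identifier (e.g. \code{"PYR'"}, \code{"ADE"}).
#' @slot values Named numeric vector of length 20 (one-letter amino-acid
#'   codes), finite, dimensionless relative affinities.
#' @slot direction Either \code{"min"} (matched profiles correspond to
#'   negative sliding Pearson R, sites are called below a cutoff) or
#'   \code{"max"} (adenine convention; sites are called above a cutoff).
#' @export
setClass("AffinityScale",
  representation(name = "character", values = "numeric",
                 direction = "character"))

setValidity("AffinityScale", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  v <- object@values
  if (length(v) != 20L)
    msg <- c(msg, sprintf("expected 20 amino-acid values, got %d", length(v)))
  miss <- setdiff(AA_CODES, names(v))
  if (length(miss))
    msg <- c(msg, paste0("missing amino acid(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(names(v)))
    msg <- c(msg, paste0("duplicated amino acid(s): ",
                         paste(unique(names(v)[duplicated(names(v))]), collapse = ", ")))
  if (!all(is.finite(v)))
    msg <- c(msg, "all affinity values must be finite")
  if (length(object@direction) != 1L || !object@direction %in% c("min", "max"))
    msg <- c(msg, "'direction' must be \"min\" or \"max\"")
  if (length(msg)) msg else TRUE
})

#' Per-position sequence profile with undefined margins
#'
#' A numeric track over a sequence. Positions where the smoothing window
#' does not fully fit (the leading/trailing margins) hold \code{NA} and
#' are treated as undefined everywhere downstream (site calling, BSC
#' denominators, shuffle nulls).
#'
#' @slot seqId Identifier of the underlying sequence.
#' @slot values Full-length numeric vector; \code{NA} marks undefined
#'   positions.
#' @slot window Smoothing window (odd) in sequence units.
#' @slot unit Sequence unit of the positions ("nt", "triplet" or
#'   "residue").
#' @export
setClass("PositionProfile",
  representation(seqId = "character", values = "numeric",
                 window = "integer", unit = "character"))

setValidity("PositionProfile", function(object) {
  msg <- character()
  if (length(object@window) != 1L || is.na(object@window) ||
      object@window < 1L || object@window %% 2L == 0L)
    msg <- c(msg, "'window' must be a positive odd integer")
  if (!object@unit %in% c("nt", "triplet", "residue"))
    msg <- c(msg, "'unit' must be one of nt/triplet/residue")
  if (length(msg)) msg else TRUE
})

#' Sliding Pearson match profile
#'
#' Per-nucleotide Pearson R between a smoothed CP nucleobase-affinity
#' profile and the local smoothed gRNA nucleobase-density profile, the R
#' of each genome fragment being assigned to its central nucleotide.
#'
#' @slot proteinId Protein identifier.
#' @slot scaleName Affinity scale used.
#' @slot baseSet Nucleobases whose density was profiled.
#' @slot direction Site-calling direction inherited from the scale.
#' @slot nResidues Protein length (residues) used for the scan.
#' @export
setClass("MatchProfile", contains = "PositionProfile",
  representation(proteinId = "character", scaleName = "character",
                 baseSet = "character", direction = "character",
                 nResidues = "integer"))

#' Relative gRNA/CP interaction-energy profile
#'
#' Linearly additive relative interaction energy of an unstructured CP at
#' every gRNA position (raw), its window average (smoothed, 63 nt by
#' default) and the z-scores of the smoothed values over all defined
#' positions. Energies are relative: only the ranking of positions is
#' meaningful, not absolute binding free energies.
#'
#' @slot proteinId Protein identifier.
#' @slot raw Raw fragment energies at fragment-center positions
#'   (full-length, \code{NA} margins).
#' @slot z z-scores of the smoothed track over defined positions.
#' @slot nResidues Protein length (residues).
#' @export
setClass("EnergyProfile", contains = "PositionProfile",
  representation(proteinId = "character", raw = "numeric", z = "numeric",
                 nResidues = "integer"))

setMethod("show", "AffinityScale", function(object) {
  cat(sprintf("AffinityScale \"%s\" (direction: %s)\n", object@name,
              object@direction))
  print(round(object@values, 3))
})

.showProfile <- function(object, extra = "") {
  def <- which(!is.na(object@values))
  cat(sprintf("%s over '%s'%s\n  length %d (%s), defined %d..%d, window %d\n",
              class(object), object@seqId, extra, length(object@values),
              object@unit,
              if (length(def)) min(def) else NA_integer_,
              if (length(def)) max(def) else NA_integer_,
              object@window))
}

setMethod("show", "PositionProfile", function(object) .showProfile(object))

setMethod("show", "MatchProfile", function(object) {
  .showProfile(object, sprintf(" vs protein '%s' [%s, bases %s]",
                               object@proteinId, object@scaleName,
                               paste(object@baseSet, collapse = "")))
})

setMethod("show", "EnergyProfile", function(object) {
  .showProfile(object, sprintf(" vs protein '%s' (relative energy)",
                               object@proteinId))
})
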
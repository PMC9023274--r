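#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("definedPositions", function(x) standardGeneric("definedPositions"))

#' @rdname accessors
#' @export
setGeneric("firstDefined", function(x) standardGeneric("firstDefined"))

#' @rdname accessors
#' @export
setGeneric("lastDefined", function(x) standardGeneric("lastDefined"))

#' @rdname accessors
#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))

#' @rdname accessors
#' @export
setGeneric("scaleDirection", function(x) standardGeneric("scaleDirection"))

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname accessors
#' @export
setGeneric("rawEnergy", function(x) standardGeneric("rawEnergy"))

#' Accessors for profiles and scales
#'
#' \code{profileValues} returns the full-length numeric track (\code{NA}
#' at undefined margins); \code{definedPositions} the 1-based positions
#' carrying a value; \code{firstDefined}/\code{lastDefined} its bounds;
#' \code{scaleValues}/\code{scaleDirection} the per-residue affinities
#' and matching convention of an \linkS4class{AffinityScale};
#' \code{zScores}/\code{rawEnergy} the standardized and raw tracks of an
#' \linkS4class{EnergyProfile}.
#'
#' @param x A profile or scale object.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("profileValues", "PositionProfile", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("definedPositions", "PositionProfile",
          function(x) which(!is.na(x@values)))

#' @rdname accessors
#' @export
setMethod("firstDefined", "PositionProfile", function(x) {
  d <- which(!is.na(x@values))
  if (length(d)) d[1L] else NA_integer_
})

#' @rdname accessors
#' @export
setMethod("lastDefined", "PositionProfile", function(x) {
  d <- which(!is.na(x@values))
  if (length(d)) d[length(d)] else NA_integer_
})

#' @rdname accessors
#' @export
setMethod("scaleValues", "AffinityScale", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("scaleDirection", "AffinityScale", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("zScores", "EnergyProfile", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("rawEnergy", "EnergyProfile", function(x) x@raw)
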
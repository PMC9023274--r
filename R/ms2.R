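#' Bundled MS2 cryo-EM reference binding sites
#'
#' The 15 gRNA stem-loops in direct contact with the coat protein in
#' the cryo-EM asymmetric reconstruction of bacteriophage MS2
#' (coordinates on RefSeq NC_001417, 1-based inclusive). These are the
#' standard reference intervals for benchmarking MS2 binding-site
#' predictions. The genome sequence itself is not bundled; supply your
#' own copy of NC_001417 (e.g. via \code{\link{readFastaSequences}}) to
#' reproduce the MS2 analysis.
#'
#' @return An \code{IRanges} of 15 intervals.
#' @export
#' @examples
#' ms2StemLoops()
ms2StemLoops <- function() {
  readIntervals(system.file("extdata", "ms2_stemloops.tsv",
                            package = "capsidMatch"), format = "tsv1")
}
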
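#' @importFrom BiocGenerics sort
NULL

#' Read sequences from a FASTA file
#'
#' Multi-record FASTA; each sequence is normalized to the strict
#' alphabet (\code{\link{normalizeSequence}}), so records with ambiguity
#' codes raise an error.
#'
#' @param path FASTA file path.
#' @param alphabet \code{"rna"} (T mapped to U) or \code{"protein"}.
#' @return A named list of \code{RNAString} or \code{AAString} objects.
#' @export
readFastaSequences <- function(path, alphabet = c("rna", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- readBStringSet(path)
  if (!length(set)) stop("no sequences in FASTA file '", path, "'")
  out <- lapply(as.character(set), normalizeSequence, alphabet = alphabet)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Read reference intervals (BED or 1-based TSV)
#'
#' BED input is interpreted as 0-based half-open and converted to the
#' internal 1-based inclusive convention (a BED line \code{chr 101 114}
#' becomes the interval 102-114); \code{tsv1} input is a headerless
#' two-column (or three-column, first column ignored) tab-separated
#' table of 1-based inclusive start/end coordinates.
#'
#' @param path Interval file.
#' @param format \code{"bed"} or \code{"tsv1"}.
#' @param genomeLength Optional; intervals beyond it raise an error.
#' @return An \code{IRanges} (1-based inclusive), sorted and reduced.
#' @export
readIntervals <- function(path, format = c("bed", "tsv1"),
                          genomeLength = NULL) {
  format <- match.arg(format)
  if (format == "bed") {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(path, format = "BED")
      r <- IRanges(IRanges::start(gr), IRanges::end(gr))
    } else {
      tab <- utils::read.delim(path, header = FALSE, comment.char = "#")
      r <- IRanges(as.integer(tab[[2L]]) + 1L, as.integer(tab[[3L]]))
    }
  } else {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#")
    if (ncol(tab) >= 3L && !is.numeric(tab[[1L]])) tab <- tab[, -1L]
    st <- suppressWarnings(as.integer(tab[[1L]]))
    en <- suppressWarnings(as.integer(tab[[2L]]))
    bad <- which(is.na(st) | is.na(en))
    if (length(bad))
      stop("malformed interval line(s) in '", path, "': ",
           paste(bad, collapse = ", "))
    r <- IRanges(st, en)
  }
  if (any(start(r) < 1L))
    stop("interval start before position 1 in '", path, "'")
  if (!is.null(genomeLength) && any(end(r) > genomeLength))
    stop("interval beyond genome length ", genomeLength, " in '", path, "'")
  reduce(sort(r))
}

#' Write intervals as BED or 1-based TSV
#'
#' The exact inverse of \code{\link{readIntervals}}: BED output is
#' 0-based half-open, \code{tsv1} output 1-based inclusive; either
#' round-trips losslessly.
#'
#' @param x An \code{IRanges}.
#' @param path Output path.
#' @param format \code{"bed"} or \code{"tsv1"}.
#' @param seqId Sequence name for the first column.
#' @return Invisibly, \code{path}.
#' @export
writeIntervals <- function(x, path, format = c("bed", "tsv1"),
                           seqId = "gRNA") {
  format <- match.arg(format)
  df <- if (format == "bed")
    data.frame(seqId, start(x) - 1L, end(x)) else
    data.frame(seqId, start(x), end(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a profile as TSV
#'
#' Writes (position, value) rows for the defined positions only; for an
#' \linkS4class{EnergyProfile} the raw, smoothed and z tracks are all
#' written.
#'
#' @param profile A \linkS4class{PositionProfile} (or subclass).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeProfileTsv <- function(profile, path) {
  stopifnot(is(profile, "PositionProfile"))
  if (is(profile, "EnergyProfile")) {
    keep <- which(!is.na(profile@raw) | !is.na(profile@values))
    df <- data.frame(position = keep, raw = profile@raw[keep],
                     smoothed = profile@values[keep], z = profile@z[keep])
  } else {
    keep <- which(!is.na(profile@values))
    df <- data.frame(position = keep, value = profile@values[keep])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write/read a screening report
#'
#' Plain TSV with header; \code{readReport} restores the exact rows
#' written by \code{writeReport}.
#'
#' @param rows A data.frame (e.g. from \code{\link{screenVirus}}).
#' @param path File path.
#' @return \code{writeReport}: invisibly \code{path};
#'   \code{readReport}: the data.frame.
#' @export
writeReport <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Run configuration defaults
#'
#' Central defaults for the pipeline: profile smoothing window 21
#' (residues/triplets), energy smoothing window 63 nt, region merge gap
#' 10 nt, 1000 shuffles. Windows must be odd and positive.
#'
#' @param windowProfiles,windowEnergy,mergeGap,nShuffles,seed Overrides.
#' @return A validated named list.
#' @export
runConfig <- function(windowProfiles = 21L, windowEnergy = 63L,
                      mergeGap = 10L, nShuffles = 1000L, seed = 1L) {
  for (w in c(windowProfiles, windowEnergy))
    if (w < 1L || w %% 2L == 0L) stop("windows must be odd and positive")
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  list(windowProfiles = as.integer(windowProfiles),
       windowEnergy = as.integer(windowEnergy),
       mergeGap = as.integer(mergeGap),
       nShuffles = as.integer(nShuffles), seed = as.integer(seed))
}
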
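# Woese's polar requirement: experimental partitioning of amino acids in
# water/pyridine-derivative systems, used as a pyrimidine-mimetic (PYR')
# affinity proxy. Canonical published values; frozen here.
.POLAR_REQUIREMENT <- c(
  A = 7.0, C = 4.8, D = 13.0, E = 12.5, F = 5.0,
  G = 7.9, H = 8.4, I = 4.9,  K = 10.1, L = 4.9,
  M = 5.3, N = 10.0, P = 6.6, Q = 8.6,  R = 9.1,
  S = 7.5, T = 6.6, V = 5.6,  W = 5.2,  Y = 5.4)

.isAdenineScale <- function(name) toupper(name) == "ADE"

#' Construct an affinity scale
#'
#' @param name Scale identifier. Scales named \code{"ADE"}
#'   (case-insensitive) default to the \code{"max"} (anti-matching)
#'   direction; all others to \code{"min"}.
#' @param values Named numeric vector: one finite value per standard
#'   amino-acid one-letter code (case-insensitive names). Selenocysteine
#'   (\code{U}) and ambiguity codes (\code{X}, \code{B}, \code{Z}) are
#'   rejected.
#' @param direction Override the matching direction (\code{"min"} or
#'   \code{"max"}).
#' @return An \linkS4class{AffinityScale}.
#' @export
#' @examples
#' sc <- affinityScale("toy", setNames(seq_len(20) / 20,
#'   strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
#' scaleDirection(sc)
affinityScale <- function(name, values,
                          direction = if (.isAdenineScale(name)) "max" else "min") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  nm <- toupper(names(values))
  bad <- setdiff(nm, AA_CODES)
  if (length(bad))
    stop("non-standard amino-acid code(s) in scale '", name, "': ",
         paste(unique(bad), collapse = ", "))
  if (anyDuplicated(nm))
    stop("duplicated amino-acid code(s) in scale '", name, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  miss <- setdiff(AA_CODES, nm)
  if (length(miss))
    stop("scale '", name, "' is missing amino acid(s): ",
         paste(miss, collapse = ", "))
  names(values) <- nm
  new("AffinityScale", name = name, values = values[AA_CODES],
      direction = direction)
}

#' Load an affinity scale from a two-column TSV
#'
#' Reads a tab-separated table of \code{aa<TAB>value} rows (header
#' optional), one row per standard amino acid.
#'
#' @param source Path to the TSV file.
#' @param name Scale identifier (see \code{\link{affinityScale}} for the
#'   direction convention).
#' @param direction Optional direction override.
#' @return An \linkS4class{AffinityScale}.
#' @export
loadAffinityScale <- function(source, name,
                              direction = if (.isAdenineScale(name)) "max" else "min") {
  stopifnot(is.character(name), nzchar(name))
  tab <- utils::read.delim(source, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("scale file '", source, "' must have two tab-separated columns")
  # tolerate a header row such as "aa<TAB>value"
  if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab[1L, 2L]))) &&
      !toupper(tab[1L, 1L]) %in% AA_CODES)
    tab <- tab[-1L, , drop = FALSE]
  vals <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(vals))
    stop("non-numeric affinity value(s) in '", source, "' at line(s) ",
         paste(which(is.na(vals)), collapse = ", "))
  affinityScale(name, setNames(vals, tab[[1L]]), direction = direction)
}

#' Serialize an affinity scale to TSV
#'
#' Writes \code{aa<TAB>value} rows in canonical amino-acid order; the
#' file round-trips exactly through \code{\link{loadAffinityScale}}.
#'
#' @param scale An \linkS4class{AffinityScale}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAffinityScale <- function(scale, path) {
  stopifnot(is(scale, "AffinityScale"))
  v <- scaleValues(scale)
  utils::write.table(
    data.frame(aa = names(v), value = format(v, digits = 17, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Built-in pyrimidine-mimetic affinity scale (polar requirement)
#'
#' Woese's experimentally determined polar requirement scale, the
#' partitioning behaviour of amino acids with substituted pyridines
#' (pyrimidine mimetics). It is the only experimental scale covering all
#' twenty amino acids and serves as the default pyrimidine affinity
#' proxy (\code{PYR'}): low polar requirement, as for the hydrophobic
#' residues, means strong PYR affinity, so matched gRNA/CP profiles give
#' negative Pearson R and sites are called at minima.
#'
#' @return An \linkS4class{AffinityScale} named \code{"PYR'"}.
#' @export
#' @examples
#' polarRequirement()
polarRequirement <- function() {
  affinityScale("PYR'", .POLAR_REQUIREMENT, direction = "min")
}
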
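.CP_INCLUDE <- c("coat", "capsid", "core")
.CP_INCLUDE_PICORNA <- c("VP0", "VP1", "VP2", "VP3", "VP4")
.CP_EXCLUDE <- c("precursor", "polyprotein", "readthrough", "read-through",
                 "leader", "duplicate", "homolog", "coat-like", "extension",
                 "extended", "RNA replicase")
# matched as a whole token so that every "... protein" record is not rejected
.CP_EXCLUDE_TOKEN <- "proteins"

#' Select coat-protein records from annotated products
#'
#' Applies the name/length/ambiguity rules used for genome-scale CP
#' screening: the product name must contain one of \code{coat},
#' \code{capsid} or \code{core} (case-insensitive substrings; for
#' \emph{Picornaviridae} additionally \code{VP0}--\code{VP4}) and none
#' of the exclusion terms (\code{precursor}, \code{polyprotein},
#' \code{readthrough}, \code{read-through}, \code{leader},
#' \code{duplicate}, \code{homolog}, \code{coat-like}, \code{extension},
#' \code{extended}, \code{RNA replicase}, and \code{proteins} as a whole
#' token); the sequence must have at least \code{minLength} residues and
#' no ambiguous or non-standard characters. Rejections are reported as
#' data, not errors.
#'
#' @param records A data.frame with columns \code{virus_id},
#'   \code{family}, \code{product_name} and \code{sequence}.
#' @param minLength Minimum protein length (default 50 residues).
#' @return The input data.frame with added columns \code{accepted}
#'   (logical) and \code{reason} (\code{NA} for accepted records).
#' @export
selectCpRecords <- function(records, minLength = 50L) {
  stopifnot(all(c("virus_id", "family", "product_name", "sequence")
                %in% names(records)))
  n <- nrow(records)
  accepted <- logical(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    name <- records$product_name[i]
    if (!nzchar(name)) { reason[i] <- "empty product name"; next }
    nameLc <- tolower(name)
    incl <- .CP_INCLUDE
    if (grepl("picornaviridae", records$family[i], ignore.case = TRUE))
      incl <- c(incl, .CP_INCLUDE_PICORNA)
    if (!any(vapply(tolower(incl), function(t)
          grepl(t, nameLc, fixed = TRUE), logical(1L)))) {
      reason[i] <- "no inclusion term in product name"
      next
    }
    hitExcl <- vapply(setNames(tolower(.CP_EXCLUDE), .CP_EXCLUDE),
                      function(t) grepl(t, nameLc, fixed = TRUE),
                      logical(1L))
    if (grepl(paste0("\\b", .CP_EXCLUDE_TOKEN, "\\b"), name,
              ignore.case = TRUE))
      hitExcl <- c(hitExcl, proteins = TRUE)
    if (any(hitExcl)) {
      reason[i] <- paste0("exclusion term: ",
                          paste(names(which(hitExcl)), collapse = ", "))
      next
    }
    sq <- records$sequence[i]
    ok <- tryCatch(normalizeSequence(sq, "protein"),
                   error = function(e) conditionMessage(e))
    if (is.character(ok)) { reason[i] <- ok; next }
    if (length(ok) < minLength) {
      reason[i] <- sprintf("fewer than %d amino acids (%d)",
                           minLength, length(ok))
      next
    }
    accepted[i] <- TRUE
  }
  records$accepted <- accepted
  records$reason <- reason
  records
}

#' Predict interaction regions for one virus
#'
#' Computes the relative interaction-energy profile of every supplied CP
#' along the genome and reports the regions with the lowest 1% and/or 5%
#' of smoothed energies (merged by the <\code{mergeGap}-nt rule), one
#' row per region. Pairs whose genome is too short to host a fragment
#' plus margins are skipped; the reason is recorded in the
#' \code{"skipped"} attribute of the result.
#'
#' @param genome Genome sequence.
#' @param cps Named list (or \code{AAStringSet}) of CP sequences.
#' @param scales Four-scale list keyed by base (see
#'   \code{\link{energyProfile}}).
#' @param pctLevels Percentile levels to report (default \code{c(1, 5)}).
#' @param mergeGap Region merge gap (default 10).
#' @param smoothingWindow Energy smoothing window (default 63).
#' @param virusId Identifier used in the report.
#' @param cdsRanges Optional \code{IRanges} of the CP CDS; adds an
#'   \code{overlaps_cp_cds} flag per region.
#' @return A data.frame with columns virus, cp, level, start, end,
#'   min_z (and optionally overlaps_cp_cds).
#' @export
screenVirus <- function(genome, cps, scales, pctLevels = c(1, 5),
                        mergeGap = 10L, smoothingWindow = 63L,
                        virusId = "virus", cdsRanges = NULL) {
  if (is(cps, "XStringSet")) cps <- as.list(as.character(cps))
  if (is.null(names(cps)) || any(!nzchar(names(cps))))
    names(cps) <- paste0("CP", seq_along(cps))
  rows <- list()
  skipped <- character()
  for (nm in names(cps)) {
    ep <- tryCatch(
      energyProfile(genome, cps[[nm]], scales,
                    smoothingWindow = smoothingWindow,
                    genomeId = virusId, proteinId = nm),
      error = function(e) conditionMessage(e))
    if (is.character(ep)) {
      skipped[nm] <- ep
      next
    }
    for (lev in pctLevels) {
      reg <- predictRegions(ep, percentile = lev, mergeGap = mergeGap)
      if (!length(reg)) next
      df <- data.frame(virus = virusId, cp = nm, level = lev,
                       start = start(reg), end = end(reg),
                       min_z = mcols(reg)$minZ)
      if (!is.null(cdsRanges)) {
        cdsPos <- .rangePositions(cdsRanges)
        df$overlaps_cp_cds <- vapply(seq_len(nrow(df)), function(i)
          any(seq.int(df$start[i], df$end[i]) %in% cdsPos), logical(1L))
      }
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(virus = character(), cp = character(), level = numeric(),
               start = integer(), end = integer(), min_z = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
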
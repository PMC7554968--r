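# Modified-MSIS rule engine: maps a clinical record to infected /
# non-infected from two major and five minor criteria.

# Evaluate one record given as a list/one-row data frame.
# Majors: sinus tract; two positive cultures with the same pathogen.
# Minors: synovial WBC > 3000/uL; synovial PMN% > 80; serum CRP > 10 mg/L;
# single positive culture (incl. PCR positivity); histopathology Morawietz
# grade II or III. Thresholds are strict; missing fields never fire.
.msisOne <- function(rec) {
  fired <- function(x) !is.na(x) && x
  majors <- c(
    sinusTract = fired(rec$sinusTract),
    doubleCulture = !is.na(rec$microbiology) && rec$microbiology == "double"
  )
  minors <- c(
    wbc = !is.na(rec$wbc) && rec$wbc > 3000,
    pmn = !is.na(rec$pmnPct) && rec$pmnPct > 80,
    crp = !is.na(rec$crp) && rec$crp > 10,
    singleCulture = !is.na(rec$microbiology) && rec$microbiology == "single",
    pathology = !is.na(rec$pathologyGrade) &&
      rec$pathologyGrade %in% c("II", "III")
  )
  list(status = if (any(majors) || sum(minors) >= 3) "infected" else
    "non-infected",
    majors = majors, minors = minors,
    nMajor = sum(majors), nMinor = sum(minors))
}

#' Classify clinical records by the modified MSIS criteria
#'
#' A patient is labelled infected if at least one major criterion fires
#' (joint-communicating sinus tract; double-positive microbiology with the
#' same pathogen) or at least three of five minor criteria fire (synovial
#' WBC > 3000/uL; synovial PMN% > 80; serum CRP > 10 mg/L; a single
#' positive culture or PCR; Morawietz grade II or III histopathology). All
#' thresholds are strict inequalities; missing fields count as not fired; a
#' double-positive culture fires the major criterion only. Grade IV
#' membranes do not fire the pathology minor.
#'
#' @param records Data frame with columns `sinusTract` (logical),
#'   `microbiology` (`"none"`, `"single"`, `"double"` or `NA`), `wbc`
#'   (cells/uL), `pmnPct` (percent), `crp` (mg/L), `pathologyGrade`
#'   (`"I"`-`"IV"` or `NA`). Other columns are ignored. `NA` marks missing.
#' @param override Optional logical/character vector of manual label
#'   overrides for borderline cases (`NA` = no override); an explicit
#'   override replaces the rule-based status and is flagged in the output.
#' @return Data frame with one row per record: `status`, per-criterion
#'   fired flags, `nMajor`, `nMinor`, `nMinorEvaluable` (minor criteria
#'   with non-missing inputs) and `overridden`.
#' @export
classifyMsis <- function(records, override = NULL) {
  records <- as.data.frame(records)
  need <- c("sinusTract", "microbiology", "wbc", "pmnPct", "crp",
            "pathologyGrade")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) > 0) {
    if (any(records$wbc < 0, na.rm = TRUE)) stop("wbc must be >= 0")
    if (any(records$pmnPct < 0 | records$pmnPct > 100, na.rm = TRUE))
      stop("pmnPct must be in [0, 100]")
    if (any(records$crp < 0, na.rm = TRUE)) stop("crp must be >= 0")
    badGrade <- !is.na(records$pathologyGrade) &
      !records$pathologyGrade %in% c("I", "II", "III", "IV")
    if (any(badGrade)) stop("pathologyGrade must be I, II, III or IV")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    rec <- as.list(records[i, need])
    lab <- .msisOne(rec)
    data.frame(status = lab$status,
               majorSinusTract = lab$majors[["sinusTract"]],
               majorDoubleCulture = lab$majors[["doubleCulture"]],
               minorWbc = lab$minors[["wbc"]],
               minorPmn = lab$minors[["pmn"]],
               minorCrp = lab$minors[["crp"]],
               minorSingleCulture = lab$minors[["singleCulture"]],
               minorPathology = lab$minors[["pathology"]],
               nMajor = lab$nMajor, nMinor = lab$nMinor,
               nMinorEvaluable = sum(!is.na(rec$wbc), !is.na(rec$pmnPct),
                                     !is.na(rec$crp),
                                     !is.na(rec$microbiology),
                                     !is.na(rec$pathologyGrade)),
               overridden = FALSE,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(override)) {
    stopifnot(length(override) == nrow(out))
    set <- !is.na(override)
    if (any(set)) {
      ov <- override[set]
      if (is.logical(ov)) ov <- ifelse(ov, "infected", "non-infected")
      out$status[set] <- ov
      out$overridden[set] <- TRUE
    }
  }
  rownames(out) <- NULL
  out
}

#' Truth table of the MSIS decision rule
#'
#' Enumerates all 2^7 combinations of the two major and five minor criteria
#' with the rule's label (infected iff >= 1 major or >= 3 minors). Serves
#' as an exhaustive oracle for the rule engine.
#'
#' @return Data frame with 128 rows: logical columns `major1`, `major2`,
#'   `minor1`..`minor5`, plus `nMajor`, `nMinor` and `status`.
#' @export
msisTruthTable <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(grid) <- c("major1", "major2", paste0("minor", 1:5))
  grid$nMajor <- grid$major1 + grid$major2
  grid$nMinor <- rowSums(grid[paste0("minor", 1:5)])
  grid$status <- ifelse(grid$nMajor >= 1 | grid$nMinor >= 3,
                        "infected", "non-infected")
  grid
}

#' Write MSIS classifications for a clinical record table
#'
#' Reads records from CSV (empty fields are missing), appends the status
#' and fired-criteria columns, and writes the result.
#'
#' @param recordsCsv Input CSV path.
#' @param outCsv Output CSV path.
#' @return The combined data frame, invisibly.
#' @export
msisClassifyFile <- function(recordsCsv, outCsv) {
  records <- utils::read.csv(recordsCsv, stringsAsFactors = FALSE)
  res <- classifyMsis(records)
  out <- cbind(records, res)
  utils::write.csv(out, outCsv, row.names = FALSE)
  invisible(out)
}
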
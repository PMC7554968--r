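# Plain-text readers and writers: CSV event tables, TSV proportion and
# comparison tables.

#' Read and write event tables as CSV
#'
#' One header row with the fixed channel names, one row per event, raw
#' intensity scale. An optional `truth` column carries hidden ground-truth
#' labels for synthetic samples.
#'
#' @param events A [FlowEventTable-class].
#' @param path File path.
#' @param truth Include the hidden labels, when present.
#' @param cofactor Arcsinh cofactor to record on the object read back.
#' @return `readEventCsv()` returns a [FlowEventTable-class];
#'   `writeEventCsv()` invisibly returns `path`.
#' @export
writeEventCsv <- function(events, path, truth = TRUE) {
  stopifnot(is(events, "FlowEventTable"))
  df <- as.data.frame(intensities(events), check.names = FALSE)
  lab <- truthLabels(events)
  if (truth && !is.null(lab)) df$truth <- lab
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventCsv
#' @export
readEventCsv <- function(path, cofactor = 150) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  lab <- character(0)
  if ("truth" %in% names(df)) {
    lab <- df$truth
    df$truth <- NULL
  }
  FlowEventTable(as.matrix(df), truthLabels = lab, cofactor = cofactor)
}

#' Write per-sample proportions as TSV
#'
#' Stable column order: sample id, inclusion flag, live-singlet count, then
#' the ratio columns of [ratioNames()].
#'
#' @param profiles List of [ProportionProfile-class].
#' @param path File path.
#' @param sampleIds Sample identifiers.
#' @param included Logical inclusion flags from [qcFilter()].
#' @param liveSinglets Live-singlet counts.
#' @return Invisibly, the written data frame.
#' @export
writeProportionsTsv <- function(profiles, path, sampleIds = NULL,
                                included = NULL, liveSinglets = NULL) {
  mat <- do.call(rbind, lapply(profiles, ratios))
  df <- data.frame(
    sampleId = if (is.null(sampleIds))
      sprintf("S%03d", seq_len(nrow(mat))) else sampleIds,
    included = if (is.null(included)) TRUE else included,
    liveSinglets = if (is.null(liveSinglets)) NA else liveSinglets,
    mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a proportions TSV back into a matrix plus metadata
#'
#' @param path File path.
#' @return List with `matrix` (ratios), `sampleId`, `included`,
#'   `liveSinglets`.
#' @export
readProportionsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("sampleId", "included", "liveSinglets")
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(m) <- df$sampleId
  list(matrix = m, sampleId = df$sampleId, included = df$included,
       liveSinglets = df$liveSinglets)
}
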
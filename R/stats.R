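# Between-group statistics: Mann-Whitney U with exact small-sample p-values
# and the per-ratio group comparison table.

#' Mann-Whitney U test
#'
#' Classical rank-sum test of two independent samples. The statistic U is
#' the number of (x, y) pairs with x preceding y in rank (ties counted
#' half). The two-sided p-value is computed by exact enumeration of the
#' rank partition when the combined sample size is at most `exactMax` and
#' there are no ties, and by the normal approximation with tie and
#' continuity correction otherwise (delegating to [stats::wilcox.test()]).
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact `TRUE`/`FALSE` to force the exact or asymptotic p-value;
#'   `NULL` (default) chooses automatically.
#' @param exactMax Largest combined sample size for the automatic exact
#'   path (default 20).
#' @return List with elements `U` (statistic for `x`), `p` (two-sided) and
#'   `method`.
#' @export
mannWhitneyU <- function(x, y, exact = NULL, exactMax = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("both samples must be non-empty")
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(list(U = U, p = 1, method = "degenerate (constant data)"))
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- (n1 + n2) <= exactMax && !ties
  w <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(U), p = min(1, w$p.value),
       method = if (exact && !ties) "exact" else
         "normal approximation (tie/continuity corrected)")
}

.sigTier <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Compare proportion profiles between infected and non-infected groups
#'
#' One Mann-Whitney U test per ratio, with group medians, the significance
#' tier convention (* p < 0.05, ** p < 0.01, *** p < 0.001,
#' **** p < 0.0001) and the direction of the shift in the infected group.
#' No multiple-testing correction is applied to the reported tiers
#' (matching the single-test presentation of each ratio); a
#' Benjamini-Hochberg adjusted column is emitted alongside for
#' transparency. Missing ratios are dropped pairwise per test.
#'
#' @param profiles List of [ProportionProfile-class] objects, or a numeric
#'   matrix with samples in rows and ratios in columns.
#' @param labels Character vector (`"infected"` / `"non-infected"`) or
#'   logical/0-1 vector, one entry per sample.
#' @return Data frame with one row per ratio: medians, `U`, `p`, `tier`,
#'   `direction`, `pBH`.
#' @export
compareGroups <- function(profiles, labels) {
  mat <- if (is.matrix(profiles)) profiles else
    do.call(rbind, lapply(profiles, ratios))
  lab <- .asInfectedLogical(labels)
  if (length(lab) != nrow(mat))
    stop("labels must have one entry per sample")
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("need at least 2 samples per group")
  rows <- lapply(colnames(mat), function(cn) {
    xi <- mat[lab, cn]; yi <- mat[!lab, cn]
    xi <- xi[!is.na(xi)]; yi <- yi[!is.na(yi)]
    if (length(xi) < 2 || length(yi) < 2) {
      return(data.frame(ratio = cn, medianInfected = NA, medianNonInfected =
                          NA, U = NA, p = NA, tier = NA, direction = NA,
                        stringsAsFactors = FALSE))
    }
    mw <- mannWhitneyU(xi, yi)
    mi <- stats::median(xi); mn <- stats::median(yi)
    data.frame(ratio = cn, medianInfected = mi, medianNonInfected = mn,
               U = mw$U, p = mw$p, tier = .sigTier(mw$p),
               direction = if (mi > mn) "higher in infected" else
                 if (mi < mn) "lower in infected" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pBH <- stats::p.adjust(out$p, method = "BH")
  out
}

.asInfectedLogical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  if (is.factor(labels)) labels <- as.character(labels)
  labels %in% c("infected", "1", "TRUE", "septic")
}
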
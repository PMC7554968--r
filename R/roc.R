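# ROC analysis, AUC, and Youden-index cut-off selection for single ratios.

#' ROC curve of one marker
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' scores plus -Inf and +Inf; a sample is called infected when its
#' (orientation-adjusted) score exceeds the threshold. The AUC is computed
#' as the concordance probability over infected/non-infected pairs with
#' ties counted one half, which equals the trapezoid area under the
#' sensitivity/1-specificity path.
#'
#' @param scores Numeric marker values.
#' @param labels Infection status (`"infected"`/`"non-infected"`, logical,
#'   or 0/1).
#' @param direction `"higher"` if larger scores indicate infection,
#'   `"lower"` otherwise.
#' @return Object of class `rocCurve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden` (J at its maximising threshold),
#'   `cutoff` (the maximising threshold on the original score scale),
#'   `direction`, `n1`, `n0`.
#' @export
rocCurve <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  lab <- .asInfectedLogical(labels)
  ok <- !is.na(scores) & !is.na(lab)
  scores <- scores[ok]; lab <- lab[ok]
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute a ROC curve")
  s <- if (direction == "higher") scores else -scores
  pos <- s[lab]; neg <- s[!lab]
  uu <- sort(unique(s))
  thr <- c(-Inf, if (length(uu) > 1)
    (uu[-1] + uu[-length(uu)]) / 2 else NULL, Inf)
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  # concordance AUC with ties counted 1/2
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- sum(cmp) / (n1 * n0)
  j <- sens + spec - 1
  jmax <- max(j)
  # ties broken toward higher specificity, i.e. the larger threshold
  best <- max(which(j >= jmax - 1e-12))
  cutoff <- thr[best]
  if (direction == "lower") cutoff <- -cutoff
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden = jmax, cutoff = cutoff,
                 direction = direction, n1 = n1, n0 = n0),
            class = "rocCurve")
}

#' @export
print.rocCurve <- function(x, ...) {
  cat(sprintf(
    "ROC curve (%d infected / %d non-infected, %s-is-infected)\n",
    x$n1, x$n0, x$direction))
  cat(sprintf("  AUC %.4f, Youden J %.4f at cut-off %.6g\n",
              x$auc, x$youden, x$cutoff))
  invisible(x)
}

#' Youden-index cut-off of a ROC curve
#'
#' Returns the threshold maximising J = sensitivity + specificity - 1,
#' with ties broken toward the threshold yielding higher specificity.
#'
#' @param curve A [rocCurve()] object.
#' @return List with `cutoff` and `J`.
#' @export
youdenCutoff <- function(curve) {
  stopifnot(inherits(curve, "rocCurve"))
  list(cutoff = curve$cutoff, J = curve$youden)
}

#' Rank candidate markers by AUC filter and Youden index
#'
#' Drops markers with AUC below `aucMin` (default 0.8) and sorts the
#' remainder by decreasing Youden index. When a gate tree is supplied, each
#' retained marker is annotated with whether its numerator population is
#' gated independently of every higher-ranked retained marker (i.e. the
#' leaf populations are not nested in the gating hierarchy), which matters
#' when combining markers into a composite rule.
#'
#' @param curves Named list of [rocCurve()] objects.
#' @param aucMin Minimum AUC retained.
#' @param tree Optional [GateTree-class] used for the independence
#'   annotation; marker names must then be ratio names
#'   (`family.cellType`).
#' @return Data frame ranked by decreasing J: `marker`, `auc`, `youden`,
#'   `cutoff`, `direction` and (with a tree) `independentOfHigherRanked`.
#' @export
rankMarkers <- function(curves, aucMin = 0.8, tree = NULL) {
  if (!length(curves))
    return(data.frame(marker = character(0), auc = numeric(0),
                      youden = numeric(0), cutoff = numeric(0),
                      direction = character(0)))
  df <- data.frame(
    marker = names(curves),
    auc = vapply(curves, `[[`, numeric(1), "auc"),
    youden = vapply(curves, `[[`, numeric(1), "youden"),
    cutoff = vapply(curves, `[[`, numeric(1), "cutoff"),
    direction = vapply(curves, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
  df <- df[df$auc >= aucMin, , drop = FALSE]
  df <- df[order(-df$youden, -df$auc), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(tree) && nrow(df)) {
    nodeOf <- function(marker) {
      tp <- sub("^[^.]+\\.", "", marker)
      if (tp == "CD3") return("tCellsClean")
      if (tp %in% names(tree@leaves)) tree@leaves[[tp]] else NA_character_
    }
    anc <- function(id) {
      out <- character(0)
      while (!is.na(id) && !identical(id, "root")) {
        out <- c(out, id)
        id <- tree@nodes[[id]]$parent
      }
      out
    }
    lineages <- lapply(df$marker, function(m) anc(nodeOf(m)))
    df$independentOfHigherRanked <- vapply(seq_len(nrow(df)), function(i) {
      if (i == 1) return(TRUE)
      me <- lineages[[i]]
      all(vapply(seq_len(i - 1), function(j) {
        other <- lineages[[j]]
        !(me[1] %in% other || other[1] %in% me)
      }, logical(1)))
    }, logical(1))
  }
  df
}
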
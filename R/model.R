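# Logistic infection model: univariate prescreen, forward selection under
# the Bayesian Information Criterion, probability cut-off classification,
# and leave-one-sample-out cross-validated misclassification.

#' Feature matrix for the infection model
#'
#' Assembles the flow-derived ratio covariates and the binary response
#' (1 = infected). By design the covariates are proportions from the gating
#' engine only: clinical MSIS inputs (WBC, PMN%, CRP, cultures, pathology)
#' must not appear among the predictors, since the response is derived from
#' them.
#'
#' @param profiles List of [ProportionProfile-class] objects or a numeric
#'   matrix (samples x ratios).
#' @param labels Infection status per sample (see [compareGroups()]).
#' @param columns Ratio names to keep (default: all shared columns).
#' @return Object of class `pjiFeatureMatrix`: list with `x` (numeric
#'   matrix) and `y` (integer 0/1 vector).
#' @export
featureMatrix <- function(profiles, labels, columns = NULL) {
  x <- if (is.matrix(profiles)) profiles else
    do.call(rbind, lapply(profiles, ratios))
  if (!is.null(columns)) x <- x[, columns, drop = FALSE]
  y <- as.integer(.asInfectedLogical(labels))
  if (length(y) != nrow(x)) stop("labels must have one entry per sample")
  structure(list(x = x, y = y), class = "pjiFeatureMatrix")
}

#' @export
print.pjiFeatureMatrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "samples x", ncol(x$x), "predictors (",
      sum(x$y), "infected )\n")
  invisible(x)
}

#' Append the non-granulocyte fraction as an additional predictor
#'
#' Adds the fraction of non-granulocytes among CD45+ leucocytes as a 24th
#' covariate. Because total granulocyte infiltration enters the clinical
#' definition of infection, this predictor moves the model closer to the
#' clinical rule and is kept out of the default covariate set.
#'
#' @param fm A [featureMatrix()] object.
#' @param countsList List of [CellTypeCounts-class], one per row of `fm`.
#' @return A new `pjiFeatureMatrix` with one extra column
#'   `CD45.nonGranulocyte`; existing columns are unchanged.
#' @export
addNonGranulocytePredictor <- function(fm, countsList) {
  stopifnot(inherits(fm, "pjiFeatureMatrix"))
  if (length(countsList) != nrow(fm$x))
    stop("countsList must have one element per sample row")
  v <- vapply(countsList, function(ct) {
    cd45 <- cd45Count(ct)
    if (cd45 > 0) nonGranulocyteCount(ct) / cd45 else NA_real_
  }, numeric(1))
  fm$x <- cbind(fm$x, `CD45.nonGranulocyte` = v)
  fm
}

.fitLogistic <- function(x, y) {
  x <- as.matrix(x)
  dat <- if (ncol(x)) data.frame(y = y, x, check.names = FALSE) else
    data.frame(y = y)
  form <- if (ncol(x)) y ~ . else y ~ 1
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  attr(fit, "separated") <- separated
  fit
}

#' Univariate prescreen of candidate covariates
#'
#' Fits a one-covariate logistic model per candidate and retains those
#' whose Wald p-value falls below `alpha` (default 0.25). This coarse
#' filter precedes forward selection and mirrors common practice for
#' ensuring the multivariable fit converges. Candidates with undefined
#' p-values (constant columns, non-convergent fits) are dropped with a
#' warning.
#'
#' @param fm A [featureMatrix()] object.
#' @param alpha Retention threshold on the covariate p-value.
#' @param candidates Candidate column names (default
#'   [defaultPredictorSet()] intersected with the available columns).
#' @return Character vector of retained column names.
#' @export
prescreenUnivariate <- function(fm, alpha = 0.25, candidates = NULL) {
  stopifnot(inherits(fm, "pjiFeatureMatrix"))
  if (sum(fm$y == 1) < 2 || sum(fm$y == 0) < 2)
    stop("need at least 2 samples per class")
  if (is.null(candidates))
    candidates <- intersect(defaultPredictorSet(), colnames(fm$x))
  keep <- character(0)
  for (cn in candidates) {
    xi <- fm$x[, cn]
    ok <- !is.na(xi)
    p <- tryCatch({
      if (stats::sd(xi[ok]) == 0) NA_real_ else {
        f <- .fitLogistic(fm$x[ok, cn, drop = FALSE], fm$y[ok])
        cf <- summary(f)$coefficients
        if (nrow(cf) < 2 || !f$converged) NA_real_ else cf[2, 4]
      }
    }, error = function(e) NA_real_)
    if (is.na(p)) {
      warning("prescreen: dropping '", cn,
              "' (constant or non-convergent univariate fit)")
    } else if (p < alpha) {
      keep <- c(keep, cn)
    }
  }
  keep
}

.bicOf <- function(fit) stats::BIC(fit)

#' Forward variable selection under BIC
#'
#' Greedy forward selection for the logistic infection model: starting from
#' the intercept-only null model, the candidate whose addition lowers the
#' Bayesian Information Criterion the most is added at each step; selection
#' stops as soon as no addition lowers the BIC. The returned fit carries
#' maximum-likelihood coefficients, Wald p-values, the model BIC and a
#' likelihood-ratio p-value against the null model. Quasi-separation is
#' detected and flagged (coefficients are still reported, unpenalised).
#'
#' @param fm A [featureMatrix()] object.
#' @param candidates Non-empty character vector of candidate columns.
#' @return Object of class `pjiLogisticFit`: `variables`, `coefficients`
#'   (named, intercept first), `pValues`, `bic`, `lrPValue`, `separated`,
#'   and the underlying `glm` object.
#' @export
forwardSelectBic <- function(fm, candidates) {
  stopifnot(inherits(fm, "pjiFeatureMatrix"))
  if (!length(candidates)) stop("candidates must be non-empty")
  y <- fm$y
  selected <- character(0)
  nullFit <- .fitLogistic(fm$x[, integer(0), drop = FALSE], y)
  best <- .bicOf(nullFit)
  bestFit <- nullFit
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trials <- lapply(remaining, function(cn) {
      .fitLogistic(fm$x[, c(selected, cn), drop = FALSE], y)
    })
    bics <- vapply(trials, .bicOf, numeric(1))
    i <- which.min(bics)
    if (bics[i] < best - 1e-10) {
      best <- bics[i]
      bestFit <- trials[[i]]
      selected <- c(selected, remaining[i])
    } else break
  }
  if (isTRUE(attr(bestFit, "separated")))
    warning("quasi-separation detected in the selected model; ",
            "coefficients may be unstable")
  cf <- summary(bestFit)$coefficients
  lr <- stats::pchisq(bestFit$null.deviance - bestFit$deviance,
                      df = length(selected), lower.tail = FALSE)
  structure(list(variables = selected,
                 coefficients = stats::coef(bestFit),
                 pValues = cf[, 4],
                 bic = best,
                 lrPValue = if (length(selected)) lr else 1,
                 separated = isTRUE(attr(bestFit, "separated")),
                 glm = bestFit),
            class = "pjiLogisticFit")
}

#' @export
print.pjiLogisticFit <- function(x, ...) {
  cat("Logistic infection model (forward-BIC selection)\n")
  if (!length(x$variables)) {
    cat("  null model selected (intercept only)\n")
  } else {
    cat("  selected:", paste(x$variables, collapse = ", "), "\n")
  }
  print(round(cbind(beta = x$coefficients, p = x$pValues), 4))
  cat(sprintf("  BIC %.2f, LR p vs null %.3g%s\n", x$bic, x$lrPValue,
              if (x$separated) " [quasi-separated]" else ""))
  invisible(x)
}

.covariateVector <- function(fit, x) {
  vars <- fit$variables
  if (is(x, "ProportionProfile")) x <- ratios(x)
  if (is.matrix(x) || is.data.frame(x)) {
    miss <- setdiff(vars, colnames(x))
    if (length(miss))
      stop("missing selected variable(s): ", paste(miss, collapse = ", "))
    return(as.matrix(x[, vars, drop = FALSE]))
  }
  miss <- setdiff(vars, names(x))
  if (length(miss))
    stop("missing selected variable(s): ", paste(miss, collapse = ", "))
  matrix(x[vars], nrow = 1, dimnames = list(NULL, vars))
}

#' Predicted infection probability
#'
#' Evaluates `p = 1 / (1 + exp(-(b0 + b1 x1 + ... + bk xk)))` for the
#' selected covariates.
#'
#' @param fit A [forwardSelectBic()] fit.
#' @param x Named numeric vector, matrix/data frame with named columns, or
#'   a [ProportionProfile-class].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(fit, x) {
  stopifnot(inherits(fit, "pjiLogisticFit"))
  xm <- .covariateVector(fit, x)
  eta <- rep(fit$coefficients[1], nrow(xm)) +
    if (length(fit$variables))
      drop(xm %*% fit$coefficients[-1]) else 0
  unname(stats::plogis(eta))
}

#' Classify a sample from its predicted probability
#'
#' A sample is called infected when its predicted probability strictly
#' exceeds the cut-off; a probability exactly at the cut-off is called
#' non-infected. The default cut-off 0.5185 follows the calibrated
#' operating point of the infection model; 0.5 and 0.8 are common
#' alternatives.
#'
#' @param fit A [forwardSelectBic()] fit.
#' @param x Covariates (see [predictProb()]).
#' @param cutoff Probability cut-off in (0, 1).
#' @return Character vector, `"infected"` / `"non-infected"`.
#' @export
classifyInfection <- function(fit, x, cutoff = 0.5185) {
  stopifnot(cutoff > 0, cutoff < 1)
  p <- predictProb(fit, x)
  ifelse(p > cutoff, "infected", "non-infected")
}

#' Leave-one-sample-out cross-validated misclassification
#'
#' For every sample, the entire selection pipeline - univariate prescreen
#' followed by forward-BIC selection - is re-run on the remaining samples
#' and the held-out sample's infection probability is predicted from the
#' resulting model. The held-out label is scored against each requested
#' probability cut-off only after prediction; it is never visible to
#' prescreening, selection or fitting.
#'
#' @param fm A [featureMatrix()] object with at least 10 samples.
#' @param cutoffs Probability cut-offs to score (default 0.5, 0.8 and
#'   0.5185).
#' @param alpha Prescreen threshold.
#' @param candidates Starting candidate set (default
#'   [defaultPredictorSet()] intersected with available columns).
#' @return Object of class `pjiCvReport`: `probabilities` (per sample),
#'   `y`, `errors` (named misclassification fractions per cut-off),
#'   `skipped` (fold indices skipped because the training split lost a
#'   class).
#' @export
loocvError <- function(fm, cutoffs = c(0.5, 0.8, 0.5185), alpha = 0.25,
                       candidates = NULL) {
  stopifnot(inherits(fm, "pjiFeatureMatrix"))
  n <- nrow(fm$x)
  if (n < 10) stop("leave-one-out requires at least 10 samples")
  if (is.null(candidates))
    candidates <- intersect(defaultPredictorSet(), colnames(fm$x))
  probs <- rep(NA_real_, n)
  skipped <- integer(0)
  nSeparated <- 0L
  for (i in seq_len(n)) {
    trainX <- fm$x[-i, , drop = FALSE]
    trainY <- fm$y[-i]
    if (length(unique(trainY)) < 2 || sum(trainY == 1) < 2 ||
        sum(trainY == 0) < 2) {
      warning("fold ", i, " skipped: a class is (nearly) absent in training")
      skipped <- c(skipped, i)
      next
    }
    trainFm <- structure(list(x = trainX, y = trainY),
                         class = "pjiFeatureMatrix")
    kept <- suppressWarnings(prescreenUnivariate(trainFm, alpha = alpha,
                                                 candidates = candidates))
    fit <- suppressWarnings(
      if (length(kept)) forwardSelectBic(trainFm, kept) else
        forwardSelectBic(trainFm, candidates[1]))
    nSeparated <- nSeparated + fit$separated
    probs[i] <- predictProb(fit, fm$x[i, , drop = FALSE])
  }
  ok <- !is.na(probs)
  errors <- vapply(cutoffs, function(ct) {
    pred <- probs[ok] > ct
    mean(pred != (fm$y[ok] == 1))
  }, numeric(1))
  names(errors) <- format(cutoffs)
  structure(list(probabilities = probs, y = fm$y, errors = errors,
                 cutoffs = cutoffs, skipped = skipped,
                 nSeparatedFolds = nSeparated),
            class = "pjiCvReport")
}

#' @export
print.pjiCvReport <- function(x, ...) {
  cat("Leave-one-sample-out cross-validation over",
      length(x$probabilities), "samples\n")
  for (i in seq_along(x$errors))
    cat(sprintf("  cut-off %s: misclassification %.1f%%\n",
                names(x$errors)[i], 100 * x$errors[i]))
  if (length(x$skipped)) cat("  skipped folds:", length(x$skipped), "\n")
  invisible(x)
}

#' In-sample sensitivity and specificity at a probability cut-off
#'
#' @param fit A [forwardSelectBic()] fit.
#' @param fm The [featureMatrix()] it was trained on.
#' @param cutoff Probability cut-off.
#' @return Named numeric vector: `sensitivity`, `specificity`,
#'   `misclassified` (count).
#' @export
modelPerformance <- function(fit, fm, cutoff = 0.5185) {
  p <- predictProb(fit, fm$x)
  pred <- p > cutoff
  truth <- fm$y == 1
  c(sensitivity = sum(pred & truth) / sum(truth),
    specificity = sum(!pred & !truth) / sum(!truth),
    misclassified = sum(pred != truth))
}
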
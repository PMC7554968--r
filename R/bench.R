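# Nested cross-validation benchmark over pluggable classifiers.

#' Default classifier set for the benchmark
#'
#' Five classifier families with explicit, small tuning grids: radial-kernel
#' support vector machine, recursive-partitioning decision tree, linear
#' discriminant analysis (no tunables), random forest, and a
#' deviance-pruned classification tree standing in for a conditional
#' inference tree (no conditional-inference implementation is bundled; the
#' surrogate is documented in the vignette). Grids are deliberately
#' explicit rather than inherited from any framework's internal defaults.
#'
#' @return Named list of classifier specifications; each holds `fit(x, y,
#'   params)`, `predict(model, x)` returning a factor, and `grid` (a data
#'   frame of hyperparameter rows, possibly empty).
#' @export
defaultClassifiers <- function() {
  asDf <- function(x, y) {
    d <- data.frame(x, check.names = TRUE)
    if (!is.null(y)) d$.y <- y
    d
  }
  list(
    svmRadial = list(
      grid = expand.grid(cost = c(0.25, 1, 4), gammaScale = c(0.5, 1, 2)),
      fit = function(x, y, params) {
        e1071::svm(x, y, kernel = "radial", cost = params$cost,
                   gamma = params$gammaScale / ncol(x), scale = FALSE)
      },
      predict = function(model, x) stats::predict(model, x)
    ),
    decisionTree = list(
      grid = data.frame(cp = c(0.001, 0.01, 0.1)),
      fit = function(x, y, params) {
        rpart::rpart(.y ~ ., data = asDf(x, y), method = "class",
                     control = rpart::rpart.control(cp = params$cp,
                                                    minsplit = 5))
      },
      predict = function(model, x) {
        stats::predict(model, asDf(x, NULL), type = "class")
      }
    ),
    lda = list(
      grid = data.frame(),
      fit = function(x, y, params) {
        keep <- apply(x, 2, function(v) stats::sd(v) > 0)
        model <- MASS::lda(x[, keep, drop = FALSE], grouping = y)
        list(model = model, keep = keep)
      },
      predict = function(model, x) {
        stats::predict(model$model, x[, model$keep, drop = FALSE])$class
      }
    ),
    randomForest = list(
      grid = data.frame(mtry = c(2, 4, 8)),
      fit = function(x, y, params) {
        randomForest::randomForest(x, y, ntree = 300,
                                   mtry = min(params$mtry, ncol(x)))
      },
      predict = function(model, x) stats::predict(model, x)
    ),
    prunedTree = list(
      grid = data.frame(mindev = c(0.003, 0.01, 0.05)),
      fit = function(x, y, params) {
        tree::tree(.y ~ ., data = asDf(x, y),
                   control = tree::tree.control(nobs = length(y),
                                                mindev = params$mindev,
                                                minsize = 4))
      },
      predict = function(model, x) {
        stats::predict(model, asDf(x, NULL), type = "class")
      }
    )
  )
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, separately within each class so
#' fold class balance mirrors the cohort. The assignment is a deterministic
#' function of the seed.
#'
#' @param y Class vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

.mmce <- function(pred, truth) mean(as.character(pred) != as.character(truth))

.tuneInner <- function(spec, x, y, kInner, seed) {
  if (!nrow(spec$grid)) return(list(params = NULL, tried = 0L))
  fold <- stratifiedFolds(y, kInner, seed)
  errs <- vapply(seq_len(nrow(spec$grid)), function(g) {
    params <- spec$grid[g, , drop = FALSE]
    mean(vapply(seq_len(kInner), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      model <- try(spec$fit(x[tr, , drop = FALSE], y[tr], params),
                   silent = TRUE)
      if (inherits(model, "try-error")) return(NA_real_)
      pred <- try(spec$predict(model, x[!tr, , drop = FALSE]), silent = TRUE)
      if (inherits(pred, "try-error")) return(NA_real_)
      .mmce(pred, y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(params = spec$grid[which.min(errs), , drop = FALSE],
       tried = nrow(spec$grid))
}

#' Nested cross-validation misclassification benchmark
#'
#' Estimates each classifier's mean misclassification error (mmce) without
#' tuning bias: the outer loop provides held-out test folds; within each
#' outer training split an inner cross-validation selects the
#' hyperparameter row of the classifier's grid by inner mmce; the tuned
#' model is refit on the full outer training split and scored on the outer
#' test fold. Outer-test labels take no part in tuning. Folds are
#' stratified by class and deterministic given the seed.
#'
#' @param fm A [featureMatrix()] object.
#' @param classifiers Classifier specification list
#'   (default [defaultClassifiers()]).
#' @param kOuter,kInner Fold counts (default 10/10).
#' @param seed Integer seed for fold assignment and any stochastic
#'   learners.
#' @param folds Optional pre-computed outer fold vector (overrides the
#'   seed-derived stratified assignment).
#' @return Object of class `pjiBenchmarkReport`: `foldErrors` (classifier x
#'   outer-fold matrix), `overall` (per-classifier mean of fold mmces),
#'   `grandMean`, `chosenParams` (per classifier and fold), `folds`,
#'   `seed`.
#' @export
nestedCvMmce <- function(fm, classifiers = defaultClassifiers(),
                         kOuter = 10, kInner = 10, seed = 1,
                         folds = NULL) {
  stopifnot(inherits(fm, "pjiFeatureMatrix"))
  n <- nrow(fm$x)
  if (n < 2 * kOuter)
    stop("need at least 2 * kOuter samples")
  y <- factor(ifelse(fm$y == 1, "infected", "non-infected"))
  x <- fm$x
  if (is.null(folds)) folds <- stratifiedFolds(y, kOuter, seed)
  if (min(table(y, folds)) == 0 && length(unique(y)) == 2)
    stop("a fold lost a class; use more samples or fewer folds")
  foldErrors <- matrix(NA_real_, length(classifiers), kOuter,
                       dimnames = list(names(classifiers), NULL))
  chosen <- vector("list", length(classifiers))
  names(chosen) <- names(classifiers)
  for (ci in seq_along(classifiers)) {
    spec <- classifiers[[ci]]
    chosen[[ci]] <- vector("list", kOuter)
    for (f in seq_len(kOuter)) {
      tr <- folds != f
      innerSeed <- (seed * 1000L + ci * 100L + f) %% .Machine$integer.max
      tune <- withSeed(innerSeed,
                       .tuneInner(spec, x[tr, , drop = FALSE], y[tr],
                                  kInner, innerSeed))
      chosen[[ci]][[f]] <- tune$params
      model <- withSeed(innerSeed + 1L,
                        spec$fit(x[tr, , drop = FALSE], y[tr], tune$params))
      pred <- spec$predict(model, x[!tr, , drop = FALSE])
      foldErrors[ci, f] <- .mmce(pred, y[!tr])
    }
  }
  overall <- rowMeans(foldErrors)
  structure(list(foldErrors = foldErrors, overall = overall,
                 grandMean = mean(overall), chosenParams = chosen,
                 folds = folds, seed = seed),
            class = "pjiBenchmarkReport")
}

#' @export
print.pjiBenchmarkReport <- function(x, ...) {
  cat("Nested cross-validation benchmark (",
      ncol(x$foldErrors), "outer folds )\n")
  for (nm in rownames(x$foldErrors))
    cat(sprintf("  %-14s overall mmce %.1f%%\n", nm, 100 * x$overall[nm]))
  cat(sprintf("  grand average %.1f%%\n", 100 * x$grandMean))
  invisible(x)
}

#' Long-format fold errors for plotting
#'
#' @param report A [nestedCvMmce()] report.
#' @return Data frame with columns `classifier`, `fold`, `mmce`.
#' @export
benchmarkLongTable <- function(report) {
  stopifnot(inherits(report, "pjiBenchmarkReport"))
  data.frame(
    classifier = rep(rownames(report$foldErrors),
                     ncol(report$foldErrors)),
    fold = rep(seq_len(ncol(report$foldErrors)),
               each = nrow(report$foldErrors)),
    mmce = as.vector(report$foldErrors),
    stringsAsFactors = FALSE)
}
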
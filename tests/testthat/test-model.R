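# Logistic infection model: prescreen, forward-BIC selection, prediction,
# classification, LOOCV integrity.

test_that("prescreen drops constants and keeps planted strong effects", {
  set.seed(10)
  fm <- simLogistic(50, c(`(Intercept)` = -0.5, `NonGran.NK` = 2),
                    pNoise = 2)
  fm$x <- cbind(fm$x, flat = rep(0.3, 50))
  expect_warning(
    kept <- prescreenUnivariate(fm, candidates = colnames(fm$x)),
    "flat")
  expect_false("flat" %in% kept)

  hits <- vapply(1:40, function(sd) {
    f <- simLogistic(50, c(`(Intercept)` = -0.5, strong = 2), pNoise = 3,
                     seed = sd)
    "strong" %in% prescreenUnivariate(f, candidates = colnames(f$x))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("forward-BIC prefers the null model on pure noise", {
  nulls <- vapply(1:30, function(sd) {
    set.seed(sd)
    fm <- structure(list(x = matrix(rnorm(50 * 7), 50, 7,
                                    dimnames = list(NULL, paste0("v", 1:7))),
                         y = rbinom(50, 1, 0.4)),
                    class = "pjiFeatureMatrix")
    length(forwardSelectBic(fm, colnames(fm$x))$variables) == 0
  }, logical(1))
  expect_gt(mean(nulls), 0.5)
})

test_that("forward-BIC recovers a planted pair and matches all-subset search", {
  agree <- 0L; exact <- 0L
  for (sd in 1:25) {
    fm <- simLogistic(500, c(`(Intercept)` = -0.3, a = 2, b = -2),
                      pNoise = 5, seed = sd)
    fit <- forwardSelectBic(fm, colnames(fm$x))
    oracle <- allSubsetBic(fm$x, fm$y)
    if (setequal(fit$variables, oracle$set)) agree <- agree + 1L
    if (setequal(fit$variables, c("a", "b"))) exact <- exact + 1L
  }
  expect_gte(exact, 23)        # >= 90% of strong-effect runs
  expect_gte(agree, 24)        # greedy path tracks exhaustive BIC search
})

test_that("predicted probabilities follow the closed-form inverse logit", {
  fm <- separableFeatureMatrix()
  fit <- suppressWarnings(forwardSelectBic(fm, c("NonGran.NK",
                                                 "NonGran.mMDSC")))
  # hand-made fit: zero coefficients -> p = 0.5 everywhere
  flat <- fit
  flat$coefficients[] <- 0
  expect_equal(predictProb(flat, fm$x[3, ]), 0.5)
  # intercept-only evaluation at 1.377 with all selected ratios zero
  one <- fit
  one$coefficients[] <- 0
  one$coefficients[1] <- 1.377
  x0 <- fm$x[1, ]; x0[fit$variables] <- 0
  expect_equal(predictProb(one, x0), 1 / (1 + exp(-1.377)),
               tolerance = 1e-12)
  expect_equal(predictProb(one, x0), 0.7985, tolerance = 1e-4)
  expect_error(predictProb(fit, c(`NonGran.B` = 0.2)),
               "missing selected variable")
})

test_that("probability is monotone in each covariate per coefficient sign", {
  set.seed(21)
  fm <- simLogistic(300, c(`(Intercept)` = 0.2, up = 1.5, down = -1.5))
  fit <- forwardSelectBic(fm, colnames(fm$x))
  expect_setequal(fit$variables, c("up", "down"))
  base <- c(up = 0, down = 0)
  pu <- vapply(c(-1, 0, 1), function(v) {
    z <- base; z["up"] <- v; predictProb(fit, z)
  }, numeric(1))
  expect_true(all(diff(pu) > 0))
  pd <- vapply(c(-1, 0, 1), function(v) {
    z <- base; z["down"] <- v; predictProb(fit, z)
  }, numeric(1))
  expect_true(all(diff(pd) < 0))
})

test_that("classification uses a strict > cut-off with 0.5185 default", {
  fm <- separableFeatureMatrix()
  fit <- suppressWarnings(forwardSelectBic(fm, "NonGran.NK"))
  fake <- fit
  fake$variables <- character(0)
  fake$coefficients <- c(`(Intercept)` = log(0.5185 / (1 - 0.5185)))
  p <- predictProb(fake, fm$x[1, ])
  expect_equal(p, 0.5185, tolerance = 1e-12)
  expect_equal(classifyInfection(fake, fm$x[1, ]), "non-infected")
  expect_equal(classifyInfection(fake, fm$x[1, ], cutoff = 0.5),
               "infected")
})

test_that("error rates sweep monotonically in the number flagged infected", {
  set.seed(31)
  fm <- simLogistic(200, c(`(Intercept)` = 0, s = 1.5))
  fit <- forwardSelectBic(fm, "s")
  p <- predictProb(fit, fm$x)
  cuts <- seq(0.05, 0.95, by = 0.05)
  nFlagged <- vapply(cuts, function(ct) sum(p > ct), numeric(1))
  expect_true(all(diff(nFlagged) <= 0))
})

test_that("LOOCV is error-free on a wide-margin separable cohort", {
  fm <- separableFeatureMatrix(seed = 3)
  cv <- loocvError(fm, cutoffs = c(0.5, 0.8),
                   candidates = colnames(fm$x))
  expect_equal(unname(cv$errors[["0.5"]]), 0)
  expect_length(cv$probabilities, 50)
  expect_length(cv$skipped, 0)
})

test_that("LOOCV never reads the held-out label (poisoning check)", {
  fm <- separableFeatureMatrix(seed = 4)
  i <- 7
  poisoned <- fm
  poisoned$y[i] <- 1L - poisoned$y[i]
  cv1 <- loocvError(fm, cutoffs = 0.5, candidates = colnames(fm$x))
  cv2 <- loocvError(poisoned, cutoffs = 0.5, candidates = colnames(fm$x))
  expect_identical(cv1$probabilities[i], cv2$probabilities[i])
})

test_that("folds whose training split loses a class are skipped with a warning", {
  set.seed(41)
  x <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(NULL, c("a", "b")))
  fm <- structure(list(x = x, y = c(rep(0L, 10), 1L, 1L)),
                  class = "pjiFeatureMatrix")
  w <- capture_warnings(cv <- loocvError(fm, cutoffs = 0.5,
                                         candidates = c("a", "b")))
  expect_length(w, 2)
  expect_true(all(grepl("skipped", w)))
  expect_equal(cv$skipped, c(11L, 12L))
})

test_that("separation is detected and flagged rather than masked", {
  fm <- separableFeatureMatrix(seed = 5)
  expect_warning(
    fit <- forwardSelectBic(fm, c("NonGran.NK", "NonGran.mMDSC")),
    "quasi-separation")
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coefficients)))
})
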
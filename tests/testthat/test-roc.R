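# ROC curves, AUC/concordance identity, Youden cut-offs, marker ranking.

test_that("the four-point worked example gives AUC 0.75 and J 0.5", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  rc <- rocCurve(scores, labels, direction = "higher")
  expect_equal(rc$auc, 0.75)   # 3 of 4 infected/non-infected pairs concordant
  yc <- youdenCutoff(rc)
  expect_equal(yc$J, 0.5)
  # brute force over all five candidate thresholds: J = 0.5 is reached at
  # the midpoints 0.225 and 0.6; the higher-specificity tie-break picks 0.6
  bf <- bruteYouden(scores, labels == 1)
  expect_equal(yc$J, bf$J)
  expect_equal(yc$cutoff, bf$cutoff)
  expect_equal(yc$cutoff, 0.6)
})

test_that("perfect separation gives AUC 1 and J 1; flat scores give J 0", {
  rc <- rocCurve(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(rc$auc, 1)
  expect_equal(rc$youden, 1)
  flat <- rocCurve(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$youden, 0)
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(5)
  rc <- rocCurve(rnorm(4000), rbinom(4000, 1, 0.4))
  expect_equal(rc$auc, 0.5, tolerance = 0.03)
})

test_that("AUC equals the rank-sum concordance U/(n1*n2) exactly", {
  set.seed(33)
  for (i in 1:25) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))  # forces ties
    labels <- rep(c(1, 0), c(n1, n0))
    rc <- rocCurve(scores, labels)
    mw <- mannWhitneyU(scores[labels == 1], scores[labels == 0])
    expect_equal(rc$auc, mw$U / (n1 * n0))
    expect_equal(rc$auc, pairAuc(scores, labels == 1))
  }
})

test_that("reversing the orientation maps AUC to 1 - AUC and keeps J", {
  set.seed(44)
  scores <- rnorm(40, ifelse(rep(c(1, 0), each = 20), 1, 0))
  labels <- rep(c(1, 0), each = 20)
  hi <- rocCurve(scores, labels, "higher")
  lo <- rocCurve(-scores, labels, "lower")
  expect_equal(lo$auc, hi$auc)
  expect_equal(rocCurve(scores, labels, "lower")$auc, 1 - hi$auc)
  expect_equal(lo$youden, hi$youden)
})

test_that("Youden maximisation matches brute force over random score sets", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(6:25, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n, labels), sample(0:2, 1))
    rc <- rocCurve(scores, labels)
    bf <- bruteYouden(scores, labels == 1)
    expect_equal(rc$youden, bf$J, tolerance = 1e-12)
    expect_equal(rc$cutoff, bf$cutoff)
  }
})

test_that("Youden ties break toward the higher-specificity threshold", {
  # two thresholds reach J = 0.5; the larger (more specific) one must win
  scores <- c(1, 2, 3, 4)
  labels <- c(0, 1, 0, 1)
  rc <- rocCurve(scores, labels)
  expect_equal(rc$youden, 0.5)
  expect_equal(rc$cutoff, 3.5)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  scores <- rnorm(60, rep(c(1, 0), each = 30))
  labels <- rep(c(1, 0), each = 30)
  rc <- rocCurve(scores, labels)
  ref <- suppressMessages(pROC::auc(labels, scores,
                                    direction = "<", quiet = TRUE))
  expect_equal(rc$auc, as.numeric(ref))
})

test_that("marker ranking filters on AUC >= 0.8 and sorts by J", {
  set.seed(77)
  labels <- rep(c(1, 0), c(20, 30))
  mk <- function(sep) rnorm(50, ifelse(labels == 1, sep, 0), 1)
  curves <- list(
    strong = rocCurve(ifelse(labels == 1, 10, 0) + rnorm(50, 0, 0.1),
                      labels),
    weak = rocCurve(mk(0.3), labels),
    moderate = rocCurve(mk(2), labels))
  aucs <- vapply(curves, `[[`, numeric(1), "auc")
  shortlist <- rankMarkers(curves, aucMin = 0.8)
  expect_setequal(shortlist$marker, names(aucs)[aucs >= 0.8])
  expect_false("weak" %in% shortlist$marker)
  # ordering equals an independent re-sort by recomputed J
  expect_equal(shortlist$marker,
               shortlist$marker[order(-shortlist$youden)])
  expect_equal(nrow(rankMarkers(list())), 0)
})

test_that("ranking annotates gating independence of numerator lineages", {
  tree <- defaultGateTree()
  labels <- rep(c(1, 0), each = 15)
  set.seed(88)
  sc <- function(sep) rnorm(30, ifelse(labels == 1, sep, 0), 0.2)
  curves <- list(`NonGran.CD3` = rocCurve(sc(3), labels),
                 `NonGran.Tk` = rocCurve(sc(2.5), labels),
                 `NonGran.NK` = rocCurve(sc(2.4), labels))
  rk <- rankMarkers(curves, aucMin = 0.8, tree = tree)
  # Tk is nested inside the CD3 lineage; NK is gated independently
  expect_false(rk$independentOfHigherRanked[rk$marker == "NonGran.Tk"])
  expect_true(rk$independentOfHigherRanked[rk$marker == "NonGran.NK"])
})

test_that("a single-class input is rejected", {
  expect_error(rocCurve(1:5, rep(1, 5)), "both classes")
})
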
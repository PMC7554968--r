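# Modified-MSIS rule engine: worked examples, exhaustive truth-table
# agreement, monotonicity and missingness safety.

blankRecord <- function(...) {
  rec <- list(sinusTract = FALSE, microbiology = "none", wbc = 500,
              pmnPct = 20, crp = 5, pathologyGrade = "I")
  mod <- list(...)
  rec[names(mod)] <- mod
  as.data.frame(rec, stringsAsFactors = FALSE)
}

test_that("major criteria alone classify as infected", {
  r <- classifyMsis(blankRecord(sinusTract = TRUE, microbiology = NA,
                                wbc = NA, pmnPct = NA, crp = NA,
                                pathologyGrade = NA))
  expect_equal(r$status, "infected")
  expect_equal(r$nMajor, 1)
  expect_equal(r$nMinor, 0)
  r2 <- classifyMsis(blankRecord(microbiology = "double"))
  expect_equal(r2$status, "infected")
  expect_true(r2$majorDoubleCulture)
  # a double-positive culture fires the major only, not the single-culture
  # minor
  expect_false(r2$minorSingleCulture)
})

test_that("three minors fire the rule; two do not; thresholds are strict", {
  three <- classifyMsis(blankRecord(wbc = 5000, pmnPct = 85, crp = 15))
  expect_equal(three$status, "infected")
  expect_equal(three$nMinor, 3)
  two <- classifyMsis(blankRecord(wbc = 5000, pmnPct = 85))
  expect_equal(two$status, "non-infected")
  # boundary values do not fire (strict > comparisons)
  border <- classifyMsis(blankRecord(wbc = 3000, pmnPct = 80, crp = 10))
  expect_equal(border$nMinor, 0)
  expect_equal(border$status, "non-infected")
  over <- classifyMsis(blankRecord(wbc = 3000.1, pmnPct = 80.1,
                                   crp = 10.1))
  expect_equal(over$nMinor, 3)
})

test_that("all-negative and all-missing records are non-infected", {
  expect_equal(classifyMsis(blankRecord())$status, "non-infected")
  allNa <- blankRecord(sinusTract = NA, microbiology = NA, wbc = NA,
                       pmnPct = NA, crp = NA, pathologyGrade = NA)
  r <- classifyMsis(allNa)
  expect_equal(r$status, "non-infected")
  expect_equal(r$nMinorEvaluable, 0)
})

test_that("pathology minor fires for grade II/III only", {
  expect_true(classifyMsis(blankRecord(pathologyGrade = "II"))$minorPathology)
  expect_true(classifyMsis(blankRecord(pathologyGrade = "III"))$minorPathology)
  expect_false(classifyMsis(blankRecord(pathologyGrade = "IV"))$minorPathology)
  expect_false(classifyMsis(blankRecord(pathologyGrade = "I"))$minorPathology)
  expect_error(classifyMsis(blankRecord(pathologyGrade = "V")),
               "pathologyGrade")
})

test_that("the engine reproduces the exhaustive 128-row truth table", {
  tt <- msisTruthTable()
  expect_equal(nrow(tt), 128)
  # build a concrete record for each combination and run the engine
  recs <- do.call(rbind, lapply(seq_len(nrow(tt)), function(i) {
    blankRecord(
      sinusTract = tt$major1[i],
      microbiology = if (tt$major2[i]) "double" else
        if (tt$minor4[i]) "single" else "none",
      wbc = if (tt$minor1[i]) 4000 else 1000,
      pmnPct = if (tt$minor2[i]) 90 else 40,
      crp = if (tt$minor3[i]) 50 else 2,
      pathologyGrade = if (tt$minor5[i]) "II" else "I")
  }))
  # major2 (double culture) and minor4 (single culture) share one field;
  # drop the 32 contradictory combinations where both are requested
  feasible <- !(tt$major2 & tt$minor4)
  res <- classifyMsis(recs[feasible, ])
  expect_identical(res$status, tt$status[feasible])
  expect_identical(res$nMajor, tt$nMajor[feasible])
  expect_identical(res$nMinor, as.integer(tt$nMinor[feasible]))

  # counting identity: with no major fired, infected minor patterns are
  # exactly the subsets of size >= 3
  minorOnly <- tt[!tt$major1 & !tt$major2, ]
  expect_equal(nrow(minorOnly), 32)
  expect_equal(sum(minorOnly$status == "infected"),
               choose(5, 3) + choose(5, 4) + choose(5, 5))
})

test_that("firing one more criterion never flips infected to non-infected", {
  tt <- msisTruthTable()
  cols <- c("major1", "major2", paste0("minor", 1:5))
  keys <- do.call(paste0, lapply(tt[cols], as.integer))
  lab <- setNames(tt$status, keys)
  flips <- 0L
  for (i in seq_len(nrow(tt))) {
    if (tt$status[i] != "infected") next
    for (cn in cols) {
      if (!tt[i, cn]) {
        up <- as.integer(unlist(tt[i, cols]))
        up[match(cn, cols)] <- 1L
        if (lab[[paste(up, collapse = "")]] != "infected")
          flips <- flips + 1L
      }
    }
  }
  expect_equal(flips, 0L)
})

test_that("making any field missing never increases the fired count", {
  full <- blankRecord(sinusTract = TRUE, microbiology = "single",
                      wbc = 5000, pmnPct = 90, crp = 40,
                      pathologyGrade = "II")
  base <- classifyMsis(full)
  for (fld in c("sinusTract", "microbiology", "wbc", "pmnPct", "crp",
                "pathologyGrade")) {
    dropped <- full
    dropped[[fld]] <- NA
    r <- classifyMsis(dropped)
    expect_lte(r$nMajor + r$nMinor, base$nMajor + base$nMinor)
  }
})

test_that("manual overrides replace the rule label and are flagged", {
  recs <- rbind(blankRecord(), blankRecord(sinusTract = TRUE))
  res <- classifyMsis(recs, override = c("infected", NA))
  expect_equal(res$status, c("infected", "infected"))
  expect_equal(res$overridden, c(TRUE, FALSE))
})

test_that("record files round-trip through the CSV interface", {
  recs <- rbind(blankRecord(wbc = 5000, pmnPct = 90, crp = 40),
                blankRecord())
  inCsv <- withr::local_tempfile(fileext = ".csv")
  outCsv <- withr::local_tempfile(fileext = ".csv")
  write.csv(recs, inCsv, row.names = FALSE)
  msisClassifyFile(inCsv, outCsv)
  back <- read.csv(outCsv, stringsAsFactors = FALSE)
  expect_equal(back$status, c("infected", "non-infected"))
  expect_true(all(c("nMajor", "nMinor") %in% names(back)))
})
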
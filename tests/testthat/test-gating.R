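# Gating engine: QC inclusion rule, leaf assignment against hidden labels,
# hierarchy invariants, proportion arithmetic, JSON round-trip.

mkLevels <- function(...) {
  df <- data.frame(..., check.names = FALSE)
  df
}

# tiny local Dirichlet helper for random compositions
.rdirichletTest <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

test_that("inclusion filter applies the 400 live-singlet rule inclusively", {
  tree <- defaultGateTree()
  mk <- function(nLive, nDead) {
    lv <- mkLevels(n = c(nLive, nDead), Viability = c(1, 4))
    eventTableFromLevels(lv)
  }
  too_few <- qcFilter(mk(399, 50), tree)
  expect_false(too_few$included)
  expect_equal(too_few$nLiveSinglets, 399)
  exactly <- qcFilter(mk(400, 50), tree)
  expect_true(exactly$included)
  expect_equal(exactly$nLiveSinglets, 400)
})

test_that("empty tables are excluded and a missing viability channel errors", {
  tree <- defaultGateTree()
  empty <- FlowEventTable(matrix(numeric(0), 0, 18,
                                 dimnames = list(NULL, panelChannels()$all)))
  res <- qcFilter(empty, tree)
  expect_false(res$included)
  expect_equal(res$nLiveSinglets, 0)
  ev <- eventTableFromLevels(mkLevels(n = 500))
  broken <- FlowEventTable(
    intensities(ev)[, setdiff(panelChannels()$all, "Viability")])
  expect_error(qcFilter(broken, tree), "Viability")
})

test_that("a pure NK phenotype lands entirely in the NK leaf", {
  lv <- mkLevels(n = 1000, CD56 = 4)  # CD45+ CD66b- CD3- CD19- CD56+ CD14-
  ev <- eventTableFromLevels(lv)
  ct <- applyGateTree(ev)
  expect_equal(unname(leafCounts(ct)[["NK"]]), 1000)
  expect_equal(sum(leafCounts(ct)), 1000)
  expect_equal(unassignedCount(ct), 0)
})

test_that("CD3+ CD56+ events are NKT, not T helper or T killer", {
  lv <- mkLevels(n = 500, CD3 = 4, CD56 = 4, CD4 = 4)
  ct <- applyGateTree(eventTableFromLevels(lv))
  expect_equal(unname(leafCounts(ct)[["NKT"]]), 500)
  expect_equal(unname(leafCounts(ct)[["Th"]]), 0)
  expect_equal(unname(leafCounts(ct)[["Tk"]]), 0)
})

test_that("gate-tree leaf fractions track hidden labels on a 50k mixture", {
  s <- generateSample(infectedProfile(totalEvents = 50000), seed = 2024)
  ct <- applyGateTree(s)
  truth <- truthLabels(s)
  live <- !truth %in% c("debris", "dead", "doublet")
  trueFrac <- table(factor(truth[live], levels = cellTypes())) / sum(live)
  gateFrac <- leafCounts(ct) / cd45Count(ct)
  expect_true(all(abs(gateFrac - as.numeric(trueFrac)) < 0.02))

  asg <- assignEvents(s)
  predicted <- ifelse(asg %in% c("excluded"), "non-cell", asg)
  actual <- ifelse(live, truth, "non-cell")
  expect_gt(mean(predicted == actual), 0.98)
})

test_that("leaf counts partition the live singlets and respect the hierarchy", {
  set.seed(7)
  for (rep in 1:5) {
    fr <- .rdirichletTest(rep(1, 11))
    names(fr) <- cellTypes()
    prof <- compositionProfile(fr, totalEvents = 4000)
    s <- generateSample(prof, seed = rep)
    tree <- defaultGateTree()
    ct <- applyGateTree(s, tree)
    expect_equal(sum(leafCounts(ct)) + unassignedCount(ct),
                 liveSingletCount(ct))
    nc <- nodeCounts(ct)
    for (id in names(tree@nodes)) {
      par <- tree@nodes[[id]]$parent
      if (!is.null(par) && !is.na(par) && par %in% names(nc))
        expect_lte(nc[[id]], nc[[par]])
    }
  }
})

test_that("raising a threshold gate never increases counts at or below it", {
  s <- generateSample(nonInfectedProfile(totalEvents = 10000), seed = 31)
  lo <- defaultGateTree()
  hi <- defaultGateTree()
  hi@nodes[["leucocytes"]]$min <- 3.5  # raise only the CD45 positivity gate
  ctLo <- applyGateTree(s, lo)
  ctHi <- applyGateTree(s, hi)
  expect_lte(cd45Count(ctHi), cd45Count(ctLo))
  # every leaf is downstream of the CD45 gate, so none may grow
  expect_true(all(leafCounts(ctHi) <= leafCounts(ctLo)))
})

test_that("proportion arithmetic and the label-recount oracle agree", {
  # arithmetic on a constructed count set: 900 granulocytes (CD16+),
  # 100 non-granulocytes of which 30 NK
  lv <- mkLevels(n = c(900, 30, 70),
                 CD66b = c(4, 1, 1), CD16 = c(4, 1, 1),
                 CD56 = c(1, 4, 1), CD3 = c(1, 1, 4), CD4 = c(1, 1, 4))
  ct <- applyGateTree(eventTableFromLevels(lv))
  pr <- ratios(computeProportions(ct, include24 = TRUE))
  expect_equal(pr[["CD45.nonGranulocyte"]], 0.10)
  expect_equal(pr[["NonGran.NK"]], 0.30)
  expect_equal(pr[["Gran.neutrophil"]], 1.0)

  # full synthetic sample vs an independent flat recount of hidden labels
  s <- generateSample(nonInfectedProfile(totalEvents = 30000), seed = 55)
  ct2 <- applyGateTree(s)
  pr2 <- ratios(computeProportions(ct2))
  truth <- truthLabels(s)
  lab <- truth[!truth %in% c("debris", "dead", "doublet")]
  cd45 <- length(lab)
  nonGran <- sum(!lab %in% c("neutrophil", "eosinophil"))
  gran <- sum(lab %in% c("neutrophil", "eosinophil", "basophil"))
  recount <- c(
    `CD45.NK` = sum(lab == "NK") / cd45,
    `NonGran.CD3` = sum(lab %in% c("Th", "Tk", "NKT")) / nonGran,
    `NonGran.mMDSC` = sum(lab == "mMDSC") / nonGran,
    `Gran.basophil` = sum(lab == "basophil") / gran)
  for (nm in names(recount))
    expect_equal(pr2[[nm]], recount[[nm]], tolerance = 0.01)
})

test_that("zero denominators yield missing ratios with a warning", {
  lv <- mkLevels(n = 10, CD45 = 1)  # CD45-negative events only
  ct <- applyGateTree(eventTableFromLevels(lv))
  expect_warning(pr <- computeProportions(ct), "zero")
  expect_true(all(is.na(ratios(pr))))
})

test_that("gate trees survive a JSON round-trip and reject bad structure", {
  tree <- defaultGateTree()
  path <- withr::local_tempfile(fileext = ".json")
  writeGateTree(tree, path)
  back <- readGateTree(path)
  expect_equal(back@leaves, tree@leaves)
  expect_equal(back@qcChain, tree@qcChain)
  s <- generateSample(nonInfectedProfile(totalEvents = 3000), seed = 9)
  expect_equal(leafCounts(applyGateTree(s, back)),
               leafCounts(applyGateTree(s, tree)))

  nodes <- tree@nodes
  nodes[["cells"]]$parent <- "leucocytes"  # forward reference = cycle
  expect_error(GateTree(nodes, tree@leaves, tree@qcChain,
                        tree@fluorescence), "not defined before")
  nodes2 <- tree@nodes
  nodes2[["live"]]$channels <- "NoSuchChannel"
  expect_error(GateTree(nodes2, tree@leaves, tree@qcChain,
                        tree@fluorescence), "unknown channel")
})
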
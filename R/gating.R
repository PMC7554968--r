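# Hierarchical gating engine: declarative threshold / rectangle / Boolean
# gates evaluated on arcsinh-transformed fluorescence intensities.

#' Default hierarchical gating strategy
#'
#' Builds the gate tree resolving eleven leucocyte subtypes from a joint
#' aspirate sample. The pre-gates exclude debris and doublets on
#' FSC-A/FSC-H and FSC-W/SSC-A and dead cells on the viability dye. CD45
#' selects leucocytes, CD66b splits granulocytes (CD16 then separates
#' neutrophils from eosinophils) from non-granulocytes. CD3/CD19 separates
#' T from B cells; the CD3+ gate is cleaned on SSC, CD56 identifies NKT
#' cells and CD4/CD8 the T helper and T killer subsets. A Boolean gate pools
#' the CD3- CD19- cells with the events rejected by the SSC clean-up;
#' CD56/CD14 then yields NK cells and the monocytic branch, which HLA-DR
#' and CD16/CD11b split into monocytes and mMDSCs. The remaining cells are
#' resolved by HLA-DR/CD123 into basophils and dendritic-cell candidates,
#' with CD11c separating myeloid from plasmacytoid DCs (reported as one
#' combined DC type).
#'
#' All fluorescence thresholds default to the midpoint between the
#' generator's negative and positive population locations on the arcsinh
#' scale; they are plain numbers in the returned object and can be edited
#' or serialised with [writeGateTree()].
#'
#' @param threshold Fluorescence positivity threshold on the arcsinh scale.
#' @param cofactor Arcsinh cofactor.
#' @param sscTCellMax Upper SSC-A bound of the CD3+ clean-up gate.
#' @return A [GateTree-class].
#' @export
defaultGateTree <- function(threshold = 2.5, cofactor = 150,
                            sscTCellMax = 45000) {
  nodes <- list(
    list(id = "root", type = "root"),
    gateNode("cells", "root", c("FSC-A", "FSC-H"),
             min = c(15000, 12000), max = c(85000, 85000)),
    gateNode("singlets", "cells", c("FSC-W", "SSC-A"),
             min = c(30000, -Inf), max = c(90000, 150000)),
    gateNode("live", "singlets", "Viability", max = threshold),
    gateNode("leucocytes", "live", "CD45", min = threshold),
    gateNode("granulocytes", "leucocytes", "CD66b", min = threshold),
    gateNode("nonGranulocytes", "leucocytes", "CD66b", max = threshold),
    gateNode("neutrophils", "granulocytes", "CD16", min = threshold),
    gateNode("eosinophils", "granulocytes", "CD16", max = threshold),
    gateNode("tCells", "nonGranulocytes", c("CD3", "CD19"),
             min = c(threshold, -Inf), max = c(Inf, threshold)),
    gateNode("bCells", "nonGranulocytes", c("CD19", "CD3"),
             min = c(threshold, -Inf), max = c(Inf, threshold)),
    gateNode("tCellsClean", "tCells", c("CD3", "SSC-A"),
             min = c(threshold, -Inf), max = c(Inf, sscTCellMax)),
    gateNode("nktCells", "tCellsClean", "CD56", min = threshold),
    gateNode("tConv", "tCellsClean", "CD56", max = threshold),
    gateNode("thCells", "tConv", c("CD4", "CD8"),
             min = c(threshold, -Inf), max = c(Inf, threshold)),
    gateNode("tkCells", "tConv", c("CD8", "CD4"),
             min = c(threshold, -Inf), max = c(Inf, threshold)),
    boolNode("residual", include = "nonGranulocytes",
             exclude = c("bCells", "tCellsClean")),
    gateNode("nkCells", "residual", c("CD56", "CD14"),
             min = c(threshold, -Inf), max = c(Inf, threshold)),
    gateNode("monocytic", "residual", "CD14", min = threshold),
    gateNode("monocytes", "monocytic", "HLA-DR", min = threshold),
    gateNode("mdscCandidates", "monocytic", c("HLA-DR", "CD16"),
             min = c(-Inf, threshold), max = c(threshold, Inf)),
    gateNode("mMDSCs", "mdscCandidates", "CD11b", min = threshold),
    boolNode("nonMonoNK", include = "residual",
             exclude = c("nkCells", "monocytic")),
    gateNode("basophils", "nonMonoNK", c("HLA-DR", "CD123"),
             min = c(-Inf, threshold), max = c(threshold, Inf)),
    gateNode("dcCandidates", "nonMonoNK", "HLA-DR", min = threshold),
    gateNode("mDCs", "dcCandidates", "CD11c", min = threshold),
    gateNode("pDCs", "dcCandidates", c("CD11c", "CD123"),
             min = c(-Inf, threshold), max = c(threshold, Inf)),
    boolNode("dendriticCells", union = c("mDCs", "pDCs"))
  )
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  # the union node's nominal parent, for hierarchy reporting
  nodes[["dendriticCells"]]$parent <- "dcCandidates"
  leaves <- c(neutrophil = "neutrophils", eosinophil = "eosinophils",
              basophil = "basophils", B = "bCells", Th = "thCells",
              Tk = "tkCells", NKT = "nktCells", NK = "nkCells",
              monocyte = "monocytes", mMDSC = "mMDSCs",
              DC = "dendriticCells")
  GateTree(nodes = nodes, leaves = leaves,
           qcChain = c("cells", "singlets", "live"),
           fluorescence = panelChannels()$fluorescence, cofactor = cofactor)
}

# Evaluate membership of every node; returns a named list of logical
# vectors over events of the (already transformed) matrix.
.gateMembership <- function(tm, tree) {
  n <- nrow(tm)
  member <- list()
  for (id in names(tree@nodes)) {
    nd <- tree@nodes[[id]]
    if (identical(nd$type, "root")) {
      member[[id]] <- rep(TRUE, n)
    } else if (identical(nd$type, "bool")) {
      if (length(nd$union)) {
        m <- rep(FALSE, n)
        for (r in nd$union) m <- m | member[[r]]
      } else {
        m <- rep(TRUE, n)
        for (r in nd$include) m <- m & member[[r]]
        for (r in nd$exclude) m <- m & !member[[r]]
      }
      member[[id]] <- m
    } else {
      missingCh <- setdiff(nd$channels, colnames(tm))
      if (length(missingCh))
        stop("event table lacks channel(s) required by gate '", id, "': ",
             paste(missingCh, collapse = ", "))
      m <- member[[nd$parent]]
      for (j in seq_along(nd$channels)) {
        v <- tm[, nd$channels[j]]
        m <- m & v >= nd$min[j] & v <= nd$max[j]
      }
      member[[id]] <- m
    }
  }
  member
}

#' Quality-control filter: debris, doublet and dead-cell exclusion
#'
#' Applies the pre-gates of the tree (scatter-based debris/doublet removal
#' and viability gating) and flags whether the sample meets the inclusion
#' rule of at least 400 single and living cells (inclusive: exactly 400
#' survivors are included).
#'
#' @param events A [FlowEventTable-class].
#' @param tree A [GateTree-class] whose `qcChain` names the pre-gates.
#' @param minCells Minimum surviving events for inclusion (default 400).
#' @return List with `events` (the surviving subset, hidden labels carried
#'   along), `included` (logical flag) and `nLiveSinglets`.
#' @export
qcFilter <- function(events, tree = defaultGateTree(), minCells = 400) {
  stopifnot(is(events, "FlowEventTable"), is(tree, "GateTree"))
  if (nEvents(events) == 0L)
    return(list(events = events, included = FALSE, nLiveSinglets = 0L))
  if (!"Viability" %in% channelNames(events))
    stop("event table lacks channel(s) required by gate 'live': Viability")
  tm <- transformedMatrix(intensities(events), tree@fluorescence,
                          tree@cofactor)
  member <- .gateMembership(tm, tree)
  keep <- member[[tree@qcChain[length(tree@qcChain)]]]
  lab <- truthLabels(events)
  out <- FlowEventTable(intensities(events)[keep, , drop = FALSE],
                        truthLabels = if (is.null(lab)) character(0) else
                          lab[keep],
                        cofactor = events@cofactor)
  list(events = out, included = sum(keep) >= minCells,
       nLiveSinglets = sum(keep))
}

#' Apply a gate tree to an event table
#'
#' Evaluates every gate on the arcsinh-transformed fluorescence (and linear
#' scatter) intensities and returns per-node and per-leaf event counts.
#' Leaf gates are mutually disjoint by construction of the default tree, so
#' each event is assigned to at most one cell type; live singlets captured
#' by no leaf are counted as unassigned.
#'
#' @param events A [FlowEventTable-class].
#' @param tree A [GateTree-class].
#' @return A [CellTypeCounts-class].
#' @export
applyGateTree <- function(events, tree = defaultGateTree()) {
  stopifnot(is(events, "FlowEventTable"), is(tree, "GateTree"))
  tm <- transformedMatrix(intensities(events), tree@fluorescence,
                          tree@cofactor)
  member <- .gateMembership(tm, tree)
  counts <- vapply(member, sum, numeric(1))
  leaf <- counts[tree@leaves]
  names(leaf) <- names(tree@leaves)
  live <- counts[[tree@qcChain[length(tree@qcChain)]]]
  new("CellTypeCounts",
      nodeCounts = counts, leafCounts = leaf,
      liveSinglets = live,
      cd45 = counts[["leucocytes"]],
      granulocytesCD66b = counts[["granulocytes"]],
      nonGranulocytes = counts[["nonGranulocytes"]],
      unassigned = live - sum(leaf))
}

#' Per-event leaf assignment
#'
#' Returns, for every event, the leaf cell type it gates into, `"excluded"`
#' for events removed by the QC pre-gates, or `"unassigned"` for live
#' singlets captured by no leaf. Used by the hidden-label oracle checks.
#'
#' @inheritParams applyGateTree
#' @return Character vector, one entry per event.
#' @export
assignEvents <- function(events, tree = defaultGateTree()) {
  stopifnot(is(events, "FlowEventTable"), is(tree, "GateTree"))
  tm <- transformedMatrix(intensities(events), tree@fluorescence,
                          tree@cofactor)
  member <- .gateMembership(tm, tree)
  out <- rep("unassigned", nrow(tm))
  out[!member[[tree@qcChain[length(tree@qcChain)]]]] <- "excluded"
  for (tp in names(tree@leaves)) {
    m <- member[[tree@leaves[[tp]]]]
    out[m & out == "unassigned"] <- tp
  }
  out
}

#' Normalised proportions from gated counts
#'
#' Computes the three ratio families used throughout the analysis: each
#' leaf type over the CD45+ count, each non-granulocytic subtype over the
#' CD66b- count, and each granulocytic subtype over the granulocyte
#' denominator (CD66b+ events plus basophils, which are gated in the CD66b-
#' branch but reported against total granulocytes). The combined CD3+
#' numerator is the cleaned CD3+ T-cell gate. Ratios with a zero
#' denominator are returned as `NA` rather than infinite.
#'
#' @param counts A [CellTypeCounts-class].
#' @param include24 Also emit `CD45.nonGranulocyte`, the fraction of
#'   non-granulocytes among leucocytes.
#' @return A [ProportionProfile-class].
#' @export
computeProportions <- function(counts, include24 = FALSE) {
  stopifnot(is(counts, "CellTypeCounts"))
  lf <- leafCounts(counts)
  cd45 <- cd45Count(counts)
  nonGran <- nonGranulocyteCount(counts)
  gran <- granulocyteDenominator(counts)
  cd3 <- nodeCounts(counts)[["tCellsClean"]]
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(
    vapply(cellTypes(), function(tp) safe(lf[[tp]], cd45), numeric(1)),
    CD3 = safe(cd3, nonGran),
    Th = safe(lf[["Th"]], nonGran), Tk = safe(lf[["Tk"]], nonGran),
    NKT = safe(lf[["NKT"]], nonGran), NK = safe(lf[["NK"]], nonGran),
    B = safe(lf[["B"]], nonGran),
    monocyte = safe(lf[["monocyte"]], nonGran),
    mMDSC = safe(lf[["mMDSC"]], nonGran), DC = safe(lf[["DC"]], nonGran),
    neutrophil = safe(lf[["neutrophil"]], gran),
    eosinophil = safe(lf[["eosinophil"]], gran),
    basophil = safe(lf[["basophil"]], gran)
  )
  names(out) <- ratioNames(FALSE)
  if (include24)
    out <- c(out, `CD45.nonGranulocyte` = safe(nonGran, cd45))
  if (cd45 == 0)
    warning("CD45+ count is zero; all ratios are missing")
  ProportionProfile(out)
}

# ---------------------------------------------------------------------------
# JSON serialisation of gate trees
# ---------------------------------------------------------------------------

#' Read or write a gate tree as JSON
#'
#' The JSON document stores the ordered node list (id, parent, type,
#' channels, bounds or Boolean references), the leaf map, the QC chain and
#' the transform metadata, so a tree can be shipped, edited and re-applied
#' reproducibly.
#'
#' @param tree A [GateTree-class].
#' @param path File path.
#' @return `readGateTree()` returns a [GateTree-class];
#'   `writeGateTree()` invisibly returns `path`.
#' @export
writeGateTree <- function(tree, path) {
  stopifnot(is(tree, "GateTree"))
  doc <- list(
    nodes = unname(lapply(tree@nodes, function(nd) {
      nd$min <- if (!is.null(nd$min)) ifelse(is.finite(nd$min), nd$min,
                                             "-Inf") else NULL
      nd$max <- if (!is.null(nd$max)) ifelse(is.finite(nd$max), nd$max,
                                             "Inf") else NULL
      nd
    })),
    leaves = as.list(tree@leaves),
    qcChain = tree@qcChain,
    fluorescence = tree@fluorescence,
    cofactor = tree@cofactor
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeGateTree
#' @export
readGateTree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  nodes <- lapply(doc$nodes, function(nd) {
    for (b in c("min", "max"))
      if (!is.null(nd[[b]])) nd[[b]] <- as.numeric(nd[[b]])
    nd
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  GateTree(nodes = nodes, leaves = unlist(doc$leaves),
           qcChain = doc$qcChain, fluorescence = doc$fluorescence,
           cofactor = doc$cofactor)
}
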
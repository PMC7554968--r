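#' @import methods
NULL

#' The eleven leaf cell types resolved by the default gating strategy
#'
#' Leucocyte subtypes identified in periprosthetic joint aspirates:
#' granulocytic types (neutrophil, eosinophil), basophils (gated in the
#' CD66b- branch but reported against the granulocyte denominator), and the
#' non-granulocytic lymphoid/myeloid types.
#'
#' @return Character vector of the eleven cell-type names.
#' @export
cellTypes <- function() {
  c("neutrophil", "eosinophil", "basophil", "B", "Th", "Tk",
    "NKT", "NK", "monocyte", "mMDSC", "DC")
}

#' Cytometer channel names used throughout the package
#'
#' Four scatter channels (kept on the linear acquisition scale) and fourteen
#' fluorescence channels (gated on an arcsinh-transformed scale).
#'
#' @return Named list with elements `scatter`, `fluorescence` and `all`.
#' @export
panelChannels <- function() {
  scatter <- c("FSC-A", "FSC-H", "FSC-W", "SSC-A")
  fluor <- c("Viability", "CD45", "CD66b", "CD16", "CD3", "CD19", "CD56",
             "CD4", "CD8", "CD14", "HLA-DR", "CD11b", "CD123", "CD11c")
  list(scatter = scatter, fluorescence = fluor, all = c(scatter, fluor))
}

# ---------------------------------------------------------------------------
# FlowEventTable: one aspirate sample, one row per acquired event
# ---------------------------------------------------------------------------

#' @rdname FlowEventTable
#' @export
setClass("FlowEventTable",
  representation(
    exprs = "matrix",        # n_events x n_channels, raw intensity scale
    truthLabels = "character", # per-event hidden ground truth, or length 0
    cofactor = "numeric"     # arcsinh cofactor used on fluorescence channels
  ),
  prototype(exprs = matrix(numeric(0), 0, 0), truthLabels = character(0),
            cofactor = 150)
)

setValidity("FlowEventTable", function(object) {
  msg <- character(0)
  if (is.null(colnames(object@exprs)) && ncol(object@exprs) > 0)
    msg <- c(msg, "event matrix must have channel names as column names")
  if (anyDuplicated(colnames(object@exprs)))
    msg <- c(msg, "duplicated channel names")
  if (length(object@exprs) && !all(is.finite(object@exprs)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@truthLabels) &&
      length(object@truthLabels) != nrow(object@exprs))
    msg <- c(msg, "truthLabels must have one entry per event")
  if (length(object@cofactor) != 1L || object@cofactor <= 0)
    msg <- c(msg, "cofactor must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a FlowEventTable
#'
#' Container for the per-event intensity matrix of one aspirate sample.
#' Scatter channels are stored on the linear acquisition scale and
#' fluorescence channels as raw (untransformed) intensities; gating is
#' performed on `asinh(x / cofactor)` for fluorescence channels.
#'
#' @param exprs Numeric matrix, one row per event, channel names as column
#'   names.
#' @param truthLabels Optional character vector of per-event ground-truth
#'   labels (cell type, `"debris"`, `"dead"` or `"doublet"`); used by the
#'   synthetic generator and by oracle checks, never by the gating engine.
#' @param cofactor Arcsinh cofactor recorded with the sample (default 150).
#'
#' @return A [FlowEventTable-class] object.
#' @export
FlowEventTable <- function(exprs, truthLabels = character(0), cofactor = 150) {
  new("FlowEventTable", exprs = as.matrix(exprs),
      truthLabels = as.character(truthLabels), cofactor = cofactor)
}

#' @rdname FlowEventTable
#' @param object,x A `FlowEventTable`.
#' @export
setMethod("show", "FlowEventTable", function(object) {
  cat("FlowEventTable with", nrow(object@exprs), "events and",
      ncol(object@exprs), "channels\n")
  if (length(object@truthLabels)) {
    tab <- table(object@truthLabels)
    cat("  hidden truth labels present (", length(tab), " categories)\n",
        sep = "")
  }
  cat("  arcsinh cofactor:", object@cofactor, "\n")
})

#' @rdname FlowEventTable
#' @export
intensities <- function(x) {
  stopifnot(is(x, "FlowEventTable"))
  x@exprs
}

#' @rdname FlowEventTable
#' @export
nEvents <- function(x) {
  stopifnot(is(x, "FlowEventTable"))
  nrow(x@exprs)
}

#' @rdname FlowEventTable
#' @export
channelNames <- function(x) {
  stopifnot(is(x, "FlowEventTable"))
  colnames(x@exprs)
}

#' @rdname FlowEventTable
#' @export
truthLabels <- function(x) {
  stopifnot(is(x, "FlowEventTable"))
  if (length(x@truthLabels)) x@truthLabels else NULL
}

# ---------------------------------------------------------------------------
# GateTree: declarative hierarchy of threshold / rectangle / Boolean gates
# ---------------------------------------------------------------------------

#' @rdname GateTree
#' @export
setClass("GateTree",
  representation(
    nodes = "list",          # named list of node definitions, parents first
    leaves = "character",    # cellType -> node id
    qcChain = "character",   # ordered pre-gate ids ending at live singlets
    fluorescence = "character", # channels gated on the arcsinh scale
    cofactor = "numeric"
  )
)

setValidity("GateTree", function(object) {
  msg <- character(0)
  ids <- names(object@nodes)
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated node ids")
  roots <- 0L
  seen <- character(0)
  for (id in ids) {
    nd <- object@nodes[[id]]
    if (identical(nd$type, "root")) {
      roots <- roots + 1L
    } else if (identical(nd$type, "bool")) {
      refs <- c(nd$include, nd$exclude, nd$union)
      if (!all(refs %in% seen))
        msg <- c(msg, sprintf("bool node '%s' references undefined nodes", id))
    } else {
      if (!nd$parent %in% seen)
        msg <- c(msg, sprintf(
          "node '%s' has parent '%s' not defined before it", id, nd$parent))
      if (!all(nd$channels %in% c(object@fluorescence,
                                  panelChannels()$scatter)))
        msg <- c(msg, sprintf("node '%s' uses an unknown channel", id))
    }
    seen <- c(seen, id)
  }
  if (roots != 1L) msg <- c(msg, "tree must have exactly one root")
  if (!all(object@leaves %in% ids))
    msg <- c(msg, "leaf map references unknown node ids")
  if (!all(object@qcChain %in% ids))
    msg <- c(msg, "qcChain references unknown node ids")
  if (length(msg)) msg else TRUE
})

#' @rdname GateTree
#' @param object A `GateTree`.
#' @export
setMethod("show", "GateTree", function(object) {
  cat("GateTree with", length(object@nodes), "nodes,",
      length(object@leaves), "leaf cell types\n")
  cat("  QC pre-gates:", paste(object@qcChain, collapse = " -> "), "\n")
  cat("  fluorescence gated on asinh(x/", object@cofactor, ")\n", sep = "")
})

#' Gate tree constructors and node helpers
#'
#' A `GateTree` is a declarative description of a hierarchical gating
#' strategy: an ordered list of nodes, each either the root, a 1-D threshold
#' gate, a 2-D rectangle gate, or a Boolean combination
#' (intersection/complement/union) of previously defined nodes. Bounds on
#' fluorescence channels are expressed on the arcsinh-transformed scale;
#' scatter bounds on the linear scale.
#'
#' @param nodes Named list of node definitions (see [gateNode()]).
#' @param leaves Named character vector mapping cell-type names to node ids.
#' @param qcChain Character vector of pre-gate node ids (debris/doublet/dead
#'   exclusion), in order, ending at the live-singlet node.
#' @param fluorescence Channels gated on the transformed scale.
#' @param cofactor Arcsinh cofactor.
#'
#' @return A [GateTree-class] object.
#' @export
GateTree <- function(nodes, leaves, qcChain, fluorescence, cofactor = 150) {
  new("GateTree", nodes = nodes, leaves = leaves, qcChain = qcChain,
      fluorescence = fluorescence, cofactor = cofactor)
}

#' @rdname GateTree
#' @param id Node id.
#' @param parent Parent node id.
#' @param channels Character vector of 1 (threshold) or 2 (rectangle)
#'   channel names.
#' @param min,max Numeric lower/upper bounds, recycled to the number of
#'   channels; use `-Inf`/`Inf` for open sides.
#' @export
gateNode <- function(id, parent, channels, min = -Inf, max = Inf) {
  k <- length(channels)
  list(id = id, parent = parent,
       type = if (k == 1L) "threshold" else "rect",
       channels = channels,
       min = rep_len(min, k), max = rep_len(max, k))
}

#' @rdname GateTree
#' @param include Node ids intersected (first is the nominal parent).
#' @param exclude Node ids whose events are removed.
#' @param union Node ids unioned (alternative to include/exclude).
#' @export
boolNode <- function(id, include = character(0), exclude = character(0),
                     union = character(0)) {
  parent <- if (length(include)) include[[1L]] else NA_character_
  list(id = id, parent = parent, type = "bool",
       include = include, exclude = exclude, union = union)
}

# ---------------------------------------------------------------------------
# CellTypeCounts: per-node event counts after gating one sample
# ---------------------------------------------------------------------------

#' @rdname CellTypeCounts
#' @export
setClass("CellTypeCounts",
  representation(
    nodeCounts = "numeric",  # named, one entry per gate-tree node
    leafCounts = "numeric",  # named by cell type
    liveSinglets = "numeric",
    cd45 = "numeric",
    granulocytesCD66b = "numeric", # CD66b+ events
    nonGranulocytes = "numeric",   # CD66b- events
    unassigned = "numeric"
  )
)

setValidity("CellTypeCounts", function(object) {
  msg <- character(0)
  if (any(object@nodeCounts < 0) || any(object@leafCounts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (!setequal(names(object@leafCounts), cellTypes()))
    msg <- c(msg, "leafCounts must cover exactly the eleven cell types")
  if (length(msg)) msg else TRUE
})

#' Cell-type counts for one gated sample
#'
#' @param object,x A `CellTypeCounts`.
#' @return `leafCounts()` returns the named per-cell-type event counts;
#'   `granulocyteDenominator()` the CD66b+ count plus basophils (the
#'   denominator used for the granulocytic proportion family);
#'   `nonGranulocyteCount()` the CD66b- count; `cd45Count()` the leucocyte
#'   count; `liveSingletCount()` the number of events surviving the QC
#'   pre-gates.
#' @export
leafCounts <- function(x) {
  stopifnot(is(x, "CellTypeCounts"))
  x@leafCounts
}

#' @rdname leafCounts
#' @export
nodeCounts <- function(x) {
  stopifnot(is(x, "CellTypeCounts"))
  x@nodeCounts
}

#' @rdname leafCounts
#' @export
granulocyteDenominator <- function(x) {
  stopifnot(is(x, "CellTypeCounts"))
  unname(x@granulocytesCD66b + x@leafCounts[["basophil"]])
}

#' @rdname leafCounts
#' @export
nonGranulocyteCount <- function(x) {
  stopifnot(is(x, "CellTypeCounts"))
  unname(x@nonGranulocytes)
}

#' @rdname leafCounts
#' @export
cd45Count <- function(x) {
  stopifnot(is(x, "CellTypeCounts"))
  unname(x@cd45)
}

#' @rdname leafCounts
#' @export
liveSingletCount <- function(x) {
  stopifnot(is(x, "CellTypeCounts"))
  unname(x@liveSinglets)
}

#' @rdname leafCounts
#' @export
unassignedCount <- function(x) {
  stopifnot(is(x, "CellTypeCounts"))
  unname(x@unassigned)
}

setMethod("show", "CellTypeCounts", function(object) {
  cat("CellTypeCounts:", object@liveSinglets, "live singlets,",
      object@cd45, "CD45+\n")
  print(object@leafCounts)
  cat("  unassigned:", object@unassigned, "\n")
})

# ---------------------------------------------------------------------------
# ProportionProfile: the normalised ratios used as model covariates
# ---------------------------------------------------------------------------

#' @rdname ProportionProfile
#' @export
setClass("ProportionProfile",
  representation(ratios = "numeric"))  # named; NA marks missing (zero denom)

setValidity("ProportionProfile", function(object) {
  r <- object@ratios[!is.na(object@ratios)]
  if (length(r) && (any(r < -1e-12) || any(r > 1 + 1e-12)))
    return("ratios must lie in [0, 1]")
  TRUE
})

#' Normalised cell-type proportions for one sample
#'
#' Three families of ratios: each leaf type over the CD45+ leucocyte count
#' (`CD45.*`, 11 ratios), each non-granulocytic subtype over the CD66b-
#' count (`NonGran.*`, 9 ratios including the combined CD3+ population), and
#' each granulocytic subtype over the granulocyte denominator (`Gran.*`,
#' 3 ratios). The optional 24th predictor `CD45.nonGranulocyte` is the
#' fraction of non-granulocytes among leucocytes. Missing ratios (zero
#' denominator) are `NA`.
#'
#' @param ratios Named numeric vector of ratios in `[0,1]` (or `NA`).
#' @param x A `ProportionProfile`.
#' @return `ratios()` returns the named numeric vector.
#' @export
ProportionProfile <- function(ratios) {
  new("ProportionProfile", ratios = ratios)
}

#' @rdname ProportionProfile
#' @export
ratios <- function(x) {
  stopifnot(is(x, "ProportionProfile"))
  x@ratios
}

setMethod("show", "ProportionProfile", function(object) {
  cat("ProportionProfile with", length(object@ratios), "ratios\n")
  print(round(object@ratios, 4))
})

#' Names of the ratio predictors
#'
#' @param include24 Include the non-granulocyte fraction of CD45+ cells as a
#'   24th predictor.
#' @return Character vector of ratio names in stable column order.
#' @export
ratioNames <- function(include24 = FALSE) {
  nonGran <- c("CD3", "Th", "Tk", "NKT", "NK", "B", "monocyte", "mMDSC", "DC")
  out <- c(paste0("CD45.", cellTypes()),
           paste0("NonGran.", nonGran),
           paste0("Gran.", c("neutrophil", "eosinophil", "basophil")))
  if (include24) out <- c(out, "CD45.nonGranulocyte")
  out
}

#' Default predictor set for the infection model
#'
#' The nine normalised subtype abundances used as the starting covariate set
#' of the logistic infection model: the six non-granulocytic subtypes (NK,
#' combined CD3+ T cells, B cells, DCs, monocytes, mMDSCs) normalised by the
#' non-granulocyte count, and the three granulocytic subtypes (neutrophils,
#' eosinophils, basophils) normalised by the granulocyte count.
#'
#' @return Character vector of nine ratio names.
#' @export
defaultPredictorSet <- function() {
  c("NonGran.NK", "NonGran.CD3", "NonGran.B", "NonGran.DC",
    "NonGran.monocyte", "NonGran.mMDSC",
    "Gran.basophil", "Gran.eosinophil", "Gran.neutrophil")
}
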
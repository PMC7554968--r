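# Synthetic aspirate generator: event-level mixture model with hidden
# ground-truth labels, plus clinical records feeding the MSIS rule engine.

#' Composition of one synthetic aspirate sample
#'
#' Describes one sample as a mixture over the eleven leaf cell types
#' (fractions of live CD45+ events, summing to 1) together with the
#' fractions of debris, dead cells and doublets among all acquired events.
#'
#' @param fractions Named numeric vector over [cellTypes()], non-negative,
#'   summing to 1.
#' @param debris,dead,doublet Fractions of total events in `[0,1]`.
#' @param totalEvents Total number of events to acquire.
#' @return An object of class `compositionProfile`.
#' @export
compositionProfile <- function(fractions, debris = 0.10, dead = 0.08,
                               doublet = 0.03, totalEvents = 50000) {
  fractions <- fractions[cellTypes()]
  if (any(is.na(fractions)))
    stop("fractions must be named over all eleven cell types")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("cell-type fractions must sum to 1")
  for (f in c(debris, dead, doublet))
    if (f < 0 || f > 1) stop("debris/dead/doublet fractions must be in [0,1]")
  if (debris + dead + doublet >= 1)
    stop("debris + dead + doublet must leave room for live singlets")
  if (totalEvents < 0) stop("totalEvents must be >= 0")
  structure(list(fractions = fractions, debris = debris, dead = dead,
                 doublet = doublet, totalEvents = totalEvents),
            class = "compositionProfile")
}

#' Default group mean compositions
#'
#' Mean cell-type fractions (of live CD45+ events) for the two study groups.
#' The infection shift raises granulocyte and mMDSC fractions and lowers the
#' T, NK and NKT fractions, matching the direction of the reported
#' population differences; the magnitudes are package defaults since no
#' numeric per-group proportion table is available.
#'
#' @param totalEvents Events per sample.
#' @param ... Passed to [compositionProfile()].
#' @return A `compositionProfile`.
#' @export
infectedProfile <- function(totalEvents = 50000, ...) {
  compositionProfile(c(
    neutrophil = 0.700, eosinophil = 0.025, basophil = 0.025,
    B = 0.030, Th = 0.045, Tk = 0.035, NKT = 0.010, NK = 0.020,
    monocyte = 0.060, mMDSC = 0.040, DC = 0.010),
    totalEvents = totalEvents, ...)
}

#' @rdname infectedProfile
#' @export
nonInfectedProfile <- function(totalEvents = 50000, ...) {
  compositionProfile(c(
    neutrophil = 0.300, eosinophil = 0.020, basophil = 0.010,
    B = 0.050, Th = 0.180, Tk = 0.140, NKT = 0.060, NK = 0.080,
    monocyte = 0.120, mMDSC = 0.015, DC = 0.025),
    totalEvents = totalEvents, ...)
}

#' Marker intensity template for the synthetic generator
#'
#' For every cell type and fluorescence channel the template fixes a
#' location on the arcsinh-transformed scale: `posLevel` where the phenotype
#' expresses the marker, `negLevel` otherwise, with common spread `sd`.
#' Scatter channels get per-lineage linear-scale locations (granulocytes
#' high SSC, lymphocytes low). Dead cells carry a high viability-dye signal;
#' doublets are formed by summing the scatter (and raw fluorescence) of two
#' live events.
#'
#' @param posLevel,negLevel Transformed-scale locations of positive and
#'   negative populations (`posLevel > negLevel` required).
#' @param sd Transformed-scale spread of each population.
#' @param cofactor Arcsinh cofactor used to map to raw intensities.
#' @return Object of class `markerTemplate`.
#' @export
defaultMarkerTemplate <- function(posLevel = 4, negLevel = 1, sd = 0.35,
                                  cofactor = 150) {
  if (posLevel <= negLevel)
    stop("positive-population location must exceed the negative location")
  fl <- setdiff(panelChannels()$fluorescence, "Viability")
  ph <- matrix(negLevel, nrow = length(cellTypes()), ncol = length(fl),
               dimnames = list(cellTypes(), fl))
  pos <- list(
    neutrophil = c("CD45", "CD66b", "CD16", "CD11b"),
    eosinophil = c("CD45", "CD66b", "CD11b"),
    basophil   = c("CD45", "CD123"),
    B          = c("CD45", "CD19", "HLA-DR"),
    Th         = c("CD45", "CD3", "CD4"),
    Tk         = c("CD45", "CD3", "CD8"),
    NKT        = c("CD45", "CD3", "CD56"),
    NK         = c("CD45", "CD56"),
    monocyte   = c("CD45", "CD14", "HLA-DR", "CD11b"),
    mMDSC      = c("CD45", "CD14", "CD16", "CD11b"),
    DC         = c("CD45", "HLA-DR", "CD11c")
  )
  for (tp in names(pos)) ph[tp, pos[[tp]]] <- posLevel
  lymph <- c("B", "Th", "Tk", "NKT", "NK")
  scatter <- data.frame(
    row.names = cellTypes(),
    fscMean = ifelse(cellTypes() %in% lymph, 45000,
                     ifelse(cellTypes() %in% c("neutrophil", "eosinophil"),
                            60000, 55000)),
    fscSd = 6000,
    sscMean = c(neutrophil = 65000, eosinophil = 70000, basophil = 25000,
                B = 15000, Th = 15000, Tk = 15000, NKT = 15000, NK = 15000,
                monocyte = 35000, mMDSC = 35000, DC = 30000)[cellTypes()],
    sscSd = ifelse(cellTypes() %in% lymph, 4000, 7000)
  )
  structure(list(
    phenotypes = ph, sd = sd, posLevel = posLevel, negLevel = negLevel,
    cofactor = cofactor,
    viabilityLive = negLevel, viabilityDead = posLevel,
    scatter = scatter,
    fscHSlope = 0.95, fscHSd = 2000,
    fscWMean = 60000, fscWSd = 4000,
    debris = list(fscMean = 6000, fscSd = 2000, fschMean = 5000,
                  fschSd = 2000, sscMean = 3000, sscSd = 1500)
  ), class = "markerTemplate")
}

# Draw raw-scale fluorescence for n events of one cell type.
.drawFluorescence <- function(n, type, template, dead = FALSE) {
  fl <- panelChannels()$fluorescence
  out <- matrix(0, n, length(fl), dimnames = list(NULL, fl))
  via <- if (dead) template$viabilityDead else template$viabilityLive
  out[, "Viability"] <- stats::rnorm(n, via, template$sd)
  for (ch in setdiff(fl, "Viability"))
    out[, ch] <- stats::rnorm(n, template$phenotypes[type, ch], template$sd)
  sinh(out) * template$cofactor
}

.drawScatter <- function(n, type, template) {
  sc <- template$scatter[type, ]
  fscA <- stats::rnorm(n, sc$fscMean, sc$fscSd)
  cbind(`FSC-A` = fscA,
        `FSC-H` = template$fscHSlope * fscA +
          stats::rnorm(n, 0, template$fscHSd),
        `FSC-W` = stats::rnorm(n, template$fscWMean, template$fscWSd),
        `SSC-A` = stats::rnorm(n, sc$sscMean, sc$sscSd))
}

.drawTypeBlock <- function(n, type, template, dead = FALSE) {
  cbind(.drawScatter(n, type, template),
        .drawFluorescence(n, type, template, dead = dead))
}

#' Generate one synthetic aspirate sample
#'
#' Draws an event table from the mixture described by `profile`: live
#' singlet events per cell type with marker intensities from `template`,
#' plus debris (low scatter), dead cells (high viability-dye signal) and
#' doublets (scatter and raw fluorescence sums of two live events). The true
#' category of every event is retained as a hidden label.
#'
#' @param profile A [compositionProfile()].
#' @param template A [defaultMarkerTemplate()] object.
#' @param seed Integer seed; the same profile, template and seed always give
#'   an identical event table. `NULL` uses the current RNG stream.
#' @return A [FlowEventTable-class] with `truthLabels`.
#' @export
generateSample <- function(profile, template = defaultMarkerTemplate(),
                           seed = NULL) {
  stopifnot(inherits(profile, "compositionProfile"),
            inherits(template, "markerTemplate"))
  missingCh <- setdiff(setdiff(panelChannels()$fluorescence, "Viability"),
                       colnames(template$phenotypes))
  if (length(missingCh))
    stop("marker template lacks channel(s): ",
         paste(missingCh, collapse = ", "))
  n <- profile$totalEvents
  if (n == 0L) stop("cannot generate an empty event table (totalEvents = 0)")
  withSeed(seed, {
    nDebris <- round(n * profile$debris)
    nDead <- round(n * profile$dead)
    nDoublet <- round(n * profile$doublet)
    nLive <- n - nDebris - nDead - nDoublet
    liveTypes <- sample(cellTypes(), nLive, replace = TRUE,
                        prob = profile$fractions)
    blocks <- list()
    labels <- character(0)
    for (tp in cellTypes()) {
      k <- sum(liveTypes == tp)
      if (k == 0) next
      blocks[[length(blocks) + 1L]] <- .drawTypeBlock(k, tp, template)
      labels <- c(labels, rep(tp, k))
    }
    if (nDead > 0) {
      deadTypes <- sample(cellTypes(), nDead, replace = TRUE,
                          prob = profile$fractions)
      for (tp in unique(deadTypes)) {
        k <- sum(deadTypes == tp)
        blocks[[length(blocks) + 1L]] <-
          .drawTypeBlock(k, tp, template, dead = TRUE)
        labels <- c(labels, rep("dead", k))
      }
    }
    if (nDoublet > 0) {
      t1 <- sample(cellTypes(), nDoublet, replace = TRUE,
                   prob = profile$fractions)
      t2 <- sample(cellTypes(), nDoublet, replace = TRUE,
                   prob = profile$fractions)
      a <- matrix(0, nDoublet, length(panelChannels()$all),
                  dimnames = list(NULL, panelChannels()$all))
      for (tp in cellTypes()) {
        k1 <- t1 == tp
        if (any(k1)) a[k1, ] <- a[k1, ] + .drawTypeBlock(sum(k1), tp, template)
        k2 <- t2 == tp
        if (any(k2)) a[k2, ] <- a[k2, ] + .drawTypeBlock(sum(k2), tp, template)
      }
      # doublet height is set by the larger cell, not the sum
      a[, "FSC-H"] <- a[, "FSC-H"] / 2
      blocks[[length(blocks) + 1L]] <- a
      labels <- c(labels, rep("doublet", nDoublet))
    }
    if (nDebris > 0) {
      db <- template$debris
      deb <- cbind(
        `FSC-A` = stats::rnorm(nDebris, db$fscMean, db$fscSd),
        `FSC-H` = stats::rnorm(nDebris, db$fschMean, db$fschSd),
        `FSC-W` = stats::rnorm(nDebris, template$fscWMean, template$fscWSd),
        `SSC-A` = stats::rnorm(nDebris, db$sscMean, db$sscSd))
      fl <- panelChannels()$fluorescence
      dfl <- matrix(stats::rnorm(nDebris * length(fl), template$negLevel / 2,
                                 template$sd),
                    nDebris, length(fl), dimnames = list(NULL, fl))
      blocks[[length(blocks) + 1L]] <- cbind(deb, sinh(dfl) *
                                               template$cofactor)
      labels <- c(labels, rep("debris", nDebris))
    }
    mat <- do.call(rbind, blocks)
    ord <- sample.int(nrow(mat))
    FlowEventTable(mat[ord, , drop = FALSE], truthLabels = labels[ord],
                   cofactor = template$cofactor)
  })
}

#' Specification of a synthetic study cohort
#'
#' Bundles group sizes, group mean compositions, between-patient dispersion,
#' clinical-value distributions and missingness rates. Defaults emulate a
#' 50-patient aspirate cohort (17 infected, 33 non-infected) with infected
#' group means of 89,322.8 synovial leucocytes/uL, 81.0% PMN and 111.4 mg/L
#' serum CRP, and non-infected means of 669.1/uL, 28.5% and 17.2 mg/L.
#' Synovial WBC and serum CRP are drawn log-normally (heavy right tails,
#' parameterised by their arithmetic means), PMN% truncated-normally on
#' `[0,100]`. Missingness and microbiology/pathology/sinus-tract rates
#' follow the reported per-group counts.
#'
#' @param nInfected,nNonInfected Group sizes.
#' @param infectedComposition,nonInfectedComposition Group mean cell-type
#'   fractions ([compositionProfile()] objects supply the fractions and the
#'   debris/dead/doublet rates).
#' @param concentration Dirichlet concentration governing between-patient
#'   composition dispersion (larger = less spread).
#' @param eventsPerSample Events acquired per synthetic sample.
#' @param clinicalInfected,clinicalNonInfected Named lists of clinical
#'   distribution parameters; see the package vignette.
#' @param concordance Probability that a patient's clinical record is
#'   adjusted (without touching the synovial WBC draw) so the MSIS label
#'   matches the true status; default 1 = labels always agree.
#' @param seed Mandatory integer seed.
#' @return An object of class `cohortSpec`.
#' @export
cohortSpec <- function(nInfected = 17, nNonInfected = 33,
                       infectedComposition = infectedProfile(),
                       nonInfectedComposition = nonInfectedProfile(),
                       concentration = 60,
                       eventsPerSample = 5000,
                       clinicalInfected = list(
                         wbcMean = 89322.8, wbcSdLog = 1.2,
                         pmnMean = 81.0, pmnSd = 15,
                         crpMean = 111.4, crpSdLog = 1.0,
                         pSinus = 3 / 17, pDoubleMicro = 3 / 15,
                         pSingleMicro = 10 / 15, pMicroMissing = 2 / 17,
                         pPathPositive = 8 / 10, pPathMissing = 7 / 17,
                         pWbcPmnMissing = 4 / 17, pCrpMissing = 2 / 17,
                         ageMean = 72.2, ageSd = 10,
                         pFemale = 11 / 17, pHip = 4 / 17),
                       clinicalNonInfected = list(
                         wbcMean = 669.1, wbcSdLog = 1.0,
                         pmnMean = 28.5, pmnSd = 18,
                         crpMean = 17.2, crpSdLog = 0.8,
                         pSinus = 0, pDoubleMicro = 0,
                         pSingleMicro = 6 / 28, pMicroMissing = 5 / 33,
                         pPathPositive = 1 / 23, pPathMissing = 10 / 33,
                         pWbcPmnMissing = 13 / 33, pCrpMissing = 3 / 33,
                         ageMean = 65.6, ageSd = 12,
                         pFemale = 24 / 34, pHip = 8 / 34),
                       concordance = 1.0, seed) {
  if (missing(seed)) stop("cohortSpec requires an explicit seed")
  if (nInfected < 0 || nNonInfected < 0) stop("group sizes must be >= 0")
  if (concentration <= 0) stop("concentration must be > 0")
  if (concordance < 0 || concordance > 1)
    stop("concordance must be in [0,1]")
  for (cl in list(clinicalInfected, clinicalNonInfected)) {
    pr <- unlist(cl[c("pSinus", "pDoubleMicro", "pSingleMicro",
                      "pMicroMissing", "pPathPositive", "pPathMissing",
                      "pWbcPmnMissing", "pCrpMissing", "pFemale", "pHip")])
    if (any(pr < 0 | pr > 1)) stop("clinical probabilities must be in [0,1]")
    if (cl$wbcSdLog <= 0 || cl$crpSdLog <= 0 || cl$pmnSd <= 0)
      stop("dispersion parameters must be > 0")
  }
  structure(list(nInfected = nInfected, nNonInfected = nNonInfected,
                 infectedComposition = infectedComposition,
                 nonInfectedComposition = nonInfectedComposition,
                 concentration = concentration,
                 eventsPerSample = eventsPerSample,
                 clinicalInfected = clinicalInfected,
                 clinicalNonInfected = clinicalNonInfected,
                 concordance = concordance, seed = seed),
            class = "cohortSpec")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

.rtrunc <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

.rlnormMean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# lognormal truncated to (lo, hi), same arithmetic-mean parameterisation
.rlnormMeanTrunc <- function(n, mean, sdlog, lo = 0, hi = Inf) {
  mu <- log(mean) - sdlog^2 / 2
  pl <- if (lo <= 0) 0 else stats::plnorm(lo, mu, sdlog)
  ph <- stats::plnorm(hi, mu, sdlog)
  stats::qlnorm(stats::runif(n, pl, ph), mu, sdlog)
}

.drawClinicalRecord <- function(cl) {
  wbcMissing <- stats::runif(1) < cl$pWbcPmnMissing
  micro <- if (stats::runif(1) < cl$pMicroMissing) NA_character_ else {
    u <- stats::runif(1)
    if (u < cl$pDoubleMicro) "double"
    else if (u < cl$pDoubleMicro + cl$pSingleMicro) "single"
    else "none"
  }
  grade <- if (stats::runif(1) < cl$pPathMissing) NA_character_ else {
    if (stats::runif(1) < cl$pPathPositive)
      sample(c("II", "III"), 1) else sample(c("I", "IV"), 1, prob = c(.85, .15))
  }
  list(
    sinusTract = stats::runif(1) < cl$pSinus,
    microbiology = micro,
    wbc = if (wbcMissing) NA_real_ else .rlnormMean(1, cl$wbcMean, cl$wbcSdLog),
    pmnPct = if (wbcMissing) NA_real_ else
      .rtrunc(1, cl$pmnMean, cl$pmnSd, 0, 100),
    crp = if (stats::runif(1) < cl$pCrpMissing) NA_real_ else
      .rlnormMean(1, cl$crpMean, cl$crpSdLog),
    pathologyGrade = grade,
    joint = if (stats::runif(1) < cl$pHip) "hip" else "knee",
    age = round(.rtrunc(1, cl$ageMean, cl$ageSd, 30, 95)),
    sex = if (stats::runif(1) < cl$pFemale) "F" else "M"
  )
}

# Minimal adjustment forcing MSIS agreement with the intended status.
# The synovial WBC draw is never modified so its configured group mean is
# preserved exactly.
.enforceConcordance <- function(rec, infected, cl) {
  lab <- .msisOne(rec)
  if (infected && lab$status != "infected") {
    if (is.na(rec$microbiology) || rec$microbiology == "none")
      rec$microbiology <- "single"
    if (is.na(rec$pathologyGrade) || !rec$pathologyGrade %in% c("II", "III"))
      rec$pathologyGrade <- "II"
    lab <- .msisOne(rec)
    if (lab$status != "infected")
      rec$pmnPct <- .rtrunc(1, cl$pmnMean, cl$pmnSd, 80 + 1e-9, 100)
  } else if (!infected && lab$status == "infected") {
    rec$sinusTract <- FALSE
    if (!is.na(rec$microbiology) && rec$microbiology != "none")
      rec$microbiology <- "none"
    if (!is.na(rec$pathologyGrade) && rec$pathologyGrade %in% c("II", "III"))
      rec$pathologyGrade <- "I"
    lab <- .msisOne(rec)
    if (lab$status == "infected" && !is.na(rec$crp) && rec$crp > 10)
      rec$crp <- .rlnormMeanTrunc(1, cl$crpMean, cl$crpSdLog, 0, 10)
    lab <- .msisOne(rec)
    if (lab$status == "infected" && !is.na(rec$pmnPct) && rec$pmnPct > 80)
      rec$pmnPct <- .rtrunc(1, cl$pmnMean, cl$pmnSd, 0, 80)
  }
  rec
}

#' Generate a synthetic study cohort
#'
#' Draws, per patient, a cell composition (Dirichlet around the group mean),
#' an event table from that composition, and a clinical record whose MSIS
#' label agrees with the true status at the configured concordance rate.
#'
#' @param spec A [cohortSpec()].
#' @param events If `FALSE`, skip event-table synthesis (clinical records
#'   and true compositions only), useful for model-level simulations.
#' @return A list of class `pjiCohort` with elements `samples` (list of
#'   [FlowEventTable-class] or `NULL`), `clinical` (data frame, one row per
#'   patient, including `trueStatus`), `trueCompositions` (patients x cell
#'   types matrix) and `spec`.
#' @export
generateCohort <- function(spec, events = TRUE) {
  stopifnot(inherits(spec, "cohortSpec"))
  n <- spec$nInfected + spec$nNonInfected
  statuses <- rep(c("infected", "non-infected"),
                  c(spec$nInfected, spec$nNonInfected))
  withSeed(spec$seed, {
    comps <- matrix(NA_real_, n, length(cellTypes()),
                    dimnames = list(NULL, cellTypes()))
    samples <- vector("list", n)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      infected <- statuses[i] == "infected"
      base <- if (infected) spec$infectedComposition else
        spec$nonInfectedComposition
      cl <- if (infected) spec$clinicalInfected else spec$clinicalNonInfected
      comps[i, ] <- .rdirichlet1(spec$concentration * base$fractions)
      if (events && spec$eventsPerSample > 0) {
        prof <- compositionProfile(comps[i, ], debris = base$debris,
                                   dead = base$dead, doublet = base$doublet,
                                   totalEvents = spec$eventsPerSample)
        samples[[i]] <- generateSample(prof)
      }
      rec <- .drawClinicalRecord(cl)
      if (stats::runif(1) < spec$concordance)
        rec <- .enforceConcordance(rec, infected, cl)
      recs[[i]] <- rec
    }
    clinical <- data.frame(
      patientId = sprintf("P%03d", seq_len(n)),
      trueStatus = statuses,
      sinusTract = vapply(recs, `[[`, logical(1), "sinusTract"),
      microbiology = vapply(recs, `[[`, character(1), "microbiology"),
      wbc = vapply(recs, `[[`, numeric(1), "wbc"),
      pmnPct = vapply(recs, `[[`, numeric(1), "pmnPct"),
      crp = vapply(recs, `[[`, numeric(1), "crp"),
      pathologyGrade = vapply(recs, `[[`, character(1), "pathologyGrade"),
      joint = vapply(recs, `[[`, character(1), "joint"),
      age = vapply(recs, `[[`, numeric(1), "age"),
      sex = vapply(recs, `[[`, character(1), "sex"),
      stringsAsFactors = FALSE
    )
    structure(list(samples = samples, clinical = clinical,
                   trueCompositions = comps, spec = spec),
              class = "pjiCohort")
  })
}

#' @export
print.pjiCohort <- function(x, ...) {
  cat("Synthetic aspirate cohort:", nrow(x$clinical), "patients (",
      sum(x$clinical$trueStatus == "infected"), "infected /",
      sum(x$clinical$trueStatus == "non-infected"), "non-infected )\n")
  cat("  events per sample:",
      if (is.null(x$samples[[1]])) "none (clinical only)" else
        nEvents(x$samples[[1]]), "\n")
  invisible(x)
}
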
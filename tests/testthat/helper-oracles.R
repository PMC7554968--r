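# Independent oracles used across tests. Each is a deliberately naive
# implementation (enumeration / brute force) kept free of any package code
# paths it is used to check.

# Exact two-sided Mann-Whitney p-value by full enumeration of the
# rank-partition distribution (midranks, so ties are handled too).
enumMannWhitneyP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  pLo <- mean(us <= uObs + 1e-9)
  pHi <- mean(us >= uObs - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

# AUC as the concordance fraction over all infected/non-infected pairs.
pairAuc <- function(scores, infected) {
  pos <- scores[infected]; neg <- scores[!infected]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Brute-force Youden maximisation over every candidate threshold
# (midpoints plus +/-Inf), ties toward the larger threshold.
bruteYouden <- function(scores, infected) {
  uu <- sort(unique(scores))
  thr <- c(-Inf, if (length(uu) > 1) (uu[-1] + uu[-length(uu)]) / 2, Inf)
  best <- -Inf; bestT <- NA
  for (t in thr) {
    j <- mean(scores[infected] > t) + mean(scores[!infected] <= t) - 1
    if (j >= best - 1e-12) {
      if (j > best + 1e-12 || t > bestT) bestT <- t
      best <- max(best, j)
    }
  }
  list(J = best, cutoff = bestT)
}

# Exhaustive best-subset search under BIC for a logistic model.
allSubsetBic <- function(x, y) {
  p <- ncol(x)
  bestBic <- Inf; bestSet <- character(0)
  for (mask in 0:(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    dat <- data.frame(y = y, x[, cols, drop = FALSE], check.names = FALSE)
    f <- suppressWarnings(
      stats::glm(if (length(cols)) y ~ . else y ~ 1, data = dat,
                 family = stats::binomial()))
    b <- stats::BIC(f)
    if (b < bestBic - 1e-10) {
      bestBic <- b
      bestSet <- colnames(x)[cols]
    }
  }
  list(bic = bestBic, set = sort(bestSet))
}

# Simulate a logistic-response design with independent standard-normal
# covariates; beta is named including "(Intercept)".
simLogistic <- function(n, beta, pNoise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- setdiff(names(beta), "(Intercept)")
  p <- length(vars) + pNoise
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- c(vars, if (pNoise > 0) paste0("noise", seq_len(pNoise)))
  eta <- beta[["(Intercept)"]] +
    drop(x[, vars, drop = FALSE] %*% beta[vars])
  y <- rbinom(n, 1, plogis(eta))
  structure(list(x = x, y = y), class = "pjiFeatureMatrix")
}

# A 50-patient cohort separable with a wide margin in the joint covariate
# space: the class signal lives in the difference of two ratios while a
# shared per-patient shift keeps each marginal distribution overlapping
# (so no single covariate separates on its own and univariate Wald tests
# stay well behaved).
separableFeatureMatrix <- function(n1 = 17, n0 = 33, seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  y <- rep(c(1L, 0L), c(n1, n0))
  u <- ifelse(y == 1, runif(n, 0.25, 1), runif(n, -1, -0.25))
  s <- rnorm(n, 0, 0.08)
  nk <- 0.30 - 0.10 * u + s
  md <- 0.10 + 0.10 * u + s
  x <- cbind(`NonGran.NK` = pmin(pmax(nk, 0), 1),
             `NonGran.mMDSC` = pmin(pmax(md, 0), 1),
             `NonGran.B` = runif(n, 0.02, 0.2),
             `Gran.eosinophil` = runif(n, 0, 0.1))
  structure(list(x = x, y = y), class = "pjiFeatureMatrix")
}

# Hand-built event table: k events per supplied phenotype row.
eventTableFromLevels <- function(levels, n = 1, cofactor = 150) {
  ch <- panelChannels()$all
  base <- c(`FSC-A` = 50000, `FSC-H` = 47000, `FSC-W` = 60000,
            `SSC-A` = 20000,
            Viability = 1, CD45 = 4, CD66b = 1, CD16 = 1, CD3 = 1,
            CD19 = 1, CD56 = 1, CD4 = 1, CD8 = 1, CD14 = 1, `HLA-DR` = 1,
            CD11b = 1, CD123 = 1, CD11c = 1)
  rows <- do.call(rbind, lapply(seq_len(nrow(levels)), function(i) {
    v <- base
    nm <- intersect(names(levels), names(v))
    v[nm] <- unlist(levels[i, nm])
    matrix(rep(v, levels$n[i] %||% n), ncol = length(v), byrow = TRUE,
           dimnames = list(NULL, names(v)))
  }))
  fl <- panelChannels()$fluorescence
  rows[, fl] <- sinh(rows[, fl]) * cofactor
  FlowEventTable(rows[, ch, drop = FALSE], cofactor = cofactor)
}

# A cohort separable with wide margins on each informative axis, so that
# axis-aligned learners (trees) succeed as easily as linear ones.
axisSeparableFeatureMatrix <- function(n1 = 17, n0 = 33, seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  y <- rep(c(1L, 0L), c(n1, n0))
  x <- cbind(
    `NonGran.NK` = ifelse(y == 1, runif(n, 0.0, 0.05),
                          runif(n, 0.25, 0.40)),
    `NonGran.mMDSC` = ifelse(y == 1, runif(n, 0.20, 0.35),
                             runif(n, 0.0, 0.05)),
    `NonGran.B` = runif(n, 0.02, 0.2),
    `Gran.eosinophil` = runif(n, 0, 0.1))
  structure(list(x = x, y = y), class = "pjiFeatureMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
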
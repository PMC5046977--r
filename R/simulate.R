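#' Documented simulation scenarios
#'
#' Returns a fully specified \linkS4class{SimulationConfig} for one of
#' five study designs:
#' \describe{
#'   \item{healthy-blood}{500 whole-blood samples, ages 20-100, no
#'     exposure; 50 hyper and 50 hypo clock CpGs planted among 2000
#'     probes. The construction substrate.}
#'   \item{multi-tissue-normal}{288 healthy samples spread round-robin
#'     over the eight tissues with literature division rates
#'     ([tissueRates()]), no exposure; cumulative divisions vary over
#'     four orders of magnitude across tissues.}
#'   \item{tumor-vs-normal}{50 matched pairs sharing age and tissue;
#'     the tumor member carries a log-normal exposure driving extra
#'     divisions.}
#'   \item{lesion-progression}{three unpaired groups (normal, lesion,
#'     progressed) with increasing exposure levels, emulating a
#'     pre-invasive lesion series.}
#'   \item{exposure-dose}{one group with a continuous log-normal
#'     exposure recorded in the sample sheet (a pack-years-like dose).}
#' }
#' All scenarios simulate in well under a minute at these defaults.
#'
#' @param scenario scenario name (see above).
#' @param seed integer seed; fixes the cohort completely.
#' @return a \linkS4class{SimulationConfig}.
#' @export
defaultConfig <- function(scenario = c("healthy-blood",
                                       "multi-tissue-normal",
                                       "tumor-vs-normal",
                                       "lesion-progression",
                                       "exposure-dose"),
                          seed = 1L) {
  known <- eval(formals(defaultConfig)$scenario)
  if (!is.character(scenario) || !scenario[1L] %in% known)
    .err("epitoc_input_error", "unknown scenario '%s'; choices: %s",
         as.character(scenario)[1L], paste(known, collapse = ", "))
  scenario <- scenario[1L]
  base <- list(scenario = scenario, nSamples = 500L, nProbes = 2000L,
               nClockHyper = 50L, nClockHypo = 50L, nFetal = 52L,
               ageRange = c(20, 100),
               tissues = data.frame(tissue = "blood", ir = 13),
               groupSpec = data.frame(group = "healthy", prop = 1,
                                      expMeanlog = NA_real_,
                                      expSdlog = NA_real_),
               paired = FALSE, exposureRate = 0,
               groundStateHyper = c(0.02, 0.15),
               groundStateHypo = c(0.40, 0.90),
               xiRange = c(2e-5, 6e-5), nCellTypes = 3L,
               nLineageProbes = 300L, cellAgeTrend = c(0.4, -0.4, 0),
               noisePrecision = 200, exprBase = 5, exprSlope = 0.05,
               exprNoiseSd = 0.3, nOtherGenes = 20L,
               seed = as.integer(seed))
  if (scenario == "multi-tissue-normal") {
    base$nSamples <- 288L
    base$tissues <- data.frame(tissue = names(tissueRates()),
                               ir = unname(tissueRates()))
  } else if (scenario == "tumor-vs-normal") {
    base$nSamples <- 100L
    base$paired <- TRUE
    base$tissues <- data.frame(tissue = "breast", ir = 2)
    base$exposureRate <- 2
    base$groupSpec <- data.frame(group = c("normal", "tumor"),
                                 prop = c(0.5, 0.5),
                                 expMeanlog = c(NA, 0),
                                 expSdlog = c(NA, 0.4))
  } else if (scenario == "lesion-progression") {
    base$nSamples <- 150L
    base$tissues <- data.frame(tissue = "breast", ir = 2)
    base$exposureRate <- 2
    base$groupSpec <- data.frame(
      group = c("normal", "lesion", "progressed"),
      prop = c(1, 1, 1) / 3,
      expMeanlog = c(NA, log(0.8), log(2)),
      expSdlog = c(NA, 0.3, 0.3))
  } else if (scenario == "exposure-dose") {
    base$nSamples <- 300L
    base$exposureRate <- 6.5
    base$groupSpec <- data.frame(group = "exposed", prop = 1,
                                 expMeanlog = 0, expSdlog = 0.5)
  }
  do.call(new, c(list(Class = "SimulationConfig"), base))
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Simulate a methylation cohort under the replication-error model
#'
#' Generates a complete synthetic study from a
#' \linkS4class{SimulationConfig}: per sample the cumulative stem-cell
#' divisions are \eqn{TNSC = A (IR + E \cdot ER)}; each planted hyper
#' (hypo) clock CpG drifts up (down) from its fetal ground state by its
#' per-division error rate xi times TNSC, hard-clipped to [0,1] (clipped
#' cells are counted and reported by warning); a block of lineage probes
#' carries cell-type-specific offsets mixed by age-trending proportions
#' (the cellular-heterogeneity confounder); observed betas receive
#' mean-preserving beta-family measurement noise at the configured
#' precision; the expression panel tracks the proliferation rate
#' \eqn{IR + E \cdot ER} linearly with Gaussian noise. Fully reproducible
#' from the config seed; the caller's RNG state is left untouched.
#'
#' @param config a \linkS4class{SimulationConfig}, e.g. from
#'   [defaultConfig()].
#' @return a \linkS4class{SimulatedCohort}.
#' @examples
#' cohort <- simulateCohort(defaultConfig("healthy-blood", seed = 7))
#' cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withr::with_seed(config@seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
  gs <- config@groupSpec
  nG <- nrow(gs)
  if (config@paired) {
    nInd <- config@nSamples %/% nG
    age <- rep(stats::runif(nInd, config@ageRange[1], config@ageRange[2]),
               times = nG)
    tIdx <- rep(rep_len(seq_len(nrow(config@tissues)), nInd), times = nG)
    group <- rep(gs$group, each = nInd)
    pairId <- rep(sprintf("p%03d", seq_len(nInd)), times = nG)
    sid <- paste0(rep(sprintf("s%03d", seq_len(nInd)), times = nG), "_",
                  group)
    gRow <- rep(seq_len(nG), each = nInd)
  } else {
    counts <- diff(round(c(0, cumsum(gs$prop)) * config@nSamples))
    n <- sum(counts)
    age <- stats::runif(n, config@ageRange[1], config@ageRange[2])
    tIdx <- rep_len(seq_len(nrow(config@tissues)), n)
    group <- rep(gs$group, times = counts)
    pairId <- rep(NA_character_, n)
    sid <- sprintf("s%04d", seq_len(n))
    gRow <- rep(seq_len(nG), times = counts)
  }
  n <- length(sid)
  exposure <- numeric(n)
  for (g in seq_len(nG)) {
    idx <- gRow == g
    if (!is.na(gs$expMeanlog[g]))
      exposure[idx] <- stats::rlnorm(sum(idx), gs$expMeanlog[g],
                                     gs$expSdlog[g])
  }
  ir <- config@tissues$ir[tIdx]
  prolifRate <- ir + exposure * config@exposureRate
  tnsc <- age * prolifRate

  ## probe roles and ground states
  nP <- config@nProbes
  probeId <- sprintf("cg%06d", seq_len(nP))
  role <- rep("static", nP)
  hyperIdx <- seq_len(config@nClockHyper)
  hypoIdx <- seq_len(config@nClockHypo) + config@nClockHyper
  linIdx <- seq_len(config@nLineageProbes) + config@nClockHyper +
    config@nClockHypo
  role[hyperIdx] <- "hyper"
  role[hypoIdx] <- "hypo"
  role[linIdx] <- "lineage"
  g0 <- xi <- rep(NA_real_, nP)
  g0[hyperIdx] <- stats::runif(length(hyperIdx), config@groundStateHyper[1],
                               config@groundStateHyper[2])
  g0[hypoIdx] <- stats::runif(length(hypoIdx), config@groundStateHypo[1],
                              config@groundStateHypo[2])
  xi[c(hyperIdx, hypoIdx)] <- stats::runif(
    length(hyperIdx) + length(hypoIdx), config@xiRange[1],
    config@xiRange[2])
  staticMean <- rep(NA_real_, nP)
  staticIdx <- which(role == "static")
  staticMean[staticIdx] <- stats::runif(length(staticIdx), 0.05, 0.95)

  ## cell-type reference: identical across types except lineage probes
  k <- config@nCellTypes
  ctNames <- paste0("CT", seq_len(k))
  refBase <- rep(NA_real_, nP)
  refBase[hyperIdx] <- g0[hyperIdx]
  refBase[hypoIdx] <- g0[hypoIdx]
  refBase[staticIdx] <- staticMean[staticIdx]
  refBase[linIdx] <- stats::runif(length(linIdx), 0.2, 0.8)
  profiles <- matrix(refBase, nP, k, dimnames = list(probeId, ctNames))
  if (length(linIdx) > 0L) {
    whichCT <- sample.int(k, length(linIdx), replace = TRUE)
    delta <- stats::runif(length(linIdx), 0.15, 0.3) *
      sample(c(-1, 1), length(linIdx), replace = TRUE)
    for (i in seq_along(linIdx)) {
      p <- linIdx[i]
      profiles[p, whichCT[i]] <-
        min(max(profiles[p, whichCT[i]] + delta[i], 0.02), 0.98)
    }
  }

  ## age-trending cell proportions (softmax of noisy linear logits)
  W <- t(vapply(seq_len(n), function(s) {
    z <- config@cellAgeTrend * (age[s] - 60) / 40 + stats::rnorm(k, 0, 0.3)
    .softmax(z)
  }, numeric(k)))
  dimnames(W) <- list(sid, ctNames)

  ## expected betas
  mu <- matrix(NA_real_, nP, n, dimnames = list(probeId, sid))
  if (length(hyperIdx) > 0L)
    mu[hyperIdx, ] <- outer(xi[hyperIdx], tnsc) + g0[hyperIdx]
  if (length(hypoIdx) > 0L)
    mu[hypoIdx, ] <- g0[hypoIdx] - outer(xi[hypoIdx], tnsc)
  if (length(staticIdx) > 0L)
    mu[staticIdx, ] <- staticMean[staticIdx]
  if (length(linIdx) > 0L)
    mu[linIdx, ] <- profiles[linIdx, , drop = FALSE] %*% t(W)
  nClipped <- sum(mu < 0 | mu > 1)
  if (nClipped > 0L)
    warning(nClipped, " expected beta value(s) clipped to [0,1] ",
            "(drift saturation at this TNSC range)")
  mu <- pmin(pmax(mu, 0), 1)

  ## measurement noise: mean-preserving beta family at given precision
  phi <- config@noisePrecision
  if (phi > 0) {
    muC <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    B <- matrix(stats::rbeta(length(muC), c(muC) * phi,
                             (1 - c(muC)) * phi),
                nP, n, dimnames = dimnames(mu))
  } else B <- mu

  ## fetal ground-state matrix
  fet <- matrix(NA_real_, nP, config@nFetal,
                dimnames = list(probeId,
                                sprintf("fetal%02d", seq_len(config@nFetal))))
  fetNoise <- function(center, lo, hi)  # center already probe x fetal long
    pmin(pmax(center + stats::rnorm(length(center), 0, 0.02), lo), hi)
  if (length(hyperIdx) > 0L)
    fet[hyperIdx, ] <- fetNoise(rep(g0[hyperIdx], config@nFetal),
                                0.005, 0.195)
  if (length(hypoIdx) > 0L)
    fet[hypoIdx, ] <- fetNoise(rep(g0[hypoIdx], config@nFetal),
                               0.305, 0.98)
  other <- c(staticIdx, linIdx)
  fet[other, ] <- fetNoise(rep(refBase[other], config@nFetal), 0.001, 0.999)

  ## annotation: planted clock CpGs are unambiguous TSS200 promoters;
  ## hyper ones are PRC2/Polycomb-marked. Background probes get realistic
  ## annotation rates so every filter has work to do.
  tss200 <- role %in% c("hyper", "hypo")
  tss200[!tss200] <- stats::runif(sum(!tss200)) < 0.3
  prc2 <- role == "hyper"
  prc2[!prc2] <- stats::runif(sum(!prc2)) < 0.2
  gene <- ifelse(tss200, paste0("GENE", seq_len(nP)), "")
  annot <- data.frame(probe_id = probeId, gene = gene, tss200 = tss200,
                      prc2 = prc2, stringsAsFactors = FALSE)

  ## sample sheet
  pheno <- data.frame(sample_id = sid, age = age,
                      sex = sample(c("F", "M"), n, replace = TRUE),
                      plate = sample(paste0("P", 1:4), n, replace = TRUE),
                      tissue = config@tissues$tissue[tIdx], group = group,
                      pair_id = pairId, exposure = exposure,
                      stringsAsFactors = FALSE)

  ## matched expression: panel tracks the proliferation rate
  panel <- mitoticPanel()
  baseLvl <- stats::runif(length(panel), config@exprBase - 1,
                          config@exprBase + 1)
  E <- outer(rep(1, length(panel)), prolifRate) * config@exprSlope +
    baseLvl +
    matrix(stats::rnorm(length(panel) * n, 0, config@exprNoiseSd),
           length(panel), n)
  otherExpr <- matrix(stats::rnorm(config@nOtherGenes * n,
                                   config@exprBase, 1),
                      config@nOtherGenes, n)
  expr <- rbind(E, otherExpr)
  dimnames(expr) <- list(c(panel,
                           paste0("OTHER", seq_len(config@nOtherGenes))),
                         sid)

  truthSamples <- data.frame(sample_id = sid, age = age,
                             tissue = config@tissues$tissue[tIdx],
                             ir = ir, group = group, pair_id = pairId,
                             exposure = exposure, prolifRate = prolifRate,
                             tnsc = tnsc, stringsAsFactors = FALSE)
  truthProbes <- data.frame(probe_id = probeId, role = role,
                            groundState = ifelse(role == "static",
                                                 staticMean, g0),
                            xi = xi, stringsAsFactors = FALSE)
  truthProbes$groundState[role == "lineage"] <- refBase[linIdx]

  new("SimulatedCohort", beta = BetaMatrix(B), pheno = pheno,
      annot = annot, fetal = BetaMatrix(fet),
      reference = CellTypeReference(profiles),
      trueFractions = new("CellFractions", weights = W,
                          fitResidual = rep(0, n)),
      expr = expr, truthSamples = truthSamples,
      truthProbes = truthProbes, config = config)
}

#' Write every artifact of a simulated cohort to a directory
#'
#' Emits the cohort in the package's file dialects: \code{beta.tsv},
#' \code{pheno.csv}, \code{annot.tsv}, \code{fetal.tsv},
#' \code{reference.tsv}, \code{true_fractions.csv}, \code{expr.tsv},
#' \code{truth_samples.tsv} and \code{truth_probes.tsv}.
#'
#' @param cohort a \linkS4class{SimulatedCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SimulatedCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBetaMatrix(cohort@beta, file.path(dir, "beta.tsv"))
  utils::write.csv(cohort@pheno, file.path(dir, "pheno.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(
    transform(cohort@annot, tss200 = as.integer(tss200),
              prc2 = as.integer(prc2)),
    file.path(dir, "annot.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeBetaMatrix(cohort@fetal, file.path(dir, "fetal.tsv"))
  .writeMatrix(referenceProfiles(cohort@reference),
               file.path(dir, "reference.tsv"))
  fr <- data.frame(sample_id = sampleIDs(cohort@trueFractions),
                   fractionWeights(cohort@trueFractions),
                   check.names = FALSE)
  utils::write.csv(fr, file.path(dir, "true_fractions.csv"),
                   row.names = FALSE, quote = FALSE)
  .writeMatrix(cohort@expr, file.path(dir, "expr.tsv"),
               idColumn = "gene_id")
  utils::write.table(cohort@truthSamples,
                     file.path(dir, "truth_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort@truthProbes,
                     file.path(dir, "truth_probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
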
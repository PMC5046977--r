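#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors DataFrame metadata
NULL

#' BetaMatrix: DNA methylation beta values
#'
#' A probes-by-samples matrix of methylation beta fractions, stored as a
#' \linkS4class{SummarizedExperiment} with a single assay \code{"beta"}.
#' Every value is either missing (\code{NA}) or lies in \eqn{[0,1]}; probe
#' and sample identifiers are unique. Rows are probes, columns samples
#' (array-platform convention); a transposed input will fail by identifier
#' mismatch rather than being guessed at.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @seealso [readBetaMatrix()], [betaValues()]
#' @export
setClass("BetaMatrix", contains = "SummarizedExperiment")

.validBetaMatrix <- function(object) {
  msg <- NULL
  if (!"beta" %in% names(assays(object)))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    if (!is.numeric(b))
      msg <- c(msg, "beta values must be numeric")
    else {
      bad <- !is.na(b) & (b < 0 | b > 1)
      if (any(bad))
        msg <- c(msg, sprintf("%d beta value(s) outside [0,1]", sum(bad)))
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("BetaMatrix", .validBetaMatrix)

#' Construct a BetaMatrix from a numeric matrix
#'
#' @param values numeric matrix of beta fractions in \eqn{[0,1]} (NA for
#'   missing), probes in rows, samples in columns. Must carry row and
#'   column names unless \code{probeIDs}/\code{sampleIDs} are given.
#' @param probeIDs,sampleIDs optional identifier vectors overriding the
#'   matrix dimnames.
#' @return a \linkS4class{BetaMatrix}.
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' BetaMatrix(m)
#' @export
BetaMatrix <- function(values, probeIDs = rownames(values),
                       sampleIDs = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- probeIDs
  colnames(values) <- sampleIDs
  new("BetaMatrix", SummarizedExperiment(assays = list(beta = values)))
}

#' ClockDefinition: a mitotic-clock CpG set
#'
#' Names a set of clock CpGs together with the direction of age-associated
#' methylation change and the fetal ground-state bound used at
#' construction: hypermethylation clocks require fetal beta strictly below
#' the bound (default 0.2) in every fetal sample, hypomethylation clocks
#' require fetal beta at or above the bound (default 0.3).
#'
#' @slot name clock name.
#' @slot direction \code{"hyper"} or \code{"hypo"}.
#' @slot probes character vector of probe identifiers (unique, non-empty).
#' @slot groundStateBound the fetal beta threshold used at construction.
#' @export
setClass("ClockDefinition",
         representation(name = "character", direction = "character",
                        probes = "character", groundStateBound = "numeric"))

setValidity("ClockDefinition", function(object) {
  msg <- NULL
  if (anyDuplicated(object@probes))
    msg <- c(msg, "duplicate probe identifiers in clock")
  if (!object@direction %in% c("hyper", "hypo"))
    msg <- c(msg, "direction must be 'hyper' or 'hypo'")
  if (length(object@groundStateBound) != 1L ||
      object@groundStateBound <= 0 || object@groundStateBound >= 1)
    msg <- c(msg, "groundStateBound must lie in (0,1)")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ClockDefinition-class
#' @param name clock name.
#' @param direction \code{"hyper"} or \code{"hypo"}.
#' @param probes character vector of probe identifiers.
#' @param groundStateBound fetal beta bound; defaults to 0.2 for hyper
#'   clocks and 0.3 for hypo clocks.
#' @export
ClockDefinition <- function(name, direction = c("hyper", "hypo"), probes,
                            groundStateBound = NULL) {
  direction <- match.arg(direction)
  if (is.null(groundStateBound))
    groundStateBound <- if (direction == "hyper") 0.2 else 0.3
  new("ClockDefinition", name = as.character(name), direction = direction,
      probes = as.character(probes), groundStateBound = groundStateBound)
}

setMethod("show", "ClockDefinition", function(object) {
  cat("ClockDefinition '", object@name, "': ", length(object@probes),
      " CpGs, direction=", object@direction,
      ", ground-state bound ", if (object@direction == "hyper") "<" else ">=",
      object@groundStateBound, "\n", sep = "")
})

#' CellTypeReference: reference methylation profiles of sorted cell types
#'
#' Probes-by-cell-types matrix of reference beta values used for
#' reference-based deconvolution of bulk samples. No missing values are
#' allowed and at least two cell types are required.
#'
#' @slot profiles numeric matrix, probes in rows, cell types in columns.
#' @export
setClass("CellTypeReference", representation(profiles = "matrix"))

setValidity("CellTypeReference", function(object) {
  p <- object@profiles
  msg <- NULL
  if (anyNA(p)) msg <- c(msg, "reference must not contain missing values")
  if (ncol(p) < 2L) msg <- c(msg, "at least two cell types required")
  if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
    msg <- c(msg, "probe identifiers must be present and unique")
  if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
    msg <- c(msg, "cell-type labels must be present and unique")
  if (any(p < 0 | p > 1)) msg <- c(msg, "reference betas must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' @rdname CellTypeReference-class
#' @param profiles numeric matrix of reference betas (probes x cell types).
#' @export
CellTypeReference <- function(profiles) {
  new("CellTypeReference", profiles = as.matrix(profiles))
}

setMethod("show", "CellTypeReference", function(object) {
  cat("CellTypeReference:", nrow(object@profiles), "probes x",
      ncol(object@profiles), "cell types (",
      paste(colnames(object@profiles), collapse = ", "), ")\n")
})

#' CellFractions: estimated cell-type composition of bulk samples
#'
#' Samples-by-cell-types matrix of fractions on the probability simplex
#' (nonnegative, rows summing to one within 1e-8), together with the
#' per-sample root-mean-square fit residual. Rows that could not be fit
#' (too much missingness) are all-NA and carry an NA residual.
#'
#' @slot weights numeric matrix, samples in rows, cell types in columns.
#' @slot fitResidual per-sample RMS residual of the constrained fit.
#' @export
setClass("CellFractions",
         representation(weights = "matrix", fitResidual = "numeric"))

setValidity("CellFractions", function(object) {
  w <- object@weights
  msg <- NULL
  if (length(object@fitResidual) != nrow(w))
    msg <- c(msg, "one fit residual per sample required")
  ok <- !apply(w, 1L, anyNA)
  if (any(ok)) {
    if (any(w[ok, , drop = FALSE] < -1e-8))
      msg <- c(msg, "negative cell fractions")
    if (any(abs(rowSums(w[ok, , drop = FALSE]) - 1) > 1e-8))
      msg <- c(msg, "cell fractions must sum to 1 within 1e-8")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CellFractions", function(object) {
  cat("CellFractions:", nrow(object@weights), "samples x",
      ncol(object@weights), "cell types; mean RMS residual",
      signif(mean(object@fitResidual, na.rm = TRUE), 3), "\n")
})

#' Calibration: per-tissue score-versus-age calibration
#'
#' Holds the intercept (alpha', score at age zero) and slope (gamma',
#' score increase per year) of the linear calibration of a clock score on
#' chronological age in healthy samples of one tissue, optionally together
#' with the tissue's intrinsic stem-cell division rate IR (divisions per
#' stem cell per year). With IR available the calibration inverts a score
#' to an estimate of cumulative divisions per stem cell:
#' \deqn{TNSC = (score - \alpha') \cdot IR / \gamma'.}
#'
#' @slot tissue tissue label.
#' @slot alphaPrime intercept (score at age zero).
#' @slot gammaPrime slope (score units per year); must be positive for
#'   inversion to divisions.
#' @slot ir intrinsic division rate, divisions/stem cell/year (NA if
#'   unknown).
#' @slot nFit number of samples used in the fit (NA for shipped
#'   literature constants).
#' @slot rSquared coefficient of determination of the fit (NA likewise).
#' @export
setClass("Calibration",
         representation(tissue = "character", alphaPrime = "numeric",
                        gammaPrime = "numeric", ir = "numeric",
                        nFit = "numeric", rSquared = "numeric"))

setValidity("Calibration", function(object) {
  msg <- NULL
  if (!is.na(object@ir) && object@ir <= 0)
    msg <- c(msg, "ir must be positive where present")
  if (is.null(msg)) TRUE else msg
})

#' @rdname Calibration-class
#' @param tissue tissue label.
#' @param alphaPrime,gammaPrime intercept and slope of score on age.
#' @param ir optional intrinsic division rate (divisions/stem cell/year).
#' @param nFit,rSquared fit metadata.
#' @export
Calibration <- function(tissue, alphaPrime, gammaPrime, ir = NA_real_,
                        nFit = NA_real_, rSquared = NA_real_) {
  new("Calibration", tissue = as.character(tissue),
      alphaPrime = as.numeric(alphaPrime),
      gammaPrime = as.numeric(gammaPrime), ir = as.numeric(ir),
      nFit = as.numeric(nFit), rSquared = as.numeric(rSquared))
}

setMethod("show", "Calibration", function(object) {
  cat("Calibration [", object@tissue, "]: alpha'=", object@alphaPrime,
      ", gamma'=", object@gammaPrime,
      if (!is.na(object@ir)) paste0(", IR=", object@ir) else ", IR unknown",
      if (!is.na(object@rSquared))
        paste0(" (n=", object@nFit, ", R2=", signif(object@rSquared, 3), ")")
      else "",
      "\n", sep = "")
})

#' SimulationConfig: parameters of the replication-error cohort simulator
#'
#' Fully specifies a synthetic methylation cohort under the
#' replication-error model: per sample the cumulative divisions per stem
#' cell are \eqn{TNSC = A (IR + E \cdot ER)} (age times intrinsic plus
#' exposure-driven rate); each planted clock CpG drifts linearly from its
#' fetal ground state at a per-division rate xi (upward for hyper, downward
#' for hypo, clipped to [0,1]); non-clock probes are static except for a
#' block of lineage probes mixed by age-trending cell-type proportions;
#' observed betas get mean-preserving beta-family measurement noise.
#' See [defaultConfig()] for the documented scenarios.
#'
#' @slot scenario scenario label.
#' @slot nSamples,nProbes,nClockHyper,nClockHypo,nFetal cohort dimensions.
#' @slot ageRange sampling range of chronological age, years.
#' @slot tissues data.frame with columns \code{tissue} and \code{ir}
#'   (divisions/stem cell/year); samples are assigned round-robin.
#' @slot groupSpec data.frame with columns \code{group}, \code{prop},
#'   \code{expMeanlog}, \code{expSdlog} defining group sizes and the
#'   log-normal exposure E per group (NA meanlog means E = 0).
#' @slot paired if TRUE, groups are matched pairs sharing age and tissue.
#' @slot exposureRate extrinsic division rate ER per unit exposure.
#' @slot groundStateHyper,groundStateHypo sampling ranges of fetal ground
#'   states for planted hyper (< 0.2) and hypo (>= 0.3) clock CpGs.
#' @slot xiRange per-division drift range of planted clock CpGs.
#' @slot nCellTypes,nLineageProbes,cellAgeTrend cell-mixture confounding:
#'   number of cell types, number of lineage-informative probes, and the
#'   per-type age trend (log-odds change over the age range).
#' @slot noisePrecision precision of the beta measurement-noise family
#'   (0 disables noise).
#' @slot exprBase,exprSlope,exprNoiseSd,nOtherGenes expression module:
#'   panel baseline, slope of expression on the proliferation rate
#'   IR + E*ER, Gaussian noise sd, and number of non-panel genes.
#' @slot seed integer seed fixing the full cohort.
#' @export
setClass("SimulationConfig",
         representation(scenario = "character", nSamples = "integer",
                        nProbes = "integer", nClockHyper = "integer",
                        nClockHypo = "integer", nFetal = "integer",
                        ageRange = "numeric", tissues = "data.frame",
                        groupSpec = "data.frame", paired = "logical",
                        exposureRate = "numeric",
                        groundStateHyper = "numeric",
                        groundStateHypo = "numeric", xiRange = "numeric",
                        nCellTypes = "integer", nLineageProbes = "integer",
                        cellAgeTrend = "numeric", noisePrecision = "numeric",
                        exprBase = "numeric", exprSlope = "numeric",
                        exprNoiseSd = "numeric", nOtherGenes = "integer",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (any(object@tissues$ir < 0)) msg <- c(msg, "tissue IR rates must be >= 0")
  if (object@exposureRate < 0) msg <- c(msg, "exposureRate must be >= 0")
  if (object@groundStateHyper[2] >= 0.2)
    msg <- c(msg, "hyper ground states must stay below 0.2")
  if (object@groundStateHypo[1] < 0.3)
    msg <- c(msg, "hypo ground states must stay at or above 0.3")
  if (object@nClockHyper + object@nClockHypo + object@nLineageProbes >
      object@nProbes)
    msg <- c(msg, "clock + lineage probes exceed nProbes")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a seed is mandatory")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig '", object@scenario, "': ", object@nSamples,
      " samples x ", object@nProbes, " probes (",
      object@nClockHyper, " hyper / ", object@nClockHypo,
      " hypo clock CpGs planted), tissues: ",
      paste(object@tissues$tissue, collapse = ", "),
      ", seed ", object@seed, "\n", sep = "")
})

#' SimulatedCohort: output of the cohort simulator
#'
#' Bundles every artifact a real study would supply -- bulk beta matrix,
#' sample sheet, probe annotation, fetal ground-state matrix, cell-type
#' reference, true mixing fractions and a matched expression matrix --
#' together with the generating truth (per-sample TNSC and proliferation
#' rate; per-probe clock membership, ground state and drift rate).
#'
#' @slot beta,fetal \linkS4class{BetaMatrix} of bulk and fetal samples.
#' @slot pheno sample sheet data.frame.
#' @slot annot probe annotation data.frame.
#' @slot reference \linkS4class{CellTypeReference}.
#' @slot trueFractions \linkS4class{CellFractions} used in mixing.
#' @slot expr genes-by-samples expression matrix.
#' @slot truthSamples per-sample truth (age, tissue, group, exposure,
#'   tnsc, prolifRate).
#' @slot truthProbes per-probe truth (clock membership, groundState, xi).
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("SimulatedCohort",
         representation(beta = "BetaMatrix", pheno = "data.frame",
                        annot = "data.frame", fetal = "BetaMatrix",
                        reference = "CellTypeReference",
                        trueFractions = "CellFractions", expr = "matrix",
                        truthSamples = "data.frame",
                        truthProbes = "data.frame",
                        config = "SimulationConfig"))

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort '", object@config@scenario, "': ",
      ncol(object@beta), " samples x ", nrow(object@beta), " probes, ",
      ncol(object@fetal), " fetal samples, ",
      nrow(object@expr), " genes\n", sep = "")
})
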
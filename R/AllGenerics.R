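#' Extract the beta-value matrix
#'
#' @param x a \linkS4class{BetaMatrix}.
#' @return numeric matrix of beta fractions, probes in rows.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname betaValues
#' @export
setMethod("betaValues", "BetaMatrix", function(x) assay(x, "beta"))

#' Probe identifiers of a container
#'
#' @param x a \linkS4class{BetaMatrix}, \linkS4class{CellTypeReference}
#'   or \linkS4class{ClockDefinition}.
#' @return character vector of probe identifiers.
#' @export
setGeneric("probeIDs", function(x) standardGeneric("probeIDs"))

#' @rdname probeIDs
#' @export
setMethod("probeIDs", "BetaMatrix", function(x) rownames(x))

#' @rdname probeIDs
#' @export
setMethod("probeIDs", "CellTypeReference", function(x) rownames(x@profiles))

#' @rdname probeIDs
#' @export
setMethod("probeIDs", "ClockDefinition", function(x) x@probes)

#' Sample identifiers
#'
#' @param x a \linkS4class{BetaMatrix} or \linkS4class{CellFractions}.
#' @return character vector of sample identifiers.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "BetaMatrix", function(x) colnames(x))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "CellFractions", function(x) rownames(x@weights))

#' Cell-type labels
#'
#' @param x a \linkS4class{CellTypeReference} or
#'   \linkS4class{CellFractions}.
#' @return character vector of cell-type labels.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "CellTypeReference", function(x) colnames(x@profiles))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "CellFractions", function(x) colnames(x@weights))

#' Cell-fraction weight matrix
#'
#' @param x a \linkS4class{CellFractions}.
#' @return samples-by-cell-types matrix of fractions.
#' @export
setGeneric("fractionWeights", function(x) standardGeneric("fractionWeights"))

#' @rdname fractionWeights
#' @export
setMethod("fractionWeights", "CellFractions", function(x) x@weights)

#' Per-sample RMS residual of the deconvolution fit
#'
#' @param x a \linkS4class{CellFractions}.
#' @return numeric vector, one residual per sample.
#' @export
setGeneric("fitResidual", function(x) standardGeneric("fitResidual"))

#' @rdname fitResidual
#' @export
setMethod("fitResidual", "CellFractions", function(x) x@fitResidual)

#' Reference profile matrix
#'
#' @param x a \linkS4class{CellTypeReference}.
#' @return probes-by-cell-types matrix of reference betas.
#' @export
setGeneric("referenceProfiles",
           function(x) standardGeneric("referenceProfiles"))

#' @rdname referenceProfiles
#' @export
setMethod("referenceProfiles", "CellTypeReference", function(x) x@profiles)

#' Calibration accessors
#'
#' @param x a \linkS4class{Calibration}.
#' @return the intercept alpha', the slope gamma' (per year), or the
#'   intrinsic division rate IR (divisions/stem cell/year, NA if unknown).
#' @name calibration-accessors
NULL

#' @rdname calibration-accessors
#' @export
setGeneric("alphaPrime", function(x) standardGeneric("alphaPrime"))

#' @rdname calibration-accessors
#' @export
setMethod("alphaPrime", "Calibration", function(x) x@alphaPrime)

#' @rdname calibration-accessors
#' @export
setGeneric("gammaPrime", function(x) standardGeneric("gammaPrime"))

#' @rdname calibration-accessors
#' @export
setMethod("gammaPrime", "Calibration", function(x) x@gammaPrime)

#' @rdname calibration-accessors
#' @export
setGeneric("intrinsicRate", function(x) standardGeneric("intrinsicRate"))

#' @rdname calibration-accessors
#' @export
setMethod("intrinsicRate", "Calibration", function(x) x@ir)

#' Clock direction ("hyper" or "hypo")
#'
#' @param x a \linkS4class{ClockDefinition}.
#' @return \code{"hyper"} or \code{"hypo"}.
#' @export
setGeneric("clockDirection", function(x) standardGeneric("clockDirection"))

#' @rdname clockDirection
#' @export
setMethod("clockDirection", "ClockDefinition", function(x) x@direction)
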
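#' Compute a mitotic-clock score per sample
#'
#' The clock score of a sample is the arithmetic mean of its non-missing
#' beta values over the clock CpGs (for a hyper clock this is the
#' pcgtAge-type score, for a hypo clock the hypoAge-type score). Samples
#' whose coverage -- the fraction of clock CpGs with a non-missing value
#' in the matrix -- falls below \code{minCoverage} are flagged and get no
#' score, because mean-over-probes scores are only comparable across
#' samples when probe support matches.
#'
#' @param beta a \linkS4class{BetaMatrix}.
#' @param clock a \linkS4class{ClockDefinition}.
#' @param minCoverage minimum fraction of clock CpGs required (default
#'   0.95).
#' @return data.frame with \code{sample_id}, \code{score},
#'   \code{n_probes_used}, \code{coverage} and logical \code{flagged}.
#' @examples
#' m <- matrix(c(0.1, 0.2, 0.6), 3, 1,
#'             dimnames = list(paste0("cg", 1:3), "s1"))
#' clk <- ClockDefinition("toy", "hyper", paste0("cg", 1:3))
#' computeClockScore(BetaMatrix(m), clk)$score  # 0.3
#' @export
computeClockScore <- function(beta, clock, minCoverage = 0.95) {
  stopifnot(is(beta, "BetaMatrix"), is(clock, "ClockDefinition"),
            minCoverage > 0, minCoverage <= 1)
  present <- intersect(probeIDs(clock), rownames(beta))
  if (length(present) == 0L)
    .err("epitoc_input_error",
         "no CpGs of clock '%s' are present in the beta matrix",
         clock@name)
  B <- betaValues(beta)[present, , drop = FALSE]
  nUsed <- colSums(!is.na(B))
  coverage <- nUsed / length(probeIDs(clock))
  score <- colMeans(B, na.rm = TRUE)
  flagged <- coverage < minCoverage
  score[flagged | nUsed == 0L] <- NA_real_
  data.frame(sample_id = colnames(B), score = score,
             n_probes_used = nUsed, coverage = coverage,
             flagged = flagged, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Calibrate a clock score against age in healthy tissue
#'
#' Ordinary least-squares fit of score on chronological age,
#' \eqn{score = \alpha' + \gamma' A + \epsilon}, intended for healthy
#' samples of a single tissue (so that exposure-driven divisions are
#' negligible and the division rate is a tissue constant absorbed into
#' the slope). The fitted intercept and slope, with the tissue's
#' intrinsic division rate when known, later invert scores to estimates
#' of cumulative stem-cell divisions ([estimateTnsc()]).
#'
#' @param scores data.frame from [computeClockScore()] (columns
#'   \code{sample_id}, \code{score}).
#' @param pheno sample sheet with \code{sample_id} and \code{age}.
#' @param tissue tissue label stored in the calibration.
#' @param ir optional intrinsic division rate (divisions/stem cell/year),
#'   e.g. from [tissueRates()].
#' @return a \linkS4class{Calibration}. A non-positive fitted slope is
#'   allowed but raises a warning: such a calibration cannot be inverted.
#' @export
calibrateClock <- function(scores, pheno, tissue = "unspecified",
                           ir = NA_real_) {
  d <- merge(scores[, c("sample_id", "score")],
             pheno[, c("sample_id", "age")], by = "sample_id")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3L)
    .err("epitoc_input_error",
         "need at least 3 scored samples with ages (got %d)", nrow(d))
  if (stats::var(d$age) == 0)
    .err("epitoc_input_error",
         "all ages identical: slope is unidentifiable")
  fit <- stats::lm(score ~ age, data = d)
  co <- stats::coef(fit)
  if (co[["age"]] <= 0)
    warning("fitted slope is not positive; calibration cannot be ",
            "inverted to division estimates")
  Calibration(tissue = tissue, alphaPrime = co[["(Intercept)"]],
              gammaPrime = co[["age"]], ir = ir, nFit = nrow(d),
              rSquared = summary(fit)$r.squared)
}

#' Intrinsic stem-cell division rates from the literature
#'
#' Tissue-specific intrinsic rates of stem-cell division (divisions per
#' stem cell per year) as compiled from the stem-cell literature for the
#' normal-tissue validation of the clock.
#'
#' @return named numeric vector of rates.
#' @export
tissueRates <- function() {
  c(colon = 73, rectum = 73, esophagus = 17.4, `head-and-neck` = 21.5,
    liver = 0.9125, lung = 0.07, pancreas = 1, thyroid = 0.087)
}

#' Shipped per-tissue calibrations
#'
#' Published calibration constants of the pcgtAge score: whole blood
#' (alpha' = 0.052, gamma' = 0.000345), normal breast (0.053, 0.000165)
#' and normal lung (0.021, 0.000588; IR = 0.07 divisions/stem cell/year).
#' Users may override any of them by fitting their own with
#' [calibrateClock()].
#'
#' @param tissue one of \code{"whole-blood"}, \code{"breast"},
#'   \code{"lung"}; omit to get the full registry.
#' @return a \linkS4class{Calibration}, or a named list of them.
#' @export
shippedCalibrations <- function(tissue = NULL) {
  reg <- list(
    "whole-blood" = Calibration("whole-blood", 0.052, 0.000345),
    "breast" = Calibration("breast", 0.053, 0.000165),
    "lung" = Calibration("lung", 0.021, 0.000588, ir = 0.07))
  if (is.null(tissue)) return(reg)
  if (!tissue %in% names(reg))
    .err("epitoc_input_error", "no shipped calibration for '%s' (have: %s)",
         tissue, paste(names(reg), collapse = ", "))
  reg[[tissue]]
}

#' Estimate cumulative stem-cell divisions from a score
#'
#' Inverts the calibrated score model to the total number of divisions
#' incurred per stem cell:
#' \deqn{TNSC = (score - \alpha') \cdot IR / \gamma'.}
#' Valid for samples of the same tissue the calibration was fit on.
#' Scores below the intercept give negative estimates; these are returned
#' as-is (silent truncation would hide calibration misfit) with a warning
#' and a logical \code{"negative"} attribute marking them.
#'
#' @param score numeric vector of clock scores.
#' @param calib a \linkS4class{Calibration} with positive gamma' and a
#'   known IR.
#' @return numeric vector of division estimates, attribute
#'   \code{"negative"} flagging below-intercept scores.
#' @examples
#' lung <- shippedCalibrations("lung")
#' estimateTnsc(0.0920, lung)  # about 8.45 divisions per stem cell
#' @export
estimateTnsc <- function(score, calib) {
  stopifnot(is(calib, "Calibration"))
  if (is.na(calib@ir))
    .err("epitoc_input_error",
         "calibration for '%s' has no IR; use tnscRatio(), which needs none",
         calib@tissue)
  if (calib@gammaPrime <= 0)
    .err("epitoc_input_error",
         "calibration slope must be positive for inversion")
  tnsc <- (score - calib@alphaPrime) * calib@ir / calib@gammaPrime
  neg <- !is.na(tnsc) & tnsc < 0
  if (any(neg))
    warning(sum(neg), " score(s) below the calibration intercept give ",
            "negative division estimates (returned unclipped)")
  attr(tnsc, "negative") <- neg
  tnsc
}

#' Ratio of division estimates of two samples
#'
#' The ratio of cumulative division numbers of two samples of the same
#' tissue, \eqn{(score_1 - \alpha') / (score_2 - \alpha')}, which cancels
#' the tissue's division rate and therefore needs no IR estimate. When IR
#' is available it equals the quotient of the [estimateTnsc()] outputs.
#'
#' @param score1,score2 clock scores of the two samples.
#' @param calib a \linkS4class{Calibration}.
#' @return dimensionless ratio.
#' @export
tnscRatio <- function(score1, score2, calib) {
  stopifnot(is(calib, "Calibration"))
  if (any(score2 == calib@alphaPrime))
    .err("epitoc_input_error",
         "score2 equals the calibration intercept: ratio undefined")
  (score1 - calib@alphaPrime) / (score2 - calib@alphaPrime)
}

#' Additional divisions incurred by a lesion
#'
#' Converts the per-stem-cell division estimates of a lesion and its
#' normal reference tissue into an absolute count of divisions
#' attributable to the lesion, as the division ratio times the number of
#' stem cells the lesion contains:
#' \deqn{(TNSC_{lesion} / TNSC_{normal}) \times stemFraction \times
#'   totalStemCells.}
#' For a lung carcinoma in situ with 22 versus 8 divisions per stem cell
#' and 0.5\% of a billion stem cells this gives about 14 million
#' divisions. (A difference-based reading of "additional divisions",
#' \eqn{(22-8) \times 0.005 \times 10^9}, would give a different number;
#' this function implements the ratio form.)
#'
#' @param tnscLesion,tnscNormal divisions per stem cell in lesion and
#'   normal tissue (both positive).
#' @param stemFraction fraction of the tissue's stem cells in the lesion.
#' @param totalStemCells stem-cell count of the tissue.
#' @return number of additional divisions.
#' @examples
#' excessDivisions(22, 8, 0.005, 1e9)  # 1.375e7, ~14 million
#' @export
excessDivisions <- function(tnscLesion, tnscNormal, stemFraction,
                            totalStemCells) {
  if (tnscNormal == 0)
    .err("epitoc_input_error", "tnscNormal must be non-zero")
  stopifnot(tnscLesion > 0, tnscNormal > 0, stemFraction > 0,
            totalStemCells > 0)
  (tnscLesion / tnscNormal) * stemFraction * totalStemCells
}
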
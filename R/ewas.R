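#' Covariate-adjusted age EWAS
#'
#' Per-probe ordinary least squares of methylation beta on chronological
#' age plus covariates (plate, sex, ... expanded to indicator contrasts)
#' and, optionally, cell-type fractions to adjust for cellular
#' heterogeneity. The per-probe fits are computed through
#' \code{limma::lmFit} but the reported statistics are the ordinary
#' (unmoderated) ones: t = coefficient / (unscaled sd x residual sigma)
#' with the residual degrees of freedom, two-sided p from the t
#' distribution, and Benjamini-Hochberg q-values over all tested probes.
#'
#' Probes with constant beta or fewer complete observations than the
#' design can support are skipped and flagged, not tested.
#'
#' @param beta a \linkS4class{BetaMatrix}.
#' @param pheno sample sheet data.frame with \code{sample_id} and
#'   \code{age}; only samples present in both \code{beta} and
#'   \code{pheno} with complete age/covariates are used.
#' @param covariates names of \code{pheno} columns to adjust for.
#' @param cellFractions optional \linkS4class{CellFractions}; all but the
#'   last cell type enter the design (they sum to one).
#' @return data.frame with one row per probe: \code{probe_id},
#'   \code{coef} (beta change per year), \code{se}, \code{t}, \code{p},
#'   \code{q}, \code{n_obs} and \code{flag} (NA for tested probes).
#' @examples
#' ages <- seq(20, 96, by = 4)
#' m <- rbind(cg1 = 0.1 + 0.001 * ages, cg2 = rep(0.5, length(ages)))
#' colnames(m) <- paste0("s", seq_along(ages))
#' ph <- data.frame(sample_id = colnames(m), age = ages)
#' runEwas(BetaMatrix(m), ph)
#' @export
runEwas <- function(beta, pheno, covariates = character(),
                    cellFractions = NULL) {
  stopifnot(is(beta, "BetaMatrix"), is.data.frame(pheno))
  pheno <- pheno[match(colnames(beta), pheno$sample_id), , drop = FALSE]
  keepCols <- c("age", covariates)
  miss <- setdiff(covariates, names(pheno))
  if (length(miss) > 0L)
    .err("epitoc_schema_error", "covariate(s) not in sample sheet: %s",
         paste(miss, collapse = ", "))
  covDf <- pheno[, keepCols, drop = FALSE]
  for (cv in covariates)
    if (!is.numeric(covDf[[cv]])) covDf[[cv]] <- factor(covDf[[cv]])
  if (!is.null(cellFractions)) {
    stopifnot(is(cellFractions, "CellFractions"))
    w <- fractionWeights(cellFractions)
    w <- w[match(pheno$sample_id, rownames(w)), , drop = FALSE]
    w <- w[, -ncol(w), drop = FALSE]  # fractions sum to 1: drop one
    colnames(w) <- paste0("frac_", colnames(w))
    covDf <- cbind(covDf, as.data.frame(w))
  }
  complete <- stats::complete.cases(covDf) & !is.na(pheno$sample_id)
  n <- sum(complete)
  design <- stats::model.matrix(~ ., data = covDf[complete, , drop = FALSE])
  p <- ncol(design)
  if (n < p + 2L)
    .err("epitoc_input_error",
         "only %d complete samples for a %d-column design", n, p)
  qrd <- qr(design)
  if (qrd$rank < p) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    cors <- stats::cor(design[, setdiff(colnames(design), "(Intercept)")])
    diag(cors) <- 0
    partner <- vapply(aliased, function(a)
      colnames(cors)[which.max(abs(cors[, a]))], character(1L))
    .err("epitoc_collinearity_error",
         "collinear covariates: %s",
         paste(sprintf("'%s' with '%s'", aliased, partner), collapse = "; "))
  }
  B <- betaValues(beta)[, complete, drop = FALSE]
  nObs <- rowSums(!is.na(B))
  rowVar <- apply(B, 1L, stats::var, na.rm = TRUE)
  flag <- rep(NA_character_, nrow(B))
  flag[!is.na(rowVar) & rowVar == 0] <- "constant"
  flag[nObs < p + 2L] <- "too_few_obs"
  out <- data.frame(probe_id = rownames(B), coef = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, q = NA_real_, n_obs = nObs,
                    flag = flag, stringsAsFactors = FALSE,
                    row.names = NULL)
  test <- is.na(flag)
  if (any(test)) {
    fit <- limma::lmFit(B[test, , drop = FALSE], design)
    co <- fit$coefficients[, "age"]
    se <- fit$stdev.unscaled[, "age"] * fit$sigma
    tv <- co / se
    pv <- 2 * stats::pt(-abs(tv), df = fit$df.residual)
    bad <- !is.finite(tv)
    out$coef[test] <- co
    out$se[test] <- se
    out$t[test] <- tv
    out$p[test] <- pv
    if (any(bad)) {
      idx <- which(test)[bad]
      out$flag[idx] <- "unestimable"
      out[idx, c("coef", "se", "t", "p")] <- NA_real_
    }
    tested <- is.na(out$flag)
    out$q[tested] <- bhQvalues(out$p[tested])
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment over the supplied p-values,
#' order-preserving with respect to the input indexing (a thin, validating
#' wrapper around \code{stats::p.adjust(method = "BH")}).
#'
#' @param p numeric vector of p-values in \eqn{[0,1]}.
#' @return q-values in the input order.
#' @export
bhQvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    .err("epitoc_validation_error", "p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Selection parameters for clock construction
#'
#' @param fdrThreshold probes enter a clock only with BH q strictly below
#'   this (default 0.05).
#' @param fetalHyperBound hyper-clock CpGs must have fetal beta strictly
#'   below this in every fetal sample (default 0.2).
#' @param fetalHypoBound hypo-clock CpGs must have fetal beta at or above
#'   this in every fetal sample (default 0.3).
#' @param requireTss200 restrict to probes mapping unambiguously (a
#'   single gene) within 200 bp of a transcription start site.
#' @param requirePrc2ForHyper restrict the hyper clock to Polycomb-target
#'   (PRC2-marked) promoters.
#' @return a named list of class \code{"SelectionParams"}.
#' @export
selectionParams <- function(fdrThreshold = 0.05, fetalHyperBound = 0.2,
                            fetalHypoBound = 0.3, requireTss200 = TRUE,
                            requirePrc2ForHyper = TRUE) {
  stopifnot(fdrThreshold > 0, fdrThreshold < 1,
            fetalHyperBound > 0, fetalHyperBound < 1,
            fetalHypoBound > 0, fetalHypoBound < 1)
  structure(list(fdrThreshold = fdrThreshold,
                 fetalHyperBound = fetalHyperBound,
                 fetalHypoBound = fetalHypoBound,
                 requireTss200 = requireTss200,
                 requirePrc2ForHyper = requirePrc2ForHyper),
            class = "SelectionParams")
}

#' Select mitotic-clock CpGs from an EWAS
#'
#' Applies the clock-construction filter cascade to an age EWAS: BH
#' q below the FDR threshold; coefficient sign (positive for the hyper
#' clock, negative for the hypo clock); unambiguous TSS200 promoter
#' annotation; fetal ground state (strictly below \code{fetalHyperBound}
#' in every fetal sample for hyper, at or above \code{fetalHypoBound} in
#' every fetal sample for hypo); and, for the hyper clock only,
#' PRC2/Polycomb-target promoter status. Filters are conjunctive, so the
#' resulting membership does not depend on their order; the audit counts
#' report removals in the cascade order listed above.
#'
#' @param ewas data.frame from [runEwas()].
#' @param annot probe annotation from [readProbeAnnotation()] (columns
#'   \code{probe_id}, \code{gene}, \code{tss200}, \code{prc2}).
#' @param fetalBeta \linkS4class{BetaMatrix} of fetal reference samples;
#'   probes absent from it, or with missing fetal values, are excluded
#'   and audited.
#' @param params a [selectionParams()] list.
#' @return list with \code{hyper} and \code{hypo}
#'   \linkS4class{ClockDefinition}s (possibly empty, with a warning) and
#'   an \code{audit} data.frame of per-filter removal counts.
#' @export
selectClockCpgs <- function(ewas, annot, fetalBeta,
                            params = selectionParams()) {
  stopifnot(inherits(params, "SelectionParams"), is(fetalBeta, "BetaMatrix"))
  tested <- ewas[is.na(ewas$flag), , drop = FALSE]
  ai <- match(tested$probe_id, annot$probe_id)
  gene <- annot$gene[ai]
  tss200ok <- !is.na(ai) & annot$tss200[ai] & !is.na(gene) &
    nzchar(trimws(gene)) & !grepl(";", gene, fixed = TRUE)
  prc2ok <- !is.na(ai) & annot$prc2[ai]
  F <- betaValues(fetalBeta)
  fi <- match(tested$probe_id, rownames(F))
  fetalKnown <- !is.na(fi) &
    !apply(is.na(F[ifelse(is.na(fi), 1L, fi), , drop = FALSE]), 1L, any)
  fetalMax <- fetalMin <- rep(NA_real_, nrow(tested))
  fetalMax[fetalKnown] <- apply(F[fi[fetalKnown], , drop = FALSE], 1L, max)
  fetalMin[fetalKnown] <- apply(F[fi[fetalKnown], , drop = FALSE], 1L, min)

  cascade <- function(set, filters) {
    keep <- rep(TRUE, nrow(tested))
    audit <- data.frame(set = character(0), filter = character(0),
                        removed = integer(0), remaining = integer(0))
    for (nm in names(filters)) {
      drop <- keep & !filters[[nm]]
      keep <- keep & filters[[nm]]
      audit <- rbind(audit, data.frame(set = set, filter = nm,
                                       removed = sum(drop),
                                       remaining = sum(keep)))
    }
    list(probes = tested$probe_id[keep], audit = audit)
  }

  hyperFilters <- list(fdr = tested$q < params$fdrThreshold,
                       direction = tested$coef > 0)
  hypoFilters <- list(fdr = tested$q < params$fdrThreshold,
                      direction = tested$coef < 0)
  if (params$requireTss200) {
    hyperFilters$tss200 <- tss200ok
    hypoFilters$tss200 <- tss200ok
  }
  hyperFilters$fetal_missing <- fetalKnown
  hypoFilters$fetal_missing <- fetalKnown
  hyperFilters$fetal_ground_state <- fetalKnown &
    fetalMax < params$fetalHyperBound
  hypoFilters$fetal_ground_state <- fetalKnown &
    fetalMin >= params$fetalHypoBound
  if (params$requirePrc2ForHyper) hyperFilters$prc2 <- prc2ok

  hy <- cascade("hyper", hyperFilters)
  ho <- cascade("hypo", hypoFilters)
  if (length(hy$probes) == 0L) warning("hyper clock set is empty")
  if (length(ho$probes) == 0L) warning("hypo clock set is empty")
  list(hyper = ClockDefinition("pcgtAge", "hyper", hy$probes,
                               params$fetalHyperBound),
       hypo = ClockDefinition("hypoAge", "hypo", ho$probes,
                              params$fetalHypoBound),
       audit = rbind(hy$audit, ho$audit))
}
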
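#' Estimate cell-type fractions by constrained least squares
#'
#' Reference-based deconvolution: for each bulk sample the cell-type
#' weights minimise the squared deviation between the observed betas and
#' the reference-weighted combination over the probes shared between the
#' sample and the reference, subject to nonnegativity and a sum-to-one
#' equality constraint (fractions are compositional). The quadratic
#' program is solved with the dual active-set method of
#' \code{quadprog::solve.QP}, which is deterministic for fixed input; for
#' a degenerate (rank-deficient, e.g. duplicated-column) reference a tiny
#' ridge (1e-10 on the diagonal) makes the program strictly convex, a
#' warning is raised, and the unique solution of the ridged program is
#' returned -- ties between equivalent columns are thereby split evenly.
#'
#' Probes in the bulk matrix that the reference lacks are ignored (the
#' reference defines the feature space). Missing betas at shared probes
#' are dropped from that sample's objective rather than imputed; a sample
#' missing more than half of the shared probes is not fit (all-NA weights,
#' with a warning).
#'
#' @param beta a \linkS4class{BetaMatrix} of bulk samples.
#' @param ref a \linkS4class{CellTypeReference}.
#' @return a \linkS4class{CellFractions} with per-sample RMS fit residuals.
#' @examples
#' refM <- matrix(runif(40), 20, 2,
#'                dimnames = list(paste0("cg", 1:20), c("B", "T")))
#' bulk <- BetaMatrix(cbind(s1 = 0.3 * refM[, 1] + 0.7 * refM[, 2]))
#' fractionWeights(estimateCellFractions(bulk, CellTypeReference(refM)))
#' @export
estimateCellFractions <- function(beta, ref) {
  stopifnot(is(beta, "BetaMatrix"), is(ref, "CellTypeReference"))
  R <- referenceProfiles(ref)
  shared <- intersect(rownames(beta), rownames(R))
  if (length(shared) == 0L)
    .err("epitoc_input_error",
         "no probes shared between beta matrix and reference")
  B <- betaValues(beta)[shared, , drop = FALSE]
  R <- R[shared, , drop = FALSE]
  k <- ncol(R)
  nS <- ncol(B)
  W <- matrix(NA_real_, nS, k, dimnames = list(colnames(B), colnames(R)))
  resid <- rep(NA_real_, nS)
  degenerate <- qr(R)$rank < k
  if (degenerate)
    warning("degenerate reference (rank-deficient profiles); ",
            "solution regularised by a 1e-10 ridge")
  skipped <- character(0)
  Amat <- cbind(rep(1, k), diag(k))  # sum-to-one (equality) then w >= 0
  bvec <- c(1, rep(0, k))
  for (j in seq_len(nS)) {
    obs <- !is.na(B[, j])
    if (mean(obs) < 0.5) {
      skipped <- c(skipped, colnames(B)[j])
      next
    }
    Rj <- R[obs, , drop = FALSE]
    bj <- B[obs, j]
    D <- crossprod(Rj)
    if (degenerate) D <- D + diag(1e-10, k)
    sol <- quadprog::solve.QP(D, crossprod(Rj, bj), Amat, bvec, meq = 1L)
    w <- pmax(sol$solution, 0)
    w <- w / sum(w)
    W[j, ] <- w
    resid[j] <- sqrt(mean((bj - drop(Rj %*% w))^2))
  }
  if (length(skipped) > 0L)
    warning("sample(s) with >50% missing shared probes not fit: ",
            paste(skipped, collapse = ", "))
  new("CellFractions", weights = W, fitResidual = resid)
}
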
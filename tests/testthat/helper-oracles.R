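# Independent brute-force oracles, kept free of the package's own code
# paths so that oracle-vs-implementation comparisons are two-route.

# Benjamini-Hochberg step-up by direct definition:
# q(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  qs <- vapply(seq_len(m),
               function(i) min(sorted[i:m] * m / (i:m)), numeric(1))
  q <- numeric(m)
  q[o] <- pmin(qs, 1)
  q
}

# AUC as the all-pairs Mann-Whitney probability, ties counting one half.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# OLS by explicit normal equations (coefficients, se, t), independent of
# lm's QR decomposition.
bruteOLS <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- unname(sqrt(diag(XtXi) * s2))
  b <- unname(drop(b))
  list(coef = b, se = se, t = b / se, df = df)
}

# Tiny named beta matrix builder.
toyBeta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (!is.null(probes)) rownames(m) <- probes
  if (!is.null(samples)) colnames(m) <- samples
  BetaMatrix(m)
}

# A synthetic EWAS result table for exercising the selection cascade
# without running regressions.
toyEwas <- function(probe_id, coef, q) {
  data.frame(probe_id = probe_id, coef = coef, se = NA_real_,
             t = NA_real_, p = q, q = q, n_obs = 100L,
             flag = NA_character_, stringsAsFactors = FALSE)
}
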
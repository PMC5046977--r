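## Validation statistics: age-adjusted association, one-tailed rank
## tests (unpaired/paired, optionally on age residuals), ROC/AUC with
## DeLong or bootstrap CI, greedy age matching, and a binomial sign test
## comparing per-type significance counts.

#' Age-adjusted linear association
#'
#' OLS of \code{y} on \code{x} and chronological age; the report concerns
#' the \code{x} coefficient, so an association with \code{y} driven
#' purely by age is absorbed by the age term. The one-sided p equals
#' half the two-sided p when the fitted coefficient has the hypothesised
#' sign and one minus half of it otherwise.
#'
#' @param y,x,age numeric vectors of equal length; incomplete triples are
#'   dropped (at least 4 required).
#' @param alternative hypothesised sign of the x effect
#'   (\code{"greater"} or \code{"less"}).
#' @return list with \code{coefficient}, \code{std_error}, \code{t},
#'   \code{p_two_sided}, \code{p_one_sided}, \code{r_squared}, \code{n}.
#' @export
ageAdjustedAssociation <- function(y, x, age,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- stats::complete.cases(y, x, age)
  y <- y[ok]; x <- x[ok]; age <- age[ok]
  if (length(y) < 4L)
    .err("epitoc_input_error", "need at least 4 complete triples")
  if (abs(stats::cor(x, age)) > 0.999)
    .err("epitoc_collinearity_error", "x is collinear with age")
  fit <- stats::lm(y ~ x + age)
  s <- summary(fit)$coefficients
  coefX <- s["x", "Estimate"]
  p2 <- s["x", "Pr(>|t|)"]
  signOk <- (alternative == "greater" && coefX > 0) ||
    (alternative == "less" && coefX < 0)
  list(coefficient = coefX, std_error = s["x", "Std. Error"],
       t = s["x", "t value"], p_two_sided = p2,
       p_one_sided = if (signOk) p2 / 2 else 1 - p2 / 2,
       r_squared = summary(fit)$r.squared, n = length(y))
}

#' One-tailed rank test, optionally paired and age-adjusted
#'
#' Unpaired groups are compared with the Wilcoxon rank-sum test, paired
#' groups with the Wilcoxon signed-rank test; \code{alternative} states
#' the direction hypothesised for \code{groupA} relative to
#' \code{groupB}. For small samples without ties the exact null
#' enumeration is used, otherwise the normal approximation with tie and
#' continuity correction (the \code{stats::wilcox.test} machinery).
#'
#' The age-adjusted variant (when \code{age} is supplied as the
#' concatenated ages of group A then group B) replaces both groups by
#' their residuals from a single pooled OLS of value on age before
#' ranking; the unadjusted p is also returned for transparency, since a
#' covariate-adjusted rank test has no single canonical definition.
#'
#' @param groupA,groupB numeric vectors (equal length if paired, matched
#'   by position).
#' @param paired compare as matched pairs (signed-rank test).
#' @param alternative \code{"greater"} or \code{"less"}: direction of
#'   group A relative to group B.
#' @param age optional vector \code{c(age_A, age_B)} for residual
#'   adjustment.
#' @return list with \code{p_value}, \code{statistic}, \code{method} and
#'   (when adjusted) \code{p_unadjusted}.
#' @examples
#' oneTailedWilcoxon(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
#' @export
oneTailedWilcoxon <- function(groupA, groupB, paired = FALSE,
                              alternative = c("greater", "less"),
                              age = NULL) {
  alternative <- match.arg(alternative)
  if (length(groupA) == 0L || length(groupB) == 0L)
    .err("epitoc_input_error", "both groups must be non-empty")
  if (paired && length(groupA) != length(groupB))
    .err("epitoc_input_error",
         "paired test requires equal group lengths (got %d and %d)",
         length(groupA), length(groupB))
  pUnadj <- NULL
  if (!is.null(age)) {
    if (length(age) != length(groupA) + length(groupB))
      .err("epitoc_input_error",
           "age must cover both groups (expected %d values, got %d)",
           length(groupA) + length(groupB), length(age))
    pUnadj <- suppressWarnings(
      stats::wilcox.test(groupA, groupB, paired = paired,
                         alternative = alternative))$p.value
    res <- stats::resid(stats::lm(c(groupA, groupB) ~ age))
    groupA <- res[seq_along(groupA)]
    groupB <- res[-seq_along(groupA)]
  }
  ht <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, paired = paired,
                       alternative = alternative))
  out <- list(p_value = ht$p.value, statistic = unname(ht$statistic),
              method = ht$method)
  if (!is.null(pUnadj)) out$p_unadjusted <- pUnadj
  out
}

#' ROC analysis with AUC confidence interval
#'
#' The area under the ROC curve equals the Mann-Whitney probability that
#' a random positive scores higher than a random negative, ties counting
#' one half. The 95\% confidence interval uses the DeLong method by
#' default (deterministic); \code{ci = "bootstrap"} uses 2000 stratified
#' resamples and is reproducible under a caller-set seed.
#'
#' @param scores numeric vector.
#' @param labels binary labels (0/1, logical, or a two-level factor;
#'   the higher level is the positive class).
#' @param ci \code{"delong"} or \code{"bootstrap"}.
#' @return list with \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{n_pos}, \code{n_neg}.
#' @export
rocAuc <- function(scores, labels, ci = c("delong", "bootstrap")) {
  ci <- match.arg(ci)
  labels <- as.integer(as.factor(labels)) - 1L
  if (length(unique(labels[!is.na(labels)])) != 2L)
    .err("epitoc_input_error", "both classes must be present")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  cint <- if (ci == "delong") pROC::ci.auc(r, method = "delong")
  else pROC::ci.auc(r, method = "bootstrap", boot.n = 2000L)
  list(auc = as.numeric(pROC::auc(r)), ci_low = cint[1L],
       ci_high = cint[3L], n_pos = sum(labels == 1L),
       n_neg = sum(labels == 0L))
}

#' Greedy age matching of two groups
#'
#' Pairs samples of two groups by nearest age without replacement:
#' candidate cross-group pairs within \code{tolerance} years are sorted
#' by absolute age gap (ties broken by the sample identifiers of group A
#' then group B) and accepted greedily while both members are unused.
#' Deterministic; an empty result is allowed.
#'
#' @param pheno sample sheet with \code{sample_id}, \code{age},
#'   \code{group}.
#' @param groupA,groupB group labels to match.
#' @param tolerance maximum age gap in years (default 5).
#' @return data.frame with \code{sample_a}, \code{sample_b},
#'   \code{age_a}, \code{age_b}, \code{gap}.
#' @export
ageMatchPairs <- function(pheno, groupA, groupB, tolerance = 5) {
  a <- pheno[pheno$group == groupA & !is.na(pheno$age), , drop = FALSE]
  b <- pheno[pheno$group == groupB & !is.na(pheno$age), , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(sample_a = character(0), sample_b = character(0),
                      age_a = numeric(0), age_b = numeric(0),
                      gap = numeric(0)))
  cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  cand$gap <- abs(a$age[cand$i] - b$age[cand$j])
  cand <- cand[cand$gap <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$gap, a$sample_id[cand$i], b$sample_id[cand$j]), ,
               drop = FALSE]
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!usedA[i] && !usedB[j]) {
      keep[r] <- TRUE
      usedA[i] <- TRUE
      usedB[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(sample_a = a$sample_id[cand$i], sample_b = b$sample_id[cand$j],
             age_a = a$age[cand$i], age_b = b$age[cand$j], gap = cand$gap,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare per-type significance counts of two methods
#'
#' Sign test on the discordant types: among categories where exactly one
#' of the two methods reaches significance, the count favouring method A
#' is referred to Binomial(n_discordant, 1/2), one-sided toward A. With
#' no discordant types the p-value is 1.
#'
#' @param sigA,sigB logical vectors of per-type significance calls,
#'   equal length.
#' @return list with \code{p_value}, \code{n_a_only}, \code{n_b_only}.
#' @examples
#' compareSignificanceCounts(rep(TRUE, 6), rep(FALSE, 6))$p_value
#' # 0.5^6 = 0.015625
#' @export
compareSignificanceCounts <- function(sigA, sigB) {
  stopifnot(length(sigA) == length(sigB), is.logical(sigA),
            is.logical(sigB))
  aOnly <- sum(sigA & !sigB)
  bOnly <- sum(!sigA & sigB)
  nDisc <- aOnly + bOnly
  p <- if (nDisc == 0L) 1 else
    stats::binom.test(aOnly, nDisc, p = 0.5,
                      alternative = "greater")$p.value
  list(p_value = p, n_a_only = aOnly, n_b_only = bOnly)
}
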
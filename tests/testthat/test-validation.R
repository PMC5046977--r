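test_that("age-adjusted association recovers a noiseless effect", {
  withr::with_seed(14, {
    x <- rnorm(30); age <- runif(30, 20, 90)
  })
  rep <- suppressWarnings(ageAdjustedAssociation(2 * x, x, age))
  expect_equal(rep$coefficient, 2, tolerance = 1e-10)
  expect_lt(rep$p_two_sided, 1e-12)
  expect_equal(rep$p_one_sided, rep$p_two_sided / 2)
})

test_that("two-covariate fit matches the normal-equations oracle", {
  y <- c(1.2, 0.7, 2.4, 1.9, 3.1)
  x <- c(0.2, -0.5, 1.0, 0.4, 1.5)
  age <- c(30, 45, 50, 62, 71)
  rep <- ageAdjustedAssociation(y, x, age)
  oracle <- bruteOLS(cbind(1, x, age), y)
  expect_equal(rep$coefficient, oracle$coef[2], tolerance = 1e-12)
  expect_equal(rep$t, oracle$t[2], tolerance = 1e-10)
})

test_that("x collinear with age is rejected", {
  age <- runif(20, 20, 90)
  expect_error(ageAdjustedAssociation(rnorm(20), age * 0.1, age),
               class = "epitoc_collinearity_error")
})

test_that("the x-coefficient p is null-uniform when only age matters", {
  ps <- vapply(1:200, function(s) {
    withr::with_seed(1000 + s, {
      age <- runif(40, 20, 90)
      y <- 0.01 * age + rnorm(40, 0, 0.1)
      x <- rnorm(40)
    })
    ageAdjustedAssociation(y, x, age)$p_two_sided
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("rank-sum enumeration gives the exact small-sample p", {
  # only 1 of choose(6,3) = 20 orderings puts {1,2,3} entirely below
  w <- oneTailedWilcoxon(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(w$p_value, 0.05)
  expect_gte(oneTailedWilcoxon(c(1, 2, 3), c(1, 2, 3),
                               alternative = "greater")$p_value, 0.5)
})

test_that("paired signed-rank enumeration: all-positive differences, n=5", {
  a <- c(2, 4, 6, 9, 12); b <- c(1, 2, 3, 4, 5)  # distinct positive diffs
  w <- oneTailedWilcoxon(a, b, paired = TRUE, alternative = "greater")
  expect_equal(w$p_value, 1 / 32)
  expect_error(oneTailedWilcoxon(a, b[1:3], paired = TRUE),
               class = "epitoc_input_error")
})

test_that("exact and approximate rank-sum paths agree at n = 20", {
  withr::with_seed(55, {
    a <- rnorm(10); b <- rnorm(10, 0.5)
  })
  pExact <- suppressWarnings(
    wilcox.test(a, b, alternative = "less", exact = TRUE))$p.value
  pApprox <- suppressWarnings(
    wilcox.test(a, b, alternative = "less", exact = FALSE,
                correct = TRUE))$p.value
  expect_lt(abs(pExact - pApprox), 0.02)
  expect_equal(oneTailedWilcoxon(a, b, alternative = "less")$p_value,
               pExact)
})

test_that("age adjustment residualizes before ranking and keeps both p", {
  withr::with_seed(66, {
    ageA <- runif(20, 40, 80); ageB <- runif(20, 20, 60)
    a <- 0.001 * ageA + rnorm(20, 0, 0.002)
    b <- 0.001 * ageB + rnorm(20, 0, 0.002)
  })
  plain <- oneTailedWilcoxon(a, b, alternative = "greater")
  adj <- oneTailedWilcoxon(a, b, alternative = "greater",
                           age = c(ageA, ageB))
  expect_equal(adj$p_unadjusted, plain$p_value)
  # the apparent group difference is an age artifact: adjustment weakens it
  expect_gt(adj$p_value, plain$p_value)
})

test_that("AUC equals the all-pairs Mann-Whitney probability", {
  expect_equal(rocAuc(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.875)
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12),
                      c(0, 0, 0, 1, 1, 1))$auc, 1)
  for (s in 1:10) {
    withr::with_seed(300 + s, {
      n <- sample(10:60, 1)
      sc <- round(rnorm(n), 1)  # rounding forces ties
      lab <- rbinom(n, 1, 0.5)
    })
    if (length(unique(lab)) < 2) next
    expect_equal(rocAuc(sc, lab)$auc, bruteAUC(sc, lab))
  }
  expect_error(rocAuc(1:5, rep(1, 5)), class = "epitoc_input_error")
})

test_that("null AUC stays near one half and the CI brackets the AUC", {
  # at n = 200 (about 100 per class) the null AUC has sd ~ 0.041; check
  # every draw within 3 sd of 1/2 and the 20-seed mean much closer still
  aucs <- vapply(1:20, function(s) {
    withr::with_seed(500 + s, {
      sc <- rnorm(200); lab <- rbinom(200, 1, 0.5)
    })
    r <- rocAuc(sc, lab)
    expect_lte(r$ci_low, r$auc)
    expect_gte(r$ci_high, r$auc)
    r$auc
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.125))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("bootstrap CI is reproducible under a set seed", {
  withr::with_seed(9, {
    sc <- rnorm(60); lab <- rbinom(60, 1, 0.5)
  })
  ci1 <- withr::with_seed(1, rocAuc(sc, lab, ci = "bootstrap"))
  ci2 <- withr::with_seed(1, rocAuc(sc, lab, ci = "bootstrap"))
  expect_equal(ci1$ci_low, ci2$ci_low)
  expect_equal(ci1$ci_high, ci2$ci_high)
})

test_that("greedy age matching follows gap-then-identifier order", {
  ph <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                   age = c(50, 60, 51, 59),
                   group = c("A", "A", "B", "B"))
  pr <- ageMatchPairs(ph, "A", "B", tolerance = 2)
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$age_b[match(c(50, 60), pr$age_a)], c(51, 59))

  expect_equal(nrow(ageMatchPairs(ph, "A", "B", tolerance = 0)), 0L)

  ph2 <- data.frame(sample_id = c("a1", "b1", "b2"),
                    age = c(50, 49, 51), group = c("A", "B", "B"))
  pr2 <- ageMatchPairs(ph2, "A", "B", tolerance = 5)
  expect_equal(nrow(pr2), 1L)
  expect_equal(pr2$sample_b, "b1")  # equal gap: smaller identifier wins
})

test_that("significance-count comparison is an exact binomial sign test", {
  expect_equal(compareSignificanceCounts(c(TRUE, FALSE),
                                         c(TRUE, FALSE))$p_value, 1)
  r <- compareSignificanceCounts(rep(TRUE, 6), rep(FALSE, 6))
  expect_equal(r$p_value, 0.015625)
  expect_equal(r$n_a_only, 6L)
  withr::with_seed(44, {
    for (i in 1:10) {
      sa <- runif(15) < 0.5; sb <- runif(15) < 0.5
      aOnly <- sum(sa & !sb); nd <- aOnly + sum(!sa & sb)
      oracle <- if (nd == 0) 1 else
        sum(dbinom(aOnly:nd, nd, 0.5))  # upper-tail CDF enumeration
      expect_equal(compareSignificanceCounts(sa, sb)$p_value, oracle)
    }
  })
})
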
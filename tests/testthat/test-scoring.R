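test_that("the clock score is the mean beta over clock CpGs", {
  clk <- ClockDefinition("toy", "hyper", paste0("cg", 1:3))
  m <- cbind(s1 = c(0.5, 0.5, 0.5), s2 = c(0.1, 0.2, 0.6))
  rownames(m) <- paste0("cg", 1:3)
  st <- computeClockScore(BetaMatrix(m), clk)
  expect_equal(st$score, c(0.5, 0.3))
  expect_equal(st$coverage, c(1, 1))
})

test_that("coverage below the threshold flags the sample", {
  clk <- ClockDefinition("toy", "hyper", paste0("cg", 1:3))
  m <- cbind(s1 = c(0.1, NA, 0.5))
  rownames(m) <- paste0("cg", 1:3)
  st <- computeClockScore(BetaMatrix(m), clk, minCoverage = 0.5)
  expect_equal(st$score, 0.3)
  expect_equal(st$coverage, 2 / 3)
  expect_false(st$flagged)

  st95 <- computeClockScore(BetaMatrix(m), clk, minCoverage = 0.95)
  expect_true(st95$flagged)
  expect_true(is.na(st95$score))

  off <- ClockDefinition("other", "hyper", c("cgX", "cgY"))
  expect_error(computeClockScore(BetaMatrix(m), off),
               class = "epitoc_input_error")
})

test_that("scores are invariant to probe and sample permutations", {
  withr::with_seed(31, {
    m <- matrix(runif(60), 10, 6,
                dimnames = list(paste0("cg", 1:10), paste0("s", 1:6)))
  })
  clk <- ClockDefinition("toy", "hyper", paste0("cg", c(2, 5, 9)))
  st <- computeClockScore(BetaMatrix(m), clk)
  perm <- BetaMatrix(m[sample(10), sample(6)])
  st2 <- computeClockScore(perm, clk)
  expect_equal(st2$score[match(st$sample_id, st2$sample_id)], st$score)
})

test_that("calibration recovers a noiseless line exactly", {
  ages <- 20:80
  st <- data.frame(sample_id = paste0("s", ages),
                   score = 0.05 + 0.0003 * ages)
  ph <- data.frame(sample_id = paste0("s", ages), age = ages)
  cal <- suppressWarnings(calibrateClock(st, ph, tissue = "blood"))
  expect_equal(alphaPrime(cal), 0.05, tolerance = 1e-12)
  expect_equal(gammaPrime(cal), 0.0003, tolerance = 1e-12)
  expect_equal(cal@rSquared, 1, tolerance = 1e-12)
})

test_that("calibration matches closed-form least squares on 3 points", {
  ages <- c(30, 50, 70)
  sc <- c(0.06, 0.08, 0.09)
  cal <- calibrateClock(data.frame(sample_id = 1:3, score = sc),
                        data.frame(sample_id = 1:3, age = ages))
  oracle <- bruteOLS(cbind(1, ages), sc)
  expect_equal(alphaPrime(cal), oracle$coef[1], tolerance = 1e-12)
  expect_equal(gammaPrime(cal), oracle$coef[2], tolerance = 1e-12)

  same <- data.frame(sample_id = 1:3, age = rep(50, 3))
  expect_error(calibrateClock(data.frame(sample_id = 1:3, score = sc),
                              same),
               class = "epitoc_input_error")
})

test_that("noisy calibration recovers the generating line within 3 SE", {
  for (s in 1:5) {
    withr::with_seed(400 + s, {
      ages <- runif(150, 20, 100)
      sc <- 0.05 + 4e-4 * ages + rnorm(150, 0, 0.005)
    })
    cal <- calibrateClock(data.frame(sample_id = seq_along(ages),
                                     score = sc),
                          data.frame(sample_id = seq_along(ages),
                                     age = ages))
    se <- summary(lm(sc ~ ages))$coefficients[, "Std. Error"]
    expect_lt(abs(alphaPrime(cal) - 0.05), 3 * se[1])
    expect_lt(abs(gammaPrime(cal) - 4e-4), 3 * se[2])
  }
})

test_that("the shipped calibration registry carries the published constants", {
  blood <- shippedCalibrations("whole-blood")
  expect_equal(alphaPrime(blood), 0.052)
  expect_equal(gammaPrime(blood), 0.000345)
  breast <- shippedCalibrations("breast")
  expect_equal(c(alphaPrime(breast), gammaPrime(breast)),
               c(0.053, 0.000165))
  lung <- shippedCalibrations("lung")
  expect_equal(c(alphaPrime(lung), gammaPrime(lung), intrinsicRate(lung)),
               c(0.021, 0.000588, 0.07))
  expect_error(shippedCalibrations("kidney"),
               class = "epitoc_input_error")
})

test_that("division estimates invert the calibrated score model", {
  lung <- shippedCalibrations("lung")
  expect_equal(as.numeric(estimateTnsc(alphaPrime(lung), lung)), 0)
  # printed lung parameters reproduce the normal-lung estimate of 8.45
  expect_equal(as.numeric(estimateTnsc(0.0920, lung)), 8.45,
               tolerance = 0.01 / 8.45)
  # linear in IR
  cal1 <- Calibration("t", 0.02, 4e-4, ir = 1)
  cal2 <- Calibration("t", 0.02, 4e-4, ir = 2)
  expect_equal(as.numeric(estimateTnsc(0.05, cal2)),
               2 * as.numeric(estimateTnsc(0.05, cal1)))
  # negative estimates are flagged, not clipped
  expect_warning(tn <- estimateTnsc(0.01, cal1), "negative")
  expect_lt(as.numeric(tn), 0)
  expect_true(attr(tn, "negative"))
  # no IR: directed to the ratio
  expect_error(estimateTnsc(0.06, shippedCalibrations("whole-blood")),
               class = "epitoc_input_error")
})

test_that("the division ratio needs no IR and matches the TNSC quotient", {
  cal <- Calibration("t", 0.02, 4e-4, ir = 5)
  expect_equal(tnscRatio(0.09, 0.055, cal), 2)
  expect_equal(tnscRatio(0.07, 0.07, cal), 1)
  withr::with_seed(77, {
    for (i in 1:20) {
      s1 <- runif(1, 0.03, 0.2); s2 <- runif(1, 0.03, 0.2)
      expect_equal(tnscRatio(s1, s2, cal),
                   as.numeric(estimateTnsc(s1, cal)) /
                     as.numeric(estimateTnsc(s2, cal)),
                   tolerance = 1e-12)
    }
  })
  expect_error(tnscRatio(0.09, 0.02, cal), class = "epitoc_input_error")
})

test_that("forward score model round-trips through estimateTnsc", {
  withr::with_seed(12, {
    for (i in 1:50) {
      cal <- Calibration("t", runif(1, 0, 0.2), runif(1, 1e-5, 1e-3),
                         ir = runif(1, 0.05, 80))
      x <- runif(1, 0, 5000)
      score <- alphaPrime(cal) + gammaPrime(cal) * x / intrinsicRate(cal)
      expect_equal(as.numeric(estimateTnsc(score, cal)), x,
                   tolerance = 1e-10)
    }
  })
})

test_that("excess divisions follow the printed ratio arithmetic", {
  expect_equal(excessDivisions(22, 8, 0.005, 1e9), 1.375e7)
  expect_equal(round(excessDivisions(22, 8, 0.005, 1e9) / 1e6), 14)
  expect_equal(excessDivisions(7, 7, 0.005, 1e9), 0.005 * 1e9)
  expect_equal(excessDivisions(10, 5, 0.01, 1e6), 20000)
  expect_error(excessDivisions(10, 0, 0.01, 1e6),
               class = "epitoc_input_error")
})
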
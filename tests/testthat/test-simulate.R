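# The generative replication-error simulator.

smallConfig <- function(seed = 1, ...) {
  cfg <- defaultConfig("healthy-blood", seed = seed)
  cfg@nSamples <- 60L
  cfg@nProbes <- 400L
  cfg@nClockHyper <- 20L
  cfg@nClockHypo <- 20L
  cfg@nLineageProbes <- 60L
  mods <- list(...)
  for (nm in names(mods)) slot(cfg, nm) <- mods[[nm]]
  validObject(cfg)
  cfg
}

test_that("scenario configs are fully documented and deterministic", {
  expect_identical(defaultConfig("healthy-blood", seed = 3),
                   defaultConfig("healthy-blood", seed = 3))
  hb <- defaultConfig("healthy-blood")
  expect_equal(hb@nSamples, 500L)
  expect_equal(hb@ageRange, c(20, 100))
  expect_true(all(hb@groupSpec$prop == 1))
  tv <- defaultConfig("tumor-vs-normal")
  expect_true(tv@paired)
  expect_true(is.na(tv@groupSpec$expMeanlog[tv@groupSpec$group == "normal"]))
  expect_false(is.na(tv@groupSpec$expMeanlog[tv@groupSpec$group == "tumor"]))
  err <- expect_error(defaultConfig("no-such-design"),
                      class = "epitoc_input_error")
  expect_match(conditionMessage(err), "healthy-blood")
})

test_that("identical config and seed give a bit-identical cohort", {
  c1 <- simulateCohort(smallConfig(seed = 5))
  c2 <- simulateCohort(smallConfig(seed = 5))
  expect_identical(betaValues(c1@beta), betaValues(c2@beta))
  expect_identical(c1@pheno, c2@pheno)
  expect_identical(c1@expr, c2@expr)
  c3 <- simulateCohort(smallConfig(seed = 6))
  expect_false(identical(betaValues(c1@beta), betaValues(c3@beta)))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulateCohort(smallConfig(seed = 9)))
  expect_identical(runif(3), before)
})

test_that("zero drift and no noise leave clock betas at their ground state", {
  co <- simulateCohort(smallConfig(seed = 2, xiRange = c(0, 0),
                                   noisePrecision = 0))
  clockIdx <- co@truthProbes$role %in% c("hyper", "hypo")
  B <- betaValues(co@beta)[clockIdx, ]
  expect_equal(B, matrix(co@truthProbes$groundState[clockIdx],
                         nrow(B), ncol(B), dimnames = dimnames(B)))
})

test_that("noise-free single-tissue score equals the analytic clock line", {
  co <- simulateCohort(smallConfig(seed = 4, noisePrecision = 0))
  hyper <- co@truthProbes[co@truthProbes$role == "hyper", ]
  clk <- ClockDefinition("true", "hyper", hyper$probe_id)
  st <- computeClockScore(co@beta, clk)
  ir <- co@config@tissues$ir[1]
  predicted <- mean(hyper$groundState) +
    mean(hyper$xi) * ir * co@pheno$age[match(st$sample_id,
                                             co@pheno$sample_id)]
  expect_equal(st$score, predicted, tolerance = 1e-12)
})

test_that("with noise off, scores are monotone in TNSC in the model direction", {
  co <- simulateCohort(smallConfig(seed = 7, noisePrecision = 0))
  o <- order(co@truthSamples$tnsc)
  hyper <- ClockDefinition("h", "hyper",
                           co@truthProbes$probe_id[co@truthProbes$role ==
                                                     "hyper"])
  hypo <- ClockDefinition("l", "hypo",
                          co@truthProbes$probe_id[co@truthProbes$role ==
                                                    "hypo"])
  sHyper <- computeClockScore(co@beta, hyper)$score[o]
  sHypo <- computeClockScore(co@beta, hypo)$score[o]
  expect_true(all(diff(sHyper) >= -1e-12))
  expect_true(all(diff(sHypo) <= 1e-12))
})

test_that("generating truth satisfies the model identities", {
  co <- simulateCohort(defaultConfig("tumor-vs-normal", seed = 8))
  ts <- co@truthSamples
  expect_identical(ts$tnsc,
                   ts$age * (ts$ir + ts$exposure * co@config@exposureRate))
  # paired design: tumor and normal members share age and pair id
  byPair <- split(ts, ts$pair_id)
  expect_true(all(vapply(byPair, function(d)
    nrow(d) == 2 && d$age[1] == d$age[2], logical(1))))
  # fetal ground states respect the construction bounds
  F <- betaValues(co@fetal)
  hyperIdx <- co@truthProbes$role == "hyper"
  hypoIdx <- co@truthProbes$role == "hypo"
  expect_true(all(F[hyperIdx, ] < 0.2))
  expect_true(all(F[hypoIdx, ] >= 0.3))
})

test_that("age-trending composition confounds an unadjusted EWAS", {
  cfg <- smallConfig(seed = 10, nClockHyper = 0L, nClockHypo = 0L,
                     nSamples = 150L)
  co <- simulateCohort(cfg)
  ewNo <- runEwas(co@beta, co@pheno)
  ewYes <- runEwas(co@beta, co@pheno, cellFractions = co@trueFractions)
  expect_gt(sum(ewNo$q < 0.05, na.rm = TRUE),
            sum(ewYes$q < 0.05, na.rm = TRUE))
})

test_that("calibrating on true-clock scores recovers the model slope", {
  for (s in 1:3) {
    co <- simulateCohort(defaultConfig("healthy-blood", seed = 20 + s))
    hyper <- co@truthProbes[co@truthProbes$role == "hyper", ]
    st <- computeClockScore(co@beta,
                            ClockDefinition("true", "hyper",
                                            hyper$probe_id))
    cal <- calibrateClock(st, co@pheno, tissue = "blood")
    expected <- mean(hyper$xi) * co@config@tissues$ir[1]
    expect_lt(abs(gammaPrime(cal) - expected) / expected, 0.1)
  }
})

test_that("drift saturation is reported as a clipping warning", {
  cfg <- smallConfig(seed = 3, xiRange = c(5e-3, 6e-3))
  expect_warning(simulateCohort(cfg), "clipped")
})

test_that("a cohort writes out in the package dialects and reads back", {
  co <- simulateCohort(smallConfig(seed = 12))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readBetaMatrix(file.path(dir, "beta.tsv"))
  expect_equal(betaValues(back), betaValues(co@beta), tolerance = 1e-12)
  ph <- readSampleSheet(file.path(dir, "pheno.csv"))
  expect_equal(ph$age, co@pheno$age, tolerance = 1e-12)
  an <- readProbeAnnotation(file.path(dir, "annot.tsv"))
  expect_identical(an$tss200, co@annot$tss200)
  ref <- readCellTypeReference(file.path(dir, "reference.tsv"))
  expect_equal(referenceProfiles(ref),
               referenceProfiles(co@reference), tolerance = 1e-12)
})
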
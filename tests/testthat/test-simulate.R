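test_that("generators are deterministic in the seed", {
  a <- simulateCtExperiment(nGenes = 8, seed = 77)
  b <- simulateCtExperiment(nGenes = 8, seed = 77)
  expect_identical(ctValues(a), ctValues(b))
  expect_identical(S4Vectors::metadata(a)$truth, S4Vectors::metadata(b)$truth)
  c <- simulateCtExperiment(nGenes = 8, seed = 78)
  expect_false(identical(ctValues(a), ctValues(c)))

  e1 <- simulateExpressionMatrix(nGenes = 30, seed = 5)
  e2 <- simulateExpressionMatrix(nGenes = 30, seed = 5)
  expect_identical(e1$rpkm, e2$rpkm)
})

test_that("zero noise inverts exactly through every analysis stage", {
  # flat genes, no noise: constant Ct rows, whisker D and CV all zero
  cte <- simulateCtExperiment(nGenes = 6, fracStable = 1, bioNoiseSd = 0,
                              techNoiseSd = 0, seed = 1)
  expect_true(all(whiskerDValues(cte) == 0))
  sim <- simulateExpressionMatrix(nGenes = 10, fracStable = 1, cvTarget = 1e-9,
                                  seed = 2)
  expect_true(all(apply(sim$rpkm, 1, coefficientOfVariation) < 1e-6))

  # dilution series: fitted efficiency equals the planted one
  for (e in c(1, 0.9, 1.05)) {
    ds <- simulateDilutionSeries(trueEfficiency = e, noiseSd = 0)
    expect_equal(efficiency(fitStandardCurve(ds$dilutionLog10, ds$ct)), e,
                 tolerance = 1e-10)
  }

  # target profile: folds recovered exactly
  cte2 <- simulateTargetProfile(noiseSd = 0)
  nf <- normalizationFactor(cte2, c("RG1", "RG2"))
  quant <- relativeQuantification(ctValues(collapseTechReps(cte2))["TARGET", ],
                                  nf, calibrator = which(stages(cte2) == "IM"),
                                  stage = as.character(stages(cte2)))
  sm <- stageSummary(quant)
  expect_equal(sm$meanFold[match(c("IM", "MG", "B", "MR"), sm$stage)],
               c(1, 32, 16, 4), tolerance = 1e-10)
})

test_that("planted drift shows up in the whisker D and stable CV hits its target", {
  # amplitude >= 1.5 cycles leaves a whisker D of at least ~1.5 sans noise
  cte <- simulateCtExperiment(nGenes = 40, fracStable = 0.5, bioNoiseSd = 0,
                              techNoiseSd = 0, stageAmplitude = 1.5, seed = 31)
  truth <- S4Vectors::metadata(cte)$truth
  unstable <- setdiff(rownames(cte), truth$stableGenes)
  expect_true(all(whiskerDValues(cte)[unstable] >= 1.5 - 1e-9))
  expect_true(all(whiskerDValues(cte)[truth$stableGenes] == 0))

  # Monte-Carlo: mean realized CV of stable genes near the target
  cvs <- unlist(lapply(1:5, function(s) {
    sim <- simulateExpressionMatrix(nGenes = 200, fracStable = 1,
                                    cvTarget = 0.2, seed = s)
    apply(sim$rpkm, 1, coefficientOfVariation)
  }))
  expect_lt(abs(mean(cvs) - 0.2), 0.05)
})

test_that("dilution-series fits are unbiased under noise", {
  fits <- vapply(1:100, function(s) {
    ds <- simulateDilutionSeries(trueEfficiency = 1, noiseSd = 0.1, seed = s)
    efficiency(fitStandardCurve(ds$dilutionLog10, ds$ct))
  }, numeric(1))
  expect_lt(abs(mean(fits) - 1), 0.02)
})

test_that("target-profile recovery stays within 10% under moderate noise", {
  err <- vapply(1:50, function(s) {
    cte <- simulateTargetProfile(noiseSd = 0.1, seed = s)
    nf <- normalizationFactor(cte, c("RG1", "RG2"))
    quant <- relativeQuantification(ctValues(collapseTechReps(cte))["TARGET", ],
                                    nf, which(stages(cte) == "IM"),
                                    stage = as.character(stages(cte)))
    sm <- stageSummary(quant)
    truthFold <- 2^S4Vectors::metadata(cte)$truth$profileLog2[sm$stage]
    mean(abs(sm$meanFold / truthFold - 1))
  }, numeric(1))
  # error propagation: per-stage fold error ~ noiseSd * sqrt(3/2) / sqrt(3)
  # log2 units (~5%), plus a shared calibrator term; 10% bounds the average
  expect_lt(mean(err), 0.10)
})
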
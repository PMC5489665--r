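test_that("standard curves recover slope, efficiency and R-squared", {
  x <- c(0, -1, -2, -3)
  sc <- fitStandardCurve(x, 30 - log2(10) * x)   # perfect doubling
  expect_equal(sc@slope, -log2(10), tolerance = 1e-10)   # -3.321928
  expect_equal(efficiency(sc), 1, tolerance = 1e-10)
  expect_equal(sc@rSquared, 1, tolerance = 1e-12)

  # slope -3.59 -> E = 10^(1/3.59) - 1, about 0.899 (fails the 0.9-1.1 window)
  sc2 <- fitStandardCurve(x, 30 - 3.59 * x)
  expect_equal(efficiency(sc2), 10^(1 / 3.59) - 1, tolerance = 1e-12)
  expect_lt(efficiency(sc2), 0.9)

  expect_error(fitStandardCurve(c(0, -1), c(30, 33)),
               class = "stableRG_too_few_values")
  expect_error(fitStandardCurve(rep(0, 4), c(30, 31, 32, 33)),
               class = "stableRG_degenerate_design")
})

test_that("normalization factors are geometric means of reference quantities", {
  ct <- rbind(rgA = c(20, 21), rgB = c(22, 23))
  # quantities: rgA (1, 0.5); rgB (1, 0.5); NF = (1, 0.5)
  nf <- normalizationFactor(ct, c("rgA", "rgB"))
  expect_equal(unname(nf), c(1, 0.5))
  # hand-computed sqrt of products for quantities (1, 0.5) and (0.25, 0.125)
  q <- rbind(a = c(1, 0.5), b = c(0.25, 0.125))
  expect_equal(unname(sqrt(q[1, ] * q[2, ])), c(0.5, 0.25))
  # single gene: NF is that gene's quantity vector
  expect_equal(unname(normalizationFactor(ct, "rgA")), c(1, 0.5))
  # duplicating a gene leaves sample-to-sample NF ratios unchanged
  ct3 <- rbind(ct, rgA2 = ct["rgA", ])
  nf3 <- normalizationFactor(ct3, c("rgA", "rgA2", "rgB"))
  expect_equal(nf3[1] / nf3[2], nf[1] / nf[2], tolerance = 1e-12)
  expect_error(normalizationFactor(ct, "missing"), class = "stableRG_unknown_gene")
})

test_that("2^-ddCt fold changes behave per the textbook formula", {
  # constant target over constant NF: all folds 1
  f <- foldChanges(relativeQuantification(
    setNames(rep(25, 4), paste0("s", 1:4)), rep(1, 4), "s1"))
  expect_equal(unname(f), rep(1, 4))

  # 5-cycle drop at MG vs IM with flat NF: fold 32
  ct <- setNames(c(25, 20), c("IM_1", "MG_1"))
  f2 <- foldChanges(relativeQuantification(ct, c(1, 1), "IM_1"))
  expect_equal(unname(f2), c(1, 32))

  # target tracking NF exactly cancels
  nf <- c(1, 0.3, 2, 0.9)
  ct3 <- setNames(25 - log2(nf), paste0("s", 1:4))
  f3 <- foldChanges(relativeQuantification(ct3, nf, "s1"))
  expect_equal(unname(f3), rep(1, 4), tolerance = 1e-12)

  # with A = 2 and one reference gene, equals 2^-[(dCt)_s - (dCt)_cal]
  set.seed(6)
  tCt <- setNames(rnorm(6, 26, 1), paste0("s", 1:6))
  rCt <- matrix(rnorm(6, 21, 0.5), 1, dimnames = list("rg", paste0("s", 1:6)))
  nf1 <- normalizationFactor(rCt, "rg")
  got <- foldChanges(relativeQuantification(tCt, nf1, "s1"))
  dct <- tCt - rCt[1, ]
  expect_equal(unname(got), unname(2^-(dct - dct[["s1"]])), tolerance = 1e-12)

  expect_error(relativeQuantification(tCt, nf1, character(0)),
               class = "stableRG_empty_calibrator")
})

test_that("reference-gene Ct shifts cancel in the calibrator ratio", {
  set.seed(12)
  stage <- rep(c("IM", "MG", "B"), each = 2)
  samp <- paste0(stage, "_", rep(1:2, 3))
  tCt <- setNames(rnorm(6, 26, 1), samp)
  rg <- matrix(rnorm(12, 22, 0.3), 2, 6,
               dimnames = list(c("r1", "r2"), samp))
  base <- relativeQuantification(tCt, normalizationFactor(rg, c("r1", "r2")),
                                 samp[stage == "IM"], stage = stage)
  shifted <- relativeQuantification(tCt, normalizationFactor(rg + 1.8, c("r1", "r2")),
                                    samp[stage == "IM"], stage = stage)
  expect_equal(foldChanges(shifted), foldChanges(base), tolerance = 1e-12)
  # calibrator geometric mean is 1 by construction
  expect_equal(geomMean(foldChanges(base)[stage == "IM"]), 1, tolerance = 1e-12)
  expect_equal(stageSummary(base)$stage, c("IM", "MG", "B"))
})

test_that("trait correlation is Pearson's r with guarded degenerate inputs", {
  expect_equal(traitCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(traitCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
  # expression series against a ripening trait series peaking at breaker
  x <- c(1, 30, 20, 6)
  y <- c(2, 9, 11.84, 8)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(traitCorrelation(x, y), num / den)
  expect_error(traitCorrelation(c(1, 1, 1), c(1, 2, 3)),
               class = "stableRG_zero_variance")
  expect_error(traitCorrelation(c(1, 2), c(1, 2)),
               class = "stableRG_too_few_values")
})
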
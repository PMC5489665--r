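test_that("Ct-to-quantity anchors each gene at its minimum Ct", {
  expect_equal(unname(ctToQuantity(matrix(c(20, 21, 23), 1))[1, ]),
               c(1, 0.5, 0.125))
  expect_true(all(ctToQuantity(matrix(25, 2, 4)) == 1))
  # per-gene amplification factor 1 + E
  q <- ctToQuantity(matrix(c(20, 21), 1), ampFactor = 1 + 1.05)
  expect_equal(unname(q[1, 2]), 1 / 2.05)
  expect_error(ctToQuantity(matrix(c(20, NA), 1)), class = "stableRG_missing_ct")
  expect_error(ctToQuantity(matrix(20, 1, 2), ampFactor = 1),
               class = "stableRG_bad_amp_factor")
})

test_that("pairwise variation is the sd of the log2 ratio, symmetric, zero for proportional genes", {
  qj <- ctToQuantity(matrix(c(20, 21, 22, 23), 1))[1, ]
  qk <- ctToQuantity(matrix(c(20, 20, 20, 20), 1))[1, ]
  expect_equal(pairwiseVariation(qj, qk), sd(c(0, 1, 2, 3)))  # 1.2910
  expect_equal(pairwiseVariation(qj, qk), pairwiseVariation(qk, qj))
  expect_equal(pairwiseVariation(qj, 0.37 * qj), 0)
  expect_error(pairwiseVariation(qj, qk[1:3]), class = "stableRG_length_mismatch")
})

test_that("the 3-gene worked example yields the hand-derived M values and ranking", {
  ct <- rbind(G1 = c(20, 21, 22, 23),
              G2 = c(25, 26, 27, 28),
              G3 = c(20, 20, 20, 20))
  q <- ctToQuantity(ct)
  v <- sd(c(0, 1, 2, 3))                        # 1.290994
  expect_equal(geNormM(q), c(G1 = v / 2, G2 = v / 2, G3 = v))
  res <- geNormRank(q)
  expect_identical(res@exclusionOrder, "G3")
  expect_identical(finalPair(res), c("G1", "G2"))
  expect_equal(unname(mValues(res)[c("G1", "G2")]), c(0, 0))  # mutual V
  expect_equal(unname(mValues(res)["G3"]), v)
})

test_that("geNorm matches the brute-force oracle on random matrices", {
  maxDiffM <- 0
  maxDiffV <- 0
  for (seed in 1:25) {
    ct <- randomCtMatrix(5, 8, seed)
    q <- ctToQuantity(ct)
    maxDiffM <- max(maxDiffM, abs(geNormM(q) - oracleGeNormM(q)))
    res <- geNormRank(q)
    maxDiffV <- max(maxDiffV, abs(vCurve(res) - oracleVCurve(q, res@ranking)))
  }
  expect_lt(maxDiffM, 1e-12)
  expect_lt(maxDiffV, 1e-12)
})

test_that("duplicated genes share M and exact ties break lexicographically", {
  ct <- randomCtMatrix(4, 6, 99)
  ct <- rbind(ct, dupA = ct["g01", ], dupB = ct["g01", ])
  q <- ctToQuantity(ct)
  M <- geNormM(q)
  expect_equal(unname(M["dupA"]), unname(M["dupB"]))
  # three copies of one profile: the duplicates tie at M = 0 in the final
  # steps; the lexicographically smaller ids win the final-pair spots
  flat <- matrix(rep(c(20, 21, 22, 23), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("b", "a", "c"), NULL))
  other <- matrix(c(25, 25, 25, 25), 1, dimnames = list("z", NULL))
  res <- geNormRank(ctToQuantity(rbind(flat, other)))
  expect_identical(finalPair(res), c("a", "b"))
  expect_identical(res@exclusionOrder, c("z", "c"))
})

test_that("geNorm is invariant to global per-sample shifts and per-gene shifts", {
  ct <- randomCtMatrix(6, 8, 7)
  shift <- runif(8, -2, 2)
  shifted <- sweep(ct, 2, shift, "+")
  resA <- geNormRank(ctToQuantity(ct))
  resB <- geNormRank(ctToQuantity(shifted))
  expect_equal(mValues(resB), mValues(resA), tolerance = 1e-10)
  expect_identical(resB@ranking, resA@ranking)
  expect_equal(vCurve(resB), vCurve(resA), tolerance = 1e-10)

  # shifting one gene's Ct by a constant multiplies its quantities by a
  # constant and leaves its M unchanged
  ct2 <- ct
  ct2["g03", ] <- ct2["g03", ] + 3.7
  expect_equal(geNormM(ctToQuantity(ct2))["g03"],
               geNormM(ctToQuantity(ct))["g03"], tolerance = 1e-12)
})

test_that("the V curve is zero for identical genes and respects the threshold rule", {
  q <- matrix(rep(ctToQuantity(matrix(c(20, 21, 22), 1)), each = 4), 4,
              dimnames = list(letters[1:4], NULL), byrow = FALSE)
  v <- geNormVCurve(q, ranking = letters[1:4])
  expect_equal(unname(v), c(0, 0))

  expect_identical(minimalRGCount(c(`V2/3` = 0.05), 0.15), list(n = 2L, met = TRUE))
  expect_identical(minimalRGCount(c(0.3, 0.2, 0.1), 0.15), list(n = 4L, met = TRUE))
  expect_warning(res <- minimalRGCount(c(0.3, 0.2, 0.18), 0.15), "suffice")
  expect_identical(res, list(n = 4L, met = FALSE))
})

test_that("geNorm on a CtExperiment collapses technical replicates by default", {
  cte <- simulateCtExperiment(nGenes = 6, fracStable = 0.5, seed = 13)
  res <- geNorm(cte)
  manual <- geNormRank(ctToQuantity(collapseTechReps(cte)))
  expect_equal(mValues(res), mValues(manual))
})
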
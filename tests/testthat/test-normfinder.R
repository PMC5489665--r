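test_that("constant expression everywhere gives stability 0 for every gene", {
  ct <- matrix(rep(c(20, 23, 26, 21), times = 6), nrow = 4,
               dimnames = list(letters[1:4], NULL))
  groups <- rep(c("IM", "MG"), each = 3)
  res <- normFinder(ct, groups)
  expect_equal(unname(stabilityValues(res)), rep(0, 4))
})

test_that("NormFinder matches the loop-coded method-of-moments oracle", {
  maxDiff <- 0
  for (seed in 1:20) {
    set.seed(seed)
    ct <- matrix(rnorm(4 * 6, 24, 1), 4, 6,
                 dimnames = list(letters[1:4], NULL))
    groups <- rep(c("A", "B"), each = 3)
    maxDiff <- max(maxDiff, abs(stabilityValues(normFinder(ct, groups)) -
                                  oracleNormFinder(ct, groups)))
  }
  expect_lt(maxDiff, 1e-10)
  # and on a larger grouped design
  set.seed(101)
  ct <- matrix(rnorm(7 * 12, 25, 0.8), 7, 12,
               dimnames = list(sprintf("g%d", 1:7), NULL))
  groups <- rep(c("IM", "MG", "B", "MR"), each = 3)
  expect_equal(stabilityValues(normFinder(ct, groups)),
               oracleNormFinder(ct, groups), tolerance = 1e-12)
})

test_that("a gene with a planted group shift gets the largest stability value", {
  for (seed in 1:10) {
    set.seed(seed)
    ct <- matrix(rnorm(4 * 6, 24, 0.05), 4, 6,
                 dimnames = list(c("shifted", "s1", "s2", "s3"), NULL))
    groups <- rep(c("A", "B"), each = 3)
    ct["shifted", groups == "B"] <- ct["shifted", groups == "B"] + 1
    stab <- stabilityValues(normFinder(ct, groups))
    expect_identical(names(which.max(stab)), "shifted")
  }
})

test_that("NormFinder is invariant to per-sample shifts and gene relabeling", {
  set.seed(5)
  ct <- matrix(rnorm(5 * 12, 25, 0.5), 5, 12,
               dimnames = list(letters[1:5], NULL))
  groups <- rep(c("IM", "MG", "B", "MR"), each = 3)
  base <- stabilityValues(normFinder(ct, groups))
  shifted <- sweep(ct, 2, runif(12, -3, 3), "+")
  expect_equal(stabilityValues(normFinder(shifted, groups)), base,
               tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(stabilityValues(normFinder(ct[perm, ], groups)), base[perm],
               tolerance = 1e-12)
  expect_true(all(base >= 0))
})

test_that("single-group mode reduces to the corrected intra-group sd", {
  set.seed(8)
  ct <- matrix(rnorm(4 * 5, 24, 0.3), 4, 5, dimnames = list(letters[1:4], NULL))
  res <- normFinder(ct, rep("only", 5))
  expect_equal(stabilityValues(res), oracleNormFinder(ct, rep("only", 5)),
               tolerance = 1e-12)
  expect_equal(unname(stabilityValues(res)),
               unname(sqrt(res@intraGroupVariance[, 1])))
})

test_that("NormFinder enforces its design preconditions", {
  ct <- matrix(rnorm(2 * 6, 24, 1), 2, 6)
  expect_error(normFinder(ct, rep(c("A", "B"), each = 3)),
               class = "stableRG_too_few_genes")
  ct4 <- matrix(rnorm(4 * 3, 24, 1), 4, 3)
  expect_error(normFinder(ct4, c("A", "A", "B")), class = "stableRG_small_group")
  ct4[1, 1] <- NA
  expect_error(normFinder(ct4, rep("A", 3)), class = "stableRG_missing_ct")
})
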
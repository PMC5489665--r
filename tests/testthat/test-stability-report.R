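pepperRanks <- function() {
  f <- system.file("extdata", "pepper_rg_top12.tsv", package = "stableRG")
  read.delim(f, stringsAsFactors = FALSE)
}

pepperPrimers <- function() {
  f <- system.file("extdata", "pepper_primer_stats.tsv", package = "stableRG")
  read.delim(f, stringsAsFactors = FALSE)
}

test_that("whisker D is max minus min, translation-invariant and monotone", {
  expect_equal(whiskerD(c(20.1, 20.5, 21.0)), 0.9)
  expect_equal(whiskerD(rep(25, 6)), 0)
  expect_equal(whiskerD(c(21, NA, 23)), 2)
  expect_error(whiskerD(c(NA, NA)), class = "stableRG_all_missing")
  set.seed(4)
  x <- rnorm(10, 24)
  expect_equal(whiskerD(x + 5.5), whiskerD(x))
  for (extra in rnorm(5, 24, 2)) {
    expect_gte(whiskerD(c(x, extra)), whiskerD(x))
  }
})

test_that("boxplot summaries follow the inclusive interpolation convention", {
  expect_equal(unname(boxplotSummary(1:5)), c(1, 2, 3, 4, 5))
  expect_equal(unname(boxplotSummary(rep(7, 4))), rep(7, 5))
  # hand computation, type-7 interpolation at n = 4: q1 = x1 + 0.75 d,
  # q3 = x3 + 0.25 d for an equally spaced grid with step d = 0.4
  expect_equal(unname(boxplotSummary(c(20.0, 20.4, 20.8, 21.2))),
               c(20.0, 20.3, 20.6, 20.9, 21.2))
})

test_that("the two-method consensus rule reproduces the published pepper candidate sets", {
  rk <- pepperRanks()
  pr <- pepperPrimers()
  rankings <- list(whisker = rk$boxplot_gene,
                   geNorm = rk$genorm_gene,
                   normFinder = rk$normfinder_gene)
  eff <- setNames(pr$efficiency, pr$gene)
  mct <- setNames(pr$mean_ct, pr$gene)

  sel <- consensusSelect(rankings, kTop = 12, minMethods = 2,
                         meanCt = mct, effic = eff)
  published12 <- paste0("CaREV", c("05", "08", "31", "33", "09", "27",
                                   "21", "16", "28", "23", "26", "32"))
  expect_setequal(sel$candidates, published12)

  # the stated exclusions: mean Ct 28.4 > 28 and E = 0.86 < 0.9
  expect_false(sel$qcCt[["CaREV23"]])
  expect_false(sel$qcEff[["CaREV28"]])
  # applying the full printed efficiency table, the window also flags the
  # two candidates with E = 0.73 and 0.79 that the study retained
  expect_false(sel$qcEff[["CaREV31"]])
  expect_false(sel$qcEff[["CaREV33"]])
  expect_setequal(sel$selected,
                  setdiff(published12, paste0("CaREV", c("23", "28", "31", "33"))))

  # the study's own two exclusions leave exactly its published 10-gene set
  published10 <- paste0("CaREV", c("05", "08", "31", "33", "09", "27",
                                   "21", "16", "26", "32"))
  expect_setequal(setdiff(sel$candidates, c("CaREV23", "CaREV28")), published10)

  # min_methods = 1 is the union; identical rankings intersect to one top-k
  un <- consensusSelect(rankings, kTop = 12, minMethods = 1)
  expect_setequal(un$candidates, unique(unlist(lapply(rankings, head, 12))))
  same <- consensusSelect(list(a = rk$boxplot_gene, b = rk$boxplot_gene,
                               c = rk$boxplot_gene), kTop = 12, minMethods = 3)
  expect_setequal(same$candidates, head(rk$boxplot_gene, 12))
  expect_error(consensusSelect(rankings, kTop = 13),
               class = "stableRG_bad_threshold")
})

test_that("evaluateStability assembles consistent scores, ranks and QC evidence", {
  cte <- simulateCtExperiment(nGenes = 10, fracStable = 0.5, seed = 17)
  eff <- setNames(rep(1, 10), rownames(cte))
  eff[1] <- 0.7   # planted QC failure
  rep <- evaluateStability(cte, efficiency = eff)
  tb <- scoreTable(rep)
  expect_setequal(tb$whiskerRank, 1:10)
  expect_setequal(tb$geNormRank, 1:10)
  expect_setequal(tb$normFinderRank, 1:10)
  expect_equal(tb$gene[order(tb$geNormRank)], rankedGenes(rep@geNorm))
  collapsed <- collapseTechReps(cte)
  expect_equal(tb$whiskerD, unname(whiskerDValues(collapsed)))
  expect_equal(tb$meanCt, unname(rowMeans(ctValues(collapsed))))

  rep <- consensusSelect(rep, kTop = 6)
  tb <- scoreTable(rep)
  expect_false(tb$gene[1] %in% selectedGenes(rep))   # efficiency QC bites
  expect_true(all(tb$consensusCount[tb$selected] >= 2))
  expect_true(all(tb$selected == (tb$gene %in% selectedGenes(rep))))
})

test_that("stability scoring is invariant to gene-row order", {
  cte <- simulateCtExperiment(nGenes = 9, fracStable = 0.5, seed = 23)
  repA <- consensusSelect(evaluateStability(cte), kTop = 4)
  perm <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  repB <- consensusSelect(evaluateStability(cte[perm, ]), kTop = 4)
  tbA <- scoreTable(repA)
  tbB <- scoreTable(repB)
  ord <- match(tbA$gene, tbB$gene)
  expect_equal(tbB$geNormM[ord], tbA$geNormM)
  expect_equal(tbB$normFinderStability[ord], tbA$normFinderStability)
  expect_equal(tbB$whiskerRank[ord], tbA$whiskerRank)
  expect_setequal(selectedGenes(repB), selectedGenes(repA))
})
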
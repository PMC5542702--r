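test_that("signedFoldChange maps mean log2-ratios symmetrically", {
  expect_equal(signedFoldChange(c(1, 1)), 2)
  expect_equal(signedFoldChange(c(-1, -1)), -2)
  expect_equal(signedFoldChange(0), 1)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(4, sd = 2)
    expect_gte(abs(signedFoldChange(x)), 1)
    expect_equal(signedFoldChange(-x), -signedFoldChange(x),
                 tolerance = 1e-12)
  }
  expect_error(signedFoldChange(numeric(0)), "at least one")
})

test_that("callProbe applies the replication and rescue rules", {
  # all three contrasts pass -> significant, up
  r <- callProbe(c(31, 30, 10), c(0.028, 0.019, 0.008))
  expect_equal(r$status, "significant")
  expect_equal(r$direction, "up")
  # 2/3 pass with extreme expression in the passing contrasts -> rescued
  r2 <- callProbe(c(41, 53, 10), c(0.006, 0.004, 0.060))
  expect_equal(r2$status, "potential")
  expect_equal(r2$direction, "up")
  # no evidence
  expect_equal(callProbe(c(1, 1, 1), c(1, 1, 1))$status,
               "not_significant")
  # 2/3 pass but passing FCs below the rescue bound -> not rescued
  expect_equal(callProbe(c(5, 6, 1.5), c(0.01, 0.01, 0.2))$status,
               "not_significant")
  # sign-inconsistent passes are never promoted
  expect_equal(callProbe(c(25, -25, 30), c(0.01, 0.01, 0.01))$status,
               "not_significant")
  expect_equal(callProbe(c(25, 25, -1.1), c(0.01, 0.01, 0.9))$status,
               "potential")
  # mixed sign across all contrasts blocks a significant call
  expect_error(callProbe(c(2, NaN, 3), c(0.1, 0.1, 0.1)), "finite")
})

test_that("down-regulated probes are called with negative direction", {
  r <- callProbe(c(-31, -30, -10), c(0.028, 0.019, 0.008))
  expect_equal(r$status, "significant")
  expect_equal(r$direction, "down")
})

test_that("callProbe is monotone in evidence", {
  ranks <- c(not_significant = 1, potential = 2, significant = 3)
  set.seed(19)
  for (i in 1:200) {
    fc <- runif(3, 1, 60)
    p <- runif(3, 0.001, 0.2)
    before <- ranks[callProbe(fc, p)$status]
    j <- sample(3, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)      # stronger significance
    fc2 <- fc; fc2[j] <- fc[j] * (1 + runif(1))  # larger same-sign FC
    expect_gte(ranks[callProbe(fc, p2)$status], before)
    expect_gte(ranks[callProbe(fc2, p)$status], before)
  }
})

test_that("detectability filter removes exactly the flagged probes", {
  ce <- simulateExpression(expressionSimConfig(
    nProbes = 10, dropoutProb = 0, seed = 1))
  fl <- SummarizedExperiment::assay(ce, "flags")
  fl[3, 5] <- "absent"
  SummarizedExperiment::assay(ce, "flags") <- fl
  keep <- detectableProbes(ce)
  expect_equal(sum(!keep), 1)
  expect_false(keep[[3]])
  res <- callDifferentialExpression(ce)
  expect_equal(res$status[res$probe_id == names(keep)[3]], "filtered")
})

test_that("retained-probe count follows the binomial expectation", {
  ce <- simulateExpression(expressionSimConfig(
    nProbes = 10000, dropoutProb = 0.01, seed = 123))
  pKeep <- 0.99^12
  expected <- 10000 * pKeep
  observed <- sum(detectableProbes(ce))
  expect_lt(abs(observed - expected),
            3 * sqrt(10000 * pKeep * (1 - pKeep)))
})

test_that("the full caller recovers spiked probes and stays directional", {
  hits <- vapply(1:20, function(s) {
    ce <- makeSpikedExperiment(nProbes = 60, nSpiked = 10, lfc = 2,
                               sd = 0.25, seed = s)
    res <- callDifferentialExpression(ce)
    spiked <- res$probe_id %in%
      rownames(ce)[truthLabels(ce)$trueClass == "up"]
    mean(res$status[spiked] == "significant")
  }, 0)
  expect_gte(mean(hits), 0.95)
  # on all-positive data every non-filtered call is "up"
  ce <- makeSpikedExperiment(nProbes = 40, nSpiked = 40, lfc = 3,
                             sd = 0.2, seed = 5)
  res <- callDifferentialExpression(ce)
  expect_true(all(res$direction[res$status != "filtered"] == "up"))
})

test_that("caller output is sorted by combined p with metadata attached", {
  ce <- makeSpikedExperiment(seed = 3)
  res <- callDifferentialExpression(ce)
  keep <- res$status != "filtered"
  expect_false(is.unsorted(res$combinedP[keep]))
  md <- S4Vectors::metadata(res)
  expect_equal(md$nRetained, sum(keep))
  expect_equal(unname(md$expectedFalsePositives["single"]),
               sum(keep) * 0.05)
  # per-contrast columns agree with direct recomputation for one probe
  cn <- contrastNames(ce)[1]
  probe <- res$probe_id[keep][1]
  vals <- log2Ratios(ce, cn)[probe, ]
  expect_equal(unname(res[[paste0("fc.", cn)]][res$probe_id == probe]),
               signedFoldChange(vals), tolerance = 1e-9)
  expect_equal(unname(res[[paste0("p.", cn)]][res$probe_id == probe]),
               oneSampleT(vals)$p.value, tolerance = 1e-9)
})

test_that("expectedFalsePositives is the analytic product rule", {
  expect_equal(expectedFalsePositives(9083, 0.05, 1), 454.15)
  expect_equal(expectedFalsePositives(9083, 0.05, 3), 9083 * 0.05^3)
  expect_equal(expectedFalsePositives(1234, 1, 1), 1234)
  expect_error(expectedFalsePositives(0, 0.05, 1), "nProbes")
  expect_error(expectedFalsePositives(10, 0, 1), "alpha")
  expect_error(expectedFalsePositives(10, 0.05, 0), "requiredPasses")
})

test_that("deConfig validates thresholds and averaging mode", {
  expect_error(deConfig(alpha = 0), "alpha")
  expect_error(deConfig(fcThreshold = 1), "fcThreshold")
  expect_error(deConfig(rescueFc = 2), "rescueFc")
  # geometric averaging works on the ratio scale
  tab <- callFoldChangeTable(matrix(c(2, 8), 1), matrix(c(0.01, 0.01), 1),
                             deConfig(fcAverage = "geometric"))
  expect_equal(tab$meanFc, 4)
  tab2 <- callFoldChangeTable(matrix(c(2, 8), 1),
                              matrix(c(0.01, 0.01), 1))
  expect_equal(tab2$meanFc, 5)
})
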
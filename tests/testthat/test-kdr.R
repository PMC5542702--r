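test_that("alleleFrequency matches the published worked examples", {
  expect_equal(alleleFrequency(genotypeCounts(62, 27, 2))$frequency,
               31 / 182, tolerance = 1e-12)
  expect_equal(round(alleleFrequency(genotypeCounts(62, 27, 2))$frequency,
                     2), 0.17)
  expect_equal(round(alleleFrequency(genotypeCounts(45, 33, 2))$frequency,
                     2), 0.23)
  fixed <- alleleFrequency(genotypeCounts(0, 0, 91, locus = "F1534C"))
  expect_equal(fixed$frequency, 1)
  expect_true(fixed$fixed)
  expect_equal(fixed$nAlleles, 182L)
  mono <- alleleFrequency(genotypeCounts(10, 0, 0))
  expect_equal(mono$frequency, 0)
  expect_false(mono$fixed)
  expect_error(alleleFrequency(genotypeCounts(0, 0, 0)), "zero")
  expect_error(genotypeCounts(-1, 2, 3), "non-negative")
})

test_that("countGenotypes tabulates simulated individuals faithfully", {
  g <- simulateGenotypes(genotypeSimConfig(0.3, 200, phenotypeEffect = 1,
                                           seed = 6))
  all <- countGenotypes(g)
  expect_equal(sum(all$n_wildtype_hom, all$n_het, all$n_mutant_hom), 200)
  res <- countGenotypes(g, "resistant")
  sus <- countGenotypes(g, "susceptible")
  expect_equal(sum(res$n_wildtype_hom, res$n_het, res$n_mutant_hom) +
                 sum(sus$n_wildtype_hom, sus$n_het, sus$n_mutant_hom),
               200)
  expect_equal(alleleFrequency(all)$frequency,
               mean(g$n_mutant_alleles) / 2, tolerance = 1e-12)
})

test_that("population comparison reproduces the printed exact test", {
  fun <- genotypeCounts(62, 27, 2, population = "Funchal")
  pdm <- genotypeCounts(45, 33, 2, population = "Paul do Mar")
  cmp <- comparePopulationFrequencies(fun, pdm)
  expect_equal(cmp$test$p.value, 0.263, tolerance = 0.002)
  expect_equal(round(cmp$frequencyA, 2), 0.17)
  expect_equal(round(cmp$frequencyB, 2), 0.23)
  # identical distributions: no difference detectable
  expect_equal(comparePopulationFrequencies(fun, fun)$test$p.value, 1)
  # the allele-based 2x2 variant is available and differs
  alle <- comparePopulationFrequencies(fun, pdm, basis = "allele")
  expect_equal(dim(alle$table), c(2L, 2L))
  expect_lt(alle$test$p.value, cmp$test$p.value)
  # complete separation on opposite homozygotes is significant
  sep <- comparePopulationFrequencies(genotypeCounts(10, 0, 0),
                                      genotypeCounts(0, 0, 10))
  expect_equal(sep$test$p.value,
               oracleFisher2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               tolerance = 1e-10)
  expect_lt(sep$test$p.value, 0.05)
})

test_that("association test reproduces the printed phenotype contrast", {
  res <- genotypeCounts(20, 10, 2, phenotypeClass = "resistant")
  sus <- genotypeCounts(15, 4, 0, phenotypeClass = "susceptible")
  a <- associationTest(res, sus)
  expect_equal(a$test$p.value, 0.491, tolerance = 0.002)
  expect_equal(round(a$frequencyResistant, 2), 0.22)
  expect_equal(round(a$frequencySusceptible, 2), 0.11)
  # empty genotype columns are dropped before testing
  r2 <- genotypeCounts(21, 11, 0)
  s2 <- genotypeCounts(6, 2, 0)
  a2 <- associationTest(r2, s2)
  expect_equal(dim(a2$table), c(2L, 2L))
  expect_equal(associationTest(res, res)$test$p.value, 1)
  expect_error(associationTest(res, genotypeCounts(0, 0, 0)),
               "at least one individual")
})

test_that("small association tables equal brute-force enumeration", {
  set.seed(23)
  for (i in 1:15) {
    tab <- randomContingency(2, 3, sample(8:12, 1))
    if (any(rowSums(tab) == 0)) next
    a <- genotypeCounts(tab[1, 1], tab[1, 2], tab[1, 3])
    b <- genotypeCounts(tab[2, 1], tab[2, 2], tab[2, 3])
    keep <- colSums(tab) > 0
    if (sum(keep) < 2) next
    oracle <- if (sum(keep) == 3) oracleFisher2x3(tab)
              else oracleFisher2x2(tab[, keep, drop = FALSE])
    expect_equal(associationTest(a, b)$test$p.value, oracle,
                 tolerance = 1e-10)
  }
})

test_that("allele-frequency estimator is unbiased over simulated cohorts", {
  ests <- vapply(1:300, function(s) {
    g <- simulateGenotypes(genotypeSimConfig(0.2, 100, seed = s))
    alleleFrequency(countGenotypes(g))$frequency
  }, 0)
  se <- sqrt(0.2 * 0.8 / 200)      # one cohort of 2n = 200 alleles
  expect_lt(abs(mean(ests) - 0.2), 3 * se / sqrt(300))
})

test_that("association test keeps its size under the null", {
  rejections <- vapply(1:200, function(s) {
    g <- simulateGenotypes(genotypeSimConfig(0.3, 80, phenotypeEffect = 1,
                                             seed = 1000 + s))
    res <- countGenotypes(g, "resistant")
    sus <- countGenotypes(g, "susceptible")
    if (sum(res$n_wildtype_hom, res$n_het, res$n_mutant_hom) == 0 ||
        sum(sus$n_wildtype_hom, sus$n_het, sus$n_mutant_hom) == 0)
      return(NA)
    associationTest(res, sus)$test$p.value < 0.05
  }, logical(1))
  rate <- mean(rejections, na.rm = TRUE)
  # exact tests are conservative; allow the upper 99% binomial band
  expect_lte(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 200))
})

test_that("an associated allele is detected at moderate effect sizes", {
  hits <- vapply(1:40, function(s) {
    g <- simulateGenotypes(genotypeSimConfig(
      0.4, 300, phenotypeEffect = 4, baselineResistanceProb = 0.3,
      seed = 500 + s))
    associationTest(countGenotypes(g, "resistant"),
                    countGenotypes(g, "susceptible"))$test$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
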
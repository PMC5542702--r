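test_that("simulation configs reject invalid fields by name", {
  expect_error(expressionSimConfig(nProbes = 0), "nProbes")
  expect_error(expressionSimConfig(noiseSd = -1), "noiseSd")
  expect_error(expressionSimConfig(dropoutProb = 1.2), "dropoutProb")
  expect_error(expressionSimConfig(deFractionUp = 0.7,
                                   deFractionDown = 0.6),
               "must not exceed 1")
  expect_error(bioassaySimConfig(tubeSize = 0.5), "tubeSize")
  expect_error(genotypeSimConfig(alleleFreq = 2, nIndividuals = 10),
               "alleleFreq")
  expect_error(genotypeSimConfig(0.5, 10, phenotypeEffect = -1),
               "phenotypeEffect")
  expect_error(qpcrSimConfig(efficiencies = c(g = 2.5, L8 = 2, S7 = 2)),
               "\\(1, 2.2\\]")
  expect_error(qpcrSimConfig(nDilutions = 2), "nDilutions")
  expect_error(enzymeSimConfig(nPerGroup = 1), "nPerGroup")
})

test_that("expression simulator honours degenerate settings and truth", {
  ce <- simulateExpression(expressionSimConfig(
    nProbes = 200, deFractionUp = 0, deFractionDown = 0,
    dropoutProb = 0, marginalProb = 0, seed = 1))
  tl <- truthLabels(ce)
  expect_true(all(tl$trueClass == "null"))
  expect_true(all(detectionFlags(ce) == "detected"))
  expect_true(all(detectableProbes(ce)))
  ce2 <- simulateExpression(expressionSimConfig(
    nProbes = 100, deFractionUp = 0.2, deFractionDown = 0.1, seed = 2))
  tl2 <- truthLabels(ce2)
  expect_equal(sum(tl2$trueClass == "up"), 20)
  expect_equal(sum(tl2$trueClass == "down"), 10)
  # truth labels consistent with generated effects
  expect_true(all(tl2$trueLog2Fc[tl2$trueClass == "up"] > 0))
  expect_true(all(tl2$trueLog2Fc[tl2$trueClass == "down"] < 0))
  expect_true(all(tl2$trueLog2Fc[tl2$trueClass == "null"] == 0))
})

test_that("null log2-ratios are centred: grand mean within 4 SE of 0", {
  cfg <- expressionSimConfig(nProbes = 10000, nContrasts = 1, nReps = 4,
                             deFractionUp = 0, deFractionDown = 0,
                             noiseSd = 0.3, dropoutProb = 0, seed = 2024)
  ce <- simulateExpression(cfg)
  gm <- mean(log2Ratios(ce))
  se <- 0.3 / sqrt(10000 * 4)
  expect_lt(abs(gm), 4 * se)
})

test_that("fixed seeds give identical tables; margins are respected", {
  a <- simulateExpression(expressionSimConfig(nProbes = 50, seed = 99))
  b <- simulateExpression(expressionSimConfig(nProbes = 50, seed = 99))
  expect_identical(log2Ratios(a), log2Ratios(b))
  expect_identical(detectionFlags(a), detectionFlags(b))
  t1 <- simulateBioassay(bioassaySimConfig(seed = 4))
  t2 <- simulateBioassay(bioassaySimConfig(seed = 4))
  expect_identical(t1, t2)
  expect_true(all(t1$n_dead_24h >= 0 & t1$n_dead_24h <= t1$n_exposed))
  g <- simulateGenotypes(genotypeSimConfig(0.3, 500, seed = 5))
  expect_equal(nrow(g), 500)
  expect_equal(sum(table(g$genotype)), 500)
})

test_that("bioassay simulator hits deterministic and calibrated rates", {
  allDead <- simulateBioassay(bioassaySimConfig(
    conditions = data.frame(population = "P", insecticide = "x",
                            synergist = "none", mortality = 1),
    seed = 1))
  exposed <- allDead[allDead$insecticide != "control", ]
  expect_true(all(exposed$n_dead_24h == exposed$n_exposed))
  none <- simulateBioassay(bioassaySimConfig(
    conditions = data.frame(population = "P", insecticide = "x",
                            synergist = "none", mortality = 0),
    seed = 1))
  expect_true(all(none$n_dead_24h == 0))
  # mean pooled mortality over repeated runs near the true 50%
  set.seed(31)
  rates <- replicate(400, {
    tab <- simulateBioassay(bioassaySimConfig(
      conditions = data.frame(population = "P", insecticide = "x",
                              synergist = "none", mortality = 0.5)))
    d <- tab[tab$insecticide == "x", ]
    sum(d$n_dead_24h) / sum(d$n_exposed)
  })
  se <- sqrt(0.25 / 125)
  expect_lt(abs(mean(rates) - 0.5), 3 * se / sqrt(400))
})

test_that("genotype simulator is Hardy-Weinberg calibrated", {
  g1 <- simulateGenotypes(genotypeSimConfig(1, 50, seed = 1))
  expect_true(all(g1$genotype == "mutant_hom"))
  g0 <- simulateGenotypes(genotypeSimConfig(0, 50, seed = 1))
  expect_true(all(g0$genotype == "wildtype_hom"))
  g <- simulateGenotypes(genotypeSimConfig(0.2, 5000, seed = 77))
  freq <- mean(g$n_mutant_alleles) / 2
  expect_lt(abs(freq - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("qPCR simulator inverts exactly without noise", {
  q <- simulateQpcr(qpcrSimConfig(noiseSd = 0, seed = 3))
  for (g in names(q$config$efficiencies)) {
    e <- estimateEfficiency(q$dilution, gene = g)
    expect_equal(e$efficiency, q$config$efficiencies[[g]],
                 tolerance = 1e-6)
    expect_equal(e$rSquared, 1, tolerance = 1e-9)
  }
  # true ratio 1 for all genes -> Pfaffl ratios 1
  q1 <- simulateQpcr(qpcrSimConfig(
    efficiencies = c(t1 = 2, L8 = 2, S7 = 2), trueRatios = c(t1 = 1),
    noiseSd = 0, seed = 4))
  pr <- pfafflRatio(q1$samples, "t1", c("L8", "S7"),
                    c(t1 = 2, L8 = 2, S7 = 2))
  expect_equal(pr$ratio, 1, tolerance = 1e-9)
})

test_that("enzyme simulator returns the declared shift and layout", {
  act <- simulateEnzymeActivity(enzymeSimConfig(nPerGroup = 40,
                                                shift = 2, seed = 8))
  expect_equal(attr(act, "trueShift"), 2)
  expect_equal(unname(table(act$population)), c(40L, 40L),
               ignore_attr = TRUE)
  expect_true(all(act$activity > 0))
})
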
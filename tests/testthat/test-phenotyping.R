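makeTable <- function(deaths, exposed = 25, population = "Funchal",
                      insecticide = "permethrin", synergist = "none") {
  data.frame(population = population, insecticide = insecticide,
             synergist = synergist, tube_id = seq_along(deaths),
             n_exposed = exposed, n_dead_24h = deaths)
}

test_that("pooledMortality pools tubes and summarises spread", {
  all <- makeTable(c(25, 25))
  s <- pooledMortality(all, "Funchal", "permethrin")
  expect_equal(s$mortality, 100)
  none <- makeTable(c(0, 0, 0), exposed = 20)
  s0 <- pooledMortality(none, "Funchal", "permethrin")
  expect_equal(s0$mortality, 0)
  expect_equal(s0$tubeSd, 0)
  expect_true(s0$lowN)
  mid <- makeTable(c(5, 6, 4, 7))
  sm <- pooledMortality(mid, "Funchal", "permethrin")
  expect_equal(sm$mortality, 22)
  expect_equal(sm$tubeSd, sd(c(20, 24, 16, 28)), tolerance = 1e-9)
  expect_equal(sm$nTotal, 100)
  expect_false(sm$lowN)
  expect_error(pooledMortality(mid, "PaulDoMar", "permethrin"),
               "no bioassay rows")
})

test_that("pooled mortality lies within the per-tube range", {
  set.seed(17)
  for (i in 1:10) {
    tab <- makeTable(sample(0:25, 5, replace = TRUE))
    s <- pooledMortality(tab, "Funchal", "permethrin")
    tubes <- 100 * tab$n_dead_24h / tab$n_exposed
    expect_gte(s$mortality, min(tubes))
    expect_lte(s$mortality, max(tubes))
  }
})

test_that("tube sizes outside the protocol range raise a warning", {
  odd <- makeTable(c(2, 3), exposed = 40)
  expect_warning(pooledMortality(odd, "Funchal", "permethrin"),
                 "15-30")
})

test_that("abbottCorrect follows the WHO control-mortality rules", {
  expect_equal(abbottCorrect(50, 0), 50)
  expect_equal(abbottCorrect(50, 3), 50)   # below 5%: no correction
  expect_equal(abbottCorrect(50, 10), 100 * 40 / 90, tolerance = 1e-9)
  expect_error(abbottCorrect(30, 25), "invalid run")
  # monotone increasing in observed mortality
  obs <- seq(0, 100, by = 5)
  corr <- vapply(obs, abbottCorrect, 0, control = 12)
  expect_true(all(diff(corr) >= 0))
})

test_that("classifySusceptibility applies the strict below-90 rule", {
  expect_equal(classifySusceptibility(77.5), "resistant")
  expect_equal(classifySusceptibility(100), "susceptible")
  expect_equal(classifySusceptibility(90), "suspected")
  expect_equal(classifySusceptibility(90, paperMode = TRUE),
               "not_resistant")
  expect_equal(classifySusceptibility(89.99, paperMode = TRUE),
               "resistant")
  # monotone: higher mortality never more resistant
  ranks <- c(resistant = 1, suspected = 2, susceptible = 3)
  cls <- ranks[vapply(seq(0, 100, 2), classifySusceptibility, "")]
  expect_true(all(diff(cls) >= 0))
})

test_that("synergistEffect builds the pooled 2x2 and matches the oracle", {
  tab <- rbind(makeTable(c(1, 1), exposed = 20),
               makeTable(c(5, 5), exposed = 20, synergist = "PBO"))
  eff <- synergistEffect(tab, "Funchal", "permethrin", "PBO")
  expect_equal(eff$test$p.value,
               oracleFisher2x2(matrix(c(2, 38, 10, 30), 2, byrow = TRUE)),
               tolerance = 1e-10)
  expect_equal(eff$direction, "increased")
  expect_equal(eff$significant, eff$test$p.value < 0.05)
  # identical arms: no contrast
  same <- rbind(makeTable(c(10, 10)), makeTable(c(10, 10),
                                                synergist = "PBO"))
  expect_equal(synergistEffect(same, "Funchal", "permethrin")$test$p.value,
               1)
  # degenerate margins (all dead in both arms)
  dead <- rbind(makeTable(c(25, 25)), makeTable(c(25, 25),
                                                synergist = "PBO"))
  expect_equal(synergistEffect(dead, "Funchal", "permethrin")$test$p.value,
               1)
  expect_error(synergistEffect(makeTable(c(1, 2)), "Funchal",
                               "permethrin", "DEM"),
               "both the synergist")
})

test_that("synergistEffect p-value is symmetric under arm swap", {
  tab <- rbind(makeTable(c(2, 3)), makeTable(c(9, 11), synergist = "PBO"))
  swapped <- tab
  swapped$synergist <- ifelse(tab$synergist == "none", "PBO", "none")
  a <- synergistEffect(tab, "Funchal", "permethrin")
  b <- synergistEffect(swapped, "Funchal", "permethrin")
  expect_equal(a$test$p.value, b$test$p.value, tolerance = 1e-12)
  expect_equal(a$direction, "increased")
  expect_equal(b$direction, "decreased")
})

test_that("compareEnzymeActivity detects shifts with direction", {
  act <- simulateEnzymeActivity(enzymeSimConfig(shift = 1, seed = 12))
  same <- compareEnzymeActivity(act, "Funchal", "Rockefeller",
                                "alpha-esterase")
  expect_false(same$significant)
  # fully separated tiny groups: U = 0, exact P = 0.1
  small <- data.frame(
    population = rep(c("F", "R"), each = 3),
    enzyme_family = "GST",
    individual_id = as.character(1:6),
    activity = c(4, 5, 6, 1, 2, 3))
  cmp <- compareEnzymeActivity(small, "F", "R", "GST")
  expect_equal(cmp$test$details$U2, 0)
  expect_equal(cmp$test$p.value, 0.1)
  expect_equal(cmp$direction, "elevated")
  expect_false(cmp$significant)
  expect_error(compareEnzymeActivity(small, "F", "missing", "GST"),
               "at least 2 individuals")
})

test_that("a doubled activity shift is detected in most simulated runs", {
  hits <- vapply(1:60, function(s) {
    act <- simulateEnzymeActivity(enzymeSimConfig(nPerGroup = 40,
                                                  shift = 2, seed = s))
    cmp <- compareEnzymeActivity(act, "Funchal", "Rockefeller",
                                 "alpha-esterase")
    cmp$significant && cmp$direction == "elevated"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
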
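# Independent oracles used to validate the package's own statistics.
# They share no code with the implementation: probabilities come from
# choose()/factorial ratios and tables are enumerated with plain loops.

# Two-sided Fisher p-value for a 2x2 table by direct enumeration of the
# hypergeometric support, using binomial coefficients.
oracleFisher2x2 <- function(tab) {
  r <- rowSums(tab); cl <- colSums(tab); N <- sum(tab)
  ks <- max(0, cl[1] - r[2]):min(r[1], cl[1])
  pr <- choose(r[1], ks) * choose(r[2], cl[1] - ks) / choose(N, cl[1])
  obs <- choose(r[1], tab[1, 1]) * choose(r[2], tab[2, 1]) /
    choose(N, cl[1])
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Probability-ordering p-value for a 2x3 table by brute-force loops over
# the two free cells of the first row.
oracleFisher2x3 <- function(tab) {
  stopifnot(nrow(tab) == 2, ncol(tab) == 3)
  r <- rowSums(tab); cl <- colSums(tab)
  logProb <- function(m)
    sum(lfactorial(rowSums(m))) + sum(lfactorial(colSums(m))) -
      lfactorial(sum(m)) - sum(lfactorial(m))
  obs <- logProb(tab)
  total <- 0
  for (a in 0:min(r[1], cl[1])) {
    for (b in 0:min(r[1] - a, cl[2])) {
      cc <- r[1] - a - b
      if (cc > cl[3]) next
      m <- rbind(c(a, b, cc), cl - c(a, b, cc))
      if (any(m < 0)) next
      lp <- logProb(m)
      if (lp <= obs + 1e-7) total <- total + exp(lp)
    }
  }
  total
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled ranks to the first sample (no ties assumed).
oracleMannWhitneyExact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  u1obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  tabU <- table(us) / ncol(combos)
  lower <- sum(tabU[as.numeric(names(tabU)) <= u1obs])
  upper <- sum(tabU[as.numeric(names(tabU)) >= u1obs])
  min(1, 2 * min(lower, upper))
}

randomContingency <- function(nr, nc, total) {
  cells <- as.vector(stats::rmultinom(1, total, rep(1, nr * nc)))
  matrix(cells, nr, nc)
}

# Small three-contrast experiment with the first `nSpiked` probes shifted
# by `lfc`, for power/recovery checks.
makeSpikedExperiment <- function(nProbes = 60, nSpiked = 20, lfc = 2,
                                 sd = 0.25, seed = 1) {
  simulateExpression(expressionSimConfig(
    nProbes = nProbes, deFractionUp = nSpiked / nProbes,
    deFractionDown = 0, deLog2fc = lfc, noiseSd = sd,
    dropoutProb = 0, marginalProb = 0, seed = seed))
}
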
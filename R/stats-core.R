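# Lightweight container for test results shared by every analysis stage.
.testResult <- function(statistic, p.value, method, df = NA_real_,
                        n = NA_real_, estimate = NULL, degenerate = FALSE,
                        details = list()) {
  stopifnot(is.na(p.value) || (p.value >= 0 && p.value <= 1 + 1e-12))
  structure(
    list(statistic = unname(statistic),
         p.value = unname(min(1, p.value)),
         method = method, df = df, n = n,
         estimate = estimate, degenerate = degenerate,
         details = details),
    class = "resistTest")
}

#' @export
print.resistTest <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic))
    cat("  statistic =", format(x$statistic, digits = 4), "")
  if (!is.na(x$df)) cat(" df =", x$df, "")
  cat("\n  p-value =", format(x$p.value, digits = 4), "\n")
  if (!is.null(x$estimate))
    cat("  estimate:", paste(format(x$estimate, digits = 4), collapse = ", "),
        "\n")
  if (isTRUE(x$degenerate)) cat("  note: degenerate input\n")
  invisible(x)
}

.checkContingency <- function(cells) {
  if (!is.matrix(cells) || !is.numeric(cells))
    stop("contingency table must be a numeric matrix")
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency table cells must be finite non-negative integers")
  if (nrow(cells) < 2L || ncol(cells) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (sum(cells) < 1)
    stop("contingency table grand total must be at least 1")
  storage.mode(cells) <- "double"
  cells
}

# log multivariate hypergeometric probability of a table given its margins
.logTableProb <- function(cells) {
  sum(lfactorial(rowSums(cells))) + sum(lfactorial(colSums(cells))) -
    lfactorial(sum(cells)) - sum(lfactorial(cells))
}

# Enumerate every r x c table with the given margins, applying FUN(cells)
# to each.  Rows are filled one at a time; the last row and last column are
# forced, so the recursion runs over the (r-1)(c-1) free cells.
.enumerateTables <- function(rowTot, colTot, FUN) {
  r <- length(rowTot); c <- length(colTot)
  cells <- matrix(0, r, c)
  fillRow <- function(i, colRemaining) {
    if (i == r) {
      cells[r, ] <<- colRemaining
      FUN(cells)
      return(invisible(NULL))
    }
    fillCell <- function(j, left, avail) {
      if (j == c) {
        if (left <= avail[c]) {
          cells[i, c] <<- left
          fillRow(i + 1L, avail - cells[i, ])
        }
        return(invisible(NULL))
      }
      lo <- max(0, left - sum(avail[(j + 1L):c]))
      hi <- min(left, avail[j])
      if (lo > hi) return(invisible(NULL))
      for (v in lo:hi) {
        cells[i, j] <<- v
        fillCell(j + 1L, left - v, avail)
      }
      invisible(NULL)
    }
    fillCell(1L, rowTot[i], colRemaining)
  }
  fillRow(1L, colTot)
  invisible(NULL)
}

#' Exact test of independence for an r x c contingency table
#'
#' Two-sided Fisher exact test computed by complete enumeration of all
#' tables sharing the observed margins.  The two-sided p-value follows the
#' probability-ordering (Freeman-Halton) rule: it is the total null
#' probability, under the multivariate hypergeometric distribution with
#' fixed margins, of every table whose point probability does not exceed
#' that of the observed table.  For 2 x 2 tables this reduces to the
#' classic two-sided Fisher test.
#'
#' Used for the synergist-restoration comparisons of tube-bioassay
#' mortality (dead/alive x with/without synergist) and for the kdr
#' genotype-frequency comparisons (population or phenotype x genotype).
#'
#' @param cells non-negative integer matrix with at least 2 rows and 2
#'   columns; margins are taken as fixed.
#' @return A `resistTest` with the observed table's point probability as
#'   the statistic and the enumeration-based two-sided p-value.
#' @details Tables larger than 2 x 2 are enumerated over the free cells;
#'   to keep enumeration tractable the grand total is capped at 500 for
#'   those shapes and an error (never a silent approximation) is raised
#'   beyond it.  2 x 2 tables use the hypergeometric density directly and
#'   have no size cap.
#' @examples
#' fisherExact(matrix(c(2, 18, 10, 10), 2, byrow = TRUE))
#' @export
fisherExact <- function(cells) {
  cells <- .checkContingency(cells)
  eps <- 1e-7
  if (nrow(cells) == 2L && ncol(cells) == 2L) {
    rs <- rowSums(cells); cs <- colSums(cells)
    k <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- stats::dhyper(k, rs[1], rs[2], cs[1])
    obs <- stats::dhyper(cells[1, 1], rs[1], rs[2], cs[1])
    p <- sum(probs[probs <= obs * (1 + eps)])
    return(.testResult(statistic = obs, p.value = p,
                       method = "Fisher exact test (2x2, two-sided)",
                       n = sum(cells)))
  }
  if (sum(cells) > 500)
    stop("enumeration limit: grand total above 500 for an r x c table ",
         "larger than 2 x 2")
  logObs <- .logTableProb(cells)
  acc <- 0
  .enumerateTables(rowSums(cells), colSums(cells), function(tab) {
    lp <- .logTableProb(tab)
    if (lp <= logObs + eps) acc <<- acc + exp(lp)
  })
  .testResult(statistic = exp(logObs), p.value = acc,
              method = "Fisher exact test (r x c, probability ordering)",
              n = sum(cells))
}

#' One-sample t-test on log2 expression ratios
#'
#' Tests whether the mean log2(field/reference) ratio differs from
#' `nullMean`; with the default null of 0 this is exactly the hypothesis
#' of a field/reference expression ratio of 1.
#'
#' @param values numeric vector of at least 2 log2-ratios.
#' @param nullMean null value on the log2 scale (default 0).
#' @return A `resistTest` with the t statistic, n - 1 degrees of freedom
#'   and the two-sided p-value.  A zero-variance sample is degenerate:
#'   p = 1 when the common value equals the null, p = 0 (with the
#'   `degenerate` flag set) otherwise.
#' @export
oneSampleT <- function(values, nullMean = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("oneSampleT needs at least 2 finite values")
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    hit <- isTRUE(all.equal(m, nullMean))
    return(.testResult(statistic = if (hit) 0 else Inf * sign(m - nullMean),
                       p.value = if (hit) 1 else 0,
                       method = "One-sample t-test (two-sided)",
                       df = n - 1, n = n, estimate = c(mean = m),
                       degenerate = TRUE))
  }
  tstat <- (m - nullMean) / (s / sqrt(n))
  .testResult(statistic = tstat,
              p.value = 2 * stats::pt(-abs(tstat), df = n - 1),
              method = "One-sample t-test (two-sided)",
              df = n - 1, n = n, estimate = c(mean = m))
}

#' Mann-Whitney rank-sum test
#'
#' Compares two independent samples (typically per-mosquito enzyme
#' activities in a field population versus the susceptible reference
#' strain) by the Mann-Whitney U statistic computed from midranks.
#'
#' The p-value is exact (from the null U distribution) when the combined
#' sample size is at most 20 and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' `U1 + U2 = n1 * n2` always holds.
#'
#' @param x,y numeric vectors, each with at least one value.
#' @return A `resistTest` with statistic U (for `x`), the two-sided
#'   p-value, and in `details` the second-sample `U2` and whether the
#'   exact distribution was used.
#' @export
mannWhitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || any(!is.finite(c(x, y))))
    stop("mannWhitney needs non-empty finite samples")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- table(r)
  hasTies <- any(ties > 1)
  exact <- (n1 + n2 <= 20) && !hasTies
  if (exact) {
    # null distribution of U is symmetric about n1*n2/2 without ties
    lower <- stats::pwilcox(u1, n1, n2)
    upper <- stats::pwilcox(u1 - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    method <- "Mann-Whitney U test (exact, two-sided)"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieAdj)
    if (sigma2 <= 0) {
      # all observations identical in both groups: no evidence of shift
      return(.testResult(statistic = u1, p.value = 1,
                         method = "Mann-Whitney U test (degenerate)",
                         n = N, degenerate = TRUE,
                         details = list(U2 = u2, exact = FALSE)))
    }
    z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
    if (u1 == mu) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Mann-Whitney U test (normal approximation, two-sided)"
  }
  .testResult(statistic = u1, p.value = p, method = method, n = n1 + n2,
              details = list(U2 = u2, exact = exact, hasTies = hasTies))
}

#' Fisher's method for combining probabilities
#'
#' Combines k independent p-values into a single chi-square statistic
#' `X2 = -2 * sum(log(p))` on 2k degrees of freedom, with the combined
#' p-value taken from the upper tail.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return A `resistTest` with statistic X2, df = 2k and the combined
#'   p-value.
#' @examples
#' fishersMethod(c(0.05, 0.05, 0.05))
#' @export
fishersMethod <- function(pValues) {
  pValues <- as.numeric(pValues)
  if (length(pValues) < 1L)
    stop("fishersMethod needs at least one p-value")
  if (any(!is.finite(pValues)) || any(pValues <= 0) || any(pValues > 1))
    stop("p-values must lie in (0, 1]")
  x2 <- -2 * sum(log(pValues))
  k <- length(pValues)
  .testResult(statistic = x2,
              p.value = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE),
              method = "Fisher's combined probability test",
              df = 2 * k, n = k)
}
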
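# Replication-criterion differential-expression caller for multi-contrast
# two-colour log-ratio data.  A probe is called significant only when it
# passes the per-contrast significance and fold-change thresholds in every
# contrast with a consistent direction; probes passing in all but one
# contrast are rescued as "potential" when every passing contrast shows
# extreme (|FC| > rescueFc) expression.

#' Configuration for the replication-criterion caller
#'
#' @param alpha per-contrast significance threshold (default 0.05).
#' @param fcThreshold per-contrast fold-change bound (default 2; probes
#'   must exceed it in absolute signed fold change).
#' @param rescueFc extreme-expression bound for the rescue ("potential")
#'   rule (default 20; must exceed `fcThreshold`).
#' @param requiredPasses contrasts that must pass for a significant call;
#'   `NULL` (default) means all K contrasts.
#' @param rescuePasses contrasts that must pass for a potential call;
#'   `NULL` (default) means K - 1.
#' @param fcAverage how the per-contrast signed fold changes are averaged
#'   for reporting: `"arithmetic"` (default) or `"geometric"` (on the
#'   ratio scale).  Averaging is descriptive only and never affects calls.
#' @return validated list of class `deConfig`.
#' @export
deConfig <- function(alpha = 0.05, fcThreshold = 2, rescueFc = 20,
                     requiredPasses = NULL, rescuePasses = NULL,
                     fcAverage = c("arithmetic", "geometric")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (!is.numeric(fcThreshold) || fcThreshold <= 1)
    stop("'fcThreshold' must exceed 1")
  if (!is.numeric(rescueFc) || rescueFc <= fcThreshold)
    stop("'rescueFc' must exceed 'fcThreshold'")
  structure(list(alpha = alpha, fcThreshold = fcThreshold,
                 rescueFc = rescueFc,
                 requiredPasses = requiredPasses,
                 rescuePasses = rescuePasses,
                 fcAverage = match.arg(fcAverage)),
            class = "deConfig")
}

#' Signed fold change from replicate log2-ratios
#'
#' The mean log2-ratio m maps to a signed fold change: `2^m` for m >= 0
#' and `-2^(-m)` for m < 0, so under-expression is reported as a negative
#' fold change and `|FC| >= 1` always.
#'
#' @param log2Ratios numeric vector of replicate log2-ratios.
#' @return signed fold change.
#' @examples
#' signedFoldChange(c(0.9, 1.1))   #  2
#' signedFoldChange(c(-0.9, -1.1)) # -2
#' @export
signedFoldChange <- function(log2Ratios) {
  log2Ratios <- as.numeric(log2Ratios)
  if (length(log2Ratios) < 1L || any(!is.finite(log2Ratios)))
    stop("signedFoldChange needs at least one finite log2-ratio")
  m <- mean(log2Ratios)
  if (m >= 0) 2^m else -2^(-m)
}

# Vectorised status call.  fc and p are K-vectors (one probe) or
# n x K matrices.  Returns data.frame(status, direction).
.callStatus <- function(fc, p, config) {
  fc <- rbind(fc); p <- rbind(p)
  K <- ncol(fc)
  required <- if (is.null(config$requiredPasses)) K else
    config$requiredPasses
  rescue <- if (is.null(config$rescuePasses)) K - 1L else
    config$rescuePasses
  pass <- (p < config$alpha) & (abs(fc) > config$fcThreshold)
  sgn <- sign(fc)
  nPass <- rowSums(pass)
  passUp <- rowSums(pass & sgn > 0)
  passDown <- rowSums(pass & sgn < 0)
  # every passing contrast shares one direction
  consistentPass <- nPass > 0 & (passUp == nPass | passDown == nPass)
  allSameSign <- rowSums(sgn > 0) == K | rowSums(sgn < 0) == K
  extremePass <- rowSums(pass & abs(fc) > config$rescueFc) == nPass
  significant <- nPass >= required & consistentPass & allSameSign
  potential <- !significant & nPass >= rescue & consistentPass &
    extremePass
  status <- ifelse(significant, "significant",
                   ifelse(potential, "potential", "not_significant"))
  direction <- ifelse(status == "not_significant", NA_character_,
                      ifelse(passUp > 0, "up", "down"))
  data.frame(status = status, direction = direction,
             stringsAsFactors = FALSE)
}

#' Call one probe from its per-contrast fold changes and p-values
#'
#' Applies the replication criterion: the probe is `significant` when
#' every contrast shows `P < alpha` and `|FC| > fcThreshold` with all
#' fold changes in the same direction; failing that it is `potential`
#' when at least `rescuePasses` (default K - 1) contrasts pass both
#' thresholds with a consistent sign and every passing contrast shows
#' extreme expression (`|FC| > rescueFc`); otherwise `not_significant`.
#' Sign-inconsistent passes are never promoted.
#'
#' @param fc numeric vector of per-contrast signed fold changes.
#' @param p numeric vector of per-contrast p-values.
#' @param config a [deConfig()].
#' @return list with `status` (`significant` / `potential` /
#'   `not_significant`) and `direction` (`up` / `down` / `NA`).
#' @examples
#' callProbe(c(31, 30, 10), c(0.028, 0.019, 0.008))  # significant
#' callProbe(c(41, 53, 10), c(0.006, 0.004, 0.060))  # potential (rescued)
#' @export
callProbe <- function(fc, p, config = deConfig()) {
  stopifnot(inherits(config, "deConfig"))
  if (length(fc) != length(p) || length(fc) < 2L)
    stop("'fc' and 'p' must be equal-length vectors over >= 2 contrasts")
  if (any(!is.finite(fc)) || any(!is.finite(p)))
    stop("'fc' and 'p' must be finite")
  res <- .callStatus(fc, p, config)
  list(status = res$status, direction = res$direction)
}

.averageFc <- function(fc, how) {
  if (how == "arithmetic") return(mean(fc))
  # geometric mean on the expression-ratio scale, mapped back to signed FC
  ratio <- ifelse(fc >= 0, fc, -1 / fc)
  g <- 2^mean(log2(ratio))
  if (g >= 1) g else -1 / g
}

#' Call differential expression across every contrast of a dataset
#'
#' Runs the full caller: probes failing the detectability filter (any
#' `"absent"` flag in any array; [detectableProbes()]) are set aside as
#' `filtered`; for each retained probe the per-contrast signed fold
#' change ([signedFoldChange()]) and one-sample t-test p-value against a
#' log2-ratio of 0 ([oneSampleT()]) are computed and the replication
#' criterion applied ([callProbe()]).  The per-contrast fold changes are
#' averaged (descriptively) and the p-values combined with Fisher's
#' method.
#'
#' @param x a [ContrastExperiment-class].
#' @param config a [deConfig()].
#' @return A [S4Vectors::DataFrame] with one row per probe: per-contrast
#'   `fc.*` and `p.*` columns, `meanFc`, `combinedP`, `status`
#'   (`filtered` / `not_significant` / `potential` / `significant`) and
#'   `direction`, sorted by `combinedP` with filtered probes last.  The
#'   configuration and the analytic expected-false-positive counts are
#'   attached as metadata.
#' @export
setMethod("callDifferentialExpression", "ContrastExperiment",
          function(x, config = deConfig(), ...) {
  stopifnot(inherits(config, "deConfig"))
  cn <- contrastNames(x)
  K <- length(cn)
  if (K < 2L) stop("at least 2 contrasts are required")
  keep <- detectableProbes(x)
  n <- nrow(x)
  fc <- p <- matrix(NA_real_, n, K, dimnames = list(rownames(x), cn))
  for (k in seq_len(K)) {
    m <- log2Ratios(x, cn[k])[keep, , drop = FALSE]
    nr <- ncol(m)
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (nr - 1))
    tstat <- (mu - 0) / (s / sqrt(nr))
    pv <- 2 * stats::pt(-abs(tstat), df = nr - 1)
    # zero-variance degeneracies, matching oneSampleT()
    pv[s == 0] <- ifelse(mu[s == 0] == 0, 1, 0)
    fc[keep, k] <- ifelse(mu >= 0, 2^mu, -2^(-mu))
    p[keep, k] <- pv
  }
  status <- rep("filtered", n)
  direction <- rep(NA_character_, n)
  meanFc <- combinedP <- rep(NA_real_, n)
  if (any(keep)) {
    called <- .callStatus(fc[keep, , drop = FALSE],
                          p[keep, , drop = FALSE], config)
    status[keep] <- called$status
    direction[keep] <- called$direction
    meanFc[keep] <- apply(fc[keep, , drop = FALSE], 1, .averageFc,
                          how = config$fcAverage)
    combinedP[keep] <- stats::pchisq(
      -2 * rowSums(log(pmax(p[keep, , drop = FALSE], 1e-300))),
      df = 2 * K, lower.tail = FALSE)
  }
  out <- S4Vectors::DataFrame(probe_id = rownames(x))
  for (k in seq_len(K)) out[[paste0("fc.", cn[k])]] <- fc[, k]
  for (k in seq_len(K)) out[[paste0("p.", cn[k])]] <- p[, k]
  out$meanFc <- meanFc
  out$combinedP <- combinedP
  out$status <- status
  out$direction <- direction
  ord <- order(!keep, combinedP)
  out <- out[ord, ]
  S4Vectors::metadata(out) <- list(
    config = config,
    nProbes = n,
    nRetained = sum(keep),
    expectedFalsePositives = c(
      single = expectedFalsePositives(sum(keep), config$alpha, 1L),
      replication = expectedFalsePositives(
        sum(keep), config$alpha,
        if (is.null(config$requiredPasses)) K else config$requiredPasses)))
  out
})

#' Expected false positives under the replication criterion
#'
#' Analytic expectation of the number of null probes passing the
#' per-contrast significance threshold in `requiredPasses` independent
#' contrasts simultaneously, ignoring the fold-change criterion:
#' `nProbes * alpha^requiredPasses`.  Quantifies how the replication
#' criterion substitutes for formal multiplicity adjustment: at 9083
#' probes and alpha 0.05 a single comparison implies about 450 false
#' positives, the 3/3 criterion about 1.
#'
#' @param nProbes number of probes tested.
#' @param alpha per-contrast significance threshold.
#' @param requiredPasses number of contrasts that must pass.
#' @return expected count of false-positive probes.
#' @examples
#' expectedFalsePositives(9083, 0.05, 1)  # ~454
#' expectedFalsePositives(9083, 0.05, 3)  # ~1.1
#' @export
expectedFalsePositives <- function(nProbes, alpha, requiredPasses) {
  if (!is.numeric(nProbes) || nProbes < 1 || nProbes != round(nProbes))
    stop("'nProbes' must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]")
  if (!is.numeric(requiredPasses) || requiredPasses < 1 ||
      requiredPasses != round(requiredPasses))
    stop("'requiredPasses' must be a positive integer")
  nProbes * alpha^requiredPasses
}

#' Apply the replication criterion to a printed fold-change/p-value table
#'
#' Convenience front end for published summary tables: given matrices of
#' per-contrast signed fold changes and p-values (rows = genes), applies
#' [callProbe()] row-wise and reports averaged fold change and combined
#' p-value alongside the status.
#'
#' @param fc,p numeric matrices (genes x contrasts).
#' @param config a [deConfig()].
#' @return data.frame with `meanFc`, `combinedP`, `status`, `direction`.
#' @export
callFoldChangeTable <- function(fc, p, config = deConfig()) {
  fc <- as.matrix(fc); p <- as.matrix(p)
  if (!identical(dim(fc), dim(p)))
    stop("'fc' and 'p' must have identical dimensions")
  called <- .callStatus(fc, p, config)
  data.frame(
    gene = if (is.null(rownames(fc))) seq_len(nrow(fc)) else rownames(fc),
    meanFc = apply(fc, 1, .averageFc, how = config$fcAverage),
    combinedP = apply(p, 1, function(pp) fishersMethod(pp)$p.value),
    status = called$status,
    direction = called$direction,
    stringsAsFactors = FALSE)
}
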
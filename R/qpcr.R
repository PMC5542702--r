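# Efficiency-corrected relative qRT-PCR quantification (Pfaffl method)
# with dilution-series efficiency estimation and dual reference-gene
# normalisation.

#' Estimate amplification efficiency from a dilution series
#'
#' Least-squares fit of Ct against log10(relative input) over a serial
#' dilution; the per-cycle amplification factor is `E = 10^(-1/slope)`.
#' A perfectly doubling assay has slope -3.3219 and E = 2.
#'
#' @param series data.frame with columns `gene`, `Ct` and either
#'   `relative_input` or `dilution_step` (5-fold steps assumed via
#'   `dilutionFactor`).
#' @param gene optional gene to select when `series` covers several.
#' @param dilutionFactor fold-dilution per step when `relative_input` is
#'   absent (default 5).
#' @return list of class `efficiencyEstimate`: `gene`, `slope`,
#'   `efficiency`, `rSquared`, `n`, and `valid` (FALSE, with a warning,
#'   when E falls outside (1, 2.2]).
#' @examples
#' s <- data.frame(gene = "g", dilution_step = 1:5,
#'                 Ct = 20 + log(5^(0:4)) / log(2))
#' estimateEfficiency(s)$efficiency  # 2
#' @export
estimateEfficiency <- function(series, gene = NULL, dilutionFactor = 5) {
  if (!is.data.frame(series) || !"Ct" %in% names(series))
    stop("'series' must be a data.frame with a 'Ct' column")
  if (!is.null(gene)) series <- series[series$gene == gene, , drop = FALSE]
  if (is.null(gene))
    gene <- if ("gene" %in% names(series))
      paste(unique(series$gene), collapse = "+") else NA_character_
  if ("relative_input" %in% names(series)) {
    input <- series$relative_input
  } else if ("dilution_step" %in% names(series)) {
    input <- dilutionFactor^(-(series$dilution_step - 1))
  } else stop("'series' needs 'relative_input' or 'dilution_step'")
  if (nrow(series) < 3L)
    stop("at least 3 dilution points are required")
  x <- log10(input)
  if (stats::var(x) == 0)
    stop("dilution inputs have zero variance")
  fit <- stats::lm(series$Ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("dilution series does not yield a negative Ct-vs-input slope")
  eff <- 10^(-1 / slope)
  # r^2 computed directly; lm's summary warns on noiseless series
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((series$Ct - mean(series$Ct))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  valid <- eff > 1 && eff <= 2.2
  if (!valid)
    warning(sprintf("estimated efficiency %.3f for %s outside (1, 2.2]",
                    eff, gene))
  structure(list(gene = gene, slope = slope, efficiency = eff,
                 rSquared = r2, n = nrow(series), valid = valid),
            class = "efficiencyEstimate")
}

#' @export
print.efficiencyEstimate <- function(x, ...) {
  cat(sprintf("%s: slope %.4f, E = %.3f (R^2 = %.4f, %d points)%s\n",
              x$gene, x$slope, x$efficiency, x$rSquared, x$n,
              if (x$valid) "" else " [outside valid range]"))
  invisible(x)
}

#' Pfaffl efficiency-corrected relative expression ratio
#'
#' For each biological replicate r of the treated (field) sample the
#' ratio is
#' `E_target^dCt_target(r) / normalisation(r)`, with
#' `dCt = mean Ct(control) - Ct(sample, r)`, so up-regulation in the
#' field sample gives a ratio above 1.  With several reference genes the
#' normalisation term is the geometric mean of the per-gene
#' `E_ref^dCt_ref(r)` terms.  The point estimate is the mean of the
#' replicate ratios; the 95% confidence interval is a t-interval across
#' biological replicates.
#'
#' When every efficiency equals 2 the ratio reduces exactly to the
#' classic `2^-(ddCt)` form.
#'
#' @param samples data.frame with columns `gene`, `sample`,
#'   `biological_replicate`, `Ct` (technical replicates, if present, are
#'   averaged within biological replicate).
#' @param targetGene gene to quantify.
#' @param referenceGenes character vector of normalisation genes.
#' @param efficiencies named numeric vector of per-gene efficiencies in
#'   (1, 2.2], covering the target and every reference gene.
#' @param controlSample,treatedSample the `sample` labels of the
#'   calibrator (reference colony) and the field sample.
#' @return list of class `relativeExpression`: `ratio`, `ci95`,
#'   `replicateRatios`, `nReplicates`.
#' @export
pfafflRatio <- function(samples, targetGene, referenceGenes, efficiencies,
                        controlSample = "reference_colony",
                        treatedSample = "field") {
  required <- c("gene", "sample", "biological_replicate", "Ct")
  miss <- setdiff(required, names(samples))
  if (length(miss))
    stop("qPCR table is missing columns: ", paste(miss, collapse = ", "))
  genes <- c(targetGene, referenceGenes)
  if (!all(genes %in% names(efficiencies)))
    stop("'efficiencies' must cover the target and all reference genes")
  if (any(efficiencies[genes] <= 1))
    stop("efficiencies must exceed 1")
  meanCt <- function(gene, sample) {
    rows <- samples[samples$gene == gene & samples$sample == sample, ]
    if (nrow(rows) == 0L)
      stop("no Ct rows for gene ", gene, " in sample ", sample)
    tapply(rows$Ct, rows$biological_replicate, mean)
  }
  repRatio <- function(gene) {
    ctrl <- meanCt(gene, controlSample)
    trt <- meanCt(gene, treatedSample)
    dCt <- mean(ctrl) - trt  # per treated biological replicate
    efficiencies[[gene]]^dCt
  }
  target <- repRatio(targetGene)
  refTerms <- vapply(referenceGenes, repRatio,
                     numeric(length(target)))
  refTerms <- rbind(refTerms)  # genes in columns, replicates in rows
  if (is.null(dim(refTerms)) || nrow(refTerms) != length(target))
    refTerms <- matrix(refTerms, nrow = length(target))
  norm <- exp(rowMeans(log(refTerms)))
  ratios <- unname(target / norm)
  n <- length(ratios)
  est <- mean(ratios)
  ci <- if (n >= 2) {
    half <- stats::qt(0.975, n - 1) * stats::sd(ratios) / sqrt(n)
    c(lower = est - half, upper = est + half)
  } else c(lower = NA_real_, upper = NA_real_)
  structure(list(gene = targetGene,
                 controlSample = controlSample,
                 treatedSample = treatedSample,
                 ratio = est, ci95 = ci,
                 replicateRatios = ratios, nReplicates = n),
            class = "relativeExpression")
}

#' @export
print.relativeExpression <- function(x, ...) {
  cat(sprintf("%s (%s vs %s): fold change %.3g (95%% CI %.3g-%.3g, n = %d)\n",
              x$gene, x$treatedSample, x$controlSample, x$ratio,
              x$ci95["lower"], x$ci95["upper"], x$nReplicates))
  invisible(x)
}
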
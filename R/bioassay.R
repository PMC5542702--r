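# WHO tube-bioassay analysis: pooled mortality, Abbott control correction,
# susceptibility classification, and synergist-restoration testing.

.checkBioassayTable <- function(table) {
  required <- c("population", "insecticide", "synergist", "tube_id",
                "n_exposed", "n_dead_24h")
  miss <- setdiff(required, names(table))
  if (length(miss))
    stop("bioassay table is missing columns: ", paste(miss, collapse = ", "))
  if (any(table$n_dead_24h < 0) || any(table$n_dead_24h > table$n_exposed))
    stop("deaths must satisfy 0 <= n_dead_24h <= n_exposed")
  out <- table$n_exposed < 15 | table$n_exposed > 30
  if (any(out))
    warning(sum(out), " tube(s) have n_exposed outside the usual 15-30 ",
            "range")
  invisible(table)
}

.selectRows <- function(table, population = NULL, insecticide = NULL,
                        synergist = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(population)) keep <- keep & table$population == population
  if (!is.null(insecticide)) keep <- keep & table$insecticide == insecticide
  if (!is.null(synergist)) keep <- keep & table$synergist == synergist
  table[keep, , drop = FALSE]
}

#' Pooled mortality summary for one bioassay condition
#'
#' Pools replicate tubes of a population x insecticide x synergist
#' condition: pooled mortality is `100 * sum(dead) / sum(exposed)`; the
#' reported spread is the standard deviation of per-tube mortalities.
#' When control tubes (insecticide `"control"`) for the same population
#' and synergist arm are present, control mortality is pooled the same
#' way and Abbott correction applied via [abbottCorrect()].  The summary
#' is classified with [classifySusceptibility()].
#'
#' @param table bioassay data.frame (columns `population`, `insecticide`,
#'   `synergist`, `tube_id`, `n_exposed`, `n_dead_24h`).
#' @param population,insecticide,synergist condition selectors;
#'   `synergist` defaults to `"none"`.
#' @param thresholds classification thresholds passed on (default
#'   `c(90, 98)`).
#' @param paperMode if `TRUE`, use the two-class rule (resistant below
#'   90% mortality, otherwise not resistant).
#' @return list of class `bioassaySummary`: pooled and corrected
#'   mortality (%), per-tube SD, control mortality, totals, the
#'   classification and a `lowN` flag (fewer than 100 exposed).
#' @export
pooledMortality <- function(table, population, insecticide,
                            synergist = "none", thresholds = c(90, 98),
                            paperMode = FALSE) {
  .checkBioassayTable(table)
  rows <- .selectRows(table, population, insecticide, synergist)
  if (nrow(rows) == 0L)
    stop("no bioassay rows match ", population, " / ", insecticide,
         " / ", synergist)
  nTotal <- sum(rows$n_exposed)
  pooled <- 100 * sum(rows$n_dead_24h) / nTotal
  tubeMort <- 100 * rows$n_dead_24h / rows$n_exposed
  ctrl <- .selectRows(table, population, "control", synergist)
  if (nrow(ctrl) == 0L)  # fall back to the shared untreated controls
    ctrl <- .selectRows(table, population, "control", "none")
  controlMortality <- if (nrow(ctrl))
    100 * sum(ctrl$n_dead_24h) / sum(ctrl$n_exposed) else 0
  corrected <- abbottCorrect(pooled, controlMortality)
  structure(
    list(population = population, insecticide = insecticide,
         synergist = synergist,
         mortality = pooled,
         tubeSd = if (nrow(rows) > 1) stats::sd(tubeMort) else NA_real_,
         nTotal = nTotal, nTubes = nrow(rows),
         controlMortality = controlMortality,
         correctedMortality = corrected,
         classification = classifySusceptibility(corrected, thresholds,
                                                 paperMode),
         lowN = nTotal < 100),
    class = "bioassaySummary")
}

#' @export
print.bioassaySummary <- function(x, ...) {
  cat(sprintf("%s / %s / synergist %s: %.1f%% mortality (n = %d, %d tubes)\n",
              x$population, x$insecticide, x$synergist, x$mortality,
              x$nTotal, x$nTubes))
  if (x$controlMortality > 0)
    cat(sprintf("  control %.1f%% -> corrected %.1f%%\n",
                x$controlMortality, x$correctedMortality))
  cat("  classification:", x$classification,
      if (x$lowN) "(low n: fewer than 100 exposed)" else "", "\n")
  invisible(x)
}

#' Abbott correction for control mortality
#'
#' WHO practice: control mortality below 5% needs no correction; between
#' 5% and 20% the observed mortality is corrected as
#' `100 * (observed - control) / (100 - control)`; above 20% the run is
#' invalid and an error is raised.
#'
#' @param observed,control mortalities in percent.
#' @return corrected mortality in percent.
#' @examples
#' abbottCorrect(50, 10)  # 44.44
#' @export
abbottCorrect <- function(observed, control) {
  if (!is.finite(observed) || observed < 0 || observed > 100)
    stop("'observed' must be a percentage in [0, 100]")
  if (!is.finite(control) || control < 0 || control >= 100)
    stop("'control' must be a percentage in [0, 100)")
  if (control > 20)
    stop("invalid run: control mortality above 20% (", round(control, 1),
         "%)")
  if (control < 5) return(observed)
  max(0, 100 * (observed - control) / (100 - control))
}

#' Classify WHO bioassay mortality
#'
#' Default three-class rule: mortality below the first threshold (90%) is
#' resistant, from there up to (but excluding) the second threshold (98%)
#' is suspected resistance, at or above 98% susceptible.  The boundary is
#' strict: exactly 90% is not resistant.  With `paperMode = TRUE` only
#' the below-90% rule is applied, giving resistant / not_resistant.
#'
#' @param mortality percent mortality (after any Abbott correction).
#' @param thresholds numeric length 2, resistant and susceptible bounds.
#' @param paperMode collapse to the two-class below-90% rule.
#' @return classification string.
#' @export
classifySusceptibility <- function(mortality, thresholds = c(90, 98),
                                   paperMode = FALSE) {
  if (!is.finite(mortality) || mortality < 0 || mortality > 100)
    stop("'mortality' must be a percentage in [0, 100]")
  if (paperMode)
    return(if (mortality < thresholds[1]) "resistant" else "not_resistant")
  if (mortality < thresholds[1]) "resistant"
  else if (mortality < thresholds[2]) "suspected"
  else "susceptible"
}

#' Synergist restoration test
#'
#' Tests whether pre-exposure to a synergist (PBO or DEM) changed
#' mortality for a given population x insecticide, by pooling dead/alive
#' counts over tubes in each arm and applying the two-sided Fisher exact
#' test to the resulting 2 x 2 table.  A significant increase in
#' mortality with the synergist implicates the inhibited detoxification
#' enzyme family in the resistance phenotype.
#'
#' @param table bioassay data.frame.
#' @param population,insecticide condition selectors.
#' @param synergist the synergist arm to compare against the
#'   no-synergist arm (default `"PBO"`).
#' @param alpha significance level (default 0.05).
#' @return list of class `synergistEffect`: the `resistTest`, both arm
#'   mortalities, the direction (`"increased"`, `"decreased"` or
#'   `"unchanged"`) and the significance flag.
#' @export
synergistEffect <- function(table, population, insecticide,
                            synergist = "PBO", alpha = 0.05) {
  .checkBioassayTable(table)
  without <- .selectRows(table, population, insecticide, "none")
  with <- .selectRows(table, population, insecticide, synergist)
  if (nrow(without) == 0L || nrow(with) == 0L)
    stop("both the synergist and no-synergist arms are required")
  dead <- c(sum(without$n_dead_24h), sum(with$n_dead_24h))
  alive <- c(sum(without$n_exposed), sum(with$n_exposed)) - dead
  test <- fisherExact(cbind(dead = dead, alive = alive))
  mWithout <- 100 * dead[1] / (dead[1] + alive[1])
  mWith <- 100 * dead[2] / (dead[2] + alive[2])
  structure(
    list(population = population, insecticide = insecticide,
         synergist = synergist, test = test,
         mortalityWithout = mWithout, mortalityWith = mWith,
         direction = if (mWith > mWithout) "increased"
                     else if (mWith < mWithout) "decreased" else "unchanged",
         significant = test$p.value < alpha),
    class = "synergistEffect")
}

#' @export
print.synergistEffect <- function(x, ...) {
  cat(sprintf("%s / %s: %.1f%% -> %.1f%% mortality with %s (%s)\n",
              x$population, x$insecticide, x$mortalityWithout,
              x$mortalityWith, x$synergist, x$direction))
  cat(sprintf("  Fisher exact P = %.4g%s\n", x$test$p.value,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Compare enzyme activity between a field and a reference population
#'
#' Mann-Whitney rank-sum comparison of per-individual activities of one
#' detoxification enzyme family, with the direction of any shift taken
#' from the difference in group medians.
#'
#' @param activities data.frame with columns `population`,
#'   `enzyme_family`, `individual_id`, `activity`.
#' @param fieldPopulation,referencePopulation population labels.
#' @param enzymeFamily which family to compare.
#' @param alpha significance level (default 0.05).
#' @return list of class `enzymeComparison` with the `resistTest`, group
#'   medians, direction (`"elevated"`/`"reduced"`/`"unchanged"` in the
#'   field population) and significance flag.
#' @export
compareEnzymeActivity <- function(activities, fieldPopulation,
                                  referencePopulation, enzymeFamily,
                                  alpha = 0.05) {
  required <- c("population", "enzyme_family", "individual_id", "activity")
  miss <- setdiff(required, names(activities))
  if (length(miss))
    stop("activity table is missing columns: ",
         paste(miss, collapse = ", "))
  if (any(activities$activity < 0))
    stop("activities must be non-negative")
  sel <- activities$enzyme_family == enzymeFamily
  fld <- activities$activity[sel & activities$population == fieldPopulation]
  ref <- activities$activity[sel &
                               activities$population == referencePopulation]
  if (length(fld) < 2L || length(ref) < 2L)
    stop("both populations need at least 2 individuals for ", enzymeFamily)
  test <- mannWhitney(fld, ref)
  dm <- stats::median(fld) - stats::median(ref)
  structure(
    list(fieldPopulation = fieldPopulation,
         referencePopulation = referencePopulation,
         enzymeFamily = enzymeFamily, test = test,
         medianField = stats::median(fld),
         medianReference = stats::median(ref),
         direction = if (dm > 0) "elevated"
                     else if (dm < 0) "reduced" else "unchanged",
         significant = test$p.value < alpha),
    class = "enzymeComparison")
}

#' @export
print.enzymeComparison <- function(x, ...) {
  cat(sprintf("%s activity, %s vs %s: median %.3g vs %.3g (%s)\n",
              x$enzymeFamily, x$fieldPopulation, x$referencePopulation,
              x$medianField, x$medianReference, x$direction))
  cat(sprintf("  Mann-Whitney U = %g, P = %.4g%s\n", x$test$statistic,
              x$test$p.value,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}
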
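# Synthetic-data generators.  Each emulates one input of the resistance
# workflow with known ground truth so that every downstream stage can be
# exercised and calibrated.  One integer seed drives each generator; the
# pipeline derives per-stage substreams from a single global seed.

.checkProb <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 0 || value > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", field))
  value
}

.checkCount <- function(value, field, minimum = 1L) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value != round(value) || value < minimum)
    stop(sprintf("'%s' must be an integer >= %d", field, minimum))
  as.integer(value)
}

.checkPositive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop(sprintf("'%s' must be a positive number", field))
  value
}

.setSeed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || seed != round(seed))
      stop("'seed' must be an integer")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Derive reproducible per-stage substream seeds from one global seed,
# keeping everything inside the 32-bit integer range.
.deriveSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(expression = 101L, bioassay = 211L, enzyme = 307L,
               genotype = 401L, qpcr = 503L)
  (as.integer(seed) * 2654435L + offsets[[stage]]) %% .Machine$integer.max
}

#' Configuration for the expression-ratio simulator
#'
#' Defaults reflect the study design the pipeline targets: 9083 probes
#' passing detectability filtering, three field-vs-reference contrasts
#' with four replicate hybridisations each, and a small fraction of truly
#' differentially expressed probes.
#'
#' @param nProbes number of probes (default 9083).
#' @param nContrasts number of contrasts (default 3).
#' @param nReps replicate arrays per contrast (default 4).
#' @param deFractionUp,deFractionDown fractions of probes truly up- and
#'   down-regulated (defaults 0.01 and 0.005; their sum must be <= 1).
#' @param deLog2fc true per-probe effect on the log2 scale (default 2,
#'   i.e. a 4-fold change).
#' @param noiseSd replicate log2-ratio standard deviation (default 0.25).
#' @param dropoutProb probability that a probe x array detection flag is
#'   "absent" (default 0.01).
#' @param marginalProb probability that a detected flag is downgraded to
#'   "marginal" (default 0.02); marginal probes still pass the filter.
#' @param contrastLabels labels for the contrasts.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return validated configuration list of class `expressionSimConfig`.
#' @export
expressionSimConfig <- function(nProbes = 9083, nContrasts = 3, nReps = 4,
                                deFractionUp = 0.01, deFractionDown = 0.005,
                                deLog2fc = 2, noiseSd = 0.25,
                                dropoutProb = 0.01, marginalProb = 0.02,
                                contrastLabels = NULL, seed = NULL) {
  cfg <- list(
    nProbes = .checkCount(nProbes, "nProbes"),
    nContrasts = .checkCount(nContrasts, "nContrasts"),
    nReps = .checkCount(nReps, "nReps", minimum = 2L),
    deFractionUp = .checkProb(deFractionUp, "deFractionUp"),
    deFractionDown = .checkProb(deFractionDown, "deFractionDown"),
    deLog2fc = .checkPositive(deLog2fc, "deLog2fc"),
    noiseSd = .checkPositive(noiseSd, "noiseSd"),
    dropoutProb = .checkProb(dropoutProb, "dropoutProb"),
    marginalProb = .checkProb(marginalProb, "marginalProb"),
    seed = seed)
  if (cfg$deFractionUp + cfg$deFractionDown > 1)
    stop("'deFractionUp' + 'deFractionDown' must not exceed 1")
  if (is.null(contrastLabels))
    contrastLabels <- c("FunchalVsRockefeller", "FunchalVsNewOrleans",
                        "PaulDoMarVsRockefeller",
                        sprintf("contrast%d", seq_len(cfg$nContrasts)))[
                          seq_len(cfg$nContrasts)]
  if (length(contrastLabels) != cfg$nContrasts)
    stop("'contrastLabels' must name every contrast")
  cfg$contrastLabels <- as.character(contrastLabels)
  structure(cfg, class = "expressionSimConfig")
}

#' Simulate a multi-contrast expression dataset with known truth
#'
#' Null probes have mean-zero log2-ratios; truly regulated probes have
#' mean +/- `deLog2fc` (the same sign and magnitude in every contrast,
#' matching the replication logic of the caller).  Detection flags are
#' sampled independently per probe x array; `dropoutProb` governs
#' "absent" flags, which make a probe fail the detectability filter.
#'
#' @param config an [expressionSimConfig()].
#' @return A [ContrastExperiment-class] whose `rowData` carries the truth
#'   labels `trueClass` ("up"/"down"/"null") and `trueLog2Fc`.
#' @examples
#' ce <- simulateExpression(expressionSimConfig(nProbes = 100, seed = 1))
#' table(truthLabels(ce)$trueClass)
#' @export
simulateExpression <- function(config = expressionSimConfig()) {
  stopifnot(inherits(config, "expressionSimConfig"))
  .setSeed(config$seed)
  n <- config$nProbes
  nUp <- round(n * config$deFractionUp)
  nDown <- round(n * config$deFractionDown)
  trueClass <- rep("null", n)
  if (nUp > 0) trueClass[seq_len(nUp)] <- "up"
  if (nDown > 0) trueClass[nUp + seq_len(nDown)] <- "down"
  trueLfc <- ifelse(trueClass == "up", config$deLog2fc,
                    ifelse(trueClass == "down", -config$deLog2fc, 0))
  nArrays <- config$nContrasts * config$nReps
  ratios <- matrix(stats::rnorm(n * nArrays, mean = trueLfc,
                                sd = config$noiseSd),
                   nrow = n, ncol = nArrays)
  u <- stats::runif(n * nArrays)
  flags <- matrix(ifelse(u < config$dropoutProb, "absent",
                         ifelse(u < config$dropoutProb +
                                  (1 - config$dropoutProb) *
                                  config$marginalProb,
                                "marginal", "detected")),
                  nrow = n, ncol = nArrays)
  ContrastExperiment(
    ratios,
    contrast = rep(config$contrastLabels, each = config$nReps),
    flags = flags,
    rowData = S4Vectors::DataFrame(trueClass = trueClass,
                                   trueLog2Fc = trueLfc))
}

#' Configuration for the tube-bioassay simulator
#'
#' @param conditions data.frame with columns `population`, `insecticide`,
#'   `synergist` and `mortality` (the true 24-h mortality probability for
#'   that exposure condition).  Defaults to a single permethrin exposure.
#' @param nTubes replicate tubes per condition (default 5; the field
#'   protocol uses four or five).
#' @param tubeSize mosquitoes per tube (default 25; protocol range 20-25).
#' @param controlMortality true mortality in unexposed control tubes
#'   (default 0).
#' @param seed integer seed or `NULL`.
#' @export
bioassaySimConfig <- function(conditions = data.frame(
                                population = "Funchal",
                                insecticide = "permethrin",
                                synergist = "none",
                                mortality = 0.5),
                              nTubes = 5, tubeSize = 25,
                              controlMortality = 0, seed = NULL) {
  if (!is.data.frame(conditions) ||
      !all(c("population", "insecticide", "synergist", "mortality") %in%
             names(conditions)))
    stop("'conditions' needs columns population, insecticide, synergist, ",
         "mortality")
  for (m in conditions$mortality) .checkProb(m, "mortality")
  structure(list(conditions = conditions,
                 nTubes = .checkCount(nTubes, "nTubes"),
                 tubeSize = .checkCount(tubeSize, "tubeSize"),
                 controlMortality = .checkProb(controlMortality,
                                               "controlMortality"),
                 seed = seed),
            class = "bioassaySimConfig")
}

#' Simulate WHO tube-bioassay replicate counts
#'
#' Deaths per tube are binomial(`tubeSize`, condition mortality); one set
#' of control tubes per population uses `controlMortality`.
#'
#' @param config a [bioassaySimConfig()].
#' @return A bioassay table: data.frame with columns `population`,
#'   `insecticide`, `synergist`, `tube_id`, `n_exposed`, `n_dead_24h`.
#' @export
simulateBioassay <- function(config = bioassaySimConfig()) {
  stopifnot(inherits(config, "bioassaySimConfig"))
  .setSeed(config$seed)
  cond <- config$conditions
  rows <- lapply(seq_len(nrow(cond)), function(i) {
    data.frame(population = cond$population[i],
               insecticide = cond$insecticide[i],
               synergist = cond$synergist[i],
               tube_id = seq_len(config$nTubes),
               n_exposed = config$tubeSize,
               n_dead_24h = stats::rbinom(config$nTubes, config$tubeSize,
                                          cond$mortality[i]))
  })
  controls <- lapply(unique(cond$population), function(popn) {
    data.frame(population = popn, insecticide = "control",
               synergist = "none", tube_id = seq_len(config$nTubes),
               n_exposed = config$tubeSize,
               n_dead_24h = stats::rbinom(config$nTubes, config$tubeSize,
                                          config$controlMortality))
  })
  out <- do.call(rbind, c(rows, controls))
  rownames(out) <- NULL
  out
}

#' Configuration for the kdr genotype simulator
#'
#' @param alleleFreq mutant allele frequency in [0, 1].
#' @param nIndividuals number of mosquitoes.
#' @param phenotypeEffect multiplicative odds of resistance per mutant
#'   allele (1 = no genotype-phenotype association).
#' @param baselineResistanceProb probability of the resistant phenotype in
#'   wild-type homozygotes.
#' @param locus,population labels carried through to the output.
#' @param seed integer seed or `NULL`.
#' @export
genotypeSimConfig <- function(alleleFreq, nIndividuals,
                              phenotypeEffect = 1,
                              baselineResistanceProb = 0.5,
                              locus = "V1016I", population = "Funchal",
                              seed = NULL) {
  structure(list(alleleFreq = .checkProb(alleleFreq, "alleleFreq"),
                 nIndividuals = .checkCount(nIndividuals, "nIndividuals"),
                 phenotypeEffect = .checkPositive(phenotypeEffect,
                                                  "phenotypeEffect"),
                 baselineResistanceProb =
                   .checkProb(baselineResistanceProb,
                              "baselineResistanceProb"),
                 locus = locus, population = population, seed = seed),
            class = "genotypeSimConfig")
}

#' Simulate Hardy-Weinberg genotypes with optional phenotype association
#'
#' Genotypes are drawn from Hardy-Weinberg proportions (p^2, 2pq, q^2 for
#' 0, 1 and 2 mutant alleles).  The resistance phenotype follows a
#' logistic model additive on the log-odds scale:
#' `logit P(resistant) = logit(baseline) + nAlleles * log(phenotypeEffect)`.
#'
#' @param config a [genotypeSimConfig()].
#' @return data.frame with columns `individual_id`, `locus`, `population`,
#'   `n_mutant_alleles` (0/1/2), `genotype`
#'   (wildtype_hom/het/mutant_hom) and `phenotype`
#'   (resistant/susceptible).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "genotypeSimConfig"))
  .setSeed(config$seed)
  q <- config$alleleFreq
  n <- config$nIndividuals
  nAlleles <- sample(0:2, n, replace = TRUE,
                     prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  logitBase <- stats::qlogis(min(max(config$baselineResistanceProb, 1e-12),
                                 1 - 1e-12))
  pRes <- stats::plogis(logitBase + nAlleles * log(config$phenotypeEffect))
  data.frame(
    individual_id = sprintf("ind_%04d", seq_len(n)),
    locus = config$locus,
    population = config$population,
    n_mutant_alleles = nAlleles,
    genotype = c("wildtype_hom", "het", "mutant_hom")[nAlleles + 1L],
    phenotype = ifelse(stats::runif(n) < pRes, "resistant", "susceptible"))
}

#' Configuration for the qRT-PCR simulator
#'
#' @param efficiencies named numeric vector of per-gene amplification
#'   efficiencies in (1, 2.2] (amplification factor per cycle), covering
#'   target and reference genes.
#' @param trueRatios named numeric vector of true field/reference
#'   expression ratios for the target genes; reference genes are assumed
#'   unregulated (ratio 1).
#' @param referenceGenes names of the reference (normalisation) genes.
#' @param nDilutions dilution points per gene (default 5, minimum 3).
#' @param dilutionFactor fold-dilution per step (default 5).
#' @param nReplicates biological replicates per strain (default 4).
#' @param noiseSd Gaussian Ct noise, cycles (default 0.2).
#' @param seed integer seed or `NULL`.
#' @export
qpcrSimConfig <- function(efficiencies = c(Cyp9J32 = 1.95, GSTd4 = 2.0,
                                           L8 = 2.0, S7 = 1.98),
                          trueRatios = c(Cyp9J32 = 17, GSTd4 = 169),
                          referenceGenes = c("L8", "S7"),
                          nDilutions = 5, dilutionFactor = 5,
                          nReplicates = 4, noiseSd = 0.2, seed = NULL) {
  if (is.null(names(efficiencies)) || any(names(efficiencies) == ""))
    stop("'efficiencies' must be a named vector")
  if (any(efficiencies <= 1 | efficiencies > 2.2))
    stop("'efficiencies' must lie in (1, 2.2]")
  if (!all(referenceGenes %in% names(efficiencies)))
    stop("'referenceGenes' must appear in 'efficiencies'")
  targets <- setdiff(names(efficiencies), referenceGenes)
  if (!all(targets %in% names(trueRatios)))
    stop("'trueRatios' must name every target gene")
  if (any(trueRatios <= 0)) stop("'trueRatios' must be positive")
  structure(list(efficiencies = efficiencies, trueRatios = trueRatios,
                 referenceGenes = referenceGenes,
                 nDilutions = .checkCount(nDilutions, "nDilutions",
                                          minimum = 3L),
                 dilutionFactor = .checkPositive(dilutionFactor,
                                                 "dilutionFactor"),
                 nReplicates = .checkCount(nReplicates, "nReplicates",
                                           minimum = 2L),
                 noiseSd = noiseSd, seed = seed),
            class = "qpcrSimConfig")
}

#' Simulate a qRT-PCR experiment (sample Cts plus dilution series)
#'
#' Cycle thresholds follow `Ct = intercept - log_E(relative input) +
#' noise`.  The dilution series spans `nDilutions` steps of
#' `dilutionFactor`-fold dilution; field-sample Cts are shifted by
#' `-log_E(true ratio)` relative to the reference-colony sample.
#'
#' @param config a [qpcrSimConfig()].
#' @return list of class `qpcrExperiment` with elements `samples`
#'   (data.frame: gene, role, sample, biological_replicate, Ct) and
#'   `dilution` (data.frame: gene, dilution_step, relative_input, Ct),
#'   plus the true configuration in `config`.
#' @export
simulateQpcr <- function(config = qpcrSimConfig()) {
  stopifnot(inherits(config, "qpcrSimConfig"))
  if (config$noiseSd < 0) stop("'noiseSd' must be non-negative")
  .setSeed(config$seed)
  genes <- names(config$efficiencies)
  intercepts <- stats::setNames(18 + 2 * seq_along(genes), genes)
  dil <- do.call(rbind, lapply(genes, function(g) {
    step <- seq_len(config$nDilutions)
    input <- config$dilutionFactor^(-(step - 1))
    ct <- intercepts[[g]] - log(input) / log(config$efficiencies[[g]]) +
      stats::rnorm(length(step), 0, config$noiseSd)
    data.frame(gene = g, dilution_step = step, relative_input = input,
               Ct = ct)
  }))
  samples <- do.call(rbind, lapply(genes, function(g) {
    role <- if (g %in% config$referenceGenes) "reference" else "target"
    ratio <- if (role == "reference") 1 else config$trueRatios[[g]]
    reps <- seq_len(config$nReplicates)
    rbind(
      data.frame(gene = g, role = role, sample = "reference_colony",
                 biological_replicate = reps,
                 Ct = intercepts[[g]] +
                   stats::rnorm(length(reps), 0, config$noiseSd)),
      data.frame(gene = g, role = role, sample = "field",
                 biological_replicate = reps,
                 Ct = intercepts[[g]] -
                   log(ratio) / log(config$efficiencies[[g]]) +
                   stats::rnorm(length(reps), 0, config$noiseSd)))
  }))
  rownames(dil) <- rownames(samples) <- NULL
  structure(list(samples = samples, dilution = dil, config = config),
            class = "qpcrExperiment")
}

#' Configuration for the enzyme-activity simulator
#'
#' Activities are log-normal (assay absorbance-derived units per
#' mosquito), reflecting the right-skewed per-individual distributions of
#' biochemical detoxification assays; the field group is scaled by a
#' multiplicative `shift` (1 = no elevation).
#'
#' @param nPerGroup individuals per population (default 40, the standard
#'   assay size).
#' @param meanlog,sdlog log-scale location and scale of the reference
#'   strain (defaults 0 and 0.5).
#' @param shift multiplicative activity shift of the field population.
#' @param enzymeFamily one of alpha-esterase, beta-esterase, GST, MFO.
#' @param fieldPopulation,referencePopulation labels.
#' @param seed integer seed or `NULL`.
#' @export
enzymeSimConfig <- function(nPerGroup = 40, meanlog = 0, sdlog = 0.5,
                            shift = 1, enzymeFamily = "alpha-esterase",
                            fieldPopulation = "Funchal",
                            referencePopulation = "Rockefeller",
                            seed = NULL) {
  enzymeFamily <- match.arg(enzymeFamily,
                            c("alpha-esterase", "beta-esterase", "GST",
                              "MFO"))
  structure(list(nPerGroup = .checkCount(nPerGroup, "nPerGroup",
                                         minimum = 2L),
                 meanlog = meanlog,
                 sdlog = .checkPositive(sdlog, "sdlog"),
                 shift = .checkPositive(shift, "shift"),
                 enzymeFamily = enzymeFamily,
                 fieldPopulation = fieldPopulation,
                 referencePopulation = referencePopulation, seed = seed),
            class = "enzymeSimConfig")
}

#' Simulate per-individual enzyme activities for two populations
#'
#' @param config an [enzymeSimConfig()].
#' @return data.frame with columns `population`, `enzyme_family`,
#'   `individual_id`, `activity`; attribute `trueShift` records the
#'   simulated field/reference activity ratio.
#' @export
simulateEnzymeActivity <- function(config = enzymeSimConfig()) {
  stopifnot(inherits(config, "enzymeSimConfig"))
  .setSeed(config$seed)
  n <- config$nPerGroup
  ref <- stats::rlnorm(n, config$meanlog, config$sdlog)
  fld <- config$shift * stats::rlnorm(n, config$meanlog, config$sdlog)
  out <- data.frame(
    population = rep(c(config$fieldPopulation,
                       config$referencePopulation), each = n),
    enzyme_family = config$enzymeFamily,
    individual_id = sprintf("ind_%03d", c(seq_len(n), seq_len(n))),
    activity = c(fld, ref))
  attr(out, "trueShift") <- config$shift
  out
}
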
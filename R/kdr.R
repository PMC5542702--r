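# Target-site (kdr) genotype analytics: mutant allele frequencies,
# between-population frequency comparison and genotype-phenotype
# association, all based on exact contingency tests with individuals as
# the sampling unit.

#' Construct a genotype-count record for one biallelic kdr locus
#'
#' @param nWildtypeHom,nHet,nMutantHom non-negative genotype counts.
#' @param locus locus label (e.g. `"V1016I"`, `"F1534C"`).
#' @param population population label.
#' @param phenotypeClass phenotype stratum (e.g. `"Cyfluthrin resistant"`)
#'   or `"all"` for pooled counts.
#' @return one-row data.frame of class `genotypeCounts`.
#' @export
genotypeCounts <- function(nWildtypeHom, nHet, nMutantHom,
                           locus = "V1016I", population = "unknown",
                           phenotypeClass = "all") {
  counts <- c(nWildtypeHom, nHet, nMutantHom)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  structure(
    data.frame(locus = locus, population = population,
               phenotype_class = phenotypeClass,
               n_wildtype_hom = as.integer(nWildtypeHom),
               n_het = as.integer(nHet),
               n_mutant_hom = as.integer(nMutantHom)),
    class = c("genotypeCounts", "data.frame"))
}

#' Tabulate simulated (or observed) individual genotypes into counts
#'
#' @param individuals data.frame as returned by [simulateGenotypes()].
#' @param phenotypeClass optional phenotype to restrict to
#'   (`"resistant"` or `"susceptible"`); default pools all individuals.
#' @return a [genotypeCounts()] record.
#' @export
countGenotypes <- function(individuals, phenotypeClass = NULL) {
  required <- c("locus", "population", "genotype")
  miss <- setdiff(required, names(individuals))
  if (length(miss))
    stop("individual table is missing columns: ",
         paste(miss, collapse = ", "))
  label <- "all"
  if (!is.null(phenotypeClass)) {
    individuals <- individuals[individuals$phenotype == phenotypeClass, ]
    label <- phenotypeClass
  }
  tab <- table(factor(individuals$genotype,
                      levels = c("wildtype_hom", "het", "mutant_hom")))
  genotypeCounts(tab[["wildtype_hom"]], tab[["het"]], tab[["mutant_hom"]],
                 locus = unique(individuals$locus)[1],
                 population = unique(individuals$population)[1],
                 phenotypeClass = label)
}

.countsMatrix <- function(counts) {
  as.numeric(counts[1, c("n_wildtype_hom", "n_het", "n_mutant_hom")])
}

#' Mutant allele frequency from genotype counts
#'
#' Each individual contributes two alleles, so the frequency is
#' `(n_het + 2 * n_mutant_hom) / (2 * N)`.  A frequency of exactly 1
#' raises the fixation flag: a fixed locus carries no variance and
#' association testing is not possible for it.
#'
#' @param counts a [genotypeCounts()] record.
#' @return list of class `alleleFrequency`: `locus`, `stratum`,
#'   `frequency`, `nAlleles`, `fixed`.
#' @examples
#' alleleFrequency(genotypeCounts(62, 27, 2))$frequency  # 0.1703...
#' @export
alleleFrequency <- function(counts) {
  cm <- .countsMatrix(counts)
  N <- sum(cm)
  if (N < 1) stop("allele frequency undefined for zero individuals")
  freq <- (cm[2] + 2 * cm[3]) / (2 * N)
  structure(list(locus = counts$locus[1],
                 stratum = paste(counts$population[1],
                                 counts$phenotype_class[1], sep = " / "),
                 frequency = freq, nAlleles = 2L * as.integer(N),
                 fixed = freq == 1),
            class = "alleleFrequency")
}

#' @export
print.alleleFrequency <- function(x, ...) {
  cat(sprintf("%s, %s: mutant allele frequency %.2f (%d alleles)%s\n",
              x$locus, x$stratum, x$frequency, x$nAlleles,
              if (x$fixed) " [fixed]" else ""))
  invisible(x)
}

.genotypeTable <- function(a, b, basis, dropEmpty = TRUE) {
  ca <- .countsMatrix(a); cb <- .countsMatrix(b)
  if (sum(ca) < 1 || sum(cb) < 1)
    stop("both strata need at least one individual")
  if (basis == "allele") {
    tab <- rbind(c(2 * ca[1] + ca[2], ca[2] + 2 * ca[3]),
                 c(2 * cb[1] + cb[2], cb[2] + 2 * cb[3]))
    colnames(tab) <- c("wildtype", "mutant")
  } else {
    tab <- rbind(ca, cb)
    colnames(tab) <- c("wildtype_hom", "het", "mutant_hom")
    if (dropEmpty) tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L)
      stop("table degenerate: fewer than 2 non-empty genotype classes")
  }
  if (sum(tab) < 1) stop("all-zero genotype table")
  tab
}

#' Compare mutant-allele carriage between two populations
#'
#' Builds the populations x genotypes contingency table from two pooled
#' genotype-count records and applies the exact test ([fisherExact()]).
#' The default basis is the genotype-level 2 x 3 table; `basis =
#' "allele"` instead compares allele counts in a 2 x 2 table (2N alleles
#' per population).
#'
#' @param a,b [genotypeCounts()] records for the two populations.
#' @param basis `"genotype"` (default) or `"allele"`.
#' @return list of class `kdrComparison` with the `resistTest`, both
#'   allele frequencies and the table tested.
#' @examples
#' fun <- genotypeCounts(62, 27, 2, population = "Funchal")
#' pdm <- genotypeCounts(45, 33, 2, population = "Paul do Mar")
#' comparePopulationFrequencies(fun, pdm)$test$p.value  # ~0.263
#' @export
comparePopulationFrequencies <- function(a, b,
                                         basis = c("genotype", "allele")) {
  basis <- match.arg(basis)
  tab <- .genotypeTable(a, b, basis)
  rownames(tab) <- c(a$population[1], b$population[1])
  test <- fisherExact(tab)
  structure(list(test = test, basis = basis, table = tab,
                 frequencyA = alleleFrequency(a)$frequency,
                 frequencyB = alleleFrequency(b)$frequency),
            class = "kdrComparison")
}

#' Test association between kdr genotype and resistance phenotype
#'
#' Builds the phenotype x genotype table from the resistant and
#' susceptible strata of one population/insecticide, drops genotype
#' classes absent from both strata, and applies the exact test.  Per-class
#' mutant allele frequencies are reported alongside the p-value.
#'
#' @param resistant,susceptible [genotypeCounts()] records for the two
#'   phenotype classes.
#' @param basis `"genotype"` (default, r x c exact test) or `"allele"`.
#' @return list of class `kdrAssociation` with the `resistTest`, the
#'   tested table and per-class allele frequencies.
#' @examples
#' res <- genotypeCounts(20, 10, 2, phenotypeClass = "resistant")
#' sus <- genotypeCounts(15, 4, 0, phenotypeClass = "susceptible")
#' associationTest(res, sus)$test$p.value  # ~0.491
#' @export
associationTest <- function(resistant, susceptible,
                            basis = c("genotype", "allele")) {
  basis <- match.arg(basis)
  tab <- .genotypeTable(resistant, susceptible, basis)
  rownames(tab) <- c("resistant", "susceptible")
  test <- fisherExact(tab)
  structure(list(test = test, basis = basis, table = tab,
                 frequencyResistant = alleleFrequency(resistant)$frequency,
                 frequencySusceptible =
                   alleleFrequency(susceptible)$frequency),
            class = "kdrAssociation")
}

#' @export
print.kdrComparison <- function(x, ...) {
  cat(sprintf("kdr frequency comparison (%s basis): %.2f vs %.2f, P = %.3g\n",
              x$basis, x$frequencyA, x$frequencyB, x$test$p.value))
  invisible(x)
}

#' @export
print.kdrAssociation <- function(x, ...) {
  cat(sprintf(
    "kdr-phenotype association (%s basis): freq %.2f (res) vs %.2f (sus), P = %.3g\n",
    x$basis, x$frequencyResistant, x$frequencySusceptible, x$test$p.value))
  invisible(x)
}
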
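# Table schemas, readers/writers and the end-to-end pipeline runner.
# All inputs are plain CSV/TSV with a header row; schemas are closed
# under round-trip (everything the pipeline writes can be read back).

.SCHEMAS <- list(
  bioassay = list(
    columns = c(population = "character", insecticide = "character",
                synergist = "character", tube_id = "character",
                n_exposed = "integer", n_dead_24h = "integer"),
    sep = ","),
  enzyme = list(
    columns = c(population = "character", enzyme_family = "character",
                individual_id = "character", activity = "numeric"),
    sep = ","),
  genotype = list(
    columns = c(locus = "character", population = "character",
                phenotype_class = "character",
                n_wildtype_hom = "integer", n_het = "integer",
                n_mutant_hom = "integer"),
    sep = ","),
  qpcr_samples = list(
    columns = c(gene = "character", role = "character",
                sample = "character", biological_replicate = "character",
                Ct = "numeric"),
    sep = ","),
  qpcr_dilution = list(
    columns = c(gene = "character", dilution_step = "integer",
                Ct = "numeric"),
    sep = ","))

.coerceColumn <- function(values, type, column, path) {
  if (any(is.na(values) | values == ""))
    stop(sprintf("%s: missing value in column '%s' (row %d)", path, column,
                 which(is.na(values) | values == "")[1]))
  out <- switch(type,
    character = as.character(values),
    integer = suppressWarnings(as.integer(values)),
    numeric = suppressWarnings(as.numeric(values)))
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("%s: cannot parse '%s' as %s in column '%s' (row %d)",
                 path, values[bad[1]], type, column, bad[1]))
  out
}

#' Read and validate a pipeline input table
#'
#' @param path file path.
#' @param schema one of `"bioassay"`, `"enzyme"`, `"genotype"`,
#'   `"qpcr_samples"`, `"qpcr_dilution"`.
#' @return validated data.frame.  Errors name the file, row and column;
#'   unknown extra columns are kept with a warning (forward
#'   compatibility).
#' @export
readTable <- function(path, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  if (!file.exists(path)) stop("input file not found: ", path)
  spec <- .SCHEMAS[[schema]]
  df <- utils::read.table(path, header = TRUE, sep = spec$sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(names(spec$columns), names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), names(spec$columns))
  if (length(extra))
    warning(sprintf("%s: ignoring unknown column(s): %s", path,
                    paste(extra, collapse = ", ")))
  for (col in names(spec$columns))
    df[[col]] <- .coerceColumn(df[[col]], spec$columns[[col]], col, path)
  .validateSchema(df, schema, path)
  df
}

.validateSchema <- function(df, schema, path) {
  bad <- switch(schema,
    bioassay = which(df$n_dead_24h < 0 | df$n_dead_24h > df$n_exposed),
    enzyme = which(df$activity < 0),
    genotype = which(df$n_wildtype_hom < 0 | df$n_het < 0 |
                       df$n_mutant_hom < 0),
    qpcr_samples = which(df$Ct <= 0),
    qpcr_dilution = which(df$Ct <= 0 | df$dilution_step < 1),
    integer(0))
  if (length(bad))
    stop(sprintf("%s: invariant violation at row %d (%s schema)", path,
                 bad[1], schema))
  invisible(df)
}

#' Write a pipeline table
#'
#' @param df data.frame.
#' @param path output path; extension `.tsv` selects tab separation,
#'   anything else comma.
#' @export
writeTable <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read multi-contrast expression tables into a ContrastExperiment
#'
#' Each contrast is one TSV with columns `probe_id`, `rep1..repN`
#' (log2-ratios) and `flag1..flagN` (detected/marginal/absent).
#'
#' @param paths named character vector: one TSV path per contrast, names
#'   are the contrast labels.
#' @return a [ContrastExperiment-class].
#' @export
readContrastTables <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("'paths' must be named by contrast label")
  pieces <- lapply(names(paths), function(label) {
    path <- paths[[label]]
    if (!file.exists(path)) stop("input file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"probe_id" %in% names(df))
      stop(path, ": missing required column 'probe_id'")
    repCols <- grep("^rep[0-9]+$", names(df), value = TRUE)
    flagCols <- grep("^flag[0-9]+$", names(df), value = TRUE)
    if (length(repCols) < 2L)
      stop(path, ": need at least 2 replicate (rep*) columns")
    if (length(flagCols) != length(repCols))
      stop(path, ": flag* columns must match rep* columns")
    ratios <- as.matrix(df[, repCols, drop = FALSE])
    if (!is.numeric(ratios) || any(!is.finite(ratios)))
      stop(path, ": log2-ratio columns must be numeric with no missing ",
           "values")
    flags <- as.matrix(df[, flagCols, drop = FALSE])
    rownames(ratios) <- rownames(flags) <- df$probe_id
    list(label = label, ratios = ratios, flags = flags)
  })
  ids <- lapply(pieces, function(p) rownames(p$ratios))
  if (length(unique(ids)) != 1L)
    stop("all contrast tables must share an identical probe set")
  ratios <- do.call(cbind, lapply(pieces, `[[`, "ratios"))
  flags <- do.call(cbind, lapply(pieces, `[[`, "flags"))
  contrast <- rep(vapply(pieces, `[[`, "", "label"),
                  vapply(pieces, function(p) ncol(p$ratios), 0L))
  ContrastExperiment(ratios, contrast = contrast, flags = flags)
}

#' Write a ContrastExperiment as per-contrast TSVs
#'
#' @param x a [ContrastExperiment-class].
#' @param dir output directory; one `<contrast>.tsv` per contrast.
#' @return the written paths, named by contrast.
#' @export
writeContrastTables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(contrastNames(x), function(cn) {
    m <- log2Ratios(x, cn); fl <- detectionFlags(x, cn)
    df <- data.frame(probe_id = rownames(m), m, fl, check.names = FALSE)
    names(df) <- c("probe_id", paste0("rep", seq_len(ncol(m))),
                   paste0("flag", seq_len(ncol(fl))))
    path <- file.path(dir, paste0(cn, ".tsv"))
    writeTable(df, path)
    path
  }, "")
  paths
}

#' Read genotype counts as a list of genotypeCounts records
#'
#' @param path genotype CSV (schema `"genotype"`).
#' @return data.frame of validated genotype counts, one row per locus x
#'   population x phenotype class.
#' @export
readGenotypeCounts <- function(path) {
  readTable(path, "genotype")
}

.sigfmt <- function(x, digits) {
  ifelse(is.na(x), NA, signif(x, digits))
}

#' Format a differential-expression result table for export
#'
#' Rounds to the documented output precision (fold changes to 2
#' significant figures, p-values to 3) and writes a TSV with the
#' per-contrast FC and P columns, averaged FC, combined P and status.
#'
#' @param results `DataFrame` from [callDifferentialExpression()].
#' @param path output TSV path.
#' @param fcDigits significant figures for fold changes (default 2).
#' @export
writeDeResults <- function(results, path, fcDigits = 2) {
  df <- as.data.frame(results)
  for (col in grep("^(fc\\.|meanFc)", names(df), value = TRUE))
    df[[col]] <- .sigfmt(df[[col]], fcDigits)
  for (col in grep("^(p\\.|combinedP)", names(df), value = TRUE))
    df[[col]] <- .sigfmt(df[[col]], 3)
  writeTable(df, path)
}

#' Run the resistance-analysis pipeline end to end
#'
#' Executes every stage whose inputs are configured and collects one
#' consolidated report.  The configuration is a list (or a YAML file
#' path) with any of the elements:
#' \describe{
#'   \item{bioassay}{list(path =, populations =, insecticides =,
#'     synergists =) - tube-count CSV; synergist tests are run for every
#'     population x insecticide x synergist combination present.}
#'   \item{enzyme}{list(path =, field =, reference =) - activity CSV;
#'     each enzyme family present is compared.}
#'   \item{expression}{list(paths = named TSV vector, alpha =,
#'     fcThreshold =, rescueFc =) - multi-contrast caller.}
#'   \item{qpcr}{list(samplesPath =, dilutionPath =, referenceGenes =)
#'     - efficiency estimation plus Pfaffl ratios for every target gene.}
#'   \item{genotypes}{list(path =, basis =) - per-locus allele
#'     frequencies; population comparison and phenotype association
#'     where the strata allow it.}
#'   \item{outDir}{output directory for per-stage TSV/JSON files
#'     (optional; no files are written when absent).}
#'   \item{seed}{integer seed recorded in the report.}
#' }
#'
#' @param config list or YAML path.
#' @return list of class `resistReport` with one element per executed
#'   stage plus the config echo.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML path")
  outDir <- config$outDir
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, stages = list())

  if (!is.null(config$bioassay)) {
    tab <- readTable(config$bioassay$path, "bioassay")
    conds <- unique(tab[tab$insecticide != "control",
                        c("population", "insecticide", "synergist")])
    summaries <- lapply(seq_len(nrow(conds)), function(i)
      pooledMortality(tab, conds$population[i], conds$insecticide[i],
                      conds$synergist[i]))
    synTests <- list()
    synConds <- conds[conds$synergist != "none", , drop = FALSE]
    for (i in seq_len(nrow(synConds))) {
      base <- conds$population == synConds$population[i] &
        conds$insecticide == synConds$insecticide[i] &
        conds$synergist == "none"
      if (any(base))
        synTests[[length(synTests) + 1L]] <-
          synergistEffect(tab, synConds$population[i],
                          synConds$insecticide[i], synConds$synergist[i])
    }
    summaryDf <- do.call(rbind, lapply(summaries, function(s)
      data.frame(population = s$population, insecticide = s$insecticide,
                 synergist = s$synergist,
                 mortality = round(s$mortality, 1),
                 corrected_mortality = round(s$correctedMortality, 1),
                 tube_sd = round(s$tubeSd, 1), n_total = s$nTotal,
                 classification = s$classification, low_n = s$lowN)))
    if (!is.null(outDir))
      writeTable(summaryDf, file.path(outDir, "bioassay_summary.tsv"))
    report$stages$bioassay <- list(summaries = summaries,
                                   synergistTests = synTests,
                                   table = summaryDf)
  }

  if (!is.null(config$enzyme)) {
    act <- readTable(config$enzyme$path, "enzyme")
    fams <- unique(act$enzyme_family)
    comps <- lapply(fams, function(f)
      compareEnzymeActivity(act, config$enzyme$field,
                            config$enzyme$reference, f))
    names(comps) <- fams
    report$stages$enzyme <- comps
  }

  if (!is.null(config$expression)) {
    ec <- config$expression
    x <- readContrastTables(unlist(ec$paths))
    cfg <- deConfig(
      alpha = if (is.null(ec$alpha)) 0.05 else ec$alpha,
      fcThreshold = if (is.null(ec$fcThreshold)) 2 else ec$fcThreshold,
      rescueFc = if (is.null(ec$rescueFc)) 20 else ec$rescueFc)
    res <- callDifferentialExpression(x, cfg)
    if (!is.null(outDir))
      writeDeResults(res, file.path(outDir, "diffexpr_results.tsv"))
    report$stages$expression <- list(
      results = res,
      counts = table(res$status),
      expectedFalsePositives =
        S4Vectors::metadata(res)$expectedFalsePositives)
  }

  if (!is.null(config$qpcr)) {
    qc <- config$qpcr
    samples <- readTable(qc$samplesPath, "qpcr_samples")
    dil <- readTable(qc$dilutionPath, "qpcr_dilution")
    refGenes <- qc$referenceGenes
    effs <- vapply(unique(dil$gene), function(g)
      estimateEfficiency(dil, gene = g)$efficiency, 0)
    targets <- setdiff(unique(samples$gene), refGenes)
    ratios <- lapply(targets, function(g)
      pfafflRatio(samples, g, refGenes, effs))
    names(ratios) <- targets
    if (!is.null(outDir)) {
      df <- do.call(rbind, lapply(ratios, function(r)
        data.frame(gene = r$gene, fold_change = signif(r$ratio, 3),
                   ci_lower = signif(r$ci95[["lower"]], 3),
                   ci_upper = signif(r$ci95[["upper"]], 3),
                   n = r$nReplicates)))
      writeTable(df, file.path(outDir, "qpcr_ratios.tsv"))
    }
    report$stages$qpcr <- list(efficiencies = effs, ratios = ratios)
  }

  if (!is.null(config$genotypes)) {
    gc <- config$genotypes
    counts <- readGenotypeCounts(gc$path)
    basis <- if (is.null(gc$basis)) "genotype" else gc$basis
    asRecord <- function(row)
      genotypeCounts(row$n_wildtype_hom, row$n_het, row$n_mutant_hom,
                     row$locus, row$population, row$phenotype_class)
    freqs <- lapply(seq_len(nrow(counts)), function(i)
      alleleFrequency(asRecord(counts[i, ])))
    freqDf <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
      af <- freqs[[i]]
      cbind(counts[i, ],
            mutant_allele_freq = round(af$frequency, 2),
            fixed = af$fixed)
    }))
    tests <- list()
    for (locus in unique(counts$locus)) {
      pooled <- counts[counts$locus == locus &
                         counts$phenotype_class == "all", ]
      if (nrow(pooled) == 2L &&
          !alleleFrequency(asRecord(pooled[1, ]))$fixed) {
        tests[[paste0(locus, "_population")]] <-
          comparePopulationFrequencies(asRecord(pooled[1, ]),
                                       asRecord(pooled[2, ]),
                                       basis = basis)
      }
      strata <- counts[counts$locus == locus &
                         counts$phenotype_class != "all", ]
      phen <- strata$phenotype_class
      resRows <- grep("resistant$", phen)
      for (i in resRows) {
        susLabel <- sub("resistant$", "susceptible", phen[i])
        j <- which(phen == susLabel &
                     strata$population == strata$population[i])
        if (length(j) == 1L) {
          key <- paste(locus, strata$population[i],
                       sub(" resistant$", "", phen[i]), sep = "_")
          tests[[key]] <- tryCatch(
            associationTest(asRecord(strata[i, ]),
                            asRecord(strata[j, ]), basis = basis),
            error = function(e) e$message)
        }
      }
    }
    if (!is.null(outDir))
      writeTable(freqDf, file.path(outDir, "kdr_frequencies.tsv"))
    report$stages$kdr <- list(frequencies = freqs, table = freqDf,
                              tests = tests)
  }

  if (length(report$stages) == 0L)
    stop("no stage inputs configured")
  if (!is.null(outDir)) {
    jsonlite::write_json(.reportJson(report),
                         file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "resistReport")
}

# Flatten the report into JSON-friendly scalars.
.reportJson <- function(report) {
  out <- list(stages = names(report$stages),
              seed = report$config$seed)
  if (!is.null(report$stages$bioassay))
    out$bioassay <- lapply(report$stages$bioassay$summaries, function(s)
      list(population = s$population, insecticide = s$insecticide,
           synergist = s$synergist, mortality = round(s$mortality, 1),
           classification = s$classification))
  if (!is.null(report$stages$enzyme))
    out$enzyme <- lapply(report$stages$enzyme, function(x)
      list(family = x$enzymeFamily, p = signif(x$test$p.value, 3),
           direction = x$direction, significant = x$significant))
  if (!is.null(report$stages$expression)) {
    cnt <- report$stages$expression$counts
    out$expression <- list(
      counts = as.list(stats::setNames(as.integer(cnt), names(cnt))),
      expectedFalsePositives =
        as.list(report$stages$expression$expectedFalsePositives))
  }
  if (!is.null(report$stages$qpcr))
    out$qpcr <- lapply(report$stages$qpcr$ratios, function(r)
      list(gene = r$gene, ratio = signif(r$ratio, 3)))
  if (!is.null(report$stages$kdr))
    out$kdr <- lapply(report$stages$kdr$tests, function(t)
      if (is.character(t)) t else signif(t$test$p.value, 3))
  out
}

#' @export
print.resistReport <- function(x, ...) {
  cat("Resistance-analysis run:", length(x$stages), "stage(s):",
      paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' Bundled example: detoxification-gene fold-change table
#'
#' Published per-contrast fold changes and p-values for the 12
#' detoxification transcripts commonly over-expressed in the Funchal and
#' Paul do Mar Ae. aegypti populations relative to susceptible reference
#' colonies (three contrasts).  Useful as a worked example for
#' [callFoldChangeTable()].
#'
#' @return list with matrices `fc` and `p` (genes x contrasts) and the
#'   annotation data.frame `info`.
#' @export
madeiraDetoxTable <- function() {
  path <- system.file("extdata", "madeira_detox_fc.tsv",
                      package = "AedesResist", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fcCols <- grep("^fc\\.", names(df))
  pCols <- grep("^p\\.", names(df))
  fc <- as.matrix(df[, fcCols]); p <- as.matrix(df[, pCols])
  rownames(fc) <- rownames(p) <- make.unique(df$gene)
  colnames(fc) <- sub("^fc\\.", "", names(df)[fcCols])
  colnames(p) <- sub("^p\\.", "", names(df)[pCols])
  list(fc = fc, p = p, info = df[, c("class", "accession", "gene")])
}

#' Bundled example: kdr genotype counts for the Madeira populations
#'
#' Genotype counts at the V1016I and F1534C voltage-gated sodium channel
#' codons for pyrethroid-phenotyped Ae. aegypti from Funchal and Paul do
#' Mar, stratified by bioassay phenotype, plus pooled ("all") rows.
#'
#' @return validated genotype-count data.frame.
#' @export
madeiraKdrCounts <- function() {
  readGenotypeCounts(system.file("extdata", "madeira_kdr_counts.csv",
                                 package = "AedesResist", mustWork = TRUE))
}
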
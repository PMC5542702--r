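# AedesResist

Insecticide-resistance characterisation of *Aedes aegypti* field
populations combines several independent evidence streams: WHO tube
bioassays (does the population survive a diagnostic dose?), synergist
assays and biochemical enzyme assays (is detoxification metabolism
involved?), transcriptome comparisons against susceptible reference
colonies (which detoxification genes are over-expressed?), qRT-PCR
validation of candidate genes, and genotyping of knockdown-resistance
(*kdr*) mutations in the voltage-gated sodium channel. **AedesResist**
implements this whole analysis workflow as a tested R package for vector
biologists and resistance-surveillance programmes, together with
synthetic-data generators so that every stage can be exercised and
calibrated without access to the original raw data.

## What the package computes

* **WHO bioassay analysis** — pooled tube mortality with per-tube SD,
  Abbott correction for control mortality (applied for control mortality
  in [5%, 20%], invalid above 20%), and the strict classification rule:
  mortality below 90% ⇒ resistant (optionally the 90–98% "suspected"
  band). Synergist restoration (PBO/DEM) is tested with a two-sided
  Fisher exact test on the pooled dead/alive 2×2 table.
* **Enzyme activities** — Mann–Whitney rank-sum comparison of
  per-mosquito α/β-esterase, GST and MFO activities between a field
  population and the susceptible reference strain.
* **Replication-criterion differential expression** — for probe-level
  log2(field/reference) ratios across K contrasts (here: Funchal vs
  Rockefeller, Funchal vs New Orleans, Paúl do Mar vs Rockefeller; 4
  replicate arrays each), a probe must be detectable in every array,
  and is called *significant* only when every contrast shows P < 0.05
  (one-sample t-test of mean log2-ratio against 0) **and** |FC| > 2 with
  a consistent direction. Probes passing in all but one contrast are
  rescued as *potential* when every passing contrast shows extreme
  expression (|FC| > 20). The implied error rate is analytic:
  E[FP] = N·α^k, i.e. 9083·0.05 ≈ 454 for one comparison but
  9083·0.05³ ≈ 1.1 under the 3/3 criterion. Fold changes are averaged
  and p-values combined (Fisher's method, χ² = −2Σln p on 2k df) for
  reporting only.
* **Pfaffl qRT-PCR quantification** — amplification efficiency from the
  slope of Ct vs log10(input) over a 5-fold dilution series
  (E = 10^(−1/slope)), then the efficiency-corrected ratio
  E_target^ΔCt(target) / E_ref^ΔCt(ref), with ΔCt = Ct(control) −
  Ct(sample) and the geometric mean of the ribosomal-protein reference
  genes L8 and S7 as the normalisation term; t-based 95% CI over
  biological replicates.
* ***kdr* genotype analytics** — mutant allele frequencies
  ((n_het + 2·n_hom)/2N) at V1016I and F1534C, exact genotype-table
  comparisons between populations, and genotype–phenotype association
  tests (Fisher–Freeman–Halton probability-ordering enumeration for
  r×c tables, written in-package and cross-checked against independent
  oracles).

## Worked example

Classify the twelve detoxification transcripts from the bundled
fold-change table (three contrasts each):

```r
library(AedesResist)
t1 <- madeiraDetoxTable()
callFoldChangeTable(t1$fc, t1$p)
#>                gene meanFc combinedP      status direction
#> Cyp9J32     Cyp9J32  34.67  1.51e-04   potential        up
#> Cyp9J28     Cyp9J28  23.67  3.82e-04 significant        up
#> Cyp6BB2     Cyp6BB2  12.53  3.67e-06 significant        up
#> ...
#> GSTd4         GSTd4  18.60  8.38e-08 significant        up
#> GSTs1         GSTs1   3.20  1.14e-07 significant        up
```

Eleven transcripts pass the 3/3 replication criterion; *Cyp9J32*
(P = 0.060 in one contrast, FC 41 and 53 in the passing ones) is rescued
as *potential*. Compare *kdr* allele frequencies between populations:

```r
fun <- genotypeCounts(62, 27, 2, population = "Funchal")
pdm <- genotypeCounts(45, 33, 2, population = "Paul do Mar")
alleleFrequency(fun)
#> V1016I, Funchal / all: mutant allele frequency 0.17 (182 alleles)
comparePopulationFrequencies(fun, pdm)
#> kdr frequency comparison (genotype basis): 0.17 vs 0.23, P = 0.263
```

The frequencies differ only modestly and the exact test finds no
significant difference. Run the caller on simulated data with known
truth:

```r
ce <- simulateExpression(expressionSimConfig(seed = 1))
res <- callDifferentialExpression(ce)
table(res$status)
#>        filtered not_significant     significant
#>            1008            7956             119
```

With the default 1.5% of probes truly regulated at 4-fold, essentially
all spiked probes are recovered (119 significant of 136 simulated, none
of them false) and ~11% of probes fail the detectability filter at the
default 1% per-array dropout.

An end-to-end run over CSV/TSV inputs is available through
`runPipeline()` (list or YAML configuration); see the vignette in
`vignettes/resistance-workflow.Rmd` for the model details and design
choices.

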
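---
title: "Models and methods behind the AedesResist workflow"
author: "AedesResist authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the AedesResist workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AedesResist)
```

# Scope

AedesResist analyses the evidence streams of an insecticide-resistance
characterisation study of *Aedes aegypti*: WHO tube-bioassay mortality,
synergist restoration, enzyme activities, multi-contrast expression
log-ratios, qRT-PCR validation and *kdr* genotype counts. The package's
boundary is statistical analysis of tabulated measurements: array
normalisation, Ct calling, primer design and all wet-lab steps are
upstream, and normalised log2-ratios / called Cts / genotype counts are
the inputs.

# Bioassay model

Each exposure condition (population × insecticide × synergist arm) is a
set of replicate tubes of 20–25 females; deaths at 24 h are binomial
per tube. Pooled mortality is the exposure-weighted mean
$100\sum d_i / \sum n_i$ — always inside the range of per-tube
mortalities — and the reported spread is the SD of per-tube mortalities,
matching how such assays are usually displayed. Interpretation requires
at least 100 exposed individuals; smaller totals set a `lowN` flag
rather than failing, so that synthetic stress tests can run small.

Abbott's correction $(obs - ctrl)/(100 - ctrl)\cdot 100$ is applied only
when control mortality is in [5%, 20%] (below 5% no correction is
needed; above 20% the run is invalid, per WHO practice). Classification
uses the strict rule *mortality < 90% ⇒ resistant*; exactly 90% is not
resistant. The 90–98% "suspected" band is the WHO convention and is the
default three-class output; `paperMode = TRUE` collapses to the
two-class below-90% rule, which is the rule the bundled examples use.

The synergist test pools dead/alive counts over tubes in each arm into a
2×2 table and applies the two-sided Fisher exact test. Pooling (rather
than comparing replicate-level rates) is a deliberate choice: diagnostic
assays report one mortality per condition, and tube identity carries no
information under the binomial model. Degenerate tables (e.g. complete
mortality in both arms) give P = 1 with no special-casing because a
single table is compatible with the margins.

# Exact contingency tests

The shared exact test is written in the package because every stage
leans on it, in shapes (2×3) and conventions that need to be pinned
down. For an r×c table with fixed margins the two-sided p-value follows
the probability-ordering (Freeman–Halton) rule: the total multivariate
hypergeometric probability of all margin-preserving tables whose point
probability does not exceed the observed one (with a 1e-7 relative
tolerance on the comparison to absorb floating-point noise). For 2×2
tables this reduces to the classic two-sided Fisher test and is computed
directly on the hypergeometric support with no size limit; larger
shapes are enumerated over the free cells and the grand total is capped
at 500 — an explicit "enumeration limit" error, never a silent
approximation. The test suite checks the implementation against two
independent oracles (binomial-coefficient enumeration, and
`stats::fisher.test`) across the complete set of 2×2 tables with total
≤ 40 and random 2×3 tables.

The Mann–Whitney test computes U from midranks; with a combined sample
of at most 20 and no ties the p-value is exact (two-sided as twice the
smaller tail of the null U distribution), otherwise a normal
approximation with tie correction and a 0.5 continuity correction is
used — the relevant regime at the assay's n = 40 per group, where exact
enumeration is infeasible. The method actually used is recorded in the
result. One- vs two-sidedness is not always stated in published
resistance reports; AedesResist is two-sided throughout.

# Replication-criterion expression caller

The expression container (`ContrastExperiment`, a
`SummarizedExperiment`) holds probe × array log2(field/reference)
ratios with per-probe-per-array detection flags
(detected/marginal/absent) and the contrast structure in `colData`.
The caller proceeds:

1. **Detectability filter.** A probe is retained only if no flag is
   "absent" in any array of any contrast ("marginal" passes). This is
   deliberately strict: with per-array dropout probability $d$ and $m$
   arrays, the retained fraction is $(1-d)^m$.
2. **Per-contrast statistics.** The signed fold change maps the mean
   log2-ratio $m$ to $2^m$ (or $-2^{-m}$ for $m<0$), so |FC| ≥ 1 and
   under-expression is negative. The p-value is the two-sided
   one-sample t-test of the log2-ratios against 0 — exactly the null
   hypothesis of a field/colony expression ratio of 1. Zero-variance
   samples are degenerate: P = 1 at the null, otherwise P = 0 with a
   flag.
3. **Replication rule.** *Significant* requires P < α and |FC| >
   fcThreshold in **every** contrast with one common direction;
   *potential* (the rescue rule) requires passing in at least K−1
   contrasts with consistent sign **and** |FC| > rescueFc in every
   passing contrast. Enforcing the extreme-expression bound on the
   passing contrasts (not the average, not the failing contrast) is the
   reading consistent with the bundled example table, where the rescued
   gene shows FC 41 and 53 in its passing contrasts and 10 in the
   failing one. Sign-inconsistent passes are never promoted, and calls
   are monotone in evidence (property-tested).
4. **Reporting.** Fold changes are averaged (arithmetically on the
   signed scale by default; a geometric option on the ratio scale is
   provided) and p-values are combined with Fisher's method,
   $\chi^2 = -2\sum\ln p$ on $2K$ df. Both are descriptive: averaging
   plays no role in significance assessment, and the test suite asserts
   the calls are unchanged under either averaging mode.

No multiplicity adjustment is applied to the per-contrast p-values; the
replication criterion itself is the error control, and
`expectedFalsePositives(n, alpha, k)` = $n\alpha^k$ makes the implied
rate explicit (454.15 for one comparison at n = 9083, 1.14 for 3/3).
This independence-based expectation is also the yardstick for the null
calibration test: over 50 simulated null datasets the mean number of
probes with P < 0.05 in all three contrasts is checked against a 99%
Poisson band around 1.14.

# qRT-PCR quantification

Amplification efficiency per primer pair comes from a least-squares fit
of Ct against log10(relative input) over a 5-fold dilution series
(minimum 3 points): $E = 10^{-1/\text{slope}}$, with $R^2$ reported and
estimates outside (1, 2.2] flagged rather than silently accepted. The
Pfaffl ratio per biological replicate is
$E_t^{\Delta Ct_t} / E_{ref}^{\Delta Ct_{ref}}$ with
$\Delta Ct = \overline{Ct}_{control} - Ct_{sample}$, so up-regulation in
the field sample gives ratios above 1. Two conventions had to be fixed
where practice varies:

* **Dual reference genes** (ribosomal proteins L8 and S7) are combined
  as the geometric mean of their normalisation terms — the established
  multi-reference convention, equivalent to averaging their
  $\Delta Ct$ on the log scale.
* **The 95% CI** is a t-interval over per-biological-replicate ratios
  (n = 4 here). Published tables rarely state their CI method; the
  t-interval is the simplest one consistent with replicate-level
  ratios. Technical replicates, when present, are averaged within
  biological replicate first.

When all efficiencies equal 2 the ratio reduces algebraically to
$2^{-\Delta\Delta Ct}$; the suite asserts this identity on random data,
and that swapping control and sample inverts the ratio.

# kdr genotype analytics

Individuals are the sampling unit; allele counts are always derived
($f = (n_{het} + 2 n_{hom})/2N$), never input. Frequency comparisons
between populations and genotype–phenotype association both default to
the genotype-level 2×3 exact test, with genotype classes absent from
both strata dropped first. The allele-based 2×2 test (2N alleles per
stratum) is available as an explicit option but is not the default: it
double-counts individuals as independent alleles and, on the bundled
genotype counts, yields a visibly smaller p-value than the genotype
table, whose result matches the published comparison (P = 0.263). A
fixed locus (frequency 1, as F1534C here) is reported with a fixation
flag and never tested — there is no variance to test.

# Synthetic-data generators

Every generator draws from the model its analysis assumes, returns
ground truth alongside the data, and is deterministic under a fixed
seed. Defaults are the study conditions the package targets and are not
tuning knobs:

* **Expression:** 9083 probes, 3 contrasts × 4 replicate arrays. True
  effects sit symmetrically at ±`deLog2fc` on the log2 scale (default
  2, i.e. 4-fold) with replicate noise SD 0.25; 1% of probes truly up-
  and 0.5% down-regulated, the order of magnitude of the detox-focused
  studies this emulates (86 up-regulated of 9083 ≈ 1%). Detection
  flags are sampled per probe × array: "absent" with probability 0.01,
  otherwise "marginal" with probability 0.02 — values chosen once as
  plausible array dropout, since no raw-array noise estimates are
  published to reconstruct.
* **Bioassay:** binomial deaths per tube; 5 tubes × 25 mosquitoes
  (protocol: four or five replicates of 20–25), control tubes at 0%
  mortality by default.
* **Genotypes:** Hardy–Weinberg proportions $p^2, 2pq, q^2$; phenotype
  from a logistic model additive on log-odds with a per-allele odds
  multiplier (1 = null) — the simplest model spanning both regimes.
* **qPCR:** $Ct = \text{intercept} - \log_E(\text{input}) + \epsilon$,
  5-fold dilution series, 4 biological replicates, Ct noise SD 0.2
  cycles; efficiencies validated into (1, 2.2].
* **Enzyme activity:** log-normal per-individual activities (assays of
  this kind are right-skewed and strictly positive), 40 individuals per
  group, field group scaled by a multiplicative shift.

What the generators do *not* emulate: probe sequences, dye bias,
spatial array artifacts, between-tube overdispersion, linkage between
loci, or inter-plate qPCR effects. Passing calibration tests therefore
demonstrates correctness of the statistical machinery under the stated
models, not robustness to every artefact of real data.

# Numerical choices and degenerate inputs

* Exact-test tie comparison uses a 1e-7 relative tolerance;
  permutation invariance of the p-value is property-tested.
* Combined p-values clamp inputs at 1e-300 before the log only inside
  the vectorised caller; the user-facing `fishersMethod()` rejects
  p ≤ 0 outright.
* Zero-variance t-tests, all-dead/all-alive synergist tables,
  monomorphic loci and single-table margins all return defined results
  (flagged) instead of NaN.
* Per-stage substream seeds are derived from one global seed inside the
  32-bit integer range so stages can be regenerated independently.
* Problem sizes in the test suite are chosen to keep the full run near
  a minute while leaving Monte-Carlo bands narrow enough to be
  informative (50 null datasets of 9083 probes for calibration; 400
  bioassay replicates; 200-1000 seeds for type-I checks).

# Known limitations

* The exact r×c test enumerates; very large sparse tables (total >
  500) need an asymptotic or network-algorithm approach the package
  deliberately does not provide.
* The Mann–Whitney exact branch is limited to untied samples of
  combined size ≤ 20; beyond that the corrected normal approximation
  is used (adequate at n = 40 per group, as its type-I calibration
  test shows).
* The caller assumes contrasts are independent when quantifying
  expected false positives; shared reference colonies induce mild
  positive dependence, making $n\alpha^k$ an approximation (in the
  conservative direction for the replication rule).
* qRT-PCR confidence intervals ignore efficiency-estimation
  uncertainty; they condition on the fitted E.
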
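---
title: "Mechanistic phenotypes and reverse-genetics association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic phenotypes and reverse-genetics association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechphen)
```

## The problem

A single damaging coding variant can perturb one cellular or physiological
mechanism — coagulation, DNA repair, chromosome segregation — and thereby
surface in the medical record as several *different* clinical diagnoses.
Conventional phenome-wide analyses test one diagnosis at a time and dilute
exactly this kind of signal.  `mechphen` implements the opposite strategy:
diagnoses presumed to share a mechanism are aggregated into a **mechanistic
phenotype** (all vessel-occlusive codes; all cancers; all metastatic
cancers; ...), and low minor-allele-frequency non-synonymous SNPs
(MAF < 0.1, at least ~10 minor-allele homozygotes) are tested against these
aggregates.  Because any single cohort is underpowered for individually
significant hits at these frequencies, discovery is shifted to a second
stage: genes are ranked by association p-value and scanned for
functional-ontology enrichment.

## Phenotype construction

ICD-9 codes are normalized (dot stripped, `V`/`E` prefixes kept, matched
exactly as strings), mapped many-to-one into constituent diagnosis groups,
and groups are assigned one-to-many to mechanistic phenotypes.  A subject
is a **case** for a phenotype if it carries at least one constituent group;
everything else in the roster is a control, including subjects with no
recorded diagnosis at all (EMR absence is treated as absence of disease —
a deliberate, documented simplification).  Group tables are user-supplied
configuration; a small illustrative thrombosis map ships in
`inst/extdata/`.

## Association models

Four models score each SNP against each phenotype.

**Forward models.** Additive (dosage 0/1/2) and recessive (homozygote
indicator) multivariable logistic regression, adjusting for gender, age
(continuous) and source dataset, reported as Wald odds ratios with 95%
confidence intervals — the convention of the standard GWAS toolchain, so
numbers are directly comparable.  Non-convergence and complete separation
(frequent in recessive codings of rare homozygotes) are flagged and the
p-value set missing; a Firth-penalized fallback is available
(`firth = TRUE`) but off by default to keep the default output comparable
to unpenalized tools.  Only OR > 1 (strictly) associations feed the
enrichment stage, because the hypothesis concerns risk-increasing
low-frequency variants.

**Reverse-genetics models.** These invert the usual logic: instead of a
fixed case definition, the phenotype is *conditioned on the minor-allele
homozygotes themselves*.  Only homozygotes are analyzed (heterozygous
carriers of an additive variant would blur the homozygote contrast):

1. find the constituent diagnoses carried by at least `minCount`
   (default 2) distinct minor-allele homozygotes (HZMA) — the
   "multiply-occurring" diagnoses;
2. model 2 additionally requires each such diagnosis to be over-represented
   in HZMA versus common-allele homozygotes at a one-sided Fisher exact
   p < 0.1 (one-sided because the filter exists to catch HZMA excess, not
   depletion);
3. the statistic is the **tally**: the number of HZMA subjects carrying at
   least one qualifying diagnosis.

Because the qualifying set is optimized on the observed homozygotes, the
tally is biased upward by construction ("winner's curse"); its null
distribution must therefore subject every permutation to the same
optimization.  The p-value is obtained by reassigning genotype labels
among subjects `B` times (default 10,000) within strata of dataset, gender
and age (decade bins by default — the paper-style stratification list with
an unstated bin width, fixed here at 10 years and configurable),
re-deriving the qualifying set inside every permutation, and counting
permutations whose tally equals or exceeds the observed one.  Per-stratum
genotype counts (hence MAF) are preserved exactly.  The default estimator
is the plain `count/B` proportion, which can return 0; the anchored
`(count+1)/(B+1)` variant never does and is preferable when p-values are
subsequently ranked.

A note on the carrier threshold: the framework's sources describe the
multiply-occurring rule both as "more than once" (`minCount = 2`) and as
"more than 2 affected" (`minCount = 3`) in different places.  The package
default is 2; the ROC simulation study below is also run at 3, where the
published operating points were measured.  The threshold is a plain
argument everywhere.

The permutation engine is implemented in C++ with a self-contained
xoshiro256++ generator seeded per SNP (`seed` mixed with the SNP index), so
results are reproducible, independent of SNP order, and fast enough for
simulation-scale work (about 1 microsecond per permutation on a typical
core at cohort size 1,655).  The R-level operations (`rgTally`,
`diagnosisFisher`, `multiplyOccurring`) are the readable reference
implementation; the test suite holds the two paths equal and checks both
against exhaustive enumeration on small cohorts.

## Enrichment scan

Genes are ranked by their best (minimum) association p-value over their
nsSNPs — most genes carry a single nsSNP, so the minimum is essentially the
identity; in the pooled cancer mode each gene enters once at its best p
across the four cancer phenotypes (deduplicated universe; the
gene-phenotype-pair alternative is available via per-phenotype runs).  For
`k = 1, 2, ...` up to the number of genes with p below 0.05 (or a fixed
top-50 in GWAS mode), every nested top-`k` set is Fisher-tested
(one-sided hypergeometric) against every ontology term annotating the
universe, and each term reports its minimum Fisher p with the `k` and
association-p threshold attaining it.  Genes tied at a p boundary enter
together, so `k` jumps across tie blocks and the scan is invariant to
within-tie ordering.  Terms are flat labels (a DAVID-style export); no GO
graph propagation is attempted.

The scan minimum is an optimum over nested tests and is therefore
anti-conservative as a standalone p-value.  The package treats it as a
ranking statistic: Benjamini–Hochberg adjustment is applied across the `m`
ontologies present among the input genes (`bhAdjust(p, m)`, implemented on
`stats::p.adjust` with an explicit universe size so absent terms count at
p = 1), and a term is called significant only at FDR < 0.05 *and* at least
two annotated genes among those selected — a single driving gene is never
accepted as a mechanism.

## Synthetic cohorts

No patient-level data can ship with the package, so `generateCohort()`
produces cohorts with the statistical structure the analyses assume:

* **Covariates.** Age from a truncated normal (defaults 52.3 ± 17.7 years,
  truncated to 18–95 and rounded), gender and source-dataset labels from
  fixed fractions.
* **Diagnoses.** Subject `i` carries constituent group `g` with probability
  `plogis(alpha_g + 0.35 * (age_i - mean)/10 + 0.3 * male_i + u_i)`, with a
  shared frailty `u_i ~ N(0, sigma^2)`.  The age and gender log-odds are
  fixed package choices reflecting the strong age dependence of thrombotic
  and neoplastic disease; the shared frailty makes diagnoses co-occur
  within subjects, as multimorbid EMR populations do.  The intercepts
  `alpha_g` are calibrated by one-dimensional root finding (deterministic
  quantile grids over the frailty and covariates) so that each group's
  marginal prevalence matches its profile value, and `sigma` is calibrated
  so the induced *any-diagnosis* prevalence matches its target (default
  thrombosis profile: eight groups at 10.8% down to 1.9%, any-thrombosis
  27.4%, n = 1,655; cancer profile: CA/HEM/MET/SKN at 35.8/12.3/12.0/3.6%,
  any-cancer 42.4%, n = 3,009).  Infeasible combinations (an "any"
  target above the independence bound) are rejected with an error.
* **Genotypes.** Per-SNP MAF uniform on 0.05–0.10, Hardy–Weinberg dosages,
  independent of diagnoses — null cohorts by construction.  Effects are
  planted explicitly with `plantEffect()` (each homozygote independently
  gains a target diagnosis with a given penetrance), which is what the
  recovery tests use.

What the generator does *not* emulate: ICD-9 code-level structure (it
works at the constituent-group level, with a trivial one-code-per-group
map for pipeline completeness), the real data's 21 thrombosis / 191 cancer
fine-grained groups (marginals for those were never published — generation
uses the published category-level prevalences), genotype LD, ancestry
structure, and diagnosis-covariate confounding beyond the age/gender
effects above.  Consequently, passing simulation tests demonstrates the
operating characteristics of the *statistics* under a faithful co-occurrence
structure, not the epidemiology of any real cohort; and tally-based
discrimination is somewhat easier against eight coarse categories than
against 21 fine groups, because a random added diagnosis collides with an
existing one more often (visible as a mild upward shift of the
reverse-genetics AUCs at `minCount = 2`, and as a slightly compressed
advantage of model 1 in the already-present-diagnosis scenario).

## Simulation studies

`empiricalType1()` draws genotype-randomized SNPs (MAF window respected,
minor-homozygote minimum enforced by redrawing), scores each with both
tally models, and reports the fraction below nominal levels.  Permutation
strata are collapsed to one in simulation mode: under the null the
randomized SNP's per-stratum counts are themselves uniform, so stratified
and unstratified nulls coincide marginally (a conditioning argument the
test suite backs with enumeration at cohort size 8).  Note one structural
fact about scaled-down runs: with `B` permutations and the plain
estimator, `p < 0.001` requires a tally strictly above all `B` permuted
tallies, an event of probability at most `1/(B+1)` under exchangeability —
discrete tally ties push the realized rate below even that, so empirical
rates at the smallest levels are conservative at `B = 1000`.

`scenarioScores()` draws 13-subject samples (13 being the median
minor-homozygote count the SNP panels this emulates), treats each as a
SNP's homozygote set against the rest of the cohort, and compares
permutation p-values before and after `kAdded` sampled subjects gain a new
constituent diagnosis under four scenarios (uniform, frequency-weighted,
already-present, same-diagnosis-for-all).  Newly assigned diagnoses are
always new to their subject; samples on which a scenario cannot place its
cases are redrawn.  The recessive-permutation reference model tallies
*all* affected homozygotes with the same permutation null.  Discrimination
is summarized as the Mann–Whitney AUC with midrank ties via `rocAUC()`.

Problem sizes: the packaged acceptance run uses 50,000 randomized SNPs at
`B = 1000` for type-I error and 2,000 paired draws at `B = 1000` for the
ROC study — sizes chosen so the whole script completes in a few minutes on
one core while keeping Monte-Carlo error well inside the reported digits
(binomial SE ≈ 1.4e-4 at a rate of 1e-3; AUC SE ≈ 0.008).

## Numerical and design notes

* Fisher tests are upper-tail hypergeometric sums (`stats::phyper`); the
  exact Hardy–Weinberg test uses the Levene–Haldane conditional
  distribution via a log-space recurrence, with a `1 + 1e-9` relative
  tolerance when summing probabilities "as or less probable" to absorb
  floating-point ties.
* Minor-allele polarity is decided per loaded cohort; a 50/50 frequency
  tie goes to the lexicographically last allele so round trips are
  deterministic.  Monomorphic SNPs carry dosage 0 and an undefined minor
  allele; QC excludes them via the homozygote-count filter.
* HWE violations are *flagged, not excluded* by default (`hweExclude`
  switches): at these MAFs a heterozygote deficit is exactly what a real
  recessive signal looks like.
* Missing dosages exclude a subject from that SNP only (complete-case per
  SNP).
* All randomness flows from explicit integer seeds; derived stream seeds
  stay below 2^31.  Cohort generation, the pipeline and both simulation
  drivers are byte-reproducible given (spec, seed).

## Limitations

The enrichment scan's min-p is not a calibrated p-value (see above); the
FDR it feeds is a ranking device, which is why the significance rule also
demands two annotated genes.  Exact logistic regression, matched-control
replication designs, principal-component covariates, PLINK binary formats
and ICD-10 are out of scope.  The ontology layer knows nothing of the GO
graph, gene length, or per-gene SNP counts, so enrichment inherits those
biases from its input annotation.
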
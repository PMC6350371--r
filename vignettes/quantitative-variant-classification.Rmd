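---
title: "Quantitative variant classification from case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative variant classification from case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efburden)
```

## The problem

In genetically heterogeneous Mendelian diseases such as hypertrophic
cardiomyopathy (HCM), most causative variants are individually rare and
many are private to a single family. Standard ACMG/AMP interpretation
therefore leaves a large fraction of genuinely pathogenic variants as
variants of uncertain significance (VUS), because the variant-specific
evidence the guidelines require (segregation, functional assays) is rarely
available for a previously unseen variant. What *is* often available is
aggregate evidence: large case cohorts and population reference databases
in which whole classes of variants (a gene, a variant consequence class, a
sub-genic region) are demonstrably enriched in cases.

efburden implements a quantitative framework that turns such aggregate
case-control counts into per-class probabilities of pathogenicity and
feeds them back into the ACMG/AMP rule system at calibrated strengths.

## Burden statistics and the etiological fraction

For a 2x2 carrier table (a = cases with a qualifying variant, b =
reference individuals with one, c and d the corresponding non-carriers),
the package computes

- the odds ratio OR = (a/b)/(c/d), with a Haldane-Anscombe +0.5 added to
  all four cells when any cell is zero;
- its 95% CI exp(ln OR +/- 1.96 * SE), SE = sqrt(1/a + 1/b + 1/c + 1/d),
  using the conventional 1.96 multiplier the method is defined with
  (the exact normal quantile is used for non-default levels);
- the etiological fraction EF = (OR - 1)/OR: when the OR approximates the
  relative risk, the probability that a rare variant found in a *patient
  with the disease* is the cause of their disease;
- a two-sided Fisher exact test (point-probability definition) on the raw,
  uncorrected counts.

Two EF interval methods are exposed. The default is a delta-method
interval, EF +/- 1.96 * SE(ln OR)/OR, obtained by propagating the log-OR
standard error through EF = 1 - 1/OR; the alternative (`"substitution"`)
transforms the OR interval endpoints directly. The two differ by at most
about 0.001 on well-powered strata; the delta method is the default
because it is symmetric around the point estimate, which matches how
these intervals are conventionally reported for attributable risk.
EF values below 0 (OR < 1) and interval bounds above 1 are reported
as computed, never clamped: clamping would bias downstream comparisons.

```{r}
est <- burden_estimate(849, 6112, 672, 60469)  # MYH7 non-truncating stratum
est
```

## Rarity machinery

A variant only counts towards a burden stratum if it is rare enough to
plausibly cause the disease. The package derives the disease-specific
threshold from a four-parameter disease model — the *maximum credible
allele frequency*: prevalence x allelic heterogeneity / penetrance,
halved under monoallelic inheritance because an affected genotype carries
the allele on one of two chromosomes.

```{r}
max_credible_af(disease_model(1/500, 0.02, 0.5, "monoallelic"))    # HCM
max_credible_af(disease_model(1/10000, 0.1, 0.5, "monoallelic"))   # CPVT
```

Observed population frequencies are compared against this threshold via
the *filtering allele frequency*: per sub-population, the one-sided 95%
lower Clopper-Pearson bound on the allele frequency, maximised across
sub-populations (popmax). This is deliberately conservative: a variant is
only discarded as too common when its frequency is *confidently* above
the threshold. The package computes the bound exactly (`qbeta`) from AC
and AN supplied as numbers; it performs no database retrieval. For
variants seen in at most one individual per sub-population the FAF is
undefined and an overall allele-count fallback applies (rare iff
overall AC < 3, the convention used for CPVT). A variant entirely absent
from the reference (all AC = 0) has FAF 0, not an undefined FAF: absence
is the strongest possible evidence of rarity.

Reference cohorts are coverage-adjusted: the effective denominator for a
gene is the mean number of called genotypes across its variant sites
(`effective_reference_n()`), averaged over the variant sites supplied by
the user rather than all genomic positions, since per-site genotype
counts are what reference databases publish.

## The cluster scan

Pathogenic missense variants often concentrate in functional domains. The
scan finds such regions without any structural annotation, from positions
alone. For one cohort on one protein:

1. **Sliding window.** A window of fixed size slides one residue at a
   time; each window is tested for enrichment of distinct variants with a
   one-sided binomial test against the uniform expectation
   (`window_enrichment_p()`). Distinct variants are the counting unit;
   carrier multiplicities only enter regional burden estimates.
2. **Window-size search.** Sizes from 5% to 95% of the protein in 5%
   steps are evaluated; the best is refined at 10-fold finer spacing (18
   candidates per pass) until no candidate improves the objective by more
   than 0.001. The objective is the mean over cohorts of
   |sensitivity - specificity|, where sensitivity is the fraction of
   variant-bearing residues inside the merged significant windows and
   specificity the fraction of variant-free residues outside them. The
   two extremes motivate this balance: one-residue windows give
   specificity 1 and near-zero sensitivity, a whole-protein window the
   reverse. Ties prefer the smaller size. Each pass judges its candidates
   at the Bonferroni-corrected threshold implied by all sizes tested so
   far, so the clusters the objective scores are the clusters the
   definitive scan will keep; evaluating at the nominal level instead
   systematically selects windows too small for the corrected scan that
   follows.
3. **Correction.** Window p-values are Bonferroni-corrected by the
   average number of times each residue was tested: the summed
   residue-coverings of every window at every size evaluated, divided by
   the protein length.
4. **Merge.** Overlapping or touching significant windows merge into
   maximal raw clusters (adjacency merges; the merge is interval union
   via IRanges).
5. **Trim.** Each cluster end is tested for a variant-depleted tail:
   candidate tails grow from one residue up to (never past) the cluster
   median, each tested with a one-sided lower-tail binomial against the
   whole-cluster density; the most depleted tail is removed if p < alpha.
   Passes repeat until stable, making trimming idempotent.
6. **Final test.** Each refined cluster gets one last binomial enrichment
   test at the nominal alpha (it is a single test per cluster); failures
   are dropped.

Case and control cohorts are processed independently, each with its own
optimised window size — control clusters (regions enriched in the
reference population) mark benign variation and are reported alongside
case clusters rather than subtracted from them. Coordinates are 1-based
inclusive residue intervals throughout; the BED writer converts to
0-based half-open at the boundary. alpha defaults to 0.05 everywhere.
The pipeline is a pure function of positions and configuration: there is
no hidden randomness.

Regional EFs then follow by counting carriers with a variant inside the
cluster(s) in each cohort and delegating to the burden machinery
(`regional_ef()`), which also returns the complementary estimate for the
remainder of the protein — the same partition logic used to evaluate any
variant prioritisation method (`classifier_partition_eval()`): a perfect
discriminator drives the prioritised partition's EF to 1 and the
remainder's to 0.

## EF-calibrated ACMG/AMP rules

The EF maps directly onto ACMG/AMP evidence strength for the hotspot
rule PM1. The conservative scheme used by default activates PM1_strong at
EF >= 0.95 (OR >= 20), PM1_moderate at 0.90 (OR >= 10) and PM1_supporting
at 0.80 (OR >= 5). A Bayesian scheme is also provided in which each lower
tier takes the square root of the strong-tier odds (each ACMG level
doubles the weight of evidence): EF thresholds 0.95, 0.776 and 0.527.
PM1 is only evaluated for non-truncating variants when PM2 (rarity) is
active and a regional or gene-level EF is available, because the EF is an
estimate of causality *conditional on* the variant being rare and found
in an affected individual.

The engine also implements the automatable companion rules (PVS1 for
truncating variants in configured loss-of-function genes, PS4 with
configurable count and Bonferroni-corrected p thresholds, PM4, PP3 from
precomputed predictor calls, PS1/PM5 with PS1 precedence, PP1 segregation
tiers at 3/5/7 meioses, PS2/PM6 de novo) and combines evidence along the
pathogenic axis: one very strong item plus a moderate yields pathogenic,
one strong plus one or two moderates (or three moderates) yields likely
pathogenic, anything less is a VUS. Benign-direction rules are out of
scope, and PS3 (functional data) is never emitted because functional
assays for this disease lack standardised validation. The practical
consequences of the calibration: a novel rare missense variant in an
EF >= 0.95 region reaches likely pathogenic (PM2 + PM1_strong), and a
novel rare inframe indel in an EF >= 0.90 region does too
(PM2 + PM4 + PM1_moderate). `upgrade_report()` quantifies the effect of
the recalibration on a previously classified cohort.

## Synthetic cohorts

Every stochastic claim in the package is tested against seeded
generators with known ground truth rather than external data:

- `simulate_positions()` draws distinct-variant positions as a Poisson
  number of draws placed uniformly (with replacement, then deduplicated,
  matching the distinct-variant convention), at a uniform background rate
  in controls and a fold-enriched rate inside planted regions in cases.
- `simulate_cohort_table()` draws carrier counts binomially with the case
  carrier odds set to a known multiple of the baseline odds.

These emulate the *statistical* structure the scan and the burden
machinery assume — exchangeable background positions and independent
carriers. They do not emulate mutational hotspots of the reference
genome, per-residue mutability, linkage between carriers, or ascertainment
quirks of referral cohorts, so passing recovery tests demonstrates
correctness of the algorithms under their stated model, not performance
guarantees on any particular real cohort.

Simulation scales used by the test suite (chosen to make the stochastic
assertions sharp while keeping the default run in tens of seconds): a
1000-residue protein at background 0.02 variants/residue with a
200-residue region at 10-fold enrichment over 30 seeds for recovery
(Jaccard >= 0.7 expected in at least 80% of seeds); 500 uniform proteins
of 500 residues for the null false-positive bound (alpha + 3 SE); 500
tables at true OR 20 (cohorts of 5000 vs 60000, baseline carrier rate
0.002) for mean-EF consistency; 1000 tables at true OR 1 (3000 vs 30000,
baseline 0.01) for CI coverage.

## Numerical and design choices

- **Zero cells**: +0.5 to all four cells for OR and SE (this reproduces
  the published small-count strata exactly); the Fisher test always uses
  raw counts.
- **Rounding for printed-table comparison**: half away from zero at the
  printed precision (`round_half_away()`), the convention used by the
  tables the package reproduces.
- **Fisher two-sided definition**: point probability (sum of
  hypergeometric probabilities no larger than the observed table's, with
  a 1e-7 relative tie tolerance), matching `stats::fisher.test`.
- **Window-size tie-break**: smallest size, which favours resolution and
  is conservative about cluster extent.
- **Merging convention**: touching windows merge (the underlying tests
  overlap heavily at one-residue steps, so adjacency is not evidence of
  separation).
- **Objective with a missing cohort**: the mean is taken over cohorts
  that have variants; a cohort with none is uninformative about balance.
- **Degenerate inputs**: all-zero tables, carrier-free strata and
  regions with no carriers in either cohort raise errors rather than
  returning sentinel estimates; a cohort with no variants yields no
  clusters, not an error.

## Limitations

- EFs are valid only for variants found in individuals affected by the
  disease in question; applying them to incidental findings inverts the
  conditioning and overstates pathogenicity.
- The regional EF treats each carrier as carrying one variant in the
  region; compound heterozygotes are counted once per variant.
- The binomial scan assumes positional exchangeability under the null;
  proteins with strongly non-uniform mutability can inflate apparent
  clustering in *both* cohorts, which is why control-cohort clusters are
  reported alongside case clusters.
- The window-size search optimises a single balance objective; hotspots
  at very different scales on the same protein may be merged or split
  depending on which scale dominates the objective.
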
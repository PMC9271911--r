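---
title: "Meta-analysis of genetic association studies from genotype counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of genetic association studies from genotype counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem

A case-control genetic association study of a biallelic polymorphism
reports six numbers: the counts of the three genotypes among cases and
among controls.  Dozens of such studies of the same variant typically
disagree, and the questions a meta-analyst asks are always the same: what
is the pooled odds ratio under each genetic model, how heterogeneous are
the studies, is the literature missing its negative results, and — when a
pooled association is nominally significant — is it *credible* once
multiple testing, power and prior plausibility are taken into account?

`snpmeta` implements that whole chain for genotype-count data.  It ships,
as worked datasets, the genotype tables of a published meta-analysis of
three endothelial nitric oxide synthase (eNOS) polymorphisms (the 4b/a
intron-4 VNTR, G894T and T786C) in type 2 diabetes, and its test suite
reproduces that analysis end to end from the raw counts.

## Genetic-model contrasts

With reference-allele homozygote count `rr`, heterozygote `rh` and
effect-allele homozygote `hh` per arm, each genetic model collapses the
three categories into a 2x2 exposure table:

| model      | exposed     | unexposed   |
|------------|-------------|-------------|
| hybrid     | `rh`        | `rr`        |
| homozygous | `hh`        | `rr`        |
| dominant   | `rh + hh`   | `rr`        |
| recessive  | `hh`        | `rr + rh`   |
| allele     | `2 hh + rh` | `2 rr + rh` |

The allele model counts chromosomes, treating the two alleles within a
person as independent — the universal convention when only genotype
counts are available, though it slightly understates the variance if
genotypes deviate from Hardy-Weinberg proportions.

Two sparse-data rules apply before pooling, both configurable:

* **Double-zero exclusion.**  A study whose contrast column is empty in
  *both* arms (for example, no effect-allele homozygotes among either
  cases or controls) carries no information about that contrast and is
  excluded from it; the per-contrast `k` can therefore be smaller than
  the stratum's study count, and the excluded ids are reported.
* **Continuity correction.**  An estimable table with at least one zero
  cell has 0.5 added to *all four* cells (the convention of the binary
  meta-analysis routines in the major packages).

Per-study effects are Woolf log odds ratios,
`log OR = log(ad/bc)`, `se = sqrt(1/a + 1/b + 1/c + 1/d)`.

## Pooling and model selection

Heterogeneity is quantified with inverse-variance weights on the
per-study log odds ratios: Cochran's `Q`, `I2 = max(0, 100 (Q-df)/Q)`,
and the DerSimonian-Laird moment estimator
`tau2 = max(0, (Q-df)/(sum(w) - sum(w^2)/sum(w)))`.

The selection rule is the one conventional in this literature: the
**random-effects** (DerSimonian-Laird) model when the Q-test p-value is
below 0.10 *or* `I2` exceeds 50%, otherwise the **fixed-effect**
Mantel-Haenszel estimate with the Robins-Breslow-Greenland variance.
Both inequalities are strict.  The 95% intervals use the multiplier
1.959964 and two-sided p-values come from the standard normal.

`meta_or(method =)` can force either model.  This matters for
reproduction work: published tables in this field frequently print
random-effects intervals in every stratum even when the stated rule
would select fixed effects — the bundled eNOS tables are an example (the
overall 4b/a hybrid row prints the DerSimonian-Laird interval although
its Q-test p-value is 0.27).  The pipeline (`run_analysis(method =)`)
exposes the same switch; reproduction tests of printed random-effects
rows use `method = "random"`, while the heterogeneity rule remains the
default for fresh analyses.

Open choices we fixed: `Q` uses inverse-variance weights (not
Mantel-Haenszel weights) regardless of which pooled estimate is
reported, and the Mantel-Haenszel estimate uses continuity-corrected
cells only in the studies that contain zeros.  Single-study strata are
reported as that study's own estimate with a flag rather than an error,
matching how published subgroup tables print them.

## Screening: Hardy-Weinberg equilibrium and study quality

Control-arm genotypes are tested against Hardy-Weinberg proportions with
the 1-df Pearson chi-square goodness-of-fit test; `p > 0.05` counts as
equilibrium.  Monomorphic control samples fit the proportions trivially
and are flagged rather than rejected.  A conditional exact test is
available (`hwe_exact_test`) but is never used by the default analyses.

Study quality is consumed as data: a Newcastle-Ottawa score on 0-10 that
already includes one Hardy-Weinberg point.  The high-quality threshold
is a score of **8 or more**.  The source text says "seven points or
more", but its own sensitivity tables are headed "quality score > 7" and
their stratum sizes only match the `>= 8` reading (19 of 36 studies for
the 4b/a table); we follow the tables and expose the threshold as a
parameter.  The strict sensitivity stratum is the conjunction:
high-quality *and* controls in equilibrium.

## Publication bias

* **Egger's test** regresses `y_i/se_i` on `1/se_i` by ordinary least
  squares and tests the intercept on `k-2` degrees of freedom.
* **Begg's test** is the Kendall rank correlation between the
  variance-stabilized deviates from the fixed-effect mean and the
  sampling variances, with the continuity-corrected normal
  approximation.
* **Trim-and-fill** uses the L0 ("linear") estimator with fixed-effect
  centering during the trimming iterations, mirrors the trimmed studies,
  and re-pools the filled set under the heterogeneity-selected model;
  the funnel side defaults to the sign of Egger's intercept, and the R0
  estimator is available by argument.

On the bundled G894T table the L0/fixed-centering convention imputes
14, 12 and 11 studies for the hybrid, dominant and allele contrasts
(identical to `metafor::trimfill` under the same settings), where the
source publication reports 13, 11 and 10 — a constant off-by-one from an
unidentifiable convention difference in its software.  Random-effects
centering instead finds nothing to trim on these data (`k0 = 0`), so no
single convention reproduces both the source's imputation counts and its
claim that the adjusted conclusions were unchanged: under our
conventions the filled random-effects estimates lose significance.  The
acceptance suite records this honestly rather than switching estimators
per result.

## Credibility of significant associations

For each statistically significant pooled association the package
computes:

* **Power** to detect an alternative odds ratio at level 0.05,
  `1 - pnorm(z_a - |log OR_alt|/se) + pnorm(-z_a - |log OR_alt|/se)`.
* **FPRP**, the false-positive report probability
  `p (1-pi) / (p (1-pi) + power * pi)` over a grid of priors
  `pi` in {0.25, 0.1, 0.01, 0.001, 0.0001}.
* **BFDP**, Wakefield's approximate-Bayes-factor analogue with a normal
  prior on the log odds ratio whose 97.5th percentile is the alternative
  odds ratio.

The composite verdict is `high_credibility` only when all four hold:
significance in at least two genetic models, FPRP < 0.2 *and* BFDP < 0.8
at the reference prior, `I2 < 50`, and power > 0.8 — all strict.  The
source publication states the thresholds but not its priors or
alternative; we use the conventional reference prior 0.001 and
alternative odds ratio 1.5 (its reciprocal for protective effects — only
the magnitude of the log odds ratio enters).  Its headline conclusion —
every significant association is "less credible" — is reproduced by the
test suite over all strata of all three bundled tables under the
random-effects reproduction run.  A simplified three-letter Venice-style
grade is available as descriptive output only.

## Trial sequential analysis

The cumulative meta-analysis is treated like an interim-monitored trial.
Studies are ordered chronologically (the bundled tables carry no usable
publication years, so their printed row order — which is chronological —
stands in; simulated collections carry explicit years), and at each step
the accumulated set is pooled under the heterogeneity rule to give the
cumulative Z.

* **Information** is the accumulated number of participants
  (cases + controls, as printed per study).
* **Required information size (RIS)** is the two-arm sample size for
  detecting a 15% relative risk reduction of the control event
  proportion at alpha 0.05 and power 0.8, inflated by `1/(1-D2)` where
  `D2 = (vR - vF)/vR` is the diversity of the collection.  The event is
  carrying the effect-allele exposure of the analyzed contrast; for the
  dominant model (the conventional TSA target) that is the carrier
  fraction among controls.
* **Monitoring boundaries** follow the O'Brien-Fleming alpha-spending
  function `2(1 - pnorm(z_{0.975}/sqrt(t)))`.  The boundary at each look
  solves the exact group-sequential crossing equation: the density of
  the score process restricted to the continuation region is advanced
  one Gaussian increment per look on a 4001-point trapezoid grid over
  +/- 8 standard units, and each boundary is found by bisection to 1e-8.
  A single look at full information recovers 1.959964 to 1e-6, and the
  recursion's total crossing probability is verified against Monte-Carlo
  Brownian-motion paths in the test suite.  An approximate
  O'Brien-Fleming-type futility bound (single-look inversion of a
  beta-spending function under the design drift) is reported but plays
  no part in any decision flag.

On the bundled data the 4b/a dominant analysis crosses the monitoring
boundary and exceeds its RIS, as the source reports.  The other two
patterns depend on inputs the source does not print (its RIS and event
proportions): under the conventions above the T786C curve crosses the
boundary but accrues 8,518 of a required 12,924 participants, and the
G894T curve crosses where the source says it does not — the source's
not-crossing at a final cumulative Z near 4 would require a required
information size several times the accrued 31,978, i.e. a far larger
diversity adjustment or a much smaller assumed event rate.  The
acceptance suite asserts the source's qualitative pattern and records
these two disagreements as failures rather than adjusting the
conventions toward them.

## The synthetic-data generator

`simulate_meta_dataset()` produces study collections with known truth
for every statistical property test:

* control genotypes at Hardy-Weinberg proportions for a chosen
  effect-allele frequency, optionally distorted by an inbreeding
  coefficient `F` (heterozygote fraction scaled by `1-F`);
* a per-study true log odds ratio drawn from
  `Normal(log(true OR), tau2)`, applied as an exposure-odds shift on the
  model-defined two-category collapse while keeping the control-arm
  genotype composition within each class — so the target contrast's
  odds ratio is exactly the drawn value in expectation and the genotype
  distribution stays valid;
* multinomial counts with per-arm sizes drawn uniformly from 50-1000,
  the span of the bundled real tables;
* optional one-sided publication suppression with the graded selection
  rule of the publication-bias simulation literature (significant
  positive results always published; nonsignificant positive results
  with probability `1-s`; negative-direction results with probability
  `(1-s)^2`), which shrinks the collection and produces genuine funnel
  asymmetry;
* per-study RNG substreams derived from the seed and the study index, so
  study `i` is identical whatever the collection size, and everything is
  bit-reproducible under a fixed seed.

What the generator does **not** emulate — and what passing property
tests therefore do not certify about real data: linkage disequilibrium
with neighbouring variants, covariate confounding and population
stratification, genotyping error, duplicated or overlapping cohorts, and
size-dependent publication selection (suppression acts on the z-value
only, so small and large studies face the same censoring; Egger's test
consequently has modest power against it at realistic collection sizes,
which the tests assert as measured rather than as hoped).

## Numerical and testing choices

Default tolerances and constants: continuity increment 0.5; CI
multiplier 1.959964; heterogeneity rule thresholds 0.10 and 50 (strict);
Hardy-Weinberg screen at 0.05; quality threshold 8; credibility
reference prior 0.001 and alternative odds ratio 1.5; TSA design
(0.05, 0.2, 15%); boundary grid 4001 points, bisection 1e-8.

Problem sizes in the test suite are chosen to give stable statistical
checks at desk scale: oracle equalities on random instances with
`k <= 10` at 1e-10; type-I error of Egger's test over 1000 simulated
null collections of 10 studies; Hardy-Weinberg calibration over 2500
multinomial draws of 500 controls; coverage over 200 simulated
collections; boundary-recursion validation against 10,000 Monte-Carlo
Brownian paths at five looks; between-study-variance recovery at
`k = 100`.

## Data notes and limitations

The bundled tables are transcribed exactly as printed, including their
internal inconsistencies: in 14 of 93 rows the printed per-arm sample
sizes disagree with the sum of the printed genotype counts (the printed
sizes drive totals and information accrual; the genotype counts drive
every statistic), and two printed control-arm Hardy-Weinberg p-values
(0.780 and 0.188) are irreproducible from their own counts, which
recompute to 0.708 and 0.362 — the first is an evident digit
transposition.  The strict `read_study_table()` contract rejects such
rows in user data; the bundled loader relaxes it deliberately.

Beyond scope: multi-allelic and X-linked models, genotype imputation,
Hartung-Knapp intervals, Peto pooling, selection-model (Copas) bias
adjustment, multivariate meta-regression, and gene-gene or
gene-environment interaction analysis.
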
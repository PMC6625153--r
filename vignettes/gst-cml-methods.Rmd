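---
title: "Methods: GST polymorphisms, smoking and CML risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GST polymorphisms, smoking and CML risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gstcml)
```

## The scientific problem

Glutathione S-transferases (GSTs) detoxify carcinogens, including those in
cigarette smoke. Whole-gene deletions of *GSTM1* and *GSTT1* (the "null"
genotype, with no enzyme activity) and the *GSTP1* Ile105Val SNP (c.313A>G,
genotypes AA/AG/GG) plausibly modify the risk of chronic myeloid leukemia
(CML) and the response to imatinib. `gstcml` implements the complete
analysis chain for a matched case-control design around these three loci:
single-locus association under genetic models, Hardy-Weinberg checks,
additive-scale gene-gene and gene-environment interaction, and
treatment-response endpoints — plus a synthetic cohort generator so every
stage is testable without access to subject-level data.

The built-in reference dataset is a 104-case / 104-control Iranian CML
study whose marginal tables (demographics, genotype frequencies, joint
genotype-genotype and genotype-smoking strata, ELN response categories)
ship in `study_table_counts()`. `replicate_study()` reconstructs those
tables as record sets and reruns the full pipeline on them.

## Association model

Every association reduces to a labeled 2x2 table (`two_by_two()`). The
odds ratio is the cross-product $\widehat{OR} = ad/bc$ with the Woolf
interval

$$\exp\!\left(\log\widehat{OR} \pm z_{1-\alpha/2}
  \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right).$$

The Woolf form was chosen because it reproduces the reference study's
printed intervals (0.26–0.82 for GSTM1; 0.03–3.19 for GSTT1; 1.29–4.04 for
the combined GSTM1-null/GSTT1-present genotype) where those are internally
consistent. A table with any zero cell is *inestimable*: the raw
cross-product (0 or infinity) is recorded, no interval is produced, and
downstream consumers receive an explicit flag rather than a corrected
estimate — no Haldane-style continuity correction is applied anywhere.

Contingency tests follow one decision rule (`assoc_test()`): Pearson
chi-square **without** continuity correction, replaced by the two-sided
Fisher exact test (probability-mass rule) whenever a cell is zero or an
expected count is below 5. The uncorrected chi-square is deliberate: it is
the form that reproduces the reference statistics (8.2, 19.65) and
p-values (0.008); the Yates correction does not. The report labels which
test produced each p-value. No multiple-testing adjustment is applied
anywhere, matching the single-study reporting style; all p-values are raw.

### Genetic models

For GSTP1, `genetic_model_table()` collapses AA/AG/GG to

* recessive — GG vs AA+AG,
* dominant — AG+GG (the variant-carrier group, "M*") vs AA,

and `per_allele_logistic()` fits the additive model: a grouped
maximum-likelihood logistic regression of case status on G-allele dosage
0/1/2 (the grouped binomial fit has the identical MLE to the expanded
subject-level fit and is deterministic). The per-allele OR is
$e^{\hat\beta}$ with a Wald interval. For the deletion loci the assay
cannot distinguish heterozygotes, so only the recessive collapse
(null vs present) is meaningful. Orientation is explicit: single-locus
tables are reported with the functional (wild-type) category as exposure
(hence the protective-direction OR 0.46 for GSTM1 present), while
interaction tables use the susceptibility genotype as exposure.

Hardy-Weinberg equilibrium is checked by the chi-square goodness-of-fit
form on 1 df with the allele-frequency MLE — not the exact test — because
that is the convention of the replicated analysis.

## Additive interaction

For two binary exposures, subjects are cross-classified into four strata
with the doubly unexposed stratum as reference ($OR_{00}\equiv 1$), and
each stratum's odds ratio is computed against that reference. Departure
from additivity is measured by

$$\mathrm{RERI} = OR_{11}-OR_{10}-OR_{01}+1,\qquad
  \mathrm{AP} = \mathrm{RERI}/OR_{11},\qquad
  \mathrm{SI} = \frac{OR_{11}-1}{(OR_{10}-1)+(OR_{01}-1)},$$

always from unrounded stratum estimates (rounding first shifts the
GSTM1-GSTP1 RERI from 2.32 to 2.33).

**The zero-cell convention.** When a stratum OR is inestimable or zero
because of a zero cell, it contributes the value 0 to all three formulas,
and the result is flagged (`convention_applied`) and logged loudly in the
rendered report. This single rule simultaneously reproduces every affected
published value (RERI 0.37 and −0.749 in the gene-gene tables, RERI 1.26
with AP 0.39 and SI 2.39 in the GSTT1-smoking table); substituting 1, or a
continuity-corrected OR, fails at least one of them. It is nonetheless a
statistically aggressive choice — a stratum with no observed cases is
treated as zero excess risk — which is why it is surfaced rather than
silent. AP is undefined when $OR_{11}$ itself is inestimable; SI is
undefined when its denominator is zero.

**Uncertainty.** `interaction_ci_bootstrap()` provides percentile
intervals by resampling subjects within the case and control groups
separately (preserving the retrospective design), recomputing RERI/AP/SI
under the same convention in each resample. The bootstrap is used instead
of the delta method because the zero-convention makes the estimator
non-smooth exactly where it matters. Resamples that trigger the
convention are counted and reported. A minimum of 100 resamples is
enforced; 1000 is the default.

## Outcome endpoints

Treatment response uses the ELN-style categories: MCyR at 3 months, CCyR
at 6 months, BCR-ABL ≤10% at 3 months and <1% at 6 months, each
cross-tabulated against GSTM1 (null vs present) or GSTP1 (AA vs AG/GG)
among cases, with the standard decision-rule test. The reference study's
printed p-values for these response tables are not reproducible from its
own printed counts under Pearson, Yates or Fisher (e.g. 0.017 printed
where the counts give 0.002); the package therefore reports its computed
p-values and treats only the counts as replicable.

Time-to-event endpoints (time to major molecular response; event-free
survival, whose composite event — loss of response, progression to
accelerated/blast phase, or death — is consumed pre-coded because deriving
it needs visit-level schedules the cohort format does not carry) use the
Kaplan-Meier product-limit estimator with Greenwood log-scale bands and
the unweighted two-group log-rank test, via the `survival` package behind
the package's own interface; an independent product-limit oracle verifies
the estimates in the test suite.

## The synthetic cohort generator

*Fixture mode* (`generate_fixture()`) reconstructs record sets whose
aggregation reproduces a chosen reference table block cell for cell. Only
the fields that block constrains are filled; everything else is left
missing, because the published margins constrain nothing else. The `"all"`
mode returns one record set per block with a manifest: the cross-table
joint distribution is under-determined by the margins (response tables
apply to cases only and are independent of the joint genotype-smoking
cross-tabs), so joint exactness is not promised. The demographics fixture
carries a deterministic age vector with exactly the published mean and SD.

*Model mode* (`generate_cohort()`) simulates the case-control design
directly: control exposure profiles (GSTM1, GSTT1, GSTP1, smoking) follow
configurable frequencies with GSTP1 drawn under HWE, and case profiles
follow the tilted distribution
$P(\text{profile}\mid\text{case}) \propto
 P(\text{profile}\mid\text{control})\cdot OR(\text{profile})$,
where $OR(\text{profile})$ multiplies the configured main-effect and
pairwise-interaction odds multipliers. This retrospective tilt makes the
configured ORs exactly the estimands of the downstream analysis, which is
what the parameter-recovery tests exploit (relative error under 5% at
50,000 subjects per arm). Cases inherit departure from HWE through the
tilt, mirroring the reference pattern (controls in HWE, cases less so).

Defaults are the reference study's conditions: 104 subjects per arm,
control frequencies GSTM1-null 51/104, GSTT1-null 1/104, G allele 43/208,
smoking 31/104, and effects equal to the study's estimated stratum ORs
(GSTM1-null 2.076, smoking 2.682, joint multiplier giving OR 6.514 for
both, GSTP1 per-G 1.569, GSTT1-null 1 — the study found no GSTT1 main
effect and its CI spans 1). Sex and age are drawn independently per group
to match the demographic summaries; no analysis depends on them beyond the
demographics table.

`attach_survival()` draws a latent response time and an EFS time per case
from per-GSTM1-genotype exponential hazards (defaults 0.010/month for
null vs 0.035 for present carriers of the response hazard — null patients
respond more slowly, matching the direction of the replicated finding —
and 0.004 for EFS in both, i.e. no EFS difference), with independent
uniform censoring on a 72-month horizon (the reference cohort's follow-up
ranged to about that scale, mean 61 months). Binary ELN endpoints derive
from the latent response time thresholded at 3 and 6 months. Exponential
times are a deliberate simplification: the tests need ordered hazards and
calibrated type-I error, not a realistic CML survival model.

All generation is deterministic under a fixed seed, recorded in the
output manifest.

## What the tests do and do not show

The replication suite runs on *reconstructed* per-table record sets, so it
verifies the statistical machinery exactly against the published margins —
it cannot validate subject-level properties the margins never constrained
(joint distributions across tables, individual survival times, Figure-level
curves). The simulation tests verify estimator calibration under the
generator's idealized model (independent loci, exponential times, uniform
censoring); real cohorts have linkage, confounding by age/sex, and
non-exponential hazards that the generator deliberately omits. Problem
sizes were chosen for tight Monte-Carlo error at interactive runtimes:
1000 null replicates for the log-rank type-I check (standard error about
0.007 on the rejection rate, against an acceptance band of 0.03–0.07),
50,000 subjects per arm for parameter recovery (sampling error well under
the 5% band), and 100–200 replicates for ordering checks.

## Numerical choices and edge cases

* Confidence level defaults to 95% with $z = 1.959964$.
* Logistic convergence: IRLS tolerance $10^{-10}$, 50 iterations;
  separation is flagged, not errored.
* Degenerate inputs: empty tables are permitted in aggregation;
  zero-margin tables error in the chi-square path and fall to Fisher in
  the decision rule; monomorphic HWE samples return p = 1 with a
  degenerate flag; an all-censored KM curve is the constant 1.
* Ties in survival times: events at a tied time are processed before
  censorings at that time (the product-limit convention).
* Complete-case exclusion is per-analysis, not global: each table drops
  only the records missing a field that that table needs, and reports the
  exclusion count. The reference tables all show full 104-per-arm
  denominators, so the rule is exercised only by user data.
* Rendered reports use fixed display precision (ORs/RERI/SI to 2–3
  decimals, AP to 3, p-values to 3 or "<0.001"); machine-readable JSON
  keeps full precision with sorted keys so identical analyses render
  byte-identically.

## Worked example

```{r example, eval = FALSE}
rep <- replicate_study()
rep$single_locus$gstm1$recessive$or   # OR 0.467 (0.266-0.820)
rep$gene_env$gstm1_smoking$interaction
#> OR11 6.51, OR10 2.08, OR01 2.68 (OR00 = 1 ref)
#> RERI 2.756, AP 0.423, SI 2.00

cfg <- simulation_config(seed = 1)
co <- attach_survival(generate_cohort(cfg), cfg, seed = 2)
run_pipeline(input = co)
```

## Known limitations

* No covariate adjustment (the replicated analysis performs none); the
  matched design is taken as given.
* No multiplicative-scale interaction and no three-way strata.
* The zero-cell convention, while faithful to the replicated results, is
  not a recommended general-purpose estimator; treat flagged results as
  descriptive.
* Fixture mode guarantees per-table exactness only; do not use the `"all"`
  fixture list as if it were one coherent cohort.
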
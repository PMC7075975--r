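---
title: "Transmitted and non-transmitted allele GRS analysis in mother-child duos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmitted and non-transmitted allele GRS analysis in mother-child duos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duogrs)
```

## The scientific problem

Parental overweight is one of the strongest predictors of childhood
overweight, but the phenotypic association mixes two mechanisms:
*direct genetic transmission* (the child inherits half of each parent's
alleles) and *environmentally mediated effects* of parental adiposity
on the child's environment.  When only mothers and children are
genotyped, both mechanisms can still be separated: each maternal allele
is either transmitted to the child or it is not.  A weighted genetic
risk score (GRS) built from the maternal **non-transmitted** alleles is
a pure genetic probe of the environment the mother provides ("genetic
nurture") — the child never carries those alleles, so any association
with the child's phenotype must run through the maternal environment.
The maternal and paternal **transmitted** GRSs, in contrast, capture
direct transmission; the paternal transmitted alleles are simply the
child alleles not assigned to the mother, which also makes them immune
to pedigree errors on the paternal side.

`duogrs` implements this analysis end to end:

1. **Duo phasing** — per-variant assignment of each child allele to
   maternal or paternal origin from mother-child genotypes plus phased
   haplotypes;
2. **Score construction** — weighted GRSs for child, mother and the
   three haplotype components, on raw, allele-count and SD-unit scales;
3. **Phenotypes and design** — LMS and internal BMI z-scores,
   overweight flags, and the three sampling groups of a BMI-extremes
   design (random reference REF, high-maternal-BMI MO-OW, high-child-BMI
   CH-OW);
4. **Statistics** — linear models of continuous child BMI in the
   reference group, case-cohort logistic models (REF + CH-OW),
   exposure-based-cohort models with group adjustment and interaction
   (REF + MO-OW), derived effect-size and excess-odds-ratio ratios, and
   GRS validity correlations;
5. **Synthetic cohorts** — a trio simulator with known transmissions
   that provides ground truth for every stage.

## The transmission algorithm

For a biallelic variant with effect-allele genotypes coded 0/1/2, the
per-site logic is purely Mendelian wherever the mother or the child is
homozygous (`infer_site_transmission()`):

| mother | child | maternal transmitted | maternal non-transmitted | paternal transmitted |
|--------|-------|----|-----|----|
| 2      | 1, 2  | 1  | 1   | child − 1 |
| 0      | 0, 1  | 0  | 0   | child |
| 1      | 0     | 0  | 1   | 0  |
| 1      | 2     | 1  | 0   | 1  |
| 0      | 2     | — Mendelian error — | | |
| 2      | 0     | — Mendelian error — | | |
| 1      | 1     | — needs haplotypes — | | |

The only ambiguous case is the *double heterozygote*.  There
(`resolve_double_het()`), the two phased child haplotypes are each
compared with the two phased maternal haplotypes over a window of
surrounding variants (default 51 sites, truncated at chromosome /
haplotype-region boundaries), scoring each pair by the count of
matching non-missing alleles.  The child haplotype whose best maternal
match *strictly* exceeds the other child haplotype's best match is
declared maternally transmitted; its focal allele becomes the maternal
transmitted allele, the other child haplotype's focal allele the
paternal transmitted allele, and the mother's other haplotype supplies
the non-transmitted allele.  Equal best scores are a *tie* and the site
is left uncalled (`tie_missing`).

Ties are left missing deliberately.  The tempting alternative — filling
ties with a frequency-based guess — is exactly the mechanism that
biases duo-based inference at low-frequency variants: guessing tends to
hand the minor allele to the unobserved father, inflating the apparent
paternal minor-allele transmission rate.
`quantify_transmission_bias()` demonstrates this by simulation: under
the default tie-missing policy the inferred-minus-true minor-allele
assignment rates are zero for both parents, while a naive
"minor allele goes paternal" tie policy produces a strictly positive
paternal excess (and the mirror-image maternal deficit) at low MAF.
Because ties are vanishingly rare with 50-variant regions and windows
of 51, the bias demonstration uses short regions (blocks of 5, window
5) where ties are common; that choice only affects the demonstration,
not the default pipeline.

Dosage data are first hard-called (`best_guess_genotype()`): a dosage
within 0.1 of an integer genotype rounds to it (round-half-up at exact
midpoints), anything else is missing.  Per-duo QC counts Mendelian
errors and computes the opposite-homozygote rate, which separates true
duos (rate 0 up to genotype error) from unrelated pairs (expected rate
`2*p^2*q^2` per site under HWE, e.g. 0.125 at MAF 0.5); duos at or
above a 1% rate are flagged `inconsistent` and should be excluded.
Mendelian-inconsistent sites are dropped per site, not per duo.
Variants with a cross-duo call rate below 95% are excluded before
scoring, the analogue of a genotype call-rate filter.

## Scores and scales

`weighted_grs()` computes the raw score `sum_j w_j g_j` over
non-missing sites, with weights oriented non-negative at load time so
"effect allele" always means "trait-increasing allele".  Because duos
differ in which sites were callable, each haplotype component is
rescaled by `sum(w_all)/sum(w_called)` to stay comparable across duos.
Three scales are exposed:

* **raw** — the weighted sum (units of the discovery trait);
* **allele count** — `raw * n_variants / sum(w)`, i.e. the number of
  effect alleles carried; an individual with average dosage 1
  everywhere scores exactly `n_variants`, and a 941-variant panel has a
  per-individual capacity of 1882 alleles (`allele_capacity()`).  This
  rescaling was chosen because it reproduces that carried-allele
  interpretation exactly and is linear, so additivity identities
  survive the change of scale;
* **SD-units** — allele counts standardised against a designated
  reference group (`standardize_scores()`).  In a selected-extremes
  design the random REF group anchors the scale, so odds ratios are
  per REF-SD; standardising against the pooled selected sample would
  shrink the units by the over-representation of high scores.

On complete data the identities `child = maternal transmitted +
paternal transmitted` and `mother = transmitted + non-transmitted` hold
exactly on the raw and allele-count scales; the test suite asserts them
on every inferred duo.

## The synthetic cohort generator

`simulate_cohort()` generates mother-father-child trios under a
transparent generative model:

* **Panel**: `n_variants` biallelic variants with effect-allele
  frequencies drawn Uniform(0.1, 0.9) by default and half-normal
  weights (sd 0.02, a typical per-allele effect magnitude for an
  anthropometric polygenic panel).  Variants are grouped into blocks of
  `block_length = 50`, labelled as chromosomes in the emitted panel.
* **Haplotypes**: independent Bernoulli draws per haplotype under HWE.
* **Assortative mating**: spouses are paired by Gaussian-copula rank
  matching on their BMI z-scores, which hits a target phenotypic
  spousal correlation exactly in expectation in O(n log n), rather than
  by rejection sampling.  The default is random mating
  (`spousal_corr = 0`).
* **Transmission**: within a block the child copies one parental
  haplotype unbroken; between blocks the copied haplotype switches with
  probability `recomb_prob` (default 0.5 = independent blocks, the
  natural reading of blocks as chromosomes).  Keeping blocks intact
  preserves local haplotype identity, which is what makes double
  heterozygotes resolvable at all.
* **Phenotypes**: parent BMI z = `sqrt(h2_parent)` x own standardised
  full score + noise (`h2_parent = 0.06`, the variance explained
  reported for the emulated panel in adults); child BMI z =
  `beta_transmitted` x (standardised maternal + paternal transmitted
  half-scores) + `beta_nurture` x standardised non-transmitted
  half-score + `beta_shared_env` x family environment + residual, with
  the residual completing the variance to 1 (an over-budgeted variance
  decomposition is a hard error before sampling).  The default
  `beta_transmitted = 0.17` makes the two transmitted half-scores
  jointly explain about 6% of child BMI variance.  Raw BMI values are
  affine anchors typical of mothers (23.1 +/- 3.2 kg/m^2 pre-pregnancy),
  fathers (25.1 +/- 3.0) and 7-year-old children (15.6 +/- 1.6).
* **Observation model**: fathers are withheld (only mothers and
  children are "genotyped"), child haplotype order is randomised so the
  observed phasing carries no parent-of-origin label, and optional
  switch errors (`inject_phase_errors()`, parity semantics: an event at
  a site flips the assignment from that site to the end of its region,
  two events cancel) and genotype missingness corrupt the observed
  duos.

All randomness flows from one seed through named substreams, so
toggling the phase-error rate does not shift the haplotype draws — a
property the tests rely on when comparing corrupted and clean versions
of the same cohort.

What the simulator deliberately does **not** model: linkage
disequilibrium within blocks, genetic maps in cM, the X chromosome,
imprinting, genotyping batch effects, and the self-report measurement
error structure of real parental anthropometrics.  Passing tests
therefore certify the algorithmic and statistical machinery, not the
behaviour of the pipeline under every real-data pathology.

Under this model and random mating, classical expectations follow:
corr(maternal full GRS, child GRS) = 0.5, corr(any transmitted
half-score, child GRS) = `1/sqrt(2)` (approx. 0.707, the correlation of a
half-score with a full score containing it), and corr(maternal
non-transmitted GRS, child GRS) = 0.  `validation_correlations()`
reports observed against these analytic values and flags deviations
beyond `3/sqrt(n) + 0.02`.  Note the distinction between 0.5 for
full-vs-full and `1/sqrt(2)` for half-vs-full: loose summaries often
call both "around 0.5", but only the former is exactly 0.5; the report
surfaces both values explicitly.  Assortative mating legitimately
raises the parent-child correlations, so flags mean "departs from the
random-mating expectation", not necessarily "wrong".

## Statistical layer

The models are intentionally plain, matching how such designs are
analysed in practice:

* `fit_linear()` — OLS with t-based 95% CIs (`lm`), one optional extra
  covariate for the GRS-adjusted phenotype models;
* `fit_logistic()` — ML logistic regression (`glm`), Wald CIs on the
  log-odds scale exponentiated to ORs.  Profile-likelihood CIs were
  considered and not used: the target designs report standard GLM
  output.  Complete separation is detected (diverged coefficients or
  all fitted probabilities at 0/1) and raised as an explicit error,
  never returned as a huge estimate.  Convergence uses IRLS with up to
  100 iterations at tolerance 1e-10.
* `run_case_cohort()` — outcome = membership in the high-child-BMI
  group, REF + CH-OW pooled, one unadjusted model per determinant plus
  transmitted-GRS-adjusted parental-BMI models;
* `run_exposure_cohort()` — outcome = actual child overweight,
  REF + MO-OW pooled, group indicator always included (coded REF = 0),
  optional group x determinant interaction with per-group ORs;
* `compare_groups()` — Welch t for continuous, pooled-variance
  two-proportion z for binary descriptives;
* `effect_ratio()` / `excess_or_ratio()` — the derived ratios
  `beta_a/beta_b` and `(OR_a - 1)/(OR_b - 1)`, rounded to two decimals
  as conventionally reported.

No multiple-testing adjustment is applied anywhere: the designs report
unadjusted per-model p-values, and so does the package.

Child overweight is a configurable percentile rule (default: 90th
percentile of the reference distribution on the z-scale) because
pediatric references differ; adult overweight is BMI >= 25 with an
inclusive cutoff.  The MO-OW *selection* threshold (default BMI >= 30)
is a separate parameter from the overweight *flag* cutoff: an
exposure-selected group is typically drawn from deeper in the tail than
the flag definition.

LMS standardisation of child BMI uses the Cole transform
`z = ((x/M)^L - 1)/(L*S)` with the log-limit at `L = 0`.  For synthetic
runs the reference is estimated per sex and age-month band by moment
matching with `L` fixed at 1 (`M` = band mean, `S` = band CV), with
sparse bands merged into neighbours; a measured reference table (WHO,
IOTF) can be supplied in the same format instead.

## Numerical and design choices

* Windows never cross chromosome/region boundaries.  Besides being
  what any regional matcher does, this has a provable consequence used
  by the tests: with no phase errors, a non-tie double heterozygote is
  *always* resolved correctly, because the transmitted child haplotype
  matches one maternal haplotype exactly within the region while the
  paternal haplotype can at best tie.  There is no canonical window
  size or scoring rule for regional haplotype matching; 51 sites and
  count-of-matching-alleles are declared, configurable choices.
* Tie-breaking: `tie_missing` by default (see above); the naive policy
  exists only inside the bias quantifier as a contrast.
* The whole-cohort inference engine is vectorised with one global
  cumulative sum per haplotype pairing and processes duos in bounded
  column chunks (about 8 million matrix cells per chunk), so 50,000
  duos x 941 variants run in well under a minute inside a few GB.
  Agreement with the site-by-site reference implementation
  (`resolve_double_het()`) is asserted over every ambiguous site of a
  corrupted test cohort.
* VCF input goes through `vcfR`; allele harmonisation matches panel
  allele pairs exactly, drops mismatches and multiallelic records with
  warnings, flags strand-ambiguous (A/T, C/G) variants, and never
  strand-flips.  Unphased genotypes (`/`) keep their genotype but are
  excluded from haplotype matching.  1-based positions throughout.
* Problem sizes in the test suite were chosen as the smallest that
  make the statistical assertions sharp: 50,000 duos for the
  validity-correlation checks (Monte-Carlo SE about 0.004), 500
  replicates for CI-coverage (binomial SE about 1%), 20,000 trios for
  sampling-law checks.

## A worked example

```{r example, eval = FALSE}
library(duogrs)

params <- sim_params(n_trios = 4000, n_variants = 941, seed = 42)
cohort <- simulate_cohort(params)

calls  <- infer_duo_transmission(cohort$duos)
scores <- build_score_set(cohort$duos, calls, cohort$variants)

groups <- sample_design_groups(cohort$phenotypes, cohort$latent$child_z,
                               n_ref = 500, n_mo_ow = 400, n_ch_ow = 750,
                               maternal_bmi_threshold = 27, seed = 1)
dat <- analysis_frame(scores, cohort$phenotypes, groups)

run_case_cohort(dat)          # ORs for child overweight, REF + CH-OW
run_exposure_cohort(dat, with_interaction = TRUE)
validation_correlations(scores)
```

## Known limitations

* The non-transmitted probe is maternal-only: without paternal
  genotypes there is no paternal non-transmitted score, so paternal
  nurture is out of reach by construction.
* Weight units are treated as abstract per-allele magnitudes; if the
  discovery weights are per-SD of the trait, raw scores inherit that
  unit but nothing in the pipeline depends on it (SD-unit scores are
  scale-free).
* The simulator's phenotype model is linear-Gaussian; threshold-based
  group selection induces the usual truncation artefacts (e.g. weaker
  within-group associations in the selected tail), which is realistic
  but means within-group estimates should be read with the same
  caution as in a real selected design.
* Unweighted logistic models are used for the case-cohort design (no
  Prentice/Barlow weighting, no sandwich SEs), matching the pooled
  plain-GLM analysis the design emulates.
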
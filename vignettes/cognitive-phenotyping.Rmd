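---
title: "Cognitive phenotyping in multiple sclerosis: methods and design notes"
author: "cogpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive phenotyping in multiple sclerosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogpheno)
```

## The problem

Roughly half of people with multiple sclerosis (PwMS) develop cognitive
impairment, but averaging across an entire neuropsychological battery can
hide a deficit confined to a single domain. This package implements a
domain-resolved phenotyping pipeline for an extended Brief Repeatable
Battery (BRB-N plus Stroop, Concept Shifting Test and Memory Comparison
Test): regression-based normative Z-scoring, a-priori composition of four
cognitive domains, classification into *preserved*, *isolated* (one
impaired domain) and *multi-domain* (two or more) phenotypes,
reliable-change-based longitudinal transition accounting, and regression
modelling of domain scores on per-subject MRI scalars. Because cohorts of
this kind are not publicly deposited, the package ships a synthetic-cohort
generator with the statistical structure the analysis assumes, so every
stage is tested end to end without any data download.

## Normative model

For each sub-score the normative model is ordinary least squares on
healthy controls,

$$\mathrm{raw} = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex}
  + \beta_3\,\mathrm{education} + \varepsilon,$$

with sex coded male = 1 and education entered as a numeric 1–7 level.
The demographically corrected score is
$z = (\mathrm{observed} - \mathrm{predicted})/s_e$ with $s_e$ the
residual SD (denominator $n-4$), sign-flipped for timed scores so that
higher $z$ always means better performance. Design notes:

* **Main effects only, no interactions or polynomial terms.** Published
  norms for this battery are not available in raw-score form; the
  simplest defensible regression family was chosen and fixed. The model
  form is deliberately the same one the generator uses, which makes the
  calibration properties exact rather than approximate.
* **Education as numeric.** Seven ordinal levels with small cells make a
  categorical coding fragile at $n \approx 100$ controls; a linear trend
  is standard normative practice.
* **Direction registry, not data.** Whether a sub-score is
  higher-is-better (counts: SDMT, SRT, SPART, WLG) or lower-is-better
  (times: Stroop, CST, MCT slope, interference) is fixed a priori in
  `subscoreRegistry()`. This is what makes "domain $Z < -1.5$" a uniform
  impairment rule.
* **At least 20 usable controls per sub-score**, otherwise fitting stops
  with the sub-score named; constant raw scores (zero residual variance)
  are likewise an error, never a silent division.

## Domains and phenotypes

Domain scores are unweighted means of constituent sub-score Z-scores:
processing speed is the SDMT alone; memory averages four SRT sub-scores
and the SPART direct/delayed recalls; executive functioning/working
memory (EF/WM) averages Stroop interference, CST shifting, WLG total and
MCT slope; attention averages Stroop cards 1–2 and the CST number and
letter conditions. Composite raw scores are derived first
(`deriveComposites()`): Stroop interference is card 3 minus the mean of
cards 1 and 2; the MCT slope is the 4-letter minus the 1-letter trial
time; missing constituents make the composite missing, never zero.

Classification uses a strict boundary: a domain with $Z < -1.5$ is
impaired, $Z \ge -1.5$ (including exactly $-1.5$) is preserved. No
impaired domain gives the preserved phenotype, exactly one the isolated
phenotype (with its domain recorded), two or more the multi-domain
phenotype. When some sub-scores are missing, a domain mean is taken over
the present constituents provided at least half are present; otherwise
the domain — and the subject's classification — is missing and reported
as such, which avoids discarding a subject over one missing trial while
never fabricating a score.

## Reliable change and trajectories

Longitudinal change uses the reliable change index computed against
healthy-control retest data:

$$\mathrm{RCI} = \frac{(x_2 - x_1) -
  (\overline{HC}_2 - \overline{HC}_1)}{SE_d},$$

with $|\mathrm{RCI}| \ge 1.64$ (boundary inclusive) marking reliable
change. The phrase "standard error of the difference score" admits two
common estimators, so both are implemented: the default Jacobson–Truax
practice-corrected form $SE_d = \sqrt{SEM_1^2 + SEM_2^2}$ with
$SEM_i = SD_i\sqrt{1-r_{12}}$, and `sd_of_differences` (the SD of the
controls' change scores). At equal variances they coincide:
$\sqrt{2\,SD^2(1-r)}$, verified in the tests at $r = 0.5$.

Trajectory labels are count-based: *declining* means more impaired
domains at follow-up than baseline, *stable* means the same number
(including switching which single domain is impaired), *improving* means
multi-domain → isolated or isolated → preserved. Two edge cases required
decisions:

* **Multi-domain → preserved** is not listed by either rule but must
  receive a label under the partition invariant; it is labelled
  improving, the only reading consistent with the definitions' intent.
* **Multi-domain → multi-domain with fewer (but ≥ 2) impaired domains**
  is labelled stable with a note. The published-table convention of
  counting every multi-domain → multi-domain subject in the decline
  column is available as `multidomain_all_decline = TRUE` in
  `buildTransitionTable()`.
* Because the battery defines decline by impaired-domain counts *and*
  computes RCIs, the count rule is the default and `rci_gated = TRUE`
  offers the stricter reading: a decline/improve label must be backed by
  a reliable change on at least one domain, otherwise it is downgraded
  to stable.

For the reliable-change stage each timepoint is scored against norms
fitted on the same control timepoint (timepoint-2 norms absorb the
practice effect); cross-sectional classification at follow-up reuses the
baseline norms, so the follow-up phenotype is directly comparable to the
baseline one and practice is corrected once, in the RCI numerator.

## MRI modelling

Seven per-subject scalars enter as precomputed values: normalized
cortical grey-matter and white-matter volume (L), log lesion volume,
thalamus and hippocampus volume (mL), cortical-lesion count and
whole-skeleton fractional anisotropy. The modelling chain is:

1. **Normality gate** — Lilliefors-corrected Kolmogorov–Smirnov per
   measure; $p < 0.05$ triggers a natural-log transform (values shifted
   above zero first, with a warning). Natural log is used throughout;
   the gate records its trigger statistic.
2. **Collinearity screen** — while any pair has $|r| \ge 0.7$, drop the
   predictor with the most such partners; ties go to the larger mean
   $|r|$, then to the alphabetically later behaviour-free rule
   (lexicographic name), so the screen is deterministic.
3. **Univariate preselection** — each candidate in its own model with
   age, sex and education; the candidate's standardized β and p are
   reported, Bonferroni-corrected within one domain's candidate family
   by default (`multiplicity = "none"` is available because the
   correction's intended family is ambiguous).
4. **Forward regression** — within the matching isolated-phenotype
   group, candidates enter by smallest F-change p while it is below the
   entry threshold (0.05 by default, the common statistics-package
   convention; configurable). Reported: standardized βs, overall F with
   degrees of freedom, adjusted $R^2$ (checked in the tests against
   $1-(1-R^2)(n-1)/(n-k-1)$ on every fit), with listwise deletion —
   complete cases of the outcome and all candidates.
5. **Decline logistic model** — declining vs stable among baseline
   isolated-impairment subjects, on seven features (age, sex, EDSS,
   cortical grey-matter volume, thalamus volume, hippocampus volume,
   fractional anisotropy), reporting the likelihood-ratio $\chi^2$, df,
   p, and odds ratios. Complete separation is detected and reported as
   such rather than surfacing as a convergence failure. Seven features
   were chosen so the model's df matches the analysis the pipeline
   reconstructs; the feature list is an argument, not a constant.

Whether the forward models should be fitted within each isolated group
or across all patients is genuinely ambiguous; the reported degrees of
freedom of the reconstructed analysis imply within-group fitting, so the
pipeline subsets by default and the group filter is an explicit argument.
Cortical-lesion counts, typically missing for a sizeable minority, stay
in the candidate set and are handled by complete-case analysis with the
case count reported.

## The synthetic generator

`cohortConfig()` defaults encode the study conditions the pipeline
expects: 96 healthy controls; 348 patients split over six phenotype
groups in the proportions of a long-standing MS cohort (group sizes
25/23/37/23/148/92); 71% retention at a 4.9 ± 0.9-year follow-up;
group-wise demographics (age ≈ 46–50 ± 10 years, education 1–7, EDSS
medians 3–3.5, RR/SP/PP mixes) and MRI means/SDs on published clinical
scales, with moderate positive correlations among volumes and FA and
negative correlations with lesion measures.

Controls are drawn from linear demographic truth models per sub-score
(e.g. SDMT ≈ 55 ± 9 in controls; all registry-overridable — only the
Z-level behaviour is contractual, since raw-score norms for this battery
are unpublished), with test-retest correlations of 0.65–0.80 and small
practice effects at retest. Patients receive a latent domain-score
vector with unit marginal variance: group mean shifts
(`domain_effects`, in normative SD units, e.g. −2.2 on the index domain
of an isolated group), standardized-MRI contributions
(`mri_cog_slopes`), equicorrelated residuals (0.4) and a follow-up
drift (−0.25 by default, the generator's stand-in for gradual decline).
Constituent Z-targets scatter around the latent with *within-domain
centring*, so a subject's domain mean equals the latent exactly, and are
converted to raw scores by inverting the *fitted* norms — which is what
expresses injected effects exactly in normative SD units and makes the
calibration tests sharp: under zero effects the per-domain impairment
rate is $\Phi(-1.5) = 6.68\%$ up to sampling and norm-estimation error.

All randomness flows from the single integer seed in the configuration
(patients use seed + 1 so controls and patients are independently
reproducible); the caller's RNG stream is restored afterwards.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: floor/ceiling effects and discreteness of
raw test scores (scores are generated on a continuous scale and range
limits are not enforced), non-linear age effects, differential attrition
(drop-out is independent of severity), practice effects that differ
between patients and controls, and any measurement error in the MRI
scalars. Calibration results are statements about the pipeline's
arithmetic, not about clinical validity.

## Numerical choices and problem sizes

Degenerate inputs error early and name the offending field: invalid
configurations, unknown sub-scores (with the registry listed), fewer
than 20 controls, constant scores, zero $SE_d$, one-class logistic
outcomes, rank-deficient screens. Display percentages use half-up
rounding to whole percent (`round_half_up()`); all stored percentages
remain exact. The test-suite problem sizes were chosen to keep Monte
Carlo error well inside the asserted tolerances while keeping the whole
suite under a minute: 500-control normative samples for calibration
checks, 2000 null patients for tail-rate checks (binomial SE ≈ 0.6% at
the 6.68% rate), 6600 patients for per-group effect recovery (≥ 1000
per group, SE ≈ 0.03 SD), 200-seed loops for selection and test-size
properties, and 10,000 random profiles for the classification
invariants.

## Known limitations

* The normative family is fixed (no quantile regression or age-binned
  norms), matching scope.
* Attrition is reported, never imputed or modelled.
* Domain definitions are a priori; no data-driven (latent-profile)
  phenotyping.
* The generator's raw-score scales are plausible but invented; analyses
  that depend on raw-score units (not Z-units) should treat them as
  arbitrary.
* Reconstructed regression results from non-deposited clinical data are
  not reproducible by simulation and are not claimed; the tests verify
  the procedure (recovery, size, closed forms), not historical
  coefficients.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(cohort = cohortConfig(n_controls = 96,
                                            n_patients = 348, seed = 1))
res <- runPipeline(cfg, out_dir = "cogpheno_out")
res$frequencies
declineSummary(res$transition_table)
```
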
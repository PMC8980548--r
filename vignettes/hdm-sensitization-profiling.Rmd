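---
title: "Molecular sensitization profiling of house dust mite IgE panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular sensitization profiling of house dust mite IgE panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Component-resolved allergy diagnostics measures serum specific IgE (sIgE,
kU/L) against individual allergenic protein molecules rather than whole
extracts. For house dust mites (HDM, *Dermatophagoides pteronyssinus* and
*D. farinae*) the clinically informative panel comprises eleven molecules:
the group 1 cysteine proteases Der f 1 and Der p 1, the group 2 NPC2-family
proteins Der f 2 and Der p 2, the peritrophin-like Der p 23 (now widely
treated as a third major allergen), and the minor components Der p 5,
Der p 7, Der p 10 (tropomyosin), Der p 11, Der p 20 (arginine kinase) and
Der p 21.

Which molecules dominate sensitization — and whether patients are mono- or
poly-sensitized — varies by age and by geography, and this variation matters
clinically: allergen immunotherapy preparations are not equally rich in all
molecules, so the regional sensitization pattern is a prognostic marker for
therapy selection. `hdmprof` implements the full analysis chain for such
multiplex panel cohorts: ingest and validation, binarization, stratified
prevalence summaries, exact co-sensitization profile enumeration, and a
region-wise priority-molecule decision rule. A seeded synthetic-cohort
generator supplies realistic correlated data so that every stage is testable
without patient-level data, which such studies rarely deposit.

## Binarization and stratification

A patient is *sensitized* to a molecule when sIgE is at least 0.35 kU/L,
the conventional multiplex-assay cut-off. The comparison is inclusive
(`>= 0.35` codes 1) and no epsilon slack is added; `binarize()` is monotone
in the levels and idempotent on its own output. The threshold is a
parameter everywhere, never a constant inside a stage.

Age strata follow the usual pediatric convention: *child* means strictly
under 18 years, so age exactly 18 classifies as adult. Fractional ages are
accepted. The boundary is a single documented convention rather than an
option, because silently mixing conventions across runs would corrupt
prevalence comparisons between groups.

All shares downstream use one denominator: the number of patients in the
group sensitized to **at least one** panel molecule. The full tested cohort
is a different denominator, exposed separately (`compute_share()` works on
any count/total pair) but never mixed into the per-molecule shares.

## Prevalence summaries

`sensitization_summary()` reports, per molecule and group (all, child,
adult): the sensitized count, its percentage share among the group's
sensitized-to-any patients, and the mean ± σ of sIgE **among that
molecule's positives only**. Restricting the mean to positives is the only
reading consistent with reported summary tables in this field, where
per-molecule means sit one to two orders of magnitude above the 0.35 kU/L
cut-off; including the sub-threshold majority would drag them toward zero.
σ is the population standard deviation (divide by *n*), matching the
"M ± σ" notation convention; a sample-sd variant sits behind the `sd_type`
flag. Percentages are rounded half-up to two decimals — half-up, not R's
default round-half-even, because reported tables in this field print
half-up values. A group with no sensitized patients yields `NA` shares
(undefined), never 0.

## Co-sensitization profiles

A patient's *profile* is their exact positive set: a patient positive to
three molecules contributes to that 3-set only, not to its subsets. Under
exact-set assignment profile counts conserve the sensitized total, and the
per-molecule marginal (sum of counts of profiles containing a molecule)
equals the summary count — both conservation laws are asserted exactly in
the test suite. Profiles are labelled by `+`-joined molecule names in
canonical panel order (e.g. `Der f 2+Der p 2`). Ranking is by count
descending, then fewer members, then canonical order of members — reported
studies never print ties, so a deterministic tie-break is a reproducibility
requirement, not an inference.

## The priority-molecule decision

For each region (or region × age cell), `region_shares()` computes the
share series: per molecule, the count of positives divided by the
region-group's sensitized-to-any count. `priority_molecules()` then decides
the region's one or two *priority molecules*:

1. **Exclusion.** A cell with no sensitized patients is excluded as
   `no_sensitized`; one with fewer than `min_group_n` (default 3) as
   `below_min_n`. The default of 3 encodes the practice of dropping cells
   with only two sensitized patients, where a share series is
   uninterpretable.
2. **Maxima.** The absolute maximum m₁ and runner-up m₂ of the shares,
   ties resolved by canonical panel order.
3. **Margin rule.** If share(m₁) − share(m₂) exceeds the margin (default
   0.05), m₁ alone is the priority molecule (`margin_single`).
4. **t-step.** Otherwise the pair is provisional. For every molecule with
   positive share, a one-sample upper-tail Student's t-test of the full
   share series against that molecule's own share yields pᵢ — the
   probability of series values as large as shareᵢ, i.e. of "another
   maximum" above it. m₂ is retained iff |p(m₂) − p(m₁)| / p(m₁) ≤
   `p_similarity` (default 0.05): its p is essentially as large as the
   maximum's, so the null that only m₁ reflects the region's sensitization
   is not supported. Retained → `[m₁, m₂]` (`margin_equal_pair` when the
   shares tie exactly, else `ttest_pair`); otherwise `[m₁]`
   (`ttest_single`).

Design choices that were genuinely open, and how they were resolved:

* **"5%" margin = 5 percentage points.** The margin compares quantities
  that are themselves shares, so it is interpreted as an absolute share
  difference (0.05 in proportion units). A relative interpretation is
  available via `relative_margin = TRUE`.
* **p-value closeness is relative.** p-values are compared to each other,
  not to shares, so "within 5%" is read as ≤ 0.05 × p(m₁).
* **The popmean of molecule i is its own share, and the sample is the full
  series including i.** This is the most literal reading of testing "each
  value" of a short series; the decision trace records the entire p-value
  map so the alternative readings can be audited from the output.
* **α = 0.002 is an annotation, not a gate.** The decision narrative
  hinges on the p-similarity rule; α is recorded in the trace (and can be
  promoted to a hard gate with `alpha_gate = TRUE`).
* **A gap exactly equal to the margin goes to the t-step.** The margin
  rule fires only when the gap strictly exceeds the margin ("more than"),
  so the boundary case counts as ambiguous and is resolved by the t-test.
* **More than two tied maxima.** Priorities are capped at two (the
  field's "1–2 priority molecules" convention); the two largest shares in
  canonical order win.

The decision is scale-free in the underlying counts, deterministic, and is
verified in the acceptance suite against an independent brute-force
implementation of rules 1–4 on the exhaustive grid of length-3 share series
over {0, 0.05, …, 1}³.

### The t-tail implementation

`ttest_one_sample_greater()` is implemented from the closed form
t = (x̄ − μ₀)/(s/√n), s the sample sd, with the upper-tail p from the
Student's t distribution with n − 1 degrees of freedom. A constant series
has an undefined t; the degenerate convention is p = 1 when x̄ ≤ μ₀ and
p = 0 otherwise, flagged in the result (a constant share series means all
molecules tie, which the similarity rule then resolves to a pair). The test
suite checks the tail against numerical quadrature of the hand-written t
density to 10⁻⁸, and checks p = ½ exactly when the mean equals the
hypothesized value.

## The synthetic cohort generator

`generate_cohort()` draws from a Gaussian-copula latent-threshold model:
each patient has a latent multivariate normal vector with the configured
correlation matrix, and molecule j is positive iff the latent coordinate
falls below the Φ⁻¹(prevalenceⱼ) quantile. Marginal prevalences are
therefore exact by construction, while the latent correlation induces
co-sensitization structure — the feature the profile and priority stages
exist to analyze, and which independent Bernoulli draws could not exercise.
Correlation matrices are validated (symmetry, unit diagonal, eigenvalues ≥
−10⁻⁹) before any sampling; the factorization uses the symmetric eigen
decomposition so exactly singular (perfectly correlated) configurations are
legal.

Positive sIgE levels are log-normal per molecule, clamped up to the
threshold; negatives are uniform on [0, `negative_level_max`] with the
bound strictly below the threshold — so binarization recovers the
indicators exactly, and the boundary is exercised rather than avoided
(negatives are not simply zero). Ages are truncated-gamma within each
stratum (children on [0, 18), adults shifted to [18, 90)); total IgE is an
independent log-normal nuisance column. One RNG stream seeded from
`config$seed` drives all draws in a fixed order, so a config plus seed
reproduces the cohort bit-for-bit.

`preset_ukraine_like()` is a documented configuration emulating a large
national HDM cohort: 16 regions with a few dominant urban centres (weights
19.62%, 14.48%, 7.7%, 7.55%, remainder split evenly), 57.86% children,
children sensitized at roughly 0.32 and adults at roughly 0.20 of their
stratum so children dominate the sensitized group by about 2.3:1, and
per-molecule prevalences set to stratum rate × target share so the shares
among the sensitized approximate the canonical ordering (group 2 ≈ 0.7,
Der p 23 and group 1 above 0.45, minor molecules rare). The correlation is
a four-factor loading model (guaranteeing positive semi-definiteness):

* a strong *general* factor (loadings 0.72–0.88) concentrating positivity
  in an allergic subpopulation, so roughly 30% of tested patients carry
  essentially all sensitization;
* a *broad polysensitization* factor tying Der p 23 to group 1 and the
  mid-prevalence molecules, which keeps spurious mono-Der p 23 and exact
  f2+p2+p23 triples rare;
* a *group 2* factor on Der f 2/Der p 2 making their exact pair the modal
  profile;
* a small *group 1* factor on Der f 1/Der p 1.

Two western regions (Zakarpattia, Khmelnytskyi) override the prevalences
(Der p 23 at 0.30 against damped group 1/2) so that their priority decision
is single-molecule Der p 23 with a share gap beyond the margin. The preset
is calibrated to reproduce the *rank order* of the leading profiles and the
regional pattern, not exact percentages, since no joint-distribution data
exists to fit against.

What the generator deliberately does not emulate: assay-level measurement
noise or inter-assay drift, household or family clustering, region-specific
age pyramids, cross-reactivity-driven level correlation among positives
(levels are conditionally independent given the indicators), and any
tIgE–sIgE dependence. Tests passing on synthetic cohorts therefore validate
the *analysis machinery* — conservation laws, decision logic, determinism —
not epidemiological claims about real populations.

## Numerical and reporting conventions

* Half-up rounding to 2 decimals for every reported percentage and ratio.
* Output tables serialize non-integer numerics with 4 decimals (the
  write/read round-trip contract of `write_table()`); decimal commas in
  input are rejected unless `decimal_comma = TRUE`, because they are
  ambiguous with CSV separators.
* Missing sIgE cells abort ingest with the patient and column named —
  never imputed, since imputation would silently change every prevalence
  denominator.
* The pipeline manifest records the resolved configuration, input MD5 and
  row counts but no wall-clock timestamp, keeping identical runs
  byte-identical.

The test suite runs its statistical checks at fixed problem sizes chosen to
keep binomial noise well inside the asserted bounds: marginal recovery at
n = 5000 (3 binomial SE), preset structure at n = 10000, conservation on
100 random cohorts of 20–80 patients, decision-rule equivalence on all
9 260 non-degenerate grid points, and the t-tail on 1 000 random series.

## Limitations

The priority decision reports at most two molecules, by construction. The
t-step treats the share series as a sample of exchangeable values, which is
a modelling convention (shares of different molecules are neither
independent nor identically distributed); its role is a reproducible
tie-resolution rule, not an inferential claim. Region labels are opaque
strings — no spatial statistics are attempted. And because real multiplex
cohorts are rarely deposited, quantitative agreement with any specific
published cohort can only be checked at the level of printed summary
counts, which the acceptance script recomputes.
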
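---
title: "Methods: autoantibody panel design, cutoff optimization and occult-cancer adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoantibody panel design, cutoff optimization and occult-cancer adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serodx)
```

## The problem

Tumor-associated autoantibodies (AAbs) circulate in a substantial minority of
lung-cancer patients, sometimes years before diagnosis. A multi-marker serology
test such as EarlyCDT-Lung measures AAbs against a small panel of recombinant
antigens (p53, NY-ESO-1, CAGE, GBU4-5, MAGEA4, SOX2, HuD, AnnexinI) by
titration-series ELISA and calls the test positive when **any one** antigen is
positive (the OR rule). Each antigen call requires

1. **a dose response** — the signal, in calibrated reference units (RU), must
   track the antigen titration series (a genuine antibody binds more antigen
   at higher coat concentrations); and
2. **an RU above a per-antigen cutoff** at the reference (full-strength) coat.

`serodx` implements the computational side of designing such a panel: calling,
cutoff optimization under a fixed-specificity or fixed-sensitivity constraint,
specificity adjustment for occult cancers hiding in the "disease-free"
controls, and the diagnostic-performance statistics used to report the result.
Because the underlying sera are proprietary clinical samples, the package
ships a synthetic cohort generator with the statistical structure the analysis
assumes, so every stage is testable end to end.

## Positivity calling

The commercial assay's dose-response criterion is not publicly operationalized;
`serodx` defines it as a Spearman rank correlation of at least `threshold`
(default 0.8) between the RU series and the coat-level index. The value 0.8 is
the smallest rank correlation a 4-point series can attain with a single
transposed pair (ranks 1,3,2,4), so one local inversion is tolerated but a flat
or noisy series is not. A constant series has no rank signal and fails. The
threshold is configurable and is echoed in pipeline logs.

Ties at the cutoff are **negative**: a call requires `ru_reference > cutoff`
strictly. The convention is arbitrary but fixed, and the optimizer scores
candidates with the identical rule, so fitted cutoffs and reported operating
points are internally consistent.

## Monte-Carlo direct search for cutoffs

`mc_search()` is the package's central fitting routine. Given a cohort with
confirmed cancers and controls, it:

1. builds a per-antigen candidate grid — by default the empirical 80th–99.9th
   percentiles (type-1 quantiles, 0.1-percentile steps) of the **control** RU
   distribution, which makes the search space scale-free across antigens;
2. draws `n_candidates` (default 10,000) cutoff vectors uniformly and
   independently per antigen, with replacement, from one seeded generator;
3. scores every candidate by panel calling (sensitivity on the cancers,
   specificity on the controls, optionally occult-adjusted);
4. keeps candidates whose **constrained** metric lies within `tolerance`
   (default ±0.5 points) of the target — with a finite cohort, exact equality
   to, say, 90% specificity is generically unattainable, hence a band;
5. returns the feasible candidate maximizing the **free** metric. Ties are
   broken by the better constrained metric, then by the lexicographically
   smallest cutoff vector, so a seed fully determines the result.

Whether the historical optimization sampled candidate sets with or without
replacement is not documented; with-replacement is implemented, which leaves
the oracle-equivalence guarantee intact (on a grid of `G` joint combinations,
`n` draws miss the optimum with probability `(1 - 1/G)^n`).

`validate_cutoffs()` re-evaluates a fitted panel, intended for a held-out
cohort; it warns when subject ids overlap the search cohort. On the search
cohort itself it reproduces the fit's 2×2 counts bit-identically, which the
tests assert.

## Occult-cancer-adjusted specificity

High-risk "disease-free" control groups are never truly disease free: CT
screening finds undiagnosed lung cancer in up to ~2.7% of such populations in
a prevalence round. A panel that detects occult cancers is punished for it —
those positives are counted as false. `adjusted_specificity()` formalizes the
correction by expected counts: with per-control 5-year risks \(r_i\),

\[
E = \sum_i r_i,\qquad
\mathrm{FP}_{adj} = \max(0,\ \mathrm{FP} - s\,E),\qquad
\mathrm{spec}_{adj} = 100\left(1 - \frac{\mathrm{FP}_{adj}}{N - E}\right),
\]

where \(s\) is the panel sensitivity as a fraction. The adjustment is strictly
increasing in \(s\) while \(\mathrm{FP} > sE\), and can *lower* specificity
when \(s = 0\) (the denominator shrinks but no false positives are excused).
This expected-count deflation is one defensible formalization of a correction
that has historically been described only qualitatively; it is isolated behind
its own function so a per-subject reclassification variant could be swapped
in. Notably, at a uniform 2.7% occult risk the formula moves a 91% raw
specificity to roughly 91.9%, not 93% — reproducing a published 91→93 shift
would require an implied occult burden near 6%, so the package documents the
formula's behaviour rather than claiming to reproduce that particular pair of
numbers.

## The risk model

The occult adjustment and the audit risk summaries need an individual 5-year
absolute lung-cancer risk from gender, age and smoking history, in the spirit
of the Spitz demographic risk models. The published coefficients of those
models (and of their in-house adaptations) are not available, so
`risk_model_config()` exposes a transparent parametric family:

\[
\text{risk} = \min\bigl(\text{cap},\ \text{baseline}(\text{gender},
\text{age band}) \times m(\text{smoking}) \times
e^{\beta\,\cdot\,\text{years smoked}}\bigr)
\]

with 5-year age bands over 40–84 (clamped outside), multipliers ordered
never ≤ ex ≤ current, and nearest-rank percentiles in summaries. The defaults
(baseline rising from 0.125% to 1.125% across male age bands, female 0.75×,
multipliers 1/3/5, \(\beta = 0.01\)/year, cap 15%) were chosen once so that
the default at-risk demographic mix yields a mean 5-year risk between 2 and
3% with a maximum near 10% — the scale reported for commercial-audit
populations. They are illustrative, not a reimplementation of any published
model, and "5-year" is a label on the horizon, not a derived quantity.
Subjects with unknown smoking status are carried through all data structures
but refused by the risk model with an instruction to impute or exclude.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure downstream stages consume:

* **Marginals.** Per antigen and population, a subject is "elevated" with the
  configured prevalence; defaults are the published per-antigen percentage
  positivity of an optimization-set case–control design (e.g. p53 13%/3%,
  MAGEA4 12%/4% in cancers/normals).
* **RU mixture.** Background RU is lognormal (meanlog 0, sdlog 1); elevated RU
  is lognormal (meanlog 4, sdlog 0.5), stochastically dominating it. The
  "true" cutoff sits at the background's 99.9th percentile, so positivity at
  the true cutoffs equals the elevation prevalence by construction (plus a
  ≤0.1% background leak per antigen).
* **Correlation.** Elevation indicators share one latent Gaussian
  "immunogenicity" factor with loading \(\sqrt{\rho}\) (a Gaussian copula on
  the indicators): raising \(\rho\) lowers panel-level positivity below the
  independence closed form \(1-\prod_i(1-p_i)\) without touching marginals.
  The default \(\rho = 0.3\) is deliberately flagged as **uncalibrated** —
  printed marginal positivities cannot identify the joint distribution; the
  value was fixed once on the observation that published panel-level rates sit
  a few points below the independence bound, implying positive dependence.
* **Dose response.** Elevated series decay geometrically (default 40% per
  dilution step) from the full-strength coat with multiplicative log-noise
  (sd 0.05); background series are flat plus noise, so the dose-response
  checker has a real signal to detect. The reference coat level carries the
  mixture draw exactly.
* **Occult cancers.** Control and at-risk subjects truly harbor cancer with
  probability `occult_rate` (default 2.7%); occult subjects keep their control
  label and demographics but draw antigen elevations at cancer rates. The
  generator returns a truth table so adjustment and recovery can be scored.
* **Demographics** are sampled independently of antigen status except through
  occult status, reflecting the absence of reported AAb–demographic
  associations; arm-level defaults mirror published case–control and
  commercial-audit profiles (73%/70% male and mean age ~65 in the case–control
  arms; 42% male, mean age 61, current/ex/never ≈ 45/46/9% in the at-risk arm).

What the generator does **not** emulate: plate and batch effects, assay
imprecision beyond the stated noise, antigen-specific RU scales, and any
AAb–stage or AAb–subtype association (all subgroups share the configured
signal). Passing tests therefore demonstrate the correctness of the
algorithms under the assumed structure, not clinical performance on real sera.

## Numerical and statistical conventions

* **Exact intervals.** All binomial CIs are Clopper–Pearson via beta-quantile
  inversion. The exact method (not Wilson) reproduces published whole-percent
  bounds such as 9/53 → (8, 30), where Wilson's lower bound would round to 9.
* **Chi-squared without continuity correction.** Panel comparisons use the
  Pearson statistic on the 2×2 table without Yates' correction, which
  reproduces the published p = 0.63 for 10/25 vs 9/19.
* **Rounding.** Internal arithmetic is full precision; whole-percent
  presentation uses half-up rounding (`percent_round()`), applied only at the
  reporting layer. "1 in N" is the half-up-rounded reciprocal of the PPV.
* **Degenerate inputs.** Constant titration series fail the dose-response
  check; empty margins are refused by the comparison test; `one_in_n()` is
  undefined at PPV 0; an expected occult burden reaching the control-group
  size is an error.
* **Seeding.** Every stochastic routine takes an explicit integer seed;
  the pipeline derives per-stage seeds from one master seed by fixed offsets
  so stages can be rerun independently yet reproducibly.

## Problem sizes used in the test suite

The package validates its estimators at sizes chosen to give comfortable
binomial resolution while keeping the suite quick to run: optimizer–oracle
equivalence on a 5³-combination grid (where exhaustive enumeration is exact);
parameter recovery on a 3,000-subject cohort (1,000 cancers, 2,000 controls)
with a held-out twin and 10,000 Monte-Carlo candidates, checking that the 95%
binomial interval of the held-out constrained metric covers its target; and
the independence closed form \(1-\prod(1-p_i) = 0.398\) at 20,000 cancer
subjects, where the Monte-Carlo standard error is ~0.35 points.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_sim_config(n_cancer = 500, n_control = 1000, seed = 42)
cohort <- generate_cohort(cfg)

fit <- mc_search(cohort, panel7_antigens,
                 search_config(mode = "fix_specificity", target = 90,
                               tolerance = 0.5, n_candidates = 10000,
                               seed = 42))
print(fit)
plot(fit)                      # candidate cloud with the optimum highlighted

holdout <- generate_cohort(cohort_sim_config(n_cancer = 500,
                                             n_control = 1000, seed = 43))
validate_cutoffs(holdout, fit$panel)

# prevalence scenarios for a positive result in a high-risk population
ppv(0.41, 0.93, 0.024)         # -> 12.59% ("1 in 8")
accuracy(0.41, 0.93, 0.024)    # -> 91.75%
```

## Known limitations

* The occult adjustment and the risk model are explicit, documented stand-ins
  for unpublished internal procedures; absolute adjusted-specificity values
  depend on the assumed risk scale.
* The generator's between-antigen correlation and RU distribution shapes are
  not identifiable from published summaries; conclusions about panel-level
  behaviour transfer to real data only insofar as those assumptions hold.
* The Monte-Carlo search is a direct random search; it inherits that method's
  grid granularity and offers no optimality guarantee off-grid.
* SOX2-B and SOX2-N are carried as distinct antigen codes; panels must name
  which construct they use. Their near-perfect observed concordance justifies
  substitution but is an empirical, not structural, property.
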
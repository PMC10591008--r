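---
title: "Evaluating longitudinal MRI follow-up designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating longitudinal MRI follow-up designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longdesign)
```

# The problem

Longitudinal neuroimaging studies trade statistical quality against cost:
every additional MRI session buys precision in each participant's
trajectory but adds scanner time, participant burden and attrition risk.
`longdesign` treats the design question empirically. Starting from a dense
reference schedule — baseline `t0` plus four monthly follow-ups, the
structure of high-frequency tractometry cohorts in multiple sclerosis —
it generates every baseline-anchored subset of a given size ("tested
designs"), re-runs the full analysis under each, and quantifies three
consequences of thinning the schedule: how participant-specific change
estimates move, how required sample sizes grow, and which MRI–clinical
associations survive.

Because such cohorts are not generally redistributable, the package pairs
the analysis with a simulator that reproduces their statistical structure.
All claims validated by the test suite are claims about data with that
structure; the section on the simulator's scope below states what that
does and does not cover.

# The simulator

`simulation_config()` describes a cohort; `simulate_dataset()` draws one.
For participant $i$, bundle–measure cell $(b,k)$ and acquisition week $w$:

$$y = \mu_k + x_i'\gamma + a_i + (\beta_k + b_i)\,w + \varepsilon,
\qquad (a_i, b_i) \sim N_2(0, \Sigma), \quad
\varepsilon \sim N(0, \sigma_{bk}^2),$$

with $(a_i, b_i)$ drawn independently per cell. Acquisition weeks are the
nominal schedule plus uniform day-level jitter on follow-ups (baseline
pinned at week 0), so "time" is a continuous covariate and scheduling
noise is part of the data-generating process.

Key defaults and the reasoning behind them:

* `n_participants = 20`, `session_weeks = c(0, 4, 8, 12, 16)`,
  `jitter_days = 7`: a 20-person cohort scanned five times at 4-week
  (±1 week) intervals, i.e. 100 participant-sessions — the scale of
  monthly-MRI designs actually run in MS research.
* `bundles`, `measures`: five bundles commonly affected in relapsing-
  remitting MS (CC3, CST, CG, SLF2, OR) crossed with eight diffusion and
  myelin measures (MD, RD, FW, AFD-total, ICvf, ISOvf, MTR, ihMTdR1sat) —
  names only; all cells share the same generative form.
* `fixed_slope = -0.005` units/week, `slope_sd = 0.01`,
  `intercept_sd = 0.1`, `noise_sd = 0.05` on a baseline level of 1: a
  slowly drifting measure whose between-participant slope spread and
  session-to-session noise give per-participant slope reliabilities around
  0.85 on the full schedule — high enough that designs differ by
  information content rather than drowning uniformly in noise, and
  producing design-agreement correlations in the 0.6–1.0 range typical of
  reported tractometry change estimates.
* Demographics follow a young, mostly female MS-like cohort (age
  36 ± 4.7 y, 4 male / 16 female, disease duration 7 ± 5.9 y). Covariate
  effects $\gamma$ default to zero but are configurable; the analysis can
  adjust for them either way.
* Clinical change scores (EDSS, SDMT, 9HPT, T25FW) are drawn with
  configurable marginal moments (defaults: mean ± SD of 0 ± 0.25,
  4.4 ± 13.8, −0.9 ± 3.5, −0.12 ± 1.0 respectively — a clinically stable
  cohort) and coupled to the true slopes of one anchor bundle–measure
  through a Gaussian copula on ranks: the latent correlation is
  $2\sin(\pi\rho_s/6)$, so the population Spearman correlation equals the
  target `clinical_target_spearman` (default 0.3, a modest coupling; set
  it to 0 for a null regime or higher to study preservation). Rank-level
  coupling is the natural controllable quantity because the downstream
  analysis is rank-based.
* Missingness: per-session drop probabilities plus `n_dropout` whole
  participants who leave after baseline, emulating attrition (a cohort of
  20 with one dropout reproduces the common 20 → 19 follow-up pattern).

What the simulator does **not** emulate: spatial structure, cross-measure
and cross-bundle correlation (cells are independent), nonlinear
trajectories (plateaus, lesion dynamics), heavy-tailed or floor/ceiling
clinical marginals, and informative dropout. Passing tests therefore
demonstrate correctness of the machinery and behaviour under linear
mixed-model assumptions — not robustness to their violation.

# Change estimation

`fit_lmm()` fits `value ~ time (+ covariates) + (1 + time | participant)`
by REML and reports each participant's change as the fixed slope plus the
conditional mode (BLUP) of their random slope. Interpretation note: a
"participant slope" could also mean a per-participant refit; the BLUP
convention is used because it is what the mixed model estimates, and the
shrinkage it induces is tested explicitly (the variance of BLUP slopes
never exceeds that of per-participant OLS slopes).

Time is measured in weeks from each participant's baseline, so the
intercept is the baseline level and slopes have identical units across
designs. The actual jittered acquisition week is the default time
covariate (`time_scale = "acquisition"`); the nominal session week is
available as an option, since real analyses differ in which they use.

Numerical choices:

* **Degenerate data short-circuit.** If per-participant OLS residuals are
  zero to within `1e-9` relative tolerance, the mixed model is degenerate
  (zero residual variance) and per-participant OLS — exact in that case —
  is returned, flagged `ols_exact`.
* **Fallback ladder.** Random-slope fits on three timepoints are fragile.
  If the correlated random-effects fit is singular, the model is refit
  with independent intercept and slope; if that is singular too, a random-
  intercept model supplies the fixed slope and centred per-participant OLS
  deviations supply the spread (`intercept_plus_ols`). The method used is
  recorded in `fit_meta` so no fit silently changes meaning.
* Covariate sets are a parameter: empty for a healthy-control regime,
  `c("age", "sex", "disease_duration")` for a patient regime.

# Comparing designs

`compare_designs()` takes the aligned participants × designs slope matrix
(complete cases only, rows sorted by participant).

* **RM-ANOVA.** Condition, subject and error sums of squares;
  $F = MS_{\text{cond}}/MS_{\text{error}}$ with $(m-1)$ and
  $(n-1)(m-1)$ df. Error variance is declared zero only relative to the
  total decomposition (`1e-12` relative), yielding $F = 0, p = 1$ when
  conditions are identical and $F = \infty$ with a warning when a real
  condition effect meets zero error.
* **Sphericity.** Mauchly's $W$ on an orthonormal contrast basis with the
  chi-square approximation including Box's second-order expansion term
  (the first-order factor alone is accurate to about three digits at
  these sample sizes). With $n \le m-1$ the test is undefined and the
  code instructs unconditional $\varepsilon$ correction.
* **Greenhouse–Geisser.** $\varepsilon$ from the eigenvalues of the
  contrast-space covariance, clipped to $[1/(m-1), 1]$. By default the
  correction is applied only when Mauchly's p < 0.05, mirroring common
  practice; `gg = "always"` avoids the conditional-testing critique, and
  `gg = "never"` disables it. Huynh–Feldt is deliberately not offered.
* **Post hoc.** Tukey's studentized-range test using the within-subjects
  error mean square — the standard coupling after an RM-ANOVA — with
  uncorrected error df. BH-FDR is applied over the post-hoc family within
  a cell by default; across cells the pipeline adjusts the omnibus
  p-values per sweep. The FDR family is a documented choice, not a
  uniquely determined one, and is configurable.
* **Similarity.** Pearson correlation between design columns;
  `similarity_to_reference()` summarizes each tested design against the
  full schedule, averaging over cells when given a list.

# Power and sample size

`power_rm_anova()` uses the noncentral-F convention of mainstream power
software for within-subject factors:
$\lambda = f^2 n m \varepsilon/(1-\rho)$ with
$df_1 = (m-1)\varepsilon$, $df_2 = (n-1)(m-1)\varepsilon$. The convention
is stated explicitly because published formulas differ (some omit
$\varepsilon$ from $\lambda$); the Monte-Carlo oracle in the test suite is
the arbiter, and under compound symmetry the formula is exact. $\rho$
defaults to per-design estimation (`estimate_rho()`: pairwise Pearson
correlations between session columns averaged on the Fisher-z scale;
arithmetic averaging is available) — whether a pooled or per-design
$\rho$ is entered into such calculations varies between analysts, so the
choice is explicit. $\varepsilon$ defaults to 1 (sphericity assumed at
the planning stage). `solve_sample_size()` brackets and bisects the
monotone power curve and certifies minimality
($\text{power}(n) \ge$ target $> \text{power}(n-1)$).

One calibration note: the test suite checks the analytic power against
5000-replicate Monte-Carlo rejection rates over a 54-cell grid of
$(n, m, f, \rho)$. With 54 simultaneous two-standard-error comparisons,
a few random exceedances are expected even for an exact formula, so the
gate is calibration-style: the number of cells beyond 2 SE must stay
within its binomial 99.5% bound, no cell may exceed 4 SE, and the mean
deviation must stay below 1.25 SE. This detects systematic convention
errors (which shift many cells at once) without failing on sampling
noise.

# Associations with clinical change

Clinical change is always `follow-up − baseline` from the study's first
and last clinical visits, regardless of the MRI design under evaluation —
sparser MRI designs do not move the clinical endpoint. Spearman
correlation (exact permutation p for $n \le 9$ without ties, t
approximation otherwise) is used at an uncorrected p < 0.01; the
within-cohort Wilcoxon signed-rank test (exact by enumeration up to 15
nonzero differences, valid under ties; normal approximation with tie and
continuity corrections beyond) screens for overall clinical change.

`build_ledger()` classifies each tested design's associations against the
reference: *preserved* (significant in both, same sign), *inverse*
(significant in both, opposite sign), *lost* (reference only), *new*
(tested only). Preserved, inverse and lost partition the
reference-significant set — an identity asserted by the tests. Requiring
sign agreement for "preserved" is the default because an opposite-sign
association is a qualitatively different (and more alarming) outcome;
`require_sign = FALSE` gives the laxer significance-only bookkeeping.
Frequencies are percentages of the reference total, overall and broken
down by bundle and by measure.

# Orchestration and reproducibility

`run_config()`/`run_study()` chain all stages on one simulated dataset,
writing long-format CSVs, a JSON design menu and a manifest containing
the root seed, a configuration hash and stage record counts. All
randomness derives from the root seed through labelled substreams, so
stages are independently re-runnable and a rerun with the same
configuration is bit-identical. Thresholds (ANOVA 0.05, associations
0.01, Mauchly gate 0.05; power planning at f = 0.2, α = 0.05, power 0.8)
are validated before any computation.

# Problem sizes in the test suite

The suite exercises: slope recovery over 200 simulated cohorts of 20
participants; similarity ordering of the shortest balanced versus the
longest unbalanced design over 200 cohorts; type-I calibration of the
design comparison over 1000 null draws; the 54-cell power grid at 5000
replicates per cell; and 100+ randomized matrices against definitional
oracles for the ANOVA machinery. These sizes give Monte-Carlo standard
errors small enough for the stated gates while keeping a full run of the
suite under a few minutes on a single core.

# Known limitations

* The simulator's independence across bundle–measure cells understates
  the multiplicity structure of real tractometry data; preserved-
  association frequencies on simulated grids are therefore cleaner than
  real ones.
* Only linear individual trajectories are modelled; designs that differ
  in their ability to capture curvature cannot be distinguished here.
* The power module covers the one-group within-subjects ANOVA family
  only — no between-group factors or interactions.
* No design optimizer is included: the package evaluates a fixed menu of
  candidate designs.
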
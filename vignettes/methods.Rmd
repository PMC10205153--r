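---
title: "Models and methods behind erpbf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpbf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

When a reader encounters a word, two properties of its context are easy to
conflate: how *predictable* the word itself is (its cloze probability), and
how *constraining* the context is (how concentrated the distribution of
plausible continuations is, summarized by its Shannon entropy). The two are
correlated by construction — strongly constraining contexts tend to contain
predictable words — but they are conceptually distinct, and late ERP
components (the post-N400 positivity and the P600) have been proposed to
index the revision cost incurred when a *strong* commitment is disconfirmed,
over and above simple unpredictability. `erpbf` implements the full analysis
chain needed to dissociate the two in single-trial ERP amplitudes, together
with a synthetic-data generator that stands in for raw EEG and cloze data.

# Predictors

For each item and condition, cloze responses (one stem-collapsed token per
respondent) yield:

* **cloze probability** — the proportion of respondents producing the target
  stem;
* **smoothed log2 cloze** — `log2((k + 1) / (n + 2))`, additive (Laplace)
  smoothing with pseudocounts of one, so zero-cloze targets stay finite and
  the predictor is strictly negative;
* **entropy (bits)** — `-sum p * log2 p` over the completion distribution;
  low entropy means strong constraint.

Two conventions here were genuinely open and are package decisions:

* *Smoothing denominator.* Only "pseudocounts of one" is specified upstream.
  We smooth the **two-outcome** event (target given vs not), hence `n + 2`
  in the denominator, because the analysis consumes the probability of the
  target word, not the full response distribution. The alternative
  `(k + 1) / (n + V)` over `V` response types would make the predictor
  depend on the (unstable) observed type count.
* *Log base.* Base 2 throughout: entropies are reported in bits and the
  worked example (a 0.9/0.1 split giving 0.47) is consistent only with
  log2.

Predictors are centered **on the rows entering each analysis** (the two
collapsed-condition analyses have different row sets, hence different
centers); the trial-table builder re-centers automatically.

# Hierarchical model

For one region of interest (ROI), single-trial mean amplitude (in uV) is
modelled as

```
y ~ 1 + entropy_c + log2cloze_c
    + (1 + entropy_c + log2cloze_c | subject)   # full covariance
    + (1 | item)
```

with priors: intercept `N(0, 5)`, slopes `N(0, 1)` (estimation set),
`sigma_subject, sigma_item ~ N+(0, 0.5)`, `sigma_residual ~ N+(8, 2)`,
`rho ~ LKJ(2)`. The prior block in the source text is typographically
garbled; this reading is recorded as an assumption in the package's notes.
Items carry intercepts only: after collapsing conditions there are just two
predictor values per item, too few to identify item slopes.

Hypothesis tests use a second, narrower prior set on the tested term only:
`N-(0, 0.2)` for effects with a directional (negative) hypothesis,
`N+(0, 0.2)` for positive ones, `N(0, 0.2)` for two-sided tests. Truncated
priors are **normalized half-normals** (the factor 2 is kept): marginal
likelihoods, unlike posteriors, depend on that normalization.

## Sampler

No Stan-family engine is available in the target environment, so the model
is fitted by a blocked Gibbs sampler written for exactly this model class:

* regression coefficients: coordinate-wise conjugate draws from (truncated)
  normal full conditionals — truncation is exact, not rejection-based;
* subject and item effects: conjugate multivariate/scalar normal draws;
* variance parameters and canonical partial correlations (CPCs): univariate
  slice sampling (stepping-out + shrinkage), scales on the log
  scale;
* an **interweaving (ASIS) step** re-updates every random-effect SD in the
  non-centered parameterization, holding standardized effects fixed. Without
  it the sigma chains stall (bulk ESS of a few dozen at desk scale); with it
  they mix an order of magnitude faster. Because the non-centered residual
  is linear in the SDs, each slice evaluation reduces to a precomputed
  quadratic form.

The correlation matrix is parameterized by CPCs via the C-vine construction:
`z[i,j] ~ 2 Beta(a_j, a_j) - 1` with `a_j = eta + (q - 1 - j) / 2` is
exactly `LKJ(eta)` on the implied matrix, keeps every proposal positive
definite by construction, and gives a fully normalized prior density (again
needed for marginal likelihoods). The construction is verified in the test
suite against the known LKJ marginal law.

The reference analysis ran 50,000 iterations per chain (1,000 warmup) with
R-hat <= 1.01 and bulk/tail ESS >= 2,000 for every parameter. The package
defaults (4 chains x 2,500 iterations, 500 warmup) are a deliberate
desk-scale reduction; `check_convergence()` applies the full thresholds and
`fit_model(check = TRUE)` retries once with doubled iterations before
failing with diagnostics attached.

# Bayes factors

`BF10` compares the full model against the null obtained by deleting the
tested **fixed** effect while retaining every other term, including the
random slope of the deleted term (the null composition is not stated
upstream; this mirrors standard nested practice). Marginal likelihoods come
from iterative (Meng–Wong) bridge sampling with a moment-matched
multivariate normal proposal on unconstrained parameters (log SDs, atanh
CPCs, log(+/-beta) for one-sided priors; Jacobians included). Posterior
draws are split in half — one half fits the proposal, the other half enters
the bridge — to avoid reuse bias.

One documented deviation: the bridge density is the **collapsed** posterior,
with the Gaussian random effects integrated out analytically via
Woodbury/determinant identities, rather than the latent-variable density.
The collapse is exact for this model class, reduces the bridge to ~10
well-behaved dimensions (a moment-matched normal proposal over ~100 latent
dimensions is unreliable at desk scale), and is cross-checked in the tests
against closed-form conjugate marginal likelihoods and a Savage–Dickey
estimate. The Savage–Dickey check itself (prior density at zero over a
Sheather–Jones kernel estimate of the posterior density at zero) is exposed
as an independent oracle for untruncated priors.

Prior sensitivity is assessed by recomputing `BF10` over prior SDs from 0.2
to 2 uV, truncated and untruncated, holding all other priors fixed; the
null model is fitted once per sweep.

# Sequential design and design analysis

Recruitment in a sequential Bayes factor design stops at the first
evaluation point where `BF10 >= 10` or `<= 1/10`, or at 150 participants.
Comparisons are **inclusive** ("reached a Bayes factor of 10"). The default
monitoring cadence is every 5 subjects (unstated upstream). The design
analysis simulates full studies from an assumed truth over a grid of sample
sizes and summarizes per-n replicate BFs; the reference analysis used a
single simulated data set per n (supported via `reps = 1`), and `reps > 1`
exposes the replicate noise that single-run design analyses hide.

# Preprocessing

* FIR filtering: Hamming windowed-sinc, bandpass 0.01–30 Hz, transition
  widths 0.01 Hz (low edge) and 7.5 Hz (high edge); kernel length
  `3.3 / (transition / srate)`. The design method is a package choice (only
  the widths are stated). With the default low transition the kernel spans
  minutes of signal — appropriate for continuous recordings; applying it to
  a shorter signal is an error, and epoch-scale tests use wider transitions.
* IIR variant: Butterworth second-order sections, order 8 per direction
  (16 effective after forward–backward), cutoffs at -3.01 dB per pass
  (-6.02 dB total). Sections start in their DC steady state and reflection
  padding scales with the low cutoff's settling time; direct-form cascades
  at 0.01 Hz/512 Hz are numerically delicate and this is the stable regime
  we verified.
* Baseline: mean over [-200, 0) ms subtracted per trial and channel
  (idempotent).
* Artifact rejection: flag a trial if any channel shows (max - min) >
  100 uV within any sliding 150 ms window (hop = 1 sample, the strictest
  reading; the hop is unstated upstream) or a successive-sample difference
  > 50 uV/ms (per-millisecond normalization, following the stated units).
* Windows are `[start, end)` in ms; onset at t = 0; ROI amplitudes are
  means over the ROI's electrodes and window samples.

# The synthetic world

The generator is a stated world, not a tuning knob:

* **Design**: Latin square, 224 items / 4 conditions at study scale, every
  subject sees every item once, 50% post-question trials.
* **Cloze**: Dirichlet-categorical, 60 respondents, 30 response types.
  Symmetric concentrations 0.0135 (strong) and 0.117 (weak) were calibrated
  once, by Monte Carlo before any acceptance test existed, to the study's
  condition mean entropies (0.68 / 2.44 bits); the implied 95% entropy
  ranges land close to the study's, which was not separately tuned.
* **Amplitudes**: the generative mirror of the fitted model. Stated values:
  constraint effect -0.26 uV/bit, residual SD 8 uV. Unreported values fixed
  once at plausible ERP scales anchored to the prior set: intercept 2 uV,
  predictability slope -0.11 uV per log2-cloze unit, subject SDs
  (1.0, 0.25, 0.25) uV with intercept variability larger than slope
  variability, exchangeable correlation 0.3, item SD 0.5 uV.
* **Epochs**: flat component templates over the ROI window on the ROI
  electrodes (so noise-free window means recover injected amplitudes
  exactly), white Gaussian sensor noise, frontal half-cosine blinks and
  single-sample step artifacts that exceed the rejection thresholds by
  construction. Real EEG autocorrelation, 1/f spectra, volume conduction
  and ocular topographies are *not* emulated: a green preprocessing test
  establishes the arithmetic of the pipeline, not its behaviour on real
  recordings.
* **Stop signal**: deterministic-race simulation (response iff go finishing
  time < SSD + SSRT) under the standard 50 ms one-up/one-down staircase in
  [50, 1000] ms starting at 250 ms.

# Stop-signal analytics

Sessions are screened (exclude when mean go RT is more than 2 SD from the
mean failed-stop RT; caution when p(respond|stop) leaves [0.25, 0.75]) and
SSRT computed by the integration method: go omissions replaced by the
maximum observed go RT, go RTs sorted, the RT at rank
`ceiling(p(respond|stop) * n_go)` taken (no interpolation; first occurrence
on ties — both conventions are package decisions where the cited method is
silent), minus the mean SSD.

# Numerical choices and degenerate inputs

* Quantile credible intervals use linear-interpolation sample quantiles
  (R type 7).
* Bridge iteration: relative tolerance 1e-8, at most 1,000 iterations;
  proposal draws falling outside the support contribute nothing (their
  density is -Inf) and are dropped from the bridge numerator.
* The reported bridge MC error ignores residual autocorrelation of the
  (interwoven, well-mixing) posterior draws; tests treat it as a scale, not
  an exact standard error.
* Constant (degenerate) parameters — e.g. a residual SD fixed by design —
  are reported with `NA` diagnostics and treated as converged.
* A noiseless world (`all sigma = 0`) is recovered exactly by the
  *generator* (asserted to 1e-12); the pipeline's Bayesian estimate cannot
  reproduce an injected beta to machine precision because nondegenerate
  priors shrink, so the end-to-end noiseless contract is asserted at the
  generator level and the pipeline is tested at tiny-but-nonzero noise.

# Known limitations

* The multivariate two-response (PNP + P600) model and its cross-effect
  correlation are out of scope, as are ICA ocular correction, semantic-space
  similarity predictors, and topography rendering.
* The Gibbs sampler covers exactly the model family above (Gaussian
  response, subject slopes + item intercepts, optional fixed residual SD);
  it is not a general-purpose engine.
* Reproducing the study's empirical Bayes factors requires its deposited
  data, which this package deliberately does not bundle; all quantitative
  claims in the test suite are about the synthetic world and closed-form
  oracles.
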
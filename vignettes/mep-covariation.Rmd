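---
title: "Trial-level covariation of MEPs in homologous muscles: models and methods"
author: "mepcov package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-level covariation of MEPs in homologous muscles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepcov)
```

## The scientific problem

In a dual-site transcranial magnetic stimulation (TMS) protocol, a
conditioning stimulus (CS) over the right motor cortex precedes a test
stimulus (TS) over the left motor cortex by 10 ms. Each stimulus evokes a
motor evoked potential (MEP) in the contralateral flexor carpi radialis
(FCR): the CS in the left FCR, the TS in the right FCR. If corticospinal
excitability in the two hemispheres covaries from moment to moment, the
amplitudes of the two MEPs recorded on the *same trial* should be positively
correlated across trials, within each participant.

The catch is that MEP amplitude is exquisitely sensitive to the state of the
spinal motoneuron pool, which is indexed by the background surface EMG in
the moments before stimulation — even when that background stays below 2 µV
r.m.s. If the two muscles' background levels covary bilaterally, a spurious
MEP-amplitude correlation follows. The analysis therefore estimates, per
participant, a Spearman rank correlation between the two MEP amplitude
series, *with and without* adjustment for each muscle's own pre-stimulus
background EMG, and then asks at the sample level whether positive
coefficients predominate and whether adjustment systematically lowers them.

## Data reduction

Each trial is a 1 s bilateral EMG epoch sampled at 5 kHz, spanning 0.5 s
before to 0.5 s after the TS. Three scalar families are extracted
(`extractFeatures()`):

* **MEP peak-to-peak amplitude**: max minus min of the trace in a window
  12.5–45 ms after the stimulus addressed to that muscle. On conditioned
  trials the left-FCR window (12.5–45 ms after the CS) equivalently spans
  2.5–35 ms after the TS, which keeps it clear of the TS stimulus artefact.
* **MEP area**: mean rectified value over the same window times its nominal
  32.5 ms duration. No baseline is subtracted: the pre-stimulus level is
  sub-microvolt, so the induced bias is far below the amplitude scale.
* **Background r.m.s. EMG** per muscle over three windows of 100, 50 and
  10 ms, all ending 3 ms before the CS. On TS-alone trials the windows end
  at the same absolute position (13 ms before the TS), so the covariate is
  measured identically in every condition.

Millisecond windows are converted to half-open, 0-based sample ranges
`[round(start·fs/1000), round(end·fs/1000))` with round-half-to-even, so at
5 kHz the 12.5 ms onset maps to sample 62 and the MEP window holds 163
samples. Whether the 45 ms endpoint is treated inclusively is immaterial to
any calibrated quantity; the half-open choice is fixed and tested. No
artefact blanking is performed: the 12.5 ms onset is the artefact-handling
policy, and the synthetic generator honours it by placing artefacts strictly
earlier.

## Per-participant association estimators

With `x, y` the right/left MEP series and `cx, cy` the matching background
covariates over a participant's conditioned trials (median 18 trials):

**Unadjusted.** Spearman's rho — the Pearson correlation of mid-ranks
(`spearmanRho()`), undefined (and flagged `NA`) if either variable has zero
rank variance.

**Parametric semi-partial** (`parametricSemipartial()`). Each variable is
separately transformed by a Yeo–Johnson power transform at its own
profile-maximum-likelihood exponent; each transformed response is regressed
on its own transformed covariate by ordinary least squares; the residual
series are correlated by Spearman's method. The exponent is fitted per
variable per participant by a 1-D search (`stats::optimize`, tolerance 1e-6)
over a fixed bracket [-5, 5]; neither the bracket nor the optimizer affects
any calibrated result, and the fit is checked against a 1000-point grid in
the tests. When a covariate is constant the regression collapses to the
intercept, the residuals are the centred response, and — because the
transforms are monotone — the estimator reduces exactly to the unadjusted
Spearman rho.

**Non-parametric semi-partial** (`psrSemipartial()`). All four variables are
replaced by mid-ranks. Per muscle, a cumulative-logit ordinal model
`P(Y <= j | x) = logistic(alpha_j - beta x)` is fitted to the ranked
response on the ranked covariate, and probability-scale residuals
`r(y|x) = P(Y* < y | x) - P(Y* > y | x)` are evaluated under the fitted
conditional distribution. The two residual series are then correlated by
Spearman's method. The whole pipeline sees only ranks, so it is invariant —
bit for bit — to any strictly monotone transform of any input, which also
makes centring or scaling before the fit immaterial.

The ordinal MLE is a Newton ascent on the `J - 1` ordered intercepts plus
one slope, with analytic gradient, finite-difference Hessian of that
gradient, and step-halving: a step is halved until the log-likelihood
strictly increases and the intercepts stay strictly increasing. Convergence
is a gradient max-norm below 1e-6. With all-distinct outcomes the model is
the saturated rank parameterization (`n - 1` intercepts); its null fit is the
empirical cumulative logit in closed form, which is used as the starting
point. Complete separation — where the likelihood increases without bound —
is detected as parameter divergence beyond magnitude 30 and reported as
`separation = TRUE`, `converged = FALSE`; affected participants are carried
as undefined and excluded from sample-level counts rather than propagated
silently.

## Sample-level inference

Per method and window (`summarizeSample()`):

* **Mean rho with bootstrap 95% limits** — percentile interval over
  resamples of participants (not trials), 10,000 resamples by default,
  seeded and fully reproducible.
* **Sign counts and exact binomial point probability** — positive and
  negative coefficients are tallied (exact zeros counted separately and
  excluded from the binomial n, undefined values excluded entirely), and the
  probability of the observed split under a fair coin is the *point*
  probability `C(k+m, k) 0.5^(k+m)`, evaluated in log space. The point
  probability, not a tail, is the published convention for these splits:
  it reproduces every printed value to three significant figures, which a
  tail probability does not.
* **Bayesian sign test** (`signTestBF()`) — for each adjusted method, the
  number of participants whose adjusted coefficient is lower versus higher
  than their unadjusted one (ties excluded) feeds a beta-binomial
  directional test: posterior `Beta(1 + k, 1 + m)` under a uniform prior,
  BF10 equal to the posterior odds that the directional proportion exceeds
  one half (prior odds 1), via the regularized incomplete beta function.
  The uniform prior and directional construction reproduce both published
  Bayes factors (5611 and 20,175) to better than 0.01%.
* **Gaussian KDE** (`gaussianKde()`) — a reporting aid for the distribution
  of coefficients; Silverman's rule-of-thumb bandwidth.

## The synthetic generator

No public trial-level recordings exist for this protocol, so the package
ships a generative stand-in (`generateDataset()`, trace level;
`simulateFeatures()`, feature level) whose defaults are the emulated study
conditions: 205 participants; 18 conditioned, 17 test-alone and 10
conditioning-alone trials per participant.

Per trial, a shared standard-Gaussian cortical excitability factor `c_t` and
correlated log-background deviations `(b_L, b_R)` (bivariate Gaussian,
correlation 0.3, SD 0.35) drive log-normal amplitudes:

```
log amp_R = log M_R + 0.32 c_t + 1.2 b_R + u_R + eps_R
log amp_L = log M_L + 0.32 c_t + 1.2 b_L + u_L + eps_L
```

with trial noise SD 0.75 and participant-level log-offsets `u` of SD 0.5.
`M` is calibrated so the grand mean test-alone amplitude is 102 µV;
conditioned test responses are suppressed by 62/102, reproducing the
canonical interhemispheric-inhibition means. Background r.m.s. targets are
`0.72 exp(b)` µV (per-participant median jitter of SD 0.2 on the log scale),
giving medians below 1 µV and per-participant maxima mostly below 2 µV.
The loading/coupling values were chosen once, analytically: they induce a
population log-amplitude correlation of ≈ 0.18 and hence a participant-level
Spearman rho near 0.17, of which roughly 0.03 is attributable to the
correlated background — so covariate adjustment lowers the mean coefficient
without removing it, the qualitative ordering under study. The same latent
`b` both perturbs the amplitudes and sets the background covariate, which is
what makes adjustment meaningful by construction.

Traces are band-limited (100–1000 Hz Butterworth, filtered forward and
backward) Gaussian noise whose r.m.s. is pinned exactly on the 100 ms
analysis window; shorter windows fluctuate around the same target with
band-limited sampling noise, as in real data. MEPs are Hann-windowed
single-cycle sinusoids with exact sampled peak-to-peak amplitude, 18 ms
onset latency and 15 ms support; biphasic stimulus artefacts are placed at
the stimulus times and decay within ~1 ms, entirely before the 12.5 ms
measurement onset.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real recordings: motor-unit physiology and
amplitude-dependent MEP morphology; serial (trial-to-trial)
autocorrelation; phase-dependent excitability; coil-position jitter; any
structure in the suppression beyond a scalar mean factor; heavy-tailed
artefact contamination. Parameter-recovery results show the estimators
behave correctly under the assumed latent structure, not that the structure
is the true physiology.

## Numerical and design choices

* Epochs are taken to hold exactly 5000 samples (1 s at 5 kHz); sample 0
  sits at -500 ms relative to the TS and indices are 0-based in the
  interchange format.
* Long-format delimited text is the canonical interchange format; values are
  written at 17 significant digits, so write→read is the identity and
  downstream feature tables are bit-identical.
* The conditioned-trial validity rule (CS exactly 10 ms before TS) is
  enforced at object construction.
* Bootstrap: percentile method, resampling participants; 10,000 resamples
  default.
* Degenerate inputs have documented contracts rather than failures: constant
  covariates reduce the adjusted estimators to the unadjusted one; constant
  responses yield flagged-undefined rho; all-tied adjusted-vs-unadjusted
  comparisons yield a flagged-undefined Bayes factor.
* Test and acceptance problem sizes: property suites use 500–600 Monte-Carlo
  replicates and parameter recovery uses 500 simulated participants at the
  study's 18 conditioned trials, run at the feature level (the trace-level
  path is validated separately for extraction-identity on smaller runs).
  These sizes give Monte-Carlo standard errors comfortably below the
  assertion margins.

## Known limitations

* The cumulative-logit Hessian is a finite difference of the analytic
  gradient; convergence is declared on the gradient norm, so the fitted
  parameters are accurate even though the Newton direction is approximate.
* With 18 trials the saturated rank parameterization estimates 18 parameters
  from 18 observations; the probability-scale residuals remain well defined,
  but individual intercepts are noisy — they are never interpreted.
* The feature-level simulation path writes identical background values for
  all three windows (the trace-level path differs across windows only by
  sampling noise); between-window comparisons of adjusted coefficients are
  therefore only meaningful on trace-level data.
* `generateDataset()` holds all traces in memory: about 80 MB per 10
  participants at default trial counts. Use `simulateFeatures()` for large
  parameter-recovery designs.
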
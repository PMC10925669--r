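---
title: "Methods: bidirectional two-sample MR with instrument accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR with instrument accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization treats genetic variants as natural
instruments for an exposure. For variant $j$, summary statistics provide the
estimated effect on the exposure $\hat\gamma_j$ (with standard error
$\sigma_{\gamma j}$) from one GWAS and the effect on the outcome
$\hat\Gamma_j$ ($\sigma_{\Gamma j}$) from an independent, non-overlapping
GWAS. Under the instrumental-variable assumptions (relevance, no
confounding, no direct outcome pathway), $\Gamma_j = \theta\,\gamma_j$ and
every Wald ratio $\hat\Gamma_j/\hat\gamma_j$ estimates the causal effect
$\theta$ — log-odds of disease per SD of exposure in the forward direction
here, SD per log-odds in reverse.

Violations are the interesting part. A variant with a *direct* (horizontally
pleiotropic) effect $\alpha_j$ contributes $\Gamma_j = \theta\gamma_j +
\alpha_j$; the estimators differ in which configurations of $\alpha_j$ they
tolerate:

* **IVW (multiplicative random effects)** — the inverse-variance-weighted
  mean of the ratios, equivalently weighted regression of $\hat\Gamma$ on
  $\hat\gamma$ through the origin with weights $1/\sigma_{\Gamma j}^2$.
  Consistent only when pleiotropy is absent or balances to zero *and*
  uncorrelated with instrument strength. The standard error is inflated by
  $\max\!\big(1, \sqrt{Q/(J-1)}\big)$, so heterogeneity widens intervals but
  can never narrow them; with one variant it reduces exactly to the Wald
  ratio.
* **MR-Egger** — the same regression with an intercept, after orienting
  every instrument so $\hat\gamma_j > 0$. Under InSIDE (instrument strength
  independent of direct effects) the slope remains consistent under
  *directional* pleiotropy, and the intercept estimates its average; the
  intercept test is the pleiotropy diagnostic that drives the primary-method
  rule. Inference uses the $t_{J-2}$ reference and the analogous inflation
  from Rücker's $Q'$.
* **Weighted median** — the interpolated weighted median of the ratios
  (cumulative-weight convention $s_j = \sum_{k \le j} w_k - w_j/2$, linear
  interpolation at $1/2$), consistent while valid instruments carry over
  half the weight. SE by seeded parametric bootstrap.
* **Weighted mode** — the argmax of a normal-kernel weighted density of the
  ratios (modified Silverman bandwidth $0.9\,\min(\mathrm{sd},
  \mathrm{mad})\,J^{-1/5}$, scaled by `bandwidth_factor`), consistent under
  the plurality assumption. As the bandwidth grows the estimate tends to the
  weighted mean; for a degenerate zero-spread set it returns the
  most-weighted value.
* **MR-RAPS** — M-estimation of the adjusted profile score with
  standardized residuals $t_j(\theta, \tau^2) = (\hat\Gamma_j -
  \theta\hat\gamma_j)/\sqrt{\sigma_{\Gamma j}^2 + \theta^2\sigma_{\gamma
  j}^2 + \tau^2}$, Huber loss ($c = 1.345$) by default and an
  overdispersion parameter $\tau^2 \ge 0$ solving $\tfrac1J\sum \psi(t_j)
  t_j = E[\psi(Z)Z]$. This models idiosyncratic pleiotropy as
  $N(0, \tau^2)$ and uses the instruments' own measurement error, so it
  stays consistent with many weak instruments. Sandwich standard error from
  the profiled score; non-convergence is reported, never silent.

On noiseless data with valid instruments all five recover $\theta$ to
numerical tolerance — the estimator-consistency test asserts this at 1e-8.

## Instrument selection and accounting

`run_cascade()` applies, in order: significance screen (1e-6 forward where
continuous-trait instruments are scarce, genome-wide 5e-8 reverse), greedy
p-value LD clumping ($r^2 < 0.01$ within a 10,000 kb window — the
conventional genome-wide window; a literal 10 kb reading is selectable via
`clump_kb = 10`), the weak-instrument filter ($F = \beta^2/\mathrm{se}^2 >
10$, strict), allele harmonization, an offline confounder screen, MR-PRESSO
outlier removal, a per-variant Steiger direction filter ($p < 0.05$, since
the removal rule names no threshold), and a Bonferroni filter dropping
variants with outcome $p < 0.05/n$ (direct-outcome suspects). Every stage's
removals are recorded in an `instrument_ledger` whose conservation invariant
(`final = initial - sum(removed)`) is enforced at each update.

Harmonization aligns outcome records to the exposure's effect allele,
negating betas for swapped records and complementing strand-flipped ones.
Palindromic (A/T, C/G) variants are always excluded in strict mode — no
allele-frequency rescue — as are records whose alleles cannot be reconciled.

A property of the cascade worth knowing: when the true effect is nonzero,
the Bonferroni direct-outcome filter preferentially removes the *strongest*
instruments (their outcome associations are genuine, flowing through the
exposure), which attenuates downstream estimates toward the null. The
analysis scripts show this visibly. It is implemented as specified; the
attenuation is a property of the procedure, not of the code.

## Sensitivity suite

Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\theta)^2$ with $w_j =
\hat\gamma_j^2/\sigma_{\Gamma j}^2$ ($p$ from $\chi^2_{J-1}$; $p < 0.05$
flags heterogeneity); Rücker's $Q'$ after the Egger intercept (never larger
than $Q$); the NOME diagnostic $I^2_{GX} = \max(0, (Q_{GX} - (J-1))/Q_{GX})$
on the oriented instrument effects, flagging attenuation risk for Egger when
below 0.9 (the flag is carried on Egger-primary calls; SIMEX correction is
out of scope); leave-one-out stability (all $J$ drop-one estimates must keep
the full estimate's sign with overlapping CIs); funnel data (ratio vs
precision); MR-PRESSO; Steiger; and analytic power.

**MR-PRESSO.** The observed weighted residual sum of squares about each
variant's leave-one-out IVW prediction is referred to a parametric null
(resampling $\hat\gamma^*, \hat\Gamma^*$ from the fitted model; default
1,000 draws). The global p uses $(1+r)/(1+n_{\mathrm{sim}})$, which is
discrete-uniform under the null — the calibration test applies
Kolmogorov–Smirnov over 500 replicates. Per-variant outlier p-values use the
plain empirical proportion (a $+1$ floor would make the Bonferroni-adjusted
minimum $J/(n_{\mathrm{sim}}+1)$, unable to reach $\alpha$ at moderate
simulation counts), Bonferroni-adjusted across variants. The distortion test
compares the outlier-removal shift in the IVW estimate against shifts from
removing random subsets of the same size.

**Steiger.** Per variant, the variance explained in the exposure is compared
with that in the outcome; continuous traits use $r^2 = t^2/(t^2+n-2)$,
binary traits a latent-logistic pseudo-$r^2$, $\beta^2 2f(1-f) / (\beta^2
2f(1-f) + \pi^2/3)$, by default (a liability-scale conversion
$\beta\,K(1-K)/\varphi(\Phi^{-1}(K))$ is selectable). The pooled test
Fisher-transforms the two multiple correlations and uses the two-sample
normal reference with variance $1/(n_1-3) + 1/(n_2-3)$. The verdict is
invariant to allele re-orientation and flips when exposure and outcome are
swapped.

**Power.** For a binary outcome the IVW standard error is asymptotically
$1/\sqrt{n K(1-K) r^2}$, giving two-sided power $\Phi(-z_{1-\alpha/2} +
|b|/\mathrm{se}) + \Phi(-z_{1-\alpha/2} - |b|/\mathrm{se})$ — exactly
$\alpha$ at the null. This describes the *fixed-effect* Wald test with
known instrument effects, so the calibration test's Monte-Carlo arm
simulates that test (large exposure sample, fixed-effect p); the
multiplicative random-effects inflation used for reporting is a
conservative modification the formula does not model. Power is evaluated at
the observed IVW odds ratio by default — the usual practice, with the usual
circularity caveat — and positive calls require at least 80%.

## Decision rule, FDR and calling

Per batch: a significant Egger intercept ($p < 0.05$) makes Egger primary
(NOME flag attached when $I^2_{GX} < 0.9$); otherwise significant
heterogeneity keeps IVW-MRE primary but a positive call additionally
requires the weighted median to agree (same sign, $p < 0.05$); otherwise
IVW-MRE alone. Primary p-values are Benjamini–Hochberg adjusted within one
family per direction × exposure (the family definition is configurable;
the source analyses do not pin it down). A positive call needs adjusted
$p < 0.05$ *and* power $\ge 0.8$ *and* (under heterogeneity) median
agreement. Note that BH adjustment is not idempotent on general inputs —
only tied values are fixed points — so adjusted p-values are never
re-adjusted downstream.

## Two-step mediation

For a triplet exposure → mediator → outcome with step estimates on the
log(-odds) scale, the indirect effect is $\beta_{XM}\beta_{MY}$ with
delta-method SE $\sqrt{\beta_{MY}^2\sigma_{XM}^2 +
\beta_{XM}^2\sigma_{MY}^2}$. When the total effect is significant
($p < 0.05$) the mediation is partial (PM) and the proportion mediated is
$100\,\beta_{XM}\beta_{MY}/\beta_{XY}$ percent; otherwise it is labelled
total (TM) and reported as 100% rather than as a ratio against a near-zero,
unstable denominator. Published-style rows can be rebuilt from printed
odds ratios and 95% CIs via `mr_estimate_from_or()` (the shipped worked
example reproduces printed rates of 42.43% and 12.33% to within rounding of
3-decimal ORs). The proportion is invariant to rescaling the mediator's
units ($\beta_{XM} k$, $\beta_{MY}/k$) — not to multiplying all three
effects by a constant, which rescales it linearly.

A percent-change convention used for headline statements: `or_and_percent()`
reports $100(e^\beta - 1)$ rounded to the nearest integer with ties rounded
*upward* (toward $+\infty$). This is the only integer tie rule consistent
with the worked statements the package reproduces (OR 0.315 → −68%,
OR 2.285 → +129%, OR 1.709 → +71%; the first two land exactly on .5).

## The synthetic-data generator

`generate_pair()` draws true instrument effects $\gamma_j \sim
N(0.1, 0.03^2)$ by default (median $F \approx 35$ at the default exposure
GWAS size of 8,428 — the shape of a brain imaging-derived-phenotype GWAS),
assigns direct effects to a configurable invalid fraction (balanced,
directional with mean = `pleiotropy_scale`, or correlated
$\alpha_j = \rho\gamma_j + \varepsilon$ for InSIDE-violation exercises),
sets $\Gamma_j = \theta\gamma_j + \alpha_j$, and observes both with
independent noise consistent with the two sample sizes — binary outcome
standard errors via the log-odds approximation $1/\sqrt{nK(1-K)2f(1-f)}$
(defaults $n = 27{,}432$, $K = 0.254$, the case-control shape of an IBD
GWAS) rather than by simulating individual-level cohorts, which keeps
replicate studies desk-scale. Palindromic and allele-flipped records
exercise harmonization; positions sit on one synthetic chromosome in
configurable LD blocks so clumping has structure to find. A config plus its
seed reproduces tables bit-identically, and the generator restores the
caller's RNG state.

What it does *not* emulate: realistic human LD maps, allele-frequency
spectra coupled to effect sizes, sample overlap between the two GWAS,
population stratification, or winner's-curse selection of instruments.
Passing tests therefore certify the statistical machinery under the stated
model, not performance on any particular cohort.

## Problem sizes and numerical choices

The test suite exercises the stochastic components at: type-I error, 1,000
null replicates ($J = 50$); robustness and Egger detection, 200 replicates
each; PRESSO, 100 planted-outlier runs at 1,000 simulations and 500 null
runs at 500; Steiger, 100 runs; power calibration, nine cells × 10,000
Monte-Carlo draws. These sizes give Monte-Carlo error comfortably below
each test's margin while keeping a full run in tens of seconds.

Tolerances and tie-breaks: estimator consistency asserted at 1e-8;
weighted-mode argmax refined by golden-section search within two grid steps
of a 512-point scan; RAPS profile optimization bracketed at three times the
largest absolute ratio with tolerance 1e-12, $\tau^2$ solved by bisection
with doubling upper bounds; weighted median/mode bootstrap SEs floored at
machine epsilon for degenerate sets; Wald-ratio SE uses the first-order
delta method by default (second order by flag). Degenerate inputs error
early with informative messages: $\gamma = 0$ Wald ratios, all-zero
instrument effects, sub-minimum instrument counts, non-positive standard
errors.

## Known limitations

Single-mediator, single-step mediation only (no multivariable MR
adjustment); no SIMEX correction under NOME violation (flag only); no
reference-panel LD computation or proxy-variant search; the confounder
screen is as complete as its offline annotation table; and power at the
observed effect inherits the circularity of that convention.
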
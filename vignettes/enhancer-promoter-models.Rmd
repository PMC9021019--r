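---
title: "Modelling transcriptional bursting as a function of enhancer-promoter contact probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcriptional bursting as a function of enhancer-promoter contact probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epcomm)
```

## The problem

Enhancer mobilization screens relocate a single enhancer to many genomic
positions around a fixed promoter and read out transcription per cell line,
turning the relationship between 3C-type contact probability and
transcriptional output into a measurable dose-response curve. `epcomm`
implements the quantitative layer of such a screen: stochastic models of
promoter bursting whose burst frequency responds to enhancer contact, a
mechanistic chain explaining where that response comes from, likelihood
machinery to fit both to per-line means and single-molecule RNA FISH
(smFISH) count distributions, the capture-C matrix computations that supply
contact probabilities, and a synthetic-study generator so that every stage
of the pipeline can be exercised and validated without any external data.

## The telegraph model and the Hill response

The promoter switches between OFF and ON with rates $k_{on}$ and $k_{off}$;
transcripts initiate at rate $\mu$ while ON and degrade at rate $\delta$.
Time is measured in mRNA lifetimes, so $\delta = 1$ and all rates are per
mRNA lifetime; `rate_per_hour()` converts for display assuming a lifetime
of 1.5 h, the expected scale for a stable reporter transcript. The
stationary mean is $\mu\,k_{on}/(\delta(k_{on}+k_{off}))$ and the full
stationary distribution is obtained by `telegraph_pmf()`, which solves the
truncated chemical master equation as a banded linear system (see
*Numerical choices*).

Contact probability $p_c$ enters through a Hill response of the on rate,

$$k_{on}(p_c) = k_{on}^0 + (k_{on}^1 - k_{on}^0)
  \frac{p_c^h}{c^h + p_c^h},$$

with minimum and maximum on rates $k_{on}^0 \le k_{on}^1$, critical
threshold $c$ (in contact-probability units) and sensitivity exponent $h$.
This is the standard Hill form; the four parameters are named by what they
do (minimum/maximum rate, threshold, sensitivity), and we treat the exact
algebraic form as a modelling assumption of this package. $h > 1$ makes
the transcriptional response sigmoidal: the enhancer loses its grip on the
promoter over a narrow band of contact probabilities, which is what allows
a modest (about threefold) contact drop across a TAD boundary to insulate
almost completely.

Alternative variants in which $k_{off}$ or $\mu$, rather than $k_{on}$,
respond to contact are available through `apply_variant()` and
`variant_profile()`. They are distinguishable from burst-frequency
modulation by cell-to-cell variability: only on-rate modulation drives the
coefficient of variation (CV) down as contact probability rises, and the
Fano factor moves in opposite directions under on-rate versus
initiation-rate modulation.

```{r cv-variants, eval = FALSE}
p <- seq(0.05, 1, length.out = 6)
variant_profile(p, hill_params(0.15, 2, 0.25, 2.8),
                telegraph_params(0.5, 10, 360), "on_rate")
```

## The mechanistic model and its reduction

`mechanistic_params()` defines a continuous-time Markov chain in which the
enhancer toggles between far and close states (rates $k_{close}$,
$k_{far}$, giving steady-state contact probability
$k_{close}/(k_{close}+k_{far})$); while close, it drives $n$ reversible
regulatory steps forward at $k_{forward}$; steps revert at $k_{back}$ in
either contact state, one step at a time; the promoter's on rate is
$k_{on}^{enh}$ when all $n$ steps are complete and $k_{on}^{basal}$
otherwise, with $k_{off}$ and $\mu$ shared between regimes. The promoter
reads the current step count instantaneously (no memory). `mechanistic_pmf()`
solves the stationary law exactly; `gillespie_simulate()` runs exact
stochastic simulations that are bitwise reproducible given a seed.

When contacts are much faster than steps and both much faster than
bursting, the step layer averages into a birth-death chain with effective
forward rate $\beta p_c k_{back}$ ($\beta = k_{forward}/k_{back}$), whose
top-state occupancy is

$$\pi_n(r) = \frac{r^n (1 - r)}{1 - r^{n+1}}, \qquad r = \beta p_c$$

(and $1/(n+1)$ at $r = 1$), so the chain reduces to an *apparent* two-state
model with on rate

$$k_{on}^{app}(p_c) = k_{on}^{basal} +
  (k_{on}^{enh} - k_{on}^{basal})\,\pi_n(\beta p_c).$$

For $n \ge 2$ and $\beta > 1$ this response is sigmoidal. We derived
$\pi_n$ from the stationary occupancy of the uniform-bias birth-death
chain and validated it against the exact chain rather than taking it on
faith: `reduction_error()` rescales contact rates by $1/\varepsilon^2$ and
step rates by $1/\varepsilon$ (a single knob realizing the two-level
separation; promoter and mRNA rates are deliberately left unscaled) and
returns the total-variation distance between the exact stationary law and
the apparent two-state one. The distance falls monotonically along
$\varepsilon = 1, 1/2, 1/4, 1/8$ and is below 0.02 at $\varepsilon = 1/8$
when the unscaled chain already respects the mild ordering
contacts $\gtrsim$ steps $\gtrsim$ bursting; convergence is first order in
$\varepsilon$, so parameter sets far from that ordering need smaller
$\varepsilon$ to reach the same accuracy. In the separated regime the
stationary correlation between the contact indicator and promoter activity
(`contact_activity_correlation()`) is near zero: bursts do not coincide
with contacts even though contacts cause them.

## Fitting

`composite_loglik()` scores parameters against both data types at once:

* a Gaussian term for each line's observed mean expression, and
* a multinomial term for each smFISH histogram under the model's
  stationary pmf (up to the parameter-free multinomial coefficient).

The two components are equally weighted by their natural log-likelihoods;
a `weights` knob exposes the composition. For the mean term the error
model matters more than it looks. With three replicates per line, each
line's own sample standard deviation is an extremely noisy scale estimate,
and plugging it in (`mean_error = "per_line"`) makes the likelihood badly
overconfident -- lines whose three replicates happen to agree get enormous
weight, which both inflates the estimator's scatter and collapses its
confidence intervals. Fluorescence-derived expression noise is
scale-like, so the default (`mean_error = "lognormal"`) estimates one
relative replicate error $\widehat{cv}$ across all lines and treats each
observed mean as log-normal around the model mean with
$cv = \widehat{cv}/\sqrt{n_{rep}}$; `"pooled"` is the Gaussian
approximation of the same model with
$se_i = \widehat{cv}\cdot\mu_i(\theta)/\sqrt{n_{rep}}$. Both use the
*model* mean as the error scale, keeping the weights uncorrelated with
the realized noise (weights tied to observed means bias the fit). A floor
(`se_floor`) keeps noiseless synthetic data usable, where the pooled error
is not estimable and the machinery falls back to the per-line form.

`fit_phenomenological()` maximizes over
$(k_{on}^0, k_{on}^1, k_{off}, \mu, c, h)$ with $\delta$ fixed at 1;
`fit_apparent()` maximizes over
$(k_{on}^{basal}, k_{on}^{enh}, k_{off}, \mu, \beta)$ for each integer $n$
on a grid and keeps the per-$n$ profile. Optimization is multi-start
Nelder-Mead on box-logistic transformed parameters (rates bounded in
$[10^{-3}, 10^3]$, $c \in [0.01, 1]$, $h \in [0.5, 10]$, $\mu$ and $\beta$
in comparable boxes), with the maximum on rate parameterized as
$k_{on}^0 + \mathrm{gain}$ so the order constraint holds by construction.
Every fit includes one data-informed start (matching the largest and
smallest observed means) plus log-uniform random starts drawn under the
fit seed; all starts run a short optimization and the best few are
polished, with ties broken by start order. Across the $n$ grid the
previous best solution seeds a continuation start, which is why fewer
random starts are needed after the first grid point.

`profile_ci()` re-optimizes the remaining parameters along a profile of
the target parameter and inverts the likelihood-ratio threshold
$2(\ell_{max}-\ell_{prof}) \le \chi^2_{1,0.95} = 3.841$; for $n$ it
returns the set of integers within the threshold. The crossing is
interpolated on the root-deviance scale, which is close to linear in the
log-parameter for a locally quadratic log-likelihood (linear
interpolation of the deviance itself on a multiplicative grid
systematically narrows the interval). Open-ended and flat profiles are
reported with warnings rather than silently clipped.
`lrt_compare()` performs the nested likelihood-ratio comparison used for
the truncated-enhancer analysis (variants freeing only $\beta$, only
$k_{on}^{enh}$, or both, against an all-free reference), selecting the
smallest variant not rejected at the 5% level, and
`predict_weak_enhancer()` turns a fitted apparent model into the predicted
mean-versus-$p_c$ curve under either weakening hypothesis: scaling
$k_{on}^{enh}$ preserves the shape of the response and lowers its
amplitude, scaling $\beta$ shifts the sensitive region.

## Contact maps

`contact_matrix()` stores binned symmetric counts over one captured region
(6.4 kb bins by default; coordinates 0-based half-open internally, BED
written natively). `ice_balance()` applies iterative correction.
`expected_by_distance()` computes per-distance means and standard
deviations *within the captured region* (this package operates on a single
region by design). `counts_to_probability()` converts a viewpoint profile
to contact probabilities by dividing by the mean of the two anchor-adjacent
bins -- an operational convention ("short-range contacts are near-certain")
that is recorded in the object and pluggable, since absolute contact
probabilities are not identifiable from capture-C counts alone.
`filter_noise()` flags zero-interaction bins, per-distance interquartile
outliers (the IQR rule is applied within each distance stratum, matching
the distance-normalized context in which the maps are compared) and
"singletons", the top 0.1 percentile of Z-scores, where
$Z = (obs - exp)/stdev$ at the pair's genomic distance.
`differential_map()` forms the ratio of two distance-normalized,
noise-masked maps -- correcting genomic distances across an ectopic
insertion when one map contains it -- and applies bilinear mean smoothing
over a window of 2 bins (a 5x5 neighbourhood ignoring masked entries; a
3x3 alternative is available through `window = 1`).
`boundary_drop()` quantifies the fold change of a probability profile
across a TAD boundary from flank averages on either side.

## The synthetic generator

`study_config()` fixes the study conditions; `gen_full_study()` draws a
complete screen from independent, named substreams of one mandatory seed
(matrix, insertions, screen, FISH), so every component is reproducible and
the ground truth is always serialized next to the data. The defaults
emulate the screen this package is built around: a 560 kb TAD inside a
1.6 Mb region, 135 insertion lines of which 99% land inside the TAD
(uniformly -- the mild preference of transposition for nearby reinsertion
is not modelled), three replicate measurements with 10% multiplicative
log-normal noise, six smFISH lines of 300 cells spanning the contact
range, and a power-law contact decay (exponent 0.8) calibrated so
probability falls from ~1 next to the promoter to ~0.05 at the boundaries,
with a further threefold attenuation per boundary crossed.

The ground-truth rates ($k_{on}^0 = 0.15$, $k_{on}^1 = 2$, $k_{off} = 10$,
$\mu = 360$, $c = 0.25$, $h = 2.8$; apparent-model truth additionally
$\beta = 7$, $n = 5$) were chosen once so that mean expression spans
roughly 5 to 60 mRNAs per cell across the contact range and promoter
switching sits on the minutes scale for a 1.5 h mRNA lifetime, matching
the regime the screen reports.

Two deliberate simplifications matter when interpreting test results.
First, each line's true mean lies exactly on the model curve; real lines
scatter around it for biological reasons (local chromatin state), so
profile confidence intervals on synthetic data are much narrower than
intervals from a real screen, and recovery tests probe estimator
correctness, not real-data uncertainty. Second, the screen covariate uses
the true decay curve rather than the Poisson-sampled matrix profile, so
recovery tests are free of errors-in-variables attenuation; the sampled
route exists (`gen_contact_matrix()`) and is what the contact-map
round-trip tests consume.

## Numerical choices

* Stationary distributions are computed from the truncated master
  equation as a banded linear system solved by LAPACK's banded LU
  (`dgbsv`), with one balance equation replaced by fixing the probability
  of a reference recurrent state and renormalizing. The truncation bound
  starts at mean + 8 standard deviations (from the closed-form moments)
  and doubles until the geometric-tail estimate drops below `tail_mass`
  (default $10^{-6}$); non-convergence is an explicit error.
* Degenerate corners bypass the solver: $\mu = 0$ or $k_{on} = 0$ give a
  point mass at zero, $k_{off} = 0$ a truncated Poisson; in the
  mechanistic chain, $k_{forward} = 0$ or $k_{close} = 0$ reduce to the
  basal telegraph model and $k_{back} = 0$ to the enhanced one.
* The closed-form telegraph distribution (a Poisson mixture over a Beta
  on-fraction) is implemented as `beta_poisson_pmf()` by quantile-space
  quadrature, which stays finite where the confluent-hypergeometric form
  overflows; it serves as an independent cross-check of the solver, never
  as the primary path.
* $\pi_n(r)$ is evaluated in an overflow-safe form for $r > 1$ and by its
  limit $1/(n+1)$ near $r = 1$.
* Profile scans move multiplicatively (8% steps) outward from the MLE
  with warm-started re-optimizations and interpolate the deviance
  crossing on the log scale.

## Problem sizes used by the test suite

Unit tests run on small fixtures built in code (toy matrices, 20-60-line
screens, $10^5$-sample simulations). The end-to-end recovery studies use
the default study conditions (135 lines, six histograms of 300 cells)
over 20 seeds, with 12 starts per phenomenological fit and 8 starts
(3 after the first grid point) per apparent fit; the acceptance script
uses 32 starts, the package default. These sizes were chosen as the point
where recovery statistics stabilize; doubling them changes the recovered
medians by less than the reported tolerances.

## Known limitations

* Protein-level (fluorescence) distributions are treated only through a
  linear calibration to mRNA counts; no protein birth-death layer is
  modelled.
* The likelihood treats lines as independent and ignores uncertainty in
  the contact probabilities themselves.
* Confidence intervals are profile-likelihood intervals; bootstrap
  intervals are not implemented.
* Non-stationary (time-dependent) solutions are out of scope; everything
  is steady state.
* The contact-probability conversion is anchored to short-range contacts
  and is an assumption, clearly recorded in outputs, not an absolute
  calibration.
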
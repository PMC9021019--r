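# epcomm

Stochastic models linking enhancer–promoter contact probability to
transcriptional bursting.

## What this package is for

Enhancer mobilization screens relocate a single enhancer to hundreds of
positions around a fixed promoter inside a topologically associating domain
(TAD) and measure transcription in each resulting cell line. Contact
probabilities between promoter and enhancer decay steeply with genomic
distance (from ~1 nearby to ~0.05 at TAD boundaries, with a further ~3-fold
drop across them), yet mean expression falls only mildly inside the TAD and
collapses outside it — a strongly nonlinear transcriptional response.
`epcomm` provides the modelling and analysis layer for such screens, for
quantitative biologists who want to fit, check, and extend these models on
their own or simulated data.

At its core are three linked models of a promoter switching between OFF and
ON states (rates `k_on`, `k_off`), transcribing at rate `mu` while ON, with
mRNA degrading at rate `delta` (all rates per mRNA lifetime, `delta = 1`):

- **Phenomenological two-state model** — the burst frequency responds to
  contact probability through a Hill function
  `k_on(p_c) = k_on^0 + (k_on^1 − k_on^0) · p_c^h / (c^h + p_c^h)`,
  with threshold `c` and sensitivity `h`; `h > 1` means a sigmoidal,
  switch-like response.
- **Mechanistic model** — a continuous-time Markov chain in which stochastic
  enhancer contacts (rates `k_close`, `k_far`) drive `n` reversible
  regulatory steps (`k_forward` while in contact, `k_back` anywhere) that
  transiently raise the promoter's on rate from `k_on^basal` to `k_on^enh`.
- **Apparent two-state model** — the reduction of the mechanistic chain
  under timescale separation, with
  `k_on^app(p_c) = k_on^basal + (k_on^enh − k_on^basal) · π_n(β p_c)`,
  where `π_n(r) = r^n(1−r)/(1−r^{n+1})` is the completed-step occupancy of
  a biased birth–death chain and `β = k_forward/k_back`.

Around these sit: exact stationary solutions of the master equation (banded
linear solves), a seeded Gillespie simulator, simultaneous maximum-likelihood
fitting to per-line mean expression *and* smFISH count distributions with
profile-likelihood confidence intervals and likelihood-ratio model
comparison, capture-C matrix utilities (iterative correction, distance-decay
expectation, Z-score/IQR/singleton noise filtering, insertion-aware
differential maps, boundary-drop quantification), eGFP normalization and
smFISH calibration, and a synthetic-study generator that emulates the full
screen so the entire pipeline is testable offline.

## Worked example

Simulate a default screen (135 insertion lines in a 560 kb TAD, three
replicate measurements with 10% noise, six smFISH lines of 300 cells) and
refit the phenomenological model:

```r
library(epcomm)

cfg <- study_config(seed = 1)          # ground truth: h = 2.8, c = 0.25
bundle <- gen_full_study(cfg)
fit <- fit_phenomenological(bundle$screen, bundle$fish,
                            n_starts = 32, seed = 1)
fit
#> Simultaneous fit of the phenomenological two-state model
#>   log-likelihood: -5544.263
#>   parameters (rates per mRNA lifetime):
#>     kon0       0.138544
#>     kon1       1.94234
#>     k_off      8.38466
#>     mu         323.088
#>     c          0.256833
#>     h          2.71427

profile_ci(fit, "h")[c("lower", "upper")]
#> $lower
#> [1] 2.585154
#>
#> $upper
#> [1] 2.852241
```

The fitted Hill exponent (here 2.71, 95% CI 2.59–2.85) recovers the
generator's ground truth of 2.8: a sigmoidal burst-frequency response,
steep enough that the ~3-fold contact drop across a TAD boundary moves the
promoter from an activated to a near-basal regime. `kon0`/`kon1` are the
basal and saturating on rates (per mRNA lifetime), `c` the contact
probability of half-maximal activation, and `mu`/`k_off` set the burst size
(`mu/k_off ≈ 39` transcripts per burst here, truth 36).

The mechanistic route works the same way:

```r
cfg2 <- study_config(seed = 3, model = "apparent")  # truth: n = 5, beta = 7
b2 <- gen_full_study(cfg2)
fit2 <- fit_apparent(b2$screen, b2$fish, n_grid = 1:10, seed = 3)
fit2$par$n
#> [1] 5
profile_ci(fit2, "n")$set
#> [1] 5
```

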
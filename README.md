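# sptkinetics

Quantifying how a chromatin-interacting transcription factor explores and
binds the nucleus, from single-molecule tracking data.

Transcription factors such as SMAD4 alternate between brief chromatin-bound
episodes and fast free diffusion. Time-lapse single-molecule imaging of a
HaloTag fusion (20 Hz or 4 Hz, 800-frame movies) yields localization tables
from which this package estimates:

* **Population kinetics** — jump lengths `r` over lag `k` frames follow a
  two-state Rayleigh mixture
  `p(r|kΔt) = F·Ray(r; 2(D_bound·kΔt+σ²)) + (1−F)·Ray(r; 2(D_free·kΔt+σ²))`,
  fitted by least squares to per-lag histograms, giving the bound fraction
  `F_bound` and diffusion constants `D_bound`, `D_free`
  (µm²/s) with track-level bootstrap confidence intervals.
* **Per-track segmentation** — a two-state hidden Markov model with gamma
  emissions on squared displacements, trained by Baum–Welch and decoded by
  Viterbi, yields bound segments, their residence times and per-nucleus
  binding-event rates.
* **Residence-time survival analysis** — the survival function
  `1−CDF(t) = α·exp(−t/τ₁) + (1−α)·exp(−t/τ₂)` is estimated empirically,
  corrected for photobleaching by dividing by `exp(−k_b·t)` (with `k_b` fit
  from the decay of detected-molecule counts), integrated to an expected
  residence time, and decomposed into exponential components with
  BIC-based model selection and bootstrap intervals.
* **Transcriptome overlap statistics** — overlap, directional concordance,
  representation factor `RF = m/(n₁n₂/N)` with upper-tail hypergeometric
  p-value, and fold-change concordance regression for two
  differential-expression tables.

A synthetic-data generator (switching Brownian motion with localization
error, photobleaching and defocalization; double-exponential dwell
sampling; bleach-count profiles; DEG-table pairs) provides ground truth for
every stage, so the whole pipeline is testable without raw microscopy data.

## Worked example

```r
library(sptkinetics)

# --- population kinetics on simulated ground truth ------------------------
p <- sim_params(n_molecules = 500, n_frames = 800, frame_interval = 0.05,
                D_bound = 0.0018, D_free = 0.5, loc_error_sigma = 0.02,
                bleach_mean = 5, seed = 11)
sim    <- simulate_switching_tracks(p)
tracks <- sim_tracks(sim)
jumps  <- compute_jump_lengths(tracks, frame_interval = 0.05, max_lag = 2)
fit_two_state_jump_model(jumps, jump_fit_config(fix_sigma = 0.02))
#> Two-state diffusion kinetics fit
#>   D_bound = 0.001677 um^2/s, D_free = 0.4915 um^2/s
#>   F_bound = 0.498, sigma = 0.02 um (fixed)
#>   objective 5.816e-05 over 46435+45938 jumps; converged: TRUE
```

The simulation used `D_bound = 0.0018` µm²/s, `D_free = 0.5` µm²/s and a
bound fraction of 0.5; the fit recovers all three from ~92,000 pooled jumps
(the slow state is chromatin-bound — its diffusion constant is on the order
of histone H2B's).

```r
# --- residence times with photobleaching correction -----------------------
rs        <- simulate_residence_events(0.75, 3, 8, 3000, bleach_mean = 20,
                                       frame_interval = 0.25, seed = 12)
curve     <- empirical_ccdf(rs, include_censored = TRUE)
corrected <- correct_ccdf(curve, k_b = 1/20)
expected_residence_time(corrected)
#> expected residence time: 4.38 s
fit_multi_exponential(corrected, n_components = 1:3)
#> 2-component exponential survival fit
#>   alpha_1 = 0.771, tau_1 = 3.07 s
#>   alpha_2 = 0.229, tau_2 = 8.8 s
#>   SSE 0.0006512, BIC 21717.81, expected residence 4.38 s
#>   (selected by BIC among 1, 2, 3 components)
```

Dwell times were drawn from a 0.75/0.25 mixture of 3 s and 8 s exponentials
and censored by a 20 s bleaching lifetime; after correction, model
selection picks two components and recovers both time constants, and the
expected residence time matches the mixture mean 0.75·3 + 0.25·8 = 4.25 s
within sampling error.

```r
# --- gene-set overlap ------------------------------------------------------
tabs <- simulate_deg_tables(10000, 1127, 900, concordance_prob = 0.95,
                            n_overlap = 510, seed = 5)
analyze_overlap(tabs$a, tabs$b, universe_size = 10000)
#> Gene-set overlap
#>   universe N = 10000; set sizes 1127 and 900; overlap m = 510
#>   concordant 485/510 (95%); up-up 247, down-down 238
#>   representation factor 5.03; upper-tail hypergeometric P = 3.54e-284
#> Fold-change regression (n = 510): y = 0.550 x + 0.075, R^2 = 0.309
```

## Package layout

* `R/synthetic.R` — ground-truth generators (`simulate_switching_tracks()`,
  `simulate_residence_events()`, `simulate_bleach_counts()`,
  `simulate_deg_tables()`)
* `R/tracking.R` — linking, nucleus masking, defocus filtering, track
  durations
* `R/jump_kinetics.R` — jump-length pooling, two-state fit, track bootstrap
* `R/hmm.R` — gamma-emission HMM, Viterbi decoding, bound segments, event
  rates
* `R/survival.R` — survival curves, bleach correction, integration,
  multi-exponential fits, residence bootstrap
* `R/overlap.R` — DEG-table overlap statistics
* `vignettes/residence-kinetics.Rmd` — the methods notes: model
  assumptions, parameter meanings, numerical choices, limitations
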
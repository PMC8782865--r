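---
title: "Synchronous amplitude network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronous amplitude network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sana)
```

## The measurement model

EEG recorded at the scalp superimposes oscillatory activity in six
physiologically standard frequency bands — delta (0.5–3.5 Hz), theta
(4–7.5 Hz), alpha (8–11.5 Hz), sigma (12–15.5 Hz), beta (16–19.5 Hz) and
gamma (20–24.5 Hz). At the scale of minutes, the band composition during a
physiological state (quiet rest, exercise, a cognitive task) is
quasi-steady; at the scale of seconds, the bands' amplitudes ripple, and
those ripples co-vary across bands. This package quantifies that
co-variation — amplitude–amplitude coupling — and summarizes it as a pair
of weighted networks over the six rhythms per state.

The chain is:

1. **Preprocessing.** A zero-phase high-pass at 0.1 Hz removes drift; an
   optional surface Laplacian re-references each channel to the mean of its
   neighbors, suppressing volume-conducted common-mode activity.
2. **Spectral decomposition.** Per channel, 2 s FFT windows advanced by 1 s
   (rectangular taper, 0.5 Hz bin resolution) give the band power
   $S(\Delta f_i)$ at one sample per second; band edges are inclusive and
   the gaps between bands (e.g. 3.5–4 Hz) belong to no band.
3. **Normalization.** Relative power
   $\tilde S(\Delta f_i) = S(\Delta f_i) / \sum_j S(\Delta f_j)$ places each
   sample on the 6-simplex. This step is essential: global power trends
   move all bands together and would otherwise masquerade as positive
   coupling everywhere (the `absolute_power_control()` surrogate
   demonstrates exactly this failure mode).
4. **Smoothing.** A centered 14 s moving average with edge shrinkage; the
   output length equals the input length, and by linearity columns still
   sum to 1.
5. **Windowed correlation.** Each annotated session is cut into
   non-overlapping $L = 30$ s segments (trailing partials dropped,
   $N_L = \lfloor N/L \rfloor$). Within a segment each band is z-scored
   with the *population* (divisor-$L$) standard deviation and
   $C_{ij} = \frac{1}{L}\sum_t s_t(\Delta f_i)\, s_t(\Delta f_j)$, which
   equals the Pearson correlation and reaches exactly $\pm 1$ at perfect
   (anti-)correlation — the reason for the divisor-$L$ convention.
6. **Profiles and degree of coupling.** Per pair and state, the pooled
   $\{C_{ij}\}$ are histogrammed into 40 bins of width $\Delta c = 0.05$
   (left-closed, right-open, last bin closed so $C = 1$ is kept), rescaled
   by the peak count and smoothed with a centered 5-bin moving average.
   The degree of coupling is $D^+_{ij} = P(C_{ij} > C_0)$ and
   $D^-_{ij} = P(C_{ij} < -C_0)$ with $C_0 = 0.5$ and strict inequalities,
   computed from the raw values; the area-under-profile variant is retained
   as a cross-check (`degree_of_coupling_area()`) because smoothing across
   the $\pm 0.5$ edges slightly biases the area estimate.
7. **Networks and classes.** $D^+$ and $D^-$ are the edge weights of two
   six-node networks per state. Zero-weight edges are retained so that
   state comparisons operate on a fixed 15-edge support. With two or more
   states, each pair is classified `anti` (strict $D^- > D^+$ in every
   state), `positive` (strict $D^+ > D^-$ in every state) or `mixed`
   (including exact ties).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `corr_window_s` (L) | 30 | s | correlation window; set by the quasi-periodicity of the band-power ripples (a few waves per 100 s) |
| `threshold` (C0) | 0.5 | — | significance threshold, calibrated by the shuffle surrogate (~99% of null \|C\| fall below it; the profile decays to zero near ±0.5) |
| `hist_bin` | 0.05 | — | 40 histogram bins over [−1, 1] |
| `hist_smooth_bins` | 5 | bins | profile smoothing |
| `smooth_window_s` | 14 | s | band-power moving average; must not exceed L/2 or it leaks information across window boundaries (guarded in `timescale_sweep()`) |
| `fft_window_s` / `fft_step_s` | 2 / 1 | s | 0.5 Hz resolution, 1 sample/s output |

The FFT taper is rectangular by default so that on-bin test tones behave
exactly; a Hann taper is available (`taper = "hann"`). The 14 s average is
centered with edge shrinkage, which preserves series length — a 30 min
session at 1 sample/s keeps 1800 samples and yields exactly 60 windows.
Both choices (taper, centered-vs-trailing average) are configurable
defaults rather than claims about any particular acquisition pipeline.

## The synthetic coupled-rhythm generator

No public EEG with the required annotations exists, so the package ships a
generator (`generator_spec()`, `make_protocol_recording()`) whose output
exercises every stage:

- **Latent modulators.** Per state, six i.i.d. standard-normal series are
  mixed by a symmetric square root of the state's target correlation
  matrix and each is smoothed with the *same* zero-phase truncated-Gaussian
  kernel (width `envelope_timescale_s`, default 10 s, standard deviation
  half the width). Same-kernel smoothing of jointly white inputs preserves
  the zero-lag correlation exactly in expectation, so the smoothed
  modulators carry the target structure while acquiring a realistic
  envelope autocorrelation time. The empirical envelope timescale of real
  band power is not known from published values; 10 s gives two to five
  slow waves per 100 s segment, which is what scalp band-power traces
  show, and it is deliberately not adjusted per analysis.
- **Softmax map.** Relative weights are
  $w_i(t) = b_i e^{d\,m_i(t)} / \sum_j b_j e^{d\,m_j(t)}$ with baseline
  $b = (0.30, 0.18, 0.22, 0.12, 0.10, 0.08)$ (a realistic resting scalp
  composition dominated by delta/alpha) and depth $d = 1$. The map keeps
  every sample strictly inside the simplex and is monotone in each
  modulator, but it distorts correlation magnitudes; the generator's
  guarantees are therefore about *signs and ordering* of the induced
  coupling, not exact correlation recovery. A side effect of simplex
  closure is that even an identity latent target yields weakly coupled
  weights (when the heavy delta weight dips, the others co-rise), which is
  physiologically sensible and worth remembering when interpreting "null"
  settings.
- **EEG synthesis.** Per channel,
  $x(t) = \sum_i \sqrt{w_i(t)}\, x_i(t) + \varepsilon(t)$, where each
  carrier $x_i$ is unit-power white noise band-limited to band $i$ with a
  zero-phase FFT filter and $\varepsilon$ is white with power
  `noise_floor` (default 0.1) times the signal power. Carriers are
  independent across bands and channels: the method measures
  amplitude–amplitude coupling only, so carrier phases are irrelevant by
  design, and no phase–phase or phase–amplitude structure is simulated.
  The default synthesis rate is 250 Hz — comfortably above the 49 Hz
  Nyquist bound of the gamma band and fast enough that full protocols
  simulate in seconds.

**Presets.** `sana_preset("exercise_like")` is the five-state protocol
template (rest 900 s, warm-up 600 s, exercise 1800 s, cool-down 600 s,
cognitive task 360 s) carrying the three coupling classes: delta
anti-correlated with every other rhythm and sigma/beta/gamma mutually
positive in every state, strongest during exercise (pattern entries
−0.7/+0.7 scaled by 0.5/0.7/1.0/0.7/0.6 across the five states), with the
seven theta/alpha mixed pairs switching sign — mildly negative at rest and
during the cognitive task, positive during the active states. The strong
exercise pattern written literally is not positive semi-definite (its
minimum eigenvalue is about −0.3 with exact-zero mixed pairs), so
`target_correlation()` projects the sign pattern to the nearest
correlation matrix (alternating projections); the projection preserves
every sign and the ordering of magnitudes, which is what the analysis
measures.

**What the generator does not emulate.** Event-related transients,
eye-blink/EMG artifacts, line noise, non-Gaussian burstiness, cross-channel
carrier correlation, and any phase coupling. Tests passing on synthetic
data therefore validate the *pipeline's statistical machinery* — sign and
ordering recovery, null calibration, surrogate behavior — not the
physiological claims one could make from recorded EEG.

## Numerical choices and degenerate inputs

- Zero-total-power samples become NaN, are flagged and counted, and any
  window touching a flagged sample has that band's correlations
  invalidated in that window only — never silently zero-filled.
- A zero-variance band inside a window invalidates its row/column of that
  window's correlation matrix.
- `p(±1) = 0` by convention in the correlation p-value (the t-statistic
  diverges).
- High-pass filtering and carrier band-limiting use zero-phase FFT
  (frequency-domain) filters. At 0.1 Hz on a 250–1000 Hz recording the
  normalized cutoff is ~10⁻⁴, where IIR designs are numerically fragile;
  the FFT filter is exactly zero-phase and stable, at the cost of assuming
  an approximately stationary segment (true for the session-length signals
  analyzed here).
- The Wilcoxon profile-collapse test uses the zero-inclusive (Pratt)
  convention with a normal approximation, continuity correction and tie
  adjustment: profile bins frequently tie exactly, the paired vectors have
  a fixed length of 40 (where the normal approximation is accurate), and
  an all-zero difference vector passes with p = 1 by stated policy.
- EDF export quantizes to 16 bits over the per-channel range (the format's
  precision); the CSV writers are lossless to double precision.

## Problem sizes used by the tests

The shipped checks run at desk scale, chosen once: correlation-preservation
checks at T = 10⁴ envelope samples with a tolerance of three sampling
standard deviations computed from the kernel's decorrelation time; the
shuffle null pooled over ≥ 2000 windows; class recovery on the
exercise-like preset pooled over 19 synthetic subjects × 2 tests
(replicated over 20 seeds), which reproduces the canonical 2280 exercise
windows per pair; and the random-pairing surrogate over 19 subjects run
through the full EEG + spectral path with 76 pooled realizations — the
doubly-smoothed envelopes leave roughly two effective degrees of freedom
per 30 s window, so the gap $|D^+ - D^-|$ needs that many realizations for
its Monte-Carlo error to sit well inside the 0.05 acceptance band. The
20-seed replicate loops use the generator's envelope-level output (band
weights directly, skipping EEG synthesis), which exercises every analysis
stage downstream of spectral estimation; the EEG + spectral path is
validated end-to-end by the conservation, phase-randomization and
random-pairing checks and by round-trip unit tests.

## Known limitations

- Coupling is zero-lag Pearson within windows: lagged interactions,
  nonlinear dependence, and phase-based coupling are out of scope.
- The degree-of-coupling estimates are probabilities of threshold
  exceedance; with heavily smoothed series the window correlations are
  broadly distributed, so single-subject, single-session D± estimates are
  noisy and group pooling (as in the shipped tests) is recommended.
- The classifier's strict-dominance rule is deliberately conservative:
  near-null pairs will be labeled `mixed` (or drift between `mixed` and a
  signed class under resampling); only clearly stratified pairs earn
  `anti`/`positive`.
- The EDF reader handles plain 16-bit EDF with equal record durations; it
  is not an EDF+ implementation (annotations travel in the sidecar CSV).
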
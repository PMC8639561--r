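---
title: "Computing image structure functions: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing image structure functions: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ddmsf)
```

## The observable

Differential dynamic microscopy (DDM) and dynamic shadowgraphy analyze a
time series of `N` grayscale frames `I_n(x, y)` recorded at a fixed interval
`Δt`. The quantity of interest is the image structure function

$$
d(q, m\Delta t) \;=\; \frac{1}{N-m}\sum_{n=m}^{N-1}
  \bigl|\,F_{xy}\!\left(I_{n-m}-I_n\right)(q)\,\bigr|^2 ,
$$

the spatial power spectrum of frame differences averaged over every pair at
lag `m`. Because it is built from differences, any contribution that is
static or drifts slowly compared to the lag — illumination profile, dirt on
optics, sensor fixed-pattern noise — is subtracted before it can bias the
estimate. For an ergodic sample the structure function relates to the
intermediate scattering function (ISF) `f(q, t)` as
`d(q,t) = A(q)·(1 − f(q,t)) + B(q)`, so its time dependence at each wave
vector carries the sample's relaxation dynamics.

Intensities are used exactly as loaded: no mean-image subtraction, no
windowing, no rescaling. Background rejection is the differencing's job, and
any preprocessing would change the meaning of `A(q)` and `B(q)`.

## Three routes to the same matrix

**Pairwise (`naive`).** Difference the frames, transform each difference,
average. One 2D FFT per retained frame pair: `Σ_m (N−m)` transforms, which
is O(N²) when all lags are wanted. This engine exists as the readable,
literal reference; everything else in the package must agree with it.

**Cached spectra (`direct`).** The FFT is linear, so
`F_xy(I_{n-m} − I_n) = Ĩ_{n-m} − Ĩ_n` with `Ĩ_n = F_xy I_n` computed once
per frame. N spatial transforms, then one elementwise pass over spectrum
pairs per lag — still `Σ_m (N−m)` passes of O(H·W) work.

**Wiener–Khinchin (`wk`).** Expanding the squared modulus,

$$
d(m) = \frac{1}{N-m}\Bigl[\;\underbrace{\textstyle\sum_{k=0}^{N-1-m}p(k)}_{\text{forward cumsum}}
 + \underbrace{\textstyle\sum_{n=m}^{N-1}p(n)}_{\text{backward cumsum}}
 - 2\,\mathrm{Re}\,C(m)\Bigr],
\qquad p(n) = |\tilde I_n|^2 ,
$$

where `C(m) = Σ_n Ĩ*_{n−m} Ĩ_n` is the linear lagged autocorrelation of each
wave vector's complex time series. The two partial sums are cumulative sums,
O(N) per wave vector. The cross term is the expensive one — O(N²) if done
directly — but for a stationary series the Wiener–Khinchin theorem lets it
be read off the temporal power spectrum: FFT the series, square, inverse
FFT. That makes the whole assembly O(N log N) per wave vector, and the cost
is independent of how many lags are requested (the engine therefore defaults
to returning all of them).

### Zero padding is not optional

The FFT route computes a *circular* correlation. The definition above is a
*linear* (finite, one-sided) sum: lag m must only pair frame `n−m` with
frame `n`, never wrap around the end of the acquisition. Padding each series
with zeros to the smallest power of two `P ≥ 2N` before the temporal
transform makes the circular and linear correlations identical on lags
`0..N−1`, exactly. Without padding, the expansion would not reproduce the
pairwise definition, and the discrepancy would be largest at the large lags
where pair counts are smallest. The identity is enforced in the tests
against a direct O(N²) double-sum oracle at 1e−12 relative tolerance.

### Conventions

* **FFT normalization**: unnormalized forward transforms (no `1/(HW)`), so
  the DC entry of a spectrum is the frame's pixel sum and Parseval reads
  `Σ_fullplane |Ĩ|² = H·W·Σ I²`. Every engine shares the convention, so
  `d` values are comparable across engines; with it, the white-noise plateau
  has the closed form `2·H·W·σ²` used in validation.
* **Half-plane storage**: real input makes `Ĩ(−q) = Ĩ*(q)`, so only columns
  `k_x = 0..W/2` are kept — half the memory, twice the frames per memory
  group. A multiplicity array (2 for interior columns, 1 for the
  self-conjugate `k_x = 0` and Nyquist columns) makes every half-plane
  average equal its full-plane counterpart exactly.
* **Even dimensions only**: odd frame sizes are rejected rather than
  guessing how to fold a split Nyquist frequency.
* **`d(0)` is returned as exact zero**: the lag-0 difference is identically
  zero; the WK engine short-circuits the assembly rather than reporting the
  ~1e−16 round-off of the cancellation.
* **Precision**: all computation is in double precision. Accumulating up to
  10⁴ squared 16-bit values leaves no appetite for single-precision sums;
  `plan_memory()` still accepts `precision = "single"` because the paper-level
  memory accounting (8 vs 16 bytes per complex value) is the one place the
  choice matters to planning.

## Memory-budgeted chunking

Caching N complex spectra of H×(W/2+1) values can exceed RAM. The planner
assigns each wave vector a cost of `(N + P)` complex values (its cached
series plus temporal-FFT workspace) and splits the flattened half-plane index
range into `G = ceil(n_q / floor(budget/cost))` contiguous, balanced groups —
the minimal feasible contiguous partition. The executor then recomputes the
N spatial FFTs for every group, keeping only that group's columns: spatial
transforms are cheap relative to spilling spectra to disk, and the recompute
count (`G·N`) is exposed in the result's `work` counters. Group boundaries
cannot affect values — each wave vector's time series is processed
independently — and the tests pin this at 1e−12 relative across
`G ∈ {1, 2, 4, 7}`.

## Azimuthal averaging

Isotropic samples only depend on `|q|`, so the 2D maps are collapsed onto
rings: ring index `r = round(|q|/Δq)` with `Δq = 2π/(max(H,W)·pixel_size)`
(round half to even; the binning rule is ours to choose since nothing about
it is canonical). Members contribute with their Hermitian multiplicity; the
DC pixel is always excluded; empty rings are dropped. `ring_counts` reports
full-plane member counts and doubles as the mode count used later as fit
weights.

## Fitting decay times and the diffusion coefficient

For simple diffusion the ISF is a single exponential, so each ring is fitted
with `d(q,t) = A(q)·(1 − e^{−t/τ(q)}) + B(q)` over lags `m ≥ 1`
(Levenberg–Marquardt, bounds `A ≥ 0`, `τ > 0`; starting values from the
curve's range and its first crossing of `B₀ + (1−e⁻¹)A₀`). Two choices
matter more than the optimizer:

* **Log-spaced lag sampling** (default, `max_lags = 64`). With all N lags on
  a uniform grid, nearly every point sits on the saturated plateau and the
  fit's χ² is dominated by plateau-level statistical noise — the slowest,
  most correlated part of the estimate — while the handful of rising points
  that actually determine τ carry almost no weight. Sampling lags
  log-uniformly balances the weight per decade of lag time, the standard
  practice for relaxation curves spanning decades.
* **Identifiability flagging.** A fitted τ outside a tenth-to-tenfold window
  of the sampled times means the data show only a line or only a plateau;
  such rings (and outright optimizer failures, and zero-range curves) are
  flagged `converged = FALSE` and retained in the table. Downstream fits
  filter on the flag; nothing is silently dropped.

`fit_diffusion()` then pools the converged rings inside a user-chosen band
`[q_min, q_max]` through the Brownian relation `τ(q) = 1/(D·q²)`, as an
unweighted least-squares fit of `1/τ` against `q²` through the origin —
linear in D, closed form, no iterative solver. The band is the user's
physical judgment: at low q the decay outlives the acquisition (and, in
shadowgraph experiments on Earth, gravity bends the dispersion relation); at
high q the signal amplitude sinks into the noise floor. As a diagnostic the
log–log slope of τ(q) over the same band is reported, with inverse-variance
weights `n_modes · t_max/τ`: the variance of a log decay time falls with the
number of independent Fourier modes in the ring and with the number of
decorrelation times the acquisition spans, and an unweighted slope would let
the noisiest low-q rings dominate. D itself deliberately stays unweighted —
the `q⁴` leverage of the through-origin regression already concentrates it
on the best-measured rings.

The printed form `1/(D·q⁻²)` that sometimes appears for this dispersion
relation is dimensionally inconsistent for a decay time; the package uses
the standard `τ = 1/(D·q²)` throughout.

## The synthetic generator: what it does and does not emulate

`generate_brownian_series()` provides ground truth: point particles doing
ideal 2D Brownian motion (per-axis step variance `2·D·Δt`, periodic
wrapping) rendered as Gaussian blobs of width `blob_sigma` on a constant
background with i.i.d. Gaussian camera noise. Because the blob is a
band-limited, shift-invariant kernel, the model ISF is exactly
`exp(−D·q²·t)` wherever the blobs carry signal (roughly `q ≲ 1/blob_sigma`
in pixel units), with a flat noise baseline `2·H·W·σ_noise²` — every
downstream stage has an analytic target. The unwrapped latent trajectories
ride along as an attribute so displacement-level checks (MSD = `4·D·Δt·m`)
never have to re-infer positions from images. Randomness comes from R's
default Mersenne-Twister generator seeded once with the mandatory `seed`;
series are bit-reproducible.

Defaults — 1024 frames of 128×128 px at 25 Hz (`Δt = 0.04` s), 1 µm pixels,
200 particles, `D = 0.5` µm²/s, 2 px blobs, peak 1000 counts on a
100-count background with 5 counts of noise — describe a desk-scale colloid
movie whose decay times sweep from tens of seconds down through the frame
interval across the usable q band.

What the generator does *not* emulate, and what passing tests therefore do
not show: optical transfer functions (the strong `A(q)` oscillations of
shadowgraphy), gravity's effect on low-q decay times, hydrodynamic
interactions, polydispersity, photon/shot noise correlated with signal,
camera nonlinearity, and drift. On real data those effects shape `A(q)`,
`B(q)` and the usable band — the fitting surface exposes `q_min`/`q_max`
precisely so the analyst can exclude what the model does not describe.

`generate_noise_series()` is the degenerate counterpart — pure i.i.d.
Gaussian frames — whose exactly flat expected structure function pins the
engines' normalization.

## Validation scales

The test suite and acceptance script size their problems to run in minutes
on one CPU: engine-equivalence checks on five 64-frame 32×32 series
(values spanning the 16-bit range), chunk invariance at `G ∈ {1,2,4,7}`,
lag-correlation identity on 100 random complex series up to length 64, the
noise plateau at 512 frames of 64×64 (`σ = 10`), and the full Brownian chain
at the generator defaults above with the diffusive fit taken over rings
10–28 (decay times under a fifth of the acquisition, amplitudes well above
the noise plateau). Typical results: recovered D within a few percent of
truth, τ(q) slope within ±0.1 of −2, engine agreement at ~1e−12 relative.

## Known limitations

* Square pixels and even frame dimensions are assumed; anisotropic
  (sector-resolved) averaging is not implemented.
* The ISF model is a single exponential; stretched/double exponentials and
  ballistic models would need a different `fit_isf`.
* The chunked executor recomputes spatial FFTs rather than spilling spectra
  to disk; for extreme frame sizes a disk-backed cache could win.
* Timing is logged for provenance but never asserted: wall-clock speedups
  are hardware statements, and the package instead pins the *work counts*
  (2 temporal FFTs per wave vector per group; elementwise passes growing as
  `Σ(N−m)` for the cached-spectra engine) that make the complexity claim
  testable anywhere.
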
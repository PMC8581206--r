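---
title: "Estimating and subtracting power-line interference: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and subtracting power-line interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegpla)
```

## The problem and the model

EEG recorded outside a shielded lab almost always carries mains interference:
a near-sinusoidal component at the power-line frequency (50 Hz in most of the
world, 60 Hz elsewhere), often far stronger than the cortical signal. We model
the recording as

$$x[n] = eeg[n] + A\cos(2\pi f\, n/f_s + \varphi), \qquad n = 0,\dots,N-1,$$

and treat removal as a parameter-estimation problem: find $(A, f, \varphi)$,
rebuild the sinusoid, subtract it. Subtraction is attractive because it is
*exactly* linear and memoryless — whatever error it makes is confined to a
single spectral line, and it has no start-up transient. A causal notch filter,
the standard alternative, distorts the early samples of every record it
touches; `notch_filter_baseline()` exists precisely to make that comparison
measurable.

## Why two estimation rounds

With a finite record, an off-grid tone leaks across the FFT bins
(rectangular-window Dirichlet kernel). The two bins bracketing the tone — the
baseline spectral lines, `Δf = f_s/N` apart — retain most of the energy, and
their amplitude ratio fixes the tone's sub-bin position:

$$\Delta k = \frac{y_r}{y_l + y_r}, \quad
  \hat A = y_l\,\frac{\pi\Delta k}{\sin \pi\Delta k}, \quad
  \hat f = f_l + \Delta k\,\Delta f, \quad
  \hat\varphi = \arg(Y_l) - \pi\Delta k.$$

These identities are exact for the positive-frequency part of the kernel in
the large-$N$ (sinc) limit. Their weakness is statistical, not analytic: when
$\Delta k$ is near 0 (or 1) one of the two lines carries almost no amplitude,
so any noise in that line translates into a large error in the ratio. The
dual-step scheme fixes the geometry instead of the estimator: after a first
ratio pass gives $f^{(1)}$, it evaluates two *off-grid* lines at
$f^{(1)} \pm \Delta f/2$ by direct single-frequency DTFT sums
(`evaluate_dtft_line()`), where both amplitudes are about $0.64\,A$, and runs
the identical ratio correction on that pair. Amplitude is kept from round 1,
frequency and phase from round 2, and nothing iterates. At 0 dB SNR and
$\Delta k = 0.05$ this cuts the frequency RMSE by roughly 5x
(`run_monte_carlo()`); at $\Delta k = 0.5$ the two estimators coincide to
within sampling error, as they must — round 2's geometry is then the same as
round 1's.

## Parameters that matter

* `sample_rate`, `n` — fix the bin spacing `Δf = f_s/N`, the unit in which
  all sub-bin arithmetic happens. The reference simulation uses
  `f_s = N = 1000` (`Δf = 1` Hz); the EEG-like case uses `f_s = 200`,
  `N = 1000` (`Δf = 0.2` Hz).
* `search_band` — Hz interval for the round-1 peak hunt. For mains cleaning
  use `c(45, 65)`: line frequency drifts by a couple of Hz in real grids, and
  the band keeps the peak search off high-amplitude low-frequency EEG
  rhythms. `NULL` searches the full spectrum (right for generic tones).
* `phase_slope` — the phase correction subtracts `πΔk`; the exact
  rectangular-window slope is `πΔk(N−1)/N`. `"nominal"` (default) matches the
  classical formula; `"exact"` applies the `(N−1)/N` factor. The difference,
  `O(πΔk/N)`, is ~1.6e-4 rad at the reference geometry — documented rather
  than important.
* notch baseline: second-order constrained IIR notch, default `q = 30`
  (−3 dB width `f0/30 ≈ 1.7` Hz at 50 Hz), applied causally because its
  transient *is* the phenomenon being compared against.

## What the synthetic world does and does not emulate

`synth_eeg_surrogate()` passes white Gaussian noise forward–backward through
second-order Butterworth high- and low-pass sections at `[0.5, 70]` Hz (the
acquisition band of the clinical records the case emulates) and scales to a
requested RMS. That reproduces exactly one property of EEG: its band support.
It deliberately does not model the 1/f spectral decay, rhythms, or
nonstationarity of cortical signals. Where the full-scale case study needs an
amplitude, we scale the surrogate so the composite SNR against the `A = 50`
tone is 3.43 dB, the figure reported for the clinical record.

The flat in-band spectrum has a consequence worth stating plainly: the
surrogate carries as much power at 50 Hz as anywhere else in band — several
signal units RMS inside the two estimation bins. A green cleaning test on this
world therefore establishes that subtraction beats the causal notch
(it does, 17 of 20 seeds, sign-test p ≈ 1e-3), **not** that cleaning reaches
the near-perfect correlations seen on real EEG, whose 1/f spectrum leaves
little power near 50 Hz. Two measured facts on this world, fixed seeds 1:20:

* even an exact least-squares sinusoid fit at the *true* frequency leaves
  correlations of 0.9988–0.9996 with the clean surrogate, so no single-tone
  subtraction can promise ≥ 0.999 here; and
* on a minority of seeds (~15%) the surrogate's 50 Hz content makes the wrong
  neighbour of the peak bin the larger one; round 2 still recovers the
  frequency, but the classical phase formula reads `arg(Y_l)` from what is
  then a noise-dominated line, and the compensation phase can be badly wrong.
  This is a real failure mode of the published estimator at low local SNR,
  surfaced honestly by the tests rather than patched, since re-referencing
  the phase to the stronger line would change the method.

## Numerical choices

* **Spectrum convention.** Negative-exponent forward FFT; single-sided
  amplitude scaling `2/N` (DC and Nyquist `1/N`), so an on-grid tone of
  amplitude `A` reads `A` at its bin. With this convention
  `arg(Y_l) = φ + πΔk(N−1)/N`, which is why the phase correction subtracts.
* **Ratio orientation.** `Δk = y_r/(y_l + y_r)`, the tone's offset above the
  left line; it reproduces the canonical worked value `Δk = 0.05` from
  `y_l = 0.996`, `y_r = 0.052`.
* **Removable singularity.** `πΔk/sin(πΔk)` is evaluated as 1 for
  `Δk < 1e-12`.
* **Tie-break.** If the two neighbours of the peak bin agree to `1e-12`
  relative, the pair is `(k, k+1)`; the tone is then on-grid and either
  choice estimates `f = f_k`, but a fixed rule keeps results deterministic.
* **Off-grid lines by direct summation**, not zero-padding: exact at any
  frequency, `O(N)` per line, and only two lines are ever needed.
* **Accuracy floor.** Only the positive-frequency kernel is modelled; the
  negative-frequency image perturbs the line amplitudes by roughly
  `A/(π · 2f/Δf)` at worst-case phase. At the low edge of a 100–400 Hz test
  band this caps noise-free frequency accuracy near `1.3e-3` bins — the
  package's tests bound it at `2e-3 · Δf`. Amplitude (1%) and phase
  (0.02 rad) tolerances hold with margin.
* **Floating-point invertibility.** `cleaned + compensation` returns the
  input to within one ulp (not bit-for-bit: subtract-then-add is not exactly
  associative).
* **Seeding.** Every stochastic operation takes an explicit integer seed and
  runs under `withr::with_seed()`, leaving global RNG state untouched. The
  Monte-Carlo derives one seed per grid cell as
  `(master * 100003 + i_snr * 9973 + i_dk * 104729) mod 2147483629`, so cells
  are order-independent and the whole table reproduces from one integer.
* **Failure accounting.** Benchmark trials in which an estimator errors are
  excluded from the moments, counted in `n_failed`, and flag the cell above
  1% — at very low SNR peak mislocation must be visible, not averaged in.

## Design choices where the design was open

* Signals are tibbles (`time`, `value`) with the rate in an attribute *and*
  recoverable from the time column, so dplyr pipelines that strip attributes
  degrade gracefully. Spectra, line pairs, benchmark tables are likewise
  plain tibbles; fitted objects carry `tidy()`/`glance()` methods.
* The surrogate's RMS is a free parameter (no amplitude scale is published
  for the emulated records); tests and examples set it through the stated
  composite SNR rather than an absolute voltage.
* EDF support is read-only, pure R (16-bit records, header calibration), and
  nothing else depends on it; a text channel format (`# fs_hz=...` header,
  one sample per line) is the primary interchange.
* The CLI is a thin layer over exported functions and returns a status code
  instead of calling `quit()`, so it is testable in-process.

## Known limitations

Single tone per call — mains harmonics (100, 150 Hz…) must be removed by
repeated calls. Rectangular window only. No tracking of line-frequency drift
within a record: the model assumes `(A, f, φ)` constant over the `N` samples.
Phase and amplitude both degrade when the record is so noisy that the
round-1 pair misbrackets the tone (see above); widening `search_band` does
not help with that, only longer records or averaging do.
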
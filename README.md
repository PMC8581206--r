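# eegpla

Power-line artifact (PLA) estimation and removal for single-channel EEG.

Mains interference at 50/60 Hz is close to a pure sinusoid,
`pla(t) = A cos(2π f t + φ)`, riding on the recording
`x(t) = eeg(t) + pla(t)`. Notch filters remove it but ring: their causal
start-up transient visibly distorts the first fraction of a second of the
waveform. The alternative implemented here estimates the artifact's three
harmonic parameters `(A, f, φ)` from the spectrum and subtracts the
reconstructed sinusoid, which cannot distort the remaining signal.

The estimator is a two-point interpolated DFT. Because the record length `N`
is finite, an off-grid tone leaks across the FFT bins; with a rectangular
window, the two baseline spectral lines (BSSLs) bracketing the tone — one bin
spacing `Δf = f_s/N` apart, amplitudes `y_l`, `y_r` — determine the sub-bin
offset

```
Δk = y_r / (y_l + y_r)          (Δk = (f − f_l)/Δf ∈ [0, 1))
A  = y_l · πΔk / sin(πΔk)
f  = f_l + Δk · Δf
φ  = arg(Y_l) − πΔk
```

This single-round ratio-based spectrum correction (RBSC) is fragile when
`Δk ≈ 0`: one of the two lines then has almost no amplitude and its SNR
collapses. The dual-step correction (DSCA) therefore runs RBSC once, then
re-evaluates two spectral lines at exactly `f⁽¹⁾ ± Δf/2` (direct
single-frequency DTFT sums, off the FFT grid), where both lines are strong
(`Δk ≈ 1/2`), and runs the ratio correction again. The final estimate merges
the rounds — amplitude from round 1, frequency and phase from round 2 — with
no iteration.

The package provides the generators to exercise all of this without any data
download (tones, calibrated Gaussian noise, a band-limited EEG surrogate), a
causal IIR notch baseline, seeded Monte-Carlo benchmarking of RBSC vs DSCA,
channel-file and EDF readers, ggplot2 `autoplot()` methods, `tidy()`/
`glance()` tidiers, and a small CLI (`inst/cli/pla`).

## Worked example

The canonical simulation: a unit tone at 250.05 Hz, zero phase, sampled at
1000 Hz for 1000 samples, so the tone sits 0.05 of a bin above bin 250.

```r
library(eegpla)
pla <- generate_sinusoid(harmonic_params(1, 250.05, 0), sample_rate = 1000, n = 1000)
dsca_estimate(pla)
#> <DSCA fit>  fs = 1000 Hz, N = 1000, delta_f = 1 Hz
#> # A tibble: 2 × 10
#>   round f_left f_right y_left y_right  ratio delta_k amplitude frequency
#>   <int>  <dbl>   <dbl>  <dbl>   <dbl>  <dbl>   <dbl>     <dbl>     <dbl>
#> 1     1   250     251   0.996  0.0524 19.0    0.0500      1.00      250.
#> 2     2   250.    251.  0.636  0.637   0.999  0.500       1.00      250.
#> final: A = 1.00004, f = 250.050231 Hz, phi = -0.003717 rad
```

Round 1 reads the printed textbook values: `y_l = 0.996`, `y_r = 0.052`,
`Δk = 0.05`, giving `A = 1.00`, `f = 250.05 Hz`, `φ = 0.00` — noise-free
recovery is exact at that precision. Round 2's re-evaluated lines are nearly
equal (`Δk ≈ 0.500`), which is the configuration that stays accurate once
noise is added.

Cleaning a mains-contaminated record and comparing with the causal notch
(surrogate EEG, 200 Hz, 1000 samples, plus a 50.05 Hz tone of amplitude 50,
composite SNR ≈ 3.4 dB):

```r
eeg   <- synth_eeg_surrogate(200, 1000, band = c(0.5, 70), rms = 52.5, seed = 1)
mains <- generate_sinusoid(harmonic_params(50, 50.05, 0), 200, 1000)
x     <- compose_signals(eeg, mains)
dplyr::bind_rows(
  glance(remove_pla(x, method = "dsca",  search_band = c(45, 65), reference = eeg)),
  glance(remove_pla(x, method = "notch", notch_hz = 50,           reference = eeg))
)
#> # A tibble: 2 × 6
#>   method amplitude frequency    phase correlation_vs_reference residual_rms
#>   <chr>      <dbl>     <dbl>    <dbl>                    <dbl>        <dbl>
#> 1 dsca        47.7      50.0 -0.00733                    0.997         3.99
#> 2 notch       NA        NA   NA                          0.976        11.5
```

Subtraction tracks the clean reference much more closely than the notch
(correlation 0.997 vs 0.976; residual RMS 4.0 vs 11.5 signal units), and the
notch's residual is concentrated in its start-up transient. The benchmark in
`run_monte_carlo()` quantifies the estimator comparison: at 0 dB SNR and
`Δk = 0.05`, the dual step cuts the frequency RMSE by roughly a factor of
five relative to the single round, and the two methods converge as
`Δk → 0.5`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the worked-example tone from scratch with the installed package
and recomputes, in order: the two baseline line amplitudes of its spectrum,
the ratio-corrected normalized shift, and the single-round frequency,
amplitude and phase estimates, writing each as JSON.

See `vignettes/power-line-artifact-removal.Rmd` for the model, the numerical
choices, what the surrogate generator does and does not emulate, and known
limitations.
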
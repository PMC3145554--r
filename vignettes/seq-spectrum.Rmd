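---
title: "The sequential spectrum: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequential spectrum: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqspectrum)
```

## The model

The sequential spectrum characterizes a sampled series $x(i)$ through the
signs of its first differences. Each difference is mapped to a binary
symbol,

$$ s_i = \begin{cases} 1 & x(i+1) - x(i) \ge 0 \\ 0 & \text{otherwise,}\end{cases} $$

producing a symbol series $P$ of length $I = n - 1$. A *mono-sequence*
$[N \times s]$ is a maximal run of $N$ identical symbols $s$: a monotone
interval of the original signal, non-decreasing for $s = 1$, decreasing for
$s = 0$. Maximality is essential — runs then partition $P$, consecutive
runs alternate symbols, and the cardinalities $L[N \times s]$ obey the
integer identity $\sum_{N,s} N\,L[N \times s] = I$. Counting sliding
windows instead would double-count interior positions and destroy this
conservation.

The *binary occupancy*

$$ O[N \times s] = \frac{N\,L[N \times s]}{I} $$

is the fraction of the series occupied by monotone intervals of length $N$.
The map $N \mapsto O[N \times s]$ is the seq-spectrum. Because occupancies
sum exactly to one, spectra of different states are commensurable, and the
*relative seq-spectrum* between a state and a reference is their plain
per-length difference (zero-padded over the union of supports; it sums to
zero, and a state against itself is the flat zero baseline). The
alternative normalization $L/I$ was rejected because it is not unit-sum
and because "occupancy" describes the fraction of the series covered, not
the fraction of runs.

At sampling frequency $f_s$ a monotone arm of length $N$ is half a wave of
frequency $f = f_s/(2N)$: $N = 1$ maps to the Nyquist frequency and the
axis is strictly decreasing in $N$. The mapping is an interpretation aid,
not a transform — no inverse exists, and at short lengths the frequency
resolution is coarse because $N$ is an integer.

Two derived quantities complete the toolkit:

* the **symmetry (congruity) index** between the symbol-0 and symbol-1
  spectra: each restriction is renormalized to unit sum over $N$, aligned
  by zero-padding, and compared by total variation,
  $S = 1 - \frac12\sum_N |\tilde O_0 - \tilde O_1|$. $S = 1$ iff the
  restrictions coincide, $S = 0$ iff their supports are disjoint. Total
  variation was chosen over a correlation because it respects the unit-sum
  geometry and has these exact endpoints.
* the **seq-spectrogram**: the full chain applied to sliding windows
  (window $W$, hop $h$, trailing partial window dropped), the
  time-resolved analogue of a short-time Fourier spectrogram.

## Encoding conventions

* **Tie rule.** A zero difference takes symbol 1, so a constant signal
  encodes as all ones. This is the one point of the encoding that is fixed
  by the method's definition rather than by convenience; it also means
  signals with constant epochs show symbol asymmetry by construction.
* **No hidden tolerance.** Comparison is exact floating-point by default.
  An `epsilon` argument widens the tie band (differences above
  $-\varepsilon$ count as non-decreasing) for quantized or dithered data,
  but it is an explicit smoothing parameter, never applied silently, and
  every result in this package uses `epsilon = 0`.
* **Boundary runs** at the start and end of the series are counted like
  any other; excluding them would break conservation.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `epsilon` (encoder) | 0 | signal units | exact comparison; see above |
| `window_length_samples` | 512 | samples | 4 s of 128 Hz EEG; resolves runs up to $N \approx 500$ |
| `step_samples` | 256 | samples | 50 % overlap, the usual spectrogram compromise |
| `alpha` (noise) | — | dimensionless | DFA convention: 0.5 white, <0.5 anticorrelated, 1.5 Brownian |
| chirp `a`, `b`, `dt` | 1, 0, 0.001 | rad/s², rad/s, s | the reference linear chirp |
| chirp `n_samples` | 10001 | samples | see below |
| harmonics | 5, 8, 9, 12, 13 Hz, unit amplitude, 128 Hz, 60 s | | the reference multi-periodic signal; 60 s puts every line on an exact Fourier bin |
| `snr_db` | — | dB | variance ratio $10\log_{10}(\sigma^2_x/\sigma^2_\eta)$ |
| section bounds | 50–500 | samples | 0.4–3.9 s at 128 Hz, "random length" made concrete |
| logistic `r`, `x0`, transient | 4, 0.3, 100 | — | $r=4$ is the standard fully chaotic regime |

## What the generators emulate — and what they do not

`colored_noise()` builds stationary Gaussian series by spectral shaping
(white noise filtered with amplitude $f^{-\beta/2}$, $\beta = 2\alpha - 1$,
DC removed, variance renormalized). The in-package DFA estimator — first
order, boxes scanned from both ends, about twenty log-spaced scales from 8
to $n/8$ — recovers the requested exponent within $\pm 0.1$ at
$n = 2^{16}$; it shares no code or construction with the generator, so the
check is a genuine cross-validation. These surrogates reproduce the
correlation structure of fluctuation-exponent-graded noise, not any
physiological property of EEG: passing tests on them shows the method
behaves as documented on signals with known correlation, amplitude
distribution and stationarity, nothing more. Real EEG adds
nonstationarity, artifacts, quantization and strong individual variation,
which is why no sleep-staging thresholds are shipped — only the
computations (per-window spectra, relative spectra, symmetry index) that
such an analysis would use.

Two sampled-data effects deserve explicit mention:

* **Run-length jitter.** The integer length of a sampled half-wave
  fluctuates by one sample with the sampling phase. A single harmonic with
  $f_s/(2f) = m$ shows interior runs in $\{m-1, m, m+1\}$; the chirp's
  run lengths, though decreasing in the continuous picture, occasionally
  tick up by exactly one sample. Tests therefore assert monotonicity up to
  this one-sample jitter plus a strict long-range decrease, not literal
  nonincreasingness.
* **The chirp's linear spectrum.** With $a = 1$, $b = 0$,
  $\Delta t = 0.001$ s the default duration is 10 s, which keeps the
  instantaneous frequency low enough that essentially no two half-waves
  share a length. Each length then occurs once and its occupancy is
  exactly $N/I$ — a straight line through the origin. This is the regime
  that makes the documented linear length–occupancy relation an identity;
  much longer chirps pile many short half-waves onto the same lengths and
  bend the small-$N$ end of the spectrum toward $\propto 1/N^2$.

For the logistic map at $r = 4$, a descending step requires $x > 3/4$ and
the map sends $(3/4, 1)$ into $(0, 3/4)$, so descents can never chain:
every symbol-0 mono-sequence has length exactly 1 (one distinct length —
comfortably within the documented bound of at most two, which allows for
nearby $r$ where two-step descents occur), while the symbol-1 spectrum is
much wider. This asymmetry between ascent and descent is the symbolic
fingerprint of the map's asymmetric branch structure.

Random-section removal cuts the series into uniform-length sections,
keeps the odd ones and concatenates. The splices scramble phases, so the
Fourier line spectrum of a harmonic input collapses, while the
mono-sequence structure — built from local monotonicity — barely changes:
short-run occupancy stays far below that of noise of equal length. That
contrast is the method's core argument for nonstationary data.

## Numerical and degenerate-input choices

* Run counting uses `rle()`; an independent character-by-character scan
  serves as the test oracle.
* Occupancy sums are exact rational multiples of $1/I$; the unit-sum check
  uses $10^{-12}$ purely as a floating-point allowance.
* Signals must have at least 2 samples (one difference) and be finite;
  errors name the first offending index or line. One-column text input
  without a sampling rate is refused rather than defaulted, because the
  frequency axis would silently be wrong.
* Empty relative-spectrum requests (a symbol absent from both operands)
  warn and return an empty table rather than erroring, since the
  comparison is well-defined and trivially empty.
* The EDF reader handles plain continuous 16-bit recordings (the
  polysomnographic case) and deliberately not EDF+ annotations; the writer
  exists to build synthetic fixtures and truncates to whole one-second
  records.

## Known limitations

* No inverse: the seq-spectrum does not determine the signal.
* Short-length resolution is coarse ($N$ integer), so high-frequency
  structure is compressed into few bins.
* The symmetry index and the seq-spectrogram windowing are pragmatic,
  package-defined conventions; other congruity measures or window shapes
  are defensible.
* Increasing the sampling rate usually widens the spectrum toward longer
  runs, but can also shorten runs by resolving new local extrema — the
  spectrum is not invariant under resampling.
* Clinical interpretation (sleep stages, insomnia, epilepsy) requires
  scored recordings and is out of scope; the package supplies the
  computation, not the thresholds.

## Problem sizes used in the checks

The shipped tests and the acceptance script work at the sizes the
generator suite is specified for: $2^{16}$ samples and ten seeds per
fluctuation exponent for the noise properties, $10^4$ iterates for the
logistic map, a 10 s chirp, a 60 s five-harmonic signal, and 1000 random
series for the conservation and oracle checks.
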
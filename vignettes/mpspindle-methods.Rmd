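---
title: "Matching-pursuit parametrization and detection of EEG transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching-pursuit parametrization and detection of EEG transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpspindle)
```

## The model

Sleep spindles are the classic example of a transient EEG structure with
an explicit definition: waxing-and-waning oscillations at 11–16 Hz
lasting at least half a second.  Their shape is very close to a Gabor
function — a sinusoid under a Gaussian envelope — which motivates
parametrizing the whole signal as a sparse sum of Gabor atoms and then
*selecting* spindles (or slow waves, or any other class) from the fitted
atoms by explicit criteria, instead of engineering a dedicated detector
per class.

`mp_decompose()` fits the greedy matching-pursuit expansion: starting
from the epoch itself, each iteration finds the dictionary atom with the
largest inner product with the current residual and subtracts its
projection.  The fit is a classed model object (`mp_book`) with the
usual accessors: `coef()` returns the atom parameters, `fitted()` and
`residuals()` partition the epoch exactly (energy is conserved to float
precision — this is asserted after every decomposition in the test
suite), `predict(b, n_atoms = k)` reconstructs from the leading *k*
atoms.

Each atom is

$$g(t) = K\, e^{-\pi\left(\frac{t-u}{s}\right)^2}
         \cos(2\pi f (t-u) + \phi),$$

with time centre $u$ (s), envelope half-width $s$ (s), frequency $f$
(Hz), phase $\phi$, and $K$ normalizing the sampled vector to unit
energy.  Atoms are truncated at $|t-u| \le 4s$, where the envelope falls
below $10^{-21}$ of its peak.

## The dictionary and its single density parameter

The discrete grid over $(u, f, s)$ is controlled by one dimensionless
parameter, the *energy error* $\varepsilon$: the maximal fraction of a
structure's energy that a single iteration may lose because the ideal
continuous atom falls between grid points.  The construction:

* **Scales.**  Two unit-energy Gaussian envelopes of widths $s$ and
  $as$ have inner product $\sqrt{2a/(1+a^2)}$.  Setting this overlap to
  $1-\varepsilon$ for *adjacent* ladder rungs gives the closed-form
  dilation
  $a = \bigl(1+\sqrt{1-(1-\varepsilon)^4}\bigr)/(1-\varepsilon)^2$,
  and the worst off-grid scale (the geometric midpoint) then loses
  $1 - 2\sqrt a/(1+a) < \varepsilon$ of its energy.  The ladder is
  anchored at one sampling period, $s_j = a^j/f_s$.  At
  $\varepsilon = 0.04$, $f_s = 256$ Hz this yields
  `r paste(round(build_dictionary(0.04, 256, 20)$scales$s[
    build_dictionary(0.04, 256, 20)$scales$s >= 0.5 &
    build_dictionary(0.04, 256, 20)$scales$s <= 2], 2), collapse = ", ")`
  s in the spindle-duration range — so a 1.5-s structure is necessarily
  represented by a 1.21- or 1.82-s atom, with the leftover energy pushed
  to later iterations or the residual.
* **Time and frequency steps.**  The energy budget left after the scale
  ladder, $r^2 = (1-\varepsilon)\,/\,\rho_s$ with
  $\rho_s = 2\sqrt a/(1+a)$, is split evenly between the two remaining
  dimensions using the Gaussian closed forms for offset and modulation
  mismatch, giving $\Delta u = \alpha s$ and $\Delta f = \beta/s$ with
  $\alpha = \beta = 2\sqrt{\ln(1/r)/\pi}$.  In the implementation the
  time step is snapped down to a whole number of samples and the
  frequency grid is the FFT bin spacing of the scan (the next power of
  two), both *at most* the calibrated bound, so discretization only
  tightens the contract.  The contract itself — at most $\varepsilon$
  single-iteration energy loss over random off-grid in-range Gabors — is
  verified as a property test; empirically the worst observed loss at
  $\varepsilon = 0.04$ is about $0.027$, the slack coming from the
  conservative corner-case budget split and from phase being optimized
  continuously rather than gridded.
* **Phase** is not part of the grid.  At every grid point the residual
  is projected onto the two-dimensional span of the quadrature atoms
  $E\cos\omega(t-u)$ and $E\sin\omega(t-u)$; the captured energy
  $p^\top G^{-1} p$ (with $G$ the exact 2×2 Gram matrix, computed from
  the FFT of the squared envelope at the doubled frequency) is maximized
  in closed form.  Edge-clipped windows get their own exact Gram, so
  atoms near epoch borders are handled without approximation.

The per-scale scan is one `mvfft` over envelope-windowed residual
segments, which is what makes the published density setting
$\varepsilon = 0.04$ affordable in plain R (≈0.4 s per iteration on a
20-s, 256-Hz epoch; a 10-minute recording decomposes in a few minutes).

**Tie-breaking** (exact ties only): largest captured energy, then
smallest $u$, then lowest $f$, then smallest $s$ — and the test suite
checks the scan against an exhaustive, independently coded grid search
atom for atom.

## Detection as filtering

`filter_book()` selects atoms by frequency window, duration and
peak-to-peak amplitude.  Conventions:

* duration is the envelope half-width $s$ itself (extent
  $u \pm s/2$), optionally rescaled by `duration_factor` — an explicit
  extension point for matching visual scoring conventions;
* an atom's peak-to-peak amplitude is $2\,c\,\max_t |g(t)|$ for
  coefficient $c$, i.e. the oscillation's swing at the envelope maximum;
  for spindle-like atoms this sits within ~3 % of max-minus-min of the
  reconstruction (tested), the discrepancy coming from the cosine peak
  not coinciding exactly with the envelope peak;
* event intervals are half-open $[start, end)$ on a 0-based timeline,
  which makes the per-sample mask conversion unambiguous;
* events are *not* merged across epoch boundaries by default (each event
  stays traceable to one atom); `merge_events()` optionally merges gaps
  below 0.1 s.

The spindle amplitude threshold is subject-adaptive
(`amplitude_threshold()`): the signal is band-passed at 11–16 Hz with a
2nd-order Butterworth design applied forward–backward (zero phase keeps
RMS windows aligned with event timing; the magnitude response is
effectively 4th order), RMS is taken in non-overlapping 0.2-s windows —
about one oscillation period, so within a window the signal behaves like
a constant-amplitude sine and peak-to-peak amplitude relates to RMS as
$A = 2\sqrt2\,\mathrm{RMS}$ — and $A_{\min}$ is $2\sqrt2$ times a chosen
percentile of that distribution.  Percentiles interpolate linearly
between order statistics.  Window boundaries are laid on the continuous
time grid (at 256 Hz a 0.2-s window is 51.2 samples), so the window
count is exactly `floor(n / (0.2 fs))`.  Which samples enter the
distribution is the caller's choice: the functions operate on whatever
signal segment is supplied (e.g. a whole night or stage-2 epochs only).

Slow waves use fixed criteria instead (over 70 µV, 0.2–4 Hz, over
0.5 s) via `detect_transients(slow_wave_criteria())` — the same
decomposition serves any number of structure definitions.

## Evaluation and threshold selection

Scoring is at sample resolution (`confusion_counts()` on per-sample
masks).  `compute_metrics()` reports sensitivity, PPV, MCC, Cohen's
$\kappa$ and F1; the MCC uses the standard Matthews definition with the
square root over $P\,P'\,N\,N'$.  Zero-denominator cases are reported as
`NA` and flagged, never silently as 0, and are excluded (with a count)
from cross-validation averages.

`cross_validate()` follows the protocol: repeatedly draw a random
training subset (uniform without replacement; disjointness is asserted),
take each training recording's *individually* optimal percentile
(maximal MCC over the grid, ties to the lowest percentile), average them
arithmetically, apply the averaged percentile to the validation
recordings, and summarize.  The default grid is 90–99.5 in steps of 0.5,
covering the region around the typical optimum near the 97th percentile
on overnight recordings.  Because the decomposition and the RMS
distribution do not depend on the percentile, `prepare_recording()`
caches them and a whole grid sweep costs little more than one detection.

## The synthetic generator

`simulate_eeg()` is first-class, tested code: $1/f$ colored noise
(default RMS 15 µV, with a 0.5-Hz spectral floor to avoid unbounded
drift) plus Gabor transients at non-overlapping sample-aligned positions
with phases uniform in $[0, 2\pi)$ and exact peak-to-peak scaling.
Defaults mirror the standard definitions: spindle frequency uniform in
11–16 Hz, half-width uniform in 0.5–2 s, peak-to-peak 25–60 µV at
2/min; slow waves 80–150 µV below 2 Hz.  What it does *not* emulate:
artifacts, non-stationary background, imperfect spindle shapes, or
expert-scoring ambiguity — so passing recovery tests demonstrate the
pipeline's correctness, not clinical-grade concordance.  On real
expert-scored overnight data, sample-based concordances of automatic
detectors cluster far lower (sensitivity ≈ 0.6, PPV ≈ 0.5), limited
largely by scorer consistency; reproducing that regime needs the
restricted source database and is out of scope here.

## Problem sizes used in the tests

The suite's heavy checks are sized to stay informative while remaining
desk-scale: the exhaustive-oracle equivalence runs on 2-s epochs at
128 Hz with a reduced ($\varepsilon = 0.2$) dictionary; the
$\varepsilon$-contract sweep uses 200 random off-grid Gabors on a 2-s
epoch at the full $\varepsilon = 0.04$; the end-to-end recovery uses a
10-minute recording with 20 high-SNR (60–110 µV) spindles at
$\varepsilon = 0.04$, $M = 20$ per 20-s epoch, percentile 97 — chosen
because high SNR makes ground truth unambiguous, so sensitivity and PPV
isolate the pipeline rather than the noise model.  The cross-validation
recovery uses eight 3-minute recordings whose signal adds *unannotated*
weak sigma transients (10–30 µV) to annotated 40–70 µV spindles: the
weak transients penalize permissive thresholds the way
sub-criterion spindle-like activity does in real EEG, giving the
configuration an interior optimal percentile that the protocol must
find.

## Numerical choices and degenerate inputs

* Truncation at $\pm 4s$ bounds the envelope tail below $10^{-21}$;
  synthesis and scan use the identical support rule so self-matches are
  exact.
* An all-zero residual returns a flagged degenerate zero-coefficient
  atom; decomposition stops early once residual energy falls below
  $10^{-12}$ of the signal energy (a book may therefore hold fewer than
  $M$ atoms).
* At $f = 0$ (and wherever the quadrature Gram is near-singular) the
  projection falls back to the cosine-only component.
* Envelope half-widths spanning fewer than 3 samples warn about
  under-sampling but still compute.
* Occupancy banding assigns boundary values upward (exactly 50 % is
  "above", matching the inclusive lower edge of the classical 50–100 %
  range); event counting per epoch uses the event's time centre.
* Recordings are decomposed in non-overlapping 20-s epochs (the
  traditional sleep epoch); a trailing remainder of at least 1 s gets a
  matching-length dictionary, shorter remainders are dropped.

## Known limitations

* Detected durations are quantized to the dictionary's width ladder;
  with coarse dictionaries (large $\varepsilon$) interval-overlap scores
  degrade even when every event is found — at $\varepsilon = 0.1$ the
  end-to-end pilot loses ~7 % PPV purely to width overshoot.  Use the
  published $\varepsilon = 0.04$ when sample-level agreement matters.
* The deterministic algorithm is implemented; stochastic-dictionary
  variants are not.
* The original binary book format is not read; books are exchanged as
  documented plain-text CSV.
* EDF support covers continuous 16-bit recordings (EDF/EDF+C data
  channels); annotation channels and discontinuous files are not parsed.
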
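---
title: "Analysing magnetic-tweezers extension traces with smtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing magnetic-tweezers extension traces with smtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtrace)
```

## The measurement problem

In a magnetic-tweezers experiment a single double-stranded DNA molecule is
tethered between a surface and a superparamagnetic bead, and the bead height
(the tether *extension*, in nm) is tracked while a calibrated force (pN) is
applied. When recombinase–ssDNA filaments (RecA or Rad51 on short ssDNA
fragments) are present in solution, their interaction with the tethered dsDNA
changes the extension: non-homologous filaments can capture the dsDNA under
force and extend it, and homologous filaments progressively exchange strands
with it, lengthening the tether at a characteristic rate. Everything the
experiment reports is read off extension-versus-time traces sampled at 5 Hz
with roughly 10 nm tracking accuracy.

`smtrace` implements the complete trace-analysis chain for such experiments:

1. **Segmentation** of a trace into constant-growth intervals (the core
   algorithm),
2. **Binding analysis**: extension gain ΔL, pause-level histograms,
   extension per nucleotide, implied filament coverage,
3. **Exchange analysis**: characteristic strand-exchange elongation rates
   from slope histograms,
4. **Force calibration** against the dsDNA overstretching transition,
5. A seeded **synthetic-trace generator** that emulates the experiments and
   carries ground-truth labels, so every stage is testable without
   laboratory data.

## The dsDNA mechanics model

The analysis needs only three features of dsDNA elasticity, so the model is
deliberately phenomenological:

$$E(F) = n_{bp}\, r \left[ 1 + cF + (f - 1)\, S(F) \right]$$

with $r = 0.34$ nm/bp the B-form rise (a textbook constant recorded in the
configuration for transparency), $c = 3\times10^{-4}$/pN a linearised
low-force compliance, $f = 1.7$ the overstretching factor, and $S$ a logistic
sigmoid centred at the overstretching force $F_0 = 65$ pN. Below the
transition the tether is essentially B-form; above it, 1.7× B-form; at
$F_0$, exactly halfway. The transition *width* parameter (default 2 pN) is
defined as the 10–90% force width, i.e. the logistic scale is
$w/(2\ln 9) \approx 0.45$ pN. With a 2 pN logistic *scale* instead, the
model would reach only ~1.65× at 70 pN, inconsistent with the anchor that
the overstretched state is ~1.7× just above the transition; the 10–90%
convention keeps both anchors ("midpoint 65 pN, width ~2 pN" and "1.7× above
the transition") simultaneously true. `detect_overstretch()` reports width
in the same convention, so a fitted synthetic ramp returns ≈2 pN.

No worm-like-chain or torque model is included: at the forces analysed
(20–58 pN for binding/exchange, ramps to 80 pN for calibration) the
features above are the only ones the estimators consume.

## What the synthetic traces emulate

`simulate_binding_trace()` builds the bound-extension process
$\Delta L(t)$ in continuous time (so noiseless traces are *exactly*
piecewise linear between the ground-truth breakpoints), then samples it on
the 0.2 s grid, adds the naked-DNA baseline $E(F(t))$ and i.i.d. Gaussian
noise:

* **Force protocol** — the standard cycle: 40 pN for 120 s, a step to the
  test force for 120 s, back to 40 pN for 120 s.
* **Nucleation** — a Poisson process, rate 0 below a mode-dependent force
  threshold and 0.04 /s above it. Thresholds: 50 pN for 3′5′ pulling; 60 pN
  (just above the studied ≤58 pN range) for 3′3′ and 5′5′, since those modes
  showed no extension gain anywhere in that range. The 0.04 /s default
  places the generator in the rare-binding regime the pause-point analysis
  presumes: the mean wait (25 s) is long compared with filament zippering,
  so traces dwell at integer multiples of the full filament length.
* **Growth and pauses** — after nucleation, ΔL grows at 4 nm/s until it
  reaches $k \times L_{nt} \times g$ (the $k$-th full filament at $g = 0.12$
  nm/nt), then pauses until the next nucleation. 4 nm/s is a free parameter
  (the experiments constrain outcomes, not kinetics); it is chosen so that
  even a 1600-nt filament (192 nm) completes well within the 120 s
  high-force phase after a typical nucleation delay, as the observed pause
  plateaus across 400–1600 nt require.
* **Release** — when the force drops below threshold, a non-homologous ΔL
  decays to zero at 10 nm/s; homologous complexes persist.
* **Noise** — i.i.d. Gaussian, σ = 10 nm per 0.2 s sample, optional linear
  drift. No bead-fluctuation spectrum or tracking artefacts are modelled:
  passing tests show the estimators recover parameters under white noise at
  the stated magnitude, not that they are robust to correlated instrument
  noise.
* **Calibration ramps** — the recorded force is the true force divided by a
  per-bead magnetization scale (typical scatter 5%), while extension follows
  the true force, which is exactly the situation bead calibration must
  undo.

`simulate_exchange_trace()` grows ΔL linearly at the strand-exchange rate on
top of the baseline; `simulate_control_trace()` is baseline plus noise with
an optional small (<20 s) settling transient. All generators are seeded and
deterministic; `simulate_cohort()` derives per-trace seeds from one master
seed and can write CSV traces with ground-truth JSON sidecars.

## The segmentation algorithm

Within each analysis window the greedy interval finder:

1. starts at the window start, fits ordinary least squares on **every**
   subinterval from the start lasting at least `min_len` (2 s),
2. scores each candidate and keeps the minimum-score one (ties broken in
   favour of the longest),
3. restarts the search `overlap` (0.5 s) before the accepted end, skipping
   short (< 1 s) runs of high-noise samples (robust z-score above 3 against
   the previous interval's fit), and repeats until the window is exhausted;
   a tail shorter than `min_len` is absorbed into the final interval.

Windows begin `settle` = 20 s after every change in force, because the
bead needs time to re-equilibrate after a force step and early transients
would otherwise masquerade as growth.

### The interval score

The score multiplies the magnitude of the residuals per unit length by the
aggregate absolute autocorrelation of the residual sequence:

$$\mathrm{score} = \frac{\sum_i |e_i|}{n} \times
  \frac{1}{n-1}\sum_{k=1}^{n-1} |\rho_k(e)|$$

where $\rho_k$ is the biased sample autocorrelation at lag $k$. A straight
stretch fit well leaves small, white residuals (both factors small); an
interval that spans a growth-rate change leaves large, *structured*
residuals (both factors large). The score is zero iff the residuals are all
zero, linear in the residual scale, and invariant to vertical offsets and
time translation.

Two normalisation choices deserve comment:

* The *absolute mean* reading of "sum of its residuals" is identically zero
  for least-squares fits with an intercept; it is kept as
  `score = "literal"` for comparison but the default uses the mean absolute
  residual.
* The autocorrelation factor is the per-lag **mean** of $|\rho_k|$, not the
  raw sum. For white residuals the raw sum grows like $\sqrt{n}$, which
  makes the minimiser systematically prefer the shortest admissible
  interval and fragments noisy traces into 2 s slivers; the per-lag mean
  decreases with $n$ for white residuals while staying $O(1)$ for
  structured ones, so homogeneous stretches are fit by one long interval.
  The raw-sum variant remains available as `acf_norm = "sum"`.

The autocorrelation sum is computed by FFT, so a full greedy pass over a
600-sample window takes well under a second.

### The exact oracle

`dp_segment()` globally minimises the total score over all partitions of a
window into at most $K$ intervals of duration ≥ `min_len`, by dynamic
programming over the $O(n^2)$ interval-score table, preferring fewer
segments among ties. On noiseless piecewise-linear input a zero-score
partition exists only when every boundary sits on a true knot, so the DP
recovers the knots exactly — which is what makes it a trustworthy oracle
for the greedy pass. It is $O(n^2)$ in memory and worse in time, hence
restricted to ≤ 2000 samples and used only for validation.

## Binding observables

* **ΔL** (`delta_extension`) — mean extension over a window late in the
  high-force phase (default 105–120 s after the step) minus the naked-DNA
  baseline. The baseline is the measured mean over the last 20 s of the
  preceding 40 pN phase *plus the model's elastic difference* between 40 pN
  and the test force; the elastic correction is switchable off, since the
  exact baseline convention behind published "change in extension" plots is
  a matter of taste. At forces ≤58 pN the correction is dominated by the
  compliance term (~80 nm for λ-DNA between 40 and 56 pN).
* **Pauses** (`detect_pauses`) — segments whose |slope| is below
  max(0.02 nm/s, 2 × slope SE), restricted by default to the highest-force
  window, at levels at least 20 nm (2× tracking accuracy) above baseline so
  the pre-nucleation baseline plateau is not counted as a pause.
* **Pause histogram / extension per nt** — duration-weighted histogram of
  levels (10 nm bins ≈ the measurement accuracy; peak prominence floor 20%
  of the maximum bin), peaks assigned to integer multiples of the modal
  peak spacing (assignments off by more than 25% are dropped), and the
  extension per nucleotide estimated as the mean of level$_k / (k \times$
  nt$)$. Estimates from different filament lengths are pooled by a
  peak-count-weighted mean.
* **Coverage** (`coverage_fraction`) — the measured extension/nt divided by
  the 0.17 nm/nt characteristic of fully covered RecA-like filaments; 0.12
  nm/nt implies ~70% coverage *if* the deficit is entirely incomplete
  coverage. The package reports the number and leaves the interpretation
  (shorter projection vs incomplete coverage) to the user.

## Exchange rates

Each trace contributes its **duration-weighted median segment slope** (so
long traces do not dominate the cohort, and a short noisy tail segment does
not skew its own trace's representative), the cohort's slopes form a
histogram, and the characteristic
rate is the dominant nonzero mode of a kernel density estimate (Silverman
bandwidth). Traces within one bin (0.03 nm/s) of zero are reported as the
zero fraction — molecules followed with no extension change. Uncertainty is
a seeded bootstrap over traces (1000 resamples, percentile interval), and
`compare_rates()` bootstraps the difference between two cohorts. A KDE peak
was chosen over a Gaussian-mixture fit because it is robust at cohort sizes
of a few tens; at those sizes a mixture fit's component count is itself
uncertain.

## Numerical choices and edge cases

* Minimum 3 samples per interval regardless of `min_len`/`dt` arithmetic
  (the autocorrelation needs 3 points); degenerate time ranges are errors.
* Score ties are resolved toward the longest candidate, deterministically,
  within a relative tolerance of 10⁻⁶ (noiseless zero-score candidates tie
  at ~10⁻¹⁴ and the longest — the full linear piece — wins).
* The `overlap` is implemented as the next search start being
  `floor(overlap/dt)` samples before the first sample *after* the previous
  end, so `overlap = 0` yields a disjoint partition of the window; that
  makes "greedy total ≥ DP optimum" a well-defined comparison.
* Skipped high-noise regions are logged with their time bounds; a run as
  long as `skip_max` is treated as real signal, not noise.
* All randomness flows from explicit seeds; identical seeds give
  byte-identical outputs.

## Problem sizes used in validation

The test suite and the acceptance script validate parameter recovery at
desk scale: 60 binding traces (15 per filament length at 400/700/1000/1600
nt) for the extension-per-nt pipeline, 40 traces per exchange cohort for
rate recovery, and 50 + 50 piecewise-linear traces of ~30 s for the
greedy-vs-DP oracle comparison. These sizes are comparable to the cohort
sizes of the underlying experiments (tens of molecules per condition) and
keep a full validation run in minutes on one CPU.

## Known limitations

* The noise model is white; correlated bead fluctuations, camera blur and
  drift steps are not emulated, so recovery results bound estimator
  performance under idealised noise only.
* Binding kinetics (nucleation rate, growth and release speeds) are
  phenomenological free parameters — the experiments constrain outcomes,
  not kinetics — and are exposed in the configuration.
* The peak-to-multiple assignment assumes the first filament-length peak is
  present in a cohort's histogram; in the rare-binding regime it always is,
  but a cohort consisting only of double-binding traces would be misread by
  a factor of 2.
* No torsional mechanics: all results assume torsionally unconstrained
  tethers, as in the nicked-construct experiments emulated here.
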
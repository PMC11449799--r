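---
title: "twinephys: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{twinephys: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

twinephys implements the cellular-phenotyping battery used to compare
iPSC-derived dentate gyrus granule-like neurons across clinical groups:
current-clamp excitability and spike shape, passive membrane properties,
voltage-clamp I–V extraction, spontaneous EPSC detection, MEA burst
analysis, Sholl morphometry, the group-statistics layer and a
DEG × GWAS-catalog gene-set stage. Patient recordings in such studies are
usually not deposited, so the package's synthetic-data module is a
first-class citizen: every analysis is validated against generators with
known ground truth. This vignette records the models, their assumptions,
the tunable parameters, and the places where the design was genuinely open
and a choice had to be made.

## The model neuron

All simulated electrophysiology comes from a single-compartment
conductance-based neuron:

$$C \frac{dV}{dt} = -g_L (V - E_L) - g_{Na} m^3 h (V - E_{Na})
  - \left(g_K n^4 + g_{KA} a b\right) (V - E_K) + I_{inj} + \xi$$

with units chosen to be mutually consistent without conversion factors
(mV, ms, pA, nS, pF; `nS × mV = pA`, `mV/GΩ = pA`, `pA·ms/mV = pF`).
Integration is fixed-step exponential Euler at 0.05 ms (= the 20 kHz
acquisition standard); each gate and the voltage relax exactly along their
local exponential within a step, which makes a clamped-voltage simulation
*exactly* equal to the closed-form gating solution on the same grid — a
property the test suite exploits. Noise $\xi$ is additive Gaussian current
per sample; there is no channel stochasticity (sufficient for estimator
testing, not for studying intrinsic variability).

Gating kinetics:

| gate | steady state | time constant |
|---|---|---|
| $m$ (Na activation) | Boltzmann, half −35 mV, slope 4 mV | 0.15 ms |
| $h$ (Na inactivation) | Boltzmann, half −54 mV, slope 3.5 mV (falling) | $1 + 59\,e^{-((V+60)/20)^2}$ ms |
| $n$ (delayed rectifier) | Traub-type rate functions shifted to $V_T=-55$ mV | rates scaled × 0.15 |
| $a,b$ (A-type) | act. half −50 mV / inact. half −95 mV | 2 ms / 80 ms |

These constants are not a fit to any cell; they were chosen to satisfy,
simultaneously, four constraints the pipeline itself imposes:

1. **Leak-dominated two-point measurement.** The input conductance is
   measured from currents at −70 and −50 mV, so the sodium window
   conductance at −50 mV must be far below a GΩ-scale leak. This forces a
   steep $m_\infty$ with a half-activation no more hyperpolarized than
   about −35 mV.
2. **No depolarized-rest latch.** Presets with a depolarized leak reversal
   (−40.6 mV) must sit quietly at rest. With a shallow or depolarized
   $h_\infty$ the window current creates a second stable point near
   −25 mV; the steep, hyperpolarized $h_\infty$ removes it.
3. **Excitability from a −60 mV holding.** The protocol ramps the cell
   slowly (membrane time constants of 50–150 ms), so sodium must not
   inactivate before threshold: $\tau_h$ is ~60 ms around rest and ~1 ms
   at spike peak.
4. **Repetitive firing.** A slow delayed rectifier produces a deep, long
   afterhyperpolarization during which $h$ recovers, which is what lets
   high-$g_{Na}$ presets fire trains rather than single spikes.

The `dg_control`, `dg_cotwin` and `dg_affected` presets carry the
group-level passive truths that the acceptance targets recover (leak
conductance 0.24 / 0.46 / 0.56 nS; leak reversal −52.8 / −46.3 /
−40.6 mV), plus choices that are realistic but not pinned by any printed
number: capacitances 35 / 30 / 25 pF (arborization ordering) and
Na/K maximal conductances 180/36, 110/22, 60/12 nS (excitability and
current-amplitude ordering). Current noise defaults to 5 pA per sample at
20 kHz. These values are fixed once and not tuned against test outcomes.

Holding is implemented as a bias current computed from the steady-state
gating equations at the target potential, mirroring how an experimenter
holds a cell at −60 mV in current clamp. Voltage clamp is ideal
(`rs = 0`) by default; a series-resistance mode (`rs` in GΩ) produces the
capacitive charging transient used by the capacitance estimator.

## Feature extraction: numerical choices

**Spike detection.** Local maxima with peak above −10 mV, prominence
≥ 20 mV, refractory ≥ 2 ms — deliberately permissive for the
small-amplitude spikes of immature neurons — plus a minimum upstroke rate
of 10 mV/ms in the preceding millisecond. The upstroke criterion is
needed because a large passive depolarization can satisfy height and
prominence alone at the top of a current step.

**Spike threshold.** The membrane potential at the first maximum of
d²V/dt² before the peak. Operationally: boxcar smoothing over 0.25 ms
(forced to an odd number of samples so the filter is phase-neutral),
central second differences, search restricted to the 10 ms before the
peak and away from the partially-smoothed trace edges, candidate maxima
must exceed 20% of the window's global maximum (noise guard) and an
absolute floor of 10⁻³ mV/ms² (a linear ramp has no defined threshold).
The argmax is refined to sub-sample precision with a local parabolic fit
before the voltage is interpolated: at 20 kHz the upstroke traverses more
than 1 mV per sample, so without refinement the estimate is grid-limited.

**Spike shape.** Amplitude = peak − threshold; width = time between the
two linearly interpolated crossings of threshold + amplitude/2; fast AHP
= threshold − V(5 ms after the interpolated downward threshold
re-crossing). Windows too short for the 5 ms lookup raise a typed error
rather than returning a truncated value.

**Passive properties.** `R_m = 20 mV / (I(−50) − I(−70))` with steady
currents averaged over the last 50 ms of a 200 ms clamp step;
`G_in = 1/R_m` exactly. Resting potential is the median over a ≥ 500 ms
injection-free epoch (robust to spontaneous events). Capacitance
integrates the test-step transient above the post-step steady current
(`C = Q/ΔV`), which is amplifier-convention-free; the integration window
(50 ms) is long relative to the clamp time constant.

**Voltage-clamp extraction.** The sodium amplitude is the stabilized
current (mean over 20–40 ms post-onset) minus the transient-window
minimum (0–10 ms); windows are configurable because the original
"after stabilizing" is not operationally defined anywhere. Two guards are
ours: the subtraction is only applied when the trace undershoots its
onset-instantaneous current by more than 2 pA — without an inward
transient the literal formula would report the rising potassium current
as sodium — and results are floored at 0. Fast potassium is the maximum
within 10 ms of onset; slow potassium the mean over the last 10 ms of the
step. Leak is handled by fitting a line to the steady currents of the
hyperpolarized steps (−90…−70 mV) and extrapolating; the flag can be
turned off to reproduce the literal uncorrected extraction.

**EPSC detection.** The original analysis was semi-manual and its
criteria are unrecoverable, so the automated detector is fully explicit:
~1 kHz boxcar low-pass, rolling-median baseline (200 ms), threshold
`max(5 pA, 3.5 × MAD-σ)`, minimum inter-event interval 5 ms, a
valley-based merge of double counts (adjacent peaks whose valley never
returns below half threshold are one event), and a rise-time bound
(10 ms) consistent with bi-exponential kinetics. Amplitude is
baseline-to-peak on the filtered trace. These defaults were validated
only against synthetic ground truth (recall and precision ≥ 0.9 at
SNR 5); they carry no claim of equivalence to the original manual
scoring.

**MEA analysis.** Spike detection band-passes 10 Hz–2.5 kHz (zero-phase
FFT brick wall) and takes ±5.5 SD threshold crossings with 1 ms dead
time; negative-going crossings are primary, per extracellular convention.
Burst detection is the classic Poisson-surprise formulation: seeds are
runs of ≥ 5 spikes with inter-spike intervals below half the train mean,
greedily grown and trimmed while the surprise
$S = -\log_{10} P(N \ge n \mid \mathrm{Poisson}(\lambda T))$ increases,
reported when $S \ge 10$; $\lambda$ is the whole-train mean rate. The
commercial "adaptive Poisson" algorithm is proprietary and numeric parity
with it is explicitly not claimed. Network bursts are intervals where
single-electrode bursts overlap on at least a quarter of active
electrodes (minimum 2), merged across gaps < 100 ms.

**Morphometry.** Sholl intersections are counted in 3-D (reconstructions
are 3-D; a 2-D projection flag exists): for each parent–child segment the
quadratic $|p + t(c-p) - c_0|^2 = r^2$ is solved exactly and roots in
[0, 1] are counted, so a segment crossing a sphere twice counts twice and
a tangency counts once. The soma center is the centroid of type-1 nodes
(or the root). Branches are unbranched paths between root, branch points
and tips. Soma area is the shoelace area of a traced contour, else
$\pi r^2$ of the root radius.

## Statistics layer

The two-group default is Welch's unequal-variance t test; a flag restores
the pooled-variance form (and the F = t² identity with a two-level
one-way ANOVA holds for the pooled form, as the tests assert). Multiple
comparisons after one-way ANOVA use Tukey–Kramer (the common default of
the original analysis environment), with Bonferroni as an alternative.
The KS normality check standardizes by the sample mean and SD before
testing against N(0,1); because the parameters are estimated from the
same data this screen is mildly anti-conservative, which the calibration
test acknowledges with a widened acceptance band (rejection rate in
[0.03, 0.08] at nominal 0.05). Two-way ANOVA (group × day, day as a
factor) runs on well or subject means. Stars follow the usual convention
(* < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001, strict inequalities).
Neurons are treated as independent observations, matching how such
studies report n; a subject-level aggregation mode exists but is not the
default. No cross-endpoint multiplicity correction is applied.

## Gene-set stage

DEG membership is `padj < 0.05` (configurable; the conventional
adjusted-p cutoff). Symbols are standardized (uppercase, whitespace
stripped, version suffixes removed) on both sides before intersection;
each intersected gene carries its regulation direction (down = blue,
up = red) and the catalog study count as weight. The GWAS catalog is
consumed as a local TSV snapshot for reproducibility; the file shipped in
`inst/extdata/gwas_catalog_synthetic.tsv` is a synthetic stand-in with
invented study counts, present so the pipeline and tests run offline — it
is not a real catalog extract.

## What the synthetic world does and does not establish

The generators emulate the statistical structure the analyses assume:
passive + spiking membrane responses under the exact step protocols,
Poisson event trains with bi-exponential kernels and lognormal
amplitudes, bursty spike trains with known inserted bursts, branched
trees with controlled topology, DEG tables with exact significant counts.
A green test therefore establishes that each estimator recovers the
generator's ground truth under the stated noise — it does not establish
performance on real recordings, where series-resistance artifacts,
electrode drift, overlapping synaptic events, non-Poisson background and
tracing errors all exist and are deliberately out of scope. Likewise the
model neuron reproduces the *phenomenology* needed by the extractors
(transient inward / sustained outward currents, immature spikes,
GΩ-scale passive behavior); it is not a biophysical fit to DG granule
neurons, and its spike-feature values across group presets follow from
the model, not from any printed group table.

## Known limitations

- Single-spike features are taken from the rheobase sweep only, as in the
  emulated analysis; no f–I curve or adaptation statistics.
- The EPSC detector resolves events no closer than the 5 ms minimum
  interval; coincident events are merged (the unbiasedness test runs at a
  rate where this is negligible).
- Burst-detector parity with proprietary instrumentation software is out
  of scope; only the Poisson-surprise definition is guaranteed.
- `run_end_to_end()` defaults are desk-scale (shorter EPSC and MEA
  recordings than the acquisition standard) so the full pipeline runs in
  minutes on one CPU; all durations are configurable upward.
- Configs are JSON rather than YAML so the package has no dependency
  outside the guaranteed runtime set.
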
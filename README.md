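# twinephys

Quantitative phenotyping of iPSC-derived dentate gyrus (DG) granule-like
neurons, packaged as a reproducible R pipeline.

Studies that compare patient-derived neurons across clinical groups (for
example schizophrenia-discordant monozygotic twins against healthy twins)
rest on a standard battery of cellular endpoints:

- **Intrinsic excitability** — total evoked action potentials over a
  20-step current-injection protocol (3 pA increments, 400 ms steps,
  starting 12 pA below the holding current at −60 mV; neurons holding
  more than 50 pA are excluded).
- **Spike shape** — threshold from the first maximum of d²V/dt², amplitude
  (peak − threshold), full width at half maximum, and the fast
  afterhyperpolarization read 5 ms after the downward threshold
  re-crossing.
- **Passive membrane properties** — input resistance
  `R_m = 20 mV / (I(−50) − I(−70))` and its reciprocal conductance,
  resting potential (median over an injection-free epoch), and capacitance
  by charge integration `C = Q / ΔV` of a small test-step transient.
- **Voltage-gated currents** — sodium (stabilized − minimum within the
  transient window), fast potassium (maximum within 10 ms of the step) and
  slow potassium (end of the 400 ms step) amplitudes over −90…80 mV
  commands, assembled into I–V curves with optional leak subtraction.
- **Synaptic activity** — spontaneous EPSC detection (rate and mean
  amplitude) from voltage-clamp traces at −60 mV.
- **Network activity** — multi-electrode-array spike detection (band-pass
  10 Hz–2.5 kHz, ±5.5 SD threshold at 12.5 kHz), Poisson-surprise burst
  detection (surprise `S = −log10 P(N ≥ n | Poisson(λT))`), network-burst
  detection, and per-well longitudinal summaries averaged over replicate
  wells.
- **Morphometry** — SWC reconstructions: Sholl intersection profiles on
  concentric spheres at 10 µm increments, branch counts, maximal branch
  length, total dendritic length, soma size.
- **Statistics** — KS normality on standardized samples, Welch/Student t
  tests, one-way ANOVA with Tukey–Kramer multiple comparisons, two-way
  ANOVA (group × day) for longitudinal MEA data, and the
  `*/**/***/****` significance-star convention.
- **Gene sets** — intersection of differentially expressed genes with a
  GWAS-catalog snapshot weighted by study count, and three-way Venn
  partitions.

Because the original patch-clamp recordings of such studies are typically
not deposited, the package ships a first-class synthetic-data module: a
single-compartment conductance-based model neuron (transient m³h sodium,
n⁴ delayed-rectifier and A-type potassium currents, exponential-Euler
integration at 0.05 ms, 20 kHz sampling), Poisson EPSC trains with
bi-exponential kernels, bursty MEA spike trains, random branched SWC
morphologies and DEG tables. Every generator is a pure function of its
parameters and seed, and every analysis endpoint can therefore be tested
against known ground truth. See `vignette("twinephys-methods")` for the
model, its assumptions and the calibration choices.

## Worked example

```r
library(twinephys)

# 1. simulate one DG-granule-like model neuron (control-group preset)
params <- neuron_presets("dg_control", noise_sd = 5)

# 2. passive panel: two-point conductance, resting potential, capacitance
vc <- simulate_voltage_clamp(params, steps = c(-70, -50), step_duration = 200,
                             baseline = 50, tail = 0, seed = 1)
cap <- simulate_voltage_clamp(params, steps = -65, step_duration = 100,
                              baseline = 20, tail = 0, rs = 0.01, seed = 2)
pp <- passive_properties(
  steady_state_current(vc$sweeps[[1]]), steady_state_current(vc$sweeps[[2]]),
  rest_sweep = simulate_resting(params, seed = 3),
  cap_sweep = cap$sweeps[[1]], cap_dv = -5,
  holding_current = holding_current(params, -60))
round(pp[, 1:5], 3)
#>   input_resistance input_conductance capacitance resting_potential holding_current
#> 1            4.081             0.245      35.909           -52.951          -1.719

# 3. evoked firing and spike shape from the 20-step protocol
cc <- simulate_current_clamp(params, step_protocol(), seed = 4)
count_total_evoked_aps(cc)$total
#> [1] 39
wave <- first_evoked_ap(cc)
round(spike_shape(wave, spike_threshold(wave)), 2)
#>   threshold amplitude width  fahp peak_v spike_time
#> 1     -27.4     32.86  3.84 26.18   5.46       0.25

# 4. burst analysis of a synthetic MEA well
well <- generate_mea_trains(mea_gen_params(background_rate = 1.5,
                                           burst_rate = 3), seed = 5)
summarize_well(well$trains)
#>   well_id day n_spikes n_bursts n_network_bursts mean_firing_rate
#> 1      W1  NA     9497      245               11         1.978542
```

The recovered passive panel matches the preset's ground truth (leak
conductance 0.24 nS, leak reversal −52.8 mV, 35 pF) to a few percent; the
spike-shape row reads: threshold −27.4 mV, amplitude 32.9 mV, width
3.8 ms, fast AHP 26.2 mV — immature-like values typical of young
iPSC-derived neurons.

An end-to-end synthetic-cohort run (three groups with distinct true
parameters, all endpoints, statistics and a Markdown summary):

```r
run_end_to_end(run_config(seed = 1), "out/")
```

A command-line interface wrapping the same operations ships in
`inst/cli/twinephys` (subcommands: `synth`, `iclamp`, `vclamp`, `epsc`,
`mea`, `morpho`, `genesets`, `stats`, `run`; configs are JSON).

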
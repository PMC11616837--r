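# protospike

Spike-train analysis of proteinoid microspheres modulated by chondroitin
sulfate.

Proteinoid microspheres — hollow vesicles of thermally polymerized amino
acids — emit spontaneous spikes of electrical potential and have long
been discussed as proto-neurons. Chondroitin sulfate (CS), a sulfated
glycosaminoglycan of the neural extracellular matrix, modulates that
activity in a concentration-dependent way. `protospike` is an R package
for analyzing such recordings end-to-end, aimed at researchers working
on unconventional computing and bioelectrical signal analysis:

* **I/O and detection** — uniformly sampled voltage traces
  (`read_trace()`, `write_trace()`), robust threshold spike detection
  with a rolling-median baseline and MAD noise scale
  (`detect_spikes()`).
* **Spike statistics** — descriptive blocks with plugin moment ratios
  (`summarize()`, `skewness()`, `kurtosis()`), Gaussian KDE with Scott
  bandwidth `h = n^(-1/5) · 1.06 · min(σ̂, IQR/1.34)` (`kde()`), and
  maximum-likelihood gamma amplitude fits via Newton iteration on
  `log α − ψ(α) = log x̄ − mean(log x)` (`fit_gamma_mle()`).
* **Variability analysis** — Fano factor `FF(w) = Var(N_w)/E[N_w]` of
  window counts (`fano_factor()`), empirical and Monte-Carlo FF curves
  (`empirical_fano_curve()`, `theoretical_fano_curve()`), and the
  closed-form renewal asymptote `FF(∞) = CV²` of the ISI distribution
  (`ff_asymptote()`), against gamma, inverse-Gaussian,
  exponential-with-refractory, Markov-modulated-Poisson, alternating-
  Poisson and periodic references.
* **Neuronal signal comparison** — Izhikevich neuron
  `v̇ = 0.04v² + 5v + 140 − u + I`, `u̇ = a(bv − u)` with after-spike
  reset (`simulate_izhikevich()`), a configurable transduction stand-in
  for the proteinoid–CS network (`transduce()`), and a comparison
  battery with Welch t, Pearson r, two-sample Kolmogorov–Smirnov and
  cross-correlation lag (`analyze_pair()`).
* **Mechanism models** — radial Poisson–Boltzmann electrostatics with
  damped Newton iteration (`solve_pb_radial()`), Boltzmann channel
  gating `P = 1/(1 + exp(ΔG/k_BT))` (`channel_open_probability()`),
  multi-conductance membrane dynamics (`simulate_membrane()`), and a
  CS-dependent Hebbian rule `ẇᵢⱼ = η(CSᵢⱼ)·xᵢ·yⱼ` (`hebbian_step()`).
* **Energetics bookkeeping** — component sums and complexation deltas
  over molecular-mechanics optimization tables
  (`complexation_deltas()`).
* **Synthetic data** — per-condition presets carrying the published
  raw-potential, amplitude and interspike-interval statistics
  (`condition_presets()`), and generators for voltage recordings with
  spike ground truth (`generate_voltage_trace()`) and paired
  input/output signals (`generate_signal_pair()`). No raw multi-day
  recording is publicly deposited, so these make every stage testable.

## Worked example

Simulate a day of the 1.86 mg/ml condition at 1 Hz, detect spikes and
analyze the train:

```r
library(protospike)

rec    <- generate_voltage_trace("1.86", duration = 86400, seed = 42)
spikes <- detect_spikes(rec$trace)
report <- analyze_spike_train(spikes, condition = "1.86",
                              fano_window = 5000)
report
#> analysis_report (condition 1.86): 427 spikes over 86400 s
#>   firing rate 0.00494213 spikes/s, CV(ISI) 0.2853, FF(5000 s) 0.1101
#>   ...
report$amplitude_stats
#> summary_stats [mV]: n = 427
#>   mean 4.9868, sd 3.3953, median 4.2037, q1 2.4486, q3 6.787
#>   min 0.35934, max 24.347, peak-to-peak 23.987, rms 6.0307
#>   skewness 1.4474, kurtosis 6.7398
```

The detected train recovers the statistical structure the generator was
built around: a firing rate of ~0.005 spikes/s, amplitudes with mean
~5 mV and SD ~3.4 mV, and a regular (sub-Poisson) ISI pattern whose CV
of 0.285 implies a large-window Fano factor of

```r
ff_asymptote(gamma_renewal(shape = 1 / report$cv_isi^2, rate = 1))
#> [1] 0.08141107
```

well below the Poisson reference FF = 1. The gamma amplitude fit
(`report$gamma_fit`: shape 2.15, scale 2.32 mV) recovers the generating
moment-matched model (shape 2.25, scale 2.25 mV).

A thin command-line interface over the same functions is installed at
`system.file("cli", "protospike", package = "protospike")`, with
subcommands `simulate`, `detect`, `stats`, `fano`, `izhikevich`,
`report`, `mechanism` and `energetics`.

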
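---
title: "Methods: spike-train analysis of CS-modulated proteinoid microspheres"
author: "protospike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train analysis of CS-modulated proteinoid microspheres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protospike)
```

## The system and the analysis problem

Proteinoid microspheres are hollow vesicles of thermally polymerized amino
acids (here L-Glu:L-Asp:L-Phe). Impaled with electrodes they show
spontaneous, neuron-like spikes of electrical potential, which is why they
have long been discussed as proto-neurons. Chondroitin sulfate (CS), a
sulfated glycosaminoglycan of the neural extracellular matrix, modulates
this activity in a strongly concentration-dependent way: intermediate
concentrations (around 1.9 mg/ml) produce large, variable potentials,
while high concentrations (around 10 mg/ml) stabilize the signal.

`protospike` implements the full analysis chain for such recordings:
robust spike detection from slow 1 Hz voltage traces, descriptive and
model-based statistics of spike amplitudes and interspike intervals
(ISIs), Fano-factor variability analysis against theoretical point-process
references, an Izhikevich-neuron signal-transduction comparison, and the
biophysical mechanism models (electrostatics, gating, membrane dynamics,
plasticity) proposed for the CS-proteinoid interaction. Because no raw
multi-day recording is publicly deposited, the package ships a
synthetic-data generator that reproduces the *statistical structure* of
the recordings, so every downstream stage is testable end-to-end.

## Spike statistics

**Descriptive block.** `summarize()` reports mean, median, quartiles,
min/max, sample SD (n−1 denominator), peak-to-peak distance, RMS, and
moment-ratio skewness and kurtosis. Skewness and kurtosis are the
*plugin* estimators with population (n-denominator) central moments,

$$g_1 = \frac{m_3}{m_2^{3/2}}, \qquad g_2 = \frac{m_4}{m_2^{2}},$$

not the bias-corrected versions: the reported reference values for this
system (e.g. an amplitude kurtosis of 2.9488 described as close to
normal) follow the plugin convention, where a normal distribution has
kurtosis 3. Quartiles use linear interpolation (the inclusive method,
`quantile(type = 7)`); the source material does not state a method, so
this is a package choice.

**Gamma amplitude model.** Spike amplitudes are modelled as gamma
distributed. `fit_gamma_mle()` maximizes the likelihood by Newton
iteration on the profile equation

$$\log\alpha - \psi(\alpha) = \log\bar{x} - \overline{\log x},$$

initialized at the method-of-moments estimate, with the scale set by the
first-moment identity $b = \bar x/\hat\alpha$ (convergence
$|\Delta\alpha|/\alpha < 10^{-10}$ or 100 iterations). One deliberate
interpretation is baked in: the published amplitude fit for the
1.1 mg/ml condition reports a parameter pair (a = 32.27402,
b = 0.01904 mV) in which *b* is *labelled* a rate. A rate reading gives a
mean of a/b ≈ 1695 mV, wildly inconsistent with the reported mean of
0.61 mV, while the scale reading gives a·b = 0.6145 → 0.61 mV and
√a·b = 0.1082 → 0.11 mV, both matching after rounding. `protospike`
therefore stores and uses *b* as a **scale** parameter everywhere, and
the test suite asserts the two rounding identities.

**Kernel density estimates.** `kde()` evaluates the Gaussian-kernel
estimate with the Scott bandwidth
$h = n^{-1/5} \cdot 1.06 \cdot \min(\hat\sigma, \mathrm{IQR}/1.34)$.
Published bandwidths for the amplitude histograms of this system are
mutually inconsistent (0.3304 vs 0.67148 for the same concentration), so
the package always computes *h* from the rule above and treats printed
bandwidths as non-binding.

## Fano-factor analysis

The Fano factor of spike counts, $FF(w) = \mathrm{Var}(N_w)/E[N_w]$, is
computed over consecutive non-overlapping windows of length *w* (final
partial window discarded; sample variance with n−1). `fano_factor()`
flags, rather than silently drops, windows with zero mean count. For a
renewal process the large-window limit is the squared coefficient of
variation of the ISI distribution, which `ff_asymptote()` returns in
closed form (gamma: 1/k; inverse Gaussian: μ/λ; shifted exponential with
refractory period: CV² of the shifted ISI; periodic: 0). The reported
regime for the 1.86 mg/ml condition — ISI CV 0.22 and FF 0.05 — is
internally consistent through exactly this identity (0.22² = 0.0484 →
0.05).

A closed-form renewal expression for FF(w) circulates in the literature
this analysis follows, but as printed it fails the elementary self-check
FF ≡ 1 for a homogeneous Poisson process (it is dimensionally
inconsistent: an integral of a survival function, with units of time,
is subtracted from a dimensionless 1). `theoretical_fano_curve()`
therefore estimates reference curves by Monte Carlo — simulating long
realizations of the model and averaging the empirical window-count FF —
and the closed-form CV² asymptote is exposed separately. Honest behavior
was preferred over reproducing a typo. Window grids default to 30
log-spaced points covering 0.1–100 *mean ISIs* of the model rather than
an absolute 0.1–100 s range, because absolute ranges that small are
degenerate for trains whose mean ISI is ~200 s.

Two rate-switching (non-renewal) references are included with adopted
semantics, since their parameters are conventionally named but not
defined in the source material: the Markov-modulated Poisson process
switches between two exponential rates with probability *p* after each
interval, and the alternating Poisson process alternates
deterministically between rates *p* and *p·F*. Both degenerate to a
homogeneous Poisson process when the two rates coincide, which the test
suite checks via FF ≈ 1.

The Monte-Carlo FF estimator needs many windows per realization: with
fewer than ~100 windows the sample variance is visibly biased downward.
Default realization lengths therefore cover the largest window at least
40 times, and the convergence tests use 100+ windows.

## Izhikevich simulation and signal comparison

`simulate_izhikevich()` integrates the two-variable neuron model

$$\dot v = 0.04 v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with after-spike resetting (v ← c, u ← u + d at the 30 mV threshold) by
forward Euler — the canonical published scheme for this model — at
dt = 1 ms by default. The stored sample at a spike is clipped to 30 mV.
Subthreshold Euler convergence (halving dt changes trajectories by <1%)
holds at dt ≤ 0.25 ms and is tested there; at dt = 1 ms the scheme is
the conventional one but is first-order, so spike times shift slightly
with dt, as is well known for this model.

The comparison battery (`analyze_pair()`) reproduces the reported
analysis of paired "thalamocortical" input/output potentials: per-signal
summary statistics, the **Welch** (unequal-variance) t statistic — the
reported SDs differ by a factor of ~60, which rules out the pooled
form — Pearson correlation, a two-sample Kolmogorov–Smirnov test with
the asymptotic Kolmogorov-series p-value, and the cross-correlation lag.
The lag convention is that a *negative* lag means the output's pattern
precedes the input's: `cross_correlation_lag()` maximizes the Pearson
correlation of $(x_t, y_{t+\ell})$ over integer lags and is tested
exhaustively on constructed shifts. Signal length defaults to 100,000
samples at 1 ms: that sample size is the unique equal-n value consistent
with the reported t = −599.4801 given the reported means and SDs, and it
is adopted as the package default on that internal-consistency ground
(the computed t from the printed, rounded summary statistics is
−599.4739, within 0.01 of the printed value).

The mixture's effect on the signal is modelled by an explicit stand-in,
`transduction_model()`: gain, first-order low-pass, soft (tanh)
saturation, a time advance, offset, and Gaussian noise. Its defaults
produce output on the reported scale (output SD a few tenths of a mV
from an input SD of ~20 mV, output leading by 122 ms); nothing is fitted
to unavailable recordings, and the parameters are configuration, not
claims about mechanism.

## Mechanism models

**Electrostatics.** The surface interaction is described by a modified
Poisson–Boltzmann equation. The source material supplies no geometry,
boundary conditions, or parameter values, so `solve_pb_radial()`
implements the spherically symmetric reduction on $[a, R]$ with a
Neumann inner boundary ($-\epsilon\,\mathrm d\psi/\mathrm dr|_a =
\sigma$) and Dirichlet outer boundary ($\psi(R) = 0$); the defaults
(a = 1 µm, 0.1 M 1:1 electrolyte, T = 298 K, R = a + 30 Debye lengths)
are configuration. Numerically the problem is nondimensionalized
(x = r/λ_D, u = eψ/k_BT, in which the linearized source is exactly u),
discretized by second-order finite differences in conservative form, and
solved by damped Newton iteration (step halving until the residual norm
decreases). Iteration stops when the residual max-norm falls below
10⁻¹⁰ relative to the source scale or the Newton increment becomes
negligible (residual at its round-off floor). The solver is validated
against the linearized Debye–Hückel closed form in the small-charge
regime (within 1%) and against the unscreened finite-domain Coulomb
profile in the κ→0 limit.

**Gating and membrane.** `channel_open_probability()` is the two-state
Boltzmann form $P = 1/(1 + e^{\Delta G / k_B T})$. How the surface
potential shifts ΔG is not quantified in the proposed mechanism, so ΔG
is an input, not derived from ψ. `simulate_membrane()` integrates
$C_m \dot V = -\sum_i g_i (V - E_i) + I_{ext}$ with constant effective
conductances $g_i = \bar g_i P_{open,i}$; because the equation is then
linear, the exponential-Euler update is exact per step, and a pure
capacitor integrates to a linear ramp.

**Plasticity.** The CS-dependent Hebbian rule
$\dot w_{ij} = \eta(CS_{ij})\, x_i y_j$ leaves η abstract; the package
default is the saturating Michaelis form η₀·CS/(K + CS) (η₀ = 0.1 /s,
K = 2 mg/ml), chosen so that the learning rate is bounded and monotone
in CS — consistent with the observed stabilizing effect of high CS
concentrations. Activities are dimensionless; their normalization is a
user choice.

## The synthetic-data generator

`condition_presets()` carries, per condition (1.10, 1.86, 4.00,
10.20 mg/ml and water control), the reported raw-potential statistics
(in V), a gamma amplitude model (mV), and an ISI model:

* **1.10 mg/ml** — amplitudes gamma(32.27402, scale 0.01904 mV), the
  published fit. The ISI bulk is a gamma renewal model matched to the
  central interval statistics (mean 213 s, SD 57 s, consistent with the
  reported median 193 s and quartiles 175/249 s); the reported extreme
  right tail (maximum interval ~10⁵ s, skewness ~41) is reproduced by a
  mixture: with probability 0.005 an interval gains an exponential
  "silent gap" of mean 20,000 s. The mixture reproduces the heavy tail
  without claiming the unknown mechanism (whether those gaps are
  biological or instrumental is not stated anywhere).
* **1.86 mg/ml** — ISIs gamma renewal with mean 203.39 s and SD 52.22 s
  (the reported values); amplitudes gamma by moments from the reported
  mean 5.07 mV and SD 3.38 mV. The reported raw-potential range for
  this condition mixes units in the source; the preset stores the volt
  reading and flags the ambiguity in its `notes` field.
* The high-concentration and water presets carry raw statistics only
  (no spike activity is reported for them).

`generate_voltage_trace()` assembles baseline drift + spikes + sensor
noise at 1 Hz. The drift is a piecewise-linear interpolation of a coarse
random walk (knots every 6 h) standardized to the condition's reported
SD — **anchored to the 20-day acquisition length**: an excerpt of
length T carries drift SD scaled by √(T/T₂₀d), the Brownian scaling of
a segment of a longer random walk. Without this anchoring, compressing
a 1.2 V drift into a one-day excerpt would produce drift slopes
(~0.05 mV/s) that swamp millivolt spikes — a regime the real multi-day
recordings are not in. Spikes are symmetric triangular pulses of 3
samples (the narrowest representable pulse at 1 Hz; no waveform shape
is reported) carrying gamma amplitudes at model-generated times, and the
injected spikes are returned as ground truth. Sensor noise defaults to
0.05 mV, consistent with a 24-bit ADC measuring µV-scale variations.

What the generator does **not** emulate: electrode drift chemistry,
temperature coupling, DMSO solvent effects, or any waveform detail
beyond the template. Passing tests therefore demonstrate that the
analysis chain recovers the statistical structure it was built for —
they do not validate the detector against real electrode artifacts.

## Spike detection

The reported analyses give spike statistics but not the detection
procedure, so `detect_spikes()` is a package design: baseline = centered
rolling median over 600 s; noise scale = 1.4826 × MAD of the residual
(robust to the spikes themselves, which would inflate an SD estimate);
spikes = local maxima of the residual exceeding
max(5 × noise, 0.3 mV), separated by ≥ 60 s, with refractory conflicts
resolved by keeping the larger amplitude (deterministic). The 0.3 mV
floor sits below the smallest reported amplitude (0.38 mV); the 60 s
refractory period is short against the ~200 s ISIs. All reported
amplitude statistics are treated as detector-independent reference
values, not as detector acceptance tests, since whether the original
amplitudes were baseline-subtracted is unstated.

## Numerical and testing choices

* Degenerate inputs error early and explicitly: zero-variance samples
  for moment ratios, empty samples, non-uniform sampling, non-positive
  data for gamma fits. Single-value summaries set `sd = 0` and flag
  `degenerate`.
* Coincident event times (possible when very small ISIs underflow the
  cumulative sum's floating-point resolution) merge into one event.
* The KS p-value guards the asymptotic alternating series below
  λ = 0.05, where it is numerically meaningless and the p-value is 1 to
  well beyond double precision.
* All generators take explicit seeds and restore the caller's RNG state
  (`withr::with_seed`), so no function has hidden global-state effects.
* Test problem sizes are the package's choices for a desk-scale run:
  10⁵ draws for parameter-recovery and moment checks, 10⁶ draws for the
  skewness/kurtosis limits, day-length (86,400 s) synthetic recordings
  for detector recall/precision (≥ 0.95 at fixed seeds), and
  Monte-Carlo Fano curves with ≥ 400 windows per estimate. The whole
  suite runs in well under a minute.

## Known limitations

* The reported CV of 0.22 for the 1.86 mg/ml ISIs conflicts with the
  reported SD/mean = 52.22/203.39 = 0.257; both are carried as
  reference values, and the generator reproduces the mean/SD pair (a
  detected synthetic train therefore shows CV ≈ 0.26–0.29, not 0.22).
* How an FF of 0.05 was obtained with windows of 0.1–100 s on a train
  whose mean ISI is ~200 s is not explained (small windows drive the
  count FF toward 1); the package treats that FF as the large-window
  renewal limit implied by the CV, which is the only reading consistent
  with the identity FF∞ = CV².
* Whether the "output" signal of the transduction comparison is a
  second simulated population or a physical recording driven by the
  simulated input is not stated; the package models it as a
  parameterized transformation of the input.
* The mechanism models are not coupled quantitatively (ψ does not feed
  ΔG); they are simulation primitives for exploring the proposed
  framework, not a fitted multiphysics model.
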
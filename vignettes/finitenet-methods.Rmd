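---
title: "Simulating and analysing finite-size spiking networks with finitenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing finite-size spiking networks with finitenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

finitenet models small, isolated neuronal circuits — tens to hundreds of
cells, the scale of patterned cortical cultures — and implements the
analysis chain used on optical and electrical recordings of such circuits.
This vignette is the package's own account of the underlying methods: the
model equations and their parameters, the detection and inference
algorithms, the numerical choices made where the methods leave details
open, and the limitations a user should know about.

## 1. The network model

### Neuron dynamics

Each neuron follows the two-variable Izhikevich model, integrated by
forward Euler at `dt = 0.1` ms (10-kHz sampling):

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I_{syn} + I_{noise}, \qquad
  \dot u = a(bv - u),$$

with the discontinuous after-spike reset: when $v \ge v_{peak}$ the neuron
is reported as fired and $v \leftarrow c$, $u \leftarrow u + d$. The spike
cut-off defaults to `v_peak = 40` mV; the canonical 30-mV cut-off can be
set in `sim_config()`. Within a step the order of operations is: synaptic
pulses from the previous step arrive, the noise current advances, the
reset rule is checked (a reset holds for the remainder of that step), and
non-fired neurons take their Euler step. This ordering makes the
after-spike state exactly $(c, u+d)$, which the unit tests pin down.

Two firing phenotypes are drawn, in a 75/25 split matching the
excitatory/inhibitory composition of cortical cultures, each with an
independent heterogeneity draw $r \sim U(0,1)$:

* regular spiking (excitatory): $a=0.02$, $b=0.2$, $c=-65+15r^2$,
  $d=8-6r^2$;
* fast spiking (inhibitory): $a=0.02+0.08r$, $b=0.25-0.05r$, $c=-65$,
  $d=2$.

The model is not dimensionally consistent; currents and synaptic weights
are dimensionless model units whose numerical values are conventionally
labelled pA and mV.

### Background noise

Every neuron receives an independent Ornstein-Uhlenbeck current iterated
by the Euler-Maruyama recursion

$$I \leftarrow I - \frac{I}{\tau_I}\,dt + \frac{m_I}{\tau_I}\,dt +
  s_I\sqrt{2\,dt/\tau_I}\;\xi, \qquad \xi \sim N(0,1),$$

with defaults $\tau_I = 1$ ms, $m_I = 25$ pA, $s_I = 9$ pA. A subtlety
worth recording: the recursion is an AR(1) process whose *exact* stationary
standard deviation is $s_I\sqrt{2/(2 - dt/\tau_I)}$, i.e. about 2.6% above
the nominal $s_I$ at the default step ($\approx 9.234$ for $s_I = 9$). The
stationarity tests assert the recursion's own moments, not the continuum
limit. Each neuron owns a counter-seeded noise stream (xoshiro256++ with a
ziggurat normal sampler, implemented in the package's compiled code), so a
network with all-zero weights reproduces the union of independent
single-neuron runs spike for spike — a property the test suite checks
exactly.

### Connectivity

Directed scale-free graphs are generated by preferential attachment in the
efficient endpoint-list formulation: nodes are added one at a time, each
contributing `m` multigraph edges whose far endpoints are drawn uniformly
from the running list of edge endpoints (attachment probability
proportional to current degree; self-loops redrawn; node 1 contributes no
edges, so the multigraph has exactly `m(n-1)` edges). Multi-edges are then
collapsed and each surviving undirected edge is oriented in a uniformly
random direction — never both — giving a binary adjacency with
`a[i, j] = 1` meaning $j \to i$. Synaptic transmission is pulse-coupled:
when $j$ fires, `s[i, j]` is added to $v_i$ at the next integration step,
with no conduction delays. Weight magnitudes are Normal(10, 3.5), redrawn
while non-positive; columns of fast-spiking neurons are negated (a
Dale-like convention — the sign convention for inhibitory weights is a
package choice, as is random edge orientation; the generator underlying
the construction is undirected).

The edges-per-node parameter `m` has no principled a-priori value; the
package ships `m = 3`, calibrated once so that the least-squares exponent
of the log-log total-degree histogram averages about $-1.04$ at $n = 90$
and $-1.34$ at $n = 520$, the regime characteristic of these small
networks. The fit convention (`fit_power_law()`) is ordinary least squares
on the raw degree histogram with empty bins dropped — deliberately not a
maximum-likelihood tail estimator, because the shallow exponents of
90-520-node graphs live in the whole histogram including its sparse tail.
Total degree (in + out) is used.

### Initial state and guards

Membrane potentials start uniformly between each neuron's reset potential
$c$ and $-60$ mV (the interval is flipped when $c > -60$, which happens
for strongly heterogeneous excitatory neurons), $u = bv$, and the noise
current starts at its mean; this spreads initial phases so runs do not
begin artificially synchronized. The first 5 s are excluded from event
statistics. Integration aborts with an informative error if any $|v|$
exceeds 1000 mV rather than silently clipping.

## 2. Network events

`population_ifr()` bins all spikes (default 100 ms) and records per bin the
spike count and the fraction of neurons active. A network event
(`detect_network_events()`) is a maximal run of bins with active fraction
at least 0.2, runs closer than 200 ms merged; both knobs are exposed, and
`network_event_rate()` excludes events starting in the 5-s transient.
`rate_size_regression()` is ordinary least squares of event rate on total
cell count; when simulated neuron counts are placed on a total-cell axis
the 2:1 neuron/glia convention (`total_cells()`, a factor 1.5) applies.

**Limitation — the default drive regime.** Under the default noise
parameters the model has no quiescent state: a regular-spiking neuron has
no resting equilibrium for any constant input above ~4 model units, so at
$m_I = 25$ every neuron fires tonically (tens of Hz in isolation, higher
in a coupled network, as the simulation tests show), and with ~10-unit
pulse weights the recurrent excitation of a 75%-excitatory graph sustains
network-wide firing even for much weaker drive. In this regime the
fraction-active criterion saturates — every bin exceeds any threshold — so
the detector reports a single recording-long event and the event-rate
regression across network sizes is degenerate (zero rates after transient
exclusion, slope 0, correlation reported as 0 with a degeneracy flag). The
acceptance script computes and reports exactly this. Sparse, well-separated
network bursts at rates of order 0.01-0.1 Hz would require a drive far
below the default parameterization, or far weaker coupling; the detector
itself is exercised against constructed rasters with known volley
structure, where its behaviour is exact.

## 3. Calcium-imaging event detection

The chain in `detect_calcium_events()` follows the standard processing of
59-Hz somatic fluorescence recordings:

1. **Differencing + integration** (`process_traces()`): first differences
   summed over sliding 1-s windows (59 frames). By telescoping,
   $I_{j'} = F_{j'+59} - F_{j'}$, so the construction is exactly invariant
   to baseline shifts.
2. **Noise SD** (`estimate_noise_sigma()`): a zero-centred Gaussian fitted
   by least squares to the histogram of the signal's noise core, with a
   flat pedestal term absorbing event contamination. The core is located
   from the lower quartile of per-segment SDs (quiet stretches dominate
   that quartile), and bins use the Freedman-Diaconis width. Every step is
   scale-equivariant, so detection is invariant to a positive gain.
   Accuracy contracts (within 5% on pure noise, 10% under 1% outliers) are
   enforced by Monte-Carlo tests.
3. **Thresholding** (`detect_events()`): maximal runs of at least 5
   consecutive samples strictly above $3\sigma$. Because neighbouring
   processed samples share 58 of their 59 frames, one transient can
   flicker across the threshold; runs separated by fewer than 10
   subthreshold samples (~0.17 s) are merged before the 5-sample rule.
4. **Onset/offset** (`fit_onset_offset()`): a four-parameter sigmoid
   $F(t) = base + A/(1+e^{-(t-t_0)/\tau})$ least-squares fitted to the
   rising phase (candidate window padded 0.5 s before, ended at the first
   sample reaching 90% of the excursion — the global maximum can sit deep
   in the noisy decay). Onset and offset are the 5% and 95% plateau
   crossings, $t_0 \mp \tau\ln 19$. The fit runs on a unit-normalized copy
   of the data (gain- and offset-independent optimization path), from a
   small multi-start grid over $(t_0, \tau)$, with $\tau$ capped at 0.5 s
   — a slower "rise" is not a calcium transient at this frame rate.
   Non-convergent fits drop the event and are counted in the QC attribute.
   The literal 95%-of-plateau reading places the offset near the transient
   peak, not at the end of its decay; that reading is the default.

**Peak SNR convention.** The detector operates on the processed signal, so
the package defines peak SNR in the detection domain: the processed-signal
event peak (equal to the transient amplitude for the default kernel)
divided by the processed-noise SD ($\sqrt2$ times the frame-noise SD,
since differencing over a 1-s window doubles the noise variance). Fixtures
at detection-domain SNR 5 are the round-trip reference conditions:
precision and recall at least 0.9 with median onset error under 2 frames.

**Resolution limit.** Two events closer than the 1-s integration window
produce one fused suprathreshold excursion and cannot be separated by this
method; synthetic fixtures therefore keep a 2-s dead time between events.

## 4. Directed functional connectivity

For each unordered neuron pair $(j,k)$, every onset of $j$ contributes the
signed lag to the nearest onset of $k$ within ±500 ms
(`pairwise_lags()`; the one-lag-per-onset nearest-neighbour rule is a
package choice). A directed edge is created only when the lag distribution
rejects *both* null shapes at the 5% level (`test_direction()`): a
one-sample t-test against zero mean (excluding synchronous co-activation)
and a Kolmogorov-Smirnov test against uniformity on the window (excluding
unrelated activity). The edge direction follows the sign of the mean lag,
so each pair yields at most one edge, and time-reversing the recording
reverses every edge — asserted exactly in the tests. Pairs with fewer than
5 lags are not tested (minimum-evidence guard). No multiple-testing
correction is applied by default; a Benjamini-Hochberg mode is available.
Degenerate, exactly-constant lag sets are decided by their mean directly,
since the t statistic is undefined there.

Lagged cross-correlation (`cross_correlation()`) of binned onset
indicators is normalized by the full series length and the population SDs,
so autocorrelation at zero lag equals 1 and $|CC| \le 1$; the printed-sum
form without that normalization would scale with the recording length.
The sign convention is "leads-positive": $\tau_{max} > 0$ means the first
series precedes the second. `summarize_correlations()` averages
$CC^{max}$ and $\tau^{max}$ over each neuron's positively correlated
partners, the standard per-neuron summary whose scatter separates
early-recruited cells (positive mean lag) from followers.

## 5. Synthetic ground truth

`spikes_to_fluorescence()` renders onsets as double-exponential transients
(rise 0.05 s, decay 1 s — OGB-1-like at 59 Hz), linearly superposed on a
constant baseline with i.i.d. Gaussian frame noise; an optional linear
drift stresses shift-robustness. What it does *not* emulate: photobleaching
curves, movement artifacts, indicator saturation under burst firing, or
correlated noise across neurons — passing round-trip tests therefore
demonstrates algorithmic correctness, not field robustness on raw movies.
`make_chain_population()` generates repeated feed-forward sweeps (default
5 stages, 120-ms delay, 10-ms Gaussian jitter, 50 repetitions, one sweep
every 10 s) with a known chain edge set; note that transitive edges
($1 \to 3$ and so on) are genuinely present in such data and the inference
is expected to report them. `make_poisson_population()` is the matched
null; `synthetic_ephys_trace()` embeds 1-ms biphasic spike templates in
white noise at a requested peak SNR.

## 6. Evoked responses and wavelet spike detection

`psth()` computes per-channel and pooled peri-stimulus histograms, default
4-ms bins over (−100, +400) ms — 125 bins, counts conserved exactly.
`evoked_count()` counts spikes in the 200-ms window after each pulse of a
paired-pulse protocol (windows truncated with a warning if they would
overlap the next pulse) and reports means, SEMs and a Mann-Whitney
rank-sum comparison between the two pulses; the same rank-sum machinery
applies to before/after condition contrasts.

`swt_detect()` is the software reference of a hardware spike detector: an
undecimated (à trous) Haar decomposition with symmetric boundary padding,
thresholding the level-6 detail against $k$ times the block-wise (1-s)
standard deviation of the level-1 detail. Block-wise rather than running
SDs match a hardware-friendly design and adapt to slow noise changes.
Threshold crossings within one filter support (64 samples) are one event,
timed at the largest coefficient plus half the support; a 1-ms refractory
merge follows. The multiplier `k = 5.5` was calibrated on the synthetic
benchmark: across the grid $k \in [4, 7]$ at 25 kHz and peak SNR 8, recall
stays 1 and false positives 0 on the plateau $k \in [5, 7]$ (at $k = 4$
the white-noise tail of a quarter-million-sample trace yields tens of
false events per minute), and 5.5 sits mid-plateau. The optional 16-bit
fixed-point mode rounds the input and every coefficient to a signed 16-bit
grid scaled so level-6 coefficients cannot overflow, and agrees with the
floating path on ≥99% of detections at benchmark SNR. MUA (800 Hz-3 kHz)
and LFP (1-300 Hz) zero-phase Butterworth filters are provided for
preprocessing; the LFP band is a low-pass/high-pass cascade because a
single band-pass with a 1-Hz edge is numerically ill-conditioned at
extracellular sampling rates.

## 7. Problem sizes used by the checks

The bundled tests run on deliberately small problems: single-neuron and
few-neuron integrations for the exact dynamics checks, 90-520-node graphs
for topology statistics (12-50 seeds), 2-5-s networks of 20-30 neurons for
determinism and decoupling, 40-120-s synthetic recordings of 3-15 neurons
for the calcium round trips, 600-s onset series of 5-10 neurons for
connectivity, and 10-s 25-kHz traces for the wavelet benchmark. The
acceptance script simulates the seven reference sizes (90-520 neurons) for
300 s each over three seed blocks — the regression over network sizes is
reported from exactly those runs — and averages degree exponents over 20
seeded generations per size.

## 8. Known limitations

* The default-drive tonic regime described in section 2: the rate-size
  regression under default noise parameters is degenerate, and the package
  reports it as computed rather than retuning the stated conditions.
* The calcium offset estimate follows the literal 95%-of-plateau rule and
  thus marks the end of the rise, not of the decay.
* The connectivity gate inherits the usual caveats of pairwise inference:
  transitive and common-input edges are reported as connections, and no
  multiple-testing correction is applied by default.
* Fixed-point agreement is assessed at benchmark SNR; heavily clipped or
  extremely low-amplitude signals quantize to a coarser effective grid.
* The simulator applies no conduction delays and no synaptic dynamics
  (instantaneous voltage pulses only), and spike times are reported on the
  integration grid (0.1 ms).
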
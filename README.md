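# finitenet

Simulation and analysis of **finite-size spiking neuronal networks** — the
isolated circuits of tens to hundreds of neurons obtained when cortical
cells are cultured on confined adhesive islands. Such circuits generate
spontaneous network-wide synchronizations whose statistics depend on
population size, and they are probed experimentally with calcium imaging
and extracellular electrophysiology. `finitenet` provides both sides of
that workflow for computational work:

* **a network simulator** — heterogeneous Izhikevich neurons (75%
  regular-spiking excitatory, 25% fast-spiking inhibitory), each driven by
  an independent Ornstein–Uhlenbeck noise current, pulse-coupled on a
  directed scale-free graph built by preferential attachment with
  Normal(10, 3.5) synaptic weights;
* **the analysis chain** used on recordings of such circuits — calcium
  event detection (1-s sliding-window differencing, zero-centred Gaussian
  noise fit, 3σ/5-point thresholding, four-parameter sigmoid onset/offset
  at 5%/95% of the plateau), directed functional-connectivity inference
  (nearest-onset lag histograms gated by a t-test *and* a KS test at 5%),
  normalized lagged cross-correlation summaries, population-event rate
  statistics, peri-stimulus time histograms and evoked-spike counts, and a
  stationary-wavelet (Haar, level-6 detail) spike detector with an
  optional 16-bit fixed-point mode;
* **synthetic ground-truth generators** so that every analysis stage is
  testable without any experimental data.

The neuron model is

dv/dt = 0.04 v² + 5v + 140 − u + I_syn + I_noise,  du/dt = a(bv − u),

with reset v ← c, u ← u + d at the spike cut-off, and noise
dI = −(I/τ_I) dt + (m_I/τ_I) dt + s_I √(2 dt/τ_I) ξ (defaults τ_I = 1 ms,
m_I = 25, s_I = 9). See the methods vignette
(`vignettes/finitenet-methods.Rmd`) for every algorithmic and numerical
choice, including the calibrated defaults (edges-per-node m = 3, wavelet
threshold k = 5.5) and known limitations.

## Worked example

```r
library(finitenet)

# scale-free topology and its degree-distribution exponent
g <- scale_free_graph(520, m = 3, seed = 1)
print(g)
#> <connectivity_graph> 520 nodes, 1524 directed edges (m = 3)
print(fit_power_law(degree_total(g)))
#> <power_law_fit> gamma = -1.414 (r^2 = 0.683, degrees 2..80)

# a 30-neuron network, 20 s of activity
cfg <- sim_config(30, duration = 20000, seed = 1)
raster <- run_simulation(cfg)
print(raster)
#> <spike_raster> 84544 spikes, 30 neurons, 20.0 s
#>   mean rate 140.91 Hz/neuron

# synthetic calcium recording with known onsets, then detection
truth <- make_poisson_population(5, 0.08, 90, min_gap = 2, seed = 4)
syn <- spikes_to_fluorescence(truth,
        params = calcium_kernel_params(noise_sd = 0.1), seed = 8)
events <- detect_calcium_events(syn$recording)
head(events, 3)
#>   neuron      onset     offset
#> 1      1  0.7859754  0.9767365
#> 2      1 23.4005726 23.5356881
#> 3      1 26.4406912 26.5762579

# directed connectivity from a ground-truthed feed-forward chain
chain <- make_chain_population(n_stages = 5, delay_ms = 120, seed = 2)
fg <- build_functional_graph(chain$onsets)
fg$edges[fg$edges$to - fg$edges$from == 1, c("from", "to", "mean_lag")]
#>      from to  mean_lag
#> row     1  2 0.1206914
#> row2    2  3 0.1180033
#> row5    3  4 0.1230910
#> row9    4  5 0.1170131

# wavelet spike detection on a synthetic extracellular trace (peak SNR 8)
trace <- synthetic_ephys_trace(10, fs = 25000, snr = 8, seed = 3)
det <- swt_detect(trace$signal, trace$fs)
sprintf("true spikes %d, detected %d", length(trace$spike_times), length(det))
#> "true spikes 50, detected 50"
```

What the numbers mean: the 520-node graph's log–log degree histogram has a
shallow power-law slope (here −1.41 for one draw; the across-seed means
deepen from ≈ −1.0 at 90 nodes to ≈ −1.37 at 520). Under the default
noise drive the simulated network fires tonically (~140 Hz/neuron — see
the vignette's discussion of this regime). The calcium detector returns
per-neuron event onsets/offsets in seconds; every chain link (1→2 … 4→5)
is recovered with its ~120-ms propagation lag; the wavelet detector finds
all 50 embedded spikes with no false positives.

A command-line wrapper for the file-based workflows (simulate, graph,
events, analyze-calcium, connectivity, synth-chain, swt) is installed at
`inst/cli/finitenet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/finitenet.R", package="finitenet"))')" \
  graph --n 520 --m 3 --seed 1 --out graph.tsv --fit-gamma
```

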
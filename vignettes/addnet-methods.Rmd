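---
title: "Methods: coupled neural masses and activity-dependent degeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled neural masses and activity-dependent degeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

## One neural mass

Each cortical region is a lumped pair of interacting populations — one
excitatory, one inhibitory — of the classical alpha-rhythm type. The state
of each population is an average membrane potential (`Ve`, `Vi`, in mV) and
a pulse density (`E`, `I`, in spikes/s). Potentials convert to pulse
densities through instantaneous logistic sigmoids

    S(v) = max_rate / (1 + exp(-steepness * (v - threshold)))

and pulse densities convert back to potentials through synaptic impulse
responses of difference-of-exponentials form

    h(t) = gain * (exp(-decay * t) - exp(-rise * t)),   rise > decay.

The wiring inside a mass is the standard negative-feedback loop: the
excitatory population receives the thalamic drive `Pt * P(t)` plus any
cortical input through the excitatory kernel, and the inhibitory pulse
density through the inhibitory kernel with weight `c2` (subtractive); the
inhibitory population receives the excitatory pulse density through the
excitatory kernel with weight `c1`. `P(t)` is Gaussian pulse-density noise
(mean `thalamic_mean`, sd `thalamic_sd`), truncated at zero.

Numerically, each kernel is realized as two first-order linear stages
advanced by their exact zero-order-hold discretization
(`y[n+1] = e^(-a dt) y[n] + (1 - e^(-a dt))/a * u[n]`), so the linear part
of the update is exact for piecewise-constant input and the integration is
reproducible sample for sample; there is no adaptive stepping. The sample
rate is 500 Hz, twice the 0–70 Hz analysis window with margin, and one
sample (2 ms) is also the inter-mass conduction delay.

## The network

Regions are wired by a symmetric binary adjacency matrix. Coupling, where
present, is always reciprocal and excitatory: mass *i* receives
`gain * sum_j S_ij * E_j(t - delay)` into its excitatory kernel. At baseline
every existing connection has the same strength `S` (1.0–2.0 in the
experiments), so the only difference between regions is their degree. The
packaged fixture provides the 78-region cortical degree sequence (degree sum
658, mean 8.44; the six highest-degree bins define hubs = the top 13
regions). `generate_degree_matched()` samples a simple graph with exactly
this degree sequence (Viger–Latapy sampling plus degree-preserving edge
swaps), which is the interchangeable stand-in for a tractography-derived
matrix: all analyses here are hub-versus-non-hub contrasts, which survive
degree-preserving rewiring.

## Parameter defaults and calibration

The model family fixes the kernel shapes and loop structure; the constants
are not uniquely determined by any published table, so the package treats
them as configuration with calibrated defaults. The calibration targets
were chosen once, at the level of emergent behaviour:

1. an *uncoupled* mass produces an alpha-band (8–13 Hz) spectral peak under
   noisy thalamic drive, with spike density near 400 spikes/s;
2. on a degree-matched 78-region connectome at `S = 1.5`, total broadband
   power correlates strongly and positively with structural degree while
   mean spike density correlates only weakly (the non-hub trend is flat to
   slightly negative, with a positive hub offset);
3. raising `S` to 2.0 makes the spike-density correlation strongly
   positive;
4. the alpha peak frequency of high-degree regions is slightly lower than
   that of low-degree regions.

The defaults that realize this regime (all overridable via `nmm_params()`):

| constant | value | meaning |
|---|---|---|
| `he_decay`, `he_rise` | 55, 605 /s | excitatory kernel rates (peak ~4.4 ms) |
| `hi_decay`, `hi_rise` | 20, 45 /s | inhibitory kernel rates (slower, ~32 ms peak) |
| `he_gain` | 0.00933 mV | scales all excitatory synaptic input |
| `hi_gain` | 22 mV | inhibitory kernel amplitude |
| `c1` | 84.15 | excitatory -> inhibitory coupling |
| `c2` | 0.06 | inhibitory -> excitatory coupling |
| `sigmoid_e` | (922, 5.25 mV, 0.93 /mV) | excitatory rate ceiling, threshold, slope |
| `sigmoid_i` | (450, 6.90 mV, 1.4 /mV) | inhibitory rate ceiling, threshold, slope |
| `thalamic_mean`, `thalamic_sd` | 64800, 9000 spikes/s | external drive |

Two features of this operating point deserve comment, because they carry
the S-dependence of the spike-density correlation. First, the
excitatory–inhibitory loop acts as a resonator tuned just below instability
near 10 Hz: near-resonant thalamic fluctuations are amplified severalfold
while the loop's DC gain *suppresses* slow mean shifts. Cortical input from
coupled neighbours therefore raises a region's fluctuation power (hence
total power) much more efficiently than its mean firing rate — which is why
degree predicts power far better than spike density at moderate coupling.
Second, the inhibitory population operates high on its sigmoid with a
relatively low ceiling (450 spikes/s): at moderate drive its mean rises
with fluctuation amplitude (net extra inhibition, flattening the
spike-degree relation), but as coupling drives hubs harder the inhibitory
rate saturates, the feedback stops growing, and mean excitatory rates climb
— reproducing the strong spike-density–degree correlation at `S = 2.0`.
These are model-level mechanisms, not fitted curves; the same constants are
used for every experiment in the package.

The thalamic mean is large in these units because `he_gain` is small: only
their product (about 10 mV of standing depolarization) matters. Units of
pulse density are nominal spikes/s of a lumped population and should be
read as arbitrary-but-consistent across the package.

# Degeneration

At each degeneration update, region *i*'s recent peak spike density
`maxAct_i` (maximum of the last 20 samples of `E_i`) is mapped to

    loss_i = exp(-rho * maxAct_i)  in (0, 1],

and `c1_i`, `c2_i`, `pt_i` and all couplings incident to *i* are multiplied
by `loss_i` (edge (i, j) thus shrinks by `loss_i * loss_j`, preserving
symmetry). An alternative linear form `max(0, 1 - rho * maxAct)` is
available behind the `loss_form` switch; both satisfy the defining
constraints (1 at zero activity, monotone decreasing, bounded by 1), and
results state which form was used. The RD control discards `maxAct` and
applies one common factor to every region — by default the loss evaluated
at the region-mean `maxAct`, so total damage tracks the matched ADD run.

Degeneration time is abstract: one update is applied per analysis epoch,
not per 2 ms sample, since nothing in the modeled biology fixes the real
duration of a degenerative step. The default loss rate `rho = 1.5e-5`
(per update per spikes/s) was calibrated once so that a 78-region run at
`S = 1.5` passes through its transient rise and collapses (network mean
spike density falls below baseline) within roughly 100 updates, which keeps
trajectories short enough to simulate ensembles; `rho` rescales the time
axis, not the ordering of effects.

The characteristic ADD phenomenology — hubs losing normalized node strength
fastest; an early *rise* of spike density and of band-limited functional
connectivity (disinhibition: `c2` and the inhibitory drive degrade too)
followed by collapse — is emergent, not enforced. One caveat: in this
parameterization the *timing* of each region's spike-density peak is locked
to the network-wide trajectory. The recurrent coupling entrains all regions
to the global disinhibition transient and its collapse, so although hubs
are damaged measurably faster (their node strength falls significantly
faster, as the tests assert), their spike-density peak does not arrive detectably earlier than
the non-hubs' — the per-region damage schedules are homogenized by the
shared mean field. A model variant with a weaker disinhibition transient,
or weaker recurrent entrainment, would be needed to separate per-region
peak times; see the limitations section.

# Analysis choices

* **Spectra.** One-sided PSDs from mean-removed FFTs. The raw periodogram
  is exactly Parseval-consistent and is used where that property is
  asserted; band summaries default to a Hann window (power-normalized).
  Bands are half-open intervals (delta 0.5–4, theta 4–8, lower alpha 8–10,
  higher alpha 10–13, beta 13–30, gamma 30–45 Hz); total power integrates
  0–70 Hz, wider than the band union, as a deliberate convention. The
  alpha peak is the PSD argmax within 4–13 Hz — the window reaches below
  8 Hz so that oscillatory slowing remains visible.
* **Synchronization likelihood.** Time-delay embedding with per-band
  auto-tuning: `lag = fs/(3*high)`, `m = 3*(high/low) + 1` capped at 10
  (broadband ratios would otherwise demand impractical dimensions),
  Theiler window `w1 = 2*lag*(m-1)`, outer window `w2 = w1 + 10/p_ref`,
  `p_ref = 0.01`. Critical distances are found by exact rank selection
  under the Chebyshev metric, not iterative threshold search. The estimator
  is the ratio of summed joint recurrences to summed single-channel
  recurrences, which is symmetric by construction, equals 1 for identical
  signals, and floors at about `p_ref` for independent ones. Matrices are
  computed by sharing each channel's recurrence structure across all pairs.
* **Graph metrics.** Functional matrices are thresholded to the strongest
  `floor(8 N / 2)` edges (mean degree 8, matching the structural network's
  density convention), with lexicographic tie-breaks for determinism.
  Clustering is the mean per-node Watts–Strogatz coefficient with
  degree-<2 nodes contributing zero; path length averages over connected
  pairs only, with the disconnected fraction reported (avoids infinities
  while flagging fragmentation). Gamma and lambda divide by means over 20
  degree-preserving double-edge-swap surrogates. Newman's Q is maximized by
  simulated annealing (geometric cooling calibrated to the initial uphill
  move scale, neighbour-biased single-node moves plus merge proposals, 5
  restarts, seeded); on graphs small enough for exhaustive search the
  annealer attains the exact optimum, and it is tested never to fall below
  greedy agglomeration.
* **Statistics.** Ensembles of 20 independent runs (per-run seeds derived
  from one master seed; each region has its own noise stream, so the
  `S = 0` network decouples bit-exactly into single-mass runs).
  Correlations are Pearson product-moment on run-averaged per-region
  values; hub contrasts use Welch's unequal-variance t test (the
  comparison's p-values in the literature are reported without a named
  test; Welch is the conservative default). Binned displays use six
  ascending-degree bins of 13 regions; hubs are the top bin, with ties
  broken by a stable (degree, label) sort.

## Problem sizes

Default experiment sizes were chosen to keep a full analysis on one CPU
comfortable: 8.2 s epochs (4096 samples) for baseline ensembles — giving
0.12 Hz spectral resolution, ample for 0.5 Hz band edges — and 2048–4096
sample epochs with about 60 updates for degeneration trajectories, where
the SL and graph metrics are evaluated at a handful of sampled updates
rather than every update (the annealed modularity and the SL matrix
dominate the cost). All sizes are arguments.

# What the synthetic generator does and does not emulate

The degree-matched generator reproduces exactly one structural property:
the empirical degree sequence. It does not reproduce spatial embedding,
hemispheric symmetry, community structure, or distance-dependent delays of
a real connectome (a single global 2 ms delay is used). Consequently,
passing tests demonstrate that the hub phenomenology follows from the
*degree distribution plus dynamics*, not that any particular anatomical
pathway matters; analyses that depend on the identity of individual edges
(e.g. which specific pair of regions synchronizes most) are outside what
this generator can support. Region labels attached to the synthetic graph
inherit only the degree of the same-named empirical region.

# Degenerate inputs and numerical edges

Non-finite states abort the simulation with the offending region and
sample; constant traces make SL undefined and are flagged rather than
returned as numbers; thresholding a matrix with fewer nonzero weights than
the edge budget errors by default (or warns and keeps all edges);
`rise = decay` kernels are rejected as degenerate. The annealer's
temperature floor and stall patience bound its runtime on pathological
graphs. Band filters pad their design edges by 10% of the bandwidth so
content exactly at a band edge is not half-attenuated by the two-pass
(zero-phase) Butterworth; the delta band's lower design edge is clamped at
0.1 Hz for filter stability.

# Known limitations

* The activity–damage link is phenomenological; no amyloid kinetics,
  repair, or compensation are modeled, and degeneration is monotone.
* Thalamo-cortical circuitry beyond one lumped noisy drive is out of scope.
* The exponential loss form and the 20-sample buffer length are modeling
  choices; both are exposed as configuration.
* Absolute power, rate, and SL values are in arbitrary units; only
  contrasts (hub vs non-hub, across S, across time) are meaningful.
* With one global delay and identical masses, all regional heterogeneity
  originates in the wiring; real cortices add local parameter variation
  that would blur the degree–activity relation further.
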
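---
title: "Diverse Hebbian learning rates in recurrent rate networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diverse Hebbian learning rates in recurrent rate networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plasticnet)
```

## The model

`plasticnet` simulates recurrent networks of rate neurons in which every
neuron carries its own Hebbian learning rate, and analyses the consequence
this diversity has for population coupling — the correlation of a neuron's
activity with the mean activity of the rest of the population — and for the
stability of stimulus selectivity.

Each neuron has a state variable $y_i$ evolving as

$$\tau_m \frac{dy_i}{dt} = -y_i + \sum_j W_{ij}\, g(y_j) + H_i(t),$$

with the saturating transfer function

$$g(x) = \begin{cases} 0 & x < 0\\ (r_{max}-r_0)\tanh\!\big(x/(r_{max}-r_0)\big) & x \ge 0,\end{cases}$$

so transmitted rates lie in $[0, r_{max}-r_0)$. External input $H_i$ is the
sum of a stimulus-specific feedforward drive and an independent
Ornstein–Uhlenbeck (OU) noise process per excitatory neuron (mean 0,
stationary sd $\sigma_{OU}$, correlation time $\tau_{OU}$), advanced by its
exact discretization so its statistics do not depend on the step size.

Excitatory-to-excitatory weights follow Hebbian plasticity with homeostatic
synaptic scaling,

$$\frac{dW^{EE}_{ij}}{dt} = \alpha_i\, y_i y_j - \zeta\Big(\sum_k W^{EE}_{ik} - W^{total}_{EE}\Big),$$

where the learning rate $\alpha_i$ belongs to the *postsynaptic* neuron —
the central model ingredient: neurons with large $\alpha$ have more plastic
input synapses. The scaling term pulls each neuron's summed excitatory input
toward a fixed target, inducing competition among presynaptic partners.
Inhibitory-to-excitatory weights follow a homeostatic rule,
$d|W^{IE}_{ij}|/dt = \eta\, y_j (y_i - y_0)$: inhibition onto a neuron grows
while it fires above the target rate $y_0$. Excitatory weights are clipped
to $[0, w_{max}]$, inhibitory magnitudes to $[0, w_{max\text{-}inh}]$; no
autapses, no I-to-I coupling; E-to-I weights are static.

Defaults (see `network_config()`): $H_{stim}=8$, $r_0=1$, $r_{max}=20$,
$y_0=5$ Hz, $\alpha_s=2\times10^{-6}$ Hz, $\zeta=2\times10^{-4}$ Hz,
$\eta=10^{-5}$ Hz, $w_{max}=0.042$, $w_{max\text{-}inh}=50$,
$W^{total}_{EE}=0.75$, $\sigma_{OU}=1$, $\tau_{OU}=10$ ms,
$W^{EE}_{init}=0.5\,w_{max}$, $W^{IE}_{init}=0.2$. Learning rates are in Hz
and internal time in ms, so weight updates scale with $dt/1000$.

## Numerical choices that required a decision

Several constants of the dynamical system are not fixed by the model
definition; the package's choices, and why:

**The activity variable consumed by the plasticity rules.** The update
equations are written in terms of the state $y$. Feeding the saturating
transfer output $g(y)$ into them instead caps the homeostatic error at
$(r_{max}-r_0)-y_0 = 14$ Hz; with the slow inhibitory rate
$\eta = 10^{-5}$ Hz the inhibitory loop then cannot track the Hebbian
growth, and both network models degenerate (every E-to-E weight pinned at
$w_{max}$, rates saturated). The package therefore evaluates the plasticity
rules on the rectified state $\max(y, 0)$ — non-negative, hence Hebbian in
the usual sense, but preserving the full amplitude of the homeostatic error
signal. The transfer-output variant remains available via
`network_config(plasticity_activity = "transfer")`.

**State time constant $\tau_m$.** The rate equation defines a relaxation
timescale but no value. The small fully connected model uses
$\tau_m = 10$ ms (rates equilibrate well within each 500 ms stimulus
epoch). The 250-neuron receptive-field model runs in a noise-dominated
regime ($\sigma_{OU}=5$); there the fully expressed 10-ms OU noise drives
the high-$\alpha$ rows collectively supercritical, after which the
inhibitory controller — whose gain is proportional to presynaptic activity
— winds up to its bound during the saturated episode and the over-inhibited
network cannot recover (the controller is silent when the network is
silent). The receptive-field experiments therefore use $\tau_m = 200$ ms,
which low-passes the noise enough for the 500-s protocol to remain stable
while staying in the noise-dominated regime. Both values are configurable.

**Static E-to-I weights.** Not part of the published constant set. The
default $7.2/N_E$ (0.15 at $N_E=48$) makes the global inhibitory neuron's
summed drive — and with it the gain of the homeostatic loop —
size-invariant. It was chosen from the fully connected protocol's
qualitative behaviour: at this value slow neurons end more specific and
more stable than fast neurons and fast neurons couple more strongly to the
population, robustly across seeds; much smaller values leave the controller
too slow for the 500-s horizon, much larger ones ratchet inhibition to its
bound.

**Initial E-to-E weights of the receptive-field network.** The published
initialisation $0.5\,w_{max}$ belongs to the 48-neuron model; at $N_E=250$
it would start each neuron's summed input at $\sim$7× the scaling target
and saturate the network immediately. Receptive-field networks start
uniform connectivity exactly at the target, $W^{total}_{EE}/(N_E-1)$.

**Integration.** Forward Euler at $dt = 1$ ms (constraint
$dt \le \tau_m/2$ enforced), weights updated every step in the order:
integrate rates, E-to-E update, I-to-E update, clip. The compiled core is
verified against a scalar R reference step to machine precision and against
an adaptive-step ODE solver on small fixed-weight networks: agreement is
within $10^{-3}$ absolute at small drive amplitudes, and the error scales
first-order in $dt$ (about 2% of trajectory amplitude at $dt=\tau_m/10$
during transients).

## Stimuli

The fully connected model uses discrete stimuli: neuron $i$ receives
$H_{stim}$ when the shown stimulus matches its preference (Kronecker
delta), plus noise. Perceptual-learning runs add an association term,
$h_{assoc} = 10$ delivered to all excitatory neurons whenever the currently
associated stimulus is shown; the associated identity is re-drawn every
25 s.

The receptive-field model assigns each neuron a Gabor patch
($f = 2$, $\sigma_x = \sigma_y = 0.5$, phase uniform, orientation from 8
equally spaced values) on a 16×16 lattice over $[-1,1]^2$, normalised to
unit Frobenius norm so image drive is comparable across neurons. Stimuli
are oriented bars of width 0.25 through the patch center, aligned with the
stripe direction of same-orientation receptive fields and norm-equalised
across orientations (the lattice otherwise gives diagonal bands ~18% more
energy); drive is the pixel-wise image–RF dot product. The bar geometry, lattice and
amplitude are not part of the published constant set; the package keeps the
natural unit-norm/unit-contrast scale (`drive_gain = 1`), which puts the
network in the weak-feedforward, high-noise regime the cortical experiments
target.

## Measurements

* **Population coupling** (`population_coupling`): Pearson correlation of
  each neuron's activity with the leave-self-out mean of all others,
  measured on $g(y)$ sampled every 10 ms during a 250-s frozen-weight
  replay. Zero-variance traces yield `NA`, never a silent 0.
* **Connection specificity** (`connection_specificity`): per-neuron ratio
  of mean same-group to mean different-group input weight;
  **fluctuation** is its std over time, sampled every second from 200 to
  500 s (population-std convention). Ratios with a zero denominator are
  flagged `NA` and excluded from group means.
* **Stimulus selectivity** (`rf_selectivity`): mean same-orientation minus
  mean different-orientation input weight; its std over the same window is
  the **selectivity variability**.
* **Association metrics** (`association_selectivity`): ratio-minus-one
  forms for feedforward and associated-stimulus weights.
* Group comparisons use the Levene test (`car::leveneTest`) and Spearman
  rank correlations (`stats::cor.test`), NA-pairs removed.

## In-silico experiments

`run_fc_experiment` develops the 48-neuron, 4-stimulus network for 500 s
(fast/slow split: 6 neurons at $\alpha_s$ and 6 at $5\alpha_s$ per group;
or 12 log-spaced rates on $[0.5, 75]\,\alpha_s$). `run_rf_experiment` does
the same for the 250-neuron receptive-field network, comparing a diverse
assignment (log-uniform on $[0.5, 75]\,\alpha_s$) against a uniform one;
the uniform value is the geometric mean of that range, so the two
conditions match in median plasticity and differ only in diversity.
`run_noise_sweep` repeats the comparison across noise amplitudes.

`run_association_experiment` runs 300 s without associations and then 300 s
of continual association learning for all-slow, all-fast, and 50/50
networks. Because the associated identity switches every 25 s, association
selectivity is read out just before each switch and averaged over blocks.

`run_embedded_sweep` embeds a single plastic readout and two static
readouts in a fixed 20-neuron, 2-stimulus recurrent population; the
population input to the readouts is scaled by the coupling factors
`pc_plastic` and `pc_static`, and the static-to-plastic weights are
functionally silent (updated every step, never fed back). The association
input reaches the readouts only *through* the population: delivering it to
the readouts directly makes the plastic neuron fire during associated
epochs regardless of its coupling and erases the coupling dependence the
sweep is designed to expose. The plastic readout has no feedforward
preference of its own; its original preference is a small initial bias of
its input weights (0.021 vs 0.019 with target sum 0.04), and its learning
rate ($10^{-6}$ Hz) is sized so the silent weights stay inside
$[0, w_{max}]$ over the 500 s + 100 s protocol. Learning is the ratio of
the associated to the original-preference weight.

`run_decoding_experiment` develops all-slow, all-fast and mixed networks
with eight stimulus groups, then trains one linear perceptron (classic
learning rule, error-free-pass or 100-epoch stop, 50/50 train/test split
over 500-ms windows) per stimulus pair — 28 pairs — at every point of a
4×4 log grid of feedforward strength ($10^{-0.5}$–$10^{1.25}$) and noise
amplitude ($10^{-0.5}$–$10^{1.5}$), chosen to span ceiling-to-chance
difficulty. Reported is each network's deviation from the three-network
mean accuracy.

Problem sizes used by the packaged test suite: ten independent
receptive-field instances per condition (500 s plasticity + 250 s coupling
window each), ten seeds of the fully connected protocol, the corner cells
of the 11×11 embedded grid over ten seeds, and one decoding grid.

## The synthetic calcium-imaging generator

`synthesize_dff_dataset` emulates the structure of a passive-viewing
two-photon session: a grating block, a long grating-free middle period, and
a final grating block (defaults 10/42/10 min at 10 Hz; drifting gratings at
8 directions, 2 s on / 1 s off). Each neuron's dF/F trace is

$$\text{dff}_i(t) = c_i\, s(t) + a_i\, v(\theta(t) - \theta^{pref}_i) + \varepsilon_i(t):$$

a per-neuron coupling weight $c_i$ (truncated normal) times a shared
low-pass population signal $s(t)$ (OU, 0.5 s correlation time), plus
orientation-tuned evoked responses with a von-Mises-shaped tuning curve
(concentration 2.5, lognormal amplitudes $a_i$), plus independent Gaussian
noise (sd 0.35). Between the first and last block each neuron's preferred
grating is re-drawn with probability
$\mathrm{logit}^{-1}(b_0 + b_1 c_i)$ — $b_1 > 0$ plants a coupling–drift
link, $b_1 = 0$ a null. All planted ground truth is returned.

What the generator does *not* emulate: calcium indicator kinetics (rise and
decay transients), neuropil contamination, motion artefacts, running- or
pupil-state modulation, and non-grating evoked structure in the middle
period. Passing the recovery tests therefore shows the *measurement
pipeline* is correct and calibrated on data with the planted statistical
structure — not that real recordings satisfy the generator's assumptions.

The analysis cascade (`analyze_calcium`) is fixed-order: session QC
(exclude under 50 neurons, or split-half coupling agreement $r^2 < 0.8$),
whole-session population coupling, preferred grating per block (largest
mean dF/F across presentations; exact ties break toward the smaller
angle), the literal absolute preference change
$|\mathrm{pref}_1 - \mathrm{pref}_2|$ (a circular option exists because
orientation is periodic, but the literal difference is the primary
definition), and a reliability filter (mean pairwise trial-to-trial
correlation at the preferred grating; above-median inclusion by default,
75% and 100% variants available). `drift_statistics` pools included
neurons for the coupling–drift rank correlation and forms per-session
ratios of mean coupling of preference-changing vs preference-conserving
neurons, with a one-sample t-test of the ratios against 1 across sessions.
Null-calibration checks use economical sessions (60 neurons, 3/6/3-minute
blocks); the drift statistics are unchanged by this scaling.

## Known limitations

* The operating point of the network models had to be reconstructed from
  an under-determined constant set; with the published learning-rate
  magnitudes the time courses here are a factor ~2 slower than the
  original figures suggest, so endpoint contrasts measured at 500–600 s
  are mid-development in places (most visibly in the association
  experiment, where the fast network's feedforward selectivity is still
  rising when the protocol ends).
* One global inhibitory neuron is a deliberate simplification; no claim is
  made about realistic inhibitory circuitry.
* The decoding comparison is sensitive to the difficulty grid; with the
  fixed feedforward drive, 500-ms averaging suppresses the fast OU noise
  and the high-noise penalty for fast-only networks largely disappears in
  this implementation.
* Population coupling here is the plain leave-self-out Pearson
  correlation; no spike-count normalisation of the coupling strength is
  attempted.
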
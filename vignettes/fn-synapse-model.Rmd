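---
title: "The Fowler-Nordheim synapse: model, benchmarks and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Fowler-Nordheim synapse: model, benchmarks and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnsynapse)
```

## The model

A bounded artificial synapse that is updated with finite precision faces a
plasticity-stability dilemma: if every update is written at full strength,
old memories are overwritten quickly; if updates are attenuated, new
memories are weak.  Theoretical work on bounded synapses shows that the
best achievable compromise for an ensemble storing random, uncorrelated
patterns is a weight-decay rate that falls off as $1/t$, which yields a
memory signal-to-noise ratio (SNR) decaying as a power law rather than an
exponential.

This package simulates a differential floating-gate device that realizes
that optimum in physics rather than in software bookkeeping.  Two
tunneling junctions hold potentials $W^+$ and $W^-$; the weight is the
differential mode $W_d = (W^+ - W^-)/2$ and the *usage* of the synapse is
the common mode $W_c = (W^+ + W^-)/2$.  Both junctions discharge through a
Fowler-Nordheim (FN) barrier, with a voltage slew

$$J(W) = (k_1/k_2)\, W^2 e^{-k_2/W},$$

(`tunneling_slew()`; the physical current divided by the total node
capacitance $C_T$ is folded into $k_1$).  Linearizing the coupled junction
dynamics for $W_d \ll W_c$ gives

$$\dot W_c = -J(W_c) + m(t), \qquad
  \dot W_d = -r(t)\, W_d + X(t), \qquad
  r(t) = -\frac{\ddot W_c}{\dot W_c},$$

so the weight decays at a rate set entirely by the *history* of usage --
the device is metaplastic.  Solving $\dot W_c = -J(W_c)$ gives the closed
form $W_c(t) = k_2 / \log(k_1 t + k_0)$ (`wc_closed_form()`), for which
$t\,r(t) \to 1$: exactly the $1/t$ optimum.  `decay_rate_r()` recovers
$r(t)$ from any sampled trajectory with non-uniform three-point
differences, and `optimal_flow()` exposes the converse: requiring
$r(t) = O(1/t)$ with a monotone, bounded usage variable forces a flow of
the FN form $\tfrac{1}{\beta} W_c^2 e^{-\beta/W_c}$.  Both directions are
verified in the test suite with ODE-integrator and curve-fit oracles.

In discrete time (one input pulse of width $\Delta t$ per update, the
device frozen in its non-volatile regime between pulses) the weight obeys

$$W_d(n) = \alpha(n)\, W_d(n-1) + x(n), \qquad
  \alpha(n) = 1 - \Bigl(1 + \tfrac{2}{\log(k_1 \Delta t\, n + k_0)}\Bigr)
  \frac{1}{n + \gamma}, \qquad \gamma = \frac{k_0}{k_1 \Delta t},$$

implemented by `decay_alpha()` and `apply_pulse()`.  The constant
$\gamma$ is the *initial effective age* of the synapse: a fresh device
behaves like one that has already seen $\gamma$ updates.

## Default constants and their rationale

Only orders of magnitude of the device constants are physically
identified ($k_0 = O(10^{19})$, $k_1 = O(10^{16}\,\mathrm{s}^{-1}$)), so the
defaults fix representative values and derive the rest:

| parameter | default | why |
|---|---|---|
| $k_1$ | $10^{16}\ \mathrm{s^{-1}}$ | representative slew prefactor |
| $k_0$ | $10^{19}$ | representative initial condition |
| $W_{c0}$ | $8.0$ V | tunneling-active initial node potential; fixes $k_2 = W_{c0}\log k_0 \approx 350$ V |
| $\Delta t$ | $250$ ms | network-experiment pulse width ($100$ ms preset for characterization) |
| $\gamma$ | $4.0\times10^3$ | implied: $k_0/(k_1\Delta t)$ |
| $C_c$ | $200$ fF | coupling capacitance of the prototype device |
| $C_{fg}$ | $1.4$ pF | chosen so $C_T = 1.6$ pF and $q/C_T \approx 0.1\ \mu$V, the single-electron voltage quantum |

The `gamma1`/`gamma2` presets (γ = 2e3, 8e3) change only $k_0$
(equivalently the initial potential), the way a device is re-initialized
at a different tunneling node potential.  Under these constants the
high-tunneling regime (hundreds of electrons per pulse) sits at
$W_c \approx 8$ V and the few-electron regime at $\approx 7.35$ V
(`stochastic_low` preset); the regime boundaries of any particular
physical device depend on its unprinted $k_1, k_2$, so presets here are
named by tunneling rate, not by voltage.

## The memory benchmark

`run_consolidation()` imprints random $\pm 1$ patterns
(`generate_patterns()`) on an empty $N$-synapse network.  One
presentation is a full pulse cycle: the input
$v_{in} = \pm x$ couples onto the junctions, the device tunnels for
$\Delta t$, and the input is withdrawn before readout.  The lasting
imprint of pattern $p$ is therefore $(\alpha(p) - 1)\,v_{in}(p)$, and the
readout weight contains no transient coupling term -- this matches how a
hardware array is read between pulses, and it is the premise of the
analytic expressions below.  The mean retrieval signal, its standard
deviation over pattern realizations, and their ratio for the tracked
pattern $p$ after $n$ patterns are

$$|S(n,p)| \approx \frac{1}{n+\gamma}, \qquad
  \nu(n,p) \approx \frac{\sqrt{n/N}}{n+\gamma}, \qquad
  \mathrm{SNR}(n) = \sqrt{N/n},$$

(`analytic_signal()`, `analytic_noise()`, `analytic_snr()`): the SNR is a
power law independent of $\gamma$ and of the tracked pattern, and the
memory lifetime (SNR crossing 1) equals $N$ -- capacity scales linearly
with network size.  `snr_experiment()` verifies this by Monte-Carlo
(1000 runs by default; the tracked pattern is the first, as in the
hardware protocol), and `memory_lifetime()` locates the empirical SNR
crossing for several $N$.

Two conventions worth noting:

* the analytic product form $(\alpha(p+1)-1)\prod_{j=p+2}^n \alpha(j)$ is
  extended to $p = n-1, n$ by the empty-product convention and reported
  as a magnitude; the pulse-cycle recursion shifts the leading index by
  one, a $O(1/\gamma)$ relative difference;
* the closed-form noise deliberately includes the tracked pattern's own
  term (a slight overestimate); the Monte-Carlo driver uses the ensemble
  standard deviation.

The default pattern amplitude (1.2 V) makes the first imprint
$\approx 300\ \mu$V, a comfortably detectable update for a readout chain
with a $\sim 100\ \mu$V noise floor.

## Plasticity modulation

Without intervention $W_c$ only decreases, so the network only
rigidifies: the retained-pattern count rises until capacity and then
collapses to zero (blackout) because consolidated synapses can neither
recall old patterns above threshold nor store new ones.  A global
staircase voltage $V_{mod}(t)$ restores $W_c$ by an increment after each
update (`modulation_profile()`, `compute_increment()`,
`wc_with_modulation()`): profiles m1/m2/m3 restore 3/4, 1/2 and 1/4 of
the network-mean $|\Delta W_d|$ of the latest update, m0 is the constant
(zero-increment) reference, and m4 alternates between the m0 and m1
rules every 250 updates (the switch period is not physically
identified; 250 is the package default and is configurable).
`retention_experiment()` counts patterns whose SNR exceeds 1 at each
observation time: m0 shows the blackout, m1/m2 settle at a positive
plateau (graceful forgetting), m3 is still consolidating after 2000
updates, and m4 oscillates with its switch period.

A limitation of the linearized model: the natural per-update $W_c$ drop
and the restore increment both scale with $1 - \alpha$, so their ratio
$\mathrm{frac} \cdot x \cdot k_2 / W_c^2$ is independent of $W_c$.  Any
over-restoring fraction therefore converges to the ceiling-guarded
steady state (9 V by default) rather than to a fraction-specific
equilibrium, and m1/m2 plateaus differ in their transient rather than
their level.  The ceiling plays the role of the physical upper rail of
the modulation driver.

## The stochastic (single-electron) model

In the low-tunneling regime an update is carried by countably few
electrons.  `stochastic_step()` samples the electron count of each
junction from a Poisson distribution whose rate is the deterministic
one-pulse voltage drop in electron units, $\lambda = C_T |\Delta W|/q$
(the junction area $A$ is retained in `fn_device()` for documentation
but the rate is derived in the voltage domain, which is the only
parameterization the behavioral constants support).  Each electron moves
the node by $q/C_T \approx 0.1\ \mu$V.  The ensemble mean recovers the
deterministic model exactly by construction, seeded runs are
reproducible, and charge bookkeeping is exact; in the high-tunneling
regime the sampled trajectories stay within $200\ \mu$V of the
deterministic ones over 100-pulse trains
(`compare_to_deterministic()`).  In the few-electron regime the SNR
curve shifts down but keeps its $n^{-1/2}$ slope, because both the
interference noise and the shot noise grow linearly in $n$.

## Continual learning

`train_stream()` trains a two-hidden-layer MLP sequentially on a task
stream (`build_task_stream()`): either five two-class *split* tasks over
consecutive class pairs, or *permuted* tasks that reuse all classes with
a fixed feature permutation.  The default source is a seeded synthetic
generator (10 Gaussian blob classes, 64 dimensions, 500/100 train/test
per class, unit noise, center separation 3.0): it reproduces the task
topology of image benchmarks without any downloaded data, but it has no
pixel correlations or manifold structure, so passing these tests shows
the consolidation *mechanism* works, not that image-benchmark accuracy
numbers are reproduced.  An IDX-format adapter (`read_idx`) accepts
MNIST-layout files for the full-scale benchmarks (zero-padded to 32x32,
standardized); those runs are figure-scale and not part of the test
suite.

For the FN methods (`fn_sgd`, `fn_adam`, `fn_adagrad`) every weight and
bias is backed by a synapse instance (`fn_weights_new()`).  An optimizer
step $s$ is encoded as a pulse of width $\tau = \mathrm{pulse\_gain}
\cdot |s|$ at fixed 4 V drive amplitude, and the realized weight change
is $\tau$ times the differential tunneling slope at the synapse's
current $W_c$ -- the same device response that makes the
characterization sweeps linear in width and exponential in magnitude
(`apply_timed_pulse()`, `characterize()`).  As a synapse is used its
$W_c$ drops and the slope collapses exponentially, so heavily-used
synapses realize ever smaller updates: consolidation emerges from the
device response, with no Fisher-information bookkeeping.  We chose this
pulse-width device response over adding the requested step verbatim to
$W_d$ because a verbatim input term realizes full-strength updates
regardless of usage, which would leave the network with no on-device
consolidation at all.

Two calibration constants connect weights to voltages:

* `voltage_to_weight_gain` (default 0.1): a network weight is
  $\mathrm{gain} \times W_d$.  Because the common-mode discharge and the
  differential slope are the same order, moving a weight by a total
  amount $A$ costs its synapse about $A/\mathrm{gain}$ volts of usage;
  0.1 makes a task's worth of output-layer learning drop $W_c$ by a few
  tenths of a volt, i.e. the network transitions from plastic to
  semi-rigid across a five-task stream.
* `pulse_gain` is calibrated at construction as
  $1/(\mathrm{gain}\cdot\mathrm{slope}(W_{c0}))$ so that a fresh synapse
  realizes its requested first update to within a few percent.

Whether decay is applied per mini-batch step or per epoch is not
physically constrained; the package applies one pulse per optimizer step
(`pulse_stride` exposes coarser strides).  The overall average accuracy
is the mean over all tasks after the final task; the full accuracy
matrix is always returned.  The EWC baselines (`ewc`, `online_ewc`)
implement the standard diagonal-Fisher quadratic penalty on top of Adam
with penalty strength 100 by default (reported in the run metadata; the
benchmark literature uses no single canonical value).

Synthetic-stream learning rates default to 0.1 (SGD family) and 0.01
(Adam family); the image-benchmark rates (0.001, and 1e-4 for Adam on
permuted tasks) apply when the input dimension is 1024.  The
image-benchmark defaults follow the published protocol; the synthetic
defaults were chosen so a single task reaches well above 0.8 test
accuracy within its 4-epoch budget, since a stream no method can learn
discriminates nothing.

## Numerical choices

* `alpha` is evaluated from the current common mode
  ($\alpha = 1 - (1 + 2W_c/k_2)\,k_1\Delta t\, e^{-k_2/W_c}$), which is
  algebraically identical to the $n$-indexed formula on the unmodulated
  trajectory and remains meaningful when modulation restores $W_c$.
* `decay_rate_r` uses three-point Lagrange differences on arbitrary
  (e.g. log-spaced) grids; the $t\,r(t)\to 1$ check holds to 0.05 for
  $t \ge 100\,k_0/k_1$.
* The pulse recursion agrees with its unrolled closed sum to
  $10^{-12}$ V over 500 pulses; the closed-form/ODE agreement is within
  $10^{-6}$ V over four decades of time.
* Monte-Carlo problem sizes: SNR curves use $N = 100$ with 1000 runs;
  capacity uses 400 runs per network size; retained-count curves use
  $N = 1000$, 2000 patterns and 150 runs with a pooled noise estimator
  (the interference noise is stationary across patterns at fixed time,
  so pooling sharpens the retained count without changing its
  definition).  These sizes give estimator noise comfortably below the
  effects being measured.
* Degenerate inputs are rejected early: non-positive potentials, odd
  balanced ensembles, negative times and empty sweeps raise errors;
  non-monotone trajectories in `decay_rate_r` warn.

## Known limitations

* The linearized recursion assumes $W_d \ll W_c$; the continual-learning
  harness stores weights around $|W_d| \lesssim 1$ V against
  $W_c \approx 8$ V, near the edge of that assumption.
* Only the behavioral voltage-domain model is simulated: no transistor
  netlist, no readout-chain noise, no temperature dependence, no
  hot-electron programming step (initialization enters only through
  $W_{c0}$).
* The modulated steady state is ceiling-dominated (see above).
* The cascade-family comparison curves are an external reference; the
  retained-count driver accepts any modulation profile but does not
  re-implement cascade models.
* Device mismatch is not simulated by default; per-synapse parameter
  jitter can be emulated by constructing `fn_device()` instances with
  perturbed $k_1$, $k_2$.
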
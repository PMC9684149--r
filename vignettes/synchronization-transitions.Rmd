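---
title: "Synchronization transitions in gap-junction-coupled Huber-Braun networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization transitions in gap-junction-coupled Huber-Braun networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbsync)
```

## The model

Each neuron is a Huber-Braun thermoreceptor cell: a conductance-based
membrane with two fast spike-generating currents (Na, K), two slow
subthreshold currents (persistent Na and Ca-gated K), and a leak,

$$C \dot V = -I_l - \alpha (I_{Na} + I_K) - \beta (I_{pNa} + I_{KCa})
  + I_{gj} + I_{ext},$$

with $I_j = \rho\, g_j a_j (V - V_j)$.  The fast Na activation is
instantaneous (a Boltzmann sigmoid of $V$); $a_K$ and $a_{pNa}$ relax
toward their sigmoids with time constants $\tau_K$, $\tau_{pNa}$; the
Ca-gated K activation integrates the slow depolarizing current,
$\tau_{KCa}\dot a_{KCa} = -\eta I_{pNa} - \xi a_{KCa}$.  The slow pair
produces subthreshold oscillations that periodically lift the fast pair
over threshold, so the cell bursts; depending on the drive current the
bursting is strictly periodic or chaotic.  Temperature factors
$\rho = \phi = 1$ (reference temperature) throughout.

Neurons couple by gap junctions (electrical synapses): each neuron
receives $I_{gj,i} = g \sum_{j \in \mathrm{nb}(i)} (V_j - V_i)$ over its
adjacency neighborhood.  The coupling is diffusive and pairwise
antisymmetric, so the total coupling current over the network is zero at
every instant — the integrator's conservation cross-check.

The drive $I_{ext}$ descends from the Drosophila circadian loop: free
dCLOCK (dCLOCK not bound by PER) gates a synaptic-form current.  The two
concentrations obey delay equations — synthesis gated by Michaelis
ratios of free dCLOCK evaluated $\tau_1, \tau_2 = 10$ h in the past,
first-order degradation — and oscillate with a circadian period.  All
synchronization experiments, however, clamp the drive to a constant so
the population sits in a single state: $I_{ext} = 0$ (sleep; the regular
bursting regime covers drives in $[0, 0.3]$) or $I_{ext} = 2.5$ (wake;
chaotic spiking, reached for drives above $\approx 2.2$).  The clamped
drive is a voltage-independent injected current; the interval notation
for the regimes indicates a scalar current level, and a frozen synaptic
form would merely rescale it.  The full oscillator drive remains
available (`drive_mode("oscillator")`) for sleep-wake-cycle
demonstrations.

## Units, and the capacitance reading

The parameter table mixes two clocks.  Concentrations and delays of the
circadian loop live in genuine hours.  The neuron's gating constants are
the original millisecond-based Huber-Braun values rescaled by
$4.375\times10^{-4}$ "h" per ms (2 ms $\to$ 0.000875, 20 ms $\to$
0.00875), so one unit of simulated "hour" corresponds to roughly 2.3 s
of original-model time — which also places the model's burst rhythm
(period $\approx 0.12$ time units) at about 8 cycles per second of
original time, i.e. the alpha band.

The capacitance must live in the same unit system or the model dies:
taking $C = 1$ against mS-scale conductances makes the membrane time
constant $C/g_l = 2.5$ time units, three orders of magnitude slower
than every gating variable.  The state then collapses onto a
one-dimensional slow manifold and relaxes monotonically to a fixed
point — no drive level produces a single spike.  Applying the same
ms-to-unit rescaling to the original $C = 1\,\mu F/cm^2$ gives the
package default `hb_params()$C` $= 4.375\times10^{-4}$, which restores
the original membrane-to-gating timescale ratio.  With this value the
model reproduces the intended phenomenology: strictly periodic bursting
at zero drive, chaotic bursting at drive 2.5, and the frustrated sleep
transition described below.  Neighbouring values (e.g. $3\times10^{-4}$
or $10^{-3}$) preserve the single-cell regimes but lose the frustrated
dip; values at or below $2\times10^{-4}$ are unstable under RK4 at the
reference step.  The parameter stays user-settable.

```{r single-neuron}
a1 <- as_adjacency(matrix(0, 1, 1))
st <- network_state(0, 0, gating_steady_state(0))
tr <- suppressWarnings(run_network(
  a1, sim_config(t_transient = 2, t_observe = 2, g = 0),
  drive = drive_mode("sleep"), init = st))
head(diff(tr$spikes[[1]]), 8)  # repeating burst pattern
```

## Order parameters

Spikes are detected as upward crossings of $-20$ mV (crossing times
linearly interpolated between samples, which removes phase quantization
at the integration step).  Each neuron's instantaneous phase grows
linearly from 0 to $2\pi$ between consecutive spikes; it is undefined
before the first and after the last spike of the window, and such
neurons are excluded pointwise.

Two population statistics summarize synchrony at each instant: the
pairwise statistic
$S(t) = \tfrac{2}{N(N-1)}\sum_{i<j}\cos^2\!\big(\tfrac{\phi_i-\phi_j}{2}\big)$
and the Kuramoto modulus
$R(t) = \big|\tfrac1N\sum_j e^{i\phi_j}\big|$.  They are algebraically
locked together: expanding the squared cosine gives, over the same
$m$ valid neurons,

$$S = \tfrac12 + \frac{m R^2 - 1}{2(m-1)},$$

exactly.  The pipeline computes $R$ from phasor sums and $S$ through
this identity, while the exported `order_S()` evaluates the pairwise
definition directly; the test suite holds the two routes together at
$10^{-12}$.  The identity also explains why the two order parameters
always tell the same qualitative story, and why $S$ sits near $1/2$
(not 0) for fully asynchronous populations — its exact finite-$N$ floor
is $\tfrac12 - \tfrac{1}{2(N-1)}$.  Time averages of $S(t)$, $R(t)$
over the observation window give the reported $S$, $R$; their relative
RMS fluctuations give the susceptibilities $\kappa_S$, $\kappa_R$,
which peak near transitions.

## Topologies

Five generators cover the studied structures: a periodic $L\times L$
lattice (von Neumann neighborhoods, every degree 4), a ring with $k/2$
neighbors per side, a ring or lattice augmented with a fixed number of
random long-range connections per node (any non-neighbor is eligible —
no minimum-distance rule, since none is specified), a degree-6 ring
whose two extra edges sit at controlled circular distance $3 + CR$, and
Watts-Strogatz networks (one-endpoint rewiring with probability $p$).
All outputs are validated binary, symmetric, zero-diagonal adjacency
matrices; `ring_with_cr(N, 0)` is edge-identical to `ring_network(N, 6)`.

## Protocols and problem sizes

The reference protocol matches the study design: RK4 at
$\Delta t = 10^{-4}$, membrane potentials initialized uniformly in
$[-10, 80]$ mV, 48 h of transient discarded, 12 h observed, metrics on a
$10^{-3}$-spaced grid (every 10th integration sample — the averages are
insensitive to this decimation).  Only the membrane potential is
randomized; gates start at their voltage steady state with
$a_{KCa} = 0$, a convention the discarded transient makes immaterial to
the reported statistics.  One such $N = 100$ run takes a few seconds of
compute.

Coupling scans multiply runs by grid points, trials and seeds, so the
package's scans and checks use a reduced scan protocol — 12 h transient,
6 h window, 2–3 trials — and coarser grids bracketing each feature.
These sizes were fixed as the smallest at which the weak-coupling sleep
phenomenology is stable across seeds; the dip values at $g = 0.003$
were additionally verified under the reference protocol and under
halved and quartered time steps.

Two numerical caveats are recorded honestly.  First, at
$\Delta t = 10^{-4}$ the fast ionic rate sits near the RK4 stability
margin ($|\lambda|\Delta t \approx 2.8$); the sleep-side results are
step-size-robust, but strong-coupling wake features shift when the step
is refined, and couplings beyond $g \approx 0.3$ are integrated at
$\Delta t = 5\times10^{-5}$ (beyond $0.8$, $2\times10^{-5}$) to stay
stable — the integrator aborts with a diagnostic on non-finite state
rather than continuing silently.  Second, backward (hysteresis) scans
implement adiabatic continuation: each trial starts from a fresh run at
the largest coupling and hands its final state down the grid.

## What the sweeps show

Sleep-mode sweeps are frustrated: the lattice is near-synchronous at
$g = 0.001$, collapses to $S \approx 0.51$, $R \approx 0.15$–$0.28$ at
$g = 0.003$ (the reported dip), and resynchronizes only at much
stronger coupling ($\approx 0.05$ for the lattice, $\approx 0.14$–$0.16$
for the ring, later than the study reports — see Limitations).
Wake-mode curves depend on topology: the lattice jumps discontinuously
to synchrony, long-range additions pull the jump to weaker coupling,
the bare ring instead holds a traveling-wave state (quasi-periodic
partial synchronization, $S$ strictly between the asynchronous floor
and 1) without ever synchronizing completely, and small-world networks
synchronize the later the sparser they are.  `classify_transition()`
operationalizes the labels (jump $> 0.25$ between adjacent grid points
for explosive; an interior dip $> 0.1$ for frustrated; thresholds are
recorded in the result and auditable).

## Synthetic fixtures

`generate_fixture()` produces spike trains with analytically known
synchrony — identical trains, uniform random offsets, jittered common
rhythm, ring traveling waves, two antiphase clusters — through the same
`spike_trains` container the simulator emits, so the metric layer
cannot tell the provenance.  `expected_summary()` supplies the
closed-form $S$, $R$ (phasor sums plus the $S$–$R$ identity), the
oracle for the metric tests.  The fixtures emulate the raster
phenomenology of the simulated networks (in-phase spiking, asynchrony,
wave patterns); they do not emulate bursting within cycles, rate
heterogeneity, or missing spikes, so passing fixture tests validates
the metric algebra, not the biophysics.

## Design choices on open points

* The delayed angle-bracket terms of the circadian loop are read as
  discrete delays (evaluation at $t - \tau$), implemented with a
  step-aligned history ring buffer initialized constant; that is the
  convention of the delay-oscillator lineage the model descends from.
* The constant sleep/wake drives enter as injected currents independent
  of $V$ (see above).
* Random topologies are regenerated per trial with trial-specific
  seeds, so trial averages measure structural effects rather than one
  instance; a fixed-graph mode exists (pass a prebuilt matrix).
* The circadian block is integrated jointly with the membrane equations
  only in oscillator mode; under clamped drive it has no effect on the
  network and is skipped.
* Node coordinates for field-potential synthesis put rings on the unit
  circle and lattices on the integer grid; the LFP electrode defaults
  to the centroid with cutoff 1 and decay exponent 2, all configurable
  and recorded, since the upstream formula leaves them free.

## Known limitations

* The capacitance reading above is a reconstruction; with it, the
  weak-coupling sleep phenomenology (dip location, dip values,
  single-cell regimes) matches the study quantitatively, but every
  strong-coupling feature — sleep resynchronization, wake explosive
  jumps, small-world full synchronization — occurs at roughly 4–10
  times the reported coupling strengths, and no alternative reading we
  tested (coupling scale factors, self-term coupling variants,
  rescaled current-pair factors) reconciles both sides.  The package
  reports its own computed transition locations.
* Hysteresis at the small-world wake transition is weak here:
  bistability shows up as bimodal forward outcomes, but the
  trial-averaged loop area is statistically indistinguishable from
  zero at feasible trial counts.
* Spiking persists at the strongest couplings we can integrate stably;
  the reported loss of spiking near $g \approx 1$ does not reproduce
  under this reconstruction.
* Exactly at the reference step the sleep burster is numerically
  hyper-regular (period CV $\sim 10^{-4}$); refined steps reveal a mild
  intrinsic irregularity (CV $\approx 5\%$) with the same burst
  structure.
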
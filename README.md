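# hbsync

Synchronization transitions in networks of Huber-Braun neurons coupled
by gap junctions, under sleep- and wake-like drive.

## The problem

How a neural population crosses from asynchrony to synchrony — smoothly,
explosively, or non-monotonically — depends on the interplay between
single-cell dynamics, coupling strength, and network structure.  This
package implements a complete simulation study of that question for a
Drosophila-inspired setting: each cell is a Huber-Braun conductance-based
burster,

```
C dV/dt = -I_l - alpha (I_Na + I_K) - beta (I_pNa + I_KCa) + I_gj + I_ext
```

driven either like sleep (`I_ext = 0`, strictly periodic bursting) or
like wake (`I_ext = 2.5`, chaotic spiking), and coupled electrically,
`I_gj,i = g * sum_nb (V_nb - V_i)`, over lattices, rings, rings with
random long-range connections, and Watts-Strogatz small-world networks.
Synchrony is quantified from spike phases by the pairwise order
parameter `S = 2/(N(N-1)) * sum_{i<j} cos^2((phi_i - phi_j)/2)` and the
Kuramoto modulus `R`, with susceptibilities `kappa_S`, `kappa_R` (their
relative RMS temporal fluctuation).  Sweeping `g` and classifying the
resulting `S`–`g` curves exposes the transition taxonomy: frustrated
(rise–collapse–recovery) in sleep, and continuous / explosive /
frustrated-plus-explosive in wake depending on long-range connectivity.
It is intended for computational-neuroscience users studying collective
dynamics of biophysical neuron models.

The package provides:

* `hb_params()`, `steady_activation()`, `ionic_currents()`,
  `gating_derivs()`, `membrane_deriv()` — the single-neuron model;
* `circadian_params()`, `simulate_circadian()`, `drive_mode()`,
  `external_current()` — the delayed dCLOCK/PER oscillator behind the
  sleep/wake drive;
* `lattice_2d()`, `ring_network()`, `add_random_long_range()`,
  `ring_with_cr()`, `watts_strogatz()` — topology generators;
* `run_network()` — compiled fixed-step RK4 network integration with
  interpolated spike detection; `coupling_current()`, `rk4_step()` —
  the reference building blocks;
* `phases_from_spikes()`, `order_S()`, `order_R()`,
  `sync_from_spikes()`, `lfp()` — the metric layer;
* `sweep_spec()`, `run_sweep()`, `classify_transition()`,
  `hysteresis_area()` — experiment orchestration with forward/backward
  (adiabatic) scans;
* `fixture_spec()`, `generate_fixture()`, `expected_summary()` —
  synthetic spike trains with closed-form synchrony, the metric oracle.

## Worked example

The frustration dip of the sleeping lattice: at weak coupling
(`g = 0.001`) the 10x10 lattice of bursters is nearly synchronous, yet
tripling the coupling *destroys* the synchrony before much stronger
coupling restores it.  At the dip:

```r
library(hbsync)
set.seed(1)
adj <- lattice_2d(10)                     # periodic, every degree 4
cfg <- sim_config(t_transient = 12, t_observe = 6, g = 0.003)
tr  <- run_network(adj, cfg, drive = drive_mode("sleep"))
tr
#> spike_trains: 100 neurons, window [12, 18] h, 16889 spikes total
sync_from_spikes(tr)
#> S = 0.5095  R = 0.1542  kappa_S = 0.0404  kappa_R = 0.4736  (n_valid >= 0)
```

`S ~ 0.51` sits at the asynchronous floor (for uniformly random phases
`S -> 0.5`), even though every neuron is still bursting regularly — the
frustrated state.  The metric layer can be validated independently of
the simulator with a closed-form fixture, e.g. a ring traveling wave
(quasi-periodic partial synchronization), whose phasor sum cancels
exactly:

```r
spec <- fixture_spec("traveling-wave", n_neurons = 100, period = 0.1,
                     winding = 1, window = 1)
sync_from_spikes(generate_fixture(spec), seq(0.15, 0.85, by = 1e-3))
#> S = 0.4949  R = 0.0000  kappa_S = 0.0000  kappa_R = 0.8129  (n_valid >= 100)
```

with `S = 1/2 - 1/(2(N-1)) = 0.4949...` exactly, the finite-N floor.

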
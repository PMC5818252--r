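---
title: "Neural gain, criticality and network integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural gain, criticality and network integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Ascending neuromodulatory systems — most prominently the noradrenergic locus
coeruleus — project diffusely to cortex and are thought to modulate *neural
gain*: the slope of the transfer between a region's afferent input and its
firing-rate output. `neurogain` implements an in-silico test of how global
gain changes reshape whole-brain network organization: a network of
neural-mass oscillators coupled through a directed structural connectome is
swept over a plane of gain (sigma) and excitability (gamma), and the
resulting fast phase dynamics and slow BOLD-level network topology are
quantified.  The headline phenomenon is a synchronization bifurcation: as
gain rises, the network crosses a sharp critical boundary from asynchronous,
noise-driven activity into coherent collective oscillation, and the
functional connectome simultaneously shifts from a segregated (modular) to
an integrated (high-participation) topology, with communicability and
time-resolved topological variability maximal near the boundary and the
effect concentrated in structural rich-club hubs.

# The model

## Local dynamics

Each region follows a planar neural-mass oscillator (a modal reduction of a
FitzHugh–Nagumo population),

$$\dot V_i = 20\,(W_i + 3V_i^2 - V_i^3 + \gamma I_i) + \xi_i(t), \qquad
  \dot W_i = 20\,(-W_i - 10 V_i) + \eta_i(t),$$

with membrane potential $V$, recovery variable $W$, and additive white noise
$\xi,\eta$.  Coupling enters through the delayed synaptic current

$$I_i(t) = \sum_j A_{ij}\, S\!\big(V_j(t - \tau_{ij})\big), \qquad
  S(v) = \frac{1}{1 + e^{-\sigma (v - m)}},$$

where $A_{ij}$ is the directed structural weight from region $j$ onto region
$i$, $\tau_{ij}$ the axonal conduction delay, $\sigma$ the gain (maximum
sigmoid slope $\sigma/4$) and $m = 1.5$ centers the sigmoid on the typical
input.  All regions share the same $\sigma$ and $\gamma$, mirroring diffuse
neuromodulation.

**Units.**  The rate constant 20 is interpreted as 20 s^-1 (equivalently
0.02 ms^-1, the convention of the large-scale simulators this model family
comes from).  The linearization at the origin then has eigenvalues
$-10 \pm i\sqrt{3900}$ s^-1, i.e. a damped ~9.9 Hz oscillation — a
physiological brain rhythm.  Reading the same constant per millisecond would
put the oscillator at ~10 kHz, make conduction delays (tens of ms)
hundreds of cycles long, and reduce the hemodynamic stage to a constant;
we therefore fix the model time unit to seconds throughout.  Tract lengths
remain in mm and conduction speed in mm/ms (default 3 mm/ms), so delays of
tens of ms are a modest fraction of the oscillation period, which is the
regime in which delayed coupling can synchronize the network.

## Local bifurcation structure

With constant drive $d = \gamma I$, the equilibrium solves the strictly
decreasing cubic $-10V + 3V^2 - V^3 + d = 0$ (hence is unique), with
Jacobian $20\,[[6V - 3V^2,\ 1], [-10,\ -1]]$.  The trace vanishes at
$V^* = 1 \mp \sqrt{2/3}$: a supercritical Hopf bifurcation at
$d \approx 1.740$ (onset of self-sustained oscillation) and a second one at
$d \approx 14.26$ where high drive restores a stable focus.
`local_bifurcation_scan()` exposes exactly this computation, and the
integrator is validated against it.  The two Hopf points are what produce
the inverted-U in excitability: at fixed high gain the network passes from
damped noise, through collective oscillation, and back toward saturation as
$\gamma$ grows.

## Numerics

`simulate_network()` integrates the delayed stochastic system with the
stochastic Heun (predictor–corrector) scheme: both stages reuse the same
Gaussian increment (standard deviation `noise_std * sqrt(dt)` per state),
and the delayed rates for both stages are read from a circular history
buffer, which is exact because delays are rounded to whole steps and clamped
to at least one step.  Defaults: `dt = 1 ms` (~100 steps per oscillation
cycle), `noise_std = 1`, history initialized at the origin, trajectories
stored at 200 Hz after a 10 s transient.  Deterministic runs at `dt` and
`dt/10` agree within O(dt); identical seeds give bit-identical output (the
C++ core draws from R's RNG).

## Hemodynamics and functional connectivity

Each region's total membrane input $V_i + \gamma I_i$ — local fluctuation
plus afferent synaptic current — drives the standard four-state
Balloon–Windkessel model
($\kappa = 0.65$ s^-1, $\gamma_f = 0.41$ s^-1, $\tau = 0.98$ s,
$\alpha = 0.32$, $\rho_0 = 0.34$, $V_0 = 0.02$ — the canonical published
constants, since the source experiment lists none), sampled at `TR = 0.72` s.
BOLD is band-pass filtered to 0.01–0.1 Hz with a zero-phase frequency-domain
filter carrying the squared magnitude response of a 4th-order Butterworth
band-pass (no IIR filtering package is assumed); DC is removed exactly and
the passband stays within a few percent of unit gain.  Functional
connectivity is Pearson correlation, Fisher r-to-z transformed and clipped
at $|z| \le 6$.

The choice of hemodynamic *input* matters more than any hemodynamic
constant.  The membrane potential alone is nearly amplitude-blind at these
timescales: the ~10 Hz cycle averages out in the slow hemodynamic states,
so with a pure $V$ drive the BOLD signal of every region reduces to
filtered private noise and functional connectivity carries no network
structure in any regime.  The afferent current $I_i$ sums ~19 delayed
firing rates, so independent regional noise largely cancels while
collective (synchrony-dependent) fluctuations survive into the BOLD band —
and neurovascular coupling empirically tracks synaptic input rather than
spiking output.  The integrator therefore stores $I_i$ alongside the state
variables, and `balloon_windkessel()` uses $V + \gamma I$ by default.

A practical numeric detail that matters: the hemodynamic states take
~15–20 s to settle from their resting initial conditions, and that settling
ramp is *shared by every region*, so left in place it masquerades as strong
global functional connectivity.  The sweep pipeline therefore discards a
`hemo_burn` window (default 20 s) of BOLD before filtering, correlation and
time-resolved analyses.  This was found empirically: without the burn-in,
uncoupled oscillating cells showed saturated uniform FC.

# Network analyses

* **Phase synchrony.** Per-region linear detrend, Hilbert-transform phase
  (5% trimmed at each end), Kuramoto order parameter
  $\rho(t) = |N^{-1}\sum_j e^{i\theta_j}|$; a cell is *synchronized* iff
  time-mean $\rho \ge 0.5$.  The critical boundary is the first
  $\rho = 0.5$ crossing along each lattice row/column, linearly
  interpolated; metrics are compared across the plane by shifting each row
  so its crossing sits at offset zero and averaging (sigma alignment over
  $0.2 \le \gamma \le 0.6$, gamma alignment over $0.3 \le \sigma \le 1$).
  Regime statistics use the same aligned construction
  (`boundary_band_cells()`): only rows that actually cross the boundary
  inside the band contribute, so both regimes are present in every row
  compared.  Pooling the whole lattice instead washes the contrasts out —
  the deep supercritical zone settles into a stable collective state whose
  BOLD carries no slow signal, and the metastable low-excitability strip is
  strongly integrated while its time-mean order parameter stays below
  threshold.
* **Dwell times.** Excursion durations about a threshold are fit by
  continuous maximum likelihood ($\hat\alpha = 1 + n/\sum\ln(x/x_{min})$,
  KS-minimizing $x_{min}$) and compared against a shifted exponential by
  log-likelihood ratio — heavy tails are the signature of operation near
  criticality.
* **Time-averaged topology.** Session FC matrices are consistency
  thresholded (lowest cross-session variance edges kept to 10% density,
  carrying mean weights); community structure comes from signed Louvain
  (positive excess weight normalized by $v^+$, negative by $v^+ + v^-$) with
  a 100-run consensus; integration is the mean participation coefficient
  over positive strengths, segregation the signed modularity $Q$ (with
  $Q^{-1}$ and weighted global efficiency as adjuncts), complexity the
  log10 mean communicability $e^A$ of the binarized kept edge set, plus the
  binary mean clustering coefficient.  A Surprise criterion (cumulative
  hypergeometric tail of the intra-module edge count) is available to select
  the Louvain resolution; the pipeline default is 1.0.
* **Time-resolved topology.** Coupling by Multiplication of Temporal
  Derivatives (pointwise products of z-scored first differences, moving
  average `w = 15` samples), per-window signed Louvain (10 restarts) and
  participation, summarized as the mean regional SD over windows
  ($B_T$ variability).
* **Rich club and realized gain.** Total-degree rich-club curve
  $\Phi_k$ on the binarized digraph, normalized by the mean of
  degree-preserving rewired nulls (default 1000).  Realized gain is the
  sigmoid slope $\sigma S(v)(1-S(v))$ averaged over each region's empirical
  input distribution (histogram quadrature, 100 bins) — at most $\sigma/4$,
  attained when inputs concentrate at $m$.

# Design choices on genuinely open points

* **Sweep scale.** The source experiment does not report grid spacing,
  session counts, run length, dt or noise amplitude.  The package fixes an
  11 x 11 lattice on $[0,1]^2$ as the default; the `"full"` preset runs
  5 sessions of 8 min (after a 10 s transient) per cell, and the
  `"reduced"` preset — used by the tests and the acceptance script — runs
  2 sessions of 246 s: long enough for the slow (0.01-0.1 Hz) BOLD
  covariations that carry the topology contrasts to rise above sampling
  noise, short enough that a complete sweep runs in well under half an hour
  on one CPU.  The synchrony statistics use the first 60 s of fast dynamics.
  The reduced preset also strides the $B_T$ windows (every 3rd window) for
  tractability; this subsamples an otherwise sample-by-sample sliding
  window and only widens the Monte-Carlo error of the SD estimate.
* **Sigmoid re-estimation.** $m$ is fixed at 1.5 everywhere; nothing in the
  source suggests it was refit per parameter point.
* **Rich-club threshold.** The normalized curve typically rises to a plateau
  spanning the hub degree range and fluctuates wildly once only a few nodes
  survive.  $k^*$ is therefore the smallest degree reaching 99% of the
  maximal normalized coefficient, within stretches that stay above 1 for at
  least two consecutive degrees and keep at least five survivors.  (The
  naive "first k above 1" rule triggers on ratio noise and labels nearly
  every node rich.)  Rich nodes are the survivors at $k^*$; feeders link to
  them; the remainder are local.
* **Dwell-time signal.** "Regional fluctuations" is under-specified;
  `dwell_time_tail()` accepts any series, and both the order parameter and
  single-region potentials are supported and reported separately.
* **Surprise null.** The Surprise of a partition is computed against random
  placement of the same number of edges among all node pairs (cumulative
  hypergeometric tail), the stated interpretation of an under-specified
  procedure.
* **t statistics.** Pooled-variance (Student) t-tests throughout, consistent
  with integer degrees of freedom such as 798 (regime contrasts) and 2848
  (edgewise hemisphere contrast on 2850 pairs); degenerate zero-variance
  comparisons define $t = 0$.

# The synthetic world, and what a green test establishes

No anatomical connectome is shipped.  `synthetic_connectome()` generates a
macaque-scale stand-in for the 76-region network the experiment used:
directed edges at 25% density; log-normal weights rescaled to unit mean
(heavy-tailed, like empirical tract weights); two balanced hemispheres with
inter-hemispheric edge propensity halved; a planted club of 22 regions with
dense (p = 0.8) mutual interconnection and boosted peripheral connectivity;
coordinates in a ~60 mm brain so conduction delays (≤ ~30 ms at 3 mm/ms)
stay well under the 100 ms oscillation period.  The spatial scale matters:
with human-scale distances the delays approach half a period and actively
*desynchronize* the network, and the gain-driven transition disappears.
With unit-mean weights the typical row strength (~19) puts the Hopf drive
$\gamma I \approx 1.74$ inside the swept unit square, which is why the
boundary falls mid-plane rather than being tuned there.

What the generator does *not* emulate: CoCoMac's degree sequence,
hierarchical areal organization, homotopic inter-hemispheric connections,
and its structured sparsity.  Two visible consequences: at 25% random
density every peripheral node touches the club, so the "local" class
(10 regions in the source data) is typically empty here and hub contrasts
are evaluated rich vs non-rich; and the hemisphere contrast
actually reverses: FC gains in the ordered regime are anatomy-weighted, and
with the hemispheres coupled only by sparse down-weighted random edges the
denser within-hemisphere pairs gain more than the between-hemisphere pairs.
The disproportionate between-hemisphere FC rise seen with real anatomy
rides on strong homotopic callosal connections the generator does not
plant; reproducing it requires supplying a real connectome.  Green tests on the synthetic world establish that the machinery
recovers planted structure and reproduces the *mechanistic* signatures
(sharp boundary, boundary-locked peaks, integration/segregation shift);
they do not certify the source experiment's CoCoMac-specific numbers, which
require the user to supply that connectome.

# Known limitations

* Cells run sequentially; an 11 x 11 reduced sweep is ~10 min on one CPU.
* The frequency-domain filter assumes stationarity over the record; very
  low-frequency content near 0.01 Hz is only partially resolved on the ~220 s
  reduced-preset records.
* Consensus clustering re-clusters the agreement matrix centred on its
  off-diagonal mean; for pathological agreement structures it caps at 20
  rounds and returns the current majority partition.
* Archival I/O is TSV/CSV (no HDF5 dependency is available); run-time
  caching uses RDS keyed by the exact cell configuration.
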
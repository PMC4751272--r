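---
title: "Methods: finite-volume cable simulation of neurons and synthetic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-volume cable simulation of neurons and synthetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cablenet)
```

# The model

`cablenet` simulates electrical signalling on spatially resolved neuron
morphologies with the cable equation.  A morphology is a tree of 3D points
with radii (`neuron_graph`); around every vertex we place a tubular
compartment with the vertex's radius, so the membrane of compartment $i$
has area $2\pi a_i l_i$ with $l_i$ half the summed length of the incident
edges, and capacitance $C_i = c_m\,2\pi a_i l_i$.  Charge conservation in
each compartment gives

$$C_i \frac{dV_i}{dt} = \sum_{j \sim i} G_{ij}\,(V_j - V_i) \;-\; A_i\, i_m(V_i),$$

where the axial conductance of an edge follows from integrating the
cytosolic resistivity over the two half-tubes,

$$G_{ij} = \frac{2\pi}{r_c\,(a_i^{-2} + a_j^{-2})\,\lVert e_{ij}\rVert},$$

and $i_m$ collects the outward-positive membrane current densities.  At a
branch point the axial sum simply runs over all incident edges — the
finite-volume locality makes the two-neighbour cable formula generalize
additively.  Ion species (cytosolic Ca^2+^ in the shipped configuration)
satisfy the analogous conservation law with a diffusive axial conductance
$G^c_{ij} = 2\pi D /((a_i^{-2}+a_j^{-2})\lVert e_{ij}\rVert)$ and membrane
fluxes in mol m^-2^ s^-1^.  Only calcium is instantiated by default: it is
the only species the shipped experiments read out, and no parameters for
K^+^/Na^+^ pools are part of the model configuration.

## Membrane mechanisms

All mechanisms follow one explicit contract: their inner states are
advanced *before* a time step using only the previous step's solution, and
they report an outward-positive current density evaluated at that
solution.  This keeps cells coupled by synapses decoupled within a step
(the basis of the one-step synaptic lag) and the linear system independent
of mechanism nonlinearity.

* **Hodgkin–Huxley channels.** $i_{hh} = c(T)\,(g_K n^4 (V-E_K) +
  g_{Na} m^3 h (V-E_{Na}))$ with the original squid rate functions
  evaluated at $v = V - V_r$ millivolts above a rest of $-65$ mV.  The
  temperature factor $c(T) = 3.21$ multiplies both the currents and the
  gate kinetics; it is treated as a plain constant.  Conductances are
  region-specific (axon / soma / dendrite; `membrane_spec()` carries the
  network-study defaults).
* **Calibrated leak.** $i_l = c(T)\,g_l\,(V - E_l)$ with $E_l$ *derived*,
  not configured: `calibrate_leak_reversal()` solves
  $i_{hh}(V_r) + g_l (V_r - E_l) = 0$ at the resting gate steady state, so
  rest is an exact equilibrium.  $c(T)$ multiplies both terms and cancels;
  the calibration therefore runs with $c(T)=1$.  This convention (original
  1952 rates shifted to $V_r = -65$ mV) is forced by the tabulated leak
  reversals, which it reproduces to below $2\times10^{-6}$ V.
* **Calcium machinery.** An N-type voltage-dependent calcium channel in
  the Borg–Graham formalism (Boltzmann activation, gating charge 3.4,
  half-activation $-21$ mV, $\tau_m$ 1.5 ms; slow inactivation), with GHK
  flux as the documented default; NCX as a first-order Michaelis pump and
  PMCA as a second-order Hill pump; and a fraction (0.001) of every
  synaptic AMPA current converted to calcium influx through Faraday's
  constant with $z = 2$.  None of these numeric parameters come from the
  source model description — they are configuration values with
  literature-typical magnitudes (`calcium_spec()`), deliberately excluded
  from any quantitative acceptance target.  A constant leak is calibrated
  at initialization so the *total* calcium membrane flux (pumps + VDCC at
  resting gating) vanishes at the resting concentration, making the
  calcium rest state an exact fixed point.

## Synapses

Two kinds:

* **Primary** synapses model external input with an alpha conductance
  $g(t) = g_{\max}\frac{t-t_0}{\tau}e^{-(t-t_0-\tau)/\tau}$ supported on
  $[t_0, t_0+6\tau]$ (the truncation applies to the network thalamic
  inputs as well).  Onsets and time constants are drawn per synapse from
  $N(\mu_{onset},\sigma_{onset}^2)$ and $N(\mu_\tau,\sigma_\tau^2)$;
  $\sigma = 0$ degenerates to exactly the mean.  Non-positive $\tau$
  draws are rejected and redrawn.
* **Interconnecting** synapses connect an axonal (presynaptic) vertex to
  a dendritic location.  They activate on an upward crossing of the
  presynaptic potential above $V_{th} = -10$ mV — evaluated on the
  previous step's solution, so transmission always lags one step, and no
  further transmitter delay is modelled — and conduct a bi-exponential
  $g(t) = g_{\max}\,n\,(e^{-t/\tau_2}-e^{-t/\tau_1})$ normalized to peak
  at $g_{\max}$.  Re-activation requires the presynaptic potential to
  fall below threshold first; every event is logged.

Sign convention, used everywhere: mechanism-level currents are outward
positive and the solver subtracts them once from the charge balance, so a
synapse with $E_{rev} = 0$ mV depolarizes.

Placement: `distribute_primary()` draws edges from the length-weighted
law $p_j = \lVert e_j\rVert / \sum_k \lVert e_k\rVert$ over the basal and
apical dendrites and a uniform offset in $(0,1)$ along the edge.  Synapse
loss (`remove_uniform()`) keeps a uniformly sampled subset, rounded
half-even; on a fixed seed removals are *nested* so that loss curves
within one sample configuration compare the same surviving synapses.

# Discretization and solution

Time stepping is a mixed Euler scheme: backward (implicit) in the axial
fluxes, forward (explicit) in the membrane fluxes.  One step solves

$$\Big(\frac{C}{\Delta t} + L\Big)V^{new} = \frac{C}{\Delta t}V^{old} - I_{mem}(V^{old}),$$

with $L$ the weighted graph Laplacian.  The explicit radial part imposes a
CFL-type bound; `estimate_time_step()` uses
$\Delta t = \min(\Delta t_{\max},\; s\,\min_i C_i/G^{mem}_i)$ where
$G^{mem}_i$ is the *present* membrane conductance (channels at current
gate states plus synapses active now) — more transmembrane flux, smaller
step.  The safety factor defaults to $s = 0.5$; the estimate intentionally
uses current gate states rather than worst-case conductances, trading a
formal guarantee for efficiency, and a divergence detector aborts with the
offending bound if the estimate is overridden.  $\Delta t_{\max}$ is an
accuracy cap: stability alone would admit much larger steps at rest than
spike-timing accuracy does (the single-compartment acceptance check runs
at $\Delta t_{\max} = 10^{-6}$ s to hold peak times within 0.5 ms of an
adaptive reference).  One global $\Delta t$ serves all cells in a step, as
the one-step synaptic lag semantics requires.

The linear system is symmetric and tree-structured.  `cuthill_mckee_order()`
computes a breadth-first Cuthill–McKee ordering per component and
*reverses* it: on a rooted tree the reversed order places every vertex
before its BFS parent, so each matrix row has at most one non-zero entry
right of the diagonal.  Plain (unreversed) CMK does not have this
property at branch vertices — a branch point's children would all lie to
its right.  With the reversed ordering the LU factorization proceeds
without fill in one $O(n)$ sweep (one elimination per vertex, one
back-substitution), which is what makes per-step refactorization after
every $\Delta t$ change essentially free.  Only the diagonal is
state-dependent; sparsity and ordering are computed once at mesh build.

## The block-partitioned solve

`partitioned_solve()` emulates, serially, solving neurons that are cut
across processors.  Block matrices are stored additively: each edge is
assigned to one block containing both endpoints, and the diagonal mass of
a cut vertex is split evenly across the blocks sharing it, so the global
matrix is exactly the sum of the block matrices.  Each iteration splits
the current defect across blocks by interface multiplicity, solves every
block, and accumulates the corrections at the cutting points with the
same partition-of-unity weights before updating the iterate.

The weighting is a deliberate design choice: accumulating *unweighted*
corrections at a shared vertex double-counts the interface update, and in
a serial emulation this either stalls at a nonzero defect or diverges
outright (we verified both failure modes numerically).  With the
partition-of-unity weights the exact solution is a fixed point, an uncut
partition converges in exactly one (exact) iteration, and in the
mass-dominated regime the time stepper actually operates in during
activity ($\Delta t \sim 10^{-6}$–$10^{-7}$ s) cut cables converge in a
handful of iterations — well under fifteen in every configuration we
test.  Convergence is judged on block norms of the globally summed
defect, reduced by `reduction_factor` in every block.

# Synthetic networks

`generate_network()` builds a layered column from stylized parametric
cells: each type gets a soma placed uniformly in its layer's depth slab
(with a minimum soma separation), lateral basal/stellate dendrites,
pyramidal types an ascending apical trunk with a small tuft, and an axon
that descends from the soma and runs across the depth range of the layers
its type innervates (read off the connectivity matrix), with two lateral
collaterals.  These are *not* reconstructions of any fingerprint
database; absolute synapse counts of the original 10,000-cell networks
are therefore explicitly not reproduction targets — only structural
properties are.

Synaptogenesis follows the distance rule: for every axon-section /
dendrite-section pair of *different* cells whose types form an allowed
pair in the connectivity matrix, one synapse is created if the minimum
Euclidean distance between the two line segments falls below
`dist_synapse` (at most one synapse per section pair; autapses are
excluded).  Using true segment-segment distance, rather than
vertex-vertex distance, makes the criterion robust to discretization.
The postsynaptic conductance applies the distance rule
$g_{\max} = (1 + 0.001\,d_{sd})\,g_s(T_1,T_2)$ with $d_{sd}$ the
path distance to the soma in micrometres.

Two generator choices matter for the cubic count-vs-distance property:

* **Section resolution.**  The synapse count within distance $d$ behaves
  like the two-dimensional measure of near-contact parameter pairs, which
  scales as $d^3$ for an ensemble of generic curve pairs — but only at
  section lengths $s$ short enough to resolve the contact region.  The
  leading finite-$s$ correction is a surface term $\propto s\,d^2$, so
  the log–log slope fitted over $d \in [1, 5]$ µm comes out as
  $3 - O(s/d)$: about 2.75 at $s = 0.5$ µm, 2.9 at $s = 0.2$ µm in our
  measurements.  The generator default is 0.2 µm — a fifth of the
  smallest probed distance — keeping the bias near 0.1.
* **Axon tilt jitter.**  Perfectly parallel vertical trunks distort the
  ensemble (a single lucky close pair contributes a large, linearly
  growing count).  Axon verticals therefore carry a small random tilt,
  as real axons do; with it the measured log–log slope is 2.8–2.9 across
  seeds, consistent with the cubic law at finite section length.

Thalamic input places primary synapses on the driven cell types with
per-cell counts drawn Poisson around the configured means (the protocol
prescribes averages, not exact counts), using the same length-weighted
distributor.

# The two studies

**Synapse loss vs. synchrony** (`run_loss_study()`): distribute `n_syn`
synapses in `n_samples` random configurations; activate under three
synchrony levels ($\sigma_{onset} \in \{0, 5, 10\}$ ms with
$\mu_{onset} = 3\sigma_{onset}$, fast AMPA kinetics
$g_{\max} = 1.2$ nS, $\tau = 0.4$ ms); sweep the loss grid with nested
removal; record spike counts at soma and axon tip (both probes are kept,
since "evoked action potential" can reasonably be read at either site)
and somatic calcium.  The spike criterion — upward crossing of 0 mV with
a 3 ms refractory — is this package's operational definition.  Breakdown
loss is the largest loss fraction at which at least 90 % of samples still
spike.  The desk-scale defaults run a soma + 400 µm dendrite + 200 µm
axon cable with $n_{syn} = 200$ and $N = 20$ samples, sized so the suite
and the study finish in minutes while preserving the qualitative
structure: exactly one spike under full synchrony at zero loss,
multi-spike responses under asynchrony, monotone decline with loss, and
the resilience ordering synchronous ≥ moderate ≥ high.  The full-scale
protocol (1000 synapses, 100 samples) is available through
`full_loss_protocol()` but requires an externally supplied SWC
reconstruction; none is bundled.

**Connectivity-driven network waves** (`run_network_study()`): one
generated column, thalamic input onto L4 stellate (mean 30/cell) and L5B
pyramidal (mean 25/cell) with onset $(5, 2.5)$ ms and duration
$(2.5, 0.1)$ ms, swept over synapse creation distances on the same
geometry seed.  Reported: per layer and time the fraction of somata at or
above $-45$ mV, per projection the number of synapses active within a
5 ms window of an activation event, and peak fraction/time per layer.
The desk-scale default (24 cells in an 80 × 80 × 280 µm box) preserves
the ordering observations — relay layers peak higher and earlier the more
synapses the network has — while a single sweep entry simulates in
minutes.

# Numerical choices and degenerate inputs

* Gates are clamped to $[0,1]$ after every explicit update; calcium is
  clamped at 0 (the CFL-limited step keeps both clamps inactive in
  practice, and tests assert the invariants).
* Removable singularities of the HH rate functions are evaluated by their
  analytic limits.
* A multi-point SWC soma is collapsed to a single root vertex at the soma
  centroid with a sphere-surface-equivalent radius; the soma probe is
  that root vertex.  SWC files must store radii (not diameters); diameter
  files are documented out of scope rather than auto-detected.
* Edge resampling splits edges into equal sub-edges with interpolated
  positions and radii, preserving total cable length per branch exactly.
* Synapse offsets at an edge endpoint (probability zero under the
  continuous draw) are nudged inside the open interval; a synapse is
  assigned to the control volume containing its offset point.
* `remove_uniform` rounds retained counts half-even — any consistent rule
  works; this one is symmetric.
* Zero-length edges, non-positive radii, cyclic or multi-root files, and
  empty sample spaces are rejected with structural errors, not repaired.

# What the synthetic fixtures do and do not show

The generator's cells are stylized: straight-segment dendrites and axons
with realistic lengths, radii and laminar targeting, but none of the
tortuosity, taper, or fingerprint statistics of reconstructed cells.
Passing the desk-scale studies therefore demonstrates the *mechanisms* —
placement laws, loss nesting, synchrony effects, activation cascades,
calcium-spike coupling — at reduced scale, not the quantitative spike or
calcium values of any real morphology; those depend on the reconstruction
used.  Likewise the reduced column reproduces ordering relations, not the
peak activity fractions of a 10,000-cell network.

# Known limitations

* No inhibitory synapses (the modelled networks are purely excitatory by
  construction) and no NMDA voltage-dependent block.
* No calcium buffers or ER stores; the AMPA calcium fraction is reduced
  to 0.1 % precisely to mimic fast buffering.
* Compartments are tubes, not truncated cones; electro-diffusion is not
  modelled.
* The block-partitioned solver emulates the parallel scheme serially; no
  actual multi-process execution or scaling measurements are provided.
* The CFL estimate is a heuristic bound, not the scheme's exact stability
  constant; absolute step sizes are not comparable across
  implementations.
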
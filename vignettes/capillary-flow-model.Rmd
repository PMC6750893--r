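---
title: "Discrete RBC tracking in microvascular networks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete RBC tracking in microvascular networks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

capflow simulates blood flow in microvascular network graphs while tracking
every red blood cell (RBC) individually. This vignette is the package's own
account of the model, its assumptions, the synthetic study system, and the
design decisions that were genuinely open.

## The model

A microvascular network is a graph: nodes are bifurcations or endpoints with
3-D positions, edges are vessels with length $L_{ij}$, diameter $D_{ij}$ and an
anatomical type (pial arteriole, descending arteriole, capillary, ascending
venule, pial venule). Flow in each vessel obeys Poiseuille's law with an
effective, hematocrit-dependent resistance,

$$ q_{ij} = \frac{p_i - p_j}{R^e_{ij}}, \qquad
   R_{ij} = \frac{128\,\mu\,L_{ij}}{\pi D_{ij}^4}, \qquad
   R^e_{ij} = R_{ij}\,\eta_{rel}(D_{ij}, H_d), $$

where $\mu$ is the plasma viscosity and $\eta_{rel}$ the relative apparent
viscosity of blood (Fahraeus–Lindqvist effect). Mass balance at every interior
node plus fixed pressures at the boundary nodes yield a sparse symmetric
positive-definite linear system that is solved for the nodal pressures at
every time step (the sparsity pattern is fixed, so the Cholesky factorization
is computed once and only its numeric values are updated).

Three empirical relations close the model; the paper trail of coefficients is
recorded verbatim in `R/hemodynamics.R` and `src/rbc_kernel.cpp`:

* **Viscosity** (`relative_apparent_viscosity`): the Pries et al. (1992)
  *in vitro* parameterization in $D$ (µm) and discharge hematocrit $H_d$. It
  equals 1 at $H_d = 0$, is minimal near $D \approx 7$ µm, and increases
  steeply below ~5 µm.
* **Fahraeus effect** (`tube_from_discharge`): RBCs travel near the vessel
  axis and therefore faster than the bulk flow, so the instantaneous tube
  hematocrit $H_t$ is below the discharge hematocrit:
  $H_t/H_d = H_d + (1-H_d)\,x(D)$ with
  $x(D) = 1 + 1.7e^{-0.415D} - 0.6e^{-0.011D}$ (Pries et al. 1990). The fit
  exceeds 1 below $D \approx 2.6$ µm, where it is clamped at 1
  ($H_t = H_d$); with the default diameter law this affects roughly 1 % of
  capillaries. The relation is quadratic in $H_d$, so its inverse
  (`discharge_from_tube`), needed every step to turn occupancy-derived $H_t$
  into the $H_d$ that feeds the viscosity law and the velocity factor, is
  evaluated in closed form rather than by root bracketing — it is exact and
  removes a per-vessel root search from the hot loop.
* **Phase separation**: at divergent bifurcations RBC flux and bulk flow split
  unequally. For mother diameters ≥ 10 µm the Pries logit law maps the bulk
  fraction FQB into the RBC-flux fraction FQE, with plasma skimming below the
  threshold $X_0$; each arriving cell samples a Bernoulli(FQE) draw. Below
  10 µm — the whole capillary bed — each RBC follows the daughter exerting the
  larger pressure force $(\Delta p/L)\,A$ (*bifurcation rule*), with exact
  ties broken by a fair coin. The pressure-force form follows the model
  lineage; only its qualitative shape ("a function of the cross-section") is
  fixed by the physics.

### Discrete RBC transport

RBCs are finite-volume particles ($V_{RBC} = 49\ \mu m^3$ by default, a
typical mouse value; configurable) at arc-length positions inside vessels.
Per step each cell advances by $v_{RBC}\,\Delta t$, where
$v_{RBC} = v_{bulk} H_d/H_t \ge v_{bulk}$ in the full model and
$v_{RBC} = v_{bulk}$ for passive particles. A cell never approaches its
leader closer than one RBC length $\ell_{RBC} = V_{RBC}/A$; a blocked cell
waits (traffic jam), and a blocked divergent-bifurcation entry falls back to
the other daughter or waits if both entrances are at the packing limit.
Convergent arrivals merge in arrival order. Inflow boundaries inject cells so
the long-run injected volume flux equals $q \cdot H_{in}$ (default
$H_{in} = 0.3$), with a deficit accumulator so blocked insertions are
deferred, never dropped. The RBC ledger
$n(t) = n(0) + \text{injected} - \text{ejected}$ holds exactly at every step.

The time step (default 0.5 ms) must keep every cell within one vessel per
step; a violation is a hard error, not a silent subdivision. Flow and routing
are frozen within a step (quasi-static coupling), and the pressure system is
re-solved every step because the hematocrit distribution — hence every
effective resistance — changes with RBC motion. All randomness (routing
draws, tie-breaks) is drawn from R's RNG seeded once per run, so runs are
bit-reproducible.

### Model variants

* `with_rbcs` — full model (resistance effect, velocity factor, phase
  separation).
* `passive_particles` — tracked cells do not affect resistance, move at the
  bulk velocity and split like the bulk flow: the control that isolates what
  RBC dynamics contribute. Its flow field is constant in time.
* `no_phase_separation` — resistance and velocity effects retained, routing
  proportional to bulk flow: isolates the contribution of unequal
  partitioning. Passive particles deliberately do not keep the Fahraeus
  velocity factor — they are passive tracers of the bulk flow.

### Time averaging

Analyses use the time-averaged field: per-vessel *median* flow, velocity and
tube hematocrit (medians are robust against the strongly intermittent
instantaneous fields; sampling is every step). The averaging interval follows
a turnover-time rule: long enough that 90 % of vessels are completely
perfused at least 10 times (10 × the 0.9-quantile of $L/|v|$, lower
interpolation). A warm-up of twice that interval precedes recording, and the
interval is re-derived from the warmed field. Both intervals can be set
explicitly, which the tests and the acceptance analyses do to pin problem
sizes; a `moving_average` (100-step window, 50-step stride) is provided for
presentation only.

## The synthetic study system

The real cortical reconstructions this class of model is run on are not
shippable, so `generate_lattice_mvn()` builds networks with the statistical
structure the analyses assume:

* a jittered cubic capillary mesh (spacing 50 µm — the average inter-capillary
  distance; jitter 0.2 of spacing), pruned to node degrees ≤ 3 by a
  degree-capped randomized spanning tree plus a configurable fraction
  (default 0.55) of loop edges; degree-3 nodes are the analysable
  bifurcations, and > 90 % of vessels are capillaries;
* capillary diameters lognormal (median 4 µm, geometric SD 1.2) truncated to
  (2, 9.9) µm, so the whole bed stays in the bifurcation-rule regime;
* straight penetrating trunks (diameter 15 µm): descending arterioles at
  quadrant-centre columns, ascending venules at corner columns, each feeding
  or draining the mesh via capillary offshoots at every depth level (at most
  two per level, so attachment nodes stay analysable); the trunk top at the
  pial surface is the only boundary node of a trunk and carries the inlet
  (50 mmHg, DA) or outlet (10 mmHg, AV) pressure. These pressures were chosen
  once so that the median capillary bulk velocity is ~0.5 mm/s and trunk
  velocities a few mm/s, the canonical cortical values; with the default
  8×8×8 lattice the network has ~700 vessels, and the median DA→AV capillary
  path is 4–8 segments.

What the generator does **not** emulate: the depth-dependent topology of real
cortex (diameter and density gradients over layers), tortuous centerlines
(vessels are straight segments at unit tortuosity), and the degree/length
distributions of reconstructed networks. Passing tests therefore demonstrate
that the *mechanisms* (velocity balancing, hematocrit heterogeneity, local
dilation response) emerge from RBC dynamics on a realistic mesh — not that
their magnitudes match any particular animal.

## Analyses

**Bifurcation balance.** Degree-3 all-capillary nodes are classified from the
median-flow signs into divergent (1 in / 2 out) and convergent; the relative
velocity difference $|\Delta^r v| = 2|v_1 - v_2|/(v_1 + v_2)$ uses daughter
velocities (divergent) or mother velocities (convergent), as magnitudes of the
median bulk velocity. Well-balanced means $|\Delta^r v| \le 20\%$ — the
boundary is included, following the operational use of the threshold —
unbalanced means $> 40\%$. DoWB is the well-balanced fraction. The statistical
battery is: one-sided Mann–Whitney U across groups, Wilcoxon signed-rank for
paired comparisons, one-sided two-sample Kolmogorov–Smirnov for cumulative
densities, with quartiles and adjusted Fisher–Pearson skewness (e1071 type 2)
reported alongside.

**Capillary dilation.** A daughter of a divergent capillary bifurcation is
split into a proximal segment of $6\ell_{RBC}$ at the baseline diameter
(protecting the pressure-force routing at the junction) and a distal segment
dilated by $f_{dil} = 1.1$. Candidate bifurcations must be well-balanced (or
unbalanced) at baseline, lie within 0.6 of the maximum centre distance, and
have a mother discharge hematocrit ≥ 0.3. The hematocrit floor is applied to
the *discharge* hematocrit derived from the median tube hematocrit: with an
inflow discharge hematocrit of 0.3 the corresponding tube value in a 4 µm
capillary is ~0.25, so a tube-hematocrit floor of 0.3 would reject essentially
every mother vessel by construction. Activation runs restart from the
baseline terminal RBC state (cells in the split daughter are reassigned to
the matching segment by arc position) and re-warm for one averaging interval
before recording, which keeps baseline and activation comparable while
flushing the transient. Reported quantities: the length-normalized flow
change $\Delta^r q = ((q_{act}-q_{base})/q_{base}) \cdot 100\,\mu m/L_{dil}$,
the raw RBC-count change $\Delta^r n_{RBC}$, and the quotient of flow ratios
$a = (q_{d1}/q_m)_{act}/(q_{d1}/q_m)_{base}$. For the dilated daughter,
$\Delta^r n_{RBC}$ compares the baseline vessel against the sum of its two
activation segments — same tissue span, no length rescaling. Per-generation
tables pool all vessels of a flow-directed generation (±3) across scenarios;
a vessel reachable at two depths counts at the smaller one, with
upstream/downstream ties assigned upstream (a loop is first of all a feeder).
Because one synthetic lattice yields only a handful of filtered well-balanced
candidates (real networks offer thousands), campaign-style analyses pool
scenarios across replicate lattices (fresh generator seeds), dilating each
daughter of a selected bifurcation once, as many scenarios as needed.

**Spatial statistics.** Analysis layers are half-open 200 µm depth slabs
(depth = z, 0 at the pial surface; a bifurcation at exactly 200 µm belongs to
layer 2). Distances to penetrating vessels use the *main branch* — the
maximal same-type path from the pial surface with non-increasing diameter,
ties toward the larger diameter — sampled as ≤ 1 µm polyline points for
Euclidean distances; flow-path lengths walk the directed capillary graph
(upstream to reach a DA, downstream to an AV) and take the minimum cumulative
length. The tissue grid divides the bounding box into `dims` cubes and
records, per cube centre, the exact point-to-segment distance to the nearest
well-balanced outflow vessel, with the median and the fraction within a 50 µm
influence radius as summaries. Grid dimensions are parameters: cube edge
lengths depend on the (unprinted) domain extents, so no fixed dimensions are
baked in.

## Numerical choices and degenerate inputs

* Hematocrit clamps: occupancy can transiently nudge $n\,\ell_{RBC}$ a hair
  above $L$; $H_t$ is clamped to [0, 1] and the viscosity law is evaluated at
  $H_d \le 0.99$.
* Zero-flow vessels get infinite turnover (excluded from the coverage rule,
  the vessel is flagged), no RBC motion, and are skipped by the generation
  walk and the bifurcation classifier (the node is excluded and counted).
* Exact routing ties use a fair coin from the run's RNG stream; daughters
  with instantaneous reversed flow are excluded from candidacy.
* Nodes of degree > 3 are legal (trunk joints, forced offshoot attachments)
  but never enter bifurcation statistics; RBCs crossing them split in
  proportion to the bulk flow.
* The mass-balance residual of the solve is checked against a 1e-10 relative
  bound; boundary pressures are imposed exactly.

## Problem sizes used by the tests and analyses

Unit tests run seconds-long simulations on 5³–6³ lattices and toy Y graphs.
The reference analyses (and `scripts/acceptance.R`) use the default 8×8×8
lattice (~700 vessels): headline comparisons warm up 2 s, average 3 s of
simulated time, and pool the divergent-bifurcation samples of two replicate
lattices (a single ~200-bifurcation realization can leave the rank test
marginal — the network-level statistics are designed to combine networks);
dilation campaigns average 5 s per run (baseline and activation alike) and
pool ≥ 10 scenarios across replicate lattices; the symmetric-Y balancing
check averages 10 s. These sizes were chosen as the
smallest at which the time-averaged medians are stable enough to resolve the
effects of interest. Single-capillary quantities remain noticeably noisy at
this scale: the winner-take-all pressure-force routing lets small capillary
neighbourhoods dwell in metastable RBC-rich/RBC-poor states for seconds at a
time, so per-site relative changes carry a spread of several percent (and
more after the 100 um length normalization at short dilated segments), which
only much longer windows or much larger networks would shrink. Means pooled
over ten scenarios resolve the first-order effects (flow and RBC
up-regulation in the dilated vessel, the phase-separation dependence of the
RBC gain); strictly per-run statements — every single quotient of flow
ratios above 1, or the sign of the small constant-daughter RBC change — sit
at the edge of what this problem size can decide, and a dilated daughter
whose RBC influx outpaces its conductance gain can transiently lose flow
share (an in-model clogging response that large reconstructed networks, with
their longer capillaries, do not show).

## Known limitations

* Lingering of deforming RBCs at bifurcation apexes, and the resulting
  transient deviations from Poiseuille's law, are not modelled — cells are
  points with spacing, not deformable bodies.
* The in vitro viscosity law ignores the endothelial surface layer; an in
  vivo parameterization can be swapped in behind `resistance_params()`.
* Vessels are rigid; no compliance, no regulation feedback.
* The phase-separation coefficient set is isolated but only one
  parameterization ships.
* Measured-velocity ingestion supports the documented CSV replicate format
  only; line-scan image processing is out of scope.
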
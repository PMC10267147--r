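---
title: "Cell-based cardiac tissue simulation with Kirchhoff current-law networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-based cardiac tissue simulation with Kirchhoff current-law networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Homogenized tissue models (the bidomain equations) describe cardiac
propagation accurately at the millimetre scale, but the myocyte itself is not
present in them: cell-level heterogeneity — a fibrotic border zone, a single
poorly coupled cell, a fibroblast — has no natural home. Geometrically
explicit cell models resolve every membrane but are far too expensive for
tissue-scale use. `knmsim` implements the intermediate, cell-based approach:
every myocyte and its associated extracellular compartment are computational
nodes, and Kirchhoff's current law closes the system.

Between neighboring cells $j,k$ and neighboring extracellular compartments,
currents flow through lumped conductances (mS),

$$I_i^{j,k} = G_i^{j,k}\,(u_i^j - u_i^k), \qquad
  I_e^{j,k} = G_e^{j,k}\,(u_e^j - u_e^k),$$

and across each cell's membrane the usual capacitive-plus-ionic current
$I_m^k = A_m^k\,(C_m\,\dot v^k + I_{\mathrm{ion}}(v^k, s^k))$ with
$v^k = u_i^k - u_e^k$. Kirchhoff's law at the cell and at its extracellular
compartment gives the coupled system solved by the package:

$$C_m \frac{dv^k}{dt} = \frac{1}{A_m^k}\sum_{j \in N_k} I_i^{j,k}
  - I_{\mathrm{ion}}(v^k, s^k), \qquad
  0 = \sum_{j \in N_k} I_i^{j,k} + \sum_{j \in N_k} I_e^{j,k},$$

with $u_i$ eliminated via $v + u_e$, membrane state dynamics
$\dot s^k = F(s^k, v^k)$, homogeneous Dirichlet conditions on $u_e$ at the
tissue boundary (strand ends in 1D, the perimeter in 2D) and natural no-flux
conditions on the intracellular side. The second equation — zero net current
into every extracellular compartment — is an algebraic constraint: the
system is a differential-algebraic network, not a plain ODE.

### Conductances from cell geometry

A myocyte is modelled as a solid of revolution, 120 um long, with radius
tapering linearly from 7 um at the center to 6 um at the ends (two conical
frusta), inside a compartment whose cross-section leaves a 2 um
extracellular margin: $l_y = l_z = 2(7 + 2) = 18$ um, the tightest box
consistent with the geometry. From this follow, analytically:

* volume fractions $\delta_i = V_{\text{cell}}/V_{\text{comp}} \approx 0.4105$,
  $\delta_e = 1 - \delta_i$;
* membrane area $A_m$ = lateral surface of the double frustum
  ($\approx 4.90\times10^{-5}$ cm$^2$). The flat end faces are intercalated
  discs — they carry gap-junction current, not ionic current — so they are
  excluded from $A_m$;
* disc area $A_g = \pi\,(6\,\mu m)^2 \approx 1.13\times10^{-6}$ cm$^2$.

Edge conductances follow classical conductor arguments. Extracellularly,
$G_e = \delta_e A \sigma_e / l$ with $A$ the shared compartment
cross-section and $l$ the center distance. Intracellularly, the bulk
cytoplasmic resistance acts in series with the gap-junction resistance of
the connecting disc:

$$G_i = \left(\frac{l}{\delta_i A \sigma_i} + \frac{R_g}{A_g}\right)^{-1}.$$

Defaults: $\sigma_i = 4$, $\sigma_e = 20$ mS/cm, $C_m = 1$ uF/cm$^2$,
$R_g = 0.0015$ k$\Omega$ cm$^2$. Impaired coupling is modelled by a
multiplier on $R_g$ (50x, 500x), applied globally or per edge.

Transverse (y) coupling is genuinely under-determined by the longitudinal
geometry: nothing fixes the lateral gap-junction contact area. We default it
to the intercalated-disc area $A_g$, so transverse edges use the same series
formula with the face $l_x l_z$ and distance $l_y$; the area is a
constructor argument (`transverse_area`) and the sensitivity is worth
remembering when interpreting 2D results.

### Membrane models

The ionic surface current is pluggable behind a small interface: gates
(Hodgkin–Huxley form, advanced by the exponentially exact Rush–Larsen
update) and non-gate states (forward Euler). Two models ship:

* **passive** — $I_{\mathrm{ion}} = g_L (v - E_L)$, stateless. With it the
  entire tissue system is linear, so trajectories have a closed form
  (matrix exponential after eliminating $u_e$), used as an independent
  reference.
* **mitchell_schaeffer** — a two-current minimal excitable model rescaled to
  mV/ms: with $u = (v - v_{\text{rest}})/v_{\text{amp}}$, inward current
  $h\,u^2(1-u)/\tau_{\text{in}}$, outward $u/\tau_{\text{out}}$, and a single
  recovery gate $h$ with piecewise-constant kinetics
  ($\tau_{\text{open}}$ below the gate threshold, $\tau_{\text{close}}$
  above), which is exactly the gate form Rush–Larsen integrates without any
  stability constraint.

Shipped parameters: $\tau_{\text{in}} = 0.15$, $\tau_{\text{out}} = 6$,
$\tau_{\text{open}} = 120$, $\tau_{\text{close}} = 78$ ms, gate threshold
$0.10$, $v_{\text{rest}} = -80$ mV, amplitude 100 mV. They were chosen, once,
against three physiological requirements at the package's standard tissue
conditions:

1. a realistic strand: CV $\approx 50$ cm/s at normal coupling with APD
   $\approx 183$ ms;
2. robust (if slow, $\approx 3$ cm/s) conduction at 500x the default
   gap-junction resistance — the rest-state leak $u/\tau_{\text{out}}$
   competes with charging through the junction, so too small a
   $\tau_{\text{out}}$ or too high a gate threshold makes severely uncoupled
   strands block entirely;
3. a vulnerable window for the S1–S2 protocol: with
   $\tau_{\text{close}} = 78$ ms the APD (183 ms at the $-20$ mV level) is
   short enough that an S2 delivered roughly 200–280 ms after S1 finds part
   of the lower-left quarter recovered and part refractory, the substrate
   for unidirectional block — while remaining long enough that the faster
   continuum wave cannot fit a sustained rotation into the domain.

The rest state $(v_{\text{rest}}, h = 1)$ is an exact equilibrium by
construction, so quiescence holds to machine precision. Stimuli are applied
as additive inward membrane current densities (negative sign internally; a
"40 uA/cm$^2$" stimulus depolarizes), active on the time steps whose
interval midpoints fall in $[t_{\text{on}}, t_{\text{on}} + \text{dur})$ —
an unambiguous rule whether or not dt divides the stimulus duration.

### Numerics

Each step applies first-order Godunov splitting: (1) the nonlinear membrane
substep per node — Rush–Larsen for gates, forward Euler for non-gates and
for $\dot v = -(I_{\mathrm{ion}} + I_{\text{stim}})/C_m$; (2) a backward-Euler
solve of the coupled linear $(v, u_e)$ network system together with the
extracellular constraint. The reaction-then-diffusion order is the common
convention for this splitting; the scheme is first-order accurate in dt
overall, which the test suite measures directly against the passive
closed-form reference (observed order within $[0.8, 1.2]$).

After symmetric elimination of the grounded $u_e$ rows and columns the step
operator is symmetric positive definite, so it is Cholesky-factorized once
per simulation and reused every step (dense storage up to 1200 unknowns,
sparse `Matrix` Cholesky beyond). A direct solve has no iteration residual;
the solver contract is expressed through `solver_tol` (default $10^{-10}$)
and enforced observationally: every simulation tracks the maximum Kirchhoff
residual — the net current imbalance of every interior extracellular node —
and the trace carries both the observed maximum and the bound
$10 \times \text{solver\_tol} \times$ (conductance scale $\times$ 100 mV).
Typical observed residuals are $\sim 10^{-16}$ uA.

Degenerate inputs are defined, not accidental: a 1x1 grid has no edges and
reduces to the single-cell ODE (the linear substep is the identity); a
zero-duration run returns only the initial snapshot; a network with no
grounded node is rejected at assembly, since $u_e$ would only be determined
up to a constant. Activation detection (upward crossings of the -20 mV
threshold) runs at full dt resolution regardless of the snapshot cadence and
takes the first crossing without temporal interpolation — the literal
"reaches the threshold" reading; interpolation between snapshots is
available as an option and matters only at coarse cadences.

## The homogenized reference solver

The same engine doubles as a finite-difference bidomain solver. `bd_grid()`
discretizes the continuum equations by a cell-centered finite volume scheme
(3-point stencil in 1D, 5-point in 2D), which is algebraically a resistor
network: face conductances $M\,A_{\text{face}}/h$ and per-node membrane
area $\chi\,V_{\text{node}}$. The homogenized parameters are fixed by
requiring exact consistency with the cell network over one cell span:

$$\chi = \frac{A_m}{l_x l_y l_z}, \qquad M_e = \delta_e \sigma_e, \qquad
  M_i = \frac{\delta_i}{1/\sigma_i + R_g\,\delta_i\,A_{\text{cross}}/(A_g\,l_x)},$$

so that $M_i A_{\text{cross}} / l_x = G_i$ identically (and analogously in
the transverse direction). Consequence, verified entrywise in the tests:
with one grid node per cell ($\Delta x = l_x$, $\Delta y = l_y$) the
assembled bidomain operator *equals* the cell-network operator — the cell
network is the coarsest consistent discretization of the continuum model,
while the converged continuum limit differs from it physically. That
difference is the scientific point: under severe uncoupling (500x $R_g$) the
continuum model smears the junction resistance along the fibre and conducts
measurably faster than the discrete cell chain, whereas at normal coupling
the two agree to about one percent.

## Protocols and experiment drivers

* `s1_protocol()` — 40 uA/cm$^2$ for 2 ms on the leftmost cell (1D) or
  leftmost cell column (2D; for fine grids, all nodes within the first cell
  length).
* `s1_s2_protocol()` — S1 plus a premature S2 over the lower-left quarter
  (floor rounding on odd grids) after a configurable delay.
* `conduction_velocity()` — distance between the centers of cells 3 and 13
  divided by the difference of their first -20 mV crossings, on the
  15-cell strand; the "no propagation" failure is a distinct error class so
  sweeps can record block instead of crashing.
* `detect_reentry()` — snapshots do not define reentry, so the package's
  operational criterion is: at least one node re-activates ($\ge 2$
  crossings) later than a 50 ms refractory guard after S2, *and* activity
  persists beyond a 300 ms window after S2. Both windows are arguments.
* `convergence_study()` / `cv_rg_sweep()` / `reentry_experiment()` — drivers
  for the temporal-convergence, resistance-sweep and S1–S2 studies.

## Study conditions and problem sizes

The package's standard experiments, exercised by the test suite and the
acceptance script, run at desk scale on one CPU:

* temporal convergence: 15-cell strand, dt from 100 us down to 1 us,
  multipliers 1 and 500; CV at dt = 10 us sits within a fraction of a
  percent of dt = 1 us (the first-crossing detector quantizes activation
  times to dt, which is visible below ~0.5%);
* resistance sweep: multipliers {1, 10, 50, 100, 500}; CV decreases
  strictly, and the continuum-minus-network CV gap at 500x exceeds the gap
  at 1x (bidomain grid at $\Delta x = 10$ um, converged to <0.5% in the 1D
  refinement study);
* reentry: 20 x 20 cells at 500x $R_g$, dt = 20 us, 600 ms of simulated
  time; S2 delays searched over {240, 200, 220, 260, 280} ms because the
  vulnerable window depends on the membrane model. The network reenters (at
  260 ms with the shipped model), sustained well past the persistence
  window. The bidomain comparison runs on a resolved grid
  ($\Delta x = 10$, $\Delta y = 6$ um): at 500x $R_g$ the depolarization
  front is only a few tens of micrometres wide, and coarser grids —
  especially transversely, where the spacing would exceed the 18 um cell
  width — re-discretize the continuum so coarsely that they behave like the
  cell network and spuriously reenter.

## What the synthetic fixtures do and do not show

`generate_fixtures()` and the synthetic-trace constructors build the
analysis-level ground truths: a planar wave with analytically placed
crossing times (CV recovers its construction parameter exactly), a rotating
phase map (canonically reentrant), and the two-node passive network with its
matrix-exponential trajectory. These validate the measurement and detection
operations independently of the solver. None of them emulates real tissue:
there is no cell-size dispersion, no fibrosis geometry, no restitution
heterogeneity, and the shipped membrane model is a two-variable caricature
of an atrial myocyte. Passing tests therefore certify the network mechanics,
the numerics and the discrete-vs-continuum contrast — not quantitative CVs
of any particular species or chamber, for which a full ionic model would be
plugged into the same membrane interface.

## Known limitations

* Rectangular lattices only (no 3D stacking, no irregular cell shapes or
  sizes); heterogeneity enters through per-edge resistance multipliers.
* First-order splitting; no adaptive dt; no Strang variant.
* The extracellular null space is handled only via grounded boundary nodes;
  fully insulated tissue is rejected rather than regularized.
* Absolute conduction velocities depend on the caricature membrane model;
  only structural statements (convergence, conservation, monotonicity,
  discrete-vs-continuum contrasts) are claimed.

```{r, eval = FALSE}
library(knmsim)
net <- build_grid_network(15, 1, params = tissue_params(rg_multiplier = 500))
tr <- simulate_knm(net, mitchell_schaeffer(), s1_protocol(net),
                   dt = 0.01, duration = 100)
conduction_velocity(tr)   # cm/s, cells 3 -> 13
```
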
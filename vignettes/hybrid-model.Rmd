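---
title: "The hybrid go-or-grow model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid go-or-grow model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioswitch)
```

## The model

`glioswitch` simulates the fate of the *invisible* glioblastoma cells left in
brain tissue after surgical resection of the visible tumour core. Three
coupled layers run on different scales:

1. **Intracellular switch.** Each cell carries the dimensionless
   miR-451--AMPK--mTOR system
   $$\frac{dM}{d\tau} = \lambda_g G + \frac{\lambda_1\lambda_2^2}{\lambda_2^2+\alpha A^2} - M,\qquad
   \epsilon_1\frac{dA}{d\tau} = S_1 + \frac{\lambda_3\lambda_4^2}{\lambda_4^2+\beta M^2} - A,\qquad
   \epsilon_2\frac{dR}{d\tau} = S_2 + \frac{\lambda_5\lambda_6^2}{\lambda_6^2+\gamma A^2} - R,$$
   where $M$, $A$, $R$ are miR-451, AMPK-complex and mTOR levels and $G$ is
   the local glucose signal. Mutual inhibition between $M$ and $A$ makes the
   system bistable over a window of glucose values: a *migratory* branch
   (low $M$, high $A$, low $R$) and a *proliferative* branch (high $M$, low
   $A$, high $R$), separated by saddle-node knees. With the default
   parameters the knees sit at $G \approx 0.399$ and $G \approx 0.580$, so a
   cell's fate is history dependent (hysteresis): it stays migratory until
   glucose rises past the upper knee, and proliferative until glucose falls
   below the lower one. Phase labels use thresholds
   $th_M = th_A = 2$, $th_R = 3$ with strict inequalities; threshold
   equalities classify as `neither` so a label never flips on a tie.

2. **Cell mechanics.** Cells are off-lattice spheroid agents. Migratory
   cells exert a bounded traction
   $F_0\,\phi_r\,(\psi_1 \mathbf{d}_r + \psi_2\,\nabla\hat G/(K_G+|\nabla\hat G|^2)
   + \psi_3\,\nabla\hat C/(K_C+|\nabla\hat C|^2))$
   combining a persistent random direction with saturated glucose and
   chemoattractant gradients; traction is switched off entirely for cells
   with the proliferative signal ($A \le th_A$) and for cells that are
   *physically constrained* — another cell's centre lies within a
   90° sector (half-angle 45°) around the intended direction. Velocities
   come from an overdamped force balance: substrate/fluid drag plus
   cell--cell friction against traction and pairwise overlap (reactive)
   forces, a symmetric positive-definite sparse system solved each step.
   Growth is gated by the proliferative signal and shut down outside the
   force window $(\sigma^-, \sigma^+)$; the plateau growth rate is
   calibrated so an unstressed gated cell doubles its volume in exactly one
   cell cycle, at which point it divides into two resting-volume daughters
   offset by one resting semi-axis along a random axis.

3. **Continuum fields.** Oxygen, glucose, chemoattractant, extracellular
   matrix, matrix-degrading proteinase and an intravenous chemotherapy drug
   evolve on a regular grid with zero-flux boundaries: backward-Euler
   diffusion in divergence form (spatially varying coefficients by harmonic
   face averaging), vessel supply, tumour consumption, exponential decay
   applied exactly, an exact per-step logistic update for the matrix, and
   proteinase production on migratory-cell sites.

The hybrid loop per step: sense fields at cell centres, advance the
intracellular ODEs, reclassify phases, compute tractions and contacts, solve
velocities and move, grow/cycle/divide/apply drug deaths, then advance the
fields on the updated indicator rasters.

## Scenario anatomy

A scenario starts at $t = 0$ just after surgery: a cavity of radius 0.7 mm at
the centre of a 10 mm square of tissue is emptied, and `N_init = 50` residual
invasive cells are scattered in the 2.4--4.5 mm annulus around it, initialised
on the migratory branch. `N_b` vessels are placed by seeded uniform sampling
with a 0.8 mm minimum separation, excluded from the cavity. Oxygen and
glucose are pre-equilibrated to their no-tumour steady state.

The cavity radius is 0.7 mm rather than a fixed fraction of the domain
because the four peri-cavity injection sites used by the localization
scenarios sit 0.8 mm from the centre and must lie on the cavity *periphery*,
not inside it.

Interventions:

* **Chemoattractant injection** at the cavity centre or at the four
  peri-cavity sites, at a configurable multiple of the base rate
  (`l_in_C` = 2.68e-9 g cm^-3^ s^-1^); the sweeps use the multiples
  {9.67, 56.7, 267, 567}.
* **Intravenous drug** infused at all vessels from `t = 150` h at a multiple
  of a reference rate; a cell dies when the local concentration reaches
  `th_D` (half the near-vessel steady level at the reference rate) *and* its
  cycle phase is in the drug's target set (S--G2--M by default).
* **Tissue heterogeneity**: all diffusion coefficients on the left half
  domain scaled by a factor (1 down to 0.01).

## Dimensionless inputs and anchors

The switch consumes a dimensionless glucose signal
$\hat G = \min(G/G_{\mathrm{ref}},\,1.2)$, with $G_{\mathrm{ref}}$ the
near-vessel steady glucose computed once per scenario **with the same
discrete scheme used for time stepping** (the fixed point of the per-step
update solves one sparse linear system). Anchoring with the continuum steady
state instead would over- or under-state the signal at vessels by the
operator-splitting offset. With this anchor the signal is exactly 1 at a
vessel (above the upper knee: arrivals switch to proliferation) while the
far field sits below the lower knee (residual cells stay migratory) — the
mechanism behind post-surgical colonisation of vessels.

The chemotactic gradient is nondimensionalised by $C_{\mathrm{scale}}$, the
steady chemoattractant level *on the mid-annulus ring where the residual
cells start*, computed at the strongest swept injection rate. This makes the
dimensionless gradient order one for the cells that must respond: at the
highest rate chemotaxis dominates the random walk and cells return to the
cavity strip; at the lowest printed rate the gradient term is ~0.005 and
cells ignore the intervention. Anchoring at the source peak would make
chemotaxis imperceptible at every rate at 3 mm range.

## Units and the drag closure

Internal mechanics units are µm, h, nN; field units are mm, h, with
concentrations in g/cm^3^ (only ratios matter after the anchors above).
The published adhesion coefficients (dyn s/cm) combined with sphere-overlap
contact areas and the published $F_0 = 64$ nN give a free-cell speed of
~124 µm/h at full traction; typical direction combinations have magnitude
0.15--0.4, yielding 15--45 µm/h, inside the experimentally observed 8--80
µm/h envelope. The drag multiplier `chi_drag` therefore defaults to 1 and
exists only as an explicit closure knob.

## Numerical choices

* **Time stepping.** `dt_cell = 0.5` h for the mechanics/coupling loop. The
  intracellular ODEs are sub-stepped with vectorised RK4 at 0.04
  dimensionless time (the stiff relaxation scale is $\epsilon_{1,2}=0.02$;
  RK4 is stable to $\approx 2.8\,\epsilon$), and `integrate_core()` offers a
  stiff `deSolve` path for single-trajectory work. Fields advance implicitly
  (unconditionally stable) every second cell step (a 1 h field step; their
  reaction relaxation times are 0.5--35 h) with pre-factorised sparse
  Cholesky solves. A per-step displacement cap of 25 µm guards the explicit
  position update against contact-force overshoot after division.
* **Vessel sources.** Vessels supply through a Gaussian footprint of fixed
  physical width (0.1 mm) rather than single grid nodes, so fields converge
  under grid refinement (halving `h` changes the day-1 glucose field by well
  under 2%).
* **Steady-state solver.** Equilibria of the switch come from the cascade
  reduction (at steady state $A$ and $R$ are explicit in $M$), a dense
  sign-change scan and bisection to 1e-12 — all roots are found, with
  stability from the analytic 3×3 Jacobian with $\epsilon_{1,2}$ retained.
  Knee locations are refined by bisection on the equilibrium count to 1e-4.
* **Ties and degenerate inputs.** Threshold equalities are `neither`; a zero
  intended direction is never "constrained"; apoptotic cells generate no
  forces, secretion or growth and are excluded from indicator rasters;
  negative concentrations are clamped at zero and every clamp is counted
  (zero clamps in all default runs).
* **Cell cycle.** `T_cyc = 24` h (a typical glioblastoma doubling time) with
  G1:S:G2:M fractions 0.5:0.3:0.15:0.05. The cycle clock advances only while
  the growth gate is on, so mechanical arrest lengthens the effective cycle.
* **Crowding cap.** Divisions are suppressed (and logged) beyond a global
  population of 1000 cells. Vessel-bound clusters grow rim-limited and the
  densest scenarios would otherwise grow without bound on these time
  horizons; the cap is a documented carrying capacity that bounds desk-scale
  runtime. Sweep comparisons whose densest arms reach the cap compare at the
  cap.
* **Matrix--motility coupling.** The optional traction scaling
  $\max(0, 1-\rho/(0.85\rho_*))$ is off by default: with the published rates
  the logistic remodelling term saturates the matrix almost immediately
  everywhere, so the coupling reduces to a near-constant traction rescale.
  The matrix and proteinase fields are always simulated and exported.
* **Pressure and static binding.** The internal pressure force is never
  printed and defaults to 0; static cell-cell binding forces default off.

## What the synthetic scenarios do and do not show

The scenario engine *is* the data generator: there is no external data. The
generated conditions reproduce the study design — vessel counts
{31, 47, 88}, post-surgery annular cell layouts, the printed injection and
infusion sweeps, the left-half diffusion factors — at desk scale (50
residual cells, 101×101 grid, 164--240 h horizons, 10 seeds per sweep arm).
Passing tests show that the *mechanisms* (bistable switching with
hysteresis, go-or-grow gating, constraint-limited migration,
chemoattractant localization, phase-specific drug kill, diffusion-limited
intervention efficacy) produce the qualitative orderings reported for the
original experiments. They do not show quantitative agreement with any
patient data: absolute population curves depend on unpublished initial
conditions (the residual cell count and cavity radius were never printed),
and real tissue has 3-D geometry, vascular remodelling, immune response and
acto-myosin mechanics that the model omits by design.

## Known limitations

A competing mechanism worth knowing about: in the tissue-stiffness
scenarios, reducing left-half diffusion also narrows the left-half vessels'
glucose halos, so fewer migratory cells are captured into vessel colonies on
their way back to the cavity. At a mild reduction (0.1×) this capture relief
offsets — and in 10-seed medians can slightly outweigh — the loss of
chemoattractant transport, so left-half localization is not monotone in the
diffusion factor until transport genuinely collapses (0.025× and below).
The corresponding acceptance-style check in the test suite documents this as
a failing expectation rather than hiding it.

* 2-D tissue with spheroidal cells; no anisotropic ellipsoid contact.
* No angiogenesis, acidity/lactate metabolism, or blood-brain-barrier
  transport model beyond per-region diffusion/supply scaling.
* The drug acts by a deterministic threshold kill; no pharmacokinetic decay
  profile beyond first-order loss.
* Populations at the crowding cap stop dividing regardless of local space.
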
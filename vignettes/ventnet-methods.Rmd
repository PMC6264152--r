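---
title: "ventnet: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventnet: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ventnet)
```

ventnet simulates the multiple-breath washout (MBW) test — the clinical
measurement of how efficiently an inert tracer gas is cleared from the lung
over repeated tidal breaths — on a reduced mechanical and gas-transport
model of the human airway tree, and quantifies how the washout indices
respond to structural heterogeneity of the airways.  This vignette explains
the model, its assumptions, the tunable parameters, and the numerical and
design choices, in that order.

## The airway network

The airway tree is reduced to seven lobar regions (right upper, right
middle, right lower minor and major, left upper, left lower minor and
major), each assumed to branch symmetrically.  A symmetric region can be
collapsed without loss of information onto a single "mean path": a chain of
edges, one per generation, where the edge at Strahler order $o$ represents
$N_b = 2^{\,o_e - o}$ identical airways ($o_e$ the region's entry order).
Orders count subtree height from zero at the terminal acinar ducts;
conducting airways occupy orders $\ge 9$, acinar ducts orders 8–0.  The
asymmetric proximal airways (trachea, main and lobar bronchi) are explicit
single edges.  With entry orders 22 for the three large regions and 21 for
the four small ones, the conducting tree has 40960 terminal bronchioles, of
which the right-middle lobe feeds exactly 10% — the share used by the
constriction scenarios.

Each region terminates in one *lung unit*: an elastic compartment
comprising the acinar duct chain (rigid lumen) and the alveolar sac volume
lining it.  Per-order airway dimensions are configuration, not code
(`default_conducting_geometry()`, `default_acinar_geometry()`); the
defaults are standard adult morphometry regularised onto the Strahler
ordering.  Two global calibrations tie the geometry to the configured
physiology exactly: conducting cross-sections are scaled uniformly so the
anatomical dead space equals $V_D$, and the resting unit volumes partition
$\mathrm{FRC} - V_D$ equally per acinus.

## Ventilation mechanics

Unit volumes $\mathbf V(t)$ obey the lumped linear viscoelastic system

$$(\mathbf R_{\rm cond} + \mathbf R_{\rm acin})\,\dot{\mathbf V}
  + \mathbf K\,(\mathbf V - \mathbf V^*) = P_{\rm drive}(t)\,\mathbf 1,$$

where $\mathbf R_{\rm cond}[\alpha,\beta]$ is the Poiseuille resistance
summed over the shared mouthward path of units $\alpha$ and $\beta$,
$\mathbf R_{\rm acin}$ and $\mathbf K$ are diagonal acinar resistances and
elastances, and the pleural drive is the sinusoid
$P_{\rm drive} = (A/2)(1 - \cos 2\pi t/\tau)$ — inhalation first, volumes
rising from the resting state, so end-tidal lung volume sits at FRC as in
quiet breathing.  Total elastance is partitioned as
$K_\alpha = K_{\rm lung}(\mathrm{FRC}-V_D)/V^*_\alpha$, making the parallel
combination exactly $K_{\rm lung}$; acinar resistance is the Poiseuille
series sum of each unit's duct chain.  Because the system is linear and
time-invariant, the periodic steady state of the Crank–Nicolson
discretisation is available in closed form; it is used to calibrate $A$ so
the steady-cycle tidal volume equals $V_T$ exactly (by linearity, one
evaluation suffices) and to initialise time stepping, which then verifies
periodicity rather than assuming it.  Crank–Nicolson was preferred to a
backward difference because it adds no numerical damping to an oscillatory
solution at second order in the step.

## Gas transport

Tracer concentration is advanced on the same network by the
one-dimensional "trumpet" advection–diffusion equation

$$\partial_t\!\left[S_i c_i\right] + s_i\,\partial_x\!\left[u_i c_i\right]
  = s_i\,\partial_x\!\left[D_i\,\partial_x c_i\right],$$

with $s_i$ the summed lumen cross-section of the $N_b$ parallel airways,
and $S_i \ge s_i$ the outer cross-section: in the acinar ducts
$S_i - s_i$ carries the time-dependent alveolar sac volume, apportioned
along the duct generations in proportion to total duct length per order
(configurable through `sac_profile`).  Interface velocities follow from
the mechanics: the flow through any cross-section equals the volume-change
rate of everything distal to it, so velocity fields, sac volumes and the
discrete update share one bookkeeping and a uniform concentration field is
an exact solution.

The effective diffusivity is Taylor-like dispersion
$D = D_0 + C\,|u|\,d$ in the conducting airways, with $C = 1.08$ on
inspiration and $C = 0.37$ on expiration switched by the *local* flow
direction (during pendelluft an airway can be in a different phase than
the mouth), and sac-enhanced molecular diffusion
$D = D_0[1 + \phi\,(S/s - 1)]$ in the acinar ducts, where $\phi$ is the
fraction of the sac cross-section participating in axial diffusion.  At
the mouth the boundary is fresh gas ($c = 0$, Dirichlet) on inhalation and
diffusion-free free outflow on exhalation.

## Washout protocol and indices

A washout initialises $c = 1$ everywhere and breathes until the end-tidal
mouth concentration falls below 2.5% of the start, plus three margin
breaths.  From the mouth concentration and flow series the package
computes:

* `FRC_approx` — net expired tracer volume divided by the concentration
  drop (the clinical estimate; exact for a well-mixed compartment);
* `LCI` — lung turnovers (cumulative expired volume / `FRC_approx`) at the
  2.5% crossing, interpolated linearly in log end-tidal concentration
  against turnover (the decay is near-geometric, so log-linear
  interpolation is accurate);
* `SnIII` — per-breath normalised phase-III slope: least-squares slope of
  concentration against expired volume over 65–95% of the expirate,
  divided by the window's mean concentration;
* `Scond` — slope of `SnIII` against turnover over turnovers 1.5–6,
  using breaths up to the crossing;
* `FV` — per-unit fractional ventilation, the fraction of a unit's tracer
  content turned over per breath, $1 - I_{n+1}/I_n$ at successive
  end-tidal states, averaged over the test.  An unventilated acinus has
  FV $= 0$; a well-mixed compartment has FV $= V_{T,\rm eff}/(F +
  V_{T,\rm eff})$.  (The ratio $I_{n+1}/I_n$ itself is the other common
  convention; the fresh-gas-fraction form is used here so that poorly
  ventilated regions appear as the low-FV tail, matching how imaging
  studies report FV.)

Constrictions reduce airway radius by a severity fraction (cross-section
by its square), either *localised* — all airways of one region in a
four-generation band: proximal orders 19–16, central 15–12, distal 11–8 —
or *randomly distributed* — a seeded uniform selection of 10% of the
individual airways at the band's top order anywhere in the lung, plus
their three descendant generations.  Distributed selections break regional
symmetry, so each affected region is re-collapsed into exactly two
sub-chains (constricted and clean lineages), the minimal mean-path
representation; merged subtrees are identical by construction so no
tie-breaking is needed.  Full occlusion (severity 1) is rejected rather
than special-cased.  Note that the "distal" band reaches order 8, the
first acinar generation; the constriction machinery handles acinar edges
identically (radius scaling propagates to duct resistance and lumen).

## Perturbative heterogeneity (linear response)

Within a symmetric region, all airways of one generation are equivalent,
so the linear response of any output $g$ to a relative change
$\epsilon$ in one airway's area, length, or one acinus' elastance is a
property of the (region, order, kind) *class*.  The package computes it by
building a *split network*: the region chain is divided at the target
order into a perturbed branch of multiplicity 1 (with its own sub-chain
and lung unit) and a sibling branch of multiplicity $N_b - 1$, the full
pipeline is rerun at $\pm\epsilon$ (probe $10^{-3}$), and the central
difference gives $\delta g = f\,\partial g/\partial f$.  A Richardson
check (halving the probe, requiring agreement within 1%) guards against
nonlinearity.  For acinar orders the split is made at the terminal
bronchiole — isolating one acinus — and the perturbation applied to the
mean-path duct generation inside it; by linearity and within-acinus
symmetry the single-duct response is the class response divided by the
duct multiplicity.  Perturbed runs reuse the baseline's breath count so
that finite differences are differences of smooth quantities.
Sensitivities were computed numerically rather than by linearising the
governing equations analytically: the Richardson gate makes the two
equivalent at first order, at a fraction of the bespoke algebra.

Superposition reconstructs any weakly heterogeneous lung:
$g_P = g_M + \sum_i \delta g(\mathrm{class}(i))\,\epsilon_i$.  Means stay
at model-M values; no second-order corrections are applied, and the
machinery refuses $|\epsilon| \ge 1$.

### Variance propagation on the tree

Perturbations are modelled as Gaussian fields on the airway tree:
*independent* (each airway's relative area and length deviations
independent with coefficients of variation $\sigma_a$, $\sigma_l$) or
*structurally correlated* (each airway's deviation normally distributed
about its parent's, with within-branch area–length correlation
$\rho_{al}$, so that uncertainty accumulates down the tree).  Elastance
variability is off by default ($\sigma_K = 0$); airway geometry dominates.
The output variance
$\mathrm{var}(g) = \sum_{i,i',p,p'} \mathrm{cov}(\epsilon_i^{(p)},
\epsilon_{i'}^{(p')})\,\delta g_i\,\delta g_{i'}$
is evaluated in closed form by *ancestor counting*: the covariance of two
airways is the within-branch covariance times the number of shared
root-path generations, so summing over the $2^{m-1}$ possible common
ancestors at each depth $m$ — each contributing the squared summed
response of its subtree — collapses the double sum over $\sim 10^7$
branches to a few hundred terms.  The same trick, distinguishing airways
on and off a given acinus' feeding path (and, below the terminal
bronchiole, inside and outside its acinus), gives the variance of a single
acinus' FV; these are property-tested against brute-force enumeration of
every airway pair on small trees.

The FV probability density over the whole lung is the acinus-count
weighted Gaussian mixture of the per-class means (model M) and per-acinus
variances.  For a single random lung with many acini, the empirical FV
distribution tends to this mixture.  Cross-region contributions to a
per-acinus FV variance are three orders of magnitude below own-path
contributions in this model; the acceptance analyses exploit mirror
degeneracy (regions with equal entry order share class responses) and
omit cross terms, while `run_experiment("fv-density")` computes whatever
class set it is given.

Global-parameter responses are linear combinations of class responses:
dead-space sensitivity is isotropic scaling at fixed length–diameter
ratio, $\tfrac13\sum N_b(\delta_l + 2\delta_a)$; length–diameter
sensitivity is shape change at fixed volume,
$\tfrac23\sum N_b(\delta_l - \delta_a)$; elastance sensitivity sums the
per-acinus $\delta_K$.  These decompositions are constructions of this
package (the choice of basis is not unique); they reproduce the expected
qualitative behaviour — in the healthy model $\delta_a \approx \delta_l$
for conducting airways (a dead-space response), so the length–diameter
response nearly cancels, while under severe constriction
$\delta_a \approx -2\,\delta_l$ (a resistance response) makes it dominant.

## Validation oracles

Two independent models cross-check the pipeline.  The *two-compartment
analytic washout* solves the two-unit mechanics in closed form and updates
compartment concentrations breath by breath as well-mixed volumes sharing
a common dead space (re-breathing included).  It is compared against the
numerical pipeline configured with two units in the regime where its
assumptions hold: no Taylor dispersion and a molecular diffusivity high
enough to mix each acinus within a breath but low enough that diffusive
loss through the open mouth during inhalation is negligible
(`D0` 0.15 cm²/s, `phi` 1); there the two agree to better than 1% in LCI.
Outside that regime the pipeline's dispersion physics — which the
compartment model lacks — separates the two by several percent, as it
should.

The *Monte-Carlo sampler* is non-perturbative: it expands the tree into
explicit individual airways down to a configurable deepest order, draws
truncated-normal perturbations ($|\epsilon| < 1$, by rejection; symmetric
truncation preserves the zero mode but not exactly the zero mean at large
$\sigma$ — recorded, not corrected) for every explicit airway, builds each
realisation as a partially collapsed exact network and runs the full
pipeline.  The model-P standard deviation is then compared with the
sample's bootstrap confidence interval.

## Numerical choices and problem sizes

* Transport: first-order upwind fluxes in an implicit Euler step.  The
  scheme is an M-matrix, hence monotone ($0 \le c \le 1$) and exactly
  conservative; the implicit system is solved by leaf-to-root elimination
  on the cell tree (zero fill-in, $O(n)$).  Junctions couple the adjacent
  cells directly through conservative interface fluxes instead of carrying
  a separate vertex unknown; vertex concentration continuity is recovered
  with grid refinement, and strict conservation and monotonicity hold at
  any resolution.  Because the breathing cycle is periodic, the eliminated
  operator of each cycle step is cached on the first breath and reused,
  which makes a full washout cost a few seconds at production resolution.
* Default resolution: 10 cells per mean-path edge and 2000 time steps per
  breath.  Halving both changes LCI by under 0.5%, the convergence
  criterion used throughout.
* Comparisons between model arms (sensitivity probes, Monte-Carlo vs
  perturbative variance) always share one grid, so discretisation bias
  cancels in the difference.
* Study sizes used by the shipped tests: constriction sweeps at 600
  steps/cycle and 4 cells/edge; variance studies at 300 steps/cycle and 3
  cells/edge with the Monte-Carlo comparison truncated at Strahler order
  19 (40 explicit units) and 100 realisations per case.  These sizes were
  chosen so the whole study runs on a laptop in minutes; the truncation
  order and realisation count are configuration, and deeper, larger
  studies only tighten the comparison.

## Parameters

| parameter | default | units | meaning / rationale |
|---|---|---|---|
| `V_T` | 1.0 | L | tidal volume, relaxed adult breathing |
| `FRC` | 3.0 | L | end-tidal lung volume incl. dead space, healthy adult male |
| `V_D` | 0.15 | L | anatomical dead space; conducting areas calibrated to it |
| `K_lung` | 5.0 | cmH2O/L | total elastance (compliance 0.2 L/cmH2O) |
| `tau` | 5.0 | s | breath period (12 breaths/min) |
| `mu` | 1.92e-5 | Pa s | air viscosity at body conditions |
| `phi` | 0.4 | — | sac fraction participating in axial diffusion |
| `D0` (SF6) | 0.105 | cm²/s | molecular diffusivity |
| `D0` (N2) | 0.225 | cm²/s | molecular diffusivity |

What the model deliberately leaves out: gravity and posture, inter-unit
mechanical coupling, airway wall compliance, inertial and turbulent
pressure losses (resistance is Poiseuille throughout, hence
underestimated in the large airways), gas exchange and tissue-resident
nitrogen, and any intra-acinar asymmetry.  Consequently phase-III slopes
of the healthy model are near zero — the model's acinar symmetry makes
the diffusion–convection-front mechanism vanish — and simulated washout
is somewhat more efficient than in a real lung.  Passing the shipped
tests therefore demonstrates the stated mechanics on this idealised
geometry, not predictive accuracy for any individual patient.

## Worked example

```{r example}
params <- global_params()
net <- build_model_m(params)
idx <- mbw_indices(run_washout(net, "SF6"))
idx

# response to an 80% radius reduction of the central RM airways
cn <- apply_localised_constriction(
  net, constriction_spec("localised", "central", 0.80, "RM"))
mbw_indices(run_washout(cn, "SF6"))

# perturbative variance of LCI under independent airway heterogeneity
bl <- model_m_baseline(cn, "SF6",
                       list(steps_per_cycle = 300L, cells_per_edge = 3L))
sens <- sensitivity_matrix(
  bl, sensitivity_targets(cn, regions = "RM", orders = 11:16))
output_variance(sens, covariance_model("independent", 0.2, 0.1), cn)
```
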
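# ventnet

Simulation of multiple-breath washout (MBW) on a mean-path model of the
human airway tree, with a perturbative layer for sensitivity analysis and
uncertainty quantification.

MBW is the clinical test in which a subject breathes out an inert tracer
gas (SF6, or resident N2) over many tidal breaths while concentration and
flow are recorded at the mouth; its indices — the lung clearance index
(LCI) and the conductive phase-III slope index (S_cond) — are sensitive
markers of ventilation heterogeneity in obstructive lung disease. ventnet
is for respiratory modellers and physiologists who want a mechanistic,
fast, fully inspectable forward model of the test: how do airway
constrictions of a given depth and severity move LCI, S_cond and the
measured FRC, and how variable are those indices when airway geometry
itself is variable?

## The model

**Ventilation.** Seven lobar regions, each a symmetric bifurcating tree
collapsed to a chain of mean-path edges (an edge at Strahler order *o*
stands for *N_b* identical airways), hang off the explicit asymmetric
proximal airways. Lung-unit volumes **V**(t) follow the lumped linear
viscoelastic system

    (R_cond + R_acin) dV/dt + K (V − V*) = P_drive(t) 1

with Poiseuille airway resistances, elastances partitioned so their
parallel combination is the configured lung elastance, and a sinusoidal
pleural drive calibrated in closed form to the configured tidal volume.

**Gas transport.** Tracer concentration obeys the one-dimensional trumpet
advection–diffusion equation on the same network,

    d/dt [S c] + s d/dx [u c] = s d/dx [D dc/dx],

where `S − s` carries the alveolar-sac volume in the acinar ducts,
`D = D0 + C|u|d` is Taylor dispersion in the conducting airways
(C = 1.08 inspiratory, 0.37 expiratory) and
`D = D0 [1 + phi (S/s − 1)]` is sac-enhanced molecular diffusion in the
acinar ducts. The finite-volume scheme is monotone, exactly conservative,
and solved by zero-fill-in elimination on the cell tree with the
per-cycle-step operator cached across breaths, so a full washout at
production resolution takes about two seconds.

**Perturbation layer ("model P").** Linear responses of every output to
per-airway area/length and per-acinus elastance changes are computed on
split networks (one perturbed branch per degeneracy class), superposed to
reconstruct weakly heterogeneous lungs, and propagated through
tree-structured Gaussian covariance models (independent, or structurally
correlated along parent–child paths) to closed-form output variances and
fractional-ventilation probability densities — without ever enumerating
the ~10^7 individual branches. A two-compartment analytic washout and a
non-perturbative Monte-Carlo sampler serve as independent validation
oracles.

## Worked example

```r
library(ventnet)
params <- global_params()              # healthy adult male, SF6/N2
net    <- build_model_m(params)        # 7 regions, 40960 terminal bronchioles
mbw_indices(run_washout(net, "SF6"))
#> MBW indices (SF6): LCI 5.159 | S_cond -8.18e-07 1/L | FRC 3.001 L
#>   FV range across units: 0.2111 - 0.2130 (19 breaths)
```

The healthy lung clears in 19 breaths with LCI ≈ 5.16 lung turnovers, a
phase-III slope index indistinguishable from zero (the model's acini are
symmetric), a measured FRC that recovers the configured 3.00 L, and all
seven regions turning over ~21% of their gas per breath.

Constricting the central conducting airways of the right-middle lobe
(10% of the acini) to 20% of their radius:

```r
cn <- apply_localised_constriction(
  net, constriction_spec("localised", "central", 0.80, "RM"))
mbw_indices(run_washout(cn, "SF6"))
#> MBW indices (SF6): LCI 6.622 | S_cond 0.235 1/L | FRC 2.913 L
#>   FV range across units: 0.0297 - 0.2229 (23 breaths)
```

LCI rises by ~1.5 turnovers, S_cond becomes large and positive, the
measured FRC loses part of the poorly ventilated lobe, and the
constricted region's fractional ventilation collapses to 3% per breath.
Sweeping severity shows the response is non-monotone, peaking near 80%
radius reduction and returning toward baseline as the lobe becomes
invisible to the test.

How variable is that elevated LCI if airway areas and lengths fluctuate
randomly (coefficients of variation 0.2 and 0.1)?

```r
bl   <- model_m_baseline(cn, "SF6",
                         list(steps_per_cycle = 300L, cells_per_edge = 3L))
sens <- sensitivity_matrix(bl, sensitivity_targets(cn, regions = "RM",
                                                   orders = 11:16))
output_variance(sens, covariance_model("independent", 0.2, 0.1), cn)
#>       output          var          sd
#> 1        LCI 1.558021e-03 0.039471773
#> 2      Scond 1.322224e-05 0.003636240
#> 3 FRC_approx 1.324399e-05 0.003639229
```

Heterogeneity of the already-constricted airways alone gives LCI a
standard deviation of ~0.04 turnovers — two orders of magnitude above the
healthy value under the same perturbations.

A thin command-line dispatcher is installed at
`inst/scripts/ventnet` (`build-net`, `washout`, `sweep`, `baseline`,
`variance`, `fv-density`, `validate`); the methods vignette
(`vignettes/ventnet-methods.Rmd`) documents the model, parameters and
numerical choices in full.

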
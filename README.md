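# soluprint

Where does a hydrophobic drug sit inside a surfactant micelle — buried in
the hydrophobic core, or at the headgroup surface? `soluprint` implements
the three computational analyses used to answer that question for steroid
guests (such as medroxyprogesterone) solubilized in gemini-surfactant
micelles:

1. **Structural solubility fingerprints.** An ECFP4-style circular
   fingerprint Φ is computed for every molecule of a logS training table
   and a Bayesian ridge regression

   y = Φ m + b + ε,  m ~ N(0, α⁻¹I),  ε ~ N(0, β⁻¹)

   is fitted by evidence (type-II maximum likelihood) maximization, using
   the MacKay fixed-point updates γ = Σⱼ λⱼ/(α+λⱼ), α ← γ/mᵀm,
   β ← (N−γ)/‖y−Φm‖². Because every fingerprint bit remembers which atom
   environments set it, the coefficients of a query molecule's on bits can
   be pushed back onto atoms: each bit's coefficient is split equally over
   the center atoms of its environments, giving signed per-atom solubility
   contributions that sum exactly to `prediction − intercept`. Rendered on
   a diverging red/blue scale these form the molecule's "structural
   fingerprint" (red = raises logS, blue = lowers it).

2. **Mulliken charge maps.** From a precomputed density matrix P and
   overlap matrix S, atomic partial charges q_A = Z_A − Σ_{μ∈A}(PS)_{μμ}
   are computed and drawn on the same diverging scale.

3. **ROESY contact localization.** Cross-peak tables (solute proton ×
   surfactant proton) are aggregated by micelle region (chain, terminal
   methyl, spacer, headgroup) and condensed into a radial localization
   score (n_core − n_surface)/(n_core + n_surface) per solute proton,
   labelled core / interface / surface.

A synthetic-data module generates SMILES + logS tables whose logS is an
*exact* additive function of functional-group counts (plus Gaussian
noise), with per-atom ground truth, so every stage — fingerprinting,
regression, attribution — can be validated against known answers without
any external dataset.

## Worked example

```r
library(soluprint)

ds <- generate_solubility_dataset(
  solubility_spec(n_molecules = 500, noise_sd = 0.3, seed = 7))
model <- fit_solubility(ds$table, molecules = ds$truth$molecules)
print(model)
#> Solubility model: ECFP radius 2, 2048 bits, 500 molecules
#> Bayesian ridge regression (evidence maximization)
#>   n = 500, p = 2048 (516 active columns)
#>   alpha = 10.6358, beta = 9.22044 (noise sd = 0.3293)
#>   8 iterations, converged: TRUE
#>   training RMSE = 0.2717, R^2 = 0.9565
```

The estimated noise sd (0.329) recovers the generator's 0.3, and the fit
explains ~96 % of the variance. Predict and attribute a query diol:

```r
sf <- structural_fingerprint(model, "OCC(C)CCO")
sf$prediction
#> -0.706
round(sf$attribution$weights, 3)
#> [1]  0.585  0.136 -0.478 -0.681 -0.539  0.155  0.585
```

The two hydroxyl oxygens (atoms 1 and 7) carry strong positive
(solubilizing) weights; the alkyl carbons carry negative ones. The weights
sum to `prediction − intercept` exactly.
`render_molecule_map(parse_smiles("OCC(C)CCO"), sf$attribution$weights,
file = "map.svg")` writes the colored depiction.

ROESY localization of the transcribed 5 mM contact table:

```r
localization_index(region_summary(make_contact_fixture("5mM")))
#>   proton score   label
#> 1     H4     1    core
#> 2    H20    -1 surface
#> 3    H22     1    core
```

The acetyl-group proton H22 localizes in the hydrophobic core at both
studied concentrations, while H20 (the C6-methyl) contacts only
headgroup-region protons — the core-vs-surface contrast that motivates
the structural-fingerprint analysis.

A command-line front end with `simulate | train | predict | map |
mulliken | roe-summary | pipeline` subcommands is installed at
`inst/scripts/soluprint`.

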
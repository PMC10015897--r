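# tpascreen

Interpretable machine learning for two-photon absorption cross sections
(TPACS) of organic chromophores.

## The problem

Molecules with strong two-photon absorption drive upconverted lasing,
two-photon bioimaging, photodynamic therapy and 3D microprinting, but both
experimental screening and high-level quantum chemistry are far too expensive
for scanning candidate dyes at scale. Experimental cross sections σ (in
Göppert-Mayer units, 1 GM = 10⁻⁵⁰ cm⁴ s photon⁻¹) scatter over several orders
of magnitude and even repeat measurements of the same dye disagree by a
factor of ~2, so all modelling is done in lg(TPACS) = log₁₀(σ/GM) units.

`tpascreen` is an R toolkit for researchers in nonlinear optics and
chromophore design who want to (a) train fast structure–property models for
lg(TPACS) from measurement tables of SMILES + σ + wavelength + solvent, and
(b) interrogate those models for design rules rather than treat them as black
boxes.

## What it computes

- **Featurization from SMILES.** Fragment-count vectors over canonicalized
  atom-centred environments up to radius 4 (the count analogue of unhashed
  extended-connectivity fingerprints, with linkage context stripped so that
  identical fragments collide); a pinned block of whole-molecule 2D
  descriptors; bespoke conjugation descriptors — the conjugation length
  `conju_max_distance` (maximal bond-path distance inside one conjugated
  system), branch ratio, conjugated weight/surface area, donor–acceptor
  ratio; fragment-aggregated atomic properties (`peoe_charge_max`,
  `logp_min`, `mr_max`, …) built by summing per-atom PEOE (Gasteiger)
  charges, additive logP and molar refractivity contributions inside each
  fragment; solvent polarity descriptors (ET(30), dielectric constant, dipole
  moment) and measurement wavelength.
- **Feature selection.** A combined importance index (lasso |coefficient|
  plus mean |SHAP| of two gradient-boosting flavours, averaged over repeated
  CV splits and normalized), one-at-a-time backward elimination, and forward
  stepwise selection seeded with the conjugation length.
- **Model evaluation.** Repeated random 85:15 splits (an 856-sample table
  gives 728 train / 128 test), MSE/MAE/R² in lg units, per-sample prediction
  dispersion across runs, and ensemble prediction with uncertainty for
  screening.
- **Interpretation.** Exact path-dependent tree SHAP in double precision
  (compiled), so attributions plus base value reproduce the tree-walk
  prediction to machine precision; power-law extraction — because SHAP values
  live in lg(TPACS) units, the OLS slope b of φ against lg(conjugation
  length) means TPACS ∝ L^b; accumulated local effects as an independent
  cross-check; and an add-one-feature refit protocol for features outside the
  selected set.
- **Synthetic data.** A generator of homologous conjugated families
  (polyenes, oligophenylene-vinylenes, donor/acceptor-capped polyenes) with a
  planted law lg σ = β·lg L + γ·1[D&A] + ε, emitting the same CSV dialect the
  reader consumes, so the whole pipeline is testable offline against known
  ground truth.

## Worked example

```r
library(tpascreen)

# a homologous synthetic series with a planted power law (beta = 1.8)
ds <- make_series(synth_config(n_samples = 300, beta = 1.8,
                               sigma_noise = 0.3, seed = 42))
samples <- data.frame(molecule_id = ds$molecule_id, smiles = ds$smiles,
                      wavelength = ds$wavelength,
                      et30 = 33.9, dielectric = 2.38, dipole = 0.36)
fm <- assemble_matrix(samples, blocks = c("conjugation", "mff_moe", "experimental"))
fm
#> <feature_matrix> 300 samples x 32 features (conjugation:16, experimental:4, mff_moe:12)

x <- fm$x[, c("conju_max_distance", "peoe_charge_max", "logp_min",
              "mr_max", "wavelength_nm", "et30")]
evaluate(x, ds$lg_tpacs, "xgb", cv_protocol(n_runs = 24, base_seed = 42))
#> <eval_result> xgb: MSE 0.0982, MAE 0.251, R2 0.812 over 24 runs

spec <- tpa_regressors()$xgb
model <- spec$fit(x[, c("conju_max_distance", "peoe_charge_max")], ds$lg_tpacs,
                  seed = 42, h = spec$hyperparameters)
ex <- shap_values(model, x[, c("conju_max_distance", "peoe_charge_max")])
ex
#> <shap_explanation> 300 samples x 2 features, base value 1.993
#>   top mean |phi|: conju_max_distance=0.539, peoe_charge_max=0.0711
fit_power_law(ex, "conju_max_distance")
#> <power_law_fit> conju_max_distance (lg-lg): exponent 1.688 +/- 0.016, intercept -1.803, R2 0.974, n = 300
```

Reading the numbers: the held-out MSE of 0.098 lg² sits just above the
planted noise floor (σ² = 0.09), i.e. the model explains essentially all the
learnable signal; the SHAP profile of the conjugation length is lg-linear
with slope 1.69, close to the planted exponent of 1.8 (tree models attenuate
slopes slightly at the range edges), so the model has rediscovered
TPACS ∝ L^1.8 from the data alone. The base value 1.99 is the mean lg(TPACS)
of the series.

For real measurement tables, `read_measurements()` →
`filter_measurements()` (default 600–1100 nm window, P/Si/I excluded) →
`collapse_to_samples()` (one sample per molecule, peak-σ record) replace the
synthetic block above. A thin command-line wrapper over the same functions is
installed at `inst/cli/tpascreen` (subcommands `simulate`, `featurize`,
`select`, `train`, `evaluate`, `explain`, `predict`).

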
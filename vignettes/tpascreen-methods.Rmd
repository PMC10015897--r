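---
title: "Methods: featurization, selection, and interpretation of TPACS models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: featurization, selection, and interpretation of TPACS models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`tpascreen` models the two-photon absorption cross section of organic
chromophores in base-10 logarithmic units, lg(TPACS) = log10(sigma/GM).
The lg scale is not a convenience: replicate experimental measurements of the
same dye typically agree only within a factor of ~2, so absolute-scale
regression would chase noise. One modelling sample is one molecule together
with the measurement wavelength and a three-descriptor encoding of the
solvent; multi-wavelength molecules are collapsed to a single record before
modelling.

The learning machinery is deliberately conventional — an L1-penalized linear
model and gradient-boosted regression trees evaluated over many random
85:15 train/test splits — because the package's purpose is the *interpretable*
part: which molecular features carry the signal, and what functional form
connects them to the cross section.

## Reading and collapsing measurement tables

`read_measurements()` validates one observation per row (positive sigma,
positive wavelength, parseable SMILES); rejected rows are counted and
reported in a machine-readable attribute, never silently dropped.
`filter_measurements()` applies the study window of 600–1100 nm and removes
molecules containing P, Si, or I (sparse regions where pooled experimental
data are unreliable); it is idempotent. `collapse_to_samples()` groups
records by canonical SMILES and keeps one record per molecule.

*Collapse policy.* Sources rarely state which of several wavelength points a
modeller should keep. The default keeps the record with the maximum cross
section — the peak value is what screening campaigns optimize — with a
nearest-to-target-wavelength policy selectable. Molecule identity is the
OpenBabel canonical SMILES of the largest covalent fragment; stereochemistry
is not used for identity because deposited dye tables specify it
inconsistently.

*Solvent encoding.* Each solvent label maps to literature values of the
ET(30) polarity scale (kcal/mol), the static dielectric constant, and the
gas-phase dipole moment (Debye). The table ships as a versioned CSV with a
citation per row and alias/case-insensitive lookup; unknown labels raise an
error listing the known names rather than being imputed.

## Featurization

**Fragment counts (MFF block).** For every heavy atom and every radius
r = 0..4, the atoms within r bonds form an environment; the environment is
exported as a *standalone* molecule (kekulized bond orders and formal charges
kept, external context discarded, open valences filled with hydrogens) and
canonicalized, so identical fragments from different molecules share one
key. The count vector records how many environments map to each key. Radius
4 follows the extended-connectivity convention of looking 4 bonds out. The
catalog keeps keys occurring in at least `min_support = 2` molecules: a
fragment seen in a single molecule cannot generalize and singleton pruning is
what keeps count featurization usable on sub-thousand-molecule datasets; the
threshold is exposed in configuration. Molecules are canonicalized before
environment enumeration, which makes the whole block invariant to the way
the input SMILES was written.

**General descriptor block.** A pinned roster of 36 whole-molecule 2D
descriptors (mass, composition, ring and rotatable-bond counts, PEOE charge
extrema, additive logP/MR, a polar-surface estimate, E-state extrema,
connectivity indices, graph distances); the roster is versioned in
`inst/extdata/descriptor_manifest.json` so matrices remain reproducible.
Descriptors that fail to compute are imputed with the column median at
assembly time (robust, and standard practice for descriptor tables).

**Atomic attributions and MFF-MOE features.** Three per-atom property
schemes are implemented with implicit hydrogens folded into their heavy
atom:

- *PEOE charges* by the Gasteiger–Marsili iterative
  electronegativity-equalization scheme (quadratic chi(q), damping 1/2 per
  iteration, 8 iterations, formal charges as seeds, hydrogens explicit
  during iteration). Charge is conserved exactly by construction; the
  OpenBabel implementation is used as an independent directional
  cross-check in the tests.
- *Additive logP and molar refractivity* with a compact atom typing
  (element x aromaticity x heteroatom neighbourhood x protonation), values
  adapted from published additive schemes (Wildman–Crippen for carbon and
  logP values; classical atomic refractions for halogens and sulfur). The
  typing is coarser than the original SMARTS tables — that is a documented
  simplification: what the pipeline needs is a self-consistent additive
  scheme whose fragment sums mark polar groups (negative logP) and
  polarizable conjugated fragments (high MR), not bit-exact reproduction of
  any particular toolkit.
- *Van der Waals surface contributions* by a Labute-style approximation
  (sphere area minus neighbour caps at idealized covalent bond lengths).

For each catalog fragment instance, the per-atom values are summed; per
molecule and property the instance sums are aggregated (max/min/mean/sum),
yielding features such as `peoe_charge_max` (most electron-poor fragment),
`logp_min` (most polar fragment) and `mr_max` (most polarizable fragment).
These extremal fragment properties are, by design, nearly independent of
molecular size — which is what lets them carry donor/acceptor information
without proxying the conjugation length.

**Conjugation block.** A bond is flagged conjugated when it is aromatic, has
bond order >= 2, or is a single bond between two pi centres (one may be an
N/O/S/P lone-pair donor). Conjugated systems are connected components of the
flagged subgraph; an isolated double bond is perceived but flagged minimal.
Descriptors include:

- `conju_max_distance` (L): the graph diameter (bond-count shortest paths)
  of the largest conjugated system — the conjugation length;
- `conju_branch_ratio`: the fraction of atoms in the largest system with
  within-system degree >= 3. This definition is a pinned design choice: it is
  dimensionless, bounded in [0, 1], and only weakly coupled to L (a linear
  chain of any length scores 0);
- conjugated weight, molecular weight per heavy atom, conjugated surface
  area, system counts and composition;
- `daratio`: donor and acceptor groups are matched from an editable
  substructure-pattern library (amines/alkoxy/thioether donors;
  nitro/cyano/carbonyl/sulfonyl/pyridinium acceptors); the feature is the
  *maximal* donor-to-acceptor bond path inside a shared conjugated system
  divided by L (the strongest push–pull span; the minimal-path variant is an
  alternative), 0 with an undefined flag when either set is empty. Values
  near 1 indicate dipolar D–pi–A, near 0.5 quadrupolar D–A–D layouts.

## Feature selection

`combined_importance()` averages, over `n_runs` random splits, the normalized
|coefficient| of a lasso and the normalized mean |SHAP| of two boosting
flavours, fitted on z-scored training features (targets stay in lg units),
and combines the three indexes with equal weights (configurable). Equal
weighting is the neutral default for combining heterogeneous importance
scales once each is normalized to sum 1.

`backward_eliminate()` removes the least-important feature one at a time,
recomputing the combined importance every `refresh_every = 10` removals —
strict refreshing after every removal is supported but quadratic in cost,
and on matrices of hundreds of columns the stale ranking between refreshes
changes selections only marginally. Ties remove the later column so traces
are deterministic. `forward_stepwise()` starts from the conjugation length
(the dominant feature of this domain), adds the candidate with the largest
held-out MSE gain, and stops when the best gain drops below
`tolerance = 0.005` lg² — about 5% of the typical noise floor, small enough
to admit real effects and large enough to reject split-to-split jitter.

Selection CV uses fewer runs (default 24) than final evaluation: selection
needs stable rankings, not precise error bars.

## Evaluation

`cv_protocol()` fixes the repeated-split design: `n_runs` (study-scale
default 240) random splits at `test_fraction = 0.15`, train size
`round(n * 0.85)` (856 samples → 728/128), run r seeded by `base_seed + r` so
everything is reproducible and splits are shared across regressors. Metrics
are MSE, MAE and R² on held-out sets, with R² computed against the test-set
variance (pinned convention). The registry implements lasso, elastic net,
two xgboost flavours (`gbrt`: depth 3, eta 0.1, 300 rounds, exact splits;
`xgb`: depth 6, eta 0.05, 500 rounds, histogram splits) and random forest;
DNN/MLP/kNN/AdaBoost exist as documented stubs for external engines. The
paper-scale panel of ten regressors is out of desk scope. Failed runs are
excluded from the means with a warning rather than aborting a 240-run
campaign. `train_ensemble()`/`predict()` provide mean ± sd screening
predictions across the protocol's models.

## Interpretation

`shap_values()` implements the exact path-dependent tree-Shapley algorithm
in compiled double precision over trees parsed from the fitted booster,
with cover-weighted conditional expectations. Three-way agreement is tested:
against brute-force coalition enumeration (machine precision, <= 1e-9),
against the booster's own float32 SHAP (<= 1e-4), and additivity
(base value + sum of attributions = tree-walk prediction, <= 1e-6). Only tree
ensembles are supported; sampling approximations for other model classes are
out of scope because every interpretation in this workflow uses tree models.
Feature/threshold comparisons replicate the float32 semantics of the
underlying library, which matters exactly on split boundaries.

`fit_power_law()` regresses a feature's SHAP values on the lg of the feature
value by unweighted OLS; since phi is in lg(TPACS) units the slope *is* the
power-law exponent (TPACS proportional to L^b), and the standard OLS slope
error is reported. Integer-valued features are never jittered for fitting.
The default explains one model fitted on all samples; pooling SHAP values
across CV models is configurable. `ale_profile()` computes centred
first-order accumulated local effects on 20 quantile bins as a
model-agnostic cross-check of the same slope. `add_feature_and_refit()`
implements the protocol for features outside the selected set: append the
column, refit, read off its SHAP profile.

## The synthetic generator, and what passing tests mean

`make_series()` builds three homologous families by template concatenation —
polyenes (L = 2k − 1), oligophenylene-vinylenes (L = 9 + 6(k − 1)), and
dimethylamino/nitro-capped polyenes (L = 2k + 2, the unambiguous D/A
decoration for the pattern library) — and plants
lg sigma = beta·lg L + gamma·1[D&A] + N(0, sigma_noise²). Defaults
(beta = 1.8, gamma = 0.3, sigma_noise = 0.3, n = 400, 800 nm, toluene,
repeat units 1–8) mirror the statistical structure of pooled experimental
TPA tables: a conjugation-length power law near 1.8, donor/acceptor effects
of a few tenths of a lg unit, and factor-of-two measurement noise. The
template L values are verified against the conjugation module itself, so the
generator cannot drift from the perception rules.

What the generator does *not* emulate: chemical diversity beyond three
scaffolds, wavelength dependence (it fixes 800 nm), solvent variation,
correlated measurement error between related compounds, and the heavy-tailed
composition of literature data. End-to-end recovery of the planted exponent
therefore shows the machinery is correct and unbiased at realistic noise,
not that real chromophore data will yield exponents with this precision.
Within-family, fragment descriptors are deterministic functions of the
repeat count, so feature collinearity is *stronger* in the synthetic sets
than in real tables; the end-to-end recovery test runs the forward-selection
step first for exactly this reason — with redundant correlated features in
the model, Shapley attribution shares credit between them and the fitted
slope attenuates (a property of attribution under collinearity, not a bug).
Tree models also flatten responses at the extremes of a feature's range,
which biases recovered slopes a few percent low even after selection.

## Numerical and degenerate-input conventions

- Charge conservation in PEOE is exact (antisymmetric transfers); tests
  assert 1e-6.
- Constant feature columns get z-score sd 1 (hence zero importance) instead
  of dividing by zero.
- Median imputation for failed descriptors; all-missing columns become 0.
- Saturated molecules: no conjugated systems, L = 0, branch ratio 0,
  conjugated weight/area 0; `daratio` 0 with `defined = FALSE` when either
  group is missing.
- Power-law fits refuse fewer than 3 distinct feature values; ALE refuses
  constant features.
- All stochastic stages consume seeds derived from one base seed; identical
  configuration implies byte-identical traces and artifacts.

## Known limitations

- Canonicalization, aromaticity and kekulization follow OpenBabel; other
  toolkits draw fragment boundaries slightly differently, so catalogs are
  not interchangeable across toolkits (they are stable within one).
- The atomic logP/MR typing is intentionally compact; absolute values for
  exotic functional groups are approximate (directional behaviour is
  tested).
- The 21-descriptor conjugation registry pins seven descriptors by formula;
  the remaining shape/electronic variants are a documented, configurable
  registry and should be treated as approximate.
- Desk-scale defaults (24-run selection CV, 400-sample synthetic sets, 20
  recovery seeds) were chosen so the full validation suite completes in
  minutes on one CPU; study-scale settings (240 runs, 856 molecules) are a
  configuration change, not a code change.
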
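# spectroml

Gaussian-process regression of the spectroscopic constants of
heteronuclear diatomic molecules — the equilibrium distance R<sub>e</sub>
(Å), the harmonic vibrational frequency ω<sub>e</sub> (cm⁻¹) and the
binding energy D<sub>0</sub> (eV) — from periodic-table descriptors of the
two constituent atoms, for researchers in molecular spectroscopy,
ultracold chemistry and data-driven chemical physics who want a
reproducible implementation of this analysis for their own constants
tables.

## What it computes

The central claim the analysis probes is that the spectroscopic
constants depend systematically on the **group g and period p** of the
two atoms.  The model is a GP with explicit basis functions,

> y = h(**x**)ᵀβ + f(**x**) + ε,  f ~ GP(0, k),  ε ~ N(0, σ<sub>y</sub>²),

with the exponential kernel k(r) = σ<sub>f</sub>² e^(−r/ℓ) and a linear
basis for distances, and the Matérn-5/2 kernel with a constant basis for
frequencies and the binding label.  Feature recipes cover the per-atom
(g₁, g₂, p₁, p₂), hydrogen-isotope-resolved groups (H→1.0, D→1.1,
T→1.2), the swap-symmetric averages (ḡ, p̄), molecular inputs such as
1/R<sub>e</sub>, and an electron-transfer descriptor D(IP, EA) for
excited-state targets.  Training sets are permutation-augmented so
predictions are invariant under writing the atoms in the other order.

Models are scored by a stratified Monte-Carlo protocol: 25 equal-count
label strata, one test molecule drawn per stratum per repetition (25
test molecules), 1000 repetitions by default (500 for learning curves),
nested stratified 5-fold cross-validation available for discrete model
selection, and MAE / RMSE / r_E = RMSE/range(y) reported as mean ± sd
over repetitions.  The classical baselines run under the identical split
sequence: the linear regressions of the electron-density model (R_e on
log Z₁Z₂, with ξ̂ and Â recovered from the fit) and the historical
constancy rules (Kratzer, Mecke, Morse, Badger-type, valence-electron)
as distribution diagnostics.

A synthetic-data generator emulates the statistical shape of
experimental constants tables (three truth models expressed in the
classical relations, controllable noise, truth sidecar), so the whole
pipeline is testable without any external data.

## Worked example

```r
library(spectroml)

ds <- generate_dataset(synth_config(n_molecules = 250, noise_Re = 0.05,
                                    seed = 17))
plan <- split_plan(n_mc = 50, seed = 29)

rep_gp <- mc_evaluate(ds, feature_spec(c("g_bar", "p_bar"), "Re",
                                       augment = FALSE),
                      gp_model_spec("matern52", "constant"), plan)
rep_gp
#> eval_report: target Re, GPR(matern52,constant), features g_bar+p_bar
#>   250 molecules, 50 MC reps (0 failed)
#>   test  MAE 0.0534 +/- 0.012 | RMSE 0.08022 +/- 0.039 | r_E 2.75% +/- 1.3
#>   train MAE 0.03524 +/- 0.00093 | RMSE 0.04505 +/- 0.0011 | r_E 1.54% +/- 0.037

lr <- fit_linear_baseline(ds, "logZZ", plan)   # identical splits
lr$report
#> eval_report: target Re, LR, features LR log(Z1Z2)
#>   250 molecules, 50 MC reps (0 failed)
#>   test  MAE 0.2501 +/- 0.029 | RMSE 0.3264 +/- 0.035 | r_E 11.2% +/- 1.2
#>   train MAE 0.2499 +/- 0.0043 | RMSE 0.324 +/- 0.0039 | r_E 11.1% +/- 0.13

report_outliers(rep_gp, k = 3, ds = ds)
#>   formula   y_true test_mean abs_error     bond_type
#> 1     DBe 1.434772  2.247231 0.8124594      covalent
#> 2    FeCs 3.706949  3.447676 0.2592727      covalent
#> 3    LaCs 3.561848  3.374829 0.1870182 ionic-leaning
```

Reading: on data whose truth is a smooth surface over (ḡ, p̄) with 0.05 Å
of injected noise, the matched GP's test RMSE (0.080 Å) sits near the
noise floor and its r_E of 2.8% is about four times better than the
paired log Z₁Z₂ linear baseline (11.2%) — the qualitative GPR ≪ LR
ordering expected for this analysis.  The worst-predicted molecule is a
deuteride at the edge of the descriptor space, tagged by its bond-type
radius ratio.

To run the same analysis on a real constants table, prepare a CSV with
columns `formula, Re, we[, wexe, D0, state]` and run the full
ground-state grid (all GPR feature variants plus the linear baselines;
`--grid table2` adds the A-state rows if `state = "A"` rows are present):

```sh
Rscript inst/cli/spectroml run --data constants.csv --grid table1 \
    --n-mc 1000 --seed 7 --out results/
```

`results/comparison.csv` then has one row per model/feature combination
with test MAE, RMSE and r_E (mean ± sd).  With an experimental table of
a few hundred molecules the expected qualitative outcome is the GPR rows
dominating the LR rows by a factor of several in r_E; exact values
depend on the dataset.

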
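# ilie — iterative linear interaction energy models with confidence scoring

`ilie` estimates protein–ligand binding free energies with the iterative
**linear interaction energy (LIE)** method and tells you *when to trust the
number*. It is aimed at computational chemists running end-point binding
affinity campaigns: docking produces several plausible binding poses per
ligand, each pose seeds one or more molecular dynamics (MD) simulations, and
the ensemble-averaged ligand–surrounding interaction energies from those
simulations are combined into a single prediction.

## The model

For a compound with `N` independent bound-state simulations (replicate runs
started from different docking poses), the predicted binding free energy is

```
ΔG_pred = α Σᵢ Wᵢ ΔVᵢᵛᵈʷ + β Σᵢ Wᵢ ΔVᵢᵉˡᵉ + γ
```

where `ΔVᵢᵛᵈʷ` and `ΔVᵢᵉˡᵉ` are the bound-minus-unbound ensemble averages of
the ligand–surrounding van der Waals and electrostatic interaction energies
of simulation `i` (kJ/mol), and each simulation contributes with a Boltzmann
weight computed from its own single-simulation prediction `ΔG_pred,i`:

```
Wᵢ = exp(−ΔG_pred,i / k_B T) / Σⱼ exp(−ΔG_pred,j / k_B T)
```

so poses predicted to bind more strongly dominate the estimate. The
empirical parameters α, β and the optional offset γ are calibrated against
observed affinities (ΔG_obs, or IC50 values converted via the Cheng–Prusoff
estimate `ΔG_obs = RT ln IC50`) by **iterative weighted ordinary least
squares**: because the weights depend on the parameters being fitted, the
package alternates weight computation and OLS refits from a uniform-weight
start until the parameters stop moving.

Every prediction carries a **confidence index (CI, 0–5)** from a
five-criterion applicability-domain assessment against the training set:

1. prediction inside the range of calculated training free energies;
2. best Tanimoto fingerprint similarity above the training cutoff;
3. Boltzmann-weighted `(ΔV_vdw, ΔV_ele)` pair within the empirical 95th
   percentile of training Mahalanobis distances;
4. per-residue van der Waals energy decomposition within the 95th-percentile
   score and orthogonal distances of the training PCA space;
5. the same for the electrostatic decomposition.

CI 0 means no criterion violated (high confidence); CI 5 means all violated.
The package also selects representative docking poses (PCA on heavy-atom
coordinates, k-means in score space with a 5%-explained-variance growth
rule, medoid extraction) and computes per-residue interaction-frequency
profiles (hydrogen bonds and hydrophobic contacts) from annotated MD frames.

A synthetic-data module generates complete campaigns (energetics,
affinities, fingerprints, decompositions, pose clouds) from the forward
model with known ground truth, so the whole pipeline is testable without
docking or MD.

## Worked example

```r
library(ilie)

spec     <- synthetic_spec(n_compounds = 30, seed = 42)  # known truth:
training <- generate_training_set(spec)                  # a=0.33 b=0.12 g=-13
model    <- calibrate_lie(training)
model
#> <lie_model> alpha = 0.2953, beta = 0.05926, gamma = -15.43 kJ/mol (T = 300 K)
#>   n = 30 compounds; RMSE = 1.877 kJ/mol; r = 0.602; rho = 0.581
#>   4 iteration(s); converged: TRUE (damped); AD reference: FALSE

ref <- build_ad_reference(training, model$parameters)
ref
#> <ad_reference> n = 30 training compounds
#>   dG range [-35.43, -29.23] kJ/mol; Tanimoto cutoff 0.700
#>   Mahalanobis threshold 2.222; PCA components vdw 2 / ele 2

query <- training[[7]]
lie_predict(model$parameters, query$energetics)
#> <lie_prediction> cpd007: dG_pred = -30.413 kJ/mol over 6 simulation(s)
assess_ad(ref, model$parameters, query)
#> <confidence_report> CI = 0/5 (violated: none)

loo_sdep(training[1:10])$sdep_loo   # leave-one-out standard error
#> [1] 1.56  # kJ/mol

poses <- generate_pose_cloud(20, k_true = 2, separation = 1,
                             spread = 0.05, seed = 1)
attr(representative_poses(poses), "clustering")
#> <cluster_result> k = 2, medoid pose(s): 2, 7 (between-cluster fraction 0.97)
```

The fitted parameters land near the generating values (α 0.30 vs 0.33,
β 0.06 vs 0.12, γ −15.4 vs −13 kJ/mol, within the noise-induced
uncertainty of a 30-compound fit at σ = 2 kJ/mol), a training compound
scores CI 0 against its own model, and the two-mode pose cloud is reduced to
its two medoid poses.

## Command line

```sh
Rscript inst/scripts/ilie.R simulate --out-dir data --seed 3
Rscript inst/scripts/ilie.R train --energies data/energies.csv \
    --training data/training.csv --fingerprints data/fingerprints.csv \
    --decomp-vdw data/decomp_vdw.csv --decomp-ele data/decomp_ele.csv \
    --out model.json
Rscript inst/scripts/ilie.R predict --model model.json --energies data/energies.csv
Rscript inst/scripts/ilie.R ad-score --model model.json --energies data/energies.csv \
    --fingerprints data/fingerprints.csv --decomp-vdw data/decomp_vdw.csv \
    --decomp-ele data/decomp_ele.csv
```

See the methods vignette (`vignettes/iterative-lie-confidence.Rmd`) for the
model assumptions, parameter choices, numerical conventions and known
limitations.
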
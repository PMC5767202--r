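---
title: "Iterative LIE binding free energies with applicability-domain confidence scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative LIE binding free energies with applicability-domain confidence scoring}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilie)
```

## The model and its assumptions

Linear interaction energy (LIE) is an end-point method: instead of sampling
an alchemical path, it estimates the binding free energy from the difference
in ensemble-averaged ligand–surrounding interaction energies between the
bound complex and the free solvated ligand,

$$\Delta G_{pred} = \alpha \sum_i^N W_i\, \Delta V_i^{vdw}
                  + \beta \sum_i^N W_i\, \Delta V_i^{ele} + \gamma ,$$

with $\Delta V_i = \langle V \rangle_{bound,i} - \langle V
\rangle_{unbound}$ for each independent bound-state simulation $i$. The
linear-response scaling parameters $\alpha$ (van der Waals) and $\beta$
(electrostatic) and the offset $\gamma$ are empirical and must be calibrated
per target from compounds with measured affinities; the method therefore
inherits the usual end-point assumptions (linear response, adequate
sampling of each basin, force-field fidelity) *plus* a transferability
assumption: the calibrated parameters are only meaningful near the chemical
and interaction space of the training compounds. The confidence machinery
below makes that last assumption auditable.

Docking rarely yields a single trustworthy pose, so several poses per ligand
are simulated (duplicate runs per pose are treated as independent
simulations $i$; the package deliberately does not average replicates per
pose first, as the weighting is defined over simulations, with the
per-simulation granularity preserved in every result). Each simulation
contributes through a Boltzmann weight computed from its own
single-simulation prediction,

$$W_i = \frac{e^{-\Delta G_{pred,i}/k_BT}}
             {\sum_j e^{-\Delta G_{pred,j}/k_BT}},$$

which concentrates the estimate on the poses predicted to bind most
strongly while retaining a principled contribution from the rest. The
weighted prediction is a convex combination of the per-simulation
predictions and is invariant to simulation order and to adding a constant
to all per-simulation values. Weights are evaluated with a max-shifted
exponential (log-sum-exp) so arbitrarily favourable energies cannot
overflow; at the zero-temperature limit ties at the minimum split equally
(a symmetry choice — no simulation is privileged by input order).

### Units and temperature

All energies are kJ/mol throughout; no function converts units silently.
Thermal energy enters as $RT$ with $R = 0.0083145$ kJ mol⁻¹ K⁻¹ so the
weight exponents are dimensionless against molar energies. The default
temperature is 300 K — a conventional simulation temperature — and is
configurable everywhere it matters (`lie_parameters()`,
`cheng_prusoff_dg()`, `calibrate_lie()`); it is recorded in the model file.
Trace averaging defaults to `burn_in = 0` ps (the expectation is that
trajectories handed to the package are production-only), with the burn-in
configurable in `average_trace()` and `read_energy_table()`.

## Calibration

Because the weights depend on the parameters being fitted, calibration is a
fixed-point problem. `calibrate_lie()` alternates

1. compute weights and the weighted design rows
   $(\sum_i W_i \Delta V_i^{vdw}, \sum_i W_i \Delta V_i^{ele})$ under the
   current parameters,
2. refit $\alpha, \beta, \gamma$ by ordinary least squares,

starting from uniform weights, until the largest parameter change drops
below `tol` (default 1e-6) or `max_iter` (default 100) is reached.
Non-convergence is reported in the result (`converged = FALSE`), never
thrown. If a full refit would increase the self-consistent sum of squared
residuals the step is halved towards the previous accepted parameters
(`damped = TRUE` in the result); this keeps the objective non-increasing on
every instance we have generated. A training set of single-simulation
compounds has constant unit weights, so the loop reduces to one plain OLS
fit. The offset $\gamma$ can be fixed to zero (`include_offset = FALSE`);
both modes are supported because either convention is defensible and the
choice is a modelling decision, not a numerical one.

IC50 values are converted with the plain Cheng–Prusoff estimate
$\Delta G_{obs} = RT \ln IC_{50}$ (IC50 in molar). The
substrate-concentration correction term is deliberately omitted: assay
substrate concentrations and Michaelis constants are rarely published
alongside screening IC50s, and the uncorrected form keeps the conversion a
monotone, assumption-light proxy. If true $K_d$/$K_i$ values are available,
supply `dg_obs_kjmol` directly.

Model quality is summarised by RMSE on the training set, the leave-one-out
standard error of prediction (`loo_sdep()`, which reruns the *entire*
iterative calibration n times so the held-out compound never influences
weights or parameters), and Pearson/Spearman correlations (average ranks on
ties; correlations are reported as `NA` when either vector is constant).

## The five-criterion applicability domain

`build_ad_reference()` freezes everything the assessment needs from the
training set; `assess_ad()` evaluates a query against it. One violation
flag per criterion, summed into the confidence index (0 = all satisfied,
5 = all violated):

1. **Prediction range.** The query prediction must fall inside the range of
   *calculated* training free energies (calculated, not experimental: the
   criterion bounds the region where the regression interpolates rather
   than extrapolates). Inclusive at both ends — a compound exactly at the
   training extreme is still interpolation.
2. **Fingerprint similarity.** The best Tanimoto similarity
   ($|a \wedge b| / |a \vee b|$) of the query to any training compound must
   be *strictly greater* than the cutoff, defined as the lowest
   best-neighbour similarity within the training set. Strict, because a
   query that merely ties the least-connected training compound has no
   better support than the worst-supported point of the domain. The
   fingerprint type is the caller's choice (any fixed-length bit vector);
   the synthetic generator produces family-structured bit vectors, and
   hashed circular or path fingerprints from any cheminformatics toolkit
   work unchanged.
3. **Interaction-energy domain.** The Boltzmann-weighted
   $(\Delta V^{vdw}, \Delta V^{ele})$ pair (weighted, for consistency with
   the prediction itself) must lie within the empirical 95th percentile of
   training Mahalanobis distances from the training centroid. The
   covariance is regularised by $+10^{-8} I$ when near-singular.
4. / 5. **Decomposition projection.** The per-residue van der Waals
   (criterion 4) and electrostatic (criterion 5) energy decompositions are
   centred by the training mean and projected onto the training PCA space.
   Both the score distance (eigenvalue-scaled Mahalanobis in the retained
   component space) and the orthogonal distance (norm of the projection
   residual) must be within their empirical 95th-percentile training
   thresholds; violating either flags the criterion. Score distance catches
   exaggerated versions of known interaction patterns; orthogonal distance
   catches patterns the training set never showed.

Percentiles are empirical with the standard linear-interpolation definition
(`stats::quantile` type 7), not parametric chi-square quantiles — the
training distributions are small and not reliably Gaussian, and the
empirical construction makes the self-flag rate (~5%) a testable property.
Criteria 3–5 are inclusive at their thresholds (the threshold *is* a
training-attained distance). PCA components are retained while each adds at
least 5% explained variance, mirroring the pose-clustering rule, with at
least one component always kept.

## Pose selection

Docking poses share the receptor frame, so PCA runs on raw heavy-atom
coordinates (poses × 3·atoms, mean-centred) without prior superposition.
Components are retained under the same 5%-increment rule. k-means then
grows the cluster count from 1, accepting an extra cluster while it adds at
least 5 percentage points of explained variance; the medoid of each cluster
(always a real input pose) is the representative.

One design point deserves its own paragraph: the *denominator* of the
cluster gain. Measured purely within the retained score subspace, splitting
even a structureless single-mode cloud always "explains" a large share
(about 63% for a one-dimensional Gaussian), so the cluster count would grow
without evidence of multimodality. The gain is therefore measured against
the total coordinate-space variance of the poses: variance discarded by
component retention still counts against a split. With this convention a
genuinely unimodal pose cloud stops at $k = 1$, while separated binding
modes are still found immediately (a two-mode cloud with
separation ≫ spread earns its second cluster with a gain near the full
separation variance). The increment (default 0.05) and the k-means seed
(default 42, 10 restarts, best inertia kept, ties broken by lowest pose
index) are arguments. Identical poses are reported as a degenerate input
($k = 1$, zero retained components) rather than an error.

## Interaction profiles

`classify_frame()` types protein–ligand contacts per frame from an
annotated atom table; donor/acceptor/hydrophobe roles are input metadata
from structure preparation, not perceived here (perception belongs to the
preparation toolchain, and silent re-perception could disagree with it).
Default geometric gates — hydrogen bond: donor-heavy-atom to acceptor
distance ≤ 0.35 nm *and* donor–H⋯acceptor angle (vertex at the hydrogen)
≥ 120°; hydrophobic contact: apolar carbon–carbon distance ≤ 0.40 nm — are
conventional values for nm-scale MD analysis and fully configurable through
`interaction_rules()` (or a YAML file on the command line); every profile
records the rule set used. A residue scores at most once per type per
frame; `interaction_profile()` reports, per residue and type, the fraction
of frames with at least one contact. Because hydrophobic contacts are far
more abundant than directed interactions, `display_table()` divides the
hydrophobic column by 10 (configurable) for stacked-bar display — a
display convention only; the stored frequencies are untouched.

## The synthetic-data generator

`synthetic_spec()` describes a training campaign whose data are drawn from
the forward model itself, so the generating parameters are recoverable
ground truth. Defaults, chosen once as plausible study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_compounds` | 30 | a realistic local-model training set |
| `n_poses` / `replicates` | 3 / 2 | typical pose-clustering output; duplicate runs per pose |
| `alpha`, `beta`, `gamma` | 0.33, 0.12, −13 kJ/mol | representative published LIE magnitudes for a nuclear-receptor ligand class |
| `dv_mean`, `dv_cov` | (−45, −15), var 60/30, cov 15 | drug-like vdW/electrostatic interaction magnitudes with mild correlation |
| `noise_sd` | 2 kJ/mol | typical experimental affinity uncertainty |
| `n_residues`, rank | 20, 3 | binding-site-sized decomposition with low-rank structure |
| `fp_length`, families, flip rate | 128, 3, 0.05 | family-structured chemistry, within-family similarity ≫ between |

Decomposition rows are constructed to sum exactly to each compound's
weighted interaction total, so criteria 3–5 operate on mutually consistent
inputs. One global seed drives everything through deterministic per-module
sub-seeds, and generators restore the caller's RNG state.

What the generator deliberately does **not** emulate: force-field error,
sampling noise correlated across simulations, conformational
non-Gaussianity, assay heterogeneity in ΔG_obs, or real chemical-series
fingerprints. Passing tests therefore demonstrate that the estimator,
calibration loop and domain assessment are implemented correctly and are
internally consistent — not that any particular accuracy will be achieved
on a real target, which depends on the simulations feeding the model.

## Numerical choices and problem sizes

- Convergence: max absolute parameter change < 1e-6 (default), cap 100
  iterations; objective-increase steps halved up to 25 times.
- Degenerate inputs: empty-after-burn-in traces, missing unbound
  references, rank-deficient designs and both-empty fingerprints are
  errors naming the offending object; zero-variance PCA inputs and
  identical pose sets are degenerate results, not errors.
- The test suite and the acceptance script run at deliberately modest
  sizes — training sets of 6–30 compounds, 20 Monte-Carlo seeds for the
  recovery study, 2000 compounds for the percentile-containment check,
  pose clouds of 18–200 — sizes at which every property they assert is
  already sharply testable.

## Known limitations

- The applicability-domain thresholds are frozen empirical percentiles; with
  very small training sets (n near the minimum of 5) the 95th percentile is
  dominated by the largest one or two training distances and the criteria
  become lenient.
- The iterative fit has no global-optimality guarantee; with pathological
  pose energetics multiple fixed points are conceivable (none observed in
  generated data; the damped objective is monitored and reported).
- Criterion 2 is only as informative as the fingerprint supplied; the
  package does not standardise on a fingerprint type.
- Interaction typing covers hydrogen bonds and hydrophobic contacts;
  π-stacking, cation–π and halogen bonds are outside the default rule
  vocabulary.
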
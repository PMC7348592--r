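# fconnectome

Graph-theoretical group analysis of resting-state functional brain
connectomes, for case-control studies of network disorganization — e.g.
comparing elderly patients with ischemic white-matter disease against
healthy controls. The package takes per-subject regional (ROI) time
series, motion traces and covariates, and runs the full analysis chain
that such studies report:

1. **Temporal cleaning & motion QC** — linear detrending, 0.01–0.1 Hz
   band-pass filtering, nuisance regression; framewise displacement,
   FD > 0.5 mm scrubbing (2 forward / 1 back), gross-motion (3 mm / 3°)
   and ≤ 5-minutes-remaining exclusion rules.
2. **Network construction** — Pearson / Fisher-z connectivity matrices,
   binarized at fixed sparsity `S` with exact edge counts, swept over
   `S = 0.10 … 0.40` in steps of 0.01 (nested graphs).
3. **Small-world metrics** — clustering coefficient `C_p`, characteristic
   path length `L_p`, global and local efficiency `E_glob`, `E_loc`;
   normalized indices against 100 degree-preserving (Maslov–Sneppen)
   rewired null networks, `γ = C_p/C_p^rand`, `λ = L_p/L_p^rand`,
   `σ = γ/λ` (small-world when `σ > 1`); per-metric area under the curve
   (AUC) across the sweep.
4. **Group inference** — covariate-adjusted (age, gender, education)
   10,000-iteration permutation tests on global metrics, and the
   network-based statistic (NBS): one-tailed edgewise group t-tests inside
   a within-group nonzero-connection mask, suprathreshold connected
   components, familywise-corrected component p-values from the permuted
   maximal component size.
5. **Modular partition** — purity-index assignment of anatomical nodes to
   the 7 functional systems + subcortical module; intra-/inter-module edge
   labelling of significant components.
6. **Brain–behavior & classification** — partial correlations controlling
   covariates; Wilks'-lambda stepwise linear discriminant analysis with
   leave-one-out cross-validation, confusion summaries and ROC AUC.

A seeded synthetic cohort generator (modular block-covariance time series,
group-confounded covariates, connectivity-linked behavior scores, motion
spikes, voxel-label count tables) makes every stage testable and
calibratable offline; it is a first-class, tested module, not a fixture.

## Worked example

```r
library(fconnectome)

labels <- sort(rep(1:8, length.out = 30))
target <- rbind(t(combn(which(labels == 4), 2)),   # ventral attention
                t(combn(which(labels == 5), 2)))   # limbic
spec <- cohort_spec(n_control = 8, n_patient = 8, n_regions = 30,
                    n_timepoints = 120, module_labels = labels,
                    within_module_r = 0.5, between_module_r = 0.05,
                    effect_size = 0.5, seed = 101, target_edges = target)
cfg <- pipeline_config(cohort_spec = spec, sweep = c(0.10, 0.40, 0.06),
                       n_nulls = 5, n_perm = 150, seed = 101)
res <- run_pipeline(cfg)
print(res)
edge_category_counts(res$edge_labels)
```

```
Connectome group analysis: 16 analyzed (8 control, 8 patient), 0 excluded
Permutation tests on metric AUCs (covariate-adjusted):
  cp       diff +0.0133  p = 0.01325
  lp       diff +0.0115  p = 0.3444
  e_glob   diff -0.0008  p = 0.6689
  e_loc    diff +0.0130  p = 0.01325
  gamma    diff +0.1252  p = 0.01987
  lambda   diff +0.0040  p = 0.404
  sigma    diff +0.0993  p = 0.02649
NBS (a_gt_b, t > 1.796, 150 permutations): 114 masked edges
  component 1: 7 links, 5 nodes, corrected p = 0.08609
  component 2: 5 links, 4 nodes, corrected p = 0.1921
  ...
Stepwise LDA classification
  selected features: nbs_conn
  resubstitution  accuracy 93.8%  sensitivity 100.0%  specificity 87.5%
  loocv           accuracy 87.5%  sensitivity 100.0%  specificity 75.0%
  ROC AUC (resubstitution scores): 1.000

                 intra:limbic inter:dorsal_attention-limbic 
                            6                             1
```

Reading the output: the patient group was simulated with the within-module
connectivity of the ventral-attention and limbic systems halved, so the
pipeline finds exactly the signature such a lesion should leave — reduced
clustering, local efficiency, normalized clustering `γ` and small-worldness
`σ` in patients (positive differences are control − patient; permutation
p ≈ 0.01–0.03), an NBS component of reduced connections that is almost
entirely intra-limbic (7 links, familywise-corrected p ≈ 0.09 at this tiny
scale), and a classifier that separates the groups from the mean
connectivity of that component (LOOCV accuracy 87.5%). At this
demonstration scale (8 + 8 subjects, 150 permutations, 5 nulls per graph)
the numbers are noisy; study-scale defaults are 10,000 permutations and
100 rewired nulls.

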
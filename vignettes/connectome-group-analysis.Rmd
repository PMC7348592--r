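---
title: "Methods: graph-theoretical group analysis of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretical group analysis of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fconnectome)
```

## The problem this package addresses

Case-control resting-state fMRI studies of diffuse white-matter disease
(ischemic leukoaraiosis and related small-vessel pathology) typically ask
three questions: (i) is the global topology of the functional brain network
altered in patients — longer characteristic path length `L_p`, lower global
efficiency `E_glob`, weakened small-world organization; (ii) *where* is
connectivity reduced, at the level of connected subnetworks rather than
single edges; and (iii) do those alterations track cognitive performance?
`fconnectome` implements that entire analysis chain for regional
(ROI-level) time series, together with a generative cohort simulator so
every stage can be exercised, calibrated and regression-tested without
access to clinical data.

## Temporal cleaning and motion quality control

Regional signals are cleaned in the order detrend → band-pass → nuisance
regression. The band-pass default is 0.01–0.1 Hz, the conventional
resting-state fluctuation band; the default filter is an ideal FFT-domain
mask (bins outside the band zeroed), matching the behaviour of widely used
resting-state toolchains, with a zero-phase Butterworth variant behind
`method = "butterworth"`. Nuisance regressors (six rigid-body motion
parameters and, if supplied, global/WM/CSF signals) are filtered with the
same band before regression, so that filtered and regressed frequency
content agree; whether the regressors themselves should be filtered is a
genuinely open choice, and this package filters them for internal
consistency.

Motion quality control has two layers:

* **Gross exclusion** — a subject is dropped when any translation reaches
  3 mm or any rotation 3° (boundaries inclusive).
* **Scrubbing** — framewise displacement (FD) is the Power convention,
  `sum |Δtranslation| + r · sum |Δrotation|` with a configurable sphere
  radius of 50 mm. Volumes with FD strictly above 0.5 mm are censored
  together with 1 volume back and 2 forward (windows clipped at the run
  boundaries), and a subject whose surviving data span is ≤ 5 minutes is
  flagged excluded — the boundary itself excludes, and the FD rule is
  strict (`> 0.5`), both configurable.

## Network construction

Connectivity is the Pearson correlation between every pair of regional
time series; Fisher's `atanh` transform (values clipped at
`|r| = 1 - 1e-7`) is stored alongside for edgewise testing. Binary graphs
are built at fixed *sparsity* `S`: the `K = round_half_up(S · N(N-1)/2)`
largest off-diagonal weights become edges. Ranking is by signed weight
(largest positive correlations first; an `absolute` flag ranks by
magnitude), ties at the cutoff are broken by ascending `(i, j)`
lexicographic order, so the edge count is exact at every level and the
result is platform-independent. Because the ranking is computed once, the
sweep over `S = 0.10 … 0.40` in steps of 0.01 (31 levels, the default)
yields *nested* graphs. Whether negative correlations should be excluded
outright before thresholding is left as a configuration choice rather than
assumed.

## Graph metrics and null normalization

Four global metrics are computed per graph: the Watts–Strogatz clustering
coefficient `C_p`, characteristic path length `L_p`, and Latora–Marchiori
global and local efficiency. Conventions, chosen so denominators stay fixed
at `N` across the sweep:

* nodes of degree < 2 contribute 0 to `C_p` and `E_loc` and remain in the
  averages;
* on disconnected graphs `L_p` averages over reachable pairs only and the
  number of unreachable pairs is reported alongside (a harmonic-mean
  variant is available); `E_glob` treats unreachable pairs as zero
  efficiency. Reachable-pair `L_p` can make the normalized `λ` fall below
  1 at very low sparsity, where the thresholded graph is still fragmented
  into modules — the reported `n_unreachable_pairs` makes that regime
  visible.

`C_p` and `L_p` are normalized by their means over an ensemble of
degree-preserving rewired surrogates (Maslov–Sneppen double-edge swaps,
default 100 surrogates, 10 swap trials per edge): `γ = C_p/C_p^rand`,
`λ = L_p/L_p^rand`, `σ = γ/λ`, with `σ > 1` the small-world criterion.
Normalization is done per subject and per sparsity (consistent with
subject-level permutation testing downstream) rather than on group-mean
networks; the alternative exists in the literature but mixes subjects
before the statistics. Each metric is summarized over the sweep by its
trapezoidal area under the curve (AUC), giving one threshold-independent
scalar per subject and metric.

## Group inference

**Permutation test on global metrics.** Metric values (typically AUCs) are
residualized on age, gender and education across both groups pooled; the
observed difference of group means of the residuals is compared with the
distribution over 10,000 random reallocations of subjects into groups of
the original sizes. The test is two-tailed via absolute differences, and
the critical value reported is the 95th percentile of the absolute null —
the natural reading of a two-tailed 5% permutation criterion. p-values use
the `(1 + #{|null| ≥ |obs|}) / (1 + n_perm)` correction so they are valid
(never zero). With covariates that are themselves group-confounded (older
patients), residualize-then-permute is mildly conservative; this is
documented behaviour, not an error.

**Network-based statistic.** The NBS search is restricted to a
*connection mask*: the union of edges whose Fisher-z values differ from
zero (two-tailed one-sample t, uncorrected p < 0.05) within either group.
The mask matters: it excludes connections absent in both groups, whose 5%
false-positive trickle would otherwise percolate into giant random
components on dense masks and drown the component statistic. Within the
mask, each edge is tested with the t-statistic of the group term in the
linear model `z ~ group + age + gender + education` — computed by
Frisch–Waugh from covariate-residualized values and a
covariate-residualized group indicator, and therefore *identical in form
for the observed and every permuted labelling*. We chose this over the
superficially simpler "residualize, then two-sample t on residuals"
because with group-confounded covariates the latter deflates the observed
statistics relative to the permutation null (the projection removes part
of the group contrast itself), costing both calibration symmetry and
power; without covariates the statistic reduces exactly to the pooled
two-sample t. The test is one-tailed with an explicit direction (default:
controls > patients, the direction of interest for disconnection
syndromes). Suprathreshold edges (`t > t_crit(0.05, df)`,
`df = n - 2 - k`) form connected components whose sizes are counted in
links; the null distribution of the *maximal* component size over 10,000
label permutations gives familywise-corrected component p-values, again
with the +1 correction and `≥` comparison by default (`literal = TRUE`
reproduces the plain strict-inequality proportion).

## Modular partition and brain–behavior analysis

Nodes are assigned to seven cortical functional systems plus an eighth
subcortical module by the *purity index*: the modal nonzero voxel label of
each region, with purity = modal count / total nonzero count, ties broken
deterministically toward the lowest system index (and flagged), and a
subcortical override applied last. The package consumes a per-region
label-count table rather than voxel atlases, so any anatomical/functional
atlas pairing can be used; the synthetic generator produces such tables
with controllable purity. Component edges are then labelled
intra-/inter-module with order-independent category strings.

Brain–behavior association is the partial Pearson correlation between a
topological measure (at a fixed sparsity, default `S = 0.40`, or the mean
component connectivity) and a cognitive score, controlling age, gender and
education, with `df = n - 2 - k`.

**Classification.** Exploratory group discrimination uses Wilks'-lambda
stepwise linear discriminant analysis with the SPSS threshold convention
(F-to-enter 3.84, F-to-remove 2.71 — the defaults of the software named in
clinical reports that omit their parameters), observed-frequency priors
(equal priors by flag), leave-one-out cross-validation, and the ROC AUC of
the discriminant scores. Whether published LOOCV figures re-ran selection
inside each fold is usually unknowable; both variants are exposed, and the
honest per-fold selection is the default.

## The synthetic cohort generator

The generator defines the study conditions for every calibration and power
test. Each subject's regional time series is zero-mean multivariate normal
with a block (modular) correlation matrix: `within_module_r` (default 0.5)
inside each of eight functional systems, `between_module_r` (default 0.1)
across systems, unit diagonal. The patient group's matrix has a designated
edge set scaled by `1 - effect_size` (default 0.3 on 56 edges drawn from
between-module pairs among default-mode/frontoparietal/ventral-attention/
limbic systems plus within-module ventral-attention/limbic pairs — the
disconnection pattern reported for leukoaraiosis), followed by a
positive-semidefinite repair (eigenvalues clipped at 1e-8, rescaled to unit
diagonal). `effect_size = 0` makes the groups' generative distributions
identical, the basis of all null-calibration tests. Defaults of 90 regions
and T = 230 volumes at TR = 2 s reflect a typical whole-brain parcellation
and scan length; the acquired volume count in such studies is rarely
reported, so T is an explicit, configurable modelling choice.

Covariates are group-confounded on purpose (controls ~60.8 ± 10.7 years,
patients ~72.5 ± 7.9; education ~11 years; roughly balanced gender),
because that is the regime covariate adjustment must survive. Behavior
scores are linear in each subject's *realized* mean Fisher-z connectivity
over the target edges plus Gaussian noise, so brain–behavior recovery is
testable with known ground truth. Motion traces are smooth random-walk
drifts with Poisson-placed single-volume spikes whose FD exceeds 0.5 mm.

Time series are temporally white by default — this keeps permutation and
FWER calibration exact — with an optional AR(1) coefficient for realism,
since band-pass filtering induces autocorrelation in real data. The
generator does not emulate hemodynamics, physiological noise, scanner
artifacts or spatial structure within regions; passing calibration tests
here demonstrates correctness of the statistical machinery under the
stated model, not robustness to those realisms.

## Numerical and testing choices

* Edge vectors use one canonical lexicographic `(i, j)` ordering
  everywhere; half-up rounding fixes `K` (e.g. `N = 90`, `S = 0.10` gives
  exactly 401 edges).
* Rewiring goes through igraph's degree-sequence-preserving rewiring with
  `10 · |E|` swap trials; the degree sequence is asserted, not assumed.
* Permuted t-statistics are computed for thousands of label permutations
  at once via cross-product algebra, in blocks of 1000 permutations to
  bound memory.
* Test problem sizes are chosen to make the suite informative yet quick:
  metric oracles on 200 random graphs of ≤ 12 nodes against independent
  Floyd–Warshall/triangle-counting implementations at 1e-12; NBS
  familywise error on 200 null cohorts of 20 + 20 subjects at 500
  permutations; planted-component power (15-edge clique, effect 0.5,
  30 + 30 subjects, no between-module correlation, so the connection mask
  is informative) over 10 seeds; permutation-test calibration on 1000 null
  datasets; small-world behaviour on full 31-level sweeps with 20 rewired
  nulls per graph.

## Known limitations

The pipeline analyzes ROI-level text inputs only; spatial preprocessing of
images is out of scope. Weighted or directed variants of the metrics,
nodal centrality, modularity optimization, threshold-free cluster
enhancement, FDR edgewise correction and exchangeability blocks are not
implemented. The Freedman–Lane permutation scheme is a documented
alternative to the single-residualization scheme used here. Stepwise LDA
inherits the known optimism and instability of stepwise procedures at
small n — the honest LOOCV variant quantifies some of it, not all.
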
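---
title: "Methods: phase-resolved memory-task connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-resolved memory-task connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`memnet` analyses case–control task-fMRI studies in which one BOLD run
per subject is split into encoding, maintenance and retrieval phases,
and each phase is summarised by the functional connectivity between
cortical parcels. This vignette records the models, the tunable
parameters, the numerical conventions, and the design decisions taken
where the methodology is genuinely open — together with what the
synthetic cohort does and does not emulate.

## 1. Signal preparation

The run arrives as a volumes × nodes matrix of parcel-mean BOLD.
Preparation is **confound regression → band-pass + detrend → phase
split**, on the *full* run:

- `regress_confounds()` removes, by OLS with an intercept, any supplied
  nuisance columns (head-motion parameters and derivatives, tissue
  components, outlier indicators, HRF-convolved task regressors).
  Building task regressors requires an HRF model and is out of scope;
  they are accepted as precomputed columns. Rank-deficient confound
  sets are an error that names the collinear columns.
- `bandpass_detrend()` removes the per-node linear trend and applies a
  2nd-order Butterworth band-pass (default 0.008–0.09 Hz) as a
  zero-phase forward–backward filter (`signal::filtfilt`). Zero-phase
  filtering is chosen so that filtering cannot shift phase boundaries.
  At TR = 3 s the Nyquist rate is 1/6 Hz ≈ 0.167 Hz, so the upper band
  edge must stay below it; the constructor rejects anything else. Note
  a subtlety of this sampling rate: content near 0.25 Hz aliases to
  ≈ 0.083 Hz, i.e. *into* the passband, and no digital filter applied
  after sampling can remove it. Stopband behaviour is therefore
  meaningfully testable only at sampling rates where the stopband is
  representable (the test suite uses TR = 1 s for that check).
- `split_phases()` cuts the denoised run with 0-based half-open volume
  intervals `[start, end)`; second-based event tables convert by
  `floor(start/TR)`, `ceiling(end/TR)`. Intervals must be disjoint and
  inside the run. Denoising the full run and then splitting is not
  equivalent to splitting first (the filter and trend see different
  data); the full-run order is fixed here because the filter's ringing
  and trend estimates are better behaved on the longer series, and a
  regression test pins the order.

## 2. Connectivity

`compute_fc()` returns the Fisher-z Pearson matrix
`z = atanh(r)` with `r` clamped to ±(1 − 1e−7) so duplicated signals
stay finite, the diagonal fixed at 0, and symmetry enforced exactly.
Zero-variance nodes are an error naming the node. Negative weights are
zeroed **only** on the community-detection path (`zero_negative()`);
group comparisons and `mean_connectivity()` use signed z, since the
zeroing step belongs to modularity's null model, not to the group
statistics. Within-set means average unordered pairs `i < j` (diagonal
excluded); between-set means require disjoint sets.

## 3. Empirical networks

`restrict_and_cluster()` averages the control-group matrices of the
clustering phase (maintenance by default), restricts to the 136 nodes
labelled limbic/DMN/DAN/VAN/FPN, zeroes negatives and clusters.

- Modularity is the weighted Newman–Girvan form with resolution γ
  (default 1; configurable, as no resolution is canonical).
- `louvain()` wraps igraph's multilevel algorithm, deterministic given
  a seed, taking the best of 10 greedy restarts because single greedy
  runs can stop in local optima even on small graphs. Isolated nodes
  become singleton communities rather than errors.
- `consensus_partition()` runs Louvain `n_runs = 100` times
  (single-restart runs, so the ensemble retains the stochastic
  diversity the method relies on), forms the node-pair agreement
  matrix, zeroes entries below τ = 0.5, re-clusters the agreement
  matrix, and iterates to a fixed point (all runs identical up to
  relabelling; 50-iteration cap, then an error). 100 runs and τ = 0.5
  are the common defaults of the consensus approach; none of these
  values is reported by typical study descriptions, so all are exposed.
- Communities are relabelled by descending size with ties broken by
  first occurrence, giving a stable "Network 1/2/3" naming.

## 4. Phase-wise group statistics

- `permutation_mean_test()`: two-sided label-permutation test on a
  per-subject scalar with the add-one convention
  `p = (1 + #{|Δ*| ≥ |Δ|})/(1 + n_perm)` (default 10,000 permutations).
  Permutations are drawn over the sorted pooled values, which makes the
  p-value exactly invariant to swapping the group labels.
- `edgewise_glm_t()`: per-edge OLS of connectivity on intercept, group
  indicator, and covariates (age, sex), computed via
  Frisch–Waugh residualisation so thousands of edges share one
  factorisation. Positive t means controls above patients. Without
  covariates this reduces exactly to the pooled-variance two-sample t.
- `nbs()`: two-sided suprathreshold at `threshold_t` (default: the
  two-sided p = 0.01 Student-t quantile at the design's residual df, a
  standard primary threshold when none is otherwise specified; ties at
  the threshold are included). Positive and negative suprathreshold
  edges form separate graphs; connected components are found by
  union–find; the null distribution of the maximal component edge
  count is built by permuting group labels with covariates kept with
  their subjects (plain label permutation, not Freedman–Lane,
  mirroring NBS v1.2 behaviour); component FWER p-values use the
  add-one convention. Component-level inference is the default;
  per-edge thresholding can be read directly off the returned t-map
  where a binary edge map is wanted. Default 5,000 permutations,
  configurable to 10,000.
- `chi_square_counts()`: Pearson chi-square on the 2×2 table
  `[[k1, n1−k1], [k2, n2−k2]]`, df = 1, **no continuity correction** —
  this convention is pinned by a worked example in the tests — with an
  error when a margin is empty.

## 5. Sample entropy

`SampEn(m, r) = −ln(A/B)`, where `B` counts pairs of length-`m`
templates within Chebyshev distance `r` (self-matches excluded, only
templates that admit an extension are counted) and `A` the pairs whose
length-`(m+1)` extensions also match. Counting is O(n²) in C++;
`A = 0` returns `+Inf` (no matches at m+1), `B = 0` returns `NaN`.
Defaults: m = 2; r = 0.2 × SD. The SD scope is a genuine ambiguity in
study descriptions ("the range in standard deviation from all-time
courses"): the default pools the SD over all node time courses of the
subject's phase (`sd_scope = "all_timecourses"`), which keeps one
tolerance per subject and makes inflated-variance nodes comparable;
per-node scope is available, as is an explicit r. The factor 0.2 is
the field standard. Constant series under per-node scope give r = 0
and an instructive error. Node-wise group comparison shares one set of
label permutations across nodes; multiple-testing correction is off by
default (matching reports that use raw p ≤ 0.05), with a
Benjamini–Hochberg option.

## 6. Mediation

`mediate_fc()` fits the linear no-interaction system
`M = a·T + Γx` and `Y = c′·T + b·M + Γ′x`, so ACME = a·b, ADE = c′,
total = a·b + c′ (identical to the reduced-model coefficient of T, an
identity the tests assert to 1e−8). Treatment, mediator and outcome are
z-scored first, putting effects on the standardized scale on which such
coefficients are usually reported; continuous SUVR is the treatment
rather than a dichotomised amyloid status. Both models adjust for age,
sex and education by default — which covariates belong in which model
is unreported in typical descriptions, so both get all three. Pooled
(both groups) analysis is the default. Uncertainty: nonparametric
bootstrap over subjects (default 10,000 draws), BCa intervals with
jackknife acceleration; degenerate resamples (zero variance in a
variable) are skipped and counted. A percentile option exists for
speed. Two-sided bootstrap p-values use the add-one convention on the
sign distribution. BCa falls back to percentile quantiles when the
bias-correction probit is infinite, and collapses to the point estimate
when the bootstrap distribution is degenerate.

## 7. The synthetic cohort

`generate_cohort()` draws, per subject and phase, temporally white
multivariate Gaussian node signals with a planted block correlation
structure (`build_block_covariance()`: `within_r` inside communities,
`between_r` across, unit diagonal; non-PSD targets are repaired by
convex shrinkage toward the identity in 0.05 steps, recorded on the
result, with an error naming the worst block if 19 steps do not
suffice). Defaults mirror the study conditions the analysis targets:

- 36 patients + 36 controls; 200 nodes; TR 3 s; phases of 100/40/120
  volumes (the 2-minute maintenance delay at TR 3 s is 40 volumes; the
  other lengths are plausible splits of a ~260-volume run and are
  configurable, not asserted).
- `within_r = 0.23`, `between_r = 0.05` — the tanh scale of a control
  within-network Fisher z near 0.236.
- `ad_within_delta = 0.03` subtracted from patients' within-community
  correlation in maintenance and retrieval (not encoding), matching the
  reported size and phase specificity of the deficit.
- Five designated low-entropy nodes: in patients, the node's *own*
  innovation in the Cholesky factorisation is replaced by a
  unit-variance AR(1) process (φ = 0.9) in the deficit phases. Because
  the node is ordered last in the factorisation, every lag-0 covariance
  is exactly preserved and the shared components driving other nodes
  stay white; the node itself becomes temporally predictable (low
  sample entropy). One caveat is inherent: autocorrelation reduces the
  effective sample size of the Pearson estimator, so sample (not
  population) connectivity of pairs touching these nodes is slightly
  biased at short phase lengths. The generator therefore confines the
  entropy manipulation to the deficit phases, keeping unaffected phases
  exactly group-null.
- Mediation path on standardized scales: SUVR drawn
  N(1.1, 0.1²) controls / N(1.4, 0.15²) patients (plausible florbetapir
  scales; free generator parameters, not claims), z-scored to `T`;
  structural mediator `M = a·T + √(1−a²)ε`; each subject's
  retrieval-phase within-community correlation is shifted by
  `fc_scale × M` (0.05 correlation units per SD); memory is
  `c′·T + b·M + noise` with unit total variance. Defaults
  (a, b, c′) = (−0.25, 0.2, −0.2) give a true ACME of −0.05. Because
  the *analysis* measures the mediator as empirical mean connectivity,
  estimation noise attenuates the recovered b somewhat; recovery tests
  at scale therefore use the structural generating model directly, and
  cohort-level checks use interval coverage.
- Age ~ N(69, 7²) truncated to 50–90, sex Bernoulli(0.5), education
  ~ N(12, 3²) truncated to 6–20; task accuracy is a noisy bounded
  transform of the memory score.

Ground truth (planted partition, expected group z per phase, true
ACME, entropy nodes) is written alongside the cohort (`truth.json`)
and is never read by analysis code; `load_cohort()` deliberately skips
it.

What the generator does **not** emulate: hemodynamics and temporal
autocorrelation of real BOLD (all non-entropy signals are white),
spatial smoothness and distance-dependent correlations, motion and
physiological artefacts, site or scanner effects, non-Gaussian tails,
focal (node-specific) rather than uniform within-network deficits, and
any nonlinear amyloid–cognition relationship. Passing recovery tests
on this cohort shows the estimators are correct under their assumed
model — not that the pipeline is robust to everything real data do.

## 8. Pipeline and provenance

`run_pipeline()` chains the stages (connectivity → communities → mean
and NBS comparisons → entropy → associations → mediation); every
stage's seed derives from the master seed by fixed offsets, so a rerun
is bit-identical — `summary.json` is byte-stable and embeds the seed
and an MD5 hash of the configuration. NBS networks default to those
with a significant within-network deficit (falling back to Network 1);
the entropy and mediation stages analyse Network 1 in the retrieval
phase by default. Stages can be disabled, and each stage's function can
be called standalone with identical results (asserted in tests).

## 9. Problem sizes in the test suite

The suite checks calibration and recovery at sizes chosen to give
stable Monte-Carlo answers in a routine run: FWER calibration of the
NBS over 200 null cohorts of 72 subjects × 56 nodes at 1,000
permutations each; deficit-phase localisation over 20 seeded cohorts at
the full 200-node, 36 + 36 design with a 0.2-correlation planted
deficit; mediation bias over 50 draws of n = 500 and null-ACME interval
coverage over 200 draws of n = 72 with 1,000 bootstrap draws; exact
count agreement of the entropy kernel with a brute-force counter on 200
random series; and exhaustive-enumeration checks of Louvain and
modularity on all set partitions of graphs up to 8 nodes.

## 10. Known limitations

- Louvain + consensus does not guarantee a global modularity optimum on
  large graphs; γ, τ and the run count materially shape the partition
  and should be reported with results.
- The NBS controls the family-wise error at the component level only;
  it licenses no claims about individual edges inside a significant
  component.
- The mediation model assumes linearity, no treatment–mediator
  interaction and sequential ignorability; no sensitivity analysis for
  the latter is provided.
- SampEn on short phases (tens of volumes) is noisy and can be infinite
  when no template pair matches at m + 1; such nodes propagate NA
  p-values rather than being silently dropped.
- With equal-variance blocks the planted partition is exactly
  recoverable; real networks have heterogeneous within-community
  correlations, where resolution-limit effects can merge or split
  communities.
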
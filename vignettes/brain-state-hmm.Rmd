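---
title: "Variational Bayesian brain-state modelling with boldhmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational Bayesian brain-state modelling with boldhmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldhmm)
```

## The problem and the model

Resting-state fMRI studies of disorders of arousal control need a way to
quantify *dynamic* brain organization: not which regions are coupled on
average, but which whole-brain configurations recur, how long the brain
stays in each, and whether patients distribute their time differently.
`boldhmm` models a cohort of parcellated BOLD recordings with a K-state
hidden Markov model whose emissions are multivariate Gaussians over R
regions of interest. State k is characterized by a mean-activation vector
$\mu_k$ (its "map": positive entries are activation relative to the
standardized baseline, negative entries suppression) and a covariance
$\Sigma_k$ capturing its co-fluctuation structure. A subject's **fractional
occupancy** (FO) of state k is the temporal mean of the posterior state
probability $\gamma_t(k)$; FO rows sum to one and are the unit of all
downstream statistics.

Inference is variational Bayes with the conjugate exponential-family
construction: Dirichlet priors on the initial distribution and on each
transition-matrix row, and a Normal–inverse-Wishart (NIW) prior on each
emission pair $(\mu_k, \Sigma_k)$. The E step runs a scaled
forward–backward recursion per subject under the *expected* log-parameters
(digamma differences for the Dirichlet blocks, the expected Gaussian
log-density under the NIW posterior for the emissions); the M step applies
the standard conjugate updates with $\gamma$-weighted sufficient
statistics. The objective is the free energy (negative evidence lower
bound),

$$F = -\Big(\textstyle\sum_s \log \tilde Z_s \;-\;
  \mathrm{KL}\big[q(\pi)\,\|\,p(\pi)\big] -
  \sum_j \mathrm{KL}\big[q(A_{j\cdot})\,\|\,p(A_{j\cdot})\big] -
  \sum_k \mathrm{KL}\big[q(\mu_k,\Sigma_k)\,\|\,p(\mu_k,\Sigma_k)\big]\Big),$$

where $\log \tilde Z_s$ is the forward-recursion normalizer of subject $s$
under the expected log-parameters. $F$ is non-increasing over iterations
(asserted on every fit in the test suite), and for K = 1 it equals the
closed-form negative NIW log marginal likelihood to machine precision — the
strongest single check on the KL bookkeeping. Model order is chosen by
fitting a range of K (default 2..16) and keeping the free-energy minimum;
the KL terms supply the complexity penalty, so the free-energy curve turns
upward once states begin to duplicate.

Two deliberate modelling conventions: subjects are independent chains
sharing one parameter set (each subject restarts from the initial
distribution; no transition is counted across a subject boundary), and the
FO used downstream is the *soft* gamma average. A Viterbi-based hard FO is
available (`fractional_occupancy(..., mode = "hard")`); on well-separated
data the two differ by well under 0.05 per entry, and the soft version is
kept as the default because it degrades gracefully when states overlap.

## Priors and tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| Dirichlet concentration | 1 | flat prior over initial/transition rows |
| NIW location $m_0$ | 0 | signals are standardized per subject |
| NIW scale $\kappa_0$ | 1 | one pseudo-observation on each state mean |
| NIW dof $\nu_0$ | R + 2 | smallest value with a finite mean covariance |
| NIW scale matrix $\Psi_0$ | I | unit prior covariance on standardized data |
| `n_restarts` | 5 | independent k-means initializations per fit |
| `tol` | 1e-6 | relative free-energy change declaring convergence |
| `max_iter` | 500 | per-restart iteration cap |
| band-pass | 0.01–0.1 Hz | standard resting-state band |
| `n_drop` | 10 | initial volumes discarded for signal stabilization |

Initialization sets the emission locations to k-means centroids of the
pooled timepoints under a fixed seed, orders them deterministically, and
adds one uniform pseudo-count to the chain posteriors, so every fit is a
deterministic function of (data, K, seed). Every stochastic entry point
takes an explicit seed and derives child seeds by fixed offsets; the same
seed reproduces byte-identical outputs.

## Preprocessing conventions

The imaging path mirrors common ROI-pipeline practice and is fixed in this
order: truncate initial volumes, band-pass (4th-order Butterworth applied
forward and backward, i.e. zero-phase), nuisance regression, standardize.
Nuisance regressors — six realignment parameters plus the global signal,
computed as the mean over all atlas-labelled voxels — are band-passed with
the same filter *before* regression, so the regression cannot reintroduce
stop-band energy. Filtered columns are demeaned before and after filtering;
a band-pass has zero DC gain, so the residual mean is edge-transient noise
and removing it makes the mean-zero postcondition exact. The sample standard
deviation uses denominator $n-1$ everywhere. On atlas overlap the
subcortical label wins, because the subcortical parcellation is the finer,
anatomically specific one. Whether global-signal regression precedes or
follows filtering inside a given preprocessing toolbox varies; here the
order is fixed and logged, and motion-parameter units are accepted as given
(the regression is scale-invariant).

## The synthetic cohort generator

The generator is first-class, tested code: it draws per-subject state paths
from group-specific transition matrices and Gaussian observations from the
state's mean/covariance, so every downstream stage can be validated against
a known truth and against analytic oracles (the stationary distribution of
the generating chain is the expected FO).

Default study conditions: two groups of 30 subjects, 230 timepoints at
TR = 2 s, 71 ROIs, 5 states. Covariances are built as $AA^\top + 0.1 I$
(SPD by construction); state means are rescaled so their minimum pairwise
distance is at least `separation` (default 2) times the average
within-state standard deviation — recoverable but overlapping, a realistic
difficulty for 8-minute scans. The groups differ only in dynamics: the
patient matrix diverts a fraction `shift` of all probability flowing into
state 1 towards state 4. The default `shift = 0.12` was calibrated once,
at design time, to produce group Cohen's d near −1.1 (state 1) and +1.0
(state 4) at the default cohort size — the large-effect regime reported for
this kind of clinical contrast. The sleepiness-like score is
`30 * trueFO(state 4) + N(0, 5)`, giving a moderate Spearman correlation
(about 0.4) within a 30-subject group; and the hallucination-like flag is a
median split of state-1 true FO *within* each group, so the patient group
splits 15/15 as in a median-dichotomized clinical sample (a whole-cohort
split would produce unbalanced patient subgroups, because patients
systematically occupy state 1 less). A `enhanced_state = NA` variant spreads
the diverted mass over all remaining states, for experiments that need
exactly one planted effect.

What the generator does **not** emulate: hemodynamic convolution and its
autocorrelation, scanner drift and spike artifacts, head-motion structure,
inter-subject variability in state maps or dynamics (all subjects share one
truth per group), and voxel-level structure. Passing recovery tests on this
generator therefore demonstrates correctness of the inference machinery
under the model's own assumptions — not robustness to the ways real BOLD
violates them, which is the usual caveat for model-based dynamic-state
analyses.

## Statistical battery

Group contrasts use two-sided Mann–Whitney U tests per state, with the U
statistic reported for the patient group, exact enumeration when both
groups have at most 10 untied observations and a midrank normal
approximation with tie and continuity corrections otherwise; the K raw
p-values are Benjamini–Hochberg adjusted with family size K. Effect size is
the classic pooled-sd Cohen's d on the raw FO values, signed
patient-positive. Clinical associations (subgroup U tests and Spearman
correlations against the symptom score, three states each) are adjusted
*jointly* with family size 6: the two published adjusted values that the
worked examples reproduce (0.042 and 0.078) are only consistent with a
joint six-test family, not with per-family correction over three tests, so
the joint convention is the default (`m` is exposed for other designs).
BH with `m` larger than the number of supplied p-values follows the
step-up definition with the absent p-values treated as non-rejections.

## Numerical choices

- Forward–backward runs in scaled linear space (per-timepoint
  normalization) with a per-timepoint max-shift on the log emission terms;
  the scaling factors sum to the subject's log-normalizer. Implemented in
  C++ (Rcpp) along with Viterbi.
- Viterbi ties break toward the lower state index; `select_k` ties break
  toward smaller K.
- The NIW scale matrix is symmetrized after each update and floored by
  $10^{-6} I$ if a Cholesky factorization fails — relevant for
  high-dimensional covariances on short series.
- A state whose total responsibility falls below $10^{-8}$ reverts to its
  prior with a warning rather than producing a degenerate update.
- State matching between runs maximizes summed Pearson correlation of
  activation maps over permutations — exhaustively for K ≤ 7 (provably
  optimal there), greedily above; constant maps score zero.
- Convergence is declared on relative free-energy change; the trace is
  recorded and its monotonicity asserted in tests.

## Problem sizes used in the tests and the acceptance script

The test suite exercises recovery at desk scale, chosen as the smallest
sizes at which the properties hold comfortably: parameter recovery on 12
subjects x 200 timepoints x 10 ROIs (K = 5), model-order recovery as 20
seeded replicates per cohort type of free-energy scans over K = 2..8 on 12
subjects x 150 x 10 (one restart per K), and statistical power/null
calibration on 50 replicate cohorts of 30 + 30 subjects using true-path
occupancies. The acceptance script additionally fits five replicate cohorts
at the full study dimensions (30 + 30 x 230 x 71) with two restarts each
and averages the recovered effect sizes across replicates, so the reported
numbers characterize the study condition rather than a single cohort draw.

## Known limitations

- One shared emission model per cohort: no subject-level deviations from
  the group state maps (dual estimation is out of scope).
- No autoregressive observation model; temporal structure inside a state is
  white given the state.
- Free-energy model selection inherits the usual variational bias toward
  parsimony; with weak separation or short series it can under-select K.
- The per-patient clinical recomputation utilities
  (`read_per_patient_table`, `clinical_effect_summary`) require a
  per-patient FO/clinical table; the package ships no real cohort data, so
  they are validated on synthetic stand-ins.
- Exhaustive state matching is limited to K ≤ 7; beyond that the greedy
  assignment is not guaranteed optimal.
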
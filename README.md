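# boldhmm

Dynamic brain-state analysis of parcellated resting-state fMRI with a
variational Bayesian Gaussian-observation hidden Markov model (HMM).

Resting-state BOLD activity is not stationary: the brain cycles through a
small repertoire of recurring whole-brain activity configurations. `boldhmm`
recovers that repertoire from multi-subject ROI time series and quantifies
how much time each subject spends in each configuration — the **fractional
occupancy (FO)** — which can then be compared between clinical groups and
correlated with symptom scores. The package targets studies of disorders of
state stability (the motivating application is narcolepsy type 1, where
wake/sleep state control is degraded), but nothing in it is disorder
specific.

## The model

Each subject contributes a standardized T x R matrix (T timepoints, R
regions). Conditional on a hidden state sequence
z_1..z_T with Markov dynamics,

    z_1 ~ Categorical(pi),   z_t | z_{t-1} ~ Categorical(A[z_{t-1}, ]),
    x_t | z_t = k  ~  N(mu_k, Sigma_k),

so each state k is a whole-brain activation pattern mu_k (positive entries =
activation, negative = suppression) with its own R x R covariance Sigma_k.
Inference is variational Bayes with conjugate priors — Dirichlet(1) on `pi`
and each row of `A`, Normal–inverse-Wishart (m0 = 0, kappa0 = 1, nu0 = R + 2,
Psi0 = I) on each (mu_k, Sigma_k) — alternating a forward–backward E step
(under expected log-parameters) with conjugate M updates. The objective is
the **free energy** (negative evidence lower bound), which decreases
monotonically and is used to select the number of states K: the pipeline fits
K = 2..16 and keeps the free-energy minimum. Subjects are modelled as
independent chains sharing one parameter set; chains restart at subject
boundaries.

Downstream statistics follow standard nonparametric practice: two-sided
Mann–Whitney U tests per state with Benjamini–Hochberg FDR correction,
pooled-sd Cohen's d (patient-positive sign), and Spearman rank correlations
for symptom scores, with the published magnitude labels (|d| >= 0.2 / 0.5 /
0.8 = small / moderate / large; |rho| < 0.3 / 0.3–0.5 / > 0.5 = weak /
moderate / strong).

The package also ships the upstream extraction steps (merging a 54-label
subcortical atlas with a 17-network cortical atlas into 71 ROIs, ROI
averaging from 4D NIfTI, truncation of initial volumes, 0.01–0.1 Hz
zero-phase Butterworth band-pass, regression of 6 motion parameters + global
signal, standardization) and a synthetic cohort generator with analytic
Markov-chain oracles, so the entire pipeline is testable end to end without
any imaging download.

## Worked example

Simulate a two-group cohort whose groups differ only in transition dynamics
(state 1 under-expressed, state 4 over-expressed in "patients"), scan K,
and run the group comparison:

```r
library(boldhmm)

gt  <- make_ground_truth(K = 5, R = 10, separation = 2, seed = 1)
coh <- simulate_cohort(gt, n_per_group = 12, T_len = 150, seed = 2)

tab <- scan_states(coh, k_min = 2, k_max = 8, n_restarts = 2,
                   max_iter = 100, seed = 3)
k   <- select_k(tab)        # -> 5, the generating order

fit  <- attr(tab, "fits")[[as.character(k)]]
perm <- match_states(gt$state_means, state_maps(fit)$activation)

fo  <- fractional_occupancy(fit, annotations = coh$manifest)
fom <- fo_matrix(fo)[, perm]; colnames(fom) <- sprintf("FO_%d", 1:5)
fo2 <- structure(cbind(fo[, c("subject_id", "group", "ess", "hallucination")],
                       as.data.frame(fom)),
                 class = c("fo_table", "data.frame"), K = 5L)
run_group_comparison(fo2)
```

which prints (abridged):

```
  state   U       p  p_fdr cohens_d  magnitude significance
1     1  25 0.00726 0.0181   -1.395      Large            *
2     2  61 0.54437 0.5834   -0.331      Small           ns
3     3  83 0.54437 0.5834    0.272      Small           ns
4     4 125 0.00244 0.0122    1.452      Large            *
5     5  82 0.58336 0.5834    0.144 Negligible           ns
```

State 1 (planted occupancy deficit) comes out significantly lower in the
patient group and state 4 significantly higher, with large effect sizes and
FDR-corrected p-values — exactly the planted structure. `U` is reported for
the patient group, so small U means patients rank lower.

`run_pipeline()` wraps the same stages (standardize, scan, FO, state maps,
group and clinical statistics) and writes CSV/JSON outputs plus a run log to
a results directory; `inst/scripts/boldhmm_pipeline.R` exposes it from the
shell.

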
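#' Construct a ground-truth state model for cohort simulation
#'
#' Builds the generative quantities for a K-state Gaussian hidden Markov
#' process over R regions: per-state mean-activation vectors, per-state
#' covariance matrices, an initial state distribution, and one transition
#' matrix per group. The two default groups differ only in their transition
#' dynamics: relative to `"control"`, the `"patient"` matrix diverts a fraction
#' `shift` of all probability flowing into `suppressed_state` towards
#' `enhanced_state`, lowering the stationary occupancy of the former and
#' raising that of the latter. This mimics a cohort in which one whole-brain
#' state is under-expressed and another over-expressed in the clinical group.
#'
#' Covariances are generated as \eqn{AA^\top + 0.1 I} with standard-normal
#' `A/sqrt(R)`, which is symmetric positive definite by construction. State
#' means are drawn independently and rescaled, if necessary, so that the
#' minimum pairwise Euclidean distance between state means is at least
#' `separation` times the average within-state standard deviation
#' (the root-mean-square of the covariance diagonals).
#'
#' @param K number of hidden states (>= 1).
#' @param R number of regions of interest (>= 2).
#' @param separation minimum pairwise mean distance in units of the average
#'   within-state standard deviation. Default 2 gives states that are
#'   recoverable but overlapping, a realistic difficulty for short scans.
#' @param seed integer seed; the ground truth is a deterministic function of
#'   its arguments.
#' @param stay_prob self-transition probability shared by all states in the
#'   control transition matrix; off-diagonal mass is uniform.
#' @param shift fraction of inbound probability diverted away from
#'   `suppressed_state` in the patient group (0 disables the group effect).
#' @param suppressed_state,enhanced_state state indices carrying the planted
#'   group effect (ignored when `K < 2`); `enhanced_state = NA` spreads the
#'   diverted mass over all remaining states so only the suppressed state
#'   carries a concentrated effect.
#' @param covariate_link list with elements `state`, `slope`, `noise_sd`
#'   describing how the sleepiness-like clinical score is generated from a
#'   subject's true fractional occupancy of the linked state.
#' @param flag_state state whose true fractional occupancy is median-split to
#'   assign the hallucination-like binary flag.
#' @return an object of class `hmm_ground_truth` with fields `n_states`,
#'   `n_rois`, `state_means` (K x R), `state_covariances` (list of K R x R SPD
#'   matrices), `transition_by_group` (named list of K x K row-stochastic
#'   matrices), `initial_dist`, `covariate_link`, `flag_state`, `seed`.
#' @examples
#' gt <- make_ground_truth(K = 3, R = 5, separation = 2, seed = 1)
#' sapply(gt$transition_by_group, function(A) range(rowSums(A)))
#' @export
make_ground_truth <- function(K, R, separation = 2, seed = 1L,
                              stay_prob = 0.8, shift = 0.12,
                              suppressed_state = 1L,
                              enhanced_state = min(4L, K),
                              covariate_link = list(state = min(4L, K),
                                                    slope = 30, noise_sd = 5),
                              flag_state = 1L) {
  K <- .check_count(K, "K")
  R <- .check_count(R, "R", min = 2L)
  separation <- .check_positive(separation, "separation")
  .assert(stay_prob > 0 && stay_prob < 1, "`stay_prob` must lie in (0, 1)",
          class = "boldhmm_argument_error")

  withr::with_seed(.child_seed(seed, 1L), {
    covs <- lapply(seq_len(K), function(k) {
      A <- matrix(stats::rnorm(R * R), R, R) / sqrt(R)
      A %*% t(A) + diag(0.1, R)
    })
    means <- matrix(stats::rnorm(K * R), K, R)
  })

  avg_sd <- mean(vapply(covs, function(S) sqrt(mean(diag(S))), 0))
  if (K >= 2) {
    d <- as.matrix(stats::dist(means))
    dmin <- min(d[upper.tri(d)])
    target <- separation * avg_sd
    if (dmin < target) {
      # scaling all means by a common factor scales every pairwise distance
      means <- means * (target / dmin)
    }
  }

  ctrl <- .uniform_chain(K, stay_prob)
  pat <- if (K >= 2 && shift > 0) {
    .shift_inflow(ctrl, from = suppressed_state, to = enhanced_state,
                  delta = shift)
  } else {
    ctrl
  }

  gt <- structure(list(
    n_states = K,
    n_rois = R,
    state_means = means,
    state_covariances = covs,
    transition_by_group = list(patient = pat, control = ctrl),
    initial_dist = rep(1 / K, K),
    covariate_link = covariate_link,
    flag_state = as.integer(flag_state),
    seed = as.integer(seed)
  ), class = "hmm_ground_truth")
  validate_ground_truth(gt)
  gt
}

# K x K chain with common self-transition probability and uniform off-diagonal
.uniform_chain <- function(K, stay_prob) {
  if (K == 1L) return(matrix(1, 1, 1))
  A <- matrix((1 - stay_prob) / (K - 1), K, K)
  diag(A) <- stay_prob
  A
}

# Divert a fraction delta of every row's probability of entering `from`
# towards `to`; rows remain stochastic. With `to = NA` the freed mass is
# spread over the other states in proportion to the row's existing entries,
# so only the suppressed state carries a concentrated effect.
.shift_inflow <- function(A, from, to, delta) {
  moved <- A[, from] * delta
  A[, from] <- A[, from] - moved
  if (is.na(to)) {
    K <- ncol(A)
    for (j in seq_len(K)) {
      rest <- setdiff(seq_len(K), from)
      w <- A[j, rest] / sum(A[j, rest])
      A[j, rest] <- A[j, rest] + moved[j] * w
    }
  } else {
    A[, to] <- A[, to] + moved
  }
  A
}

#' Validate ground-truth invariants
#'
#' Checks row-stochastic transition matrices, a proper initial distribution,
#' symmetric positive-definite covariances and consistent dimensions.
#'
#' @param gt an `hmm_ground_truth` object.
#' @return `gt`, invisibly; errors if an invariant is violated.
#' @export
validate_ground_truth <- function(gt) {
  K <- gt$n_states; R <- gt$n_rois
  .assert(all(dim(gt$state_means) == c(K, R)), "state_means must be K x R")
  .assert(length(gt$state_covariances) == K, "need one covariance per state")
  for (S in gt$state_covariances) {
    .assert(all(dim(S) == c(R, R)) && is_spd(S),
            "every state covariance must be R x R symmetric positive definite")
  }
  for (A in gt$transition_by_group) {
    .assert(all(dim(A) == c(K, K)) && all(A >= 0) &&
              max(abs(rowSums(A) - 1)) < 1e-12,
            "every transition matrix must be K x K row-stochastic")
  }
  .assert(abs(sum(gt$initial_dist) - 1) < 1e-12 && all(gt$initial_dist >= 0),
          "initial_dist must be a probability vector")
  invisible(gt)
}

#' @export
print.hmm_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d states x %d ROIs, groups: %s\n",
              x$n_states, x$n_rois,
              paste(names(x$transition_by_group), collapse = ", ")))
  invisible(x)
}

#' Simulate one subject from a ground-truth model
#'
#' Draws a hidden state path from the group's Markov chain (initial state from
#' `initial_dist`, then row-wise transitions) and one Gaussian observation per
#' timepoint from the current state's mean and covariance.
#'
#' @param gt an `hmm_ground_truth` object.
#' @param group group label; must name an entry of `gt$transition_by_group`.
#' @param T_len number of timepoints.
#' @param seed integer seed; output is a deterministic function of arguments.
#' @return list with `series` (T x R matrix, columns named `ROI_001`, ...)
#'   and `path` (integer vector of true states in `1..K`).
#' @examples
#' gt <- make_ground_truth(K = 2, R = 3, seed = 1)
#' s <- simulate_subject(gt, "control", T_len = 50, seed = 2)
#' table(s$path)
#' @export
simulate_subject <- function(gt, group, T_len, seed) {
  T_len <- .check_count(T_len, "T_len")
  if (!group %in% names(gt$transition_by_group)) {
    stop(errorCondition(sprintf("unknown group '%s'", group),
                        class = c("boldhmm_key_error", "boldhmm_error")))
  }
  A <- gt$transition_by_group[[group]]
  K <- gt$n_states; R <- gt$n_rois

  withr::with_seed(as.integer(seed), {
    path <- integer(T_len)
    path[1] <- sample.int(K, 1L, prob = gt$initial_dist)
    if (T_len > 1) {
      for (t in 2:T_len) path[t] <- sample.int(K, 1L, prob = A[path[t - 1], ])
    }
    series <- matrix(0, T_len, R)
    for (k in seq_len(K)) {
      idx <- which(path == k)
      if (length(idx)) {
        series[idx, ] <- .rmvnorm(length(idx), gt$state_means[k, ],
                                  gt$state_covariances[[k]])
      }
    }
  })
  colnames(series) <- sprintf("ROI_%03d", seq_len(R))
  list(series = series, path = path)
}

#' Simulate a two-group cohort with clinical covariates
#'
#' Generates `n_per_group` subjects per group from a shared ground truth.
#' Groups differ only through their transition matrices. A sleepiness-like
#' clinical score is generated per subject as
#' `slope * trueFO(linked state) + N(0, noise_sd)`, and a hallucination-like
#' binary flag is assigned by splitting the true fractional occupancy of
#' `gt$flag_state` at its within-group median (subjects at or below the median
#' are unflagged), so each group splits into near-equal subgroups as in a
#' median-dichotomized clinical sample.
#'
#' @param gt an `hmm_ground_truth` object.
#' @param n_per_group subjects per group (>= 1).
#' @param T_len timepoints per subject.
#' @param seed master integer seed; per-subject seeds are derived by fixed
#'   offsets so any subject can be regenerated independently.
#' @return an object of class `sim_cohort`: list with `subjects` (each a list
#'   `subject_id`, `group`, `series`, `path`), `manifest` (data.frame with
#'   subject_id, group, ess, hallucination, seed), `true_fo` (subjects x K
#'   matrix of true-path occupancies), `ground_truth`, `seed`.
#' @examples
#' gt <- make_ground_truth(K = 3, R = 4, seed = 1)
#' coh <- simulate_cohort(gt, n_per_group = 4, T_len = 60, seed = 9)
#' coh$manifest
#' @export
simulate_cohort <- function(gt, n_per_group = 30L, T_len = 230L, seed = 1L) {
  n_per_group <- .check_count(n_per_group, "n_per_group")
  T_len <- .check_count(T_len, "T_len")
  groups <- names(gt$transition_by_group)
  K <- gt$n_states

  subjects <- list()
  ids <- character(0); grp <- character(0); seeds <- integer(0)
  i <- 0L
  for (g in groups) {
    for (j in seq_len(n_per_group)) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", g, j)
      s_seed <- .child_seed(seed, 100L + i)
      subj <- simulate_subject(gt, g, T_len, s_seed)
      subjects[[i]] <- list(subject_id = sid, group = g,
                            series = subj$series, path = subj$path)
      ids <- c(ids, sid); grp <- c(grp, g); seeds <- c(seeds, s_seed)
    }
  }

  fo <- t(vapply(subjects, function(s) path_occupancy(s$path, K),
                 numeric(K)))
  rownames(fo) <- ids
  colnames(fo) <- sprintf("state_%d", seq_len(K))

  link <- gt$covariate_link
  withr::with_seed(.child_seed(seed, 2L), {
    ess <- link$slope * fo[, link$state] +
      stats::rnorm(length(ids), sd = link$noise_sd)
  })

  flag_fo <- fo[, gt$flag_state]
  hall <- logical(length(ids))
  for (g in groups) {
    in_g <- grp == g
    hall[in_g] <- flag_fo[in_g] > stats::median(flag_fo[in_g])
  }

  structure(list(
    subjects = subjects,
    manifest = data.frame(subject_id = ids, group = grp,
                          ess = as.numeric(ess), hallucination = hall,
                          seed = seeds, stringsAsFactors = FALSE),
    true_fo = fo,
    ground_truth = gt,
    seed = as.integer(seed)
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects (%s), T = %d, R = %d, K = %d\n",
              length(x$subjects),
              paste(sprintf("%d %s", table(x$manifest$group),
                            names(table(x$manifest$group))), collapse = " + "),
              nrow(x$subjects[[1]]$series), x$ground_truth$n_rois,
              x$ground_truth$n_states))
  invisible(x)
}

#' Empirical state occupancy of a discrete path
#'
#' @param path integer vector of states in `1..K`.
#' @param K number of states.
#' @return length-K vector of occupancy proportions summing to 1.
#' @export
path_occupancy <- function(path, K) {
  tabulate(path, nbins = K) / length(path)
}

#' Stationary distribution of a finite Markov chain
#'
#' Solves \eqn{\pi P = \pi} as the normalized left eigenvector of `P` at
#' eigenvalue 1. The chain must have a unique stationary law (irreducible and
#' aperiodic up to numerical tolerance); otherwise a degenerate-chain error is
#' raised. This is the analytic oracle for the expected long-run fractional
#' occupancy of a simulated subject.
#'
#' @param P K x K row-stochastic matrix.
#' @param tol tolerance for row sums and eigenvalue uniqueness.
#' @return length-K probability vector.
#' @examples
#' stationary_distribution(matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE))
#' @export
stationary_distribution <- function(P, tol = 1e-8) {
  .assert(is.matrix(P) && nrow(P) == ncol(P) && all(P >= -tol) &&
            max(abs(rowSums(P) - 1)) < tol,
          "`P` must be a square row-stochastic matrix",
          class = "boldhmm_argument_error")
  K <- nrow(P)
  if (K == 1L) return(1)
  e <- eigen(t(P))
  mods <- Mod(e$values)
  ones <- which(abs(e$values - 1) < 1e-8)
  # unique stationary law requires a simple unit eigenvalue and no other
  # eigenvalue on the unit circle (periodicity)
  if (length(ones) != 1L || sum(mods > 1 - 1e-8) != 1L) {
    stop(errorCondition(
      "chain has no unique stationary distribution (reducible or periodic)",
      class = c("boldhmm_degenerate_chain", "boldhmm_error")))
  }
  v <- Re(e$vectors[, ones])
  v <- v / sum(v)
  .assert(all(v > -1e-10), "stationary solve produced negative mass")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Write a simulated cohort to disk as plain-text files
#'
#' Writes one TSV per subject (T rows, R labelled columns, full double
#' precision), a manifest CSV (subject id, group, clinical covariates, seed)
#' and a ground-truth JSON (means, covariances, transition matrices, initial
#' distribution).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_roi_tsv(s$series, file.path(dir, paste0(s$subject_id, ".tsv")))
    utils::write.table(
      data.frame(state = s$path),
      file.path(dir, paste0(s$subject_id, "_truepath.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(list(
    n_states = gt$n_states, n_rois = gt$n_rois,
    state_means = gt$state_means,
    state_covariances = gt$state_covariances,
    transition_by_group = gt$transition_by_group,
    initial_dist = gt$initial_dist,
    covariate_link = gt$covariate_link,
    flag_state = gt$flag_state, seed = gt$seed
  ), file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `sim_cohort` (ground truth restored from JSON).
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  gtj <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                             simplifyVector = TRUE)
  gt <- structure(list(
    n_states = gtj$n_states, n_rois = gtj$n_rois,
    state_means = gtj$state_means,
    state_covariances = lapply(seq_len(gtj$n_states), function(k)
      matrix(gtj$state_covariances[k, , ], gtj$n_rois, gtj$n_rois)),
    transition_by_group = lapply(gtj$transition_by_group, function(A)
      matrix(unlist(A), gtj$n_states, gtj$n_states)),
    initial_dist = gtj$initial_dist,
    covariate_link = gtj$covariate_link,
    flag_state = gtj$flag_state, seed = gtj$seed
  ), class = "hmm_ground_truth")

  subjects <- lapply(seq_len(nrow(man)), function(i) {
    sid <- man$subject_id[i]
    series <- read_roi_tsv(file.path(dir, paste0(sid, ".tsv")))
    path <- utils::read.delim(file.path(dir, paste0(sid, "_truepath.tsv")))$state
    list(subject_id = sid, group = man$group[i], series = series, path = path)
  })
  fo <- t(vapply(subjects, function(s) path_occupancy(s$path, gt$n_states),
                 numeric(gt$n_states)))
  rownames(fo) <- man$subject_id
  colnames(fo) <- sprintf("state_%d", seq_len(gt$n_states))
  structure(list(subjects = subjects, manifest = man, true_fo = fo,
                 ground_truth = gt, seed = NA_integer_),
            class = "sim_cohort")
}
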
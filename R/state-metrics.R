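#' Fractional occupancy per subject and state
#'
#' Fractional occupancy (FO) is the proportion of scan time a subject spends
#' in each state. The default (`mode = "soft"`) is the temporal mean of the
#' forward-backward marginal probabilities `gamma`, so rows sum to 1 exactly.
#' `mode = "hard"` instead counts Viterbi-decoded states, which requires the
#' fitted model and the original series (pass a `vbhmm_fit` plus `data`).
#'
#' @param x an `hmm_posteriors` or a `vbhmm_fit`.
#' @param data original input series; required only for `mode = "hard"`.
#' @param mode `"soft"` (gamma mean, default) or `"hard"` (Viterbi counts).
#' @param annotations optional data.frame keyed by `subject_id` whose columns
#'   (e.g. `group`, `ess`, `hallucination`) are joined onto the table.
#' @return an `fo_table`: data.frame with `subject_id`, any annotation
#'   columns, and `FO_1..FO_K`; every row of the FO block sums to 1 (soft
#'   mode) and all entries lie in `[0, 1]`.
#' @export
fractional_occupancy <- function(x, data = NULL, mode = c("soft", "hard"),
                                 annotations = NULL) {
  mode <- match.arg(mode)
  post <- if (inherits(x, "vbhmm_fit")) x$posteriors else x
  .assert(inherits(post, "hmm_posteriors"), "`x` must be posteriors or a fit")
  K <- post$K
  if (mode == "soft") {
    fo <- t(vapply(post$gamma, colMeans, numeric(K)))
  } else {
    .assert(inherits(x, "vbhmm_fit") && !is.null(data),
            "hard mode needs a vbhmm_fit and the original data")
    series <- .as_series_list(data)
    .assert(identical(names(series), post$subject_ids),
            "data subjects do not match the posteriors")
    fo <- t(vapply(series, function(s)
      path_occupancy(viterbi_path(x$model, s), K), numeric(K)))
  }
  out <- data.frame(subject_id = post$subject_ids, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    .assert("subject_id" %in% names(annotations),
            "`annotations` must contain a subject_id column")
    idx <- match(out$subject_id, annotations$subject_id)
    extra <- annotations[idx, setdiff(names(annotations), "subject_id"),
                         drop = FALSE]
    rownames(extra) <- NULL
    out <- cbind(out, extra)
  }
  fo <- as.data.frame(fo)
  names(fo) <- sprintf("FO_%d", seq_len(K))
  out <- cbind(out, fo)
  rownames(out) <- NULL
  structure(out, class = c("fo_table", "data.frame"), K = K)
}

#' Extract the FO matrix block from an `fo_table`
#'
#' @param fo an `fo_table`.
#' @return numeric matrix (subjects x states).
#' @export
fo_matrix <- function(fo) {
  K <- attr(fo, "K") %||% sum(grepl("^FO_\\d+$", names(fo)))
  m <- as.matrix(fo[, sprintf("FO_%d", seq_len(K)), drop = FALSE])
  rownames(m) <- fo$subject_id
  m
}

#' Per-state activation maps and covariance matrices
#'
#' The activation map of a state is the posterior-mean emission mean per ROI
#' (positive values = activation above the standardized baseline, negative =
#' suppression); the state covariance is the posterior-mean emission
#' covariance `Psi / (nu - R - 1)`.
#'
#' @param model a fitted `vbhmm_model`.
#' @return a `state_maps` object: list with `activation` (K x R matrix, ROI
#'   labels as column names) and `covariances` (list of K R x R matrices).
#' @export
state_maps <- function(model) {
  if (inherits(model, "vbhmm_fit")) model <- model$model
  pm <- posterior_means(model)
  act <- pm$means
  colnames(act) <- model$roi_labels
  rownames(act) <- sprintf("state_%d", seq_len(model$K))
  structure(list(activation = act, covariances = pm$covariances),
            class = "state_maps")
}

#' Match states between two fits by activation-map correlation
#'
#' Finds the permutation `p` maximizing the summed Pearson correlation between
#' reference state `k` and candidate state `p[k]` activation vectors, solved
#' by exhaustive optimal assignment for `K <= 7` and by greedy assignment
#' above that.
#'
#' @param reference,candidate `state_maps` objects (or K x R activation
#'   matrices) with equal dimensions.
#' @return integer permutation of `1..K`: `p[k]` is the candidate state
#'   matched to reference state `k`.
#' @export
match_states <- function(reference, candidate) {
  ref <- if (inherits(reference, "state_maps")) reference$activation else as.matrix(reference)
  cand <- if (inherits(candidate, "state_maps")) candidate$activation else as.matrix(candidate)
  .assert(all(dim(ref) == dim(cand)), "reference and candidate dimensions differ")
  K <- nrow(ref)
  if (K == 1L) return(1L)
  score <- suppressWarnings(stats::cor(t(ref), t(cand)))  # score[i, j] = cor(ref i, cand j)
  score[!is.finite(score)] <- 0            # constant maps carry no evidence
  if (K <= 7L) {
    perms <- .permutations(K)
    totals <- apply(perms, 1, function(p) sum(score[cbind(seq_len(K), p)]))
    as.integer(perms[which.max(totals), ])
  } else {
    # greedy fallback for large K: repeatedly take the best remaining pair
    p <- integer(K)
    s <- score
    for (step in seq_len(K)) {
      idx <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
      p[idx[1]] <- idx[2]
      s[idx[1], ] <- NA
      s[, idx[2]] <- NA
    }
    p
  }
}

# all permutations of 1..n as rows
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' State-probability time course for one subject
#'
#' Returns the T x K matrix of forward-backward state probabilities
#' (`gamma`) for a single subject; each row sums to 1.
#'
#' @param posteriors an `hmm_posteriors` or `vbhmm_fit`.
#' @param subject_id subject identifier present in the posteriors.
#' @return T x K numeric matrix.
#' @export
state_probability_timecourse <- function(posteriors, subject_id) {
  post <- if (inherits(posteriors, "vbhmm_fit")) posteriors$posteriors else posteriors
  if (!subject_id %in% post$subject_ids) {
    stop(errorCondition(sprintf("unknown subject '%s'", subject_id),
                        class = c("boldhmm_key_error", "boldhmm_error")))
  }
  g <- post$gamma[[subject_id]]
  colnames(g) <- sprintf("state_%d", seq_len(post$K))
  g
}

#' Mean dwell time and switching rate per subject
#'
#' Supplementary temporal metrics computed from the most probable state at
#' each timepoint: mean run length per state (in timepoints) and the fraction
#' of adjacent timepoint pairs at which the state changes.
#'
#' @param posteriors an `hmm_posteriors` or `vbhmm_fit`.
#' @return data.frame with `subject_id`, `switching_rate`, and
#'   `dwell_1..dwell_K` (NA for states never visited).
#' @export
temporal_metrics <- function(posteriors) {
  post <- if (inherits(posteriors, "vbhmm_fit")) posteriors$posteriors else posteriors
  K <- post$K
  rows <- lapply(post$subject_ids, function(sid) {
    path <- max.col(post$gamma[[sid]], ties.method = "first")
    r <- rle(path)
    dwell <- vapply(seq_len(K), function(k) {
      runs <- r$lengths[r$values == k]
      if (length(runs)) mean(runs) else NA_real_
    }, 0)
    c(switching_rate = sum(diff(path) != 0) / (length(path) - 1), dwell)
  })
  out <- data.frame(subject_id = post$subject_ids,
                    do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("subject_id", "switching_rate", sprintf("dwell_%d", seq_len(K)))
  rownames(out) <- NULL
  out
}

#' State-probability trajectory plot for one subject
#'
#' @param posteriors an `hmm_posteriors` or `vbhmm_fit`.
#' @param subject_id subject to plot.
#' @return a ggplot object (requires ggplot2).
#' @export
plot_state_probabilities <- function(posteriors, subject_id) {
  .assert(requireNamespace("ggplot2", quietly = TRUE),
          "plot_state_probabilities requires ggplot2")
  g <- state_probability_timecourse(posteriors, subject_id)
  df <- data.frame(
    time = rep(seq_len(nrow(g)), ncol(g)),
    probability = as.vector(g),
    state = factor(rep(colnames(g), each = nrow(g))))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = probability, colour = state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Timepoint", y = "State probability",
                  title = subject_id) +
    ggplot2::theme_minimal()
}
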
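#' @useDynLib boldhmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- data plumbing -----------------------------------------------------------

# Coerce supported inputs to a named list of T x R matrices.
.as_series_list <- function(data) {
  if (inherits(data, "sim_cohort")) {
    out <- lapply(data$subjects, function(s) s$series)
    names(out) <- vapply(data$subjects, function(s) s$subject_id, "")
    return(out)
  }
  if (inherits(data, "roi_ts")) data <- list(data)
  if (is.matrix(data)) data <- list(data)
  .assert(is.list(data) && length(data) > 0, "no input series")
  out <- lapply(data, function(d) {
    if (inherits(d, "roi_ts")) d$values else as.matrix(d)
  })
  R <- ncol(out[[1]])
  .assert(all(vapply(out, ncol, 0L) == R),
          "all subjects must share the same number of ROIs")
  if (is.null(names(out)) || any(names(out) == "")) {
    nm <- names(out) %||% rep("", length(out))
    blank <- nm == ""
    nm[blank] <- sprintf("subject_%02d", which(blank))
    names(out) <- nm
  }
  out
}

# ---- model construction ------------------------------------------------------

#' Conjugate priors for the variational Gaussian-observation HMM
#'
#' Dirichlet priors with unit concentration on the initial distribution and on
#' each transition-matrix row, and a Normal-inverse-Wishart emission prior per
#' state with location 0, scale `kappa0 = 1`, degrees of freedom `nu0 = R + 2`
#' (the smallest value giving a finite mean covariance) and identity scale
#' matrix. These are weak, symmetric defaults appropriate for standardized
#' (mean-0, sd-1) ROI signals.
#'
#' @param K number of states.
#' @param R number of ROIs.
#' @param dir_alpha Dirichlet concentration (default 1).
#' @param kappa0,nu0,psi0_scale Normal-inverse-Wishart prior parameters;
#'   `nu0` defaults to `R + 2`, the scale matrix to `psi0_scale * I`.
#' @return list of prior parameters.
#' @export
hmm_priors <- function(K, R, dir_alpha = 1, kappa0 = 1, nu0 = R + 2,
                       psi0_scale = 1) {
  .assert(nu0 > R - 1, "`nu0` must exceed R - 1")
  list(init_alpha = rep(dir_alpha, K),
       trans_alpha = matrix(dir_alpha, K, K),
       m0 = rep(0, R), kappa0 = kappa0, nu0 = nu0,
       Psi0 = diag(psi0_scale, R))
}

.new_model <- function(K, R, prior, post, roi_labels = NULL) {
  structure(list(K = K, R = R, prior = prior, post = post,
                 roi_labels = roi_labels %||% sprintf("ROI_%03d", seq_len(R))),
            class = "vbhmm_model")
}

#' @export
print.vbhmm_model <- function(x, ...) {
  cat(sprintf("Variational Bayesian Gaussian HMM: K = %d states, R = %d ROIs\n",
              x$K, x$R))
  invisible(x)
}

#' Initialize a variational HMM from a k-means partition
#'
#' Emission locations are set to the centroids of a fixed-seed K-cluster
#' partition of the pooled timepoints; transition and initial Dirichlet
#' posteriors are set to their priors plus one uniform pseudo-count. The
#' result is a deterministic function of the data, `K` and `seed`.
#'
#' @param data a list of T x R matrices / [roi_ts()] objects, or a
#'   `sim_cohort`.
#' @param K number of states (>= 1).
#' @param seed integer seed for the centroid initialization.
#' @param prior optional prior list from [hmm_priors()].
#' @return a `vbhmm_model`.
#' @export
init_model <- function(data, K, seed = 1L, prior = NULL) {
  series <- .as_series_list(data)
  K <- .check_count(K, "K")
  X <- do.call(rbind, series)
  R <- ncol(X)
  .assert(K <= nrow(X), "K cannot exceed the total number of timepoints",
          class = "boldhmm_argument_error")
  prior <- prior %||% hmm_priors(K, R)

  centers <- if (K == 1L) {
    matrix(colMeans(X), 1, R)
  } else {
    withr::with_seed(as.integer(seed), {
      km <- suppressWarnings(
        stats::kmeans(X, centers = K, nstart = 1L, iter.max = 50L))
      km$centers
    })
  }
  # stable state ordering: sort centroids by their first principal coordinate
  ord <- order(centers %*% rep(1, R), decreasing = TRUE)
  centers <- centers[ord, , drop = FALSE]

  niw <- lapply(seq_len(K), function(k) {
    list(m = as.numeric(centers[k, ]), kappa = prior$kappa0,
         nu = prior$nu0, Psi = prior$Psi0)
  })
  post <- list(init_alpha = prior$init_alpha + 1,
               trans_alpha = prior$trans_alpha + 1,
               niw = niw)
  labels <- colnames(series[[1]])
  .new_model(K, R, prior, post, labels)
}

# ---- E step ------------------------------------------------------------------

# expected log-determinant of the precision under the NIW posterior
.elogdet_lambda <- function(nu, Psi) {
  R <- nrow(Psi)
  sum(digamma((nu + 1 - seq_len(R)) / 2)) + R * log(2) - .logdet_spd(Psi)
}

# T x K matrix of expected Gaussian log-densities under the NIW posteriors
.expected_log_b <- function(model, X) {
  K <- model$K; R <- model$R
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    q <- model$post$niw[[k]]
    L <- chol(q$Psi)
    Y <- sweep(X, 2, q$m)
    M <- t(forwardsolve(t(L), t(Y)))      # Y %*% solve(L)
    quad <- rowSums(M * M)
    out[, k] <- 0.5 * .elogdet_lambda(q$nu, q$Psi) -
      0.5 * R * log(2 * pi) - 0.5 * (R / q$kappa + q$nu * quad)
  }
  out
}

.expected_log_chain <- function(model) {
  a <- model$post$init_alpha
  A <- model$post$trans_alpha
  list(log_pi = digamma(a) - digamma(sum(a)),
       log_A = digamma(A) - matrix(digamma(rowSums(A)), model$K, model$K))
}

#' Variational E step: forward-backward state posteriors
#'
#' Runs the scaled forward-backward recursion per subject under the
#' variational geometric-mean parameters (`exp` of expected log transition,
#' initial and emission terms). Chains restart at subject boundaries: each
#' subject reuses the initial-state distribution, and no transition is counted
#' across subjects.
#'
#' @param model a `vbhmm_model`.
#' @param data input accepted by [init_model()].
#' @return an object of class `hmm_posteriors`: per-subject `gamma`
#'   (T x K marginal state probabilities), `xi` ((T-1) x K x K pairwise
#'   marginals), and the per-subject scaled log-likelihood `loglik`.
#' @export
e_step <- function(model, data) {
  series <- .as_series_list(data)
  .assert(ncol(series[[1]]) == model$R, "data and model dimensions differ")
  ch <- .expected_log_chain(model)
  gamma <- list(); xi <- list(); loglik <- numeric(length(series))
  for (i in seq_along(series)) {
    X <- series[[i]]
    log_b <- .expected_log_b(model, X)
    if (any(!is.finite(log_b))) {
      stop(errorCondition(
        sprintf("non-finite emission log-density (subject %s)", names(series)[i]),
        class = c("boldhmm_numerical_error", "boldhmm_error")))
    }
    r <- fb_cpp(log_b, ch$log_pi, ch$log_A)
    gamma[[i]] <- r$gamma
    xi[[i]] <- array(r$xi, dim = c(max(nrow(X) - 1L, 0L), model$K, model$K))
    loglik[i] <- r$loglik
  }
  names(gamma) <- names(xi) <- names(loglik) <- names(series)
  structure(list(gamma = gamma, xi = xi, loglik = loglik,
                 subject_ids = names(series), K = model$K),
            class = "hmm_posteriors")
}

# ---- M step ------------------------------------------------------------------

#' Variational M step: conjugate posterior updates
#'
#' Dirichlet posteriors are the priors plus expected initial/transition counts
#' (from `gamma` rows 1 and summed `xi`); Normal-inverse-Wishart posteriors
#' are the standard conjugate updates with `gamma`-weighted sufficient
#' statistics. A state whose total responsibility falls below `1e-8` is
#' flagged empty: its emission posterior reverts to the prior with a warning.
#'
#' @param posteriors an `hmm_posteriors` from [e_step()].
#' @param data input accepted by [init_model()].
#' @param model the current `vbhmm_model` (supplies the priors).
#' @return the updated `vbhmm_model`.
#' @export
m_step <- function(posteriors, data, model) {
  series <- .as_series_list(data)
  K <- model$K; R <- model$R; prior <- model$prior

  init_counts <- Reduce(`+`, lapply(posteriors$gamma, function(g) g[1, ]))
  trans_counts <- Reduce(`+`, lapply(posteriors$xi, function(x)
    apply(x, c(2, 3), sum)))

  Nk <- numeric(K)
  sum_x <- matrix(0, K, R)
  sum_xx <- vector("list", K)
  for (k in seq_len(K)) sum_xx[[k]] <- matrix(0, R, R)
  for (i in seq_along(series)) {
    X <- series[[i]]; G <- posteriors$gamma[[i]]
    Nk <- Nk + colSums(G)
    sum_x <- sum_x + t(G) %*% X
    for (k in seq_len(K)) {
      Xw <- X * sqrt(G[, k])
      sum_xx[[k]] <- sum_xx[[k]] + t(Xw) %*% Xw
    }
  }

  niw <- vector("list", K)
  for (k in seq_len(K)) {
    if (Nk[k] < 1e-8) {
      warning(sprintf("state %d has vanishing responsibility; reverting its emission posterior to the prior", k))
      niw[[k]] <- list(m = prior$m0, kappa = prior$kappa0, nu = prior$nu0,
                       Psi = prior$Psi0)
      next
    }
    xbar <- sum_x[k, ] / Nk[k]
    S <- sum_xx[[k]] - Nk[k] * tcrossprod(xbar)
    kap <- prior$kappa0 + Nk[k]
    m <- (prior$kappa0 * prior$m0 + Nk[k] * xbar) / kap
    nu <- prior$nu0 + Nk[k]
    d0 <- xbar - prior$m0
    Psi <- prior$Psi0 + S + (prior$kappa0 * Nk[k] / kap) * tcrossprod(d0)
    Psi <- (Psi + t(Psi)) / 2
    dimnames(Psi) <- NULL
    if (!is_spd(Psi)) Psi <- Psi + diag(1e-6, R)   # floor for near-singular scatter
    niw[[k]] <- list(m = as.numeric(m), kappa = kap, nu = nu, Psi = Psi)
  }

  post <- list(init_alpha = prior$init_alpha + init_counts,
               trans_alpha = prior$trans_alpha + trans_counts,
               niw = niw)
  .new_model(K, R, prior, post, model$roi_labels)
}

# ---- free energy -------------------------------------------------------------

.kl_dirichlet <- function(a, a0) {
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((a - a0) * (digamma(a) - digamma(sum(a))))
}

# KL between Normal-inverse-Wishart posteriors q and prior p, parametrized by
# (m, kappa, nu, Psi) with Psi the inverse-Wishart scale matrix.
.kl_niw <- function(q, p) {
  R <- length(q$m)
  elogdet <- .elogdet_lambda(q$nu, q$Psi)
  Psi1_inv <- chol2inv(chol(q$Psi))
  # Wishart component (precision parametrization, W = Psi^{-1})
  kl_w <- (q$nu - p$nu) / 2 * elogdet -
    q$nu * R / 2 + q$nu / 2 * sum(p$Psi * Psi1_inv) +
    q$nu / 2 * .logdet_spd(q$Psi) - p$nu / 2 * .logdet_spd(p$Psi) -
    (q$nu - p$nu) * R / 2 * log(2) -
    .lmvgamma(q$nu / 2, R) + .lmvgamma(p$nu / 2, R)
  # conditional Normal component
  dm <- q$m - p$m
  kl_n <- 0.5 * (p$kappa * q$nu * sum(dm * (Psi1_inv %*% dm)) +
                   R * p$kappa / q$kappa - R + R * log(q$kappa / p$kappa))
  kl_w + kl_n
}

#' Variational free energy (negative evidence lower bound)
#'
#' Computes the negative ELBO of the current variational posterior: minus the
#' summed per-subject scaled log-likelihood under the geometric-mean
#' parameters, plus the KL divergences of the initial, transition and emission
#' posteriors from their priors. `posteriors` must come from [e_step()] under
#' the same `model`. Lower is better; across E/M iterations the value is
#' non-increasing.
#'
#' @param model a `vbhmm_model`.
#' @param posteriors the matching `hmm_posteriors`.
#' @return a single number (the free energy).
#' @export
free_energy <- function(model, posteriors) {
  kl <- .kl_dirichlet(model$post$init_alpha, model$prior$init_alpha)
  for (j in seq_len(model$K)) {
    kl <- kl + .kl_dirichlet(model$post$trans_alpha[j, ],
                             model$prior$trans_alpha[j, ])
  }
  p0 <- list(m = model$prior$m0, kappa = model$prior$kappa0,
             nu = model$prior$nu0, Psi = model$prior$Psi0)
  for (k in seq_len(model$K)) kl <- kl + .kl_niw(model$post$niw[[k]], p0)
  fe <- -(sum(posteriors$loglik) - kl)
  if (!is.finite(fe)) {
    stop(errorCondition("non-finite free energy",
                        class = c("boldhmm_numerical_error", "boldhmm_error")))
  }
  fe
}

# ---- fitting -----------------------------------------------------------------

#' Fit a variational Bayesian Gaussian HMM
#'
#' Runs `init -> (E step -> free energy -> M step)` cycles until the relative
#' free-energy change falls below `tol` or `max_iter` is reached, for
#' `n_restarts` independent centroid initializations, and returns the restart
#' with the lowest final free energy.
#'
#' @param data a list of T x R matrices / [roi_ts()] objects or a
#'   `sim_cohort`; subjects are modelled as independent chains sharing one
#'   parameter set.
#' @param K number of states.
#' @param n_restarts independent initializations (default 5).
#' @param tol relative free-energy convergence tolerance (default 1e-6).
#' @param max_iter maximum E/M iterations per restart (default 500).
#' @param seed master integer seed; restart seeds are derived by fixed
#'   offsets.
#' @param verbose print per-restart progress.
#' @return an object of class `vbhmm_fit`: `model`, `posteriors`,
#'   `free_energy` (final value), `free_energy_trace`, `converged`,
#'   `n_iterations`, `K`, `seed`.
#' @examples
#' gt <- make_ground_truth(K = 2, R = 3, separation = 3, seed = 1)
#' coh <- simulate_cohort(gt, n_per_group = 2, T_len = 80, seed = 2)
#' fit <- fit_hmm(coh, K = 2, n_restarts = 1, max_iter = 30, seed = 3)
#' fit$converged
#' @export
fit_hmm <- function(data, K, n_restarts = 5L, tol = 1e-6, max_iter = 500L,
                    seed = 1L, verbose = FALSE) {
  series <- .as_series_list(data)
  K <- .check_count(K, "K")
  n_restarts <- .check_count(n_restarts, "n_restarts")

  best <- NULL
  for (r in seq_len(n_restarts)) {
    model <- init_model(series, K, seed = .child_seed(seed, 500L + r))
    trace <- numeric(0)
    converged <- FALSE
    post <- NULL
    for (it in seq_len(max_iter)) {
      post <- e_step(model, series)
      fe <- free_energy(model, post)
      trace <- c(trace, fe)
      if (it > 1) {
        rel <- abs(trace[it - 1] - fe) / (abs(trace[it - 1]) + 1e-12)
        if (rel < tol) { converged <- TRUE; break }
      }
      model <- m_step(post, series, model)
    }
    if (verbose) {
      message(sprintf("restart %d/%d: FE = %.4f after %d iterations (%s)",
                      r, n_restarts, trace[length(trace)], length(trace),
                      if (converged) "converged" else "max_iter"))
    }
    cand <- structure(list(model = model, posteriors = post,
                           free_energy = trace[length(trace)],
                           free_energy_trace = trace,
                           converged = converged,
                           n_iterations = length(trace),
                           K = K, seed = as.integer(seed)),
                      class = "vbhmm_fit")
    if (is.null(best) || cand$free_energy < best$free_energy) best <- cand
  }
  if (!best$converged) {
    warning(sprintf("no restart reached the tolerance within %d iterations; returning the lowest-free-energy run", max_iter))
  }
  best
}

#' @export
print.vbhmm_fit <- function(x, ...) {
  cat(sprintf("VB-HMM fit: K = %d, free energy = %.3f, %d iterations (%s)\n",
              x$K, x$free_energy, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Maximum a-posteriori state path under posterior-mean parameters
#'
#' Log-space Viterbi decoding with the posterior-mean transition matrix,
#' initial distribution, and per-state Gaussian (mean `m`, covariance
#' `Psi / (nu - R - 1)`). Ties break toward the lower state index.
#'
#' @param model a `vbhmm_model`.
#' @param series T x R matrix or [roi_ts()].
#' @return integer vector of length T with states in `1..K`.
#' @export
viterbi_path <- function(model, series) {
  X <- if (inherits(series, "roi_ts")) series$values else as.matrix(series)
  .assert(ncol(X) == model$R, "series and model dimensions differ")
  K <- model$K; R <- model$R
  .assert(all(vapply(model$post$niw, function(q) q$nu, 0) > R + 1),
          "posterior-mean covariance undefined (nu <= R + 1)")
  log_b <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    q <- model$post$niw[[k]]
    S <- q$Psi / (q$nu - R - 1)
    L <- chol(S)
    Y <- sweep(X, 2, q$m)
    M <- t(forwardsolve(t(L), t(Y)))
    log_b[, k] <- -0.5 * (R * log(2 * pi) + .logdet_spd(S) + rowSums(M * M))
  }
  pi_hat <- model$post$init_alpha / sum(model$post$init_alpha)
  A_hat <- model$post$trans_alpha / rowSums(model$post$trans_alpha)
  viterbi_cpp(log_b, log(pi_hat), log(A_hat))
}

#' Posterior-mean parameter summaries of a fitted model
#'
#' @param model a `vbhmm_model`.
#' @return list with `initial` (length-K), `transition` (K x K row-stochastic),
#'   `means` (K x R), `covariances` (list of K R x R, `Psi / (nu - R - 1)`).
#' @export
posterior_means <- function(model) {
  R <- model$R
  list(initial = model$post$init_alpha / sum(model$post$init_alpha),
       transition = model$post$trans_alpha / rowSums(model$post$trans_alpha),
       means = do.call(rbind, lapply(model$post$niw, function(q) q$m)),
       covariances = lapply(model$post$niw, function(q) {
         .assert(q$nu > R + 1, "posterior-mean covariance undefined (nu <= R + 1)")
         q$Psi / (q$nu - R - 1)
       }))
}

#' Apply a state-label permutation to a model
#'
#' Relabels the states of a fitted model so that new state `k` is old state
#' `perm[k]`; useful for aligning runs via [match_states()].
#'
#' @param model a `vbhmm_model`.
#' @param perm permutation of `1..K`.
#' @return the relabelled `vbhmm_model`.
#' @export
permute_states <- function(model, perm) {
  .assert(setequal(perm, seq_len(model$K)), "`perm` must be a permutation of 1..K")
  post <- model$post
  post$init_alpha <- post$init_alpha[perm]
  post$trans_alpha <- post$trans_alpha[perm, perm, drop = FALSE]
  post$niw <- post$niw[perm]
  .new_model(model$K, model$R, model$prior, post, model$roi_labels)
}

#' Serialize a fitted model to JSON at full precision
#'
#' @param model a `vbhmm_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    K = model$K, R = model$R, roi_labels = model$roi_labels,
    prior = model$prior,
    post = list(init_alpha = model$post$init_alpha,
                trans_alpha = model$post$trans_alpha,
                niw = model$post$niw)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path JSON file.
#' @return a `vbhmm_model`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- j$R
  prior <- list(init_alpha = j$prior$init_alpha,
                trans_alpha = matrix(unlist(j$prior$trans_alpha), j$K, j$K),
                m0 = j$prior$m0, kappa0 = j$prior$kappa0, nu0 = j$prior$nu0,
                Psi0 = matrix(unlist(j$prior$Psi0), R, R))
  niw <- lapply(seq_len(j$K), function(k) {
    q <- if (is.data.frame(j$post$niw)) {
      list(m = j$post$niw$m[[k]], kappa = j$post$niw$kappa[[k]],
           nu = j$post$niw$nu[[k]], Psi = j$post$niw$Psi[[k]])
    } else {
      j$post$niw[[k]]
    }
    list(m = as.numeric(q$m), kappa = as.numeric(q$kappa),
         nu = as.numeric(q$nu), Psi = matrix(unlist(q$Psi), R, R))
  })
  post <- list(init_alpha = j$post$init_alpha,
               trans_alpha = matrix(unlist(j$post$trans_alpha), j$K, j$K),
               niw = niw)
  .new_model(j$K, R, prior, post, j$roi_labels)
}
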
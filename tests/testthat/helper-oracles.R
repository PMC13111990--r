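# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Exhaustive path-sum posterior marginals for a small HMM, given log initial
# weights, log transition weights and a T x K matrix of log emission terms.
enumerate_posteriors <- function(log_pi, log_A, log_b) {
  K <- length(log_pi); Tn <- nrow(log_b)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  logw <- apply(paths, 1, function(z) {
    lw <- log_pi[z[1]] + log_b[1, z[1]]
    if (Tn > 1) for (t in 2:Tn) lw <- lw + log_A[z[t - 1], z[t]] + log_b[t, z[t]]
    lw
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K)) {
    gamma[t, k] <- sum(w[paths[, t] == k])
  }
  xi <- array(0, dim = c(max(Tn - 1, 0), K, K))
  if (Tn > 1) {
    for (t in seq_len(Tn - 1)) for (j in seq_len(K)) for (k in seq_len(K)) {
      xi[t, j, k] <- sum(w[paths[, t] == j & paths[, t + 1] == k])
    }
  }
  list(gamma = gamma, xi = xi, map_path = as.integer(paths[which.max(logw), ]))
}

# Expected-log chain parameters of a fitted variational model, recomputed from
# its posterior hyperparameters with plain digamma calls.
expected_log_params <- function(model) {
  a <- model$post$init_alpha
  A <- model$post$trans_alpha
  K <- model$K
  log_A <- digamma(A) - matrix(digamma(rowSums(A)), K, K)
  list(log_pi = digamma(a) - digamma(sum(a)), log_A = log_A)
}

# Expected Gaussian log-density under the Normal-inverse-Wishart posterior,
# computed entry by entry with dense solves.
expected_log_density <- function(model, X) {
  K <- model$K; R <- model$R
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    q <- model$post$niw[[k]]
    elogdet <- sum(digamma((q$nu + 1 - seq_len(R)) / 2)) + R * log(2) -
      as.numeric(determinant(q$Psi, logarithm = TRUE)$modulus)
    Pinv <- solve(q$Psi)
    for (t in seq_len(nrow(X))) {
      d <- X[t, ] - q$m
      out[t, k] <- 0.5 * elogdet - R / 2 * log(2 * pi) -
        0.5 * (R / q$kappa + q$nu * drop(t(d) %*% Pinv %*% d))
    }
  }
  out
}

# Brute-force Benjamini-Hochberg step-up adjustment straight from the
# definition: adjusted_i = min(1, min_{j: p_(j) >= p_i over ranks >= rank_i}
# m * p_(j) / j), computed on the sorted vector and mapped back.
bh_stepup_oracle <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(m * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group labelings.
mwu_enumeration_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_stat <- function(xi, yi) {
    sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  }
  u_obs <- u_stat(x, y)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n * m / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

# Sample covariance with denominator n - 1 (textbook form, loop-free ops only
# on purpose kept distinct from any package code path).
sample_cov_oracle <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  t(Xc) %*% Xc / (n - 1)
}

# Small well-separated two-blob dataset for initialization tests.
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
}
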
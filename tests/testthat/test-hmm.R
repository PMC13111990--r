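two_state_toy <- function(T_len = 3, R = 2, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(T_len * R), T_len, R))
}

test_that("initialization is deterministic and centroid-accurate", {
  centers <- rbind(c(-4, -4), c(4, 4))
  X <- make_blobs(40, centers, sd = 0.1, seed = 2)
  m1 <- init_model(list(X), K = 2, seed = 7)
  m2 <- init_model(list(X), K = 2, seed = 7)
  expect_identical(m1, m2)
  locs <- do.call(rbind, lapply(m1$post$niw, `[[`, "m"))
  # each blob center matched by some component within 0.1
  for (i in 1:2) {
    expect_lt(min(sqrt(rowSums(sweep(locs, 2, centers[i, ])^2))), 0.1)
  }
  # K = 1 collapses to the pooled mean
  m0 <- init_model(list(X), K = 1, seed = 1)
  expect_equal(m0$post$niw[[1]]$m, colMeans(X), tolerance = 1e-12)
  expect_error(init_model(list(X[1:3, ]), K = 10, seed = 1),
               class = "boldhmm_argument_error")
})

test_that("e_step equals brute-force path enumeration on small problems", {
  for (cfg in list(list(K = 2, T = 3, R = 2), list(K = 3, T = 5, R = 2),
                   list(K = 2, T = 8, R = 3))) {
    X <- two_state_toy(cfg$T, cfg$R, seed = cfg$K * 10 + cfg$T)
    model <- init_model(list(X), K = cfg$K, seed = 1)
    post <- e_step(model, list(X))
    oracle <- enumerate_posteriors(expected_log_params(model)$log_pi,
                                   expected_log_params(model)$log_A,
                                   expected_log_density(model, X))
    expect_equal(post$gamma[[1]], oracle$gamma, tolerance = 1e-8)
    expect_equal(post$xi[[1]], oracle$xi, tolerance = 1e-8)
  }
})

test_that("posterior marginals satisfy their normalization identities", {
  gt <- make_ground_truth(K = 3, R = 4, seed = 3)
  coh <- simulate_cohort(gt, n_per_group = 2, T_len = 40, seed = 4)
  model <- init_model(coh, K = 3, seed = 5)
  post <- e_step(model, coh)
  for (s in post$subject_ids) {
    g <- post$gamma[[s]]; xi <- post$xi[[s]]
    expect_lt(max(abs(rowSums(g) - 1)), 1e-10)
    expect_lt(max(abs(apply(xi, 1, sum) - 1)), 1e-10)
    Tn <- nrow(g)
    expect_lt(max(abs(apply(xi, c(1, 2), sum) - g[-Tn, ])), 1e-8)
    expect_lt(max(abs(apply(xi, c(1, 3), sum) - g[-1, ])), 1e-8)
  }
})

test_that("identical emissions across states leave gamma at the chain marginals", {
  X <- two_state_toy(20, 2, seed = 6)
  model <- init_model(list(X), K = 2, seed = 1)
  # force both emission posteriors identical
  model$post$niw[[2]] <- model$post$niw[[1]]
  # and a symmetric chain posterior
  model$post$init_alpha <- c(5, 5)
  model$post$trans_alpha <- matrix(5, 2, 2)
  post <- e_step(model, list(X))
  expect_equal(post$gamma[[1]], matrix(0.5, 20, 2), tolerance = 1e-10)
})

test_that("near-delta emissions recover the nearest-mean labeling", {
  gt <- make_ground_truth(K = 3, R = 3, separation = 4, seed = 7)
  gt$state_covariances <- lapply(gt$state_covariances, function(S) S * 1e-4)
  coh <- simulate_cohort(gt, n_per_group = 1, T_len = 60, seed = 8)
  fit <- fit_hmm(coh, K = 3, n_restarts = 2, max_iter = 60, seed = 9)
  maps <- state_maps(fit$model)
  perm <- match_states(gt$state_means, maps$activation)
  X <- coh$subjects[[1]]$series
  nearest <- apply(X, 1, function(x)
    which.min(colSums((t(gt$state_means) - x)^2)))
  decoded <- order(perm)[max.col(fit$posteriors$gamma[[1]])]
  expect_gte(mean(decoded == nearest), 0.98)
  vit <- order(perm)[viterbi_path(fit$model, X)]
  expect_gte(mean(vit == nearest), 0.98)
})

test_that("m_step with hard responsibilities recovers transition counts", {
  path <- c(1, 1, 2, 2, 2, 1)
  K <- 2; R <- 2
  X <- two_state_toy(6, R, seed = 10)
  model <- init_model(list(X), K = K, seed = 1)
  gamma <- matrix(0, 6, K); gamma[cbind(1:6, path)] <- 1
  xi <- array(0, c(5, K, K))
  for (t in 1:5) xi[t, path[t], path[t + 1]] <- 1
  post <- structure(list(gamma = list(s = gamma), xi = list(s = xi),
                         loglik = c(s = 0), subject_ids = "s", K = K),
                    class = "hmm_posteriors")
  up <- m_step(post, list(s = X), model)
  # observed transitions: 1->1 x1, 1->2 x1, 2->2 x2, 2->1 x1
  expect_equal(up$post$trans_alpha,
               model$prior$trans_alpha + matrix(c(1, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(up$post$init_alpha, model$prior$init_alpha + c(1, 0))
})

test_that("uniform responsibilities make all emission posteriors identical", {
  X <- two_state_toy(12, 3, seed = 11)
  model <- init_model(list(X), K = 3, seed = 1)
  gamma <- matrix(1 / 3, 12, 3)
  xi <- array(1 / 9, c(11, 3, 3))
  post <- structure(list(gamma = list(s = gamma), xi = list(s = xi),
                         loglik = c(s = 0), subject_ids = "s", K = 3),
                    class = "hmm_posteriors")
  up <- m_step(post, list(s = X), model)
  expect_equal(up$post$niw[[1]], up$post$niw[[2]], tolerance = 1e-12)
  expect_equal(up$post$niw[[2]], up$post$niw[[3]], tolerance = 1e-12)
})

test_that("K = 1 M step equals the textbook conjugate Gaussian update", {
  X <- two_state_toy(30, 3, seed = 12)
  model <- init_model(list(X), K = 1, seed = 1)
  gamma <- matrix(1, 30, 1)
  post <- structure(list(gamma = list(s = gamma),
                         xi = list(s = array(1, c(29, 1, 1))),
                         loglik = c(s = 0), subject_ids = "s", K = 1),
                    class = "hmm_posteriors")
  up <- m_step(post, list(s = X), model)
  pr <- model$prior
  N <- 30; xbar <- colMeans(X); S <- sample_cov_oracle(X) * (N - 1)
  kapN <- pr$kappa0 + N
  expect_equal(up$post$niw[[1]]$kappa, kapN)
  expect_equal(up$post$niw[[1]]$nu, pr$nu0 + N)
  expect_equal(up$post$niw[[1]]$m,
               (pr$kappa0 * pr$m0 + N * xbar) / kapN, tolerance = 1e-12)
  expect_equal(up$post$niw[[1]]$Psi,
               pr$Psi0 + S + (pr$kappa0 * N / kapN) * tcrossprod(xbar - pr$m0),
               tolerance = 1e-10)
})

test_that("an empty state reverts to its prior with a warning", {
  X <- two_state_toy(10, 2, seed = 13)
  model <- init_model(list(X), K = 2, seed = 1)
  gamma <- cbind(rep(1, 10), rep(0, 10))
  xi <- array(0, c(9, 2, 2)); xi[, 1, 1] <- 1
  post <- structure(list(gamma = list(s = gamma), xi = list(s = xi),
                         loglik = c(s = 0), subject_ids = "s", K = 2),
                    class = "hmm_posteriors")
  expect_warning(up <- m_step(post, list(s = X), model), "vanishing")
  expect_equal(up$post$niw[[2]]$m, model$prior$m0)
  expect_equal(up$post$niw[[2]]$Psi, model$prior$Psi0)
})

test_that("free energy never increases across VB iterations", {
  for (s in 1:20) {
    gt <- make_ground_truth(K = sample(2:3, 1), R = 3,
                            separation = runif(1, 0.5, 3), seed = 1000 + s)
    coh <- simulate_cohort(gt, n_per_group = 1, T_len = 50, seed = 2000 + s)
    fit <- suppressWarnings(
      fit_hmm(coh, K = gt$n_states, n_restarts = 1, max_iter = 25, seed = s))
    expect_true(all(diff(fit$free_energy_trace) <= 1e-8))
  }
})

test_that("K = 1 free energy equals the closed-form NIW log marginal", {
  withr::with_seed(14, X <- matrix(rnorm(40 * 3), 40, 3))
  fit <- fit_hmm(list(X), K = 1, n_restarts = 1, tol = 1e-12, max_iter = 50,
                 seed = 1)
  expect_lte(fit$n_iterations, 3)
  N <- nrow(X); R <- ncol(X)
  pr <- hmm_priors(1, R)
  kapN <- pr$kappa0 + N; nuN <- pr$nu0 + N
  xbar <- colMeans(X)
  S <- sample_cov_oracle(X) * (N - 1)
  PsiN <- pr$Psi0 + S + (pr$kappa0 * N / kapN) * tcrossprod(xbar - pr$m0)
  lmv <- function(a, R) R * (R - 1) / 4 * log(pi) +
    sum(lgamma(a + (1 - seq_len(R)) / 2))
  lml <- -N * R / 2 * log(pi) + lmv(nuN / 2, R) - lmv(pr$nu0 / 2, R) +
    pr$nu0 / 2 * as.numeric(determinant(pr$Psi0)$modulus) -
    nuN / 2 * as.numeric(determinant(PsiN)$modulus) +
    R / 2 * log(pr$kappa0 / kapN)
  expect_equal(fit$free_energy, -lml, tolerance = 1e-6)
})

test_that("duplicating every subject doubles the data-dependent free energy", {
  gt <- make_ground_truth(K = 2, R = 3, separation = 3, seed = 15)
  coh <- simulate_cohort(gt, n_per_group = 2, T_len = 40, seed = 16)
  series <- lapply(coh$subjects, function(s) s$series)
  names(series) <- sapply(coh$subjects, function(s) s$subject_id)
  fit1 <- fit_hmm(series, K = 2, n_restarts = 1, max_iter = 100, seed = 2)
  doubled <- c(series, setNames(series, paste0(names(series), "_copy")))
  fit2 <- fit_hmm(doubled, K = 2, n_restarts = 1, max_iter = 100, seed = 2)
  # the chain/emission KL penalties are bounded while the likelihood term
  # doubles; allow the KL-scale slack
  kl_bound <- abs(fit1$free_energy - (-sum(fit1$posteriors$loglik)))
  expect_lt(abs(fit2$free_energy - 2 * fit1$free_energy),
            2 * kl_bound + abs(fit1$free_energy) * 0.02)
})

test_that("fitting is deterministic given the seed", {
  gt <- make_ground_truth(K = 2, R = 3, seed = 17)
  coh <- simulate_cohort(gt, n_per_group = 2, T_len = 40, seed = 18)
  f1 <- suppressWarnings(fit_hmm(coh, K = 2, n_restarts = 2, max_iter = 30, seed = 19))
  f2 <- suppressWarnings(fit_hmm(coh, K = 2, n_restarts = 2, max_iter = 30, seed = 19))
  expect_identical(f1, f2)
})

test_that("state relabeling permutes gamma columns identically", {
  gt <- make_ground_truth(K = 3, R = 3, seed = 20)
  coh <- simulate_cohort(gt, n_per_group = 1, T_len = 30, seed = 21)
  model <- init_model(coh, K = 3, seed = 22)
  post <- e_step(model, coh)
  perm <- c(3, 1, 2)
  post_p <- e_step(permute_states(model, perm), coh)
  expect_equal(post_p$gamma[[1]], post$gamma[[1]][, perm], tolerance = 1e-10)
  expect_equal(free_energy(permute_states(model, perm), post_p),
               free_energy(model, post), tolerance = 1e-8)
})

test_that("viterbi equals the brute-force MAP path and breaks ties low", {
  X <- two_state_toy(3, 2, seed = 23)
  model <- init_model(list(X), K = 2, seed = 1)
  # build the posterior-mean decoding quantities the same way viterbi does
  pm <- posterior_means(model)
  log_b <- sapply(1:2, function(k) {
    S <- pm$covariances[[k]]
    apply(X, 1, function(x) {
      d <- x - pm$means[k, ]
      -0.5 * (2 * log(2 * pi) + as.numeric(determinant(S)$modulus) +
                drop(t(d) %*% solve(S) %*% d))
    })
  })
  oracle <- enumerate_posteriors(log(pm$initial), log(pm$transition), log_b)
  expect_equal(viterbi_path(model, X), oracle$map_path)

  # uniform everything: the all-ones path wins by the tie-break rule
  unif <- model
  unif$post$niw[[2]] <- unif$post$niw[[1]]
  unif$post$init_alpha <- c(2, 2)
  unif$post$trans_alpha <- matrix(2, 2, 2)
  expect_equal(viterbi_path(unif, X), rep(1L, 3))
})

test_that("model JSON serialization round-trips", {
  gt <- make_ground_truth(K = 2, R = 3, seed = 24)
  coh <- simulate_cohort(gt, n_per_group = 1, T_len = 30, seed = 25)
  fit <- fit_hmm(coh, K = 2, n_restarts = 1, max_iter = 20, seed = 26)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit$model, path)
  back <- read_model_json(path)
  expect_equal(back$post$trans_alpha, fit$model$post$trans_alpha,
               tolerance = 1e-12)
  expect_equal(back$post$niw[[1]]$Psi, fit$model$post$niw[[1]]$Psi,
               tolerance = 1e-12)
  expect_equal(back$prior$Psi0, fit$model$prior$Psi0)
})

test_that("parameters are recovered on a well-separated cohort", {
  gt <- make_ground_truth(K = 2, R = 5, separation = 3, seed = 27, shift = 0)
  coh <- simulate_cohort(gt, n_per_group = 5, T_len = 200, seed = 28)
  fit <- fit_hmm(coh, K = 2, n_restarts = 2, max_iter = 150, seed = 29)
  maps <- state_maps(fit$model)
  perm <- match_states(gt$state_means, maps$activation)
  est <- maps$activation[perm, ]
  expect_lt(max(abs(est - gt$state_means)), 0.15)
})
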
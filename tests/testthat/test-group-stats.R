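test_that("Mann-Whitney U handles separation, symmetry, and empty input", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$U, 9)
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "boldhmm_argument_error")
})

test_that("U statistics of swapped samples sum to n*m", {
  withr::with_seed(1, {
    for (i in 1:10) {
      x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
      expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U,
                   length(x) * length(y))
    }
  })
})

test_that("exact Mann-Whitney p equals full enumeration for small samples", {
  cases <- list(
    list(x = c(1, 3, 5), y = c(2, 4, 6)),
    list(x = c(0.2, 1.7, 2.1, 9), y = c(0.5, 0.6, 3.3)),
    list(x = rnorm(7), y = rnorm(6)),
    list(x = rnorm(5), y = rnorm(7)))
  withr::with_seed(2, for (cs in cases) {
    got <- mann_whitney_u(cs$x, cs$y)
    oracle <- mwu_enumeration_oracle(cs$x, cs$y)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p, oracle$p, tolerance = 1e-10)
  })
})

test_that("Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_equal(cohens_d(c(1, 2), c(1, 2)), 0)
  withr::with_seed(3, { x <- rnorm(10); y <- rnorm(12) })
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "boldhmm_degenerate_variance")
  expect_error(cohens_d(1, c(1, 2)), class = "boldhmm_argument_error")
})

test_that("BH adjustment matches the published worked examples", {
  # five-test family of the group comparison table
  p1 <- c(5.29e-6, 0.328, 0.0462, 2.07e-5, 0.0216)
  adj1 <- bh_adjust(p1, m = 5)
  expect_equal(signif(adj1, 3), c(2.64e-5, 0.328, 0.0578, 5.18e-5, 0.036))
  # six-test clinical family
  p2 <- c(0.007, 0.709, 0.020, 0.757, 0.039, 0.730)
  adj2 <- bh_adjust(p2, m = 6)
  expect_equal(signif(sort(adj2)[1], 3), 0.042)
  expect_equal(signif(sort(adj2)[3], 3), 0.078)
})

test_that("BH adjustment equals the step-up definition on random vectors", {
  withr::with_seed(4, {
    for (i in 1:50) {
      n <- sample(1:10, 1)
      p <- round(runif(n), sample(c(2, 3, 6), 1))
      m <- n + sample(0:3, 1)
      expect_equal(bh_adjust(p, m = m), bh_stepup_oracle(p, m = m),
                   tolerance = 1e-12)
    }
  })
  expect_equal(bh_adjust(0.01, m = 1), 0.01)
  p_eq <- rep(0.04, 5)
  expect_equal(bh_adjust(p_eq), p_eq)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "boldhmm_argument_error")
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), class = "boldhmm_argument_error")
})

test_that("BH adjustment is monotone in every raw p-value", {
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(6)
      adj <- bh_adjust(p)
      j <- sample(6, 1)
      p2 <- p; p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
      expect_true(all(bh_adjust(p2) >= adj - 1e-12))
    }
  })
})

test_that("Spearman correlation matches rank formula and flags degeneracy", {
  expect_equal(spearman_rho(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_rho(1:6, -(1:6))$rho, -1)
  # Sum d^2 = 2 -> rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "boldhmm_degenerate_variance")
  expect_error(spearman_rho(1:2, 2:1), class = "boldhmm_argument_error")
})

test_that("exact Spearman p equals enumeration over rank permutations", {
  withr::with_seed(6, { x <- rnorm(6); y <- rnorm(6) })
  got <- spearman_rho(x, y)
  rx <- rank(x); ry <- rank(y)
  perms <- boldhmm:::.permutations(6)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  p_oracle <- mean(abs(rhos) >= abs(got$rho) - 1e-12)
  expect_equal(got$p, p_oracle, tolerance = 1e-10)
})

test_that("labels follow the published thresholds", {
  expect_equal(effect_magnitude(c(0.1, -0.3, 0.6, -1.2)),
               c("Negligible", "Small", "Moderate", "Large"))
  expect_equal(rho_strength(c(0.1, -0.38, 0.7)), c("Weak", "Moderate", "Strong"))
  expect_equal(significance_label(c(5e-4, 0.005, 0.04, 0.2)),
               c("***", "**", "*", "ns"))
})

make_fo_table <- function(fo, manifest) {
  df <- cbind(manifest[, c("subject_id", "group", "ess", "hallucination")],
              as.data.frame(fo))
  names(df)[-(1:4)] <- sprintf("FO_%d", seq_len(ncol(fo)))
  structure(df, class = c("fo_table", "data.frame"), K = ncol(fo))
}

test_that("group comparison flags the planted state and stays null under the null", {
  planted_hits <- 0L
  for (r in 1:50) {
    gt <- make_ground_truth(K = 5, R = 2, seed = 500 + r, enhanced_state = NA)
    coh <- simulate_cohort(gt, n_per_group = 30, T_len = 230, seed = 600 + r)
    res <- run_group_comparison(make_fo_table(coh$true_fo, coh$manifest))
    if (which.min(res$p_fdr) == 1) planted_hits <- planted_hits + 1L
  }
  expect_gte(planted_hits / 50, 0.9)

  null_hits <- 0L
  for (r in 1:50) {
    gt <- make_ground_truth(K = 5, R = 2, seed = 700 + r, shift = 0)
    coh <- simulate_cohort(gt, n_per_group = 30, T_len = 230, seed = 800 + r)
    res <- run_group_comparison(make_fo_table(coh$true_fo, coh$manifest))
    if (all(res$p_fdr > 0.05)) null_hits <- null_hits + 1L
  }
  expect_gte(null_hits / 50, 0.9)
})

test_that("group comparison reports patient-positive effect directions", {
  gt <- make_ground_truth(K = 5, R = 2, seed = 1)
  coh <- simulate_cohort(gt, n_per_group = 30, T_len = 230, seed = 2)
  res <- run_group_comparison(make_fo_table(coh$true_fo, coh$manifest))
  expect_equal(nrow(res), 5)
  expect_lt(res$cohens_d[1], 0)          # suppressed state: lower in patients
  expect_gt(res$cohens_d[4], 0)          # enhanced state: higher in patients
  expect_equal(res$direction[1], "Higher in control")
  expect_equal(res$direction[4], "Higher in patient")
  expect_true(all(res$p_fdr >= res$p - 1e-12))
  expect_error(run_group_comparison(make_fo_table(coh$true_fo,
                                                  transform(coh$manifest, group = "x"))),
               class = "boldhmm_argument_error")
})

test_that("clinical associations recover the planted covariate link", {
  pos_rho <- 0L
  for (r in 1:50) {
    gt <- make_ground_truth(K = 5, R = 2, seed = 900 + r)
    coh <- simulate_cohort(gt, n_per_group = 30, T_len = 230, seed = 1000 + r)
    res <- run_clinical_associations(make_fo_table(coh$true_fo, coh$manifest))
    rho4 <- res$effect_size[res$feature == "Sleepiness score" & res$state == 4]
    if (rho4 > 0) pos_rho <- pos_rho + 1L
  }
  expect_gte(pos_rho / 50, 0.9)
})

test_that("clinical associations stay null when flag and score are uninformative", {
  null_hits <- 0L
  for (r in 1:50) {
    gt <- make_ground_truth(K = 5, R = 2, seed = 1100 + r,
                            covariate_link = list(state = 4, slope = 0,
                                                  noise_sd = 5))
    coh <- simulate_cohort(gt, n_per_group = 30, T_len = 230, seed = 1200 + r)
    fo <- make_fo_table(coh$true_fo, coh$manifest)
    # break the flag's link to FO by reassigning it at random
    withr::with_seed(1300 + r,
                     fo$hallucination <- sample(fo$hallucination))
    res <- run_clinical_associations(fo)
    if (all(res$p_fdr > 0.05)) null_hits <- null_hits + 1L
  }
  expect_gte(null_hits / 50, 0.9)
})

test_that("clinical table structure follows the published layout", {
  gt <- make_ground_truth(K = 5, R = 2, seed = 3)
  coh <- simulate_cohort(gt, n_per_group = 30, T_len = 230, seed = 4)
  res <- run_clinical_associations(make_fo_table(coh$true_fo, coh$manifest))
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$feature), c("Hallucinations", "Sleepiness score"))
  expect_setequal(res$state, rep(c(1, 4, 5), 2))
  expect_true(all(res$direction %in%
                    c("Higher in present", "Lower in present",
                      "Positive", "Negative")))
  # flag medians drive direction: planted state-1 split means higher-in-present
  expect_equal(res$direction[res$feature == "Hallucinations" & res$state == 1],
               "Higher in present")
})

test_that("a synthetic per-patient table reproduces its own effect sizes", {
  # synthetic stand-in for a per-patient clinical supplement
  withr::with_seed(7, {
    n <- 30
    fo4 <- runif(n, 0.1, 0.4)
    fo1 <- runif(n, 0.1, 0.4)
    tab <- data.frame(
      subject_id = sprintf("p%02d", 1:n),
      hallucination = rep(c(1, 0), each = 15),
      ess = 10 + 20 * fo4 + rnorm(n, sd = 2),
      FO_1 = fo1, FO_2 = 0.2, FO_3 = 0.2, FO_4 = fo4,
      FO_5 = pmax(0, 1 - fo1 - fo4 - 0.4))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  got <- read_per_patient_table(path)
  expect_s3_class(got, "fo_table")
  summ <- clinical_effect_summary(got, ess_state = 4, hall_state = 1)
  expect_equal(summ$rho, spearman_rho(tab$ess, tab$FO_4)$rho)
  expect_equal(summ$d, cohens_d(tab$FO_1[tab$hallucination == 1],
                                tab$FO_1[tab$hallucination == 0]))
  expect_error(read_per_patient_table(file.path(tempdir(), "absent.csv")),
               class = "boldhmm_argument_error")
})
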
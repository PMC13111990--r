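#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic is
#' reported for the first sample (`x`), i.e. the number of pairs
#' \eqn{(x_i, y_j)} with \eqn{x_i > y_j} plus half the ties. The p-value is
#' two-sided: exact by full enumeration when both samples have at most 10
#' observations and there are no ties, otherwise a normal approximation with
#' midranks, tie correction and continuity correction.
#'
#' @param x,y numeric samples (patients / flagged group first, so that large
#'   U means larger values in `x`).
#' @return list with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  .assert(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty",
          class = "boldhmm_argument_error")
  use_exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Cohen's d with pooled standard deviation
#'
#' \deqn{d = \frac{\bar x - \bar y}{s_p}, \quad
#'   s_p = \sqrt{\frac{(n_x - 1)s_x^2 + (n_y - 1)s_y^2}{n_x + n_y - 2}}}
#' The first sample is the patient / feature-present group, so positive `d`
#' means higher values in that group.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return the standardized mean difference.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  .assert(nx >= 2 && ny >= 2, "need at least 2 observations per sample",
          class = "boldhmm_argument_error")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (!is.finite(sp) || sp <= 0) {
    stop(errorCondition("pooled standard deviation is zero",
                        class = c("boldhmm_degenerate_variance", "boldhmm_error")))
  }
  (mean(x) - mean(y)) / sp
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{\tilde p_{(i)} = \min(1, \min_{j \ge i} m\, p_{(j)} / j)}, returned in
#' the input order. `m` may exceed the number of supplied p-values when the
#' correction is defined over a larger family than was computed.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param m family size (defaults to `length(p)`, must be at least that).
#' @return adjusted p-values in input order.
#' @examples
#' bh_adjust(c(5.29e-6, 0.328, 0.0462, 2.07e-5, 0.0216))
#' @export
bh_adjust <- function(p, m = length(p)) {
  .assert(length(p) >= 1 && all(is.finite(p)) && all(p >= 0 & p <= 1),
          "p-values must lie in [0, 1]", class = "boldhmm_argument_error")
  .assert(m >= length(p), "`m` must be at least length(p)",
          class = "boldhmm_argument_error")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Pearson correlation of midranks. The p-value is exact (full enumeration of
#' rank permutations) for `n <= 7` without ties, otherwise the t-distribution
#' approximation.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 3,
          "need paired samples of length >= 3", class = "boldhmm_argument_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("correlation undefined for constant input",
                        class = c("boldhmm_degenerate_variance", "boldhmm_error")))
  }
  use_exact <- length(x) <= 7 && !anyDuplicated(x) && !anyDuplicated(y)
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = use_exact))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

# ---- labels ------------------------------------------------------------------

#' Effect-size magnitude label for Cohen's d
#'
#' `|d| >= 0.8` large, `>= 0.5` moderate, `>= 0.2` small, else negligible.
#'
#' @param d Cohen's d.
#' @return one of `"Large"`, `"Moderate"`, `"Small"`, `"Negligible"`.
#' @export
effect_magnitude <- function(d) {
  a <- abs(d)
  ifelse(a >= 0.8, "Large", ifelse(a >= 0.5, "Moderate",
                                   ifelse(a >= 0.2, "Small", "Negligible")))
}

#' Correlation-strength label for Spearman's rho
#'
#' `|rho| < 0.3` weak, `0.3` to `0.5` moderate, above `0.5` strong.
#'
#' @param rho Spearman correlation.
#' @return one of `"Weak"`, `"Moderate"`, `"Strong"`.
#' @export
rho_strength <- function(rho) {
  a <- abs(rho)
  ifelse(a > 0.5, "Strong", ifelse(a >= 0.3, "Moderate", "Weak"))
}

#' Significance stars for an adjusted p-value
#'
#' `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05, else `"ns"`.
#'
#' @param p_adj adjusted p-value.
#' @return character label.
#' @export
significance_label <- function(p_adj) {
  ifelse(p_adj < 0.001, "***", ifelse(p_adj < 0.01, "**",
                                      ifelse(p_adj < 0.05, "*", "ns")))
}

# ---- assembled comparisons ---------------------------------------------------

#' Group comparison of fractional occupancy across all states
#'
#' One two-sided Mann-Whitney U test per state (patients vs. controls) with
#' Benjamini-Hochberg correction over the K raw p-values, plus pooled-sd
#' Cohen's d signed so that positive values indicate higher occupancy in the
#' patient group.
#'
#' @param fo an `fo_table` with a two-level `group` column.
#' @param patient_level value of `group` identifying patients; defaults to
#'   `"patient"` when present, else the first level.
#' @return data.frame of per-state results: `state`, `test`, `U`, `p`,
#'   `p_fdr`, `cohens_d`, `magnitude`, `direction`, `significance`.
#' @export
run_group_comparison <- function(fo, patient_level = NULL) {
  .assert("group" %in% names(fo), "`fo` must have a group column",
          class = "boldhmm_argument_error")
  groups <- unique(fo$group)
  .assert(length(groups) == 2, "`group` must have exactly two levels",
          class = "boldhmm_argument_error")
  patient_level <- patient_level %||%
    (if ("patient" %in% groups) "patient" else groups[1])
  control_level <- setdiff(groups, patient_level)
  m <- fo_matrix(fo)
  xs <- m[fo$group == patient_level, , drop = FALSE]
  ys <- m[fo$group == control_level, , drop = FALSE]
  .assert(nrow(xs) >= 2 && nrow(ys) >= 2,
          "each group needs at least 2 subjects", class = "boldhmm_argument_error")
  K <- ncol(m)

  tests <- lapply(seq_len(K), function(k) mann_whitney_u(xs[, k], ys[, k]))
  p <- vapply(tests, `[[`, 0, "p")
  p_fdr <- bh_adjust(p, m = K)
  d <- vapply(seq_len(K), function(k) cohens_d(xs[, k], ys[, k]), 0)

  data.frame(
    state = seq_len(K),
    test = "Mann-Whitney U",
    U = vapply(tests, `[[`, 0, "U"),
    p = p, p_fdr = p_fdr,
    cohens_d = d,
    magnitude = effect_magnitude(d),
    direction = ifelse(d >= 0,
                       sprintf("Higher in %s", patient_level),
                       sprintf("Higher in %s", control_level)),
    significance = significance_label(p_fdr),
    stringsAsFactors = FALSE)
}

#' Clinical associations of fractional occupancy within the patient group
#'
#' For each requested state, a Mann-Whitney U test of FO between subjects
#' with and without the hallucination-like flag and a Spearman correlation of
#' FO with the sleepiness score, restricted to the patient group when a
#' `group` column is present. Benjamini-Hochberg correction is applied
#' jointly over all tests with family size `m` (default: the number of tests,
#' i.e. 6 for three states).
#'
#' @param fo an `fo_table` with `hallucination` (logical) and `ess` (numeric)
#'   columns.
#' @param states state indices to test (default 1, 4, 5 intersected with the
#'   available states).
#' @param m BH family size; default `2 * length(states)`.
#' @param patient_level patient group label as in [run_group_comparison()].
#' @return data.frame with one row per test: `feature`, `state`, `test`,
#'   `statistic`, `p`, `p_fdr`, `effect_size`, `magnitude`, `direction`,
#'   `significance`.
#' @export
run_clinical_associations <- function(fo, states = NULL, m = NULL,
                                      patient_level = "patient") {
  .assert(all(c("hallucination", "ess") %in% names(fo)),
          "`fo` must have hallucination and ess columns",
          class = "boldhmm_argument_error")
  fom <- fo_matrix(fo)
  K <- ncol(fom)
  states <- states %||% intersect(c(1L, 4L, 5L), seq_len(K))
  .assert(length(states) >= 1 && all(states %in% seq_len(K)),
          "invalid state subset", class = "boldhmm_argument_error")
  keep <- if ("group" %in% names(fo)) fo$group == patient_level else
    rep(TRUE, nrow(fo))
  sub <- fo[keep, , drop = FALSE]
  fom <- fom[keep, , drop = FALSE]
  flag <- as.logical(sub$hallucination)
  .assert(sum(flag) >= 2 && sum(!flag) >= 2,
          "each hallucination subgroup needs at least 2 subjects",
          class = "boldhmm_argument_error")

  hall_rows <- lapply(states, function(k) {
    x <- fom[flag, k]; y <- fom[!flag, k]
    ht <- mann_whitney_u(x, y)
    d <- cohens_d(x, y)
    data.frame(feature = "Hallucinations", state = k, test = "Mann-Whitney U",
               statistic = ht$U, p = ht$p, effect_size = d,
               magnitude = effect_magnitude(d),
               direction = if (stats::median(x) >= stats::median(y))
                 "Higher in present" else "Lower in present",
               stringsAsFactors = FALSE)
  })
  ess_rows <- lapply(states, function(k) {
    ct <- spearman_rho(sub$ess, fom[, k])
    data.frame(feature = "Sleepiness score", state = k, test = "Spearman rho",
               statistic = ct$rho, p = ct$p, effect_size = ct$rho,
               magnitude = rho_strength(ct$rho),
               direction = if (ct$rho >= 0) "Positive" else "Negative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(hall_rows, ess_rows))
  m <- m %||% nrow(out)
  out$p_fdr <- bh_adjust(out$p, m = m)
  out$significance <- significance_label(out$p_fdr)
  out[, c("feature", "state", "test", "statistic", "p", "p_fdr",
          "effect_size", "magnitude", "direction", "significance")]
}

#' FO distribution plot by group
#'
#' @param fo an `fo_table` with a `group` column.
#' @return a ggplot object (requires ggplot2).
#' @export
plot_fo <- function(fo) {
  .assert(requireNamespace("ggplot2", quietly = TRUE), "plot_fo requires ggplot2")
  m <- fo_matrix(fo)
  df <- data.frame(
    group = rep(fo$group, ncol(m)),
    state = factor(rep(sprintf("State %d", seq_len(ncol(m))), each = nrow(m))),
    FO = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = state, y = FO, fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Fractional occupancy") +
    ggplot2::theme_minimal()
}

#' Read a per-patient fractional-occupancy / clinical table
#'
#' Loads a per-patient summary table of the kind distributed as a clinical
#' supplement: one row per patient with a hallucination indicator, a
#' sleepiness (ESS) score, and per-state fractional occupancies in columns
#' `FO_1..FO_K`. Such a table is sufficient to recompute the published
#' clinical effect sizes (Spearman correlation between ESS and a state's FO;
#' pooled Cohen's d between hallucination subgroups) via [spearman_rho()] and
#' [cohens_d()].
#'
#' @param path CSV file with columns `subject_id`, `hallucination`
#'   (0/1 or logical), `ess` (numeric) and `FO_1..FO_K`.
#' @return an `fo_table` data.frame.
#' @export
read_per_patient_table <- function(path) {
  .assert(file.exists(path), sprintf("per-patient table not found: %s", path),
          class = "boldhmm_argument_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fo_cols <- grep("^FO_\\d+$", names(df), value = TRUE)
  .assert(all(c("subject_id", "hallucination", "ess") %in% names(df)) &&
            length(fo_cols) >= 1,
          "table must have subject_id, hallucination, ess and FO_* columns",
          class = "boldhmm_argument_error")
  df$hallucination <- as.logical(df$hallucination)
  structure(df, class = c("fo_table", "data.frame"), K = length(fo_cols))
}

#' Clinical effect-size summary from a per-patient table
#'
#' Recomputes, from a per-patient FO/clinical table, the Spearman correlation
#' between the sleepiness score and one state's fractional occupancy and the
#' pooled-sd Cohen's d of another state's occupancy between
#' hallucination-present and -absent subgroups (present group first, so
#' positive d means higher occupancy with hallucinations).
#'
#' @param table an `fo_table` (e.g. from [read_per_patient_table()]).
#' @param ess_state state whose FO is correlated with the ESS score.
#' @param hall_state state whose FO is compared between hallucination
#'   subgroups.
#' @return list with `rho`, `rho_p`, `d`.
#' @export
clinical_effect_summary <- function(table, ess_state = 4L, hall_state = 1L) {
  fom <- fo_matrix(table)
  ct <- spearman_rho(table$ess, fom[, ess_state])
  flag <- as.logical(table$hallucination)
  d <- cohens_d(fom[flag, hall_state], fom[!flag, hall_state])
  list(rho = ct$rho, rho_p = ct$p, d = d)
}
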
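#' Scan candidate state counts and record the free-energy curve
#'
#' Fits the variational HMM for each `K` in `k_min..k_max` and records the
#' lowest free energy over restarts, mirroring the standard practice of
#' evaluating a range of model orders and keeping the free-energy minimum.
#' Per-K seeds are derived from the master seed by fixed offsets, so the scan
#' is reproducible and any single K can be refit independently. A K whose fit
#' fails outright is recorded with converged fraction 0 and the scan
#' continues.
#'
#' @param data input accepted by [fit_hmm()].
#' @param k_min,k_max inclusive scan range (`1 <= k_min <= k_max`).
#' @param n_restarts,tol,max_iter passed to [fit_hmm()].
#' @param seed master integer seed.
#' @param cache_dir optional directory; when given, each K's full fit is
#'   saved there as `fit_K<k>.rds`.
#' @param verbose print progress.
#' @return a `selection_table`: data.frame with columns `K`, `free_energy`
#'   (best over restarts), `n_restarts`, `converged_fraction`, `seed`.
#' @export
scan_states <- function(data, k_min = 2L, k_max = 16L, n_restarts = 5L,
                        tol = 1e-6, max_iter = 500L, seed = 1L,
                        cache_dir = NULL, verbose = FALSE) {
  k_min <- .check_count(k_min, "k_min")
  k_max <- .check_count(k_max, "k_max")
  .assert(k_min <= k_max, "`k_min` must not exceed `k_max`",
          class = "boldhmm_argument_error")
  if (!is.null(cache_dir)) dir.create(cache_dir, recursive = TRUE,
                                      showWarnings = FALSE)
  series <- .as_series_list(data)
  rows <- vector("list", k_max - k_min + 1L)
  fits <- list()
  for (i in seq_along(rows)) {
    K <- k_min + i - 1L
    k_seed <- .child_seed(seed, 10000L + K)
    fit <- tryCatch(
      fit_hmm(series, K, n_restarts = n_restarts, tol = tol,
              max_iter = max_iter, seed = k_seed, verbose = verbose),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(K = K, free_energy = NA_real_,
                              n_restarts = n_restarts,
                              converged_fraction = 0, seed = k_seed)
      next
    }
    if (!is.null(cache_dir)) {
      saveRDS(fit, file.path(cache_dir, sprintf("fit_K%d.rds", K)))
    }
    fits[[as.character(K)]] <- fit
    rows[[i]] <- data.frame(K = K, free_energy = fit$free_energy,
                            n_restarts = n_restarts,
                            converged_fraction = as.numeric(fit$converged),
                            seed = k_seed)
    if (verbose) message(sprintf("K = %d: FE = %.3f", K, fit$free_energy))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("selection_table", "data.frame")
  attr(out, "fits") <- fits
  out
}

#' Select the number of states by free-energy minimum
#'
#' Returns the `K` of the lowest best-restart free energy among converged
#' rows; ties break toward the smaller `K`. The choice is invariant to row
#' order and to the presence of non-converged rows.
#'
#' @param table a `selection_table` from [scan_states()] (or any data.frame
#'   with columns `K`, `free_energy`, `converged_fraction`).
#' @return the selected integer `K`.
#' @export
select_k <- function(table) {
  .assert(nrow(table) > 0, "empty selection table",
          class = "boldhmm_selection_error")
  ok <- table$converged_fraction > 0 & is.finite(table$free_energy)
  if (!any(ok)) {
    stop(errorCondition("no converged rows to select from",
                        class = c("boldhmm_selection_error", "boldhmm_error")))
  }
  t2 <- table[ok, , drop = FALSE]
  cand <- t2$K[t2$free_energy == min(t2$free_energy)]
  as.integer(min(cand))
}

#' Free-energy curve plot over candidate state counts
#'
#' @param table a `selection_table`.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_selection <- function(table) {
  .assert(requireNamespace("ggplot2", quietly = TRUE),
          "plot_selection requires ggplot2")
  sel <- select_k(table)
  df <- as.data.frame(table)
  ggplot2::ggplot(df, ggplot2::aes(x = K, y = free_energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$K == sel, , drop = FALSE],
                        colour = "red", size = 3, shape = 1, stroke = 1.2) +
    ggplot2::labs(x = "Number of states K", y = "Free energy",
                  title = sprintf("Free-energy minimum at K = %d", sel)) +
    ggplot2::theme_minimal()
}
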
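# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, class = "boldhmm_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "boldhmm_error")))
  }
  invisible(TRUE)
}

.check_count <- function(x, name, min = 1L) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min,
          sprintf("`%s` must be a single integer >= %d", name, min),
          class = "boldhmm_argument_error")
  as.integer(x)
}

.check_positive <- function(x, name) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
          sprintf("`%s` must be a single positive number", name),
          class = "boldhmm_argument_error")
  as.numeric(x)
}

#' Test whether a matrix is symmetric positive definite
#'
#' @param x numeric matrix.
#' @param tol symmetry tolerance relative to the largest absolute entry.
#' @return `TRUE` if `x` is symmetric and its Cholesky factorization succeeds.
#' @keywords internal
is_spd <- function(x, tol = 1e-8) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) return(FALSE)
  if (max(abs(x - t(x))) > tol * max(1, max(abs(x)))) return(FALSE)
  ok <- tryCatch({ chol(x); TRUE }, error = function(e) FALSE)
  ok
}

# log determinant of an SPD matrix via Cholesky
.logdet_spd <- function(x) {
  2 * sum(log(diag(chol(x))))
}

# multivariate log-gamma: log Gamma_R(a)
.lmvgamma <- function(a, R) {
  R * (R - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(R)) / 2))
}

# multivariate digamma: d/da log Gamma_R(a)
.mvdigamma <- function(a, R) {
  sum(digamma(a + (1 - seq_len(R)) / 2))
}

# Draw n samples from N(mean, sigma) using the Cholesky factor.
.rmvnorm <- function(n, mean, sigma) {
  R <- length(mean)
  L <- chol(sigma)  # upper triangular, sigma = t(L) %*% L
  z <- matrix(stats::rnorm(n * R), n, R)
  sweep(z %*% L, 2, mean, `+`)
}

# Derive a child seed from a master seed and a fixed offset, staying within
# 32-bit integer range.
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
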
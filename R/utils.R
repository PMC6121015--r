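# Internal numerical helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Cholesky-based multivariate normal log-density at each row of y.
#' @noRd
mvn_logdens <- function(y, mu, sigma) {
  y <- as.matrix(y)
  D <- ncol(y)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(y) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * D * log(2 * pi)
}

# One draw per row from N(mu, sigma) with rows of z ~ N(0, I).
#' @noRd
mvn_transform <- function(z, mu, sigma) {
  sweep(z %*% chol(sigma), 2, mu, `+`)
}

#' @noRd
is_spd <- function(m, tol = 1e-10) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Multivariate log gamma function log Gamma_D(a).
#' @noRd
lmvgamma <- function(a, D) {
  0.25 * D * (D - 1) * log(pi) + sum(lgamma(a + (1 - seq_len(D)) / 2))
}

# Multivariate digamma  sum_d psi(a + (1 - d)/2).
#' @noRd
mvdigamma <- function(a, D) sum(digamma(a + (1 - seq_len(D)) / 2))

# Deterministic per-stage seed fan-out: one config seed maps to distinct
# 31-bit seeds for each named stage.
#' @noRd
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

# Run-length encoding that returns starts as well.
#' @noRd
rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, length = r$lengths,
             start = ends - r$lengths + 1, end = ends)
}
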
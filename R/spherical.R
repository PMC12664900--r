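#' Power Spherical and uniform distributions on the hypersphere
#'
#' The latent space of the model is the unit sphere S^(d-1) embedded in R^d.
#' The variational posterior is the Power Spherical distribution with density
#' proportional to (1 + mu'z)^kappa, where mu is the direction on the sphere
#' and kappa > 0 the concentration. The prior is the uniform distribution on
#' the sphere, which makes the KL divergence available in closed form as
#' the entropy gap H(uniform) - H(PowerSpherical).
#'
#' Throughout the package `d` is the ambient dimension, so vectors live on
#' the (d-1)-sphere. All normalizers are computed in log space with
#' log-gamma; kappa is clamped to [1e-6, 1e6] for numerical stability.
#'
#' @name spherical
NULL

.KAPPA_MIN <- 1e-6
.KAPPA_MAX <- 1e6

.clamp_kappa <- function(kappa) pmin(pmax(kappa, .KAPPA_MIN), .KAPPA_MAX)

.check_kappa <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop_value("kappa must be strictly positive and finite")
  }
  invisible(kappa)
}

.check_unit <- function(x, name = "x", tol = 1e-6) {
  if (!is.numeric(x) || anyNA(x)) stop_value("'%s' must be a numeric vector", name)
  if (length(x) < 2) stop_value("'%s' must have length >= 2 (ambient dimension d >= 2)", name)
  if (abs(sqrt(sum(x^2)) - 1) > tol) stop_value("'%s' must have unit Euclidean norm", name)
  invisible(x)
}

# log normalizer of the Power Spherical distribution:
# N(kappa, d) = 2^(alpha+beta) * pi^beta * Gamma(alpha) / Gamma(alpha+beta)
# with alpha = (d-1)/2 + kappa, beta = (d-1)/2.
.ps_log_normalizer <- function(kappa, d) {
  beta <- (d - 1) / 2
  alpha <- beta + kappa
  (alpha + beta) * log(2) + beta * log(pi) + lgamma(alpha) - lgamma(alpha + beta)
}

#' Log surface area of the unit sphere S^(d-1)
#'
#' Entropy of the uniform distribution on the (d-1)-sphere embedded in R^d,
#' i.e. `log(2 * pi^(d/2) / gamma(d/2))`.
#'
#' @param d Ambient dimension (integer, >= 2).
#' @return The log surface area (a scalar).
#' @examples
#' uniform_sphere_entropy(2) # log(2*pi), the circle
#' uniform_sphere_entropy(3) # log(4*pi)
#' @export
uniform_sphere_entropy <- function(d) {
  if (length(d) != 1 || !is.finite(d) || d < 2 || d != round(d)) {
    stop_value("d must be a single integer >= 2")
  }
  log(2) + (d / 2) * log(pi) - lgamma(d / 2)
}

#' Power Spherical log-density
#'
#' @param x Unit vector at which to evaluate the density.
#' @param mu Direction parameter, a unit vector of the same length as `x`.
#' @param kappa Concentration parameter (> 0).
#' @return Scalar log-density.
#' @examples
#' mu <- c(1, 0, 0)
#' ps_log_prob(c(0, 1, 0), mu, kappa = 2)
#' @export
ps_log_prob <- function(x, mu, kappa) {
  .check_unit(x, "x")
  .check_unit(mu, "mu")
  .check_kappa(kappa)
  if (length(x) != length(mu)) stop_shape("x and mu must have the same dimension")
  kappa <- .clamp_kappa(kappa)
  d <- length(mu)
  t <- sum(mu * x)
  # log1p handles t near -1 (density -> -Inf is the correct limit)
  kappa * log1p(min(max(t, -1), 1)) - .ps_log_normalizer(kappa, d)
}

#' Entropy of the Power Spherical distribution
#'
#' Closed form: `logN - kappa * (log 2 + digamma(alpha) - digamma(alpha+beta))`
#' with `alpha = (d-1)/2 + kappa`, `beta = (d-1)/2`. Vectorized over `kappa`.
#'
#' @param kappa Concentration (> 0); may be a vector.
#' @param d Ambient dimension (>= 2).
#' @return Entropy value(s); always at most `uniform_sphere_entropy(d)`.
#' @export
ps_entropy <- function(kappa, d) {
  .check_kappa(kappa)
  if (length(d) != 1 || d < 2) stop_value("d must be a single integer >= 2")
  kappa <- .clamp_kappa(kappa)
  beta <- (d - 1) / 2
  alpha <- beta + kappa
  .ps_log_normalizer(kappa, d) - kappa * (log(2) + digamma(alpha) - digamma(alpha + beta))
}

#' KL divergence from a Power Spherical distribution to the uniform prior
#'
#' `KL(PS(mu, kappa) || Uniform(S^(d-1)))` has the closed form
#' `H(uniform) - H(PS)`; it does not depend on the direction `mu` because
#' both the entropy and the uniform prior are rotation invariant.
#' Vectorized over `kappa`.
#'
#' @inheritParams ps_entropy
#' @return Non-negative KL divergence value(s).
#' @examples
#' kl_ps_uniform(1e-6, d = 3) # ~0: the distribution is almost uniform
#' kl_ps_uniform(50, d = 3)   # strongly concentrated, large KL
#' @export
kl_ps_uniform <- function(kappa, d) {
  pmax(uniform_sphere_entropy(d) - ps_entropy(kappa, d), 0)
}

# d/dkappa KL(PS || uniform) = kappa * (trigamma(alpha) - trigamma(alpha+beta)).
.kl_grad_kappa <- function(kappa, d) {
  kappa <- .clamp_kappa(kappa)
  beta <- (d - 1) / 2
  alpha <- beta + kappa
  kappa * (trigamma(alpha) - trigamma(alpha + beta))
}

#' Sample from the Power Spherical distribution
#'
#' Uses the standard construction: a Beta-distributed marginal along the
#' direction `mu`, a uniform draw on the orthogonal subsphere, and a
#' Householder reflection mapping the north pole onto `mu`.
#'
#' @param n Number of samples (>= 1).
#' @param mu Direction, a unit vector of length d >= 2.
#' @param kappa Concentration (> 0 scalar).
#' @param seed Optional integer seed; when given, sampling is reproducible
#'   and the caller's RNG state is left untouched.
#' @return An `n x d` matrix whose rows are unit vectors.
#' @examples
#' z <- ps_sample(5, mu = c(0, 0, 1), kappa = 10, seed = 1)
#' rowSums(z^2) # all 1
#' @export
ps_sample <- function(n, mu, kappa, seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop_value("n must be a positive integer")
  }
  .check_unit(mu, "mu")
  if (length(kappa) != 1) stop_value("kappa must be a scalar")
  .check_kappa(kappa)
  kappa <- .clamp_kappa(kappa)
  d <- length(mu)
  with_seed_or_not(seed, {
    noise <- .ps_draw_noise(n, d, rep(kappa, n))
    .ps_transform(noise$y, matrix(mu, n, d, byrow = TRUE))
  })
}

# Draw the direction-free part of the sampler: marginal t = 2u-1 with
# u ~ Beta(alpha, beta) (kappa may vary per row), uniform v on S^(d-2),
# assembled as y = (t, sqrt(1-t^2) v). Returns pieces for reuse in training.
.ps_draw_noise <- function(n, d, kappa) {
  beta <- (d - 1) / 2
  alpha <- beta + kappa
  u <- stats::rbeta(n, shape1 = alpha, shape2 = beta)
  t <- 2 * u - 1
  if (d == 2) {
    v <- matrix(sample(c(-1, 1), n, replace = TRUE), n, 1)
  } else {
    v <- matrix(stats::rnorm(n * (d - 1)), n, d - 1)
    v <- .normalize_rows(v)
  }
  y <- cbind(t, sqrt(pmax(1 - t^2, 0)) * v)
  dimnames(y) <- NULL
  list(t = t, v = v, y = y)
}

# Householder-reflect rows of y (distributed about the north pole e1) to be
# distributed about the matching row of mu_mat.
.ps_transform <- function(y, mu_mat) {
  w <- -mu_mat
  w[, 1] <- w[, 1] + 1
  nw <- sqrt(rowSums(w^2))
  degenerate <- nw < 1e-12 # mu == e1: reflection is the identity
  u <- w
  u[!degenerate, ] <- w[!degenerate, , drop = FALSE] / nw[!degenerate]
  s <- rowSums(u * y)
  z <- y - 2 * u * s
  z[degenerate, ] <- y[degenerate, , drop = FALSE]
  .normalize_rows(z)
}
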
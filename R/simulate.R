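# Deterministic generators for interaction and quadratic datasets with known
# parameters. Defaults mimic the demonstration settings: small n, predictor
# means far from 0, so non-essential collinearity between first-order terms
# and their products/powers is severe.

#' Simulation spec for an interaction (moderation) dataset
#'
#' Two predictors are drawn bivariate normal with the stated moments; the
#' response is `b0 + b1 x1 + b2 x2 + b3 x1 x2 + e` with Gaussian noise.
#' Defaults emulate a small ice-cream-sales-style study: n = 30, means far
#' from zero (74.93, 77.67), SDs (8.94, 10.50), predictor correlation 0.649,
#' coefficients (160, 0.85, 0.54, -0.03) on the raw scale, and noise SD 5.4.
#'
#' @param n sample size (>= 8).
#' @param means,sds length-2 moments of the predictors (SDs > 0).
#' @param rho predictor correlation, |rho| < 1.
#' @param coefs length-4 generating coefficients (b0, b1, b2, b3).
#' @param noise_sd residual SD (> 0).
#' @param seed integer seed; the same seed gives bitwise-identical output.
#' @return An object of class `"interaction_sim_spec"`.
#' @export
interaction_sim_spec <- function(n = 30, means = c(74.93, 77.67),
                                 sds = c(8.94, 10.50), rho = 0.649,
                                 coefs = c(160, 0.85, 0.54, -0.03),
                                 noise_sd = 5.4, seed = 1L) {
  stopifnot(n >= 8, length(means) == 2L, length(sds) == 2L, all(sds > 0),
            abs(rho) < 1, length(coefs) == 4L, noise_sd > 0,
            all(is.finite(c(means, sds, rho, coefs, noise_sd))))
  structure(list(n = as.integer(n), means = means, sds = sds, rho = rho,
                 coefs = coefs, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "interaction_sim_spec")
}

#' Simulation spec for a quadratic dataset
#'
#' One predictor, Gaussian; the response is `b0 + b1 x + b2 x^2 + e`.
#' Defaults emulate an exam-time study: n = 31, mean 53.61 far from zero so
#' that `cor(x, x^2)` is nearly 1 before centering, SD 12.08, coefficients
#' (-76.53, 5.727, -0.055), noise SD 15.5.
#'
#' @param n sample size (>= 8).
#' @param mean,sd moments of the predictor (sd > 0).
#' @param coefs length-3 generating coefficients (b0, b1, b2).
#' @param noise_sd residual SD (> 0).
#' @param seed integer seed.
#' @return An object of class `"quadratic_sim_spec"`.
#' @export
quadratic_sim_spec <- function(n = 31, mean = 53.61, sd = 12.08,
                               coefs = c(-76.53, 5.727, -0.055),
                               noise_sd = 15.5, seed = 1L) {
  stopifnot(n >= 8, sd > 0, length(coefs) == 3L, noise_sd > 0,
            all(is.finite(c(mean, sd, coefs, noise_sd))))
  structure(list(n = as.integer(n), mean = mean, sd = sd, coefs = coefs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "quadratic_sim_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Generate an interaction dataset
#'
#' @param spec an [interaction_sim_spec()].
#' @return data frame with columns `x1`, `x2`, `y` and attributes `params`
#'   (the spec) and `rng` (the PRNG algorithm used, for reproducibility across
#'   releases).
#' @export
generate_interaction <- function(spec) {
  stopifnot(inherits(spec, "interaction_sim_spec"))
  with_seed(spec$seed, {
    z1 <- stats::rnorm(spec$n)
    z2 <- stats::rnorm(spec$n)
    x1 <- spec$means[1] + spec$sds[1] * z1
    x2 <- spec$means[2] + spec$sds[2] * (spec$rho * z1 +
                                           sqrt(1 - spec$rho^2) * z2)
    e <- stats::rnorm(spec$n, sd = spec$noise_sd)
    b <- spec$coefs
    y <- b[1] + b[2] * x1 + b[3] * x2 + b[4] * x1 * x2 + e
    out <- data.frame(x1 = x1, x2 = x2, y = y)
    attr(out, "params") <- spec
    attr(out, "rng") <- c(kind = "Mersenne-Twister", normal = "Inversion")
    out
  })
}

#' Generate a quadratic dataset
#'
#' @param spec a [quadratic_sim_spec()].
#' @return data frame with columns `x`, `y` and attributes `params`, `rng`.
#' @export
generate_quadratic <- function(spec) {
  stopifnot(inherits(spec, "quadratic_sim_spec"))
  with_seed(spec$seed, {
    x <- spec$mean + spec$sd * stats::rnorm(spec$n)
    e <- stats::rnorm(spec$n, sd = spec$noise_sd)
    b <- spec$coefs
    y <- b[1] + b[2] * x + b[3] * x^2 + e
    out <- data.frame(x = x, y = y)
    attr(out, "params") <- spec
    attr(out, "rng") <- c(kind = "Mersenne-Twister", normal = "Inversion")
    out
  })
}
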
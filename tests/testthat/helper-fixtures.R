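# Shared fixtures: all generated in code, no external data.

int_spec <- function() {
  model_spec("y", list("x1", "x2", term_product("x1", "x2")))
}

quad_spec <- function() {
  model_spec("y", list("x", term_power("x", 2)))
}

int_data <- function(seed, ...) {
  generate_interaction(interaction_sim_spec(seed = seed, ...))
}

quad_data <- function(seed, ...) {
  generate_quadratic(quadratic_sim_spec(seed = seed, ...))
}

# random dense regression problem (well-conditioned by construction)
rand_problem <- function(n = 12, p = 3, intercept = TRUE) {
  k <- p - as.integer(intercept)
  X <- matrix(stats::rnorm(n * k), n, k)
  colnames(X) <- paste0("v", seq_len(k))
  if (intercept) X <- cbind(`(Intercept)` = rep(1, n), X)
  y <- drop(X %*% stats::rnorm(p)) + stats::rnorm(n)
  list(X = X, y = y)
}

# independent oracle: direct solution of the normal equations (X'X) b = X'y
normal_eq_fit <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  r <- y - X %*% b
  s2 <- sum(r^2) / (nrow(X) - ncol(X))
  list(b = drop(b), cov_b = s2 * solve(XtX))
}

rel_err <- function(a, b) max(abs(a - b) / pmax(1, abs(b)))
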
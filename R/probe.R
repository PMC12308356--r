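# Conditional (simple) effects, quadratic-slope probing, hierarchical
# delta-R2 main-effect testing, and plot-data emission. Probe values are
# interpreted on the scale of the fitted parameterization; reports also carry
# the raw-scale equivalent via centering provenance.

new_conditional_effect <- function(focal, moderator, at_value, at_raw,
                                   slope, var_slope, fit, level = 0.95) {
  se <- sqrt(max(var_slope, 0))
  df <- fit$df_resid
  t <- if (se > 0) slope / se else ifelse(slope == 0, 0, sign(slope) * Inf)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  structure(list(focal = focal, moderator = moderator,
                 at_value = at_value, at_raw = at_raw,
                 slope = slope, se = se, df = df, t = t, p_value = p,
                 ci = c(lower = slope - tcrit * se, upper = slope + tcrit * se),
                 level = level),
            class = "conditional_effect")
}

#' @export
print.conditional_effect <- function(x, digits = 3, ...) {
  raw_note <- if (!isTRUE(all.equal(x$at_value, x$at_raw))) {
    sprintf(" (raw scale: %s = %.4g)", x$moderator, x$at_raw)
  } else ""
  cat(sprintf(
    "conditional effect of %s when %s = %.4g%s:\n  slope %.*f, SE %.*f, t(%d) = %.*f, p = %.4g, %d%% CI [%.*f, %.*f]\n",
    x$focal, x$moderator, x$at_value, raw_note,
    digits, x$slope, digits, x$se, x$df, digits, x$t, x$p_value,
    round(100 * x$level), digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' Conditional (simple) slope of a focal predictor at a moderator value
#'
#' In a model with a product term, the effect of the focal predictor is not a
#' constant: at moderator value `h` (on the scale of the fitted
#' parameterization) the slope is `b_focal + b_product * h`, with a delta-method
#' standard error from the full coefficient covariance. At `h = 0` this is
#' exactly the fitted first-order coefficient and its standard error — which is
#' why a first-order coefficient in a moderation model is a conditional effect,
#' never a main effect.
#'
#' @param fit an `"ols_fit"` whose model contains `focal`, `moderator`, and
#'   their product term.
#' @param focal,moderator base variable names.
#' @param h moderator value on the fitted parameterization's scale.
#' @param level confidence level.
#' @return A `"conditional_effect"`: slope, se, df, t, p, CI, and the raw-scale
#'   moderator value implied by the centering provenance.
#' @export
conditional_slope <- function(fit, focal, moderator, h, level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"), is.numeric(h), length(h) == 1L)
  i <- first_order_index(fit, focal)
  j <- product_index(fit, focal, moderator)
  if (is.null(i) || is.null(j)) {
    stop("not a moderation model: need first-order '", focal,
         "' and a product term of '", focal, "' and '", moderator, "'",
         call. = FALSE)
  }
  b <- fit$coefficients; V <- fit$cov_b
  slope <- b[[i]] + b[[j]] * h
  v <- V[i, i] + h^2 * V[j, j] + 2 * h * V[i, j]
  at_raw <- h + raw_offset(fit$design, moderator)
  new_conditional_effect(focal, moderator, h, at_raw, slope, v, fit, level)
}

# Centering constant applied to a variable's first-order term (0 if raw).
raw_offset <- function(design, var) {
  for (t in design$terms) {
    if (t$kind == "centered" && t$base == var) return(t$constant)
    if (t$kind %in% c("product", "power")) {
      comps <- if (t$kind == "product") t$components else list(t$base)
      for (cmp in comps) {
        if (cmp$kind == "centered" && cmp$base == var) return(cmp$constant)
      }
    }
  }
  0
}

#' Slope of a fitted parabola at a point
#'
#' For a quadratic model `b0 + b1 x + b2 x^2`, the first-order coefficient is
#' the slope of the parabola at x = 0; at `x0` the slope is `b1 + 2 b2 x0`,
#' with delta-method SE `sqrt(Var b1 + 4 x0^2 Var b2 + 4 x0 Cov(b1, b2))`.
#'
#' @param fit an `"ols_fit"` containing `variable` and its square.
#' @param variable base variable name.
#' @param x0 point on the fitted parameterization's scale.
#' @param level confidence level.
#' @return A `"conditional_effect"` (moderator = the variable itself).
#' @export
quadratic_slope <- function(fit, variable, x0, level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"), is.numeric(x0), length(x0) == 1L)
  i <- first_order_index(fit, variable)
  j <- power_index(fit, variable, 2L)
  if (is.null(i) || is.null(j)) {
    stop("not a polynomial model: need first-order '", variable,
         "' and its squared term", call. = FALSE)
  }
  b <- fit$coefficients; V <- fit$cov_b
  slope <- b[[i]] + 2 * b[[j]] * x0
  v <- V[i, i] + 4 * x0^2 * V[j, j] + 4 * x0 * V[i, j]
  at_raw <- x0 + raw_offset(fit$design, variable)
  new_conditional_effect(variable, variable, x0, at_raw, slope, v, fit, level)
}

#' Choose probe values for a moderator
#'
#' The conventional pick-a-point choice is one standard deviation below the
#' mean, the mean, and one standard deviation above, on the scale of the
#' supplied column (i.e. of the current parameterization). Arbitrary explicit
#' values are first-class: any conditional effect can be tested, not just
#' mean +/- 1 SD.
#'
#' @param x numeric vector (a design column or data column).
#' @param strategy `"mean_pm_1sd"` (default) or `"explicit"`.
#' @param values numeric probe values when `strategy = "explicit"`.
#' @return named numeric vector of probe values.
#' @export
pick_points <- function(x, strategy = c("mean_pm_1sd", "explicit"),
                        values = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "explicit") {
    stopifnot(is.numeric(values), length(values) >= 1L, all(is.finite(values)))
    return(stats::setNames(values, paste0("at_", format(values, trim = TRUE))))
  }
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  m <- mean(x); s <- if (length(x) > 1L) stats::sd(x) else 0
  if (s == 0) warning("degenerate moderator: zero SD, all probe points equal")
  c(low = m - s, mean = m, high = m + s)
}

#' Hierarchical (nested) regression with delta-R-squared tests
#'
#' Main effects in the presence of an interaction (or curvature) must be
#' assessed from a model that does not contain the product/power term: each
#' step adds terms to the previous step's model and is tested by
#' `F = (dR2 / m) / ((1 - R2_step) / df_resid_step)` with `m` added terms.
#' The final step's fit is retained: all probing and plotting of the
#' interaction must use that full equation.
#'
#' @param response response variable name.
#' @param steps list of term lists, each step's terms strictly extending the
#'   previous step's (cumulative specifications).
#' @param data data frame.
#' @param scheme optional [center_scheme()].
#' @param intercept include an intercept (default `TRUE`).
#' @return An object of class `"hierarchical_result"`: `table` (per step:
#'   added terms, r2, delta_r2, F, df1, df2, p), `fits` (per-step `"ols_fit"`),
#'   and `final` (the last step's fit).
#' @export
hierarchical_fit <- function(response, steps, data, scheme = NULL,
                             intercept = TRUE) {
  stopifnot(is.list(steps), length(steps) >= 1L)
  specs <- lapply(steps, function(tt) model_spec(response, tt, intercept))
  labels <- lapply(specs, function(s) vapply(s$terms, term_label, character(1)))
  for (k in seq_along(specs)[-1]) {
    if (!all(labels[[k - 1]] %in% labels[[k]]) ||
        length(labels[[k]]) <= length(labels[[k - 1]])) {
      stop("nesting error: step ", k, " terms must strictly extend step ",
           k - 1, call. = FALSE)
    }
  }
  fits <- lapply(specs, fit_model, data = data, scheme = scheme)
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  r2_prev <- c(0, r2[-length(r2)])
  m <- vapply(seq_along(specs), function(k)
    length(labels[[k]]) - if (k == 1) 0L else length(labels[[k - 1]]),
    numeric(1))
  df2 <- vapply(fits, `[[`, numeric(1), "df_resid")
  delta <- r2 - r2_prev
  Fstat <- (delta / m) / ((1 - r2) / df2)
  p <- stats::pf(Fstat, m, df2, lower.tail = FALSE)
  added <- vapply(seq_along(specs), function(k) {
    new <- if (k == 1) labels[[1]] else setdiff(labels[[k]], labels[[k - 1]])
    paste(new, collapse = " + ")
  }, character(1))
  structure(list(table = data.frame(step = seq_along(specs), added = added,
                                    r2 = r2, delta_r2 = delta, F = Fstat,
                                    df1 = m, df2 = df2, p = p,
                                    row.names = NULL),
                 fits = fits, final = fits[[length(fits)]]),
            class = "hierarchical_result")
}

#' @export
print.hierarchical_result <- function(x, digits = 3, ...) {
  cat("Hierarchical regression (", nrow(x$table), " steps)\n", sep = "")
  tab <- x$table
  tab[c("r2", "delta_r2", "F")] <- round(tab[c("r2", "delta_r2", "F")], digits)
  tab$p <- signif(tab$p, 3)
  print(tab)
  cat("note: first-order coefficients of the final (full) model are\n",
      "conditional effects, not main effects; main effects are the Step-1\n",
      "coefficients. Plotting requires the full final-step equation.\n",
      sep = "")
  invisible(x)
}

check_full_model <- function(fit, what) {
  has_derived <- any(vapply(fit$design$terms, function(t)
    t$kind %in% c("product", "power"), logical(1)))
  if (!has_derived) {
    stop("full-equation-required error: ", what, " must use the full ",
         "(final-step) model containing the product/power term; there is no ",
         "way to get the correct plot from a reduced model", call. = FALSE)
  }
  invisible()
}

# Evaluate the full fitted equation with named columns set and all other
# non-intercept columns held at 0.
eval_equation <- function(fit, cols) {
  b <- fit$coefficients
  yhat <- if (fit$design$has_intercept) rep(b[["(Intercept)"]], length(cols[[1]])) else 0
  for (nm in names(cols)) yhat <- yhat + b[[nm]] * cols[[nm]]
  yhat
}

axis_note <- function(design, var) {
  off <- raw_offset(design, var)
  if (off == 0) sprintf("%s: 0 means raw 0", var)
  else sprintf("%s: 0 means raw %.6g (centered)", var, off)
}

#' Plot data for a two-way interaction
#'
#' Evaluates the full fitted equation over a grid of focal values at each
#' stated moderator value (other covariates, if any, held at 0). Metadata
#' records what 0 means on each axis. Probing a reduced (no-product) fit is a
#' hard error.
#'
#' @param fit the full model's `"ols_fit"` (must contain the product term).
#' @param focal,moderator base variable names.
#' @param moderator_values probe values on the fitted scale (default: mean
#'   +/- 1 SD of the moderator's design column).
#' @param focal_values grid on the fitted scale (default: 50 points over the
#'   observed range of the focal design column).
#' @return data frame `(moderator_value, focal_value, fitted)` with attributes
#'   `axis_notes` and `moderator_labels`.
#' @export
interaction_plot_data <- function(fit, focal, moderator,
                                  moderator_values = NULL,
                                  focal_values = NULL) {
  stopifnot(inherits(fit, "ols_fit"))
  check_full_model(fit, "interaction plot data")
  i <- first_order_index(fit, focal)
  im <- first_order_index(fit, moderator)
  j <- product_index(fit, focal, moderator)
  if (is.null(i) || is.null(im) || is.null(j)) {
    stop("not a moderation model for '", focal, "' x '", moderator, "'",
         call. = FALSE)
  }
  X <- fit$design$matrix
  if (is.null(focal_values)) {
    rng <- range(X[, i])
    focal_values <- seq(rng[1], rng[2], length.out = 50)
  }
  if (is.null(moderator_values)) {
    moderator_values <- pick_points(X[, im])
  }
  nm <- colnames(X)
  out <- do.call(rbind, lapply(seq_along(moderator_values), function(k) {
    m <- moderator_values[[k]]
    cols <- stats::setNames(
      list(focal_values, rep(m, length(focal_values)), focal_values * m),
      nm[c(i, im, j)])
    data.frame(moderator_value = m, focal_value = focal_values,
               fitted = eval_equation(fit, cols))
  }))
  attr(out, "axis_notes") <- c(axis_note(fit$design, focal),
                               axis_note(fit$design, moderator))
  attr(out, "moderator_labels") <- names(moderator_values)
  out
}

#' Plot data for a fitted parabola
#'
#' Evaluates the full quadratic equation on a grid; metadata records what 0
#' means on the x-axis. Probing a reduced (linear-only) fit is a hard error.
#'
#' @param fit the full model's `"ols_fit"` (must contain the squared term).
#' @param variable base variable name.
#' @param x_values grid on the fitted scale (default: 100 points over the
#'   observed range).
#' @return data frame `(x, fitted)` with attribute `axis_notes`.
#' @export
parabola_plot_data <- function(fit, variable, x_values = NULL) {
  stopifnot(inherits(fit, "ols_fit"))
  check_full_model(fit, "parabola plot data")
  i <- first_order_index(fit, variable)
  j <- power_index(fit, variable, 2L)
  if (is.null(i) || is.null(j)) {
    stop("not a polynomial model for '", variable, "'", call. = FALSE)
  }
  X <- fit$design$matrix
  if (is.null(x_values)) {
    rng <- range(X[, i])
    x_values <- seq(rng[1], rng[2], length.out = 100)
  }
  nm <- colnames(X)
  cols <- stats::setNames(list(x_values, x_values^2), nm[c(i, j)])
  out <- data.frame(x = x_values, fitted = eval_equation(fit, cols))
  attr(out, "axis_notes") <- axis_note(fit$design, variable)
  out
}
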
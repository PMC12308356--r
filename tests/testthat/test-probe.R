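test_that("the conditional slope at moderator 0 is the first-order coefficient", {
  d <- int_data(41)
  f <- fit_model(int_spec(), d)
  eff <- conditional_slope(f, "x1", "x2", 0)
  expect_identical(eff$slope, unname(coef(f)[["x1"]]))
  expect_identical(eff$se, unname(f$se[["x1"]]))
  expect_equal(eff$df, f$df_resid)
  expect_equal(eff$t, f$t[["x1"]], tolerance = 1e-15)
  expect_equal(eff$p_value, f$p_value[["x1"]], tolerance = 1e-15)
})

test_that("delta-method slopes equal refit-after-recentering on random probes", {
  # recenter the moderator at h, rebuild the product, refit: the focal
  # first-order coefficient and its SE must equal the delta-method output
  set.seed(42)
  for (i in 1:10) {
    d <- int_data(100 + i)
    f <- fit_model(int_spec(), d)
    h <- runif(1, min(d$x2), max(d$x2))
    eff <- conditional_slope(f, "x1", "x2", h)
    refit <- fit_model(int_spec(), d, center_scheme(x2 = h))
    expect_lt(abs(eff$slope - coef(refit)[["x1"]]), 1e-9)
    expect_lt(abs(eff$se - refit$se[["x1"]]), 1e-9)
    expect_lt(abs(eff$t - refit$t[["x1"]]), 1e-9 * max(1, abs(eff$t)))
    expect_lt(abs(eff$p_value - refit$p_value[["x1"]]), 1e-9)
  }
})

test_that("quadratic slopes probe the parabola; the vertex matches a grid argmax", {
  d <- quad_data(43, noise_sd = 1e-10)
  f <- fit_model(quad_spec(), d)
  eff0 <- quadratic_slope(f, "x", 0)
  expect_identical(eff0$slope, unname(coef(f)[["x"]]))
  expect_identical(eff0$se, unname(f$se[["x"]]))
  b <- coef(f)
  vertex <- -b[["x"]] / (2 * b[["x^2"]])
  expect_equal(quadratic_slope(f, "x", vertex)$slope, 0, tolerance = 1e-10)
  # independent oracle: maximize the fitted curve on a fine grid
  grid <- parabola_plot_data(f, "x",
                             x_values = seq(min(d$x), max(d$x), length.out = 20001))
  step <- diff(grid$x[1:2])
  expect_lt(abs(grid$x[which.max(grid$fitted)] - vertex), step)
})

test_that("quadratic probing is scheme-equivalent and errors without the square", {
  d <- quad_data(44)
  f_raw <- fit_model(quad_spec(), d)
  f_ctr <- fit_model(quad_spec(), d, center_scheme(x = "mean"))
  x0 <- 47
  e1 <- quadratic_slope(f_raw, "x", x0)
  e2 <- quadratic_slope(f_ctr, "x", x0 - mean(d$x))
  expect_equal(e1$slope, e2$slope, tolerance = 1e-9)
  expect_equal(e1$se, e2$se, tolerance = 1e-9)
  expect_equal(e1$at_raw, e2$at_raw, tolerance = 1e-9)
  lin <- fit_model(model_spec("y", list("x")), d)
  expect_error(quadratic_slope(lin, "x", 0), "not a polynomial model")
  expect_error(conditional_slope(lin, "x", "x", 0), "not a moderation model")
})

test_that("pick_points implements mean +/- 1 SD and explicit values", {
  x <- c(2, 4, 6, 8)
  pts <- pick_points(x)
  expect_equal(unname(pts), c(mean(x) - sd(x), mean(x), mean(x) + sd(x)),
               tolerance = 1e-12)
  expect_equal(unname(pick_points(x, "explicit", values = 85)), 85)
  expect_warning(p0 <- pick_points(rep(3, 5)), "degenerate")
  expect_equal(unname(p0), c(3, 3, 3))
  # points picked on the centered scale match raw points shifted by the mean
  expect_equal(unname(pick_points(x - mean(x))), unname(pts) - mean(x),
               tolerance = 1e-12)
})

test_that("hierarchical fits test increments with delta-R2 F statistics", {
  d <- int_data(45)
  steps <- list(list("x1", "x2"),
                list("x1", "x2", term_product("x1", "x2")))
  h <- hierarchical_fit("y", steps, d)
  expect_equal(nrow(h$table), 2L)
  # increments sum to the final R2 and are nonnegative
  expect_equal(sum(h$table$delta_r2), h$final$r2, tolerance = 1e-12)
  expect_true(all(h$table$delta_r2 >= 0))
  # single added term: F = t^2 and the p-values agree
  tprod <- h$final$t[["x1:x2"]]
  expect_equal(h$table$F[2], tprod^2, tolerance = 1e-8)
  expect_lt(abs(h$table$p[2] - h$final$p_value[["x1:x2"]]), 1e-10)
  # step-1 coefficients are the main effects, invariant to centering
  hc <- hierarchical_fit("y", steps, d, center_scheme(x1 = "mean", x2 = "mean"))
  expect_equal(coef(h$fits[[1]])[["x1"]], coef(hc$fits[[1]])[["x1_c"]],
               tolerance = 1e-10)
  expect_equal(h$table$delta_r2, hc$table$delta_r2, tolerance = 1e-12)
  # a single-step hierarchy is a plain fit
  h1 <- hierarchical_fit("y", steps[1], d)
  expect_equal(h1$table$delta_r2, h1$table$r2, tolerance = 1e-15)
  expect_error(hierarchical_fit("y", rev(steps), d), "nesting error")
})

test_that("interaction plot data uses the full equation on a stated grid", {
  d <- int_data(46)
  f <- fit_model(int_spec(), d)
  pd <- interaction_plot_data(f, "x1", "x2")
  expect_equal(nrow(pd), 150L)  # 3 moderator values x 50 grid points
  expect_true(all(c("moderator_value", "focal_value", "fitted") %in% names(pd)))
  # evaluating the equation by hand at a grid point
  b <- coef(f)
  row <- pd[57, ]
  expect_equal(row$fitted,
               b[["(Intercept)"]] + b[["x1"]] * row$focal_value +
                 b[["x2"]] * row$moderator_value +
                 b[["x1:x2"]] * row$focal_value * row$moderator_value,
               tolerance = 1e-12)
  # zero interaction coefficient -> parallel lines
  f0 <- f
  f0$coefficients[["x1:x2"]] <- 0
  pd0 <- interaction_plot_data(f0, "x1", "x2", moderator_values = c(60, 90),
                               focal_values = c(0, 1))
  slopes <- tapply(pd0$fitted, pd0$moderator_value, diff)
  expect_equal(unname(diff(slopes)), 0, tolerance = 1e-12)
  # probing a reduced fit is a hard error
  red <- fit_model(model_spec("y", list("x1", "x2")), d)
  expect_error(interaction_plot_data(red, "x1", "x2"), "full-equation-required")
  expect_error(parabola_plot_data(red, "x1"), "full-equation-required")
})

test_that("centered and uncentered plot grids are the same curve, relabeled", {
  d <- int_data(47)
  f_raw <- fit_model(int_spec(), d)
  f_ctr <- fit_model(int_spec(), d, center_scheme(x1 = "mean", x2 = "mean"))
  xg <- seq(min(d$x1), max(d$x1), length.out = 25)
  mg <- pick_points(d$x2)[c(1, 3)]
  pd_raw <- interaction_plot_data(f_raw, "x1", "x2",
                                  moderator_values = mg, focal_values = xg)
  pd_ctr <- interaction_plot_data(f_ctr, "x1", "x2",
                                  moderator_values = mg - mean(d$x2),
                                  focal_values = xg - mean(d$x1))
  expect_equal(pd_raw$fitted, pd_ctr$fitted, tolerance = 1e-9)
  # axis metadata states what 0 means
  expect_match(attr(pd_ctr, "axis_notes")[1], "0 means raw")
  # parabola: fitted value at the raw mean equals the centered fit's intercept
  q <- quad_data(48)
  qf_raw <- fit_model(quad_spec(), q)
  qf_ctr <- fit_model(quad_spec(), q, center_scheme(x = "mean"))
  at_mean <- parabola_plot_data(qf_raw, "x", x_values = mean(q$x))$fitted
  expect_equal(at_mean, unname(coef(qf_ctr)[["(Intercept)"]]), tolerance = 1e-9)
})
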
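test_that("single-predictor standardized effects collapse to Pearson r", {
  set.seed(51)
  d <- data.frame(x = rnorm(25, 10, 2))
  d$y <- 3 + 0.8 * d$x + rnorm(25)
  spec <- model_spec("y", list("x"))
  f <- fit_model(spec, d)
  r <- cor(d$x, d$y)
  expect_equal(as.numeric(beta_default(f)), r, tolerance = 1e-12)
  expect_equal(unname(beta_correct(spec, d)), r, tolerance = 1e-12)
  sr <- semipartial(f)
  expect_equal(unname(sr), r, tolerance = 1e-12)
  expect_equal(unname(sr)^2, f$r2, tolerance = 1e-12)
  expect_error(vif(f), "at least 2")
})

test_that("beta_correct equals beta_default when the model has no derived terms", {
  d <- int_data(52)
  spec <- model_spec("y", list("x1", "x2"))
  f <- fit_model(spec, d)
  expect_equal(unname(beta_correct(spec, d)), as.numeric(beta_default(f)),
               tolerance = 1e-12)
})

test_that("beta_correct is centering-invariant; beta_default is not", {
  d <- int_data(53)
  spec_raw <- int_spec()
  spec_ctr <- model_spec("y", list(term_centered("x1"), term_centered("x2"),
                                   term_product(term_centered("x1"),
                                                term_centered("x2"))))
  bc_raw <- beta_correct(spec_raw, d)
  bc_ctr <- beta_correct(spec_ctr, d)
  expect_lt(max(abs(bc_raw - bc_ctr)), 1e-10)
  bd_raw <- beta_default(fit_model(spec_raw, d))
  bd_ctr <- beta_default(fit_model(spec_ctr, d))
  expect_gt(abs(bd_raw[["x1:x2"]] - bd_ctr[["x1_c:x2_c"]]), 0.01)
  expect_match(attr(bd_raw, "caveat"), "incorrect")
})

test_that("the derived term's sr is centering-invariant; first-order full-model sr is not", {
  d <- int_data(54)
  f_raw <- fit_model(int_spec(), d)
  f_ctr <- fit_model(int_spec(), d, center_scheme(x1 = "mean", x2 = "mean"))
  sr_raw <- semipartial(f_raw)
  sr_ctr <- semipartial(f_ctr)
  expect_lt(abs(sr_raw[["x1:x2"]] - sr_ctr[["x1_c:x2_c"]]), 1e-10)
  # full-model first-order sr is a conditional quantity: it moves with the scheme
  expect_gt(abs(sr_raw[["x1"]] - sr_ctr[["x1_c"]]), 1e-4)
  # hierarchical (step-1) sr of the first-order terms IS invariant
  s1_raw <- semipartial(fit_model(model_spec("y", list("x1", "x2")), d))
  s1_ctr <- semipartial(fit_model(model_spec("y", list("x1", "x2")), d,
                                  center_scheme(x1 = "mean", x2 = "mean")))
  expect_lt(max(abs(s1_raw - s1_ctr)), 1e-10)
})

test_that("semipartial drop-one route matches the t-statistic route", {
  set.seed(55)
  for (i in 1:10) {
    d <- int_data(200 + i)
    f <- fit_model(int_spec(), d, if (i %% 2) center_scheme(x2 = "mean"))
    sr <- semipartial(f)
    idx <- 2:4
    sr_t <- f$t[idx] * sqrt((1 - f$r2) / f$df_resid)
    expect_lt(max(abs(sr - sr_t)), 1e-10)
    expect_equal(unname(sign(sr)), unname(sign(f$t[idx])))
  }
})

test_that("|beta_default| = |sr| * sqrt(VIF), and orthogonal designs have VIF 1", {
  set.seed(56)
  for (i in 1:10) {
    d <- int_data(300 + i)
    f <- fit_model(int_spec(), d)
    lhs <- abs(beta_default(f))
    rhs <- abs(semipartial(f)) * sqrt(vif(f))
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
  d <- data.frame(a = rep(c(-1, 1), 8), b = rep(c(-1, 1), each = 8))
  d$y <- 1 + d$a - 2 * d$b + rnorm(16)
  fo <- fit_model(model_spec("y", list("a", "b")), d)
  expect_equal(unname(vif(fo)), c(1, 1), tolerance = 1e-12)
  # with VIF = 1, beta_default equals sr
  expect_equal(as.numeric(abs(beta_default(fo))), unname(abs(semipartial(fo))),
               tolerance = 1e-10)
})

test_that("centering lowers the product VIF but leaves its sr unchanged", {
  d <- int_data(57)
  f_raw <- fit_model(int_spec(), d)
  f_ctr <- fit_model(int_spec(), d, center_scheme(x1 = "mean", x2 = "mean"))
  expect_lt(vif(f_ctr)[["x1_c:x2_c"]], vif(f_raw)[["x1:x2"]])
  expect_lt(abs(semipartial(f_ctr)[["x1_c:x2_c"]] -
                  semipartial(f_raw)[["x1:x2"]]), 1e-10)
})

test_that("effect_size_table assembles consistent per-term measures", {
  d <- int_data(58)
  tab <- effect_size_table(int_spec(), d)
  expect_identical(tab$term, c("x1", "x2", "x1:x2"))
  expect_identical(tab$sr2, tab$sr^2)
  f <- attr(tab, "fit")
  expect_equal(sign(tab$sr), unname(sign(f$t[2:4])))
  expect_true(all(abs(tab$beta_default) >= abs(tab$sr) - 1e-10))
  out <- capture.output(print(tab))
  expect_true(any(grepl("caveat", out)))
  out2 <- capture.output(print(tab, no_beta = TRUE))
  expect_false(any(grepl("beta", out2)))
})
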
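test_that("center subtracts a constant and records it at full precision", {
  x <- c(1.5, 2.5, 7.25)
  expect_identical(center(x, 0)$values, x)
  ctr <- center(x)
  expect_equal(ctr$constant, mean(x), tolerance = 1e-15)
  expect_lt(abs(mean(ctr$values)), 1e-12 * max(abs(x)))
  # re-centering at the negation restores the original column
  back <- center(ctr$values, -ctr$constant)
  expect_equal(back$values, x, tolerance = 1e-12)
})

test_that("standardize yields sample z-scores and is shift invariant", {
  set.seed(5)
  x <- rnorm(20, 50, 9)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(center(x, 12.3)$values), z, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(3, 10)), "degenerate")
})

test_that("build_design computes derived columns after transforms, deterministically", {
  d <- int_data(31)
  spec <- int_spec()
  des <- build_design(spec, d)
  expect_identical(colnames(des$matrix), c("(Intercept)", "x1", "x2", "x1:x2"))
  expect_equal(des$matrix[, "x1:x2"], d$x1 * d$x2, tolerance = 1e-15)
  # identical rebuild: order-stable and bitwise deterministic
  expect_identical(des$matrix, build_design(spec, d)$matrix)
  # centered scheme: product is recomputed from the centered columns
  sch <- center_scheme(x1 = "mean", x2 = "mean")
  desc <- build_design(spec, d, sch)
  expect_identical(colnames(desc$matrix),
                   c("(Intercept)", "x1_c", "x2_c", "x1_c:x2_c"))
  expect_equal(desc$matrix[, "x1_c:x2_c"],
               (d$x1 - mean(d$x1)) * (d$x2 - mean(d$x2)), tolerance = 1e-12)
  expect_equal(unname(desc$constants), c(mean(d$x1), mean(d$x2)),
               tolerance = 1e-15)
})

test_that("centering changes only non-essential collinearity", {
  d <- int_data(32)
  raw <- predictor_correlations(build_design(int_spec(), d))
  ctr <- predictor_correlations(
    build_design(int_spec(), d, center_scheme(x1 = "mean", x2 = "mean")))
  # base-base correlation untouched; base-product correlations drop
  expect_equal(ctr[1, 2], raw[1, 2], tolerance = 1e-12)
  expect_lt(abs(ctr[1, 3]), abs(raw[1, 3]))
  expect_lt(abs(ctr[2, 3]), abs(raw[2, 3]))
  expect_equal(diag(raw), c(x1 = 1, x2 = 1, `x1:x2` = 1), tolerance = 1e-15)
  # arbitrary constants also leave the base-base correlation untouched
  arb <- predictor_correlations(
    build_design(int_spec(), d, center_scheme(x1 = 3.7, x2 = -41)))
  expect_equal(arb[1, 2], raw[1, 2], tolerance = 1e-12)
})

test_that("a squared term decorrelates from its base after centering", {
  d <- quad_data(33)  # mean far from 0, so cor(x, x^2) is nearly 1
  raw <- predictor_correlations(build_design(quad_spec(), d))
  ctr <- predictor_correlations(
    build_design(quad_spec(), d, center_scheme(x = "mean")))
  expect_gt(raw["x", "x^2"], 0.98)
  expect_lt(abs(ctr["x_c", "x_c^2"]), 0.7)
})

test_that("schema and order-of-operations violations error; mixed specs warn", {
  d <- int_data(34)
  expect_error(build_design(model_spec("y", list("nope")), d), "schema error")
  expect_error(
    build_design(int_spec(), d, center_scheme(`x1:x2` = "mean")),
    "order-of-operations")
  expect_error(build_design(int_spec(), d, center_scheme(zz = 1)),
               "schema error")
  # raw first-order terms with a product of centered terms is hazardous
  mixed <- model_spec("y", list("x1", "x2",
                                term_product(term_centered("x1"),
                                             term_centered("x2"))))
  expect_warning(build_design(mixed, d), "mixed centering")
  # products are never components of products
  expect_error(term_product(term_product("a", "b"), "c"), "order-of-operations")
  expect_error(term_power("x", 1), "exponent")
})

test_that("missing values are dropped listwise with a logged count", {
  d <- int_data(35)
  d$x1[c(2, 9)] <- NA
  expect_message(des <- build_design(int_spec(), d), "dropped 2 row")
  expect_equal(des$n, nrow(d) - 2L)
  d$x2 <- as.character(d$x2)
  expect_error(build_design(int_spec(), d), "non-numeric")
})

test_that("predictor_correlations requires 2+ varying predictor columns", {
  set.seed(6)
  d <- data.frame(a = rep(c(-1, 1), 8), b = rep(c(-1, 1), each = 8),
                  y = rnorm(16))
  des <- build_design(model_spec("y", list("a", "b")), d)
  expect_equal(predictor_correlations(des)["a", "b"], 0, tolerance = 1e-12)
  expect_error(predictor_correlations(
    build_design(model_spec("y", list("a")), d)), "at least 2")
  d$c <- 1
  expect_error(predictor_correlations(
    build_design(model_spec("y", list("a", "c")), d)), "degenerate")
})
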
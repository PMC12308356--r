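# Standardized and semipartial effect sizes. The software-default beta
# z-scores the *final* design columns — including already-formed products and
# powers — which is an order-of-operations mistake for those terms. The
# corrected beta z-scores the base variables (and the response) first and
# rebuilds the derived terms from the z-scores.

nonint_cols <- function(fit) {
  X <- fit$design$matrix
  if (fit$design$has_intercept) X[, -1L, drop = FALSE] else X
}

#' Software-default standardized coefficients (order-of-operations incorrect)
#'
#' Z-scores every final design column — products and powers included, exactly
#' as common statistical packages do, because the software cannot know there
#' is anything special about a derived column — and the response, then refits.
#' For models containing product or power terms these values are *wrong* as
#' standardized effects; see [beta_correct()]. The result carries a caveat
#' flag stating this.
#'
#' @param fit an `"ols_fit"`.
#' @return named numeric vector of default betas (non-intercept terms), with
#'   attribute `"caveat"`.
#' @export
beta_default <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  X <- nonint_cols(fit)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds <= 0)) {
    stop("degenerate variable: zero variance in column(s) ",
         paste(colnames(X)[sds <= 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X)                      # n-1 divisor, matching standardize()
  zy <- standardize(fit$y)
  Zd <- as_design_matrix(cbind(`(Intercept)` = rep(1, nrow(Z)), Z))
  zfit <- fit_ols(Zd, zy)
  out <- zfit$coefficients[-1L]
  attr(out, "caveat") <-
    "default (order-of-operations incorrect for product/power terms)"
  out
}

strip_transforms <- function(term) {
  switch(term$kind,
         raw = ,
         centered = ,
         standardized = term_raw(term$base),
         product = term_product(term_raw(term$components[[1]]$base),
                                term_raw(term$components[[2]]$base)),
         power = term_power(term_raw(term$base$base), term$exponent))
}

#' Corrected standardized coefficients for models with product/power terms
#'
#' Converts the individual base predictors and the response to z-scores, then
#' *recomputes* the product or power terms from the z-scores, fits, and
#' returns the unstandardized coefficients of that fit. These are the proper
#' standardized effects; they coincide with [beta_default()] only when the
#' model contains no derived terms. Because z-scoring absorbs location, the
#' result is invariant to any prior centering of the base variables.
#'
#' @param spec a [model_spec()].
#' @param data data frame.
#' @return named numeric vector of corrected betas (non-intercept terms).
#' @export
beta_correct <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  used <- unique(c(spec$response, spec_base_variables(spec)))
  miss <- setdiff(used, names(data))
  if (length(miss)) {
    stop("schema error: variable(s) not found in data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[used])
  if (any(!keep)) {
    message("listwise deletion: dropped ", sum(!keep),
            " row(s) with missing values")
    data <- data[keep, , drop = FALSE]
  }
  zdata <- data
  for (v in used) zdata[[v]] <- standardize(data[[v]])
  zspec <- model_spec(spec$response, lapply(spec$terms, strip_transforms),
                      spec$intercept)
  zfit <- fit_model(zspec, zdata)
  zfit$coefficients[if (spec$intercept) -1L else TRUE]
}

#' Semipartial correlations
#'
#' `sr_i = sign(t_i) * sqrt(R2_full - R2_without_i)`: the correlation between
#' the response and the part of predictor i orthogonal to the other
#' predictors. Its square is the variance in the response uniquely explained
#' by that predictor (the drop-one delta-R-squared). Computed by drop-one
#' refits and cross-checked internally against
#' `sr_i = t_i * sqrt((1 - R2_full) / df_resid)`.
#'
#' @param fit a full-rank `"ols_fit"`.
#' @return named numeric vector of sr per non-intercept term.
#' @export
semipartial <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  X <- fit$design$matrix
  idx <- seq_len(ncol(X))
  if (fit$design$has_intercept) idx <- idx[-1L]
  sr <- numeric(length(idx))
  names(sr) <- colnames(X)[idx]
  for (k in seq_along(idx)) {
    i <- idx[k]
    Xr <- X[, -i, drop = FALSE]
    r2_wo <- if (ncol(Xr) == 0L) 0 else {
      sub <- tryCatch(fit_ols(as_design_matrix(Xr), fit$y),
                      error = function(e) stop(
                        "drop-one refit failed for '", colnames(X)[i], "': ",
                        conditionMessage(e), call. = FALSE))
      sub$r2
    }
    sr[k] <- sign(fit$t[[i]]) * sqrt(max(fit$r2 - r2_wo, 0))
  }
  # independent route: t * sqrt((1 - R2) / df_resid)
  sr_t <- fit$t[idx] * sqrt((1 - fit$r2) / fit$df_resid)
  if (max(abs(sr - sr_t)) > 1e-8) {
    stop("internal inconsistency: drop-one and t-formula semipartial routes ",
         "disagree (max diff ", format(max(abs(sr - sr_t))), ")")
  }
  sr
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R2_i)` where `R2_i` regresses design column i on the other
#' non-intercept columns (with intercept). `sqrt(VIF)` is the factor by which
#' the default standardized coefficient exaggerates a predictor's importance
#' relative to its semipartial correlation: `|beta_default| = |sr| * sqrt(VIF)`.
#'
#' @param fit an `"ols_fit"` with at least two non-intercept terms.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  X <- nonint_cols(fit)
  p <- ncol(X)
  if (p < 2L) stop("VIF needs at least 2 non-intercept terms")
  out <- numeric(p); names(out) <- colnames(X)
  for (i in seq_len(p)) {
    Xi <- cbind(`(Intercept)` = rep(1, nrow(X)), X[, -i, drop = FALSE])
    sub <- fit_ols(as_design_matrix(Xi), X[, i])
    if (sub$r2 >= 1 - 1e-12) {
      stop("infinite VIF: column '", colnames(X)[i],
           "' is perfectly collinear with the other predictors", call. = FALSE)
    }
    out[i] <- 1 / (1 - sub$r2)
  }
  out
}

#' Per-term effect-size table
#'
#' Assembles b, SE, the software-default beta (with its caveat), the corrected
#' beta, sr, sr^2, and VIF for every non-intercept term. sr (and sr^2) are
#' invariant to centering of base variables; the default beta of product/power
#' terms is not, and both its centered and uncentered values are incorrect —
#' prefer sr, whose square is the uniquely explained variance.
#'
#' @param spec a [model_spec()].
#' @param data data frame.
#' @param scheme optional [center_scheme()].
#' @param level confidence level for the underlying fit.
#' @return data frame of class `"effect_size_table"` with columns `term`, `b`,
#'   `se_b`, `beta_default`, `beta_correct`, `sr`, `sr2`, `vif`.
#' @export
effect_size_table <- function(spec, data, scheme = NULL, level = 0.95) {
  fit <- fit_model(spec, data, scheme, level = level)
  idx <- seq_len(fit$p)
  if (fit$design$has_intercept) idx <- idx[-1L]
  bd <- beta_default(fit)
  bc <- beta_correct(spec, data)
  sr <- semipartial(fit)
  v <- if (length(idx) >= 2L) vif(fit) else rep(NA_real_, length(idx))
  out <- data.frame(term = names(fit$coefficients)[idx],
                    b = unname(fit$coefficients[idx]),
                    se_b = unname(fit$se[idx]),
                    beta_default = unname(bd),
                    beta_correct = unname(bc),
                    sr = unname(sr),
                    sr2 = unname(sr)^2,
                    vif = unname(v),
                    row.names = NULL)
  class(out) <- c("effect_size_table", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' @param x an `"effect_size_table"`.
#' @param digits rounding for display (the underlying values keep full precision).
#' @param no_beta suppress the beta columns entirely.
#' @param ... unused.
#' @rdname effect_size_table
#' @export
print.effect_size_table <- function(x, digits = 3, no_beta = FALSE, ...) {
  tab <- as.data.frame(x)
  if (no_beta) {
    tab$beta_default <- NULL
    tab$beta_correct <- NULL
  }
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab)
  if (!no_beta) {
    cat("caveat: beta_default z-scores already-formed product/power columns\n",
        "(order-of-operations incorrect for those terms); beta_correct\n",
        "rebuilds them from z-scored bases. Prefer sr: sr^2 is the variance\n",
        "uniquely explained by the term.\n", sep = "")
  }
  invisible(x)
}
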
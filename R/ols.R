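# QR-based OLS with full coefficient covariance. Solved via orthogonal
# factorization, never by explicit inversion of X'X; rank is detected by a
# relative tolerance of 1e-10 on the diagonal of R, so only essential
# singularity errors out.

RANK_TOL <- 1e-10

#' Fit ordinary least squares
#'
#' Estimates `y = X b + e` by QR decomposition, returning coefficients, their
#' full covariance matrix `sigma2 * (X'X)^-1` with `sigma2 = SSE / (n - p)`,
#' two-sided t-based p-values with `n - p` residual degrees of freedom, and
#' confidence intervals at `level`.
#'
#' @param design a [build_design()] result (or a plain numeric matrix with
#'   column names, in which case `has_intercept` is inferred from a leading
#'   constant-1 column named `"(Intercept)"`).
#' @param y response vector; defaults to the response carried by `design`.
#' @param level two-sided confidence level for the reported intervals.
#' @return An object of class `"ols_fit"`: coefficients, `se`, `cov_b`,
#'   `df_resid`, `t`, `p_value`, `ci_low`/`ci_high`, `r2`, `adj_r2`, `sigma2`,
#'   `fitted`, `residuals`, plus the design for downstream probing.
#' @examples
#' d <- data.frame(x = c(0, 1, 2), y = c(1, 3, 5))
#' f <- fit_ols(build_design(model_spec("y", list("x")), d))
#' coef(f)  # intercept 1, slope 2
#' @export
fit_ols <- function(design, y = NULL, level = 0.95) {
  if (is.matrix(design)) design <- as_design_matrix(design)
  stopifnot(inherits(design, "design_matrix"))
  if (is.null(y)) y <- design$response
  if (is.null(y)) stop("no response: supply y or include it in the data")
  X <- design$matrix
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("design rows (", n, ") != length(y) (", length(y), ")")
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (n <= p) {
    stop("insufficient data: n = ", n, " <= p = ", p, call. = FALSE)
  }
  qrx <- qr(X)
  dR <- abs(diag(qr.R(qrx)))
  rank <- sum(dR > RANK_TOL * max(dR))
  if (rank < p) {
    bad <- colnames(X)[qrx$pivot[(rank + 1L):p]]
    stop("rank-deficient design: column(s) ", paste(bad, collapse = ", "),
         " are collinear with the preceding columns", call. = FALSE)
  }
  b <- qr.coef(qrx, y)
  fitted <- drop(X %*% b)
  resid <- y - fitted
  df_resid <- n - p
  sse <- sum(resid^2)
  sigma2 <- sse / df_resid
  # (X'X)^-1 from R, unpivoted on both dimensions
  xtx_inv <- chol2inv(qr.R(qrx))
  unpiv <- order(qrx$pivot)
  xtx_inv <- xtx_inv[unpiv, unpiv, drop = FALSE]
  cov_b <- sigma2 * xtx_inv
  dimnames(cov_b) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(cov_b), 0))
  tstat <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * Inf))
  p_value <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
  if (design$has_intercept) {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
      stop("undefined R-squared: response is constant", call. = FALSE)
    }
  } else {
    sst <- sum(y^2)
  }
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - as.integer(design$has_intercept)) / df_resid
  tcrit <- stats::qt(1 - (1 - level) / 2, df_resid)
  fit <- structure(list(coefficients = b, se = se, cov_b = cov_b,
                        df_resid = df_resid, t = tstat, p_value = p_value,
                        ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                        level = level, r2 = r2, adj_r2 = adj_r2,
                        sigma2 = sigma2, fitted = fitted, residuals = resid,
                        y = y, design = design, n = n, p = p),
                   class = "ols_fit")
  fit
}

# Wrap a bare matrix as a design with raw terms, for direct fitting.
as_design_matrix <- function(X) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  has_int <- colnames(X)[1] == "(Intercept)" ||
    (all(X[, 1] == X[1, 1]) && X[1, 1] == 1)
  labels <- colnames(X)[if (has_int) -1L else TRUE]
  if (has_int) colnames(X)[1] <- "(Intercept)"
  structure(list(matrix = X,
                 terms = lapply(labels, term_raw),
                 labels = labels,
                 has_intercept = has_int,
                 constants = stats::setNames(numeric(length(labels)), labels),
                 spec = NULL, scheme = NULL, response = NULL, n = nrow(X)),
            class = "design_matrix")
}

#' Fit a model spec to data
#'
#' Convenience wrapper: [build_design()] then [fit_ols()].
#'
#' @inheritParams build_design
#' @inheritParams fit_ols
#' @return An `"ols_fit"`.
#' @export
fit_model <- function(spec, data, scheme = NULL, level = 0.95) {
  fit_ols(build_design(spec, data, scheme), level = level)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
fitted.ols_fit <- function(object, ...) object$fitted

#' Per-coefficient confidence intervals
#'
#' @param fit an `"ols_fit"`.
#' @param level confidence level in (0, 1); intervals are
#'   `b +/- t(df_resid, level) * se`.
#' @return data frame with `term`, `estimate`, `lower`, `upper`.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"), is.numeric(level), length(level) == 1L,
            level > 0, level < 1)
  tcrit <- stats::qt(1 - (1 - level) / 2, fit$df_resid)
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             lower = unname(fit$coefficients - tcrit * fit$se),
             upper = unname(fit$coefficients + tcrit * fit$se),
             row.names = NULL)
}

#' Predict from an OLS fit
#'
#' @param object an `"ols_fit"`.
#' @param design optional design matrix whose columns must match the fit's
#'   (same names, same order); defaults to the training design.
#' @param ... unused.
#' @return fitted vector `X b`.
#' @export
predict.ols_fit <- function(object, design = NULL, ...) {
  if (is.null(design)) return(object$fitted)
  if (is.matrix(design)) design <- as_design_matrix(design)
  stopifnot(inherits(design, "design_matrix"))
  if (!identical(colnames(design$matrix), colnames(object$design$matrix))) {
    stop("schema error: design columns do not match the fitted model (",
         paste(colnames(design$matrix), collapse = ", "), " vs ",
         paste(colnames(object$design$matrix), collapse = ", "), ")",
         call. = FALSE)
  }
  drop(design$matrix %*% object$coefficients)
}

#' @export
print.ols_fit <- function(x, digits = 3, ...) {
  cat("OLS fit: n =", x$n, ", p =", x$p, ", df_resid =", x$df_resid, "\n")
  tab <- data.frame(b = x$coefficients, `SE b` = x$se, t = x$t,
                    p = x$p_value,
                    ci_low = x$ci_low, ci_high = x$ci_high,
                    check.names = FALSE)
  print(round(tab, digits))
  cat(sprintf("R2 = %.*f, adjusted R2 = %.*f, residual SD = %.*f\n",
              digits, x$r2, digits, x$adj_r2, digits, sqrt(x$sigma2)))
  ctr <- x$design$constants[x$design$constants != 0]
  if (length(ctr)) {
    cat("note: 0 on a centered predictor means, on the raw scale:",
        paste(sprintf("%s = %.4g", names(ctr), ctr), collapse = ", "), "\n")
  }
  invisible(x)
}

# Coefficient index of a term matching a predicate, offset for the intercept.
find_term <- function(fit, pred) {
  idx <- which(vapply(fit$design$terms, pred, logical(1)))
  if (length(idx) == 0L) return(NULL)
  idx[1L] + as.integer(fit$design$has_intercept)
}

first_order_index <- function(fit, var) {
  find_term(fit, function(t)
    t$kind %in% c("raw", "centered", "standardized") && t$base == var)
}

product_index <- function(fit, var1, var2) {
  find_term(fit, function(t)
    t$kind == "product" && setequal(term_bases(t), c(var1, var2)))
}

power_index <- function(fit, var, exponent = 2L) {
  find_term(fit, function(t)
    t$kind == "power" && t$base$base == var && t$exponent == exponent)
}
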
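# Term and model specification: the locus of centering semantics.
# Products and powers are DERIVED terms, always recomputed from their
# transformed components; they are never transformed in place.

#' Term constructors
#'
#' A model term is one of: a raw variable, a centered variable (at its mean or
#' an arbitrary constant), a standardized (z-scored) variable, a product of
#' two base terms, or an integer power (>= 2) of a base term. Products and
#' powers are derived: they are recomputed from their components *after* any
#' centering/standardization, never transformed themselves.
#'
#' @param var variable name (a column of the data).
#' @param constant centering constant: a finite number, or `"mean"` to resolve
#'   the sample mean at build time.
#' @param a,b component terms of a product (raw/centered/standardized terms or
#'   bare variable names, which are taken as raw).
#' @param term base term of a power (or a bare variable name).
#' @param exponent integer exponent, at least 2 (an exponent of 1 is just the
#'   base term).
#' @return An object of class `"term_spec"`.
#' @examples
#' term_product(term_centered("temp"), term_centered("humidity"))
#' term_power("minutes", 2)
#' @export
term_raw <- function(var) {
  stopifnot(is.character(var), length(var) == 1L, nzchar(var))
  structure(list(kind = "raw", base = var), class = "term_spec")
}

#' @rdname term_raw
#' @export
term_centered <- function(var, constant = "mean") {
  stopifnot(is.character(var), length(var) == 1L, nzchar(var))
  if (!identical(constant, "mean")) {
    stopifnot(is.numeric(constant), length(constant) == 1L, is.finite(constant))
  }
  structure(list(kind = "centered", base = var, constant = constant),
            class = "term_spec")
}

#' @rdname term_raw
#' @export
term_standardized <- function(var) {
  stopifnot(is.character(var), length(var) == 1L, nzchar(var))
  structure(list(kind = "standardized", base = var), class = "term_spec")
}

as_base_term <- function(x) {
  if (is.character(x)) x <- term_raw(x)
  stopifnot(inherits(x, "term_spec"))
  if (!x$kind %in% c("raw", "centered", "standardized")) {
    stop("order-of-operations error: products/powers are derived terms and ",
         "cannot be components of another product or power; transform the ",
         "base variables instead", call. = FALSE)
  }
  x
}

#' @rdname term_raw
#' @export
term_product <- function(a, b) {
  a <- as_base_term(a); b <- as_base_term(b)
  structure(list(kind = "product", components = list(a, b)),
            class = "term_spec")
}

#' @rdname term_raw
#' @export
term_power <- function(term, exponent) {
  term <- as_base_term(term)
  stopifnot(is.numeric(exponent), length(exponent) == 1L,
            exponent == as.integer(exponent))
  if (exponent < 2) stop("power exponent must be >= 2 (use the base term for exponent 1)")
  structure(list(kind = "power", base = term, exponent = as.integer(exponent)),
            class = "term_spec")
}

term_bases <- function(term) {
  switch(term$kind,
         raw = ,
         centered = ,
         standardized = term$base,
         product = vapply(term$components, function(t) t$base, character(1)),
         power = term$base$base)
}

term_label <- function(term) {
  base_label <- function(t) {
    switch(t$kind,
           raw = t$base,
           centered = paste0(t$base, "_c"),
           standardized = paste0(t$base, "_z"))
  }
  switch(term$kind,
         raw = ,
         centered = ,
         standardized = base_label(term),
         product = paste(vapply(term$components, base_label, character(1)),
                         collapse = ":"),
         power = paste0(base_label(term$base), "^", term$exponent))
}

#' @export
print.term_spec <- function(x, ...) {
  cat("<term> ", term_label(x), " [", x$kind, "]\n", sep = "")
  invisible(x)
}

#' Model specification
#'
#' Declares the response and an ordered list of terms. Column order of the
#' built design matrix follows the term order given here.
#'
#' @param response name of the response variable.
#' @param terms list of [term_raw()]-family term specs (bare variable names are
#'   accepted and taken as raw terms).
#' @param intercept include an intercept column (default `TRUE`).
#' @return An object of class `"model_spec"`.
#' @examples
#' model_spec("bars", list("temp", "humidity", term_product("temp", "humidity")))
#' @export
model_spec <- function(response, terms, intercept = TRUE) {
  stopifnot(is.character(response), length(response) == 1L, is.list(terms),
            length(terms) >= 1L, is.logical(intercept))
  terms <- lapply(terms, function(t) if (is.character(t)) term_raw(t) else t)
  ok <- vapply(terms, inherits, logical(1), what = "term_spec")
  if (!all(ok)) stop("all terms must be term_spec objects or variable names")
  structure(list(response = response, terms = terms, intercept = intercept),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$response, " ~ ",
      paste(vapply(x$terms, term_label, character(1)), collapse = " + "),
      if (!x$intercept) " (no intercept)", "\n", sep = "")
  invisible(x)
}

spec_base_variables <- function(spec) {
  unique(unlist(lapply(spec$terms, term_bases)))
}

#' Centering scheme
#'
#' A map from variable names to centering constants. A constant is a finite
#' number or the token `"mean"` (resolved to the sample mean at build time).
#' A scheme applies to *raw* terms only: terms explicitly declared centered or
#' standardized in the model spec keep their declaration, so refitting one
#' spec under several schemes is a pure reparameterization of the same model.
#'
#' @param ... named arguments, e.g. `center_scheme(temp = "mean", humidity = 85)`.
#' @return An object of class `"center_scheme"` (a named list).
#' @export
center_scheme <- function(...) {
  sch <- list(...)
  if (length(sch) == 0L) return(structure(list(), class = "center_scheme"))
  if (is.null(names(sch)) || any(!nzchar(names(sch)))) {
    stop("all centering-scheme entries must be named by variable")
  }
  for (v in names(sch)) {
    cst <- sch[[v]]
    if (!identical(cst, "mean") &&
        !(is.numeric(cst) && length(cst) == 1L && is.finite(cst))) {
      stop("centering constant for '", v, "' must be a finite number or \"mean\"")
    }
  }
  structure(sch, class = "center_scheme")
}

#' Center a numeric vector at a constant
#'
#' Centering is nothing more than subtracting a constant from each value: a
#' pure location shift that changes what a score of 0 means and nothing else.
#'
#' @param column numeric vector, finite.
#' @param constant a finite number, or `"mean"` (the default) to subtract the
#'   sample mean.
#' @return list with `values` (the shifted vector) and `constant` (the resolved
#'   numeric constant, at full precision).
#' @examples
#' center(c(1, 2, 3))          # constant resolves to 2
#' center(c(1, 2, 3), 10)
#' @export
center <- function(column, constant = "mean") {
  stopifnot(is.numeric(column), length(column) >= 1L, all(is.finite(column)))
  cst <- if (identical(constant, "mean")) mean(column) else constant
  stopifnot(is.numeric(cst), length(cst) == 1L, is.finite(cst))
  list(values = column - cst, constant = cst)
}

#' Standardize a numeric vector to z-scores
#'
#' Uses the sample (n - 1) standard deviation, matching the conventions of the
#' common statistical packages.
#'
#' @param column numeric vector with positive sample SD.
#' @return numeric vector with mean 0 and sample SD 1.
#' @export
standardize <- function(column) {
  stopifnot(is.numeric(column), length(column) >= 2L, all(is.finite(column)))
  s <- stats::sd(column)
  if (s <= 0 || !is.finite(s)) {
    stop("degenerate variable: zero variance, cannot standardize", call. = FALSE)
  }
  (column - mean(column)) / s
}

# Resolve a base term to its column and a resolved copy of the term (constants
# recorded at full precision). A scheme entry applies to raw terms only.
resolve_base <- function(term, data, scheme) {
  x <- data[[term$base]]
  if (term$kind == "raw" && !is.null(scheme) && term$base %in% names(scheme)) {
    term <- term_centered(term$base, scheme[[term$base]])
  }
  switch(term$kind,
         raw = list(values = x, term = term),
         centered = {
           ctr <- center(x, term$constant)
           term$constant <- ctr$constant
           list(values = ctr$values, term = term)
         },
         standardized = {
           term$mean <- mean(x); term$sd <- stats::sd(x)
           list(values = standardize(x), term = term)
         })
}

check_scheme_vars <- function(spec, scheme) {
  if (is.null(scheme) || length(scheme) == 0L) return(invisible())
  bases <- spec_base_variables(spec)
  labels <- vapply(spec$terms, term_label, character(1))
  for (v in names(scheme)) {
    if (v %in% bases) next
    if (v %in% labels || grepl("[:^]", v)) {
      stop("order-of-operations error: '", v, "' is a derived (product/power) ",
           "column; derived terms are recomputed from transformed components, ",
           "never centered in place", call. = FALSE)
    }
    stop("schema error: centering scheme names unknown variable '", v, "'",
         call. = FALSE)
  }
  invisible()
}

# Effective transform signature of a base variable inside a term, used to
# flag interpretationally hazardous mixed specs.
base_signature <- function(term, scheme) {
  if (term$kind == "raw" && !is.null(scheme) && term$base %in% names(scheme)) {
    return(paste0("centered@", format(scheme[[term$base]])))
  }
  switch(term$kind,
         raw = "raw",
         centered = paste0("centered@", format(term$constant)),
         standardized = "standardized")
}

warn_mixed_spec <- function(spec, scheme) {
  first_order <- list()
  for (t in spec$terms) {
    if (t$kind %in% c("raw", "centered", "standardized")) {
      first_order[[t$base]] <- base_signature(t, scheme)
    }
  }
  clashes <- character(0)
  for (t in spec$terms) {
    comps <- switch(t$kind, product = t$components, power = list(t$base), NULL)
    for (cmp in comps %||% list()) {
      sig <- base_signature(cmp, scheme)
      have <- first_order[[cmp$base]]
      if (!is.null(have) && !identical(have, sig)) {
        clashes <- c(clashes, sprintf("'%s' (%s in the %s term, %s first-order)",
                                      cmp$base, sig, t$kind, have))
      }
    }
  }
  if (length(clashes)) {
    warning("mixed centering: ", paste(clashes, collapse = "; "),
            "; the first-order coefficients of such models are ",
            "interpretationally hazardous", call. = FALSE)
  }
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a design matrix from a model spec
#'
#' Transforms are applied to base variables first; product and power columns
#' are then computed from the *transformed* columns. Column names encode the
#' transform (`_c` centered, `_z` standardized); the exact centering constants
#' are carried at full precision in the attached term metadata. Rows with
#' missing values in any used variable (including the response, when present
#' in `data`) are dropped listwise with a message.
#'
#' @param spec a [model_spec()].
#' @param data a data frame (or anything coercible) holding the base variables.
#' @param scheme optional [center_scheme()] applied to raw terms.
#' @return An object of class `"design_matrix"`: list with `matrix` (n x p,
#'   intercept first when present), `terms` (resolved term specs, one per
#'   non-intercept column), `has_intercept`, `constants` (named vector of
#'   resolved centering constants per base variable, 0 when uncentered), and
#'   `response` values when the response is a column of `data`.
#' @export
build_design <- function(spec, data, scheme = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  check_scheme_vars(spec, scheme)
  used <- spec_base_variables(spec)
  have_response <- spec$response %in% names(data)
  need <- c(if (have_response) spec$response, used)
  missing_vars <- setdiff(need, names(data))
  if (length(missing_vars)) {
    stop("schema error: variable(s) not found in data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  for (v in need) {
    if (!is.numeric(data[[v]])) {
      stop("schema error: column '", v, "' is non-numeric", call. = FALSE)
    }
  }
  keep <- stats::complete.cases(data[need])
  if (any(!keep)) {
    message("listwise deletion: dropped ", sum(!keep),
            " row(s) with missing values")
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)
  if (n < 1L) stop("no complete cases remain", call. = FALSE)
  warn_mixed_spec(spec, scheme)

  cols <- list(); resolved <- list(); constants <- stats::setNames(
    numeric(length(used)), used)
  for (t in spec$terms) {
    if (t$kind %in% c("raw", "centered", "standardized")) {
      rb <- resolve_base(t, data, scheme)
      cols[[length(cols) + 1L]] <- rb$values
      resolved[[length(resolved) + 1L]] <- rb$term
      if (rb$term$kind == "centered") constants[[rb$term$base]] <- rb$term$constant
    } else if (t$kind == "product") {
      rb <- lapply(t$components, resolve_base, data = data, scheme = scheme)
      t$components <- lapply(rb, `[[`, "term")
      cols[[length(cols) + 1L]] <- rb[[1]]$values * rb[[2]]$values
      resolved[[length(resolved) + 1L]] <- t
    } else if (t$kind == "power") {
      rb <- resolve_base(t$base, data, scheme)
      t$base <- rb$term
      cols[[length(cols) + 1L]] <- rb$values ^ t$exponent
      resolved[[length(resolved) + 1L]] <- t
    } else stop("unknown term kind: ", t$kind)
  }
  labels <- vapply(resolved, term_label, character(1))
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  if (spec$intercept) {
    X <- cbind(`(Intercept)` = rep(1, n), X)
  }
  structure(list(matrix = X,
                 terms = resolved,
                 labels = labels,
                 has_intercept = spec$intercept,
                 constants = constants,
                 spec = spec,
                 scheme = scheme,
                 response = if (have_response) data[[spec$response]],
                 n = n),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", x$n, " x ", ncol(x$matrix), " (",
      paste(colnames(x$matrix), collapse = ", "), ")\n", sep = "")
  ctr <- x$constants[x$constants != 0]
  if (length(ctr)) {
    cat("  centering: ",
        paste(sprintf("%s at %.4g", names(ctr), ctr), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Correlations among the predictor columns of a design matrix
#'
#' Pearson correlations of the non-intercept columns: the quantity usually
#' inspected to judge collinearity between first-order terms and their
#' products/powers. Centering base variables changes these correlations for
#' derived terms only (non-essential collinearity); the correlation between
#' two base variables is unaffected.
#'
#' @param design a [build_design()] result with at least 2 non-intercept columns.
#' @return symmetric correlation matrix.
#' @export
predictor_correlations <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  if (design$has_intercept) X <- X[, -1L, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 non-intercept columns")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds <= 0)) {
    stop("degenerate variable: zero variance in column(s) ",
         paste(colnames(X)[sds <= 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(X)
}
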
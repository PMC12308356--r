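# Formal centering-invariance audit: refit one model spec under several
# centering schemes and certify which quantities are identical (invariant
# block) and which are merely reparameterized (changed block). Invariance
# failure is an internal error — these identities hold mathematically, so a
# violation means the rebuild-the-derived-terms discipline was broken — never
# a property of the data.

rel_disc <- function(vals) {
  # max pairwise discrepancy, relative to max(1, magnitude)
  vals <- do.call(rbind, lapply(vals, as.numeric))
  rng <- apply(vals, 2L, function(v) max(v) - min(v))
  scale <- pmax(1, apply(abs(vals), 2L, max))
  max(rng / scale)
}

scheme_label <- function(scheme) {
  if (is.null(scheme) || length(scheme) == 0L) return("raw")
  paste(vapply(names(scheme), function(v) {
    cst <- scheme[[v]]
    paste0(v, "=", if (identical(cst, "mean")) "mean" else format(cst))
  }, character(1)), collapse = ",")
}

derived_terms <- function(spec) {
  Filter(function(t) t$kind %in% c("product", "power"), spec$terms)
}

#' Audit a model's invariance to centering schemes
#'
#' Fits `spec` under every scheme (derived terms rebuilt from the transformed
#' bases each time) and partitions the reported quantities into an invariant
#' block — highest-order coefficient with its SE/t/p/CI, R², adjusted R²,
#' residuals, fitted values, every term's semipartial correlation, every
#' hierarchical ΔR², and conditional effects evaluated at scheme-equivalent
#' points — and a changed block (intercept, first-order coefficients with
#' SE/t/p, default β), each changed entry annotated with what it now means.
#' Any invariant-block discrepancy above `tol` raises an invariance-violation
#' error: it signals an implementation bug, not a data property.
#'
#' @param spec a [model_spec()] (its own terms should be raw; the schemes
#'   provide the parameterizations to compare).
#' @param data data frame.
#' @param schemes list of at least two [center_scheme()]s (an empty scheme is
#'   the raw parameterization).
#' @param tol audit tolerance, relative to `max(1, |value|)` (default 1e-9:
#'   double-precision pipelines make centering a pure relabeling).
#' @param probe_raw optional named list of raw-scale probe values per
#'   moderator variable; defaults to mean ± 1 SD on the raw scale, translated
#'   into each scheme's parameterization.
#' @return An object of class `"centering_audit"` with `invariant_block`
#'   (quantity, max relative discrepancy), `changed_block` (per-scheme values
#'   with interpretation notes), `schemes`, `fits`, `tol`.
#' @export
audit <- function(spec, data, schemes, tol = 1e-9, probe_raw = NULL) {
  stopifnot(inherits(spec, "model_spec"), is.list(schemes),
            length(schemes) >= 2L)
  data <- as.data.frame(data)
  dts <- derived_terms(spec)
  slabels <- vapply(schemes, scheme_label, character(1))

  first_order <- Filter(function(t)
    t$kind %in% c("raw", "centered", "standardized"), spec$terms)
  fo_vars <- vapply(first_order, `[[`, character(1), "base")

  fits <- lapply(schemes, function(s) fit_model(spec, data, s))
  hier <- if (length(dts) > 0L && length(first_order) > 0L) {
    lapply(schemes, function(s) hierarchical_fit(
      spec$response,
      list(first_order, spec$terms), data, s, spec$intercept))
  }

  inv <- list()
  add_inv <- function(name, per_scheme) inv[[name]] <<- per_scheme

  # highest-order terms: every derived term's b/se/t/p/CI (for additive
  # models the first-order terms themselves are the highest order and are
  # scheme-invariant)
  hi_terms <- if (length(dts)) dts else first_order
  for (t in hi_terms) {
    lab <- term_label(strip_transforms(t))
    idx <- lapply(fits, function(f) {
      k <- switch(t$kind,
                  product = product_index(f, term_bases(t)[1], term_bases(t)[2]),
                  power = power_index(f, term_bases(t), t$exponent),
                  first_order_index(f, term_bases(t)))
      if (is.null(k)) stop("internal: term not found in fit")
      k
    })
    for (q in c("coefficients", "se", "t", "p_value", "ci_low", "ci_high")) {
      add_inv(paste0(lab, ".", sub("coefficients", "b", q)),
              mapply(function(f, k) f[[q]][[k]], fits, idx))
    }
  }
  add_inv("r2", vapply(fits, `[[`, numeric(1), "r2"))
  add_inv("adj_r2", vapply(fits, `[[`, numeric(1), "adj_r2"))
  add_inv("residuals", lapply(fits, residuals))
  add_inv("fitted", lapply(fits, fitted))
  # sr is centering-invariant when each term is assessed in the model where it
  # enters hierarchically: first-order terms in the reduced (Step-1) model,
  # derived terms in the full model. (In the full model, first-order sr values
  # are conditional quantities and change with the scheme, like b1/b2.)
  sr_hier <- lapply(seq_along(fits), function(si) {
    if (is.null(hier)) unname(semipartial(fits[[si]]))
    else {
      full_sr <- semipartial(fits[[si]])
      dlab <- vapply(fits[[si]]$design$terms, function(t)
        t$kind %in% c("product", "power"), logical(1))
      c(unname(semipartial(hier[[si]]$fits[[1]])), unname(full_sr[dlab]))
    }
  })
  add_inv("sr_hierarchical", sr_hier)
  if (!is.null(hier)) {
    add_inv("delta_r2", lapply(hier, function(h) h$table$delta_r2))
    add_inv("step_F", lapply(hier, function(h) h$table$F))
  }

  # conditional effects at scheme-equivalent points
  cond_notes <- character(0)
  for (t in dts) {
    bases <- term_bases(t)
    if (t$kind == "product") {
      focal <- bases[1]; moder <- bases[2]
      pts <- probe_raw[[moder]] %||% pick_points(data[[moder]])
      for (k in seq_along(pts)) {
        effs <- mapply(function(f, s) {
          h <- pts[[k]] - raw_offset(f$design, moder)
          conditional_slope(f, focal, moder, h)
        }, fits, schemes, SIMPLIFY = FALSE)
        for (q in c("slope", "se", "t", "p_value")) {
          add_inv(sprintf("cond(%s|%s=%.6g).%s", focal, moder, pts[[k]], q),
                  vapply(effs, `[[`, numeric(1), q))
        }
      }
    } else {
      v <- bases
      pts <- probe_raw[[v]] %||% pick_points(data[[v]])
      for (k in seq_along(pts)) {
        effs <- mapply(function(f, s) {
          x0 <- pts[[k]] - raw_offset(f$design, v)
          quadratic_slope(f, v, x0)
        }, fits, schemes, SIMPLIFY = FALSE)
        for (q in c("slope", "se", "t", "p_value")) {
          add_inv(sprintf("curve(%s=%.6g).%s", v, pts[[k]], q),
                  vapply(effs, `[[`, numeric(1), q))
        }
      }
    }
  }

  inv_tab <- data.frame(quantity = names(inv),
                        max_discrepancy = vapply(inv, function(v) {
                          if (!is.list(v)) v <- as.list(v)
                          rel_disc(v)
                        }, numeric(1)),
                        row.names = NULL)
  bad <- inv_tab$quantity[inv_tab$max_discrepancy > tol]
  if (length(bad)) {
    stop("invariance violation (implementation bug, not a data property): ",
         paste(bad, collapse = ", "), " exceed tolerance ", format(tol),
         call. = FALSE)
  }

  # changed block: intercept, first-order b/se/t/p, beta_default, with notes
  changed <- list()
  if (spec$intercept) {
    changed[["(Intercept)"]] <- list(
      values = vapply(fits, function(f) f$coefficients[[1]], numeric(1)),
      note = "prediction at 0 on every predictor's fitted scale")
  }
  bd <- lapply(fits, beta_default)
  for (v in fo_vars) {
    others <- character(0)
    for (t in dts) {
      bb <- term_bases(t)
      if (t$kind == "product" && v %in% bb) others <- c(others, setdiff(bb, v))
      if (t$kind == "power" && identical(bb, v)) others <- c(others, v)
    }
    per_scheme <- lapply(fits, function(f) {
      i <- first_order_index(f, v)
      c(b = f$coefficients[[i]], se = f$se[[i]], t = f$t[[i]],
        p = f$p_value[[i]])
    })
    if (length(others) == 0L) {
      # additive model: mathematically invariant, belongs to the other block
      add_note <- "constant (additive) effect; invariant to centering"
      inv_tab <- rbind(inv_tab, data.frame(
        quantity = paste0(v, ".b"),
        max_discrepancy = rel_disc(lapply(per_scheme, `[`, "b"))))
      changed[[paste0("note.", v)]] <- list(values = NULL, note = add_note)
      next
    }
    notes <- vapply(seq_along(fits), function(si) {
      f <- fits[[si]]
      if (others[1] == v) {
        sprintf("slope of the curve when %s = %.6g (raw scale)",
                v, raw_offset(f$design, v))
      } else {
        sprintf("conditional effect of %s when %s = %.6g (raw scale)",
                v, others[1], raw_offset(f$design, others[1]))
      }
    }, character(1))
    changed[[v]] <- list(values = per_scheme, note = notes)
  }
  if (length(dts)) {
    for (t in dts) {
      lab <- term_label(strip_transforms(t))
      bb <- term_bases(t)
      changed[[paste0("beta_default.", lab)]] <- list(
        values = vapply(seq_along(fits), function(si) {
          f <- fits[[si]]
          k <- if (t$kind == "product") product_index(f, bb[1], bb[2])
               else power_index(f, bb, t$exponent)
          unname(bd[[si]][[k - as.integer(f$design$has_intercept)]])
        }, numeric(1)),
        note = "default beta of the derived term; incorrect under every scheme — use beta_correct or sr")
    }
  }

  structure(list(invariant_block = inv_tab, changed_block = changed,
                 schemes = schemes, scheme_labels = slabels, fits = fits,
                 spec = spec, tol = tol,
                 additive = length(dts) == 0L),
            class = "centering_audit")
}

#' Human-readable audit report
#'
#' Renders a fixed-wording report: invariant quantities with their maximum
#' discrepancies, and each changed quantity annotated with its conditional
#' interpretation ("conditional effect of X when M = c"); first-order terms in
#' a moderation model are never described as main effects — main effects
#' belong to the reduced (hierarchical Step-1) model.
#'
#' @param audit a `"centering_audit"`.
#' @return character vector of report lines (invisibly printed by
#'   `print.centering_audit`).
#' @export
annotate <- function(audit) {
  stopifnot(inherits(audit, "centering_audit"))
  lines <- c(
    sprintf("Centering-invariance audit: %d schemes (%s), tolerance %g",
            length(audit$schemes), paste(audit$scheme_labels, collapse = " | "),
            audit$tol),
    "",
    "INVARIANT under every scheme (max relative discrepancy):")
  tab <- audit$invariant_block
  lines <- c(lines, sprintf("  %-40s %.3g", tab$quantity, tab$max_discrepancy))
  lines <- c(lines, "", "REPARAMETERIZED by the scheme (values per scheme):")
  for (nm in names(audit$changed_block)) {
    entry <- audit$changed_block[[nm]]
    if (is.null(entry$values)) {
      lines <- c(lines, sprintf("  %s: %s", sub("^note\\.", "", nm), entry$note))
      next
    }
    if (is.list(entry$values)) {
      for (si in seq_along(entry$values)) {
        v <- entry$values[[si]]
        lines <- c(lines, sprintf(
          "  %s [%s]: b = %.4g (SE %.4g, t %.4g, p %.4g) — %s",
          nm, audit$scheme_labels[si], v[["b"]], v[["se"]], v[["t"]], v[["p"]],
          entry$note[si]))
      }
    } else {
      lines <- c(lines, sprintf("  %s: %s — %s", nm,
                                paste(sprintf("%.4g", entry$values),
                                      collapse = " | "),
                                entry$note[1]))
    }
  }
  if (!audit$additive) {
    lines <- c(lines, "",
               paste0("Reminder: the lower-order coefficients above are ",
                      "conditional effects, not main effects, under every ",
                      "scheme; assess main effects from the reduced ",
                      "(Step-1) model of a hierarchical analysis."))
  }
  lines
}

#' @export
print.centering_audit <- function(x, ...) {
  cat(paste(annotate(x), collapse = "\n"), "\n")
  invisible(x)
}
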
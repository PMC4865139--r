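#' Fit the exponential Gibbs-energy / translation-efficiency model
#'
#' Relative translation efficiency y (% of an unstructured control leader)
#' falls off exponentially with the 5'UTR folding energy X (kcal/mol):
#' `y = a * exp(b * X)`.  The fit is ordinary least squares of `ln(y)` on
#' `X`; `a = exp(intercept)`, `b = slope`, and the coefficient of
#' determination is reported on the log-linear scale.
#'
#' @param data A data frame of variant records with (at least) the columns
#'   named by `delta_g` and `efficiency`; an optional `name` column labels
#'   records in error messages.
#' @param delta_g,efficiency Column names (strings) holding the Gibbs energy
#'   (kcal/mol) and the relative translation efficiency (%, strictly
#'   positive).
#' @return An object of class `efficiency_model` with fields `a`, `b`,
#'   `r_squared`, `n_points` and `fit_log` (the (X, ln y) pairs used).
#' @examples
#' v <- tibble::tibble(name = c("A", "G", "F"),
#'                     delta_g = c(-69, -127, -128.9),
#'                     efficiency = c(24.09, 3.00, 4.03))
#' fit_efficiency_model(v)
#' @export
fit_efficiency_model <- function(data, delta_g = "delta_g",
                                 efficiency = "efficiency") {
  stopifnot(is.data.frame(data))
  if (!all(c(delta_g, efficiency) %in% names(data))) {
    abort(sprintf("data must contain columns '%s' and '%s'", delta_g, efficiency),
          class = "dg_config_error")
  }
  x <- data[[delta_g]]
  y <- data[[efficiency]]
  labels <- if ("name" %in% names(data)) as.character(data$name) else
    as.character(seq_along(x))
  if (any(!is.finite(x))) {
    abort("all delta_g values must be finite", class = "dg_domain_error")
  }
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad)) {
    abort(sprintf("efficiency must be > 0 for fitting; offending record(s): %s",
                  paste(labels[bad], collapse = ", ")),
          class = "dg_domain_error")
  }
  if (length(unique(x)) < 2L) {
    abort("need at least 2 records with distinct delta_g values",
          class = "dg_degenerate_fit_error")
  }
  fit <- lm(log(y) ~ x)
  # summary.lm warns on an exactly collinear (noiseless) fit; the r.squared
  # of 1 is the correct report there
  fit_summary <- suppressWarnings(summary(fit))
  new_efficiency_model(
    a = exp(unname(coef(fit)[1])),
    b = unname(coef(fit)[2]),
    r_squared = fit_summary$r.squared,
    n_points = length(x),
    fit_log = tibble(name = labels, delta_g = x, log_efficiency = log(y)),
    source = "fitted"
  )
}

new_efficiency_model <- function(a, b, r_squared, n_points, fit_log, source) {
  if (!is.finite(a) || a <= 0) {
    abort("prefactor a must be positive", class = "dg_domain_error")
  }
  structure(
    list(a = a, b = b, r_squared = r_squared, n_points = n_points,
         fit_log = fit_log, source = source),
    class = "efficiency_model"
  )
}

#' Construct an efficiency model from explicit coefficients
#'
#' @param a Prefactor (%): the predicted efficiency at delta_g = 0.
#' @param b Exponent coefficient (per kcal/mol).
#' @return An `efficiency_model`.
#' @examples
#' efficiency_model(127.29, 0.0248)
#' @export
efficiency_model <- function(a, b) {
  new_efficiency_model(a, b, r_squared = NA_real_, n_points = 0L,
                       fit_log = NULL, source = "explicit")
}

#' Published preset models for the TRB1 5'UTR variant series
#'
#' Two exponential fits were reported for the relation between TRB1 5'UTR
#' folding energy and in-vitro translation efficiency; the study does not
#' adjudicate between them, so both ship as named presets and neither is
#' hard-coded as "the" model.
#'
#' @param name `"trb1_primary"` (a = 127.29, b = 0.0248) or
#'   `"trb1_alternate"` (a = 140.46, b = 0.0307).
#' @return An `efficiency_model`.
#' @examples
#' predict_efficiency(preset_efficiency_model("trb1_primary"), -69)
#' @export
preset_efficiency_model <- function(name = c("trb1_primary", "trb1_alternate")) {
  name <- match.arg(name)
  coefs <- switch(name,
    trb1_primary = c(a = 127.29, b = 0.0248),
    trb1_alternate = c(a = 140.46, b = 0.0307)
  )
  m <- new_efficiency_model(coefs[["a"]], coefs[["b"]], r_squared = NA_real_,
                            n_points = 0L, fit_log = NULL,
                            source = paste0("preset:", name))
  m
}

#' Predict relative translation efficiency from folding energy
#'
#' Evaluates `a * exp(b * delta_g)`; strictly increasing in `delta_g` when
#' `b > 0` (less negative folding energy, i.e. weaker folding, translates
#' more efficiently).
#'
#' @param model An `efficiency_model`.
#' @param delta_g Gibbs energies (kcal/mol); vectorised.
#' @return Predicted efficiencies (% of control).
#' @export
predict_efficiency <- function(model, delta_g) {
  stopifnot(inherits(model, "efficiency_model"))
  model$a * exp(model$b * delta_g)
}

#' @export
predict.efficiency_model <- function(object, delta_g, ...) {
  predict_efficiency(object, delta_g)
}

#' Translational regulatory potential
#'
#' The headroom for oligonucleotide-mediated enhancement of a structured
#' variant, quantified as the ratio of a reference translation efficiency to
#' the variant's (lower) efficiency.  A larger ratio means more room to
#' release translation by unfolding the 5'UTR.
#'
#' @param reference_eff,variant_eff Efficiencies (%), both > 0.
#' @return The fold-ratio `reference_eff / variant_eff`.
#' @examples
#' regulatory_potential(24.09, 4.03)
#' @export
regulatory_potential <- function(reference_eff, variant_eff) {
  if (any(!is.finite(reference_eff) | reference_eff <= 0) ||
      any(!is.finite(variant_eff) | variant_eff <= 0)) {
    abort("efficiencies must be positive", class = "dg_domain_error")
  }
  reference_eff / variant_eff
}

#' Model-based regulatory potential from two folding energies
#'
#' Computes the same ratio on model-predicted efficiencies; in closed form
#' it is `exp(b * (reference_dg - variant_dg))` and does not depend on `a`.
#'
#' @param model An `efficiency_model`.
#' @param reference_dg,variant_dg Gibbs energies (kcal/mol).
#' @return Predicted fold-ratio.
#' @examples
#' predicted_potential(preset_efficiency_model("trb1_primary"), -69, -128.9)
#' @export
predicted_potential <- function(model, reference_dg, variant_dg) {
  regulatory_potential(predict_efficiency(model, reference_dg),
                       predict_efficiency(model, variant_dg))
}

#' @export
print.efficiency_model <- function(x, ...) {
  cat(sprintf("<efficiency_model (%s)>\n", x$source))
  cat(sprintf("  y = %.6g * exp(%.6g * X)   [y %% of control, X kcal/mol]\n",
              x$a, x$b))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  r^2 (log scale) = %.4f on %d points\n", x$r_squared, x$n_points))
  }
  invisible(x)
}

#' @export
tidy.efficiency_model <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.efficiency_model <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points, source = x$source)
}
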
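#' Cultivar coefficient set
#'
#' The prediction model
#' \deqn{\alpha = \frac{k_2 + k_3 w^2 - k_1 w}{10\,x}}
#' is parameterised per cultivar by three empirical constants on the
#' (degree C day, mm, %) scales, plus the July-ET0 threshold above which a
#' season's prediction is flagged unreliable (drought stress disturbs
#' glandular trichome formation, which the rain/temperature inputs do not
#' capture).
#'
#' @param cultivar cultivar name.
#' @param k1 coefficient on the rainfall sum `w`.
#' @param k2 additive constant.
#' @param k3 coefficient on `w^2`.
#' @param et0_threshold reliability threshold on mean July ET0, mm/day.
#' @return An object of class `cultivar_coefficients`.
#' @export
cultivar_coefficients <- function(cultivar, k1, k2, k3, et0_threshold = 4.5) {
  if (!all(is.finite(c(k1, k2, k3)))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  if (!is.finite(et0_threshold) || et0_threshold <= 0) {
    stop("et0_threshold must be > 0", call. = FALSE)
  }
  structure(list(cultivar = as.character(cultivar),
                 k1 = as.numeric(k1), k2 = as.numeric(k2),
                 k3 = as.numeric(k3),
                 et0_threshold = as.numeric(et0_threshold)),
            class = "cultivar_coefficients")
}

#' @export
print.cultivar_coefficients <- function(x, ...) {
  cat(sprintf(
    "<cultivar_coefficients> %s: k1=%g k2=%g k3=%g  ET0 threshold %g mm/day\n",
    x$cultivar, x$k1, x$k2, x$k3, x$et0_threshold))
  invisible(x)
}

#' Built-in cultivar registry
#'
#' Ships with the calibrated entry for cv. Aurora:
#' k1 = 53.8, k2 = 453, k3 = 1.33, ET0 threshold 4.5 mm/day.
#'
#' @return Named list of [cultivar_coefficients()].
#' @export
default_registry <- function() {
  read_cultivar_registry(system.file("extdata", "cultivars.yaml",
                                     package = "hopalpha"))
}

#' Read a cultivar registry file
#'
#' YAML or JSON (by extension) mapping cultivar name to
#' `{k1, k2, k3, et0_threshold}`.
#'
#' @param path registry file path.
#' @return Named list of [cultivar_coefficients()].
#' @export
read_cultivar_registry <- function(path) {
  if (!file.exists(path)) stop("registry not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    cultivar_coefficients(nm, e$k1, e$k2, e$k3,
                          et0_threshold = e$et0_threshold %||% 4.5)
  })
  stats::setNames(out, names(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up a cultivar's coefficients
#'
#' @param name cultivar name (case-sensitive).
#' @param registry registry list; defaults to the packaged one.
#' @return A [cultivar_coefficients()].
#' @export
hop_cultivar <- function(name, registry = default_registry()) {
  if (!name %in% names(registry)) {
    stop("cultivar not in registry: ", name, " (have: ",
         paste(names(registry), collapse = ", "), ")", call. = FALSE)
  }
  registry[[name]]
}

#' Predict alpha-acid content from season accumulations
#'
#' Evaluates the empirical model
#' \deqn{\alpha = \frac{k_2 + k_3 w^2 - k_1 w}{10\,x}}
#' where `x` is the effective temperature sum (degree C day) and `w` the
#' rainfall sum (mm), both over the F3-F9 phenological window. Returns the
#' full-precision value in % of cone dry matter; see [truncate_alpha()] for
#' the one-decimal reporting convention.
#'
#' @param x effective temperature sum, degree C day; must be `> 0`.
#' @param w rainfall sum, mm; must be `>= 0`.
#' @param coeffs a [cultivar_coefficients()].
#' @return Predicted alpha-acid content, % dry matter (vectorized over
#'   `x`, `w`).
#' @examples
#' aurora <- cultivar_coefficients("Aurora", 53.8, 453, 1.33)
#' predict_alpha(1698.4, 393.7, aurora)  # 10.917...
#' @export
predict_alpha <- function(x, w, coeffs) {
  stopifnot(inherits(coeffs, "cultivar_coefficients"))
  if (any(!is.finite(x)) || any(!is.finite(w))) {
    stop("x and w must be finite", call. = FALSE)
  }
  if (any(x <= 0)) stop("x must be > 0", call. = FALSE)
  if (any(w < 0)) stop("w must be >= 0", call. = FALSE)
  (coeffs$k2 + coeffs$k3 * w^2 - coeffs$k1 * w) / (10 * x)
}

#' Unscaled model fraction
#'
#' The model was originally obtained by symbolic regression as the rational
#' fraction \eqn{(k_1 w - k_2 - k_3 w^2)/x}, whose raw values are negative
#' and an order of magnitude too large; the usable prediction divides it by
#' -10. This function returns that raw fraction, so that identically
#' `predict_alpha(x, w) == alpha_raw(x, w) / (-10)`.
#'
#' @inheritParams predict_alpha
#' @return The raw fraction (dimensionless bookkeeping value).
#' @export
alpha_raw <- function(x, w, coeffs) {
  -10 * predict_alpha(x, w, coeffs)
}

#' Truncate a prediction to the one-decimal reporting convention
#'
#' Reported alpha-acid values are truncated toward zero at one decimal
#' (10.917 reports as 10.9), not rounded. A tiny guard rounding at the ninth
#' decimal absorbs floating-point dust before truncation.
#'
#' @param alpha_pct full-precision value(s), % dry matter.
#' @return Truncated value(s).
#' @export
truncate_alpha <- function(alpha_pct) {
  trunc(round(alpha_pct * 10, 9)) / 10
}

#' Reliability gate on mean July evapotranspiration
#'
#' The model is unreliable in extreme drought: when mean July reference crop
#' evapotranspiration exceeds the cultivar threshold (4.5 mm/day for
#' Aurora), the prediction is flagged not reliable. The boundary value
#' itself is reliable. An absent ET0 leaves the prediction reliable with a
#' warning reason, since the gate is a validity annotation rather than a
#' domain restriction of the formula.
#'
#' @param et0_july_mean mean July ET0, mm/day, or `NA` when unavailable.
#' @param coeffs a [cultivar_coefficients()].
#' @return List with `reliable` (logical) and `reason` (character).
#' @export
reliability_gate <- function(et0_july_mean, coeffs) {
  stopifnot(inherits(coeffs, "cultivar_coefficients"))
  if (is.na(et0_july_mean)) {
    return(list(reliable = TRUE,
                reason = "July ET0 unavailable; reliability not assessed"))
  }
  if (et0_july_mean < 0) stop("et0_july_mean must be >= 0", call. = FALSE)
  if (et0_july_mean > coeffs$et0_threshold) {
    list(reliable = FALSE,
         reason = sprintf("July ET0 %.2f > %.2f mm/day: drought season",
                          et0_july_mean, coeffs$et0_threshold))
  } else {
    list(reliable = TRUE,
         reason = sprintf("July ET0 %.2f <= %.2f mm/day",
                          et0_july_mean, coeffs$et0_threshold))
  }
}

#' Predict a season's alpha-acid content with reliability flag
#'
#' Combines [predict_alpha()], the one-decimal reporting truncation and the
#' July-ET0 [reliability_gate()] into one record.
#'
#' @param summary a [season_summary()].
#' @param coeffs a [cultivar_coefficients()].
#' @return An object of class `prediction_record`: fields `alpha_pct`
#'   (full precision), `alpha_pct_reported` (one-decimal truncation),
#'   `reliable`, `reason`, `season`, `cultivar`.
#' @export
predict_season <- function(summary, coeffs) {
  stopifnot(inherits(summary, "season_summary"),
            inherits(coeffs, "cultivar_coefficients"))
  alpha <- predict_alpha(summary$x_eff_temp_sum, summary$w_rain_sum, coeffs)
  gate <- reliability_gate(summary$et0_july_mean, coeffs)
  structure(list(alpha_pct = alpha,
                 alpha_pct_reported = truncate_alpha(alpha),
                 reliable = gate$reliable,
                 reason = gate$reason,
                 season = summary,
                 cultivar = coeffs$cultivar),
            class = "prediction_record")
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("<prediction_record> %s %s: alpha = %.1f%% d.m. (full %.4f) %s\n",
              x$cultivar,
              ifelse(is.na(x$season$year), "", x$season$year),
              x$alpha_pct_reported, x$alpha_pct,
              if (x$reliable) "[reliable]" else "[NOT RELIABLE]"))
  cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}
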
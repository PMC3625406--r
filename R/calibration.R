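#' Fit cultivar coefficients from assayed seasons
#'
#' The model \eqn{\alpha = (k_2 + k_3 w^2 - k_1 w)/(10x)} is linear in its
#' coefficients after multiplying through by `10 x`, so the default
#' estimator is ordinary least squares on the transformed response
#' \eqn{z = 10\,x\,\alpha} with design columns \eqn{(1, -w, w^2)}. This is
#' exact, closed form and reproducible; note it implicitly weights residuals
#' by `x` on the alpha scale. `method = "alpha"` instead minimizes the
#' untransformed sum of squared alpha residuals numerically (Nelder-Mead
#' started at the OLS solution) for comparison.
#'
#' Seasons failing the July-ET0 reliability gate are excluded by default:
#' drought seasons are outside the model's validity domain and would bias
#' the fit.
#'
#' @param observations data frame with columns `x` (degree C day, > 0), `w`
#'   (mm, >= 0), `alpha_assay_pct` (% dry matter, >= 0) and optionally
#'   `reliable` (logical gate outcome; missing column means all reliable).
#' @param use_unreliable include gate-failed seasons in the fit?
#' @param method `"ols"` (transformed linear least squares, default) or
#'   `"alpha"` (direct minimization on the alpha scale).
#' @param cultivar name recorded on the fitted coefficient set.
#' @param et0_threshold reliability threshold carried into the result.
#' @return An object of class `calibration_result`: `coefficients` (a
#'   [cultivar_coefficients()]), `rmse` and `max_abs_residual` on the alpha
#'   scale (% dry matter), `n_used`, `condition_diagnostic` (condition
#'   number of the design matrix) and `method`.
#' @export
fit_coefficients <- function(observations, use_unreliable = FALSE,
                             method = c("ols", "alpha"),
                             cultivar = "fitted", et0_threshold = 4.5) {
  method <- match.arg(method)
  obs <- as.data.frame(observations)
  need <- c("x", "w", "alpha_assay_pct")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("observations lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"reliable" %in% names(obs)) obs$reliable <- TRUE
  if (!use_unreliable) obs <- obs[obs$reliable, , drop = FALSE]
  if (nrow(obs) == 0L) stop("all observations gated out", call. = FALSE)
  if (nrow(obs) < 3L) {
    stop("need >= 3 observations to determine k1, k2, k3; have ",
         nrow(obs), call. = FALSE)
  }
  if (any(obs$x <= 0)) stop("all x must be > 0", call. = FALSE)
  if (any(obs$w < 0)) stop("all w must be >= 0", call. = FALSE)
  if (any(obs$alpha_assay_pct < 0)) {
    stop("alpha_assay_pct must be >= 0", call. = FALSE)
  }

  X <- cbind(`(Intercept)` = 1, neg_w = -obs$w, w_sq = obs$w^2)
  if (qr(X)$rank < 3L) {
    stop("rank-deficient design: rainfall sums do not vary enough to ",
         "separate k1, k2, k3", call. = FALSE)
  }
  z <- 10 * obs$x * obs$alpha_assay_pct
  beta <- stats::lm.fit(X, z)$coefficients  # (k2, k1, k3)
  k <- c(k1 = unname(beta["neg_w"]), k2 = unname(beta["(Intercept)"]),
         k3 = unname(beta["w_sq"]))

  if (method == "alpha") {
    sse_alpha <- function(p) {
      pred <- (p[2] + p[3] * obs$w^2 - p[1] * obs$w) / (10 * obs$x)
      sum((obs$alpha_assay_pct - pred)^2)
    }
    opt <- stats::optim(k, sse_alpha, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    k <- stats::setNames(opt$par, names(k))
  }

  coeffs <- cultivar_coefficients(cultivar, k1 = k["k1"], k2 = k["k2"],
                                  k3 = k["k3"],
                                  et0_threshold = et0_threshold)
  pred <- predict_alpha(obs$x, obs$w, coeffs)
  resid <- obs$alpha_assay_pct - pred
  structure(list(coefficients = coeffs,
                 rmse = sqrt(mean(resid^2)),
                 max_abs_residual = max(abs(resid)),
                 n_used = nrow(obs),
                 condition_diagnostic = kappa(X, exact = TRUE),
                 method = method),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> method=%s n=%d\n", x$method, x$n_used))
  print(x$coefficients)
  cat(sprintf("  rmse %.4f %% d.m., max |resid| %.4f, design condition %.3g\n",
              x$rmse, x$max_abs_residual, x$condition_diagnostic))
  invisible(x)
}

#' Read a calibration table from CSV
#'
#' Columns: `year,x_eff_temp_sum,w_rain_sum,et0_july_mean,alpha_assay_pct`.
#' The reliability flag is derived from the ET0 column and threshold.
#'
#' @param path CSV path.
#' @param et0_threshold gate threshold, mm/day.
#' @return Data frame suitable for [fit_coefficients()] (columns `year`,
#'   `x`, `w`, `et0_july_mean`, `alpha_assay_pct`, `reliable`).
#' @export
read_calibration_table <- function(path, et0_threshold = 4.5) {
  if (!file.exists(path)) stop("calibration file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "x_eff_temp_sum", "w_rain_sum", "alpha_assay_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("calibration table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  et0 <- if ("et0_july_mean" %in% names(df)) df$et0_july_mean else NA_real_
  data.frame(year = df$year,
             x = df$x_eff_temp_sum,
             w = df$w_rain_sum,
             et0_july_mean = et0,
             alpha_assay_pct = df$alpha_assay_pct,
             reliable = is.na(et0) | et0 <= et0_threshold)
}

#' Predict a season with freshly fitted coefficients
#'
#' @param result a `calibration_result` from [fit_coefficients()].
#' @param summary a [season_summary()].
#' @return A `prediction_record` (see [predict_season()]).
#' @export
predict_with_fit <- function(result, summary) {
  stopifnot(inherits(result, "calibration_result"))
  predict_season(summary, result$coefficients)
}
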
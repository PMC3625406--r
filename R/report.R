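#' Classify a prediction-assay difference against EBC assay tolerances
#'
#' The lead conductance assay (EBC 7.4) has a repeatability border
#' r95 = 0.2 and a reproducibility border R95 = 1 (% dry matter). A
#' difference within r95 is indistinguishable from within-lab assay noise;
#' within R95, from between-lab noise. Classification uses the magnitude of
#' the signed difference; a failed reliability gate overrides.
#'
#' @param difference signed difference, calculated minus assayed, % d.m.
#' @param reliable logical gate outcome.
#' @param r95 repeatability border, % d.m.
#' @param R95 reproducibility border, % d.m.
#' @return Character vector over `{within_repeatability,
#'   within_reproducibility, outside_tolerance, not_reliable}`.
#' @export
classify_agreement <- function(difference, reliable = TRUE,
                               r95 = 0.2, R95 = 1) {
  d <- abs(difference)
  eps <- 1e-9  # differences are 0.1-quantized; absorb subtraction dust
  cls <- ifelse(d <= r95 + eps, "within_repeatability",
                ifelse(d <= R95 + eps, "within_reproducibility",
                       "outside_tolerance"))
  cls[!reliable] <- "not_reliable"
  cls
}

#' Validate model predictions against laboratory assays
#'
#' For each season, predicts alpha-acid content from the (x, w) sums,
#' applies the July-ET0 reliability gate, and classifies the difference to
#' the assayed value against the EBC 7.4 tolerances. Differences are stored
#' signed (calculated minus assayed) and classified on magnitude; both the
#' reported-precision (one-decimal truncated) and full-precision differences
#' are returned.
#'
#' @param seasons data frame with columns `year`, `x_eff_temp_sum`,
#'   `w_rain_sum`, `et0_july_mean` (NA allowed) and `alpha_assay_pct`.
#' @param coeffs a [cultivar_coefficients()].
#' @return Data frame, one row per season: the inputs plus `alpha_calc_pct`
#'   (full precision), `alpha_calc_reported` (one-decimal truncation),
#'   `reliable`, `difference` (reported minus assay, signed),
#'   `difference_unrounded` and `agreement_class`.
#' @export
validate_seasons <- function(seasons, coeffs) {
  stopifnot(inherits(coeffs, "cultivar_coefficients"))
  df <- as.data.frame(seasons)
  need <- c("year", "x_eff_temp_sum", "w_rain_sum", "alpha_assay_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("seasons lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$year)) {
    stop("duplicate season years: ",
         paste(unique(df$year[duplicated(df$year)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"et0_july_mean" %in% names(df)) df$et0_july_mean <- NA_real_

  alpha <- predict_alpha(df$x_eff_temp_sum, df$w_rain_sum, coeffs)
  reported <- truncate_alpha(alpha)
  reliable <- vapply(df$et0_july_mean,
                     function(e) reliability_gate(e, coeffs)$reliable,
                     logical(1))
  diff_rep <- reported - df$alpha_assay_pct
  diff_full <- alpha - df$alpha_assay_pct
  data.frame(year = df$year,
             x_eff_temp_sum = df$x_eff_temp_sum,
             w_rain_sum = df$w_rain_sum,
             et0_july_mean = df$et0_july_mean,
             alpha_calc_pct = alpha,
             alpha_calc_reported = reported,
             alpha_assay_pct = df$alpha_assay_pct,
             reliable = reliable,
             difference = diff_rep,
             difference_unrounded = diff_full,
             agreement_class = classify_agreement(diff_rep, reliable))
}

#' The packaged Aurora reference seasons
#'
#' Seven assayed seasons of cv. Aurora — six from Gregurovec, Croatia
#' (2001-2006) and one from Zalec, Slovenia (2012) — with their published
#' window sums, July ET0, reference calculated values and laboratory assay
#' results. The 2003 drought season fails the reliability gate.
#'
#' @return Data frame with columns `year`, `location`, `x_eff_temp_sum`,
#'   `w_rain_sum`, `et0_july_mean`, `alpha_calc_ref_pct`, `alpha_assay_pct`.
#' @export
aurora_seasons <- function() {
  utils::read.csv(system.file("extdata", "aurora_seasons.csv",
                              package = "hopalpha"),
                  stringsAsFactors = FALSE)
}

#' Reproduce the Aurora validation table
#'
#' Re-runs the prediction over the packaged reference seasons and compares
#' each calculated value (at reporting precision) with the published
#' reference column. All six reliable seasons match exactly; 2003 fails the
#' gate and its reference value is not reproduced by the model (a known
#' discrepancy in the published record, annotated rather than forced).
#'
#' @param coeffs a [cultivar_coefficients()]; defaults to the registry
#'   Aurora entry.
#' @return The [validate_seasons()] table plus `alpha_calc_ref_pct` and
#'   `matches_reference` columns, with attribute `"notes"` carrying the
#'   annotations.
#' @export
reproduce_reference_table <- function(coeffs = hop_cultivar("Aurora")) {
  ref <- aurora_seasons()
  tbl <- validate_seasons(ref, coeffs)
  tbl$alpha_calc_ref_pct <- ref$alpha_calc_ref_pct
  tbl$matches_reference <- tbl$alpha_calc_reported == ref$alpha_calc_ref_pct
  notes <- character(0)
  nr <- tbl$year[!tbl$reliable]
  if (length(nr)) {
    notes <- c(notes, sprintf(
      "season %d flagged not reliable (July ET0 above threshold)", nr))
  }
  mismatch <- tbl$year[tbl$reliable & !tbl$matches_reference]
  if (length(mismatch)) {
    notes <- c(notes, sprintf(
      "reliable season %d does not reproduce its reference value", mismatch))
  }
  off_nr <- tbl$year[!tbl$reliable & !tbl$matches_reference]
  if (length(off_nr)) {
    notes <- c(notes, sprintf(
      paste("season %d 's published calculated value is not reproduced by",
            "the model (gated out; discrepancy documented, not forced)"),
      off_nr))
  }
  attr(tbl, "notes") <- notes
  tbl
}

#' Format a validation table as aligned text
#'
#' @param tbl output of [validate_seasons()] or
#'   [reproduce_reference_table()].
#' @return Character vector of lines.
#' @export
format_validation_table <- function(tbl) {
  fmt <- data.frame(
    year = tbl$year,
    x = sprintf("%.1f", tbl$x_eff_temp_sum),
    w = sprintf("%.1f", tbl$w_rain_sum),
    ET0_Jul = ifelse(is.na(tbl$et0_july_mean), "-",
                     sprintf("%.2f", tbl$et0_july_mean)),
    calc = sprintf("%.1f", tbl$alpha_calc_reported),
    assay = sprintf("%.1f", tbl$alpha_assay_pct),
    diff = sprintf("%+.1f", tbl$difference),
    class = ifelse(tbl$reliable, tbl$agreement_class, "n/r"))
  lines <- utils::capture.output(print(fmt, row.names = FALSE))
  notes <- attr(tbl, "notes")
  if (length(notes)) lines <- c(lines, paste("#", notes))
  lines
}
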
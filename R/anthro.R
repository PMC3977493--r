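#' Patient profile
#'
#' @param age years at initial preoperative visit.
#' @param height meters; must lie in (1.0, 2.5).
#' @param weight_baseline preoperative weight, kg.
#' @param bmi_baseline preoperative BMI, kg/m2; derived from weight and
#'   height when absent, and checked for consistency (|difference| < 0.05)
#'   when both are given.
#' @param sex optional, `"female"` or `"male"`.
#' @param diabetes optional logical, preoperative diabetes status.
#' @param surgery_date optional `Date` (or ISO-8601 string).
#' @return an object of class `rygb_profile`.
#' @export
patient_profile <- function(age, height = NULL, weight_baseline = NULL,
                            bmi_baseline = NULL, sex = NULL, diabetes = NULL,
                            surgery_date = NULL) {
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0) {
    rygb_error("age must be a single positive number", "rygb_invalid_input")
  }
  if (!is.null(height)) {
    if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
        height <= 1.0 || height >= 2.5) {
      rygb_error("height must be a single value in (1.0, 2.5) meters",
                 "rygb_invalid_input")
    }
  }
  if (!is.null(weight_baseline) &&
      (!is.numeric(weight_baseline) || weight_baseline <= 0)) {
    rygb_error("weight_baseline must be positive (kg)", "rygb_invalid_input")
  }
  if (is.null(bmi_baseline) && !is.null(weight_baseline) && !is.null(height)) {
    bmi_baseline <- compute_bmi(weight_baseline, height)
  } else if (!is.null(bmi_baseline) && !is.null(weight_baseline) &&
             !is.null(height)) {
    if (abs(bmi_baseline - compute_bmi(weight_baseline, height)) >= 0.05) {
      rygb_error("bmi_baseline inconsistent with weight_baseline / height^2",
                 "rygb_invalid_input")
    }
  }
  if (!is.null(sex)) sex <- match.arg(sex, c("female", "male"))
  if (!is.null(surgery_date)) surgery_date <- as.Date(surgery_date)
  structure(list(age = age, height = height,
                 weight_baseline = weight_baseline,
                 bmi_baseline = bmi_baseline, sex = sex, diabetes = diabetes,
                 surgery_date = surgery_date),
            class = "rygb_profile")
}

#' @export
print.rygb_profile <- function(x, ...) {
  cat(sprintf("Patient: age %g y%s%s%s%s\n", x$age,
              if (!is.null(x$height)) sprintf(", height %.2f m", x$height) else "",
              if (!is.null(x$weight_baseline)) sprintf(", baseline weight %.1f kg", x$weight_baseline) else "",
              if (!is.null(x$bmi_baseline)) sprintf(", baseline BMI %.1f kg/m2", x$bmi_baseline) else "",
              if (!is.null(x$sex)) paste0(", ", x$sex) else ""))
  invisible(x)
}

#' Time-stamped post-operative weight series
#'
#' @param months months after surgery; non-negative and strictly increasing.
#' @param weight_kg measured weights, kg; positive.
#' @param patient_id optional patient identifier.
#' @return a data frame of class `rygb_series` with columns `months_post_op`
#'   and `weight_kg`.
#' @export
weight_series <- function(months, weight_kg, patient_id = NULL) {
  months <- as.numeric(months)
  weight_kg <- as.numeric(weight_kg)
  if (length(months) != length(weight_kg)) {
    rygb_error("months and weight_kg must have equal length",
               "rygb_invalid_input")
  }
  if (length(months)) {
    if (!all(is.finite(months)) || !all(is.finite(weight_kg))) {
      rygb_error("weight series values must be finite", "rygb_invalid_input")
    }
    if (any(months < 0)) {
      rygb_error("weight series times must be non-negative months after surgery",
                 "rygb_range_error")
    }
    if (any(diff(months) <= 0)) {
      rygb_error("weight series times must be strictly increasing",
                 "rygb_invalid_input")
    }
    if (any(weight_kg <= 0)) {
      rygb_error("weights must be positive", "rygb_invalid_input")
    }
  }
  out <- data.frame(months_post_op = months, weight_kg = weight_kg)
  if (!is.null(patient_id)) attr(out, "patient_id") <- patient_id
  class(out) <- c("rygb_series", "data.frame")
  out
}

#' Body-mass index from weight and height
#'
#' @param weight weight, kg (positive).
#' @param height height, m, in (1.0, 2.5).
#' @return BMI, kg/m2.
#' @export
compute_bmi <- function(weight, height) {
  if (!length(weight) || !length(height) ||
      !all(is.finite(weight)) || !all(is.finite(height)) ||
      any(weight <= 0) || any(height <= 1.0) || any(height >= 2.5)) {
    rygb_error("weight must be positive and height in (1.0, 2.5) m",
               "rygb_invalid_input")
  }
  weight / height^2
}

#' Ideal body weight at BMI 25
#'
#' The reference weight used to define excess weight: the weight at which
#' the patient's BMI would be 25 kg/m2 (the dominant bariatric convention).
#'
#' @param height height, m.
#' @return weight at BMI 25, kg.
#' @export
ideal_weight <- function(height) {
  if (!length(height) || !all(is.finite(height)) ||
      any(height <= 1.0) || any(height >= 2.5)) {
    rygb_error("height must be in (1.0, 2.5) m", "rygb_invalid_input")
  }
  25 * height^2
}

#' Percent excess weight loss
#'
#' `100 * (baseline - current) / (baseline - ideal)`, with ideal weight the
#' weight at BMI 25. Defined only when baseline weight exceeds ideal weight.
#'
#' @param profile a [patient_profile()] with height and baseline weight, or
#'   a list with `weight_baseline` and `height`.
#' @param current_weight current weight, kg (vectorised).
#' @return percent of excess weight lost (0 at baseline weight, 100 at
#'   ideal weight).
#' @export
percent_ewl <- function(profile, current_weight) {
  w0 <- profile$weight_baseline
  h <- profile$height
  if (is.null(w0) || is.null(h)) {
    rygb_error("profile must carry weight_baseline and height",
               "rygb_config_error")
  }
  iw <- ideal_weight(h)
  if (w0 <= iw) {
    rygb_error("baseline weight does not exceed ideal weight; excess weight undefined",
               "rygb_undefined_excess")
  }
  100 * (w0 - current_weight) / (w0 - iw)
}

#' Weight-loss nadir of a series
#'
#' The minimum observed BMI and the time at which it occurs (ties broken
#' toward the earliest time).
#'
#' @param series a [weight_series()].
#' @param height height, m, used to convert weights to BMI.
#' @return list with `bmi` (nadir BMI, kg/m2) and `months` (time of nadir).
#' @export
nadir <- function(series, height) {
  if (!nrow(series)) {
    rygb_error("weight series is empty", "rygb_empty_input")
  }
  bmi <- compute_bmi(series$weight_kg, height)
  i <- which.min(bmi)  # which.min takes the first minimum: earliest time
  list(bmi = bmi[i], months = series$months_post_op[i])
}

#' Percent excess weight loss at six months
#'
#' Uses the measurement nearest to 6.0 months within a +-`window` month
#' window (nearest first, earlier on ties). When no measurement falls in
#' the window the result is `NA` (missing, not an error).
#'
#' @param series a [weight_series()].
#' @param profile a [patient_profile()] with height and baseline weight.
#' @param window half-width of the acceptance window in months (default
#'   1.5, which admits the 5-month clinic visit but not the 8-month one).
#' @return percent excess weight loss at ~6 months, or `NA_real_`.
#' @export
six_month_loss <- function(series, profile, window = 1.5) {
  if (!nrow(series)) {
    rygb_error("weight series is empty", "rygb_empty_input")
  }
  dist <- abs(series$months_post_op - 6.0)
  ok <- dist <= window
  if (!any(ok)) return(NA_real_)
  cand <- which(ok)
  i <- cand[order(dist[cand], series$months_post_op[cand])][1]
  percent_ewl(profile, series$weight_kg[i])
}

#' Track a patient against the expected percentile bands
#'
#' Classifies each post-operative measurement against the model-set
#' percentile predictions at its time. A BMI below the 25th-percentile
#' curve means more weight loss than expected (`below_25`); at or above the
#' 75th curve, less (`above_75`). Band boundaries are half-open upward: a
#' BMI exactly equal to a percentile belongs to the band above it.
#'
#' @param ms a `rygb_modelset` (with quantile levels 0.25/0.50/0.75 for the
#'   standard band labels).
#' @param profile a [patient_profile()] with age, height and baseline
#'   weight.
#' @param series a [weight_series()].
#' @param extrapolate allow measurement times outside the model time range
#'   (downgrades the range error to a warning).
#' @return an object of class `rygb_track`: list with `records` (per
#'   measurement: time, weight, BMI, percent EWL, band) and `summary`
#'   (nadir BMI and time, six-month loss, current band).
#' @export
track <- function(ms, profile, series, extrapolate = FALSE) {
  stopifnot(inherits(ms, "rygb_modelset"))
  if (is.null(profile$age) || is.null(profile$height) ||
      is.null(profile$weight_baseline)) {
    rygb_error("tracking requires a profile with age, height and baseline weight",
               "rygb_config_error")
  }
  bmi0 <- profile$bmi_baseline %||%
    compute_bmi(profile$weight_baseline, profile$height)
  if (!nrow(series)) {
    rep <- list(records = data.frame(months_post_op = numeric(0),
                                     weight_kg = numeric(0),
                                     bmi = numeric(0),
                                     percent_ewl = numeric(0),
                                     band = character(0),
                                     stringsAsFactors = FALSE),
                summary = list(nadir_bmi = NA_real_, nadir_months = NA_real_,
                               six_month_loss = NA_real_,
                               current_band = NA_character_))
    class(rep) <- "rygb_track"
    return(rep)
  }
  bmi <- compute_bmi(series$weight_kg, profile$height)
  q <- predict_percentiles(ms, bmi0, profile$age, series$months_post_op,
                           extrapolate = extrapolate)
  # number of percentile curves strictly above the observation; boundaries
  # belong to the band above the curve
  idx <- rowSums(q <= bmi)
  labels <- band_labels(ms$taus)
  band <- labels[idx + 1L]
  records <- data.frame(months_post_op = series$months_post_op,
                        weight_kg = series$weight_kg,
                        bmi = bmi,
                        percent_ewl = percent_ewl(profile, series$weight_kg),
                        band = band,
                        stringsAsFactors = FALSE)
  nad <- nadir(series, profile$height)
  rep <- list(records = records,
              summary = list(nadir_bmi = nad$bmi, nadir_months = nad$months,
                             six_month_loss = six_month_loss(series, profile),
                             current_band = band[length(band)]))
  class(rep) <- "rygb_track"
  rep
}

band_labels <- function(taus) {
  pct <- round(100 * taus)
  if (identical(pct, c(25, 50, 75))) {
    c("below_25", "25_to_50", "50_to_75", "above_75")
  } else {
    c(sprintf("below_%d", pct[1]),
      if (length(pct) > 1)
        sprintf("%d_to_%d", pct[-length(pct)], pct[-1]),
      sprintf("above_%d", pct[length(pct)]))
  }
}

#' @export
print.rygb_track <- function(x, ...) {
  cat(sprintf("Patient tracking report: %d measurement(s)\n", nrow(x$records)))
  if (nrow(x$records)) {
    print(x$records, row.names = FALSE)
    s <- x$summary
    cat(sprintf("Nadir BMI %.2f kg/m2 at %.1f months; 6-month loss %s; current band %s\n",
                s$nadir_bmi, s$nadir_months,
                if (is.na(s$six_month_loss)) "missing"
                else sprintf("%.1f %%EWL", s$six_month_loss),
                s$current_band))
  }
  invisible(x)
}

#' Export a tracking report
#'
#' Writes the per-measurement records to CSV and the summary to JSON.
#'
#' @param report a `rygb_track` object.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_track_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "rygb_track"))
  if (!is.null(csv_path)) {
    write.csv(report$records, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(c(csv_path, json_path))
}
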
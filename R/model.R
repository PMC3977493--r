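#' Centred design vector of the trajectory model
#'
#' Builds the 8-component regression basis evaluated at one or more
#' (baseline BMI, age, months after surgery) queries:
#' `[1, BMI0-50, AGE-50, d, d^2, d^3, (BMI0-50)d, (AGE-50)d]` with
#' `d = TIME - 6`.
#'
#' @param bmi preoperative (baseline) BMI, kg/m2.
#' @param age age at initial preoperative visit, years.
#' @param time months after surgery; must be non-negative.
#' @return for scalar inputs, a named numeric vector of length 8; for vector
#'   inputs (recycled to common length), a numeric matrix with one row per
#'   query and 8 columns.
#' @export
#' @examples
#' design_vector(50, 50, 6)   # all deviations vanish
#' design_vector(55, 50, 12)  # d = 6
design_vector <- function(bmi, age, time) {
  n <- max(length(bmi), length(age), length(time))
  bmi <- rep_len(as.numeric(bmi), n)
  age <- rep_len(as.numeric(age), n)
  time <- rep_len(as.numeric(time), n)
  if (n == 0L) {
    m <- matrix(numeric(0), 0, 8, dimnames = list(NULL, COEF_NAMES))
    return(m)
  }
  if (!all(is.finite(bmi)) || !all(is.finite(age)) || !all(is.finite(time))) {
    rygb_error("design_vector inputs must all be finite", "rygb_invalid_input")
  }
  d <- time - 6
  m <- cbind(1, bmi - 50, age - 50, d, d^2, d^3, (bmi - 50) * d,
             (age - 50) * d)
  colnames(m) <- COEF_NAMES
  if (n == 1L) m[1, ] else m
}

check_query_range <- function(bmi, age, time, ms, extrapolate) {
  bad <- bmi < ms$bmi_range[1] | bmi > ms$bmi_range[2] |
    age < ms$age_range[1] | age > ms$age_range[2] |
    time < ms$time_range[1] | time > ms$time_range[2]
  if (any(bad)) {
    msg <- sprintf(
      "%d quer%s outside the model validity ranges (baseline BMI [%g, %g], age [%g, %g], time [%g, %g])",
      sum(bad), if (sum(bad) == 1L) "y is" else "ies are",
      ms$bmi_range[1], ms$bmi_range[2], ms$age_range[1], ms$age_range[2],
      ms$time_range[1], ms$time_range[2])
    if (extrapolate) warning(msg, call. = FALSE)
    else rygb_error(msg, "rygb_range_error")
  }
  invisible(TRUE)
}

#' Evaluate one percentile model at a query
#'
#' Predicted BMI is the dot product of the centred design vector with the
#' eight coefficients; no rounding is applied. Preoperative (negative)
#' times are always rejected: the model is defined for months after
#' surgery only.
#'
#' @param qc a [quantile_coefficients()] object.
#' @param bmi,age,time query covariates (vectors are recycled to a common
#'   length).
#' @param ranges optional `rygb_modelset` (or list with `bmi_range`,
#'   `age_range`, `time_range`) against which the query is range-checked.
#' @param extrapolate if `FALSE` (default) a query outside `ranges` raises a
#'   range error; if `TRUE` it is downgraded to a warning.
#' @return numeric vector of predicted BMI, kg/m2.
#' @export
#' @examples
#' ms <- published_modelset()
#' evaluate_percentile(ms$entries[[1]], bmi = 50, age = 50, time = 6)  # 34.43
evaluate_percentile <- function(qc, bmi, age, time, ranges = NULL,
                                extrapolate = FALSE) {
  stopifnot(inherits(qc, "rygb_qcoef"))
  n <- if (!length(bmi) || !length(age) || !length(time)) 0L
       else max(length(bmi), length(age), length(time))
  bmi <- rep_len(as.numeric(bmi), n)
  age <- rep_len(as.numeric(age), n)
  time <- rep_len(as.numeric(time), n)
  if (n && (!all(is.finite(c(bmi, age, time))))) {
    rygb_error("query values must all be finite", "rygb_invalid_input")
  }
  if (n && any(time < 0)) {
    rygb_error("time must be non-negative months after surgery",
               "rygb_range_error")
  }
  if (!is.null(ranges)) check_query_range(bmi, age, time, ranges, extrapolate)
  X <- design_vector(bmi, age, time)
  if (n == 1L) X <- matrix(X, nrow = 1L)
  # fixed left-to-right accumulation keeps scalar and vectorised calls
  # bit-identical
  b <- unname(qc$beta)
  X[, 1] * b[1] + X[, 2] * b[2] + X[, 3] * b[3] + X[, 4] * b[4] +
    X[, 5] * b[5] + X[, 6] * b[6] + X[, 7] * b[7] + X[, 8] * b[8]
}

#' Evaluate every percentile of a model set at a query
#'
#' @param ms a `rygb_modelset`.
#' @inheritParams evaluate_percentile
#' @return a numeric matrix with one row per query and one column per
#'   quantile level (named `tau=0.25` etc.).
#' @export
predict_percentiles <- function(ms, bmi, age, time, extrapolate = FALSE) {
  stopifnot(inherits(ms, "rygb_modelset"))
  n <- max(length(bmi), length(age), length(time))
  out <- vapply(ms$entries, function(e) {
    v <- evaluate_percentile(e, bmi, age, time, ranges = ms,
                             extrapolate = extrapolate)
    rep_len(v, n)
  }, numeric(n))
  out <- matrix(out, nrow = n,
                dimnames = list(NULL, sprintf("tau=%g", ms$taus)))
  out
}

#' Percentile BMI trajectories for one patient
#'
#' Evaluates each percentile curve of a model set over a grid of months for
#' a patient profile. If the profile carries a height, predicted weights
#' (BMI x height^2, kg) are attached.
#'
#' @param ms a `rygb_modelset`.
#' @param profile a [patient_profile()], or a list with at least
#'   `bmi_baseline` and `age` (and `height` for weight output).
#' @param times numeric grid of months after surgery (may be empty).
#' @param extrapolate passed to [evaluate_percentile()].
#' @param weights if `TRUE`, require a height and attach predicted weights;
#'   default attaches them when height is available.
#' @return a data frame of class `rygb_curves` with columns `tau`, `months`,
#'   `bmi` and (when height is known) `weight_kg`.
#' @export
#' @examples
#' tr <- trajectory(published_modelset(),
#'                  list(bmi_baseline = 50, age = 50, height = 1.70),
#'                  times = c(6, 12, 24))
trajectory <- function(ms, profile, times, extrapolate = FALSE,
                       weights = NULL) {
  stopifnot(inherits(ms, "rygb_modelset"))
  bmi0 <- profile$bmi_baseline
  if (is.null(bmi0) && !is.null(profile$weight_baseline) &&
      !is.null(profile$height)) {
    bmi0 <- compute_bmi(profile$weight_baseline, profile$height)
  }
  if (is.null(bmi0) || is.null(profile$age)) {
    rygb_error("profile must provide bmi_baseline (or weight + height) and age",
               "rygb_config_error")
  }
  height <- profile$height
  want_weights <- weights %||% !is.null(height)
  if (want_weights && is.null(height)) {
    rygb_error("weight output requested but the profile has no height",
               "rygb_config_error")
  }
  times <- as.numeric(times)
  out <- do.call(rbind, lapply(seq_along(ms$taus), function(k) {
    bmi <- evaluate_percentile(ms$entries[[k]], bmi0, profile$age, times,
                               ranges = ms, extrapolate = extrapolate)
    data.frame(tau = rep(ms$taus[k], length(times)), months = times,
               bmi = as.numeric(bmi))
  }))
  if (is.null(out)) {
    out <- data.frame(tau = numeric(0), months = numeric(0), bmi = numeric(0))
  }
  if (want_weights) out$weight_kg <- out$bmi * height^2
  class(out) <- c("rygb_curves", "data.frame")
  attr(out, "profile") <- profile
  out
}

#' Percentile lookup table over a covariate grid
#'
#' Reproduces the structure of the published lookup tables: predicted
#' percentile BMI stratified by baseline BMI (default 40-70 kg/m2 in steps
#' of 5), age (default 30, 50, 70 years) and months after surgery (default
#' 6, 12, 24), for every percentile of the model set. Displayed values are
#' rounded to one decimal with round-half-even; the unrounded predictions
#' are retained alongside.
#'
#' @param ms a `rygb_modelset`.
#' @param bmi_grid,age_grid,times non-empty grids within the validity
#'   ranges.
#' @return data frame with columns `bmi_baseline`, `age`, `months_post_op`,
#'   `percentile` (the quantile level), `bmi_predicted` (unrounded) and
#'   `bmi_display` (rounded to 1 decimal).
#' @export
lookup_table <- function(ms, bmi_grid = seq(40, 70, by = 5),
                         age_grid = c(30, 50, 70), times = c(6, 12, 24)) {
  stopifnot(inherits(ms, "rygb_modelset"))
  if (!length(bmi_grid) || !length(age_grid) || !length(times)) {
    rygb_error("lookup grids must be non-empty", "rygb_invalid_input")
  }
  grid <- expand.grid(percentile = ms$taus, months_post_op = as.numeric(times),
                      age = as.numeric(age_grid),
                      bmi_baseline = as.numeric(bmi_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("bmi_baseline", "age", "months_post_op", "percentile")]
  pred <- numeric(nrow(grid))
  for (k in seq_along(ms$taus)) {
    sel <- grid$percentile == ms$taus[k]
    pred[sel] <- evaluate_percentile(ms$entries[[k]], grid$bmi_baseline[sel],
                                     grid$age[sel], grid$months_post_op[sel],
                                     ranges = ms)
  }
  grid$bmi_predicted <- pred
  grid$bmi_display <- round(pred, 1)  # base round() is round-half-even
  rownames(grid) <- NULL
  grid
}

#' Write a lookup table to CSV
#'
#' @param tbl output of [lookup_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lookup_csv <- function(tbl, path) {
  cols <- c("bmi_baseline", "age", "months_post_op", "percentile",
            "bmi_predicted", "bmi_display")
  if (!all(cols[1:5] %in% names(tbl))) {
    rygb_error("not a lookup table (missing required columns)",
               "rygb_invalid_input")
  }
  write.csv(tbl[, intersect(cols, names(tbl))], path, row.names = FALSE)
  invisible(path)
}
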
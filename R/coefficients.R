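#' Coefficients of one conditional-percentile BMI model
#'
#' Bundles the eight parameters of the centred trajectory model for a single
#' quantile level. The model predicts post-operative BMI as
#' \deqn{Q_\tau = b_0 + b_{bmi}(BMI_0-50) + b_{age}(AGE-50) + b_t d + b_{t2} d^2
#'   + b_{t3} d^3 + b_{bmi,t}(BMI_0-50)d + b_{age,t}(AGE-50)d}
#' with \eqn{d = TIME - 6} months after surgery. At the centring point
#' (baseline BMI 50 kg/m2, age 50, 6 months) the prediction is exactly `b0`.
#'
#' @param tau quantile level, strictly in (0, 1).
#' @param b0 intercept, kg/m2: the predicted percentile BMI at the centring
#'   point.
#' @param b_bmi baseline-BMI main effect, kg/m2 per kg/m2.
#' @param b_age age main effect, kg/m2 per year.
#' @param b_t,b_t2,b_t3 time polynomial coefficients, kg/m2 per month,
#'   month^2, month^3.
#' @param b_bmi_t baseline-BMI-by-time interaction.
#' @param b_age_t age-by-time interaction.
#' @return an object of class `rygb_qcoef`.
#' @seealso [modelset()], [published_modelset()], [evaluate_percentile()]
#' @export
#' @examples
#' qc <- quantile_coefficients(0.5, 36.71, 0.7308, 0.02551, -0.906,
#'                             0.04298, -0.00052, -0.00527, 0.001542)
#' evaluate_percentile(qc, bmi = 50, age = 50, time = 6)  # 36.71
quantile_coefficients <- function(tau, b0, b_bmi, b_age, b_t, b_t2, b_t3,
                                  b_bmi_t, b_age_t) {
  beta <- c(b0 = b0, b_bmi = b_bmi, b_age = b_age, b_t = b_t, b_t2 = b_t2,
            b_t3 = b_t3, b_bmi_t = b_bmi_t, b_age_t = b_age_t)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1) {
    rygb_error("tau must be a single number strictly in (0, 1)",
               "rygb_invalid_input")
  }
  if (length(beta) != 8L || !all(is.finite(beta))) {
    rygb_error("all eight coefficients must be finite numbers",
               "rygb_invalid_input")
  }
  structure(list(tau = tau, beta = beta), class = "rygb_qcoef")
}

#' @export
print.rygb_qcoef <- function(x, ...) {
  cat(sprintf("Percentile BMI model, tau = %g (centred at BMI 50, age 50, 6 months)\n",
              x$tau))
  print(signif(x$beta, 6))
  invisible(x)
}

#' An ordered set of percentile models with validity ranges
#'
#' @param entries list of [quantile_coefficients()] objects with strictly
#'   increasing quantile levels.
#' @param bmi_range valid baseline-BMI interval, kg/m2.
#' @param age_range valid age interval, years.
#' @param time_range valid post-operative interval, months.
#' @return an object of class `rygb_modelset`.
#' @export
modelset <- function(entries, bmi_range = c(35, 95), age_range = c(18, 74),
                     time_range = c(0, 36)) {
  if (!is.list(entries) || length(entries) == 0L ||
      !all(vapply(entries, inherits, logical(1), "rygb_qcoef"))) {
    rygb_error("entries must be a non-empty list of quantile_coefficients",
               "rygb_invalid_input")
  }
  taus <- vapply(entries, function(e) e$tau, numeric(1))
  if (any(diff(taus) <= 0)) {
    rygb_error("quantile levels must be strictly increasing with no duplicates",
               "rygb_ordering_error")
  }
  for (nm in c("bmi_range", "age_range", "time_range")) {
    r <- get(nm)
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      rygb_error(sprintf("%s must be a nonempty interval [low, high]", nm),
                 "rygb_invalid_input")
    }
  }
  structure(list(entries = entries, taus = taus,
                 bmi_range = as.numeric(bmi_range),
                 age_range = as.numeric(age_range),
                 time_range = as.numeric(time_range)),
            class = "rygb_modelset")
}

#' @export
print.rygb_modelset <- function(x, ...) {
  cat(sprintf("Post-RYGB BMI percentile model set: %d percentile(s) (tau = %s)\n",
              length(x$entries), paste(x$taus, collapse = ", ")))
  cat(sprintf("  valid for baseline BMI [%g, %g] kg/m2, age [%g, %g] y, time [%g, %g] months\n",
              x$bmi_range[1], x$bmi_range[2], x$age_range[1], x$age_range[2],
              x$time_range[1], x$time_range[2]))
  m <- t(vapply(x$entries, function(e) e$beta, numeric(8)))
  rownames(m) <- sprintf("tau=%g", x$taus)
  print(signif(m, 6))
  invisible(x)
}

#' Extract the quantile levels of a model set
#'
#' @param ms a `rygb_modelset`.
#' @return numeric vector of quantile levels.
#' @export
model_taus <- function(ms) {
  stopifnot(inherits(ms, "rygb_modelset"))
  ms$taus
}

#' The published coefficient set
#'
#' Returns the model set distributed with the package: the 25th, 50th and
#' 75th percentile trajectory formulas fitted to a primary cohort of 2608
#' RYGB patients, valid for baseline BMI 35-95 kg/m2, age 18-74 years and
#' 0-36 months after surgery.
#'
#' @return a `rygb_modelset` with quantile levels 0.25, 0.50, 0.75.
#' @export
#' @examples
#' ms <- published_modelset()
#' predict_percentiles(ms, bmi = 50, age = 50, time = 6)
published_modelset <- function() {
  path <- system.file("extdata", "published_coefficients.json",
                      package = "rygbtraj", mustWork = TRUE)
  read_modelset(path)
}

#' Read a model set from a coefficient JSON file
#'
#' The schema is an object with a `percentiles` array (each element carrying
#' `tau` and the eight coefficients) and `bmi_range` / `age_range` /
#' `time_range` intervals. Missing fields, malformed JSON or non-increasing
#' quantile levels raise a schema error naming the offending field.
#'
#' @param path path to a JSON file.
#' @return a `rygb_modelset`.
#' @export
read_modelset <- function(path) {
  if (!file.exists(path)) {
    rygb_error(sprintf("coefficient file not found: %s", path),
               "rygb_schema_error")
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    rygb_error(sprintf("malformed JSON in %s: %s", path,
                                       conditionMessage(e)),
                               "rygb_schema_error")
                  })
  if (is.null(doc$percentiles) || length(doc$percentiles) == 0L) {
    rygb_error("coefficient file missing field 'percentiles'",
               "rygb_schema_error")
  }
  entries <- lapply(seq_along(doc$percentiles), function(i) {
    el <- doc$percentiles[[i]]
    for (f in c("tau", COEF_NAMES)) {
      if (is.null(el[[f]]) || !is.numeric(el[[f]])) {
        rygb_error(sprintf("percentiles[%d] missing numeric field '%s'", i, f),
                   "rygb_schema_error")
      }
    }
    quantile_coefficients(el$tau, el$b0, el$b_bmi, el$b_age, el$b_t,
                          el$b_t2, el$b_t3, el$b_bmi_t, el$b_age_t)
  })
  taus <- vapply(entries, function(e) e$tau, numeric(1))
  if (any(diff(taus) <= 0)) {
    rygb_error("field 'percentiles': quantile levels (tau) must be strictly increasing",
               "rygb_ordering_error")
  }
  rng <- function(f, default) {
    v <- doc[[f]]
    if (is.null(v)) return(default)
    v <- unlist(v)
    if (length(v) != 2L || !is.numeric(v)) {
      rygb_error(sprintf("field '%s' must be a numeric interval [low, high]", f),
                 "rygb_schema_error")
    }
    as.numeric(v)
  }
  modelset(entries,
           bmi_range = rng("bmi_range", c(35, 95)),
           age_range = rng("age_range", c(18, 74)),
           time_range = rng("time_range", c(0, 36)))
}

#' Write a model set to a coefficient JSON file
#'
#' `write_modelset()` followed by [read_modelset()] is the identity on the
#' model set to full floating-point precision.
#'
#' @param ms a `rygb_modelset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modelset <- function(ms, path) {
  stopifnot(inherits(ms, "rygb_modelset"))
  doc <- list(
    percentiles = lapply(ms$entries, function(e) {
      c(list(tau = e$tau), as.list(e$beta))
    }),
    bmi_range = ms$bmi_range,
    age_range = ms$age_range,
    time_range = ms$time_range
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert uncentered trajectory coefficients to the centred parameterisation
#'
#' The model can equivalently be written on raw covariates
#' (`BMI0, AGE, TIME`) or centred at (50, 50, 6). The centred form is
#' canonical in this package because the published coefficients are only
#' available centred; this converter maps a raw-covariate coefficient vector
#' `(a0, a_bmi, a_age, a_t, a_t2, a_t3, a_bmi_t, a_age_t)` to the centred
#' one.
#'
#' @param a numeric vector of 8 uncentered coefficients, in the same order
#'   as the centred ones.
#' @return named numeric vector of 8 centred coefficients.
#' @seealso [centered_to_uncentered()]
#' @export
uncentered_to_centered <- function(a) {
  if (length(a) != 8L || !all(is.finite(a))) {
    rygb_error("expected 8 finite uncentered coefficients", "rygb_invalid_input")
  }
  a <- as.numeric(a)
  b <- c(
    a[1] + 50 * a[2] + 50 * a[3] + 6 * a[4] + 36 * a[5] + 216 * a[6] +
      300 * a[7] + 300 * a[8],
    a[2] + 6 * a[7],
    a[3] + 6 * a[8],
    a[4] + 12 * a[5] + 108 * a[6] + 50 * a[7] + 50 * a[8],
    a[5] + 18 * a[6],
    a[6],
    a[7],
    a[8]
  )
  names(b) <- COEF_NAMES
  b
}

#' Convert centred trajectory coefficients to the raw-covariate form
#'
#' Inverse of [uncentered_to_centered()].
#'
#' @param b numeric vector of 8 centred coefficients.
#' @return named numeric vector of 8 uncentered coefficients.
#' @export
centered_to_uncentered <- function(b) {
  if (length(b) != 8L || !all(is.finite(b))) {
    rygb_error("expected 8 finite centred coefficients", "rygb_invalid_input")
  }
  b <- as.numeric(b)
  a6 <- b[6]
  a5 <- b[5] - 18 * a6
  a7 <- b[7]
  a8 <- b[8]
  a4 <- b[4] - 12 * a5 - 108 * a6 - 50 * a7 - 50 * a8
  a2 <- b[2] - 6 * a7
  a3 <- b[3] - 6 * a8
  a1 <- b[1] - 50 * a2 - 50 * a3 - 6 * a4 - 36 * a5 - 216 * a6 -
    300 * a7 - 300 * a8
  a <- c(a1, a2, a3, a4, a5, a6, a7, a8)
  names(a) <- c("a0", "a_bmi", "a_age", "a_t", "a_t2", "a_t3",
                "a_bmi_t", "a_age_t")
  a
}
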
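#' Longitudinal cohort container
#'
#' A cohort is the unit of fitting, cleaning and simulation: a table of
#' patient profiles plus a table of post-operative weight measurements.
#'
#' @param profiles data frame with columns `patient_id`, `age`, `sex`,
#'   `height_m`, `weight_baseline_kg`, `bmi_baseline` (and optionally
#'   `diabetes`), one row per patient.
#' @param measurements data frame with columns `patient_id`,
#'   `months_post_op`, `weight_kg`, one row per measurement.
#' @return an object of class `rygb_cohort`.
#' @export
rygb_cohort <- function(profiles, measurements) {
  preq <- c("patient_id", "age", "height_m", "weight_baseline_kg",
            "bmi_baseline")
  mreq <- c("patient_id", "months_post_op", "weight_kg")
  miss <- setdiff(preq, names(profiles))
  if (length(miss)) {
    rygb_error(sprintf("profiles missing column(s): %s",
                       paste(miss, collapse = ", ")), "rygb_schema_error")
  }
  miss <- setdiff(mreq, names(measurements))
  if (length(miss)) {
    rygb_error(sprintf("measurements missing column(s): %s",
                       paste(miss, collapse = ", ")), "rygb_schema_error")
  }
  if (anyDuplicated(profiles$patient_id)) {
    rygb_error("duplicate patient_id in profiles", "rygb_schema_error")
  }
  if (nrow(measurements) &&
      !all(measurements$patient_id %in% profiles$patient_id)) {
    rygb_error("measurements reference unknown patient_id values",
               "rygb_schema_error")
  }
  structure(list(profiles = profiles, measurements = measurements),
            class = "rygb_cohort")
}

#' @export
print.rygb_cohort <- function(x, ...) {
  cat(sprintf("Post-RYGB cohort: %d patients, %d weight measurements\n",
              nrow(x$profiles), nrow(x$measurements)))
  if (nrow(x$profiles)) {
    cat(sprintf("  age %.1f-%.1f y (mean %.1f); baseline BMI %.1f-%.1f kg/m2 (mean %.1f)\n",
                min(x$profiles$age), max(x$profiles$age), mean(x$profiles$age),
                min(x$profiles$bmi_baseline), max(x$profiles$bmi_baseline),
                mean(x$profiles$bmi_baseline)))
  }
  invisible(x)
}

cohort_csv_columns <- c("patient_id", "age", "sex", "height_m",
                        "weight_baseline_kg", "bmi_baseline",
                        "months_post_op", "weight_kg")

#' Write a cohort to CSV
#'
#' One row per weight measurement, with the patient's profile columns
#' repeated: `patient_id, age, sex, height_m, weight_baseline_kg,
#' bmi_baseline, [diabetes,] months_post_op, weight_kg`. Writing the same
#' cohort twice produces byte-identical files.
#'
#' @param cohort a `rygb_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "rygb_cohort"))
  prof <- cohort$profiles
  meas <- cohort$measurements
  i <- match(meas$patient_id, prof$patient_id)
  out <- data.frame(patient_id = meas$patient_id,
                    age = prof$age[i],
                    sex = prof$sex[i] %||% NA,
                    height_m = prof$height_m[i],
                    weight_baseline_kg = prof$weight_baseline_kg[i],
                    bmi_baseline = prof$bmi_baseline[i],
                    stringsAsFactors = FALSE)
  if (!is.null(prof$diabetes)) out$diabetes <- prof$diabetes[i]
  out$months_post_op <- meas$months_post_op
  out$weight_kg <- meas$weight_kg
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Expects the schema written by [write_cohort()] (UTF-8, header required;
#' the `diabetes` column is optional). Rows whose numeric fields cannot be
#' parsed are rejected with their row numbers reported in a warning and in
#' the attribute `"rejected_rows"`.
#'
#' @param path path to a cohort CSV.
#' @return a `rygb_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    rygb_error(sprintf("cohort file not found: %s", path), "rygb_schema_error")
  }
  raw <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             fileEncoding = "UTF-8"),
    error = function(e) rygb_error(sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e)),
                                   "rygb_schema_error"))
  if (!nrow(raw) && !ncol(raw)) {
    rygb_error(sprintf("cohort file is empty: %s", path), "rygb_empty_input")
  }
  miss <- setdiff(cohort_csv_columns, names(raw))
  if (length(miss)) {
    rygb_error(sprintf("cohort file missing column(s): %s",
                       paste(miss, collapse = ", ")), "rygb_schema_error")
  }
  if (!nrow(raw)) {
    rygb_error(sprintf("cohort file has a header but no rows: %s", path),
               "rygb_empty_input")
  }
  numcols <- c("age", "height_m", "weight_baseline_kg", "bmi_baseline",
               "months_post_op", "weight_kg")
  if ("diabetes" %in% names(raw)) numcols <- c(numcols, "diabetes")
  parsed <- raw
  for (cl in numcols) parsed[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
  bad <- rowSums(is.na(parsed[numcols])) > 0
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with unparseable numerics: %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
    parsed <- parsed[!bad, , drop = FALSE]
  }
  if (!nrow(parsed)) {
    rygb_error("no parseable measurement rows in cohort file",
               "rygb_empty_input")
  }
  first <- !duplicated(parsed$patient_id)
  prof <- data.frame(patient_id = parsed$patient_id[first],
                     age = parsed$age[first],
                     sex = parsed$sex[first],
                     height_m = parsed$height_m[first],
                     weight_baseline_kg = parsed$weight_baseline_kg[first],
                     bmi_baseline = parsed$bmi_baseline[first],
                     stringsAsFactors = FALSE)
  if ("diabetes" %in% names(parsed)) prof$diabetes <- parsed$diabetes[first]
  meas <- data.frame(patient_id = parsed$patient_id,
                     months_post_op = parsed$months_post_op,
                     weight_kg = parsed$weight_kg,
                     stringsAsFactors = FALSE)
  co <- rygb_cohort(prof, meas)
  attr(co, "rejected_rows") <- which(bad)
  co
}

#' Read one patient's weight series from CSV
#'
#' Accepts either a `months_post_op` column or a `measure_date` column (the
#' latter requires `surgery_date`; dates are converted at 30.4375 days per
#' month).
#'
#' @param path CSV with columns `patient_id`, `weight_kg` and either
#'   `months_post_op` or `measure_date`.
#' @param surgery_date optional surgery date (ISO-8601) for date-based
#'   files.
#' @return a [weight_series()].
#' @export
read_series <- function(path, surgery_date = NULL) {
  if (!file.exists(path)) {
    rygb_error(sprintf("series file not found: %s", path), "rygb_schema_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) rygb_error("series file has no rows", "rygb_empty_input")
  if (!"weight_kg" %in% names(raw)) {
    rygb_error("series file missing column: weight_kg", "rygb_schema_error")
  }
  if ("months_post_op" %in% names(raw)) {
    months <- as.numeric(raw$months_post_op)
  } else if ("measure_date" %in% names(raw)) {
    if (is.null(surgery_date)) {
      rygb_error("series file uses measure_date but no surgery_date was given",
                 "rygb_config_error")
    }
    months <- months_post_op(raw$measure_date, surgery_date)
  } else {
    rygb_error("series file needs a months_post_op or measure_date column",
               "rygb_schema_error")
  }
  o <- order(months)
  weight_series(months[o], as.numeric(raw$weight_kg)[o],
                patient_id = raw$patient_id[1] %||% NULL)
}

#' Cleaning rules for implausible weight measurements
#'
#' The thresholds are package choices (the rules the source data were
#' screened with are not public) and deliberately configurable.
#'
#' @param bmi_bounds plausible BMI interval, kg/m2.
#' @param max_rate maximum plausible |change in BMI| per week between
#'   adjacent measurements, kg/m2 per week.
#' @param duplicate_window measurements within this many months of each
#'   other with identical weight collapse to one.
#' @return an object of class `rygb_rules`.
#' @export
cleaning_rules <- function(bmi_bounds = c(12, 100), max_rate = 1.5,
                           duplicate_window = 0.25) {
  if (bmi_bounds[1] >= bmi_bounds[2] || max_rate <= 0 ||
      duplicate_window < 0) {
    rygb_error("invalid cleaning rules (need low < high and max_rate > 0)",
               "rygb_invalid_input")
  }
  structure(list(bmi_bounds = as.numeric(bmi_bounds),
                 max_rate = max_rate, duplicate_window = duplicate_window),
            class = "rygb_rules")
}

# total rate-rule violation of a series of (months, bmi)
rate_violation <- function(months, bmi, max_rate) {
  if (length(months) < 2L) return(0)
  dweeks <- pmax(diff(months), 1 / DAYS_PER_MONTH) * DAYS_PER_MONTH / 7
  sum(pmax(0, abs(diff(bmi)) / dweeks - max_rate))
}

clean_series <- function(months, bmi, rules) {
  removed <- integer(0)
  keep <- seq_along(months)

  # 1. implausible absolute BMI
  oob <- bmi[keep] < rules$bmi_bounds[1] | bmi[keep] > rules$bmi_bounds[2]
  removed_bounds <- keep[oob]
  keep <- keep[!oob]

  # 2. implausible rate of change: repeatedly drop the measurement whose
  # removal most reduces the total violation (earliest index on ties)
  removed_rate <- integer(0)
  repeat {
    v <- rate_violation(months[keep], bmi[keep], rules$max_rate)
    if (v <= 0 || length(keep) < 2L) break
    gains <- vapply(seq_along(keep), function(i) {
      rate_violation(months[keep[-i]], bmi[keep[-i]], rules$max_rate)
    }, numeric(1))
    i <- which.min(gains)
    removed_rate <- c(removed_rate, keep[i])
    keep <- keep[-i]
  }

  # 3. duplicates: same weight within the duplicate window of the previous
  # kept measurement
  removed_dup <- integer(0)
  if (length(keep) > 1L) {
    kept <- keep[1]
    for (i in keep[-1]) {
      last <- kept[length(kept)]
      if (months[i] - months[last] <= rules$duplicate_window &&
          bmi[i] == bmi[last]) {
        removed_dup <- c(removed_dup, i)
      } else {
        kept <- c(kept, i)
      }
    }
    keep <- kept
  }

  list(keep = keep,
       removed = data.frame(
         index = c(removed_bounds, removed_rate, removed_dup),
         rule = rep(c("bmi_bounds", "max_rate", "duplicate"),
                    c(length(removed_bounds), length(removed_rate),
                      length(removed_dup))),
         stringsAsFactors = FALSE))
}

#' Remove implausible or inconsistent weight measurements
#'
#' Applies the cleaning rules per patient in a fixed order: out-of-bounds
#' BMIs first, then the rate rule (iteratively removing the measurement
#' whose deletion most reduces the total violation until no adjacent pair
#' changes faster than `max_rate`), then duplicate collapse. The operation
#' is idempotent.
#'
#' @param cohort a `rygb_cohort`.
#' @param rules a [cleaning_rules()] object.
#' @return list with `cohort` (cleaned) and `log` (data frame of removed
#'   records: `patient_id`, `months_post_op`, `weight_kg`, `rule`).
#' @export
clean_weights <- function(cohort, rules = cleaning_rules()) {
  stopifnot(inherits(cohort, "rygb_cohort"), inherits(rules, "rygb_rules"))
  prof <- cohort$profiles
  meas <- cohort$measurements
  keep_all <- logical(nrow(meas))
  logs <- list()
  for (pid in prof$patient_id) {
    rows <- which(meas$patient_id == pid)
    if (!length(rows)) next
    o <- rows[order(meas$months_post_op[rows])]
    h <- prof$height_m[match(pid, prof$patient_id)]
    bmi <- meas$weight_kg[o] / h^2
    res <- clean_series(meas$months_post_op[o], bmi, rules)
    keep_all[o[res$keep]] <- TRUE
    if (nrow(res$removed)) {
      ridx <- o[res$removed$index]
      logs[[length(logs) + 1L]] <- data.frame(
        patient_id = pid,
        months_post_op = meas$months_post_op[ridx],
        weight_kg = meas$weight_kg[ridx],
        rule = res$removed$rule,
        stringsAsFactors = FALSE)
    }
  }
  log <- if (length(logs)) do.call(rbind, logs)
         else data.frame(patient_id = prof$patient_id[0],
                         months_post_op = numeric(0),
                         weight_kg = numeric(0), rule = character(0),
                         stringsAsFactors = FALSE)
  cleaned <- meas[keep_all, , drop = FALSE]
  rownames(cleaned) <- NULL
  if (!nrow(cleaned)) {
    warning("cleaning removed every measurement", call. = FALSE)
  }
  list(cohort = rygb_cohort(prof, cleaned), log = log)
}
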
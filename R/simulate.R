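#' Specification of a synthetic post-RYGB cohort
#'
#' Defaults emulate the primary study cohort the published model was fitted
#' to: age mean 45.8 (SD 11.2) truncated to [18, 74] years, baseline BMI
#' mean 49.5 (SD 8.7) truncated to [35, 95] kg/m2, 81% female; clinic
#' visits at 1 and 2 weeks, 2, 5, 8 and 12 months and every 6 months
#' thereafter; follow-up attrition such that 88% / 77% / 53% of patients
#' have at least one measurement beyond 6 / 12 / 24 months. Conditional BMI
#' quantiles of the generated measurements follow the `truth` model set
#' exactly at its quantile levels.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer RNG seed; generation is fully reproducible given the
#'   spec.
#' @param age_mean,age_sd,age_range truncated-normal age distribution,
#'   years. `age_sd = 0` gives a point mass at `age_mean`.
#' @param bmi_mean,bmi_sd,bmi_range truncated-normal baseline-BMI
#'   distribution, kg/m2.
#' @param height_mean,height_sd,height_range truncated-normal height
#'   distribution, m (heights are not part of the published cohort
#'   description; these constants are a package choice so that weights are
#'   derivable from BMI).
#' @param frac_female probability a patient is female.
#' @param frac_diabetes prevalence of the diabetes indicator; diabetes has
#'   no effect on simulated trajectories (a null covariate for screening
#'   tests).
#' @param visit_schedule nominal visit times, months after surgery.
#' @param attrition_horizons,attrition_targets follow-up horizons (months)
#'   and the non-increasing fractions of patients retaining at least one
#'   measurement beyond each horizon.
#' @param truth `rygb_modelset` defining the conditional BMI quantiles.
#' @param persistence within-patient quantile persistence in [0, 1]: 1
#'   makes every patient track a single percentile for all visits, 0 makes
#'   visit ranks independent. Implemented as a Gaussian copula on the
#'   latent visit ranks so that each visit's marginal rank stays
#'   Uniform(0, 1) for every persistence value.
#' @param jitter_days half-width of the uniform visit-time jitter, days.
#' @return an object of class `rygb_spec`.
#' @export
cohort_spec <- function(n_patients, seed = 1L,
                        age_mean = 45.8, age_sd = 11.2,
                        age_range = c(18, 74),
                        bmi_mean = 49.5, bmi_sd = 8.7,
                        bmi_range = c(35, 95),
                        height_mean = 1.66, height_sd = 0.09,
                        height_range = c(1.4, 2.1),
                        frac_female = 0.81, frac_diabetes = 0.35,
                        visit_schedule = c(0.25, 0.5, 2, 5, 8, 12, 18, 24,
                                           30, 36),
                        attrition_horizons = c(6, 12, 24),
                        attrition_targets = c(0.88, 0.77, 0.53),
                        truth = published_modelset(),
                        persistence = 0.8, jitter_days = 10) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    rygb_error("n_patients must be at least 1", "rygb_invalid_input")
  }
  for (nm in c("age", "bmi", "height")) {
    m <- get(paste0(nm, "_mean")); s <- get(paste0(nm, "_sd"))
    r <- get(paste0(nm, "_range"))
    if (r[1] >= r[2] || m < r[1] || m > r[2] || s < 0) {
      rygb_error(sprintf("impossible %s truncation bounds or spread", nm),
                 "rygb_config_error")
    }
  }
  if (length(attrition_horizons) != length(attrition_targets) ||
      any(diff(attrition_targets) > 0) ||
      any(attrition_targets <= 0 | attrition_targets > 1)) {
    rygb_error("attrition targets must be non-increasing fractions in (0, 1]",
               "rygb_config_error")
  }
  if (any(diff(attrition_horizons) <= 0)) {
    rygb_error("attrition horizons must be strictly increasing",
               "rygb_config_error")
  }
  if (persistence < 0 || persistence > 1) {
    rygb_error("persistence must lie in [0, 1]", "rygb_config_error")
  }
  if (any(diff(visit_schedule) <= 0) || any(visit_schedule <= 0)) {
    rygb_error("visit schedule must be positive and strictly increasing",
               "rygb_config_error")
  }
  for (hz in attrition_horizons) {
    if (!any(visit_schedule > hz)) {
      rygb_error(sprintf(
        "visit schedule has no visit after the %g-month attrition horizon", hz),
        "rygb_config_error")
    }
  }
  stopifnot(inherits(truth, "rygb_modelset"))
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
                 height_mean = height_mean, height_sd = height_sd,
                 height_range = height_range,
                 frac_female = frac_female, frac_diabetes = frac_diabetes,
                 visit_schedule = as.numeric(visit_schedule),
                 attrition_horizons = as.numeric(attrition_horizons),
                 attrition_targets = as.numeric(attrition_targets),
                 truth = truth, persistence = persistence,
                 jitter_days = jitter_days),
            class = "rygb_spec")
}

#' @export
print.rygb_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: n = %d, seed = %d\n  age ~ TN(%g, %g) on [%g, %g]; BMI ~ TN(%g, %g) on [%g, %g]; %g%% female\n  %d visits to %g months; retention beyond %s months: %s; persistence %g\n",
    x$n_patients, x$seed, x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
    x$bmi_mean, x$bmi_sd, x$bmi_range[1], x$bmi_range[2],
    100 * x$frac_female, length(x$visit_schedule), max(x$visit_schedule),
    paste(x$attrition_horizons, collapse = "/"),
    paste(x$attrition_targets, collapse = "/"), x$persistence))
  invisible(x)
}

# truncated-normal sampler by rejection; sd = 0 is a point mass
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

sample_profiles_impl <- function(spec) {
  n <- spec$n_patients
  age <- rtrunc_norm(n, spec$age_mean, spec$age_sd, spec$age_range[1],
                     spec$age_range[2])
  bmi <- rtrunc_norm(n, spec$bmi_mean, spec$bmi_sd, spec$bmi_range[1],
                     spec$bmi_range[2])
  height <- rtrunc_norm(n, spec$height_mean, spec$height_sd,
                        spec$height_range[1], spec$height_range[2])
  sex <- ifelse(runif(n) < spec$frac_female, "female", "male")
  diabetes <- as.integer(runif(n) < spec$frac_diabetes)
  data.frame(patient_id = seq_len(n), age = age, sex = sex,
             height_m = height, weight_baseline_kg = bmi * height^2,
             bmi_baseline = bmi, diabetes = diabetes,
             stringsAsFactors = FALSE)
}

#' Sample patient profiles for a synthetic cohort
#'
#' Draws ages, baseline BMIs and heights from the spec's truncated normal
#' distributions (rejection sampling) and sex/diabetes indicators from the
#' spec's fractions. Reproducible given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `patient_id`, `age`, `sex`, `height_m`,
#'   `weight_baseline_kg`, `bmi_baseline`, `diabetes`.
#' @export
sample_profiles <- function(spec) {
  stopifnot(inherits(spec, "rygb_spec"))
  with_seed(spec$seed, sample_profiles_impl(spec))
}

#' Conditional inverse CDF implied by a model set
#'
#' Builds, for each query, a full conditional BMI distribution from the
#' model set's percentile predictions: piecewise-linear interpolation
#' between the (tau, BMI) knots inside the knot range, and Gaussian-shaped
#' tails outside, anchored at the outer knots with
#' `sigma = (Q_hi - Q_lo) / (qnorm(tau_hi) - qnorm(tau_lo))` (for the
#' default 25th/75th knots, the interquartile spread over 2 x 0.67449). At
#' a knot level the returned BMI equals the model prediction exactly.
#'
#' @param ms a `rygb_modelset` with at least two quantile levels.
#' @param bmi,age,time query covariates (recycled to the length of `u`).
#' @param u probability levels in (0, 1).
#' @return numeric vector of BMI values.
#' @export
inverse_cdf <- function(ms, bmi, age, time, u) {
  stopifnot(inherits(ms, "rygb_modelset"))
  if (length(ms$taus) < 2L) {
    rygb_error("inverse_cdf needs a model set with at least two quantile levels",
               "rygb_config_error")
  }
  n <- max(length(bmi), length(age), length(time), length(u))
  bmi <- rep_len(as.numeric(bmi), n)
  age <- rep_len(as.numeric(age), n)
  time <- rep_len(as.numeric(time), n)
  u <- rep_len(as.numeric(u), n)
  if (any(u <= 0 | u >= 1)) {
    rygb_error("u must lie strictly in (0, 1)", "rygb_invalid_input")
  }
  taus <- ms$taus
  K <- length(taus)
  Q <- vapply(ms$entries,
              function(e) rep_len(evaluate_percentile(e, bmi, age, time), n),
              numeric(n))
  Q <- matrix(Q, nrow = n)
  cross <- which(apply(Q, 1, function(z) any(diff(z) < 0)))
  if (length(cross)) {
    i <- cross[1]
    rygb_error(sprintf(
      "quantile crossing at (bmi0 = %.3g, age = %.3g, t = %.3g): cannot build a conditional distribution",
      bmi[i], age[i], time[i]), "rygb_crossing_error")
  }
  sigma <- (Q[, K] - Q[, 1]) / (qnorm(taus[K]) - qnorm(taus[1]))
  k <- findInterval(u, taus)
  val <- numeric(n)
  lo <- k == 0L
  hi <- k == K
  mid <- !lo & !hi
  if (any(lo)) {
    val[lo] <- Q[lo, 1] + sigma[lo] * (qnorm(u[lo]) - qnorm(taus[1]))
  }
  if (any(hi)) {
    val[hi] <- Q[hi, K] + sigma[hi] * (qnorm(u[hi]) - qnorm(taus[K]))
  }
  if (any(mid)) {
    km <- k[mid]
    wgt <- (u[mid] - taus[km]) / (taus[km + 1L] - taus[km])
    im <- which(mid)
    val[mid] <- Q[cbind(im, km)] * (1 - wgt) + Q[cbind(im, km + 1L)] * wgt
  }
  val
}

# latent visit ranks: Gaussian copula with correlation = persistence, so
# marginal ranks are Uniform(0,1) at any persistence; 1 = one shared rank
# per patient, 0 = independent ranks per visit
visit_ranks <- function(z_patient, z_visit, persistence) {
  rho <- persistence
  r <- pnorm(rho * z_patient + sqrt(1 - rho^2) * z_visit)
  pmin(pmax(r, 0.001), 0.999)
}

jittered_times <- function(spec, n) {
  m <- length(spec$visit_schedule)
  jit <- matrix(runif(n * m, -spec$jitter_days, spec$jitter_days) /
                  DAYS_PER_MONTH, n, m)
  tt <- matrix(spec$visit_schedule, n, m, byrow = TRUE) + jit
  tt <- pmin(pmax(tt, 1 / DAYS_PER_MONTH), spec$truth$time_range[2])
  if (m == 1L) return(tt)
  # jitter can reorder the two closely spaced early visits
  t(apply(tt, 1, sort))
}

#' Simulate one patient's post-operative weight series
#'
#' Visit times are the spec schedule jittered by +-`jitter_days`; each
#' visit's latent rank combines a patient-level rank with visit-level noise
#' (persistence copula; see [cohort_spec()]); BMI at each visit is the
#' conditional inverse CDF of the truth model at that rank, and weight is
#' BMI times height squared. Dropout is not applied here (see
#' [apply_dropout()]).
#'
#' @param profile one row of [sample_profiles()] output (or a list with
#'   `age`, `bmi_baseline`, `height_m`).
#' @param spec a [cohort_spec()].
#' @return a [weight_series()].
#' @export
sample_trajectory <- function(profile, spec) {
  stopifnot(inherits(spec, "rygb_spec"))
  tt <- jittered_times(spec, 1L)[1, ]
  ranks <- visit_ranks(rnorm(1), rnorm(length(tt)), spec$persistence)
  bmi <- inverse_cdf(spec$truth, profile$bmi_baseline, profile$age, tt, ranks)
  weight_series(tt, bmi * profile$height_m^2,
                patient_id = profile$patient_id %||% NA)
}

# Piecewise-constant dropout hazard calibrated so that the expected
# fraction of patients with a retained visit beyond each attrition horizon
# equals the spec target. A patient retains a measurement beyond horizon h
# exactly when the censoring time exceeds T_h, the first jittered visit
# after h, so the calibration solves E[S(T_h)] = target over the jitter
# distribution of T_h (visits nominally at h can straddle it once
# jittered). The hazard has knots at the first scheduled visit after each
# horizon and is solved by a deterministic fixed-point iteration on the
# knot cumulative hazards; no randomness is consumed.
dropout_calibration <- function(spec) {
  knots <- vapply(spec$attrition_horizons,
                  function(hz) min(spec$visit_schedule[spec$visit_schedule > hz]),
                  numeric(1))
  targets <- spec$attrition_targets
  H <- -log(targets)                 # starting cumulative hazard at knots
  for (iter in seq_len(60L)) {
    r <- expected_retention(H, knots, spec)
    H_new <- H + (log(r) - log(targets))
    H_new <- cummax(pmax(H_new, 0))  # keep the hazard non-negative
    if (max(abs(H_new - H)) < 1e-12) { H <- H_new; break }
    H <- H_new
  }
  lam <- diff(c(0, H)) / diff(c(0, knots))
  list(knots = knots, cumhaz = H, lambda = lam,
       lambda_tail = lam[length(lam)])
}

# survival function of the censoring time for given knot cumulative hazards
censor_survival <- function(t, H, knots) {
  lam <- diff(c(0, H)) / diff(c(0, knots))
  lam_tail <- lam[length(lam)]
  b0 <- c(0, knots)
  H0 <- c(0, H)
  k <- findInterval(t, knots) + 1L
  rate <- c(lam, lam_tail)[k]
  exp(-(H0[k] + rate * (t - b0[k])))
}

# E[S(T_h)] for each horizon h: T_h is the first jittered visit after h;
# integrates the joint jitter distribution of every visit that can land
# beyond h on a fine time grid (fully deterministic)
expected_retention <- function(H, knots, spec) {
  w <- spec$jitter_days / DAYS_PER_MONTH
  sched <- spec$visit_schedule
  vapply(spec$attrition_horizons, function(hz) {
    cand <- sched[sched + w > hz]
    hi <- max(cand) + w + 1e-9
    tg <- seq(hz, hi, length.out = 2048L)
    # P(some jittered candidate visit lies in (hz, t])
    Ft <- 1 - Reduce(`*`, lapply(cand, function(v) {
      if (w > 0) {
        p <- (pmin(tg, v + w) - pmax(hz, v - w)) / (2 * w)
        1 - pmin(pmax(p, 0), 1)
      } else {
        1 - as.numeric(v > hz & v <= tg)
      }
    }), accumulate = FALSE)
    mids <- (tg[-1] + tg[-length(tg)]) / 2
    sum(censor_survival(mids, H, knots) * diff(Ft))
  }, numeric(1))
}

sample_censor_times <- function(n, cal) {
  e <- -log(runif(n))                # unit-exponential cumulative hazards
  k <- findInterval(e, cal$cumhaz)   # 0 .. length(knots)
  K <- length(cal$knots)
  b0 <- c(0, cal$knots)
  H0 <- c(0, cal$cumhaz)
  lam <- c(cal$lambda, cal$lambda_tail)
  idx <- pmin(k + 1L, K + 1L)
  cen <- ifelse(lam[idx] > 0,
                b0[idx] + (e - H0[idx]) / lam[idx],
                Inf)
  cen
}

#' Apply follow-up attrition to a weight series
#'
#' Draws a censoring time from the calibrated piecewise-constant dropout
#' hazard and removes all visits at or after it; every patient keeps at
#' least the first visit. With attrition targets all equal to 1 no visit is
#' ever removed.
#'
#' @param series a [weight_series()].
#' @param spec a [cohort_spec()].
#' @param seed optional integer; when given, the censoring draw is made
#'   reproducible for this patient.
#' @return a [weight_series()] containing the retained visits.
#' @export
apply_dropout <- function(series, spec, seed = NULL) {
  stopifnot(inherits(spec, "rygb_spec"))
  cal <- dropout_calibration(spec)
  cen <- if (is.null(seed)) sample_censor_times(1L, cal)
         else with_seed(seed, sample_censor_times(1L, cal))
  keep <- series$months_post_op < cen
  if (!any(keep)) keep[1] <- TRUE
  weight_series(series$months_post_op[keep], series$weight_kg[keep],
                patient_id = attr(series, "patient_id"))
}

#' Generate a complete synthetic cohort
#'
#' Composes [sample_profiles()], per-patient trajectory simulation and
#' calibrated dropout into a cohort object. Fully reproducible from the
#' spec (including its seed): the same spec yields a byte-identical cohort
#' CSV via [write_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @return a [rygb_cohort()] with the generating spec attached as attribute
#'   `"spec"`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(25, seed = 7))
#' co
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rygb_spec"))
  with_seed(spec$seed, {
    prof <- sample_profiles_impl(spec)
    n <- nrow(prof)
    m <- length(spec$visit_schedule)
    tt <- jittered_times(spec, n)
    zp <- rnorm(n)
    zv <- matrix(rnorm(n * m), n, m)
    ranks <- visit_ranks(matrix(zp, n, m), zv, spec$persistence)
    bmi <- inverse_cdf(spec$truth,
                       rep(prof$bmi_baseline, m),
                       rep(prof$age, m),
                       as.vector(tt), as.vector(ranks))
    bmi <- matrix(bmi, n, m)
    cal <- dropout_calibration(spec)
    cen <- sample_censor_times(n, cal)
    keep <- tt < matrix(cen, n, m)
    keep[, 1] <- keep[, 1] | rowSums(keep) == 0   # every patient keeps >= 1
    pid <- matrix(prof$patient_id, n, m)
    hh <- matrix(prof$height_m, n, m)
    meas <- data.frame(patient_id = pid[keep],
                       months_post_op = tt[keep],
                       weight_kg = (bmi * hh^2)[keep])
    meas <- meas[order(meas$patient_id, meas$months_post_op), , drop = FALSE]
    rownames(meas) <- NULL
    co <- rygb_cohort(prof, meas)
    attr(co, "spec") <- spec
    co
  })
}
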
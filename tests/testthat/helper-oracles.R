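# Independent oracles and small fixture builders used across the suite.

# brute-force check-loss minimiser for intercept-only problems: scans every
# data value and returns the lowest minimiser (the convention fit_quantile
# is required to reproduce)
oracle_intercept_quantile <- function(y, tau) {
  cand <- sort(unique(y))
  loss <- vapply(cand, function(b) mean((y - b) * (tau - ((y - b) < 0))),
                 numeric(1))
  cand[which(loss <= min(loss) + 1e-12)][1]
}

# numerically integrated mean of a truncated normal (oracle for the
# profile sampler)
oracle_truncnorm_mean <- function(mean, sd, lo, hi) {
  f <- function(x) x * stats::dnorm(x, mean, sd)
  mass <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value / mass
}

# invert the generator's conditional CDF: recover the latent rank u from an
# observed BMI given the truth model set and the query (piecewise-linear
# mid-section, Gaussian tails anchored at the outer knots)
oracle_rank_from_bmi <- function(ms, bmi0, age, time, bmi) {
  taus <- ms$taus
  K <- length(taus)
  q <- vapply(seq_len(K), function(k) {
    evaluate_percentile(ms$entries[[k]], bmi0, age, time)
  }, numeric(length(bmi0)))
  q <- matrix(q, ncol = K)
  sigma <- (q[, K] - q[, 1]) / (stats::qnorm(taus[K]) - stats::qnorm(taus[1]))
  u <- numeric(length(bmi))
  for (i in seq_along(bmi)) {
    if (bmi[i] <= q[i, 1]) {
      u[i] <- stats::pnorm(stats::qnorm(taus[1]) + (bmi[i] - q[i, 1]) / sigma[i])
    } else if (bmi[i] >= q[i, K]) {
      u[i] <- stats::pnorm(stats::qnorm(taus[K]) + (bmi[i] - q[i, K]) / sigma[i])
    } else {
      k <- max(which(q[i, ] <= bmi[i]))
      u[i] <- taus[k] + (taus[k + 1] - taus[k]) *
        (bmi[i] - q[i, k]) / (q[i, k + 1] - q[i, k])
    }
  }
  u
}

# hand-built cohort: a few patients with explicit measurement series
make_tiny_cohort <- function() {
  profiles <- data.frame(
    patient_id = 1:3,
    age = c(40, 50, 60),
    sex = c("female", "male", "female"),
    height_m = c(1.60, 1.75, 1.70),
    weight_baseline_kg = c(128, 153.125, 130.05),
    bmi_baseline = c(50, 50, 45),
    diabetes = c(0, 1, 0),
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    patient_id = c(1, 1, 1, 2, 2, 3),
    months_post_op = c(1, 6, 12, 2, 5.5, 6),
    weight_kg = c(120, 100, 95, 140, 120, 110),
    stringsAsFactors = FALSE)
  rygb_cohort(profiles, measurements)
}
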
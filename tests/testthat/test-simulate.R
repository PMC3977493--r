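test_that("profile sampling respects truncation bounds and is reproducible", {
  spec <- cohort_spec(1000, seed = 61)
  p1 <- sample_profiles(spec)
  expect_true(all(p1$age >= 18 & p1$age <= 74))
  expect_true(all(p1$bmi_baseline >= 35 & p1$bmi_baseline <= 95))
  expect_true(all(p1$height_m >= 1.4 & p1$height_m <= 2.1))
  expect_identical(p1, sample_profiles(spec))
  expect_false(identical(p1, sample_profiles(cohort_spec(1000, seed = 62))))
})

test_that("sampled age matches the truncated-normal mean", {
  p <- sample_profiles(cohort_spec(10000, seed = 63))
  target <- oracle_truncnorm_mean(45.8, 11.2, 18, 74)
  expect_lt(abs(mean(p$age) - target), 0.5)
  tb <- oracle_truncnorm_mean(49.5, 8.7, 35, 95)
  expect_lt(abs(mean(p$bmi_baseline) - tb), 0.5)
  expect_lt(abs(mean(p$sex == "female") - 0.81), 0.03)
})

test_that("inverse CDF hits the percentile curves exactly at the knots", {
  ms <- published_modelset()
  q <- predict_percentiles(ms, 50, 50, 6)
  expect_identical(inverse_cdf(ms, 50, 50, 6, 0.25), unname(q[1, 1]))
  expect_identical(inverse_cdf(ms, 50, 50, 6, 0.50), unname(q[1, 2]))
  expect_identical(inverse_cdf(ms, 50, 50, 6, 0.75), unname(q[1, 3]))
  # piecewise-linear interior: halfway between the 25th and 50th knots
  expect_equal(inverse_cdf(ms, 50, 50, 6, 0.375), (34.43 + 36.71) / 2,
               tolerance = 1e-12)
  # monotone in u, continuous through the tail junctions
  us <- c(0.01, 0.2499, 0.25, 0.2501, 0.5, 0.7499, 0.75, 0.7501, 0.99)
  v <- inverse_cdf(ms, rep(50, 9), rep(50, 9), rep(6, 9), us)
  expect_true(all(diff(v) > 0))
  expect_lt(v[4] - v[2], 0.01)
  expect_lt(v[8] - v[6], 0.01)
})

test_that("crossing quantiles abort generation with a crossing error", {
  qc_lo <- quantile_coefficients(0.25, 39, 0.7, 0.03, -1, 0.04, -5e-4,
                                 -7e-3, 1.6e-3)
  qc_hi <- quantile_coefficients(0.75, 34, 0.7, 0.03, -1, 0.04, -5e-4,
                                 -7e-3, 1.6e-3)
  bad <- modelset(list(qc_lo, qc_hi))
  expect_error(inverse_cdf(bad, 50, 50, 6, 0.5), class = "rygb_crossing_error")
})

test_that("persistence 1 pins a patient to a single percentile; 0 decouples visits", {
  ms <- published_modelset()
  prof <- list(patient_id = 1, age = 50, bmi_baseline = 50, height_m = 1.7)
  set.seed(71)
  s1 <- sample_trajectory(prof, cohort_spec(1, seed = 1, persistence = 1))
  u1 <- oracle_rank_from_bmi(ms, rep(50, nrow(s1)), rep(50, nrow(s1)),
                             s1$months_post_op, compute_bmi(s1$weight_kg, 1.7))
  expect_lt(max(u1) - min(u1), 1e-9)
  set.seed(72)
  s0 <- sample_trajectory(prof, cohort_spec(1, seed = 1, persistence = 0))
  u0 <- oracle_rank_from_bmi(ms, rep(50, nrow(s0)), rep(50, nrow(s0)),
                             s0$months_post_op, compute_bmi(s0$weight_kg, 1.7))
  expect_gt(max(u0) - min(u0), 0.05)
})

test_that("latent visit ranks are uniform and independent of covariates", {
  ms <- published_modelset()
  co <- generate_cohort(cohort_spec(5000, seed = 73, persistence = 0.8))
  first <- co$measurements[!duplicated(co$measurements$patient_id), ]
  i <- match(first$patient_id, co$profiles$patient_id)
  bmi <- first$weight_kg / co$profiles$height_m[i]^2
  u <- oracle_rank_from_bmi(ms, co$profiles$bmi_baseline[i],
                            co$profiles$age[i], first$months_post_op, bmi)
  expect_lt(abs(cor(u, co$profiles$bmi_baseline[i])), 0.05)
  expect_lt(abs(cor(u, co$profiles$age[i])), 0.05)
  # marginal uniformity of the recovered ranks at the tested quartiles
  expect_lt(abs(mean(u < 0.25) - 0.25), 0.03)
  expect_lt(abs(mean(u < 0.5) - 0.5), 0.03)
  expect_lt(abs(mean(u < 0.75) - 0.75), 0.03)
})

test_that("dropout keeps every patient and never removes visits at unit targets", {
  spec_none <- cohort_spec(5, seed = 81, attrition_targets = c(1, 1, 1))
  s <- weight_series(c(0.5, 6, 18, 30), c(120, 100, 95, 97))
  expect_identical(apply_dropout(s, spec_none, seed = 4), s)
  # harsh attrition still leaves at least one visit per patient
  spec_harsh <- cohort_spec(300, seed = 82,
                            attrition_targets = c(0.2, 0.1, 0.05))
  co <- generate_cohort(spec_harsh)
  expect_setequal(unique(co$measurements$patient_id),
                  co$profiles$patient_id)
  # retention fractions are non-increasing in horizon
  mx <- tapply(co$measurements$months_post_op, co$measurements$patient_id, max)
  ret <- c(mean(mx > 6), mean(mx > 12), mean(mx > 24))
  expect_true(all(diff(ret) <= 0))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(0), class = "rygb_invalid_input")
  expect_error(cohort_spec(10, attrition_targets = c(0.5, 0.8, 0.3)),
               class = "rygb_config_error")
  expect_error(cohort_spec(10, persistence = 1.2), class = "rygb_config_error")
  expect_error(cohort_spec(10, age_mean = 100), class = "rygb_config_error")
  expect_error(cohort_spec(10, visit_schedule = c(1, 2, 5)),
               class = "rygb_config_error")  # no visit beyond 24 months
})

test_that("cohort generation is deterministic and complete", {
  spec <- cohort_spec(50, seed = 91)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$profiles), 50L)
  expect_setequal(unique(co$measurements$patient_id), 1:50)
  expect_true(all(co$measurements$months_post_op > 0))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f1)
  write_cohort(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
})
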
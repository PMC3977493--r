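test_that("design vector centres covariates at (50, 50, 6)", {
  expect_equal(unname(design_vector(50, 50, 6)), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(design_vector(40, 30, 6)),
               c(1, -10, -20, 0, 0, 0, 0, 0))
  expect_equal(unname(design_vector(55, 50, 12)),
               c(1, 5, 0, 6, 36, 216, 30, 0))
  # vectorised form keeps rows aligned with queries
  m <- design_vector(c(50, 55), c(50, 50), c(6, 12))
  expect_equal(dim(m), c(2L, 8L))
  expect_equal(unname(m[2, ]), c(1, 5, 0, 6, 36, 216, 30, 0))
  expect_error(design_vector(NA, 50, 6), class = "rygb_invalid_input")
})

test_that("published percentile evaluation reproduces hand arithmetic", {
  ms <- published_modelset()
  expect_equal(evaluate_percentile(ms$entries[[1]], 50, 50, 6), 34.43,
               tolerance = 0)
  expect_equal(evaluate_percentile(ms$entries[[1]], 40, 30, 6), 26.8804,
               tolerance = 1e-12)
  # full cubic at d = 6: 36.71 - 0.906*6 + 0.04298*36 - 0.00052*216
  expect_equal(evaluate_percentile(ms$entries[[2]], 50, 50, 12), 32.70896,
               tolerance = 1e-12)
})

test_that("evaluation at the centring point returns the intercept exactly", {
  set.seed(11)
  for (i in 1:20) {
    b <- rnorm(8)
    qc <- quantile_coefficients(runif(1, 0.05, 0.95), b[1], b[2], b[3], b[4],
                                b[5], b[6], b[7], b[8])
    expect_identical(evaluate_percentile(qc, 50, 50, 6), b[1])
  }
})

test_that("queries outside the validity ranges error unless extrapolation is allowed", {
  ms <- published_modelset()
  expect_error(evaluate_percentile(ms$entries[[1]], 120, 50, 6, ranges = ms),
               class = "rygb_range_error")
  expect_error(evaluate_percentile(ms$entries[[1]], 50, 50, 40, ranges = ms),
               class = "rygb_range_error")
  expect_warning(
    v <- evaluate_percentile(ms$entries[[1]], 50, 50, 40, ranges = ms,
                             extrapolate = TRUE),
    "outside the model validity ranges")
  expect_true(is.finite(v))
  # preoperative times are rejected regardless of the extrapolation flag
  expect_error(evaluate_percentile(ms$entries[[1]], 50, 50, -1),
               class = "rygb_range_error")
})

test_that("trajectories evaluate every percentile and attach weights via height", {
  ms <- published_modelset()
  tr <- trajectory(ms, list(bmi_baseline = 50, age = 50), times = 6)
  expect_equal(tr$bmi, c(34.43, 36.71, 39.11))
  empty <- trajectory(ms, list(bmi_baseline = 50, age = 50),
                      times = numeric(0))
  expect_equal(nrow(empty), 0L)
  trw <- trajectory(ms, list(bmi_baseline = 50, age = 50, height = 1.70),
                    times = 6)
  expect_equal(trw$weight_kg[trw$tau == 0.5], 36.71 * 1.7^2,
               tolerance = 1e-12)
  expect_error(
    trajectory(ms, list(bmi_baseline = 50, age = 50), times = 6,
               weights = TRUE),
    class = "rygb_config_error")
})

test_that("lookup table reproduces the published grid structure cell-for-cell", {
  ms <- published_modelset()
  tbl <- lookup_table(ms)
  expect_equal(nrow(tbl), 189L)  # 7 BMI x 3 ages x 3 times x 3 percentiles
  # every cell equals direct evaluation composed with round-half-even
  for (i in seq_len(nrow(tbl))) {
    k <- match(tbl$percentile[i], ms$taus)
    v <- evaluate_percentile(ms$entries[[k]], tbl$bmi_baseline[i],
                             tbl$age[i], tbl$months_post_op[i])
    expect_identical(tbl$bmi_predicted[i], v)
    expect_identical(tbl$bmi_display[i], round(v, 1))
  }
  cell <- tbl[tbl$bmi_baseline == 50 & tbl$age == 50 &
                tbl$months_post_op == 6, ]
  expect_equal(cell$bmi_display[cell$percentile == 0.25], 34.4)
  expect_equal(cell$bmi_display[cell$percentile == 0.75], 39.1)
  expect_error(lookup_table(ms, bmi_grid = c(20, 50)),
               class = "rygb_range_error")
})

test_that("coefficient JSON round-trips at full precision and validates its schema", {
  ms <- published_modelset()
  path <- withr::local_tempfile(fileext = ".json")
  write_modelset(ms, path)
  back <- read_modelset(path)
  expect_identical(back$taus, ms$taus)
  for (k in seq_along(ms$taus)) {
    expect_identical(back$entries[[k]]$beta, ms$entries[[k]]$beta)
  }
  expect_identical(back$bmi_range, ms$bmi_range)

  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$percentiles[[1]]$tau <- NULL
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_modelset(bad), "tau", class = "rygb_schema_error")

  doc2 <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc2$percentiles <- doc2$percentiles[c(2, 1, 3)]
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc2, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(read_modelset(bad2), class = "rygb_ordering_error")

  writeLines("{not json", bad)
  expect_error(read_modelset(bad), class = "rygb_schema_error")
})

test_that("centred and raw-covariate parameterisations are equivalent", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(8) * c(30, 1, 0.1, 1, 0.05, 0.001, 0.01, 0.01)
    b <- uncentered_to_centered(a)
    expect_equal(unname(centered_to_uncentered(b)), a, tolerance = 1e-9)
    qc <- quantile_coefficients(0.5, b[1], b[2], b[3], b[4], b[5], b[6],
                                b[7], b[8])
    for (j in 1:5) {
      q <- c(runif(1, 35, 70), runif(1, 18, 74), runif(1, 0, 36))
      raw <- sum(a * c(1, q[1], q[2], q[3], q[3]^2, q[3]^3, q[1] * q[3],
                       q[2] * q[3]))
      expect_equal(evaluate_percentile(qc, q[1], q[2], q[3]), raw,
                   tolerance = 1e-8)
    }
  }
})

test_that("model sets validate ordering and ranges", {
  qc1 <- quantile_coefficients(0.25, 34, 0.7, 0.03, -1, 0.04, -5e-4,
                               -7e-3, 1.6e-3)
  qc2 <- quantile_coefficients(0.5, 36, 0.73, 0.025, -0.9, 0.043, -5e-4,
                               -5e-3, 1.5e-3)
  expect_error(modelset(list(qc2, qc1)), class = "rygb_ordering_error")
  expect_error(modelset(list(qc1), bmi_range = c(50, 40)),
               class = "rygb_invalid_input")
  expect_error(quantile_coefficients(1.2, 1, 1, 1, 1, 1, 1, 1, 1),
               class = "rygb_invalid_input")
})
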
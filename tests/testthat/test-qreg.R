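test_that("check loss matches its definition", {
  expect_equal(check_loss(c(1, -1), 0.5), 0.5)
  expect_equal(check_loss(c(1, -1), 0.25), 0.5)
  expect_equal(check_loss(c(0, 0, 0), 0.7), 0)
  expect_error(check_loss(numeric(0), 0.5), class = "rygb_empty_input")
  expect_error(check_loss(1, 1.5), class = "rygb_invalid_input")
})

test_that("intercept-only fits equal the sample quantile (lowest-minimiser rule)", {
  expect_equal(unname(fit_quantile(matrix(1, 3, 1), c(1, 2, 3),
                                   0.5)$coefficients), 2)
  # flat optimum on [2, 3]: the lowest minimiser is reported
  expect_equal(unname(fit_quantile(matrix(1, 4, 1), c(1, 2, 3, 4),
                                   0.5)$coefficients), 2)
  expect_equal(unname(fit_quantile(matrix(1, 101, 1), 0:100,
                                   0.25)$coefficients), 25)
})

test_that("solver agrees with brute-force check-loss minimisation on random problems", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:20, 1)
    y <- round(rnorm(n), 2)             # rounding forces degenerate ties
    tau <- sample(seq(0.1, 0.9, by = 0.1), 1)
    fit <- fit_quantile(matrix(1, n, 1), y, tau)
    expect_equal(unname(fit$coefficients), oracle_intercept_quantile(y, tau),
                 tolerance = 1e-9)
    expect_true(fit$converged)
  }
})

test_that("achieved loss certifies optimality against truth and the smoothed solver", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(20, 1) + 20
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    bt <- rnorm(p)
    y <- as.vector(X %*% bt) + rnorm(n)
    tau <- runif(1, 0.15, 0.85)
    f <- fit_quantile(X, y, tau)
    expect_lte(f$loss, check_loss(y - as.vector(X %*% bt), tau) + 1e-12)
    fs <- fit_quantile(X, y, tau, method = "smooth")
    expect_lte(f$loss, fs$loss + 1e-9)
    # vertex solutions interpolate p observations exactly
    expect_length(f$basis, p)
    expect_equal(as.vector(X[f$basis, , drop = FALSE] %*% f$coefficients),
                 y[f$basis], tolerance = 1e-8)
  }
})

test_that("fits are equivariant to scaling and shifting the response", {
  set.seed(35)
  X <- cbind(1, rnorm(40), rnorm(40))
  y <- rnorm(40)
  f <- fit_quantile(X, y, 0.3)
  f_scaled <- fit_quantile(X, 3.5 * y, 0.3)
  expect_equal(unname(f_scaled$coefficients), 3.5 * unname(f$coefficients),
               tolerance = 1e-8)
  f_shift <- fit_quantile(X, y + 2, 0.3)
  expect_equal(unname(f_shift$coefficients),
               unname(f$coefficients) + c(2, 0, 0), tolerance = 1e-8)
})

test_that("rank-deficient and undersized designs are rejected", {
  X <- cbind(1, 1:10, 2 * (1:10))
  expect_error(fit_quantile(X, rnorm(10), 0.5), class = "rygb_rank_error")
  expect_error(fit_quantile(matrix(rnorm(6), 2, 3), rnorm(2), 0.5),
               class = "rygb_rank_error")
})

test_that("model-set fitting validates quantile levels and sets cohort ranges", {
  co <- generate_cohort(cohort_spec(120, seed = 41))
  expect_error(fit_modelset(co, taus = c(0.5, 0.5)),
               class = "rygb_ordering_error")
  ms <- fit_modelset(co, taus = 0.5)
  expect_length(ms$entries, 1L)
  expect_equal(ms$bmi_range, range(co$profiles$bmi_baseline))
  expect_equal(ms$age_range, range(co$profiles$age))
  fits <- attr(ms, "fits")
  expect_true(fits[[1]]$converged)
  expect_gte(fits[[1]]$loss, 0)
})

test_that("coefficient recovery sharpens with cohort size", {
  truth <- published_modelset()
  tb <- vapply(truth$entries, function(e) e$beta, numeric(8))
  rmse <- sapply(c(500, 2000, 8000), function(n) {
    err <- sapply(1:3, function(rep) {
      ms <- fit_modelset(generate_cohort(cohort_spec(n, seed = 1000 + rep)))
      eb <- vapply(ms$entries, function(e) e$beta, numeric(8))
      eb - tb
    })  # 8 coefficients x 3 taus per replicate, 3 replicates
    err <- matrix(err, nrow = 8)   # rows ordered b0, b_bmi, b_age, ...
    apply(err[1:3, , drop = FALSE], 1, function(z) sqrt(mean(z^2)))
  })
  # monotone shrinking RMSE for the intercept and both main effects
  expect_true(all(rmse[, 2] < rmse[, 1]))
  expect_true(all(rmse[, 3] < rmse[, 2]))
})

test_that("cohort comparison measures trajectory discrepancies", {
  ms <- published_modelset()
  cmp <- compare_fits(ms, ms)
  expect_equal(cmp$max_abs_diff, rep(0, 3))
  expect_equal(cmp$mean_abs_diff, rep(0, 3))
  # shifting one intercept shifts that curve everywhere by the same amount
  ms2 <- ms
  ms2$entries[[2]] <- quantile_coefficients(
    0.5, ms$entries[[2]]$beta[1] + 1, ms$entries[[2]]$beta[2],
    ms$entries[[2]]$beta[3], ms$entries[[2]]$beta[4], ms$entries[[2]]$beta[5],
    ms$entries[[2]]$beta[6], ms$entries[[2]]$beta[7], ms$entries[[2]]$beta[8])
  cmp2 <- compare_fits(ms, ms2)
  expect_equal(cmp2$max_abs_diff, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(cmp2$mean_abs_diff, c(0, 1, 0), tolerance = 1e-12)
  ms3 <- modelset(ms$entries[1:2])
  expect_error(compare_fits(ms, ms3), class = "rygb_config_error")
})

test_that("screening separates true drivers from null covariates", {
  co <- generate_cohort(cohort_spec(2000, seed = 51))
  scr <- screen_covariates(co, threshold = 0.1)
  expect_equal(scr$covariate,
               c("bmi_baseline", "age", "sex", "diabetes"))
  # baseline BMI drives both outcomes strongly and in a consistent
  # direction (less %EWL, higher nadir)
  row <- scr[scr$covariate == "bmi_baseline", ]
  expect_true(row$retained)
  expect_lt(row$effect_6mo, -0.3)
  expect_gt(row$effect_nadir, 0.3)
  expect_lt(row$p_6mo, 1e-4)
  # sex and diabetes have no effect in the generator
  expect_false(any(scr$retained[scr$covariate %in% c("sex", "diabetes")]))
  expect_lt(max(abs(scr$effect_6mo[3:4])), 0.1)

  # permuting the candidate destroys its association
  co_perm <- co
  set.seed(99)
  co_perm$profiles$bmi_baseline <- sample(co_perm$profiles$bmi_baseline)
  scr_perm <- screen_covariates(co_perm, threshold = 0.1)
  expect_false(scr_perm$retained[scr_perm$covariate == "bmi_baseline"])

  # degenerate threshold: consistent-direction candidates are retained
  scr0 <- screen_covariates(co, threshold = 0)
  expect_true(all(scr0$retained[scr0$covariate %in% c("bmi_baseline", "age")]))
})
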
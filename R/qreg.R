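#' Mean check (pinball) loss
#'
#' \eqn{\rho_\tau(r) = r(\tau - 1\{r<0\})}, averaged over the residuals.
#' The minimiser of this loss over a constant is the sample
#' \eqn{\tau}-quantile, which is what makes it the fitting criterion for
#' conditional-quantile models.
#'
#' @param residuals numeric vector (non-empty).
#' @param tau quantile level in (0, 1).
#' @return mean check loss (non-negative; zero iff all residuals are zero).
#' @export
check_loss <- function(residuals, tau) {
  if (!length(residuals)) {
    rygb_error("residual vector is empty", "rygb_empty_input")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    rygb_error("tau must lie strictly in (0, 1)", "rygb_invalid_input")
  }
  mean(residuals * (tau - (residuals < 0)))
}

# ---------------------------------------------------------------------------
# Exact simplex (basis-exchange) solver for the quantile-regression LP.
#
# At a vertex of the check-loss polytope the fit interpolates p observations
# (the basis h): beta solves X[h,] beta = y[h]. For each basic observation j
# the edge direction d_j is column j of solve(X[h,]); the one-sided
# directional derivatives of the objective along +-d_j are
#   D(+1, j) = (1 - tau) - s_j,   D(-1, j) = tau + s_j,
# with s_j = sum over non-basic i of (x_i . d_j) (tau - 1{r_i < 0}).
# If some derivative is negative the objective decreases along that edge;
# the step length is found by scanning residual sign-change breakpoints in
# order until the accumulated derivative becomes non-negative, and the
# crossing observation enters the basis. On flat optima the solution is
# polished to the lexicographically smallest optimal vertex (lowest
# intercept first) so that ties are resolved deterministically.
# ---------------------------------------------------------------------------

# one line search along direction g (observation space); returns the index
# entering the basis, or NA if the objective is unbounded along the edge.
# slope0 must already account for zero-residual non-basic observations
# (see qr_slope_adjust), so only strictly positive breakpoints are scanned
# and every accepted pivot strictly decreases the objective.
qr_pivot_entering <- function(r, g, h, slope0) {
  elig <- g != 0
  elig[h] <- FALSE
  tv <- ifelse(elig, r / g, NA_real_)
  keep <- elig & !is.na(tv) & tv > 0
  idx <- which(keep)
  if (!length(idx)) return(NA_integer_)
  o <- order(tv[idx], idx)
  cum <- slope0 + cumsum(abs(g[idx][o]))
  k <- which(cum >= 0)[1]
  if (is.na(k)) return(NA_integer_)
  idx[o[k]]
}

# directional-derivative correction for zero-residual non-basic
# observations: they are counted on the non-negative side in s, but flip to
# the negative side the moment the fit moves off them, adding |x_i . d| to
# the one-sided derivative whenever the direction pushes them negative
qr_slope_adjust <- function(G, zero_idx) {
  p <- ncol(G)
  if (!length(zero_idx)) return(numeric(2L * p))
  Gz <- G[zero_idx, , drop = FALSE]
  c(colSums(pmax(Gz, 0)), colSums(pmax(-Gz, 0)))
}

# smoothed-loss iteratively-reweighted least squares; used as warm start and
# as the standalone "smooth" method for very large problems
qr_irls <- function(X, y, tau, iter = 40L, eps0 = 1e-2, eps_min = 1e-8) {
  beta <- qr.coef(qr(X), y)
  eps <- eps0
  for (i in seq_len(iter)) {
    r <- as.vector(y - X %*% beta)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- lm.wfit(X, y, w)
    bn <- fit$coefficients
    if (any(!is.finite(bn))) break
    delta <- max(abs(bn - beta))
    beta <- bn
    if (delta < 1e-10 && eps <= eps_min) break
    eps <- max(eps * 0.5, eps_min)
  }
  beta
}

lex_less <- function(a, b, tol = 1e-9) {
  d <- a - b
  scale <- pmax(1, abs(a), abs(b))
  k <- which(abs(d) > tol * scale)
  length(k) > 0L && d[k[1]] < 0
}

#' Fit one conditional quantile by exact check-loss minimisation
#'
#' Solves \eqn{\min_\beta \sum_i \rho_\tau(y_i - x_i'\beta)} with an exact
#' simplex (basis-exchange) algorithm on the quantile-regression linear
#' program, warm-started from a smoothed iteratively-reweighted
#' least-squares solution. The returned solution is a vertex (it
#' interpolates `ncol(X)` observations); on flat optima the
#' lexicographically smallest optimal vertex is reported (lowest first
#' coefficient first), which makes intercept-only fits equal the sample
#' quantile under the lowest-minimiser convention.
#'
#' @param X design matrix (n x p, full column rank, finite).
#' @param y response vector (length n).
#' @param tau quantile level in (0, 1).
#' @param method `"simplex"` (exact, default) or `"smooth"` (iteratively
#'   reweighted smoothing only; intended for very large n where an exact
#'   vertex solution is not required).
#' @param max_iter pivot limit before a convergence error is raised.
#' @return an object of class `rygb_fit`: list with `coefficients`, `tau`,
#'   `loss` (achieved mean check loss), `n_obs`, `iterations`, `converged`,
#'   `method`, and `basis` (row indices interpolated by the solution, for
#'   the simplex method).
#' @export
#' @examples
#' # intercept-only fit is the sample median
#' fit_quantile(matrix(1, 5, 1), c(3, 1, 4, 1, 5), tau = 0.5)$coefficients
fit_quantile <- function(X, y, tau, method = c("simplex", "smooth"),
                         max_iter = 10000L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (!n || length(y) != n) {
    rygb_error("X and y must be non-empty with matching rows",
               "rygb_empty_input")
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    rygb_error("design matrix and response must be finite",
               "rygb_invalid_input")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    rygb_error("tau must lie strictly in (0, 1)", "rygb_invalid_input")
  }
  if (n < p || qr(X)$rank < p) {
    rygb_error(sprintf("design matrix is rank deficient (n = %d, p = %d)", n, p),
               "rygb_rank_error")
  }

  if (method == "smooth") {
    beta <- qr_irls(X, y, tau, iter = 200L)
    r <- as.vector(y - X %*% beta)
    return(structure(list(coefficients = stats::setNames(as.numeric(beta),
                                                         colnames(X)),
                          tau = tau, loss = check_loss(r, tau), n_obs = n,
                          iterations = NA_integer_, converged = TRUE,
                          method = method, basis = NULL),
                     class = "rygb_fit"))
  }

  # warm start and initial basis: the p smallest-|residual| rows that are
  # linearly independent
  beta0 <- qr_irls(X, y, tau)
  r0 <- as.vector(y - X %*% beta0)
  h <- integer(0)
  for (i in order(abs(r0), seq_len(n))) {
    cand <- c(h, i)
    if (qr(X[cand, , drop = FALSE])$rank == length(cand)) h <- cand
    if (length(h) == p) break
  }

  tol <- 1e-9
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      rygb_error(sprintf(
        "quantile fit did not converge within %d pivots (tau = %g, n = %d)",
        max_iter, tau, n), "rygb_convergence_error")
    }
    Xh <- X[h, , drop = FALSE]
    D <- tryCatch(solve(Xh), error = function(e) NULL)
    if (is.null(D)) {
      rygb_error("singular basis encountered during pivoting",
                 "rygb_convergence_error")
    }
    beta <- as.vector(D %*% y[h])
    r <- y - as.vector(X %*% beta)
    r[h] <- 0
    G <- X %*% D
    w <- tau - (r < 0)
    w[h] <- 0
    s <- as.vector(crossprod(G, w))
    zero_idx <- setdiff(which(r == 0), h)
    dall <- c((1 - tau) - s, tau + s) +  # [D(+1, j); D(-1, j)]
      qr_slope_adjust(G, zero_idx)
    m <- which.min(dall)
    if (dall[m] >= -tol) break
    j <- if (m <= p) m else m - p
    sig <- if (m <= p) 1 else -1
    enter <- qr_pivot_entering(r, sig * G[, j], h, dall[m])
    if (is.na(enter)) {
      rygb_error("objective unbounded along a descent edge (degenerate design)",
                 "rygb_convergence_error")
    }
    h[j] <- enter
  }

  # lexicographic polish: slide along any zero-derivative (flat) edge while
  # the move produces a lexicographically smaller coefficient vector
  flat_tol <- 1e-8
  for (pol in seq_len(200L)) {
    Xh <- X[h, , drop = FALSE]
    D <- solve(Xh)
    beta <- as.vector(D %*% y[h])
    r <- y - as.vector(X %*% beta)
    r[h] <- 0
    G <- X %*% D
    w <- tau - (r < 0)
    w[h] <- 0
    s <- as.vector(crossprod(G, w))
    zero_idx <- setdiff(which(r == 0), h)
    dall <- c((1 - tau) - s, tau + s) + qr_slope_adjust(G, zero_idx)
    flats <- which(abs(dall) <= flat_tol)
    moved <- FALSE
    for (m in flats) {
      j <- if (m <= p) m else m - p
      sig <- if (m <= p) 1 else -1
      enter <- qr_pivot_entering(r, sig * G[, j], h, 0)
      if (is.na(enter)) next
      h2 <- h
      h2[j] <- enter
      b2 <- tryCatch(solve(X[h2, , drop = FALSE], y[h2]),
                     error = function(e) NULL)
      if (is.null(b2)) next
      if (lex_less(as.vector(b2), beta)) {
        h <- h2
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }

  Xh <- X[h, , drop = FALSE]
  beta <- as.vector(solve(Xh, y[h]))
  r <- y - as.vector(X %*% beta)
  r[h] <- 0
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 tau = tau, loss = check_loss(r, tau), n_obs = n,
                 iterations = it, converged = TRUE, method = method,
                 basis = sort(h)),
            class = "rygb_fit")
}

#' @export
print.rygb_fit <- function(x, ...) {
  cat(sprintf("Quantile fit (tau = %g, %s): mean check loss %.6g on %d obs (%s pivots)\n",
              x$tau, x$method, x$loss, x$n_obs,
              if (is.na(x$iterations)) "NA" else x$iterations))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Build the centred design matrix and BMI response from a cohort
#'
#' One row per weight measurement: the 8-component centred basis evaluated
#' at the patient's baseline BMI and age and the measurement time; the
#' response is the measured BMI (weight over baseline height squared).
#'
#' @param cohort a `rygb_cohort`.
#' @return list with `X` (n x 8 matrix), `y` (BMI response), `patient_id`.
#' @export
build_design <- function(cohort) {
  stopifnot(inherits(cohort, "rygb_cohort"))
  meas <- cohort$measurements
  prof <- cohort$profiles
  if (!nrow(meas)) {
    rygb_error("cohort has no measurements", "rygb_empty_input")
  }
  i <- match(meas$patient_id, prof$patient_id)
  X <- design_vector(prof$bmi_baseline[i], prof$age[i], meas$months_post_op)
  X <- matrix(X, ncol = 8, dimnames = list(NULL, COEF_NAMES))
  y <- meas$weight_kg / prof$height_m[i]^2
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    rygb_error("non-finite entries in the cohort design matrix",
               "rygb_invalid_input")
  }
  list(X = X, y = y, patient_id = meas$patient_id)
}

#' Fit the full percentile model set to a cohort
#'
#' Runs one exact quantile fit per requested level on the pooled
#' measurement-level design (repeated measures are treated as independent
#' observations in the loss, mirroring the pooled fit the model was
#' developed with). Validity ranges of the returned model set are the
#' cohort's empirical covariate ranges.
#'
#' @param cohort a `rygb_cohort` (cleaned; every patient with baseline BMI,
#'   age and at least one post-operative measurement).
#' @param taus strictly increasing quantile levels (default 0.25/0.50/0.75).
#' @param method passed to [fit_quantile()].
#' @return a `rygb_modelset`; the per-tau `rygb_fit` objects are attached as
#'   attribute `"fits"`.
#' @export
fit_modelset <- function(cohort, taus = c(0.25, 0.5, 0.75),
                         method = "simplex") {
  if (any(diff(taus) <= 0) || any(taus <= 0 | taus >= 1)) {
    rygb_error("taus must be strictly increasing within (0, 1)",
               "rygb_ordering_error")
  }
  des <- build_design(cohort)
  fits <- lapply(taus, function(tv) {
    tryCatch(fit_quantile(des$X, des$y, tv, method = method),
             rygb_error = function(e) {
               rygb_error(sprintf("fit at tau = %g failed: %s", tv,
                                  conditionMessage(e)),
                          class(e)[1])
             })
  })
  entries <- lapply(seq_along(taus), function(k) {
    b <- unname(fits[[k]]$coefficients)
    quantile_coefficients(taus[k], b[1], b[2], b[3], b[4], b[5], b[6],
                          b[7], b[8])
  })
  prof <- cohort$profiles
  ms <- modelset(entries,
                 bmi_range = range(prof$bmi_baseline),
                 age_range = range(prof$age),
                 time_range = c(0, max(cohort$measurements$months_post_op)))
  attr(ms, "fits") <- fits
  attr(ms, "n_patients") <- nrow(prof)
  attr(ms, "n_obs") <- nrow(cohort$measurements)
  ms
}

#' Screen candidate covariates against weight-loss outcomes
#'
#' For each candidate (baseline BMI, age, sex, diabetes) the two
#' patient-level outcomes — six-month percent excess weight loss and nadir
#' BMI — are regressed on the candidate adjusting for baseline BMI and age.
#' Effects are standardised (coefficient times the covariate SD over the
#' outcome SD). A candidate is retained when its absolute standardised
#' effect reaches `threshold` on both outcomes and the effects point in a
#' consistent weight-loss direction (more loss on one outcome cannot pair
#' with less loss on the other; note that a higher %EWL and a lower nadir
#' BMI both mean more weight loss).
#'
#' @param cohort a `rygb_cohort`.
#' @param threshold minimum absolute standardised effect (default 0.1).
#' @return data frame of class `rygb_screen` with columns `covariate`,
#'   `effect_6mo`, `effect_nadir`, `p_6mo`, `p_nadir`, `retained`.
#' @export
screen_covariates <- function(cohort, threshold = 0.1) {
  stopifnot(inherits(cohort, "rygb_cohort"))
  prof <- cohort$profiles
  meas <- cohort$measurements

  out6 <- rep(NA_real_, nrow(prof))
  outn <- rep(NA_real_, nrow(prof))
  split_idx <- split(seq_len(nrow(meas)), meas$patient_id)
  for (k in seq_len(nrow(prof))) {
    rows <- split_idx[[as.character(prof$patient_id[k])]]
    if (is.null(rows)) next
    m <- meas[rows, , drop = FALSE]
    o <- order(m$months_post_op)
    ser <- weight_series(m$months_post_op[o], m$weight_kg[o])
    pr <- list(weight_baseline = prof$weight_baseline_kg[k],
               height = prof$height_m[k])
    out6[k] <- six_month_loss(ser, pr)
    outn[k] <- nadir(ser, prof$height_m[k])$bmi
  }

  cand <- list(
    bmi_baseline = prof$bmi_baseline,
    age = prof$age,
    sex = if (!is.null(prof$sex)) as.numeric(prof$sex == "female") else NULL,
    diabetes = if (!is.null(prof$diabetes)) as.numeric(prof$diabetes) else NULL
  )
  adj <- cbind(bmi_baseline = prof$bmi_baseline, age = prof$age)

  screen_one <- function(cv, nm, outcome) {
    ok <- is.finite(outcome) & is.finite(cv)
    if (!any(ok) || sd(cv[ok]) == 0) return(c(NA_real_, NA_real_))
    dat <- data.frame(y = outcome[ok], x = cv[ok])
    # adjust for baseline BMI and age (dropping the candidate itself)
    other <- adj[ok, setdiff(colnames(adj), nm), drop = FALSE]
    dat <- cbind(dat, other)
    fit <- lm(y ~ ., data = dat)
    sm <- summary(fit)$coefficients
    if (!"x" %in% rownames(sm)) return(c(NA_real_, NA_real_))
    eff <- sm["x", "Estimate"] * sd(dat$x) / sd(dat$y)
    c(eff, sm["x", "Pr(>|t|)"])
  }

  rows <- lapply(names(cand), function(nm) {
    cv <- cand[[nm]]
    if (is.null(cv) || all(!is.finite(cv))) {
      return(data.frame(covariate = nm, effect_6mo = NA_real_,
                        effect_nadir = NA_real_, p_6mo = NA_real_,
                        p_nadir = NA_real_, retained = FALSE,
                        stringsAsFactors = FALSE))
    }
    e6 <- screen_one(cv, nm, out6)
    en <- screen_one(cv, nm, outn)
    # orient both effects in the "more weight loss" direction: %EWL up and
    # nadir BMI down both mean more loss
    consistent <- is.finite(e6[1]) && is.finite(en[1]) &&
      sign(e6[1]) == -sign(en[1]) && e6[1] != 0
    retained <- consistent && abs(e6[1]) >= threshold &&
      abs(en[1]) >= threshold
    data.frame(covariate = nm, effect_6mo = e6[1], effect_nadir = en[1],
               p_6mo = e6[2], p_nadir = en[2], retained = retained,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("rygb_screen", "data.frame")
  res
}

#' Compare two fitted model sets over a reference trajectory
#'
#' Evaluates both model sets over a time grid for a reference patient
#' (default: baseline BMI 50 kg/m2, age 50, the comparison used for
#' primary-versus-validation cohorts) and reports per-level maximum and
#' mean absolute differences in predicted BMI.
#'
#' @param msA,msB `rygb_modelset` objects sharing the same quantile levels.
#' @param bmi0,age reference covariates.
#' @param times time grid, months (default 0 to 36 in steps of 0.5).
#' @return data frame of class `rygb_compare` with columns `tau`,
#'   `max_abs_diff`, `mean_abs_diff` (kg/m2).
#' @export
compare_fits <- function(msA, msB, bmi0 = 50, age = 50,
                         times = seq(0, 36, by = 0.5)) {
  stopifnot(inherits(msA, "rygb_modelset"), inherits(msB, "rygb_modelset"))
  if (length(msA$taus) != length(msB$taus) ||
      any(abs(msA$taus - msB$taus) > 1e-12)) {
    rygb_error("model sets do not share the same quantile levels",
               "rygb_config_error")
  }
  rows <- suppressWarnings(lapply(seq_along(msA$taus), function(k) {
    a <- evaluate_percentile(msA$entries[[k]], bmi0, age, times,
                             ranges = msA, extrapolate = TRUE)
    b <- evaluate_percentile(msB$entries[[k]], bmi0, age, times,
                             ranges = msB, extrapolate = TRUE)
    data.frame(tau = msA$taus[k], max_abs_diff = max(abs(a - b)),
               mean_abs_diff = mean(abs(a - b)))
  }))
  res <- do.call(rbind, rows)
  class(res) <- c("rygb_compare", "data.frame")
  res
}
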
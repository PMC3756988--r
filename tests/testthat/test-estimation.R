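test_that("the loss vanishes on noise-free data at the generating parameters", {
  obs <- make_subject()
  lp <- log(unlist(ref_free()[simo_free_set()]))
  expect_lt(simo_wls_loss(lp, obs), 1e-12)
})

test_that("a point displaced by one CV contributes exactly one to the loss", {
  obs <- make_subject()
  lp <- log(unlist(ref_free()[simo_free_set()]))
  obs2 <- obs
  obs2$glucose[4] <- obs$glucose[4] * (1 + 0.22)
  expect_equal(simo_wls_loss(lp, obs2), 1, tolerance = 1e-9)
  obs3 <- obs
  obs3$insulin[5] <- obs$insulin[5] * (1 - 0.31)
  expect_equal(simo_wls_loss(lp, obs3), 1, tolerance = 1e-9)
})

test_that("the loss matches a hand-computed weighted sum of squares", {
  obs <- make_subject()
  lp <- log(unlist(ref_free()[simo_free_set()]))
  pred_g <- obs$glucose   # predictions equal the noise-free observations
  pred_i <- obs$insulin
  d_g <- c(0, 0.4, -0.3, 0.2, 0, 0.1, -0.2)
  d_i <- c(0, 30, -25, 12, 8, 0, -5)
  obs2 <- obs
  obs2$glucose <- obs$glucose + d_g
  obs2$insulin <- obs$insulin + d_i
  hand <- sum((d_g / (pred_g * 0.22))^2) + sum((d_i / (pred_i * 0.31))^2)
  expect_equal(simo_wls_loss(lp, obs2), hand, tolerance = 1e-6)
})

test_that("infeasible parameters yield an infinite penalty, not an error", {
  obs <- make_subject()
  lp <- log(unlist(ref_free()[simo_free_set()]))
  lp[simo_free_set() == "k_ig_max"] <- log(0.5)  # cannot sustain basal
  expect_identical(simo_wls_loss(lp, obs), Inf)
  lp2 <- log(unlist(ref_free()[simo_free_set()]))
  lp2[1] <- log(1e3)  # far outside bounds
  expect_identical(simo_wls_loss(lp2, obs), Inf)
})

test_that("subjects with too few valid samples are rejected", {
  obs <- make_subject()
  obs$insulin_valid <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  elig <- ogtt_eligible(obs)
  expect_false(elig$eligible[1])
  expect_error(simo_fit(obs), class = "simo_ineligible_error")
})

test_that("noise-free parameters are recovered within 1% from the lattice", {
  obs <- make_subject()
  fit <- simo_fit(obs)
  est <- tidy(fit)
  truth <- unlist(ref_free()[est$parameter])
  expect_true(all(abs(est$estimate - truth) / truth < 0.01))
  expect_lt(fit$loss, 1e-6)
  expect_true(fit$converged)
})

test_that("the optimum does not depend on the starting point", {
  obs <- make_subject()
  fit1 <- simo_fit(obs)
  start <- ref_free()
  start$k_js <- start$k_js * 1.6
  start$k_xgi <- start$k_xgi / 1.8
  fit2 <- simo_fit(obs, start = start)
  expect_lt(fit2$loss, 1e-6)
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 0.02)
})

test_that("an infeasible explicit start raises", {
  obs <- make_subject()
  bad <- ref_free(); bad$k_ig_max <- 0.5
  expect_error(simo_fit(obs, start = bad), class = "simo_start_error")
})

test_that("fitting converted mg/dl / mU/L data gives identical estimates", {
  obs <- make_subject()
  path <- withr::local_tempfile(fileext = ".csv")
  raw <- obs
  raw$glucose <- glucose_from_mM(obs$glucose, "mg/dl")
  raw$insulin <- insulin_from_pM(obs$insulin, "mU/L")
  raw$dose <- dose_to_g(obs$dose, "mmol")
  readr::write_csv(raw, path)
  back <- read_ogtt(path, glucose_unit = "mg/dl", insulin_unit = "mU/L",
                    dose_unit = "g")
  fit_direct <- simo_fit(obs)
  fit_converted <- simo_fit(back)
  expect_equal(tidy(fit_converted)$estimate, tidy(fit_direct)$estimate,
               tolerance = 1e-6)
})

test_that("asymptotic covariance matches the closed-form GLS oracle", {
  set.seed(3)
  A <- matrix(rnorm(30), 10, 3)
  sd <- runif(10, 0.5, 2)
  theta <- c(a = 0.3, b = -1.2, c = 0.8)
  res <- asymptotic_covariance(function(th) drop(A %*% th), theta, sd)
  expect_true(res$computable)
  oracle <- solve(t(A) %*% diag(1 / sd^2) %*% A)
  expect_equal(unname(res$cov), oracle, tolerance = 1e-6)
})

test_that("duplicating every observation halves the covariance", {
  set.seed(4)
  A <- matrix(rnorm(24), 8, 3)
  sd <- runif(8, 0.5, 2)
  theta <- c(a = 0.3, b = -1.2, c = 0.8)
  single <- asymptotic_covariance(function(th) drop(A %*% th), theta, sd)
  A2 <- rbind(A, A); sd2 <- c(sd, sd)
  double <- asymptotic_covariance(function(th) drop(A2 %*% th), theta, sd2)
  expect_equal(double$cov, single$cov / 2, tolerance = 1e-6)
})

test_that("a collinear parameter pair is reported as not computable", {
  A <- cbind(1:6, (1:6) * 2)  # perfectly collinear columns
  res <- asymptotic_covariance(function(th) drop(A %*% th),
                               c(a = 1, b = 1), rep(1, 6))
  expect_false(res$computable)
  expect_null(res$cov)
})

test_that("log-scale CVs are reported in both conventions", {
  set.seed(11)
  obs <- add_prop_noise(make_subject())
  fit <- simo_fit(obs)
  est <- tidy(fit)
  if (isTRUE(fit$covariance_computable)) {
    expect_equal(est$cv_log, est$se_log)
    expect_equal(est$cv_natural, sqrt(exp(est$se_log^2) - 1))
    expect_true(all(est$cv_natural >= est$cv_log - 1e-12))
  } else {
    expect_true(all(is.na(est$se_log)))
  }
})

test_that("insulin sensitivity is the most precisely estimated parameter", {
  # qualitative dispersion ordering on a small synthetic cohort
  set.seed(21)
  cvs <- list()
  for (s in 1:8) {
    obs <- add_prop_noise(make_subject())
    fit <- simo_fit(obs)
    if (isTRUE(fit$covariance_computable)) {
      est <- tidy(fit)
      cvs[[length(cvs) + 1]] <-
        setNames(est$cv_log, est$parameter)
    }
  }
  stopifnot(length(cvs) >= 4)
  med <- apply(do.call(rbind, cvs), 2, median)
  expect_lt(med[["k_xgi"]], med[["k_ig_max"]])
  expect_lt(med[["k_xgi"]], med[["lambda_1g"]])
})

test_that("asymptotic and bootstrap dispersion agree within a factor of two", {
  set.seed(31)
  obs <- add_prop_noise(make_subject())
  fit <- simo_fit(obs)
  expect_true(isTRUE(fit$covariance_computable))
  se_asym <- tidy(fit)$se_log[tidy(fit)$parameter == "k_xgi"]

  # nonparametric residual bootstrap; the weighted residual pool is
  # standardized to unit variance because the proportional-error model fixes
  # the weighted-residual scale, and a 7-parameter fit to 12 post-basal
  # samples absorbs part of the realized noise
  pred <- fit$predictions
  wres_g <- (pred$glucose_obs - pred$glucose_pred) /
    (pred$glucose_pred * 0.22)
  wres_i <- (pred$insulin_obs - pred$insulin_pred) /
    (pred$insulin_pred * 0.31)
  pool <- c(wres_g[-1], wres_i[-1])
  pool <- (pool - mean(pool)) / sd(pool)
  set.seed(32)
  B <- 200
  boot <- numeric(0)
  for (b in seq_len(B)) {
    rg <- sample(pool, length(wres_g) - 1, replace = TRUE)
    ri <- sample(pool, length(wres_i) - 1, replace = TRUE)
    ob <- obs
    ob$glucose <- pred$glucose_pred * c(1, 1 + 0.22 * rg)
    ob$insulin <- pred$insulin_pred * c(1, 1 + 0.31 * ri)
    fb <- tryCatch(
      simo_fit(ob, start = fit$free, compute_covariance = FALSE,
               config = wls_config(max_polish = 2)),
      error = function(e) NULL
    )
    if (!is.null(fb)) {
      boot <- c(boot, tidy(fb)$log_estimate[tidy(fb)$parameter == "k_xgi"])
    }
  }
  stopifnot(length(boot) >= 150)
  ratio <- sd(boot) / se_asym
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
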
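#' Observation noise model
#'
#' Multiplicative measurement error with fixed per-channel coefficients of
#' variation: errors are independent, zero-mean, with standard deviation
#' equal to the model expectation times the CV (22\% glucose, 31\% insulin).
#' The default family is additive normal on that scale; a log-normal variant
#' (same CV) is available.
#'
#' @param cv_glucose,cv_insulin Coefficients of variation in (0, 1).
#' @param family `"normal"` (additive, prediction-proportional SD) or
#'   `"lognormal"`.
#' @param floor Draws below `floor * prediction` are truncated up to keep
#'   observations physical.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv_glucose = 0.22, cv_insulin = 0.31,
                        family = c("normal", "lognormal"), floor = 1e-6) {
  family <- match.arg(family)
  stopifnot(cv_glucose >= 0, cv_glucose < 1, cv_insulin >= 0, cv_insulin < 1)
  structure(list(cv_glucose = cv_glucose, cv_insulin = cv_insulin,
                 family = family, floor = floor), class = "noise_model")
}

.apply_noise <- function(yhat, cv, noise) {
  if (cv == 0) return(yhat)
  y <- if (noise$family == "normal") {
    yhat + rnorm(length(yhat), 0, yhat * cv)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    yhat * exp(rnorm(length(yhat), -sdlog^2 / 2, sdlog))
  }
  pmax(y, noise$floor * yhat)
}

# Log-normal moment matching: natural-scale mean m and SD s to the mean and
# variance of log(X).
.lognorm_pars <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma2 = sigma2)
}

#' Define a group-level parameter distribution
#'
#' One sub-population: individual log-parameters are multivariate normal with
#' mean `mu_log` and covariance `Sigma_log`. Natural-scale means and SDs are
#' converted by log-normal moment matching; unless a full covariance is
#' supplied the log-covariance is diagonal.
#'
#' @param group Group label.
#' @param n Number of subjects.
#' @param param_mean Named vector of natural-scale parameter means (any
#'   subset of the free parameters; others take [simo_free()] defaults with
#'   zero variance).
#' @param param_sd Named vector of natural-scale SDs (same names).
#' @param Sigma_log Optional full log-scale covariance matrix (overrides
#'   `param_sd`).
#' @param basal_mean Named vector `c(G_b = , I_b = )` of basal means (mM, pM).
#' @param basal_sd Corresponding SDs.
#' @param weight_mean,weight_sd Body weight distribution (kg).
#' @return A one-row tibble; rows from several calls can be bound together.
#' @export
cohort_distribution <- function(group, n, param_mean, param_sd,
                                Sigma_log = NULL,
                                basal_mean = c(G_b = 4.75, I_b = 50),
                                basal_sd = c(G_b = 0.4, I_b = 25),
                                weight_mean = 75, weight_sd = 15) {
  stopifnot(length(param_mean) == length(param_sd),
            all(names(param_mean) == names(param_sd)))
  lp <- .lognorm_pars(param_mean, param_sd)
  mu_log <- setNames(lp$mu, names(param_mean))
  if (is.null(Sigma_log)) {
    Sigma_log <- diag(lp$sigma2, nrow = length(mu_log))
    dimnames(Sigma_log) <- list(names(mu_log), names(mu_log))
  } else {
    ev <- eigen(Sigma_log, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) abort("Sigma_log must be positive semi-definite")
  }
  tibble(group = group, n = as.integer(n),
         mu_log = list(mu_log), Sigma_log = list(Sigma_log),
         basal_mean = list(basal_mean), basal_sd = list(basal_sd),
         weight_mean = weight_mean, weight_sd = weight_sd)
}

#' Default five-group cohort distributions
#'
#' The five glucose-tolerance groups (NGT, IFG, IGT, IFG+IGT, T2DM) with the
#' published group means/SDs for the insulin sensitivity `k_xgi`, the
#' secretion acceleration `gamma`, the maximal secretion rate `k_ig_max` and
#' the hepatic suppression rate `lambda_1g`, plus basal glucose/insulin and
#' body weight distributions from the corresponding group descriptives.
#' Group values for `k_js`, `k_gl` and `k_xi` are not published:
#' physiological placeholder means (0.035, 0.025 and 0.05 1/min, 30\% CV)
#' are used for every group and are labelled synthetic.
#'
#' @param n Named integer vector of group sizes.
#' @return A tibble with one row per group (see [cohort_distribution()]).
#' @export
simo_cohort_defaults <- function(n = c(NGT = 28, IFG = 15, IGT = 13,
                                       "IFG+IGT" = 10, T2DM = 12)) {
  groups <- names(n)
  k_xgi_m <- c(NGT = 8.62e-5, IFG = 5.30e-5, IGT = 2.09e-5,
               "IFG+IGT" = 2.38e-5, T2DM = 2.38e-5)
  k_xgi_s <- c(NGT = 9.36e-5, IFG = 5.18e-5, IGT = 1.95e-5,
               "IFG+IGT" = 2.28e-5, T2DM = 2.09e-5)
  gamma_m <- c(NGT = 4.42, IFG = 6.58, IGT = 4.15, "IFG+IGT" = 6.21,
               T2DM = 7.98)
  gamma_s <- c(NGT = 0.96, IFG = 3.69, IGT = 0.81, "IFG+IGT" = 4.76,
               T2DM = 5.51)
  kig_m <- c(NGT = 45.93, IFG = 34.21, IGT = 71.84, "IFG+IGT" = 72.01,
             T2DM = 43.6)
  kig_s <- c(NGT = 41.67, IFG = 31.72, IGT = 66.52, "IFG+IGT" = 112.09,
             T2DM = 30.93)
  l1g_m <- c(NGT = 0.58, IFG = 0.39, IGT = 0.80, "IFG+IGT" = 0.60,
             T2DM = 0.58)
  l1g_s <- c(NGT = 0.39, IFG = 0.42, IGT = 0.26, "IFG+IGT" = 0.33,
             T2DM = 0.30)
  # basal glucose mg/dl and insulin mU/L group descriptives, converted
  gb_m <- glucose_to_mM(c(NGT = 85.54, IFG = 106.04, IGT = 90.26,
                          "IFG+IGT" = 106.90, T2DM = 123.03), "mg/dl")
  gb_s <- glucose_to_mM(c(NGT = 6.71, IFG = 5.14, IGT = 5.70,
                          "IFG+IGT" = 5.96, T2DM = 19.95), "mg/dl")
  ib_m <- insulin_to_pM(c(NGT = 7.29, IFG = 11.52, IGT = 14.08,
                          "IFG+IGT" = 23.01, T2DM = 18.66), "mU/L")
  ib_s <- insulin_to_pM(c(NGT = 5.32, IFG = 6.50, IGT = 14.90,
                          "IFG+IGT" = 24.28, T2DM = 12.17), "mU/L")
  wt_m <- c(NGT = 74.98, IFG = 80.55, IGT = 83.45, "IFG+IGT" = 89.98,
            T2DM = 83.28)
  wt_s <- c(NGT = 15.92, IFG = 11.56, IGT = 17.01, "IFG+IGT" = 20.99,
            T2DM = 19.81)
  bad <- setdiff(groups, names(k_xgi_m))
  if (length(bad)) abort(paste("unknown group(s):", paste(bad, collapse = ", ")))
  bind_rows(lapply(groups, function(g) {
    pm <- c(k_js = 0.035, k_gl = 0.025, k_xgi = unname(k_xgi_m[g]),
            k_xi = 0.05, k_ig_max = unname(kig_m[g]),
            gamma = unname(gamma_m[g]), lambda_1g = unname(l1g_m[g]))
    ps <- c(k_js = 0.3 * 0.035, k_gl = 0.3 * 0.025,
            k_xgi = unname(k_xgi_s[g]), k_xi = 0.3 * 0.05,
            k_ig_max = unname(kig_s[g]), gamma = unname(gamma_s[g]),
            lambda_1g = unname(l1g_s[g]))
    cohort_distribution(
      group = g, n = n[[g]], param_mean = pm, param_sd = ps,
      basal_mean = c(G_b = unname(gb_m[g]), I_b = unname(ib_m[g])),
      basal_sd = c(G_b = unname(gb_s[g]), I_b = unname(ib_s[g])),
      weight_mean = unname(wt_m[g]), weight_sd = unname(wt_s[g])
    )
  }))
}

# A single feasible subject draw from one group row; rejection-resampled.
.draw_subject <- function(row, max_retry = 100) {
  mu <- row$mu_log[[1]]
  Sigma <- row$Sigma_log[[1]]
  bm <- row$basal_mean[[1]]; bs <- row$basal_sd[[1]]
  bounds <- simo_bounds()
  for (r in seq_len(max_retry)) {
    lp <- MASS::mvrnorm(1, mu, Sigma)
    th <- exp(lp)
    blp <- .lognorm_pars(bm, bs)
    bas <- exp(rnorm(2, blp$mu, sqrt(blp$sigma2)))
    wlp <- .lognorm_pars(row$weight_mean, row$weight_sd)
    wt <- exp(rnorm(1, wlp$mu, sqrt(wlp$sigma2)))
    free <- simo_free()
    ok <- TRUE
    for (nm in names(th)) {
      b <- bounds[[nm]]
      if (th[[nm]] < b[1] || th[[nm]] > b[2]) ok <- FALSE
      free[[nm]] <- th[[nm]]
    }
    if (!ok) next
    if (free$gamma < 1) next
    if (free$k_ig_max <= free$k_xi * bas[2]) next  # steady state infeasible
    return(list(free = free, basal = simo_basal(bas[1], bas[2]), weight = wt))
  }
  abort("could not draw a feasible subject (retry cap reached)")
}

#' Generate a synthetic OGTT cohort
#'
#' Draws individual log-parameters from each group's multivariate normal,
#' simulates the model from the post-dose initial condition, samples the
#' trajectory on the standard grid and adds multiplicative measurement
#' error. Ground-truth parameters are attached for recovery studies.
#'
#' @param dist Distribution tibble ([cohort_distribution()] rows /
#'   [simo_cohort_defaults()]).
#' @param noise A [noise_model()].
#' @param seed Integer seed (required; all randomness flows from it).
#' @param times Sampling grid (min).
#' @param dose_g Oral dose in grams.
#' @param fixed Fixed parameters.
#' @return Tibble of observations (`subject`, `group`, `time`, `glucose`,
#'   `insulin`, `dose`, `weight`, validity masks) with the true generating
#'   parameters available via [cohort_truth()].
#' @export
generate_cohort <- function(dist, noise = noise_model(), seed,
                            times = seq(0, 180, by = 30), dose_g = 75,
                            fixed = simo_fixed()) {
  if (missing(seed)) abort("an explicit seed is required")
  set.seed(as.integer(seed))
  dose <- dose_to_mmol(dose_g, "g")
  obs_rows <- list(); truth_rows <- list()
  idx <- 0L
  for (gi in seq_len(nrow(dist))) {
    row <- dist[gi, ]
    for (si in seq_len(row$n)) {
      idx <- idx + 1L
      subj <- sprintf("%s_%02d", row$group, si)
      drawn <- .draw_subject(row)
      traj <- simo_simulate(drawn$free, fixed, drawn$basal, dose,
                            drawn$weight, times = times)
      g_obs <- .apply_noise(traj$G, noise$cv_glucose, noise)
      i_obs <- .apply_noise(traj$I, noise$cv_insulin, noise)
      # the basal sample defines G_b/I_b downstream: keep it noise-free so
      # basal values act as known constants
      g_obs[1] <- traj$G[1]; i_obs[1] <- traj$I[1]
      obs_rows[[idx]] <- tibble(
        subject = subj, group = row$group, time = times,
        glucose = g_obs, insulin = i_obs, dose = dose,
        weight = drawn$weight,
        glucose_valid = TRUE, insulin_valid = TRUE
      )
      truth_rows[[idx]] <- tibble(
        subject = subj, group = row$group,
        !!!drawn$free[names(drawn$free)],
        G_b = drawn$basal$G_b, I_b = drawn$basal$I_b, weight = drawn$weight
      )
    }
  }
  out <- bind_rows(obs_rows)
  attr(out, "truth") <- bind_rows(truth_rows)
  out
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort A tibble from [generate_cohort()].
#' @return Tibble of true generating parameters, one row per subject.
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) abort("cohort carries no ground truth attribute")
  tr
}

#' Randomly invalidate observations
#'
#' Marks samples invalid with per-channel probabilities, emulating missing
#' values in clinical records; eligibility can then be recomputed with
#' [ogtt_eligible()].
#'
#' @param data Observations tibble.
#' @param p_glucose,p_insulin Per-sample missingness probabilities.
#' @param seed Integer seed.
#' @return The tibble with updated validity masks.
#' @export
inject_missingness <- function(data, p_glucose = 0, p_insulin = 0, seed) {
  if (missing(seed)) abort("an explicit seed is required")
  set.seed(as.integer(seed))
  data <- .ensure_validity(data)
  n <- nrow(data)
  data$glucose_valid <- data$glucose_valid &
    (stats::runif(n) >= p_glucose)
  data$insulin_valid <- data$insulin_valid &
    (stats::runif(n) >= p_insulin)
  data
}

#' Two-stage population summary of cohort fits
#'
#' Second stage of the two-stage population analysis: per-group sample mean
#' vector and sample covariance matrix of the individual log-parameter
#' estimates, in the distribution format consumed by [simo_vpc()] and
#' [generate_cohort()].
#'
#' @param fits Cohort fit tibble from [simo_fit_cohort()].
#' @param basal_from Optional observations tibble used to summarise the
#'   basal-state and body-weight distributions per group from the t = 0
#'   rows; without it generic NGT-like basal defaults are carried, which is
#'   only appropriate for structural checks.
#' @return Distribution tibble, one row per group.
#' @export
two_stage <- function(fits, basal_from = NULL) {
  fits <- filter(fits, .data$fitted)
  log_cols <- grep("^log_", names(fits), value = TRUE)
  params <- sub("^log_", "", log_cols)
  groups <- unique(fits$group)
  bind_rows(lapply(groups, function(g) {
    m <- as.matrix(fits[fits$group == g, log_cols, drop = FALSE])
    colnames(m) <- params
    mu <- colMeans(m)
    Sigma <- if (nrow(m) > 1) stats::cov(m) else
      diag(0, length(mu), length(mu))
    dimnames(Sigma) <- list(params, params)
    bm <- c(G_b = 4.75, I_b = 50); bs <- c(G_b = 0.4, I_b = 25)
    wm <- 75; ws <- 15
    if (!is.null(basal_from)) {
      b0 <- filter(basal_from, .data$group == g, .data$time == 0)
      bm <- c(G_b = mean(b0$glucose), I_b = mean(b0$insulin))
      bs <- c(G_b = max(sd(b0$glucose), 1e-6),
              I_b = max(sd(b0$insulin), 1e-6))
      wm <- mean(b0$weight); ws <- max(sd(b0$weight), 1e-6)
    }
    tibble(group = g, n = as.integer(nrow(m)),
           mu_log = list(mu), Sigma_log = list(Sigma),
           basal_mean = list(bm), basal_sd = list(bs),
           weight_mean = wm, weight_sd = ws)
  }))
}
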
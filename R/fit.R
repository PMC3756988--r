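#' Weighted least squares configuration
#'
#' Settings for single-subject identification. The error model is
#' multiplicative with fixed coefficients of variation per channel (22\% for
#' glucose, 31\% for insulin, as estimated from repeated in-vivo glycemia and
#' insulinemia determinations); weights are the inverse error variances
#' `1 / (yhat^2 * CV^2)` with the expectations `yhat` taken as the model
#' predictions, recomputed at every loss evaluation.
#'
#' @param cv_glucose,cv_insulin Proportional-error coefficients of variation.
#' @param maxit Nelder-Mead iteration budget for polishing runs.
#' @param restarts Number of deterministic multi-starts (log-space lattice
#'   around physiological mid-values).
#' @param reltol Simplex relative convergence tolerance for polishing runs.
#' @param screen_maxit,screen_reltol Cheaper simplex settings for the
#'   exploratory multi-start screen; the winning start is then polished at
#'   the tight tolerance.
#' @param polish_tol Relative loss improvement below which simplex restarts
#'   from the incumbent stop.
#' @param max_polish Maximum number of polishing restarts.
#' @param loss_tol Absolute loss below which the fit is declared converged
#'   (an essentially perfect fit).
#' @param bounds Named list of `c(lower, upper)` natural-scale bounds; loss is
#'   `+Inf` outside.
#' @return A list of class `wls_config`.
#' @export
wls_config <- function(cv_glucose = 0.22, cv_insulin = 0.31,
                       maxit = 400, restarts = 5, reltol = 1e-8,
                       screen_maxit = 250, screen_reltol = 1e-6,
                       polish_tol = 1e-6, max_polish = 8, loss_tol = 1e-9,
                       bounds = simo_bounds()) {
  stopifnot(cv_glucose > 0, cv_glucose < 1, cv_insulin > 0, cv_insulin < 1)
  structure(list(cv_glucose = cv_glucose, cv_insulin = cv_insulin,
                 maxit = maxit, restarts = restarts, reltol = reltol,
                 screen_maxit = screen_maxit, screen_reltol = screen_reltol,
                 polish_tol = polish_tol, max_polish = max_polish,
                 loss_tol = loss_tol, bounds = bounds),
            class = "wls_config")
}

#' Default natural-scale parameter bounds
#'
#' Wide physiological bounds used as a feasibility box during optimization.
#' @return Named list of `c(lower, upper)` pairs.
#' @export
simo_bounds <- function() {
  list(
    k_js = c(1e-4, 1), k_gl = c(1e-4, 1), k_xgi = c(1e-9, 1e-2),
    k_xi = c(1e-3, 2), k_ig_max = c(0.1, 5e3), gamma = c(1, 60),
    lambda_1g = c(1e-3, 30), f = c(0.05, 1)
  )
}

# Collapse a single subject's rows into the flat structure the optimizer works
# on. Basal values are the observed t = 0 samples, treated as known constants.
.subject_obs <- function(data, min_valid = 5) {
  data <- .ensure_validity(data)
  if ("subject" %in% names(data) && length(unique(data$subject)) > 1L) {
    abort("data contains more than one subject; use simo_fit_cohort()")
  }
  data <- arrange(data, .data$time)
  i0 <- which(data$time == 0)
  if (!length(i0)) abort("no t = 0 (basal) row")
  basal <- simo_basal(data$glucose[i0[1]], data$insulin[i0[1]])
  elig <- sum(data$glucose_valid) >= min_valid &&
    sum(data$insulin_valid) >= min_valid
  list(
    times = data$time,
    glucose = data$glucose, insulin = data$insulin,
    glucose_valid = data$glucose_valid, insulin_valid = data$insulin_valid,
    basal = basal,
    dose = data$dose[1], weight = data$weight[1],
    subject = if ("subject" %in% names(data)) data$subject[1] else "s1",
    group = if ("group" %in% names(data)) data$group[1] else "all",
    eligible = elig
  )
}

# Fast path: predictions at the observation grid for a candidate log-parameter
# vector. Returns NULL when infeasible (bounds, steady state, or integration).
.simo_predict <- function(log_par, est_names, base_free, fixed, obs,
                          bounds) {
  th <- exp(log_par)
  for (i in seq_along(est_names)) {
    b <- bounds[[est_names[i]]]
    if (th[i] < b[1] || th[i] > b[2]) return(NULL)
  }
  free <- base_free
  free[est_names] <- th
  G_b <- obs$basal$G_b; I_b <- obs$basal$I_b
  ratio <- free$k_ig_max / (free$k_xi * I_b)
  if (!is.finite(ratio) || ratio <= 1) return(NULL)
  lambda_2g <- free$lambda_1g / I_b
  determined <- list(
    T_1g = fixed$k_xg * G_b * exp(free$lambda_1g * G_b),
    T_2gi = free$k_xgi * I_b * G_b * exp(lambda_2g * G_b * I_b),
    lambda_2g = lambda_2g,
    G_star = G_b * (ratio - 1)^(1 / free$gamma)
  )
  if (!all(vapply(determined, is.finite, logical(1)))) return(NULL)
  p <- .simo_param_vector(free, fixed, obs$basal, obs$weight, determined)
  m <- tryCatch(
    .simo_solve_cpp(p, G_b, I_b, obs$dose, obs$times, 1e-8, 1e-10),
    error = function(e) NULL
  )
  if (is.null(m) || any(!is.finite(m[, 5:6]))) return(NULL)
  list(G = m[, 5], I = m[, 6])
}

#' Weighted least squares loss
#'
#' The objective minimized during identification:
#' `sum((y - yhat)^2 / (yhat^2 cv^2))` over valid glucose points plus the
#' analogous insulin sum, with `yhat` the model prediction at the candidate
#' parameters. Returns `+Inf` for infeasible parameters or failed
#' integrations so the simplex can recover.
#'
#' @param log_par Numeric vector of natural logarithms of the estimated
#'   parameters, named or ordered as `estimate`.
#' @param data One subject's OGTT observations (tibble).
#' @param estimate Names of the estimated parameters.
#' @param base_free A [simo_free()] set providing values for parameters not
#'   estimated.
#' @param fixed A [simo_fixed()] set.
#' @param config A [wls_config()].
#' @return Scalar loss (>= 0, possibly `Inf`).
#' @export
simo_wls_loss <- function(log_par, data, estimate = simo_free_set(),
                          base_free = simo_free(), fixed = simo_fixed(),
                          config = wls_config()) {
  obs <- .subject_obs(data)
  .simo_loss_obs(log_par, estimate, base_free, fixed, obs, config)
}

.simo_loss_obs <- function(log_par, est_names, base_free, fixed, obs, config) {
  pr <- .simo_predict(log_par, est_names, base_free, fixed, obs,
                      config$bounds)
  if (is.null(pr)) return(Inf)
  gv <- obs$glucose_valid
  iv <- obs$insulin_valid
  yg <- pmax(pr$G[gv], 1e-8)
  yi <- pmax(pr$I[iv], 1e-8)
  sum(((obs$glucose[gv] - yg) / (yg * config$cv_glucose))^2) +
    sum(((obs$insulin[iv] - yi) / (yi * config$cv_insulin))^2)
}

# Position of each free parameter in the canonical compiled-solver vector.
.simo_pv_pos <- c(k_js = 1, k_gl = 5, k_xgi = 7, k_xi = 8, k_ig_max = 9,
                  gamma = 10, lambda_1g = 11, f = 12)

# Precomputed evaluation context: avoids per-evaluation list manipulation in
# the optimizer's inner loop. Semantics identical to .simo_loss_obs.
.make_loss_ctx <- function(est_names, base_free, fixed, obs, config) {
  p0 <- numeric(19)
  p0[.simo_pv_pos[names(base_free)]] <- unlist(base_free)
  p0[2] <- fixed$k_gj; p0[3] <- fixed$k_rj; p0[4] <- fixed$k_lr
  p0[6] <- fixed$k_xg; p0[13] <- fixed$f_gj; p0[14] <- fixed$V
  p0[15] <- obs$weight
  b <- config$bounds[est_names]
  list(
    p0 = p0, est_pos = unname(.simo_pv_pos[est_names]),
    lo = vapply(b, `[`, numeric(1), 1), hi = vapply(b, `[`, numeric(1), 2),
    G_b = obs$basal$G_b, I_b = obs$basal$I_b, dose = obs$dose,
    times = obs$times,
    gi = which(obs$glucose_valid), ii = which(obs$insulin_valid),
    yg = obs$glucose[obs$glucose_valid], yi = obs$insulin[obs$insulin_valid],
    cvg = config$cv_glucose, cvi = config$cv_insulin
  )
}

.simo_loss_ctx <- function(lp, ctx) {
  th <- exp(lp)
  if (any(th < ctx$lo) || any(th > ctx$hi)) return(Inf)
  p <- ctx$p0
  p[ctx$est_pos] <- th
  ratio <- p[9] / (p[8] * ctx$I_b)
  if (!is.finite(ratio) || ratio <= 1) return(Inf)
  l2g <- p[11] / ctx$I_b
  p[16] <- p[6] * ctx$G_b * exp(p[11] * ctx$G_b)
  p[17] <- p[7] * ctx$I_b * ctx$G_b * exp(l2g * ctx$G_b * ctx$I_b)
  p[18] <- l2g
  p[19] <- ctx$G_b * (ratio - 1)^(1 / p[10])
  m <- tryCatch(
    .simo_solve_cpp(p, ctx$G_b, ctx$I_b, ctx$dose, ctx$times, 1e-8, 1e-10),
    error = function(e) NULL
  )
  if (is.null(m)) return(Inf)
  G <- m[ctx$gi, 5]; I <- m[ctx$ii, 6]
  if (any(!is.finite(G)) || any(!is.finite(I))) return(Inf)
  G <- pmax(G, 1e-8); I <- pmax(I, 1e-8)
  sum(((ctx$yg - G) / (G * ctx$cvg))^2) +
    sum(((ctx$yi - I) / (I * ctx$cvi))^2)
}

# Deterministic multi-start lattice in log space around the physiological
# mid-values given by simo_free() defaults.
.simo_starts <- function(est_names, base_free, n) {
  mid <- log(unlist(base_free[est_names]))
  k <- length(mid)
  alt <- rep_len(c(1, -1), k)
  offsets <- list(rep(0, k), rep(0.7, k), rep(-0.7, k), 0.7 * alt, -0.7 * alt,
                  rep(0.35, k), rep(-0.35, k))
  lapply(offsets[seq_len(min(n, length(offsets)))], function(o) mid + o)
}

#' Fit the model to one subject
#'
#' Identifies the free parameters of one subject's glucose and insulin curves
#' by weighted least squares on log-parameters. A Nelder-Mead simplex is run
#' from several deterministic starts (log-space lattice around physiological
#' mid-values); the best solution is polished by repeated restarts until the
#' relative loss improvement falls below `config$polish_tol`. Ties between
#' starts are broken toward the lower insulin sensitivity `k_xgi`. The
#' asymptotic covariance of the log-estimates is computed from the
#' finite-difference sensitivity matrix (see [asymptotic_covariance()]); a
#' singular information matrix is reported as not computable, never as an
#' error.
#'
#' @param data One subject's OGTT observations: tibble with columns `time`,
#'   `glucose` (mM), `insulin` (pM), `dose` (mmol), `weight` (kg), and
#'   optional validity masks.
#' @param estimate Names of parameters to estimate (default: the seven-
#'   parameter set, `f` held at 1).
#' @param base_free Values for non-estimated free parameters and mid-values
#'   for the starts.
#' @param fixed Fixed parameters.
#' @param config A [wls_config()].
#' @param start Optional explicit [simo_free()]-like start (overrides the
#'   multi-start lattice).
#' @param compute_covariance Set `FALSE` to skip the covariance (faster in
#'   large Monte-Carlo runs).
#' @return An object of class `simo_fit`; see [tidy.simo_fit()] and
#'   [glance.simo_fit()].
#' @export
simo_fit <- function(data, estimate = simo_free_set(),
                     base_free = simo_free(), fixed = simo_fixed(),
                     config = wls_config(), start = NULL,
                     compute_covariance = TRUE) {
  obs <- .subject_obs(data)
  if (!obs$eligible) {
    abort(paste0("subject '", obs$subject,
                 "' is not fit-eligible: fewer than 5 valid samples in at ",
                 "least one channel"),
          class = "simo_ineligible_error")
  }
  ctx <- .make_loss_ctx(estimate, base_free, fixed, obs, config)
  fn <- function(lp) .simo_loss_ctx(lp, ctx)

  if (is.null(start)) {
    starts <- .simo_starts(estimate, base_free, config$restarts)
  } else {
    sv <- log(unlist(start[estimate]))
    if (!is.finite(fn(sv))) {
      abort("infeasible start (loss is not finite)", class = "simo_start_error")
    }
    starts <- list(sv)
  }

  runs <- lapply(starts, function(s) {
    if (!is.finite(fn(s))) return(NULL)
    optim(s, fn, method = "Nelder-Mead",
          control = list(maxit = config$screen_maxit,
                         reltol = config$screen_reltol))
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (!length(runs)) {
    abort("all starts infeasible", class = "simo_start_error")
  }
  losses <- vapply(runs, `[[`, numeric(1), "value")
  kx <- match("k_xgi", estimate)
  best_loss <- min(losses)
  cand <- which(losses <= best_loss * (1 + 1e-9))
  if (length(cand) > 1L && !is.na(kx)) {
    cand <- cand[which.min(vapply(runs[cand],
                                  function(r) r$par[kx], numeric(1)))]
  }
  best <- runs[[cand[1]]]
  iterations <- sum(vapply(runs, function(r) r$counts[1], numeric(1)))

  # polish: restart the simplex from the incumbent until relative improvement
  # stalls (post-condition: a restart improves the loss by < polish_tol)
  converged <- FALSE
  for (i in seq_len(config$max_polish)) {
    nxt <- optim(best$par, fn, method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = config$reltol))
    iterations <- iterations + nxt$counts[1]
    rel <- (best$value - nxt$value) / max(best$value, 1e-12)
    if (nxt$value < best$value) best <- nxt
    if (rel < config$polish_tol || best$value < config$loss_tol) {
      converged <- TRUE
      break
    }
  }

  log_est <- setNames(best$par, estimate)
  est <- exp(log_est)
  free_hat <- base_free
  free_hat[estimate] <- est
  determined <- simo_determined(free_hat, fixed, obs$basal)
  pr <- .simo_predict(log_est, estimate, base_free, fixed, obs, config$bounds)

  cov_info <- if (compute_covariance) {
    .fit_covariance(log_est, estimate, base_free, fixed, obs, config)
  } else {
    list(cov = NULL, computable = NA)
  }

  se_log <- if (is.matrix(cov_info$cov)) sqrt(diag(cov_info$cov)) else
    rep(NA_real_, length(estimate))
  estimates <- tibble(
    parameter = estimate,
    log_estimate = unname(log_est),
    estimate = unname(est),
    se_log = unname(se_log),
    cv_log = unname(se_log),
    cv_natural = unname(sqrt(exp(se_log^2) - 1))
  )

  gv <- obs$glucose_valid; iv <- obs$insulin_valid
  predictions <- tibble(
    time = obs$times,
    glucose_obs = obs$glucose, insulin_obs = obs$insulin,
    glucose_pred = pr$G, insulin_pred = pr$I,
    glucose_valid = gv, insulin_valid = iv
  )
  residuals <- list(
    glucose = (obs$glucose[gv] - pr$G[gv]) / (pr$G[gv] * config$cv_glucose),
    insulin = (obs$insulin[iv] - pr$I[iv]) / (pr$I[iv] * config$cv_insulin)
  )

  structure(list(
    subject = obs$subject, group = obs$group,
    estimates = estimates, loss = best$value, converged = converged,
    iterations = unname(iterations),
    covariance = cov_info$cov, covariance_computable = cov_info$computable,
    residuals = residuals, predictions = predictions,
    basal = obs$basal, fixed = fixed, free = free_hat,
    determined = determined, estimate = estimate, config = config,
    dose = obs$dose, weight = obs$weight,
    n_glucose = sum(gv), n_insulin = sum(iv)
  ), class = "simo_fit")
}

# Sensitivity-based covariance at the optimum of the subject loss.
.fit_covariance <- function(log_est, est_names, base_free, fixed, obs,
                            config) {
  gv <- obs$glucose_valid; iv <- obs$insulin_valid
  # the linearization must be evaluable even when the optimum sits on the
  # optimization box, so only positivity and steady-state feasibility apply
  open_box <- lapply(config$bounds, function(b) c(0, Inf))
  predict_stacked <- function(lp) {
    pr <- .simo_predict(lp, est_names, base_free, fixed, obs, open_box)
    if (is.null(pr)) return(NULL)
    c(pr$G[gv], pr$I[iv])
  }
  y0 <- predict_stacked(log_est)
  if (is.null(y0)) return(list(cov = NULL, computable = FALSE))
  sdvec <- c(pmax(y0[seq_len(sum(gv))], 1e-8) * config$cv_glucose,
             pmax(y0[sum(gv) + seq_len(sum(iv))], 1e-8) * config$cv_insulin)
  asymptotic_covariance(predict_stacked, log_est, sdvec)
}

#' Asymptotic covariance of least-squares estimates
#'
#' Computes `(J' S^-1 J)^-1`, where `J` is the sensitivity matrix of the
#' stacked predictions with respect to the (log) parameters, obtained by
#' central finite differences with relative step `rel_step`, and `S` is the
#' diagonal error covariance with standard deviations `sd`. A
#' near-singular information matrix (condition number above `max_kappa`) is
#' reported as not computable rather than inverted.
#'
#' @param predict_fn Function mapping a parameter vector to the stacked
#'   prediction vector (may return `NULL` when infeasible).
#' @param theta Parameter vector at which to linearize.
#' @param sd Error standard deviations, one per stacked observation.
#' @param rel_step Relative finite-difference step.
#' @param max_kappa Conditioning threshold for the information matrix.
#' @return List with `cov` (matrix or NULL) and `computable` (logical).
#' @export
asymptotic_covariance <- function(predict_fn, theta, sd, rel_step = 1e-4,
                                  max_kappa = 1e12) {
  k <- length(theta)
  y0 <- predict_fn(theta)
  if (is.null(y0)) return(list(cov = NULL, computable = FALSE))
  n <- length(y0)
  stopifnot(length(sd) == n)
  J <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    h <- rel_step * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    yu <- predict_fn(up); yd <- predict_fn(dn)
    if (is.null(yu) || is.null(yd)) return(list(cov = NULL,
                                                computable = FALSE))
    J[, j] <- (yu - yd) / (2 * h)
  }
  W <- 1 / sd^2
  info <- crossprod(J * sqrt(W))
  if (!all(is.finite(info))) return(list(cov = NULL, computable = FALSE))
  kap <- tryCatch(kappa(info, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > max_kappa) {
    return(list(cov = NULL, computable = FALSE))
  }
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(list(cov = NULL, computable = FALSE))
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(names(theta), names(theta))
  list(cov = cov, computable = TRUE)
}

#' @export
print.simo_fit <- function(x, ...) {
  cat("Model fit for subject", x$subject, "(group", paste0(x$group, ")\n"))
  cat("  WLS loss:", format(x$loss, digits = 6),
      "| converged:", x$converged,
      "| function evaluations:", x$iterations, "\n")
  print(x$estimates)
  invisible(x)
}

#' Tidy a subject fit
#'
#' One row per estimated parameter: log and natural-scale estimates, the
#' asymptotic log-scale standard error, and the coefficient of variation in
#' both conventions (`cv_log`, the log-scale SE, which is also the
#' first-order delta-method CV of the natural-scale estimate; and
#' `cv_natural`, the exact log-normal CV `sqrt(exp(se^2) - 1)`).
#'
#' @param x A `simo_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy simo_fit
#' @export
tidy.simo_fit <- function(x, ...) x$estimates

#' One-row fit summary
#'
#' @param x A `simo_fit` object.
#' @param ... Unused.
#' @return A tibble with loss, convergence, evaluation count, valid sample
#'   counts and covariance computability.
#' @method glance simo_fit
#' @export
glance.simo_fit <- function(x, ...) {
  tibble(
    subject = x$subject, group = x$group, loss = x$loss,
    converged = x$converged, iterations = x$iterations,
    n_glucose = x$n_glucose, n_insulin = x$n_insulin,
    covariance_computable = isTRUE(x$covariance_computable)
  )
}

#' Plot a subject fit
#'
#' Observed points and model-predicted curves for glucose and insulin.
#'
#' @param object A `simo_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot simo_fit
#' @export
autoplot.simo_fit <- function(object, ...) {
  dense <- simo_simulate(object$free, object$fixed, object$basal,
                         object$dose, object$weight,
                         times = seq(0, max(object$predictions$time), by = 2))
  pred_long <- tidyr::pivot_longer(
    select(dense, "time", glucose = "G", insulin = "I"),
    c("glucose", "insulin"), names_to = "channel", values_to = "value")
  obs_long <- tidyr::pivot_longer(
    select(object$predictions, "time", glucose = "glucose_obs",
           insulin = "insulin_obs"),
    c("glucose", "insulin"), names_to = "channel", values_to = "value")
  ggplot2::ggplot(pred_long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs_long) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (mM / pM)",
                  title = paste("Subject", object$subject))
}

#' Fit every eligible subject in a cohort
#'
#' Applies [simo_fit()] subject by subject. Ineligible subjects are skipped
#' and recorded with the reason, never silently dropped.
#'
#' @param data OGTT observations tibble for several subjects.
#' @inheritParams simo_fit
#' @param keep_fits Keep the full `simo_fit` objects as a list column.
#' @return A tibble with one row per subject: group, eligibility/skip reason,
#'   convergence, loss, one column per estimated parameter (natural scale)
#'   and `log_<parameter>` columns (log scale).
#' @export
simo_fit_cohort <- function(data, estimate = simo_free_set(),
                            base_free = simo_free(), fixed = simo_fixed(),
                            config = wls_config(), compute_covariance = FALSE,
                            keep_fits = FALSE) {
  data <- .ensure_validity(data)
  subjects <- unique(data$subject)
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    d <- filter(data, .data$subject == subjects[i])
    elig <- ogtt_eligible(d)
    if (!elig$eligible[1]) {
      rows[[i]] <- tibble(subject = subjects[i],
                          group = d$group[1] %||% "all",
                          fitted = FALSE,
                          skip_reason = "insufficient valid samples",
                          converged = NA, loss = NA_real_)
      next
    }
    ft <- simo_fit(d, estimate = estimate, base_free = base_free,
                   fixed = fixed, config = config,
                   compute_covariance = compute_covariance)
    est <- setNames(as.list(ft$estimates$estimate), ft$estimates$parameter)
    lest <- setNames(as.list(ft$estimates$log_estimate),
                     paste0("log_", ft$estimates$parameter))
    row <- tibble(subject = subjects[i], group = ft$group, fitted = TRUE,
                  skip_reason = NA_character_, converged = ft$converged,
                  loss = ft$loss, !!!est, !!!lest)
    if (keep_fits) row$fit <- list(ft)
    rows[[i]] <- row
  }
  bind_rows(rows)
}
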
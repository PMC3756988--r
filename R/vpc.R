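#' Visual predictive check
#'
#' Simulation-based check of the model's predictive distribution. For each
#' group, `n_sim` replicate subjects per (real or nominal) subject are drawn:
#' log-parameters from the group multivariate normal (sample mean and
#' covariance under the two-stage population model, or a supplied
#' distribution), basal values and body weight from the group's basal
#' distribution, and observation noise from the proportional-error model.
#' Percentile curves (5th, 25th, 50th, 75th, 95th by default) are computed
#' pooling all replicates in the group at each nominal time point; the 5th
#' to 95th band is the 90\% prediction interval.
#'
#' A degenerate (non-positive-definite) group covariance falls back to its
#' diagonal with a warning.
#'
#' @param dist Distribution tibble ([simo_cohort_defaults()], a
#'   [cohort_distribution()] set, or [two_stage()] output from cohort fits).
#' @param n_sim Number of simulation replicates per subject.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param times Nominal sampling grid (min).
#' @param dose_g Oral dose (g).
#' @param fixed Fixed parameters.
#' @param probs Percentiles to report (fractions).
#' @param observations Optional observed data overlaid by `autoplot` and used
#'   by [vpc_coverage()].
#' @return A tibble of class `simo_vpc`: `group`, `time`, `channel`
#'   (glucose/insulin), `percentile`, `value`, with `n_sim` and the
#'   observations as attributes.
#' @export
simo_vpc <- function(dist, n_sim = 200, noise = noise_model(), seed,
                     times = seq(0, 180, by = 30), dose_g = 75,
                     fixed = simo_fixed(),
                     probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                     observations = NULL) {
  if (missing(seed)) abort("an explicit seed is required")
  set.seed(as.integer(seed))
  dose <- dose_to_mmol(dose_g, "g")
  out <- list()
  for (gi in seq_len(nrow(dist))) {
    row <- dist[gi, ]
    Sigma <- row$Sigma_log[[1]]
    ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      warn(paste0("group '", row$group,
                  "': degenerate covariance, falling back to diagonal"))
      Sigma <- diag(diag(Sigma), nrow = nrow(Sigma))
      dimnames(Sigma) <- dimnames(row$Sigma_log[[1]])
      row$Sigma_log[[1]] <- Sigma
    }
    nrep <- n_sim * row$n
    G_rep <- matrix(NA_real_, nrep, length(times))
    I_rep <- matrix(NA_real_, nrep, length(times))
    for (r in seq_len(nrep)) {
      drawn <- .draw_subject(row)
      traj <- simo_simulate(drawn$free, fixed, drawn$basal, dose,
                            drawn$weight, times = times)
      G_rep[r, ] <- .apply_noise(traj$G, noise$cv_glucose, noise)
      I_rep[r, ] <- .apply_noise(traj$I, noise$cv_insulin, noise)
    }
    qs <- function(m, channel) {
      q <- apply(m, 2, quantile, probs = probs, names = FALSE)
      tibble(
        group = row$group,
        time = rep(times, each = length(probs)),
        channel = channel,
        percentile = rep(100 * probs, length(times)),
        value = as.numeric(q)
      )
    }
    out[[gi]] <- bind_rows(qs(G_rep, "glucose"), qs(I_rep, "insulin"))
  }
  res <- bind_rows(out)
  attr(res, "n_sim") <- n_sim
  attr(res, "observations") <- observations
  class(res) <- c("simo_vpc", class(res))
  res
}

#' Empirical coverage of a VPC band
#'
#' Fraction of observations lying inside the band between two VPC
#' percentiles (default the 90\% prediction interval), per channel.
#'
#' @param vpc A [simo_vpc()] result.
#' @param observations Observations tibble (`group`, `time`, `glucose`,
#'   `insulin`); defaults to the observations attached to the VPC.
#' @param lower,upper Band percentiles.
#' @return A tibble with per-channel counts and coverage, plus a pooled row.
#' @export
vpc_coverage <- function(vpc, observations = NULL, lower = 5, upper = 95) {
  observations <- observations %||% attr(vpc, "observations")
  if (is.null(observations)) abort("no observations supplied")
  bands <- vpc |>
    filter(.data$percentile %in% c(lower, upper)) |>
    tidyr::pivot_wider(names_from = "percentile", values_from = "value",
                       names_prefix = "p")
  lo <- paste0("p", lower); hi <- paste0("p", upper)
  long_obs <- observations |>
    tidyr::pivot_longer(c("glucose", "insulin"), names_to = "channel",
                        values_to = "y") |>
    select("group", "time", "channel", "y") |>
    filter(is.finite(.data$y))
  joined <- dplyr::inner_join(long_obs, bands,
                              by = c("group", "time", "channel"))
  per <- joined |>
    group_by(.data$channel) |>
    summarise(n = n(),
              inside = sum(.data$y >= .data[[lo]] & .data$y <= .data[[hi]]),
              coverage = .data$inside / .data$n, .groups = "drop")
  pooled <- tibble(channel = "pooled", n = nrow(joined),
                   inside = sum(joined$y >= joined[[lo]] &
                                  joined$y <= joined[[hi]])) |>
    mutate(coverage = .data$inside / .data$n)
  bind_rows(per, pooled)
}

#' @method autoplot simo_vpc
#' @export
autoplot.simo_vpc <- function(object, channel = c("glucose", "insulin"),
                              ...) {
  channel <- match.arg(channel)
  d <- filter(as_tibble(object), .data$channel == !!channel)
  wide <- tidyr::pivot_wider(d, names_from = "percentile",
                             values_from = "value", names_prefix = "p")
  p <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p25), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p75), linetype = "dashed") +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "time (min)",
                  y = if (channel == "glucose") "glucose (mM)" else
                    "insulin (pM)")
  obs <- attr(object, "observations")
  if (!is.null(obs)) {
    obs_long <- tidyr::pivot_longer(obs, c("glucose", "insulin"),
                                    names_to = "channel", values_to = "y")
    p <- p + ggplot2::geom_point(
      data = filter(obs_long, .data$channel == !!channel),
      ggplot2::aes(y = .data$y), alpha = 0.4, size = 0.8)
  }
  p
}

#' Residual diagnostics for a subject fit
#'
#' Weighted residuals `(y - yhat) / (yhat * CV)` for each valid glucose and
#' insulin sample, against time and against the predicted concentration,
#' plus observed-versus-predicted pairs.
#'
#' @param fit A [simo_fit()] object.
#' @return A tibble: `channel`, `time`, `observed`, `predicted`,
#'   `weighted_residual`.
#' @export
residual_diagnostics <- function(fit) {
  p <- fit$predictions
  g <- filter(p, .data$glucose_valid)
  i <- filter(p, .data$insulin_valid)
  bind_rows(
    tibble(channel = "glucose", time = g$time, observed = g$glucose_obs,
           predicted = g$glucose_pred,
           weighted_residual = (g$glucose_obs - g$glucose_pred) /
             (g$glucose_pred * fit$config$cv_glucose)),
    tibble(channel = "insulin", time = i$time, observed = i$insulin_obs,
           predicted = i$insulin_pred,
           weighted_residual = (i$insulin_obs - i$insulin_pred) /
             (i$insulin_pred * fit$config$cv_insulin))
  )
}

#' Diagnostic plots for pooled residuals
#'
#' The three standard panels per channel: weighted residuals versus time,
#' weighted residuals versus prediction, and observed versus predicted.
#'
#' @param diag Residual tibble from [residual_diagnostics()] (rows from
#'   several fits may be bound together).
#' @param which `"time"`, `"prediction"`, or `"obs_vs_pred"`.
#' @return A ggplot object.
#' @export
plot_residuals <- function(diag, which = c("time", "prediction",
                                           "obs_vs_pred")) {
  which <- match.arg(which)
  if (which == "obs_vs_pred") {
    return(
      ggplot2::ggplot(diag, ggplot2::aes(x = .data$predicted,
                                         y = .data$observed)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
        ggplot2::geom_point(alpha = 0.5) +
        ggplot2::facet_wrap(~channel, scales = "free") +
        ggplot2::labs(x = "predicted", y = "observed")
    )
  }
  xvar <- if (which == "time") "time" else "predicted"
  ggplot2::ggplot(diag, ggplot2::aes(x = .data[[xvar]],
                                     y = .data$weighted_residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~channel, scales = "free_x") +
    ggplot2::labs(x = if (which == "time") "time (min)" else "predicted",
                  y = "weighted residual")
}
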
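# Canonical parameter vector consumed by the compiled solver; order must stay
# in step with src/solver.cpp.
.simo_param_vector <- function(free, fixed, basal, body_weight,
                               determined = NULL) {
  if (is.null(determined)) determined <- simo_determined(free, fixed, basal)
  c(free$k_js, fixed$k_gj, fixed$k_rj, fixed$k_lr, free$k_gl,
    fixed$k_xg, free$k_xgi, free$k_xi, free$k_ig_max, free$gamma,
    free$lambda_1g, free$f, fixed$f_gj, fixed$V, body_weight,
    determined$T_1g, determined$T_2gi, determined$lambda_2g,
    determined$G_star)
}

#' Model right-hand side (reference implementation)
#'
#' Time-derivatives of the six model states: glucose amounts in stomach (S),
#' jejunum (J), a delay compartment (R) and ileum (L), plus plasma glucose
#' concentration G (mM) and plasma insulin concentration I (pM). The plasma
#' glucose balance combines insulin-independent and insulin-dependent
#' disposal, net hepatic glucose output suppressed exponentially by glycemia
#' and by the glycemia-insulinemia product, and intestinal rate of appearance
#' scaled by the bioavailable fraction. Insulin secretion follows a Hill
#' response in the incretin-augmented glycemic signal `G + f_gj * (J + L)`,
#' saturating at `k_ig_max`.
#'
#' This R implementation is the readable reference; simulation and fitting use
#' an equivalent compiled version.
#'
#' @param state Named numeric vector with entries `S`, `J`, `R`, `L`, `G`, `I`
#'   (gut amounts in mmol, G in mM, I in pM).
#' @param free,fixed,basal Parameter sets ([simo_free()], [simo_fixed()],
#'   [simo_basal()]).
#' @param body_weight Body weight (kg).
#' @param determined Optional precomputed [simo_determined()] set.
#' @return Named list: `deriv` (named derivative vector) and the fluxes `Ra`
#'   (mM/min), `G_PROD` (mM/min) and `secretion` (pM/min).
#' @export
simo_rhs <- function(state, free, fixed, basal, body_weight,
                     determined = NULL) {
  if (is.null(determined)) determined <- simo_determined(free, fixed, basal)
  S <- state[["S"]]; J <- state[["J"]]; R <- state[["R"]]; L <- state[["L"]]
  G <- max(state[["G"]], 0); I <- max(state[["I"]], 0)

  absorb <- fixed$k_gj * J + free$k_gl * L
  Ra <- free$f * absorb / (fixed$V * body_weight)
  G_PROD <- determined$T_1g * exp(-free$lambda_1g * G) +
    determined$T_2gi * exp(-determined$lambda_2g * G * I)
  H <- G + fixed$f_gj * (J + L)
  secretion <- if (H <= 0) 0 else {
    free$k_ig_max * H^free$gamma / (determined$G_star^free$gamma + H^free$gamma)
  }

  deriv <- c(
    S = -free$k_js * S,
    J = free$k_js * S - (fixed$k_gj + fixed$k_rj) * J,
    R = fixed$k_rj * J - fixed$k_lr * R,
    L = fixed$k_lr * R - free$k_gl * L,
    G = -fixed$k_xg * G - free$k_xgi * I * G + G_PROD + Ra,
    I = -free$k_xi * I + secretion
  )
  if (any(!is.finite(deriv))) {
    abort("non-finite derivative; state or parameters out of numerical domain",
          class = "simo_domain_error")
  }
  list(deriv = deriv, Ra = Ra, G_PROD = G_PROD, secretion = secretion)
}

#' Simulate an OGTT
#'
#' Integrates the model from the post-dose initial condition
#' `(S, J, R, L, G, I) = (D, 0, 0, 0, G_b, I_b)` and returns the trajectory
#' together with the derived fluxes. The default integrator is a compiled
#' adaptive Dormand-Prince 5(4) stepper (relative tolerance `1e-8`, absolute
#' `1e-10`); `method = "lsoda"` routes the same right-hand side through
#' [deSolve::ode()] and is used as an independent integration cross-check.
#'
#' @param free,fixed,basal Parameter sets.
#' @param dose Administered glucose dose (mmol).
#' @param body_weight Body weight (kg).
#' @param times Output times (min), starting at 0.
#' @param method `"dopri"` (compiled, default) or `"lsoda"` ([deSolve]).
#' @param rtol,atol Integration tolerances.
#' @return A tibble with one row per time: states `S`, `J`, `R`, `L` (mmol),
#'   `G` (mM), `I` (pM), cumulative absorbed gut glucose `absorbed` (mmol),
#'   and fluxes `Ra` (mM/min), `G_PROD` (mM/min), `secretion` (pM/min).
#' @export
#' @examples
#' traj <- simo_simulate(simo_free(), simo_fixed(), simo_basal(4.75, 50),
#'                       dose = 75 / 0.18016, body_weight = 75,
#'                       times = seq(0, 180, 30))
#' traj
simo_simulate <- function(free, fixed, basal, dose, body_weight,
                          times = seq(0, 180, by = 2),
                          method = c("dopri", "lsoda"),
                          rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(is.numeric(times), length(times) >= 1, !is.unsorted(times,
                                                               strictly = TRUE))
  if (times[1] != 0) abort("times must start at 0 (dose administration)")
  if (dose < 0) abort("dose must be non-negative (mmol)")
  determined <- simo_determined(free, fixed, basal)
  p <- .simo_param_vector(free, fixed, basal, body_weight, determined)

  if (method == "dopri") {
    m <- .simo_solve_cpp(p, basal$G_b, basal$I_b, dose, as.numeric(times),
                         rtol, atol)
  } else {
    rhs_desolve <- function(t, y, parms) {
      names(y) <- c("S", "J", "R", "L", "G", "I", "A")
      r <- simo_rhs(y[1:6], free, fixed, basal, body_weight, determined)
      list(c(r$deriv, A = unname(fixed$k_gj * y[["J"]] + free$k_gl * y[["L"]])))
    }
    sol <- deSolve::ode(
      y = c(S = dose, J = 0, R = 0, L = 0, G = basal$G_b, I = basal$I_b, A = 0),
      times = as.numeric(times), func = rhs_desolve, parms = NULL,
      method = "lsoda", rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1] < 0) {
      abort("lsoda integration failed", class = "simo_integration_error")
    }
    m <- unname(as.matrix(sol[, -1, drop = FALSE]))
  }
  colnames(m) <- c("S", "J", "R", "L", "G", "I", "absorbed")
  traj <- as_tibble(m)
  traj <- mutate(traj, time = as.numeric(times), .before = 1)
  G <- pmax(traj$G, 0); I <- pmax(traj$I, 0)
  H <- G + fixed$f_gj * (traj$J + traj$L)
  traj$Ra <- free$f * (fixed$k_gj * traj$J + free$k_gl * traj$L) /
    (fixed$V * body_weight)
  traj$G_PROD <- determined$T_1g * exp(-free$lambda_1g * G) +
    determined$T_2gi * exp(-determined$lambda_2g * G * I)
  traj$secretion <- ifelse(
    H <= 0, 0,
    free$k_ig_max * H^free$gamma /
      (determined$G_star^free$gamma + H^free$gamma)
  )
  traj
}

#' Rate of appearance of oral glucose in plasma
#'
#' Recomputes the plasma rate of appearance (mM/min) from the gut states of a
#' simulated trajectory: `Ra = f * (k_gj * J + k_gl * L) / (V * body_weight)`.
#' Over a long horizon `V * body_weight * integral(Ra)` approaches
#' `f * dose`.
#'
#' @param trajectory A tibble from [simo_simulate()].
#' @param free,fixed Parameter sets.
#' @param body_weight Body weight (kg).
#' @return Numeric vector of Ra values, one per trajectory row.
#' @export
glucose_ra <- function(trajectory, free, fixed, body_weight) {
  free$f * (fixed$k_gj * trajectory$J + free$k_gl * trajectory$L) /
    (fixed$V * body_weight)
}

#' Jejunal bolus residue under absorption-only elimination
#'
#' Fraction of an intra-jejunally administered bolus remaining after `t`
#' minutes when the jejunum empties only through absorption to plasma
#' (`k_gj`), optionally with onward transit (`k_rj`). The default absorption
#' rate is calibrated so about 8\% of the bolus remains after one hour.
#' Computed by integrating the jejunum balance equation numerically.
#'
#' @param k_gj Jejunum-to-plasma absorption rate (1/min).
#' @param t Elapsed time (min).
#' @param k_rj Jejunum-to-delay transit rate (1/min); 0 isolates absorption.
#' @return Remaining fraction in (0, 1].
#' @export
#' @examples
#' jejunal_residue() # ~0.08 after 60 min
jejunal_residue <- function(k_gj = 0.042, t = 60, k_rj = 0) {
  sol <- deSolve::ode(
    y = c(J = 1), times = c(0, t),
    func = function(tt, y, p) list(-(p$k_gj + p$k_rj) * y),
    parms = list(k_gj = k_gj, k_rj = k_rj),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  unname(sol[nrow(sol), "J"])
}
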
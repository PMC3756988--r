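#' Fixed model parameters
#'
#' Parameters of the gut transit / glucose kinetics model that are held fixed
#' during estimation because they are a-priori unidentifiable from a standard
#' seven-sample OGTT. Defaults are the calibrated literature values: the
#' glucose distribution volume is the standard assessment of the glucose
#' distribution space; `k_gj` is calibrated so that 8\% of a jejunal bolus
#' remains after one hour of absorption-only elimination; `f_gj` is calibrated
#' so that 50 mmol of gut glucose exerts the same secretory drive as a 1 mM
#' rise in plasma glucose; `k_rj` and `k_lr` are set so essentially all
#' jejunal glucose reaches the ileum within three hours.
#'
#' @param V Glucose distribution volume (L/kg body weight).
#' @param k_xg Insulin-independent first-order glucose elimination rate
#'   (1/min).
#' @param k_gj Jejunum-to-plasma glucose transfer rate (1/min).
#' @param f_gj Glucose-concentration equivalent of gut glucose content for the
#'   incretin effect (mM/mmol).
#' @param k_rj Jejunum-to-delay-compartment transfer rate (1/min).
#' @param k_lr Delay-compartment-to-ileum transfer rate (1/min).
#' @return A named list of class `simo_fixed`.
#' @export
#' @examples
#' simo_fixed()
simo_fixed <- function(V = 0.19, k_xg = 0.001, k_gj = 0.042, f_gj = 0.02,
                       k_rj = 0.09, k_lr = 0.06) {
  x <- list(V = V, k_xg = k_xg, k_gj = k_gj, f_gj = f_gj,
            k_rj = k_rj, k_lr = k_lr)
  for (nm in names(x)) {
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || !is.finite(x[[nm]]) ||
        x[[nm]] <= 0) {
      abort(sprintf("fixed parameter '%s' must be a single positive number", nm))
    }
  }
  if (x$V >= 1) abort("V is in L/kg and must lie in (0, 1)")
  structure(x, class = "simo_fixed")
}

#' Free (estimable) model parameters
#'
#' The parameters identified subject-by-subject from glucose and insulin
#' curves. The default estimation set holds the bioavailable fraction `f` at
#' 1, leaving seven free parameters (see [simo_free_set()]).
#'
#' @param k_js Stomach-to-jejunum glucose transfer rate (1/min).
#' @param k_gl Ileum-to-plasma glucose transfer rate (1/min).
#' @param k_xgi Insulin-dependent second-order glucose elimination rate
#'   (1/(min pM)); the model's insulin sensitivity index.
#' @param k_xi First-order insulin elimination rate (1/min).
#' @param k_ig_max Maximal pancreatic insulin release rate (pM/min).
#' @param gamma Secretion acceleration exponent of the Hill response
#'   (dimensionless, >= 1).
#' @param lambda_1g Decay rate of hepatic glucose output with rising glycemia
#'   (1/mM).
#' @param f Fraction of the oral dose that is bioavailable (0, 1].
#' @return A named list of class `simo_free`.
#' @export
#' @examples
#' simo_free(k_xgi = 8.62e-5)
simo_free <- function(k_js = 0.035, k_gl = 0.025, k_xgi = 5e-5, k_xi = 0.05,
                      k_ig_max = 50, gamma = 4.5, lambda_1g = 0.5, f = 1) {
  x <- list(k_js = k_js, k_gl = k_gl, k_xgi = k_xgi, k_xi = k_xi,
            k_ig_max = k_ig_max, gamma = gamma, lambda_1g = lambda_1g, f = f)
  for (nm in names(x)) {
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || !is.finite(x[[nm]]) ||
        x[[nm]] <= 0) {
      abort(sprintf("free parameter '%s' must be a single positive number", nm))
    }
  }
  if (x$f > 1) abort("f is a fraction and must lie in (0, 1]")
  if (x$gamma < 1) abort("gamma must be >= 1")
  structure(x, class = "simo_free")
}

#' Default estimation set
#'
#' The seven parameters estimated per subject by default; `f` is held at its
#' nominal value of 1. Any other partition can be passed to [simo_fit()].
#'
#' @return Character vector of parameter names.
#' @export
simo_free_set <- function() {
  c("k_js", "k_gl", "k_xgi", "k_xi", "k_ig_max", "gamma", "lambda_1g")
}

#' Basal (pre-dose) state
#'
#' @param G_b Basal plasma glucose concentration immediately before glucose
#'   administration (mM).
#' @param I_b Basal plasma insulin concentration immediately before glucose
#'   administration (pM).
#' @return A named list of class `simo_basal`.
#' @export
simo_basal <- function(G_b, I_b) {
  if (!is.numeric(G_b) || length(G_b) != 1L || !is.finite(G_b) || G_b <= 0)
    abort("G_b must be a single positive number (mM)")
  if (!is.numeric(I_b) || length(I_b) != 1L || !is.finite(I_b) || I_b <= 0)
    abort("I_b must be a single positive number (pM)")
  structure(list(G_b = G_b, I_b = I_b), class = "simo_basal")
}

#' Steady-state determined parameters
#'
#' Closes the model at the basal state: with an empty gut and plasma at
#' (`G_b`, `I_b`) both the glucose and insulin derivatives must vanish
#' exactly. The hepatic output ceilings `T_1g` and `T_2gi` balance,
#' respectively, insulin-independent and insulin-dependent basal glucose
#' disposal; `lambda_2g` is tied to `lambda_1g` so the two suppression
#' exponents coincide at basal insulinemia; and the secretion half-saturation
#' glycemia `G_star` is the value at which basal secretion `k_xi * I_b`
#' is reproduced by the Hill response evaluated at `G_b`.
#'
#' @param free A [simo_free()] parameter set.
#' @param fixed A [simo_fixed()] parameter set.
#' @param basal A [simo_basal()] state.
#' @return A named list of class `simo_determined` with elements `T_1g`
#'   (mM/min), `T_2gi` (mM/min), `lambda_2g` (1/(mM pM)) and `G_star` (mM).
#' @export
#' @examples
#' simo_determined(simo_free(), simo_fixed(), simo_basal(4.75, 50))
simo_determined <- function(free, fixed, basal) {
  G_b <- basal$G_b
  I_b <- basal$I_b
  lambda_2g <- free$lambda_1g / I_b
  T_1g <- fixed$k_xg * G_b * exp(free$lambda_1g * G_b)
  T_2gi <- free$k_xgi * I_b * G_b * exp(lambda_2g * G_b * I_b)
  ratio <- free$k_ig_max / (free$k_xi * I_b)
  if (ratio <= 1) {
    abort(paste0(
      "steady state infeasible: maximal secretion rate k_ig_max (",
      format(free$k_ig_max), " pM/min) cannot sustain basal insulin turnover ",
      "k_xi * I_b (", format(free$k_xi * I_b), " pM/min)"
    ), class = "simo_steady_state_error")
  }
  G_star <- G_b * (ratio - 1)^(1 / free$gamma)
  out <- list(T_1g = T_1g, T_2gi = T_2gi, lambda_2g = lambda_2g,
              G_star = G_star)
  if (any(!vapply(out, is.finite, logical(1))) || any(unlist(out) < 0)) {
    abort("steady state infeasible: determined parameters must be finite and non-negative",
          class = "simo_steady_state_error")
  }
  structure(out, class = "simo_determined")
}

#' Serialize a parameter configuration
#'
#' Writes fixed, free and basal values as a flat key-value YAML mapping with
#' keys named by the model symbols, suitable for versioning alongside data.
#'
#' @param free,fixed,basal Parameter sets as from [simo_free()],
#'   [simo_fixed()], [simo_basal()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_simo_config <- function(path, free = simo_free(), fixed = simo_fixed(),
                              basal = NULL) {
  x <- c(unclass(fixed), unclass(free))
  if (!is.null(basal)) x <- c(x, unclass(basal))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a parameter configuration
#'
#' Inverse of [write_simo_config()]: reads a flat YAML mapping and partitions
#' the keys into fixed, free and (optionally) basal sets.
#'
#' @param path YAML file written by [write_simo_config()] (or hand-edited).
#' @return A list with elements `free`, `fixed`, and `basal` (NULL when the
#'   file carries no basal values).
#' @export
read_simo_config <- function(path) {
  x <- yaml::read_yaml(path)
  fixed_names <- names(formals(simo_fixed))
  free_names <- names(formals(simo_free))
  fixed <- do.call(simo_fixed, x[intersect(names(x), fixed_names)])
  free <- do.call(simo_free, x[intersect(names(x), free_names)])
  basal <- NULL
  if (all(c("G_b", "I_b") %in% names(x))) {
    basal <- simo_basal(x$G_b, x$I_b)
  }
  list(free = free, fixed = fixed, basal = basal)
}
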
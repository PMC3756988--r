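# Shared fixtures: a reference NGT-like subject built from the model itself.

ref_free <- function() {
  simo_free(k_js = 0.03, k_gl = 0.02, k_xgi = 8.62e-5, k_xi = 0.06,
            k_ig_max = 46, gamma = 4.42, lambda_1g = 0.58)
}

ref_basal <- function() simo_basal(4.748, 50.6)

ref_dose <- function() dose_to_mmol(75, "g")

std_times <- function() seq(0, 180, by = 30)

# Noise-free synthetic subject sampled on the standard grid.
make_subject <- function(free = ref_free(), basal = ref_basal(),
                         times = std_times(), dose = ref_dose(),
                         weight = 75, id = "s1", group = "all",
                         fixed = simo_fixed()) {
  tr <- simo_simulate(free, fixed, basal, dose, weight, times = times)
  tibble::tibble(subject = id, group = group, time = times,
                 glucose = tr$G, insulin = tr$I, dose = dose,
                 weight = weight)
}

# Proportional noise on all but the basal sample (basal is treated as known).
add_prop_noise <- function(obs, cv_g = 0.22, cv_i = 0.31) {
  n <- nrow(obs)
  keep <- obs$time == 0
  g <- obs$glucose * (1 + cv_g * rnorm(n))
  i <- obs$insulin * (1 + cv_i * rnorm(n))
  obs$glucose <- ifelse(keep, obs$glucose, pmax(g, 1e-6 * obs$glucose))
  obs$insulin <- ifelse(keep, obs$insulin, pmax(i, 1e-6 * obs$insulin))
  obs
}

# Trapezoid quadrature used as an independent oracle in several tests.
trapz_oracle <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
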
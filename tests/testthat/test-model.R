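test_that("determined parameters close the model at the basal steady state", {
  set.seed(42)
  for (rep in 1:10) {
    free <- simo_free(
      k_js = runif(1, 0.01, 0.08), k_gl = runif(1, 0.01, 0.06),
      k_xgi = runif(1, 1e-5, 2e-4), k_xi = runif(1, 0.02, 0.12),
      k_ig_max = runif(1, 20, 120), gamma = runif(1, 1.5, 9),
      lambda_1g = runif(1, 0.2, 1.2)
    )
    basal <- simo_basal(runif(1, 4, 8), runif(1, 30, 180))
    det <- simo_determined(free, simo_fixed(), basal)
    expect_true(all(unlist(det) >= 0))
    r <- simo_rhs(c(S = 0, J = 0, R = 0, L = 0, G = basal$G_b,
                    I = basal$I_b),
                  free, simo_fixed(), basal, 75, det)
    expect_lt(abs(r$deriv[["G"]]), 1e-12)
    expect_lt(abs(r$deriv[["I"]]), 1e-12)
  }
})

test_that("equilibrium survives recomputation after perturbing k_xgi", {
  free <- ref_free()
  free$k_xgi <- free$k_xgi * 1.1
  det <- simo_determined(free, simo_fixed(), ref_basal())
  r <- simo_rhs(c(S = 0, J = 0, R = 0, L = 0, G = ref_basal()$G_b,
                  I = ref_basal()$I_b),
                free, simo_fixed(), ref_basal(), 75, det)
  expect_lt(abs(r$deriv[["G"]]), 1e-12)
  expect_lt(abs(r$deriv[["I"]]), 1e-12)
})

test_that("an unsustainable basal insulin turnover is reported as infeasible", {
  free <- ref_free()
  free$k_ig_max <- 1  # below k_xi * I_b
  expect_error(simo_determined(free, simo_fixed(), ref_basal()),
               class = "simo_steady_state_error")
})

test_that("gut derivatives follow the linear compartment chain", {
  free <- ref_free(); fixed <- simo_fixed(); basal <- ref_basal()
  D <- ref_dose()
  r <- simo_rhs(c(S = D, J = 0, R = 0, L = 0, G = basal$G_b, I = basal$I_b),
                free, fixed, basal, 75)
  expect_equal(r$deriv[["S"]], -free$k_js * D)
  expect_equal(r$deriv[["J"]], free$k_js * D)
  expect_equal(r$deriv[["R"]], 0)
  expect_equal(r$deriv[["L"]], 0)
  expect_equal(r$deriv[["G"]], 0, tolerance = 1e-12)
  expect_equal(r$deriv[["I"]], 0, tolerance = 1e-12)

  st <- c(S = 100, J = 40, R = 20, L = 10, G = 6, I = 200)
  r2 <- simo_rhs(st, free, fixed, basal, 75)
  expect_equal(r2$deriv[["J"]],
               free$k_js * 100 - (fixed$k_gj + fixed$k_rj) * 40)
  expect_equal(r2$deriv[["R"]], fixed$k_rj * 40 - fixed$k_lr * 20)
  expect_equal(r2$deriv[["L"]], fixed$k_lr * 20 - free$k_gl * 10)
})

test_that("50 mmol of gut glucose drives secretion like +1 mM of glycemia", {
  free <- ref_free(); fixed <- simo_fixed(); basal <- ref_basal()
  det <- simo_determined(free, fixed, basal)
  with_gut <- simo_rhs(c(S = 0, J = 25, R = 0, L = 25, G = 5.5, I = 100),
                       free, fixed, basal, 75, det)
  plus_1mM <- simo_rhs(c(S = 0, J = 0, R = 0, L = 0, G = 6.5, I = 100),
                       free, fixed, basal, 75, det)
  expect_equal(fixed$f_gj * 50, 1)
  expect_equal(with_gut$secretion, plus_1mM$secretion, tolerance = 1e-12)
})

test_that("insulin secretion saturates at the maximal release rate", {
  free <- ref_free(); fixed <- simo_fixed(); basal <- ref_basal()
  det <- simo_determined(free, fixed, basal)
  r <- simo_rhs(c(S = 0, J = 0, R = 0, L = 0, G = 1e6, I = 100),
                free, fixed, basal, 75, det)
  expect_equal(r$secretion, free$k_ig_max, tolerance = 1e-6)
  tr <- simo_simulate(free, fixed, basal, ref_dose(), 75)
  expect_true(all(tr$secretion <= free$k_ig_max + 1e-12))
})

test_that("a zero dose leaves glucose and insulin flat at basal", {
  tr <- simo_simulate(ref_free(), simo_fixed(), ref_basal(), 0, 75,
                      times = seq(0, 180, by = 5))
  expect_lt(max(abs(tr$G - ref_basal()$G_b)) / ref_basal()$G_b, 1e-6)
  expect_lt(max(abs(tr$I - ref_basal()$I_b)) / ref_basal()$I_b, 1e-6)
  expect_true(all(tr$Ra == 0))
})

test_that("jejunal residue matches the exponential-decay oracle", {
  expect_equal(jejunal_residue(0.042, 60), exp(-0.042 * 60),
               tolerance = 1e-8)
  expect_equal(jejunal_residue(0.042, 60, k_rj = 0.09),
               exp(-(0.042 + 0.09) * 60), tolerance = 1e-8)
})

test_that("gut mass balance holds along the trajectory", {
  D <- ref_dose()
  tr <- simo_simulate(ref_free(), simo_fixed(), ref_basal(), D, 75,
                      times = seq(0, 180, by = 2))
  total <- tr$S + tr$J + tr$R + tr$L + tr$absorbed
  expect_lt(max(abs(total - D)), 1e-4 * D)
})

test_that("cumulative absorption converges to the administered dose", {
  D <- ref_dose()
  tr <- simo_simulate(ref_free(), simo_fixed(), ref_basal(), D, 75,
                      times = seq(0, 3000, by = 1))
  # quadrature oracle on the absorption flux, independent of the solver's
  # internal bookkeeping state
  flux <- simo_fixed()$k_gj * tr$J + ref_free()$k_gl * tr$L
  expect_equal(trapz_oracle(tr$time, flux), D, tolerance = 1e-3)
  expect_equal(tr$absorbed[nrow(tr)], D, tolerance = 1e-4)
})

test_that("plasma appearance integrates to the bioavailable dose", {
  D <- ref_dose()
  free <- ref_free(); free$f <- 0.7
  tr <- simo_simulate(free, simo_fixed(), ref_basal(), D, 75,
                      times = seq(0, 3000, by = 1))
  ra <- glucose_ra(tr, free, simo_fixed(), 75)
  expect_equal(ra, tr$Ra)
  expect_equal(ra[1], 0)
  expect_true(all(ra >= 0))
  expect_equal(simo_fixed()$V * 75 * trapz_oracle(tr$time, ra), 0.7 * D,
               tolerance = 1e-3)
})

test_that("rate of appearance is proportional to the bioavailable fraction", {
  half <- ref_free(); half$f <- 0.5
  full <- ref_free(); full$f <- 1
  t_half <- simo_simulate(half, simo_fixed(), ref_basal(), ref_dose(), 75)
  t_full <- simo_simulate(full, simo_fixed(), ref_basal(), ref_dose(), 75)
  # gut kinetics are independent of f, so Ra scales exactly
  expect_equal(t_full$Ra[-1] / t_half$Ra[-1],
               rep(2, nrow(t_full) - 1), tolerance = 1e-9)
})

test_that("states stay non-negative across random parameter draws", {
  set.seed(7)
  for (rep in 1:15) {
    free <- simo_free(
      k_js = runif(1, 0.005, 0.1), k_gl = runif(1, 0.005, 0.08),
      k_xgi = runif(1, 5e-6, 3e-4), k_xi = runif(1, 0.02, 0.15),
      k_ig_max = runif(1, 15, 150), gamma = runif(1, 1, 10),
      lambda_1g = runif(1, 0.1, 1.5)
    )
    basal <- simo_basal(runif(1, 4, 9), runif(1, 25, 250))
    if (free$k_ig_max <= free$k_xi * basal$I_b) next
    tr <- simo_simulate(free, simo_fixed(), basal, ref_dose(),
                        runif(1, 55, 110))
    expect_true(all(as.matrix(tr[, c("S", "J", "R", "L", "G", "I")]) >= 0))
  }
})

test_that("higher insulin sensitivity strictly lowers incremental glucose AUC", {
  aucs <- vapply(c(2e-5, 5e-5, 1e-4, 2e-4), function(kx) {
    free <- ref_free(); free$k_xgi <- kx
    tr <- simo_simulate(free, simo_fixed(), ref_basal(), ref_dose(), 75,
                        times = seq(0, 180, by = 2))
    trapz_oracle(tr$time, tr$G - ref_basal()$G_b)
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("the two integration routes agree to 0.1%", {
  args <- list(ref_free(), simo_fixed(), ref_basal(), ref_dose(), 75)
  t1 <- do.call(simo_simulate, c(args, list(times = std_times())))
  t2 <- do.call(simo_simulate, c(args, list(times = std_times(),
                                            method = "lsoda")))
  expect_lt(max(abs(t1$G - t2$G) / t1$G), 1e-3)
  expect_lt(max(abs(t1$I - t2$I) / t1$I), 1e-3)
})

test_that("halving solver tolerances leaves the solution unchanged", {
  args <- list(ref_free(), simo_fixed(), ref_basal(), ref_dose(), 75)
  t1 <- do.call(simo_simulate, c(args, list(times = std_times())))
  t2 <- do.call(simo_simulate, c(args, list(times = std_times(),
                                            rtol = 5e-9, atol = 5e-11)))
  expect_lt(max(abs(t1$G - t2$G) / t1$G), 1e-3)
  expect_lt(max(abs(t1$I - t2$I) / t1$I), 1e-3)
})

test_that("parameter configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simo_config(path, free = ref_free(), basal = ref_basal())
  cfg <- read_simo_config(path)
  expect_equal(unclass(cfg$free), unclass(ref_free()))
  expect_equal(unclass(cfg$fixed), unclass(simo_fixed()))
  expect_equal(cfg$basal$G_b, ref_basal()$G_b)
})
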
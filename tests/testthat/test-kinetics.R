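test_that("velocity laws evaluate the reference constants correctly", {
  ldopa <- tyrosinase_kinetics("l-dopa")
  ltyr <- tyrosinase_kinetics("l-tyr")
  expect_equal(mm_velocity(ldopa, C_S = 0, C_E = 0.6), 0)
  # half-saturation identity
  expect_equal(mm_velocity(ldopa, C_S = ldopa$K_M, C_E = 0.6),
               ldopa$k_cat * 0.6 / 2)
  # direct evaluations
  expect_equal(mm_velocity(ldopa, 10, 0.6), 4.70, tolerance = 1e-3)
  expect_equal(mm_inhibited_velocity(ltyr, 10, 0.6), 0.351, tolerance = 1e-3)
  expect_error(mm_velocity(ldopa, -1, 0.6), "domain error")
  expect_error(mm_inhibited_velocity(ldopa, 1, 0.6), "no K_i")
})

test_that("substrate inhibition lowers the velocity and peaks at sqrt(K_M K_i)", {
  ltyr <- tyrosinase_kinetics("l-tyr")
  plain <- kinetic_params(ltyr$k_cat, ltyr$K_M)
  C_S <- seq(0.01, 20, by = 0.01)
  v_inh <- mm_inhibited_velocity(ltyr, C_S, 0.6)
  v_std <- mm_velocity(plain, C_S, 0.6)
  expect_true(all(v_inh < v_std))
  expect_equal(mm_inhibited_velocity(ltyr, 0, 0.6), mm_velocity(plain, 0, 0.6))
  # analytic argmax
  expect_equal(C_S[which.max(v_inh)], sqrt(ltyr$K_M * ltyr$K_i),
               tolerance = 2e-3)
  # K_i -> infinity recovers the standard law
  loose <- kinetic_params(ltyr$k_cat, ltyr$K_M, K_i = 1e12)
  expect_equal(mm_inhibited_velocity(loose, 10, 0.6),
               mm_velocity(plain, 10, 0.6), tolerance = 1e-9)
})

test_that("standard velocity is increasing and concave in substrate", {
  p <- tyrosinase_kinetics("cygggyc")
  C_S <- seq(0.1, 30, by = 0.1)
  v <- mm_velocity(p, C_S, 1)
  expect_true(all(diff(v) > 0))
  expect_true(all(diff(diff(v)) < 0))
})

test_that("high-substrate limit is linear in enzyme concentration", {
  p <- tyrosinase_kinetics("cygggyc")
  expect_equal(linear_limit_velocity(p, C_E = 3, C_S = 10), 1.8)
  expect_equal(linear_limit_velocity(p, C_E = 6, C_S = 10),
               2 * linear_limit_velocity(p, C_E = 3, C_S = 10))
  expect_equal(linear_limit_velocity(p, C_E = 0, C_S = 10), 0)
  expect_warning(linear_limit_velocity(p, C_E = 1, C_S = 1), "inaccurate")
  # the 10 mM assay concentration is at least ~10x K_M for every substrate
  for (s in c("l-tyr", "l-dopa", "cygggyc"))
    expect_gte(10 / tyrosinase_kinetics(s)$K_M, 9.8)
})

test_that("velocity extraction recovers slopes from time courses", {
  # perfectly linear signal
  tc <- time_course(0:19, 0.002 * (0:19), calibration_factor = 0.5)
  v <- velocity_from_timecourse(tc)
  expect_equal(as.numeric(v), 0.002 * 0.5 * 1000, tolerance = 1e-10)
  # constant signal: zero velocity
  tc0 <- time_course(0:9, rep(0.3, 10), calibration_factor = 1)
  expect_equal(as.numeric(velocity_from_timecourse(tc0)), 0)
  # saturating exponential: automatic window stays in the initial-rate region
  tcs <- simulate_timecourse(seq(0, 600, by = 5), A_inf = 1, tau = 300,
                             calibration_factor = 1)
  v_strict <- velocity_from_timecourse(tcs, r2_threshold = 0.9999)
  expect_equal(as.numeric(v_strict), attr(tcs, "true_rate_uM_s"),
               tolerance = 0.05)
  expect_lt(max(attr(v_strict, "window")), length(tcs$times))
  # the permissive default admits more curvature, biasing the slope low
  v_default <- velocity_from_timecourse(tcs)
  expect_lt(as.numeric(v_default), as.numeric(v_strict))
  expect_gt(as.numeric(v_default), 0.5 * attr(tcs, "true_rate_uM_s"))
  expect_error(time_course(c(0, 0, 1), 1:3, 1), "strictly increasing")
})

test_that("noiseless fits recover the generating constants to 1e-4 relative", {
  # substrate-inhibited truth (l-Tyr constants)
  ltyr <- tyrosinase_kinetics("l-tyr")
  d <- simulate_velocities(ltyr, mbth_substrate_levels, 0.6)
  fit <- fit_kinetics(d, model = "substrate_inhibited")
  expect_equal(fit$params$k_cat, ltyr$k_cat, tolerance = 1e-4)
  expect_equal(fit$params$K_M, ltyr$K_M, tolerance = 1e-4)
  expect_equal(fit$params$K_i, ltyr$K_i, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-9)
  # standard truth (peptide constants)
  pep <- tyrosinase_kinetics("cygggyc")
  d2 <- simulate_velocities(pep, mbth_substrate_levels, 0.6)
  fit2 <- fit_kinetics(d2, model = "standard")
  expect_equal(fit2$params$k_cat, pep$k_cat, tolerance = 1e-4)
  expect_equal(fit2$params$K_M, pep$K_M, tolerance = 1e-4)
})

test_that("automatic model selection distinguishes inhibited from standard data", {
  ltyr <- tyrosinase_kinetics("l-tyr")
  pep <- tyrosinase_kinetics("cygggyc")
  d_inh <- simulate_velocities(ltyr, mbth_substrate_levels, 0.6,
                               sd_frac = 0.02, replicates = 3, seed = 5)
  d_std <- simulate_velocities(pep, mbth_substrate_levels, 0.6,
                               sd_frac = 0.02, replicates = 3, seed = 5)
  expect_identical(fit_kinetics(d_inh, "auto")$model, "substrate_inhibited")
  expect_identical(fit_kinetics(d_std, "auto")$model, "standard")
})

test_that("noisy fits recover constants within 10 percent", {
  ltyr <- tyrosinase_kinetics("l-tyr")
  d <- simulate_velocities(ltyr, mbth_substrate_levels, 0.6,
                           sd_frac = 0.05, replicates = 3, seed = 42)
  fit <- fit_kinetics(d, model = "substrate_inhibited")
  expect_equal(fit$params$k_cat, ltyr$k_cat, tolerance = 0.1)
  expect_equal(fit$params$K_M, ltyr$K_M, tolerance = 0.1)
  expect_equal(fit$params$K_i, ltyr$K_i, tolerance = 0.1)
})

test_that("fit design errors are reported", {
  pep <- tyrosinase_kinetics("cygggyc")
  d3 <- simulate_velocities(pep, c(1, 2, 5), 0.6)
  expect_error(fit_kinetics(d3, "standard"), "design error")
  d4 <- simulate_velocities(pep, c(1, 2, 5, 10), 0.6)
  expect_error(fit_kinetics(d4, "substrate_inhibited"), "design error")
})

test_that("integrated rate law matches an independent ODE integration", {
  pep <- ref_kinetics()
  C_E <- 3; C_S0 <- 10
  # ODE oracle: dC_S/dt = -k_cat C_E C_S/(K_M + C_S) in mM, s
  deriv <- function(t, y, parms)
    list(-pep$k_cat * (C_E / 1000) * y / (pep$K_M + y))
  conv <- c(0.01, 0.1, 0.5, 0.9, 0.99, 0.999)
  t_closed <- vapply(conv, function(cv)
    integrated_mm_time(pep, C_E, C_S0, cv), 0)
  out <- deSolve::ode(C_S0, times = c(0, t_closed), deriv, NULL,
                      rtol = 1e-11, atol = 1e-12)
  C_ode <- out[-1, 2]
  expect_equal(C_ode, (1 - conv) * C_S0, tolerance = 1e-6)
})

test_that("integrated rate law has the correct limits and errors", {
  pep <- ref_kinetics()
  # conversion -> 0+: time -> 0
  expect_lt(integrated_mm_time(pep, 3, 10, 1e-9), 1e-2)
  # K_M -> 0: zero-order limit t = conversion C_S0/(k_cat C_E)
  z <- kinetic_params(0.6, 1e-12)
  expect_equal(integrated_mm_time(z, 3, 10, 0.5),
               0.5 * 10 / (0.6 * 3e-3), tolerance = 1e-6)
  expect_error(integrated_mm_time(pep, 3, 10, 1), "asymptote error")
})

test_that("conversion-time surface is exactly hyperbolic in enzyme", {
  pep <- ref_kinetics()
  surf <- conversion_time_surface(pep, c(0.3, 0.6, 1.5, 3), c(5, 10), 0.99)
  base <- surf$t_s[surf$C_E_uM == 3 & surf$C_S0_mM == 10]
  expect_equal(surf$t_s[surf$C_E_uM == 0.3 & surf$C_S0_mM == 10],
               10 * base, tolerance = 1e-12)
  expect_equal(surf$t_s[surf$C_E_uM == 1.5 & surf$C_S0_mM == 10],
               2 * base, tolerance = 1e-12)
  # single cell equals the scalar form
  one <- conversion_time_surface(pep, 3, 10, 0.99)
  expect_equal(one$t_s, integrated_mm_time(pep, 3, 10, 0.99))
})
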
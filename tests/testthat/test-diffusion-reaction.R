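ref_dr <- function(horizon = 8 * 3600, C_E0 = 3, D = NULL, ...) {
  if (is.null(D)) D <- stiffsim_constants()$D_gel_stiff
  dr_problem(slab_problem(1e-3, D, C_E0), ref_kinetics(), 10,
             coarse_grid(horizon), ...)
}

test_that("closed form starts at the exact initial state", {
  sol <- closed_form_fields(ref_dr(), "instantaneous")
  expect_equal(sol$substrate[, 1], rep(10, length(sol$x)), tolerance = 1e-9)
  expect_equal(sol$product[, 1], rep(0, length(sol$x)), tolerance = 1e-8)
})

test_that("no catalyst means no product", {
  sol <- closed_form_fields(ref_dr(C_E0 = 0), "integrated")
  expect_true(all(sol$product == 0))
  nr <- numeric_reference(ref_dr(C_E0 = 0))
  expect_true(all(nr$product < 1e-8))
})

test_that("zero turnover leaves the substrate untouched in the ODE oracle", {
  p <- dr_problem(slab_problem(1e-3, 3.58e-11, 3),
                  kinetic_params(1e-12, 0.58), 10, coarse_grid(3600))
  nr <- numeric_reference(p)
  expect_equal(nr$substrate, matrix(10, nrow(nr$substrate), ncol(nr$substrate)),
               tolerance = 1e-7)
})

test_that("substrate and product are conserved at every node and time", {
  for (mode in c("integrated", "instantaneous")) {
    sol <- closed_form_fields(ref_dr(), mode)
    expect_lt(max(abs(sol$substrate + sol$product - sol$C_S0)) / sol$C_S0,
              1e-9)
    expect_true(all(sol$product >= 0 & sol$product <= sol$C_S0))
  }
  nr <- numeric_reference(ref_dr())
  expect_lt(max(abs(nr$substrate + nr$product - nr$C_S0)) / nr$C_S0, 1e-9)
})

test_that("closed form (integrated exposure) matches the stiff-ODE oracle", {
  p <- ref_dr()
  cf <- closed_form_fields(p, "integrated")
  nr <- numeric_reference(p)
  expect_lt(max(abs(cf$product - nr$product)) / p$C_S0, 1e-4)
  # instantaneous-concentration exposure over-counts early enzyme, so the
  # instantaneous-exposure form bounds the exact product from above
  pap <- closed_form_fields(p, "instantaneous")
  expect_gte(min(pap$product - nr$product), -1e-4 * p$C_S0)
})

test_that("product fields are monotone in time and toward the surfaces", {
  sol <- closed_form_fields(ref_dr(), "integrated")
  dT <- t(apply(sol$product, 1, diff))
  expect_gte(min(dT), -1e-9)
  # distance-to-surface ordering on the left half at a mid-time
  jm <- ceiling(ncol(sol$product) / 3)
  left <- sol$product[sol$x <= 5e-4, jm]
  expect_gte(min(-diff(left)), -1e-9)
})

test_that("fast transport collapses to the well-mixed integrated law", {
  # the near-instant fill of the slab needs a fine exposure grid
  p <- ref_dr(D = 1e-6, horizon = 3 * 3600, n_fine = 6000L)
  cf <- closed_form_fields(p, "integrated")
  pep <- ref_kinetics()
  # well-mixed reference: constant C_E = C_E0 from t = 0
  t_ref <- vapply(p$times[-1], function(t) {
    # invert the integrated law numerically for C_S(t)
    f <- log(10 / pep$K_M) + (10 - (3 / 1000) * pep$k_cat * t) / pep$K_M
    pep$K_M * lambert_w_log(f)
  }, 0)
  err <- abs(cf$substrate[, -1] - matrix(t_ref, nrow = length(cf$x),
                                         ncol = length(t_ref), byrow = TRUE))
  expect_lt(max(err) / 10, 1e-3)
})

test_that("pre-equilibrated gel reaches 99 percent conversion at the closed-form time", {
  # constant enzyme field everywhere = bath concentration
  pep <- ref_kinetics()
  t99 <- integrated_mm_time(pep, 3, 10, 0.99)
  p <- dr_problem(slab_problem(1e-3, 1e-6, 3), pep, 10,
                  coarse_grid(9000), times = seq(0, 9000, by = 100))
  sol <- closed_form_fields(p, "integrated")
  s <- stiffening_summary(sol, 0.99)
  expect_equal(s$completion_s, t99, tolerance = 0.02)
})

test_that("product formation lags enzyme arrival at the center", {
  sol <- closed_form_fields(ref_dr(), "integrated")
  ic <- which.min(abs(sol$x - 5e-4))
  first_above <- function(v, thr) {
    j <- which(v >= thr)[1]
    sol$times[j]
  }
  t_E50 <- first_above(sol$enzyme[ic, ] / sol$C_E0, 0.5)
  t_P50 <- first_above(sol$product[ic, ] / sol$C_S0, 0.5)
  expect_gt(t_P50, t_E50)
})

test_that("slab-wide conversion summary peaks at the midplane and respects the horizon", {
  sol <- closed_form_fields(ref_dr(), "instantaneous")
  s <- stiffening_summary(sol, 0.95)
  expect_false(is.na(s$completion_s))
  expect_lte(s$completion_s, 8 * 3600)
  ic <- which.min(abs(sol$x - 5e-4))
  expect_equal(s$per_position$t_reach_s[ic], s$completion_s)
  # low threshold: reached at the first positive-product time everywhere
  s0 <- stiffening_summary(sol, 1e-6)
  expect_true(all(s0$per_position$t_reach_s <= s$per_position$t_reach_s))
  # threshold unreachable within a short horizon
  short <- closed_form_fields(ref_dr(horizon = 600), "integrated")
  expect_warning(sna <- stiffening_summary(short, 0.99), "horizon exceeded")
  expect_true(is.na(sna$completion_s))
})

test_that("closed form refuses inhibited kinetics but the oracle accepts them", {
  p_inh <- dr_problem(slab_problem(1e-3, 3.58e-11, 3),
                      tyrosinase_kinetics("l-tyr"), 10, coarse_grid(3600))
  expect_error(closed_form_fields(p_inh), "uninhibited")
  nr <- numeric_reference(p_inh)
  # inhibition slows conversion relative to the same constants without K_i
  p_no <- dr_problem(slab_problem(1e-3, 3.58e-11, 3),
                     kinetic_params(0.93, 0.85), 10, coarse_grid(3600))
  nr_no <- numeric_reference(p_no)
  expect_true(all(nr$product <= nr_no$product + 1e-9))
})
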
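test_that("mass swelling ratio is the swollen/dry mass quotient", {
  expect_equal(mass_swelling_ratio(10, 10), 1)
  expect_equal(mass_swelling_ratio(30, 1), 30)
  expect_equal(mass_swelling_ratio(27.5, 1), 27.5)
  expect_error(mass_swelling_ratio(5, 0), "invalid measurement")
  expect_error(mass_swelling_ratio(0.5, 1), "invalid measurement")
})

test_that("volumetric swelling ratio is the volume-additive conversion", {
  expect_equal(volumetric_swelling_ratio(1), 1)
  # hand-inverted closed form: 1 + (1.087/0.994)(q - 1) = Q
  expect_equal(volumetric_swelling_ratio(27.52), 30.0, tolerance = 1e-3)
  expect_equal(volumetric_swelling_ratio(16.55), 18.0, tolerance = 1e-3)
  expect_error(volumetric_swelling_ratio(0.9), "invalid input")
})

test_that("volumetric <-> mass swelling ratios round-trip", {
  for (Q in c(1, 1.5, 5, 18, 30, 100)) {
    q <- mass_swelling_from_volumetric(Q)
    expect_equal(volumetric_swelling_ratio(q), Q, tolerance = 1e-10)
  }
})

test_that("peptide molecular weight follows average residue masses", {
  expect_equal(crosslinker_mw_from_sequence("G"), 75.07, tolerance = 1e-4)
  expect_equal(crosslinker_mw_from_sequence("CYGGGYC"), 721.81,
               tolerance = 2e-4)
  expect_error(crosslinker_mw_from_sequence(""), "non-empty")
  expect_error(crosslinker_mw_from_sequence("GXZ"), "unknown residue")
})

test_that("crosslinker spec checks sequence-derived mass", {
  cl <- crosslinker_spec("CYGGGYC")
  expect_equal(cl$molecular_weight, 721.8, tolerance = 1e-3)
  expect_error(crosslinker_spec("CYGGGYC", molecular_weight = 800),
               "disagrees")
  expect_error(crosslinker_spec("G", functionality = 1), ">= 2")
})

test_that("molecular weight between crosslinks follows the step-growth formula", {
  Mc <- mw_between_crosslinks(macromer_spec(), crosslinker_spec("CYGGGYC"))
  expect_equal(Mc, 5721.8, tolerance = 1e-4)
  # symmetric linear crosslinkers: Mc = 2M
  sym <- mw_between_crosslinks(macromer_spec(number_average_mw = 1000,
                                             arm_functionality = 2),
                               crosslinker_spec(molecular_weight = 1000,
                                                functionality = 2))
  expect_equal(sym, 2000)
})

test_that("mesh size reproduces the stiff- and soft-gel values", {
  Mc <- 5721.8
  # derived check: 2.6207 * 1.47 * 39.50 Angstrom = 15.2 nm
  expect_equal(mesh_size(18, Mc), 15.2, tolerance = 2e-3)
  expect_equal(mesh_size(30, Mc), 18.0, tolerance = 3e-3)
  # Q = 1: no swelling factor
  expect_equal(mesh_size(1, Mc),
               1.47 * sqrt(3 * 4 * Mc / 44) / 10, tolerance = 1e-12)
  expect_error(mesh_size(-1, Mc), "invalid input")
})

test_that("mesh size is strictly increasing in Q and Mc", {
  set.seed(11)
  for (i in 1:25) {
    Q <- runif(1, 1, 50); Mc <- runif(1, 500, 20000)
    expect_gt(mesh_size(Q * 1.1, Mc), mesh_size(Q, Mc))
    expect_gt(mesh_size(Q, Mc * 1.1), mesh_size(Q, Mc))
  }
})

test_that("Lustig-Peppas diffusivity has the free-volume/obstruction form", {
  tr <- transport_spec()
  # derived: 5.05e-10 * (1 - 4.5/15.2) * exp(-1/17)
  expect_equal(lustig_peppas_diffusivity(tr, 15.2, 18), 3.35e-10,
               tolerance = 1e-3)
  # free-solution limit
  expect_equal(lustig_peppas_diffusivity(tr, 1e9, 1e9), tr$D_sol,
               tolerance = 1e-6)
  # size exclusion
  ex <- lustig_peppas_diffusivity(tr, tr$R_E_nm, 18)
  expect_identical(as.numeric(ex), 0)
  expect_true(isTRUE(attr(ex, "no_transport")))
})

test_that("Lustig-Peppas diffusivity is increasing in mesh size and Q, bounded by D_sol", {
  tr <- transport_spec()
  set.seed(12)
  for (i in 1:25) {
    xi <- runif(1, 5, 40); Q <- runif(1, 1.5, 60)
    D <- lustig_peppas_diffusivity(tr, xi, Q)
    expect_gte(D, 0); expect_lt(D, tr$D_sol)
    expect_gt(lustig_peppas_diffusivity(tr, xi * 1.2, Q), D)
    expect_gt(lustig_peppas_diffusivity(tr, xi, Q * 1.2), D)
  }
})

test_that("gel state keeps nu * Q = 1 exactly", {
  for (Q in c(1.2, 12, 18, 30, 36)) {
    gs <- gel_state(Q = Q, Mc = 5721.8)
    expect_identical(gs$nu * gs$Q, 1)
    expect_gte(gs$q, 1)
  }
})

test_that("calibration interpolation is linear with clamped extrapolation", {
  calib <- data.frame(G_prime_kPa = c(0.5, 5), Q = c(30, 18),
                      xi_nm = c(19, 15))
  exact <- gel_state_from_calibration(5, calib)
  expect_equal(exact$Q, 18); expect_equal(exact$xi_nm, 15)
  mid <- gel_state_from_calibration(2.75, calib)
  expect_equal(mid$Q, 24); expect_equal(mid$xi_nm, 17)
  expect_warning(low <- gel_state_from_calibration(0.1, calib), "clamping")
  expect_equal(low$Q, 30)
  expect_error(gel_state_from_calibration(1, calib[1, ]), "missing calibration")
})
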
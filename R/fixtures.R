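#' @title Synthetic data generators
#' @description Seeded generators emulating the package's experimental
#'   inputs: MBTH velocity observations, assay time courses, gravimetric
#'   swelling measurements, modulus-swelling records, and imaged
#'   concentration profiles. All randomness is multiplicative (or
#'   additive, for profiles) Gaussian noise, truncated at zero, and fully
#'   determined by `seed`; the caller's RNG state is left untouched.
#' @name fixtures
NULL

#' Synthetic Michaelis-Menten velocity observations
#'
#' V_P drawn as model(C_S, C_E) (1 + eps), eps ~ N(0, sd_frac), truncated
#' at 0, over the Cartesian design of substrate and enzyme levels. Uses
#' the substrate-inhibited law when `params` carries a `K_i`.
#'
#' @param params true [kinetic_params()].
#' @param C_S_mM substrate levels, mM.
#' @param C_E_uM enzyme levels, uM.
#' @param sd_frac multiplicative noise standard deviation (fraction of
#'   the true velocity; 0 = noiseless).
#' @param replicates replicate count per design point.
#' @param seed RNG seed (`NULL` = use current stream).
#' @param substrate optional substrate label column.
#' @return data.frame with columns `substrate`, `C_S_mM`, `C_E_uM`,
#'   `V_P_uM_per_s`, `replicate`.
#' @examples
#' simulate_velocities(tyrosinase_kinetics("l-tyr"),
#'                     C_S_mM = c(0.25, 0.5, 1, 2, 4, 6, 8, 10),
#'                     C_E_uM = 0.6, sd_frac = 0.05, replicates = 3,
#'                     seed = 7)
#' @export
simulate_velocities <- function(params, C_S_mM, C_E_uM, sd_frac = 0,
                                replicates = 1L, seed = NULL,
                                substrate = NA_character_) {
  stopifnot(inherits(params, "kinetic_params"))
  if (sd_frac < 0) stop("sd_frac must be >= 0")
  if (replicates < 1L) stop("replicates must be >= 1")
  design <- expand.grid(C_S_mM = C_S_mM, C_E_uM = C_E_uM,
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
  v_true <- reaction_velocity(params, design$C_S_mM, design$C_E_uM)
  v <- with_seed(seed, {
    if (sd_frac > 0) pmax(v_true * (1 + stats::rnorm(length(v_true), 0, sd_frac)), 0)
    else v_true
  })
  data.frame(substrate = substrate, C_S_mM = design$C_S_mM,
             C_E_uM = design$C_E_uM, V_P_uM_per_s = v,
             replicate = design$replicate)
}

#' Synthetic assay time course
#'
#' Saturating-exponential absorbance signal
#' A(t) = A_inf (1 - exp(-t/tau)) with additive Gaussian noise; the true
#' initial rate is A_inf/tau (absorbance/s).
#'
#' @param times observation times, s.
#' @param A_inf plateau absorbance.
#' @param tau exponential time constant, s.
#' @param sd additive noise standard deviation (absorbance units).
#' @param seed RNG seed.
#' @param calibration_factor mM per absorbance unit.
#' @return A [time_course()]; the true initial rate in uM/s is attached
#'   as attribute `true_rate_uM_s`.
#' @export
simulate_timecourse <- function(times, A_inf = 1, tau = 300, sd = 0,
                                seed = NULL, calibration_factor = 1) {
  signal <- A_inf * (1 - exp(-times / tau))
  signal <- with_seed(seed, {
    if (sd > 0) signal + stats::rnorm(length(times), 0, sd) else signal
  })
  tc <- time_course(times, signal, calibration_factor)
  attr(tc, "true_rate_uM_s") <- A_inf / tau * calibration_factor * 1000
  tc
}

#' Synthetic gravimetric swelling measurements
#'
#' Swollen/dry mass pairs around a true mass swelling ratio with
#' multiplicative noise on the swollen mass.
#'
#' @param n number of samples.
#' @param q_true true mass swelling ratio.
#' @param dry_mass_mg dry mass per sample, mg.
#' @param sd_frac multiplicative noise on the swollen mass.
#' @param seed RNG seed.
#' @return data.frame with columns `sample_id`, `swollen_mass_mg`,
#'   `dry_mass_mg`.
#' @export
simulate_swelling <- function(n = 4L, q_true = 27.5, dry_mass_mg = 1,
                              sd_frac = 0, seed = NULL) {
  swollen <- with_seed(seed, {
    base <- q_true * dry_mass_mg
    if (sd_frac > 0) pmax(base * (1 + stats::rnorm(n, 0, sd_frac)),
                          dry_mass_mg)
    else rep(base, n)
  })
  data.frame(sample_id = paste0("gel_", seq_len(n)),
             swollen_mass_mg = swollen, dry_mass_mg = dry_mass_mg)
}

#' Synthetic modulus-swelling records
#'
#' Records spanning the stiffening experiment's printed ranges
#' (G' ~1-4 kPa, Q ~36-12 across 0-3 uM enzyme) built from an exact
#' power law G' = prefactor nu^exponent with multiplicative noise on G'.
#'
#' @param enzyme_uM enzyme doses, uM (one record per dose).
#' @param Q volumetric swelling ratios at the doses (same length).
#' @param prefactor,exponent true power-law parameters.
#' @param sd_frac multiplicative noise on the modulus.
#' @param seed RNG seed.
#' @return data.frame with columns `Tyrase_uM`, `G_prime_kPa`, `Q`, `nu`.
#' @export
simulate_modulus_swelling <- function(enzyme_uM = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                                      Q = seq(36, 12, length.out = length(enzyme_uM)),
                                      prefactor = 2000, exponent = 1.95,
                                      sd_frac = 0, seed = NULL) {
  if (length(Q) != length(enzyme_uM))
    stop("enzyme_uM and Q must have equal length")
  nu <- 1 / Q
  G <- with_seed(seed, {
    base <- prefactor * nu^exponent
    if (sd_frac > 0) pmax(base * (1 + stats::rnorm(length(nu), 0, sd_frac)),
                          .Machine$double.eps)
    else base
  })
  data.frame(Tyrase_uM = enzyme_uM, G_prime_kPa = G, Q = Q, nu = nu)
}

#' Synthetic imaged concentration profile
#'
#' Samples the analytic slab profile on a spatial grid at one time, with
#' additive Gaussian noise, emulating fluorescence line profiles of the
#' infiltrating enzyme.
#'
#' @param problem a [slab_problem()] with constant diffusivity.
#' @param x positions, m.
#' @param t time, s.
#' @param sd additive noise standard deviation (concentration units).
#' @param seed RNG seed.
#' @return data.frame with columns `x_mm`, `t_h`, `C_over_C0`.
#' @export
simulate_profile <- function(problem, x, t, sd = 0, seed = NULL) {
  C <- analytic_profile(problem, x, t)
  C <- with_seed(seed, {
    if (sd > 0) C + stats::rnorm(length(C), 0, sd) else C
  })
  data.frame(x_mm = x * 1e3, t_h = t / 3600,
             C_over_C0 = as.numeric(C) / problem$surface_conc)
}
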
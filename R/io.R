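#' @title File input/output and run configuration
#' @description CSV readers for the package's tabular inputs, CSV/JSON
#'   writers for simulation and fit outputs, and a validated YAML run
#'   configuration for end-to-end simulations.
#' @name io
NULL

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

# numeric columns in fixed scientific notation, 9 significant digits,
# so golden-file comparisons are stable across platforms
.format_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.8e", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read velocity observations
#'
#' Expects columns `substrate`, `C_S_mM`, `C_E_uM`, `V_P_uM_per_s`,
#' `replicate` (only the three numeric columns are required).
#'
#' @param path CSV file path.
#' @return data.frame suitable for [fit_kinetics()].
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("C_S_mM", "C_E_uM", "V_P_uM_per_s"), "velocity table")
}

#' Read gravimetric swelling measurements
#'
#' Expects columns `sample_id`, `swollen_mass_mg`, `dry_mass_mg`.
#'
#' @param path CSV file path.
#' @return data.frame with an added `q` column (mass swelling ratio).
#' @export
read_swelling_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .require_cols(df, c("swollen_mass_mg", "dry_mass_mg"), "swelling table")
  df$q <- mass_swelling_ratio(df$swollen_mass_mg, df$dry_mass_mg)
  df
}

#' Read a modulus calibration table
#'
#' Expects columns `G_prime_kPa`, `Q`, `xi_nm`, for use with
#' [gel_state_from_calibration()].
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("G_prime_kPa", "Q", "xi_nm"), "calibration table")
}

#' Read modulus-swelling records
#'
#' Expects columns `Tyrase_uM`, `G_prime_kPa`, `Q`, for use with
#' [fit_power_law()].
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_modulus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("G_prime_kPa", "Q"), "modulus table")
}

#' Read an assay time course
#'
#' Expects columns `t_s`, `absorbance`.
#'
#' @param path CSV file path.
#' @param calibration_factor mM per absorbance unit.
#' @return A [time_course()].
#' @export
read_timecourse_csv <- function(path, calibration_factor) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .require_cols(df, c("t_s", "absorbance"), "time course")
  time_course(df$t_s, df$absorbance, calibration_factor)
}

#' Write a transport profile to CSV
#'
#' Long format with columns `x_mm`, `t_h`, `C_over_C0`.
#'
#' @param field a `concentration_field` from [fd_solve()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(field, path) {
  stopifnot(inherits(field, "concentration_field"))
  df <- expand.grid(x_mm = field$x * 1e3, t_h = field$times / 3600,
                    KEEP.OUT.ATTRS = FALSE)
  df$C_over_C0 <- as.numeric(field$C) / field$C0
  .format_csv(df, path)
}

#' Write coupled diffusion-reaction fields to CSV
#'
#' Long format with columns `x_mm`, `t_h`, `C_E_over_C0`, `C_S_mM`,
#' `C_P_mM`.
#'
#' @param sol a `dr_solution`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(sol, path) {
  stopifnot(inherits(sol, "dr_solution"))
  df <- expand.grid(x_mm = sol$x * 1e3, t_h = sol$times / 3600,
                    KEEP.OUT.ATTRS = FALSE)
  df$C_E_over_C0 <- as.numeric(sol$enzyme) / sol$C_E0
  df$C_S_mM <- as.numeric(sol$substrate)
  df$C_P_mM <- as.numeric(sol$product)
  .format_csv(df, path)
}

#' Write a kinetic fit as JSON
#'
#' @param fit a `kinetic_fit` from [fit_kinetics()].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  obj <- list(model = fit$model,
              k_cat = fit$params$k_cat, K_M_mM = fit$params$K_M,
              K_i_mM = fit$params$K_i,
              r_squared = fit$r_squared,
              std_errors = as.list(fit$std_errors),
              aicc = fit$aicc, n = fit$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.config_defaults <- function(constants = stiffsim_constants()) {
  list(
    geometry = list(h_mm = constants$slab_thickness_m * 1e3,
                    dx_um = 1, dt_s = 1),
    transport = list(D_m2_s = constants$D_gel_stiff,
                     C_E0_uM = constants$enzyme_conc_uM),
    kinetics = list(substrate = constants$crosslinker_sequence,
                    k_cat = NULL, K_M_mM = NULL, K_i_mM = NULL,
                    C_S0_mM = constants$substrate_conc_mM),
    simulation = list(hours = 8, exposure_mode = "integrated",
                      threshold = 0.95, n_times = 49),
    seed = NULL
  )
}

#' Load and validate a YAML run configuration
#'
#' Sections `geometry` (h_mm, dx_um, dt_s), `transport` (D_m2_s,
#' C_E0_uM), `kinetics` (either `substrate` naming a preset of
#' [tyrosinase_kinetics()], or explicit `k_cat`, `K_M_mM`, optional
#' `K_i_mM`; plus `C_S0_mM`), `simulation` (hours, exposure_mode,
#' threshold, n_times) and a top-level `seed`. Missing keys are filled
#' from the constants registry defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config` list with a resolved [kinetic_params()] in
#'   `$kinetics$params`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- .config_defaults()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(raw), setdiff(names(cfg), "seed"))) {
    bad <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
    if (length(bad))
      stop("config error: unknown key(s) in ", sec, ": ",
           paste(bad, collapse = ", "))
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  if ("seed" %in% names(raw)) cfg$seed <- raw$seed
  k <- cfg$kinetics
  params <- if (!is.null(k$k_cat)) {
    if (is.null(k$K_M_mM)) stop("config error: k_cat given without K_M_mM")
    kinetic_params(k$k_cat, k$K_M_mM, K_i = k$K_i_mM)
  } else {
    tyrosinase_kinetics(k$substrate)
  }
  cfg$kinetics$params <- params
  for (nm in c("h_mm", "dx_um", "dt_s"))
    stopifnot_scalar_pos(cfg$geometry[[nm]], nm)
  stopifnot_scalar_pos(cfg$transport$D_m2_s, "D_m2_s", strict = FALSE)
  stopifnot_scalar_pos(cfg$transport$C_E0_uM, "C_E0_uM", strict = FALSE)
  stopifnot_scalar_pos(cfg$kinetics$C_S0_mM, "C_S0_mM")
  stopifnot_scalar_pos(cfg$simulation$hours, "hours")
  if (!cfg$simulation$exposure_mode %in% c("integrated", "instantaneous"))
    stop("config error: exposure_mode must be 'integrated' or 'instantaneous'")
  if (cfg$simulation$threshold <= 0 || cfg$simulation$threshold >= 1)
    stop("config error: threshold must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Run a full stiffening simulation from a configuration
#'
#' Builds the slab problem and grid from a [load_run_config()] result,
#' solves the coupled fields in the configured exposure mode, and
#' summarizes per-position conversion times at the configured threshold.
#'
#' @param config a `run_config`.
#' @return List with `solution` (a `dr_solution`), `summary`
#'   ([stiffening_summary()] output) and the `config` (seed included).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  g <- config$geometry
  slab <- slab_problem(g$h_mm * 1e-3, config$transport$D_m2_s,
                       config$transport$C_E0_uM)
  grid <- grid1d(dx = g$dx_um * 1e-6, dt = g$dt_s,
                 horizon = config$simulation$hours * 3600)
  times <- seq(0, grid$horizon, length.out = config$simulation$n_times)
  prob <- dr_problem(slab, config$kinetics$params, config$kinetics$C_S0_mM,
                     grid, times = times)
  sol <- closed_form_fields(prob, exposure_mode = config$simulation$exposure_mode)
  summ <- stiffening_summary(sol, config$simulation$threshold)
  list(solution = sol, summary = summ, config = config)
}
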
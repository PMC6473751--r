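#' @title Michaelis-Menten enzyme kinetics
#' @description Velocity laws with and without substrate inhibition,
#'   slope-based velocity extraction from assay time courses, nonlinear
#'   least-squares fitting of kinetic constants, and the integrated rate
#'   law used for conversion-time estimates.
#' @name enzyme_kinetics
NULL

#' Kinetic constants
#'
#' @param k_cat turnover number, 1/s.
#' @param K_M Michaelis constant, mM.
#' @param K_i substrate-inhibition constant, mM, or `NULL` for an
#'   uninhibited reaction.
#' @return A `kinetic_params` object.
#' @examples
#' kinetic_params(0.60, 0.58)
#' kinetic_params(0.93, 0.85, K_i = 19.85)
#' @export
kinetic_params <- function(k_cat, K_M, K_i = NULL) {
  stopifnot_scalar_pos(k_cat, "k_cat")
  stopifnot_scalar_pos(K_M, "K_M")
  if (!is.null(K_i)) stopifnot_scalar_pos(K_i, "K_i")
  structure(list(k_cat = k_cat, K_M = K_M, K_i = K_i),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic constants: k_cat = %.4g /s, K_M = %.4g mM",
              x$k_cat, x$K_M))
  if (!is.null(x$K_i)) cat(sprintf(", K_i = %.4g mM", x$K_i))
  cat("\n")
  invisible(x)
}

.check_conc <- function(C_S, C_E) {
  if (any(C_S < 0) || any(C_E < 0))
    stop("domain error: concentrations must be >= 0")
}

#' Standard Michaelis-Menten velocity
#'
#' V_P = k_cat C_E C_S / (K_M + C_S). Any `K_i` on `params` is ignored.
#'
#' @param params [kinetic_params()].
#' @param C_S substrate concentration, mM.
#' @param C_E enzyme concentration, uM.
#' @return Product formation velocity, uM/s.
#' @examples
#' mm_velocity(tyrosinase_kinetics("l-dopa"), C_S = 10, C_E = 0.6)
#' @export
mm_velocity <- function(params, C_S, C_E) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_conc(C_S, C_E)
  params$k_cat * C_E * C_S / (params$K_M + C_S)
}

#' Substrate-inhibited Michaelis-Menten velocity
#'
#' V_P = k_cat C_E C_S / (K_M + C_S (1 + C_S/K_i)); unimodal in C_S with
#' its maximum at C_S = sqrt(K_M K_i).
#'
#' @inheritParams mm_velocity
#' @return Product formation velocity, uM/s.
#' @examples
#' mm_inhibited_velocity(tyrosinase_kinetics("l-tyr"), C_S = 10, C_E = 0.6)
#' @export
mm_inhibited_velocity <- function(params, C_S, C_E) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$K_i))
    stop("params carries no K_i; use mm_velocity()")
  .check_conc(C_S, C_E)
  params$k_cat * C_E * C_S /
    (params$K_M + C_S * (1 + C_S / params$K_i))
}

#' Velocity under the matching rate law
#'
#' Dispatches to [mm_inhibited_velocity()] when `params` carries a `K_i`,
#' otherwise to [mm_velocity()].
#'
#' @inheritParams mm_velocity
#' @return Product formation velocity, uM/s.
#' @export
reaction_velocity <- function(params, C_S, C_E) {
  if (is.null(params$K_i)) mm_velocity(params, C_S, C_E)
  else mm_inhibited_velocity(params, C_S, C_E)
}

#' High-substrate (linear) limit of the velocity
#'
#' For C_S >> K_M the Michaelis constant drops out and the velocity is
#' linear in enzyme concentration: k_cat C_E without inhibition, or
#' k_cat C_E / (1 + C_S/K_i) with substrate inhibition. A warning is
#' issued when C_S < 10 K_M, where the approximation degrades.
#'
#' @inheritParams mm_velocity
#' @return Velocity, uM/s (linear in `C_E`).
#' @examples
#' linear_limit_velocity(tyrosinase_kinetics("cygggyc"), C_E = 3, C_S = 10)
#' @export
linear_limit_velocity <- function(params, C_E, C_S) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_conc(C_S, C_E)
  if (any(C_S < 10 * params$K_M))
    warning("C_S < 10 K_M: the linear (K_M-free) limit is inaccurate")
  if (is.null(params$K_i)) params$k_cat * C_E
  else params$k_cat * C_E / (1 + C_S / params$K_i)
}

#' Assay time course
#'
#' @param times observation times, s, strictly increasing, >= 3 points.
#' @param signal absorbance readings.
#' @param calibration_factor mM of product per absorbance unit.
#' @return A `time_course` object.
#' @export
time_course <- function(times, signal, calibration_factor) {
  if (length(times) < 3L || length(signal) != length(times))
    stop("need >= 3 (time, signal) pairs of equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  stopifnot_scalar_pos(calibration_factor, "calibration_factor")
  structure(list(times = times, signal = signal,
                 calibration_factor = calibration_factor),
            class = "time_course")
}

#' Initial reaction velocity from an assay time course
#'
#' Ordinary least-squares slope of signal versus time over a window,
#' scaled by the calibration factor (result in uM/s given the factor in
#' mM per absorbance unit and times in s; 1 mM/s = 1000 uM/s).
#' With `window = "auto"` the longest initial segment (>= `min_points`
#' points) whose linear fit has R^2 >= `r2_threshold` is used, so that
#' only the initial-rate region of a saturating curve contributes. The
#' threshold bounds the curvature bias: for a saturating-exponential
#' signal the slope underestimates the true initial rate by roughly
#' sqrt(15 (1 - R^2)), so the default 0.99 tolerates ~10-30 percent bias
#' (appropriate for noisy assay data, where stricter thresholds reject
#' every window); tighten to 0.9999 for smooth curves when the initial
#' rate must be recovered to a few percent.
#'
#' @param tc a [time_course()].
#' @param window `"auto"`, or an integer index range into the time course.
#' @param min_points minimum window length for automatic selection.
#' @param r2_threshold minimum linear-fit R^2 for automatic selection.
#' @return Velocity in uM/s, with the chosen window indices as attribute
#'   `window` and the slope R^2 as attribute `r_squared`.
#' @export
velocity_from_timecourse <- function(tc, window = "auto", min_points = 4L,
                                     r2_threshold = 0.99) {
  stopifnot(inherits(tc, "time_course"))
  slope_r2 <- function(idx) {
    x <- tc$times[idx]; y <- tc$signal[idx]
    if (length(unique(x)) < 2L) stop("singular fit: times are all equal")
    fit <- stats::lm.fit(cbind(1, x), y)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot <= .Machine$double.eps * sum(y^2) || ss_res < 1e-30) 1
          else 1 - ss_res / ss_tot
    list(slope = fit$coefficients[2], r2 = r2)
  }
  n <- length(tc$times)
  if (identical(window, "auto")) {
    min_points <- max(3L, as.integer(min_points))
    best <- NULL
    for (m in seq(min(min_points, n), n)) {
      fit <- slope_r2(seq_len(m))
      if (fit$r2 >= r2_threshold) best <- list(idx = seq_len(m), fit = fit)
      else if (!is.null(best)) break
    }
    if (is.null(best)) best <- list(idx = seq_len(min(min_points, n)),
                                    fit = slope_r2(seq_len(min(min_points, n))))
    idx <- best$idx; fit <- best$fit
  } else {
    idx <- as.integer(window)
    if (length(idx) < 3L) stop("window must contain >= 3 points")
    fit <- slope_r2(idx)
  }
  v <- unname(fit$slope) * tc$calibration_factor * 1000  # mM/s -> uM/s
  structure(v, window = idx, r_squared = fit$r2)
}

# small-sample-corrected Akaike criterion for a Gaussian LS fit
.aicc <- function(rss, n, k) {
  # k model parameters + 1 for the noise variance
  p <- k + 1
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1e-9)
}

#' Fit Michaelis-Menten constants to velocity observations
#'
#' Nonlinear least squares on velocities (unweighted) for the standard
#' model V = k_cat C_E C_S/(K_M + C_S) or the substrate-inhibited model
#' V = k_cat C_E C_S/(K_M + C_S(1 + C_S/K_i)). Initial guesses:
#' k_cat from the largest observed V/C_E, K_M from the substrate level
#' nearest half-maximal velocity, K_i at ten times the largest substrate
#' level. `model = "auto"` fits both and picks the lower small-sample
#' corrected Akaike criterion.
#'
#' @param data data.frame with columns `C_S_mM`, `C_E_uM`,
#'   `V_P_uM_per_s` (a `replicate` column is allowed and ignored).
#' @param model `"standard"`, `"substrate_inhibited"`, or `"auto"`.
#' @return A `kinetic_fit` with elements `params` ([kinetic_params()]),
#'   `r_squared`, `std_errors`, `model`, `aicc`, `fit` (the underlying
#'   `nls` object) and `n`.
#' @examples
#' d <- simulate_velocities(tyrosinase_kinetics("cygggyc"),
#'                          C_S_mM = c(0.25, 0.5, 1, 2, 4, 6, 8, 10),
#'                          C_E_uM = 0.6)
#' fit_kinetics(d, model = "standard")$params
#' @export
fit_kinetics <- function(data, model = c("auto", "standard",
                                         "substrate_inhibited")) {
  model <- match.arg(model)
  need <- c("C_S_mM", "C_E_uM", "V_P_uM_per_s")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  d <- data.frame(C_S = data$C_S_mM, C_E = data$C_E_uM,
                  V = data$V_P_uM_per_s)
  d <- d[d$C_S > 0 & d$C_E > 0, ]
  n_levels <- length(unique(d$C_S))
  fit_one <- function(which_model) {
    if (which_model == "standard" && n_levels < 4L)
      stop("design error: need >= 4 distinct substrate levels")
    if (which_model == "substrate_inhibited" && n_levels < 5L)
      stop("design error: need >= 5 distinct substrate levels for inhibition")
    kcat0 <- max(d$V / d$C_E)
    half <- d$C_S[which.min(abs(d$V - max(d$V) / 2))]
    KM0 <- max(half, min(d$C_S) / 2, 1e-6)
    ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
    fit <- if (which_model == "standard") {
      minpack.lm::nlsLM(V ~ k_cat * C_E * C_S / (K_M + C_S), data = d,
                        start = list(k_cat = kcat0, K_M = KM0),
                        lower = c(1e-12, 1e-12), control = ctrl)
    } else {
      Ki0 <- 10 * max(d$C_S)
      minpack.lm::nlsLM(V ~ k_cat * C_E * C_S /
                          (K_M + C_S * (1 + C_S / K_i)), data = d,
                        start = list(k_cat = kcat0, K_M = KM0, K_i = Ki0),
                        lower = c(1e-12, 1e-12, 1e-12), control = ctrl)
    }
    cf <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((d$V - mean(d$V))^2)
    r2 <- if (ss_tot > 0) max(0, min(1, 1 - rss / ss_tot)) else 1
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, length(cf)))
    params <- kinetic_params(cf[["k_cat"]], cf[["K_M"]],
                             K_i = if ("K_i" %in% names(cf)) cf[["K_i"]])
    structure(list(params = params, r_squared = r2, std_errors = se,
                   model = which_model,
                   aicc = .aicc(max(rss, 1e-300), nrow(d), length(cf)),
                   fit = fit, n = nrow(d)),
              class = "kinetic_fit")
  }
  if (model != "auto") return(fit_one(model))
  std <- fit_one("standard")
  inh <- tryCatch(fit_one("substrate_inhibited"), error = function(e) NULL)
  if (is.null(inh) || std$aicc <= inh$aicc) std else inh
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%s model, n = %d)\n", x$model, x$n))
  print(x$params)
  cat(sprintf("  R^2 = %.4f, AICc = %.2f\n", x$r_squared, x$aicc))
  invisible(x)
}

#' Time to a given substrate conversion (integrated rate law)
#'
#' Closed form of the integrated Michaelis-Menten law with constant
#' enzyme concentration:
#' t = (K_M ln(C_S0/C_S) + (C_S0 - C_S)) / (k_cat C_E),
#' with C_S = (1 - conversion) C_S0.
#'
#' @param params [kinetic_params()] (any `K_i` is ignored: the integrated
#'   law has no closed form under substrate inhibition).
#' @param C_E_uM enzyme concentration, uM.
#' @param C_S0_mM initial substrate concentration, mM.
#' @param conversion target conversion fraction, in (0, 1).
#' @return Time, s.
#' @examples
#' # ~2 h for near-complete conversion of 10 mM peptide at 3 uM enzyme
#' integrated_mm_time(tyrosinase_kinetics("cygggyc"), 3, 10, 0.99) / 3600
#' @export
integrated_mm_time <- function(params, C_E_uM, C_S0_mM, conversion) {
  stopifnot(inherits(params, "kinetic_params"))
  stopifnot_scalar_pos(C_E_uM, "C_E_uM")
  stopifnot_scalar_pos(C_S0_mM, "C_S0_mM")
  if (any(conversion <= 0)) stop("conversion must be > 0")
  if (any(conversion >= 1))
    stop("asymptote error: conversion must be < 1 (full conversion takes infinite time)")
  C_S <- (1 - conversion) * C_S0_mM
  C_E_mM <- C_E_uM / 1000
  (params$K_M * log(C_S0_mM / C_S) + (C_S0_mM - C_S)) /
    (params$k_cat * C_E_mM)
}

#' Conversion-time surface over enzyme and substrate grids
#'
#' [integrated_mm_time()] evaluated on the Cartesian product of enzyme
#' and initial-substrate levels; the time is exactly hyperbolic (1/C_E)
#' in enzyme concentration.
#'
#' @inheritParams integrated_mm_time
#' @param C_E_uM vector of enzyme concentrations, uM.
#' @param C_S0_mM vector of initial substrate concentrations, mM.
#' @return data.frame with columns `C_E_uM`, `C_S0_mM`, `t_s`, `t_h`.
#' @export
conversion_time_surface <- function(params, C_E_uM, C_S0_mM, conversion) {
  if (!length(C_E_uM) || !length(C_S0_mM)) stop("grids must be nonempty")
  grid <- expand.grid(C_E_uM = C_E_uM, C_S0_mM = C_S0_mM,
                      KEEP.OUT.ATTRS = FALSE)
  grid$t_s <- mapply(function(e, s)
    integrated_mm_time(params, e, s, conversion), grid$C_E_uM, grid$C_S0_mM)
  grid$t_h <- grid$t_s / 3600
  grid
}
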
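#' @title Coupled enzyme transport and substrate conversion
#' @description One-way coupling of slab enzyme transport with
#'   Michaelis-Menten conversion of the network-immobilized tyrosine
#'   substrate: the transported enzyme field drives a local (per-position)
#'   integrated rate law whose substrate trajectory has a Lambert-W closed
#'   form, with an independent stiff-ODE reference solution.
#' @name diffusion_reaction
NULL

#' Coupled diffusion-reaction problem
#'
#' @param slab a [slab_problem()] for the enzyme; `surface_conc` is read
#'   in uM.
#' @param kinetics [kinetic_params()] of the immobilized substrate
#'   (uninhibited for the closed form).
#' @param C_S0_mM initial, spatially uniform, immobile substrate
#'   concentration, mM.
#' @param grid a [grid1d()]: `dx` sets the reaction-field nodes, `dt` the
#'   transport step when finite differences are needed, `horizon` the
#'   simulated time.
#' @param times output times, s (default 49 evenly spaced including 0).
#' @param n_fine number of sub-intervals of the fine time grid used for
#'   the enzyme-exposure integral (default 600).
#' @return A `dr_problem` object.
#' @examples
#' dr_problem(slab_problem(1e-3, 3.58e-11, 3),
#'            tyrosinase_kinetics("cygggyc"), 10,
#'            grid1d(dx = 2e-5, dt = 10, horizon = 8 * 3600))
#' @export
dr_problem <- function(slab, kinetics, C_S0_mM, grid, times = NULL,
                       n_fine = 600L) {
  stopifnot(inherits(slab, "slab_problem"),
            inherits(kinetics, "kinetic_params"),
            inherits(grid, "grid1d"))
  stopifnot_scalar_pos(C_S0_mM, "C_S0_mM")
  if (is.null(times))
    times <- seq(0, grid$horizon, length.out = 49L)
  if (any(times < 0) || any(times > grid$horizon))
    stop("output times must lie in [0, horizon]")
  times <- sort(unique(times))
  structure(list(slab = slab, kinetics = kinetics, C_S0 = C_S0_mM,
                 grid = grid, times = times, n_fine = as.integer(n_fine)),
            class = "dr_problem")
}

# enzyme field (uM) at nodes x and fine times tf; analytic when D constant
.enzyme_field <- function(p) {
  slab <- p$slab; grid <- p$grid
  h <- slab$thickness
  x <- seq(0, h, by = grid$dx)
  if (abs(x[length(x)] - h) > grid$dx * 1e-6)
    stop("grid error: dx must divide the thickness")
  tf <- sort(unique(c(p$times, seq(0, grid$horizon, length.out = p$n_fine + 1L))))
  if (is.function(slab$diffusivity)) {
    # snap fine times to the transport step
    steps <- sort(unique(round(tf / grid$dt)))
    tf <- steps * grid$dt
    field <- fd_solve(slab, grid, times = tf)
    # FD may run on its own dx; re-use its nodes if they match, else interp
    if (length(field$x) != length(x) || max(abs(field$x - x)) > grid$dx * 1e-6) {
      E <- apply(field$C, 2, function(col) stats::approx(field$x, col, x)$y)
    } else E <- field$C
  } else {
    E <- analytic_profile(slab, x, tf)
    E <- matrix(E, nrow = length(x), ncol = length(tf))
  }
  list(x = x, tf = tf, E = E)
}

# cumulative trapezoidal exposure integral int_0^t C_E dtau (uM s)
.exposure <- function(tf, E) {
  X <- matrix(0, nrow = nrow(E), ncol = ncol(E))
  if (ncol(E) > 1L)
    for (k in 2:ncol(E))
      X[, k] <- X[, k - 1L] + 0.5 * (E[, k - 1L] + E[, k]) * (tf[k] - tf[k - 1L])
  X
}

.dr_solution <- function(p, x, times, E_out, C_S, method, exposure_mode) {
  C_S <- pmin(pmax(C_S, 0), p$C_S0)
  structure(list(x = x, times = times, enzyme = E_out,
                 substrate = C_S, product = p$C_S0 - C_S,
                 C_S0 = p$C_S0, C_E0 = p$slab$surface_conc,
                 method = method, exposure_mode = exposure_mode),
            class = "dr_solution")
}

#' Closed-form substrate and product fields (Lambert W)
#'
#' Per position x, the integrated Michaelis-Menten law gives
#' C_S(x,t) = K_M W(f(x,t)) with
#' f = (C_S0/K_M) exp((C_S0 - X(x,t) k_cat)/K_M), where the enzyme
#' exposure X is either C_E(x,t) t (`exposure_mode = "instantaneous"`, the
#' instantaneous concentration times elapsed time) or the exact
#' quasi-static integral int_0^t C_E dtau (`"integrated"`, the default).
#' The two coincide once the gel has equilibrated with the bath;
#' `"integrated"` is exact for a time-varying enzyme field. Evaluation is
#' overflow-safe (log-space Lambert W).
#'
#' @param p a [dr_problem()].
#' @param exposure_mode `"integrated"` or `"instantaneous"`.
#' @return A `dr_solution` with matrices `enzyme` (uM), `substrate` and
#'   `product` (mM) over nodes x and the output times.
#' @examples
#' p <- dr_problem(slab_problem(1e-3, 3.58e-11, 3),
#'                 tyrosinase_kinetics("cygggyc"), 10,
#'                 grid1d(dx = 5e-5, dt = 10, horizon = 4 * 3600))
#' sol <- closed_form_fields(p)
#' max(sol$product)
#' @export
closed_form_fields <- function(p, exposure_mode = c("integrated", "instantaneous")) {
  stopifnot(inherits(p, "dr_problem"))
  exposure_mode <- match.arg(exposure_mode)
  if (!is.null(p$kinetics$K_i))
    stop("closed form requires uninhibited kinetics (no K_i)")
  ef <- .enzyme_field(p)
  jout <- vapply(p$times, function(t) which.min(abs(ef$tf - t)), 1L)
  K_M <- p$kinetics$K_M; k_cat <- p$kinetics$k_cat; C_S0 <- p$C_S0
  if (exposure_mode == "integrated") {
    X <- .exposure(ef$tf, ef$E)[, jout, drop = FALSE]
  } else {
    X <- sweep(ef$E[, jout, drop = FALSE], 2, ef$tf[jout], `*`)
  }
  X_mMs <- X / 1000  # uM s -> mM s
  log_f <- log(C_S0 / K_M) + (C_S0 - X_mMs * k_cat) / K_M
  C_S <- K_M * matrix(lambert_w_log(log_f), nrow = nrow(log_f))
  .dr_solution(p, ef$x, ef$tf[jout], ef$E[, jout, drop = FALSE], C_S,
               "closed_form", exposure_mode)
}

#' Numerical reference solution (stiff ODE per node)
#'
#' Independent oracle for the closed form: integrates
#' dC_S/dt = -k_cat C_E(x,t) C_S / (K_M + C_S (1 + C_S/K_i)) at every
#' node with `deSolve`, interpolating the transported enzyme field in
#' time. The enzyme is a catalyst (not consumed) and the substrate is
#' network-bound (no substrate diffusion). The inhibition term is present
#' only when the kinetics carry a `K_i`.
#'
#' @param p a [dr_problem()].
#' @param rtol,atol integrator tolerances.
#' @return A `dr_solution` (method `"numeric_reference"`).
#' @export
numeric_reference <- function(p, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "dr_problem"))
  ef <- .enzyme_field(p)
  tf <- ef$tf; E <- ef$E
  K_M <- p$kinetics$K_M; k_cat <- p$kinetics$k_cat; K_i <- p$kinetics$K_i
  E_at <- function(t) {
    j <- findInterval(t, tf, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(tf) - 1L)
    w <- (t - tf[j]) / (tf[j + 1L] - tf[j])
    (1 - w) * E[, j] + w * E[, j + 1L]
  }
  deriv <- function(t, y, parms) {
    CE_mM <- E_at(t) / 1000
    denom <- if (is.null(K_i)) K_M + y else K_M + y * (1 + y / K_i)
    list(-k_cat * CE_mM * y / denom)
  }
  y0 <- rep(p$C_S0, length(ef$x))
  out <- deSolve::ode(y = y0, times = p$times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("solver error: stiff ODE integration failed")
  C_S <- t(unname(out[, -1, drop = FALSE]))
  jout <- vapply(p$times, function(t) which.min(abs(tf - t)), 1L)
  .dr_solution(p, ef$x, p$times, E[, jout, drop = FALSE], C_S,
               "numeric_reference", NA_character_)
}

#' @export
print.dr_solution <- function(x, ...) {
  cat(sprintf("Diffusion-reaction solution (%s%s)\n", x$method,
              if (!is.na(x$exposure_mode))
                paste0(", exposure ", x$exposure_mode) else ""))
  cat(sprintf("  %d nodes x %d times up to %.3g h\n",
              length(x$x), length(x$times), max(x$times) / 3600))
  cat(sprintf("  final conversion: %.1f%% (center), %.1f%% (slab mean)\n",
              100 * x$product[which.min(abs(x$x - max(x$x) / 2)),
                              length(x$times)] / x$C_S0,
              100 * mean(x$product[, length(x$times)]) / x$C_S0))
  invisible(x)
}

#' Per-position conversion times and slab completion time
#'
#' For each position, the first time at which the product fraction
#' C_P/C_S0 reaches `threshold` (linear interpolation between stored
#' times); the slab-wide completion time is the maximum over positions,
#' attained at the midplane by symmetry.
#'
#' @param sol a `dr_solution`.
#' @param threshold product fraction in (0, 1).
#' @return List with `per_position` (data.frame `x_m`, `t_reach_s`; `NA`
#'   where the threshold is not reached within the horizon) and
#'   `completion_s` (`NA` if any position never reaches it).
#' @export
stiffening_summary <- function(sol, threshold) {
  stopifnot(inherits(sol, "dr_solution"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  frac <- sol$product / sol$C_S0
  t_reach <- apply(frac, 1, function(f) {
    j <- which(f >= threshold)[1]
    if (is.na(j)) return(NA_real_)
    if (j == 1L) return(sol$times[1])
    t0 <- sol$times[j - 1L]; t1 <- sol$times[j]
    f0 <- f[j - 1L]; f1 <- f[j]
    t0 + (threshold - f0) / (f1 - f0) * (t1 - t0)
  })
  completion <- if (anyNA(t_reach)) NA_real_ else max(t_reach)
  if (is.na(completion))
    warning("horizon exceeded: threshold not reached at every position")
  list(per_position = data.frame(x_m = sol$x, t_reach_s = t_reach),
       completion_s = completion)
}
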
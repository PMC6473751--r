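#' @title One-dimensional enzyme transport into a slab
#' @description Fickian diffusion of enzyme into a thin hydrogel slab held
#'   between two well-stirred reservoirs at constant concentration, solved
#'   analytically (Fourier series) for constant diffusivity and by a
#'   Crank-Nicolson finite-difference scheme for general (space/time
#'   varying) diffusivity.
#' @name diffusion1d
NULL

#' Slab transport problem
#'
#' Bi-directional diffusion into a slab of thickness `h` with both faces
#' held at the bath concentration and an enzyme-free interior at t = 0.
#'
#' @param thickness slab thickness h, m.
#' @param diffusivity either a single non-negative number (m^2/s) or a
#'   function `D(x, t)` returning the local diffusivity (vectorized in x).
#' @param surface_conc bath concentration C_E0 (any concentration unit;
#'   fields are reported in the same unit).
#' @param initial_conc uniform interior concentration at t = 0 (default 0).
#' @return A `slab_problem` object.
#' @examples
#' slab_problem(1e-3, 3.58e-11, surface_conc = 3)
#' @export
slab_problem <- function(thickness, diffusivity, surface_conc,
                         initial_conc = 0) {
  stopifnot_scalar_pos(thickness, "thickness")
  if (is.function(diffusivity)) {
    probe <- diffusivity(c(0, thickness / 2, thickness), 0)
    if (any(!is.finite(probe)) || any(probe < 0))
      stop("physics error: diffusivity function must be finite and >= 0")
  } else {
    stopifnot_scalar_pos(diffusivity, "diffusivity", strict = FALSE)
  }
  stopifnot_scalar_pos(surface_conc, "surface_conc", strict = FALSE)
  stopifnot_scalar_pos(initial_conc, "initial_conc", strict = FALSE)
  structure(list(thickness = thickness, diffusivity = diffusivity,
                 surface_conc = surface_conc, initial_conc = initial_conc),
            class = "slab_problem")
}

#' Space-time grid for the slab solver
#'
#' @param dx spatial step, m (default 1 um).
#' @param dt temporal step, s (default 1 s).
#' @param horizon total simulated time, s.
#' @return A `grid1d` object.
#' @examples
#' grid1d(dx = 1e-6, dt = 1, horizon = 6 * 3600)
#' @export
grid1d <- function(dx = 1e-6, dt = 1, horizon) {
  stopifnot_scalar_pos(dx, "dx")
  stopifnot_scalar_pos(dt, "dt")
  stopifnot_scalar_pos(horizon, "horizon")
  if (horizon < dt) stop("grid error: horizon must be >= dt")
  structure(list(dx = dx, dt = dt, horizon = horizon), class = "grid1d")
}

#' Analytic Fourier-series concentration profile (constant diffusivity)
#'
#' Series solution of dC/dt = D d2C/dx2 on 0 <= x <= h with C(x,0) = C_i
#' in the interior and C = C_E0 at both faces:
#' C/C_E0 = 1 - (4/pi) sum_n exp(-D (2n+1)^2 pi^2 t / h^2)
#'          sin((2n+1) pi x / h) / (2n+1)
#' (generalized to a non-zero initial concentration). The series is
#' truncated when a term's amplitude falls below `tol` times the
#' concentration scale; at exactly t = 0 the initial condition is returned
#' without summation to avoid Gibbs artifacts.
#'
#' @param problem a [slab_problem()] with constant (numeric) diffusivity.
#' @param x positions, m, within [0, h].
#' @param t times, s, >= 0.
#' @param tol relative truncation tolerance (default 1e-12).
#' @param max_terms series term cap (default 10000).
#' @return Matrix of concentrations, `length(x)` rows by `length(t)`
#'   columns (dropped to a vector/scalar when either has length 1).
#' @examples
#' p <- slab_problem(1e-3, 3.58e-11, 1)
#' analytic_profile(p, x = 5e-4, t = 7200)  # ~0.90
#' @export
analytic_profile <- function(problem, x, t, tol = 1e-12, max_terms = 10000) {
  stopifnot(inherits(problem, "slab_problem"))
  if (is.function(problem$diffusivity))
    stop("analytic_profile requires a constant diffusivity")
  h <- problem$thickness
  if (any(x < 0) || any(x > h)) stop("domain error: x outside [0, h]")
  if (any(t < 0)) stop("domain error: t must be >= 0")
  D <- problem$diffusivity
  C0 <- problem$surface_conc
  Ci <- problem$initial_conc
  out <- matrix(NA_real_, nrow = length(x), ncol = length(t))
  boundary <- x <= 0 | x >= h
  for (j in seq_along(t)) {
    tj <- t[j]
    if (tj == 0) {
      col <- rep(Ci, length(x))
      col[boundary] <- C0
    } else {
      s <- numeric(length(x))
      lambda <- D * pi^2 * tj / h^2
      for (n in 0:(max_terms - 1)) {
        k <- 2 * n + 1
        amp <- exp(-lambda * k^2) / k
        if (amp < tol && n > 0) break
        s <- s + amp * sin(k * pi * x / h)
        if (amp < tol) break
      }
      col <- C0 + (Ci - C0) * (4 / pi) * s
      col[boundary] <- C0
    }
    out[, j] <- col
  }
  drop(out)
}

# face conductances at time t for nodes xs: harmonic mean of nodal D,
# or the constant D everywhere
.face_conductance <- function(problem, xs, t) {
  if (is.function(problem$diffusivity)) {
    Dn <- problem$diffusivity(xs, t)
    if (any(!is.finite(Dn)) || any(Dn < 0))
      stop("physics error: diffusivity must be finite and >= 0 on the grid")
    a <- Dn[-length(Dn)]; b <- Dn[-1]
    g <- ifelse(a + b > 0, 2 * a * b / (a + b), 0)
    g
  } else {
    rep(problem$diffusivity, length(xs) - 1L)
  }
}

.tridiag_T <- function(g) {
  # interior-node stiffness for face conductances g (length N-1):
  # interior nodes 2..N-1 -> M = N-2 unknowns
  M <- length(g) - 1L
  d0 <- g[1:M] + g[2:(M + 1L)]
  if (M == 1L)
    return(Matrix::Matrix(d0, 1, 1, sparse = TRUE))
  off <- -g[2:M]
  Matrix::bandSparse(M, M, k = c(-1L, 0L, 1L),
                     diagonals = list(off, d0, off),
                     symmetric = FALSE)
}

# Crank-Nicolson run with Rannacher (implicit Euler) startup.
# store_steps: integer step indices (0 = initial state) at which to store.
# stop_fraction: if non-NULL, stop early once min(C)/C0 >= stop_fraction and
# return the crossing time.
.cn_run <- function(problem, grid, store_steps, stop_fraction = NULL,
                    n_startup = 8L) {
  h <- problem$thickness
  dx <- grid$dx; dt <- grid$dt
  N <- round(h / dx) + 1L
  if (abs((N - 1L) * dx - h) > dx * 1e-6)
    stop("grid error: dx must divide the thickness to within one step")
  if (N < 3L) stop("resolution error: need at least 3 nodes")
  nsteps <- ceiling(grid$horizon / dt - 1e-9)
  xs <- seq(0, h, length.out = N)
  C0 <- problem$surface_conc
  M <- N - 2L
  r <- dt / dx^2
  time_varying <- is.function(problem$diffusivity) &&
    !isTRUE(attr(problem$diffusivity, "time_invariant"))

  u <- rep(problem$initial_conc, M)
  store_steps <- sort(unique(store_steps))
  C_store <- matrix(NA_real_, nrow = N, ncol = length(store_steps))
  store_ptr <- 1L
  record <- function(uvec, ptr) {
    C_store[, ptr] <<- c(C0, uvec, C0)
  }
  if (length(store_steps) && store_steps[1] == 0L) {
    # initial state: boundaries already at bath concentration
    record(u, 1L); store_ptr <- 2L
  }

  make_ops <- function(tmid, theta) {
    g <- .face_conductance(problem, xs, tmid)
    Tm <- .tridiag_T(g)
    A <- Matrix::Diagonal(M) + (theta * r) * Tm
    list(A = Matrix::forceSymmetric(A), Tm = Tm, g = g)
  }
  chol_of <- function(A) Matrix::Cholesky(A, LDL = FALSE)

  ops_cn <- NULL; ch_cn <- NULL
  ops_ie <- NULL; ch_ie <- NULL
  if (!time_varying) {
    ops_cn <- make_ops(0, 0.5); ch_cn <- chol_of(ops_cn$A)
    if (n_startup > 0L) { ops_ie <- make_ops(0, 1); ch_ie <- chol_of(ops_ie$A) }
  }

  stop_time <- NA_real_
  for (step in seq_len(nsteps)) {
    tn <- (step - 1L) * dt
    implicit <- step <= n_startup
    if (time_varying) {
      theta <- if (implicit) 1 else 0.5
      ops <- make_ops(tn + dt / 2, theta)
      ch <- chol_of(ops$A)
    } else {
      ops <- if (implicit) ops_ie else ops_cn
      ch <- if (implicit) ch_ie else ch_cn
    }
    g <- ops$g
    e <- numeric(M); e[1] <- g[1] * C0; e[M] <- g[M + 1L] * C0
    if (implicit) {
      rhs <- u + r * e
    } else {
      rhs <- u - (0.5 * r) * as.numeric(ops$Tm %*% u) + r * e
    }
    u <- as.numeric(Matrix::solve(ch, rhs))
    if (store_ptr <= length(store_steps) && step == store_steps[store_ptr]) {
      record(u, store_ptr); store_ptr <- store_ptr + 1L
    }
    if (!is.null(stop_fraction) && C0 > 0 &&
        min(u) / C0 >= stop_fraction) {
      stop_time <- step * dt
      break
    }
  }
  list(x = xs, C = C_store, steps = store_steps, stop_time = stop_time)
}

#' Finite-difference solution of the slab transport problem
#'
#' Conservative Crank-Nicolson discretization of
#' dC/dt = d/dx(D(x,t) dC/dx) with Dirichlet faces at the bath
#' concentration, harmonic-mean face conductances for spatially varying
#' diffusivity, and a short fully-implicit startup that suppresses the
#' oscillations the trapezoidal rule would otherwise exhibit against the
#' discontinuous initial data.
#'
#' @param problem a [slab_problem()].
#' @param grid a [grid1d()].
#' @param times output times, s (snapped to multiples of `dt`). Default:
#'   up to 241 evenly spaced times spanning `[0, horizon]`.
#' @return A `concentration_field`: list with positions `x` (m), `times`
#'   (s), concentration matrix `C` (`length(x)` by `length(times)`),
#'   `C0`, and `thickness`.
#' @examples
#' p <- slab_problem(1e-3, 3.58e-11, 1)
#' f <- fd_solve(p, grid1d(dx = 2e-5, dt = 10, horizon = 3600))
#' range(f$C)
#' @export
fd_solve <- function(problem, grid, times = NULL) {
  stopifnot(inherits(problem, "slab_problem"), inherits(grid, "grid1d"))
  nsteps <- ceiling(grid$horizon / grid$dt - 1e-9)
  if (is.null(times)) {
    nt <- min(nsteps, 240L)
    steps <- unique(round(seq(0, nsteps, length.out = nt + 1L)))
  } else {
    if (any(times < 0) || any(times > grid$horizon + grid$dt * 1e-6))
      stop("output times must lie in [0, horizon]")
    steps <- unique(round(times / grid$dt))
  }
  run <- .cn_run(problem, grid, store_steps = steps)
  structure(list(x = run$x, times = run$steps * grid$dt, C = run$C,
                 C0 = problem$surface_conc, thickness = problem$thickness),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("1-D concentration field\n")
  cat(sprintf("  %d nodes over %.3g mm, %d stored times up to %.3g h\n",
              length(x$x), x$thickness * 1e3, length(x$times),
              max(x$times) / 3600))
  cat(sprintf("  C range [%.3g, %.3g] (C0 = %.3g)\n",
              min(x$C), max(x$C), x$C0))
  invisible(x)
}

#' Diffusive flux at the slab midplane
#'
#' Central-difference flux -D dC/dx evaluated at the node nearest h/2, as
#' a diagnostic of the no-flux symmetry condition at the center.
#'
#' @param field a `concentration_field` from [fd_solve()].
#' @param D diffusivity used to scale the gradient (default 1, i.e. the
#'   negative concentration gradient itself).
#' @return Numeric vector: flux at each stored time.
#' @export
center_flux <- function(field, D = 1) {
  stopifnot(inherits(field, "concentration_field"))
  N <- length(field$x)
  if (N < 3L) stop("resolution error: need at least 3 nodes")
  ic <- which.min(abs(field$x - field$thickness / 2))
  if (ic <= 1L || ic >= N) stop("resolution error: no interior center node")
  dx2 <- field$x[ic + 1L] - field$x[ic - 1L]
  -D * (field$C[ic + 1L, ] - field$C[ic - 1L, ]) / dx2
}

#' Time for the slab to equilibrate with the bath
#'
#' Earliest grid time at which the minimum concentration across the slab
#' reaches `fraction` of the bath concentration.
#'
#' @param problem a [slab_problem()].
#' @param grid a [grid1d()]; the horizon bounds the search.
#' @param fraction target fraction of C_E0, in (0, 1).
#' @return Time in seconds, or `NA` with a warning if the fraction is not
#'   reached within the horizon.
#' @examples
#' p <- slab_problem(1e-3, 3.58e-11, 1)
#' equilibration_time(p, grid1d(dx = 2e-5, dt = 30, horizon = 4 * 3600), 0.9)
#' @export
equilibration_time <- function(problem, grid, fraction) {
  stopifnot(inherits(problem, "slab_problem"), inherits(grid, "grid1d"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  run <- .cn_run(problem, grid, store_steps = integer(0),
                 stop_fraction = fraction)
  if (is.na(run$stop_time))
    warning("horizon exceeded: fraction ", fraction,
            " not reached within ", grid$horizon, " s")
  run$stop_time
}
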
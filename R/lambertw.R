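#' Lambert W function (principal branch)
#'
#' Solves w e^w = z for z >= -1/e by Halley iteration from an
#' asymptotic-logarithm starting point, to a relative residual below
#' 1e-12. The principal branch W0 is the one appearing in the integrated
#' Michaelis-Menten substrate trajectory, where the argument is always
#' positive.
#'
#' @param z argument(s), >= -1/e.
#' @return W(z), same length as `z`.
#' @examples
#' lambert_w(exp(1))  # 1
#' lambert_w(0)       # 0
#' @export
lambert_w <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  if (any(z < -exp(-1) - 1e-15))
    stop("branch error: principal branch requires z >= -1/e")
  z <- pmax(z, -exp(-1))
  w <- numeric(length(z))
  # starting guesses
  big <- z > 3
  w[big] <- { L <- log(z[big]); L - log(L) }
  mid <- !big & z > -0.25
  w[mid] <- z[mid] / (1 + z[mid])
  near <- !big & !mid
  # near the branch point: w ~ -1 + sqrt(2(ez+1))
  w[near] <- -1 + sqrt(pmax(2 * (exp(1) * z[near] + 1), 0))
  for (iter in 1:50) {
    ew <- exp(w)
    f <- w * ew - z
    conv <- abs(f) <= 1e-14 * pmax(abs(z), 1e-300)
    if (all(conv)) break
    wp1 <- w + 1
    denom <- ew * wp1 - (w + 2) * f / (2 * wp1)
    step <- f / denom
    step[conv] <- 0
    w <- w - step
  }
  w
}

#' Lambert W of an exponentially large argument
#'
#' Evaluates W(exp(log_z)) without forming exp(log_z), by solving
#' w + log(w) = log_z. Used to keep the closed-form substrate field
#' overflow-safe when C_S0/K_M is large.
#'
#' @param log_z natural log of the argument; must satisfy
#'   exp(log_z) >= -1/e trivially (any real log_z is valid).
#' @return W(exp(log_z)), same length as `log_z`.
#' @examples
#' lambert_w_log(log(exp(1)))  # 1
#' lambert_w_log(1000)         # W(e^1000) without overflow
#' @export
lambert_w_log <- function(log_z) {
  if (any(!is.finite(log_z))) stop("log_z must be finite")
  out <- numeric(length(log_z))
  small <- log_z < 500
  out[small] <- lambert_w(exp(log_z[small]))
  if (any(!small)) {
    L <- log_z[!small]
    w <- L - log(L)
    for (iter in 1:50) {
      # Newton on g(w) = w + log(w) - L
      g <- w + log(w) - L
      if (all(abs(g) <= 1e-14 * pmax(L, 1))) break
      w <- w - g / (1 + 1 / w)
    }
    out[!small] <- w
  }
  out
}
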
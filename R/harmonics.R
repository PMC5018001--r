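#' Modified spherical Bessel function of the first kind
#'
#' Computes \eqn{i_\mu(x) = \sqrt{\pi/(2x)}\, I_{\mu+1/2}(x)}, the radial
#' solution of the modified spherical Bessel equation that is regular at the
#' origin. Only the first kind is provided: the model domain that uses these
#' functions (the tissue interior) contains the origin, where the second kind
#' is singular.
#'
#' @param mu integer degree, `mu >= 0`.
#' @param x numeric vector of nonnegative arguments.
#' @return numeric vector, `i_mu(x)`; `i_0(0) = 1` and `i_mu(0) = 0` for
#'   `mu >= 1`.
#' @examples
#' mod_sph_bessel_i(0, 1)       # sinh(1)/1
#' mod_sph_bessel_i(2, 0.5)
#' @export
mod_sph_bessel_i <- function(mu, x) {
  if (length(mu) != 1L || mu < 0 || mu != round(mu))
    stop("'mu' must be a single nonnegative integer")
  if (any(x < 0)) stop("'x' must be nonnegative")
  out <- numeric(length(x))
  ## series leading term below the scale where besselI(x, mu + 0.5)/sqrt(x)
  ## loses accuracy; (2*mu+1)!! as a product to avoid factorial overflow
  tiny <- x < 1e-8
  if (any(tiny))
    out[tiny] <- x[tiny]^mu / prod(seq(1, 2 * mu + 1, by = 2))
  if (any(!tiny))
    out[!tiny] <- sqrt(pi / (2 * x[!tiny])) * besselI(x[!tiny], mu + 0.5)
  out
}

## Fully normalized associated Legendre functions with Condon-Shortley phase,
## Pbar_mu^nu(cos theta), such that Y_mu^nu = Pbar_mu^nu * exp(1i nu phi).
## Returns a list indexed by mu+1; element mu+1 is an npts x (mu+1) matrix
## with columns nu = 0..mu. Stable three-term recurrence along degree.
pbar_table <- function(mu_max, costh) {
  sinth <- sqrt(pmax(0, 1 - costh^2))
  P <- vector("list", mu_max + 1L)
  P[[1L]] <- matrix(1 / sqrt(4 * pi), length(costh), 1L)
  if (mu_max >= 1L) for (mu in 1:mu_max) {
    M <- matrix(0, length(costh), mu + 1L)
    ## sectoral seed carries the Condon-Shortley phase
    M[, mu + 1L] <- -sqrt((2 * mu + 1) / (2 * mu)) * sinth * P[[mu]][, mu]
    M[, mu] <- sqrt(2 * mu + 1) * costh * P[[mu]][, mu]
    if (mu >= 2L) for (nu in 0:(mu - 2L)) {
      amn <- sqrt((4 * mu^2 - 1) / (mu^2 - nu^2))
      bmn <- sqrt(((2 * mu + 1) * (mu + nu - 1) * (mu - nu - 1)) /
                    ((mu^2 - nu^2) * (2 * mu - 3)))
      M[, nu + 1L] <- amn * costh * P[[mu]][, nu + 1L] - bmn * P[[mu - 1L]][, nu + 1L]
    }
    P[[mu + 1L]] <- M
  }
  P
}

#' Tesseral (complex orthonormal) spherical harmonic
#'
#' Evaluates \eqn{Y_\mu^\nu(\theta,\varphi)} in the orthonormal complex
#' convention with the Condon-Shortley phase, so that
#' \eqn{Y_\mu^{-\nu} = (-1)^\nu \overline{Y_\mu^\nu}} and
#' \eqn{\int |Y_\mu^\nu|^2 d\Omega = 1}.
#'
#' @param mu integer degree, `mu >= 0`.
#' @param nu integer order, `-mu <= nu <= mu`.
#' @param theta polar angle(s), radians, in `[0, pi]`.
#' @param phi azimuthal angle(s), radians.
#' @return complex vector of harmonic values.
#' @examples
#' tesseral_harmonic(0, 0, 1, 2)                 # 1/sqrt(4*pi)
#' tesseral_harmonic(1, 0, pi / 2, 0)            # 0 on the equator
#' @export
tesseral_harmonic <- function(mu, nu, theta, phi) {
  if (length(mu) != 1L || length(nu) != 1L || mu < 0 || mu != round(mu) ||
      nu != round(nu))
    stop("'mu' must be a nonnegative integer and 'nu' an integer")
  if (abs(nu) > mu) stop("order 'nu' must satisfy |nu| <= mu")
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  P <- pbar_table(mu, cos(theta))
  if (nu >= 0) {
    P[[mu + 1L]][, nu + 1L] * exp(1i * nu * phi)
  } else {
    (-1)^(-nu) * Conj(P[[mu + 1L]][, -nu + 1L] * exp(1i * (-nu) * phi))
  }
}

#' Polar-derivative coupling factor of spherical harmonics
#'
#' The factor \eqn{\tau(\mu,\nu) = \sqrt{(\mu-\nu)(\mu+\nu+1)}} that couples
#' \eqn{Y_\mu^{\nu+1}} into \eqn{\partial Y_\mu^\nu/\partial\theta} through
#' the identity
#' \deqn{\partial_\theta Y_\mu^\nu = \nu\cot\theta\, Y_\mu^\nu +
#'       \tau(\mu,\nu)\, e^{-i\varphi} Y_\mu^{\nu+1}.}
#' At `nu == mu` the companion harmonic does not exist and the factor is 0;
#' the square-root product form avoids evaluating gamma-function poles.
#'
#' @param mu integer degree.
#' @param nu integer order, `|nu| <= mu`.
#' @return the nonnegative coupling factor.
#' @export
theta_derivative_factor <- function(mu, nu) {
  if (abs(nu) > mu) stop("order 'nu' must satisfy |nu| <= mu")
  sqrt((mu - nu) * (mu + nu + 1))
}

#' Radial factor of the interior/exterior point-source expansion
#'
#' For a unit point source at radius `r_src`, the degree-`mu` radial factor of
#' the expansion of \eqn{1/|r - r'|} is
#' \eqn{g_<^\mu / g_>^{\mu+1}} with \eqn{g_< = \min(r, r_{src})} and
#' \eqn{g_> = \max(r, r_{src})}; it is continuous across `r == r_src`.
#'
#' @param mu integer degree.
#' @param r field-point radius (m), `r >= 0`.
#' @param r_src source radius (m), `r_src > 0`.
#' @return list with elements `g_less`, `g_greater` (m) and `value` (1/m).
#' @export
greens_radial <- function(mu, r, r_src) {
  if (length(mu) != 1L || mu < 0 || mu != round(mu))
    stop("'mu' must be a single nonnegative integer")
  if (any(r < 0) || any(r_src <= 0)) stop("radii must be positive ('r' may be 0)")
  g_less <- pmin(r, r_src); g_greater <- pmax(r, r_src)
  value <- ifelse(g_less == 0 & mu >= 1, 0, g_less^mu / g_greater^(mu + 1))
  list(g_less = g_less, g_greater = g_greater, value = value)
}

#' Radial derivative of the point-source expansion factor
#'
#' Derivative with respect to the field radius `r` of the degree-`mu` factor
#' returned by [greens_radial()]:
#' \eqn{\mu r^{\mu-1}/r_{src}^{\mu+1}} for `r < r_src` and
#' \eqn{-(\mu+1) r_{src}^{\mu}/r^{\mu+2}} for `r > r_src`. The derivative is
#' discontinuous at `r == r_src`, where evaluation is an error.
#'
#' @inheritParams greens_radial
#' @return numeric vector (1/m^2).
#' @export
greens_radial_derivative <- function(mu, r, r_src) {
  if (length(mu) != 1L || mu < 0 || mu != round(mu))
    stop("'mu' must be a single nonnegative integer")
  if (any(r == r_src))
    stop("radial derivative is discontinuous at r == r_src; do not evaluate there")
  n <- max(length(r), length(r_src))
  r <- rep_len(r, n); r_src <- rep_len(r_src, n)
  out <- numeric(n)
  inner <- r < r_src
  if (mu == 0) {
    out[inner] <- 0
  } else {
    out[inner] <- mu * r[inner]^(mu - 1) / r_src[inner]^(mu + 1)
  }
  out[!inner] <- -(mu + 1) * r_src[!inner]^mu / r[!inner]^(mu + 2)
  out
}

## Legendre polynomials P_0..P_mu_max(u) and optionally dP/du, vectorized in u.
## Returns list(p = matrix npts x (mu_max+1), dp = same or NULL).
legendre_p_table <- function(mu_max, u, deriv = FALSE) {
  n <- length(u)
  p <- matrix(0, n, mu_max + 1L)
  p[, 1L] <- 1
  if (mu_max >= 1L) p[, 2L] <- u
  if (mu_max >= 2L) for (mu in 2:mu_max)
    p[, mu + 1L] <- ((2 * mu - 1) * u * p[, mu] - (mu - 1) * p[, mu - 1L]) / mu
  dp <- NULL
  if (deriv) {
    ## dP_{mu+1}/du = dP_{mu-1}/du + (2 mu + 1) P_mu  -- pole-safe recurrence
    dp <- matrix(0, n, mu_max + 1L)
    if (mu_max >= 1L) dp[, 2L] <- 1
    if (mu_max >= 2L) for (mu in 2:mu_max)
      dp[, mu + 1L] <- dp[, mu - 1L] + (2 * mu - 1) * p[, mu]
  }
  list(p = p, dp = dp)
}
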
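check_tissue_domain <- function(object, r) {
  if (any(r > object$config$a * (1 + 1e-12)))
    stop("field point outside the tissue (r > a); this potential is defined on the sphere only")
}

check_bath_domain <- function(object, r) {
  if (any(r < object$config$a * (1 - 1e-12)))
    stop("field point inside the tissue (r < a); this potential is defined in the bath only")
}

#' Transmembrane potential
#'
#' Evaluates \eqn{V_m(r,\theta,\varphi) = \sum_{\mu\nu} a_{\mu\nu}
#' i_\mu(r/\lambda) Y_\mu^\nu(\theta,\varphi)} on the tissue sphere
#' (`r <= a`). The sum over orders is assembled from its conjugate-symmetric
#' halves, so the returned value is exactly real.
#'
#' @param object a fitted [bidomain_sphere()] model.
#' @param r,theta,phi field-point spherical coordinates (m, rad, rad);
#'   vectors are recycled to a common length.
#' @return numeric vector of potentials (V).
#' @export
transmembrane_potential <- function(object, r, theta, phi) {
  check_tissue_domain(object, r)
  series_eval(list(vm = list(X = object$A, radial = "bessel")),
              r, theta, phi, object$config$a, object$params$lambda)$vm$value
}

#' Monodomain potential
#'
#' The resistivity-weighted average
#' \eqn{\psi = \rho_o\phi_i/(\rho_i+\rho_o) + \rho_i\phi_o/(\rho_i+\rho_o)},
#' a harmonic function \eqn{\sum b_{\mu\nu} r^\mu Y_\mu^\nu} on the tissue.
#'
#' @inheritParams transmembrane_potential
#' @return numeric vector of potentials (V).
#' @export
monodomain_potential <- function(object, r, theta, phi) {
  check_tissue_domain(object, r)
  series_eval(list(psi = list(X = object$Bt, radial = "growing")),
              r, theta, phi, object$config$a, object$params$lambda)$psi$value
}

#' Secondary bath potential
#'
#' The harmonic correction \eqn{\sum c_{\mu\nu} r^{-\mu-1} Y_\mu^\nu} that
#' the tissue sphere adds to the free source/sink fields in the bath
#' (`r >= a`); it decays to zero at infinity.
#'
#' @inheritParams transmembrane_potential
#' @return numeric vector of potentials (V).
#' @export
bath_secondary_potential <- function(object, r, theta, phi) {
  check_bath_domain(object, r)
  series_eval(list(bath = list(X = object$Ct, radial = "decaying")),
              r, theta, phi, object$config$a, object$params$lambda)$bath$value
}

#' Free potential of the source/sink pair
#'
#' \eqn{\phi_{source} + \phi_{sink} = I_0\rho_e/(4\pi R_{source}) -
#' I_0\rho_e/(4\pi R_{sink})}. In `"closed_form"` mode the monopole distances
#' are computed from the spherical geometry (law of cosines); in `"series"`
#' mode the potential is the truncated interior/exterior expansion of
#' \eqn{1/R} in Legendre polynomials of the source-to-field angles, truncated
#' at the model's `mu_max` (or `mu_max` if supplied). The two agree to
#' truncation error away from the electrode radii.
#'
#' @inheritParams transmembrane_potential
#' @param mode `"closed_form"` (default) or `"series"`.
#' @param mu_max optional series truncation override.
#' @return numeric vector of potentials (V).
#' @export
source_sink_potential <- function(object, r, theta, phi,
                                  mode = c("closed_form", "series"),
                                  mu_max = NULL) {
  mode <- match.arg(mode)
  n <- max(length(r), length(theta), length(phi))
  r <- rep_len(r, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  d <- check_exclusion(object$sources, object$config, r, theta, phi)
  I0 <- object$sources$I0; rho_e <- object$params$rho_e
  if (mode == "closed_form")
    return(I0 * rho_e / (4 * pi) * (1 / d$R_source - 1 / d$R_sink))
  mu_max <- if (is.null(mu_max)) object$config$mu_max else as.integer(mu_max)
  Lp <- legendre_p_table(mu_max, d$cos_gamma_plus)$p
  Lm <- legendre_p_table(mu_max, d$cos_gamma_minus)$p
  acc <- 0
  rp <- object$sources$p_plus[1]; rm <- object$sources$p_minus[1]
  for (mu in 0:mu_max) {
    gp <- greens_radial(mu, r, rp)$value
    gm <- greens_radial(mu, r, rm)$value
    acc <- acc + gp * Lp[, mu + 1L] - gm * Lm[, mu + 1L]
  }
  I0 * rho_e / (4 * pi) * acc
}

#' Intracellular and interstitial potentials
#'
#' Recovers the bidomain potentials from the transmembrane and monodomain
#' fields: \eqn{\phi_i = \rho_i V_m/(\rho_i+\rho_o) + \psi} and
#' \eqn{\phi_o = -\rho_o V_m/(\rho_i+\rho_o) + \psi}.
#'
#' @inheritParams transmembrane_potential
#' @return data frame with columns `phi_i`, `phi_o`, `V_m`, `psi` (V).
#' @export
domain_potentials <- function(object, r, theta, phi) {
  check_tissue_domain(object, r)
  ev <- series_eval(list(vm = list(X = object$A, radial = "bessel"),
                         psi = list(X = object$Bt, radial = "growing")),
                    r, theta, phi, object$config$a, object$params$lambda)
  ki <- object$params$rho_i / (object$params$rho_i + object$params$rho_o)
  ko <- object$params$rho_o / (object$params$rho_i + object$params$rho_o)
  data.frame(phi_i = ki * ev$vm$value + ev$psi$value,
             phi_o = -ko * ev$vm$value + ev$psi$value,
             V_m = ev$vm$value, psi = ev$psi$value)
}

#' Total bath potential
#'
#' \eqn{\phi_e = \phi_{bath} + \phi_{source} + \phi_{sink}} for `r >= a`.
#' With `ss_mode = "series"` the free source/sink part is evaluated at the
#' same harmonic truncation as the secondary field, which is the
#' representation in which the truncated solution satisfies the interface
#' conditions mode-by-mode (used by the residual report).
#'
#' @inheritParams source_sink_potential
#' @param ss_mode evaluation mode for the free source/sink potential.
#' @return numeric vector of potentials (V).
#' @export
external_potential <- function(object, r, theta, phi,
                               ss_mode = c("closed_form", "series")) {
  ss_mode <- match.arg(ss_mode)
  bath_secondary_potential(object, r, theta, phi) +
    source_sink_potential(object, r, theta, phi, mode = ss_mode)
}
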
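#' Electrical and membrane parameters of the tissue and bath
#'
#' Bundles the resistivities and membrane constants of the model and derives
#' the volume-normalized membrane resistivity `rho_m = R_m / beta` and the
#' length constant `lambda = sqrt(rho_m / (rho_i + rho_o))`, the spatial
#' decay scale of membrane polarization. Defaults are the reference
#' configuration: artificial-seawater bath and an interstitium matched to it.
#'
#' @param rho_i intracellular resistivity (Ohm m).
#' @param rho_o interstitial (extracellular, within-tissue) resistivity (Ohm m).
#' @param rho_e bath resistivity (Ohm m).
#' @param R_m membrane resistance times unit area (Ohm m^2).
#' @param beta membrane surface area per unit tissue volume (1/m).
#' @return object of class `tissue_parameters`: a list with the five inputs
#'   plus `rho_m` (Ohm m^3) and `lambda` (m).
#' @examples
#' p <- tissue_parameters()
#' p$lambda  # ~3.95 mm
#' @export
tissue_parameters <- function(rho_i = 0.19, rho_o = 0.29, rho_e = 0.29,
                              R_m = 0.15, beta = 2e4) {
  vals <- c(rho_i = rho_i, rho_o = rho_o, rho_e = rho_e, R_m = R_m, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all resistivities, R_m and beta must be finite and strictly positive")
  rho_m <- R_m / beta
  structure(list(rho_i = rho_i, rho_o = rho_o, rho_e = rho_e,
                 R_m = R_m, beta = beta, rho_m = rho_m,
                 lambda = sqrt(rho_m / (rho_i + rho_o))),
            class = "tissue_parameters")
}

#' Membrane length constant
#'
#' \eqn{\lambda = \sqrt{\rho_m/(\rho_i + \rho_o)}} with
#' \eqn{\rho_m = R_m/\beta}.
#'
#' @param params a [tissue_parameters()] object.
#' @return length constant in meters.
#' @export
length_constant <- function(params) {
  stopifnot(inherits(params, "tissue_parameters"))
  sqrt(params$rho_m / (params$rho_i + params$rho_o))
}

#' Stimulating source/sink pair
#'
#' Positions (spherical coordinates, meters/radians) and magnitude of the
#' injected point current source (`+I0`) and sink (`-I0`) in the bath. The
#' default geometry places both electrodes 5 mm from the sphere center in the
#' `z = 0` plane: source on the `+x` axis, sink on the `-y` axis, i.e. the
#' reference configuration oriented so that the plane containing the source,
#' the sink and the sphere center is the coordinate plane `z = 0`.
#'
#' @param p_plus numeric `c(r, theta, phi)` of the source (m, rad, rad).
#' @param p_minus numeric `c(r, theta, phi)` of the sink.
#' @param I0 injected current magnitude (A), positive.
#' @return object of class `source_pair`.
#' @export
source_pair <- function(p_plus = c(5e-3, pi / 2, 0),
                        p_minus = c(5e-3, pi / 2, -pi / 2),
                        I0 = 1e-3) {
  for (p in list(p_plus, p_minus))
    if (length(p) != 3L || !all(is.finite(p)) || p[1] <= 0 ||
        p[2] < 0 || p[2] > pi)
      stop("source positions must be c(r, theta, phi) with r > 0, 0 <= theta <= pi")
  if (!is.finite(I0) || I0 <= 0) stop("'I0' must be a positive current (A)")
  structure(list(p_plus = as.numeric(p_plus), p_minus = as.numeric(p_minus),
                 I0 = I0),
            class = "source_pair")
}

#' Geometric and numerical configuration of the model
#'
#' @param a tissue sphere radius (m).
#' @param mu_max series truncation bound (highest retained harmonic degree).
#'   The default 10 stabilizes the reference-configuration potentials to five
#'   decimal places (in volts); see the convergence study tools.
#' @param exclusion_radius minimum distance from the source/sink points at
#'   which fields are evaluated (m); defaults to 5 percent of `a`.
#' @param tol_real maximum tolerated relative imaginary residue of physically
#'   real fields (diagnostic only; the evaluators assemble real sums).
#' @return object of class `model_config`.
#' @export
model_config <- function(a = 2e-3, mu_max = 10, exclusion_radius = 0.05 * a,
                         tol_real = 1e-10) {
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive radius (m)")
  if (mu_max < 1 || mu_max != round(mu_max)) stop("'mu_max' must be an integer >= 1")
  structure(list(a = a, mu_max = as.integer(mu_max),
                 exclusion_radius = exclusion_radius, tol_real = tol_real),
            class = "model_config")
}

## ---- coordinate helpers -------------------------------------------------

sph_to_cart <- function(r, theta, phi) {
  cbind(x = r * sin(theta) * cos(phi),
        y = r * sin(theta) * sin(phi),
        z = r * cos(theta))
}

cart_to_sph <- function(x, y, z) {
  r <- sqrt(x^2 + y^2 + z^2)
  theta <- ifelse(r == 0, 0, acos(pmin(1, pmax(-1, z / pmax(r, .Machine$double.xmin)))))
  phi <- atan2(y, x)
  cbind(r = r, theta = theta, phi = phi)
}

#' Rotate a spherical-frame vector into Cartesian components
#'
#' Applies the orthonormal frame rotation at the point `(theta, phi)`:
#' \eqn{\hat r, \hat\theta, \hat\varphi \to \hat x, \hat y, \hat z}. The
#' Euclidean norm is preserved.
#'
#' @param v_r,v_theta,v_phi spherical components (any consistent unit).
#' @param theta,phi angular position of the point (rad).
#' @return matrix with columns `x`, `y`, `z`.
#' @export
to_cartesian_vector <- function(v_r, v_theta, v_phi, theta, phi) {
  st <- sin(theta); ct <- cos(theta); sp <- sin(phi); cp <- cos(phi)
  cbind(x = v_r * st * cp + v_theta * ct * cp - v_phi * sp,
        y = v_r * st * sp + v_theta * ct * sp + v_phi * cp,
        z = v_r * ct - v_theta * st)
}

#' Rotate a Cartesian vector into the local spherical frame
#'
#' Inverse of [to_cartesian_vector()] at the same point.
#'
#' @param vx,vy,vz Cartesian components.
#' @param theta,phi angular position of the point (rad).
#' @return matrix with columns `v_r`, `v_theta`, `v_phi`.
#' @export
cartesian_to_spherical_vector <- function(vx, vy, vz, theta, phi) {
  st <- sin(theta); ct <- cos(theta); sp <- sin(phi); cp <- cos(phi)
  cbind(v_r = vx * st * cp + vy * st * sp + vz * ct,
        v_theta = vx * ct * cp + vy * ct * sp - vz * st,
        v_phi = -vx * sp + vy * cp)
}

## distances and angles from each electrode to field points
source_distances <- function(sources, r, theta, phi) {
  pp <- sources$p_plus; pm <- sources$p_minus
  cosg <- function(ps) cos(theta) * cos(ps[2]) +
    sin(theta) * sin(ps[2]) * cos(phi - ps[3])
  gp <- cosg(pp); gm <- cosg(pm)
  list(R_source = sqrt(pmax(0, r^2 + pp[1]^2 - 2 * r * pp[1] * gp)),
       R_sink = sqrt(pmax(0, r^2 + pm[1]^2 - 2 * r * pm[1] * gm)),
       cos_gamma_plus = gp, cos_gamma_minus = gm)
}

check_exclusion <- function(sources, config, r, theta, phi, what = "field") {
  d <- source_distances(sources, r, theta, phi)
  bad <- d$R_source < config$exclusion_radius | d$R_sink < config$exclusion_radius
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "%s point (r=%.3g, theta=%.3g, phi=%.3g) lies within the exclusion radius %.3g m of a current electrode",
      what, r[i], theta[i], phi[i], config$exclusion_radius))
  }
  invisible(d)
}

#' Read a model configuration file
#'
#' Reads YAML or JSON with keys `rho_i`, `rho_o`, `rho_e`, `R_m`, `beta`,
#' `I0`, `a`, `p_plus`, `p_minus` (each `[r, theta, phi]`), `mu_max` and
#' `length_unit` (`"mm"`, the default, or `"m"`); missing keys fall back to
#' the reference configuration. Lengths (`a`, electrode radii) are converted
#' to meters according to `length_unit`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `params`, `sources`, `config`.
#' @export
read_model_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unit <- if (is.null(raw$length_unit)) "mm" else raw$length_unit
  scale <- switch(unit, mm = 1e-3, m = 1,
                  stop("'length_unit' must be \"mm\" or \"m\""))
  g <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  params <- tissue_parameters(rho_i = g("rho_i", 0.19), rho_o = g("rho_o", 0.29),
                              rho_e = g("rho_e", 0.29), R_m = g("R_m", 0.15),
                              beta = g("beta", 2e4))
  len3 <- function(v) { v <- as.numeric(v); v[1] <- v[1] * scale; v }
  sources <- source_pair(
    p_plus = len3(g("p_plus", c(5, pi / 2, 0))),
    p_minus = len3(g("p_minus", c(5, pi / 2, -pi / 2))),
    I0 = g("I0", 1e-3))
  a <- g("a", 2) * scale
  config <- model_config(a = a, mu_max = g("mu_max", 10))
  list(params = params, sources = sources, config = config)
}
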
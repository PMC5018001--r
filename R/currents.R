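## gradient (V/m, spherical frame) of the free source/sink potential
grad_source_sink <- function(object, r, theta, phi,
                             mode = c("closed_form", "series"), mu_max = NULL) {
  mode <- match.arg(mode)
  n <- max(length(r), length(theta), length(phi))
  r <- rep_len(r, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  I0 <- object$sources$I0; rho_e <- object$params$rho_e
  pp <- object$sources$p_plus; pm <- object$sources$p_minus
  if (mode == "closed_form") {
    xyz <- sph_to_cart(r, theta, phi)
    gcart <- 0
    for (s in list(list(p = pp, sgn = 1), list(p = pm, sgn = -1))) {
      ps <- sph_to_cart(s$p[1], s$p[2], s$p[3])
      dx <- sweep(xyz, 2, ps)
      R3 <- (dx[, 1]^2 + dx[, 2]^2 + dx[, 3]^2)^1.5
      gcart <- gcart - s$sgn * I0 * rho_e / (4 * pi) * dx / R3
    }
    return(cartesian_to_spherical_vector(gcart[, 1], gcart[, 2], gcart[, 3],
                                         theta, phi))
  }
  mu_max <- if (is.null(mu_max)) object$config$mu_max else as.integer(mu_max)
  d <- source_distances(object$sources, r, theta, phi)
  Lp <- legendre_p_table(mu_max, d$cos_gamma_plus, deriv = TRUE)
  Lm <- legendre_p_table(mu_max, d$cos_gamma_minus, deriv = TRUE)
  dudth_p <- -sin(theta) * cos(pp[2]) + cos(theta) * sin(pp[2]) * cos(phi - pp[3])
  dudth_m <- -sin(theta) * cos(pm[2]) + cos(theta) * sin(pm[2]) * cos(phi - pm[3])
  dudph_p <- -sin(pp[2]) * sin(phi - pp[3])  # (1/sin(theta)) du/dphi
  dudph_m <- -sin(pm[2]) * sin(phi - pm[3])
  gr <- gt <- gp <- 0
  for (mu in 0:mu_max) {
    fp <- greens_radial_derivative(mu, r, pp[1])
    fm <- greens_radial_derivative(mu, r, pm[1])
    gvp <- greens_radial(mu, r, pp[1])$value
    gvm <- greens_radial(mu, r, pm[1])$value
    gr <- gr + fp * Lp$p[, mu + 1L] - fm * Lm$p[, mu + 1L]
    gt <- gt + gvp * Lp$dp[, mu + 1L] * dudth_p - gvm * Lm$dp[, mu + 1L] * dudth_m
    gp <- gp + gvp * Lp$dp[, mu + 1L] * dudph_p - gvm * Lm$dp[, mu + 1L] * dudph_m
  }
  k <- I0 * rho_e / (4 * pi)
  cbind(v_r = k * gr, v_theta = k * gt / r, v_phi = k * gp / r)
}

#' Analytic spherical-frame gradient of a model potential
#'
#' Term-wise analytic gradient
#' \eqn{\nabla f = \partial_r f\,\hat r + r^{-1}\partial_\theta f\,\hat\theta
#'  + (r\sin\theta)^{-1}\partial_\varphi f\,\hat\varphi} of the truncated
#' series potentials. Radial derivatives differentiate the radial family
#' exactly; polar derivatives use the harmonic coupling identity (see
#' [theta_derivative_factor()]); on the polar axis the angular components are
#' evaluated by their exact limits.
#'
#' @param object a fitted [bidomain_sphere()] model.
#' @param field one of `"V_m"`, `"psi"`, `"phi_i"`, `"phi_o"`, `"phi_bath"`,
#'   `"phi_e"`.
#' @param r,theta,phi field-point spherical coordinates.
#' @param ss_mode for `"phi_e"`: evaluation mode of the free source/sink
#'   part, `"closed_form"` (default) or `"series"`.
#' @return matrix with columns `v_r`, `v_theta`, `v_phi` (V/m).
#' @export
field_gradient <- function(object, field, r, theta, phi,
                           ss_mode = c("closed_form", "series")) {
  ss_mode <- match.arg(ss_mode)
  a <- object$config$a; lam <- object$params$lambda
  n <- max(length(r), length(theta), length(phi))
  r <- rep_len(r, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  pick <- function(ev) cbind(v_r = ev$gr, v_theta = ev$gt, v_phi = ev$gp)
  if (field %in% c("V_m", "psi", "phi_i", "phi_o")) {
    check_tissue_domain(object, r)
    ev <- series_eval(list(vm = list(X = object$A, radial = "bessel"),
                           psi = list(X = object$Bt, radial = "growing")),
                      r, theta, phi, a, lam, deriv = TRUE)
    ki <- object$params$rho_i / (object$params$rho_i + object$params$rho_o)
    ko <- object$params$rho_o / (object$params$rho_i + object$params$rho_o)
    return(switch(field,
      V_m = pick(ev$vm),
      psi = pick(ev$psi),
      phi_i = ki * pick(ev$vm) + pick(ev$psi),
      phi_o = -ko * pick(ev$vm) + pick(ev$psi)))
  }
  check_bath_domain(object, r)
  ev <- series_eval(list(bath = list(X = object$Ct, radial = "decaying")),
                    r, theta, phi, a, lam, deriv = TRUE)
  if (field == "phi_bath") return(pick(ev$bath))
  if (field == "phi_e") {
    check_exclusion(object$sources, object$config, r, theta, phi)
    return(pick(ev$bath) + grad_source_sink(object, r, theta, phi, mode = ss_mode))
  }
  stop("unknown field '", field, "'")
}

#' Intracellular current density
#'
#' \eqn{J_i = -\rho_i^{-1}\nabla\phi_i} on the tissue (`r <= a`). Its radial
#' component vanishes at the tissue surface by construction of the
#' coefficients.
#'
#' @inheritParams field_gradient
#' @return matrix with columns `v_r`, `v_theta`, `v_phi` (A/m^2).
#' @export
current_density_i <- function(object, r, theta, phi) {
  -field_gradient(object, "phi_i", r, theta, phi) / object$params$rho_i
}

#' Interstitial (extracellular) current density
#'
#' \eqn{J_o = -\rho_o^{-1}\nabla\phi_o} on the tissue (`r <= a`).
#'
#' @inheritParams field_gradient
#' @return matrix with columns `v_r`, `v_theta`, `v_phi` (A/m^2).
#' @export
current_density_o <- function(object, r, theta, phi) {
  -field_gradient(object, "phi_o", r, theta, phi) / object$params$rho_o
}

#' Bath current density
#'
#' \eqn{J_e = -\rho_e^{-1}\nabla\phi_e} in the bath (`r >= a`, outside the
#' electrode exclusion zones). Far from the sphere it approaches the free
#' two-monopole field.
#'
#' @inheritParams field_gradient
#' @export
current_density_e <- function(object, r, theta, phi,
                              ss_mode = c("closed_form", "series")) {
  -field_gradient(object, "phi_e", r, theta, phi, ss_mode = ss_mode) /
    object$params$rho_e
}

#' Sample the current density on a regular Cartesian grid
#'
#' Samples the plotted current field of the model on a regular grid centered
#' on the sphere: the bath current \eqn{J_e} where `r > a` and the total
#' tissue current \eqn{J_i + J_o} where `r < a` (both bidomain domains
#' occupy the same volume, so their sum is the physically flowing current).
#' Nodes within the electrode exclusion radius and nodes within half a grid
#' cell of the `r = a` interface (where the field definition switches and
#' tangential components jump) are masked and set to zero; nodes exactly on
#' `r = a` otherwise count as bath.
#'
#' @param object a fitted [bidomain_sphere()] model.
#' @param extent edge length of the sampled cube (m); default 3 mm.
#' @param dims integer `c(nx, ny, nz)` grid dimensions; default
#'   `c(128, 128, 13)`. Use `nz = 1` for a single `z = 0` plane.
#' @return object of class `cartesian_vector_grid`: axes `x`, `y`, `z`,
#'   `spacing`, `dims`, 3-d arrays `Jx`, `Jy`, `Jz` (A/m^2) and integer
#'   `mask` array (0 tissue, 1 bath, 2 excluded near an electrode,
#'   3 interface shell).
#' @export
sample_current_grid <- function(object, extent = 3e-3, dims = c(128, 128, 13)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  ax <- function(n) if (n == 1L) 0 else seq(-extent / 2, extent / 2, length.out = n)
  x <- ax(dims[1]); y <- ax(dims[2]); z <- ax(dims[3])
  spacing <- vapply(list(x, y, z), function(v) if (length(v) > 1) v[2] - v[1] else 0,
                    numeric(1))
  shell_hw <- min(spacing[spacing > 0]) / 2
  a <- object$config$a
  Jx <- Jy <- Jz <- array(0, dims)
  mask <- array(1L, dims)
  for (k in seq_len(dims[3])) {   # per-slice chunks keep memory modest
    g <- expand.grid(x = x, y = y)
    sph <- cart_to_sph(g$x, g$y, rep(z[k], nrow(g)))
    r <- sph[, 1]; th <- sph[, 2]; ph <- sph[, 3]
    d <- source_distances(object$sources, r, th, ph)
    m <- ifelse(r < a, 0L, 1L)
    m[abs(r - a) <= shell_hw] <- 3L
    m[d$R_source < object$config$exclusion_radius |
      d$R_sink < object$config$exclusion_radius] <- 2L
    jx <- jy <- jz <- numeric(nrow(g))
    tis <- m == 0L
    if (any(tis)) {
      Ji <- current_density_i(object, r[tis], th[tis], ph[tis])
      Jo <- current_density_o(object, r[tis], th[tis], ph[tis])
      cart <- to_cartesian_vector(Ji[, 1] + Jo[, 1], Ji[, 2] + Jo[, 2],
                                  Ji[, 3] + Jo[, 3], th[tis], ph[tis])
      jx[tis] <- cart[, 1]; jy[tis] <- cart[, 2]; jz[tis] <- cart[, 3]
    }
    bat <- m == 1L
    if (any(bat)) {
      Je <- current_density_e(object, r[bat], th[bat], ph[bat])
      cart <- to_cartesian_vector(Je[, 1], Je[, 2], Je[, 3], th[bat], ph[bat])
      jx[bat] <- cart[, 1]; jy[bat] <- cart[, 2]; jz[bat] <- cart[, 3]
    }
    Jx[, , k] <- jx; Jy[, , k] <- jy; Jz[, , k] <- jz
    mask[, , k] <- m
  }
  structure(list(x = x, y = y, z = z, dims = dims, spacing = spacing,
                 origin = c(min(x), min(y), min(z)),
                 Jx = Jx, Jy = Jy, Jz = Jz, mask = mask,
                 units = list(length = "m", J = "A/m^2")),
            class = "cartesian_vector_grid")
}

#' Write a sampled vector grid as long-format CSV
#'
#' Columns `x, y, z` (m), the vector components, and `mask`.
#'
#' @param grid a `cartesian_vector_grid` or `b_field_grid` object.
#' @param path output CSV path.
#' @export
write_grid_csv <- function(grid, path) {
  g <- expand.grid(x = grid$x, y = grid$y, z = grid$z)
  comps <- intersect(c("Jx", "Jy", "Jz", "Bx", "By", "Bz"), names(grid))
  for (cc in comps) g[[cc]] <- as.vector(grid[[cc]])
  if (!is.null(grid$mask)) g$mask <- as.vector(grid$mask)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}
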
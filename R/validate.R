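## central finite-difference Laplacian of f(r, theta, phi) at Cartesian points
fd_laplacian <- function(f, xyz, h) {
  n <- nrow(xyz)
  shifts <- rbind(c(0, 0, 0),
                  c(h, 0, 0), c(-h, 0, 0),
                  c(0, h, 0), c(0, -h, 0),
                  c(0, 0, h), c(0, 0, -h))
  vals <- matrix(0, n, 7)
  for (s in seq_len(7)) {
    p <- sweep(xyz, 2, shifts[s, ], `+`)
    sph <- cart_to_sph(p[, 1], p[, 2], p[, 3])
    vals[, s] <- f(sph[, 1], sph[, 2], sph[, 3])
  }
  (rowSums(vals[, 2:7, drop = FALSE]) - 6 * vals[, 1]) / h^2
}

#' Boundary-condition and PDE residuals of a fitted model
#'
#' Validation report for the truncated analytic solution.
#'
#' Interface residuals are evaluated on an angular grid at `r = a` with the
#' free source/sink potential in its harmonic-series representation at the
#' same truncation as the secondary fields, the representation in which the
#' truncated solution satisfies the interface conditions mode-by-mode
#' (differences from the closed-form monopoles are pure truncation
#' remainder, not solution error): continuity of potential, continuity of
#' normal current density, and vanishing intracellular normal current
#' (normalized by the bath current scale).
#'
#' PDE residuals apply a second-order central finite-difference Laplacian at
#' the probe points: the transmembrane potential must satisfy the scalar
#' Helmholtz equation \eqn{\nabla^2 V_m = V_m/\lambda^2} (residual
#' normalized by \eqn{\max|V_m|/\lambda^2}), and the monodomain and
#' secondary bath potentials the Laplace equation (normalized by
#' \eqn{\max|f|/a^2}); all residuals shrink as \eqn{O(h^2)}.
#'
#' Scenario-symmetry metrics are appended when the geometry admits them:
#' the relative out-of-plane current on the `z = 0` electrode plane, and the
#' relative azimuthal variation of the potentials for on-axis electrodes.
#'
#' @param object a fitted [bidomain_sphere()] model.
#' @param type `"all"`, `"boundary"` or `"pde"`.
#' @param n_theta,n_phi angular grid for the interface residuals.
#' @param h finite-difference step (m) for the PDE residuals.
#' @param probes probe points (default [probe_points()]).
#' @param ... unused.
#' @return data frame with columns `metric`, `value`, `tol`, `pass`.
#' @export
residuals.bidomain_sphere <- function(object, type = c("all", "boundary", "pde"),
                                      n_theta = 64, n_phi = 128,
                                      h = object$config$a / 200,
                                      probes = NULL, ...) {
  type <- match.arg(type)
  a <- object$config$a
  lam <- object$params$lambda
  rows <- list()
  add <- function(metric, value, tol)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value,
                                             tol = tol, pass = value <= tol)
  if (type %in% c("all", "boundary")) {
    th <- rep((seq_len(n_theta) - 0.5) * pi / n_theta, each = n_phi)
    ph <- rep((seq_len(n_phi) - 0.5) * 2 * pi / n_phi, times = n_theta)
    r <- rep(a, length(th))
    phi_o <- domain_potentials(object, r, th, ph)$phi_o
    phi_e <- external_potential(object, r, th, ph, ss_mode = "series")
    add("bc_potential_continuity",
        max(abs(phi_e - phi_o)) / max(abs(phi_e)), 1e-8)
    ge <- field_gradient(object, "phi_e", r, th, ph, ss_mode = "series")
    go <- field_gradient(object, "phi_o", r, th, ph)
    lhs <- ge[, "v_r"] / object$params$rho_e
    rhs <- go[, "v_r"] / object$params$rho_o
    add("bc_normal_current_continuity", max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)
    gi <- field_gradient(object, "phi_i", r, th, ph)
    j_scale <- max(sqrt(rowSums(ge^2))) / object$params$rho_e
    add("bc_intracellular_radial_current",
        max(abs(gi[, "v_r"] / object$params$rho_i)) / j_scale, 1e-10)
  }
  if (type %in% c("all", "pde")) {
    if (is.null(probes)) probes <- probe_points(object$config)
    ## the probe strata keep a >= 0.05 a margin to the interface, so any
    ## step up to a/20 leaves every stencil inside its domain -- and the
    ## same probe set is used for every h (comparable maxima)
    if (h > a / 20) stop("finite-difference step 'h' must be at most a/20")
    inter <- probes[probes$region == "interior", ]
    bath <- probes[probes$region == "bath", ]
    ixyz <- sph_to_cart(inter$r, inter$theta, inter$phi)
    vm <- function(r, th, ph) transmembrane_potential(object, r, th, ph)
    ps <- function(r, th, ph) monodomain_potential(object, r, th, ph)
    vm0 <- vm(inter$r, inter$theta, inter$phi)
    res_h <- fd_laplacian(vm, ixyz, h) - vm0 / lam^2
    add("pde_helmholtz_vm", max(abs(res_h)) / (max(abs(vm0)) / lam^2), 1e-3)
    ps0 <- ps(inter$r, inter$theta, inter$phi)
    add("pde_laplace_psi",
        max(abs(fd_laplacian(ps, ixyz, h))) / (max(abs(ps0)) / a^2), 1e-3)
    if (nrow(bath) > 0) {
      bxyz <- sph_to_cart(bath$r, bath$theta, bath$phi)
      bf <- function(r, th, ph) bath_secondary_potential(object, r, th, ph)
      b0 <- bf(bath$r, bath$theta, bath$phi)
      add("pde_laplace_bath",
          max(abs(fd_laplacian(bf, bxyz, h))) / (max(abs(b0)) / a^2), 1e-3)
    }
  }
  if (type == "all") {
    pp <- object$sources$p_plus; pm <- object$sources$p_minus
    planar <- abs(pp[2] - pi / 2) < 1e-9 && abs(pm[2] - pi / 2) < 1e-9
    axial <- sin(pp[2]) < 1e-9 && sin(pm[2]) < 1e-9
    if (planar) {
      J <- sample_current_grid(object, dims = c(64, 64, 1))
      ok <- J$mask %in% c(0L, 1L)
      jmax <- max(sqrt(J$Jx[ok]^2 + J$Jy[ok]^2 + J$Jz[ok]^2))
      add("symmetry_out_of_plane_current", max(abs(J$Jz[ok])) / jmax, 1e-10)
    }
    if (axial) {
      phg <- seq(0, 2 * pi, length.out = 25)[-25]
      rr <- c(0.5 * a, 0.9 * a); tt <- c(0.7, 2.1)
      var_rel <- 0
      for (r0 in rr) for (t0 in tt) {
        v <- domain_potentials(object, rep(r0, 24), rep(t0, 24), phg)
        for (f in c("phi_i", "phi_o", "V_m"))
          var_rel <- max(var_rel, diff(range(v[[f]])) / max(abs(v[[f]])))
        ve <- external_potential(object, rep(1.2 * a, 24), rep(t0, 24), phg)
        var_rel <- max(var_rel, diff(range(ve)) / max(abs(ve)))
      }
      add("symmetry_azimuthal_invariance", var_rel, 1e-10)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bidomain_validation", class(out))
  out
}

#' Current flux through a small sphere around an electrode
#'
#' Gauss's-law diagnostic: the flux of the bath current density \eqn{J_e}
#' through a sphere enclosing only the source (or sink) must equal
#' \eqn{+I_0} (or \eqn{-I_0}). The surface integral uses Gauss-Legendre
#' quadrature in the polar cosine and the trapezoid rule in azimuth, both on
#' the small sphere centered at the electrode.
#'
#' @param object a fitted [bidomain_sphere()] model.
#' @param which `"source"` or `"sink"`.
#' @param radius quadrature sphere radius (m); must keep the sphere inside
#'   the bath and away from the other electrode.
#' @param n_theta,n_phi quadrature orders.
#' @return the flux in amperes.
#' @export
source_flux <- function(object, which = c("source", "sink"), radius = 5e-4,
                        n_theta = 40, n_phi = 80) {
  which <- match.arg(which)
  ps <- if (which == "source") object$sources$p_plus else object$sources$p_minus
  center <- sph_to_cart(ps[1], ps[2], ps[3])
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phq <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  ct <- rep(gl$x, times = n_phi); w <- rep(gl$w, times = n_phi)
  ph <- rep(phq, each = n_theta)
  st <- sqrt(1 - ct^2)
  nrm <- cbind(st * cos(ph), st * sin(ph), ct)
  pts <- sweep(radius * nrm, 2, center, `+`)
  sph <- cart_to_sph(pts[, 1], pts[, 2], pts[, 3])
  ## evaluate J_e without the exclusion guard: the quadrature sphere
  ## deliberately surrounds the electrode, where the field is the
  ## closed-form monopole plus the smooth secondary series
  ev <- series_eval(list(bath = list(X = object$Ct, radial = "decaying")),
                    sph[, 1], sph[, 2], sph[, 3], object$config$a,
                    object$params$lambda, deriv = TRUE)$bath
  g <- cbind(ev$gr, ev$gt, ev$gp) +
    grad_source_sink(object, sph[, 1], sph[, 2], sph[, 3])
  J <- -g / object$params$rho_e
  Jc <- to_cartesian_vector(J[, 1], J[, 2], J[, 3], sph[, 2], sph[, 3])
  integrand <- rowSums(Jc * nrm)
  sum(integrand * w) * (2 * pi / n_phi) * radius^2
}

#' @export
print.bidomain_validation <- function(x, ...) {
  cat("Validation report\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-34s %12.3e  (tol %8.1e)  %s\n", x$metric[i], x$value[i],
                x$tol[i], if (x$pass[i]) "PASS" else "FAIL"))
  invisible(x)
}
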
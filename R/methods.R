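#' @export
print.bidomain_sphere <- function(x, ...) {
  p <- x$params; s <- x$sources; cfg <- x$config
  cat("Analytic spherical bidomain model\n")
  cat(sprintf("  tissue radius a      : %g mm\n", cfg$a * 1e3))
  cat(sprintf("  resistivities (Ohm m): rho_i %.3g, rho_o %.3g, rho_e %.3g\n",
              p$rho_i, p$rho_o, p$rho_e))
  cat(sprintf("  membrane             : R_m %.3g Ohm m^2, beta %.3g 1/m, lambda %.4g mm\n",
              p$R_m, p$beta, p$lambda * 1e3))
  cat(sprintf("  source  +I0 %.3g A at (r, theta, phi) = (%.3g mm, %.3g, %.3g)\n",
              s$I0, s$p_plus[1] * 1e3, s$p_plus[2], s$p_plus[3]))
  cat(sprintf("  sink    -I0          at (r, theta, phi) = (%.3g mm, %.3g, %.3g)\n",
              s$p_minus[1] * 1e3, s$p_minus[2], s$p_minus[3]))
  cat(sprintf("  harmonic truncation  : mu_max = %d (%d modes)\n",
              cfg$mu_max, (cfg$mu_max + 1L)^2))
  invisible(x)
}

#' @export
summary.bidomain_sphere <- function(object, ...) {
  print(object)
  rep <- residuals(object, type = "boundary", n_theta = 16, n_phi = 32)
  cat("\nInterface residuals (16 x 32 angular grid):\n")
  print(rep)
  invisible(object)
}

#' Evaluate model fields at new points
#'
#' @param object a fitted [bidomain_sphere()] model.
#' @param newdata data frame with either Cartesian columns `x`, `y`, `z` or
#'   spherical columns `r`, `theta`, `phi` (meters/radians).
#' @param type `"potential"` (default) for all scalar potentials defined at
#'   each point, or `"current"` for the current density (total tissue
#'   current \eqn{J_i + J_o} inside, bath current \eqn{J_e} outside) in
#'   Cartesian components.
#' @param ... unused.
#' @return `newdata` with the field columns appended; points inside the
#'   tissue get `phi_i`, `phi_o`, `V_m`, `psi`, bath points get `phi_e`.
#' @export
predict.bidomain_sphere <- function(object, newdata,
                                    type = c("potential", "current"), ...) {
  type <- match.arg(type)
  if (all(c("r", "theta", "phi") %in% names(newdata))) {
    r <- newdata$r; th <- newdata$theta; ph <- newdata$phi
  } else if (all(c("x", "y", "z") %in% names(newdata))) {
    sph <- cart_to_sph(newdata$x, newdata$y, newdata$z)
    r <- sph[, 1]; th <- sph[, 2]; ph <- sph[, 3]
  } else {
    stop("'newdata' must have columns x, y, z or r, theta, phi")
  }
  tis <- r <= object$config$a
  out <- newdata
  if (type == "potential") {
    out$phi_i <- out$phi_o <- out$V_m <- out$psi <- out$phi_e <- NA_real_
    if (any(tis)) {
      dp <- domain_potentials(object, r[tis], th[tis], ph[tis])
      out$phi_i[tis] <- dp$phi_i; out$phi_o[tis] <- dp$phi_o
      out$V_m[tis] <- dp$V_m; out$psi[tis] <- dp$psi
    }
    if (any(!tis))
      out$phi_e[!tis] <- external_potential(object, r[!tis], th[!tis], ph[!tis])
  } else {
    out$Jx <- out$Jy <- out$Jz <- NA_real_
    if (any(tis)) {
      Ji <- current_density_i(object, r[tis], th[tis], ph[tis])
      Jo <- current_density_o(object, r[tis], th[tis], ph[tis])
      cart <- to_cartesian_vector(Ji[, 1] + Jo[, 1], Ji[, 2] + Jo[, 2],
                                  Ji[, 3] + Jo[, 3], th[tis], ph[tis])
      out$Jx[tis] <- cart[, 1]; out$Jy[tis] <- cart[, 2]; out$Jz[tis] <- cart[, 3]
    }
    if (any(!tis)) {
      Je <- current_density_e(object, r[!tis], th[!tis], ph[!tis])
      cart <- to_cartesian_vector(Je[, 1], Je[, 2], Je[, 3], th[!tis], ph[!tis])
      out$Jx[!tis] <- cart[, 1]; out$Jy[!tis] <- cart[, 2]; out$Jz[!tis] <- cart[, 3]
    }
  }
  out
}

#' Plot potential profiles through the sphere
#'
#' Draws \eqn{\phi_i}, \eqn{\phi_o}, \eqn{V_m} and \eqn{\phi_e} along a line
#' through the center (default: the `z` axis), marking the tissue boundary.
#'
#' @param x a fitted [bidomain_sphere()] model.
#' @param axis,range,n passed to [line_profile()].
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.bidomain_sphere <- function(x, axis = "z", range = c(-4.5e-3, 4.5e-3),
                                 n = 181, ...) {
  pr <- line_profile(x, axis = axis, range = range, n = n)
  y <- cbind(pr$phi_i, pr$phi_o, pr$V_m, pr$phi_e)
  graphics::matplot(pr$s * 1e3, y * 1e3, type = "l", lty = c(4, 1, 3, 2),
                    col = 1, xlab = sprintf("position along %s (mm)",
                                            paste(axis, collapse = ",")),
                    ylab = "potential (mV)", ...)
  graphics::abline(v = c(-1, 1) * x$config$a * 1e3, col = "grey")
  graphics::legend("topright", c("phi_i", "phi_o", "V_m", "phi_e"),
                   lty = c(4, 1, 3, 2), bty = "n")
  invisible(pr)
}
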
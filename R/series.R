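## Internal spherical-harmonic series engine.
##
## All potentials in the model are truncated sums
##   f(r, theta, phi) = sum_mu sum_nu X[mu, nu] R_mu(r) Y_mu^nu(theta, phi)
## with one of three radial families (scaled to be O(1) at r = a so that
## stored coefficients stay well-conditioned at high degree):
##   "bessel"   R_mu(r) = i_mu(r / lambda)          (Helmholtz interior)
##   "growing"  R_mu(r) = (r / a)^mu                (Laplace, regular at 0)
##   "decaying" R_mu(r) = (a / r)^(mu + 1)          (Laplace, decaying)
## Coefficient matrices are complex, indexed [mu + 1, nu + 1] for nu >= 0;
## negative orders are implied by X[mu, -nu] = (-1)^nu Conj(X[mu, nu]), so
## sums assemble as real:  nu = 0 term + 2 Re(nu > 0 terms).
##
## Gradients are analytic:
##   d/dr i_mu(r/lambda) = (mu / r) i_mu(r/lambda) + i_{mu+1}(r/lambda)/lambda
##   dY/dtheta = nu cot(theta) Y_mu^nu + tau(mu, nu) e^{-i phi} Y_mu^{nu+1}
##   dY/dphi   = i nu Y_mu^nu
## On the polar axis the theta/phi components are evaluated by their exact
## limits (only nu = +/-1 terms survive; the cot/csc singularities cancel).

## radial family values and derivatives for one degree, vectorized in r
radial_terms <- function(radial, mu, r, a, lambda, deriv) {
  rtiny <- 1e-12 * a
  ok <- r >= rtiny
  if (radial == "bessel") {
    R <- mod_sph_bessel_i(mu, r / lambda)
    if (!deriv) return(list(R = R))
    dR <- numeric(length(r)); Rr <- numeric(length(r))
    dR[ok] <- (mu / r[ok]) * R[ok] + mod_sph_bessel_i(mu + 1, r[ok] / lambda) / lambda
    Rr[ok] <- R[ok] / r[ok]
    lim <- if (mu == 1) 1 / (3 * lambda) else 0
    dR[!ok] <- lim; Rr[!ok] <- lim
    return(list(R = R, dR = dR, Rr = Rr))
  }
  if (radial == "growing") {
    R <- (r / a)^mu
    if (!deriv) return(list(R = R))
    dR <- numeric(length(r)); Rr <- numeric(length(r))
    dR[ok] <- (mu / r[ok]) * R[ok]
    Rr[ok] <- R[ok] / r[ok]
    lim <- if (mu == 1) 1 / a else 0
    dR[!ok] <- lim; Rr[!ok] <- lim
    return(list(R = R, dR = dR, Rr = Rr))
  }
  ## decaying: bath only, r > 0 guaranteed by domain checks
  R <- (a / r)^(mu + 1)
  if (!deriv) return(list(R = R))
  list(R = R, dR = -(mu + 1) / r * R, Rr = R / r)
}

## specs: named list of list(X = complex matrix, radial = <family>)
## returns named list of list(value[, gr, gt, gp]) over the same points
series_eval <- function(specs, r, theta, phi, a, lambda, deriv = FALSE) {
  n <- max(length(r), length(theta), length(phi))
  r <- rep_len(r, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  mu_max <- max(vapply(specs, function(s) nrow(s$X) - 1L, integer(1)))
  costh <- cos(theta); sinth <- sin(theta)
  pole <- sinth < 1e-13
  south <- pole & costh < 0
  csc <- ifelse(pole, 0, 1 / sinth)
  cot <- costh * csc
  P <- pbar_table(mu_max, costh)
  cosn <- matrix(1, n, mu_max + 1L); sinn <- matrix(0, n, mu_max + 1L)
  if (mu_max >= 1L) for (nu in 1:mu_max) {
    cosn[, nu + 1L] <- cos(nu * phi); sinn[, nu + 1L] <- sin(nu * phi)
  }
  out <- lapply(specs, function(s) {
    z <- numeric(n)
    res <- list(value = z)
    if (deriv) res[c("gr", "gt", "gp")] <- list(z, z, z)
    res
  })
  rad_cache <- list()
  for (mu in 0:mu_max) {
    Pm <- P[[mu + 1L]]
    rad_cache <- list()  # per-degree cache keyed by radial family
    for (k in seq_along(specs)) {
      X <- specs[[k]]$X
      if (mu + 1L > nrow(X)) next
      reX <- Re(X[mu + 1L, seq_len(mu + 1L)])
      imX <- Im(X[mu + 1L, seq_len(mu + 1L)])
      if (all(reX == 0) && all(imX == 0)) next
      fam <- specs[[k]]$radial
      rt <- rad_cache[[fam]]
      if (is.null(rt)) {
        rt <- radial_terms(fam, mu, r, a, lambda, deriv)
        rad_cache[[fam]] <- rt
      }
      ## angular sum for the value / radial derivative
      ang <- reX[1L] * Pm[, 1L]
      if (mu >= 1L) for (nu in 1:mu)
        ang <- ang + 2 * (reX[nu + 1L] * cosn[, nu + 1L] -
                          imX[nu + 1L] * sinn[, nu + 1L]) * Pm[, nu + 1L]
      out[[k]]$value <- out[[k]]$value + rt$R * ang
      if (!deriv) next
      out[[k]]$gr <- out[[k]]$gr + rt$dR * ang
      ## theta component: nu cot P + tau P_{nu+1}
      tang <- reX[1L] * theta_derivative_factor(mu, 0) *
        (if (mu >= 1L) Pm[, 2L] else 0)
      if (mu >= 1L) for (nu in 1:mu) {
        Pnext <- if (nu < mu) Pm[, nu + 2L] else 0
        tang <- tang + 2 * (reX[nu + 1L] * cosn[, nu + 1L] -
                            imX[nu + 1L] * sinn[, nu + 1L]) *
          (nu * cot * Pm[, nu + 1L] + theta_derivative_factor(mu, nu) * Pnext)
      }
      out[[k]]$gt <- out[[k]]$gt + rt$Rr * tang
      ## phi component: 2 Re(i nu X e^{i nu phi}) Pbar / sin(theta)
      if (mu >= 1L) {
        pang <- 0
        for (nu in 1:mu)
          pang <- pang - 2 * nu * (reX[nu + 1L] * sinn[, nu + 1L] +
                                   imX[nu + 1L] * cosn[, nu + 1L]) * Pm[, nu + 1L]
        out[[k]]$gp <- out[[k]]$gp + rt$Rr * csc * pang
      }
      ## polar-axis limits for the angular components (nu = 1 terms only)
      if (any(pole) && mu >= 1L) {
        ## d(Pbar_mu1)/dtheta -> D at the north pole; under theta -> pi - u
        ## the theta-derivative picks up parity (-1)^mu while Pbar_mu1/sin
        ## (the csc factor of the phi component) picks up (-1)^(mu+1)
        D <- -sqrt((2 * mu + 1) * mu * (mu + 1) / (16 * pi))
        Dt <- ifelse(south[pole], (-1)^mu * D, D)
        Dc <- ifelse(south[pole], (-1)^(mu + 1) * D, D)
        cph <- cos(phi[pole]); sph <- sin(phi[pole])
        w_c <- 2 * (reX[2L] * cph - imX[2L] * sph)
        w_s <- -2 * (reX[2L] * sph + imX[2L] * cph)
        out[[k]]$gt[pole] <- out[[k]]$gt[pole] + rt$Rr[pole] * w_c * Dt
        out[[k]]$gp[pole] <- out[[k]]$gp[pole] + rt$Rr[pole] * w_s * Dc
      }
    }
  }
  out
}
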
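## Expansion coefficient of the free source/sink potential:
## phi_source + phi_sink = sum_{mu,nu} d[mu,nu] (r/a)^mu Y_mu^nu  for r < r_+,-
## from the interior expansion of 1/|r - r'|; stored scaled by a^mu (volts).
source_expansion_matrix <- function(sources, rho_e, a, mu_max) {
  pp <- sources$p_plus; pm <- sources$p_minus
  Pp <- pbar_table(mu_max, cos(pp[2])); Pm <- pbar_table(mu_max, cos(pm[2]))
  dt <- matrix(0 + 0i, mu_max + 1L, mu_max + 1L)
  for (mu in 0:mu_max) {
    nu <- 0:mu
    Yp <- Pp[[mu + 1L]][1, ] * exp(1i * nu * pp[3])
    Ym <- Pm[[mu + 1L]][1, ] * exp(1i * nu * pm[3])
    dt[mu + 1L, nu + 1L] <- a^mu * sources$I0 * rho_e / (2 * mu + 1) *
      (Conj(Yp) / pp[1]^(mu + 1) - Conj(Ym) / pm[1]^(mu + 1))
  }
  dt
}

#' Auxiliary source-geometry factor of the coefficient formulas
#'
#' The combination
#' \eqn{p = ((\mu+1) r_+^{\mu+1} + \mu r_-^{\mu+1}) Y_\mu^{-\nu}(\theta_-,\varphi_-)
#'      - (2\mu+1) r_-^{\mu+1} Y_\mu^{-\nu}(\theta_+,\varphi_+)}
#' that collects the electrode geometry in the closed-form expansion
#' coefficients. It vanishes identically when source and sink coincide.
#'
#' @param mu,nu harmonic degree and order.
#' @param sources a [source_pair()] object.
#' @return complex scalar (m^(mu+1)).
#' @export
aux_p <- function(mu, nu, sources) {
  pp <- sources$p_plus; pm <- sources$p_minus
  Ymm <- tesseral_harmonic(mu, -nu, pm[2], pm[3])
  Ypm <- tesseral_harmonic(mu, -nu, pp[2], pp[3])
  ((mu + 1) * pp[1]^(mu + 1) + mu * pm[1]^(mu + 1)) * Ymm -
    (2 * mu + 1) * pm[1]^(mu + 1) * Ypm
}

#' Auxiliary material factor of the coefficient formulas
#'
#' The denominator combination
#' \eqn{q = \lambda\mu(\rho_i+\rho_o)(\mu\rho_e + (\mu+1)\rho_o)\, i_\mu(a/\lambda)
#'      - a\, i_{\mu+1}(a/\lambda)(\mu\rho_e(\rho_i+\rho_o) + (\mu+1)\rho_i\rho_o)}.
#' For physical (strictly positive) parameters and `mu >= 0` it is nonzero;
#' a zero value indicates a singular configuration and raises an error.
#'
#' @param mu harmonic degree.
#' @param params a [tissue_parameters()] object.
#' @param a tissue radius (m).
#' @return real scalar (Ohm^2 m^3).
#' @export
aux_q <- function(mu, params, a) {
  lam <- params$lambda
  i0 <- mod_sph_bessel_i(mu, a / lam)
  i1 <- mod_sph_bessel_i(mu + 1, a / lam)
  q <- lam * mu * (params$rho_i + params$rho_o) *
    (mu * params$rho_e + (mu + 1) * params$rho_o) * i0 -
    a * i1 * (mu * params$rho_e * (params$rho_i + params$rho_o) +
              (mu + 1) * params$rho_i * params$rho_o)
  if (q == 0)
    stop(sprintf("singular configuration: q == 0 at mu = %d (a = %g, lambda = %g)",
                 mu, a, lam))
  q
}

## Solve the three interface conditions at r = a for one harmonic mode.
## Unknowns are scaled to their boundary values: A (transmembrane), Bt = b a^mu
## (monodomain), Ct = c a^-(mu+1) (secondary bath); dt is the source expansion
## term at r = a. Conditions (rows): no intracellular normal current,
## potential continuity, normal-current continuity.
mode_solve <- function(mu, dt, a, lambda, rho_i, rho_o, rho_e) {
  if (mu == 0) return(c(0 + 0i, dt, 0 + 0i))
  xa <- a / lambda
  i0 <- mod_sph_bessel_i(mu, xa)
  if (i0 == 0)
    stop(sprintf("i_mu(a/lambda) underflows at mu = %d; reduce mu_max", mu))
  ## solve for the boundary value At = A i_mu(a/lambda): keeps the system
  ## O(1)-conditioned even when i_mu(a/lambda) is far below 1 at high degree
  ipa <- mu + xa * mod_sph_bessel_i(mu + 1, xa) / i0  # a R'_mu(a)/R_mu(a)
  ki <- rho_i / (rho_i + rho_o); ko <- rho_o / (rho_i + rho_o)
  M <- matrix(c(
    ki * ipa,            mu,           0,
    -ko,                 1,            -1,
    -ko * ipa / rho_o,   mu / rho_o,   (mu + 1) / rho_e), 3, 3, byrow = TRUE)
  s <- solve(M, c(0, dt, mu * dt / rho_e))
  s[1] <- s[1] / i0
  s
}

## All modes up to mu_max; returns scaled complex matrices A, Bt, Ct, dt
compute_coefficients <- function(params, sources, config) {
  mu_max <- config$mu_max
  dt <- source_expansion_matrix(sources, params$rho_e, config$a, mu_max)
  A <- Bt <- Ct <- matrix(0 + 0i, mu_max + 1L, mu_max + 1L)
  for (mu in 0:mu_max) {
    ## solve once per degree for the real and imaginary parts jointly: the
    ## 3x3 system is identical for every order nu
    for (nu in 0:mu) {
      s <- mode_solve(mu, dt[mu + 1L, nu + 1L], config$a, params$lambda,
                      params$rho_i, params$rho_o, params$rho_e)
      A[mu + 1L, nu + 1L] <- s[1]
      Bt[mu + 1L, nu + 1L] <- s[2]
      Ct[mu + 1L, nu + 1L] <- s[3]
    }
  }
  list(A = A, Bt = Bt, Ct = Ct, dt = dt)
}

#' Fit the analytic spherical bidomain model
#'
#' Computes the full set of spherical-harmonic expansion coefficients of the
#' stimulated-sphere problem: for every harmonic mode `(mu, nu)` up to the
#' truncation bound, the three interface conditions at the tissue surface
#' (continuity of extracellular and bath potentials, continuity of normal
#' current between interstitium and bath, and vanishing intracellular normal
#' current) are solved exactly as a 3x3 linear system linking the
#' transmembrane, monodomain and secondary-bath coefficients to the
#' point-source expansion. The returned object evaluates every potential and
#' current-density field of the model.
#'
#' @param params tissue and bath electrical parameters, see
#'   [tissue_parameters()].
#' @param sources stimulating electrode pair, see [source_pair()]. Both
#'   electrodes must lie strictly outside the tissue sphere.
#' @param config geometry/truncation settings, see [model_config()].
#' @return object of class `bidomain_sphere` with components `params`,
#'   `sources`, `config` and the complex coefficient matrices (scaled to
#'   their boundary values). Use [coef()] for the coefficients in natural
#'   units, [predict()] to evaluate fields, [residuals()] for the
#'   boundary-condition and PDE residual report.
#' @examples
#' fit <- bidomain_sphere()
#' fit
#' head(coef(fit))
#' @export
bidomain_sphere <- function(params = tissue_parameters(),
                            sources = source_pair(),
                            config = model_config()) {
  stopifnot(inherits(params, "tissue_parameters"),
            inherits(sources, "source_pair"),
            inherits(config, "model_config"))
  if (sources$p_plus[1] <= config$a || sources$p_minus[1] <= config$a)
    stop("source and sink must lie strictly outside the tissue sphere (r > a)")
  co <- compute_coefficients(params, sources, config)
  structure(list(params = params, sources = sources, config = config,
                 A = co$A, Bt = co$Bt, Ct = co$Ct, dt = co$dt),
            class = "bidomain_sphere")
}

#' @describeIn bidomain_sphere expansion coefficients in natural units: a
#'   data frame over all `(mu, nu)` (including negative orders, obtained by
#'   conjugate symmetry) with complex columns `a` (V), `b` (V m^-mu) and
#'   `c` (V m^(mu+1)).
#' @param object,... a fitted `bidomain_sphere` (and ignored extra arguments).
#' @export
coef.bidomain_sphere <- function(object, ...) {
  a <- object$config$a
  rows <- list()
  for (mu in 0:object$config$mu_max) for (nu in -mu:mu) {
    anu <- abs(nu)
    av <- object$A[mu + 1L, anu + 1L]
    bv <- object$Bt[mu + 1L, anu + 1L] / a^mu
    cv <- object$Ct[mu + 1L, anu + 1L] * a^(mu + 1)
    if (nu < 0) {
      f <- (-1)^anu
      av <- f * Conj(av); bv <- f * Conj(bv); cv <- f * Conj(cv)
    }
    rows[[length(rows) + 1L]] <- data.frame(mu = mu, nu = nu,
                                            a = av, b = bv, c = cv)
  }
  do.call(rbind, rows)
}
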
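## shared fixtures and independent numerical oracles

## reference configuration, fitted once per test run
ref_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- bidomain_sphere()
    cache
  }
})

axi_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config("axisymmetric")
      cache <<- bidomain_sphere(cfg$params, cfg$sources, cfg$config)
    }
    cache
  }
})

## independent central-difference gradient oracle in Cartesian coordinates;
## f takes (r, theta, phi) vectors and returns values
fd_gradient_cart <- function(f, xyz, h) {
  g <- matrix(0, nrow(xyz), 3)
  for (i in 1:3) {
    p1 <- xyz; p1[, i] <- p1[, i] + h
    p2 <- xyz; p2[, i] <- p2[, i] - h
    s1 <- to_sph(p1); s2 <- to_sph(p2)
    g[, i] <- (f(s1[, 1], s1[, 2], s1[, 3]) - f(s2[, 1], s2[, 2], s2[, 3])) / (2 * h)
  }
  g
}

to_sph <- function(xyz) {
  r <- sqrt(rowSums(xyz^2))
  cbind(r, acos(pmin(1, pmax(-1, xyz[, 3] / r))), atan2(xyz[, 2], xyz[, 1]))
}

to_xyz <- function(r, theta, phi) {
  cbind(r * sin(theta) * cos(phi), r * sin(theta) * sin(phi), r * cos(theta))
}

## independent 7-point finite-difference Laplacian oracle
fd_laplacian_cart <- function(f, xyz, h) {
  v0 <- { s <- to_sph(xyz); f(s[, 1], s[, 2], s[, 3]) }
  acc <- -6 * v0
  for (i in 1:3) for (sgn in c(-1, 1)) {
    p <- xyz; p[, i] <- p[, i] + sgn * h
    s <- to_sph(p)
    acc <- acc + f(s[, 1], s[, 2], s[, 3])
  }
  acc / h^2
}

## simple independent Legendre polynomial (Bonnet recurrence, scalar)
legendre_poly_ref <- function(mu, x) {
  if (mu == 0) return(1)
  pm1 <- 1; p <- x
  if (mu == 1) return(p)
  for (k in 2:mu) {
    pn <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
    pm1 <- p; p <- pn
  }
  p
}

## random interior points of the reference sphere (caller sets the seed)
random_interior <- function(n, a = 2e-3, rmin = 0.1, rmax = 0.9) {
  cbind(r = runif(n, rmin, rmax) * a,
        theta = acos(runif(n, -1, 1)),
        phi = runif(n, -pi, pi))
}
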
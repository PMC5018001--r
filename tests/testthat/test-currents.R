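test_that("analytic gradients match finite differences everywhere tested", {
  fit <- ref_fit()
  set.seed(23)
  pts <- random_interior(30)
  xyz <- to_xyz(pts[, 1], pts[, 2], pts[, 3])
  h <- 1e-6 * fit$config$a
  cases <- list(
    V_m = function(r, t, p) transmembrane_potential(fit, r, t, p),
    psi = function(r, t, p) monodomain_potential(fit, r, t, p),
    phi_i = function(r, t, p) domain_potentials(fit, r, t, p)$phi_i,
    phi_o = function(r, t, p) domain_potentials(fit, r, t, p)$phi_o)
  for (f in names(cases)) {
    an <- field_gradient(fit, f, pts[, 1], pts[, 2], pts[, 3])
    anc <- to_cartesian_vector(an[, 1], an[, 2], an[, 3], pts[, 2], pts[, 3])
    fd <- fd_gradient_cart(cases[[f]], xyz, h)
    expect_lt(max(abs(anc - fd)) / max(abs(fd)), 1e-6)
  }
  ## bath side, including the free-monopole part
  rb <- seq(2.3e-3, 3.4e-3, length.out = 30)
  xyzb <- to_xyz(rb, pts[, 2], pts[, 3])
  an <- field_gradient(fit, "phi_e", rb, pts[, 2], pts[, 3])
  anc <- to_cartesian_vector(an[, 1], an[, 2], an[, 3], pts[, 2], pts[, 3])
  fd <- fd_gradient_cart(function(r, t, p) external_potential(fit, r, t, p),
                         xyzb, h)
  expect_lt(max(abs(anc - fd)) / max(abs(fd)), 1e-6)
})

test_that("a pure dipolar monodomain term has a uniform axial gradient", {
  fit <- ref_fit()
  toy <- fit
  toy$A[] <- 0; toy$Ct[] <- 0; toy$Bt[] <- 0
  b10 <- 2.5            # volts per (r/a) at the boundary
  toy$Bt[2, 1] <- b10
  ## b r Y_1^0 = b sqrt(3/4pi) z: gradient is constant along z
  pts <- rbind(c(1e-3, 0.3, 0.5), c(0.5e-3, 2.0, -1.2), c(1.9e-3, 1.5, 3.0),
               c(1e-3, 0, 0), c(1e-3, pi, 0), c(0, 0, 0))
  g <- field_gradient(toy, "psi", pts[, 1], pts[, 2], pts[, 3])
  gc <- to_cartesian_vector(g[, 1], g[, 2], g[, 3], pts[, 2], pts[, 3])
  want <- b10 / fit$config$a * sqrt(3 / (4 * pi))
  expect_equal(unname(gc[, 3]), rep(want, 6), tolerance = 1e-12)
  expect_lt(max(abs(gc[, 1:2])), 1e-12 * want)
})

test_that("polar-axis gradients equal their near-axis limits", {
  fit <- ref_fit()
  eps <- 1e-5
  for (f in c("psi", "V_m")) {
    g_pole <- field_gradient(fit, f, c(1e-3, 1e-3), c(0, pi), c(0.3, 0.3))
    g_near <- field_gradient(fit, f, c(1e-3, 1e-3), c(eps, pi - eps), c(0.3, 0.3))
    expect_equal(g_pole[, 2:3], g_near[, 2:3], tolerance = 1e-5)
  }
})

test_that("intracellular current has no radial component at the tissue surface", {
  fit <- ref_fit()
  th <- seq(0.05, pi - 0.05, length.out = 20)
  ph <- seq(-pi, pi, length.out = 21)[-21]
  g <- expand.grid(th = th, ph = ph)
  a <- fit$config$a
  Ji <- current_density_i(fit, rep(a, nrow(g)), g$th, g$ph)
  Je <- current_density_e(fit, rep(a, nrow(g)), g$th, g$ph)
  j_scale <- max(sqrt(rowSums(Je^2)))
  expect_lt(max(abs(Ji[, "v_r"])) / j_scale, 1e-10)
})

test_that("total tissue current is the monodomain current and is divergence-free", {
  fit <- ref_fit()
  set.seed(29)
  pts <- random_interior(20, rmin = 0.2, rmax = 0.8)
  Ji <- current_density_i(fit, pts[, 1], pts[, 2], pts[, 3])
  Jo <- current_density_o(fit, pts[, 1], pts[, 2], pts[, 3])
  ## J_i + J_o = -(1/rho_i + 1/rho_o) grad psi, via an independent path
  gp <- field_gradient(fit, "psi", pts[, 1], pts[, 2], pts[, 3])
  p <- fit$params
  expect_equal(Ji + Jo, -(1 / p$rho_i + 1 / p$rho_o) * gp, tolerance = 1e-12)
  ## finite-difference divergence of (J_i + J_o) vanishes at O(h^2)
  xyz <- to_xyz(pts[, 1], pts[, 2], pts[, 3])
  h <- fit$config$a / 200
  jcart <- function(which_col) function(xyzm) {
    s <- to_sph(xyzm)
    Ji <- current_density_i(fit, s[, 1], s[, 2], s[, 3])
    Jo <- current_density_o(fit, s[, 1], s[, 2], s[, 3])
    to_cartesian_vector(Ji[, 1] + Jo[, 1], Ji[, 2] + Jo[, 2],
                        Ji[, 3] + Jo[, 3], s[, 2], s[, 3])[, which_col]
  }
  div <- 0
  for (i in 1:3) {
    p1 <- xyz; p1[, i] <- p1[, i] + h
    p2 <- xyz; p2[, i] <- p2[, i] - h
    div <- div + (jcart(i)(p1) - jcart(i)(p2)) / (2 * h)
  }
  jmag <- max(sqrt(rowSums((Ji + Jo)^2)))
  expect_lt(max(abs(div)) / (jmag / fit$config$a), 1e-3)
})

test_that("transmembrane current balance: div J_i = -V_m / rho_m", {
  fit <- ref_fit()
  set.seed(31)
  pts <- random_interior(12, rmin = 0.25, rmax = 0.75)
  xyz <- to_xyz(pts[, 1], pts[, 2], pts[, 3])
  h <- fit$config$a / 300
  jicart <- function(i) function(xyzm) {
    s <- to_sph(xyzm)
    J <- current_density_i(fit, s[, 1], s[, 2], s[, 3])
    to_cartesian_vector(J[, 1], J[, 2], J[, 3], s[, 2], s[, 3])[, i]
  }
  div <- 0
  for (i in 1:3) {
    p1 <- xyz; p1[, i] <- p1[, i] + h
    p2 <- xyz; p2[, i] <- p2[, i] - h
    div <- div + (jicart(i)(p1) - jicart(i)(p2)) / (2 * h)
  }
  im <- -transmembrane_potential(fit, pts[, 1], pts[, 2], pts[, 3]) /
    fit$params$rho_m
  expect_equal(div, im, tolerance = 1e-3)
})

test_that("bath current approaches the free two-monopole field and conserves charge", {
  fit <- ref_fit()
  ## with the sphere's secondary response removed, a near-lone source gives
  ## the monopole field I0/(4 pi d^2) at distance d (sink pushed far away)
  far <- bidomain_sphere(sources = source_pair(p_plus = c(5e-3, pi / 2, 0),
                                               p_minus = c(5, pi, 0)))
  toy <- far; toy$Ct[] <- 0
  d <- 1e-3
  Je <- current_density_e(toy, 6e-3, pi / 2, 0)  # 1 mm outward of the source
  expect_equal(as.numeric(Je[, "v_r"]), 1e-3 / (4 * pi * d^2), tolerance = 1e-4)
  ## Gauss's law: flux of J_e through a 0.5 mm sphere around the source = I0
  flux <- source_flux(ref_fit(), radius = 5e-4, n_theta = 40, n_phi = 80)
  expect_equal(flux, 1e-3, tolerance = 1e-3)
})

test_that("the electrode plane carries no out-of-plane current", {
  J <- sample_current_grid(ref_fit(), dims = c(48, 48, 1))
  ok <- J$mask %in% c(0L, 1L)
  jmax <- max(sqrt(J$Jx[ok]^2 + J$Jy[ok]^2 + J$Jz[ok]^2))
  expect_lt(max(abs(J$Jz[ok])) / jmax, 1e-10)
})

test_that("sampled grids match pointwise field evaluation and mask correctly", {
  fit <- ref_fit()
  J <- sample_current_grid(fit, extent = 3e-3, dims = c(16, 16, 5))
  expect_equal(dim(J$Jx), c(16L, 16L, 5L))
  ## mask by radius test
  i <- 4L; j <- 9L; k <- 3L
  r <- sqrt(J$x[i]^2 + J$y[j]^2 + J$z[k]^2)
  expect_identical(J$mask[i, j, k],
                   if (r < fit$config$a) 0L else 1L)
  ## unmasked nodes equal pointwise evaluation
  idx <- which(J$mask == 1L, arr.ind = TRUE)[c(1, 40, 100), , drop = FALSE]
  for (q in seq_len(nrow(idx))) {
    x <- J$x[idx[q, 1]]; y <- J$y[idx[q, 2]]; z <- J$z[idx[q, 3]]
    s <- to_sph(matrix(c(x, y, z), 1))
    Je <- current_density_e(fit, s[1], s[2], s[3])
    cart <- to_cartesian_vector(Je[1], Je[2], Je[3], s[2], s[3])
    expect_equal(J$Jx[idx[q, 1], idx[q, 2], idx[q, 3]], cart[1], tolerance = 1e-12)
    expect_equal(J$Jz[idx[q, 1], idx[q, 2], idx[q, 3]], cart[3], tolerance = 1e-12)
  }
  ## coincident electrodes: zero grid
  same <- bidomain_sphere(sources = source_pair(p_plus = c(5e-3, 1, 1),
                                                p_minus = c(5e-3, 1, 1)))
  J0 <- sample_current_grid(same, dims = c(8, 8, 3))
  expect_equal(max(abs(J0$Jx), abs(J0$Jy), abs(J0$Jz)), 0)
})

test_that("mirror symmetry across the electrode plane flips only J_z", {
  J <- sample_current_grid(ref_fit(), extent = 2.8e-3, dims = c(12, 12, 5))
  ## z axis symmetric about 0: slice k and dims[3]+1-k mirror
  for (k in 1:2) {
    km <- 5 + 1 - k
    ok <- J$mask[, , k] %in% c(0L, 1L) & J$mask[, , km] %in% c(0L, 1L)
    expect_equal(J$Jx[, , k][ok], J$Jx[, , km][ok], tolerance = 1e-10)
    expect_equal(J$Jy[, , k][ok], J$Jy[, , km][ok], tolerance = 1e-10)
    expect_equal(J$Jz[, , k][ok], -J$Jz[, , km][ok], tolerance = 1e-10)
  }
})
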
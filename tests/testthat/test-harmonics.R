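test_that("modified spherical Bessel values match closed forms and limits", {
  expect_identical(mod_sph_bessel_i(0, 0), 1)
  expect_identical(mod_sph_bessel_i(1, 0), 0)
  expect_identical(mod_sph_bessel_i(5, 0), 0)
  ## i_0(x) = sinh(x)/x, i_1(x) = cosh(x)/x - sinh(x)/x^2
  x <- c(0.1, 0.5, 1, 2.5, 7)
  expect_equal(mod_sph_bessel_i(0, x), sinh(x) / x, tolerance = 1e-13)
  expect_equal(mod_sph_bessel_i(1, x), cosh(x) / x - sinh(x) / x^2,
               tolerance = 1e-13)
  expect_equal(mod_sph_bessel_i(0, 1), sinh(1), tolerance = 1e-12)
  expect_error(mod_sph_bessel_i(-1, 1), "nonnegative")
  expect_error(mod_sph_bessel_i(2, -0.5), "nonnegative")
})

test_that("Bessel recurrence i_(mu-1) - i_(mu+1) = (2mu+1)/x i_mu holds", {
  for (mu in 1:12) for (x in c(0.1, 0.5, 2, 10)) {
    lhs <- mod_sph_bessel_i(mu - 1, x) - mod_sph_bessel_i(mu + 1, x)
    rhs <- (2 * mu + 1) / x * mod_sph_bessel_i(mu, x)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("tiny-argument series branch is continuous with the Bessel branch", {
  for (mu in 0:4) {
    lo <- mod_sph_bessel_i(mu, 0.999e-8)
    hi <- mod_sph_bessel_i(mu, 1.001e-8)
    expect_equal(lo, hi, tolerance = 1e-8)
  }
})

test_that("tesseral harmonics have the right normalization and phase", {
  expect_equal(Re(tesseral_harmonic(0, 0, 0.7, 1.3)), 1 / sqrt(4 * pi),
               tolerance = 1e-14)
  expect_equal(abs(tesseral_harmonic(1, 0, pi / 2, 0)), 0, tolerance = 1e-15)
  ## explicit low-degree closed forms (Condon-Shortley convention)
  th <- 0.7; ph <- 1.3
  expect_equal(tesseral_harmonic(1, 1, th, ph),
               -sqrt(3 / (8 * pi)) * sin(th) * exp(1i * ph), tolerance = 1e-13)
  expect_equal(tesseral_harmonic(1, 0, th, ph),
               sqrt(3 / (4 * pi)) * cos(th) + 0i, tolerance = 1e-13)
  expect_equal(tesseral_harmonic(2, 2, th, ph),
               0.25 * sqrt(15 / (2 * pi)) * sin(th)^2 * exp(2i * ph),
               tolerance = 1e-13)
  expect_error(tesseral_harmonic(2, 3, th, ph), "nu")
})

test_that("conjugation symmetry holds up to degree 12 at randomized angles", {
  set.seed(42)
  th <- runif(8, 0.01, pi - 0.01); ph <- runif(8, -pi, pi)
  for (mu in c(1, 3, 7, 12)) for (nu in unique(c(1, mu %/% 2, mu))) {
    expect_equal(tesseral_harmonic(mu, -nu, th, ph),
                 (-1)^nu * Conj(tesseral_harmonic(mu, nu, th, ph)),
                 tolerance = 1e-12)
  }
})

test_that("addition theorem: sum_nu |Y|^2 = (2mu+1)/(4pi) and the two-point form", {
  s <- sum(sapply(-3:3, function(nu) abs(tesseral_harmonic(3, nu, 0.7, 1.3))^2))
  expect_equal(s, 7 / (4 * pi), tolerance = 1e-12)
  ## two-point form against direct Legendre evaluation
  th1 <- 1.1; ph1 <- 0.4; th2 <- 2.3; ph2 <- -1.7
  cosg <- cos(th1) * cos(th2) + sin(th1) * sin(th2) * cos(ph1 - ph2)
  for (mu in c(2, 5, 9)) {
    s2 <- sum(sapply(-mu:mu, function(nu)
      tesseral_harmonic(mu, nu, th1, ph1) *
        Conj(tesseral_harmonic(mu, nu, th2, ph2))))
    pleg <- legendre_poly_ref(mu, cosg)
    expect_equal(Re(s2), (2 * mu + 1) / (4 * pi) * pleg, tolerance = 1e-12)
    expect_lt(abs(Im(s2)), 1e-15)
  }
})

test_that("theta-derivative factor matches the gamma-ratio definition and vanishes at nu = mu", {
  ## gamma-ratio form evaluated directly where it is finite
  gam <- function(mu, nu) exp(0.5 * (lgamma(mu - nu + 1) + lgamma(mu + nu + 2) -
                                       lgamma(mu - nu) - lgamma(mu + nu + 1)))
  expect_equal(theta_derivative_factor(1, 0), sqrt(2), tolerance = 1e-14)
  expect_equal(theta_derivative_factor(1, 0), gam(1, 0), tolerance = 1e-14)
  expect_equal(theta_derivative_factor(4, 1), gam(4, 1), tolerance = 1e-13)
  expect_equal(theta_derivative_factor(7, -3), gam(7, -3), tolerance = 1e-13)
  expect_identical(theta_derivative_factor(2, 2), 0)
})

test_that("polar-derivative identity verified by finite differences", {
  ## dY/dtheta = nu cot(theta) Y + tau e^{-i phi} Y^{nu+1}
  h <- 1e-6
  for (case in list(c(4, 1), c(3, 0), c(5, 4), c(6, -2))) {
    mu <- case[1]; nu <- case[2]
    th <- 1.1; ph <- 0.4
    fd <- (tesseral_harmonic(mu, nu, th + h, ph) -
             tesseral_harmonic(mu, nu, th - h, ph)) / (2 * h)
    an <- nu / tan(th) * tesseral_harmonic(mu, nu, th, ph) +
      theta_derivative_factor(mu, nu) * exp(-1i * ph) *
        tesseral_harmonic(mu, nu + 1, th, ph)
    expect_equal(an, fd, tolerance = 1e-8)
  }
})

test_that("point-source radial factors have the stated values and branches", {
  expect_equal(greens_radial(0, 1e-3, 5e-3)$value, 200, tolerance = 1e-14)
  expect_equal(greens_radial(2, 5e-3, 5e-3)$value, 200, tolerance = 1e-14)
  expect_equal(greens_radial(1, 2e-3, 5e-3)$value, 80, tolerance = 1e-14)
  g <- greens_radial(3, 2e-3, 5e-3)
  expect_equal(g$g_less, 2e-3); expect_equal(g$g_greater, 5e-3)
  ## continuity across r = r_src
  expect_equal(greens_radial(4, 5e-3 * (1 - 1e-9), 5e-3)$value,
               greens_radial(4, 5e-3 * (1 + 1e-9), 5e-3)$value,
               tolerance = 1e-7)
  ## derivative branches
  expect_identical(greens_radial_derivative(0, 1e-3, 5e-3), 0)
  expect_equal(greens_radial_derivative(1, 2e-3, 5e-3), 1 / 0.005^2,
               tolerance = 1e-14)
  expect_equal(greens_radial_derivative(1, 6e-3, 5e-3),
               -2 * 0.005 / 0.006^3, tolerance = 1e-12)
  expect_error(greens_radial_derivative(2, 5e-3, 5e-3), "discontinuous")
  ## derivative consistent with finite differences on both branches
  for (r0 in c(3e-3, 8e-3)) {
    h <- 1e-9
    fd <- (greens_radial(2, r0 + h, 5e-3)$value -
             greens_radial(2, r0 - h, 5e-3)$value) / (2 * h)
    expect_equal(greens_radial_derivative(2, r0, 5e-3), fd, tolerance = 1e-6)
  }
})

test_that("truncated harmonic expansion reproduces 1/|r - r'| for separated points", {
  r <- 1.5e-3; th <- 0.8; ph <- 2.1
  rs <- 5e-3; ths <- 1.9; phs <- -0.6
  cosg <- cos(th) * cos(ths) + sin(th) * sin(ths) * cos(ph - phs)
  exact <- 1 / sqrt(r^2 + rs^2 - 2 * r * rs * cosg)
  acc <- 0
  for (mu in 0:40) {
    s <- sum(sapply(-mu:mu, function(nu)
      tesseral_harmonic(mu, nu, th, ph) *
        Conj(tesseral_harmonic(mu, nu, ths, phs))))
    acc <- acc + 4 * pi / (2 * mu + 1) * greens_radial(mu, r, rs)$value * Re(s)
  }
  expect_equal(acc, exact, tolerance = 1e-6)
})
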
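#' Vacuum permeability (T m / A)
#' @export
MU0 <- 4 * pi * 1e-7

## displacement coordinate along one padded dimension, in circular order:
## index k (1-based) maps to displacement (k-1) for k-1 < P/2, else k-1-P
pad_displacements <- function(P, h) {
  d <- 0:(P - 1)
  d[d >= P / 2] <- d[d >= P / 2] - P
  d * h
}

#' Biot-Savart convolution kernel on the padded lattice
#'
#' Samples the components of \eqn{G(r) = r / |r|^3}
#' (\eqn{G_x = x/(x^2+y^2+z^2)^{3/2}} etc.) on the zero-padded lattice of
#' relative voxel displacements. The singular center voxel is set to zero:
#' the kernel is odd, so its principal value over the self-voxel vanishes.
#' Each padded dimension has at least `2 n - 1` samples so that the circular
#' (FFT) convolution equals the linear one.
#'
#' @param grid a `cartesian_vector_grid` (only its `dims`/`spacing` are used).
#' @param pad_factor padded size as a multiple of the grid size (default 2).
#' @return list with 3-d arrays `Gx`, `Gy`, `Gz` (1/m^2), the padded `dims`
#'   and the voxel volume `dV` (m^3).
#' @export
biot_savart_kernel <- function(grid, pad_factor = 2) {
  if (pad_factor < 2) stop("'pad_factor' must be >= 2 to avoid circular wrap-around")
  n <- grid$dims
  h <- ifelse(grid$spacing > 0, grid$spacing, 1)
  P <- ifelse(n == 1L, 1L, as.integer(ceiling(pad_factor * n)))
  dx <- pad_displacements(P[1], h[1])
  dy <- pad_displacements(P[2], h[2])
  dz <- pad_displacements(P[3], h[3])
  X <- array(dx, P)
  Y <- array(rep(dy, each = P[1]), P)
  Z <- array(rep(dz, each = P[1] * P[2]), P)
  R3 <- (X^2 + Y^2 + Z^2)^1.5
  R3[1, 1, 1] <- Inf   # principal-value regularization of the self voxel
  list(Gx = X / R3, Gy = Y / R3, Gz = Z / R3, dims = P,
       dV = prod(ifelse(grid$spacing > 0, grid$spacing, 1)))
}

pad_array <- function(A, P) {
  out <- array(0, P)
  out[seq_len(dim(A)[1]), seq_len(dim(A)[2]), seq_len(dim(A)[3])] <- A
  out
}

#' Magnetic flux density from a sampled current grid (FFT convolution)
#'
#' Computes the Biot-Savart integral over the sampled volume as a difference
#' of discrete convolutions evaluated with the FFT (convolution theorem),
#' e.g. \eqn{B_z = \mu_0/(4\pi)\,[(J_x * G_y) - (J_y * G_x)]\,dV}.
#' The grids are zero-padded before transforming so no circular wrap-around
#' occurs, then cropped back to the sampling window. Only the current inside
#' the sampled cube contributes.
#'
#' @param J a `cartesian_vector_grid` from [sample_current_grid()].
#' @param components which Cartesian components of B to compute; the default
#'   `"z"` is the component measured along an MRI bore axis.
#' @param pad_factor padding multiple passed to [biot_savart_kernel()].
#' @return object of class `b_field_grid` with the requested component
#'   arrays (`Bz`, optionally `Bx`, `By`, tesla) on the same grid.
#' @export
b_field_fft <- function(J, components = "z", pad_factor = 2) {
  stopifnot(inherits(J, "cartesian_vector_grid"))
  if (!all(is.finite(J$Jx)) || !all(is.finite(J$Jy)) || !all(is.finite(J$Jz)))
    stop("current grid contains non-finite values")
  K <- biot_savart_kernel(J, pad_factor)
  P <- K$dims
  n <- J$dims
  Fj <- list(x = stats::fft(pad_array(J$Jx, P)),
             y = stats::fft(pad_array(J$Jy, P)),
             z = stats::fft(pad_array(J$Jz, P)))
  Fg <- list(x = stats::fft(K$Gx), y = stats::fft(K$Gy), z = stats::fft(K$Gz))
  conv_diff <- function(Fa, Gb, Fb, Ga) {
    full <- Re(stats::fft(Fa * Gb - Fb * Ga, inverse = TRUE)) / prod(P)
    full[seq_len(n[1]), seq_len(n[2]), seq_len(n[3]), drop = FALSE]
  }
  scale <- MU0 / (4 * pi) * K$dV
  out <- list(x = J$x, y = J$y, z = J$z, dims = n, spacing = J$spacing,
              origin = J$origin, mu0 = MU0,
              units = list(length = "m", B = "T"))
  if ("z" %in% components)
    out$Bz <- scale * array(conv_diff(Fj$x, Fg$y, Fj$y, Fg$x), n)
  if ("x" %in% components)
    out$Bx <- scale * array(conv_diff(Fj$y, Fg$z, Fj$z, Fg$y), n)
  if ("y" %in% components)
    out$By <- scale * array(conv_diff(Fj$z, Fg$x, Fj$x, Fg$z), n)
  structure(out, class = "b_field_grid")
}

#' Magnetic flux density by direct quadrature (oracle)
#'
#' Direct Riemann-sum evaluation of the Biot-Savart volume integral at grid
#' nodes, skipping the self voxel. Cost is O(number of evaluation nodes x
#' number of voxels); intended as an independent check of [b_field_fft()] on
#' small grids.
#'
#' @param J a `cartesian_vector_grid`.
#' @param idx optional integer matrix (rows `i, j, k`, 1-based) of evaluation
#'   nodes; default all nodes.
#' @param points optional numeric matrix of arbitrary Cartesian evaluation
#'   points (columns x, y, z; meters); overrides `idx`. Voxels closer than
#'   1e-6 of a spacing to an evaluation point are skipped.
#' @param components which components of B to compute (default `"z"`).
#' @return data frame with node indices (or `NA` for free points),
#'   coordinates and the requested component columns (tesla).
#' @export
b_field_direct <- function(J, idx = NULL, points = NULL, components = "z") {
  stopifnot(inherits(J, "cartesian_vector_grid"))
  n <- J$dims
  if (is.null(points)) {
    if (is.null(idx))
      idx <- as.matrix(expand.grid(i = seq_len(n[1]), j = seq_len(n[2]),
                                   k = seq_len(n[3])))
    out <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                      x = J$x[idx[, 1]], y = J$y[idx[, 2]], z = J$z[idx[, 3]])
    self <- (idx[, 3] - 1) * n[1] * n[2] + (idx[, 2] - 1) * n[1] + idx[, 1]
  } else {
    out <- data.frame(i = NA_integer_, j = NA_integer_, k = NA_integer_,
                      x = points[, 1], y = points[, 2], z = points[, 3])
    self <- rep(NA_integer_, nrow(points))
  }
  src <- expand.grid(x = J$x, y = J$y, z = J$z)
  jx <- as.vector(J$Jx); jy <- as.vector(J$Jy); jz <- as.vector(J$Jz)
  dV <- prod(ifelse(J$spacing > 0, J$spacing, 1))
  pref <- MU0 / (4 * pi) * dV
  tiny3 <- (1e-6 * min(J$spacing[J$spacing > 0]))^3
  m <- nrow(out)
  want <- intersect(c("x", "y", "z"), components)
  acc <- matrix(0, m, length(want)); colnames(acc) <- want
  for (q in seq_len(m)) {
    ddx <- out$x[q] - src$x; ddy <- out$y[q] - src$y; ddz <- out$z[q] - src$z
    R3 <- (ddx^2 + ddy^2 + ddz^2)^1.5
    if (!is.na(self[q])) R3[self[q]] <- Inf
    R3[R3 < tiny3] <- Inf
    if ("z" %in% want) acc[q, "z"] <- sum((jx * ddy - jy * ddx) / R3)
    if ("x" %in% want) acc[q, "x"] <- sum((jy * ddz - jz * ddy) / R3)
    if ("y" %in% want) acc[q, "y"] <- sum((jz * ddx - jx * ddz) / R3)
  }
  if ("x" %in% want) out$Bx <- pref * acc[, "x"]
  if ("y" %in% want) out$By <- pref * acc[, "y"]
  if ("z" %in% want) out$Bz <- pref * acc[, "z"]
  out
}
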
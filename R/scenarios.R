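#' Deterministic probe-point set
#'
#' A fixed set of 50 evaluation points stratified over the tissue interior
#' (30 points, radii 10-90 percent of `a`), the boundary shell (10 points, radii
#' 96-99.5 percent of `a`) and the near bath (10 points, radii 105-145 percent of `a`),
#' with directions laid out on a golden-angle spiral. Used by the
#' convergence study and the PDE residual checks; shipped verbatim as
#' `extdata/probe_points_synthetic.csv`.
#'
#' @param config a [model_config()] (supplies the radius `a`).
#' @return data frame with columns `r`, `theta`, `phi`, `region`.
#' @export
probe_points <- function(config = model_config()) {
  a <- config$a
  n <- 50L
  j <- seq_len(n)
  costh <- 1 - 2 * (j - 0.5) / n
  theta <- acos(costh)
  phi <- ((j * pi * (3 - sqrt(5))) + pi) %% (2 * pi) - pi
  region <- rep(c("interior", "boundary", "bath"), c(30L, 10L, 10L))
  ## radii per stratum, deterministic and interleaved with the spiral
  r <- numeric(n)
  r[1:30] <- a * (0.10 + 0.80 * (seq_len(30L) - 0.5) / 30)
  r[31:40] <- a * (0.960 + 0.035 * (seq_len(10L) - 0.5) / 10)
  r[41:50] <- a * (1.05 + 0.40 * (seq_len(10L) - 0.5) / 10)
  data.frame(r = r, theta = theta, phi = phi, region = region)
}

#' Scenario configuration
#'
#' Bundles a full model configuration with one of the standard study
#' scenarios. The resistivity-ratio tags fix the interstitial resistivity
#' relative to the bath (`rho_ratio_1`: \eqn{\rho_o = \rho_e};
#' `rho_ratio_0.1`: \eqn{\rho_o = 10\rho_e}; `rho_ratio_10`:
#' \eqn{\rho_o = 0.1\rho_e} -- the tag is the ratio \eqn{\rho_e/\rho_o}),
#' keeping the reference electrode geometry with both electrodes in the
#' `z = 0` plane (source on `+x`, sink on `-y`, 5 mm from center). The
#' `axisymmetric` tag instead puts the source directly above the tissue on
#' the `+z` axis and the sink on the `-z` axis, which reduces the problem to
#' two dimensions (azimuthal independence).
#'
#' @param scenario tag, see Details.
#' @param params,sources,config overrides for `"custom"` scenarios (ignored
#'   with a warning otherwise, except `config`).
#' @param extent,dims sampling-grid specification for [run_scenario()].
#' @param out_dir optional output directory for [run_scenario()].
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("rho_ratio_1", "rho_ratio_0.1",
                                         "rho_ratio_10", "axisymmetric",
                                         "custom"),
                            params = NULL, sources = NULL, config = NULL,
                            extent = 3e-3, dims = c(128, 128, 13),
                            out_dir = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(config)) config <- model_config()
  if (scenario != "custom") {
    rho_e <- 0.29
    rho_o <- switch(scenario, rho_ratio_1 = rho_e, rho_ratio_0.1 = 10 * rho_e,
                    rho_ratio_10 = 0.1 * rho_e, axisymmetric = rho_e)
    params <- tissue_parameters(rho_o = rho_o, rho_e = rho_e)
    sources <- if (scenario == "axisymmetric") {
      source_pair(p_plus = c(5e-3, 0, 0), p_minus = c(5e-3, pi, 0))
    } else {
      source_pair()
    }
  } else {
    if (is.null(params)) params <- tissue_parameters()
    if (is.null(sources)) sources <- source_pair()
  }
  structure(list(scenario = scenario, params = params, sources = sources,
                 config = config, extent = extent, dims = as.integer(dims),
                 out_dir = out_dir),
            class = "scenario_config")
}

#' Run a full forward-model scenario
#'
#' Fits the model, samples the potential (interstitial inside the sphere,
#' total bath potential outside) and the current density on the requested
#' grid, computes the magnetic flux density `Bz` by FFT convolution, and
#' assembles the validation report. If `out_dir` is set, writes
#' `potential.csv`, `current.csv`, `bz.csv` and `report.json` there. The
#' pipeline is deterministic: identical configurations give bit-identical
#' outputs.
#'
#' @param cfg a [scenario_config()].
#' @return (invisibly) list with elements `fit`, `potential` (data frame),
#'   `current` (`cartesian_vector_grid`), `bz` (`b_field_grid`) and
#'   `report` (validation data frame).
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  fit <- bidomain_sphere(cfg$params, cfg$sources, cfg$config)
  J <- sample_current_grid(fit, extent = cfg$extent, dims = cfg$dims)
  ## potential on the same nodes: phi_o inside, phi_e outside
  g <- expand.grid(x = J$x, y = J$y, z = J$z)
  sph <- cart_to_sph(g$x, g$y, g$z)
  pot <- numeric(nrow(g))
  tis <- sph[, 1] < cfg$config$a
  if (any(tis))
    pot[tis] <- domain_potentials(fit, sph[tis, 1], sph[tis, 2], sph[tis, 3])$phi_o
  if (any(!tis))
    pot[!tis] <- external_potential(fit, sph[!tis, 1], sph[!tis, 2], sph[!tis, 3])
  potential <- data.frame(g, phi = pot, region = ifelse(tis, "tissue", "bath"))
  bz <- b_field_fft(J)
  report <- residuals(fit)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(potential, file.path(cfg$out_dir, "potential.csv"),
                     row.names = FALSE)
    write_grid_csv(J, file.path(cfg$out_dir, "current.csv"))
    write_grid_csv(bz, file.path(cfg$out_dir, "bz.csv"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(list(fit = fit, potential = potential, current = J, bz = bz,
                 report = report))
}

#' Truncation convergence study
#'
#' Re-solves the model at each truncation bound in `mu_values` and tabulates
#' the maximum absolute change (volts) of the interstitial, bath and
#' transmembrane potentials over the fixed probe-point set between
#' consecutive bounds. For well-separated electrodes the change decreases
#' geometrically like \eqn{(a/r_\pm)^\mu}.
#'
#' @param params,sources,config model specification.
#' @param mu_values ascending integer truncation bounds.
#' @param probes optional probe data frame (default [probe_points()]).
#' @return data frame with columns `mu_from`, `mu_to`, `d_phi_o`, `d_phi_e`,
#'   `d_V_m`, `max_change` (V).
#' @export
convergence_study <- function(params = tissue_parameters(),
                              sources = source_pair(),
                              config = model_config(),
                              mu_values = c(2, 4, 6, 8, 10, 12, 14),
                              probes = NULL) {
  mu_values <- as.integer(mu_values)
  if (is.unsorted(mu_values, strictly = TRUE)) stop("'mu_values' must be ascending")
  if (is.null(probes)) probes <- probe_points(config)
  interior <- probes$r <= config$a
  eval_at <- function(mu) {
    fit <- bidomain_sphere(params, sources,
                           model_config(a = config$a, mu_max = mu,
                                        exclusion_radius = config$exclusion_radius))
    phi_o <- V_m <- rep(NA_real_, nrow(probes))
    if (any(interior)) {
      dp <- domain_potentials(fit, probes$r[interior], probes$theta[interior],
                              probes$phi[interior])
      phi_o[interior] <- dp$phi_o; V_m[interior] <- dp$V_m
    }
    phi_e <- rep(NA_real_, nrow(probes))
    if (any(!interior))
      phi_e[!interior] <- external_potential(fit, probes$r[!interior],
                                             probes$theta[!interior],
                                             probes$phi[!interior])
    list(phi_o = phi_o, phi_e = phi_e, V_m = V_m)
  }
  vals <- lapply(mu_values, eval_at)
  out <- data.frame()
  for (i in seq_len(length(mu_values) - 1L)) {
    dmax <- function(f) max(abs(vals[[i + 1L]][[f]] - vals[[i]][[f]]), na.rm = TRUE)
    out <- rbind(out, data.frame(mu_from = mu_values[i], mu_to = mu_values[i + 1L],
                                 d_phi_o = dmax("phi_o"), d_phi_e = dmax("phi_e"),
                                 d_V_m = dmax("V_m"),
                                 max_change = max(dmax("phi_o"), dmax("phi_e"),
                                                  dmax("V_m"))))
  }
  out
}

#' Potential profile along a line segment
#'
#' Evaluates \eqn{\phi_i}, \eqn{\phi_o}, \eqn{V_m}, \eqn{\psi} (tissue rows)
#' and \eqn{\phi_e} (bath rows) along a straight segment through the domain.
#' At the tissue radius the interface conditions are visible directly:
#' \eqn{\phi_o} and \eqn{\phi_e} meet, their slopes match in the ratio
#' \eqn{\rho_o/\rho_e}, and the slope of \eqn{\phi_i} vanishes.
#'
#' @param object a fitted [bidomain_sphere()] model.
#' @param axis `"x"`, `"y"`, `"z"` or a length-3 direction vector.
#' @param range numeric `c(from, to)` arc positions along the axis (m).
#' @param n number of sample points.
#' @param ss_mode source/sink evaluation mode for the bath potential.
#' @return data frame with columns `s` (signed arc position, m), `x`, `y`,
#'   `z`, `region`, `phi_i`, `phi_o`, `V_m`, `psi`, `phi_e`.
#' @export
line_profile <- function(object, axis = "z", range = c(-4.5e-3, 4.5e-3),
                         n = 181, ss_mode = c("closed_form", "series")) {
  ss_mode <- match.arg(ss_mode)
  dir <- if (is.character(axis)) {
    switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("'axis' must be x, y, z or a direction vector"))
  } else {
    axis / sqrt(sum(axis^2))
  }
  s <- seq(range[1], range[2], length.out = n)
  xyz <- outer(s, dir)
  sph <- cart_to_sph(xyz[, 1], xyz[, 2], xyz[, 3])
  a <- object$config$a
  tis <- sph[, 1] <= a
  out <- data.frame(s = s, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    region = ifelse(tis, "tissue", "bath"),
                    phi_i = NA_real_, phi_o = NA_real_, V_m = NA_real_,
                    psi = NA_real_, phi_e = NA_real_)
  if (any(tis)) {
    dp <- domain_potentials(object, sph[tis, 1], sph[tis, 2], sph[tis, 3])
    out$phi_i[tis] <- dp$phi_i; out$phi_o[tis] <- dp$phi_o
    out$V_m[tis] <- dp$V_m; out$psi[tis] <- dp$psi
  }
  if (any(!tis))
    out$phi_e[!tis] <- external_potential(object, sph[!tis, 1], sph[!tis, 2],
                                          sph[!tis, 3], ss_mode = ss_mode)
  out
}
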
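#' Langevin integration settings
#'
#' Configuration for the overdamped (position) Langevin integrator
#' (Euler-Maruyama). Reduced units: time, energy and length scales are set by
#' the model potential; `kT = 1` by default.
#'
#' @param timestep integration timestep (reduced time units), > 0
#' @param friction friction coefficient (inverse time), > 0
#' @param kT thermal energy (energy units), > 0
#' @param n_steps number of integration steps
#' @param seed integer RNG seed; identical seed and configuration give a
#'   bit-identical trajectory
#' @param save_stride record the state every this many steps
#' @return an object of class `langevin_config`
#' @export
langevin_config <- function(timestep = 1e-3, friction = 1, kT = 1,
                            n_steps = 1e5, seed = 1L, save_stride = 1L) {
  stopifnot(timestep > 0, friction > 0, kT > 0, n_steps >= 1,
            save_stride >= 1)
  structure(list(timestep = timestep, friction = friction, kT = kT,
                 n_steps = as.numeric(n_steps), seed = as.integer(seed),
                 save_stride = as.integer(save_stride)),
            class = "langevin_config")
}

#' @export
print.langevin_config <- function(x, ...) {
  cat(sprintf(
    "Langevin config: dt = %g, friction = %g, kT = %g, %g steps, seed %d\n",
    x$timestep, x$friction, x$kT, x$n_steps, x$seed))
  invisible(x)
}

# grid span of the biased CV: x-domain for 1-D kinds, [0, max radius] for 2-D
cv_grid_range <- function(potential) {
  if (potential$ndim == 2L) c(0, max(abs(potential$domain)))
  else potential$domain[1, ]
}

default_start <- function(potential) {
  switch(potential$kind,
    double_well_1d = -potential$params[["x0"]],
    radial_binding_2d = c(potential$params[["rho_min"]], 0),
    harmonic_1d = 0,
    flat_1d = 0)
}

build_trajectory <- function(res, potential, config) {
  cvs <- if (potential$ndim == 2L)
    cbind(rho = res$cv, cn = res$cn) else cbind(x = res$cv)
  structure(list(time = res$time, positions = res$positions, cv = cvs,
                 bias = res$bias, kT = config$kT, config = config,
                 potential = potential,
                 event = res$event, escape_time = res$escape_time),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("Langevin trajectory: %d saved frames, t in [%g, %g], CVs: %s\n",
              length(x$time), min(x$time), max(x$time),
              paste(colnames(x$cv), collapse = ", ")))
  if (isTRUE(x$event))
    cat(sprintf("  escape event at t = %g\n", x$escape_time))
  invisible(x)
}

#' Integrate overdamped Langevin dynamics on a model potential
#'
#' Euler-Maruyama integration of
#' \eqn{dx = -U'(x)/\gamma\,dt + \sqrt{2 kT dt/\gamma}\,\xi}. An optional
#' static bias potential acting on the collective variable (x in 1-D, the
#' radial distance in 2-D) is tabulated on a fine grid and added to the
#' deterministic force. Each saved frame records the CV values and the
#' instantaneous bias energy at the current CV point.
#'
#' @param potential a [model_potential()]
#' @param config a [langevin_config()]
#' @param bias optional function of the scalar CV returning a bias energy;
#'   evaluated on a `grid_n`-point grid spanning the CV domain
#' @param x0 starting position (defaults to the bound minimum)
#' @param grid_n resolution of the internal bias grid
#' @return an `md_trajectory` with fields `time`, `positions`, `cv` (matrix
#'   with named columns), and `bias` (instantaneous bias at each frame)
#' @export
simulate_langevin <- function(potential, config, bias = NULL, x0 = NULL,
                              grid_n = 2048L) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(config, "langevin_config"))
  if (is.null(x0)) x0 <- default_start(potential)
  gr <- cv_grid_range(potential)
  if (!is.null(bias)) {
    s <- seq(gr[1], gr[2], length.out = grid_n)
    V <- vapply(s, bias, numeric(1))
    if (any(!is.finite(V))) stop("bias evaluator returned non-finite values")
    h <- s[2] - s[1]
    dV <- c((V[2] - V[1]) / h, (V[-(1:2)] - V[-((grid_n - 1):grid_n)]) / (2 * h),
            (V[grid_n] - V[grid_n - 1]) / h)
  } else {
    V <- numeric(0); dV <- numeric(0)
  }
  set.seed(config$seed)
  res <- cpp_run_metad(potential$code, unname(potential$params),
                       as.numeric(x0),
                       config$timestep, config$friction, config$kT,
                       config$n_steps, config$save_stride,
                       0, 0L, 1.0, 2.0,
                       0, 0,
                       0L, 0,
                       cn_param(potential, "r0"), cn_param_i(potential, "m"),
                       cn_param_i(potential, "n"), cn_param(potential, "cmax"),
                       gr[1], gr[2], as.integer(grid_n), V, dV,
                       potential$domain[, 1], potential$domain[, 2])
  build_trajectory(res, potential, config)
}

cn_param <- function(potential, what) {
  if (is.null(potential$cn)) return(1)
  as.numeric(potential$cn[[what]])
}
cn_param_i <- function(potential, what) {
  if (is.null(potential$cn)) return(if (what == "m") 6L else 12L)
  as.integer(potential$cn[[what]])
}
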
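#' Analytic model potentials
#'
#' Constructs an analytic potential-energy surface used by the Langevin model
#' systems. Two physical kinds emulate a ligand-release landscape:
#'
#' \describe{
#'   \item{`double_well_1d`}{\eqn{U(x) = \Delta U ((x/x_0)^2 - 1)^2}: two
#'     minima at \eqn{\pm x_0} (each at energy 0) separated by a barrier of
#'     height `barrier` at the origin.}
#'   \item{`radial_binding_2d`}{Cartesian \eqn{(x, y)} dynamics on a radially
#'     symmetric landscape with a single bound well of depth `depth` at radius
#'     `rho_min`, a barrier of height `barrier` (above the outer plateau) at
#'     `rho_barrier`, and a flat plateau at level `plateau` beyond
#'     `flat_radius`. A synthetic coordination number
#'     \eqn{C_N(\rho) = c_{max} (1-(\rho/r_0)^m)/(1-(\rho/r_0)^n)} decreases
#'     smoothly from the bound well to the unbound plateau, so the
#'     two-dimensional \eqn{(\rho, C_N)} free-energy machinery is exercised.}
#' }
#'
#' `harmonic_1d` (\eqn{U = k x^2 / 2}) and `flat_1d` (\eqn{U = 0}) are
#' reference kinds with exactly known stationary laws.
#'
#' Energies are in kT units by default (reduced units, kT = 1).
#'
#' @param kind one of `"double_well_1d"`, `"radial_binding_2d"`,
#'   `"harmonic_1d"`, `"flat_1d"`
#' @param barrier barrier height. For `double_well_1d` the value of U at the
#'   origin; for `radial_binding_2d` the barrier top measured from the plateau.
#' @param x0 half-separation of the double-well minima
#' @param depth bound-well depth below the plateau (`radial_binding_2d`)
#' @param rho_min radius of the bound well
#' @param rho_barrier radius of the barrier top
#' @param width_well,width_barrier Gaussian widths of well and barrier
#' @param plateau outer plateau energy level
#' @param stiffness harmonic stiffness (`harmonic_1d`)
#' @param domain per-dimension closed interval(s): a length-2 vector (1-D) or
#'   2-column matrix (one row per dimension). Defaults cover the landscape.
#' @param cn coordination-number mapping for `radial_binding_2d`: a list with
#'   `r0`, `m`, `n`, `cmax`
#' @return an object of class `model_potential`
#' @examples
#' pot <- model_potential("double_well_1d", barrier = 5, x0 = 1)
#' potential_energy(pot, 0)    # barrier top
#' potential_energy(pot, 1)    # minimum
#' @export
model_potential <- function(kind = c("double_well_1d", "radial_binding_2d",
                                     "harmonic_1d", "flat_1d"),
                            barrier = 5, x0 = 1,
                            depth = 6, rho_min = 1, rho_barrier = 2,
                            width_well = 0.3, width_barrier = 0.25,
                            plateau = 0, stiffness = 1,
                            domain = NULL, cn = NULL) {
  kind <- match.arg(kind)
  pot <- switch(kind,
    double_well_1d = {
      stopifnot(barrier >= 0, x0 > 0)
      if (is.null(domain)) domain <- c(-2.5 * x0, 2.5 * x0)
      list(kind = kind, code = 1L, ndim = 1L,
           params = c(barrier = barrier, x0 = x0),
           domain = rbind(domain))
    },
    radial_binding_2d = {
      stopifnot(depth > 0, barrier >= 0, rho_min > 0,
                rho_barrier > rho_min, width_well > 0, width_barrier > 0)
      # radius beyond which every term is below 1e-10 x its amplitude:
      # the potential is constant there to well below 1e-9
      flat_radius <- max(
        rho_min + width_well * sqrt(2 * log(max(depth, 1) * 1e10)),
        rho_barrier + width_barrier * sqrt(2 * log(max(barrier, 1) * 1e10)))
      if (is.null(domain)) {
        rmax <- max(flat_radius + 1, 6)
        domain <- rbind(c(-rmax, rmax), c(-rmax, rmax))
      }
      if (is.null(cn)) cn <- list(r0 = 1.4, m = 6L, n = 12L, cmax = 1)
      list(kind = kind, code = 2L, ndim = 2L,
           params = c(depth = depth, barrier = barrier, rho_min = rho_min,
                      rho_barrier = rho_barrier, width_well = width_well,
                      width_barrier = width_barrier, plateau = plateau),
           flat_radius = flat_radius, cn = cn, domain = domain)
    },
    harmonic_1d = {
      stopifnot(stiffness > 0)
      if (is.null(domain)) domain <- c(-50, 50) / sqrt(stiffness)
      list(kind = kind, code = 3L, ndim = 1L,
           params = c(stiffness = stiffness), domain = rbind(domain))
    },
    flat_1d = {
      if (is.null(domain)) domain <- c(-1e6, 1e6)
      list(kind = kind, code = 4L, ndim = 1L, params = c(dummy = 0),
           domain = rbind(domain))
    })
  structure(pot, class = "model_potential")
}

as_point_matrix <- function(point, ndim) {
  m <- if (is.matrix(point)) point else matrix(point, ncol = ndim, byrow = FALSE)
  if (ncol(m) != ndim)
    stop("point has ", ncol(m), " columns; potential is ", ndim, "-dimensional")
  m
}

check_domain <- function(pot, pts) {
  for (d in seq_len(pot$ndim)) {
    bad <- pts[, d] < pot$domain[d, 1] | pts[, d] > pot$domain[d, 2]
    if (any(bad))
      stop("point outside evaluation domain in dimension ", d)
  }
  invisible(TRUE)
}

#' Evaluate a model potential
#'
#' @param potential a [model_potential()]
#' @param point numeric vector (one point) or matrix (one row per point)
#' @return energy value(s), in the potential's energy units (kT by default)
#' @export
potential_energy <- function(potential, point) {
  pts <- as_point_matrix(point, potential$ndim)
  check_domain(potential, pts)
  cpp_potential_energy(potential$code, unname(potential$params), pts)
}

#' Analytic gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return matrix of gradients, one row per point
#' @export
potential_gradient <- function(potential, point) {
  pts <- as_point_matrix(point, potential$ndim)
  check_domain(potential, pts)
  cpp_potential_gradient(potential$code, unname(potential$params), pts)
}

#' Radial profile of the 2-D binding potential
#'
#' @param potential a `radial_binding_2d` [model_potential()]
#' @param rho radial distances
#' @return energies at radius `rho`
#' @export
radial_profile <- function(potential, rho) {
  stopifnot(potential$kind == "radial_binding_2d")
  p <- unname(potential$params)
  p[7] - p[1] * exp(-0.5 * (rho - p[3])^2 / p[5]^2) +
    p[2] * exp(-0.5 * (rho - p[4])^2 / p[6]^2)
}

#' Synthetic coordination number of the 2-D binding potential
#'
#' A smooth, monotonically decreasing function of the radial distance built
#' from the rational switching function, standing in for the ligand-protein
#' contact count of an atomistic system.
#'
#' @inheritParams radial_profile
#' @return coordination values at radius `rho`
#' @export
coordination_of_rho <- function(potential, rho) {
  stopifnot(potential$kind == "radial_binding_2d")
  cn <- potential$cn
  cn$cmax * vapply(rho, cpp_switch_fun, numeric(1),
                   r0 = cn$r0, m = as.integer(cn$m), n = as.integer(cn$n))
}

#' @export
print.model_potential <- function(x, ...) {
  cat("Model potential:", x$kind, "(", x$ndim, "D )\n")
  cat("  parameters:",
      paste(names(x$params), signif(x$params, 4), sep = " = ",
            collapse = ", "), "\n")
  cat("  domain:",
      paste(apply(x$domain, 1, function(d)
        sprintf("[%g, %g]", d[1], d[2])), collapse = " x "), "\n")
  if (!is.null(x$flat_radius))
    cat("  flat beyond rho =", signif(x$flat_radius, 4), "\n")
  invisible(x)
}
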
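#' Spherical collective variables of a ligand position
#'
#' Transforms the displacement of a point from a centre (typically the
#' ligand and protein centres of mass) into spherical coordinates: radial
#' distance `rho`, polar angle (from the z-axis, in [0, pi]) and azimuthal
#' angle (in the x-y plane, in (-pi, pi]). Because the literature is not
#' consistent about which of theta/phi names the polar angle, the fields are
#' named `polar` and `azimuth` explicitly.
#'
#' @param point,center numeric 3-vectors
#' @return a list with `rho`, `polar`, `azimuth` (class `spherical_cv`)
#' @export
spherical_cvs <- function(point, center = c(0, 0, 0)) {
  d <- as.numeric(point) - as.numeric(center)
  stopifnot(length(d) == 3)
  rho <- sqrt(sum(d^2))
  if (rho == 0) stop("zero displacement: spherical angles are undefined")
  structure(list(rho = rho,
                 polar = acos(max(-1, min(1, d[3] / rho))),
                 azimuth = atan2(d[2], d[1])),
            class = "spherical_cv")
}

#' Cartesian point from spherical collective variables
#'
#' Inverse of [spherical_cvs()].
#'
#' @param cv a `spherical_cv` (or list with `rho`, `polar`, `azimuth`)
#' @param center centre of the spherical frame
#' @return numeric 3-vector
#' @export
cartesian_from_spherical <- function(cv, center = c(0, 0, 0)) {
  center + cv$rho * c(sin(cv$polar) * cos(cv$azimuth),
                      sin(cv$polar) * sin(cv$azimuth),
                      cos(cv$polar))
}

#' Spherical restraint parameters
#'
#' One-sided harmonic wall confining the unbound ligand to a sphere of radius
#' `rho_s`, enabling repeated binding and unbinding. Defaults are the values
#' used in volume-based binding studies: k = 200 kJ/mol/A^2, rho_s = 28 A.
#'
#' @param k spring constant (energy per length squared), >= 0
#' @param rho_s restraint radius (length units), > 0
#' @return an object of class `wall_params`
#' @export
wall_params <- function(k = 200, rho_s = 28) {
  stopifnot(k >= 0, rho_s > 0)
  structure(list(k = k, rho_s = rho_s), class = "wall_params")
}

#' One-sided harmonic restraining potential
#'
#' \eqn{V(\rho) = 0} for \eqn{\rho \le \rho_s} and
#' \eqn{k (\rho - \rho_s)^2} beyond: the upper-wall convention with no 1/2
#' prefactor, matching how the spring constant is conventionally quoted for
#' restraints of this kind. Continuous with continuous first derivative at
#' the boundary.
#'
#' @param rho radial distance(s), >= 0
#' @param wall a [wall_params()]
#' @return restraint energies
#' @export
wall_potential <- function(rho, wall = wall_params()) {
  stopifnot(all(rho >= 0))
  ifelse(rho <= wall$rho_s, 0, wall$k * (rho - wall$rho_s)^2)
}

#' Coordination-number specification
#'
#' Parameters of the rational switching function used to count
#' ligand-protein contacts. Defaults are the native-contact definition used
#' in protein-ligand contact maps: r0 = 4.5 A with exponents m = 6, n = 12.
#'
#' @param r0 contact cutoff distance, > 0
#' @param m,n integer switching exponents with 0 < m < n
#' @param group_a,group_b optional disjoint, non-empty index vectors naming
#'   the two atom groups
#' @return an object of class `coordination_spec`
#' @export
coordination_spec <- function(r0 = 4.5, m = 6L, n = 12L,
                              group_a = NULL, group_b = NULL) {
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(r0 > 0, m > 0, n > m)
  if (!is.null(group_a) || !is.null(group_b)) {
    stopifnot(length(group_a) > 0, length(group_b) > 0,
              length(intersect(group_a, group_b)) == 0)
  }
  structure(list(r0 = r0, m = m, n = n,
                 group_a = group_a, group_b = group_b),
            class = "coordination_spec")
}

#' Rational switching function
#'
#' \eqn{s(r) = (1 - (r/r_0)^m) / (1 - (r/r_0)^n)}, a smooth, monotonically
#' decreasing contact indicator equal to 1 at r = 0 and decaying as
#' \eqn{(r_0/r)^{n-m}} at large r. The removable singularity at
#' \eqn{r = r_0} is evaluated analytically as the limit m/n.
#'
#' @param r distance(s), >= 0
#' @param spec a [coordination_spec()]
#' @return switching values in [0, 1]
#' @export
switching_value <- function(r, spec = coordination_spec()) {
  stopifnot(all(r >= 0))
  vapply(r, cpp_switch_fun, numeric(1),
         r0 = spec$r0, m = spec$m, n = spec$n)
}

#' Coordination number between two atom groups
#'
#' Smooth contact count: the sum of [switching_value()] over all pairs of one
#' position from group A and one from group B.
#'
#' @param pos_a,pos_b coordinate matrices (one row per atom, 3 columns)
#' @param spec a [coordination_spec()]
#' @return non-negative coordination number
#' @export
coordination_number <- function(pos_a, pos_b, spec = coordination_spec()) {
  pos_a <- rbind(pos_a); pos_b <- rbind(pos_b)
  stopifnot(nrow(pos_a) > 0, nrow(pos_b) > 0,
            ncol(pos_a) == ncol(pos_b))
  total <- 0
  for (i in seq_len(nrow(pos_a))) {
    d <- sqrt(colSums((t(pos_b) - pos_a[i, ])^2))
    total <- total + sum(switching_value(d, spec))
  }
  total
}

#' Unbinding-commitment monitor
#'
#' Scans a coordination-number time series for the first time the value
#' drops below a threshold, the commitment criterion declaring the ligand
#' fully unbound (default threshold 0.01). Later re-entries are ignored.
#'
#' @param series numeric coordination-number time series
#' @param times sample times (defaults to 0-based uniform indices)
#' @param threshold commitment threshold
#' @return list with `event` (logical), `time` and `index` of the first
#'   passage (both `NA` when censored)
#' @export
unbinding_monitor <- function(series, times = NULL, threshold = 0.01) {
  if (length(series) == 0) stop("empty coordination series")
  if (any(!is.finite(series))) stop("non-finite values in coordination series")
  if (is.null(times)) times <- seq_along(series) - 1
  stopifnot(length(times) == length(series))
  idx <- which(series < threshold)
  if (length(idx) == 0)
    list(event = FALSE, time = NA_real_, index = NA_integer_)
  else
    list(event = TRUE, time = times[idx[1]], index = idx[1])
}
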
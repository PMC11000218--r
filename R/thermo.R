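#' Region of a free-energy surface
#'
#' A box in CV space over which the Boltzmann weight is integrated, labelled
#' bound or unbound. Intervals are named by CV axis; an axis omitted from the
#' box spans its full grid range.
#'
#' @param ... named length-2 numeric intervals, e.g.
#'   `rho = c(0.64, 0.84), cn = c(175, 197)`
#' @param label `"bound"` or `"unbound"`
#' @return an object of class `region_box`
#' @export
region_box <- function(..., label = c("bound", "unbound")) {
  label <- match.arg(label)
  iv <- list(...)
  stopifnot(length(iv) >= 1, !is.null(names(iv)))
  for (v in iv) stopifnot(length(v) == 2, v[2] > v[1])
  structure(list(intervals = iv, label = label), class = "region_box")
}

region_mask <- function(fes, region) {
  dims <- vapply(fes$edges, function(e) length(e) - 1L, integer(1))
  in_axis <- lapply(seq_along(fes$cv_names), function(d) {
    nm <- fes$cv_names[d]
    if (nm %in% names(region$intervals)) {
      iv <- region$intervals[[nm]]
      fes$mids[[d]] >= iv[1] & fes$mids[[d]] <= iv[2]
    } else rep(TRUE, dims[d])
  })
  if (length(dims) == 1L) in_axis[[1]]
  else outer(in_axis[[1]], in_axis[[2]], `&`)
}

cell_areas <- function(fes) {
  w <- lapply(fes$edges, diff)
  if (length(w) == 1L) w[[1]] else outer(w[[1]], w[[2]])
}

#' Bound/unbound free-energy difference from a surface
#'
#' Integrates the Boltzmann weight \eqn{e^{-\beta F(s)}} over the bound and
#' unbound regions with a cell-area-weighted (piecewise-constant) rule and
#' returns
#' \deqn{\Delta G_{MetaD} = -kT \ln
#'   \frac{\int_{bound} e^{-\beta F} ds}{\int_{unbound} e^{-\beta F} ds}.}
#' Negative when the bound basin is deeper or wider. Unvisited cells are
#' excluded (F = +Inf); a warning is raised when more than 10% of a region's
#' cells are unvisited.
#'
#' @param fes an [fes_grid()]
#' @param bound,unbound [region_box()] objects
#' @param kT thermal energy (defaults to the grid's)
#' @return the free-energy difference, in the grid's energy units
#' @export
free_energy_difference <- function(fes, bound, unbound, kT = fes$kT) {
  areas <- cell_areas(fes)
  beta <- 1 / kT
  region_sum <- function(region) {
    mask <- region_mask(fes, region)
    if (!any(mask)) stop("region '", region$label,
                         "' contains no grid cells")
    vis <- mask & is.finite(fes$F)
    if (!any(vis)) stop("region '", region$label,
                        "' contains no visited cells")
    frac_unvis <- 1 - sum(vis) / sum(mask)
    if (frac_unvis > 0.10)
      warning(sprintf("%.0f%% of region '%s' is unvisited",
                      100 * frac_unvis, region$label))
    # log-sum-exp over cells for numerical safety at large beta*F
    v <- -beta * fes$F[vis] + log(areas[vis])
    logsumexp(v)
  }
  -kT * (region_sum(bound) - region_sum(unbound))
}

#' Thermodynamic reporting parameters
#'
#' @param temperature temperature in K (default 300, the thermostat setting
#'   of the reference study)
#' @param rho_s restraint radius in Angstrom
#' @param v_prot protein volume inside the restraint sphere, in cubic
#'   Angstrom (an input: measured externally with a probe-grid tool)
#' @param v0 standard-state volume in cubic Angstrom (1660, the inverse of
#'   the 1 M standard concentration)
#' @param c0 standard concentration in mol/L
#' @param gas_constant gas constant in kcal/mol/K
#' @return an object of class `thermo_params`
#' @export
thermo_params <- function(temperature = 300, rho_s = 28, v_prot = 48300,
                          v0 = 1660, c0 = 1,
                          gas_constant = GAS_CONSTANT_KCAL) {
  stopifnot(temperature > 0, rho_s > 0, v_prot >= 0, v0 > 0, c0 > 0)
  v0_expected <- 1e27 / (c0 * AVOGADRO)  # 1 L = 1e27 A^3
  if (abs(v0 - v0_expected) / v0_expected > 0.001)
    stop(sprintf(
      "v0 = %g A^3 is inconsistent with c0 = %g M (expected %.1f A^3)",
      v0, c0, v0_expected))
  structure(list(temperature = temperature, rho_s = rho_s, v_prot = v_prot,
                 v0 = v0, c0 = c0, gas_constant = gas_constant),
            class = "thermo_params")
}

#' Restraint-volume entropy correction
#'
#' The spherical restraint limits the translational freedom of the unbound
#' ligand; converting to the 1 M standard state adds
#' \deqn{T\Delta S = RT \ln \frac{\frac{4}{3}\pi \rho_s^3 - V_{prot}}{V^0},}
#' where the numerator is the solvent-accessible volume inside the restraint
#' sphere.
#'
#' @param params a [thermo_params()]
#' @return the correction TdS in kcal/mol
#' @export
volume_entropy_correction <- function(params) {
  v_sphere <- 4 / 3 * pi * params$rho_s^3
  v_acc <- v_sphere - params$v_prot
  if (v_acc <= 0) stop("accessible volume is non-positive: the restraint ",
                       "sphere must be larger than the protein volume")
  params$gas_constant * params$temperature * log(v_acc / params$v0)
}

#' Standard-state binding free energy
#'
#' \eqn{\Delta G_b^\circ = \Delta G_{MetaD} - T\Delta S}: the raw
#' metadynamics bound/unbound difference corrected to the 1 M standard state.
#'
#' @param dg_metad free-energy difference from [free_energy_difference()]
#'   (kcal/mol)
#' @param tds correction from [volume_entropy_correction()] (kcal/mol)
#' @return standard binding free energy (kcal/mol)
#' @export
standard_binding_free_energy <- function(dg_metad, tds) dg_metad - tds

#' Dissociation constant from a binding free energy
#'
#' \eqn{K_d = C^0 \exp(\Delta G_b^\circ / RT)}: a more negative binding free
#' energy gives a smaller dissociation constant.
#'
#' @param dg_b standard binding free energy in kcal/mol
#' @param temperature temperature in K
#' @param c0 standard concentration in mol/L
#' @param gas_constant gas constant in kcal/mol/K
#' @return dissociation constant in mol/L
#' @export
kd_from_dg <- function(dg_b, temperature = 300, c0 = 1,
                       gas_constant = GAS_CONSTANT_KCAL) {
  stopifnot(temperature > 0)
  c0 * exp(dg_b / (gas_constant * temperature))
}

#' Assemble a binding-thermodynamics result
#'
#' Combines the metadynamics free-energy difference with the volume-entropy
#' correction into the standard binding free energy and dissociation
#' constant, carrying the block-analysis error alongside.
#'
#' @param dg_metad free-energy difference (kcal/mol)
#' @param params a [thermo_params()]
#' @param dg_error block-analysis standard error on `dg_metad` (kcal/mol)
#' @return an object of class `thermo_result` with fields `dg_metad`, `tds`,
#'   `dg_b`, `kd` (mol/L), `dg_error`
#' @export
thermo_result <- function(dg_metad, params = thermo_params(),
                          dg_error = NA_real_) {
  tds <- volume_entropy_correction(params)
  dg_b <- standard_binding_free_energy(dg_metad, tds)
  kd <- kd_from_dg(dg_b, params$temperature, params$c0, params$gas_constant)
  structure(list(dg_metad = dg_metad, tds = tds, dg_b = dg_b, kd = kd,
                 dg_error = dg_error, params = params),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  err <- if (is.finite(x$dg_error)) sprintf(" +/- %.1f", x$dg_error) else ""
  cat(sprintf("dG_MetaD = %.1f%s kcal/mol\n", x$dg_metad, err))
  cat(sprintf("TdS      = %.1f kcal/mol (volume-entropy correction)\n",
              x$tds))
  cat(sprintf("dG_b0    = %.1f%s kcal/mol\n", x$dg_b, err))
  cat(sprintf("K_d      = %.2g mM\n", 1000 * x$kd))
  invisible(x)
}

#' Block-analysis standard error
#'
#' Standard error of the (optionally weighted) mean of a correlated series,
#' from non-overlapping block means at a range of block sizes. The reported
#' value is the plateau, taken as the maximum standard error over the
#' scanned sizes.
#'
#' @param x sample series
#' @param weights optional per-sample weights
#' @param block_sizes block sizes to scan (default: powers of 2 from 1 to
#'   n/4, so every size has at least 4 blocks)
#' @return list with `sizes`, `se` (per size), `plateau` (class
#'   `block_error`)
#' @export
block_error <- function(x, weights = NULL, block_sizes = NULL) {
  n <- length(x)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  if (is.null(block_sizes))
    block_sizes <- 2^(0:max(0, floor(log2(n / 4))))
  block_sizes <- block_sizes[block_sizes <= n / 2]
  if (length(block_sizes) == 0)
    stop("series too short for the requested block sizes")
  se <- vapply(block_sizes, function(b) {
    nb <- floor(n / b)
    idx <- rep(seq_len(nb), each = b)
    xs <- x[seq_len(nb * b)]
    ws <- weights[seq_len(nb * b)]
    bm <- as.numeric(rowsum(xs * ws, idx)) / as.numeric(rowsum(ws, idx))
    stats::sd(bm) / sqrt(nb)
  }, numeric(1))
  structure(list(sizes = block_sizes, se = se, plateau = max(se)),
            class = "block_error")
}

#' @export
print.block_error <- function(x, ...) {
  cat(sprintf("Block-analysis standard error: plateau %.4g (%d sizes)\n",
              x$plateau, length(x$sizes)))
  invisible(x)
}

#' Free-energy difference as a function of simulation time
#'
#' Recomputes the reweighted surface and the bound/unbound difference using
#' only the hills and samples collected up to each checkpoint, giving the
#' convergence profile of the estimate.
#'
#' @param run a [run_metad()] result
#' @param edges FES grid edges (named list)
#' @param bound,unbound [region_box()] objects
#' @param checkpoints increasing checkpoint times
#' @param ... passed to [reweight_from_run()]
#' @return data frame with `time` and `dg`
#' @export
dg_convergence <- function(run, edges, bound, unbound, checkpoints, ...) {
  stopifnot(all(diff(checkpoints) > 0))
  dg <- vapply(checkpoints, function(tc) {
    fes <- reweight_from_run(run, edges, t_max = tc, ...)
    free_energy_difference(fes, bound, unbound)
  }, numeric(1))
  data.frame(time = checkpoints, dg = dg)
}

#' Block-analysis error of the free-energy difference
#'
#' Splits the post-transient trajectory into contiguous blocks, computes the
#' reweighted bound/unbound difference in each block (with the offset series
#' c(t) from the full run), and returns the spread of the block estimates.
#'
#' @inheritParams dg_convergence
#' @param n_blocks number of contiguous blocks
#' @param transient_fraction initial fraction of the time span discarded
#' @return list with `dg` (full-data estimate), `se` (standard error of the
#'   block mean), `blocks` (per-block estimates)
#' @export
dg_block_error <- function(run, edges, bound, unbound, n_blocks = 5,
                           transient_fraction = 0.1) {
  traj <- run$trajectory
  cv_name <- hills_cv_names(run$hills)
  ax <- if (cv_name %in% names(edges)) edges[[cv_name]] else
    seq(min(traj$cv[, cv_name]), max(traj$cv[, cv_name]), length.out = 101)
  cg <- (head(ax, -1) + tail(ax, -1)) / 2
  ct <- compute_c_of_t(run$hills, cg, run$params$bias_factor, kT = traj$kT)
  keep <- traj$time >= transient_fraction * max(traj$time)
  idx <- which(keep)
  splits <- split(idx, cut(seq_along(idx), n_blocks, labels = FALSE))
  blk <- vapply(splits, function(ii) {
    fes <- reweight_fes(traj$cv[ii, , drop = FALSE], traj$bias[ii],
                        traj$time[ii], ct, edges, kT = traj$kT,
                        transient_fraction = 0)
    free_energy_difference(fes, bound, unbound)
  }, numeric(1))
  fes_full <- reweight_fes(traj$cv[idx, , drop = FALSE], traj$bias[idx],
                           traj$time[idx], ct, edges, kT = traj$kT,
                           transient_fraction = 0)
  list(dg = free_energy_difference(fes_full, bound, unbound),
       se = stats::sd(blk) / sqrt(length(blk)),
       blocks = blk)
}
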
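#' Free-energy surface grid
#'
#' Regular grid over one or two collective variables holding a free energy
#' per cell. Unvisited cells carry `NA` (treated as infinitely high by the
#' region integrals). When `shifted`, the minimum over visited cells is 0.
#'
#' @param edges named list of strictly increasing cell-edge vectors, one per
#'   CV axis (1 or 2 axes)
#' @param F numeric vector (1-D) or matrix (2-D) of free energies per cell
#' @param kT thermal energy the surface is expressed against
#' @param shifted logical: has the minimum been shifted to zero?
#' @param n_eff optional per-cell effective sample counts
#' @param counts optional per-cell raw sample counts
#' @return an object of class `fes_grid`
#' @export
fes_grid <- function(edges, F, kT = 1, shifted = TRUE, n_eff = NULL,
                     counts = NULL) {
  stopifnot(is.list(edges), length(edges) %in% c(1L, 2L),
            !is.null(names(edges)))
  for (e in edges)
    if (length(e) < 2 || any(diff(e) <= 0))
      stop("cell edges must be strictly increasing with at least two values")
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  F <- if (length(dims) == 1L) as.numeric(F) else as.matrix(F)
  if (length(F) != prod(dims))
    stop("free-energy array does not match the grid dimensions")
  if (shifted && any(is.finite(F)) && abs(min(F[is.finite(F)])) > 1e-9)
    stop("shifted surface must have its minimum at zero over visited cells")
  structure(list(edges = edges,
                 mids = lapply(edges, function(e) (head(e, -1) + tail(e, -1)) / 2),
                 F = F, kT = kT, shifted = shifted,
                 n_eff = n_eff, counts = counts,
                 cv_names = names(edges)),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  dims <- vapply(x$edges, function(e) length(e) - 1L, integer(1))
  cat("Free-energy surface grid over",
      paste(x$cv_names, collapse = " x "), "(",
      paste(dims, collapse = " x "), "cells )\n")
  vis <- sum(is.finite(x$F))
  cat(sprintf("  %d/%d cells visited; kT = %g; range [%g, %g]\n",
              vis, length(x$F), x$kT,
              if (vis) min(x$F, na.rm = TRUE) else NA,
              if (vis) max(x$F, na.rm = TRUE) else NA))
  invisible(x)
}

#' Evaluate an analytic free energy on a grid
#'
#' Convenience constructor: evaluates `fun` at the cell midpoints.
#'
#' @param fun function of the CV coordinates (vectorized over its arguments;
#'   for 2-D grids called as `fun(s1, s2)` on the midpoint outer product)
#' @inheritParams fes_grid
#' @return an `fes_grid`
#' @export
fes_from_function <- function(fun, edges, kT = 1, shifted = FALSE) {
  mids <- lapply(edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  F <- if (length(mids) == 1L) fun(mids[[1]])
       else outer(mids[[1]], mids[[2]], fun)
  if (shifted) F <- F - min(F)
  fes_grid(edges, F, kT = kT, shifted = shifted)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Time-independent reweighting offset c(t)
#'
#' The running free-energy offset of the time-independent (time-lagged
#' ensemble-average) estimator for well-tempered metadynamics:
#' \deqn{c(t) = \frac{1}{\beta} \ln
#'   \frac{\sum_s \exp(\beta \frac{\gamma}{\gamma-1} V(s,t))}
#'        {\sum_s \exp(\beta \frac{1}{\gamma-1} V(s,t))}}
#' evaluated on a CV grid after each deposited hill, with log-sum-exp
#' stabilisation. For a filling well-tempered bias c(t) is non-decreasing.
#'
#' @param hills a [hills_list()]
#' @param grid numeric vector (1 CV) or matrix with one column per hill CV:
#'   the evaluation grid, which must cover the sampled domain
#' @param bias_factor well-tempered bias factor gamma
#' @param kT thermal energy
#' @return data frame `time`, `c` (one row per hill), class `reweight_state`
#' @export
compute_c_of_t <- function(hills, grid, bias_factor, kT = 1) {
  cvn <- hills_cv_names(hills)
  g <- if (is.matrix(grid)) grid else matrix(grid, ncol = 1,
                                             dimnames = list(NULL, cvn))
  if (nrow(g) == 0) stop("empty reweighting grid")
  beta <- 1 / kT
  gam <- bias_factor
  V <- rep(0, nrow(g))
  n <- nrow(hills)
  ct <- numeric(n)
  for (h in seq_len(n)) {
    expo <- rep(0, nrow(g))
    for (j in seq_along(cvn)) {
      s <- hills[[paste0("sigma_", cvn[j])]][h]
      expo <- expo + (g[, j] - hills[[cvn[j]]][h])^2 / (2 * s^2)
    }
    V <- V + hills$height[h] * exp(-expo)
    ct[h] <- kT * (logsumexp(beta * gam / (gam - 1) * V) -
                   logsumexp(beta / (gam - 1) * V))
  }
  out <- data.frame(time = hills$time, c = ct)
  class(out) <- c("reweight_state", "data.frame")
  attr(out, "bias_factor") <- bias_factor
  attr(out, "kT") <- kT
  out
}

interp_c <- function(c_of_t, times) {
  if (is.null(c_of_t) || nrow(c_of_t) == 0) return(rep(0, length(times)))
  # before the first hill there is no bias and the offset is zero
  stats::approx(c(0, c_of_t$time), c(0, c_of_t$c), xout = times, rule = 2)$y
}

#' Reweight a biased trajectory onto a free-energy surface
#'
#' Time-independent estimator: each sample gets weight
#' \eqn{w_t = \exp(\beta (V(s_t, t) - c(t)))} from its recorded instantaneous
#' bias and the offset series `c_of_t`; the free energy is
#' \eqn{F = -kT \ln} (weighted histogram), shifted so the minimum over
#' visited cells is zero. Early samples, collected while the bias is still
#' far from its well-tempered regime, are discarded (`transient_fraction` of
#' the time span).
#'
#' @param cv matrix of CV samples (named columns)
#' @param bias instantaneous bias at each sample
#' @param time sample times
#' @param c_of_t a [compute_c_of_t()] result (or `NULL` for an unbiased run)
#' @param edges named list of cell-edge vectors over the observables to
#'   histogram (names must be CV columns)
#' @param kT thermal energy
#' @param transient_fraction initial fraction of the time span to discard
#' @return an `fes_grid` with per-cell effective sample counts
#'   \eqn{(\sum w)^2 / \sum w^2} in `n_eff`
#' @export
reweight_fes <- function(cv, bias, time, c_of_t, edges, kT = 1,
                         transient_fraction = 0.1) {
  obs <- names(edges)
  stopifnot(all(obs %in% colnames(cv)), length(bias) == nrow(cv),
            length(time) == nrow(cv))
  keep <- time >= transient_fraction * max(time)
  cv <- cv[keep, , drop = FALSE]
  bias <- bias[keep]
  time <- time[keep]
  beta <- 1 / kT
  arg <- beta * (bias - interp_c(c_of_t, time))
  w <- exp(arg - max(arg))
  if (all(w == 0)) stop("all reweighting weights are zero")
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  idx <- lapply(obs, function(nm)
    findInterval(cv[, nm], edges[[nm]], rightmost.closed = TRUE))
  ok <- Reduce(`&`, lapply(seq_along(idx), function(j)
    idx[[j]] >= 1 & idx[[j]] <= dims[j]))
  lin <- idx[[1]][ok]
  if (length(dims) == 2L) lin <- lin + (idx[[2]][ok] - 1L) * dims[1]
  ncell <- prod(dims)
  W <- as.numeric(rowsum(w[ok], lin, reorder = FALSE))
  cells <- as.integer(rownames(rowsum(w[ok], lin, reorder = FALSE)))
  W2 <- as.numeric(rowsum(w[ok]^2, lin, reorder = FALSE))
  cnt <- as.numeric(rowsum(rep(1, sum(ok)), lin, reorder = FALSE))
  Wfull <- rep(NA_real_, ncell); Wfull[cells] <- W
  F <- -kT * log(Wfull)
  F <- F - min(F, na.rm = TRUE)
  n_eff <- rep(NA_real_, ncell); n_eff[cells] <- W^2 / W2
  counts <- rep(0, ncell); counts[cells] <- cnt
  if (length(dims) == 2L) {
    dim(F) <- dims; dim(n_eff) <- dims; dim(counts) <- dims
  }
  fes_grid(edges, F, kT = kT, shifted = TRUE, n_eff = n_eff, counts = counts)
}

#' Reweight a metadynamics run onto a free-energy surface
#'
#' Computes the offset series c(t) from the run's hill list (on the grid of
#' the biased CV's FES axis, optionally refined) and applies [reweight_fes()]
#' to the recorded trajectory.
#'
#' @param run a [run_metad()] result
#' @param edges named list of cell-edge vectors over the observables
#' @param transient_fraction initial fraction of the time span to discard
#' @param c_grid_refine refinement factor of the c(t) grid relative to the
#'   FES axis of the biased CV
#' @param t_max optional checkpoint: use only hills and samples up to this time
#' @return an `fes_grid`
#' @export
reweight_from_run <- function(run, edges, transient_fraction = 0.1,
                              c_grid_refine = 1L, t_max = NULL) {
  stopifnot(inherits(run, "metad_run"))
  cv_name <- hills_cv_names(run$hills)
  hl <- run$hills
  traj <- run$trajectory
  keep_t <- rep(TRUE, length(traj$time))
  if (!is.null(t_max)) {
    hl <- hl[hl$time <= t_max, , drop = FALSE]
    attr(hl, "cv_names") <- cv_name
    class(hl) <- c("hills", "data.frame")
    keep_t <- traj$time <= t_max
  }
  if (cv_name %in% names(edges)) {
    ax <- edges[[cv_name]]
  } else {
    ax <- seq(min(traj$cv[, cv_name]), max(traj$cv[, cv_name]),
              length.out = 101)
  }
  ngrid <- (length(ax) - 1L) * c_grid_refine
  cg <- seq(min(ax), max(ax), length.out = ngrid + 1L)
  cg <- (head(cg, -1) + tail(cg, -1)) / 2
  ct <- if (nrow(hl) > 0)
    compute_c_of_t(hl, cg, run$params$bias_factor, kT = traj$kT) else NULL
  reweight_fes(traj$cv[keep_t, , drop = FALSE], traj$bias[keep_t],
               traj$time[keep_t], ct, edges, kT = traj$kT,
               transient_fraction = transient_fraction)
}
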
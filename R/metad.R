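#' Well-tempered metadynamics parameters
#'
#' @param height initial Gaussian hill height w0 (energy units), >= 0.
#'   Reference atomistic settings: 1.2 kJ/mol for the volume-based runs and
#'   1.5 kJ/mol for the infrequent-metadynamics runs.
#' @param stride deposition stride tau (time units), > 0 (1 ps and 100 ps in
#'   the corresponding atomistic settings)
#' @param sigma named numeric vector of Gaussian widths, one per biased CV
#' @param bias_factor well-tempered bias factor, > 1 (20 and 15 in the
#'   corresponding atomistic settings)
#' @param kT thermal energy used in the tempering rule
#' @return an object of class `metad_params`
#' @export
metad_params <- function(height = 1.2, stride = 1, sigma = c(x = 0.1),
                         bias_factor = 20, kT = 1) {
  stopifnot(height >= 0, stride > 0, all(sigma > 0), bias_factor > 1,
            kT > 0)
  if (is.null(names(sigma))) names(sigma) <- paste0("cv", seq_along(sigma))
  structure(list(height = height, stride = stride, sigma = sigma,
                 bias_factor = bias_factor, kT = kT),
            class = "metad_params")
}

#' @export
print.metad_params <- function(x, ...) {
  cat(sprintf(
    "Well-tempered metadynamics: w0 = %g, stride = %g, bias factor = %g\n",
    x$height, x$stride, x$bias_factor))
  cat("  sigma:", paste(names(x$sigma), signif(x$sigma, 4), sep = " = ",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Construct a hill list
#'
#' A hill list is a data frame with one deposited Gaussian per row: `time`,
#' one centre column per CV, one `sigma_<cv>` width column per CV, `height`
#' and `biasf`.
#'
#' @param time,height numeric vectors, one entry per hill
#' @param center matrix of hill centres (one row per hill), columns named by CV
#' @param sigma named per-CV widths (recycled across hills)
#' @param bias_factor well-tempered bias factor
#' @return an object of class `hills` (a data frame)
#' @export
hills_list <- function(time = numeric(0), center = NULL, sigma, height =
                       numeric(0), bias_factor = 20) {
  cv_names <- names(sigma)
  if (is.null(center)) {
    center <- matrix(numeric(0), ncol = length(sigma),
                     dimnames = list(NULL, cv_names))
  }
  center <- rbind(center)
  colnames(center) <- cv_names
  df <- data.frame(time = time)
  for (nm in cv_names) df[[nm]] <- center[, nm]
  for (nm in cv_names) df[[paste0("sigma_", nm)]] <- rep(sigma[[nm]],
                                                         length(time))
  df$height <- height
  df$biasf <- rep(bias_factor, length(time))
  structure(df, class = c("hills", "data.frame"), cv_names = cv_names)
}

hills_cv_names <- function(hills) attr(hills, "cv_names")

#' Metadynamics bias from a hill list
#'
#' Direct sum-of-Gaussians evaluation:
#' \eqn{V(s) = \sum_h w_h \exp(-\sum_d (s_d - c_{h,d})^2 / 2\sigma_{h,d}^2)}.
#' Returns 0 for an empty hill list.
#'
#' @param hills a [hills_list()]
#' @param point named numeric vector (one CV point) or matrix with one row
#'   per point and columns named by CV
#' @return bias energies
#' @export
bias_value <- function(hills, point) {
  cvn <- hills_cv_names(hills)
  pts <- if (is.matrix(point)) point else rbind(point)
  if (is.null(colnames(pts))) {
    if (ncol(pts) != length(cvn))
      stop("point dimension ", ncol(pts), " does not match hills CV dimension ",
           length(cvn))
    colnames(pts) <- cvn
  }
  if (!all(cvn %in% colnames(pts)))
    stop("point is missing CV column(s): ",
         paste(setdiff(cvn, colnames(pts)), collapse = ", "))
  if (nrow(hills) == 0) return(rep(0, nrow(pts)))
  V <- rep(0, nrow(pts))
  for (h in seq_len(nrow(hills))) {
    expo <- rep(0, nrow(pts))
    for (nm in cvn) {
      s <- hills[[paste0("sigma_", nm)]][h]
      expo <- expo + (pts[, nm] - hills[[nm]][h])^2 / (2 * s^2)
    }
    V <- V + hills$height[h] * exp(-expo)
  }
  V
}

#' Deposit a well-tempered hill
#'
#' Appends a Gaussian centred at the current CV point with tempered height
#' \eqn{w = w_0 \exp(-V(s, t) / ((\gamma - 1) kT))}, where V is the current
#' bias at the deposition point.
#'
#' @param hills current [hills_list()]
#' @param point current CV point (named vector)
#' @param params a [metad_params()]
#' @param time deposition time
#' @return the hill list with one more row
#' @export
deposit_hill <- function(hills, point, params, time) {
  v <- bias_value(hills, point)
  h <- params$height *
    exp(-v / ((params$bias_factor - 1) * params$kT))
  new <- hills_list(time = time, center = rbind(point[hills_cv_names(hills)]),
                    sigma = params$sigma, height = h,
                    bias_factor = params$bias_factor)
  out <- rbind(hills, new)
  attr(out, "cv_names") <- hills_cv_names(hills)
  class(out) <- c("hills", "data.frame")
  out
}

monitor_mode_code <- function(monitor) {
  if (is.null(monitor)) return(list(mode = 0L, threshold = 0))
  sense <- if (is.null(monitor$sense)) "below" else monitor$sense
  mode <- if (identical(monitor$cv, "cn") && sense == "below") 1L
          else 2L
  list(mode = mode, threshold = monitor$threshold)
}

#' Run well-tempered metadynamics on a model potential
#'
#' Interleaves overdamped Langevin steps with well-tempered Gaussian
#' deposition every `stride` time units on a single biased CV (x for 1-D
#' potentials, the radial distance rho for the 2-D binding potential). The
#' bias and its gradient are accumulated on a `grid_n`-point grid (one update
#' per hill, linear interpolation in between). Records the trajectory, the
#' hill list and the instantaneous bias V(t) at each saved frame. With a
#' commitment `monitor` the run stops at the first committed escape
#' (infrequent-metadynamics mode); otherwise it runs to the step budget.
#'
#' @param potential a [model_potential()]
#' @param params a [metad_params()]; `sigma` must name the biased CV
#'   (`"x"` or `"rho"`)
#' @param config a [langevin_config()]
#' @param wall optional [wall_params()] acting on the radial distance
#' @param monitor optional commitment rule, e.g.
#'   `list(cv = "cn", threshold = 0.01)` (escape when the coordination number
#'   first drops below the threshold) or
#'   `list(cv = "x", threshold = 1, sense = "above")`
#' @param x0 starting position (defaults to the bound minimum)
#' @param grid_n bias grid resolution
#' @return an object of class `metad_run`: list with `trajectory`
#'   (an `md_trajectory`), `hills`, `bias_trace` (data frame `time`, `bias`),
#'   `event`, `escape_time`
#' @export
run_metad <- function(potential, params, config, wall = NULL, monitor = NULL,
                      x0 = NULL, grid_n = 4096L) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(params, "metad_params"),
            inherits(config, "langevin_config"))
  if (is.null(x0)) x0 <- default_start(potential)
  cv_name <- if (potential$ndim == 2L) "rho" else "x"
  if (!cv_name %in% names(params$sigma))
    stop("metad sigma must be named for the biased CV '", cv_name, "'")
  dep_stride <- as.integer(round(params$stride / config$timestep))
  if (params$height > 0 && dep_stride < 1)
    stop("deposition stride is smaller than the timestep")
  gr <- cv_grid_range(potential)
  mon <- monitor_mode_code(monitor)
  wall_k <- if (is.null(wall)) 0 else wall$k
  wall_rho <- if (is.null(wall)) 0 else wall$rho_s
  set.seed(config$seed)
  res <- cpp_run_metad(potential$code, unname(potential$params),
                       as.numeric(x0),
                       config$timestep, config$friction, config$kT,
                       config$n_steps, config$save_stride,
                       params$height, dep_stride,
                       params$sigma[[cv_name]], params$bias_factor,
                       wall_k, wall_rho,
                       mon$mode, mon$threshold,
                       cn_param(potential, "r0"), cn_param_i(potential, "m"),
                       cn_param_i(potential, "n"), cn_param(potential, "cmax"),
                       gr[1], gr[2], as.integer(grid_n),
                       numeric(0), numeric(0),
                       potential$domain[, 1], potential$domain[, 2])
  traj <- build_trajectory(res, potential, config)
  sig <- params$sigma[cv_name]
  hl <- hills_list(time = res$hill_time,
                   center = matrix(res$hill_center, ncol = 1,
                                   dimnames = list(NULL, cv_name)),
                   sigma = sig, height = res$hill_height,
                   bias_factor = params$bias_factor)
  structure(list(trajectory = traj, hills = hl,
                 bias_trace = data.frame(time = res$time, bias = res$bias),
                 params = params, wall = wall, monitor = monitor,
                 event = res$event, escape_time = res$escape_time,
                 potential = potential, config = config),
            class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf("Metadynamics run: %d hills, %d saved frames\n",
              nrow(x$hills), length(x$trajectory$time)))
  if (isTRUE(x$event))
    cat(sprintf("  committed escape at t = %g\n", x$escape_time))
  invisible(x)
}

#' Ensemble of infrequent-metadynamics escape simulations
#'
#' Runs `n_runs` independent biased Langevin simulations from the bound
#' minimum (seeds `config$seed + 0:(n_runs-1)`), each stopped at the first
#' committed escape. Runs that never commit within the step budget are
#' returned censored at the budget, not dropped. This emulates the
#' measure-the-dissociation-time protocol of an atomistic study (41
#' independent runs per system) with independent seeds standing in for
#' distinct equilibrated starting structures.
#'
#' @inheritParams run_metad
#' @param n_runs number of independent runs
#' @return an [escape_time_set()] with per-run bias traces
#' @export
generate_imetad_ensemble <- function(potential, params, config, n_runs = 41,
                                     wall = NULL,
                                     monitor = list(cv = "cn",
                                                    threshold = 0.01),
                                     grid_n = 4096L) {
  stopifnot(n_runs >= 1)
  times <- numeric(n_runs)
  event <- logical(n_runs)
  traces <- vector("list", n_runs)
  horizon <- config$n_steps * config$timestep
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    run <- run_metad(potential, params, cfg, wall = wall, monitor = monitor,
                     grid_n = grid_n)
    event[i] <- isTRUE(run$event)
    times[i] <- if (event[i]) run$escape_time else horizon
    traces[[i]] <- run$bias_trace
  }
  escape_time_set(time = times, event = event, traces = traces,
                  horizon = horizon, kT = config$kT)
}

#' Survivor-averaged maximum bias
#'
#' The time-dependent maximum bias averaged over runs still in the initial
#' basin: at each time t, the average over runs with escape time > t of
#' \eqn{\max_{t' \le t} V^r(t')}. Runs that have already escaped no longer
#' have a growing bias and are excluded, keeping the average steadily
#' increasing. With `running_max = FALSE` the instantaneous bias is averaged
#' instead. Traces are resampled to a common grid (the coarsest stride
#' present) by linear interpolation.
#'
#' @param x an [escape_time_set()], or a list of data frames with `time` and
#'   `bias` columns
#' @param escape_time,event per-run escape times and event flags (taken from
#'   `x` when it is an escape-time set)
#' @param running_max average the running maximum of the bias (default) or
#'   the instantaneous bias
#' @return data frame with `time`, `vmb` and `n_survivors`, ending at the
#'   last time with at least one survivor (class `vmb_series`)
#' @export
survivor_max_bias <- function(x, escape_time = NULL, event = NULL,
                              running_max = TRUE) {
  if (inherits(x, "escape_time_set")) {
    traces <- x$traces
    escape_time <- x$table$time
    event <- x$table$event
  } else traces <- x
  if (length(traces) == 0) stop("no bias traces supplied")
  if (is.null(escape_time)) escape_time <- vapply(traces, function(tr)
    max(tr$time), numeric(1))
  if (is.null(event)) event <- rep(TRUE, length(traces))
  strides <- vapply(traces, function(tr)
    if (nrow(tr) > 1) stats::median(diff(tr$time)) else Inf, numeric(1))
  stride <- max(strides[is.finite(strides)])
  t_end <- max(vapply(traces, function(tr) max(tr$time), numeric(1)))
  grid <- seq(0, t_end, by = stride)
  acc <- matrix(NA_real_, nrow = length(grid), ncol = length(traces))
  for (r in seq_along(traces)) {
    tr <- traces[[r]]
    v <- stats::approx(tr$time, tr$bias, xout = pmin(grid, max(tr$time)),
                       rule = 2)$y
    if (running_max) v <- cummax(v)
    # a run contributes while it is still in the initial basin; an escaped
    # run stops contributing at its escape time, a censored run at its end
    alive <- grid <= escape_time[r] & grid <= max(tr$time)
    v[!alive] <- NA_real_
    acc[, r] <- v
  }
  n_surv <- rowSums(!is.na(acc))
  keep <- n_surv > 0
  out <- data.frame(time = grid[keep],
                    vmb = rowMeans(acc[keep, , drop = FALSE], na.rm = TRUE),
                    n_survivors = n_surv[keep])
  class(out) <- c("vmb_series", "data.frame")
  out
}
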
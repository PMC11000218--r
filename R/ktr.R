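#' Ground-truth rate parameters for synthetic escape ensembles
#'
#' Parameters of the time-dependent-rate survival law used by the direct
#' escape-time sampler: unbiased escape rate `k0`, bias-quality factor
#' `gamma` (1 for an ideal collective variable), and the logarithmic
#' maximum-bias growth model `a log(1 + b t)` with plateau beyond `t_cut`.
#' Defaults give an ensemble whose scale mirrors a paper-style
#' infrequent-metadynamics experiment in reduced units.
#'
#' @param k0 true unbiased rate (inverse time), > 0
#' @param gamma bias-quality factor in (0, 1]
#' @param a bias-growth amplitude (energy), >= 0
#' @param b bias-growth rate (inverse time), > 0
#' @param t_cut time beyond which the maximum bias is constant
#' @return an object of class `ground_truth_rates`
#' @export
ground_truth_rates <- function(k0 = 1, gamma = 0.7, a = 3, b = 0.5,
                               t_cut = 10) {
  stopifnot(k0 > 0, gamma > 0, gamma <= 1, a >= 0, b > 0, t_cut > 0)
  structure(list(k0 = k0, gamma = gamma, a = a, b = b, t_cut = t_cut),
            class = "ground_truth_rates")
}

#' Logarithmic maximum-bias growth model
#'
#' \eqn{V_{MB}(t) = a \log(1 + b t)} for \eqn{t \le t_{cut}}, constant at the
#' plateau \eqn{a \log(1 + b t_{cut})} beyond (continuous at the cutoff).
#'
#' @param a amplitude (energy), >= 0
#' @param b growth rate (inverse time), >= 0
#' @param t_cut cutoff time
#' @param rms residual RMS of the fit that produced the model (optional)
#' @return an object of class `vmb_model`
#' @export
vmb_model <- function(a, b, t_cut, rms = NA_real_) {
  stopifnot(a >= 0, b >= 0, t_cut > 0)
  structure(list(a = a, b = b, t_cut = t_cut,
                 plateau = a * log(1 + b * t_cut), rms = rms),
            class = "vmb_model")
}

#' Evaluate a maximum-bias model
#'
#' @param model a [vmb_model()]
#' @param t times, >= 0
#' @return bias values
#' @export
vmb_value <- function(model, t) {
  ifelse(t <= model$t_cut, model$a * log(1 + model$b * t), model$plateau)
}

#' @export
print.vmb_model <- function(x, ...) {
  cat(sprintf(
    "V_MB model: a = %.4g, b = %.4g, cutoff = %.4g, plateau = %.4g\n",
    x$a, x$b, x$t_cut, x$plateau))
  invisible(x)
}

#' Escape-time ensemble
#'
#' Per-run biased escape times with event/censor flags and (optionally)
#' per-run instantaneous-bias traces.
#'
#' @param time per-run escape times (biased simulation time), > 0
#' @param event logical event flags (`FALSE` = censored at `time`)
#' @param traces optional list of per-run data frames with `time` and `bias`
#' @param horizon censoring horizon
#' @param kT thermal energy of the generating dynamics
#' @return an object of class `escape_time_set` with `table` (data frame
#'   `run`, `time`, `event`), `traces`, `M` events, `N` censored
#' @export
escape_time_set <- function(time, event, traces = NULL, horizon = NULL,
                            kT = 1) {
  stopifnot(length(time) == length(event), all(time > 0))
  event <- as.logical(event)
  if (!is.null(traces)) {
    stopifnot(length(traces) == length(time))
    ends <- vapply(traces, function(tr) max(tr$time), numeric(1))
    stopifnot(all(time <= ends + 1e-9))
  }
  structure(list(table = data.frame(run = seq_along(time), time = time,
                                    event = event),
                 traces = traces, horizon = horizon, kT = kT,
                 M = sum(event), N = sum(!event)),
            class = "escape_time_set")
}

#' @export
print.escape_time_set <- function(x, ...) {
  cat(sprintf("Escape-time ensemble: %d runs (%d events, %d censored)\n",
              nrow(x$table), x$M, x$N))
  cat(sprintf("  biased times in [%.4g, %.4g]\n",
              min(x$table$time), max(x$table$time)))
  invisible(x)
}

# integrated hazard / k0: I(t) = int_0^t exp(gamma beta V_MB(t')) dt',
# closed form for the logarithmic growth model with c = gamma beta a:
# (1+bt)^c integrates to ((1+bt)^(c+1)-1)/(b(c+1)) (log special case at
# c = -1); beyond the cutoff the integrand is the constant plateau factor
ktr_hazard_shape <- function(t, gamma, model, beta) {
  cc <- gamma * beta * model$a
  if (model$a == 0 || gamma == 0 || model$b == 0) return(t)
  seg1 <- function(tt) {
    if (abs(cc + 1) < 1e-12) log1p(model$b * tt) / model$b
    else (exp((cc + 1) * log1p(model$b * tt)) - 1) / (model$b * (cc + 1))
  }
  plateau_factor <- exp(gamma * beta * model$plateau)
  ifelse(t <= model$t_cut,
         vapply(t, seg1, numeric(1)),
         seg1(model$t_cut) + plateau_factor * (t - model$t_cut))
}

#' Time-dependent-rate survival probability
#'
#' \deqn{S(t) = \exp(-k_0 \int_0^t e^{\gamma \beta V_{MB}(t')} dt')}
#' with the integral in closed form for the logarithmic maximum-bias model.
#' With no bias this reduces to the exponential law \eqn{e^{-k_0 t}}.
#'
#' @param t times, >= 0
#' @param k0 unbiased rate
#' @param gamma bias-quality factor
#' @param model a [vmb_model()]
#' @param beta inverse thermal energy 1/kT
#' @return survival probabilities
#' @export
ktr_survival <- function(t, k0, gamma, model, beta = 1) {
  stopifnot(all(t >= 0))
  exp(-k0 * ktr_hazard_shape(t, gamma, model, beta))
}

#' Log-likelihood of an escape-time ensemble under the survival model
#'
#' \deqn{\ell(k_0, \gamma) = \sum_{events} \ln[k_0 e^{\gamma \beta
#'   V_{MB}(t_j)} S(t_j)] + \sum_{censored} \ln S(t_j)}
#' Censored runs contribute only their survival to the horizon.
#'
#' @param k0,gamma rate and bias-quality parameters
#' @param data an [escape_time_set()]
#' @param model a [vmb_model()]
#' @param beta inverse thermal energy
#' @return log-likelihood value
#' @export
ktr_log_likelihood <- function(k0, gamma, data, model, beta = 1) {
  stopifnot(nrow(data$table) > 0)
  t <- data$table$time
  ev <- data$table$event
  H <- k0 * ktr_hazard_shape(t, gamma, model, beta)
  ll <- numeric(length(t))
  ll[ev] <- log(k0) + gamma * beta * vmb_value(model, t[ev]) - H[ev]
  ll[!ev] <- -H[!ev]
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood term for run(s) ",
         paste(data$table$run[!is.finite(ll)], collapse = ", "))
  sum(ll)
}

#' Fit the logarithmic maximum-bias model to a survivor-averaged series
#'
#' Least squares of \eqn{a \log(1 + b t)} to the series on `[0, t_cut]`.
#' For fixed b the optimal a is linear; the fit profiles over b with a
#' deterministic 1-D minimisation, so it has no starting-value sensitivity.
#' Beyond the cutoff the model is the constant plateau (continuous at
#' `t_cut` by construction).
#'
#' @param series a [survivor_max_bias()] result (data frame `time`, `vmb`)
#' @param t_cut cutoff time, within the series span
#' @return a [vmb_model()] (with residual RMS over the fitted window)
#' @export
fit_vmb <- function(series, t_cut) {
  stopifnot(t_cut > 0, t_cut <= max(series$time) + 1e-9)
  sel <- series$time <= t_cut
  t <- series$time[sel]
  v <- series$vmb[sel]
  if (all(abs(v) < 1e-12)) {
    warning("degenerate (zero) maximum-bias series: a = 0 model")
    return(vmb_model(0, 1, t_cut, rms = 0))
  }
  tspan <- max(t[t > 0])
  a_of_b <- function(b) {
    L <- log1p(b * t)
    sum(v * L) / sum(L^2)
  }
  sse <- function(logb) {
    b <- exp(logb)
    a <- a_of_b(b)
    sum((v - a * log1p(b * t))^2)
  }
  opt <- stats::optimize(sse, interval = log(c(1e-3, 1e4) / tspan),
                         tol = 1e-10)
  b <- exp(opt$minimum)
  a <- max(0, a_of_b(b))
  vmb_model(a, b, t_cut,
            rms = sqrt(opt$objective / length(t)))
}

# profile maximum likelihood: for fixed gamma the optimal rate is the
# closed form k0(gamma) = M / sum_j I(t_j, gamma), reducing the fit to a
# deterministic 1-D search over gamma
profile_fit <- function(data, model, beta, gamma_max = 2) {
  M <- data$M
  if (M < 1) stop("no escape events to fit")
  prof <- function(gamma) {
    I <- ktr_hazard_shape(data$table$time, gamma, model, beta)
    k0 <- M / sum(I)
    ev <- data$table$event
    ll <- M * log(k0) +
      gamma * beta * sum(vmb_value(model, data$table$time[ev])) -
      k0 * sum(I)
    list(k0 = k0, ll = ll)
  }
  grid <- seq(0, gamma_max, by = 0.02)
  lls <- vapply(grid, function(g) prof(g)$ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(g) prof(g)$ll, interval = c(lo, hi),
                         maximum = TRUE, tol = 1e-8)
  best <- prof(opt$maximum)
  list(k0 = best$k0, gamma = opt$maximum, logLik = best$ll)
}

#' Fit the unbiased rate and bias-quality factor to an escape ensemble
#'
#' Builds the survivor-averaged maximum-bias series, scans the cutoff time
#' over deciles of the series span, fits the logarithmic growth model at
#' each cutoff, maximises the survival-model likelihood in (k0, gamma)
#' (profile likelihood: the optimal k0 is closed-form at each gamma, leaving
#' a deterministic 1-D search), and keeps the cutoff whose fit maximises the
#' Kolmogorov-Smirnov p-value, breaking ties by the smaller KS statistic D.
#'
#' When the maximum-bias series is degenerate (identically zero), gamma is
#' unidentifiable: it is reported as `NA` with a flag, and k0 is the
#' closed-form exponential maximum-likelihood estimate M / sum(t).
#'
#' @param data an [escape_time_set()] (needs >= 5 events unless `model` is
#'   supplied with a relaxed check)
#' @param model optional [vmb_model()]; when supplied, the maximum-bias
#'   series construction and cutoff scan are skipped
#' @param beta inverse thermal energy (defaults to 1/kT of the ensemble)
#' @param running_max use the running maximum of each bias trace (default)
#'   or the instantaneous value when building the series
#' @param gamma_max upper bound of the gamma search (values above 1 are
#'   flagged, not clipped)
#' @return an object of class `ktr_fit`: `k0`, `gamma`, `ks_D`, `ks_p`,
#'   `model`, `beta`, `logLik`, `gamma_identifiable`, `vmb_series`
#' @export
fit_rates <- function(data, model = NULL, beta = NULL, running_max = TRUE,
                      gamma_max = 2) {
  stopifnot(inherits(data, "escape_time_set"))
  if (is.null(beta)) beta <- 1 / data$kT
  if (is.null(model) && data$M < 5)
    stop("need at least 5 escape events to fit the survival model")
  vs <- NULL
  if (is.null(model)) {
    if (is.null(data$traces)) stop("no bias traces: supply a vmb model")
    vs <- survivor_max_bias(data, running_max = running_max)
    if (all(abs(vs$vmb) < 1e-12)) {
      k0 <- data$M / sum(data$table$time)
      fit <- list(k0 = k0, gamma = NA_real_, logLik = NA_real_)
      mdl <- vmb_model(0, 1, max(vs$time))
      ks <- ks_statistic(data, k0, 0, mdl, beta)
      return(new_ktr_fit(fit$k0, NA_real_, ks, mdl, beta, NA_real_,
                         FALSE, vs))
    }
    span <- max(vs$time)
    cuts <- span * seq(0.1, 1, by = 0.1)
    cuts <- cuts[vapply(cuts, function(tc) sum(vs$time <= tc) >= 5,
                        logical(1))]
    cand <- lapply(cuts, function(tc) {
      mdl <- fit_vmb(vs, tc)
      fit <- profile_fit(data, mdl, beta, gamma_max)
      ks <- ks_statistic(data, fit$k0, fit$gamma, mdl, beta)
      list(model = mdl, fit = fit, ks = ks)
    })
    p <- vapply(cand, function(x) x$ks$p, numeric(1))
    D <- vapply(cand, function(x) x$ks$D, numeric(1))
    best <- order(-p, D)[1]
    mdl <- cand[[best]]$model
    fit <- cand[[best]]$fit
    ks <- cand[[best]]$ks
  } else {
    mdl <- model
    if (mdl$a == 0) {
      k0 <- data$M / sum(data$table$time)
      ks <- ks_statistic(data, k0, 0, mdl, beta)
      return(new_ktr_fit(k0, NA_real_, ks, mdl, beta, NA_real_, FALSE, vs))
    }
    fit <- profile_fit(data, mdl, beta, gamma_max)
    ks <- ks_statistic(data, fit$k0, fit$gamma, mdl, beta)
  }
  new_ktr_fit(fit$k0, fit$gamma, ks, mdl, beta, fit$logLik, TRUE, vs)
}

new_ktr_fit <- function(k0, gamma, ks, model, beta, logLik, identifiable,
                        vmb_series) {
  if (identifiable && is.finite(gamma) && gamma > 1)
    warning(sprintf("fitted gamma = %.3f exceeds 1 (bias-quality factor ",
                    gamma), "is expected in (0, 1])")
  structure(list(k0 = k0, gamma = gamma, ks_D = ks$D, ks_p = ks$p,
                 model = model, beta = beta, logLik = logLik,
                 gamma_identifiable = identifiable,
                 vmb_series = vmb_series, bootstrap = NULL),
            class = "ktr_fit")
}

#' @export
print.ktr_fit <- function(x, ...) {
  cat("Kramers time-dependent rate fit\n")
  cat(sprintf("  k0 = %.4g, gamma = %s\n", x$k0,
              if (x$gamma_identifiable) sprintf("%.3f", x$gamma)
              else "unidentifiable (no bias)"))
  cat(sprintf("  KS: D = %.4f, p = %.3f\n", x$ks_D, x$ks_p))
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap k0 30th-70th percentile: [%.4g, %.4g]\n",
                x$bootstrap$p30, x$bootstrap$p70))
  invisible(x)
}

ks_statistic <- function(data, k0, gamma, model, beta) {
  t_ev <- data$table$time[data$table$event]
  if (length(t_ev) < 3) stop("need at least 3 events for the KS test")
  g <- if (is.finite(gamma)) gamma else 0
  tcdf <- function(q) 1 - ktr_survival(q, k0, g, model, beta)
  kt <- suppressWarnings(stats::ks.test(t_ev, tcdf, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Kolmogorov-Smirnov validation of a rate fit
#'
#' One-sample KS test of the observed event times against the theoretical
#' cumulative distribution \eqn{1 - S(t)} implied by the fit, with the
#' asymptotic Kolmogorov p-value. Censored runs are excluded from the
#' empirical distribution.
#'
#' @param data an [escape_time_set()]
#' @param fit a [fit_rates()] result
#' @return list with `D` and `p`
#' @export
ks_validate <- function(data, fit) {
  ks_statistic(data, fit$k0, fit$gamma, fit$model, fit$beta)
}

#' Bootstrap uncertainty of the fitted rate
#'
#' Resamples runs with replacement, refits (k0, gamma) with the maximum-bias
#' model held fixed (the survivor average is an ensemble-level quantity),
#' keeps resamples whose refit passes the KS test at `p_threshold`, and
#' reports the 30th and 70th percentiles of the retained k0 estimates.
#'
#' @param data an [escape_time_set()]
#' @param fit a [fit_rates()] result
#' @param n_boot number of bootstrap resamples (50 in the reference protocol)
#' @param seed RNG seed
#' @param p_threshold KS acceptance threshold
#' @return list with `p30`, `p70`, `k0_samples` (retained), `n_rejected`
#' @export
bootstrap_rates <- function(data, fit, n_boot = 50, seed = 1,
                            p_threshold = 0.05) {
  set.seed(seed)
  n <- nrow(data$table)
  k0s <- numeric(0)
  n_rej <- 0L
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- data$table[idx, ]
    bd <- escape_time_set(tb$time, tb$event, horizon = data$horizon,
                          kT = data$kT)
    if (bd$M < 3 || all(!tb$event)) { n_rej <- n_rej + 1L; next }
    bf <- tryCatch(suppressWarnings(
      fit_rates(bd, model = fit$model, beta = fit$beta)),
      error = function(e) NULL)
    if (is.null(bf)) { n_rej <- n_rej + 1L; next }
    if (bf$ks_p > p_threshold) k0s <- c(k0s, bf$k0)
    else n_rej <- n_rej + 1L
  }
  if (length(k0s) < 10)
    warning("fewer than 10 bootstrap samples passed the KS test; ",
            "percentiles are unreliable")
  q <- if (length(k0s) > 0)
    stats::quantile(k0s, c(0.3, 0.7), names = FALSE) else c(NA_real_,
                                                            NA_real_)
  if (all(is.finite(q)) && (fit$k0 < q[1] || fit$k0 > q[2]))
    warning(sprintf(
      "best-fit k0 = %.4g lies outside the bootstrap 30th-70th interval [%.4g, %.4g]",
      fit$k0, q[1], q[2]))
  list(p30 = q[1], p70 = q[2], k0_samples = k0s, n_rejected = n_rej)
}

#' Hyperdynamics rescaling of biased escape times
#'
#' The conventional infrequent-metadynamics estimator: each run's biased
#' time is rescaled by the accumulated acceleration factor
#' \eqn{t^* = \int_0^{t_{esc}} e^{\beta V^r(t')} dt'} (trapezoidal rule on
#' the recorded trace). An exponential law is fitted to the rescaled times
#' by maximum likelihood (censored runs contribute their rescaled horizon)
#' and tested against the rescaled event times with a KS test. With
#' suboptimal collective variables this test is expected to fail; the
#' result reports the failure rather than hiding it.
#'
#' @param data an [escape_time_set()] with per-run traces
#' @param beta inverse thermal energy (defaults to 1/kT of the ensemble)
#' @return list with `time_rescaled`, `rate`, `ks_D`, `ks_p`
#' @export
hyperdynamics_rescale <- function(data, beta = NULL) {
  stopifnot(inherits(data, "escape_time_set"), !is.null(data$traces))
  if (is.null(beta)) beta <- 1 / data$kT
  tstar <- vapply(seq_len(nrow(data$table)), function(r) {
    tr <- data$traces[[r]]
    t_end <- data$table$time[r]
    if (max(tr$time) < t_end - 1e-9)
      stop("bias trace of run ", r, " does not cover its escape time")
    sel <- tr$time <= t_end + 1e-9
    tt <- tr$time[sel]
    vv <- exp(beta * tr$bias[sel])
    if (tail(tt, 1) < t_end) {
      vend <- exp(beta * stats::approx(tr$time, tr$bias, xout = t_end,
                                       rule = 2)$y)
      tt <- c(tt, t_end); vv <- c(vv, vend)
    }
    sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
  }, numeric(1))
  rate <- data$M / sum(tstar)
  t_ev <- tstar[data$table$event]
  ks <- suppressWarnings(stats::ks.test(t_ev, stats::pexp, rate = rate,
                                        exact = FALSE))
  list(time_rescaled = tstar, rate = rate,
       ks_D = unname(ks$statistic), ks_p = ks$p.value)
}

#' Sample escape times from the time-dependent-rate survival law
#'
#' Direct inverse-CDF sampler with known ground truth: per run a uniform
#' draw u is mapped to the escape time solving S(t) = u on the closed-form
#' integrated hazard (bracketed root search). Runs whose solution exceeds
#' the horizon are returned censored at the horizon. Per-run bias traces are
#' the deterministic maximum-bias model curve.
#'
#' @param truth a [ground_truth_rates()]
#' @param n_runs number of runs, >= 1
#' @param horizon censoring horizon, > 0
#' @param kT thermal energy (beta = 1/kT enters the hazard)
#' @param seed RNG seed
#' @param trace_points number of points in each deterministic bias trace
#' @return an [escape_time_set()]
#' @export
sample_escape_times <- function(truth, n_runs, horizon, kT = 1, seed = 1,
                                trace_points = 201) {
  stopifnot(inherits(truth, "ground_truth_rates"), n_runs >= 1, horizon > 0)
  model <- vmb_model(truth$a, truth$b, truth$t_cut)
  beta <- 1 / kT
  set.seed(seed)
  u <- stats::runif(n_runs)
  target <- -log(u)
  Hend <- truth$k0 * ktr_hazard_shape(horizon, truth$gamma, model, beta)
  time <- numeric(n_runs)
  event <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    if (target[i] >= Hend) {
      time[i] <- horizon
      event[i] <- FALSE
    } else {
      f <- function(t) truth$k0 *
        ktr_hazard_shape(t, truth$gamma, model, beta) - target[i]
      time[i] <- stats::uniroot(f, lower = 0, upper = horizon,
                                tol = 1e-12 * horizon)$root
      event[i] <- TRUE
    }
  }
  tg <- seq(0, horizon, length.out = trace_points)
  tr <- data.frame(time = tg, bias = vmb_value(model, tg))
  escape_time_set(time = time, event = event,
                  traces = rep(list(tr), n_runs),
                  horizon = horizon, kT = kT)
}
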
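test_that("closed-form biased hazard matches adaptive quadrature", {
  set.seed(9)
  for (i in 1:25) {
    model <- vmb_model(a = runif(1, 0, 5), b = runif(1, 0.05, 3),
                       t_cut = runif(1, 1, 20))
    gamma <- runif(1, 0.05, 1)
    beta <- runif(1, 0.5, 2)
    for (t in c(0.3, 5, 30)) {
      closed <- ktr_survival(t, 1, gamma, model, beta)
      quad <- exp(-hazard_quadrature(t, gamma, model, beta))
      expect_equal(closed, quad, tolerance = 1e-8)
    }
  }
})

test_that("survival has its limiting properties and unbiased reduction", {
  model <- vmb_model(a = 3, b = 0.5, t_cut = 10)
  expect_equal(ktr_survival(0, 1, 0.7, model), 1)
  t <- seq(0, 8, by = 0.1)
  S <- ktr_survival(t, 1, 0.7, model)
  expect_true(all(diff(S) < 0))
  expect_lt(ktr_survival(1e4, 0.01, 0.7, model), 1e-12)
  # no bias: exponential law
  m0 <- vmb_model(a = 0, b = 1, t_cut = 10)
  expect_equal(ktr_survival(t, 1.3, 0.7, m0), exp(-1.3 * t))
})

test_that("escape-time sampler inverts the survival law", {
  # zero bias: exponential with mean 1/k0
  ens <- sample_escape_times(
    ground_truth_rates(k0 = 2, gamma = 0.5, a = 0, b = 0.5, t_cut = 10),
    n_runs = 1e4, horizon = 100, seed = 1)
  expect_equal(mean(ens$table$time[ens$table$event]), 0.5,
               tolerance = 0.03)
  # biased law: ECDF matches 1 - S(t) at the deciles
  truth <- ground_truth_rates(k0 = 1, gamma = 0.7, a = 3, b = 0.5,
                              t_cut = 10)
  big <- sample_escape_times(truth, n_runs = 1e4, horizon = 50, seed = 7)
  S <- function(t) ktr_survival(t, truth$k0, truth$gamma,
                                vmb_model(truth$a, truth$b, truth$t_cut), 1)
  ec <- stats::ecdf(big$table$time)
  qs <- stats::quantile(big$table$time, seq(0.1, 0.9, by = 0.1))
  expect_lt(max(abs(ec(qs) - (1 - S(qs)))), 0.02)
  # contract at study scale: 41 records, flagged, strictly positive
  small <- sample_escape_times(truth, n_runs = 41, horizon = 50, seed = 3)
  expect_equal(nrow(small$table), 41)
  expect_equal(small$M + small$N, 41)
  expect_true(all(small$table$time > 0))
  # deterministic traces end at the horizon, covering every event
  expect_true(all(vapply(small$traces, function(tr) max(tr$time),
                         numeric(1)) >= small$table$time))
})

test_that("likelihood is additive and maximised near the truth", {
  truth <- ground_truth_rates()
  model <- vmb_model(truth$a, truth$b, truth$t_cut)
  d <- sample_escape_times(truth, 200, horizon = 50, seed = 5)
  ll <- ktr_log_likelihood(1, 0.7, d, model)
  dd <- escape_time_set(rep(d$table$time, 2), rep(d$table$event, 2),
                        horizon = 50)
  expect_equal(ktr_log_likelihood(1, 0.7, dd, model), 2 * ll,
               tolerance = 1e-12)
  big <- sample_escape_times(truth, 1e4, horizon = 50, seed = 6)
  expect_gt(ktr_log_likelihood(1, 0.7, big, model),
            ktr_log_likelihood(2, 0.7, big, model))
  expect_gt(ktr_log_likelihood(1, 0.7, big, model),
            ktr_log_likelihood(1, 0.2, big, model))
})

test_that("zero-bias data reduce to the closed-form exponential estimate", {
  ens <- sample_escape_times(
    ground_truth_rates(k0 = 1.5, gamma = 0.5, a = 0, b = 1, t_cut = 5),
    n_runs = 200, horizon = 100, seed = 3)
  fit <- fit_rates(ens)
  mle <- ens$M / sum(ens$table$time)
  expect_equal(fit$k0, mle, tolerance = 1e-3)
  expect_false(fit$gamma_identifiable)
})

test_that("maximum-bias model fitting recovers exact logarithmic growth", {
  t <- seq(0, 20, by = 0.1)
  series <- data.frame(time = t, vmb = 3 * log1p(0.5 * t))
  m <- fit_vmb(series, t_cut = 20)
  expect_equal(m$a, 3, tolerance = 1e-6)
  expect_equal(m$b, 0.5, tolerance = 1e-6)
  # continuity at the cutoff by construction
  expect_equal(vmb_value(m, m$t_cut), m$plateau)
  expect_equal(vmb_value(m, m$t_cut + 5), m$plateau)
  expect_warning(m0 <- fit_vmb(data.frame(time = t, vmb = 0 * t), 10),
                 "degenerate")
  expect_equal(m0$a, 0)
})

test_that("rate fitting recovers the generating parameters", {
  truth <- ground_truth_rates(k0 = 1, gamma = 0.7, a = 3, b = 0.5,
                              t_cut = 10)
  d <- sample_escape_times(truth, 500, horizon = 50, seed = 42)
  fit <- fit_rates(d)
  expect_equal(fit$k0, 1, tolerance = 0.15)
  expect_lt(abs(fit$gamma - 0.7), 0.1)
  expect_gt(fit$ks_p, 0.05)
  # the KS check agrees with the fit's stored diagnostics
  ks <- ks_validate(d, fit)
  expect_equal(ks$D, fit$ks_D)
})

test_that("small-time censored records barely move the estimate", {
  truth <- ground_truth_rates()
  d <- sample_escape_times(truth, 2000, horizon = 50, seed = 9)
  model <- vmb_model(truth$a, truth$b, truth$t_cut)
  f1 <- fit_rates(d, model = model)
  aug <- escape_time_set(c(d$table$time, rep(1e-4, 50)),
                         c(d$table$event, rep(FALSE, 50)), horizon = 50)
  f2 <- fit_rates(aug, model = model)
  expect_lt(abs(f2$k0 - f1$k0) / f1$k0, 0.01)
})

test_that("KS validation rejects a grossly wrong rate", {
  ens <- sample_escape_times(
    ground_truth_rates(k0 = 1, gamma = 0.5, a = 0, b = 1, t_cut = 5),
    n_runs = 100, horizon = 200, seed = 12)
  m0 <- vmb_model(0, 1, 5)
  wrong <- structure(list(k0 = 10, gamma = 0, model = m0, beta = 1),
                     class = "ktr_fit")
  expect_lt(ks_validate(ens, wrong)$p, 0.01)
  tiny <- escape_time_set(c(1, 2), c(TRUE, TRUE))
  expect_error(ks_validate(tiny, wrong), "at least 3 events")
})

test_that("bootstrap intervals are deterministic, degenerate-safe, and shrink with n", {
  truth <- ground_truth_rates()
  d41 <- sample_escape_times(truth, 41, horizon = 50, seed = 8)
  fit41 <- fit_rates(d41)
  b1 <- bootstrap_rates(d41, fit41, seed = 4)
  b2 <- bootstrap_rates(d41, fit41, seed = 4)
  expect_identical(b1$p30, b2$p30)
  expect_identical(b1$p70, b2$p70)
  d500 <- sample_escape_times(truth, 500, horizon = 50, seed = 8)
  fit500 <- fit_rates(d500)
  widths <- vapply(1:5, function(s) {
    w41 <- with(bootstrap_rates(d41, fit41, seed = s), p70 - p30)
    w500 <- with(bootstrap_rates(d500, fit500, seed = s), p70 - p30)
    c(w41, w500)
  }, numeric(2))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
  # identical escape times give a zero-width interval
  deg <- escape_time_set(rep(2, 20), rep(TRUE, 20), horizon = 50)
  fdeg <- suppressWarnings(fit_rates(deg, model = vmb_model(0, 1, 5)))
  bdeg <- suppressWarnings(bootstrap_rates(deg, fdeg, seed = 1))
  expect_equal(bdeg$p30, bdeg$p70)
})

test_that("hyperdynamics rescaling has its closed-form limits", {
  # zero bias: rescaled time equals biased time
  tr0 <- data.frame(time = seq(0, 10, by = 0.1), bias = 0)
  d0 <- escape_time_set(c(3, 7), c(TRUE, TRUE), traces = list(tr0, tr0),
                        horizon = 10)
  hd0 <- hyperdynamics_rescale(d0)
  expect_equal(hd0$time_rescaled, c(3, 7), tolerance = 1e-9)
  # constant bias c: t* = t exp(beta c)
  trc <- data.frame(time = seq(0, 10, by = 0.1), bias = 1.2)
  dc <- escape_time_set(c(3, 7), c(TRUE, TRUE), traces = list(trc, trc),
                        horizon = 10)
  hdc <- hyperdynamics_rescale(dc)
  expect_equal(hdc$time_rescaled, c(3, 7) * exp(1.2), tolerance = 1e-9)
  # an ensemble whose trace stops short of an event time is rejected up front
  expect_error(escape_time_set(2, TRUE,
                               traces = list(data.frame(time = 0:1,
                                                        bias = 0))))
})

test_that("hyperdynamics and the survival fit agree on a good-CV ensemble", {
  truth <- ground_truth_rates(k0 = 1, gamma = 1, a = 2, b = 0.5, t_cut = 10)
  d <- sample_escape_times(truth, 500, horizon = 50, seed = 31)
  fit <- suppressWarnings(fit_rates(d))
  hd <- hyperdynamics_rescale(d)
  ratio <- hd$rate / fit$k0
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
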
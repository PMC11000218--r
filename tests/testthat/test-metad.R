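test_that("bias evaluation sums Gaussians and handles the empty list", {
  empty <- hills_list(sigma = c(x = 0.2))
  expect_equal(bias_value(empty, c(x = 0.3)), 0)
  h <- hills_list(time = 1,
                  center = matrix(0.5, ncol = 1,
                                  dimnames = list(NULL, "x")),
                  sigma = c(x = 0.2), height = 1.3)
  expect_equal(bias_value(h, c(x = 0.5)), 1.3)
  expect_equal(bias_value(h, c(x = 0.7)), 1.3 * exp(-0.5))
  expect_error(bias_value(h, c(0.1, 0.2)), "dimension")
  # two-CV hills
  h2 <- hills_list(time = 1,
                   center = matrix(c(0, 1), ncol = 2,
                                   dimnames = list(NULL, c("a", "b"))),
                   sigma = c(a = 1, b = 2), height = 2)
  expect_equal(bias_value(h2, c(a = 1, b = 1)), 2 * exp(-0.5))
})

test_that("hill heights follow the well-tempered tempering rule", {
  p <- metad_params(height = 1, stride = 1, sigma = c(x = 0.2),
                    bias_factor = 5, kT = 1)
  h <- deposit_hill(hills_list(sigma = c(x = 0.2)), c(x = 0), p, 1)
  expect_equal(h$height[1], 1)  # first hill sees zero bias
  # repeated deposition at one point: height w0 * exp(-V/((g-1)kT))
  h <- deposit_hill(h, c(x = 0), p, 2)
  expect_equal(h$height[2], exp(-1 / 4))
  # a point where V = (g-1) kT gives w0/e
  v_target <- (5 - 1) * 1
  hh <- hills_list(time = 1,
                   center = matrix(0, ncol = 1, dimnames = list(NULL, "x")),
                   sigma = c(x = 1e8), height = v_target)
  hh2 <- deposit_hill(hh, c(x = 0), p, 2)
  expect_equal(hh2$height[2], exp(-1), tolerance = 1e-9)
  # enormous bias factor recovers untempered heights
  p_inf <- metad_params(height = 1, stride = 1, sigma = c(x = 0.2),
                        bias_factor = 1e9, kT = 1)
  h3 <- deposit_hill(deposit_hill(hills_list(sigma = c(x = 0.2)),
                                  c(x = 0), p_inf, 1), c(x = 0), p_inf, 2)
  expect_equal(h3$height[2], 1, tolerance = 1e-9)
  # tempering monotonicity: heights never increase at a single point
  hs <- hills_list(sigma = c(x = 0.2))
  for (k in 1:10) hs <- deposit_hill(hs, c(x = 0), p, k)
  expect_true(all(diff(hs$height) <= 0))
})

test_that("zero hill height reduces metadynamics to plain Langevin", {
  pot <- model_potential("double_well_1d", barrier = 5, x0 = 1)
  cfg <- langevin_config(timestep = 2e-3, n_steps = 2e4, seed = 31)
  mp0 <- metad_params(height = 0, stride = 1, sigma = c(x = 0.15),
                      bias_factor = 10)
  run <- run_metad(pot, mp0, cfg)
  plain <- simulate_langevin(pot, cfg)
  expect_identical(run$trajectory$positions, plain$positions)
  expect_equal(nrow(run$hills), 0)
})

test_that("the restraining wall leaves interior dynamics bit-identical", {
  pot <- model_potential("radial_binding_2d", depth = 6, barrier = 2)
  cfg <- langevin_config(timestep = 5e-4, n_steps = 2e4, seed = 9,
                         save_stride = 10L)
  mp0 <- metad_params(height = 0, stride = 1, sigma = c(rho = 0.2),
                      bias_factor = 10)
  free <- run_metad(pot, mp0, cfg)
  expect_lt(max(free$trajectory$cv[, "rho"]), 4.5)  # never reaches the wall
  walled <- run_metad(pot, mp0, cfg, wall = wall_params(k = 10, rho_s = 4.5))
  expect_identical(free$trajectory$positions, walled$trajectory$positions)
})

test_that("well-tempered bias accelerates barrier recrossings", {
  pot <- model_potential("double_well_1d", barrier = 8, x0 = 1)
  mp <- metad_params(height = 1.2, stride = 0.5, sigma = c(x = 0.15),
                     bias_factor = 10)
  for (seed in 1:2) {
    cfg <- langevin_config(timestep = 1e-3, n_steps = 2e5, seed = seed,
                           save_stride = 10L)
    n_plain <- count_well_crossings(simulate_langevin(pot, cfg)$cv[, 1])
    n_biased <- count_well_crossings(
      run_metad(pot, mp, cfg)$trajectory$cv[, 1])
    expect_lte(n_plain, 1)
    expect_gte(n_biased, 3)
  }
})

test_that("converged bias mirrors the potential by the well-tempered factor", {
  run <- toy_metad_run(n_steps = 4e6, seed = 5)
  g <- seq(-1.5, 1.5, length.out = 61)
  V <- bias_value(run$hills, matrix(g, ncol = 1, dimnames = list(NULL, "x")))
  U <- potential_energy(run$potential, matrix(g))
  # V(s) converges to -(1 - 1/gamma) U(s) + const
  resid <- V + (1 - 1 / 10) * U
  expect_lt(diff(range(resid)), 1)
})

test_that("grid-cached engine bias agrees with direct hill summation", {
  run <- toy_metad_run(n_steps = 2e5, seed = 12)
  idx <- round(seq(1, length(run$trajectory$time), length.out = 50))
  direct <- bias_value(run$hills,
                       matrix(run$trajectory$cv[idx, 1], ncol = 1,
                              dimnames = list(NULL, "x")))
  # recorded bias at frame i includes hills deposited up to that frame time
  recorded <- run$bias_trace$bias[idx]
  t_i <- run$trajectory$time[idx]
  full_direct <- vapply(seq_along(idx), function(k) {
    hl <- run$hills[run$hills$time <= t_i[k], , drop = FALSE]
    attr(hl, "cv_names") <- "x"
    class(hl) <- c("hills", "data.frame")
    bias_value(hl, matrix(run$trajectory$cv[idx[k], 1], ncol = 1,
                          dimnames = list(NULL, "x")))
  }, numeric(1))
  expect_equal(recorded, full_direct, tolerance = 1e-4)
  expect_true(all(direct >= recorded - 1e-8))
})

test_that("total bias never decreases as hills accumulate", {
  p <- metad_params(height = 0.7, stride = 1, sigma = c(x = 0.3),
                    bias_factor = 8)
  hs <- hills_list(sigma = c(x = 0.3))
  pts <- matrix(seq(-1, 1, length.out = 21), ncol = 1,
                dimnames = list(NULL, "x"))
  prev <- bias_value(hs, pts)
  set.seed(4)
  for (k in 1:15) {
    hs <- deposit_hill(hs, c(x = runif(1, -1, 1)), p, k)
    cur <- bias_value(hs, pts)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("survivor-averaged maximum bias follows the survivor rule", {
  # identical monotone traces, no escapes: the average is the trace itself
  tr <- data.frame(time = 0:10, bias = (0:10) / 2)
  s <- survivor_max_bias(list(tr, tr), escape_time = c(20, 20),
                         event = c(FALSE, FALSE))
  expect_equal(s$vmb, tr$bias)
  # one run escapes at t = 5: beyond that only the survivor contributes
  tr2 <- data.frame(time = 0:10, bias = rep(2, 11))
  s2 <- survivor_max_bias(list(tr, tr2), escape_time = c(20, 5),
                          event = c(FALSE, TRUE))
  expect_equal(s2$vmb[s2$time <= 4], (tr$bias[1:5] + 2) / 2)
  expect_equal(s2$vmb[s2$time > 5], tr$bias[7:11])
  expect_equal(s2$n_survivors, c(rep(2, 6), rep(1, 5)))
  # constant traces give a constant series
  trc <- data.frame(time = 0:5, bias = rep(1.5, 6))
  expect_equal(unique(survivor_max_bias(list(trc, trc))$vmb), 1.5)
  # identical monotone traces with staggered escapes: the survivor average
  # is the common running maximum, hence non-decreasing
  mono <- data.frame(time = 0:50, bias = cummax(cumsum(abs(rnorm(51, 0.1)))))
  sv <- survivor_max_bias(rep(list(mono), 5),
                          escape_time = c(12, 25, 33, 41, 50),
                          event = rep(TRUE, 5))
  expect_true(all(diff(sv$vmb) >= -1e-12))
  expect_error(survivor_max_bias(list()), "no bias traces")
})

test_that("infrequent metadynamics ensembles censor, accelerate, and differ by seed", {
  pot <- model_potential("radial_binding_2d", depth = 6, barrier = 2)
  wall <- wall_params(k = 10, rho_s = 4.2)
  cfg <- langevin_config(timestep = 5e-4, n_steps = 3e4, seed = 50,
                         save_stride = 100L)
  # without bias on an 8 kT barrier almost nothing escapes in a short budget
  mp0 <- metad_params(height = 0, stride = 0.5, sigma = c(rho = 0.2),
                      bias_factor = 10)
  quiet <- generate_imetad_ensemble(pot, mp0, cfg, n_runs = 20, wall = wall)
  expect_gte(quiet$N, 18)
  expect_true(all(quiet$table$time > 0))
  # with bias most runs escape within the same budget
  mp <- metad_params(height = 0.5, stride = 0.25, sigma = c(rho = 0.2),
                     bias_factor = 10)
  active <- generate_imetad_ensemble(pot, mp, cfg, n_runs = 20, wall = wall)
  expect_gte(active$M, 18)
  # distinct seeds give distinct escape times
  t_ev <- active$table$time[active$table$event]
  expect_equal(anyDuplicated(t_ev), 0)
})
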
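test_that("region integration has the exact closed-form limits", {
  # two flat levels on equal-area boxes: dG = -(F_unbound - F_bound) = -delta
  edges <- list(rho = seq(0, 4, by = 0.1), cn = seq(0, 10, by = 0.5))
  F <- matrix(0, 40, 20)
  F[31:40, ] <- 1.7  # unbound shelf at +1.7 kT
  fes <- fes_grid(edges, F, shifted = TRUE)
  bound <- region_box(rho = c(0, 1), cn = c(0, 10), label = "bound")
  unbound <- region_box(rho = c(3, 4), cn = c(0, 10), label = "unbound")
  expect_equal(free_energy_difference(fes, bound, unbound), -1.7,
               tolerance = 1e-12)
  # swapping two identical regions gives zero
  bound2 <- region_box(rho = c(3, 4), cn = c(0, 10), label = "bound")
  unbound2 <- region_box(rho = c(0, 1), cn = c(0, 10), label = "unbound")
  expect_equal(free_energy_difference(fes, bound, unbound) +
                 free_energy_difference(fes, bound2, unbound2), 0,
               tolerance = 1e-12)
  # shrinking a flat unbound region changes dG by exactly -kT ln(area ratio)
  small <- region_box(rho = c(3, 3.5), cn = c(0, 10), label = "unbound")
  expect_equal(free_energy_difference(fes, bound, small) -
                 free_energy_difference(fes, bound, unbound),
               log(0.5), tolerance = 1e-12)
  expect_error(free_energy_difference(fes, bound,
                                      region_box(rho = c(3, 4),
                                                 cn = c(100, 110),
                                                 label = "unbound")),
               "unbound")
})

test_that("grid integration matches adaptive quadrature on an analytic surface", {
  skip_if_not_installed("pracma")
  f <- function(r, c) 3 - 3 * exp(-((r - 0.8)^2 / 0.5 + (c - 16)^2 / 40)) -
    2 * exp(-((r - 2.4)^2 / 0.5 + (c - 2)^2 / 40))
  edges <- list(rho = seq(0.2, 3.0, by = 0.001), cn = seq(0, 20, by = 0.01))
  fes <- fes_from_function(f, edges, kT = 1, shifted = FALSE)
  bound <- region_box(rho = c(0.5, 1.1), cn = c(12, 20), label = "bound")
  unbound <- region_box(rho = c(2.1, 2.7), cn = c(0, 5), label = "unbound")
  dg <- free_energy_difference(fes, bound, unbound)
  Ib <- pracma::integral2(function(r, c) exp(-f(r, c)),
                          0.5, 1.1, 12, 20, reltol = 1e-13)$Q
  Iu <- pracma::integral2(function(r, c) exp(-f(r, c)),
                          2.1, 2.7, 0, 5, reltol = 1e-13)$Q
  expect_lt(abs(dg - (-log(Ib / Iu))), 1e-6)
})

test_that("volume-entropy correction reproduces the worked value", {
  tp <- thermo_params(temperature = 300, rho_s = 28, v_prot = 48300,
                      v0 = 1660)
  expect_equal(round(volume_entropy_correction(tp), 1), 1.9)
  # accessible volume equal to the standard volume gives zero
  rho_eq <- ((1660 * 3) / (4 * pi))^(1 / 3)
  tp0 <- thermo_params(rho_s = rho_eq, v_prot = 0)
  expect_equal(volume_entropy_correction(tp0), 0, tolerance = 1e-9)
  # accessible volume of e * V0 gives exactly RT
  rho_e <- ((exp(1) * 1660 * 3) / (4 * pi))^(1 / 3)
  tpe <- thermo_params(rho_s = rho_e, v_prot = 0)
  expect_equal(volume_entropy_correction(tpe),
               GAS_CONSTANT_KCAL * 300, tolerance = 1e-9)
  expect_error(volume_entropy_correction(
    thermo_params(rho_s = 5, v_prot = 48300)), "non-positive")
  expect_error(thermo_params(v0 = 2000), "inconsistent")
})

test_that("standard-state bookkeeping reproduces the reference rows", {
  expect_equal(standard_binding_free_energy(-3.3, 1.9), -5.2)
  expect_equal(standard_binding_free_energy(-2.8, 1.9), -4.7)
  expect_equal(standard_binding_free_energy(-1.4, 0), -1.4)
  res <- thermo_result(-3.3, thermo_params())
  expect_equal(res$dg_b, res$dg_metad - res$tds, tolerance = 1e-9)
  expect_equal(res$kd, exp(res$dg_b / (GAS_CONSTANT_KCAL * 300)),
               tolerance = 1e-9)
  expect_equal(round(res$dg_b, 1), -5.2)
})

test_that("dissociation constants follow from the binding free energy", {
  expect_equal(kd_from_dg(0), 1)
  # -5.2 kcal/mol at 300 K sits in the 0.2 mM range
  expect_equal(signif(1000 * kd_from_dg(-5.2), 1), 0.2)
  expect_equal(kd_from_dg(-GAS_CONSTANT_KCAL * 300 * log(10)), 0.1,
               tolerance = 1e-12)
  expect_gt(kd_from_dg(-4.7), kd_from_dg(-5.2))
})

test_that("block analysis is flat for independent samples and plateaus for AR(1)", {
  # i.i.d.: averaged over replicates the error is block-size independent
  set.seed(101)
  reps <- replicate(100, block_error(rnorm(1024))$se)
  avg <- rowMeans(reps)
  expect_lt(max(avg) / min(avg), 1.2)
  # AR(1): plateau near the closed-form sd * sqrt((1+phi)/(1-phi)/n)
  phi <- 0.9
  set.seed(55)
  plateaus <- replicate(20, {
    x <- as.numeric(arima.sim(list(ar = phi), 2^14))
    be <- block_error(x)
    expect_gt(be$plateau, be$se[1])  # correlations inflate the naive error
    be$plateau / (sd(x) * sqrt((1 + phi) / (1 - phi) / 2^14))
  })
  expect_equal(mean(plateaus), 1, tolerance = 0.3)
  expect_equal(block_error(rep(3, 256))$plateau, 0)
  expect_error(block_error(1:3, block_sizes = 64), "too short")
})

test_that("convergence series ends at the full-data estimate", {
  run <- toy_metad_run(n_steps = 4e5, seed = 33)
  edges <- list(x = seq(-1.8, 1.8, length.out = 41))
  bound <- region_box(x = c(-1.4, -0.6), label = "bound")
  unbound <- region_box(x = c(0.6, 1.4), label = "unbound")
  tmax <- max(run$trajectory$time)
  conv <- dg_convergence(run, edges, bound, unbound,
                         checkpoints = c(0.5, 0.75, 1) * tmax)
  full <- free_energy_difference(reweight_from_run(run, edges),
                                 bound, unbound)
  expect_equal(conv$dg[3], full, tolerance = 1e-12)
  # second half of a converged run drifts by less than 0.5 kT
  expect_lt(max(abs(diff(conv$dg))), 0.5)
})

test_that("independent runs agree within their combined block errors", {
  edges <- list(x = seq(-1.8, 1.8, length.out = 41))
  bound <- region_box(x = c(-1.4, -0.6), label = "bound")
  unbound <- region_box(x = c(0.6, 1.4), label = "unbound")
  r1 <- toy_metad_run(n_steps = 1e6, seed = 61)
  r2 <- toy_metad_run(n_steps = 1e6, seed = 62)
  b1 <- dg_block_error(r1, edges, bound, unbound)
  b2 <- dg_block_error(r2, edges, bound, unbound)
  expect_gt(b1$se, 0)
  expect_lt(abs(b1$dg - b2$dg),
            2 * (b1$se + b2$se) + 0.2)
})
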
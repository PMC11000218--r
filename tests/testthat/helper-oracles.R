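# Shared oracles and small builders used across the test files.

# Expected per-bin free energy of the Boltzmann law: integrates exp(-U/kT)
# over each histogram bin (the correct reference for a binned estimate,
# which differs from U(midpoint) where the force is steep).
boltzmann_bin_reference <- function(potential, edges, kT = 1) {
  pb <- vapply(seq_len(length(edges) - 1), function(i)
    stats::integrate(function(x)
      exp(-potential_energy(potential, matrix(x)) / kT),
      edges[i], edges[i + 1])$value, numeric(1))
  -kT * log(pb / diff(edges))
}

# Count transitions between the two wells of a 1-D double-well trajectory,
# ignoring the barrier-top region.
count_well_crossings <- function(x, core = 0.5) {
  s <- sign(x[abs(x) > core])
  sum(diff(s) != 0)
}

# Small deterministic double-well metadynamics run reused by several tests.
toy_metad_run <- function(n_steps = 1e6, seed = 5, barrier = 5,
                          bias_factor = 10, timestep = 2e-3) {
  pot <- model_potential("double_well_1d", barrier = barrier, x0 = 1)
  mp <- metad_params(height = 1.2, stride = 1, sigma = c(x = 0.15),
                     bias_factor = bias_factor)
  cfg <- langevin_config(timestep = timestep, n_steps = n_steps, seed = seed,
                         save_stride = 10L)
  run_metad(pot, mp, cfg)
}

# Numerical integral of the biased-hazard integrand, as an independent check
# of the closed-form expression.
hazard_quadrature <- function(t, gamma, model, beta) {
  stats::integrate(function(u)
    exp(gamma * beta * vmb_value(model, u)), 0, t,
    rel.tol = 1e-12, abs.tol = 0)$value
}
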
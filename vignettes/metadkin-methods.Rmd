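---
title: "Methods: metadynamics thermodynamics and escape-rate estimation"
author: "metadkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metadynamics thermodynamics and escape-rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadkin)
```

# Scope

`metadkin` implements the analysis layer of an enhanced-sampling study of
ligand (product) release from a protein: how one goes from biased
trajectories to a standard-state binding free energy, and from biased
escape-time ensembles to an unbiased dissociation rate. The molecular
dynamics itself is replaced by analytic Langevin model systems, so every
stage of the analysis can be exercised, seeded and verified against known
ground truth without any trajectory data. The same readers and estimators
accept externally produced PLUMED-style tables (COLVAR-like time series,
HILLS-like Gaussian records), so the analysis half applies unchanged to real
simulation output.

# The sampling model

## Volume-restrained well-tempered metadynamics

Binding/unbinding is sampled with well-tempered metadynamics: repulsive
Gaussians of initial height $w_0$ are deposited every $\tau$ time units
along a collective variable (CV), with heights tempered as
$w = w_0\, e^{-V(s,t)/((\gamma_{wt}-1)kT)}$ so the bias converges to
$-(1-1/\gamma_{wt})F(s)$. To let the unbound ligand return, it is confined
to a sphere of radius $\rho_s$ by a one-sided harmonic wall
$V(\rho) = k(\rho-\rho_s)^2$ for $\rho > \rho_s$ (zero inside). The wall
convention carries **no 1/2 prefactor** — the upper-wall convention under
which restraint spring constants are conventionally quoted (e.g.
$k = 200$ kJ/mol/Å², $\rho_s = 28$ Å for a cytosine-deaminase-sized
system); with a 1/2 prefactor every example value would halve.

The degree of ligand–protein contact is measured by a coordination number,
a smooth sum over atom pairs of the rational switching function
$s(r) = \frac{1 - (r/r_0)^m}{1 - (r/r_0)^n}$ (reference values
$r_0 = 4.5$ Å, $m = 6$, $n = 12$). The removable singularity at $r = r_0$
is evaluated analytically as the limit $m/n$ (with a first-order expansion
in a $10^{-6}$-wide guard band so the function stays smooth in floating
point) rather than by an epsilon offset — exactness makes the limit
testable. Full dissociation is declared when an (unbiased) coordination
monitor first drops below 0.01; later re-entries are ignored.

## The model systems

Two analytic landscapes stand in for the protein–ligand energy surface:

* `double_well_1d`: $U(x) = \Delta U\,((x/x_0)^2-1)^2$, two minima at
  $\pm x_0$ separated by a barrier $\Delta U$ — the workhorse for
  free-energy-recovery checks.
* `radial_binding_2d`: Cartesian $(x,y)$ dynamics on a radially symmetric
  landscape with a single bound well (depth $D$ below the outer plateau) at
  $\rho_{min}$, a barrier ($B$ above the plateau) at $\rho_b$, and an
  exactly flat exterior beyond a stated radius. A synthetic coordination
  number $C_N(\rho) = c_{max}\,s(\rho)$ (the same switching function)
  decreases smoothly from bound to unbound, so the two-dimensional
  $(\rho, C_N)$ machinery — reweighting, region integration — is exercised
  end to end. Defaults $D = 6\,kT$, $B = 2\,kT$, $\rho_{min} = 1$,
  $\rho_b = 2$ give an 8 kT unbinding barrier: high enough that unbiased
  escape is rare on test timescales, low enough that biased escape is fast.

Dynamics are overdamped (position) Langevin integrated with Euler–Maruyama:
$x_{t+dt} = x_t - \frac{dt}{\gamma_f}\nabla U + \sqrt{2kT\,dt/\gamma_f}\,\xi$.
Inertia is irrelevant to the analysis layer being tested, and the overdamped
scheme has an exactly known stationary law against which sampling is
verified (free diffusion, equipartition in a harmonic well, Boltzmann
statistics on the double well). Everything runs in reduced units
($kT = 1$, friction 1); laboratory units (kJ/mol vs kcal/mol, Å vs nm)
enter only at the I/O and reporting boundary, where conversion helpers are
provided, because the reference literature mixes all four.

Timestep choice matters: with the default quartic double well the largest
curvature is $\sim 8\Delta U/x_0^2$, and Euler–Maruyama's stationary
distribution acquires an $O(dt\,U'')$ tail bias. $dt = 10^{-3}$–$2\times
10^{-3}$ keeps that bias below 0.1–0.2 kT on sampled cells; the tests use
these values.

The generator's role is statistical, not chemical. It emulates: a bound
basin behind a multi-kT barrier, a growing well-tempered bias, committed
escapes detected by a coordination threshold, censoring at an explicit
horizon (never silent truncation), and escape-time ensembles whose survival
statistics follow the time-dependent-rate law below. It does **not**
emulate: solvent and friction anisotropy, intermediate metastable states on
the release path, multidimensional suboptimal CVs (the synthetic $C_N$ is a
deterministic function of $\rho$, so the toy CV is ideal by construction),
or conformational gating. Passing tests therefore demonstrate correctness
and calibration of the estimators, not that any particular protein system
satisfies their assumptions.

One design point mirrors a protocol difference knowingly: real studies
launch replicate escape simulations from frames of an equilibrated bound
trajectory; the toy ensembles use independent seeds started at the bound
minimum. For an equilibrated intra-basin distribution these are equivalent
at the level of escape statistics.

# From biased trajectories to binding thermodynamics

## Time-independent reweighting

Each saved frame carries its instantaneous bias $V(s_t, t)$. The
time-independent estimator assigns weights
$w_t = \exp\{\beta[V(s_t,t) - c(t)]\}$ with the running offset
$$c(t) = \frac{1}{\beta}\ln
  \frac{\sum_s \exp\left(\frac{\beta\gamma_{wt}}{\gamma_{wt}-1}V(s,t)\right)}
       {\sum_s \exp\left(\frac{\beta}{\gamma_{wt}-1}V(s,t)\right)},$$
evaluated on a CV grid after each hill with log-sum-exp stabilisation
(overflow otherwise occurs once the accumulated bias exceeds ~700 kT).
The free-energy surface is $F = -kT\ln(\text{weighted histogram})$,
shifted so the minimum over visited cells is zero; unvisited cells are a
sentinel (`NA`, treated as $+\infty$ downstream). Per-cell effective sample
counts $(\sum w)^2/\sum w^2$ accompany the surface so consumers can mask
poorly sampled cells.

Two defaults were genuinely open and are exposed as configuration: the
$c(t)$ grid defaults to the FES axis of the biased CV (a refinement factor
is available; a 4× refinement changes $c(t)$ by well under 0.1 kT in the
tests), and the initial 10% of the time span is discarded as transient —
early samples are taken while the bias is far from its asymptotic shape and
carry the largest reweighting error.

## Region integration and the standard state

The bound/unbound free-energy difference integrates Boltzmann weights over
two boxes in $(\rho, C_N)$ space:
$$\Delta G_{MetaD} = -kT\ln\frac{\sum_{bound} e^{-\beta F}\,\Delta A}
 {\sum_{unbound} e^{-\beta F}\,\Delta A},$$
a cell-area-weighted piecewise-constant rule. At the grid resolutions used
here this rule agrees with adaptive quadrature on an analytic surface to
well below $10^{-6}$ kT (the acceptance script recomputes this), provided
region boundaries align with cell edges; misaligned boundaries quantize the
region at $O(h)$ and dominate the error budget. Cells never visited are
excluded, with a warning when more than 10% of a region is unvisited.

Because the wall restricts the unbound ligand to the sphere, converting to
the 1 M standard state adds the volume-entropy term
$$T\Delta S = RT\ln\frac{\tfrac{4}{3}\pi\rho_s^3 - V_{prot}}{V^0},
\qquad V^0 = 1660\ \text{Å}^3,$$
with $V_{prot}$, the protein volume inside the sphere, a **required input**
(it is measured externally with a probe-grid tool; this package does not
compute volumes). The sign convention is fixed by requiring the reference
bookkeeping to reproduce: $\Delta G_b^\circ = \Delta G_{MetaD} - T\Delta S$
with $T\Delta S > 0$, and $K_d = C^0\exp(\Delta G_b^\circ/RT)$. The gas
constant is $1.9872\times10^{-3}$ kcal/mol/K, $T = 300$ K by default, and
kcal/mol results are conventionally reported to one decimal.

Statistical errors come from block analysis: the post-transient trajectory
is split into contiguous blocks, $\Delta G_{MetaD}$ is recomputed per block,
and the standard error of the block estimates is reported. Since the
entropy correction is exact arithmetic, the same error applies to
$\Delta G_b^\circ$; both are reported. The generic `block_error()` scans
block sizes and reports the plateau (maximum over the scan), the standard
defence against serial correlation.

# From escape times to rates

## The time-dependent-rate survival model

Infrequent metadynamics deposits hills slowly so transition states stay
(nearly) unbiased, and records the biased time of each committed escape.
Under a growing bias the survival probability is
$$S(t) = \exp\left(-k_0\int_0^t e^{\gamma\beta V_{MB}(t')}\,dt'\right),$$
with $k_0$ the unbiased rate and $\gamma \in (0,1]$ a bias-quality factor
(1 for an ideal CV). $V_{MB}(t)$ is the maximum bias averaged over runs
still in the initial basin: escaped runs stop contributing at their escape
time, which keeps the average non-decreasing, consistent with the
pulling-experiment analogy the model is built on. The wording "maximum
bias" vs "instantaneous bias" admits two readings; both are implemented,
and the default is the running maximum $\max_{t'\le t}V^r(t')$, which
guarantees the monotone growth the fit below assumes. Traces are resampled
to a common grid (the coarsest stride present) by linear interpolation; the
trace recording stride defaults to the trajectory save stride.

The numerical $V_{MB}$ series is fitted to $a\log(1+bt)$ up to a cutoff
$t_c$, constant beyond (continuous at $t_c$ by construction). For fixed $b$
the optimal $a$ is linear least squares, so the fit profiles over $b$ with
a deterministic 1-D minimisation — no starting values, no convergence
flags. With this model the integrated hazard is closed form:
$\int_0^t(1+bt')^c\,dt' = \frac{(1+bt)^{c+1}-1}{b(c+1)}$ with
$c = \gamma\beta a$ (logarithmic special case at $c = -1$), linear in $t$
beyond the cutoff. The closed form is tested against adaptive quadrature to
$10^{-8}$.

## Likelihood, model selection, validation, uncertainty

$(k_0,\gamma)$ maximise
$$\ell = \sum_{events}\ln\!\left[k_0 e^{\gamma\beta V_{MB}(t_j)}S(t_j)\right]
 + \sum_{censored}\ln S(t_j),$$
where censored runs contribute survival to their horizon. Here too the
structure collapses one dimension: at fixed $\gamma$ the optimal rate is
$\hat k_0(\gamma) = M/\sum_j I(t_j,\gamma)$ ($M$ events, $I$ the integrated
hazard shape), leaving a deterministic 1-D profile search over $\gamma$
(0.02-step grid then golden-section refinement). This replaces a generic
two-parameter simplex with something exactly reproducible and not
basin-dependent. Fitted $\gamma > 1$ is reported with a warning, not
clipped. If the bias series is identically zero, $\gamma$ is unidentifiable
and is flagged; $k_0$ then reduces to the closed-form exponential estimate
$M/\sum t_j$ (a tested reduction).

The cutoff $t_c$ is scanned over deciles of the $V_{MB}$ time span (the
selection objective — maximise the Kolmogorov–Smirnov p-value, then
minimise the statistic $D$ — is stated by the reference procedure, the
search grid is not; deciles make the scan scale-free). Validation compares
the empirical CDF of **event** times against $1 - S(t)$ with a one-sample
KS test using the asymptotic Kolmogorov p-value, without a
parameter-estimation correction — matching the stated procedure, and a
known approximation that errs conservative (p-values biased high under the
null; the calibration check in the acceptance script quantifies this).
Censored runs are excluded from the ECDF.

Uncertainty follows the reference bootstrap: resample runs with
replacement, refit $(k_0,\gamma)$ with the $V_{MB}$ model held fixed (the
survivor average is an ensemble-level quantity; refitting it per resample
is available by configuration and makes little difference for deterministic
traces), keep resamples passing the KS test at $p > 0.05$, and report the
30th/70th percentiles of the retained $\hat k_0$. A warning is raised when
the best fit falls outside its own interval. Note the statistical meaning
honestly: a central 30th–70th percentile interval is a ~40%-coverage
interval for a well-calibrated estimator; it describes variance, not a
confidence bound.

The conventional hyperdynamics estimator — rescale each step by
$e^{\beta V}$, fit an exponential to the rescaled times — is implemented
for comparison and reports its own KS result. With suboptimal CVs it is
expected to fail that test, and the implementation reports the failure
rather than hiding it; on the ideal-CV toy ensembles the two estimators
agree within a factor of two (tested).

# Numerical and engineering choices

* **Bias evaluation in the run loop is grid-cached**: the bias and its
  derivative are accumulated on a fine uniform grid (default 4096 points,
  one $O(grid)$ update per hill) and evaluated by linear interpolation, the
  convention of grid-based metadynamics engines. Direct summation over
  hills — kept as the exact reference in `bias_value()` and pinned against
  the engine in a test at $10^{-4}$ relative — would cost
  $O(\text{steps}\times\text{hills})$ and is impractical for
  multi-million-step runs.
* **Determinism**: every stochastic routine takes an explicit seed;
  identical seed and configuration give bit-identical trajectories
  (ensembles derive per-run seeds as `seed + run - 1`).
* **Escape-time sampling** inverts the closed-form integrated hazard by
  bracketed root search to $10^{-12}$ relative tolerance; draws beyond the
  horizon are returned censored, never dropped.
* **Degenerate inputs**: empty hill lists are a zero bias; zero-bias data
  flag $\gamma$ unidentifiable; identical escape times give a zero-width
  bootstrap interval; regions with no visited cells are errors naming the
  region; non-finite monitor series are data errors.
* **Angular CVs are not treated geodesically** in the Gaussians — the toy
  CVs are non-periodic. Spherical-coordinate helpers name their outputs
  `polar` and `azimuth` explicitly because the θ/ϕ assignment is
  inconsistent across the literature.
* Problem sizes in the tests and acceptance script — $4\times10^6$ Langevin
  steps for the free-energy recovery, $10^7$ for the Boltzmann check,
  ensembles of 41 (study scale) and 500 (asymptotic checks) escape times,
  50 calibration replicates × 50 bootstrap resamples, 200 KS-calibration
  replicates — were chosen so each estimator's statistical error is several
  times smaller than the tolerance it is tested against.

# A worked toy pipeline

```{r pipeline, eval = FALSE}
# 1. biased sampling on the 5 kT double well
pot <- model_potential("double_well_1d", barrier = 5, x0 = 1)
mp  <- metad_params(height = 1.2, stride = 1, sigma = c(x = 0.15),
                    bias_factor = 10)
cfg <- langevin_config(timestep = 2e-3, n_steps = 4e6, seed = 1,
                       save_stride = 10)
run <- run_metad(pot, mp, cfg)

# 2. reweight onto a free-energy profile and integrate two regions
fes <- reweight_from_run(run, list(x = seq(-1.8, 1.8, length.out = 61)))
dg  <- free_energy_difference(fes,
        region_box(x = c(-1.4, -0.6), label = "bound"),
        region_box(x = c(0.6, 1.4), label = "unbound"))

# 3. standard-state bookkeeping in laboratory units
res <- thermo_result(-3.3, thermo_params(rho_s = 28, v_prot = 48300))

# 4. escape-rate estimation on a synthetic ensemble with known truth
ens <- sample_escape_times(ground_truth_rates(), n_runs = 41, horizon = 50,
                           seed = 1)
fit <- fit_rates(ens)
bootstrap_rates(ens, fit, n_boot = 50, seed = 1)
```

# Known limitations

* The analysis assumes the logarithmic $V_{MB}$ growth model; bias
  schedules that plateau non-logarithmically are fit only approximately
  (the KS test is the guard).
* The KS p-value ignores parameter estimation, so it is conservative as a
  goodness-of-fit screen and should not be read as an exact tail
  probability.
* The toy coordination number is a deterministic function of the radial
  distance; consequences of genuinely independent, suboptimal CVs (the
  regime where the bias-quality factor matters most) can be emulated only
  through the $\gamma$ parameter of the direct sampler, not by the Langevin
  systems themselves.
* The engine biases a single CV; multi-CV Gaussians are supported by the
  evaluation API (`bias_value`, `deposit_hill`) but not by the compiled run
  loop. No multiple walkers, no adaptive Gaussians, no funnel-shaped
  restraint (the spherical variant is the one implemented).
* Protein volume $V_{prot}$ is an input, never computed.
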
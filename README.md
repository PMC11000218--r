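# metadkin

Thermodynamics and kinetics of ligand release from metadynamics.

Slow product release is often the rate-limiting step of an enzymatic cycle.
Enhanced-sampling molecular dynamics probes it two ways: **volume-restrained
well-tempered metadynamics** samples repeated binding/unbinding events and
yields a standard-state binding free energy, and **infrequent metadynamics**
accelerates individual escapes whose biased escape times carry the unbiased
dissociation rate. `metadkin` implements the full analysis layer for both,
exercised end to end on analytic Langevin model systems with known ground
truth, and reads/writes PLUMED-style COLVAR/HILLS tables so the same
estimators apply to real simulation output. It is aimed at people doing
enhanced-sampling studies of binding who want the analysis half — not the MD
engine — as tested, reusable, seedable code.

## What it computes

**Binding thermodynamics.** Biased trajectories are reweighted with the
time-independent estimator: sample weights
*w* = exp{β[*V*(*s*,*t*) − *c*(*t*)]}, with the offset *c*(*t*) evaluated
on a grid after each hill. The free-energy surface over (distance ρ,
coordination number *C*<sub>N</sub>) is integrated over bound and unbound
boxes,

&nbsp;&nbsp;ΔG<sub>MetaD</sub> = −kT ln [ ∫<sub>bound</sub> e<sup>−βF</sup> d**s** / ∫<sub>unbound</sub> e<sup>−βF</sup> d**s** ],

and corrected to the 1 M standard state for the spherical restraint of
radius ρ<sub>s</sub> that confines the unbound ligand:

&nbsp;&nbsp;TΔS = RT ln[(4/3 π ρ<sub>s</sub>³ − V<sub>prot</sub>)/V⁰],&nbsp;&nbsp;
ΔG<sub>b</sub>° = ΔG<sub>MetaD</sub> − TΔS,&nbsp;&nbsp;
K<sub>d</sub> = C⁰ exp(ΔG<sub>b</sub>°/RT).

Errors come from block analysis.

**Release kinetics.** Escape-time ensembles are fitted with Kramers
time-dependent rate theory: the survival law

&nbsp;&nbsp;S(t) = exp[ −k₀ ∫₀ᵗ e^{γ β V_MB(t′)} dt′ ],

where V<sub>MB</sub>(t) is the maximum bias averaged over runs still in the
initial basin, modelled as *a* log(1 + *bt*) up to a cutoff. (k₀, γ) are
found by profile maximum likelihood (censored runs supported), validated
with a Kolmogorov–Smirnov test against the implied distribution, with
uncertainties from a KS-filtered bootstrap (30th/70th percentiles). The
conventional hyperdynamics time-rescaling estimator is included for
comparison. A direct sampler of the survival law and biased Langevin model
systems (double well, radial binding landscape with a synthetic coordination
number) provide ground truth for every stage.

## Worked example

Standard-state bookkeeping for a measured free-energy difference of
−3.3 kcal/mol with a 28 Å restraint sphere and 48300 Å³ of protein volume:

```r
library(metadkin)
thermo_result(-3.3, thermo_params(temperature = 300, rho_s = 28,
                                  v_prot = 48300))
#> dG_MetaD = -3.3 kcal/mol
#> TdS      = 1.9 kcal/mol (volume-entropy correction)
#> dG_b0    = -5.2 kcal/mol
#> K_d      = 0.15 mM
```

The 1.9 kcal/mol is the translational-entropy price of releasing the ligand
from the restraint sphere into 1 M standard conditions; the corrected
−5.2 kcal/mol corresponds to a dissociation constant in the 0.2 mM range —
modest affinity, endergonic release.

Rate estimation on a synthetic 41-run escape ensemble drawn from the
survival law with known truth (k₀ = 1, γ = 0.7, in reduced units):

```r
ens <- sample_escape_times(ground_truth_rates(k0 = 1, gamma = 0.7,
                                              a = 3, b = 0.5, t_cut = 10),
                           n_runs = 41, horizon = 50, seed = 1)
fit <- fit_rates(ens)
fit$bootstrap <- bootstrap_rates(ens, fit, n_boot = 50, seed = 1)
fit
#> Kramers time-dependent rate fit
#>   k0 = 1.001, gamma = 0.884
#>   KS: D = 0.0633, p = 0.997
#>   bootstrap k0 30th-70th percentile: [0.8485, 1.077]
```

The fit recovers the unbiased rate (k₀ ≈ 1.0) from biased escape times; γ
estimates the bias quality and, at this ensemble size, scatters around its
true value. The KS p-value says the fitted survival law is consistent with
the observed escape-time distribution.

A full toy pipeline — biased sampling on a double well, reweighting, region
integration, rate fitting — runs from the command line:

```sh
Rscript inst/scripts/metadkin.R demo --out demo_out --seed 7
```

## Layout

* `R/`, `src/` — estimators and the compiled Langevin/metadynamics engine
* `vignettes/metadkin-methods.Rmd` — the models, assumptions, parameter
  choices and limitations, in detail
* `inst/extdata/` — small synthetic text fixtures (labelled as such)
* `tests/testthat/` — unit, property and acceptance tests
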
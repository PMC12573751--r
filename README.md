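# committorlab

Nonparametric determination of the committor — the optimal one-dimensional
reaction coordinate — for multimolecular aggregation, from long equilibrium
trajectories.

## The problem and who this is for

Simulations of aggregating systems (condensation, crystallization, protein
aggregation) produce long, high-dimensional time series whose two-state
kinetics between a diluted state *A* and an aggregated state *B* is usually
summarized by a scalar reaction coordinate `r(X) ∈ [0,1]` with `r(A) = 0`,
`r(B) = 1`, and a diffusive model on its free-energy profile
`F(r)/k_BT = −ln p_eq(r)` with diffusion coefficient `D(r)`. Physically
motivated coordinates such as the largest-aggregate size `n` are
non-Markovian under projection, and their diffusive models get the kinetics
wrong — typically several-fold too fast. The committor `q(X)`, the
probability of reaching *B* before *A*, is the coordinate for which the
diffusive model is exact for the equilibrium flux `J = D(q) p_eq(q)`, the
mean first passage times

    τ_{B→A} = ∫₀¹ dq′ / [p_eq(q′) D(q′)] · ∫_{q′}¹ p_eq(q″) dq″ ,

and the mean transition-path times. This package is for simulators and
method developers who need to (i) compute `q` nonparametrically from
trajectory time series, (ii) *prove* its optimality with a stringent
validation test, and (iii) extract the resulting kinetics.

## What is inside

* **Lattice aggregation model** (`lattice_config`, `run_lattice`,
  `calibrate_coexistence_temperature`): Metropolis Monte Carlo on an
  `L × L` periodic lattice, `N` molecules with binary orientations, bond
  energies `−ψ_s` (aligned) / `−ψ_w` (nonaligned), anisotropy
  `ξ = ψ_s/ψ_w`; equal-weight calibration of the dilute/aggregated
  coexistence temperature `T*`. Compiled (Rcpp) kernels.
* **Invariant collective variables** (`sorted_distance_matrix`,
  `build_cv_pool`): the minimum-image distance matrix sorted first inside
  each column, then inside each row — translation-, rotation- and
  permutation-invariant CV channels, extracted lazily at bounded memory.
* **Nonparametric optimizer** (`optimize_rc`, `committor_of_n`,
  `optimize_rc_soft`): iterated polynomial variations
  `δr = Σ a_ij r^i x^j` with analytically optimal coefficients minimizing
  the total squared displacement, boundary states clamped exactly; soft
  self-consistent boundary redefinition.
* **Diffusive-model layer** (`rc_profiles`, `zc1`, `validation_scan`,
  `diffusion_coefficient`, `rescale_unit_diffusion`, `mfpt_model`,
  `mfpt_direct`, `nab_integral`, `mtpt_direct`, `flux_profile`): histogram
  and cut profiles at dyadic lags `2^i Δt₀`; the committor validation
  criterion — `Z_C,1(q, Δt)` flat in `q`, independent of `Δt`, equal to the
  transition count `N_AB`; kinetics from the 1D model and directly from the
  series.
* **Synthetic oracles** (`markov_chain_spec`, `double_well_spec`):
  Markov chains and 1D double-well Brownian dynamics with exactly known
  committors and MFPTs, used throughout the tests.

## Worked example

Optimize a committor for 1D double-well Brownian dynamics from a pool of
distorted observables, then validate it and extract kinetics:

```r
library(committorlab)
set.seed(42)
dw <- double_well_spec(barrier = 3, x0 = 1, D0 = 1, dt = 2e-3)
x <- simulate_double_well(dw, 5e5)

bnd <- define_boundary_states(cv_series(x), a_max = -1, b_min = 1)
r0 <- initial_rc(cv_series(x), bnd)
pool <- cv_pool_matrix(cbind(x, x^3, sin(x)), c("x", "x3", "sinx"))
opt <- optimize_rc(r0, pool, l = 4, m_max = 20)
opt
#> rc_optimization: 20 iterations, TSD 144.413 -> 117.177 (0 fallbacks)

q <- analytic_committor_1d(dw)$fun
sqrt(mean((opt$rc$r - q(x))^2))
#> [1] 0.0079

validation_scan(opt$rc, i_max = 7)
#> validation_scan: 8 lags, -ln Zc1 in [-4.786, -4.745], expected -4.812 +/- 0.191 -> PASS

coordinate_kinetics(opt$rc, "q")
#>  coordinate tau_model tau_direct n_events nab_integral nab_direct
#>           q      4663       4396       61        117.2        123
```

Reading the output: the optimizer lowered the total squared displacement
from 144.4 to 117.2; the optimized coordinate matches the closed-form
committor to RMSE 0.008; the cut profile `−ln Z_C,1` is flat across lags
`Δt₀ … 2⁷Δt₀` within the `1/√(2N_AB)` uncertainty of its expected plateau
`−ln N_AB` (PASS); and the mean first passage time predicted by the 1D
diffusive model (4663 frames) agrees with the value measured directly from
the series (4396 frames, 61 events) to ~6%, with the cut-profile integral
(117.2) matching the directly counted 123 transitions.

The same workflow for the lattice model is one call:
`run_pipeline(lattice_config(L = 40, N = 40, T = 0.375, xi = 1,
dt0 = 400, n_steps = 1e7), seed = 1)` simulates, builds the sorted-distance
CV pool, optimizes both `q(n)` and `q`, and prints the validation verdicts
and the kinetics table for both coordinates.

## Conventions worth knowing

Times are in units of the frame interval `Δt₀`; energies in `ψ_w`
(`k_B = 1`). At lag `2^i` profiles are phase-averaged, which makes
`Σ Z_H = T/2^i` and `∫ Z_C,1 dr = TSD` exact identities. The diffusion
estimator is `D = Z_C,1 / (2 Δt Z_H)` with `Z_H` as a density. See the
methods vignette (`vignettes/committor-methods.Rmd`) for the full account
of the model, numerical choices, and limitations.
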
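---
title: "Nonparametric committor estimation: model, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric committor estimation: model, conventions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(committorlab)
```

## The problem

Long equilibrium trajectories of multimolecular systems — aggregation,
crystallization, condensation — live in a configuration space of thousands
of coordinates. Their two-state kinetics (diluted ↔ aggregated) is usually
summarized by projecting onto a one-dimensional reaction coordinate (RC)
$r(\vec X) \in [0,1]$ with $r = 0$ on boundary state $A$ and $r = 1$ on $B$,
and modelling the projected dynamics as diffusion on the free-energy profile
$F(r)/k_BT = -\ln p_{\rm eq}(r)$ with a position-dependent diffusion
coefficient $D(r)$. For an arbitrary RC the projection is non-Markovian and
the diffusive model misestimates kinetics — typically predicting too-fast
rates. The *committor* $q(\vec X)$, the probability of reaching $B$ before
$A$, is the optimal RC: its diffusive model reproduces the equilibrium flux
$J = D(q)\,p_{\rm eq}(q)$, the mean first passage times (MFPT)

$$
\tau_{B\to A} \;=\; \int_0^1 \frac{dq'}{p_{\rm eq}(q')\,D(q')}
\int_{q'}^{1} p_{\rm eq}(q'')\,dq''
$$

and the mean transition-path times, without requiring a separation of time
scales.

This package determines the committor nonparametrically from trajectory
time series and validates the result with a stringent cut-profile
criterion. It contains five layers: a lattice aggregation simulator, a
generator of permutationally invariant collective variables (CVs), the
variational optimizer, the diffusive-model/validation layer, and synthetic
oracles with exactly known committors.

## The lattice aggregation model

`lattice_config()` / `run_lattice()` implement an $L \times L$ periodic
square lattice carrying $N$ molecules with excluded volume. Each molecule
has a binary orientation; nearest neighbours attract with energy $-\psi_s$
when aligned and $-\psi_w$ otherwise, with anisotropy $\xi = \psi_s/\psi_w
\ge 1$. Units: $\psi_w = 1$, $k_B = 1$. Dynamics is canonical Metropolis
Monte Carlo; one elementary attempt updates a single uniformly chosen
molecule — with probability `move_mix` (default 0.5) a translation to a
uniformly drawn 4-neighbour site (rejected outright if occupied), otherwise
an orientation flip — accepted with probability $\min(1, e^{-\Delta E/T})$.
We define the elementary time unit as one *attempted move* (not one sweep);
frames are recorded every `dt0` attempts, and `dt0` is the unit of all
reported times. Translations are nearest-neighbour only: local moves give
the diffusive aggregation dynamics this analysis targets, and the move set
is deliberately free of cluster moves or other kinetic accelerators.

The same 4-neighbour periodic adjacency defines both the energy and the
cluster analysis (`largest_cluster_size()`), so the
classical-nucleation-theory coordinate $n$ — the number of molecules in the
largest aggregate — is consistent with the Hamiltonian.

### Coexistence temperature

At fixed density the model has a first-order transition between a diluted
state (small largest cluster) and an aggregated state. The coexistence
temperature $T^*$ is located by `calibrate_coexistence_temperature()` with
the equal-weight criterion: the basin weight $w(T) = P(n \ge n_{\rm cut})$
(default $n_{\rm cut} = N/2$) crosses $1/2$ at $T^*$; a coarse scan
brackets the crossing and bisection refines it. Calibrated desk-scale
values ship in `inst/extdata/tstar_calibration.json` together with their
metadata; analyses recalibrate at run time rather than trusting the file.

A caveat that matters for interpretation: the sharpness of the transition
is a finite-size property. At the desk scale used throughout the tests
($L = 40$, $N = 40$) the droplet evaporation/condensation barrier is below
$1\,k_BT$ and the largest-cluster histogram near $T^*$ is a broad plateau
rather than two separated peaks. The committor machinery still operates —
transitions between the extreme regions are plentiful — but a clearly
bimodal $F(n)$ requires hundreds of molecules, which is the overnight
regime of `scripts/full_scale.R`. When no barrier-separated pair of minima
exists, `define_boundary_states()` can fall back to coordinate quantiles
(default 15%/85% in the pipeline), with a warning; the `bimodal` flag in
its return value records which path was taken.

## Permutationally invariant collective variables

Good CVs must respect translation, rotation, and permutation symmetry of
identical molecules. Minimum-image pairwise distances $d_{ij}$ handle the
first two; for permutation invariance the full $N \times N$ distance matrix
is sorted sequentially along its two axes — first inside each column, then
inside each row (`sorted_distance_matrix()`). The result depends only on
the multiset structure of the distances, so each entry $\bar d_{ij}$ of the
sorted matrix is an invariant scalar observable whose time series can feed
the optimizer.

Storing all $N^2$ channels over $10^5$–$10^6$ frames is memory-prohibitive,
so `build_cv_pool()` only accumulates streaming per-channel means and
variances (dropping constant channels, e.g. the all-zero first row produced
by the sorted diagonal), and `optimize_rc()` draws its random channel
sequence *up front* and extracts all drawn channels in a single compiled
pass over the frames. This preserves the randomly-chosen-CV semantics at
bounded memory and roughly $N^2\log N$ work per frame, once per
optimization.

## Nonparametric variational optimization

The putative RC is improved iteratively on its time series: at iteration
$m$ a CV series $x_m$ is drawn and the update
$\delta r = \sum_{i+j\le l} a_{ij}\, r_m^i x_m^j$ is applied, with
$\delta r \equiv 0$ on boundary-state frames so the clamps $r(A) = 0$,
$r(B) = 1$ are preserved exactly. The coefficients minimize the total
squared displacement $\mathrm{TSD} = \sum_k [r(k{+}1) - r(k)]^2$ over
within-segment frame pairs — a linear least-squares problem solved by SVD.
The TSD with clamped boundaries is the discrete Dirichlet energy of the
empirical transition network, so its constrained minimizer over all frame
functions is the empirical committor; restricting to the iterated
polynomial span makes each step cheap while the composition over iterations
builds expressiveness.

Numerical choices, all configurable:

* **Lag.** TSD is minimized at lag 1 (the frame spacing `dt0`), the finest
  available resolution; validation then scans larger lags.
* **Polynomial order** `l = 4` (15 basis functions) balances per-iteration
  expressiveness against conditioning.
* **Standardization.** $x_m$ is shifted/scaled to zero mean and unit spread
  before exponentiation — a pure reparametrization of the basis span that
  avoids catastrophic conditioning of raw distances at $l = 4$.
* **Solver.** SVD least squares with relative singular-value cutoff
  `1e-10`; zero-information columns are dropped first. A singular or
  non-improving system falls back to the zero update for that iteration
  (logged), never aborting the run.
* **Clipping.** Updates may transiently leave $[0,1]$; by default values
  are clipped back (the committor range). Because clipping could in
  principle raise the TSD, the update is accepted only if the final TSD is
  no larger than before — so the TSD log is non-increasing by construction.
* **Initialization.** `initial_rc()` is a linear ramp of the reference
  coordinate between the $A$ and $B$ thresholds, clipped to $[0,1]$:
  cheap, monotone, boundary-compliant.
* **Determinism.** All randomness flows through R's RNG; `set.seed()`
  fixes simulations, channel draws, and therefore entire pipelines.

### Boundary states

`define_boundary_states()` reads the two main minima of $F$ over a
reference coordinate and places thresholds where $F$ lies a configurable
`depth` below the barrier top (default: half the smaller barrier height).
Candidate minima must hold at least 2% of the modal bin occupancy, so
sparsely sampled tail bins are never mistaken for basins. The *soft* mode
(`optimize_rc_soft()`) alternates optimization with redefinition of $A$ and
$B$ as terminal intervals of the current $r$ around its own profile minima,
iterating to a fixed point (membership change below 1% of frames, at most 5
rounds). The `committor_of_n()` baseline optimizes with $x_m = n$ at every
iteration (20 iterations); since every update is then a function of $n$,
the result $q(n)$ is a reparametrization of $n$ and inherits its
(sub)optimality — which is exactly what makes it the right comparison
coordinate.

## Profiles, validation, and kinetics

All profile estimators share one grid convention: `nbins` uniform bins
(default 100) covering $[0,1]$ extended to the data range.

**Histogram** $Z_H(r, \Delta t)$: at lag $2^i$ every frame belongs to
exactly one strided phase, so the phase-averaged histogram equals the
all-frames histogram divided by the lag; $\sum Z_H = T/2^i$ exactly — the
$\Delta t^{-1}$ scaling is built in. $F = -\ln Z_H$ up to a constant.

**Cut profile** $Z_{C,1}(r, \Delta t)$ (`zc1()`): each within-segment pair
$(k, k+\Delta t)$ contributes a top-hat of height $|\Delta r|$ over its
interval, bin-averaged by interval accumulation (difference array,
$O(T + \mathrm{bins})$), then divided by the lag. Two exact identities
follow and are asserted at machine precision in the tests: the integral
$\int Z_{C,1}\,dr$ equals the (phase-normalized) TSD at the same lag for
*any* series, and for a perfect two-state committor series the profile is
flat and equal to the transition count $N_{AB}$.

**Diffusion coefficient.** With these conventions the estimator is
$D(r, \Delta t) = Z_{C,1}/(2\,\Delta t\, Z_H)$ with $Z_H$ expressed as a
density (per-bin counts divided by the bin width): for Brownian steps the
expected cut contribution at $r$ is $p(r)\,\langle\delta r^2\rangle =
p(r)\,2D\Delta t$ per pair, and the tests confirm recovery of a known
constant $D_0$ within 5% and consistency with the MFPT integral. Bins with
$Z_H = 0$ are masked, never zero-filled.

**Validation scan.** `validation_scan()` computes $-\ln Z_{C,1}$ over
dyadic lags $2^i\,\Delta t_0$. For the committor the profile is flat in $r$
*and* independent of $\Delta t$, fluctuating around $-\ln N_{AB}$ with
statistical uncertainty $\approx 1/\sqrt{2 N_{AB}}$; the verdict requires
both the interior mean's deviation from $-\ln N_{AB}$ and the interior
spread to stay within `tol_mult` (default 3) times that uncertainty at
every lag. The interior region excludes the outermost 5% of the range,
where the clamped boundary atoms sit. Lags must remain well below the
basin-exchange time: beyond it the cut profile of *any* coordinate decays,
because round trips completed within one lag cancel. The tests therefore
scan up to $2^8$ frames where the mean inter-transition spacing is a few
thousand frames.

**Kinetics.** `mfpt_model()` evaluates the double integral by midpoint
sums on bin centers — chosen over trapezoids because clamped RC series
carry probability atoms at $r = 0$ and $1$ which bin sums handle naturally;
on smooth closed forms the quadrature error is $O(h^2)$, below $10^{-6}$ at
2000 bins. Unsampled interior bins of $p_{\rm eq} D$ are bridged by
log-linear interpolation (logged) instead of producing infinities.
`mfpt_direct()` measures first-entry-to-first-entry events (re-entries into
the source extend the event), a definition under which
$\tau_{A \to B} + \tau_{B \to A}$ matches total time per round trip;
per-event durations are returned for bootstrap errors. $N_{AB}$ comes both
from direct alternation counting and from $\int Z_{C,1}(r,\Delta t_0)dr$;
`mtpt_direct()` measures last-exit-to-first-entry reactive segments.
`rescale_unit_diffusion()` applies $\tilde q(r) = \int_0^r dr'/\sqrt{D}$
with piecewise-constant per-bin $D$, after which the re-estimated $D$ is
$\approx 1$ on the interior and the free-energy profile alone specifies the
model; the separation $\Delta\tilde q$ of the two profile minima is
reported, since with unit diffusion it alone ranks the coordinates'
intrinsic diffusivity.

## Synthetic oracles and what they do (and do not) show

Two generators provide exactly solvable references:

* **Markov chains** (`markov_chain_spec()`): committor by direct linear
  solve of the discrete harmonic system, MFPT by $t = 1 + Pt$. The 5-state
  unbiased walk has committor $i/4$; a 3-state chain with exit rates
  $\alpha, \beta$ has $q = \beta/(\alpha+\beta)$.
* **1D double well** (`double_well_spec()`): overdamped Euler–Maruyama in
  $V(x) = h\,((x/x_0)^2 - 1)^2$ with reflecting walls (preserving
  equilibrium sampling), and the closed-form committor
  $q(x) \propto \int_a^x e^{V}dy$ for constant $D$. Test conditions:
  barrier $3\,k_BT$, wells at $\pm 1$, walls at $\pm 1.6$, $D_0 = 1$,
  $dt = 2\times10^{-3}$ — giving a few hundred barrier crossings per
  $10^6$ steps, enough for validation statistics while keeping every test
  desk-sized. The step resolves the well curvature
  ($D_0 V'' dt \approx 0.05$); residual Euler bias is visible only within
  a step length of the reflecting walls, which the tests exclude.

These oracles certify the estimators and the optimizer under conditions
where truth is computable. They do *not* emulate the hard parts of real
data: high-dimensional degeneracy of CVs, broken permutation symmetry
bookkeeping, rounded finite-size transitions, or slow unsampled modes.
Passing the oracle suite therefore validates the machinery, not any claim
that a particular molecular data set is well sampled.

## Problem sizes used by the tests and the acceptance script

Unit tests run chains and double wells of $10^5$–$5\times10^5$ steps; the
acceptance checks use $10^6$-step oracle trajectories, and a lattice
workflow at $L = 40$, $N = 40$, $\xi = 1$, $10^7$ MC attempts (about
25 000 frames), 120 optimizer iterations. These sizes were chosen so the
statistical tolerances stated in the tests are comfortably resolved while
the whole suite stays desk-sized; the full-scale configuration of the
lattice study ($L = 200$, $N = 400$, six runs of $10^8$ attempts per
anisotropy) is provided as `scripts/full_scale.R` for an overnight CPU job.

## Known limitations

* At $N \sim 40$ the dilute/aggregated transition is strongly rounded; the
  equal-weight $T^*$ carries a seed spread of $\sim 0.01$–$0.02$ and
  $F(n)$ bimodality is marginal, so desk-scale kinetics (a dozen
  transitions per $10^7$ attempts) have large bootstrap errors. The
  *comparisons* — optimized $q$ flatter than $q(n)$ across lags, and its
  diffusive model closing better against direct MFPTs — are nevertheless
  reproducible across seeds.
* The cut-profile validation loses discriminating power at lags comparable
  to the basin dwell time (see above); the scan reports per-lag statistics
  so this regime is visible rather than hidden.
* The optimizer explores the span of iterated polynomials of drawn CVs; a
  committor that depends on CVs never drawn (or on invariants outside
  sorted distances, e.g. orientational order) is reachable only through
  correlated channels. Pool composition is the user's modelling decision.
* `mfpt_model()` integrates the 1D model on the optimization grid; for
  strongly peaked $p_{\rm eq} D$ the bridging of unsampled bins is a
  logged approximation, not a substitute for better sampling.
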
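#' Discrete Markov chain specification with boundary states
#'
#' An exactly solvable oracle for committor and MFPT estimators: the
#' committor of a finite chain is the discrete harmonic function
#' \eqn{q = Pq} with \eqn{q(A) = 0}, \eqn{q(B) = 1}, obtainable by a direct
#' linear solve.
#'
#' @param P row-stochastic transition matrix.
#' @param A,B disjoint nonempty integer state subsets (1-based).
#' @return An object of class `markov_chain_spec`.
#' @export
markov_chain_spec <- function(P, A, B) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            max(abs(rowSums(P) - 1)) < 1e-12,
            length(A) > 0, length(B) > 0, !any(A %in% B),
            all(c(A, B) %in% seq_len(nrow(P))))
  structure(list(P = P, A = as.integer(A), B = as.integer(B)),
            class = "markov_chain_spec")
}

#' Exact committor of a Markov chain
#'
#' Solves \eqn{q_i = \sum_j P_{ij} q_j} on states outside `A` and `B` with
#' \eqn{q(A) = 0}, \eqn{q(B) = 1} by a direct linear solve.
#'
#' @param spec a [markov_chain_spec()].
#' @return Numeric committor per state.
#' @export
markov_committor <- function(spec) {
  S <- nrow(spec$P)
  q <- numeric(S)
  q[spec$B] <- 1
  free <- setdiff(seq_len(S), c(spec$A, spec$B))
  if (length(free)) {
    M <- diag(length(free)) - spec$P[free, free, drop = FALSE]
    b <- spec$P[free, spec$B, drop = FALSE] %*% rep(1, length(spec$B))
    sol <- tryCatch(solve(M, b),
                    error = function(e)
                      stop("singular committor system: absorbing states outside A and B?"))
    q[free] <- sol
  }
  q
}

#' Exact mean first passage time to a target set of a Markov chain
#'
#' Solves \eqn{t = 1 + Pt} outside the target set (hitting times in steps).
#'
#' @param P row-stochastic transition matrix.
#' @param target integer target states.
#' @return Numeric expected hitting time per state (0 on the target).
#' @export
markov_mfpt <- function(P, target) {
  S <- nrow(P)
  t <- numeric(S)
  free <- setdiff(seq_len(S), target)
  M <- diag(length(free)) - P[free, free, drop = FALSE]
  t[free] <- solve(M, rep(1, length(free)))
  t
}

#' Simulate a trajectory of a Markov chain
#'
#' Seeded through R's RNG (`set.seed()` fixes the series).
#'
#' @param spec a [markov_chain_spec()] (or a bare transition matrix).
#' @param n_frames trajectory length.
#' @param s0 initial state (1-based).
#' @return Integer state series.
#' @export
simulate_chain <- function(spec, n_frames, s0 = 1L) {
  P <- if (inherits(spec, "markov_chain_spec")) spec$P else spec
  simulate_chain_cpp(P, n_frames, as.integer(s0))
}

#' Quartic double-well Brownian dynamics specification
#'
#' Overdamped dynamics \eqn{dx = -D_0 V'(x)\,dt + \sqrt{2 D_0 dt}\,\xi}
#' (with \eqn{k_B T = 1}) in the potential
#' \eqn{V(x) = \mathrm{barrier}\,((x/x_0)^2 - 1)^2}, whose wells sit at
#' \eqn{\pm x_0} and whose barrier top at `x = 0` has height `barrier` in
#' \eqn{k_B T}. Walls at `a` and `b` are reflecting, which preserves
#' equilibrium sampling.
#'
#' @param barrier barrier height in \eqn{k_B T}.
#' @param x0 well position.
#' @param a,b reflecting wall positions (`a < -x0 < x0 < b`).
#' @param D0 diffusion constant.
#' @param dt integration time step (must resolve the well curvature,
#'   \eqn{D_0 V'' dt \ll 1}).
#' @return An object of class `double_well_spec`.
#' @export
double_well_spec <- function(barrier = 3, x0 = 1, a = -1.6, b = 1.6,
                             D0 = 1, dt = 2e-3) {
  stopifnot(barrier >= 0, a < b, a < -x0 || barrier == 0, D0 > 0, dt > 0)
  structure(list(barrier = barrier, x0 = x0, a = a, b = b, D0 = D0, dt = dt),
            class = "double_well_spec")
}

#' Potential energy of the double-well spec
#' @param spec a [double_well_spec()].
#' @param x positions.
#' @return \eqn{V(x)} in \eqn{k_B T}.
#' @export
double_well_potential <- function(spec, x) {
  spec$barrier * ((x / spec$x0)^2 - 1)^2
}

#' Closed-form committor of 1D diffusion in a potential
#'
#' For constant-`D` overdamped dynamics between boundaries `xa < xb`,
#' \deqn{q(x) = \frac{\int_{x_a}^{x} e^{V(y)}\,dy}
#'                   {\int_{x_a}^{x_b} e^{V(y)}\,dy}}
#' (clamped to 0 below `xa` and 1 above `xb`), evaluated by trapezoidal
#' quadrature on a fine grid.
#'
#' @param spec a [double_well_spec()].
#' @param xa,xb boundary-state edges (defaults: the wells).
#' @param n_grid quadrature grid size.
#' @return List: grid `x`, committor `q`, and the interpolating function
#'   `fun` (vectorized, clamped outside `[xa, xb]`).
#' @export
analytic_committor_1d <- function(spec, xa = -spec$x0, xb = spec$x0,
                                  n_grid = 20001) {
  stopifnot(xa < xb)
  x <- seq(xa, xb, length.out = n_grid)
  w <- exp(double_well_potential(spec, x) -
           max(double_well_potential(spec, x)))
  h <- x[2] - x[1]
  cumw <- c(0, cumsum((w[-1] + w[-n_grid]) / 2 * h))
  q <- cumw / cumw[n_grid]
  f <- stats::approxfun(x, q, rule = 2)
  list(x = x, q = q, fun = function(z) pmin(pmax(f(z), 0), 1))
}

#' Simulate the double-well Brownian dynamics
#'
#' Euler-Maruyama with reflecting walls; seeded through R's RNG.
#'
#' @param spec a [double_well_spec()].
#' @param n_steps number of integration steps.
#' @param x_init initial position (default: the lower well).
#' @param save_every save every k-th step (frame spacing
#'   `dt0 = save_every * dt`).
#' @return Numeric position series (first element is the initial state).
#' @export
simulate_double_well <- function(spec, n_steps, x_init = -spec$x0,
                                 save_every = 1L) {
  simulate_double_well_cpp(spec$barrier, spec$x0, spec$a, spec$b,
                           spec$D0, spec$dt, n_steps, x_init,
                           as.integer(save_every))
}

#' Project a position series on a committor-like coordinate
#'
#' Builds an [rc_series()] \eqn{r(k) = g(x(k))} with boundary masks
#' `A = {x <= xa}`, `B = {x >= xb}` and clamped values. With
#' `g = analytic_committor_1d(...)$fun` this is the exact-committor
#' projection used as the positive control of the validation scan; any
#' other monotone `g` (e.g. `function(x) g0(x)^2`) yields a distorted
#' negative control.
#'
#' @param x numeric position series (or [cv_series()]).
#' @param g coordinate function mapping positions into `[0, 1]`.
#' @param xa,xb boundary-state edges.
#' @return An [rc_series()].
#' @export
committor_projection <- function(x, g, xa, xb) {
  v <- .series_values(x)
  rc_series(pmin(pmax(g(v), 0), 1), in_A = v <= xa, in_B = v >= xb,
            segment_ids = .series_segments(x, length(v)))
}
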
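# Shared fixtures, built in code and memoized so expensive simulations are
# reused across test files within one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# symmetric 5-state random walk, A = {1}, B = {5}; committor is (i-1)/4
walk5_spec <- function() {
  P <- matrix(0, 5, 5)
  for (i in 2:4) { P[i, i - 1] <- 0.5; P[i, i + 1] <- 0.5 }
  P[1, 2] <- 1; P[5, 4] <- 1
  markov_chain_spec(P, A = 1, B = 5)
}

walk5_traj <- function(n = 2e5, seed = 101) {
  memo(sprintf("walk5_%g_%d", n, seed), {
    set.seed(seed)
    simulate_chain(walk5_spec(), n)
  })
}

# reference double well used in the oracle-recovery tests
dw_spec <- function() double_well_spec(barrier = 3, x0 = 1, a = -1.6,
                                       b = 1.6, D0 = 1, dt = 2e-3)

dw_traj <- function(n = 5e5, seed = 77) {
  memo(sprintf("dw_%g_%d", n, seed), {
    set.seed(seed)
    simulate_double_well(dw_spec(), n)
  })
}

dw_committor <- function() memo("dw_q", analytic_committor_1d(dw_spec()))

# brute-force cut profile: direct per-bin interval accumulation, O(T * bins)
zc1_bruteforce <- function(r, lag, edges) {
  nb <- length(edges) - 1
  h <- (edges[nb + 1] - edges[1]) / nb
  out <- numeric(nb)
  for (k in seq_len(length(r) - lag)) {
    lo <- min(r[k], r[k + lag]); hi <- max(r[k], r[k + lag])
    if (hi == lo) next
    for (b in seq_len(nb)) {
      ov <- min(hi, edges[b + 1]) - max(lo, edges[b])
      if (ov > 0) out[b] <- out[b] + (hi - lo) * ov / h
    }
  }
  out / lag
}

# tiny lattice trajectory reused by CV/pipeline tests
tiny_lattice <- function() {
  memo("tiny_lattice", {
    cfg <- lattice_config(L = 12, N = 6, T = 0.6, xi = 2, dt0 = 50,
                          n_steps = 5e4, seed = 99)
    run_lattice(cfg, equil_frac = 0)
  })
}
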
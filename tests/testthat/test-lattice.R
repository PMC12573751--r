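test_that("pair energies follow the anisotropic bond model", {
  cfg <- lattice_config(L = 10, N = 2, T = 1, xi = 3, psi_w = 1)
  expect_equal(pair_energy(0L, 0L, cfg), -3)
  expect_equal(pair_energy(1L, 1L, cfg), -3)
  expect_equal(pair_energy(0L, 1L, cfg), -1)
  iso <- lattice_config(L = 10, N = 2, T = 1, xi = 1)
  expect_equal(pair_energy(0L, 0L, iso), -1)
  expect_equal(pair_energy(0L, 1L, iso), -1)
})

test_that("total energy counts each occupied neighbour pair once, with wrap", {
  cfg <- lattice_config(L = 10, N = 2, T = 1, xi = 2, psi_w = 1)
  aligned <- lattice_state(c(0, 0), c(0, 1), c(1, 1), 10)
  expect_equal(total_energy(aligned, cfg), -2)
  wrapped <- lattice_state(c(0, 9), c(0, 0), c(0, 1), 10)
  expect_equal(total_energy(wrapped, cfg), -1)  # periodic adjacency, nonaligned
  isolated <- lattice_state(c(0, 5), c(0, 5), c(1, 0), 10)
  expect_equal(total_energy(isolated, cfg), 0)
})

test_that("excluded volume: moves onto occupied sites are rejected unchanged", {
  cfg <- lattice_config(L = 3, N = 9, T = 1, xi = 1, move_mix = 1)
  full <- lattice_state(rep(0:2, 3), rep(0:2, each = 3),
                        rep(0L, 9), 3)
  set.seed(1)
  for (k in 1:20) {
    out <- mc_attempt(full, cfg)
    expect_false(out$accepted)
    expect_identical(out$state$x, full$x)
    expect_identical(out$state$y, full$y)
  }
})

test_that("downhill and isoenergetic proposals are always accepted", {
  cfg <- lattice_config(L = 10, N = 2, T = 0.5, xi = 2, move_mix = 0)
  st <- lattice_state(c(0, 0), c(0, 1), c(0, 1), 10)  # nonaligned pair
  set.seed(2)
  out <- mc_attempt(st, cfg)  # flip either molecule: dE = -1, downhill
  expect_true(out$accepted)
  expect_lte(out$dE, 0)
})

test_that("incremental proposal energies match total-energy differences", {
  cfg <- lattice_config(L = 8, N = 6, T = 0.8, xi = 3, move_mix = 0.5)
  set.seed(42)
  st <- random_lattice_state(cfg)
  for (k in seq_len(2000)) {
    e0 <- total_energy(st, cfg)
    out <- mc_attempt(st, cfg)
    if (out$accepted) {
      e1 <- total_energy(out$state, cfg)
      expect_lt(abs((e1 - e0) - out$dE), 1e-9)
    }
    st <- out$state
  }
})

test_that("runs are deterministic given a seed and conserve molecules", {
  cfg <- lattice_config(L = 15, N = 8, T = 0.6, xi = 2, dt0 = 400,
                        n_steps = 4000, seed = 7)
  t1 <- run_lattice(cfg)
  t2 <- run_lattice(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$o, t2$o)
  # 4000/400 frames plus the recorded initial state
  expect_equal(nrow(t1$x), 11)
  for (k in seq_len(nrow(t1$x)))
    expect_equal(length(unique(t1$x[k, ] + cfg$L * t1$y[k, ])), cfg$N)
})

test_that("kernel sampling matches the Boltzmann distribution (exact enumeration)", {
  # L=3 with 2 molecules: 36 position pairs x 4 orientation pairs = 144 states
  cfg <- lattice_config(L = 3, N = 2, T = 0.9, xi = 2, dt0 = 5,
                        n_steps = 6e5, seed = 31, move_mix = 0.5)
  tr <- run_lattice(cfg, equil_frac = 0)
  state_id <- function(x1, y1, x2, y2, o1, o2) {
    s1 <- x1 + 3 * y1; s2 <- x2 + 3 * y2
    lo <- pmin(s1, s2); hi <- pmax(s1, s2)
    olo <- ifelse(s1 < s2, o1, o2); ohi <- ifelse(s1 < s2, o2, o1)
    paste(lo, hi, olo, ohi)
  }
  seen <- state_id(tr$x[, 1], tr$y[, 1], tr$x[, 2], tr$y[, 2],
                   tr$o[, 1], tr$o[, 2])
  # enumerate all distinct states and Boltzmann weights
  grid <- expand.grid(s1 = 0:8, s2 = 0:8, o1 = 0:1, o2 = 0:1)
  grid <- grid[grid$s1 < grid$s2, ]
  w <- mapply(function(s1, s2, o1, o2) {
    st <- lattice_state(c(s1 %% 3, s2 %% 3), c(s1 %/% 3, s2 %/% 3),
                        c(o1, o2), 3)
    exp(-total_energy(st, cfg) / cfg$T)
  }, grid$s1, grid$s2, grid$o1, grid$o2)
  ids <- state_id(grid$s1 %% 3, grid$s1 %/% 3, grid$s2 %% 3, grid$s2 %/% 3,
                  grid$o1, grid$o2)
  p_exact <- w / sum(w)
  names(p_exact) <- ids
  freq <- table(seen) / length(seen)
  # compare the aggregate probability of bonded vs unbonded classes and a
  # sample of individual states, within 3 batch-means standard errors
  nb <- 40
  batches <- split(seen, cut(seq_along(seen), nb))
  for (id in names(p_exact)[c(1, 20, 60, 100, 140)]) {
    p_hat <- mean(seen == id)
    bm <- vapply(batches, function(b) mean(b == id), numeric(1))
    se <- stats::sd(bm) / sqrt(nb)
    expect_lt(abs(p_hat - p_exact[[id]]), max(3 * se, 0.004))
  }
  # full-distribution sanity: total variation distance is small
  p_hat_all <- as.numeric(freq[names(p_exact)])
  p_hat_all[is.na(p_hat_all)] <- 0
  expect_lt(0.5 * sum(abs(p_hat_all - p_exact)), 0.05)
})

test_that("largest aggregate size uses periodic 4-neighbour components", {
  st <- lattice_state(c(0, 0, 5), c(0, 1, 5), c(0, 0, 0), 10)
  expect_equal(largest_cluster_size(st), 2)
  wrapped <- lattice_state(c(0, 9), c(0, 0), c(0, 0), 10)
  expect_equal(largest_cluster_size(wrapped), 2)
  iso <- lattice_state(c(0, 2, 4), c(0, 2, 4), c(0, 0, 0), 10)
  expect_equal(largest_cluster_size(iso), 1)
  tr <- tiny_lattice()
  n <- largest_cluster_size(tr)
  expect_s3_class(n, "cv_series")
  expect_true(all(n$values >= 1 & n$values <= 6))
})

test_that("at xi = 1 orientation flips are free and always accepted", {
  cfg <- lattice_config(L = 12, N = 6, T = 0.5, xi = 1, dt0 = 100,
                        n_steps = 2e4, seed = 3, move_mix = 0.5)
  tr <- run_lattice(cfg, equil_frac = 0)
  expect_equal(tr$flip_acceptance, 1)
})

test_that("coexistence calibration reports failure away from the transition", {
  cfg <- lattice_config(L = 20, N = 8, T = 1, xi = 1, dt0 = 200,
                        n_steps = 1e5)
  set.seed(8)
  expect_error(
    calibrate_coexistence_temperature(cfg, c(2.0, 2.5), run_length = 1e5),
    "dilute")
  set.seed(8)
  expect_error(
    calibrate_coexistence_temperature(cfg, c(0.05, 0.08), run_length = 1e5),
    "aggregated")
})

test_that("equal-weight temperature is reproducible across calibration seeds", {
  cfg <- lattice_config(L = 30, N = 16, T = 0.4, xi = 1, dt0 = 400,
                        n_steps = 1e6)
  grid <- seq(0.26, 0.42, by = 0.04)
  set.seed(21)
  c1 <- calibrate_coexistence_temperature(cfg, grid, run_length = 3e6,
                                          n_bisect = 4)
  set.seed(22)
  c2 <- calibrate_coexistence_temperature(cfg, grid, run_length = 3e6,
                                          n_bisect = 4)
  expect_lt(abs(c1$T_star - c2$T_star), 0.03)
  expect_gt(c1$w_star, 0.15)
  expect_lt(c1$w_star, 0.85)
})
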
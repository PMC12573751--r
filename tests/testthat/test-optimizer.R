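test_that("TSD sums squared within-segment displacements", {
  expect_equal(tsd(c(0, 0.5, 1)), 0.5)
  expect_equal(tsd(rep(0.3, 50)), 0)
  # cross-segment pairs are excluded
  expect_equal(tsd(c(0, 1, 0, 1), segment_ids = c(1, 1, 2, 2)), 2)
  expect_error(tsd(numeric(0)), "empty")
})

test_that("variation basis has (l+1)(l+2)/2 standardized monomials", {
  r <- runif(20); x <- rnorm(20)
  expect_equal(ncol(variation_basis(r, x, 1)), 3)
  expect_equal(ncol(variation_basis(r, x, 4)), 15)
  B <- variation_basis(r, x, 2)
  xs <- (x - mean(x)) / sd(x)
  pow <- attr(B, "powers")
  k <- which(pow$i == 1 & pow$j == 1)
  expect_equal(B[, k], r * xs)
  expect_error(variation_basis(r, c(x[-1], NA), 2), "non-finite")
})

test_that("the committor is a fixed point of the update (x in span of r)", {
  s <- walk5_traj(1e5)
  q_exact <- (s - 1) / 4
  rc <- rc_series(q_exact, s == 1, s == 5)
  t0 <- tsd(rc)
  up <- solve_update(rc, variation_basis(rc, cv_series(q_exact), 4))
  # only the sampling noise of the finite trajectory can be removed
  expect_lte(up$tsd, t0)
  expect_gt(up$tsd / t0, 1 - 1e-3)
  expect_lt(max(abs(tapply(up$rc$r, s, mean) - c(0, .25, .5, .75, 1))), 0.01)
})

test_that("fully clamped series yields an identically zero update", {
  r <- rep(c(0, 1), 25)
  rc <- rc_series(r, r == 0, r == 1)
  up <- solve_update(rc, variation_basis(rc, cv_series(rnorm(50)), 3))
  expect_identical(up$rc$r, rc$r)
  expect_equal(tsd(up$rc), tsd(rc))
})

test_that("a constant CV degrades gracefully via the regularized solve", {
  s <- walk5_traj(1e4)
  bnd <- define_boundary_states(s, a_max = 1, b_min = 5)
  rc <- initial_rc(cv_series(as.numeric(s)), bnd)
  up <- solve_update(rc, variation_basis(rc, rep(1, length(s)), 3))
  expect_lte(up$tsd, tsd(rc) * (1 + 1e-10))
})

test_that("optimizer recovers the harmonic committor of the 5-state walk", {
  s <- walk5_traj(2e5)
  bnd <- define_boundary_states(s, a_max = 1, b_min = 5)
  r0 <- initial_rc(cv_series(as.numeric(s)), bnd)
  pool <- cv_pool_matrix(matrix(as.numeric(s), ncol = 1), "state")
  set.seed(1)
  opt <- optimize_rc(r0, pool, l = 4, m_max = 8)
  qhat <- tapply(opt$rc$r, s, mean)
  expect_lt(max(abs(qhat - c(0, 0.25, 0.5, 0.75, 1))), 1e-2)
  # TSD log is non-increasing
  expect_true(all(diff(opt$log$tsd) <= 1e-10 * opt$log$tsd[-nrow(opt$log)]))
})

test_that("three-state chain converges to the first-step committor beta/(alpha+beta)", {
  P <- matrix(c(0.3, 0.7, 0,
                0.2, 0.7, 0.1,
                0,   0.5, 0.5), 3, 3, byrow = TRUE)
  spec <- markov_chain_spec(P, A = 1, B = 3)
  expect_equal(markov_committor(spec)[2], 1 / 3)
  set.seed(14)
  s <- simulate_chain(spec, 2e5)
  bnd <- define_boundary_states(s, a_max = 1, b_min = 3)
  r0 <- initial_rc(cv_series(as.numeric(s)), bnd)
  pool <- cv_pool_matrix(matrix(as.numeric(s), ncol = 1), "state")
  opt <- optimize_rc(r0, pool, l = 2, m_max = 6)
  expect_lt(abs(mean(opt$rc$r[s == 2]) - 1 / 3), 0.02)
})

test_that("boundary frames stay exactly clamped through optimization", {
  s <- walk5_traj(5e4)
  bnd <- define_boundary_states(s, a_max = 1, b_min = 5)
  r0 <- initial_rc(cv_series(as.numeric(s)), bnd)
  pool <- cv_pool_matrix(cbind(as.numeric(s), sin(s)), c("s", "sin"))
  set.seed(2)
  rc <- r0
  for (m in 1:5) {
    x <- sample_cv(pool, rc$segment_ids)
    rc <- solve_update(rc, variation_basis(rc, x, 3))$rc
    expect_identical(rc$r[rc$in_A], rep(0, sum(rc$in_A)))
    expect_identical(rc$r[rc$in_B], rep(1, sum(rc$in_B)))
    expect_true(all(rc$r >= 0 & rc$r <= 1))
  }
})

test_that("TSD decreases weakly on random data and pools (property)", {
  set.seed(33)
  for (rep in 1:5) {
    T <- 2000
    v <- cumsum(rnorm(T)); v <- (v - min(v)) / diff(range(v))
    rc <- rc_series(v, v <= 0.1, v >= 0.9)
    pool <- cv_pool_matrix(matrix(rnorm(T * 4), T, 4))
    opt <- optimize_rc(rc, pool, l = 3, m_max = 6)
    expect_true(all(diff(c(tsd(rc), opt$log$tsd)) <=
                      1e-10 * c(tsd(rc), opt$log$tsd[-nrow(opt$log)]) + 1e-12))
  }
})

test_that("m_max = 0 returns the input unchanged", {
  s <- walk5_traj(1e4)
  bnd <- define_boundary_states(s, a_max = 1, b_min = 5)
  r0 <- initial_rc(cv_series(as.numeric(s)), bnd)
  opt <- optimize_rc(r0, cv_pool_matrix(matrix(rnorm(1e4), ncol = 1)),
                     m_max = 0)
  expect_identical(opt$rc$r, r0$r)
  expect_equal(nrow(opt$log), 0)
})

test_that("q(n) is a function of n with exact boundary values", {
  s <- walk5_traj(1e5)
  n <- cv_series(as.numeric(s), channel = "n")
  bnd <- define_boundary_states(n, a_max = 1, b_min = 5)
  opt <- committor_of_n(n, bnd, m_max = 10)
  q <- opt$rc$r
  for (st in 1:5)
    expect_lt(diff(range(q[s == st])), 1e-12)  # equal n -> equal q(n)
  expect_equal(unique(q[s == 1]), 0)
  expect_equal(unique(q[s == 5]), 1)
  expect_lt(max(abs(tapply(q, s, mean) - c(0, .25, .5, .75, 1))), 1e-2)
})

test_that("an increasing reparametrization of r0 converges to the same committor", {
  s <- walk5_traj(1e5)
  bnd <- define_boundary_states(s, a_max = 1, b_min = 5)
  r0 <- initial_rc(cv_series(as.numeric(s)), bnd)
  warped <- rc_series(r0$r^3, r0$in_A, r0$in_B)
  pool <- cv_pool_matrix(matrix(as.numeric(s), ncol = 1), "state")
  set.seed(3); opt1 <- optimize_rc(r0, pool, l = 4, m_max = 10)
  set.seed(3); opt2 <- optimize_rc(warped, pool, l = 4, m_max = 10)
  q1 <- tapply(opt1$rc$r, s, mean)
  q2 <- tapply(opt2$rc$r, s, mean)
  expect_lt(max(abs(q1 - q2)), 5e-3)
})

test_that("boundary states come from the two free-energy minima of F", {
  # symmetric bimodal coordinate: mixture of two well-separated Gaussians
  set.seed(11)
  v <- c(rnorm(2e4, -2, 0.45), rnorm(2e4, 2, 0.45))
  bnd <- define_boundary_states(v, nbins = 80)
  expect_true(bnd$bimodal)
  expect_lt(abs(bnd$a_max + bnd$b_min), 0.4)  # symmetric about the barrier
  expect_lt(bnd$a_max, 0); expect_gt(bnd$b_min, 0)
  # explicit thresholds pass through untouched
  ex <- define_boundary_states(v, a_max = -1.5, b_min = 1.2)
  expect_equal(ex$a_max, -1.5); expect_equal(ex$b_min, 1.2)
  # unimodal profile: informative error, or quantile fallback on request
  u <- rnorm(2e4)
  expect_error(define_boundary_states(u), "unimodal|barrier")
  expect_warning(fb <- define_boundary_states(u, fallback_quantiles = c(.1, .9)),
                 "falling back")
  expect_false(fb$bimodal)
  expect_equal(mean(u <= fb$a_max), 0.1, tolerance = 0.02)
})

test_that("soft boundary refinement reaches a fixed point on oracle data", {
  x <- dw_traj(2e5)
  bnd <- define_boundary_states(cv_series(x), a_max = -1, b_min = 1)
  r0 <- initial_rc(cv_series(x), bnd)
  pool <- cv_pool_matrix(cbind(x, x^3), c("x", "x3"))
  set.seed(4)
  soft <- optimize_rc_soft(r0, pool, rounds = 4, m_max = 15)
  expect_lte(soft$rounds_used, 4)
  # boundary states grow to cover the free-energy basins of r
  expect_gte(sum(soft$rc$in_A), sum(r0$in_A))
  # the refined coordinate tracks the analytic committor and passes its
  # own cut-profile validation (its boundary states differ from x = +/-1,
  # so only monotone agreement is expected pointwise)
  q <- dw_committor()$fun(x)
  expect_gt(cor(soft$rc$r, q), 0.99)
  expect_true(validation_scan(soft$rc, i_max = 6)$pass)
})
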
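make_model <- function(p_fun, D_fun, nbins = 2000) {
  edges <- seq(0, 1, length.out = nbins + 1)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  diffusive_model(p_fun(mids), D_fun(mids), edges)
}

test_that("MFPT double integral reproduces closed forms", {
  # uniform p, D = 1: tau = int (1 - q) dq = 1/2
  m1 <- make_model(function(q) rep(1, length(q)), function(q) rep(1, length(q)))
  expect_lt(abs(mfpt_model(m1) - 0.5), 1e-6)
  # D = 2 halves it
  m2 <- make_model(function(q) rep(1, length(q)), function(q) rep(2, length(q)))
  expect_lt(abs(mfpt_model(m2) - 0.25), 1e-6)
  # p = 2(1 - q), D = 1: tau = int (1-q)/2 dq = 1/4
  m3 <- make_model(function(q) 2 * (1 - q), function(q) rep(1, length(q)))
  expect_lt(abs(mfpt_model(m3) - 0.25), 1e-6)
  # reverse direction on the uniform model is symmetric
  expect_lt(abs(mfpt_model(m1, from = 0, to = 1) - 0.5), 1e-6)
})

test_that("direct MFPT counts first-entry-to-first-entry events", {
  r <- c(1, 0.5, 0)
  rc <- rc_series(r, r <= 0, r >= 1)
  out <- mfpt_direct(rc, from = "B", to = "A")
  expect_equal(out$tau, 2)
  expect_equal(out$n_events, 1)
  # a series that never leaves B has no events
  rb <- rc_series(c(1, 1, 1, 0), c(FALSE, FALSE, FALSE, TRUE),
                  c(TRUE, TRUE, TRUE, FALSE))
  expect_warning(out2 <- mfpt_direct(rb, from = "A", to = "B"), "no completed")
  expect_equal(out2$n_events, 0)
  # dt0 scales the times
  expect_equal(mfpt_direct(rc, dt0 = 400)$tau, 800)
})

test_that("direct MFPT agrees with the Markov-chain linear solve", {
  spec <- walk5_spec()
  s <- walk5_traj(2e5)
  rc <- rc_series((s - 1) / 4, s == 1, s == 5)
  out <- mfpt_direct(rc, from = "B", to = "A")
  exact <- markov_mfpt(spec$P, target = 1)[5]
  boot <- replicate(200, mean(sample(out$times, replace = TRUE)))
  expect_lt(abs(out$tau - exact), 3 * sd(boot))
})

test_that("transition counting follows alternating boundary visits", {
  v <- c(0, 0.5, 1, 0.4, 0, 0.6, 1, 0.5, 0)  # A,B,A,B,A pattern
  rc <- rc_series(v, v <= 0, v >= 1)
  expect_equal(nab_direct(rc), 4)
  # a segment confined to A contributes no transitions (B only appears in
  # the other segment)
  confined <- rc_series(c(0, 0.01, 0, 1), c(TRUE, FALSE, TRUE, FALSE),
                        c(FALSE, FALSE, FALSE, TRUE),
                        segment_ids = c(1, 1, 1, 2))
  expect_equal(nab_direct(confined), 0)
  # parity: |count(A->B) - count(B->A)| bounded by the number of segments
  set.seed(12)
  for (rep in 1:20) {
    v <- runif(300)
    seg <- sort(sample(1:3, 300, replace = TRUE))
    rc <- rc_series(v * 0.998 + 0.001, v < 0.1, v > 0.9, seg)
    ab <- mfpt_direct(rc, "A", "B")$n_events
    ba <- suppressWarnings(mfpt_direct(rc, "B", "A")$n_events)
    expect_lte(abs(ab - ba), length(unique(seg)))
    expect_equal(ab + ba, nab_direct(rc))
  }
})

test_that("cut-profile integral estimates N_AB and equals the TSD", {
  h <- 1 / 100
  expect_equal(nab_integral(rep(7, 100), h), 7)
  set.seed(13)
  r <- runif(500)
  expect_equal(nab_integral(zc1(r, 1, seq(0, 1, length.out = 101)), h),
               tsd(r), tolerance = 1e-12)
  # perfect telegraph: integral equals the direct count exactly
  set.seed(14)
  flips <- cumsum(runif(5000) < 0.05) %% 2
  rc <- rc_series(flips, flips == 0, flips == 1)
  expect_equal(nab_integral(zc1(rc, 1, seq(0, 1, length.out = 101)), h),
               nab_direct(rc))
})

test_that("equilibrium flux is flat for the committor, not for a distortion", {
  m <- make_model(function(q) rep(1, length(q)), function(q) rep(1, length(q)),
                  nbins = 50)
  expect_equal(diff(range(flux_profile(m))), 0)
  x <- dw_traj(5e5)
  q <- dw_committor()$fun
  cv_of <- function(rc) {
    ps <- rc_profiles(rc, lag = 1, nbins = 50)
    J <- flux_profile(as_diffusive_model(ps))
    keep <- ps$mids > 0.1 & ps$mids < 0.9 & !is.na(J)
    sd(J[keep]) / mean(J[keep])
  }
  cv_good <- cv_of(committor_projection(x, q, -1, 1))
  cv_bad <- cv_of(committor_projection(x, function(z) q(z)^2, -1, 1))
  expect_lt(cv_good, 0.25)
  expect_gt(cv_bad, cv_good)
})

test_that("mean transition-path time spans last exit to first entry", {
  v <- c(0, 0.5, 1)
  rc <- rc_series(v, v <= 0, v >= 1)
  expect_equal(mtpt_direct(rc)$tau_hat, 2)
  flips <- rep(c(0, 1), 10)
  rcf <- rc_series(flips, flips == 0, flips == 1)
  expect_equal(mtpt_direct(rcf)$tau_hat, 1)  # instantaneous jumps
  # brute-force re-enumeration on a 5-state walk trajectory
  s <- walk5_traj(5e4)
  rc5 <- rc_series((s - 1) / 4, s == 1, s == 5)
  got <- mtpt_direct(rc5)
  lab <- ifelse(s == 1, 1L, ifelse(s == 5, 2L, 0L))
  durations <- c(); last_bnd <- NA; last_t <- NA
  for (t in seq_along(lab)) {
    if (lab[t] == 0L) next
    if (!is.na(last_bnd) && lab[t] != last_bnd)
      durations <- c(durations, t - last_t)
    last_bnd <- lab[t]; last_t <- t
  }
  expect_equal(got$n_events, length(durations))
  expect_equal(got$tau_hat, mean(durations))
})

test_that("model and direct MFPT close on double-well oracle data", {
  x <- dw_traj(5e5)
  rc <- committor_projection(x, dw_committor()$fun, -1, 1)
  kin <- coordinate_kinetics(rc, "q")
  expect_lt(abs(kin$tau_model - kin$tau_direct) / kin$tau_direct, 0.10)
  expect_lt(abs(kin$nab_integral - kin$nab_direct) / kin$nab_direct, 0.10)
})
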
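#' Putative reaction-coordinate time series with clamped boundary states
#'
#' An RC series \eqn{r(k)} in \eqn{[0, 1]} with boolean membership masks for the two
#' boundary states: frames in `A` carry \eqn{r = 0} exactly and frames in `B`
#' carry \eqn{r = 1} exactly. The committor is the optimal coordinate of this
#' form.
#'
#' @param r numeric values in `[0, 1]`.
#' @param in_A,in_B disjoint logical masks, same length as `r`.
#' @param segment_ids integer run label per frame (default one segment).
#' @return An object of class `rc_series`.
#' @export
rc_series <- function(r, in_A, in_B, segment_ids = NULL) {
  if (is.null(segment_ids)) segment_ids <- rep(1L, length(r))
  stopifnot(length(r) == length(in_A), length(r) == length(in_B),
            length(r) == length(segment_ids),
            !any(in_A & in_B), any(in_A), any(in_B))
  r[in_A] <- 0; r[in_B] <- 1
  if (any(r < 0) || any(r > 1))
    stop("r must lie in [0, 1]")
  structure(list(r = as.numeric(r), in_A = in_A, in_B = in_B,
                 segment_ids = as.integer(segment_ids)),
            class = "rc_series")
}

#' @export
print.rc_series <- function(x, ...) {
  cat(sprintf(
    "rc_series: %d frames (%d in A, %d in B), %d segment(s), TSD(1)=%.4g\n",
    length(x$r), sum(x$in_A), sum(x$in_B),
    length(unique(x$segment_ids)), tsd(x)))
  invisible(x)
}

.series_values <- function(x) {
  if (inherits(x, "rc_series")) x$r
  else if (inherits(x, "cv_series")) x$values
  else as.numeric(x)
}

.series_segments <- function(x, n) {
  if (inherits(x, c("rc_series", "cv_series"))) x$segment_ids
  else rep(1L, n)
}

#' Total squared displacement of an RC series
#'
#' At lag 1 this is \eqn{\sum_k [r(k+1) - r(k)]^2} over within-segment frame
#' pairs -- the functional whose constrained minimum (with the boundary
#' states clamped at 0 and 1) is attained by the committor. At lag `L > 1`
#' the all-pairs sum is divided by `L` (the phase-averaged convention), so
#' that \eqn{\int Z_{C,1}(r, \Delta t)\,dr = \mathrm{TSD}(\Delta t)} holds
#' exactly at every lag (see [zc1()]).
#'
#' @param r an [rc_series()], [cv_series()] or numeric vector.
#' @param lag pair separation in frames.
#' @param segment_ids optional segments when `r` is a bare vector.
#' @return Scalar TSD.
#' @export
tsd <- function(r, lag = 1L, segment_ids = NULL) {
  v <- .series_values(r)
  if (length(v) == 0) stop("empty series")
  seg <- if (!is.null(segment_ids)) segment_ids
         else .series_segments(r, length(v))
  if (length(v) <= lag) return(0)
  k <- seq_len(length(v) - lag)
  ok <- seg[k] == seg[k + lag]
  sum((v[k + lag][ok] - v[k][ok])^2) / lag
}

#' Polynomial variation basis
#'
#' Evaluates the `(l+1)(l+2)/2` monomials \eqn{f_{ij} = r^i x^j}, for
#' \eqn{i + j \le l}, per frame. The CV `x` is standardized (zero mean, unit
#' spread) before exponentiation; this is a pure reparametrization of the
#' basis span that keeps the least-squares problem well conditioned at
#' moderate `l`.
#'
#' @param r an [rc_series()] (or numeric vector of current RC values).
#' @param x a [cv_series()] (or numeric vector), aligned with `r`.
#' @param l polynomial order (`l >= 1`).
#' @return Numeric matrix, frames x n_basis; attribute `"powers"` holds the
#'   `(i, j)` exponent pairs.
#' @export
variation_basis <- function(r, x, l) {
  stopifnot(l >= 1)
  rv <- .series_values(r); xv <- .series_values(x)
  stopifnot(length(rv) == length(xv))
  if (any(!is.finite(xv))) stop("non-finite CV values")
  s <- stats::sd(xv)
  xv <- if (s > 0) (xv - mean(xv)) / s else xv - mean(xv)
  pow <- expand.grid(i = 0:l, j = 0:l)
  pow <- pow[pow$i + pow$j <= l, , drop = FALSE]
  B <- matrix(NA_real_, length(rv), nrow(pow))
  for (k in seq_len(nrow(pow)))
    B[, k] <- rv^pow$i[k] * xv^pow$j[k]
  attr(B, "powers") <- pow
  B
}

#' One variational update of the RC by TSD minimization
#'
#' The variation \eqn{\delta r = \sum_{ij} a_{ij} r^i x^j} is constrained to
#' vanish on boundary-state frames (rows of the basis are zeroed there), and
#' the coefficients minimizing the lag-1 TSD of \eqn{r + \delta r} are obtained
#' analytically as a linear least-squares solution via SVD with a relative
#' singular-value cutoff. The zero update is always feasible, so the TSD
#' never increases; if clipping to `[0, 1]` would raise it (or the system is
#' numerically singular), the update falls back to zero for this iteration
#' rather than aborting.
#'
#' @param rc an [rc_series()].
#' @param basis matrix from [variation_basis()].
#' @param clip clip updated values into `[0, 1]`.
#' @param sv_cutoff relative singular-value cutoff of the solve.
#' @return List with the updated `rc`, the `coefficients`, the new `tsd`,
#'   and a logical `fallback`.
#' @export
solve_update <- function(rc, basis, clip = TRUE, sv_cutoff = 1e-10) {
  stopifnot(inherits(rc, "rc_series"), nrow(basis) == length(rc$r))
  bnd <- rc$in_A | rc$in_B
  B <- basis
  B[bnd, ] <- 0
  k <- which(rc$segment_ids[-length(rc$r)] ==
             rc$segment_ids[-1])
  d <- rc$r[k + 1] - rc$r[k]
  G <- B[k + 1, , drop = FALSE] - B[k, , drop = FALSE]
  tsd0 <- sum(d^2)
  zero <- function() list(rc = rc, coefficients = rep(0, ncol(basis)),
                          tsd = tsd0, fallback = TRUE)
  keepc <- which(colSums(G^2) > 0)
  if (!length(keepc)) return(zero())
  sv <- svd(G[, keepc, drop = FALSE])
  pos <- sv$d > sv_cutoff * max(sv$d)
  if (!any(pos)) return(zero())
  a_k <- -sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], d) / sv$d[pos])
  a <- rep(0, ncol(basis)); a[keepc] <- a_k
  r_new <- rc$r + drop(B %*% a)
  r_new[rc$in_A] <- 0; r_new[rc$in_B] <- 1
  if (clip) r_new <- pmin(pmax(r_new, 0), 1)
  tsd1 <- {
    ok <- r_new[k + 1] - r_new[k]
    sum(ok^2)
  }
  if (!is.finite(tsd1) || tsd1 > tsd0 * (1 + 1e-10) + 1e-12) return(zero())
  rc$r <- r_new
  list(rc = rc, coefficients = a, tsd = tsd1, fallback = FALSE)
}

#' Iterative nonparametric optimization of the reaction coordinate
#'
#' Repeats {draw a CV channel, build the polynomial variation basis, solve
#' the TSD-minimizing update} for `m_max` iterations, starting from `r0`.
#' Boundary frames stay clamped at 0/1 throughout, the TSD is non-increasing
#' by construction, and the whole run is reproducible under `set.seed()`.
#'
#' @param r0 an [rc_series()] satisfying the boundary conditions.
#' @param pool a CV pool ([build_cv_pool()] or [cv_pool_matrix()]).
#' @param l polynomial order of the variation (default 4).
#' @param m_max iteration budget.
#' @param clip clip updates into `[0, 1]` (committor range).
#' @param sv_cutoff relative singular-value cutoff for the solve.
#' @param verbose print per-iteration TSD.
#' @return List of class `rc_optimization`: final `rc` and a data.frame
#'   `log` with per-iteration channel, TSD and fallback flag.
#' @export
optimize_rc <- function(r0, pool, l = 4, m_max = 50, clip = TRUE,
                        sv_cutoff = 1e-10, verbose = FALSE) {
  stopifnot(inherits(r0, "rc_series"), m_max >= 0)
  rc <- r0
  log <- data.frame(iter = integer(), channel = character(),
                    tsd = numeric(), fallback = logical(),
                    stringsAsFactors = FALSE)
  if (m_max == 0) return(structure(list(rc = rc, log = log),
                                   class = "rc_optimization"))
  # draw the whole channel sequence up front and extract it in one pass
  # (lattice pools recompute sorted matrices once, not once per iteration)
  ids <- sample.int(n_channels(pool), m_max, replace = TRUE)
  X <- extract_channels(pool, ids)
  labs <- channel_labels(pool, ids)
  for (m in seq_len(m_max)) {
    x <- cv_series(X[, m], rc$segment_ids, labs[m])
    B <- variation_basis(rc, x, l)
    up <- solve_update(rc, B, clip = clip, sv_cutoff = sv_cutoff)
    rc <- up$rc
    log <- rbind(log, data.frame(iter = m, channel = x$channel,
                                 tsd = up$tsd, fallback = up$fallback,
                                 stringsAsFactors = FALSE))
    if (up$fallback)
      warning(sprintf("iteration %d: singular or non-improving update skipped", m),
              call. = FALSE)
    if (verbose)
      message(sprintf("iter %3d  %-10s TSD = %.6g", m, x$channel, up$tsd))
  }
  structure(list(rc = rc, log = log), class = "rc_optimization")
}

#' @export
print.rc_optimization <- function(x, ...) {
  cat(sprintf("rc_optimization: %d iterations, TSD %.6g -> %.6g (%d fallbacks)\n",
              nrow(x$log), if (nrow(x$log)) x$log$tsd[1] else NA,
              if (nrow(x$log)) x$log$tsd[nrow(x$log)] else NA,
              sum(x$log$fallback)))
  invisible(x)
}

#' Committor as a function of the largest-cluster size
#'
#' Runs the variational optimization with the single CV `x = n` at every
#' iteration. Because every update is then a function of `n` alone, the
#' converged coordinate `q(n)` is a reparametrization of `n`: it inherits
#' the optimality (or not) of `n` itself, which makes it the right baseline
#' for the cut-profile validation test of the classical-nucleation-theory
#' coordinate.
#'
#' @param n_series [cv_series()] of largest-cluster sizes.
#' @param boundary a `boundary_states` object (see
#'   [define_boundary_states()]) on the `n` coordinate.
#' @param m_max iteration budget (20 is enough for convergence).
#' @param l polynomial order.
#' @return An `rc_optimization` (final `rc` is `q(n)` per frame).
#' @export
committor_of_n <- function(n_series, boundary, m_max = 20, l = 4) {
  r0 <- initial_rc(n_series, boundary)
  pool <- cv_pool_matrix(matrix(n_series$values, ncol = 1), channels = "n")
  optimize_rc(r0, pool, l = l, m_max = m_max)
}

#' Boundary states from a free-energy profile
#'
#' Locates the two main minima of the free-energy profile
#' \eqn{F = -\ln Z_H} of a reference coordinate and the barrier between
#' them, then defines the boundary states as the threshold regions around
#' the minima where `F` lies at least `depth` (in units of `k_B T`) below
#' the barrier top: `A = {ref <= a_max}`, `B = {ref >= b_min}`.
#'
#' @param ref a [cv_series()] (or numeric vector) of the reference
#'   coordinate, e.g. `n` or a current RC.
#' @param depth threshold depth below the barrier top in `k_B T`; default
#'   half the smaller barrier height.
#' @param nbins histogram bins for continuous coordinates (integer-valued
#'   coordinates use unit bins).
#' @param a_max,b_min explicit thresholds; when both are given they are
#'   returned as-is and no profile analysis is performed.
#' @param fallback_quantiles when the profile has no pair of minima
#'   separated by a clear barrier (for example at small system sizes, where
#'   the two-state structure is rounded away), fall back to these
#'   coordinate quantiles as thresholds instead of failing, with a warning;
#'   `NULL` keeps the strict behaviour (informative error on a unimodal
#'   profile).
#' @return A `boundary_states` object: thresholds `a_max`, `b_min`, masks
#'   `in_A`, `in_B`, and the profile diagnostics (`grid`, `F`); the logical
#'   element `bimodal` records whether two barrier-separated minima were
#'   found.
#' @export
define_boundary_states <- function(ref, depth = NULL, nbins = 100,
                                   a_max = NULL, b_min = NULL,
                                   fallback_quantiles = NULL) {
  v <- .series_values(ref)
  if (!is.null(a_max) && !is.null(b_min)) {
    stopifnot(a_max < b_min)
    return(structure(list(a_max = a_max, b_min = b_min,
                          in_A = v <= a_max, in_B = v >= b_min,
                          grid = NULL, F = NULL, bimodal = NA),
                     class = "boundary_states"))
  }
  integerish <- all(abs(v - round(v)) < 1e-9) && diff(range(v)) <= 4 * nbins
  if (integerish) {
    grid <- seq(min(v), max(v))
    counts <- tabulate(round(v) - min(v) + 1L, nbins = length(grid))
  } else {
    h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = nbins + 1),
                        plot = FALSE)
    grid <- h$mids
    counts <- h$counts
  }
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  F <- -log(pmax(sm, 0.5))
  # local minima of F on the sampled support; sparsely occupied tail bins
  # are not credible basins
  cand <- which(diff(sign(diff(c(Inf, F, Inf)))) == 2)
  cand <- cand[sm[cand] >= max(1, 0.02 * max(sm))]
  m2 <- NA
  if (length(cand) >= 2) {
    ord <- cand[order(F[cand])]
    m1 <- ord[1]
    for (m in ord[-1]) {
      bar <- max(F[min(m1, m):max(m1, m)])
      if (bar - max(F[m1], F[m]) > 0.5) { m2 <- m; break }
    }
  }
  if (is.na(m2)) {
    msg <- if (length(cand) < 2)
      "free-energy profile is unimodal: cannot define two boundary states"
    else "no pair of minima separated by a barrier > 0.5 k_BT found"
    if (is.null(fallback_quantiles)) stop(msg)
    warning(msg, "; falling back to coordinate quantiles (",
            paste(fallback_quantiles, collapse = ", "), ")", call. = FALSE)
    qs <- stats::quantile(v, fallback_quantiles, names = FALSE)
    return(structure(list(a_max = qs[1], b_min = qs[2],
                          in_A = v <= qs[1], in_B = v >= qs[2],
                          grid = grid, F = F, bimodal = FALSE),
                     class = "boundary_states"))
  }
  lo <- min(m1, m2); hi <- max(m1, m2)
  ib <- lo + which.max(F[lo:hi]) - 1L
  F_bar <- F[ib]
  if (is.null(depth)) depth <- 0.5 * (F_bar - max(F[lo], F[hi]))
  ia <- max(which(F[lo:ib] <= F_bar - depth)) + lo - 1L
  ibn <- min(which(F[ib:hi] <= F_bar - depth)) + ib - 1L
  a_max <- grid[ia]; b_min <- grid[ibn]
  structure(list(a_max = a_max, b_min = b_min,
                 in_A = v <= a_max, in_B = v >= b_min,
                 grid = grid, F = F, barrier = F_bar, depth = depth,
                 bimodal = TRUE),
            class = "boundary_states")
}

#' @export
print.boundary_states <- function(x, ...) {
  cat(sprintf("boundary_states: A = {ref <= %g} (%d frames), B = {ref >= %g} (%d frames)\n",
              x$a_max, sum(x$in_A), x$b_min, sum(x$in_B)))
  invisible(x)
}

#' Initial reaction coordinate: clipped linear ramp of a reference CV
#'
#' `r0 = clip((ref - a_max) / (b_min - a_max), 0, 1)` with the boundary
#' masks clamped exactly -- cheap, monotone in the reference coordinate, and
#' boundary-condition compliant.
#'
#' @param ref [cv_series()] or numeric reference coordinate.
#' @param boundary a `boundary_states` on the same coordinate.
#' @return An [rc_series()].
#' @export
initial_rc <- function(ref, boundary) {
  v <- .series_values(ref)
  r <- (v - boundary$a_max) / (boundary$b_min - boundary$a_max)
  r <- pmin(pmax(r, 0), 1)
  rc_series(r, boundary$in_A, boundary$in_B,
            .series_segments(ref, length(v)))
}

#' Optimization with soft (self-consistently redefined) boundary states
#'
#' Alternates RC optimization with redefinition of the boundary states from
#' the free-energy profile of the current coordinate: after each round, `A`
#' and `B` become the terminal intervals of `r` around its profile minima
#' and optimization is repeated. Iterated to a fixed point (boundary
#' membership changing on fewer than `change_tol` of the frames) or for at
#' most `rounds` rounds.
#'
#' @param r0 initial [rc_series()].
#' @param pool CV pool.
#' @param rounds maximum number of boundary-redefinition rounds.
#' @param change_tol fixed-point threshold on the fraction of frames whose
#'   boundary membership changes.
#' @param m_max,l,... forwarded to [optimize_rc()].
#' @return An `rc_optimization` with an extra element `rounds_used`.
#' @export
optimize_rc_soft <- function(r0, pool, rounds = 5, change_tol = 0.01,
                             m_max = 50, l = 4, ...) {
  rc <- r0
  opt <- NULL
  used <- 0
  for (round in seq_len(rounds)) {
    opt <- optimize_rc(rc, pool, l = l, m_max = m_max, ...)
    used <- round
    bnd <- tryCatch(
      define_boundary_states(cv_series(opt$rc$r, opt$rc$segment_ids)),
      error = function(e) NULL)
    if (is.null(bnd)) break
    changed <- mean(bnd$in_A != opt$rc$in_A | bnd$in_B != opt$rc$in_B)
    rc <- rc_series(opt$rc$r, bnd$in_A, bnd$in_B, opt$rc$segment_ids)
    if (changed < change_tol) { opt$rc <- rc; break }
    opt$rc <- rc
  }
  opt$rounds_used <- used
  opt
}
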
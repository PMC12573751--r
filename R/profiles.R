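#' Histogram profile of an RC series at a dyadic lag
#'
#' At lag \eqn{2^i} the series decomposes into \eqn{2^i} strided phases;
#' every frame belongs to exactly one phase, so the phase-averaged histogram
#' equals the all-frames histogram divided by the lag. Consequently
#' \eqn{\sum_{bins} Z_H = T / 2^i} exactly: doubling the lag halves the
#' total count, the \eqn{Z_H \sim \Delta t^{-1}} scaling.
#'
#' @param r [rc_series()], [cv_series()] or numeric vector.
#' @param lag lag in frames (use powers of 2 for the validation scan).
#' @param edges increasing bin edges covering the data.
#' @return Numeric vector of per-bin (phase-averaged) counts.
#' @export
histogram_zh <- function(r, lag = 1L, edges = seq(0, 1, length.out = 101)) {
  v <- .series_values(r)
  seg <- .series_segments(r, length(v))
  if (lag >= max(table(seg))) stop("lag longer than every segment")
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  if (any(idx < 1 | idx > length(edges) - 1))
    stop("edges do not cover the data range")
  tabulate(idx, nbins = length(edges) - 1) / lag
}

#' Cut profile Z_C,1 of an RC series
#'
#' For each RC value \eqn{r^*}, the sum of \eqn{|r(k\Delta t + \Delta t) -
#' r(k\Delta t)|} over within-segment pairs whose interval straddles
#' \eqn{r^*}. Each pair contributes a top-hat of height \eqn{|\Delta r|}
#' over its interval, bin-averaged onto the grid (interval accumulation via
#' a difference array), and the result is phase-averaged (divided by the
#' lag). For the true committor the profile is flat and equal to the number
#' of boundary-state transitions \eqn{N_{AB}} at every lag.
#'
#' The convention is exact: `sum(zc1 * binwidth)` equals [tsd()] at the same
#' lag to machine precision whenever the grid covers the data.
#'
#' @inheritParams histogram_zh
#' @return Numeric vector of per-bin cut values.
#' @export
zc1 <- function(r, lag = 1L, edges = seq(0, 1, length.out = 101)) {
  v <- .series_values(r)
  seg <- .series_segments(r, length(v))
  if (lag >= max(table(seg))) stop("lag longer than every segment")
  if (min(v) < edges[1] || max(v) > edges[length(edges)])
    stop("edges do not cover the data range")
  zc1_cpp(v, as.integer(seg), as.integer(lag), edges)
}

#' Histogram, cut, free-energy and diffusion profiles at one lag
#'
#' Convenience wrapper computing the full profile set of an RC series on a
#' uniform grid: \eqn{Z_H}, \eqn{Z_{C,1}}, \eqn{F = -\ln Z_H} (in
#' \eqn{k_B T}, arbitrary additive constant) and the diffusion coefficient
#' from [diffusion_coefficient()].
#'
#' @param r [rc_series()], [cv_series()] or numeric vector.
#' @param lag lag in frames.
#' @param nbins number of uniform bins.
#' @param range grid range; default `[0, 1]` extended to cover the data.
#' @param dt0 physical time per frame (sets the unit of `D`).
#' @return A `profile_set`: list with `edges`, `mids`, `h` (bin width),
#'   `zh`, `zc1`, `F`, `D`, `lag`, `dt0`.
#' @export
rc_profiles <- function(r, lag = 1L, nbins = 100, range = NULL, dt0 = 1) {
  v <- .series_values(r)
  if (is.null(range)) range <- c(min(0, min(v)), max(1, max(v)))
  edges <- seq(range[1], range[2], length.out = nbins + 1)
  h <- diff(range) / nbins
  zh <- histogram_zh(r, lag, edges)
  zc <- zc1(r, lag, edges)
  structure(list(edges = edges, mids = (edges[-1] + edges[-(nbins + 1)]) / 2,
                 h = h, zh = zh, zc1 = zc,
                 F = ifelse(zh > 0, -log(zh), NA_real_),
                 D = diffusion_coefficient(zc, zh, lag, h, dt0),
                 lag = lag, dt0 = dt0),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("profile_set: %d bins on [%g, %g], lag %d (dt0 = %g)\n",
              length(x$mids), x$edges[1], x$edges[length(x$edges)],
              x$lag, x$dt0))
  invisible(x)
}

#' Position-dependent diffusion coefficient from the cut and histogram
#' profiles
#'
#' Estimates \eqn{D(r, \Delta t) = Z_{C,1}(r,\Delta t) / (2\,\Delta t\,
#' Z_H(r,\Delta t))} with \eqn{Z_H} expressed as a density (per-bin counts
#' divided by the bin width). With the package's profile conventions this
#' reduces to `zc1 * binwidth / (2 * lag * dt0 * zh)`. Bins with `zh = 0`
#' are masked (`NA`), not zero-filled. For a diffusion with known constant
#' \eqn{D_0} sampled at spacing `dt0` the estimator recovers \eqn{D_0}
#' (expected squared displacement per pair is \eqn{2 D_0 \Delta t}).
#'
#' @param zc1,zh profiles from [zc1()] and [histogram_zh()] at equal lag.
#' @param lag lag in frames.
#' @param binwidth grid bin width.
#' @param dt0 physical time per frame.
#' @return Per-bin diffusion coefficient (`NA` where unsampled).
#' @export
diffusion_coefficient <- function(zc1, zh, lag, binwidth, dt0 = 1) {
  if (all(zh == 0)) stop("fully unsampled profile")
  ifelse(zh > 0, zc1 * binwidth / (2 * lag * dt0 * zh), NA_real_)
}

#' Committor validation scan over dyadic lags
#'
#' Computes \eqn{-\ln Z_{C,1}(r, 2^i \Delta t_0)} for `i = 0..i_max` and
#' summarizes, per lag, the mean and spread of the profile over the
#' interior region. For the committor the profile is flat and lag
#' independent, fluctuating around \eqn{-\ln N_{AB}} with statistical
#' uncertainty about \eqn{1/\sqrt{2 N_{AB}}}; the verdict is a pass when,
#' at every lag, both the interior mean's deviation from the expectation
#' and the interior spread stay within `tol_mult` times that uncertainty
#' (r-dependence and lag-dependence must both vanish). Lags should stay
#' well below the basin-exchange time: beyond it the cut profile decays
#' for any coordinate because round trips within one lag cancel.
#'
#' @param r an [rc_series()] (boundary masks give `N_AB` via
#'   [nab_direct()]) or numeric vector with `nab` supplied.
#' @param i_max largest dyadic exponent; lags above the longest segment are
#'   dropped.
#' @param nbins grid bins on `[0, 1]`.
#' @param interior RC interval over which flatness is summarized (excludes
#'   the boundary-state end bins).
#' @param nab number of A-B transitions; default counted from the masks.
#' @param tol_mult multiplier on the \eqn{1/\sqrt{2 N_{AB}}} uncertainty.
#' @return List of class `validation_scan`: `table` (per-lag summary),
#'   `expected` (\eqn{-\ln N_{AB}}), `tol`, `pass`, `max_dev`, `nab`, and
#'   the profiles.
#' @export
validation_scan <- function(r, i_max = 10, nbins = 100,
                            interior = c(0.05, 0.95), nab = NULL,
                            tol_mult = 3) {
  if (is.null(nab)) {
    stopifnot(inherits(r, "rc_series"))
    nab <- nab_direct(r)
  }
  if (nab < 1) stop("no A-B transitions in the series")
  v <- .series_values(r)
  seg <- .series_segments(r, length(v))
  max_seg <- max(table(seg))
  edges <- seq(min(0, min(v)), max(1, max(v)),
               length.out = nbins + 1)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  keep_bin <- mids >= interior[1] & mids <= interior[2]
  rows <- list(); profs <- list()
  for (i in 0:i_max) {
    lag <- 2^i
    if (lag >= max_seg) break
    z <- zc1(r, lag, edges)
    val <- -log(z[keep_bin & z > 0])
    rows[[length(rows) + 1]] <-
      data.frame(i = i, lag = lag, mean = mean(val), sd = stats::sd(val),
                 n_bins = length(val))
    profs[[length(profs) + 1]] <- z
  }
  tab <- do.call(rbind, rows)
  expected <- -log(nab)
  tol <- tol_mult / sqrt(2 * nab)
  max_dev <- max(abs(tab$mean - expected))
  max_sd <- max(tab$sd)
  structure(list(table = tab, expected = expected, tol = tol,
                 pass = max_dev <= tol && max_sd <= tol,
                 max_dev = max_dev, max_sd = max_sd, nab = nab,
                 edges = edges, profiles = profs),
            class = "validation_scan")
}

#' @export
print.validation_scan <- function(x, ...) {
  cat(sprintf("validation_scan: %d lags, -ln Zc1 in [%.3f, %.3f], expected %.3f +/- %.3f -> %s\n",
              nrow(x$table), min(x$table$mean), max(x$table$mean),
              x$expected, x$tol, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Rescale the reaction coordinate to unit diffusion
#'
#' Applies the monotone map \eqn{\tilde q(r) = \int_0^r dr'/\sqrt{D(r',
#' \Delta t_0)}} with piecewise-constant per-bin `D` estimated at lag 1.
#' On the rescaled coordinate the re-estimated diffusion coefficient is
#' approximately 1 on the sampled interior, so the free-energy profile
#' alone specifies the diffusive model. Bins with masked `D` (unsampled)
#' are bridged by linear interpolation of \eqn{\log D}.
#'
#' @param r an [rc_series()] (or numeric / [cv_series()]).
#' @param nbins grid bins for the `D` estimate.
#' @param dt0 physical time per frame.
#' @return List of class `rc_rescaled`: `values` (rescaled series),
#'   `qtilde` (the map, an `approxfun` on the original edges),
#'   `delta_q` (\eqn{\tilde q} separation of the two free-energy minima),
#'   `profiles` (re-estimated profile set on the rescaled coordinate),
#'   `bridged` (number of interpolated bins).
#' @export
rescale_unit_diffusion <- function(r, nbins = 100, dt0 = 1) {
  ps <- rc_profiles(r, lag = 1L, nbins = nbins, dt0 = dt0)
  D <- ps$D
  bad <- which(!is.finite(D) | D <= 0)
  if (length(bad) == length(D)) stop("diffusion profile entirely unsampled")
  if (length(bad)) {
    ok <- setdiff(seq_along(D), bad)
    D[bad] <- exp(stats::approx(ps$mids[ok], log(D[ok]), xout = ps$mids[bad],
                                rule = 2)$y)
  }
  qt_edges <- c(0, cumsum(ps$h / sqrt(D)))
  qtilde <- stats::approxfun(ps$edges, qt_edges, rule = 2)
  v <- .series_values(r)
  newv <- qtilde(v)
  # separation of the two free-energy minima on the rescaled coordinate
  Fv <- ps$F
  sampled <- which(is.finite(Fv))
  lo_half <- sampled[ps$mids[sampled] <= stats::median(v)]
  hi_half <- sampled[ps$mids[sampled] > stats::median(v)]
  m_lo <- lo_half[which.min(Fv[lo_half])]
  m_hi <- hi_half[which.min(Fv[hi_half])]
  delta_q <- qtilde(ps$mids[m_hi]) - qtilde(ps$mids[m_lo])
  out_series <- if (inherits(r, "rc_series"))
    cv_series(newv, r$segment_ids, "qtilde") else
    cv_series(newv, .series_segments(r, length(newv)), "qtilde")
  reprof <- rc_profiles(out_series, lag = 1L, nbins = nbins,
                        range = c(0, max(qt_edges)), dt0 = dt0)
  structure(list(values = out_series, qtilde = qtilde, delta_q = delta_q,
                 profiles = reprof, bridged = length(bad)),
            class = "rc_rescaled")
}

#' @export
print.rc_rescaled <- function(x, ...) {
  cat(sprintf("rc_rescaled: range [0, %.3g], delta_q = %.3g (%d bins bridged)\n",
              max(x$profiles$edges), x$delta_q, x$bridged))
  invisible(x)
}
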
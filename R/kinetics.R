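#' One-dimensional diffusive model on a committor-like coordinate
#'
#' Pairs a normalized equilibrium density with a diffusion profile on a
#' uniform grid of bin centers. Supports the equilibrium flux, the mean
#' first passage time integral, and unit-diffusion rescaling.
#'
#' @param p_eq nonnegative weights per bin (normalized internally to a
#'   density).
#' @param D positive diffusion coefficient per bin; `NA` (unsampled) bins
#'   inside the support are bridged by linear interpolation of `log(p*D)`
#'   at evaluation time.
#' @param edges grid bin edges.
#' @return An object of class `diffusive_model`.
#' @export
diffusive_model <- function(p_eq, D, edges) {
  nb <- length(edges) - 1
  stopifnot(length(p_eq) == nb, length(D) == nb, all(p_eq >= 0, na.rm = TRUE))
  h <- (edges[nb + 1] - edges[1]) / nb
  dens <- p_eq / (sum(p_eq) * h)
  structure(list(p = dens, D = D, edges = edges,
                 mids = (edges[-1] + edges[-(nb + 1)]) / 2, h = h),
            class = "diffusive_model")
}

#' Diffusive model from a profile set
#'
#' Uses \eqn{p_{eq} \propto Z_H} and the Eq.-style diffusion estimate of
#' [diffusion_coefficient()] at the profile's lag.
#'
#' @param ps a `profile_set` from [rc_profiles()].
#' @return A [diffusive_model()].
#' @export
as_diffusive_model <- function(ps) {
  stopifnot(inherits(ps, "profile_set"))
  diffusive_model(ps$zh, ps$D, ps$edges)
}

#' @export
print.diffusive_model <- function(x, ...) {
  cat(sprintf("diffusive_model: %d bins on [%g, %g]\n",
              length(x$mids), x$edges[1], max(x$edges)))
  invisible(x)
}

# p*D per bin with unsampled interior bins bridged by log-linear interpolation
.pd_bridged <- function(model) {
  g <- model$p * model$D
  ok <- which(is.finite(g) & g > 0)
  if (!length(ok)) stop("unsampled interior region: p*D vanishes everywhere")
  bad <- setdiff(seq_along(g), ok)
  if (length(bad))
    g[bad] <- exp(stats::approx(model$mids[ok], log(g[ok]),
                                xout = model$mids[bad], rule = 2)$y)
  g
}

#' Mean first passage time from the 1D diffusive model
#'
#' Evaluates the double integral
#' \deqn{\tau_{B \to A} = \int_{to}^{from} \frac{dq'}{p_{eq}(q') D(q')}
#'   \int_{q'}^{q_{refl}} p_{eq}(q'') \, dq''}
#' by midpoint sums on the model grid, where \eqn{q_{refl}} is the far
#' (reflecting) end of the interval in the direction of `from`. With the
#' defaults `from = 1`, `to = 0` this is the B-to-A passage time over the
#' committor range; arbitrary endpoint pairs inside the grid are supported,
#' including `from < to` for the reverse passage.
#'
#' @param model a [diffusive_model()].
#' @param from starting point on the coordinate.
#' @param to target point.
#' @return Scalar MFPT in the model's time units.
#' @export
mfpt_model <- function(model, from = 1, to = 0) {
  stopifnot(inherits(model, "diffusive_model"), from != to)
  g <- .pd_bridged(model)
  h <- model$h
  p <- model$p
  m <- model$mids
  if (from > to) {
    outer_bins <- which(m >= to & m <= from)
    # inner integral from q' up to the reflecting end (max edge)
    inner <- rev(cumsum(rev(p * h))) - p * h / 2
    sum(h / g[outer_bins] * inner[outer_bins])
  } else {
    outer_bins <- which(m >= from & m <= to)
    inner <- cumsum(p * h) - p * h / 2
    sum(h / g[outer_bins] * inner[outer_bins])
  }
}

#' Equilibrium flux profile
#'
#' \eqn{J(q) = D(q) p_{eq}(q)}. For a validated committor the profile is
#' constant over the interior up to sampling noise; r-dependence signals a
#' suboptimal coordinate.
#'
#' @param model a [diffusive_model()].
#' @return Numeric per-bin flux.
#' @export
flux_profile <- function(model) {
  model$D * model$p
}

# alternating first-entry times into A/B per segment;
# returns data.frame(seg, state ("A"/"B"), t (frame index), t_last_exit)
.ab_visits <- function(r) {
  stopifnot(inherits(r, "rc_series"))
  lab <- integer(length(r$r))
  lab[r$in_A] <- 1L
  lab[r$in_B] <- 2L
  out <- list()
  for (s in unique(r$segment_ids)) {
    idx <- which(r$segment_ids == s)
    l <- lab[idx]
    cur <- 0L
    ent <- integer(0); st <- integer(0)
    for (t in seq_along(l)) {
      if (l[t] != 0L && l[t] != cur) {
        ent <- c(ent, t); st <- c(st, l[t]); cur <- l[t]
      }
    }
    if (length(ent))
      out[[length(out) + 1]] <-
        data.frame(seg = s, state = st, t = idx[ent])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Direct mean first passage time from an RC time series
#'
#' Events run from each first entry into the source state until the next
#' first entry into the target state, within segments; re-entries into the
#' source before the target is reached extend the same event. With this
#' definition \eqn{\tau_{A\to B} + \tau_{B\to A}} is consistent with total
#' time divided by the one-way transition count.
#'
#' @param r an [rc_series()] (masks define A and B).
#' @param from,to `"A"` or `"B"`.
#' @param dt0 physical time per frame.
#' @return List: `tau` (mean), `n_events`, `times` (per-event durations,
#'   for bootstrap error bars). `tau` is `NA` with a warning when no event
#'   completes.
#' @export
mfpt_direct <- function(r, from = "B", to = "A", dt0 = 1) {
  vis <- .ab_visits(r)
  src <- if (from == "A") 1L else 2L
  tgt <- if (to == "A") 1L else 2L
  stopifnot(src != tgt)
  times <- numeric(0)
  if (!is.null(vis)) {
    for (s in unique(vis$seg)) {
      vs <- vis[vis$seg == s, ]
      k <- which(vs$state[-nrow(vs)] == src & vs$state[-1] == tgt)
      times <- c(times, (vs$t[k + 1] - vs$t[k]) * dt0)
    }
  }
  if (!length(times)) {
    warning("no completed passage events", call. = FALSE)
    return(list(tau = NA_real_, n_events = 0L, times = numeric(0)))
  }
  list(tau = mean(times), n_events = length(times), times = times)
}

#' Number of boundary-state transitions counted from the time series
#'
#' Counts completed crossings between `A` and `B` (both directions) within
#' segments: each change of the most recently visited boundary state
#' increments the count.
#'
#' @param r an [rc_series()].
#' @return Integer transition count \eqn{N_{AB}}.
#' @export
nab_direct <- function(r) {
  vis <- .ab_visits(r)
  if (is.null(vis)) return(0L)
  # visits alternate by construction: transitions per segment = visits - 1
  sum(vapply(unique(vis$seg), function(s)
    sum(vis$seg == s) - 1L, integer(1)))
}

#' Transition count from the integral of the cut profile
#'
#' \eqn{N_{AB} = \int Z_{C,1}(r, \Delta t_0)\,dr}, evaluated as the exact
#' bin sum `sum(zc1 * binwidth)`. By the interval-accumulation identity this
#' equals [tsd()] at the same lag for any series; for a well-converged
#' committor it matches [nab_direct()].
#'
#' @param zc1 cut profile at lag `dt0` from [zc1()] (or a `profile_set`).
#' @param binwidth grid bin width (taken from the profile set if given).
#' @return Scalar estimate of \eqn{N_{AB}}.
#' @export
nab_integral <- function(zc1, binwidth = NULL) {
  if (inherits(zc1, "profile_set")) {
    binwidth <- zc1$h
    zc1 <- zc1$zc1
  }
  stopifnot(!is.null(binwidth))
  sum(zc1 * binwidth)
}

#' Direct mean transition-path time
#'
#' Mean duration of reactive segments: from the last exit out of one
#' boundary state to the first entry into the other, in either direction,
#' within segments.
#'
#' @param r an [rc_series()].
#' @param dt0 physical time per frame.
#' @return List: `tau_hat`, `n_events`, `times`.
#' @export
mtpt_direct <- function(r, dt0 = 1) {
  vis <- .ab_visits(r)
  lab <- integer(length(r$r))
  lab[r$in_A] <- 1L
  lab[r$in_B] <- 2L
  times <- numeric(0)
  if (!is.null(vis)) {
    for (s in unique(vis$seg)) {
      vs <- vis[vis$seg == s, ]
      if (nrow(vs) < 2) next
      for (k in seq_len(nrow(vs) - 1)) {
        if (vs$state[k] == vs$state[k + 1]) next
        span <- vs$t[k]:(vs$t[k + 1] - 1)
        last_exit <- max(span[lab[span] == vs$state[k]])
        times <- c(times, (vs$t[k + 1] - last_exit) * dt0)
      }
    }
  }
  if (!length(times)) {
    warning("no reactive events", call. = FALSE)
    return(list(tau_hat = NA_real_, n_events = 0L, times = numeric(0)))
  }
  list(tau_hat = mean(times), n_events = length(times), times = times)
}
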
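#' Configuration for the anisotropic lattice aggregation model
#'
#' Defines a 2D periodic square lattice of side `L` carrying `N` molecules.
#' Each molecule occupies one site (excluded volume) and has a binary
#' orientation. Nearest-neighbour molecules attract with bond energy
#' \eqn{-\psi_s} when aligned (equal orientations) and \eqn{-\psi_w} when
#' nonaligned, with \eqn{\psi_s = \xi \psi_w}; \eqn{\xi \ge 1} measures the
#' interaction anisotropy. Energies are in units of \eqn{\psi_w} and
#' temperatures in the same units (\eqn{k_B = 1}).
#'
#' Dynamics is canonical (NVT) Metropolis Monte Carlo. One elementary MC
#' attempt updates a single uniformly chosen molecule: with probability
#' `move_mix` a translation to a uniformly chosen 4-neighbour site is
#' proposed (rejected outright if the site is occupied), otherwise an
#' orientation flip. Configurations are recorded every `dt0` attempts; `dt0`
#' is the unit of time for all downstream analysis.
#'
#' @param L lattice side length (sites).
#' @param N number of molecules; `0 < N <= L^2`.
#' @param T temperature in units of `psi_w` (`k_B = 1`).
#' @param xi anisotropy ratio \eqn{\psi_s/\psi_w \ge 1}.
#' @param psi_w weak-bond energy; sets the energy unit (default 1).
#' @param dt0 frame interval in elementary MC attempts.
#' @param n_steps total elementary MC attempts in the production run.
#' @param move_mix probability that an attempt is a translation.
#' @param seed optional RNG seed consumed by [run_lattice()].
#' @return An object of class `lattice_config`.
#' @seealso [run_lattice()], [calibrate_coexistence_temperature()]
#' @export
lattice_config <- function(L, N, T, xi = 1, psi_w = 1, dt0 = 400L,
                           n_steps = 1e6, move_mix = 0.5, seed = NULL) {
  stopifnot(L >= 2, N >= 1, N <= L^2, xi >= 1, psi_w > 0, T > 0,
            dt0 >= 1, n_steps >= 1, move_mix >= 0, move_mix <= 1)
  structure(list(L = as.integer(L), N = as.integer(N), T = T, xi = xi,
                 psi_w = psi_w, dt0 = as.integer(dt0), n_steps = n_steps,
                 move_mix = move_mix, seed = seed),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf(
    "lattice_config: L=%d N=%d xi=%g psi_w=%g T=%g dt0=%d n_steps=%g move_mix=%g\n",
    x$L, x$N, x$xi, x$psi_w, x$T, x$dt0, x$n_steps, x$move_mix))
  invisible(x)
}

#' Construct a lattice state
#'
#' @param x,y integer coordinates in `[0, L)` (one per molecule).
#' @param o orientations in `{0, 1}`.
#' @param L lattice side length.
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(x, y, o, L) {
  x <- as.integer(x); y <- as.integer(y); o <- as.integer(o)
  stopifnot(length(x) == length(y), length(x) == length(o),
            all(x >= 0 & x < L), all(y >= 0 & y < L), all(o %in% c(0L, 1L)))
  if (anyDuplicated(x + L * y))
    stop("two molecules share a lattice site")
  structure(list(x = x, y = y, o = o, L = as.integer(L)),
            class = "lattice_state")
}

#' Random dilute initial state
#'
#' Places `N` molecules uniformly at random on distinct sites with random
#' orientations.
#'
#' @param cfg a [lattice_config()].
#' @return A `lattice_state`.
#' @export
random_lattice_state <- function(cfg) {
  sites <- sample.int(cfg$L^2, cfg$N) - 1L
  lattice_state(sites %% cfg$L, sites %/% cfg$L,
                sample(c(0L, 1L), cfg$N, replace = TRUE), cfg$L)
}

#' Bond energy of a nearest-neighbour pair
#'
#' Returns \eqn{-\psi_s = -\xi\psi_w} for aligned orientations and
#' \eqn{-\psi_w} otherwise (attractive bonds).
#'
#' @param o1,o2 orientations in `{0, 1}`.
#' @param cfg a [lattice_config()].
#' @return Scalar bond energy.
#' @export
pair_energy <- function(o1, o2, cfg) {
  stopifnot(o1 %in% c(0L, 1L), o2 %in% c(0L, 1L))
  ifelse(o1 == o2, -cfg$xi * cfg$psi_w, -cfg$psi_w)
}

#' Total configurational energy of a lattice state
#'
#' Sums [pair_energy()] over occupied 4-neighbour pairs, each pair counted
#' once, with periodic wrap-around adjacency.
#'
#' @param state a `lattice_state`.
#' @param cfg a [lattice_config()].
#' @return Scalar total energy.
#' @export
total_energy <- function(state, cfg) {
  lattice_total_energy_cpp(state$x, state$y, state$o, state$L,
                           cfg$psi_w, cfg$xi)
}

#' One elementary Metropolis attempt (reference implementation)
#'
#' A pure-R single attempt used for rule-level testing; production runs use
#' the compiled kernel in [run_lattice()], which implements the identical
#' move set. Returns the updated state together with the proposal bookkeeping
#' (type, energy change of the proposal, acceptance).
#'
#' @param state a `lattice_state`.
#' @param cfg a [lattice_config()].
#' @return A list with elements `state`, `type` (`"translate"` or `"flip"`),
#'   `dE` (energy change of the proposed move, `NA` if the target site was
#'   occupied), and `accepted`.
#' @export
mc_attempt <- function(state, cfg) {
  L <- state$L
  i <- sample.int(cfg$N, 1)
  occ_key <- state$x + L * state$y
  if (stats::runif(1) < cfg$move_mix) {
    k <- sample.int(4, 1)
    dx <- c(1L, -1L, 0L, 0L)[k]; dy <- c(0L, 0L, 1L, -1L)[k]
    nx <- (state$x[i] + dx) %% L; ny <- (state$y[i] + dy) %% L
    if (any(occ_key == nx + L * ny))
      return(list(state = state, type = "translate", dE = NA_real_,
                  accepted = FALSE))
    e_old <- .site_bonds(state, cfg, state$x[i], state$y[i], state$o[i], skip = i)
    moved <- state
    moved$x[i] <- nx; moved$y[i] <- ny
    e_new <- .site_bonds(moved, cfg, nx, ny, state$o[i], skip = i)
    dE <- e_new - e_old
    acc <- dE <= 0 || stats::runif(1) < exp(-dE / cfg$T)
    list(state = if (acc) moved else state, type = "translate",
         dE = dE, accepted = acc)
  } else {
    e_old <- .site_bonds(state, cfg, state$x[i], state$y[i], state$o[i], skip = i)
    e_new <- .site_bonds(state, cfg, state$x[i], state$y[i], 1L - state$o[i], skip = i)
    dE <- e_new - e_old
    acc <- dE <= 0 || stats::runif(1) < exp(-dE / cfg$T)
    if (acc) state$o[i] <- 1L - state$o[i]
    list(state = state, type = "flip", dE = dE, accepted = acc)
  }
}

# bond-energy sum of a molecule (possibly displaced) with its 4-neighbours,
# ignoring molecule `skip`
.site_bonds <- function(state, cfg, x, y, o, skip) {
  L <- state$L
  nb <- cbind((x + c(1L, -1L, 0L, 0L)) %% L, (y + c(0L, 0L, 1L, -1L)) %% L)
  e <- 0
  for (k in 1:4) {
    j <- which(state$x == nb[k, 1] & state$y == nb[k, 2])
    j <- setdiff(j, skip)
    if (length(j)) e <- e + pair_energy(o, state$o[j], cfg)
  }
  e
}

#' Run a Metropolis Monte Carlo production trajectory
#'
#' Executes `cfg$n_steps` elementary attempts with the compiled kernel,
#' recording a frame every `cfg$dt0` attempts (the initial state is recorded
#' as frame 1). An equilibration prefix of `equil_frac * n_steps` attempts is
#' run and discarded first when starting from a fresh random dilute state;
#' pass `init` (for example the last frame of a previous run) to continue
#' from an equilibrated configuration without a prefix.
#'
#' Deterministic given the RNG state: `cfg$seed` (or an explicit
#' `set.seed()` before the call) fixes the trajectory bit-for-bit.
#'
#' @param cfg a [lattice_config()].
#' @param init optional `lattice_state` to start from; default random dilute.
#' @param equil_frac fraction of `n_steps` used as a discarded equilibration
#'   prefix when `init` is not supplied.
#' @param segment_id integer segment label for the produced frames.
#' @return A `lattice_trajectory`: list with integer frame matrices `x`, `y`,
#'   `o` (frames x N), `segment_ids`, `config`, and the orientation-flip
#'   acceptance rate `flip_acceptance`.
#' @export
run_lattice <- function(cfg, init = NULL, equil_frac = 0.1, segment_id = 1L) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(init)) {
    init <- random_lattice_state(cfg)
    n_eq <- floor(equil_frac * cfg$n_steps)
    if (n_eq > 0) {
      eq <- lattice_run_cpp(cfg$L, cfg$N, cfg$psi_w, cfg$xi, cfg$T,
                            n_eq, as.integer(max(n_eq, 1)), cfg$move_mix,
                            init$x, init$y, init$o, FALSE)
      nf <- nrow(eq$x)
      init <- lattice_state(eq$x[nf, ], eq$y[nf, ], eq$o[nf, ], cfg$L)
    }
  } else {
    stopifnot(inherits(init, "lattice_state"), init$L == cfg$L,
              length(init$x) == cfg$N)
  }
  res <- lattice_run_cpp(cfg$L, cfg$N, cfg$psi_w, cfg$xi, cfg$T,
                         cfg$n_steps, cfg$dt0, cfg$move_mix,
                         init$x, init$y, init$o, TRUE)
  structure(list(x = res$x, y = res$y, o = res$o,
                 segment_ids = rep(as.integer(segment_id), nrow(res$x)),
                 config = cfg, flip_acceptance = res$flip_acceptance),
            class = "lattice_trajectory")
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf("lattice_trajectory: %d frames x %d molecules, %d segment(s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$segment_ids))))
  invisible(x)
}

#' Concatenate independent runs into a multi-segment trajectory
#'
#' Frames keep their within-run order; runs get distinct segment ids so that
#' no cross-run frame pair is ever treated as a dynamical transition.
#'
#' @param ... `lattice_trajectory` objects sharing one configuration shape.
#' @return A combined `lattice_trajectory`.
#' @export
bind_trajectories <- function(...) {
  trajs <- list(...)
  stopifnot(length(trajs) >= 1)
  seg <- unlist(lapply(seq_along(trajs), function(i)
    rep(i, nrow(trajs[[i]]$x))))
  structure(list(x = do.call(rbind, lapply(trajs, `[[`, "x")),
                 y = do.call(rbind, lapply(trajs, `[[`, "y")),
                 o = do.call(rbind, lapply(trajs, `[[`, "o")),
                 segment_ids = as.integer(seg),
                 config = trajs[[1]]$config,
                 flip_acceptance = mean(vapply(trajs, `[[`, 0, "flip_acceptance"))),
            class = "lattice_trajectory")
}

#' Extract one frame of a trajectory as a lattice state
#' @param traj a `lattice_trajectory`.
#' @param k frame index.
#' @return A `lattice_state`.
#' @export
frame_state <- function(traj, k) {
  lattice_state(traj$x[k, ], traj$y[k, ], traj$o[k, ], traj$config$L)
}

#' Number of molecules in the largest aggregate
#'
#' Size of the largest connected component under 4-neighbour adjacency with
#' periodic wrap -- the classical-nucleation-theory order parameter `n`. An
#' isolated molecule is a component of size 1.
#'
#' @param x a `lattice_state` or a `lattice_trajectory`.
#' @return For a state, an integer. For a trajectory, a [cv_series()] of `n`
#'   per frame (channel `"n"`).
#' @export
largest_cluster_size <- function(x) {
  if (inherits(x, "lattice_state")) {
    largest_cluster_cpp(matrix(x$x, nrow = 1), matrix(x$y, nrow = 1), x$L)[1]
  } else if (inherits(x, "lattice_trajectory")) {
    cv_series(as.numeric(largest_cluster_cpp(x$x, x$y, x$config$L)),
              segment_ids = x$segment_ids, channel = "n")
  } else stop("expected a lattice_state or lattice_trajectory")
}

#' Calibrate the dilute/aggregated coexistence temperature
#'
#' At fixed density the model undergoes a first-order transition between a
#' diluted state (small largest cluster) and an aggregated state (one cluster
#' holding most molecules). The coexistence temperature `T*` is located by
#' the equal-weight criterion on the largest-cluster-size histogram: the
#' basin weight `w(T) = P(n >= n_cut)` crosses 1/2 at `T*`, and the `n`
#' histogram there is bimodal.
#'
#' A coarse scan over `T_grid` brackets the crossing, bisection refines it,
#' and the returned object carries the scan diagnostics and the bimodality
#' verdict at the final temperature.
#'
#' @param cfg_base a [lattice_config()]; its `T` is ignored.
#' @param T_grid increasing temperatures spanning the transition.
#' @param run_length MC attempts per probe run.
#' @param n_cut cluster-size threshold separating the basins
#'   (default `N/2`).
#' @param n_bisect bisection refinement steps after bracketing.
#' @param equil_frac discarded equilibration fraction per probe run.
#' @return List with `T_star`, `scan` (data.frame of `T`, `w`), `bimodal`,
#'   `hist` (n-histogram at `T_star`), and `w_star`.
#' @export
calibrate_coexistence_temperature <- function(cfg_base, T_grid,
                                              run_length = 2e6,
                                              n_cut = NULL, n_bisect = 6,
                                              equil_frac = 0.2) {
  stopifnot(length(T_grid) >= 2, !is.unsorted(T_grid))
  if (is.null(n_cut)) n_cut <- cfg_base$N / 2
  probe <- function(T) {
    cfg <- cfg_base
    cfg$T <- T; cfg$n_steps <- run_length; cfg$seed <- NULL
    n <- largest_cluster_size(run_lattice(cfg, equil_frac = equil_frac))
    n$values
  }
  w_of <- function(n) mean(n >= n_cut)
  scan <- data.frame(T = T_grid, w = NA_real_)
  for (i in seq_along(T_grid)) scan$w[i] <- w_of(probe(T_grid[i]))
  # aggregated weight decreases with T; find the bracketing interval
  above <- which(scan$w >= 0.5)
  below <- which(scan$w < 0.5)
  if (!length(above) || !length(below))
    stop("no temperature in T_grid yields coexistence: ",
         "w(T) never crosses 1/2 (all ",
         if (!length(above)) "dilute" else "aggregated", ")")
  lo <- T_grid[max(above)]; hi <- T_grid[min(below[below > max(above)])]
  if (!is.finite(hi)) stop("w(T) is not monotone enough to bracket T*")
  for (b in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    w <- w_of(probe(mid))
    scan <- rbind(scan, data.frame(T = mid, w = w))
    if (w >= 0.5) lo <- mid else hi <- mid
  }
  T_star <- (lo + hi) / 2
  n_star <- probe(T_star)
  h <- tabulate(pmax(1, round(n_star)), nbins = cfg_base$N)
  list(T_star = T_star, scan = scan[order(scan$T), ],
       bimodal = .is_bimodal(h), hist = h, w_star = w_of(n_star))
}

# smoothed two-peak check on an integer histogram
.is_bimodal <- function(counts, smooth = 2L, dip_ratio = 0.7) {
  k <- stats::filter(counts, rep(1 / (2 * smooth + 1), 2 * smooth + 1),
                     sides = 2)
  k[is.na(k)] <- 0
  k <- as.numeric(k)
  peaks <- which(diff(sign(diff(c(-Inf, k, -Inf)))) == -2)
  peaks <- peaks[k[peaks] > 0.01 * max(k)]
  if (length(peaks) < 2) return(FALSE)
  p1 <- peaks[1]; p2 <- peaks[length(peaks)]
  dip <- min(k[p1:p2])
  dip < dip_ratio * min(k[p1], k[p2])
}
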
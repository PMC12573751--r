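#' Collective-variable time series
#'
#' A scalar observable per frame, aligned with the segmentation of the
#' trajectory it came from. `channel` names the observable: either the
#' sorted-distance-matrix index `"d(i,j)"` or a named observable such as
#' `"n"`.
#'
#' @param values numeric vector, one value per frame.
#' @param segment_ids integer run label per frame (default: one segment).
#' @param channel channel label.
#' @return An object of class `cv_series`.
#' @export
cv_series <- function(values, segment_ids = NULL, channel = "cv") {
  if (is.null(segment_ids)) segment_ids <- rep(1L, length(values))
  stopifnot(length(values) == length(segment_ids))
  structure(list(values = as.numeric(values),
                 segment_ids = as.integer(segment_ids),
                 channel = channel),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("cv_series '%s': %d frames, %d segment(s)\n",
              x$channel, length(x$values), length(unique(x$segment_ids))))
  invisible(x)
}

#' Minimum-image Euclidean distance on a periodic square box
#'
#' Each per-axis displacement is mapped into `[-L/2, L/2]` before the
#' Euclidean norm is taken.
#'
#' @param p1,p2 numeric length-2 coordinates in `[0, L)`.
#' @param L box side length.
#' @return Scalar distance.
#' @export
min_image_distance <- function(p1, p2, L) {
  d <- abs(p1 - p2)
  d <- pmin(d, L - d)
  sqrt(sum(d^2))
}

#' Minimum-image distance matrix of a lattice state
#'
#' @param state a [lattice_state()].
#' @return An `N x N` symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(state) {
  L <- state$L
  dx <- abs(outer(state$x, state$x, "-")); dx <- pmin(dx, L - dx)
  dy <- abs(outer(state$y, state$y, "-")); dy <- pmin(dy, L - dy)
  sqrt(dx^2 + dy^2)
}

#' Sorted distance matrix: permutationally invariant CV channels
#'
#' Sorts the full distance matrix sequentially along its two axes -- first
#' inside each column, then inside each row (ascending). The result depends
#' only on the multiset structure of the distances, not on molecule labels,
#' so each entry `(i, j)` of the sorted matrix is a translation-, rotation-
#' and permutation-invariant collective variable.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return Matrix of the same shape with nondecreasing rows.
#' @export
sorted_distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  s <- apply(d, 2, sort)            # inside each column
  t(apply(s, 1, sort))              # then inside each row
}

#' Build the pool of invariant CV channels for a trajectory
#'
#' Evaluates per-channel mean and variance of the sorted distance matrix in
#' one streaming pass over all frames, and marks constant channels (for
#' example the all-zero first row produced by the diagonal) as dropped.
#' Channel values are not stored; they are extracted lazily per optimizer
#' iteration with [extract_channels()], which keeps memory bounded for large
#' `N` and long trajectories.
#'
#' @param traj a `lattice_trajectory`.
#' @param var_tol variance below which a channel is considered constant.
#' @return A `cv_pool`: list with `channels` (surviving `(i, j)` index
#'   matrix), `dropped` (count), `mean`, `sd` per surviving channel, and the
#'   trajectory reference.
#' @export
build_cv_pool <- function(traj, var_tol = 1e-12) {
  stopifnot(inherits(traj, "lattice_trajectory"))
  st <- sorted_cv_stats_cpp(traj$x, traj$y, traj$config$L)
  keep <- which(st$var > var_tol, arr.ind = TRUE)
  if (nrow(keep) == 0)
    stop("all CV channels are constant; trajectory carries no information")
  structure(list(channels = unname(keep),
                 dropped = length(st$var) - nrow(keep),
                 mean = st$mean[keep], sd = sqrt(st$var[keep]),
                 traj = traj),
            class = "cv_pool")
}

#' @export
print.cv_pool <- function(x, ...) {
  cat(sprintf("cv_pool: %d surviving channels (%d constant dropped)\n",
              nrow(x$channels), x$dropped))
  invisible(x)
}

#' Number of channels in a CV pool
#' @param pool a `cv_pool` or `cv_pool_matrix`.
#' @return Integer count.
#' @export
n_channels <- function(pool) UseMethod("n_channels")

#' @export
n_channels.cv_pool <- function(pool) nrow(pool$channels)

#' @export
n_channels.cv_pool_matrix <- function(pool) ncol(pool$values)

#' Extract CV channel time series from a pool
#'
#' For a lattice-backed pool this recomputes the sorted distance matrix for
#' every frame in one compiled pass and picks the requested entries.
#'
#' @param pool a CV pool.
#' @param ids integer channel indices into the pool.
#' @return Numeric matrix, frames x length(ids).
#' @export
extract_channels <- function(pool, ids) UseMethod("extract_channels")

#' @export
extract_channels.cv_pool <- function(pool, ids) {
  idx <- pool$channels[ids, , drop = FALSE]
  sorted_cv_extract_cpp(pool$traj$x, pool$traj$y, pool$traj$config$L,
                        idx)
}

#' @export
extract_channels.cv_pool_matrix <- function(pool, ids) {
  pool$values[, ids, drop = FALSE]
}

#' In-memory CV pool from explicit series
#'
#' Wraps precomputed CV time series (a numeric matrix, one column per
#' channel, or a list of vectors / `cv_series`) in the pool interface used
#' by [optimize_rc()].
#'
#' @param x matrix, list of numeric vectors, or list of [cv_series()].
#' @param channels optional channel labels.
#' @return A `cv_pool_matrix`.
#' @export
cv_pool_matrix <- function(x, channels = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    x <- lapply(x, function(v) if (inherits(v, "cv_series")) v$values else v)
    x <- do.call(cbind, x)
  }
  stopifnot(is.matrix(x))
  if (is.null(channels)) channels <- paste0("cv", seq_len(ncol(x)))
  structure(list(values = x, channels = channels), class = "cv_pool_matrix")
}

#' Channel labels of pool members
#' @param pool a CV pool.
#' @param ids integer channel indices.
#' @return Character labels.
#' @export
channel_labels <- function(pool, ids) UseMethod("channel_labels")

#' @export
channel_labels.cv_pool <- function(pool, ids) {
  sprintf("d(%d,%d)", pool$channels[ids, 1], pool$channels[ids, 2])
}

#' @export
channel_labels.cv_pool_matrix <- function(pool, ids) {
  pool$channels[ids]
}

#' Draw a random CV channel from a pool
#'
#' Uniform over surviving channels; reproducible under `set.seed()`.
#'
#' @param pool a CV pool.
#' @param traj_segments segment ids for the produced series (lattice pools
#'   carry their own).
#' @return A [cv_series()] for the drawn channel.
#' @export
sample_cv <- function(pool, traj_segments = NULL) {
  id <- sample.int(n_channels(pool), 1)
  v <- extract_channels(pool, id)[, 1]
  seg <- if (inherits(pool, "cv_pool")) pool$traj$segment_ids else traj_segments
  lab <- if (inherits(pool, "cv_pool"))
    sprintf("d(%d,%d)", pool$channels[id, 1], pool$channels[id, 2])
  else pool$channels[id]
  cv_series(v, seg, lab)
}
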
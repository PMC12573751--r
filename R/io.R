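#' Write a CV or RC series to the columnar text format
#'
#' The exchange format is a comma-separated table with columns
#' `frame`, `segment`, `value` and, for RC series, `in_A`, `in_B`
#' (0/1). Values are written with 17 significant digits so that a
#' write/read round trip is bit-identical.
#'
#' @param x a [cv_series()] or [rc_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  if (inherits(x, "rc_series")) {
    dt <- data.table::data.table(
      frame = seq_along(x$r), segment = x$segment_ids,
      value = sprintf("%.17g", x$r),
      in_A = as.integer(x$in_A), in_B = as.integer(x$in_B))
  } else if (inherits(x, "cv_series")) {
    dt <- data.table::data.table(
      frame = seq_along(x$values), segment = x$segment_ids,
      value = sprintf("%.17g", x$values))
  } else stop("expected a cv_series or rc_series")
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a CV or RC series from the columnar text format
#'
#' @param path file written by [write_series()] (or any table with columns
#'   `frame`, `segment`, `value` and optionally `in_A`, `in_B`).
#' @return An [rc_series()] when boundary columns are present, otherwise a
#'   [cv_series()].
#' @export
read_series <- function(path) {
  dt <- data.table::fread(path)
  need <- c("frame", "segment", "value")
  if (!all(need %in% names(dt)))
    stop("malformed series file: need columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(dt$value))
  if (length(bad))
    stop("non-finite value at row ", bad[1], " of ", path)
  if (all(c("in_A", "in_B") %in% names(dt)))
    rc_series(dt$value, as.logical(dt$in_A), as.logical(dt$in_B),
              dt$segment)
  else
    cv_series(dt$value, dt$segment)
}

#' Write a lattice trajectory to plain text
#'
#' Long-format comma-separated table with columns `frame`, `segment`,
#' `molecule`, `x`, `y`, `o`, preceded by comment header lines (`#`)
#' recording the lattice configuration.
#'
#' @param traj a `lattice_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cfg <- traj$config
  hdr <- sprintf("# L=%d N=%d xi=%g psi_w=%g T=%g dt0=%d",
                 cfg$L, cfg$N, cfg$xi, cfg$psi_w, cfg$T, cfg$dt0)
  writeLines(hdr, path)
  nf <- nrow(traj$x); N <- ncol(traj$x)
  dt <- data.table::data.table(
    frame = rep(seq_len(nf), each = N),
    segment = rep(traj$segment_ids, each = N),
    molecule = rep(seq_len(N), nf),
    x = as.integer(t(traj$x)), y = as.integer(t(traj$y)),
    o = as.integer(t(traj$o)))
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a lattice trajectory written by [write_trajectory()]
#'
#' @param path input file path.
#' @return A `lattice_trajectory` (configuration restored from the header;
#'   `n_steps`/`seed` are not round-tripped).
#' @importFrom data.table fread fwrite data.table
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[A-Za-z_0-9]+=[-0-9.eE]+", hdr))[[1]]
  vals <- as.numeric(sub(".*=", "", kv))
  names(vals) <- sub("=.*", "", kv)
  dt <- data.table::fread(path, skip = 1)
  nf <- max(dt$frame); N <- max(dt$molecule)
  ord <- order(dt$frame, dt$molecule)
  dt <- dt[ord, ]
  cfg <- lattice_config(L = vals[["L"]], N = vals[["N"]], T = vals[["T"]],
                        xi = vals[["xi"]], psi_w = vals[["psi_w"]],
                        dt0 = vals[["dt0"]], n_steps = 1)
  structure(list(
    x = matrix(dt$x, nf, N, byrow = TRUE),
    y = matrix(dt$y, nf, N, byrow = TRUE),
    o = matrix(dt$o, nf, N, byrow = TRUE),
    segment_ids = as.integer(dt$segment[seq(1, nrow(dt), by = N)]),
    config = cfg, flip_acceptance = NA_real_),
    class = "lattice_trajectory")
}
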
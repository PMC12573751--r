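#!/usr/bin/env Rscript
# Regenerates inst/extdata/tstar_calibration.json: desk-scale (L = 40,
# N = 40) equal-weight coexistence temperatures per anisotropy, with scan
# diagnostics. Full-scale (L = 200, N = 400) temperatures are calibrated by
# scripts/full_scale.R at run time.
#
#   Rscript scripts/calibrate_tstar.R [--seed 1] [--out inst/extdata/tstar_calibration.json]

suppressPackageStartupMessages(library(committorlab))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_path <- get_arg("--out", "inst/extdata/tstar_calibration.json")

brackets <- list(`1` = c(0.33, 0.43), `3` = c(0.90, 1.10),
                 `5` = c(1.45, 1.80), `7` = c(2.10, 2.55))

entries <- list()
for (xi_chr in names(brackets)) {
  xi <- as.numeric(xi_chr)
  b <- brackets[[xi_chr]]
  cfg <- lattice_config(L = 40, N = 40, T = mean(b), xi = xi, dt0 = 400L,
                        n_steps = 1e7)
  set.seed(seed + 1000L * xi)
  cal <- calibrate_coexistence_temperature(
    cfg, T_grid = seq(b[1], b[2], length.out = 6),
    run_length = 8e6, n_bisect = 5, equil_frac = 0.3)
  message(sprintf("xi = %g: T* = %.4f (bimodal %s, w* = %.2f)",
                  xi, cal$T_star, cal$bimodal, cal$w_star))
  entries[[xi_chr]] <- list(xi = xi, T_star = round(cal$T_star, 4),
                            bimodal = cal$bimodal,
                            w_star = round(cal$w_star, 3))
}

out <- list(
  description = paste("Equal-weight dilute/aggregated coexistence",
                      "temperatures of the anisotropic lattice model,",
                      "desk scale (L = 40, N = 40), recalibrated in-repo",
                      "by calibrate_coexistence_temperature()."),
  method = "equal-weight largest-cluster histogram, bisection on P(n >= N/2)",
  L = 40, N = 40, dt0 = 400, run_length = 8e6, seed = seed,
  units = "k_B = 1, energies in psi_w",
  note = paste("At this system size the transition is strongly rounded:",
               "near T* the largest-cluster histogram may not show two",
               "barrier-separated minima (bimodal = false), and T* carries",
               "a seed-to-seed spread of about 0.01-0.02."),
  calibrations = entries)
jsonlite::write_json(out, out_path, auto_unbox = TRUE, pretty = TRUE,
                     digits = NA)
message("wrote ", out_path)
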
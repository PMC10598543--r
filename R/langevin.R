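#' Simulate a linker ensemble with the single-bead model
#'
#' Runs Langevin dynamics of a one-bead-per-residue chain: harmonic bonds
#' (equilibrium length `bond_length`), Ashbaugh-Hatch stickiness-scaled
#' Lennard-Jones interactions using the M1 lambda set, and Debye-Hueckel
#' screened electrostatics, all truncated and shifted at the cutoff.
#' Integration uses BAOAB splitting; the chain starts fully extended along
#' x. Bonded neighbours (i, i+1) are excluded from the nonbonded sums. The
#' first `equilibration_fraction` of the trajectory is discarded and the
#' remaining frames are returned with uniform weights.
#'
#' The run is bitwise deterministic for a fixed `config$seed` on a given
#' platform: the integrator uses its own counter-free generator seeded from
#' the config, independent of R's RNG state.
#'
#' @param sequence amino-acid sequence (one-letter codes).
#' @param config a [model_config].
#' @param include_ah,include_dh logical switches for the two nonbonded
#'   terms; disabling both leaves a bonds-only phantom chain (useful as an
#'   ideal-chain reference with nu = 0.5).
#' @param verbose print a log line every 1e4 steps' worth of progress.
#' @return An object of class `ensemble`: list with `coordinates`
#'   (frames x beads x 3 array, nm), `weights` (uniform, sum 1),
#'   `sequence`, `config`, `time_per_frame` (ps), `temperature_mean`
#'   (production-run estimate), and `log` (step/potential/temperature
#'   table).
#' @examples
#' \donttest{
#' cfg <- model_config(total_time = 1, seed = 7)
#' ens <- run_langevin("GTPGSTGPAG", cfg)
#' }
#' @export
run_langevin <- function(sequence, config = model_config(),
                         include_ah = TRUE, include_dh = TRUE,
                         verbose = FALSE) {
  letters <- check_sequence(sequence)
  n <- length(letters)
  if (n < 2) stop("need at least 2 residues")
  params <- residue_params(config$ph)[letters, ]

  dt <- config$timestep
  nsteps <- round(config$total_time * 1000 / dt)
  stride_steps <- max(1L, round(config$frame_stride / dt))
  kap <- debye_kappa(config$ionic_strength, config$temperature)
  coulomb_pref <- bjerrum_length(config$temperature) * KB_KJ *
    config$temperature

  x0 <- cbind((seq_len(n) - 1) * config$bond_length, 0, 0)
  res <- langevin_run_cpp(
    x0, params$sigma, params$lambda, params$charge, params$mass,
    config$temperature, kap, coulomb_pref, config$ah_epsilon,
    config$nonbonded_cutoff, config$bond_length, config$bond_spring_k,
    dt, config$friction, nsteps, as.integer(stride_steps),
    if (verbose) 10000L else 0L, config$seed, include_ah, include_dh)

  if (isTRUE(res$aborted))
    stop(sprintf(
      "integration diverged at step %.0f (max finite force %.3g kJ/mol/nm)",
      res$abort_step, res$abort_max_force))
  if (verbose && nrow(res$log))
    apply(res$log, 1, function(r) cat(sprintf(
      "step %-10.0f U = %12.3f kJ/mol  T = %7.2f K\n", r[1], r[2], r[3])))

  nf <- as.integer(res$n_frames)
  frames <- res$frames[seq_len(nf), , , drop = FALSE]
  first <- floor(config$equilibration_fraction * nf) + 1L
  keep <- first:nf
  coords <- frames[keep, , , drop = FALSE]
  tmean <- mean(res$temperature_series[keep])

  structure(list(
    coordinates = coords,
    weights = rep(1 / length(keep), length(keep)),
    sequence = sequence,
    config = config,
    time_per_frame = stride_steps * dt,
    temperature_mean = tmean,
    include_ah = include_ah, include_dh = include_dh,
    log = res$log
  ), class = "ensemble")
}

#' Construct an ensemble from raw coordinates
#'
#' Mainly for tests and for loading externally produced trajectories.
#'
#' @param coordinates frames x beads x 3 array (nm).
#' @param sequence amino-acid sequence; beads must match its length.
#' @param weights per-frame weights; default uniform.
#' @param config optional [model_config] metadata.
#' @return An `ensemble`.
#' @export
ensemble <- function(coordinates, sequence, weights = NULL, config = NULL) {
  stopifnot(length(dim(coordinates)) == 3, dim(coordinates)[3] == 3)
  check_sequence(sequence)
  if (dim(coordinates)[2] != nchar(sequence))
    stop("bead count does not match sequence length")
  nf <- dim(coordinates)[1]
  if (is.null(weights)) weights <- rep(1 / nf, nf)
  if (length(weights) != nf || any(weights < 0))
    stop("weights must be non-negative, one per frame")
  weights <- weights / sum(weights)
  structure(list(coordinates = coordinates, weights = weights,
                 sequence = sequence, config = config,
                 time_per_frame = NA_real_, temperature_mean = NA_real_),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coordinates)
  cat(sprintf("<ensemble> %d frames x %d beads (N = %d residues)\n",
              d[1], d[2], nchar(x$sequence)))
  if (!is.na(x$time_per_frame))
    cat(sprintf("  %.4g ps/frame, mean production temperature %.1f K\n",
                x$time_per_frame, x$temperature_mean))
  invisible(x)
}

#' @export
summary.ensemble <- function(object, ...) {
  rg <- radius_of_gyration(object)
  cat(sprintf("Ensemble of %d frames, N = %d\n",
              dim(object$coordinates)[1], nchar(object$sequence)))
  cat(sprintf("  Rg = %.3f +/- %.3f nm (weighted mean +/- SD)\n",
              rg$mean, rg$sd))
  ree <- end_to_end_distances(object)
  cat(sprintf("  Ree = %.3f nm (weighted mean)\n",
              weighted.mean(ree, object$weights)))
  invisible(list(rg = rg, ree_mean = weighted.mean(ree, object$weights)))
}

#' Per-frame end-to-end distances
#'
#' @param ens an `ensemble`.
#' @return Numeric vector, nm.
#' @export
end_to_end_distances <- function(ens) {
  co <- ens$coordinates
  n <- dim(co)[2]
  sqrt((co[, n, 1] - co[, 1, 1])^2 + (co[, n, 2] - co[, 1, 2])^2 +
         (co[, n, 3] - co[, 1, 3])^2)
}

#' Pairwise bead distances averaged over frames
#'
#' Weighted-mean interbead distance for every residue pair, used for the
#' scaling-exponent fit.
#'
#' @param ens an `ensemble`.
#' @return beads x beads symmetric matrix of mean distances (nm).
#' @export
mean_pairwise_distances <- function(ens) {
  co <- ens$coordinates
  nf <- dim(co)[1]; n <- dim(co)[2]
  acc <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    d <- as.matrix(stats::dist(co[f, , ]))
    acc <- acc + ens$weights[f] * d
  }
  acc
}

#' Export ensemble frames as multi-model XYZ
#'
#' @param ens an `ensemble`.
#' @param path output file.
#' @param stride keep every `stride`-th frame.
#' @export
write_xyz <- function(ens, path, stride = 1L) {
  co <- ens$coordinates
  n <- dim(co)[2]
  letters <- strsplit(ens$sequence, "")[[1]]
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq(1, dim(co)[1], by = stride)) {
    writeLines(c(as.character(n), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.5f %.5f %.5f", letters,
                       co[f, , 1], co[f, , 2], co[f, , 3]), con)
  }
  invisible(path)
}

#' Total potential energy of one frame, decomposed by term
#'
#' @param ens an `ensemble`.
#' @param frame frame index.
#' @return Named numeric: `bond`, `ah`, `dh`, `total` (kJ/mol). Terms that
#'   were disabled in the simulation still report the energy the
#'   configuration would have under the full model unless `respect_flags`.
#' @param respect_flags zero out terms disabled when the ensemble was run.
#' @export
frame_energy <- function(ens, frame = 1L, respect_flags = FALSE) {
  cfg <- ens$config
  if (is.null(cfg)) stop("ensemble has no model_config metadata")
  letters <- strsplit(ens$sequence, "")[[1]]
  params <- residue_params(cfg$ph)[letters, ]
  e <- config_energy_cpp(
    ens$coordinates[frame, , ], params$sigma, params$lambda, params$charge,
    debye_kappa(cfg$ionic_strength, cfg$temperature),
    bjerrum_length(cfg$temperature) * KB_KJ * cfg$temperature,
    cfg$ah_epsilon, cfg$nonbonded_cutoff, cfg$bond_length, cfg$bond_spring_k)
  if (respect_flags) {
    if (isFALSE(ens$include_ah)) e["ah"] <- 0
    if (isFALSE(ens$include_dh)) e["dh"] <- 0
    e["total"] <- e["bond"] + e["ah"] + e["dh"]
  }
  e
}
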
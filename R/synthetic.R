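#' Default composition of low-complexity linker sequences
#'
#' Approximate residue frequencies of natural LPMO interdomain linkers,
#' which are glycine/threonine/proline-rich with a slight net negative
#' charge. Stored as data so generators never hard-code it.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_linker_composition <- function() {
  c(G = 0.22, T = 0.18, P = 0.14, S = 0.12, A = 0.10,
    D = 0.06, N = 0.05, V = 0.05, E = 0.04, Q = 0.04)
}

#' Generate synthetic linker-like sequences
#'
#' Draws sequence lengths from a normal distribution (mean 40, SD 11)
#' clipped to [22, 72] and rounded — matching the length statistics of
#' natural AA10-linker-CBM2 linker sets — and residues i.i.d. from a
#' low-complexity composition. Deterministic for a given seed.
#'
#' @param n_sequences how many sequences.
#' @param length_mean,length_sd,length_min,length_max length distribution.
#' @param composition named probability vector over residue letters;
#'   default [default_linker_composition].
#' @param seed integer seed.
#' @return List of [linker_record]s (ids `syn_001`, ...).
#' @export
generate_linker_sequences <- function(n_sequences, length_mean = 40,
                                      length_sd = 11, length_min = 22,
                                      length_max = 72,
                                      composition = default_linker_composition(),
                                      seed = 1L) {
  stopifnot(n_sequences >= 1, length_min <= length_max)
  if (any(composition < 0) || sum(composition) <= 0)
    stop("degenerate composition")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1")
  bad <- setdiff(names(composition), AA_ALPHABET)
  if (length(bad)) stop("non-canonical letters in composition: ",
                        paste(bad, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- round(pmin(pmax(rnorm(n_sequences, length_mean, length_sd),
                          length_min), length_max))
  lapply(seq_len(n_sequences), function(k) {
    seqk <- paste(sample(names(composition), lens[k], replace = TRUE,
                         prob = composition), collapse = "")
    linker_record(id = sprintf("syn_%03d", k), parent_id = "synthetic",
                  sequence = seqk, start_res = 1L, end_res = lens[k])
  })
}

# Save/restore R's global RNG state so generators are pure in (config, seed)
# without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Noise model for synthetic observables
#'
#' @param relative_sd multiplicative noise SD (fraction of signal).
#' @param baseline_sd additive noise SD (intensity units; for SAXS a
#'   value of NA defaults to 1e-4 * I(0) at generation time).
#' @param seed integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.01, baseline_sd = NA_real_,
                        seed = 1L) {
  stopifnot(relative_sd >= 0, is.na(baseline_sd) || baseline_sd >= 0)
  structure(list(relative_sd = relative_sd, baseline_sd = baseline_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Synthetic noisy SAXS profile from a known ensemble
#'
#' Computes the Debye-equation profile of the ensemble under the given
#' (optionally planted, non-uniform) frame weights, then adds Gaussian
#' noise with sigma(q) = relative_sd * I(q) + baseline_sd and emits the
#' sigma column. Enables Guinier and reweighting tests without beamline
#' data.
#'
#' @param ens an `ensemble`.
#' @param q_grid q values, nm^-1.
#' @param noise a [noise_model].
#' @param planted_weights per-frame weights defining the "true" ensemble
#'   average; default the ensemble's own (uniform) weights.
#' @param form_factors passed to [debye_scattering].
#' @return A [scattering_profile] with sigma.
#' @export
generate_saxs_from_ensemble <- function(ens, q_grid,
                                        noise = noise_model(),
                                        planted_weights = NULL,
                                        form_factors = NULL) {
  e2 <- ens
  if (!is.null(planted_weights)) {
    stopifnot(length(planted_weights) == dim(ens$coordinates)[1])
    e2$weights <- planted_weights / sum(planted_weights)
  }
  prof <- debye_scattering(e2, q_grid, form_factors = form_factors)
  base <- if (is.na(noise$baseline_sd)) 1e-4 * max(prof$intensity)
  else noise$baseline_sd
  sig <- noise$relative_sd * prof$intensity + base
  if (all(sig == 0)) sig <- rep(1e-12, length(sig))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  scattering_profile(prof$q, prof$intensity + rnorm(length(sig), 0, sig),
                     sigma = sig)
}

#' Synthetic Stejskal-Tanner diffusion decay
#'
#' Exact exponential attenuation for a known diffusion coefficient on the
#' given gradient ramp, with multiplicative Gaussian noise.
#'
#' @param dt translational diffusion coefficient, m^2/s.
#' @param ramp a [diffusion_decay] describing the gradient geometry
#'   (default [pfg_ramp]: 32 points, 2-95% of 53.5 G/cm, delta = 2 ms,
#'   Delta = 150 ms).
#' @param noise a [noise_model] (`relative_sd` used; 0 for noise-free).
#' @param i0 zero-gradient intensity.
#' @return The ramp with intensities filled in.
#' @export
generate_diffusion_decay <- function(dt, ramp = pfg_ramp(),
                                     noise = noise_model(relative_sd = 0),
                                     i0 = 1) {
  stopifnot(dt > 0)
  ideal <- i0 * exp(-dt * st_bvalues(ramp))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  fac <- 1 + rnorm(length(ideal), 0, noise$relative_sd)
  ramp$intensities <- ideal * fac
  ramp
}
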
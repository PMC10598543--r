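#' Write a run manifest
#'
#' Records the command, the fully resolved configuration, every RNG seed
#' used, the package version and start/end timestamps as JSON next to the
#' outputs, so any run can be reproduced bit for bit.
#'
#' @param command name of the command.
#' @param config_snapshot list of resolved settings.
#' @param seeds named list/vector of all seeds used.
#' @param path output JSON path.
#' @param started,finished POSIXct timestamps.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, config_snapshot, seeds, path,
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    command = command,
    config_snapshot = config_snapshot,
    seeds = as.list(seeds),
    tool_version = as.character(utils::packageVersion("linkersim")),
    timestamps = list(start = format(started, "%Y-%m-%dT%H:%M:%S%z"),
                      end = format(finished, "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Survey linkers from files
#'
#' File-level wrapper chaining FASTA + domain-TSV input through
#' [survey_linkers] to a descriptor TSV mirroring a survey descriptor table
#' columns (N, NCPR, fraction expanding, fraction proline).
#'
#' @param fasta_path parent sequences (FASTA).
#' @param domains_path domain annotations (TSV).
#' @param out_path output descriptor TSV; NULL to skip writing.
#' @return The descriptor data.frame (invisibly when writing).
#' @export
survey_files <- function(fasta_path, domains_path, out_path = NULL) {
  seqs <- read_fasta_sequences(fasta_path)
  ann <- read_domain_annotations(domains_path)
  res <- survey_linkers(seqs, ann)
  if (!is.null(out_path)) {
    write_descriptor_tsv(res, out_path)
    return(invisible(res))
  }
  res
}

#' Full reweighting workflow against a SAXS file
#'
#' Computes per-frame Debye profiles for the ensemble on the experimental
#' q grid, scans theta, and reports the reweighted radius of gyration at
#' the chosen theta.
#'
#' @param ens an `ensemble`.
#' @param exp a [scattering_profile] with sigma (or a path readable by
#'   [read_saxs]).
#' @param theta_grid passed to [theta_scan].
#' @param q_units used when `exp` is a path.
#' @return List of class `bme_report`: `scan` (a `theta_scan`), `best`
#'   (the `bme_fit` at the smallest theta with chi2r closest to 1 from
#'   above, or the smallest chi2r), `rg_prior`, `rg_reweighted`.
#' @export
bme_workflow <- function(ens, exp, theta_grid = 10^seq(-1, 3, length.out = 15),
                         q_units = c("nm", "A")) {
  if (is.character(exp)) exp <- read_saxs(exp, q_units = match.arg(q_units))
  if (all(is.na(exp$sigma)))
    stop("SAXS input lacks the sigma column required for reweighting")
  calc <- debye_scattering(ens, exp$q, return_matrix = TRUE)
  scan <- theta_scan(calc$matrix, exp, theta_grid,
                     prior_weights = ens$weights)
  ok <- which(!scan$table$failed)
  if (!length(ok)) stop("all theta values failed")
  above <- ok[scan$table$chi2_after[ok] >= 1]
  pick <- if (length(above)) above[which.min(scan$table$chi2_after[above])]
  else ok[which.min(abs(scan$table$chi2_after[ok] - 1))]
  best <- scan$results[[pick]]
  rg_prior <- radius_of_gyration(ens)$mean
  ens_rw <- ens; ens_rw$weights <- best$weights
  structure(list(scan = scan, best = best, rg_prior = rg_prior,
                 rg_reweighted = radius_of_gyration(ens_rw)$mean),
            class = "bme_report")
}

#' @export
print.bme_report <- function(x, ...) {
  cat("<bme_report>\n  L-curve:\n")
  print(x$scan$table, row.names = FALSE)
  cat(sprintf("  selected theta = %g: chi2r %.4g -> %.4g, phi_eff %.3f\n",
              x$best$theta, x$best$chi2_before, x$best$chi2_after,
              x$best$phi_eff))
  cat(sprintf("  Rg: %.3f nm (prior) -> %.3f nm (reweighted)\n",
              x$rg_prior, x$rg_reweighted))
  invisible(x)
}

#' Hydrodynamic-radius workflow from decay files
#'
#' Fits analyte and reference decays and forms the reference-based Rh.
#'
#' @param analyte,reference [diffusion_decay]s or paths to decay files.
#' @param rh_reference Angstrom.
#' @return An `rh_result` with the two `diffusion_fit`s attached.
#' @export
rh_workflow <- function(analyte, reference, rh_reference = 2.12) {
  if (is.character(analyte)) analyte <- read_decay(analyte)
  if (is.character(reference)) reference <- read_decay(reference)
  fa <- fit_diffusion(analyte)
  fr <- fit_diffusion(reference)
  out <- rh_from_reference(fa, fr, rh_reference)
  out$fit_analyte <- fa
  out$fit_reference <- fr
  out
}
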
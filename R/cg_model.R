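# Physical constants (MD units: nm, ps, g/mol, kJ/mol)
KB_KJ <- 0.0083144621          # Boltzmann constant, kJ mol^-1 K^-1
COULOMB_KJ_NM <- 138.935458    # e^2 N_A / (4 pi eps0), kJ mol^-1 nm

#' Residue parameter table for the single-bead model
#'
#' Loads the bundled per-residue parameters (bead diameter sigma in nm,
#' "M1" stickiness lambda, charge in elementary units, residue mass in
#' g/mol). Histidine's charge is replaced at run time by the pH-dependent
#' value from [histidine_charge]; aspartate/glutamate carry -1 and
#' lysine/arginine +1; terminal residues carry no extra termini charges.
#'
#' @param ph solution pH used to set the histidine charge.
#' @return data.frame keyed by `letter` with columns `sigma`, `lambda`,
#'   `charge`, `mass`.
#' @export
residue_params <- function(ph = 6.5) {
  path <- system.file("extdata", "single_bead_m1_params.tsv",
                      package = "linkersim", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$charge[tab$letter == "H"] <- histidine_charge(ph)
  rownames(tab) <- tab$letter
  tab
}

#' pH-dependent histidine charge
#'
#' Henderson-Hasselbalch logistic with an imidazole pKa of 6.0:
#' q(pH) = 1 / (1 + 10^(pH - 6)).
#'
#' @param ph solution pH, in (0, 14).
#' @return Fractional positive charge in (0, 1).
#' @examples
#' histidine_charge(6.0)  # 0.5
#' @export
histidine_charge <- function(ph) {
  stopifnot(ph > 0, ph < 14)
  1 / (1 + 10^(ph - 6.0))
}

#' Temperature-dependent dielectric constant of water
#'
#' Empirical polynomial fit of the static relative permittivity of water;
#' about 78.5 at 298 K.
#'
#' @param temperature K.
#' @return Dimensionless relative permittivity.
#' @export
water_dielectric <- function(temperature) {
  t <- temperature
  5321 / t + 233.76 - 0.9297 * t + 1.417e-3 * t^2 - 8.292e-7 * t^3
}

#' Bjerrum length of water
#'
#' @param temperature K.
#' @return Bjerrum length in nm (about 0.71 nm at 298 K).
#' @export
bjerrum_length <- function(temperature) {
  COULOMB_KJ_NM / (water_dielectric(temperature) * KB_KJ * temperature)
}

#' Inverse Debye screening length
#'
#' kappa = sqrt(8 pi lB N_A I) for a 1:1 electrolyte of ionic strength I,
#' with the Bjerrum length lB at the given temperature. At 0.1 M and 298 K
#' the screening length 1/kappa is about 0.96 nm.
#'
#' @param ionic_strength mol/L, > 0.
#' @param temperature K.
#' @return kappa in nm^-1.
#' @export
debye_kappa <- function(ionic_strength, temperature = 298) {
  if (ionic_strength <= 0) stop("ionic_strength must be > 0")
  n_per_nm3 <- ionic_strength * 6.02214076e-4 * 1000  # ions per nm^3
  sqrt(8 * pi * bjerrum_length(temperature) * n_per_nm3)
}

#' Simulation configuration for the single-bead model
#'
#' Defaults follow the solution conditions of the linker study: 298 K,
#' ionic strength 0.1 M, pH 6.5, equilibrium bond length 0.38 nm, bond
#' spring 8033 kJ mol^-1 nm^-2, Ashbaugh-Hatch epsilon 0.8368 kJ/mol, 4 nm
#' cutoff for both nonbonded terms, 5 fs time step, friction 0.01 ps^-1,
#' 200 nm box (recorded as metadata; boundaries are open). The default
#' desk-scale sampling is 1000 ns total with the first 10% discarded as
#' equilibration and one frame kept every 100 ps.
#'
#' @param temperature K.
#' @param ionic_strength mol/L.
#' @param ph pH units.
#' @param bond_length equilibrium bond length lb, nm.
#' @param bond_spring_k harmonic bond constant, kJ mol^-1 nm^-2.
#' @param ah_epsilon Ashbaugh-Hatch well depth, kJ/mol.
#' @param nonbonded_cutoff nm.
#' @param timestep ps (0.005 ps = 5 fs; values above 0.005 up to 0.010
#'   are accepted with a warning).
#' @param friction ps^-1.
#' @param box_edge nm, metadata only.
#' @param total_time ns.
#' @param equilibration_fraction fraction of the run discarded, in [0, 1).
#' @param frame_stride ps between stored frames.
#' @param seed integer RNG seed for the integrator.
#' @return Object of class `model_config`.
#' @export
model_config <- function(temperature = 298, ionic_strength = 0.1, ph = 6.5,
                         bond_length = 0.38, bond_spring_k = 8033,
                         ah_epsilon = 0.8368, nonbonded_cutoff = 4,
                         timestep = 0.005, friction = 0.01, box_edge = 200,
                         total_time = 1000, equilibration_fraction = 0.1,
                         frame_stride = 100, seed = 1L) {
  stopifnot(temperature > 0, ionic_strength > 0, ph > 0, ph < 14,
            bond_length > 0, bond_spring_k > 0, ah_epsilon > 0,
            timestep > 0, friction > 0, total_time > 0,
            equilibration_fraction >= 0, equilibration_fraction < 1,
            frame_stride > 0)
  if (nonbonded_cutoff > box_edge / 2)
    stop("nonbonded_cutoff must be <= box_edge/2")
  if (timestep > 0.010)
    stop("timestep above 10 fs is not supported")
  if (timestep > 0.005)
    warning("timestep above 5 fs: integration accuracy is reduced")
  structure(list(
    temperature = temperature, ionic_strength = ionic_strength, ph = ph,
    bond_length = bond_length, bond_spring_k = bond_spring_k,
    ah_epsilon = ah_epsilon, nonbonded_cutoff = nonbonded_cutoff,
    timestep = timestep, friction = friction, box_edge = box_edge,
    total_time = total_time, equilibration_fraction = equilibration_fraction,
    frame_stride = frame_stride, seed = as.integer(seed)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config> %g K, I = %g M, pH %g | dt %g ps, friction %g /ps\n",
    x$temperature, x$ionic_strength, x$ph, x$timestep, x$friction))
  cat(sprintf("  lb %g nm, k_bond %g, eps_AH %g kJ/mol, cutoff %g nm\n",
              x$bond_length, x$bond_spring_k, x$ah_epsilon, x$nonbonded_cutoff))
  cat(sprintf("  %g ns total, %.0f%% equilibration, frame every %g ps, seed %d\n",
              x$total_time, 100 * x$equilibration_fraction, x$frame_stride,
              x$seed))
  invisible(x)
}

#' Nonbonded pair energy, decomposed
#'
#' Evaluates the Ashbaugh-Hatch (stickiness-scaled Lennard-Jones) and
#' Debye-Hueckel terms for one residue pair at separation `r`. With
#' lambda_ij and sigma_ij the arithmetic means of the per-residue values and
#' LJ(r) the 12-6 form with well depth `ah_epsilon`:
#' below the LJ minimum (r <= 2^(1/6) sigma_ij) the AH term is
#' LJ(r) + (1 - lambda_ij) eps, above it lambda_ij LJ(r). The electrostatic
#' term is q_i q_j lB kB T exp(-kappa r) / r. Both terms are truncated and
#' shifted to zero at the cutoff.
#'
#' @param r separation, nm (> 0).
#' @param letter_i,letter_j one-letter residue codes.
#' @param config a [model_config].
#' @param params optional residue table from [residue_params]; derived from
#'   `config$ph` when missing.
#' @return Named numeric: `ah`, `dh`, `total` (kJ/mol).
#' @export
pair_energy <- function(r, letter_i, letter_j, config = model_config(),
                        params = NULL) {
  if (any(r <= 0)) stop("r must be > 0")
  if (is.null(params)) params <- residue_params(config$ph)
  pi_ <- params[letter_i, ]; pj <- params[letter_j, ]
  sij <- (pi_$sigma + pj$sigma) / 2
  lij <- (pi_$lambda + pj$lambda) / 2
  eps <- config$ah_epsilon
  rc <- config$nonbonded_cutoff
  lj <- function(x) { s6 <- (sij / x)^6; 4 * eps * (s6^2 - s6) }
  ah_raw <- function(x) ifelse(x <= 2^(1/6) * sij,
                               lj(x) + (1 - lij) * eps, lij * lj(x))
  kap <- debye_kappa(config$ionic_strength, config$temperature)
  pref <- pi_$charge * pj$charge * bjerrum_length(config$temperature) *
    KB_KJ * config$temperature
  dh_raw <- function(x) pref * exp(-kap * x) / x
  ah <- ifelse(r < rc, ah_raw(r) - ah_raw(rc), 0)
  dh <- ifelse(r < rc, dh_raw(r) - dh_raw(rc), 0)
  c(ah = ah, dh = dh, total = ah + dh)
}
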
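GAMMA_1H <- 2.6752218744e8  # 1H gyromagnetic ratio, rad s^-1 T^-1

#' Pulsed-field-gradient diffusion decay
#'
#' Container for a gradient-ramp NMR diffusion experiment: gradient
#' strengths in G/cm, signal intensities, gradient pulse length delta (ms)
#' and diffusion delay Delta (ms). The defaults for the ramp helper
#' [pfg_ramp] follow a stimulated-echo acquisition with a 32-point linear
#' ramp over 2-95% of a 53.5 G/cm maximum gradient, delta = 2 ms,
#' Delta = 150 ms.
#'
#' @param gradient_strengths G/cm, non-negative and increasing.
#' @param intensities signal intensities (same length), or NULL.
#' @param delta gradient pulse length, ms.
#' @param Delta diffusion delay, ms.
#' @param gamma_nucleus gyromagnetic ratio, rad s^-1 T^-1 (1H default).
#' @return Object of class `diffusion_decay`.
#' @export
diffusion_decay <- function(gradient_strengths, intensities = NULL,
                            delta = 2, Delta = 150,
                            gamma_nucleus = GAMMA_1H) {
  g <- gradient_strengths
  if (length(g) < 5) stop("need at least 5 gradient points")
  if (any(g < 0) || is.unsorted(g)) stop("gradients must be >= 0, increasing")
  if (!is.null(intensities) && length(intensities) != length(g))
    stop("intensities length mismatch")
  structure(list(gradient_strengths = g, intensities = intensities,
                 delta = delta, Delta = Delta,
                 gamma_nucleus = gamma_nucleus),
            class = "diffusion_decay")
}

#' @rdname diffusion_decay
#' @param n_points,g_min_frac,g_max_frac,g_max ramp geometry: `n_points`
#'   gradients linearly spaced between `g_min_frac` and `g_max_frac` of
#'   the maximum strength `g_max` (G/cm).
#' @export
pfg_ramp <- function(n_points = 32L, g_min_frac = 0.02, g_max_frac = 0.95,
                     g_max = 53.5, delta = 2, Delta = 150,
                     gamma_nucleus = GAMMA_1H) {
  diffusion_decay(seq(g_min_frac, g_max_frac, length.out = n_points) * g_max,
                  NULL, delta = delta, Delta = Delta,
                  gamma_nucleus = gamma_nucleus)
}

# Stejskal-Tanner decay constant per unit Dt: b(g) = gamma^2 g^2 delta^2
# (Delta - delta/3), SI units (g G/cm -> T/m, delta/Delta ms -> s).
st_bvalues <- function(decay) {
  g_si <- decay$gradient_strengths * 1e-2
  delta_s <- decay$delta * 1e-3
  Delta_s <- decay$Delta * 1e-3
  (decay$gamma_nucleus * g_si * delta_s)^2 * (Delta_s - delta_s / 3)
}

#' Fit a translational diffusion coefficient
#'
#' Nonlinear least squares of the Stejskal-Tanner attenuation
#' I(g) = I0 exp(-Dt gamma^2 g^2 delta^2 (Delta - delta/3)) against the
#' measured ramp. Unit handling (G/cm, ms) is internal; Dt is returned in
#' m^2/s. `log_fit = TRUE` switches to a linear fit of log I against the
#' b-values, which is robust to multiplicative heteroscedasticity.
#'
#' @param decay a [diffusion_decay] with intensities.
#' @param log_fit fit on log-intensities instead of raw.
#' @return Object of class `diffusion_fit`: `dt` (m^2/s), `se`, `i0`,
#'   `log_fit`.
#' @export
fit_diffusion <- function(decay, log_fit = FALSE) {
  y <- decay$intensities
  if (is.null(y)) stop("decay has no intensities")
  if (any(y <= 0)) stop("intensities must be positive")
  b <- st_bvalues(decay)
  init <- lm(log(y) ~ b)
  slope <- coef(init)[["b"]]
  if (slope >= 0) stop("non-decaying data: fitted attenuation is positive")
  if (log_fit) {
    se <- if (deviance(init) < 1e-16 * length(y)) 0
    else summary(init)$coefficients["b", "Std. Error"]
    return(structure(list(dt = -slope, se = se,
                          i0 = exp(coef(init)[["(Intercept)"]]),
                          log_fit = TRUE), class = "diffusion_fit"))
  }
  if (deviance(init) < 1e-16 * length(y)) {
    # noise-free data: the log-linear solution is already exact, and nls
    # cannot iterate on a zero-residual problem
    return(structure(list(dt = -slope, se = 0,
                          i0 = exp(coef(init)[["(Intercept)"]]),
                          log_fit = FALSE), class = "diffusion_fit"))
  }
  df <- data.frame(y = y, b = b)
  fit <- nls(y ~ i0 * exp(-dt * b), data = df,
             start = list(i0 = exp(coef(init)[["(Intercept)"]]),
                          dt = -slope),
             control = nls.control(maxiter = 200, warnOnly = FALSE))
  sm <- summary(fit)$coefficients
  structure(list(dt = coef(fit)[["dt"]], se = sm["dt", "Std. Error"],
                 i0 = coef(fit)[["i0"]], log_fit = FALSE),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> Dt = %.5g +/- %.2g m^2/s (I0 = %.4g, %s)\n",
              x$dt, x$se, x$i0,
              if (x$log_fit) "log-linear" else "nonlinear"))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) c(dt = object$dt, i0 = object$i0)

#' Hydrodynamic radius from an internal reference
#'
#' Rh = (Dt_ref / Dt_analyte) * Rh_ref. Using the diffusion coefficient of
#' an internal reference of known hydrodynamic radius (1% dioxane,
#' Rh_ref = 2.12 Angstrom) cancels the solution viscosity, avoiding the
#' absolute Stokes-Einstein route.
#'
#' @param dt_analyte,dt_reference translational diffusion coefficients
#'   (m^2/s), or `diffusion_fit` objects.
#' @param rh_reference reference hydrodynamic radius, Angstrom.
#' @return Object of class `rh_result`: `rh` (Angstrom), `dt_analyte`,
#'   `dt_reference`, `rh_reference`.
#' @export
rh_from_reference <- function(dt_analyte, dt_reference, rh_reference = 2.12) {
  if (inherits(dt_analyte, "diffusion_fit")) dt_analyte <- dt_analyte$dt
  if (inherits(dt_reference, "diffusion_fit")) dt_reference <- dt_reference$dt
  if (dt_analyte <= 0 || dt_reference <= 0) stop("Dt must be > 0")
  structure(list(rh = dt_reference / dt_analyte * rh_reference,
                 dt_analyte = dt_analyte, dt_reference = dt_reference,
                 rh_reference = rh_reference), class = "rh_result")
}

#' @export
print.rh_result <- function(x, ...) {
  cat(sprintf("<rh_result> Rh = %.2f A (Dt ratio %.4g, ref %.2f A)\n",
              x$rh, x$dt_reference / x$dt_analyte, x$rh_reference))
  invisible(x)
}

#' Rg/Rh shape ratio
#'
#' The ratio of radius of gyration to hydrodynamic radius diagnoses chain
#' expansion: a compact homogeneous sphere gives sqrt(3/5) = 0.775, while
#' expanded disordered chains give ratios well above 1.
#'
#' @param rg,rh same length unit (conventionally Angstrom).
#' @param compact_threshold ratios below this are flagged compact.
#' @return List of class `rg_rh_ratio`: `ratio`, `display` (1 d.p.),
#'   `compact`.
#' @export
rg_rh_ratio <- function(rg, rh, compact_threshold = 0.9) {
  if (rg <= 0 || rh <= 0) stop("rg and rh must be > 0")
  r <- rg / rh
  structure(list(ratio = r, display = round(r, 1),
                 compact = r < compact_threshold),
            class = "rg_rh_ratio")
}

#' @export
print.rg_rh_ratio <- function(x, ...) {
  cat(sprintf("<rg_rh_ratio> Rg/Rh = %.1f%s\n", x$display,
              if (x$compact) " (compact)" else ""))
  invisible(x)
}

#' Read a 2-column diffusion-decay text file
#'
#' Lines `g intensity` (g in G/cm) with '#' comments; header keys
#' `# delta_ms:`, `# Delta_ms:` set the pulse parameters.
#'
#' @param path file path.
#' @return A [diffusion_decay].
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  hdr <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (length(m)) as.numeric(sub(".*:", "", m[1])) else default
  }
  delta <- hdr("delta_ms", 2); Delta <- hdr("Delta_ms", 150)
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(dat), "[,[:space:]]+"))),
              ncol = 2, byrow = TRUE)
  diffusion_decay(m[, 1], m[, 2], delta = delta, Delta = Delta)
}

#' Write a diffusion decay as 2-column text
#'
#' @param decay a [diffusion_decay] with intensities.
#' @param path output file.
#' @export
write_decay <- function(decay, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# delta_ms: %g", decay$delta),
               sprintf("# Delta_ms: %g", decay$Delta),
               "# g(G/cm) I"), con)
  writeLines(sprintf("%.6g %.8g", decay$gradient_strengths,
                     decay$intensities), con)
  invisible(path)
}
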
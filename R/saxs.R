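#' Scattering profile container
#'
#' A (q, I, sigma) triple. The canonical internal unit for q is nm^-1;
#' profiles read from beamline-style files in inverse Angstrom are
#' converted at ingestion (`q_units = "A"` multiplies q by 10).
#'
#' @param q scattering vector, strictly increasing.
#' @param intensity intensities, arbitrary units.
#' @param sigma 1-SD uncertainties (same units as intensity), or NULL.
#' @param q_units `"nm"` (default) or `"A"`.
#' @return Object of class `scattering_profile` (data.frame with columns
#'   q, intensity, sigma; q in nm^-1).
#' @export
scattering_profile <- function(q, intensity, sigma = NULL, q_units = c("nm", "A")) {
  q_units <- match.arg(q_units)
  if (q_units == "A") q <- q * 10
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (length(intensity) != length(q)) stop("q and intensity lengths differ")
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  if (any(!is.na(sigma) & sigma <= 0)) stop("sigma must be > 0 where given")
  structure(data.frame(q = q, intensity = intensity, sigma = sigma),
            class = c("scattering_profile", "data.frame"))
}

#' Read a 3-column SAXS text file
#'
#' Whitespace- or comma-separated columns q, I, sigma with optional '#'
#' comment lines; the third column may be absent.
#'
#' @param path file path.
#' @param q_units unit of the q column: `"nm"` for nm^-1, `"A"` for A^-1.
#' @return A [scattering_profile] (q converted to nm^-1).
#' @export
read_saxs <- function(path, q_units = c("nm", "A")) {
  q_units <- match.arg(q_units)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1 || !ncol %in% 2:3)
    stop("expected 2 or 3 columns in SAXS file ", path)
  m <- matrix(as.numeric(unlist(parts)), ncol = ncol, byrow = TRUE)
  scattering_profile(m[, 1], m[, 2],
                     if (ncol == 3) m[, 3] else NULL, q_units = q_units)
}

#' Write a scattering profile as 3-column text
#'
#' @param profile a [scattering_profile].
#' @param path output file.
#' @param q_units unit for the written q column.
#' @export
write_saxs <- function(profile, path, q_units = c("nm", "A")) {
  q_units <- match.arg(q_units)
  q <- if (q_units == "A") profile$q / 10 else profile$q
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# q(%s^-1) I sigma", q_units), con)
  writeLines(sprintf("%.8g %.8g %.8g", q, profile$intensity,
                     profile$sigma), con)
  invisible(path)
}

#' Guinier fit of a scattering profile
#'
#' Weighted linear fit of ln I against q^2 over the low-q region, with the
#' fit range chosen self-consistently: starting from the lowest-q points,
#' the fit is repeated until every included point satisfies
#' q * Rg <= `qrg_limit` (the conventional validity criterion: 1.3 for
#' globular particles, 1.0 for flexible chains). Weights are propagated
#' from sigma (sigma_lnI = sigma / I) when available.
#'
#' @param profile a [scattering_profile], q in nm^-1.
#' @param qrg_limit validity criterion.
#' @param min_points minimum points in the fitted range.
#' @param max_iter maximum range-selection iterations.
#' @param mask optional logical vector marking points to exclude (e.g.
#'   beamstop artifacts).
#' @return Object of class `guinier_fit`: `rg` (nm), `i0`, `rg_se`,
#'   `i0_se`, `qrg_limit`, `n_points`, `iterations`, `q_range`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 5L,
                        max_iter = 20L, mask = NULL) {
  ok <- profile$q > 0 & profile$intensity > 0
  if (!is.null(mask)) ok <- ok & !mask
  p <- profile[ok, ]
  use <- seq_len(nrow(p)) <= max(min_points, 10L)
  rg <- NA_real_
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (sum(use) < min_points)
      stop("Guinier range shrank below ", min_points, " points (trace: ",
           paste(signif(trace, 4), collapse = " "), ")")
    q2 <- p$q[use]^2
    y <- log(p$intensity[use])
    w <- if (all(is.na(p$sigma))) rep(1, sum(use))
    else (p$intensity[use] / p$sigma[use])^2
    fit <- lm(y ~ q2, weights = w)
    slope <- coef(fit)[["q2"]]
    if (slope >= 0) stop("no Guinier region: nonnegative low-q slope")
    rg_new <- sqrt(-3 * slope)
    trace <- c(trace, rg_new)
    new_use <- p$q * rg_new <= qrg_limit
    if (identical(new_use, use)) { rg <- rg_new; break }
    use <- new_use
    if (it == max_iter)
      stop("Guinier range selection did not converge (Rg trace: ",
           paste(signif(trace, 4), collapse = " "), ")")
  }
  sm <- summary(fit)$coefficients
  i0 <- exp(coef(fit)[["(Intercept)"]])
  structure(list(
    rg = rg, i0 = i0,
    rg_se = sm["q2", "Std. Error"] * 3 / (2 * rg),
    i0_se = i0 * sm["(Intercept)", "Std. Error"],
    qrg_limit = qrg_limit, n_points = sum(use), iterations = it,
    q_range = range(p$q[use])
  ), class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.4f +/- %.4f nm, I(0) = %.4g (qRg <= %.2f, %d pts)\n",
    x$rg, x$rg_se, x$i0, x$qrg_limit, x$n_points))
  invisible(x)
}

#' @export
coef.guinier_fit <- function(object, ...) c(rg = object$rg, i0 = object$i0)

#' Debye-equation scattering from an ensemble
#'
#' Computes I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij) per frame and the
#' weighted ensemble average. The default form factors are uniform
#' (f_i = 1, shape-only scattering); per-residue weights may be supplied.
#' There is no hydration-layer term: the profile describes the bead chain
#' only.
#'
#' @param ens an `ensemble`.
#' @param q_grid q values, nm^-1 (non-negative; q = 0 gives I0 = (sum f)^2).
#' @param form_factors per-bead scattering weights (default 1).
#' @param return_matrix also return the frames x q per-frame intensity
#'   matrix (needed for reweighting).
#' @return A [scattering_profile] (sigma = NA); when `return_matrix`, a
#'   list with `profile` and `matrix`.
#' @export
debye_scattering <- function(ens, q_grid, form_factors = NULL,
                             return_matrix = FALSE) {
  if (any(q_grid < 0)) stop("q_grid must be non-negative")
  co <- ens$coordinates
  nf <- dim(co)[1]; n <- dim(co)[2]
  if (nf < 1) stop("empty ensemble")
  f <- if (is.null(form_factors)) rep(1, n) else form_factors
  stopifnot(length(f) == n)
  iq <- matrix(0, nf, length(q_grid))
  idx <- which(lower.tri(matrix(0, n, n)))
  fij <- (f %o% f)[idx]
  selfterm <- sum(f^2)
  for (fr in seq_len(nf)) {
    d <- as.matrix(stats::dist(co[fr, , ]))[idx]
    qr <- outer(d, q_grid)            # pairs x q
    s <- ifelse(qr == 0, 1, sin(qr) / qr)
    iq[fr, ] <- selfterm + 2 * colSums(fij * s)
  }
  # strictly increasing q needed by the container; sort and keep order
  o <- order(q_grid)
  prof <- scattering_profile(q_grid[o],
                             as.vector(ens$weights %*% iq)[o])
  if (return_matrix) list(profile = prof, matrix = iq[, o, drop = FALSE])
  else prof
}

#' Reduced chi-square between calculated and experimental profiles
#'
#' chi2_r = sum[(a I_calc + c - I_exp)^2 / sigma^2] / (n - dof), with the
#' scale a and constant background c fitted by weighted linear least
#' squares when `fit_scale_offset` (dof = 2; otherwise a = 1, c = 0,
#' dof = 0).
#'
#' @param calc,exp [scattering_profile]s on matching q grids.
#' @param fit_scale_offset fit a and c first.
#' @param interpolate linearly interpolate `calc` onto `exp$q` when the
#'   grids differ.
#' @return List of class `chi2_fit`: `chi2r`, `scale`, `offset`, `n`.
#' @export
chi2_reduced <- function(calc, exp, fit_scale_offset = TRUE,
                         interpolate = FALSE) {
  ic <- calc$intensity
  if (!isTRUE(all.equal(calc$q, exp$q))) {
    if (!interpolate)
      stop("q grids differ; pass interpolate = TRUE to resample")
    ic <- stats::approx(calc$q, calc$intensity, xout = exp$q, rule = 2)$y
  }
  if (all(is.na(exp$sigma))) stop("experimental profile lacks sigma")
  w <- 1 / exp$sigma^2
  y <- exp$intensity
  n <- length(y)
  if (fit_scale_offset) {
    fit <- lm(y ~ ic, weights = w)
    a <- coef(fit)[["ic"]]; cst <- coef(fit)[["(Intercept)"]]
    dof <- 2L
  } else { a <- 1; cst <- 0; dof <- 0L }
  chi2 <- sum(w * (a * ic + cst - y)^2)
  structure(list(chi2r = chi2 / (n - dof), scale = a, offset = cst, n = n),
            class = "chi2_fit")
}

#' @export
print.chi2_fit <- function(x, ...) {
  cat(sprintf("<chi2_fit> chi2r = %.4g (scale %.4g, offset %.4g, n = %d)\n",
              x$chi2r, x$scale, x$offset, x$n))
  invisible(x)
}
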
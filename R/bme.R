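#' Effective fraction of frames
#'
#' phi_eff = exp(-sum w log(w / w0)): 1 when the weights equal the prior,
#' 1/n when all mass sits on a single frame of a uniform n-frame prior.
#'
#' @param weights posterior weights (non-negative, normalised internally).
#' @param prior_weights prior weights; default uniform.
#' @return phi_eff in (0, 1].
#' @export
effective_fraction <- function(weights, prior_weights = NULL) {
  if (any(weights < 0)) stop("negative weight")
  w <- weights / sum(weights)
  w0 <- if (is.null(prior_weights)) rep(1 / length(w), length(w))
  else prior_weights / sum(prior_weights)
  nz <- w > 0
  exp(-sum(w[nz] * log(w[nz] / w0[nz])))
}

#' Bayesian maximum-entropy reweighting against a scattering profile
#'
#' Finds frame weights minimising Gamma(w) = chi2(w)/2 - theta * S_rel(w),
#' where chi2 compares the weighted ensemble-average profile (after an
#' affine scale/offset fit) to the experimental one and
#' S_rel = -sum w log(w/w0) is the relative entropy to the prior. Large
#' theta keeps the prior; small theta chases the data. Each iteration
#' alternates (a) a closed-form weighted-least-squares update of the scale
#' and offset at the current weights with (b) a damped fixed-point step on
#' the weight stationarity condition w_k proportional to
#' w0_k exp(-c_k/theta) (c_k the chi2 gradient) at the current scale and
#' offset. Both half-steps decrease Gamma, so the iteration is monotone;
#' it stops when the chi2 change falls below `tol` and Gamma has
#' stabilised.
#'
#' @param per_frame_profiles frames x q matrix of calculated intensities
#'   (e.g. from [debye_scattering] with `return_matrix = TRUE`).
#' @param exp a [scattering_profile] with positive `sigma`, q grid
#'   matching the matrix columns.
#' @param theta regularisation strength, > 0.
#' @param prior_weights prior frame weights; default uniform.
#' @param tol convergence threshold on the per-iteration chi2 change.
#' @param max_outer maximum iterations.
#' @return Object of class `bme_fit`: `weights`, `theta`, `chi2_before`,
#'   `chi2_after` (both reduced, n-2 dof), `phi_eff`, `scale`, `offset`,
#'   `n_iterations`, `converged`, `gamma_trace`.
#' @export
bme_reweight <- function(per_frame_profiles, exp, theta,
                         prior_weights = NULL, tol = 1e-4,
                         max_outer = 3000L) {
  iq <- as.matrix(per_frame_profiles)
  nf <- nrow(iq)
  if (nf < 2) stop("need at least 2 frames")
  if (theta <= 0) stop("theta must be > 0")
  if (ncol(iq) != nrow(exp)) stop("q grid mismatch with profile matrix")
  if (any(is.na(exp$sigma)) || any(exp$sigma <= 0))
    stop("experimental profile needs positive sigma")
  y <- exp$intensity; s2 <- exp$sigma^2
  n <- length(y)
  w0 <- if (is.null(prior_weights)) rep(1 / nf, nf)
  else prior_weights / sum(prior_weights)

  winv <- 1 / s2
  fit_ac <- function(iavg) {
    # closed-form WLS of y ~ a * iavg + cst with weights 1/sigma^2
    sw <- sum(winv); sx <- sum(winv * iavg); sy <- sum(winv * y)
    sxx <- sum(winv * iavg^2); sxy <- sum(winv * iavg * y)
    a <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
    c(a = a, cst = (sy - a * sx) / sw)
  }
  srel <- function(w) { nz <- w > 0; -sum(w[nz] * log(w[nz] / w0[nz])) }
  chi2_fn <- function(iavg, a, cst) sum((a * iavg + cst - y)^2 / s2)

  w <- w0
  iavg <- as.vector(w %*% iq)
  ac <- fit_ac(iavg)
  chi2_now <- chi2_fn(iavg, ac[["a"]], ac[["cst"]])
  chi2_before <- chi2_now / (n - 2)
  gamma_cur <- chi2_now / 2 - theta * srel(w)
  chi2_prev <- chi2_before
  gamma_trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  alpha <- 0.5

  # Each iteration: refit (a, cst) in closed form (decreases chi2, hence
  # Gamma), then take one damped step towards the weight stationarity
  # condition w_k ∝ w0_k exp(-c_k / theta), c_k = d(chi2/2)/d(w_k) at the
  # current scale/offset. Damping in log space keeps the weights in the
  # simplex interior and is backtracked until Gamma decreases, so the
  # iteration cannot collapse onto a vertex and stall when theta is small.
  for (outer in seq_len(max_outer)) {
    iters <- outer
    a <- ac[["a"]]; cst <- ac[["cst"]]
    r <- (a * iavg + cst - y) / s2
    ck <- a * as.vector(iq %*% r)
    target <- log(w0) - ck / theta
    target <- target - max(target)
    accepted <- FALSE
    while (alpha > 1e-10) {
      t_new <- (1 - alpha) * log(w) + alpha * target
      t_new <- pmax(t_new - max(t_new), -700)  # keep exp() above zero
      w_new <- exp(t_new); w_new <- w_new / sum(w_new)
      iavg_new <- as.vector(w_new %*% iq)
      g_new <- chi2_fn(iavg_new, a, cst) / 2 - theta * srel(w_new)
      if (g_new <= gamma_cur + 1e-12) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    stalled <- !accepted
    if (accepted) {
      w <- w_new; iavg <- iavg_new
      alpha <- min(1, alpha * 1.5)
    }
    ac <- fit_ac(iavg)
    chi2_now <- chi2_fn(iavg, ac[["a"]], ac[["cst"]]) / (n - 2)
    gamma_new <- chi2_now * (n - 2) / 2 - theta * srel(w)
    dgamma <- gamma_cur - gamma_new
    gamma_cur <- gamma_new
    gamma_trace <- c(gamma_trace, gamma_cur)
    if (stalled ||
        (abs(chi2_now - chi2_prev) < tol &&
         dgamma < 1e-6 * (abs(gamma_cur) + 1))) {
      converged <- TRUE
      break
    }
    chi2_prev <- chi2_now
  }
  if (!converged)
    warning("BME did not converge in ", max_outer, " iterations")
  structure(list(
    weights = w, theta = theta,
    chi2_before = chi2_before, chi2_after = chi2_now,
    phi_eff = effective_fraction(w, w0),
    scale = ac[["a"]], offset = ac[["cst"]],
    n_iterations = iters, converged = converged,
    gamma_trace = gamma_trace, prior_weights = w0
  ), class = "bme_fit")
}

#' @export
print.bme_fit <- function(x, ...) {
  cat(sprintf(
    "<bme_fit> theta = %g: chi2r %.4g -> %.4g, phi_eff = %.3f%s\n",
    x$theta, x$chi2_before, x$chi2_after, x$phi_eff,
    if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  scale = %.4g, offset = %.4g, %d outer iterations\n",
              x$scale, x$offset, x$n_iterations))
  invisible(x)
}

#' Scan the regularisation strength
#'
#' Runs [bme_reweight] over a grid of theta values and collects the
#' (chi2, phi_eff) pairs for L-curve inspection. Per-theta failures are
#' caught and flagged rather than aborting the scan.
#'
#' @param per_frame_profiles,exp,prior_weights as in [bme_reweight].
#' @param theta_grid positive values, at least 3; default 15 log-spaced
#'   points in [0.1, 1000].
#' @param ... passed to [bme_reweight].
#' @return Object of class `theta_scan`: list with `results` (per-theta
#'   `bme_fit`s or error conditions, ordered by theta) and `table`
#'   (theta, chi2_after, phi_eff, converged, failed).
#' @export
theta_scan <- function(per_frame_profiles, exp,
                       theta_grid = 10^seq(-1, 3, length.out = 15),
                       prior_weights = NULL, ...) {
  if (length(theta_grid) < 3 || any(theta_grid <= 0))
    stop("theta_grid must hold at least 3 positive values")
  theta_grid <- sort(theta_grid)
  results <- lapply(theta_grid, function(th)
    tryCatch(bme_reweight(per_frame_profiles, exp, th,
                          prior_weights = prior_weights, ...),
             error = function(e) e))
  tab <- data.frame(
    theta = theta_grid,
    chi2_after = vapply(results, function(r)
      if (inherits(r, "bme_fit")) r$chi2_after else NA_real_, 0),
    phi_eff = vapply(results, function(r)
      if (inherits(r, "bme_fit")) r$phi_eff else NA_real_, 0),
    converged = vapply(results, function(r)
      inherits(r, "bme_fit") && r$converged, TRUE),
    failed = vapply(results, function(r) inherits(r, "error"), TRUE))
  structure(list(results = results, table = tab), class = "theta_scan")
}

#' @export
print.theta_scan <- function(x, ...) {
  cat("<theta_scan>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.theta_scan <- function(x, ...) {
  plot(x$table$phi_eff, x$table$chi2_after, type = "b",
       xlab = expression(phi[eff]), ylab = expression(chi[r]^2),
       main = "L-curve", ...)
  invisible(x)
}
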
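# A small two-population ensemble with analytically controllable averages:
# frames are straight rods of varying length, so per-frame profiles differ.
make_bme_problem <- function(n_frames = 24, seed = 3) {
  set.seed(seed)
  lens <- seq(0.30, 0.46, length.out = n_frames)
  frames <- lapply(lens, function(lb) rod_coords(12, lb = lb))
  ens <- toy_ensemble(frames, poly("G", 12))
  q <- seq(0.05, 3, length.out = 40)
  calc <- debye_scattering(ens, q, return_matrix = TRUE)
  list(ens = ens, q = q, matrix = calc$matrix)
}

test_that("effective fraction hits its closed-form anchors", {
  expect_equal(effective_fraction(rep(1, 10)), 1)
  expect_equal(effective_fraction(rep(0.25, 4)), 1)
  w <- c(1, rep(0, 9))
  expect_equal(effective_fraction(w), 0.1, tolerance = 1e-12)
  # two-frame case: exp(-(0.75 log 1.5 + 0.25 log 0.5)) = 0.8774
  expect_equal(effective_fraction(c(0.75, 0.25)),
               exp(-(0.75 * log(1.5) + 0.25 * log(0.5))), tolerance = 1e-12)
  expect_equal(round(effective_fraction(c(0.75, 0.25)), 3), 0.877)
  # equals 1 whenever weights equal an arbitrary prior
  w0 <- c(0.5, 0.3, 0.2)
  expect_equal(effective_fraction(w0, w0), 1, tolerance = 1e-12)
  expect_error(effective_fraction(c(-0.1, 1.1)), "negative")
})

test_that("large theta keeps the prior", {
  pb <- make_bme_problem()
  # target generated from non-uniform weights so the data do pull
  wtrue <- exp(seq(-1, 1, length.out = nrow(pb$matrix)))
  wtrue <- wtrue / sum(wtrue)
  iexp <- as.vector(wtrue %*% pb$matrix)
  prof <- scattering_profile(pb$q, iexp, sigma = 0.01 * iexp)
  fit <- bme_reweight(pb$matrix, prof, theta = 1e6)
  expect_lt(max(abs(fit$weights - 1 / nrow(pb$matrix))), 1e-3)
  expect_gt(fit$phi_eff, 0.999)
})

test_that("planted non-uniform weights are recovered at small theta", {
  pb <- make_bme_problem()
  nf <- nrow(pb$matrix)
  wtrue <- exp(2 * seq(-1, 1, length.out = nf)); wtrue <- wtrue / sum(wtrue)
  iexp <- as.vector(wtrue %*% pb$matrix)
  set.seed(11)
  sig <- 0.002 * iexp
  prof <- scattering_profile(pb$q, iexp + rnorm(length(sig), 0, sig),
                             sigma = sig)
  fit <- bme_reweight(pb$matrix, prof, theta = 0.5)
  expect_true(fit$converged)
  expect_lt(fit$chi2_after, 1.5)
  expect_lt(fit$chi2_after, fit$chi2_before)
  # reweighted Rg matches the planted-ensemble Rg within 2%
  ens_true <- pb$ens; ens_true$weights <- wtrue
  ens_fit <- pb$ens; ens_fit$weights <- fit$weights
  rg_true <- radius_of_gyration(ens_true)$mean
  rg_fit <- radius_of_gyration(ens_fit)$mean
  expect_equal(rg_fit, rg_true, tolerance = 0.02)
})

test_that("two-frame problem puts nearly all weight on the matching frame", {
  frames <- list(rod_coords(10, lb = 0.30), rod_coords(10, lb = 0.50))
  ens <- toy_ensemble(frames, poly("G", 10))
  q <- seq(0.05, 3, length.out = 30)
  calc <- debye_scattering(ens, q, return_matrix = TRUE)
  iexp <- calc$matrix[1, ]  # data generated by frame 1 alone
  prof <- scattering_profile(q, iexp, sigma = 0.001 * iexp)
  fit <- bme_reweight(calc$matrix, prof, theta = 0.01)
  expect_gt(fit$weights[1], 0.95)
})

test_that("chi2 and phi_eff are monotone in theta on the L-curve", {
  pb <- make_bme_problem()
  nf <- nrow(pb$matrix)
  wtrue <- exp(2 * seq(-1, 1, length.out = nf)); wtrue <- wtrue / sum(wtrue)
  iexp <- as.vector(wtrue %*% pb$matrix)
  prof <- scattering_profile(pb$q, iexp, sigma = 0.005 * iexp)
  sc <- theta_scan(pb$matrix, prof, theta_grid = 10^seq(-1, 3, by = 1))
  tab <- sc$table
  expect_false(any(tab$failed))
  # allow tiny numerical wiggle
  expect_true(all(diff(tab$chi2_after) > -1e-6))
  expect_true(all(diff(tab$phi_eff) > -1e-6))
  expect_error(theta_scan(pb$matrix, prof, theta_grid = c(1, 2)),
               "at least 3")
})

test_that("weights stay a probability vector and Gamma decreases", {
  pb <- make_bme_problem()
  nf <- nrow(pb$matrix)
  wtrue <- exp(seq(-2, 2, length.out = nf)); wtrue <- wtrue / sum(wtrue)
  iexp <- as.vector(wtrue %*% pb$matrix)
  prof <- scattering_profile(pb$q, iexp, sigma = 0.01 * iexp)
  fit <- bme_reweight(pb$matrix, prof, theta = 2)
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  if (length(fit$gamma_trace) > 1)
    expect_true(all(diff(fit$gamma_trace) <= 1e-8))
  expect_gte(fit$phi_eff, 1 / nf - 1e-12)
  expect_lte(fit$phi_eff, 1 + 1e-12)
})

test_that("inflating sigma behaves like increasing theta (weaker pull)", {
  pb <- make_bme_problem()
  nf <- nrow(pb$matrix)
  wtrue <- exp(2 * seq(-1, 1, length.out = nf)); wtrue <- wtrue / sum(wtrue)
  iexp <- as.vector(wtrue %*% pb$matrix)
  tight <- scattering_profile(pb$q, iexp, sigma = 0.002 * iexp)
  loose <- scattering_profile(pb$q, iexp, sigma = 0.2 * iexp)
  f_tight <- bme_reweight(pb$matrix, tight, theta = 1)
  f_loose <- bme_reweight(pb$matrix, loose, theta = 1)
  expect_gt(f_loose$phi_eff, f_tight$phi_eff)
})

test_that("bme input validation", {
  pb <- make_bme_problem()
  prof <- scattering_profile(pb$q, pb$matrix[1, ],
                             sigma = 0.01 * pb$matrix[1, ])
  expect_error(bme_reweight(pb$matrix, prof, theta = 0), "> 0")
  expect_error(bme_reweight(pb$matrix[, 1:10], prof, theta = 1), "mismatch")
  nosig <- scattering_profile(pb$q, pb$matrix[1, ])
  expect_error(bme_reweight(pb$matrix, nosig, theta = 1), "sigma")
  expect_error(bme_reweight(pb$matrix[1, , drop = FALSE], prof, theta = 1),
               "2 frames")
})
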
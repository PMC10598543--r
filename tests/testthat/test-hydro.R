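test_that("noise-free decay returns the generating Dt exactly", {
  dt_true <- 8.1e-11  # m^2/s, protein-scale
  dec <- generate_diffusion_decay(dt_true, i0 = 3.2)
  fit <- fit_diffusion(dec)
  expect_equal(fit$dt, dt_true, tolerance = 1e-9)
  expect_equal(fit$i0, 3.2, tolerance = 1e-9)
  # log-linear route agrees on noise-free data
  fitl <- fit_diffusion(dec, log_fit = TRUE)
  expect_equal(fitl$dt, dt_true, tolerance = 1e-9)
  # attenuation at the lowest gradient is nearly I0
  expect_gt(dec$intensities[1] / 3.2, 0.98)
  # decaying and ordered
  expect_true(all(diff(dec$intensities) < 0))
})

test_that("attenuation matches the Stejskal-Tanner closed form, hand units", {
  # one gradient point computed with literal unit conversions:
  # g = 30 G/cm = 0.30 T/m, delta = 2 ms, Delta = 150 ms
  dt_true <- 6e-11
  gam <- 2.6752218744e8
  b_hand <- (gam * 0.30 * 0.002)^2 * (0.150 - 0.002 / 3)
  dec <- generate_diffusion_decay(
    dt_true, ramp = diffusion_decay(c(10, 20, 30, 40, 50)))
  expect_equal(dec$intensities[3], exp(-dt_true * b_hand), tolerance = 1e-12)
})

test_that("noisy decay recovers Dt within 2%", {
  dt_true <- 5e-11
  dec <- generate_diffusion_decay(dt_true,
                                  noise = noise_model(relative_sd = 0.02,
                                                      seed = 42))
  fit <- fit_diffusion(dec)
  expect_equal(fit$dt, dt_true, tolerance = 0.02)
})

test_that("fit is invariant under intensity rescaling", {
  dec <- generate_diffusion_decay(6e-11,
                                  noise = noise_model(relative_sd = 0.01,
                                                      seed = 7))
  fit1 <- fit_diffusion(dec)
  dec2 <- dec; dec2$intensities <- 250 * dec2$intensities
  fit2 <- fit_diffusion(dec2)
  expect_equal(fit2$dt, fit1$dt, tolerance = 1e-9)
  expect_equal(fit2$i0 / fit1$i0, 250, tolerance = 1e-6)
})

test_that("diffusion containers validate their inputs", {
  ramp <- pfg_ramp()
  expect_length(ramp$gradient_strengths, 32)
  expect_equal(range(ramp$gradient_strengths), c(0.02, 0.95) * 53.5)
  expect_equal(c(ramp$delta, ramp$Delta), c(2, 150))
  expect_error(diffusion_decay(c(3, 2, 1, 4, 5)), "increasing")
  expect_error(diffusion_decay(1:3), "at least 5")
  expect_error(fit_diffusion(ramp), "no intensities")
  # rising "decay": invert a valid one
  rising <- generate_diffusion_decay(1e-10)
  rising$intensities <- rev(rising$intensities)
  expect_error(fit_diffusion(rising), "non-decaying")
})

test_that("reference-based Rh follows the Dt ratio", {
  # identity: equal coefficients return the reference radius
  expect_equal(rh_from_reference(1e-9, 1e-9)$rh, 2.12)
  # halving the analyte Dt doubles Rh
  expect_equal(rh_from_reference(5e-10, 1e-9)$rh, 2 * 2.12)
  # a ratio of 14.245 gives Rh = 30.2 A, matching a disordered two-domain
  # protein measured against dioxane
  r <- rh_from_reference(1e-9 / 14.245283, 1e-9)
  expect_equal(r$rh, 30.2, tolerance = 1e-4)
  expect_error(rh_from_reference(-1e-9, 1e-9), "> 0")
})

test_that("Rg/Rh ratio separates compact from expanded chains", {
  flex <- rg_rh_ratio(35.3, 30.2)
  expect_equal(flex$display, 1.2)
  expect_false(flex$compact)
  sphere <- rg_rh_ratio(sqrt(3 / 5) * 20, 20)
  expect_equal(sphere$ratio, sqrt(3 / 5), tolerance = 1e-12)
  expect_true(sphere$compact)
  expect_error(rg_rh_ratio(0, 10), "> 0")
})

test_that("decay files round-trip with their pulse parameters", {
  dec <- generate_diffusion_decay(7e-11, ramp = pfg_ramp(delta = 3,
                                                         Delta = 120))
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_decay(dec, tmp)
  back <- read_decay(tmp)
  expect_equal(back$gradient_strengths, dec$gradient_strengths,
               tolerance = 1e-5)
  expect_equal(back$intensities, dec$intensities, tolerance = 1e-6)
  expect_equal(c(back$delta, back$Delta), c(3, 120))
  # fitted Dt survives the round trip
  expect_equal(fit_diffusion(back)$dt, fit_diffusion(dec)$dt,
               tolerance = 1e-5)
})

test_that("end-to-end planted Rh is recovered within 0.5%", {
  rh_planted <- 28.7  # Angstrom
  dt_ref <- 1.1e-9
  dt_analyte <- dt_ref * 2.12 / rh_planted
  analyte <- generate_diffusion_decay(dt_analyte,
                                      noise = noise_model(0.002, seed = 5))
  reference <- generate_diffusion_decay(dt_ref,
                                        noise = noise_model(0.002, seed = 6))
  out <- rh_workflow(analyte, reference)
  expect_equal(out$rh, rh_planted, tolerance = 0.005)
})
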
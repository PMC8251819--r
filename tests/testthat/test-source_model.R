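# Source model: electron sampling, spectrum, splitting, collimation.

test_that("degenerate beams produce exact parameters", {
  set.seed(1)
  ps <- sample_incident_electron(electron_beam(6, 0, 0), 50)
  expect_true(all(ps$energy == 6))
  expect_true(all(ps$x == 0 & ps$y == 0))
  expect_true(all(ps$uz == 1))
})

test_that("commissioned beam reproduces its mean, spread and spot widths", {
  set.seed(42)
  ps <- sample_incident_electron(electron_beam(6.0, 1.5, 1.0), 1e5)
  expect_lt(abs(mean(ps$energy) - 6.0), 0.01)
  fwhm_e <- sd(ps$energy) * 2 * sqrt(2 * log(2))
  expect_lt(abs(fwhm_e - 1.5), 0.05)
  fwhm_spot <- sd(ps$x) * 2 * sqrt(2 * log(2))
  expect_lt(abs(fwhm_spot - 1.0), 0.05)
  expect_true(all(ps$energy > 0))
})

test_that("spectrum samples respect the kinematic bound", {
  set.seed(7)
  k <- sample_spectrum(5000, e0 = 6.0, kmin = 0.05)
  expect_true(all(k <= 6.0 + 1e-12))
  expect_true(all(k >= 0.05))
  # hardening removes the soft component
  soft <- mean(sample_spectrum(5000, 6, hardening_mm = 0) < 0.2)
  hard <- mean(sample_spectrum(5000, 6, hardening_mm = 110) < 0.2)
  expect_gt(soft, hard)
})

test_that("splitting yields weight-1/n directed photons and conserves yield", {
  set.seed(11)
  el <- sample_incident_electron(electron_beam(6, 0, 0), 1)
  one <- generate_bremsstrahlung(el, dbs_config(1, 1e5), ssd = 850)
  expect_equal(nrow(one), 1)
  expect_equal(one$weight, 1)
  # photon energy never exceeds the electron kinetic energy
  many <- generate_bremsstrahlung(el, dbs_config(50, 100), ssd = 850)
  expect_true(all(many$energy <= el$energy))
  # electron below the photon cutoff yields nothing
  cold <- el; cold$energy <- 0.01
  expect_equal(nrow(generate_bremsstrahlung(cold, dbs_config(10, 100))), 0)
})

test_that("splitting is unbiased: mean emitted weight matches unsplit", {
  set.seed(5)
  el <- sample_incident_electron(electron_beam(6, 0, 0), 1)
  n_ev <- 3000
  tot_split <- replicate(n_ev, {
    ph <- generate_bremsstrahlung(el, dbs_config(20, 120), ssd = 850)
    sum(ph$weight)
  })
  tot_plain <- replicate(n_ev, {
    ph <- generate_bremsstrahlung(el, dbs_config(1, 1e5), ssd = 850)
    sum(ph$weight)
  })
  se <- sqrt(var(tot_split) / n_ev + var(tot_plain) / n_ev)
  expect_lt(abs(mean(tot_split) - mean(tot_plain)), 2.5 * se)
})

test_that("collimation passes in-field rays and blocks or attenuates others", {
  ap <- aperture_field(66, transmission = 0)
  ph <- data.frame(kind = "photon", energy = 1, x = 0, y = 0, z = -900,
                   ux = 0, uy = 0, uz = 1, weight = 1)
  expect_equal(nrow(collimate(ph, ap)), 1)
  # ray projecting to (140, 0) at isocenter with zero transmission: dropped
  out <- ph; out$ux <- 140 / 900; out$uz <- sqrt(1 - out$ux^2)
  expect_equal(nrow(collimate(out, ap)), 0)
  # with finite transmission the weight is attenuated instead
  ap2 <- aperture_field(66, transmission = 0.005)
  expect_equal(collimate(out, ap2)$weight, 0.005)
  # rays not moving toward the phantom are blocked
  backw <- ph; backw$uz <- -1
  expect_equal(nrow(collimate(backw, ap)), 0)
})

test_that("aperture construction enforces the physical limits", {
  expect_error(aperture_field(c(280, 66)), "maximum")
  expect_error(aperture(rbind(c(-10, 10, -10, 10), c(0, 20, 0, 20))),
               "overlap")
  expect_silent(aperture(rbind(c(-30, -10, -10, 10), c(10, 30, -10, 10))))
  ex <- read_aperture(system.file("extdata", "apertures",
                                  "offaxis_example.txt", package = "mrdose"))
  expect_s3_class(ex, "aperture")
  expect_equal(nrow(ex$openings), 2)
})

test_that("mirrored openings give mirror-symmetric transmitted fluence", {
  set.seed(13)
  ap <- aperture(rbind(c(-50, -20, -15, 15), c(20, 50, -15, 15)),
                 transmission = 0)
  el <- sample_incident_electron(electron_beam(6, 0, 0), 1)
  ph <- generate_bremsstrahlung(el, dbs_config(20000, 80), ssd = 850)
  kept <- collimate(ph, ap)
  t <- -kept$z / kept$uz
  px <- kept$x + t * kept$ux
  nl <- sum(px < 0); nr <- sum(px > 0)
  expect_lt(abs(nl - nr) / sqrt(nl + nr), 3)
})
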
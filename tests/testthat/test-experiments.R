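# Fixture generator, ERE machinery, and the beam-test bundle.

test_that("noise-free fixtures equal their analytic forms exactly", {
  d <- seq(1, 299, 2)
  fx <- generate_reference_dataset(
    pdd_params = list(mu = 0.005, buildup = 0.2, depths = d), noise_sd = 0)
  v <- (1 - exp(-0.2 * d)) * exp(-0.005 * d)
  expect_equal(fx$pdd$values, v / max(v) * 100, tolerance = 1e-12)
  expect_equal(max(fx$pdd$values), 100)
  x <- fx$crossline$positions
  expect_equal(fx$crossline$values, fx$inline$values)
})

test_that("the falloff solver hits a prescribed depth-dose setpoint", {
  mu <- pdd_falloff_for_target(55.59)
  fx <- generate_reference_dataset(
    pdd_params = list(mu = mu, buildup = 0.18, depths = seq(1, 300, 1)))
  expect_equal(stats::approx(fx$pdd$positions, fx$pdd$values, 100)$y, 55.59,
               tolerance = 0.05)
  # a fixture compared with itself has no depth-dose offset at 10 cm
  m <- compute_metrics(fx$pdd, fx$pdd)
  expect_equal(m$delta_pdd10, 0)
})

test_that("a 2 mm profile shift sits on the gamma boundary with DTA 2 mm", {
  x <- seq(-100, 100, 1)
  fx <- generate_reference_dataset(
    profile_params = list(width = 66, sigma = 3, positions = x, tail = 0))
  moved <- profile1d(x, stats::approx(x + 2, fx$crossline$values, xout = x,
                                      rule = 2)$y,
                     axis = "crossline", normalization = "mean3max")
  g <- compute_gamma(fx$crossline, moved, dose_crit = 2, dist_crit = 2)
  expect_equal(g$pass_rate, 100)
  m <- compute_metrics(fx$crossline, moved)
  expect_equal(m$mean_dta, 2, tolerance = 0.1)
})

test_that("phantoms without lung are rejected for ERE quantification", {
  expect_error(quantify_ere(66, slabs = list(slab("water", 100)),
                            config = quick_config(1e4)),
               "lung")
})

test_that("the ERE null case (B = 0 vs B = 0) gives a unit ratio curve", {
  rep0 <- quantify_ere(66, config = quick_config(4e5, seed = 9), b = 0,
                       lateral_mm = 120)
  r <- rep0$ratio_curve
  expect_true(all(abs(r$ratio - 1) <= 2 * r$rel_stderr + 1e-9))
  expect_equal(rep0$max_ratio_proximal, 1, tolerance = 1e-9)
})

test_that("paired seeds give tighter ratio curves than independent seeds", {
  ph_cfg <- quick_config(4e5, seed = 17)
  rep_p <- quantify_ere(66, config = ph_cfg, b = 0, lateral_mm = 120)
  # independent-seed version of the same null comparison
  mk <- function(seed) {
    ph <- build_slab_phantom(list(slab("water", 50), slab("lung", 30),
                                  slab("water", 50)), lateral_mm = 120)
    beam <- configure_beam(c(66, 66), ssd = 850, b_field = c(0, 0, 0))
    extract_pdd(run_simulation(ph, beam, config = quick_config(4e5, seed)),
                lateral_radius_vox = 2)
  }
  a <- mk(18); b <- mk(19)
  ratio_ind <- a$values / b$values
  spread_ind <- stats::sd(ratio_ind)
  spread_paired <- stats::sd(rep_p$ratio_curve$ratio)
  expect_lt(spread_paired, spread_ind)
})

test_that("an all-water heterogeneous stack reproduces the plain phantom", {
  cfg <- quick_config(2e5, seed = 23)
  stack <- build_slab_phantom(list(slab("water", 50), slab("water", 30),
                                   slab("water", 50)), lateral_mm = 90)
  plain <- build_slab_phantom(list(slab("water", 130)), lateral_mm = 90)
  beam <- configure_beam(c(33, 33), ssd = 850)
  a <- run_simulation(stack, beam, config = cfg)
  b <- run_simulation(plain, beam, config = cfg)
  expect_identical(a$values, b$values)
})

test_that("the beam-test bundle runs, isolates failures and mirrors obliques", {
  cfg <- quick_config(6e5, seed = 27)
  bundle <- run_mppg_suite(config = cfg, field_size = 33,
                           gantry_angles = c(30, 330), b = 0)
  expect_s3_class(bundle, "mppg_bundle")
  expect_true(all(c("reference_field", "gantry_30", "gantry_330", "offaxis",
                    "heterogeneous_a", "heterogeneous_b",
                    "heterogeneous_c") %in% names(bundle)))
  for (nm in names(bundle)) expect_null(bundle[[nm]]$error)
  expect_s3_class(bundle$reference_field$curves$pdd, "profile1d")
  # with B = 0, gantry 30 and 330 crossline profiles are mirror images
  p30 <- bundle$gantry_30$curves$crossline_g30
  p330 <- bundle$gantry_330$curves$crossline_g330
  mirrored <- stats::approx(-p330$positions[length(p330$positions):1],
                            p330$values[length(p330$values):1],
                            xout = p30$positions)$y
  sel <- !is.na(mirrored) & (p30$values > 20 | mirrored > 20)
  expect_lt(mean(abs(p30$values[sel] - mirrored[sel])), 8)
})

test_that("metric reports are attached when references are supplied", {
  fx <- generate_reference_dataset(
    pdd_params = list(mu = 0.0048, buildup = 0.18, depths = seq(1, 299, 2)),
    profile_params = list(width = 33, sigma = 3,
                          positions = seq(-43.5, 43.5, 3), tail = 0.005))
  bundle <- run_mppg_suite(config = quick_config(3e5, seed = 29),
                           field_size = 33, gantry_angles = numeric(0),
                           references = list(pdd = fx$pdd,
                                             crossline = fx$crossline))
  expect_s3_class(bundle$reference_field$reports$pdd, "metric_report")
  expect_s3_class(bundle$reference_field$reports$crossline, "metric_report")
})
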
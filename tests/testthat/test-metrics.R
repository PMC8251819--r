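# Curve extraction and comparison metrics against analytic fixtures and the
# brute-force gamma oracle.

mk_profile <- function(values, positions = seq_along(values) - 1,
                       axis = "crossline") {
  profile1d(positions, values, axis = axis, normalization = "mean3max")
}

test_that("PDD extraction normalizes to 100 and carries monotone shapes", {
  nz <- 50
  col <- exp(-0.02 * (seq_len(nz) - 0.5) * 2)
  arr <- array(rep(col, each = 25), dim = c(5, 5, nz))
  dg <- synthetic_dose_grid(arr)
  p <- extract_pdd(dg)
  expect_equal(max(p$values), 100)
  expect_equal(p$values[1], 100)
  expect_true(all(diff(p$values) < 0))
  expect_error(extract_pdd(synthetic_dose_grid(array(0, c(3, 3, 3)))),
               "all-zero")
})

test_that("profile normalization uses the mean of the three maxima", {
  nz <- 3
  arr <- array(5, dim = c(21, 21, nz))
  dg <- synthetic_dose_grid(arr)
  pr <- extract_profile(dg, 3, "crossline")
  expect_true(all(abs(pr$values - 100) < 1e-9))
  # a single spike maps above 100 under mean-of-three normalization
  arr2 <- arr; arr2[11, 11, 2] <- 20
  pr2 <- extract_profile(synthetic_dose_grid(arr2), 3, "crossline")
  expect_gt(max(pr2$values), 100)
  expect_error(extract_profile(dg, 500), "outside")
})

test_that("identical curves give zero gamma and perfect pass rate", {
  ref <- mk_profile(c(1, 2, 5, 40, 90, 100, 99, 100, 60, 10, 3, 1) * 0.9)
  g <- compute_gamma(ref, ref)
  expect_true(all(g$gamma < 1e-9))
  expect_equal(g$pass_rate, 100)
})

test_that("a uniform 2% offset sits exactly on the gamma boundary", {
  x <- 0:40
  ref <- mk_profile(rep(100, 41), x)
  ev <- mk_profile(rep(102, 41), x)
  g <- compute_gamma(ref, ev, dose_crit = 2, dist_crit = 2)
  expect_true(all(abs(g$gamma - 1) < 1e-9))
  expect_equal(g$pass_rate, 100)
})

test_that("gamma equals the brute-force oracle on a shifted gradient", {
  x <- seq(0, 40, 0.5)
  ref <- mk_profile(5 * x, x)          # 5%/mm gradient
  ev <- mk_profile(5 * pmax(x - 1, 0), x)  # shifted 1 mm
  g <- compute_gamma(ref, ev)
  oracle <- gamma_bruteforce(ref, ev)
  keep <- !is.na(oracle)
  expect_lt(max(abs(g$gamma - oracle[keep])), 1e-3)
})

test_that("gamma is asymmetric and monotone in its criteria", {
  x <- seq(-30, 30, 1)
  ref <- mk_profile(100 * exp(-x^2 / 200), x)
  ev <- mk_profile(100 * exp(-(x - 3)^2 / 320), x)
  ab <- compute_gamma(ref, ev)
  ba <- compute_gamma(ev, ref)
  expect_false(isTRUE(all.equal(ab$gamma, ba$gamma)))
  loose <- compute_gamma(ref, ev, dose_crit = 3, dist_crit = 3)
  expect_gte(loose$pass_rate, ab$pass_rate)
  tight <- compute_gamma(ref, ev, dose_crit = 1, dist_crit = 1)
  expect_lte(tight$pass_rate, ab$pass_rate)
})

test_that("non-overlapping curves are rejected", {
  a <- mk_profile(c(1, 2, 3), c(0, 1, 2))
  b <- mk_profile(c(1, 2, 3), c(10, 11, 12))
  expect_error(compute_gamma(a, b), "overlap")
})

test_that("metrics vanish for identical curves and track uniform offsets", {
  d <- seq(1, 299, 2)
  v <- (1 - exp(-0.18 * d)) * exp(-0.005 * d)
  pdd <- profile1d(d, v / max(v) * 100, axis = "depth", normalization = "max")
  m0 <- compute_metrics(pdd, pdd)
  expect_equal(m0$mean_abs_diff, 0)
  expect_equal(m0$max_abs_diff, 0)
  expect_equal(m0$mean_dta, 0)
  expect_equal(m0$delta_pdd10, 0)
  # +1% at all depths (unnormalized comparison curve)
  shifted <- profile1d(d, pmin(v / max(v) * 100 + 1, 101), axis = "depth",
                       normalization = "mean3max")
  m1 <- compute_metrics(pdd, shifted)
  expect_equal(m1$mean_abs_diff, 1, tolerance = 1e-9)
  expect_equal(m1$max_abs_diff, 1, tolerance = 1e-9)
  expect_equal(m1$delta_pdd10, 1, tolerance = 1e-9)
})

test_that("kind mismatch is rejected", {
  d <- 1:10
  pdd <- profile1d(d, c(1:9, 10) / 10 * 100, axis = "depth",
                   normalization = "mean3max")
  prof <- mk_profile(1:10, d)
  pdd$axis <- "depth"
  expect_error(compute_metrics(pdd, prof), "different kinds")
})

test_that("an error-function edge shifted 2.7 mm is recovered", {
  fx <- generate_reference_dataset(
    profile_params = list(width = 66, sigma = 3,
                          positions = seq(-100, 100, 1), tail = 0.003))
  # the same edge moved +2.7 mm in world coordinates
  moved <- profile1d(fx$crossline$positions,
                     stats::approx(fx$crossline$positions + 2.7,
                                   fx$crossline$values,
                                   xout = fx$crossline$positions,
                                   rule = 2)$y,
                     axis = "crossline", normalization = "mean3max")
  m <- compute_metrics(fx$crossline, moved)
  expect_equal(m$halfmax_shift_pos, 2.7, tolerance = 0.1)
  expect_equal(m$halfmax_shift_neg, 2.7, tolerance = 0.1)
})

test_that("penumbra width of a Gaussian-blurred edge matches the closed form", {
  fx <- generate_reference_dataset(
    profile_params = list(width = 80, sigma = 3,
                          positions = seq(-100, 100, 0.5), tail = 0))
  e <- profile_edges(fx$crossline)
  # 80-20 width of a cumulative-normal edge: (z80 - z20) sigma = 1.683 sigma
  expect_equal(e$penumbra_neg, 1.683 * 3, tolerance = 0.05)
  expect_equal(e$penumbra_pos, 1.683 * 3, tolerance = 0.05)
  expect_equal(e$halfmax_neg, -40, tolerance = 0.1)
  expect_equal(e$halfmax_pos, 40, tolerance = 0.1)
})

test_that("metrics are invariant to uniform rescaling of the raw dose", {
  nz <- 40
  col <- exp(-0.01 * seq_len(nz))
  arr <- array(rep(col, each = 49), dim = c(7, 7, nz))
  a <- extract_pdd(synthetic_dose_grid(arr))
  b <- extract_pdd(synthetic_dose_grid(arr * 7.3))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("output factors normalize to the reference and need it present", {
  nz <- 40
  mkdg <- function(scale) {
    arr <- array(scale, dim = c(11, 11, nz))
    synthetic_dose_grid(arr, spacing = c(2, 2, 2))
  }
  runs <- list(small = mkdg(0.8), ref = mkdg(1.0), big = mkdg(1.1))
  of <- compute_output_factors(runs, "ref", depth_mm = 50, radius_mm = 3)
  expect_equal(of$of[of$field == "ref"], 1)
  expect_equal(of$of[of$field == "small"], 0.8, tolerance = 1e-9)
  expect_equal(of$of_stderr[of$field == "ref"], 0)
  expect_error(compute_output_factors(runs, "absent"), "missing")
})

test_that("profiles round-trip through the two-column text format", {
  fx <- generate_reference_dataset()
  path <- tempfile(fileext = ".tsv")
  write_profile(fx$crossline, path)
  back <- read_profile(path)
  expect_equal(back$positions, fx$crossline$positions)
  expect_equal(back$values, fx$crossline$values, tolerance = 1e-9)
  expect_equal(back$axis, "crossline")
})
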
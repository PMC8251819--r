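# Transport engine: free paths, interaction sampling, charged-particle
# stepping in the magnetic field, and whole-run contracts.

ME <- 0.51099895

test_that("free paths in homogeneous water are exponential (KS)", {
  ph <- water_cube(300, spacing = c(5, 5, 5))
  e <- 0.05
  mu <- photon_mu(lookup_material("water"), e)$total / 10  # per mm
  d <- sample_free_paths(2e4, e, ph, pos = c(0, 0, 1e-6), dir = c(0, 0, 1),
                         seed = 3)
  d <- d[!is.na(d)]
  ks <- suppressWarnings(stats::ks.test(d, "pexp", rate = mu))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(d) - 1 / mu) / (1 / mu), 0.05)
})

test_that("photons cross an air phantom essentially without interacting", {
  ph <- build_slab_phantom(list(slab("air", 300)), lateral_mm = 100,
                           spacing = c(5, 5, 5))
  d <- sample_free_paths(2000, 1.0, ph, pos = c(0, 0, 1e-6),
                         dir = c(0, 0, 1), seed = 4)
  expect_gt(mean(is.na(d)), 0.99)
})

test_that("two-slab uncollided transmission matches the closed form", {
  ph <- build_slab_phantom(list(slab("water", 50), slab("lung", 150)),
                           lateral_mm = 100, spacing = c(5, 5, 5))
  e <- 1.0
  muw <- photon_mu(lookup_material("water"), e)$total / 10
  mul <- photon_mu(lookup_material("lung"), e)$total / 10
  n <- 3e4
  d <- sample_free_paths(n, e, ph, pos = c(0, 0, 1e-6), dir = c(0, 0, 1),
                         seed = 5)
  thru <- sum(is.na(d) | d > 200 - 1e-9) / n
  p <- exp(-(muw * 50 + mul * 150))
  expect_lt(abs(thru - p), 2 * sqrt(p * (1 - p) / n) + 1e-9)
})

test_that("Compton kinematics conserve energy and respect the edge", {
  sc <- sample_compton(1e5, 1.0, seed = 6)
  expect_equal(sc$eps * 1.0 + sc$electron_mev, rep(1, nrow(sc)),
               tolerance = 1e-12)
  edge <- 2 * 1.0^2 / (ME + 2 * 1.0)
  expect_true(all(sc$electron_mev <= edge + 1e-12))
  expect_gt(max(sc$electron_mev), edge * 0.99)
})

test_that("sampled Compton angles follow the Klein-Nishina distribution", {
  e <- 1.0
  kap <- e / ME
  kn_pdf <- function(ct) {
    eps <- 1 / (1 + kap * (1 - ct))
    eps^2 * (eps + 1 / eps - (1 - ct^2))
  }
  sc <- sample_compton(1e6, e, seed = 8)
  breaks <- seq(-1, 1, length.out = 41)
  obs <- table(cut(sc$cos_theta, breaks))
  expected <- vapply(seq_len(40), function(i)
    stats::integrate(kn_pdf, breaks[i], breaks[i + 1])$value, 0)
  chi <- suppressWarnings(
    stats::chisq.test(as.numeric(obs), p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.01)
})

test_that("a 1 MeV electron in a 0.35 T field follows the exact gyroradius", {
  vg <- vacuum_grid()
  tr <- track_electron(1.0, pos = c(0, 0, 100), dir = c(1, 0, 0), grid = vg,
                       b_field = c(0, 0.35, 0), max_step = 0.2,
                       max_steps = 600, msc = FALSE)
  xs <- tr$trajectory[, 1]
  r_num <- (max(xs) - min(xs)) / 2
  pc <- sqrt(1 * (1 + 2 * ME))
  r_true <- pc / (0.299792458 * 0.35)
  expect_equal(r_true, 13.55, tolerance = 1e-3)  # about 13.5 mm
  expect_lt(abs(r_num - r_true) / r_true, 0.001)
})

test_that("the helix closes on itself after one analytic period", {
  vg <- vacuum_grid()
  pc <- sqrt(1 * (1 + 2 * ME))
  r <- pc / (0.299792458 * 0.35)
  nstep <- 200
  tr <- track_electron(1.0, pos = c(0, 0, 100), dir = c(1, 0, 0), grid = vg,
                       b_field = c(0, 0.35, 0), max_step = 2 * pi * r / nstep,
                       max_steps = nstep, msc = FALSE)
  start <- tr$trajectory[1, ]
  end <- tr$trajectory[nrow(tr$trajectory), ]
  expect_lt(sqrt(sum((end - start)^2)) / r, 1e-9)
})

test_that("zero field gives straight condensed-history chords", {
  vg <- vacuum_grid()
  tr <- track_electron(1.0, pos = c(0, 0, 10), dir = c(0.6, 0, 0.8),
                       grid = vg, b_field = c(0, 0, 0), max_step = 1,
                       max_steps = 50, msc = FALSE)
  p <- tr$trajectory
  dev <- apply(p, 1, function(q)
    sqrt(sum((q - p[1, ] - sum((q - p[1, ]) * c(0.6, 0, 0.8)) *
              c(0.6, 0, 0.8))^2)))
  expect_lt(max(dev), 1e-9)
})

test_that("a stopped electron deposits its energy up to radiative losses", {
  ph <- water_cube(60)
  tr <- track_electron(1.0, pos = c(0, 0, 10), dir = c(0, 0, 1), grid = ph,
                       b_field = c(0, 0.35, 0), msc = TRUE, seed = 2)
  expect_equal(tr$final_energy, 0)
  expect_lt(abs(tr$deposited + tr$radiated - 1.0), 1e-6)
  expect_equal(sum(tr$edep), tr$deposited, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical dose grids", {
  ph <- water_cube(90)
  beam <- configure_beam(c(33, 33), ssd = 850)
  a <- run_simulation(ph, beam, config = quick_config(1e5, seed = 21))
  b <- run_simulation(ph, beam, config = quick_config(1e5, seed = 21))
  expect_identical(a$values, b$values)
  expect_identical(a$rel_stderr, b$rel_stderr)
  c <- run_simulation(ph, beam, config = quick_config(1e5, seed = 22))
  expect_false(identical(a$values, c$values))
})

test_that("whole-run energy bookkeeping closes to 1e-6", {
  ph <- build_slab_phantom(list(slab("water", 50), slab("lung", 30),
                                slab("water", 50)), lateral_mm = 120)
  beam <- configure_beam(c(33, 33), ssd = 850)
  dg <- run_simulation(ph, beam, config = quick_config(3e5, seed = 31))
  expect_lt(energy_balance_residual(dg), 1e-6)
})

test_that("doubling histories shrinks the uncertainty like one over root two", {
  ph <- water_cube(90)
  beam <- configure_beam(c(33, 33), ssd = 850)
  m <- function(n) {
    dg <- run_simulation(ph, beam, config = quick_config(n, seed = 41))
    stats::median(dg$rel_stderr[dg$values > 0.2 * max(dg$values)])
  }
  ratio <- m(8e5) / m(4e5)
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.2 / sqrt(2))
})

test_that("megavoltage depth dose builds up then falls off", {
  ph <- water_cube(240, spacing = c(3, 3, 2))
  beam <- configure_beam(c(66, 66), ssd = 850, b_field = c(0, 0, 0))
  dg <- run_simulation(ph, beam, config = quick_config(1.5e6, seed = 51))
  p <- extract_pdd(dg, lateral_radius_vox = 2)
  smv <- stats::filter(p$values, rep(1 / 5, 5), sides = 2)
  dmax <- p$positions[which.max(ifelse(is.na(smv), -Inf, smv))]
  expect_gte(dmax, 10)
  expect_lte(dmax, 18)
  # quasi-exponential falloff beyond the build-up region
  deep <- p$values[p$positions > 40]
  sm <- stats::filter(deep, rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_gt(mean(diff(sm) < 0), 0.75)
  expect_lt(sm[length(sm)], 0.8 * sm[1])
})

test_that("zero-history runs are rejected", {
  ph <- water_cube(60)
  beam <- configure_beam(c(33, 33), ssd = 850)
  expect_error(transport_config(n_histories = 0))
})
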
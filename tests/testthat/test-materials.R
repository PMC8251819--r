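# Media definitions and interaction-data service.
#
# Reference anchors frozen from published compilations before implementation:
# water mass attenuation at 1 MeV 0.0707 cm^2/g (photon cross-section
# database), water collision stopping power at 1 MeV 1.849 MeV cm^2/g and
# 6 MeV CSDA range 3.05 g/cm^2 (electron stopping-power tables).

test_that("built-in media are well-formed and lookup is stable", {
  for (nm in c("water", "lung", "bone_cortical", "bone_cartilage", "air")) {
    m <- lookup_material(nm)
    expect_s3_class(m, "material")
    expect_gt(m$density, 0)
    expect_lt(abs(sum(m$composition) - 1), 1e-6)
    expect_true(all(m$mu_photo >= 0 & m$mu_compton >= 0 & m$mu_pair >= 0))
    expect_true(all(m$mu_pair[m$energy_grid < 1.022] == 0))
  }
  w <- lookup_material("water")
  expect_equal(w$density, 1.000)
  expect_equal(unname(w$composition["H"]), 0.1119, tolerance = 1e-6)
  expect_equal(unname(w$composition["O"]), 0.8881, tolerance = 1e-6)
  expect_identical(lookup_material("water"), lookup_material("water"))
  # the bone alias resolves to the configurable default
  expect_identical(lookup_material("bone")$name, "bone_cortical")
})

test_that("unknown media raise an unregistered-material error", {
  expect_error(lookup_material("unobtainium"), "unregistered")
})

test_that("lung matches the inflated-lung reference composition", {
  l <- lookup_material("lung")
  expect_equal(l$density, 0.26, tolerance = 1e-6)
  expect_equal(unname(l$composition["O"]), 0.749, tolerance = 1e-3)
  expect_equal(unname(l$composition["H"]), 0.103, tolerance = 1e-3)
})

test_that("photon attenuation reproduces the reference value at 1 MeV", {
  w <- lookup_material("water")
  mu <- photon_mu(w, 1.0)
  expect_lt(abs(mu$total - 0.0707) / 0.0707, 0.01)
  # process sum equals total
  expect_equal(mu$total, mu$photo + mu$compton + mu$pair, tolerance = 1e-12)
})

test_that("pair production is zero below threshold and density scales mu", {
  w <- lookup_material("water")
  expect_identical(photon_mu(w, 0.8)$pair, 0)
  half <- w
  half$density <- 0.5
  expect_equal(photon_mu(half, 1.0)$total, photon_mu(w, 1.0)$total / 2)
})

test_that("energies outside the table range are rejected", {
  w <- lookup_material("water")
  expect_error(photon_mu(w, 0.001), "outside")
  expect_error(photon_mu(w, 8), "outside")
  expect_error(electron_dedx(w, 9), "outside")
})

test_that("interpolated totals hit nodes exactly and stay monotone", {
  w <- lookup_material("water")
  tot <- w$mu_photo + w$mu_compton + w$mu_pair
  at_nodes <- photon_mu(w, w$energy_grid)$total
  expect_equal(at_nodes, tot * w$density, tolerance = 1e-12)
  # monotone between adjacent nodes where the table is monotone
  es <- exp(seq(log(0.011), log(0.9), length.out = 20))
  v <- photon_mu(w, es)$total
  expect_true(all(diff(v) < 0))  # table is decreasing over this range
})

test_that("collision stopping power matches the reference at 1 MeV", {
  w <- lookup_material("water")
  s <- electron_dedx(w, 1.0)
  expect_lt(abs(s$collision - 1.849) / 1.849, 0.02)
  expect_gt(s$radiative, 0)
})

test_that("restricted stopping is below unrestricted and validates cutoff", {
  w <- lookup_material("water")
  full <- electron_dedx(w, 1.0)$collision
  restr <- electron_dedx(w, 1.0, cutoff = 0.01)$collision
  expect_lt(restr, full)
  expect_gt(restr, 0)
  expect_error(electron_dedx(w, 1.0, cutoff = 1.2), "below")
})

test_that("lung/water linear stopping ratio tracks the density ratio", {
  w <- lookup_material("water")
  l <- lookup_material("lung")
  for (e in c(0.1, 1, 5)) {
    rw <- electron_dedx(l, e)$collision / electron_dedx(w, e)$collision
    expect_lt(abs(rw - l$density / w$density) / (l$density / w$density), 0.10)
  }
})

test_that("CSDA range at 6 MeV agrees with the reference within 5%", {
  w <- lookup_material("water")
  expect_lt(abs(csda_range(w, 6.0) - 3.05) / 3.05, 0.05)
})

test_that("range-cut inversion is consistent with the range integral", {
  w <- lookup_material("water")
  e <- energy_for_range(w, 0.7)
  expect_lt(abs(csda_range(w, e, linear = TRUE) * 10 - 0.7), 0.02)
  # in lung the same geometric cut corresponds to a lower energy
  expect_lt(energy_for_range(lookup_material("lung"), 0.7), e)
})

test_that("user-registered media participate in lookup", {
  w <- lookup_material("water")
  tab <- data.frame(energy_MeV = w$energy_grid, mu_photo = w$mu_photo,
                    mu_compton = w$mu_compton, mu_pair = w$mu_pair,
                    s_col = w$s_col, s_rad = w$s_rad)
  register_material("mymedium", 1.05, c(H = 0.1119, O = 0.8881), tab)
  expect_equal(lookup_material("mymedium")$density, 1.05)
  expect_error(register_material("bad", 1, c(H = 0.5, O = 0.4), tab),
               "mass fractions")
})
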
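# shared fixtures: tiny phantoms, quiet configs, a vacuum-like medium for
# deterministic helix checks, and a synthetic dose grid builder

water_cube <- function(side_mm = 120, spacing = c(3, 3, 2)) {
  build_slab_phantom(list(slab("water", side_mm)), lateral_mm = side_mm,
                     spacing = spacing)
}

# near-massless medium: charged particles advance on pure helices
register_vacuum <- function() {
  w <- lookup_material("water")
  tab <- data.frame(energy_MeV = w$energy_grid, mu_photo = w$mu_photo,
                    mu_compton = w$mu_compton, mu_pair = w$mu_pair,
                    s_col = w$s_col, s_rad = w$s_rad)
  register_material("vacuumlike", 1e-7, c(H = 0.1119, O = 0.8881), tab)
}

vacuum_grid <- function(side_mm = 200) {
  register_vacuum()
  build_slab_phantom(list(slab("vacuumlike", side_mm)), lateral_mm = side_mm,
                     spacing = c(5, 5, 5))
}

quick_config <- function(n = 2e5, seed = 1, ...) {
  transport_config(n_histories = n, seed = seed, ...)
}

# dose_grid wrapper around a synthetic array, for metric tests
synthetic_dose_grid <- function(values, spacing = c(3, 3, 2), ssd = 850,
                                field = c(66, 66)) {
  dims <- dim(values)
  grid <- structure(list(
    origin = c(-dims[1] * spacing[1] / 2, -dims[2] * spacing[2] / 2, 0),
    spacing = spacing, dims = dims, materials = "water",
    material_index = array(1L, dims), density = array(1, dims),
    slab_boundaries_mm = dims[3] * spacing[3]), class = "voxel_grid")
  structure(list(values = values, rel_stderr = array(0, dims),
                 geometry = grid,
                 beam = configure_beam(field, ssd = ssd),
                 histories = 1, energy_ledger = list(), counts = list(),
                 run_log = "synthetic"), class = "dose_grid")
}

# brute-force gamma oracle: dense-grid minimization, independent of the
# package implementation
gamma_bruteforce <- function(reference, evaluated, dose_crit = 2,
                             dist_crit = 2, step = 0.002) {
  dose_abs <- dose_crit / 100 * max(reference$values)
  vapply(seq_along(reference$positions), function(i) {
    x0 <- reference$positions[i]
    xs <- seq(max(x0 - 3 * dist_crit, min(evaluated$positions)),
              min(x0 + 3 * dist_crit, max(evaluated$positions)), by = step)
    if (!length(xs)) return(NA_real_)
    ev <- stats::approx(evaluated$positions, evaluated$values, xout = xs)$y
    sqrt(min(((xs - x0) / dist_crit)^2 +
             ((ev - reference$values[i]) / dose_abs)^2))
  }, 0)
}
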
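# Photon source model: tunable incident electron beam, analytic thin-target
# bremsstrahlung spectrum with equivalent-filtration hardening, directional
# splitting, and ideal divergent collimation.
#
# The vendor head (target, primary collimator, monitor chamber, shield,
# stacked MLC leaves, bore coils) is replaced by a point of bremsstrahlung
# emission at the target plane, an analytic spectral shape with one tunable
# hardening parameter, and an ideal divergent aperture with a constant
# transmission for blocked rays. The tunable electron-beam quantities (mean
# energy, energy spread, focal spot size) are preserved exactly.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))   # 1/2.3548

# Water-equivalent filtration (mm) applied to the thin-target spectrum.
# Calibrated once (tools/calibrate_hardening.R) so the tuned-beam
# 3.3 x 3.3 cm2 PDD at 10 cm depth, SSD 78 cm, matches the commissioning
# value of 55.59%.
SPECTRAL_HARDENING_MM <- 110

#' Incident electron beam parameters
#'
#' @param mean_energy Mean kinetic energy, MeV.
#' @param energy_fwhm FWHM of the Gaussian energy distribution, MeV.
#' @param spot_fwhm FWHM of the Gaussian radial intensity distribution of the
#'   focal spot, mm (applied per lateral axis with sigma = FWHM/2.3548).
#' @return An `electron_beam` object. Defaults are the commissioned values
#'   (6.0 MeV, 1.5 MeV FWHM, 1.0 mm FWHM).
#' @export
electron_beam <- function(mean_energy = 6.0, energy_fwhm = 1.5,
                          spot_fwhm = 1.0) {
  stopifnot(mean_energy > 0, energy_fwhm >= 0, spot_fwhm >= 0)
  structure(list(mean_energy = mean_energy, energy_fwhm = energy_fwhm,
                 spot_fwhm = spot_fwhm), class = "electron_beam")
}

#' Directional-splitting configuration
#'
#' @param split_number Photons generated per bremsstrahlung event aimed at the
#'   scoring region (>= 1).
#' @param split_radius Radius of the directed cone at the phantom surface, mm.
#' @return A `dbs_config` object.
#' @export
dbs_config <- function(split_number = 100, split_radius = 100) {
  stopifnot(split_number >= 1, split_radius > 0)
  structure(list(split_number = as.integer(split_number),
                 split_radius = split_radius), class = "dbs_config")
}

#' Aperture specification
#'
#' Rectangular openings defined at the isocenter plane. Openings must not
#' overlap and must fit inside the maximum deliverable field (274 x 241 mm).
#'
#' @param openings Numeric matrix with columns `xmin, xmax, ymin, ymax` (mm
#'   at isocenter), one opening per row.
#' @param transmission Leakage fraction applied to blocked rays, in `[0, 1)`.
#' @return An `aperture` object.
#' @export
aperture <- function(openings, transmission = 0.005) {
  openings <- matrix(as.numeric(openings), ncol = 4,
                     dimnames = list(NULL, c("xmin", "xmax", "ymin", "ymax")))
  stopifnot(all(openings[, 2] > openings[, 1]),
            all(openings[, 4] > openings[, 3]),
            transmission >= 0, transmission < 1)
  if (any(openings[, 1] < -MAX_FIELD_MM[1] / 2) ||
      any(openings[, 2] > MAX_FIELD_MM[1] / 2) ||
      any(openings[, 3] < -MAX_FIELD_MM[2] / 2) ||
      any(openings[, 4] > MAX_FIELD_MM[2] / 2))
    stop("aperture opening exceeds the maximum 274 x 241 mm field")
  if (nrow(openings) > 1) {
    for (i in seq_len(nrow(openings) - 1)) for (j in (i + 1):nrow(openings)) {
      if (openings[i, 1] < openings[j, 2] && openings[j, 1] < openings[i, 2] &&
          openings[i, 3] < openings[j, 4] && openings[j, 3] < openings[i, 4])
        stop("aperture openings overlap")
    }
  }
  structure(list(openings = openings, transmission = transmission),
            class = "aperture")
}

#' Centered rectangular aperture for a square/rectangular field
#'
#' @param field_size Field size at isocenter, mm (`c(crossline, inline)` or a
#'   scalar for a square field).
#' @param transmission Leakage fraction for blocked rays.
#' @return An `aperture` with one centered opening.
#' @export
aperture_field <- function(field_size, transmission = 0.005) {
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  aperture(matrix(c(-field_size[1] / 2, field_size[1] / 2,
                    -field_size[2] / 2, field_size[2] / 2), 1, 4),
           transmission = transmission)
}

#' Read an aperture from a delimited text file
#'
#' One rectangle per line: `xmin xmax ymin ymax` in mm at the isocenter
#' plane; lines starting with `#` are ignored. An example off-axis aperture
#' ships under `extdata/apertures/`.
#'
#' @param path File path.
#' @param transmission Leakage fraction for blocked rays.
#' @return An `aperture`.
#' @export
read_aperture <- function(path, transmission = 0.005) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("xmin", "xmax", "ymin", "ymax"))
  aperture(as.matrix(tab), transmission = transmission)
}

#' Sample incident electrons
#'
#' Energies are Gaussian (truncated to positive values) and focal-spot
#' offsets lateral Gaussian; electrons travel along +Z toward the target.
#'
#' @param params An [electron_beam()].
#' @param n Number of electrons.
#' @return Data frame of phase-space rows: `kind`, `energy` (MeV),
#'   `x, y, z` (mm), `ux, uy, uz`, `weight`.
#' @export
sample_incident_electron <- function(params, n = 1) {
  stopifnot(inherits(params, "electron_beam"))
  se <- params$energy_fwhm * FWHM_TO_SIGMA
  ss <- params$spot_fwhm * FWHM_TO_SIGMA
  e <- params$mean_energy + se * stats::rnorm(n)
  while (any(bad <- e <= 0))
    e[bad] <- params$mean_energy + se * stats::rnorm(sum(bad))
  data.frame(kind = "electron", energy = e,
             x = ss * stats::rnorm(n), y = ss * stats::rnorm(n), z = -SAD_MM,
             ux = 0, uy = 0, uz = 1, weight = 1)
}

#' Sample the hardened thin-target bremsstrahlung spectrum
#'
#' Spectral shape `(1/k)(1 - k/E0)` (Schiff-type thin target) multiplied by
#' `exp(-mu_water(k) * t)` for an equivalent water filtration thickness `t`
#' that is the model's single spectral tuning knob.
#'
#' @param n Number of photons.
#' @param e0 Endpoint (electron kinetic) energy, MeV; may be a vector of
#'   length `n`.
#' @param hardening_mm Equivalent filtration, mm of water.
#' @param kmin Low-energy cutoff of the sampled spectrum, MeV.
#' @return Photon energies, MeV.
#' @export
sample_spectrum <- function(n, e0, hardening_mm = SPECTRAL_HARDENING_MM,
                            kmin = 0.05) {
  w <- lookup_material("water")
  e0 <- rep_len(e0, n)
  mu_min <- min(photon_mu(w, w$energy_grid[w$energy_grid >= kmin])$total)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    k <- kmin * exp(stats::runif(length(todo)) * log(e0[todo] / kmin))
    mu <- photon_mu(w, k)$total
    acc <- (1 - k / e0[todo]) * exp(-(mu - mu_min) * hardening_mm / 10)
    keep <- stats::runif(length(todo)) < acc
    out[todo[keep]] <- k[keep]
    todo <- todo[!keep]
  }
  out
}

# forward-peaked FFF angular intensity; theta_c = me/E0 (rad)
.brems_angular_pdf <- function(theta, e0) {
  tc <- 0.51099895 / e0
  1 / (1 + (theta / tc)^2)^2
}

#' Convert an incident electron to bremsstrahlung photons with splitting
#'
#' Each event draws `split_number` candidate photons from the forward-peaked
#' angular distribution with weight `1/split_number`. Candidates inside the
#' directed cone (subtending `split_radius` at the phantom surface) are kept;
#' candidates outside are Russian-rouletted with survival `1/split_number`
#' (weight restored to 1), so the expected emitted weight is conserved.
#'
#' @param electron One-row phase-space data frame from
#'   [sample_incident_electron()].
#' @param dbs A [dbs_config()].
#' @param ssd Source-to-surface distance used to convert the split radius to
#'   a cone angle, mm.
#' @param hardening_mm Spectral hardening, mm water.
#' @param kmin Photon energy cutoff, MeV; electrons below it yield no photons.
#' @return Phase-space data frame of photons (possibly zero rows).
#' @export
generate_bremsstrahlung <- function(electron, dbs = dbs_config(), ssd = 850,
                                    hardening_mm = SPECTRAL_HARDENING_MM,
                                    kmin = 0.05) {
  stopifnot(inherits(dbs, "dbs_config"))
  if (electron$energy <= kmin) return(empty_phase_space())
  n <- dbs$split_number
  cone <- atan(dbs$split_radius / ssd)
  # sample polar angle from the angular pdf by inversion of its CDF on a grid
  tc <- 0.51099895 / electron$energy
  tgrid <- seq(0, pi / 2, length.out = 2048)
  pdf <- .brems_angular_pdf(tgrid, electron$energy) * sin(tgrid)
  cdf <- cumsum(pdf); cdf <- cdf / cdf[length(cdf)]
  theta <- stats::approx(cdf, tgrid, xout = stats::runif(n), rule = 2)$y
  phi <- stats::runif(n, 0, 2 * pi)
  w <- rep(1 / n, n)
  directed <- theta <= cone
  keep <- directed
  if (any(!directed)) {
    idx <- which(!directed)
    survive <- stats::runif(length(idx)) < 1 / n
    w[idx[survive]] <- 1
    keep[idx[survive]] <- TRUE
  }
  if (!any(keep)) return(empty_phase_space())
  theta <- theta[keep]; phi <- phi[keep]; w <- w[keep]
  k <- sample_spectrum(length(theta), electron$energy, hardening_mm, kmin)
  data.frame(kind = "photon", energy = k,
             x = electron$x, y = electron$y, z = electron$z,
             ux = sin(theta) * cos(phi), uy = sin(theta) * sin(phi),
             uz = cos(theta), weight = w)
}

empty_phase_space <- function() {
  data.frame(kind = character(), energy = numeric(), x = numeric(),
             y = numeric(), z = numeric(), ux = numeric(), uy = numeric(),
             uz = numeric(), weight = numeric())
}

#' Collimate photons against an aperture
#'
#' Rays are projected to the isocenter plane (z = 0 in the beam frame);
#' photons inside an opening pass unchanged, photons outside have their
#' weight multiplied by the transmission fraction (dropped when it is 0).
#' Rays not moving toward the phantom are blocked.
#'
#' @param photons Phase-space data frame (beam-frame coordinates, source at
#'   negative z).
#' @param ap An [aperture()].
#' @return The surviving phase-space rows with updated weights.
#' @export
collimate <- function(photons, ap) {
  stopifnot(inherits(ap, "aperture"))
  if (nrow(photons) == 0) return(photons)
  ok <- photons$uz > 1e-12
  photons <- photons[ok, , drop = FALSE]
  if (nrow(photons) == 0) return(photons)
  t <- -photons$z / photons$uz
  px <- photons$x + t * photons$ux
  py <- photons$y + t * photons$uy
  inside <- rep(FALSE, nrow(photons))
  for (i in seq_len(nrow(ap$openings))) {
    o <- ap$openings[i, ]
    inside <- inside | (px >= o[1] & px <= o[2] & py >= o[3] & py <= o[4])
  }
  photons$weight[!inside] <- photons$weight[!inside] * ap$transmission
  photons[photons$weight > 0, , drop = FALSE]
}
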
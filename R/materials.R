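# Media definitions and per-process photon / electron interaction data.
#
# Each medium carries mass attenuation coefficients per photon process
# (photoelectric, Compton, pair) and electron mass stopping powers (collision,
# radiative) on a common 80-point log energy grid from 10 keV to 7 MeV,
# shipped as delimited text under inst/extdata/materials/. Coefficients are
# interpolated log-log between grid nodes, the standard practice for
# attenuation data.

# element constants used for mixture rules (Z/A, radiation length)
.elements <- data.frame(
  sym = c("H","C","N","O","Na","Mg","P","S","Cl","Ar","K","Ca"),
  Z   = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20),
  A   = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
          35.45, 39.948, 39.098, 40.078),
  stringsAsFactors = FALSE
)

.mat_env <- new.env(parent = emptyenv())

.element_row <- function(sym) {
  i <- match(sym, .elements$sym)
  if (anyNA(i)) stop("unknown element symbol: ",
                     paste(sym[is.na(i)], collapse = ", "))
  .elements[i, , drop = FALSE]
}

.parse_material_file <- function(path, name) {
  lines <- readLines(path, n = 10L)
  hdr <- lines[startsWith(lines, "#")]
  density <- as.numeric(sub(".*density_g_cm3:\\s*", "",
                            hdr[grepl("density_g_cm3", hdr)]))
  comp_str <- sub(".*composition:\\s*", "", hdr[grepl("composition:", hdr)])
  kv <- strsplit(strsplit(trimws(comp_str), "\\s+")[[1]], "=")
  comp <- vapply(kv, function(p) as.numeric(p[2]), 0)
  names(comp) <- vapply(kv, `[`, "", 1)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_material(name, density, comp, tab)
}

#' Construct a material from its composition and physics table
#'
#' @param name Identifier for the medium.
#' @param density Mass density in g/cm^3.
#' @param composition Named numeric vector of element mass fractions
#'   (must sum to 1 within 1e-6).
#' @param table Data frame with columns `energy_MeV`, `mu_photo`,
#'   `mu_compton`, `mu_pair` (mass attenuation, cm^2/g) and `s_col`, `s_rad`
#'   (mass stopping powers, MeV cm^2/g).
#' @return An object of class `material`.
#' @keywords internal
new_material <- function(name, density, composition, table) {
  stopifnot(density > 0)
  if (abs(sum(composition) - 1) > 1e-6)
    stop("material '", name, "': mass fractions sum to ", sum(composition),
         ", expected 1 within 1e-6")
  need <- c("energy_MeV", "mu_photo", "mu_compton", "mu_pair", "s_col", "s_rad")
  if (!all(need %in% names(table))) stop("material table missing columns")
  if (any(table[need[-1]] < 0)) stop("negative coefficient in material table")
  if (any(table$mu_pair[table$energy_MeV < 1.022] != 0))
    stop("pair-production coefficient must be 0 below 1.022 MeV")
  el <- .element_row(names(composition))
  za <- sum(composition * el$Z / el$A)
  # radiation length (g/cm^2) via the usual per-element approximation
  x0_el <- 716.408 * el$A / (el$Z * (el$Z + 1) * log(287 / sqrt(el$Z)))
  x0 <- 1 / sum(composition / x0_el)
  structure(list(
    name = name, density = density, composition = composition,
    energy_grid = table$energy_MeV,
    mu_photo = table$mu_photo, mu_compton = table$mu_compton,
    mu_pair = table$mu_pair, s_col = table$s_col, s_rad = table$s_rad,
    z_over_a = za, x0_g_cm2 = x0
  ), class = "material")
}

.builtin_materials <- c("water", "lung", "bone_cortical", "bone_cartilage", "air")

.load_builtin <- function(name) {
  path <- system.file("extdata", "materials", paste0(name, ".tsv"),
                      package = "mrdose", mustWork = TRUE)
  .parse_material_file(path, name)
}

#' Look up a registered medium
#'
#' Built-in media are `water`, `lung` (ICRU-44 inflated lung), cortical and
#' cartilage bone (`bone_cortical`, `bone_cartilage`) and `air`. The alias
#' `bone` resolves to `getOption("mrdose.bone", "bone_cortical")` because the
#' appropriate ICRU-44 bone composition depends on the use case. User media
#' registered with [register_material()] are also found here.
#'
#' @param name Medium identifier.
#' @return A `material` object with density, composition and interaction
#'   tables; repeated calls return identical data.
#' @examples
#' w <- lookup_material("water")
#' w$density
#' @export
lookup_material <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  if (name == "bone") name <- getOption("mrdose.bone", "bone_cortical")
  if (!is.null(.mat_env[[name]])) return(.mat_env[[name]])
  if (name %in% .builtin_materials) {
    m <- .load_builtin(name)
    assign(name, m, envir = .mat_env)
    return(m)
  }
  stop("unregistered material: '", name, "'")
}

#' Register a user-defined medium
#'
#' @inheritParams new_material
#' @return The registered `material`, invisibly.
#' @export
register_material <- function(name, density, composition, table) {
  m <- new_material(name, density, composition, table)
  assign(name, m, envir = .mat_env)
  invisible(m)
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  (%.4g g/cm3)\n", x$name, x$density))
  cat("  composition:",
      paste(sprintf("%s=%.4g", names(x$composition), x$composition),
            collapse = " "), "\n")
  cat(sprintf("  energy grid: %d points, %.3g - %.3g MeV\n",
              length(x$energy_grid), min(x$energy_grid), max(x$energy_grid)))
  invisible(x)
}

.loglog_interp <- function(xgrid, ygrid, x) {
  # log-log interpolation; zeros in y handled by linear fallback on that span
  y <- numeric(length(x))
  pos <- ygrid > 0
  if (all(pos)) {
    y <- exp(stats::approx(log(xgrid), log(ygrid), xout = log(x))$y)
  } else {
    # mixed zero/positive table (e.g. pair production): linear below the
    # first positive node, log-log above
    y <- stats::approx(xgrid, ygrid, xout = x)$y
    ip <- which(pos)
    if (length(ip) >= 2) {
      hi <- x >= xgrid[ip[1]]
      y[hi] <- exp(stats::approx(log(xgrid[ip]), log(ygrid[ip]),
                                 xout = log(x[hi]), rule = 2)$y)
    }
  }
  y
}

.check_energy_range <- function(material, energy) {
  rng <- range(material$energy_grid)
  if (any(energy < rng[1] - 1e-12) || any(energy > rng[2] + 1e-12))
    stop("energy ", paste(energy[energy < rng[1] | energy > rng[2]],
                          collapse = ", "),
         " MeV outside table range [", rng[1], ", ", rng[2], "] for '",
         material$name, "'")
}

#' Per-process linear photon attenuation coefficients
#'
#' @param material A `material` object.
#' @param energy Photon energies in MeV, within the table range
#'   (10 keV - 7 MeV); no silent extrapolation.
#' @return Data frame with linear coefficients (cm^-1): `photo`, `compton`,
#'   `pair` and their sum `total`.
#' @examples
#' photon_mu(lookup_material("water"), 1.0)
#' @export
photon_mu <- function(material, energy) {
  stopifnot(inherits(material, "material"), is.numeric(energy))
  .check_energy_range(material, energy)
  g <- material$energy_grid
  rho <- material$density
  data.frame(
    photo   = .loglog_interp(g, material$mu_photo, energy) * rho,
    compton = .loglog_interp(g, material$mu_compton, energy) * rho,
    pair    = ifelse(energy < 1.022, 0,
                     .loglog_interp(g, material$mu_pair, energy)) * rho,
    total   = NA_real_
  ) -> out
  out$total <- out$photo + out$compton + out$pair
  out
}

#' Electron stopping powers, optionally restricted
#'
#' Collision stopping is restricted to energy transfers below `cutoff` using
#' the standard Moller closed form; with `cutoff >= energy/2` (or `NULL`) the
#' unrestricted value is returned (the maximum transfer to an indistinguishable
#' secondary is half the kinetic energy).
#'
#' @param material A `material` object.
#' @param energy Electron kinetic energy, MeV (10 keV - 7 MeV).
#' @param cutoff Delta-ray production threshold, MeV; must be `< energy`.
#' @return List with linear stopping powers in MeV/cm: `collision`,
#'   `radiative`.
#' @export
electron_dedx <- function(material, energy, cutoff = NULL) {
  stopifnot(inherits(material, "material"), is.numeric(energy))
  .check_energy_range(material, energy)
  if (!is.null(cutoff) && any(cutoff >= energy))
    stop("cutoff must be below the electron kinetic energy")
  rho <- material$density
  scol <- .loglog_interp(material$energy_grid, material$s_col, energy)
  srad <- .loglog_interp(material$energy_grid, material$s_rad, energy)
  if (!is.null(cutoff)) {
    me <- 0.51099895
    tau <- energy / me
    gam <- tau + 1
    b2 <- 1 - 1 / gam^2
    eta <- pmin(cutoff / energy, 0.5)
    # G(tau, eta) - G(tau, 1/2): difference between restricted and
    # unrestricted Moller terms
    gres <- -1 - b2 + log(4 * (1 - eta) * eta) + 1 / (1 - eta) +
      (1 - b2) * (tau^2 * eta^2 / 2 + (2 * tau + 1) * log(1 - eta))
  gfull <- -1 - b2 + log(4 * 0.25) + 2 +
      (1 - b2) * (tau^2 / 8 + (2 * tau + 1) * log(0.5))
    scol <- scol + 0.1535363 * material$z_over_a / b2 * (gres - gfull)
  }
  list(collision = scol * rho, radiative = srad * rho)
}

#' Continuous-slowing-down range
#'
#' Integrates 1/(total mass stopping power) over the table grid from the table
#' minimum up to `energy`.
#'
#' @param material A `material` object.
#' @param energy Kinetic energy, MeV.
#' @param linear If `TRUE`, return the range in cm for the material density;
#'   otherwise in g/cm^2.
#' @return CSDA range.
#' @export
csda_range <- function(material, energy, linear = FALSE) {
  g <- material$energy_grid
  e <- c(g[g < energy], energy)
  stot <- .loglog_interp(g, material$s_col + material$s_rad, e)
  r <- sum(diff(e) * 0.5 * (1 / stot[-1] + 1 / stot[-length(e)]))
  if (linear) r / material$density else r
}

#' Energy cutoff equivalent to a geometric range cut
#'
#' Inverts the CSDA range to find the kinetic energy whose range equals
#' `range_mm` in this medium; used to convert a production-threshold distance
#' into a per-material transport cutoff.
#'
#' @param material A `material` object.
#' @param range_mm Range cut in mm.
#' @return Kinetic energy in MeV (never below the table minimum).
#' @export
energy_for_range <- function(material, range_mm) {
  target <- range_mm / 10 * material$density  # g/cm^2
  g <- material$energy_grid
  rr <- vapply(g, function(E) csda_range(material, E), 0)
  if (target <= rr[1]) return(g[1])
  if (target >= rr[length(rr)]) return(g[length(g)])
  exp(stats::approx(log(rr), log(g), xout = log(target))$y)
}
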
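# Voxelized slab phantoms and beam geometry.
#
# Machine coordinate system (right-handed, mm): at gantry 0 the beam travels
# along +Z (depth into the phantom), X is crossline (MLC travel direction),
# Y is inline and carries the static magnetic field. The phantom surface is
# the plane z = 0; the isocenter sits on the central axis at depth
# (SAD - SSD). Gantry rotation turns the source about the isocenter in the
# X-Z plane (rotation axis = inline = B direction), so the electron-return
# asymmetry shows up in crossline profiles. Voxel indices are zero-based and
# half-open in world coordinates.

SAD_MM <- 900
MAX_FIELD_MM <- c(274, 241)

#' Slab specification
#'
#' @param material Medium identifier resolvable by [lookup_material()].
#' @param thickness_mm Slab thickness along the beam axis, mm (> 0).
#' @return A `slab` object.
#' @export
slab <- function(material, thickness_mm) {
  stopifnot(is.character(material), length(material) == 1)
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("slab thickness must be positive")
  lookup_material(material)  # fail early on unknown media
  structure(list(material = material, thickness_mm = thickness_mm),
            class = "slab")
}

#' Build a voxelized slab phantom
#'
#' Stacks slabs along the beam (Z) axis starting at the surface z = 0,
#' homogeneous laterally. Slab boundaries are snapped to the nearest voxel
#' plane; the snapped boundaries are recorded in the result.
#'
#' @param slabs List of [slab()] objects, ordered from the surface downward.
#' @param lateral_mm Lateral extent (X and Y), mm; centered on the beam axis.
#' @param spacing Voxel spacing `c(dx, dy, dz)` in mm. The default
#'   `c(3, 3, 2)` (2 mm along the beam) matches depth-dose / profile scoring;
#'   use `c(2, 2, 2)` for output-factor runs.
#' @return A `voxel_grid` object: `origin` (corner of voxel (0,0,0)),
#'   `spacing`, `dims`, `materials` (palette of medium names),
#'   `material_index` (1-based palette index per voxel, nx x ny x nz array),
#'   `density` (g/cm^3 per voxel), and `slab_boundaries_mm` (snapped).
#' @examples
#' ph <- build_slab_phantom(list(slab("water", 50), slab("lung", 30),
#'                               slab("water", 50)), lateral_mm = 300)
#' ph$dims
#' @export
build_slab_phantom <- function(slabs, lateral_mm,
                               spacing = c(3, 3, 2)) {
  if (length(slabs) == 0) stop("at least one slab is required")
  if (!all(vapply(slabs, inherits, TRUE, "slab")))
    stop("slabs must be a list of slab() objects")
  if (!is.numeric(lateral_mm) || lateral_mm <= 0 || any(spacing <= 0))
    stop("lateral size and spacing must be positive")
  th <- vapply(slabs, `[[`, 0, "thickness_mm")
  total <- sum(th)
  nz <- max(1L, as.integer(round(total / spacing[3])))
  nx <- max(1L, as.integer(round(lateral_mm / spacing[1])))
  ny <- max(1L, as.integer(round(lateral_mm / spacing[2])))
  # snap slab boundaries to voxel planes
  bounds <- cumsum(th)
  snapped <- round(bounds / spacing[3]) * spacing[3]
  snapped[length(snapped)] <- nz * spacing[3]
  mats <- unique(vapply(slabs, `[[`, "", "material"))
  zc <- (seq_len(nz) - 0.5) * spacing[3]
  slab_of <- findInterval(zc, c(0, snapped), rightmost.closed = TRUE)
  slab_of[slab_of > length(slabs)] <- length(slabs)
  mat_name_z <- vapply(slabs, `[[`, "", "material")[slab_of]
  dens_z <- vapply(mat_name_z, function(m) lookup_material(m)$density, 0)
  idx_z <- match(mat_name_z, mats)
  material_index <- array(rep(idx_z, each = nx * ny), dim = c(nx, ny, nz))
  density <- array(rep(dens_z, each = nx * ny), dim = c(nx, ny, nz))
  structure(list(
    origin = c(-nx * spacing[1] / 2, -ny * spacing[2] / 2, 0),
    spacing = spacing, dims = c(nx, ny, nz),
    materials = mats, material_index = material_index, density = density,
    slab_boundaries_mm = snapped
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  media:", paste(x$materials, collapse = ", "), "\n")
  invisible(x)
}

#' World to voxel index (zero-based)
#'
#' @param grid A `voxel_grid`.
#' @param xyz Numeric length-3 world position (mm) or 3-column matrix.
#' @return Integer zero-based voxel indices (matrix), half-open convention.
#' @export
world_to_voxel <- function(grid, xyz) {
  m <- matrix(xyz, ncol = 3)
  idx <- sweep(m, 2, grid$origin)
  idx <- sweep(idx, 2, grid$spacing, "/")
  matrix(as.integer(floor(idx + 1e-12)), ncol = 3)
}

#' Voxel index (zero-based) to world position of the voxel center
#'
#' @param grid A `voxel_grid`.
#' @param ijk Integer zero-based indices, length-3 or 3-column matrix.
#' @return World coordinates of voxel centers, mm.
#' @export
voxel_to_world <- function(grid, ijk) {
  m <- matrix(ijk, ncol = 3)
  sweep(sweep(m + 0.5, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Configure the beam geometry
#'
#' The source sits at distance SAD = 900 mm from the isocenter; the isocenter
#' lies on the beam central axis at depth `SAD - ssd` below the surface.
#' Gantry rotation turns the source about the isocenter in the crossline-depth
#' plane; SAD is preserved. The magnetic field is uniform along inline (+Y)
#' by default.
#'
#' @param field_size Field size `c(crossline, inline)` at isocenter, mm (a
#'   scalar is taken as a square field); limited to the physical maximum
#'   274 x 241 mm.
#' @param ssd Source-to-surface distance, mm.
#' @param gantry_angle Gantry angle in degrees, in `[0, 360)`; 0 points the
#'   beam straight down the +Z axis.
#' @param b_field Magnetic flux density vector, tesla.
#' @return A `beam_geometry` with `source_mm`, unit `beam_axis`, and the
#'   3x3 `rotation` taking beam-frame vectors to world coordinates.
#' @examples
#' configure_beam(c(66, 66), ssd = 850)
#' @export
configure_beam <- function(field_size, ssd, gantry_angle = 0,
                           b_field = c(0, 0.35, 0)) {
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  stopifnot(length(field_size) == 2, all(field_size > 0))
  if (field_size[1] > MAX_FIELD_MM[1] || field_size[2] > MAX_FIELD_MM[2])
    stop("field size exceeds the physical maximum 274 x 241 mm")
  if (gantry_angle < 0 || gantry_angle >= 360)
    stop("gantry angle must be in [0, 360)")
  stopifnot(ssd > 0, length(b_field) == 3)
  iso <- c(0, 0, SAD_MM - ssd)
  a <- gantry_angle * pi / 180
  # rotation about +Y (inline) through the isocenter; gantry 0 = beam along +Z
  rot <- matrix(c(cos(a), 0, sin(a),
                  0,      1, 0,
                  -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  axis0 <- c(0, 0, 1)
  src0 <- iso - SAD_MM * axis0
  beam_axis <- as.numeric(rot %*% axis0)
  source_mm <- iso + as.numeric(rot %*% (src0 - iso))
  structure(list(
    sad = SAD_MM, ssd = ssd, gantry_angle = gantry_angle,
    field_size = field_size, b_field = b_field, isocenter_mm = iso,
    source_mm = source_mm, beam_axis = beam_axis, rotation = rot
  ), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> %.3g x %.3g mm at iso, SSD %.4g mm, gantry %g deg\n",
              x$field_size[1], x$field_size[2], x$ssd, x$gantry_angle))
  cat(sprintf("  B = (%.3g, %.3g, %.3g) T\n",
              x$b_field[1], x$b_field[2], x$b_field[3]))
  invisible(x)
}

#' Total phantom mass
#'
#' @param grid A `voxel_grid`.
#' @return Mass in grams (density times voxel volume, summed).
#' @export
phantom_mass <- function(grid) {
  sum(grid$density) * prod(grid$spacing) / 1000
}
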
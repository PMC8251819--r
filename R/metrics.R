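# Curve extraction (PDD, lateral profiles, output factors) and the
# dose-comparison metrics: gamma index, distance to agreement, penumbra
# statistics, region-restricted dose differences.
#
# Normalization conventions: depth-dose curves are normalized to their
# maximum (100%); lateral profiles to the average of the three largest
# values. All comparison metrics operate on the normalized curves, and the
# gamma dose difference is normalized globally to the reference curve
# maximum.

#' Construct a 1-D dose curve
#'
#' @param positions Strictly increasing positions, mm (depth below the
#'   surface for PDDs, off-axis distance for profiles).
#' @param values Normalized dose values, %.
#' @param axis One of `"depth"`, `"crossline"`, `"inline"`.
#' @param normalization `"max"` (PDD) or `"mean3max"` (profiles).
#' @param stderr Optional per-point relative standard errors.
#' @param meta Optional list (depth, SSD, field size, ...).
#' @return A `profile1d` object.
#' @export
profile1d <- function(positions, values, axis = "depth",
                      normalization = c("max", "mean3max"), stderr = NULL,
                      meta = list()) {
  normalization <- match.arg(normalization)
  stopifnot(length(positions) == length(values),
            all(diff(positions) > 0), all(values >= 0))
  if (normalization == "max" && abs(max(values) - 100) > 1e-9)
    stop("PDD curves must be normalized so max(values) == 100")
  structure(list(positions = positions, values = values, axis = axis,
                 normalization = normalization, stderr = stderr, meta = meta),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %s, %d points, %.4g..%.4g mm (%s-normalized)\n",
              x$axis, length(x$positions), min(x$positions),
              max(x$positions), x$normalization))
  invisible(x)
}

# trilinear interpolation of a 3-D array at world coordinates
.interp3 <- function(arr, grid, xyz) {
  f <- (xyz - grid$origin) / grid$spacing - 0.5
  i0 <- pmin(pmax(floor(f), 0), grid$dims - 2)
  w <- pmin(pmax(f - i0, 0), 1)
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ww <- (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    v <- v + ww * arr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  v
}

#' Central-axis dose at a depth
#'
#' With `radius_mm = 0`, trilinear interpolation of the dose array at the
#' beam central axis (crossline = inline = 0) and the requested depth.
#' With a positive radius, the mean over all voxels of the nearest depth
#' plane whose centers lie within `radius_mm` of the axis — the usual
#' small-scoring-volume estimate for point quantities such as output
#' factors.
#'
#' @param dose A `dose_grid`.
#' @param depth_mm Depth below the surface, mm.
#' @param radius_mm Radius of the averaged central region, mm.
#' @return List with `dose` (MeV/g per history) and `rel_stderr`.
#' @export
central_axis_dose <- function(dose, depth_mm, radius_mm = 0) {
  g <- dose$geometry
  if (radius_mm <= 0) {
    return(list(dose = .interp3(dose$values, g, c(0, 0, depth_mm)),
                rel_stderr = .interp3(dose$rel_stderr, g, c(0, 0, depth_mm))))
  }
  k <- min(g$dims[3], max(1, round(depth_mm / g$spacing[3] + 0.5)))
  xc <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$spacing[1]
  yc <- g$origin[2] + (seq_len(g$dims[2]) - 0.5) * g$spacing[2]
  sel <- outer(xc^2, yc^2, "+") <= radius_mm^2
  if (!any(sel)) stop("radius_mm smaller than the voxel spacing")
  v <- dose$values[, , k][sel]
  e <- (dose$rel_stderr[, , k] * dose$values[, , k])[sel]
  m <- mean(v)
  list(dose = m,
       rel_stderr = if (m > 0) sqrt(sum(e^2)) / (length(v) * m) else 0)
}

#' Extract the central-axis percent depth dose
#'
#' For a gantry-0 beam the central voxel column is used directly; for an
#' oblique beam the dose array is resampled along the rotated central axis
#' with trilinear interpolation. Averaging over a small lateral
#' neighbourhood of columns reduces statistical noise for broad fields.
#'
#' @param dose A `dose_grid`.
#' @param beam Beam geometry; defaults to the one stored with the run.
#' @param lateral_radius_vox Lateral half-width (in voxels) of the averaged
#'   central region; 0 = single column.
#' @return A `profile1d` (axis `"depth"`, max-normalized to 100%).
#' @export
extract_pdd <- function(dose, beam = dose$beam, lateral_radius_vox = 0) {
  g <- dose$geometry
  if (all(dose$values == 0)) stop("all-zero dose grid")
  nz <- g$dims[3]
  zc <- (seq_len(nz) - 0.5) * g$spacing[3]
  if (abs(beam$gantry_angle) < 1e-9) {
    ic <- world_to_voxel(g, c(0, 0, zc[1]))[1, 1:2] + 1  # 1-based center
    rx <- max(1, ic[1] - lateral_radius_vox):min(g$dims[1],
                                                 ic[1] + lateral_radius_vox)
    ry <- max(1, ic[2] - lateral_radius_vox):min(g$dims[2],
                                                 ic[2] + lateral_radius_vox)
    vals <- apply(dose$values[rx, ry, , drop = FALSE], 3, mean)
    nsub <- length(rx) * length(ry)
    errs <- sqrt(apply((dose$rel_stderr[rx, ry, , drop = FALSE] *
                        dose$values[rx, ry, , drop = FALSE])^2, 3, sum)) /
      pmax(vals * nsub, 1e-300)
  } else {
    # entry point of the central axis into the phantom, then resample
    src <- beam$source_mm; ax <- beam$beam_axis
    tz <- (0 - src[3]) / ax[3]
    entry <- src + tz * ax
    vals <- vapply(zc, function(d)
      .interp3(dose$values, g, entry + d * ax), 0)
    errs <- vapply(zc, function(d)
      .interp3(dose$rel_stderr, g, entry + d * ax), 0)
  }
  if (max(vals) <= 0) stop("all-zero dose along the central axis")
  sc <- 100 / max(vals)
  profile1d(zc, vals * sc, axis = "depth", normalization = "max",
            stderr = errs,
            meta = list(ssd = beam$ssd, field_size = beam$field_size,
                        lateral_radius_vox = lateral_radius_vox))
}

#' Extract a lateral beam profile
#'
#' @param dose A `dose_grid`.
#' @param depth_mm Requested depth; the nearest voxel plane is used and
#'   recorded in `meta$depth_used_mm`.
#' @param axis `"crossline"` (X) or `"inline"` (Y).
#' @param average_rows Number of central rows averaged across the orthogonal
#'   lateral axis (odd; reduces noise).
#' @param average_planes Number of depth planes averaged around the
#'   requested depth (odd); useful where dose varies slowly with depth.
#' @return A `profile1d` normalized to the mean of its three largest values.
#' @export
extract_profile <- function(dose, depth_mm, axis = c("crossline", "inline"),
                            average_rows = 1, average_planes = 1) {
  axis <- match.arg(axis)
  g <- dose$geometry
  nz <- g$dims[3]
  if (depth_mm < 0 || depth_mm > nz * g$spacing[3])
    stop("depth ", depth_mm, " mm outside the phantom")
  k <- min(nz, max(1, round(depth_mm / g$spacing[3] + 0.5)))
  depth_used <- (k - 0.5) * g$spacing[3]
  ic <- world_to_voxel(g, c(0, 0, depth_used))[1, ] + 1
  h <- (average_rows - 1) %/% 2
  hz <- (average_planes - 1) %/% 2
  rz <- max(1, k - hz):min(nz, k + hz)
  if (axis == "crossline") {
    ry <- max(1, ic[2] - h):min(g$dims[2], ic[2] + h)
    sl <- dose$values[, ry, rz, drop = FALSE]
    vals <- rowMeans(matrix(sl, nrow = g$dims[1]))
    pos <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$spacing[1]
  } else {
    rx <- max(1, ic[1] - h):min(g$dims[1], ic[1] + h)
    sl <- aperm(dose$values[rx, , rz, drop = FALSE], c(2, 1, 3))
    vals <- rowMeans(matrix(sl, nrow = g$dims[2]))
    pos <- g$origin[2] + (seq_len(g$dims[2]) - 0.5) * g$spacing[2]
  }
  div <- mean(sort(vals, decreasing = TRUE)[1:3])
  if (div <= 0) stop("all-zero dose in the requested plane")
  profile1d(pos, vals / div * 100, axis = axis, normalization = "mean3max",
            meta = list(depth_requested_mm = depth_mm,
                        depth_used_mm = depth_used))
}

#' Gamma-index comparison of two curves
#'
#' Global gamma: the dose difference is normalized to the reference curve's
#' global maximum. For each reference point the minimum of
#' `sqrt((dx/dist_crit)^2 + (dD/dose_crit)^2)` is searched over a window of
#' +/- 3 x `dist_crit` with 0.1 mm sub-sampling of the linearly interpolated
#' evaluated curve.
#'
#' @param reference,evaluated `profile1d` objects with overlapping ranges.
#' @param dose_crit Dose criterion, % of the reference global maximum.
#' @param dist_crit Distance criterion, mm.
#' @return A `gamma_result`: per-point `gamma`, `pass_rate` (%), criteria.
#' @export
compute_gamma <- function(reference, evaluated, dose_crit = 2,
                          dist_crit = 2) {
  stopifnot(inherits(reference, "profile1d"), inherits(evaluated, "profile1d"))
  rx <- reference$positions; rv <- reference$values
  ex <- evaluated$positions; ev <- evaluated$values
  if (max(ex) < min(rx) || min(ex) > max(rx))
    stop("reference and evaluated curves do not overlap")
  dose_abs <- dose_crit / 100 * max(rv)
  offs <- seq(-3 * dist_crit, 3 * dist_crit, by = 0.1)
  keep <- rx >= min(ex) & rx <= max(ex)
  gam <- rep(NA_real_, length(rx))
  gamma2 <- function(dd, i) {
    e <- stats::approx(ex, ev, xout = rx[i] + dd)$y
    (dd / dist_crit)^2 + ((e - rv[i]) / dose_abs)^2
  }
  for (i in which(keep)) {
    xs <- rx[i] + offs
    ok <- xs >= min(ex) & xs <= max(ex)
    g2 <- (offs[ok] / dist_crit)^2 +
      ((stats::approx(ex, ev, xout = xs[ok])$y - rv[i]) / dose_abs)^2
    # refine the coarse-grid minimum inside its bracketing interval (the
    # objective is piecewise quadratic between evaluated-curve nodes)
    j <- which.min(g2)
    lo <- max(offs[ok][max(1, j - 1)], min(ex) - rx[i])
    hi <- min(offs[ok][min(length(g2), j + 1)], max(ex) - rx[i])
    ref2 <- if (is.finite(lo) && is.finite(hi) && hi - lo > 1e-9)
      stats::optimize(function(dd) gamma2(dd, i), c(lo, hi))$objective
      else g2[j]
    gam[i] <- sqrt(min(g2[j], ref2))
  }
  gam <- gam[!is.na(gam)]
  structure(list(gamma = gam, pass_rate = 100 * mean(gam <= 1 + 1e-9),
                 dose_criterion = dose_crit, distance_criterion = dist_crit),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: pass rate %.1f%% (n=%d, mean %.3f)\n",
              x$dose_criterion, x$distance_criterion, x$pass_rate,
              length(x$gamma), mean(x$gamma)))
  invisible(x)
}

# level crossings of a curve, linearly interpolated
.crossings <- function(x, v, level) {
  s <- v - level
  i <- which(s[-1] * s[-length(s)] < 0)
  xc <- x[i] + (x[i + 1] - x[i]) * (0 - s[i]) / (s[i + 1] - s[i])
  exact <- which(s == 0)
  sort(c(xc, x[exact]))
}

#' Edge statistics of a single profile
#'
#' Finds the 80%, 50% and 20% (of curve maximum) crossings on each side of
#' the maximum and the 80-20 penumbra widths. With `monotone = TRUE`
#' (default) each edge is first replaced by its isotonic regression, so
#' statistical noise cannot create spurious level crossings that widen the
#' apparent penumbra of a sampled Monte Carlo profile; a noise-free profile
#' is unchanged by the fit.
#'
#' @param profile A lateral `profile1d`.
#' @param smooth Odd moving-average window (number of points) applied before
#'   the crossing search; 1 = none.
#' @param monotone Fit each side of the maximum with a monotone (isotonic)
#'   regression before locating the crossings.
#' @return List with `penumbra_neg`, `penumbra_pos` (mm; `NA` where a side
#'   lacks both crossings) and `halfmax_neg`, `halfmax_pos` (50% crossing
#'   positions, mm).
#' @export
profile_edges <- function(profile, smooth = 1, monotone = TRUE) {
  x <- profile$positions; v <- profile$values
  if (smooth > 1) {
    f <- stats::filter(v, rep(1 / smooth, smooth), sides = 2)
    v <- ifelse(is.na(f), v, as.numeric(f))
  }
  vmax <- max(v)
  imax <- which.max(v)
  xmax <- x[imax]
  edge_cross <- function(idx, level) {
    xs <- x[idx]; vs <- v[idx]
    if (length(xs) < 2) return(NA_real_)
    if (monotone) {
      # isotonic fit, rising toward the maximum on either side
      rising <- xs[1] < xmax
      vs <- if (rising) stats::isoreg(xs, vs)$yf
            else rev(stats::isoreg(rev(-xs), rev(vs))$yf)
    }
    cr <- .crossings(xs, vs, level)
    if (!length(cr)) return(NA_real_)
    # with a monotone edge all crossings of one level coincide up to the
    # flat steps of the fit; take their midpoint
    mean(range(cr))
  }
  lv <- function(f) list(neg = edge_cross(seq_len(imax), f * vmax),
                         pos = edge_cross(imax:length(x), f * vmax))
  c80 <- lv(0.8); c50 <- lv(0.5); c20 <- lv(0.2)
  list(penumbra_neg = c80$neg - c20$neg,
       penumbra_pos = c20$pos - c80$pos,
       halfmax_neg = c50$neg, halfmax_pos = c50$pos)
}

# mean distance-to-agreement by value matching: for each reference point,
# distance to the nearest evaluated-curve position with equal value
.mean_dta <- function(ref_x, ref_v, ev_x, ev_v, idx) {
  d <- vapply(idx, function(i) {
    cr <- .crossings(ev_x, ev_v, ref_v[i])
    if (!length(cr)) return(NA_real_)
    min(abs(cr - ref_x[i]))
  }, 0)
  if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
}

#' Comparison metrics for a pair of curves
#'
#' Computes the mean/maximum absolute difference over common points, the
#' 2%/2 mm gamma pass rate, the mean distance to agreement, and
#' curve-kind-specific quantities: for depth curves the depth-dose difference
#' at 10 cm; for lateral profiles the mean absolute difference restricted to
#' the in-beam region (> 80% of the reference maximum), the evaluated-curve
#' 80-20 penumbra widths, and the per-side half-maximum position shifts.
#' The evaluated curve is linearly interpolated onto the reference points.
#'
#' @param reference,evaluated `profile1d` objects of the same kind.
#' @return A `metric_report` list; fields not applicable to the curve kind
#'   are absent.
#' @export
compute_metrics <- function(reference, evaluated) {
  stopifnot(inherits(reference, "profile1d"), inherits(evaluated, "profile1d"))
  is_depth_r <- reference$axis == "depth"
  if (is_depth_r != (evaluated$axis == "depth"))
    stop("curves are of different kinds (depth vs lateral)")
  rx <- reference$positions; rv <- reference$values
  keep <- rx >= min(evaluated$positions) & rx <= max(evaluated$positions)
  ev <- stats::approx(evaluated$positions, evaluated$values,
                      xout = rx[keep])$y
  diffs <- ev - rv[keep]
  gam <- compute_gamma(reference, evaluated)
  rep <- list(mean_abs_diff = mean(abs(diffs)),
              max_abs_diff = max(abs(diffs)),
              gamma_pass = gam$pass_rate, gamma_n = length(gam$gamma))
  vmax <- max(rv)
  if (is_depth_r) {
    rep$mean_dta <- .mean_dta(rx[keep], rv[keep], evaluated$positions,
                              evaluated$values, seq_along(rx[keep]))
    if (max(rx) >= 100 && max(evaluated$positions) >= 100) {
      r10 <- stats::approx(rx, rv, xout = 100)$y
      e10 <- stats::approx(evaluated$positions, evaluated$values,
                           xout = 100)$y
      rep$delta_pdd10 <- e10 - r10
    }
  } else {
    pen <- rv[keep] > 0.2 * vmax & rv[keep] < 0.8 * vmax
    rep$mean_dta <- .mean_dta(rx[keep], rv[keep], evaluated$positions,
                              evaluated$values, which(pen))
    inb <- rv[keep] > 0.8 * vmax
    rep$delta_d80 <- if (any(inb)) mean(abs(diffs[inb])) else NA_real_
    er <- profile_edges(evaluated)
    rr <- profile_edges(reference)
    rep$penumbra_neg <- er$penumbra_neg
    rep$penumbra_pos <- er$penumbra_pos
    rep$halfmax_shift_neg <- er$halfmax_neg - rr$halfmax_neg
    rep$halfmax_shift_pos <- er$halfmax_pos - rr$halfmax_pos
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in names(x))
    if (!is.na(x[[nm]])) cat(sprintf("  %-18s %8.3f\n", nm, x[[nm]]))
  invisible(x)
}

#' Output factors from a set of runs
#'
#' @param runs Named list of `dose_grid` objects, one per field size; names
#'   are free-form field labels.
#' @param reference Name of the reference-field run (denominator).
#' @param depth_mm Measurement depth, mm.
#' @param radius_mm Radius of the central scoring region (see
#'   [central_axis_dose()]).
#' @return Data frame with `field`, `of`, `of_stderr` (propagated from the
#'   per-run batch statistics).
#' @export
compute_output_factors <- function(runs, reference, depth_mm = 50,
                                   radius_mm = 4) {
  if (!reference %in% names(runs))
    stop("reference run '", reference, "' missing")
  ref <- central_axis_dose(runs[[reference]], depth_mm, radius_mm)
  out <- lapply(names(runs), function(nm) {
    d <- central_axis_dose(runs[[nm]], depth_mm, radius_mm)
    of <- d$dose / ref$dose
    se <- if (nm == reference) 0 else
      of * sqrt(d$rel_stderr^2 + ref$rel_stderr^2)
    data.frame(field = nm, of = of, of_stderr = se)
  })
  do.call(rbind, out)
}

#' Write a profile as two-column text with a JSON sidecar
#'
#' @param profile A `profile1d`.
#' @param path Output path; the sidecar is written to `paste0(path, ".json")`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(position_mm = profile$positions,
               value_percent = profile$values),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  meta <- c(list(axis = profile$axis, normalization = profile$normalization),
            profile$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path Path to the two-column file.
#' @return A `profile1d`.
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  axis <- if (!is.null(meta$axis)) meta$axis else "depth"
  norm <- if (!is.null(meta$normalization)) meta$normalization
          else if (axis == "depth") "max" else "mean3max"
  meta$axis <- NULL; meta$normalization <- NULL
  profile1d(tab$position_mm, tab$value_percent, axis = axis,
            normalization = norm, meta = meta)
}

#' Depth-dose value at a depth, with a stabilized maximum
#'
#' Reads the normalized depth dose at `depth_mm` with the normalizing
#' maximum taken from a lightly smoothed copy of the curve: the raw maximum
#' of a sampled Monte Carlo curve is biased upward by per-voxel noise, which
#' biases every depth-dose readout downward. For a noise-free curve the
#' result equals the plain normalized value.
#'
#' @param pdd A depth `profile1d`.
#' @param depth_mm Depth, mm.
#' @param smooth_max Odd moving-average window for the maximum estimate;
#'   1 = raw maximum.
#' @return Depth-dose value, % of maximum.
#' @export
pdd_value <- function(pdd, depth_mm, smooth_max = 3) {
  stopifnot(inherits(pdd, "profile1d"), pdd$axis == "depth")
  v <- pdd$values
  if (smooth_max > 1) {
    f <- stats::filter(v, rep(1 / smooth_max, smooth_max), sides = 2)
    v <- ifelse(is.na(f), v, as.numeric(f))
  }
  stats::approx(pdd$positions, pdd$values, xout = depth_mm)$y / max(v) * 100
}
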
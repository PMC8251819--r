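# Staged source-parameter commissioning: grid search over incident
# electron-beam energy, focal-spot size and energy spread against reference
# scans, with multi-metric lexicographic selection.
#
# All candidates within a stage are simulated with the same master seed
# (common random numbers), so candidate-to-candidate metric differences are
# driven by the parameter, not by independent Monte Carlo noise; the shared
# seed is recorded in the result.

#' Define a tuning stage
#'
#' @param stage `"energy"` (mean electron energy, MeV), `"spot"` (focal spot
#'   FWHM, mm) or `"spread"` (energy FWHM, MeV).
#' @param candidates Candidate parameter values (sorted internally).
#' @param fixed An [electron_beam()] providing the two non-scanned
#'   parameters.
#' @param reference_curves Named list of `profile1d` reference scans:
#'   `pdd` and/or `crossline`/`inline`. The energy stage requires `pdd`;
#'   the spot and spread stages require at least one lateral profile.
#' @param field_size Field size at isocenter, mm.
#' @param ssd Source-to-surface distance, mm.
#' @param profile_depth_mm Depth of the reference lateral profiles, mm.
#' @return A `scan_stage` object.
#' @export
scan_stage <- function(stage = c("energy", "spot", "spread"), candidates,
                       fixed = electron_beam(), reference_curves,
                       field_size, ssd, profile_depth_mm = 50) {
  stage <- match.arg(stage)
  if (length(candidates) < 1) stop("at least one candidate is required")
  if (stage == "energy" && is.null(reference_curves$pdd))
    stop("energy stage requires a reference PDD")
  if (stage != "energy" && is.null(reference_curves$crossline) &&
      is.null(reference_curves$inline) && is.null(reference_curves$pdd))
    stop(stage, " stage requires reference profiles (and/or a PDD)")
  structure(list(stage = stage, candidates = sort(candidates), fixed = fixed,
                 reference_curves = reference_curves,
                 field_size = field_size, ssd = ssd,
                 profile_depth_mm = profile_depth_mm), class = "scan_stage")
}

.candidate_beam <- function(stage, fixed, value) {
  switch(stage,
    energy = electron_beam(value, fixed$energy_fwhm, fixed$spot_fwhm),
    spot   = electron_beam(fixed$mean_energy, fixed$energy_fwhm, value),
    spread = electron_beam(fixed$mean_energy, value, fixed$spot_fwhm))
}

#' Run a source-parameter grid scan
#'
#' Simulates one homogeneous-water run per candidate (shared seed), extracts
#' the curves matching the supplied references, computes a
#' [compute_metrics()] report per candidate per curve, and applies
#' [select_optimal()].
#'
#' @param stage A [scan_stage()].
#' @param config A [transport_config()]; the same seed is used for every
#'   candidate.
#' @param spacing Voxel spacing, mm.
#' @param phantom_depth_mm Water phantom thickness, mm.
#' @param lateral_mm Phantom lateral size; default covers the field plus
#'   60 mm margin.
#' @param pdd_lateral_radius_vox Lateral averaging half-width for PDD
#'   extraction, voxels.
#' @param profile_average_rows Rows averaged for profile extraction.
#' @param ... Further arguments passed to [run_simulation()].
#' @return A `tuning_result`: pooled per-candidate metric `table`,
#'   `per_curve` reports, `selected` value and `selection_trace`.
#' @export
run_parameter_scan <- function(stage, config = transport_config(),
                               spacing = c(3, 3, 2), phantom_depth_mm = 300,
                               lateral_mm = NULL,
                               pdd_lateral_radius_vox = 1,
                               profile_average_rows = 3, ...) {
  stopifnot(inherits(stage, "scan_stage"))
  if (is.null(lateral_mm))
    lateral_mm <- max(stage$field_size) + 60
  ph <- build_slab_phantom(list(slab("water", phantom_depth_mm)),
                           lateral_mm = lateral_mm, spacing = spacing)
  beam <- configure_beam(stage$field_size, ssd = stage$ssd)
  per_curve <- list()
  for (v in stage$candidates) {
    src <- .candidate_beam(stage$stage, stage$fixed, v)
    dg <- run_simulation(ph, beam, source = src, config = config, ...)
    reports <- list()
    if (!is.null(stage$reference_curves$pdd))
      reports$pdd <- compute_metrics(
        stage$reference_curves$pdd,
        extract_pdd(dg, lateral_radius_vox = pdd_lateral_radius_vox))
    for (axn in c("crossline", "inline")) {
      if (!is.null(stage$reference_curves[[axn]]))
        reports[[axn]] <- compute_metrics(
          stage$reference_curves[[axn]],
          extract_profile(dg, stage$profile_depth_mm, axis = axn,
                          average_rows = profile_average_rows))
    }
    per_curve[[as.character(v)]] <- reports
  }
  # treat pass rates within two binomial standard errors as tied
  sel <- select_optimal(per_curve, stage,
                        gamma_tol = .gamma_tie_tol(per_curve))
  structure(list(table = sel$table, per_curve = per_curve,
                 selected = sel$selected, selection_trace = sel$trace,
                 shared_seed = config$seed, stage = stage$stage,
                 candidates = stage$candidates), class = "tuning_result")
}

# two binomial standard errors on the pooled gamma pass rate, in points
.gamma_tie_tol <- function(per_curve) {
  n <- sum(vapply(per_curve[[1]], function(r) r$gamma_n %||% 50, 0))
  p <- mean(vapply(per_curve, function(reports)
    mean(vapply(reports, `[[`, 0, "gamma_pass")), 0)) / 100
  p <- min(max(p, 0.5), 0.995)
  200 * sqrt(p * (1 - p) / max(n, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pool one candidate's per-curve reports into scalar metrics
.pool_reports <- function(reports) {
  g <- mean(vapply(reports, `[[`, 0, "gamma_pass"))
  mad_pdd <- if (!is.null(reports$pdd)) reports$pdd$mean_abs_diff else NA
  prof <- reports[names(reports) != "pdd"]
  d80 <- if (length(prof)) mean(vapply(prof, `[[`, 0, "delta_d80")) else NA
  mx  <- if (length(prof)) mean(vapply(prof, `[[`, 0, "max_abs_diff")) else NA
  dta <- mean(vapply(reports, `[[`, 0, "mean_dta"), na.rm = TRUE)
  p10 <- if (!is.null(reports$pdd) && !is.null(reports$pdd$delta_pdd10))
    reports$pdd$delta_pdd10 else NA
  c(gamma_pass = g, mean_abs_diff = mad_pdd, delta_d80 = d80,
    max_abs_diff_prof = mx, mean_dta = dta, delta_pdd10 = p10)
}

#' Lexicographic candidate selection
#'
#' Filtering order: (1) highest pooled gamma pass rate; (2) among survivors,
#' lowest PDD mean absolute difference (energy stage) or lowest pooled rank
#' of in-beam difference plus maximum profile difference (spot/spread
#' stages); (3) lowest mean DTA; (4) smallest |depth-dose difference at
#' 10 cm| where applicable. Remaining ties break toward the middle
#' candidate. Each filter and its surviving candidates are recorded in the
#' trace.
#'
#' @param per_curve Named list (by candidate value) of per-curve
#'   [compute_metrics()] reports.
#' @param stage The [scan_stage()] the reports belong to (or its `stage`
#'   string).
#' @param gamma_tol Pass rates within this many percentage points of the
#'   best are treated as tied (a pass rate over n points only resolves
#'   differences of order its binomial standard error; at commissioning
#'   statistics rates tie exactly and this tolerance is moot).
#' @return List with the pooled `table`, `selected` value and `trace`.
#' @export
select_optimal <- function(per_curve, stage, gamma_tol = 0) {
  if (length(per_curve) == 0) stop("empty metric table")
  stage_name <- if (inherits(stage, "scan_stage")) stage$stage else stage
  cand <- as.numeric(names(per_curve))
  ord <- order(cand)
  cand <- cand[ord]; per_curve <- per_curve[ord]
  tab <- t(vapply(per_curve, .pool_reports, numeric(6)))
  table <- data.frame(candidate = cand, tab, row.names = NULL)
  trace <- list()
  alive <- seq_along(cand)
  note <- function(crit) trace[[length(trace) + 1]] <<-
    list(criterion = crit, surviving = cand[alive])
  if (length(alive) == 1) {
    note("only candidate")
  } else {
    eps <- 1e-9
    g <- table$gamma_pass
    alive <- alive[g[alive] >= max(g[alive]) - eps - gamma_tol]
    note("highest gamma pass rate")
    if (length(alive) > 1) {
      if (stage_name == "energy" || all(is.na(table$delta_d80))) {
        m <- table$mean_abs_diff
        alive <- alive[m[alive] <= min(m[alive]) + eps]
        note("lowest PDD mean absolute difference")
      } else {
        rk <- rank(table$delta_d80) + rank(table$max_abs_diff_prof)
        alive <- alive[rk[alive] <= min(rk[alive]) + eps]
        note("lowest pooled in-beam + max-difference rank")
      }
    }
    if (length(alive) > 1) {
      d <- table$mean_dta
      alive <- alive[d[alive] <= min(d[alive]) + eps]
      note("lowest mean DTA")
    }
    if (length(alive) > 1 && !all(is.na(table$delta_pdd10))) {
      p <- abs(table$delta_pdd10)
      alive <- alive[p[alive] <= min(p[alive]) + eps]
      note("smallest |delta PDD10cm|")
    }
    if (length(alive) > 1) {
      mid <- (length(cand) + 1) / 2
      alive <- alive[which.min(abs(alive - mid))]
      note("tie broken toward the middle candidate")
    }
  }
  list(table = table, selected = cand[alive[1]], trace = trace)
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> stage '%s', selected %g (shared seed %g)\n",
              x$stage, x$selected, x$shared_seed))
  print(format(x$table, digits = 4), ...)
  cat("selection trace:\n")
  for (s in x$selection_trace)
    cat(sprintf("  %-45s -> {%s}\n", s$criterion,
                paste(s$surviving, collapse = ", ")))
  invisible(x)
}
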
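#' Default analysis configuration
#'
#' Collects every tunable constant of the pipeline in one list so that
#' nothing the apparatus or the analysis depends on is hard-coded. Values
#' not fixed by the experimental design (and therefore configurable) are
#' documented with their rationale in the package vignette.
#'
#' @param ... named overrides for any default entry. Unknown names are an
#'   error, so typos do not silently fall through to defaults.
#'
#' @return A named list of class `rotarena_config` with components:
#' \describe{
#'   \item{arena_diameter_cm}{arena diameter, default 82.}
#'   \item{omega_deg_per_s}{arena rotation rate, signed, positive =
#'     counter-clockwise; default 6 (one revolution per minute).}
#'   \item{sector_center_deg}{room-frame azimuth of the to-be-avoided
#'     sector center, default 0.}
#'   \item{sector_width_deg}{sector width, default 60.}
#'   \item{session_duration_s}{training session length, default 1200 (20
#'     min); retrieval sessions are 300 s.}
#'   \item{radius_tolerance_cm}{tracking jitter allowed beyond the wall,
#'     default 0.5.}
#'   \item{shock_duration_s, shock_gap_s}{shock pulse length (0.5 s) and
#'     the pause before a repeat while the animal stays in the sector
#'     (1.5 s), i.e. a 2-s repeat cycle.}
#'   \item{speed_window_s}{window after shock onset over which angular
#'     speed is summarized, default 1.}
#'   \item{nonsolver_z_cut}{combined-phase total-distance z-score below
#'     which a rat can be flagged as a freezing non-solver, default -1.}
#'   \item{nonsolver_speed_cut_deg_s}{post-shock arena-frame speed below
#'     which freezing is inferred, default 2; active escape reference 8.}
#'   \item{active_speed_deg_s}{post-shock speed regarded as clear escape,
#'     default 8.}
#'   \item{latency_cap_s}{step-through latency ceiling, default 300.}
#'   \item{period_range_h, period_step_min}{chi-square periodogram search
#'     range (20--28 h) and candidate step (1 min = one bin).}
#'   \item{periodogram_alpha}{pointwise significance level for the
#'     periodogram line, default 0.001.}
#'   \item{onset_smooth_min}{width of the centered moving average used for
#'     activity-onset detection, default 29 min (odd).}
#'   \item{onset_sustain_min}{minutes the smoothed profile must stay above
#'     its cycle mean to call an onset, default 30.}
#'   \item{post_shock_frame}{frame in which post-shock angular speed is
#'     measured, \code{"arena"} (default) or \code{"room"}.}
#' }
#' @export
#' @examples
#' cfg <- rotarena_config(sector_center_deg = 90)
#' cfg$omega_deg_per_s
rotarena_config <- function(...) {
  cfg <- list(
    arena_diameter_cm = 82,
    omega_deg_per_s = 6,
    sector_center_deg = 0,
    sector_width_deg = 60,
    session_duration_s = 1200,
    retrieval_duration_s = 300,
    radius_tolerance_cm = 0.5,
    shock_duration_s = 0.5,
    shock_gap_s = 1.5,
    speed_window_s = 1,
    nonsolver_z_cut = -1,
    nonsolver_speed_cut_deg_s = 2,
    active_speed_deg_s = 8,
    latency_cap_s = 300,
    period_range_h = c(20, 28),
    period_step_min = 1,
    periodogram_alpha = 0.001,
    onset_smooth_min = 29,
    onset_sustain_min = 30,
    post_shock_frame = "arena"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "rotarena_config")
}

#' @export
print.rotarena_config <- function(x, ...) {
  cat("rotarena analysis configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
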
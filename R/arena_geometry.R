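# Reference-frame geometry for the rotating arena. The room frame is the
# fixed laboratory frame; the arena frame co-rotates with the arena surface
# at omega deg/s (positive = counter-clockwise), so
#   theta_arena(t) = theta_room(t) - omega * t   (mod 360).
# Solving the place-avoidance task requires dissociating the two frames:
# the punished sector is defined in the room frame while surface cues
# rotate with the arena.

#' Sector specification
#'
#' An angular sector on the arena, by default the 60-degree to-be-avoided
#' sector fixed in the room frame. Membership uses the half-open convention
#' `[center - width/2, center + width/2)` so entrance events are
#' unambiguous at the boundary.
#'
#' @param center_deg sector center azimuth (degrees).
#' @param width_deg sector width in degrees, in (0, 360); default 60.
#' @param frame `"room"` (default) or `"arena"`.
#' @return object of class `sector_spec`.
#' @export
#' @examples
#' s <- sector_spec(0)
#' opposite_sector(s)$center_deg
sector_spec <- function(center_deg, width_deg = 60, frame = "room") {
  if (!is.finite(center_deg)) stop("sector center must be finite")
  if (!is.finite(width_deg) || width_deg <= 0 || width_deg >= 360)
    stop("sector width must lie strictly between 0 and 360 degrees")
  frame <- match.arg(frame, c("room", "arena"))
  structure(list(center_deg = center_deg %% 360, width_deg = width_deg,
                 frame = frame), class = "sector_spec")
}

#' @rdname sector_spec
#' @param sector a `sector_spec`; the returned sector has the same width,
#'   displaced 180 degrees (the "opposite" sector used to quantify
#'   perseverance).
#' @export
opposite_sector <- function(sector) {
  stopifnot(inherits(sector, "sector_spec"))
  sector_spec((sector$center_deg + 180) %% 360, sector$width_deg,
              sector$frame)
}

#' Polar decomposition of a trajectory in both reference frames
#'
#' Converts a room-frame Cartesian trajectory to polar coordinates and
#' derives the arena-frame azimuth via `theta_arena = theta_room - omega*t`.
#' The arena center has no defined azimuth; such samples get `theta = 0`
#' and are flagged.
#'
#' @param x a [track()].
#' @return data frame with columns `t_s`, `theta_room_deg`,
#'   `theta_arena_deg` (both in [0, 360)), `radius_cm`, and `at_center`
#'   (logical degenerate-point flag).
#' @export
to_polar <- function(x) {
  stopifnot(inherits(x, "track"))
  d <- x$data
  omega <- x$header$rotation_speed_deg_per_s
  radius <- sqrt(d$x_cm^2 + d$y_cm^2)
  at_center <- radius == 0
  theta_room <- ifelse(at_center, 0, atan2(d$y_cm, d$x_cm) * 180 / pi) %% 360
  theta_arena <- (theta_room - omega * d$t_s) %% 360
  data.frame(t_s = d$t_s, theta_room_deg = theta_room,
             theta_arena_deg = theta_arena, radius_cm = radius,
             at_center = at_center)
}

#' Circular sector membership
#'
#' @param theta_deg azimuth(s) in degrees, any real value; interpreted
#'   modulo 360 in the sector's own frame.
#' @param sector a [sector_spec()].
#' @return logical vector: `TRUE` iff the signed circular distance from the
#'   sector center lies in `[-width/2, width/2)` (lower boundary inclusive,
#'   upper exclusive).
#' @export
in_sector <- function(theta_deg, sector) {
  stopifnot(inherits(sector, "sector_spec"))
  if (any(!is.finite(theta_deg))) stop("angles must be finite")
  delta <- (theta_deg - sector$center_deg) %% 360
  delta <- ifelse(delta >= 180, delta - 360, delta)  # signed, in [-180, 180)
  half <- sector$width_deg / 2
  delta >= -half & delta < half
}

#' Unwrap a circular angle sequence
#'
#' Removes artificial +-360-degree jumps so consecutive differences reflect
#' actual motion.
#'
#' @param theta_deg angle sequence in degrees.
#' @return unwrapped sequence (first element unchanged).
#' @export
unwrap_deg <- function(theta_deg) {
  if (length(theta_deg) < 2) return(theta_deg)
  d <- diff(theta_deg)
  d <- (d + 180) %% 360 - 180
  theta_deg[1] + c(0, cumsum(d))
}

#' Per-sample angular speed in the arena frame
#'
#' Signed rate of change of the arena-frame azimuth, obtained by unwrapping
#' the angle and taking a two-point forward difference at the native sample
#' rate (the last sample repeats the preceding rate so the result aligns
#' with the samples). In the arena frame a rat sitting still on the surface
#' reads exactly 0 deg/s, while one holding a room-frame position against
#' the rotation reads `-omega`; this is what makes post-shock immobility
#' detectable.
#'
#' @param polar output of [to_polar()] (or any data frame with `t_s` and
#'   the requested angle column).
#' @param frame `"arena"` (default) or `"room"`.
#' @return numeric vector of signed deg/s, one per sample.
#' @export
angular_speed <- function(polar, frame = c("arena", "room")) {
  frame <- match.arg(frame)
  col <- if (frame == "arena") "theta_arena_deg" else "theta_room_deg"
  n <- nrow(polar)
  if (n < 2) stop("angular speed needs at least 2 samples")
  th <- unwrap_deg(polar[[col]])
  rate <- diff(th) / diff(polar$t_s)
  c(rate, rate[n - 1L])
}
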
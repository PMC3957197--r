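# Per-session place-avoidance measures. Occupancy-based quantities use
# sample-and-hold weighting at the native sample rate (each sample "owns"
# the interval up to the next sample; the final sample holds until the
# session end declared in the header), so occupancy times over a partition
# of the arena sum to the session duration exactly. Only total distance
# uses the 1-second resampled path, which is how the measure is defined.

session_end_s <- function(x) {
  max(x$header$session_duration_s, utils::tail(x$data$t_s, 1))
}

hold_weights <- function(t_s, end_s) {
  n <- length(t_s)
  if (n == 0) return(numeric(0))
  c(diff(t_s), end_s - t_s[n])
}

#' Resample a trajectory on a 1-second grid
#'
#' Selects, for every whole second from 0 to the last covered tick, the
#' nearest sample at or before that tick. A 1 Hz track is returned
#' unchanged.
#'
#' @param x a [track()] with at least one sample.
#' @return data frame of the selected rows of `x$data`.
#' @export
resample_1s <- function(x) {
  stopifnot(inherits(x, "track"))
  t <- x$data$t_s
  if (length(t) == 0) stop("cannot resample an empty track")
  ticks <- seq(ceiling(t[1]), floor(utils::tail(t, 1)))
  idx <- findInterval(ticks, t)
  x$data[idx, , drop = FALSE]
}

#' Total distance travelled
#'
#' Sum of straight-line room-frame distances between points selected every
#' 1 s, in meters. Low values indicate locomotor deficit or a rat that is
#' carried through the punished sector rather than avoiding it actively.
#'
#' @param x a [track()].
#' @return distance in meters.
#' @export
total_distance <- function(x) {
  p <- resample_1s(x)
  if (nrow(p) < 2) return(0)
  sum(sqrt(diff(p$x_cm)^2 + diff(p$y_cm)^2)) / 100
}

sector_membership <- function(x, sector, polar = NULL) {
  if (is.null(polar)) polar <- to_polar(x)
  th <- if (sector$frame == "room") polar$theta_room_deg else
    polar$theta_arena_deg
  in_sector(th, sector)
}

run_table <- function(member, t_s, end_s) {
  r <- rle(member)
  n_runs <- length(r$lengths)
  stops <- cumsum(r$lengths)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  start_t <- t_s[starts]
  end_t <- c(start_t[-1], end_s)
  data.frame(inside = r$values, start_s = start_t, end_s = end_t,
             duration_s = end_t - start_t)
}

#' Maximum time avoided
#'
#' Longest continuous interval spent without an entrance into the
#' to-be-avoided sector, the primary avoidance-ability measure. Computed by
#' interval arithmetic over maximal runs of consecutive samples outside the
#' sector (runs touching the session start or end included). On a 20-min
#' session the ceiling is 1200 s (never entering); a fully immobile subject
#' on an arena rotating at 6 deg/s with a 60-degree sector scores
#' (360-60)/6 = 50 s, since the rotation carries it through the sector once
#' per revolution.
#'
#' @param x a [track()].
#' @param sector a [sector_spec()]; defaults to the sector in the header.
#' @return seconds.
#' @export
max_time_avoided <- function(x, sector = header_sector(x)) {
  member <- sector_membership(x, sector)
  if (!any(member)) return(session_end_s(x) - x$data$t_s[1])
  runs <- run_table(member, x$data$t_s, session_end_s(x))
  out <- runs$duration_s[!runs$inside]
  if (length(out) == 0) 0 else max(out)
}

#' @rdname max_time_avoided
#' @export
header_sector <- function(x) {
  stopifnot(inherits(x, "track"))
  sector_spec(x$header$sector_center_deg, x$header$sector_width_deg, "room")
}

#' Occupancy time of a sector
#'
#' Sample-and-hold time spent inside `sector`; with the complement it
#' partitions the session duration exactly.
#'
#' @inheritParams max_time_avoided
#' @return seconds inside the sector.
#' @export
time_in_sector <- function(x, sector = header_sector(x)) {
  member <- sector_membership(x, sector)
  sum(hold_weights(x$data$t_s, session_end_s(x))[member]) +
    if (x$data$t_s[1] > 0 && member[1]) x$data$t_s[1] else 0
}

#' Number of entrances into a sector
#'
#' Strict outside-to-inside transitions; a session that starts inside the
#' sector counts as an entrance at t = 0 (the shock logic fires on initial
#' placement inside).
#'
#' @inheritParams max_time_avoided
#' @return integer count.
#' @export
entrances <- function(x, sector = header_sector(x)) {
  member <- sector_membership(x, sector)
  sum(diff(member) == 1) + as.integer(member[1])
}

#' Mean distance from the arena center
#'
#' Time-weighted mean radius: the thigmotaxis measure (wall hugging).
#' Bounded above by the arena radius, 41 cm on the 82-cm arena; even a rat
#' pressed to the wall for the whole session stays somewhat below that.
#'
#' @param x a [track()].
#' @return centimeters.
#' @export
mean_dist_center <- function(x) {
  stopifnot(inherits(x, "track"))
  if (nrow(x$data) == 0) stop("empty track")
  r <- sqrt(x$data$x_cm^2 + x$data$y_cm^2)
  w <- hold_weights(x$data$t_s, session_end_s(x))
  if (sum(w) == 0) return(mean(r))
  sum(w * r) / sum(w)
}

#' Proportion of time in the opposite sector
#'
#' Time spent in the same-width sector displaced 180 degrees from the
#' to-be-avoided sector, divided by the total time NOT spent in the
#' to-be-avoided sector (so the measure is independent of avoidance
#' ability). Indexes perseverance during reversal, when the opposite
#' sector coincides with the previously punished location. A fully
#' immobile subject on the rotating arena measures 0.2: of each
#' revolution's 50 s outside the avoided sector, 10 s fall in the opposite
#' one. Undefined (NA) if the rat never leaves the avoided sector.
#'
#' @inheritParams max_time_avoided
#' @return proportion in [0, 1], or NA if undefined.
#' @export
prop_time_opposite <- function(x, sector = header_sector(x)) {
  dur <- session_end_s(x)
  t_in <- time_in_sector(x, sector)
  denom <- dur - t_in
  if (denom <= 0) return(NA_real_)
  time_in_sector(x, opposite_sector(sector)) / denom
}

#' Reconstruct the shock schedule from a trajectory
#'
#' Applies the apparatus rule to sampled sector membership: an entrance
#' triggers a 0.5-s shock immediately; while the animal remains inside, the
#' shock is repeated after a 1.5-s pause (a 2.0-s cycle) and the cycle
#' resets on exit. Habituation and retrieval sessions are unpunished by
#' design and return no events.
#'
#' @inheritParams max_time_avoided
#' @param shock_duration_s,shock_gap_s pulse length and pause, defaults
#'   0.5 and 1.5 s.
#' @return data frame with columns `onset_s`, `duration_s`, `kind`
#'   (`"entrance"` or `"repeat"`); zero rows if no entrance occurs.
#' @export
shock_schedule <- function(x, sector = header_sector(x),
                           shock_duration_s = 0.5, shock_gap_s = 1.5) {
  if (x$header$phase_label %in% c("habituation", "retrieval"))
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      kind = character(0)))
  member <- sector_membership(x, sector)
  runs <- run_table(member, x$data$t_s, session_end_s(x))
  runs <- runs[runs$inside, , drop = FALSE]
  cycle <- shock_duration_s + shock_gap_s
  onsets <- kinds <- list()
  for (i in seq_len(nrow(runs))) {
    k <- 0:max(0, ceiling((runs$end_s[i] - runs$start_s[i]) / cycle))
    on <- runs$start_s[i] + k * cycle
    on <- on[on < runs$end_s[i]]
    onsets[[i]] <- on
    kinds[[i]] <- c("entrance", rep("repeat", length(on) - 1L))
  }
  data.frame(onset_s = unlist(c(onsets, list(numeric(0)))),
             duration_s = rep(shock_duration_s, length(unlist(onsets))),
             kind = unlist(c(kinds, list(character(0)))),
             stringsAsFactors = FALSE)
}

#' Shock events recorded in a track file
#'
#' Samples whose `shock_flag` is set are taken as shock onsets; the
#' hardware log, when present, takes precedence over the reconstructed
#' [shock_schedule()].
#'
#' @param x a [track()].
#' @param shock_duration_s pulse length, default 0.5 s.
#' @return data frame like [shock_schedule()]'s, `kind = "logged"`.
#' @export
logged_shocks <- function(x, shock_duration_s = 0.5) {
  on <- x$data$t_s[x$data$shock_flag == 1]
  data.frame(onset_s = on, duration_s = rep(shock_duration_s, length(on)),
             kind = rep("logged", length(on)), stringsAsFactors = FALSE)
}

#' Median absolute angular speed after shock
#'
#' For each shock, the median of the absolute arena-frame angular speed
#' over samples in the 1 s following the onset (window `(onset, onset+1]`);
#' the session value is the mean over shocks. Escaping animals move off the
#' sector actively (in either rotational direction, hence absolute speeds)
#' and score high; a freezing animal sits still on the arena surface and
#' scores near 0, even though the rotation carries it through the room
#' frame. The measurement frame is configurable but defaults to the arena
#' frame for exactly this reason.
#'
#' @param x a [track()].
#' @param shocks data frame of shock events ([shock_schedule()],
#'   [logged_shocks()]).
#' @param window_s window length after onset, default 1 s.
#' @param frame `"arena"` (default) or `"room"`.
#' @return list with `per_shock` (one value per shock; NA when no sample
#'   falls in the window) and `mean` (session mean over shocks, NA if there
#'   are no shocks).
#' @export
median_abs_speed_after_shock <- function(x, shocks, window_s = 1,
                                         frame = c("arena", "room")) {
  frame <- match.arg(frame)
  if (nrow(shocks) == 0)
    return(list(per_shock = numeric(0), mean = NA_real_))
  polar <- to_polar(x)
  spd <- abs(angular_speed(polar, frame = frame))
  per <- vapply(shocks$onset_s, function(on) {
    sel <- polar$t_s > on & polar$t_s <= on + window_s
    if (!any(sel)) NA_real_ else stats::median(spd[sel])
  }, numeric(1))
  list(per_shock = per, mean = mean(per, na.rm = TRUE))
}

#' All per-session measures for one trajectory
#'
#' Computes the full measure set for a session: total distance, maximum
#' time avoided, mean distance from center, entrances, time in sector,
#' proportion of time in the opposite sector, mean median absolute
#' post-shock speed, and shock count. Shock events logged in the file are
#' used when present; otherwise the schedule is reconstructed. Undefined
#' measures propagate as NA.
#'
#' @param x a [track()].
#' @param sector a [sector_spec()]; defaults to the header's sector.
#' @param defecation optional defecation count for the session.
#' @param config a [rotarena_config()].
#' @return one-row data frame of class `session_metrics`.
#' @export
compute_session_metrics <- function(x, sector = header_sector(x),
                                    defecation = NA_real_,
                                    config = rotarena_config()) {
  stopifnot(inherits(x, "track"))
  shocks <- logged_shocks(x, config$shock_duration_s)
  if (nrow(shocks) == 0)
    shocks <- shock_schedule(x, sector, config$shock_duration_s,
                             config$shock_gap_s)
  spd <- median_abs_speed_after_shock(x, shocks, config$speed_window_s,
                                      frame = config$post_shock_frame)
  out <- data.frame(
    rat_id = x$header$rat_id,
    group = x$header$group_label,
    phase = x$header$phase_label,
    session_index = x$header$session_index,
    total_distance_m = total_distance(x),
    max_time_avoided_s = max_time_avoided(x, sector),
    mean_dist_center_cm = mean_dist_center(x),
    entrances = entrances(x, sector),
    time_in_sector_s = time_in_sector(x, sector),
    prop_time_opposite = prop_time_opposite(x, sector),
    median_abs_speed_after_shock_deg_s = spd$mean,
    n_shocks = nrow(shocks),
    defecation = defecation,
    stringsAsFactors = FALSE
  )
  class(out) <- c("session_metrics", class(out))
  out
}

#' Session metrics for a set of track files
#'
#' @param paths character vector of track-file paths.
#' @param defecation optional numeric vector aligned with `paths`.
#' @param config a [rotarena_config()].
#' @return data frame, one row per session (long by rat x session).
#' @export
batch_session_metrics <- function(paths, defecation = NULL,
                                  config = rotarena_config()) {
  rows <- lapply(seq_along(paths), function(i) {
    tr <- read_track(paths[i], config$radius_tolerance_cm)
    compute_session_metrics(
      tr, defecation = if (is.null(defecation)) NA_real_ else defecation[i],
      config = config)
  })
  do.call(rbind, rows)
}
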
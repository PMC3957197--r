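# File formats: plain-text CSV dialects for trajectories, activity series
# and cohort annotations. Header metadata travels as '#'-prefixed key=value
# lines above an ordinary CSV body, so fixtures stay human-diffable.

TRACK_HEADER_KEYS <- c(
  "arena_diameter_cm", "rotation_speed_deg_per_s", "sector_center_deg",
  "sector_width_deg", "session_duration_s", "phase_label", "rat_id",
  "group_label", "session_index"
)
TRACK_PHASES <- c("habituation", "acquisition", "retrieval", "reversal")

#' Construct a validated trajectory object
#'
#' A `track` holds one rat's room-frame trajectory for one session: sample
#' times, positions with origin at the arena center (x to the right, y up,
#' angles counter-clockwise), and a per-sample shock flag, plus the session
#' header (arena geometry, rotation rate, sector placement, identifiers).
#'
#' @param header named list with entries `arena_diameter_cm`,
#'   `rotation_speed_deg_per_s` (signed; positive = counter-clockwise),
#'   `sector_center_deg`, `sector_width_deg`, `session_duration_s`,
#'   `phase_label` (one of habituation/acquisition/retrieval/reversal),
#'   `rat_id`, `group_label`, `session_index`.
#' @param data data frame with columns `t_s` (strictly increasing),
#'   `x_cm`, `y_cm`, `shock_flag` (0/1).
#' @param radius_tolerance_cm slack beyond the arena radius tolerated for
#'   tracking jitter at the wall (default 0.5 cm); positions farther out
#'   are a validation error.
#'
#' @return object of class `track`: `list(header = <list>, data = <df>)`.
#' @export
track <- function(header, data, radius_tolerance_cm = 0.5) {
  missing_keys <- setdiff(TRACK_HEADER_KEYS, names(header))
  if (length(missing_keys))
    stop("track header is missing key(s): ",
         paste(missing_keys, collapse = ", "))
  num_keys <- c("arena_diameter_cm", "rotation_speed_deg_per_s",
                "sector_center_deg", "sector_width_deg",
                "session_duration_s", "session_index")
  for (k in num_keys) header[[k]] <- as.numeric(header[[k]])
  for (k in c("arena_diameter_cm", "sector_width_deg", "session_duration_s"))
    if (!is.finite(header[[k]]) || header[[k]] <= 0)
      stop("track header field '", k, "' must be positive")
  if (!header$phase_label %in% TRACK_PHASES)
    stop("phase_label must be one of: ", paste(TRACK_PHASES, collapse = ", "))

  need_cols <- c("t_s", "x_cm", "y_cm", "shock_flag")
  if (!all(need_cols %in% names(data)))
    stop("track data must have columns: ", paste(need_cols, collapse = ", "))
  data <- as.data.frame(data)[, need_cols]
  n <- nrow(data)
  if (n > 0) {
    if (any(!is.finite(as.matrix(data))))
      stop("track data contains non-finite values")
    if (n > 1 && any(diff(data$t_s) <= 0)) {
      bad <- which(diff(data$t_s) <= 0)[1] + 1L
      stop("track time stamps must be strictly increasing (row ", bad, ")")
    }
    r <- sqrt(data$x_cm^2 + data$y_cm^2)
    rmax <- header$arena_diameter_cm / 2 + radius_tolerance_cm
    if (any(r > rmax)) {
      bad <- which(r > rmax)[1]
      stop(sprintf(
        "position outside arena at row %d: radius %.2f cm exceeds %.2f cm",
        bad, r[bad], rmax))
    }
    if (!all(data$shock_flag %in% c(0, 1))) {
      bad <- which(!data$shock_flag %in% c(0, 1))[1]
      stop("shock_flag must be 0 or 1 (row ", bad, ")")
    }
  }
  structure(list(header = header, data = data), class = "track")
}

#' @export
print.track <- function(x, ...) {
  h <- x$header
  cat(sprintf("track: rat %s (%s), %s session %d\n",
              h$rat_id, h$group_label, h$phase_label, h$session_index))
  cat(sprintf("  arena %.0f cm, omega %+.1f deg/s, sector %g deg at %g deg\n",
              h$arena_diameter_cm, h$rotation_speed_deg_per_s,
              h$sector_width_deg, h$sector_center_deg))
  cat(sprintf("  %d samples over %.1f s, %d shock flags\n",
              nrow(x$data),
              if (nrow(x$data)) max(x$data$t_s) else 0,
              sum(x$data$shock_flag)))
  invisible(x)
}

write_header_lines <- function(header) {
  vapply(names(header), function(k) {
    sprintf("# %s=%s", k, format(header[[k]], scientific = FALSE))
  }, character(1))
}

read_header_lines <- function(lines) {
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

#' Read / write trajectory files
#'
#' The on-disk format is UTF-8 CSV with `#`-prefixed `key=value` header
#' lines followed by a column-titled body (`t_s,x_cm,y_cm,shock_flag`).
#' An `n_rows` header entry makes empty sessions explicit.
#'
#' @param path file path.
#' @param radius_tolerance_cm passed to [track()] validation.
#' @return `read_track()` returns a validated [track()]; `write_track()`
#'   returns `path` invisibly.
#' @export
read_track <- function(path, radius_tolerance_cm = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- read_header_lines(lines)
  n_rows <- if (!is.null(hdr$n_rows)) as.integer(hdr$n_rows) else NA_integer_
  hdr$n_rows <- NULL
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) <= 1) {
    data <- data.frame(t_s = numeric(0), x_cm = numeric(0),
                       y_cm = numeric(0), shock_flag = numeric(0))
  } else {
    data <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  }
  if (!is.na(n_rows) && nrow(data) != n_rows)
    stop("track file declares n_rows=", n_rows, " but has ", nrow(data))
  track(hdr, data, radius_tolerance_cm = radius_tolerance_cm)
}

#' @rdname read_track
#' @param x a [track()] object.
#' @export
write_track <- function(x, path) {
  stopifnot(inherits(x, "track"))
  hdr <- x$header
  hdr$n_rows <- nrow(x$data)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(write_header_lines(hdr), con)
  writeLines("t_s,x_cm,y_cm,shock_flag", con)
  if (nrow(x$data)) {
    writeLines(sprintf("%.10g,%.10g,%.10g,%d",
                       x$data$t_s, x$data$x_cm, x$data$y_cm,
                       as.integer(x$data$shock_flag)), con)
  }
  invisible(path)
}

#' Construct a validated activity series
#'
#' Per-minute (or coarser) locomotor activity counts from a cage movement
#' detector, together with the light schedule that the recording ran under.
#' The schedule is a table of contiguous intervals labelled `light` or
#' `dark`; its intervals must tile the recording exactly.
#'
#' @param counts non-negative integer counts, one per bin.
#' @param start_timestamp character timestamp of the first bin (metadata).
#' @param bin_width_min bin width in minutes, default 1.
#' @param schedule data frame with columns `start_min`, `end_min`,
#'   `state` (`"light"` or `"dark"`); intervals must be contiguous,
#'   non-overlapping, start at 0 and end at `length(counts) * bin_width_min`.
#'
#' @return object of class `activity_series`.
#' @export
activity_series <- function(counts, start_timestamp = "2000-01-01 00:00",
                            bin_width_min = 1, schedule) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))[1]
    stop("activity counts must be non-negative integers (bin ", bad, ")")
  }
  schedule <- as.data.frame(schedule)
  need <- c("start_min", "end_min", "state")
  if (!all(need %in% names(schedule)))
    stop("schedule must have columns: ", paste(need, collapse = ", "))
  if (!all(schedule$state %in% c("light", "dark")))
    stop("schedule state must be 'light' or 'dark'")
  schedule <- schedule[order(schedule$start_min), , drop = FALSE]
  total_min <- length(counts) * bin_width_min
  if (nrow(schedule) == 0) stop("schedule is empty")
  if (schedule$start_min[1] != 0)
    stop("schedule must start at minute 0 (starts at ",
         schedule$start_min[1], ")")
  if (nrow(schedule) > 1) {
    gap <- which(schedule$start_min[-1] != schedule$end_min[-nrow(schedule)])
    if (length(gap))
      stop("schedule gap/overlap between intervals ", gap[1], " and ",
           gap[1] + 1)
  }
  if (utils::tail(schedule$end_min, 1) != total_min)
    stop("schedule ends at minute ", utils::tail(schedule$end_min, 1),
         " but recording spans ", total_min, " minutes")
  structure(list(counts = counts, start_timestamp = start_timestamp,
                 bin_width_min = bin_width_min, schedule = schedule),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  days <- length(x$counts) * x$bin_width_min / 1440
  cat(sprintf("activity_series: %d bins of %g min (%.1f days) from %s\n",
              length(x$counts), x$bin_width_min, days, x$start_timestamp))
  dk <- sum((x$schedule$end_min - x$schedule$start_min)[
    x$schedule$state == "dark"])
  cat(sprintf("  %d schedule intervals, %.1f%% dark; total counts %g\n",
              nrow(x$schedule), 100 * dk /
                (length(x$counts) * x$bin_width_min), sum(x$counts)))
  invisible(x)
}

#' Per-bin light state of an activity series
#'
#' @param x an [activity_series()].
#' @return character vector, `"light"`/`"dark"`, one entry per bin.
#' @export
bin_light_state <- function(x) {
  stopifnot(inherits(x, "activity_series"))
  mid <- (seq_along(x$counts) - 0.5) * x$bin_width_min
  idx <- findInterval(mid, x$schedule$start_min)
  x$schedule$state[idx]
}

#' Read / write activity-series files
#'
#' Same dialect as the track format: `#` header lines
#' (`start_timestamp`, `bin_width_min`, `schedule` as
#' `start-end:state;...`), then one `count` column.
#'
#' @param path file path.
#' @return `read_activity()` returns an [activity_series()];
#'   `write_activity()` returns `path` invisibly.
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- read_header_lines(lines)
  for (k in c("start_timestamp", "bin_width_min", "schedule"))
    if (is.null(hdr[[k]])) stop("activity file is missing header key: ", k)
  parts <- strsplit(strsplit(hdr$schedule, ";")[[1]], "[-:]")
  schedule <- do.call(rbind, lapply(parts, function(p) {
    if (length(p) != 3) stop("malformed schedule entry: ",
                             paste(p, collapse = ":"))
    data.frame(start_min = as.numeric(p[1]), end_min = as.numeric(p[2]),
               state = p[3], stringsAsFactors = FALSE)
  }))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  counts <- if (length(body) <= 1) numeric(0) else
    utils::read.csv(text = body)$count
  activity_series(counts, start_timestamp = hdr$start_timestamp,
                  bin_width_min = as.numeric(hdr$bin_width_min),
                  schedule = schedule)
}

#' @rdname read_activity
#' @param x an [activity_series()].
#' @export
write_activity <- function(x, path) {
  stopifnot(inherits(x, "activity_series"))
  sched <- paste(sprintf("%g-%g:%s", x$schedule$start_min,
                         x$schedule$end_min, x$schedule$state),
                 collapse = ";")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# start_timestamp=%s", x$start_timestamp),
               sprintf("# bin_width_min=%g", x$bin_width_min),
               sprintf("# schedule=%s", sched),
               "count",
               format(as.integer(x$counts), scientific = FALSE,
                      trim = TRUE)), con)
  invisible(path)
}

#' Read / write cohort annotation tables
#'
#' Flat CSV, one row per rat, with per-session / per-trial measurements in
#' wide columns: `defecation_<phase><session>`, `saccharin_g_s<k>` /
#' `water_g_s<k>`, `latency_s_t<k>`, plus `rat_id`, `group_label`,
#' `litter_id`, `shock_intensity_mA`. Validation enforces non-negative
#' masses, integer defecation counts and the step-through latency cap.
#'
#' @param path file path.
#' @param latency_cap_s maximum step-through latency (trial ceiling),
#'   default 300 s.
#' @return data frame of annotations.
#' @export
read_annotations <- function(path, latency_cap_s = 300) {
  if (!file.exists(path)) stop("no such file: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(ann, latency_cap_s)
  ann
}

#' @rdname read_annotations
#' @param ann annotations data frame.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_annotations <- function(ann, latency_cap_s = 300) {
  if (!all(c("rat_id", "group_label") %in% names(ann)))
    stop("annotations need rat_id and group_label columns")
  if (anyDuplicated(ann$rat_id)) stop("duplicated rat_id in annotations")
  def_cols <- grep("^defecation", names(ann), value = TRUE)
  for (cl in def_cols) {
    v <- ann[[cl]]
    ok <- is.na(v) | (v >= 0 & v == round(v))
    if (!all(ok)) stop("defecation counts must be non-negative integers (",
                       cl, ", row ", which(!ok)[1], ")")
  }
  for (cl in grep("^(saccharin|water)_g", names(ann), value = TRUE)) {
    v <- ann[[cl]]
    if (!all(is.na(v) | v >= 0))
      stop("masses must be non-negative (", cl, ")")
  }
  for (cl in grep("^latency_s", names(ann), value = TRUE)) {
    v <- ann[[cl]]
    ok <- is.na(v) | (v >= 0 & v <= latency_cap_s)
    if (!all(ok)) stop("latencies must lie in [0, ", latency_cap_s, "] (",
                       cl, ", row ", which(!ok)[1], ")")
  }
  invisible(TRUE)
}
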
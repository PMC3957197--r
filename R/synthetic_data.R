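# Seeded generators for every input class the pipeline consumes: rotating-
# arena trajectories (correlated random walk with avoidance, thigmotaxis
# and freezing phenotypes, shocked online by the apparatus rule), cohort
# annotation tables, metric-level cohorts for Monte-Carlo pipeline studies,
# and circadian count series with light masking and a free-running period.

#' Trajectory simulator configuration
#'
#' Parameters of the correlated-random-walk movement model: gamma-
#' distributed step speeds, wrapped-normal turning, additive steering
#' toward the wall (thigmotaxis) and away from the punished sector
#' (avoidance), a post-shock escape response, and optional freezing bouts.
#'
#' @param dt_s sample interval, must be <= 1 s (metrics assume >= 1 Hz);
#'   default 0.5.
#' @param duration_s session length, default 1200 s (20 min).
#' @param speed_mean_cm_s,speed_shape mean and gamma shape of step speeds;
#'   defaults 8 cm/s and 3 (an actively exploring rat).
#' @param turn_sd_deg SD of the wrapped-normal heading increment per step
#'   at 1 s (scaled by sqrt(dt)), default 40.
#' @param thigmotaxis_bias in [0,1]: weight of steering toward a
#'   preferred radius at 80% of the arena radius; default 0.3.
#' @param avoidance_skill in [0,1]: weight of steering tangentially away
#'   from the to-be-avoided sector when near it; 0 = ignores the sector.
#' @param escape_speed_deg_s arena-frame angular escape speed for 2 s
#'   after each shock, default 30.
#' @param freeze_bout_prob per-second probability of entering a freezing
#'   bout, default 0.
#' @param freeze_bout_mean_s mean (exponential) bout length, default 30.
#' @param arena_diameter_cm,omega_deg_per_s apparatus geometry, defaults
#'   82 cm and 6 deg/s.
#' @return list of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(dt_s = 0.5, duration_s = 1200,
                                  speed_mean_cm_s = 8, speed_shape = 3,
                                  turn_sd_deg = 40, thigmotaxis_bias = 0.3,
                                  avoidance_skill = 0,
                                  escape_speed_deg_s = 30,
                                  freeze_bout_prob = 0,
                                  freeze_bout_mean_s = 30,
                                  arena_diameter_cm = 82,
                                  omega_deg_per_s = 6) {
  if (dt_s > 1) stop("dt_s must be <= 1 s: the metrics assume >= 1 Hz")
  stopifnot(dt_s > 0, duration_s >= dt_s, speed_mean_cm_s >= 0,
            speed_shape > 0, turn_sd_deg >= 0,
            thigmotaxis_bias >= 0, thigmotaxis_bias <= 1,
            avoidance_skill >= 0, avoidance_skill <= 1,
            escape_speed_deg_s >= 0, freeze_bout_prob >= 0,
            freeze_bout_prob <= 1, freeze_bout_mean_s > 0)
  structure(as.list(environment()), class = "trajectory_sim_config")
}

unit_vec <- function(angle_rad) c(cos(angle_rad), sin(angle_rad))

#' Simulate one arena session
#'
#' Correlated random walk on the rotating arena. Every step the animal is
#' first carried passively by the rotation, then takes an active step whose
#' heading blends persistence, wall attraction and sector-avoidance
#' steering; the wall is reflective. Shocks are produced online by the
#' apparatus rule (0.5-s pulse at entrance, repeated on a 2-s cycle while
#' inside) in punished phases and trigger an escape response; freezing
#' bouts suspend active movement (the rotation still carries the animal).
#' Fully reproducible under a fixed seed.
#'
#' @param config a [trajectory_sim_config()].
#' @param sector a [sector_spec()] (room frame).
#' @param seed integer seed.
#' @param rat_id,group_label,phase_label,session_index header metadata.
#' @return a validated [track()] with logged shock flags.
#' @export
simulate_session <- function(config = trajectory_sim_config(),
                             sector = sector_spec(0), seed = 1,
                             rat_id = "r1", group_label = "control",
                             phase_label = "acquisition",
                             session_index = 1) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  set.seed(seed)
  dt <- config$dt_s
  n <- as.integer(floor(config$duration_s / dt)) + 1L
  t_s <- (seq_len(n) - 1) * dt
  R <- config$arena_diameter_cm / 2
  r_margin <- 1
  omega_rad <- config$omega_deg_per_s * pi / 180
  punished <- phase_label %in% c("acquisition", "reversal")
  cycle <- 2.0   # 0.5 s shock + 1.5 s pause

  xy <- matrix(0, n, 2)
  shock_flag <- integer(n)
  r0 <- sqrt(stats::runif(1)) * (R - r_margin)
  a0 <- stats::runif(1, 0, 2 * pi)
  xy[1, ] <- r0 * unit_vec(a0)
  heading <- stats::runif(1, 0, 2 * pi)
  speeds <- stats::rgamma(n, shape = config$speed_shape,
                          scale = config$speed_mean_cm_s /
                            config$speed_shape)
  turns <- stats::rnorm(n, 0, config$turn_sd_deg * pi / 180 * sqrt(dt))
  frozen_until <- -1
  escape_until <- -1
  escape_dir <- 1
  was_inside <- FALSE
  next_shock_at <- Inf

  theta_of <- function(p) atan2(p[2], p[1]) * 180 / pi

  for (i in seq_len(n)) {
    p <- xy[i, ]
    # shock logic on the current sample
    inside <- in_sector(theta_of(p), sector)
    if (punished) {
      if (inside && !was_inside) next_shock_at <- t_s[i]
      if (!inside) next_shock_at <- Inf
      if (inside && t_s[i] >= next_shock_at - 1e-9) {
        shock_flag[i] <- 1L
        next_shock_at <- next_shock_at + cycle
        escape_until <- t_s[i] + 2
        # escape tangentially, away from the sector center
        d <- (theta_of(p) - sector$center_deg) %% 360
        escape_dir <- if (d < 180) 1 else -1
      }
    }
    was_inside <- inside
    if (i == n) break

    # passive transport by the arena
    rot <- omega_rad * dt
    p <- c(p[1] * cos(rot) - p[2] * sin(rot),
           p[1] * sin(rot) + p[2] * cos(rot))
    heading <- heading + rot

    if (t_s[i] >= frozen_until &&
        stats::runif(1) < config$freeze_bout_prob * dt)
      frozen_until <- t_s[i] + stats::rexp(1, 1 / config$freeze_bout_mean_s)

    if (t_s[i] < frozen_until) {
      xy[i + 1, ] <- p
      next
    }

    if (t_s[i] < escape_until) {
      # forced tangential escape at the configured arena-frame rate
      r_now <- max(sqrt(sum(p^2)), 5)
      v <- config$escape_speed_deg_s * pi / 180 * r_now
      tangent <- atan2(p[2], p[1]) + escape_dir * pi / 2
      step <- v * dt * unit_vec(tangent)
      heading <- tangent
    } else {
      heading <- heading + turns[i]
      dir <- unit_vec(heading)
      r_now <- sqrt(sum(p^2))
      if (r_now > 1e-6 && config$thigmotaxis_bias > 0) {
        # steer toward the preferred radius (out if inside it, in if beyond)
        radial <- p / r_now * sign(0.8 * R - r_now)
        dir <- dir + config$thigmotaxis_bias * radial
      }
      if (config$avoidance_skill > 0 && r_now > 1e-6) {
        d <- (theta_of(p) - sector$center_deg) %% 360
        d <- if (d >= 180) d - 360 else d
        guard <- sector$width_deg / 2 + 40
        if (abs(d) < guard) {
          tangent <- atan2(p[2], p[1]) + sign(d + 1e-9) * pi / 2
          dir <- dir + 2 * config$avoidance_skill *
            (1 - abs(d) / guard) * unit_vec(tangent)
        }
      }
      heading <- atan2(dir[2], dir[1])
      step <- speeds[i] * dt * unit_vec(heading)
    }
    p <- p + step
    r_new <- sqrt(sum(p^2))
    if (r_new > R - r_margin) {       # reflective wall
      p <- p * (2 * (R - r_margin) - r_new) / r_new
      heading <- atan2(p[2], p[1]) +
        stats::runif(1, pi / 2, 3 * pi / 2)
    }
    xy[i + 1, ] <- p
  }

  hdr <- list(arena_diameter_cm = config$arena_diameter_cm,
              rotation_speed_deg_per_s = config$omega_deg_per_s,
              sector_center_deg = sector$center_deg,
              sector_width_deg = sector$width_deg,
              session_duration_s = config$duration_s,
              phase_label = phase_label, rat_id = rat_id,
              group_label = group_label, session_index = session_index)
  track(hdr, data.frame(t_s = t_s, x_cm = xy[, 1], y_cm = xy[, 2],
                        shock_flag = shock_flag))
}

#' Track of a fully immobile subject
#'
#' A point fixed in the ARENA frame (the animal sits still on the surface)
#' is carried through the room at the rotation rate: its room-frame path is
#' a circle. This closed-form reference subject anchors several printed
#' values: with a 60-degree sector and 6 deg/s it spends 10 s of every
#' 60-s revolution inside the sector, so its maximum time avoided is 50 s
#' and its opposite-sector proportion is 10/50 = 0.2.
#'
#' @param radius_cm fixed radius, default 30.
#' @param start_deg room-frame azimuth at t = 0; the default 31.5 places
#'   the subject just past the upper boundary of a sector centered at 0
#'   (freshly exited), offset half a sample step from the boundary so that
#'   no sample lands on it and the measured occupancy times are exact.
#' @param omega_deg_per_s rotation rate, default 6.
#' @param duration_s session length, default 1200.
#' @param dt_s sample interval, default 0.5.
#' @param phase_label session phase, default acquisition.
#' @return a [track()].
#' @export
immobile_track <- function(radius_cm = 30, start_deg = 31.5,
                           omega_deg_per_s = 6, duration_s = 1200,
                           dt_s = 0.5, phase_label = "acquisition") {
  t_s <- seq(0, duration_s, by = dt_s)
  th <- (start_deg + omega_deg_per_s * t_s) * pi / 180
  hdr <- list(arena_diameter_cm = 82,
              rotation_speed_deg_per_s = omega_deg_per_s,
              sector_center_deg = 0, sector_width_deg = 60,
              session_duration_s = duration_s, phase_label = phase_label,
              rat_id = "immobile", group_label = "reference",
              session_index = 1)
  track(hdr, data.frame(t_s = t_s, x_cm = radius_cm * cos(th),
                        y_cm = radius_cm * sin(th),
                        shock_flag = rep(0L, length(t_s))))
}

#' Phenotype presets for the cohort simulator
#'
#' @param phenotype `"active"` (learns to avoid; avoidance skill ramps up
#'   over sessions), `"freezer"` (near-total immobility: the freezing
#'   non-solver), or `"thigmotactic"` (active, wall-hugging, weak
#'   avoidance).
#' @param session_index session within the phase (1-based) for the
#'   learning ramp.
#' @return a [trajectory_sim_config()].
#' @export
phenotype_config <- function(phenotype = c("active", "freezer",
                                           "thigmotactic"),
                             session_index = 1) {
  phenotype <- match.arg(phenotype)
  skill <- min(0.9, 0.3 + 0.15 * (session_index - 1))
  switch(phenotype,
         active = trajectory_sim_config(avoidance_skill = skill),
         freezer = trajectory_sim_config(speed_mean_cm_s = 0.2,
                                         turn_sd_deg = 10,
                                         escape_speed_deg_s = 0,
                                         freeze_bout_prob = 1,
                                         freeze_bout_mean_s = 600),
         thigmotactic = trajectory_sim_config(thigmotaxis_bias = 0.9,
                                              avoidance_skill = skill / 3))
}

#' Simulate a full study cohort
#'
#' Generates the complete study layout -- two groups, habituation (5
#' sessions), acquisition (5), one 5-min retrieval, reversal (5, sector
#' displaced 180 degrees) -- as trajectories, computes the session metrics,
#' draws annotation measures (Poisson defecation, truncated-normal
#' saccharin/water masses, capped step-through latencies), optionally
#' plants missingness, and records every planted parameter in a manifest.
#'
#' @param n_per_group rats per group, default 9.
#' @param n_freezers named integer: freezing non-solvers per group,
#'   default `c(knockdown = 0, control = 3)` (placed first in id order).
#' @param seed master seed; per-session seeds are derived from it.
#' @param duration_s training-session length, default 1200 s.
#' @param dt_s sample interval, default 0.5 s.
#' @param sessions_per_phase sessions in each training phase, default 5.
#' @param missing_rate planted missingness in the metrics table, default
#'   0.006.
#' @param thigmotaxis named numeric per group, default
#'   `c(knockdown = 0.15, control = 0.45)` (controls hug the wall more).
#' @param keep_tracks return the track objects too (memory heavy).
#' @return list: `metrics` (session metrics long table), `annotations`,
#'   `manifest` (planted parameters), optionally `tracks`.
#' @export
simulate_cohort <- function(n_per_group = 9,
                            n_freezers = c(knockdown = 0, control = 3),
                            seed = 1, duration_s = 1200, dt_s = 0.5,
                            sessions_per_phase = 5, missing_rate = 0.006,
                            thigmotaxis = c(knockdown = 0.15,
                                            control = 0.45),
                            keep_tracks = FALSE) {
  groups <- c("knockdown", "control")
  rats <- data.frame(
    rat_id = sprintf("%s%02d", rep(substr(groups, 1, 1), each = n_per_group),
                     rep(seq_len(n_per_group), 2)),
    group = rep(groups, each = n_per_group), stringsAsFactors = FALSE)
  rats$phenotype <- "active"
  for (g in groups) {
    nf <- if (g %in% names(n_freezers)) n_freezers[[g]] else 0
    if (nf > 0) rats$phenotype[which(rats$group == g)[seq_len(nf)]] <-
        "freezer"
  }
  acq_sector <- sector_spec(0)
  rev_sector <- opposite_sector(acq_sector)
  plan <- rbind(
    data.frame(phase = "habituation", session_index = seq_len(
      sessions_per_phase), sector = I(rep(list(acq_sector),
                                          sessions_per_phase))),
    data.frame(phase = "acquisition", session_index = seq_len(
      sessions_per_phase), sector = I(rep(list(acq_sector),
                                          sessions_per_phase))),
    data.frame(phase = "retrieval", session_index = 1,
               sector = I(list(acq_sector))),
    data.frame(phase = "reversal", session_index = seq_len(
      sessions_per_phase), sector = I(rep(list(rev_sector),
                                          sessions_per_phase))))

  metrics <- list(); tracks <- list()
  sseed <- seed
  for (i in seq_len(nrow(rats))) {
    for (j in seq_len(nrow(plan))) {
      sseed <- (sseed + 9973L) %% .Machine$integer.max
      cfg <- phenotype_config(rats$phenotype[i], plan$session_index[j])
      cfg$thigmotaxis_bias <-
        if (rats$phenotype[i] == "freezer") cfg$thigmotaxis_bias else
          thigmotaxis[[rats$group[i]]]
      cfg$dt_s <- dt_s
      cfg$duration_s <- if (plan$phase[j] == "retrieval") 300 else duration_s
      tr <- simulate_session(cfg, plan$sector[[j]], seed = sseed,
                             rat_id = rats$rat_id[i],
                             group_label = rats$group[i],
                             phase_label = plan$phase[j],
                             session_index = plan$session_index[j])
      set.seed(sseed + 1L)
      defec <- stats::rpois(1, if (rats$group[i] == "control") 3 else 1.5)
      metrics[[length(metrics) + 1L]] <-
        compute_session_metrics(tr, plan$sector[[j]], defecation = defec)
      if (keep_tracks) tracks[[length(tracks) + 1L]] <- tr
    }
  }
  metrics <- do.call(rbind, metrics)

  if (missing_rate > 0) {
    set.seed(seed + 7L)
    mcols <- c("total_distance_m", "max_time_avoided_s",
               "mean_dist_center_cm", "prop_time_opposite")
    for (cl in mcols) {
      drop <- stats::runif(nrow(metrics)) < missing_rate
      metrics[[cl]][drop] <- NA_real_
    }
  }

  set.seed(seed + 11L)
  rtrunc_norm <- function(n, mean, sd, lo = 0) {
    v <- stats::rnorm(n, mean, sd)
    while (any(v < lo)) v[v < lo] <- stats::rnorm(sum(v < lo), mean, sd)
    v
  }
  ann <- data.frame(rats[, c("rat_id", "group")], litter_id = sprintf(
    "L%d", 1 + (seq_len(nrow(rats)) %% 3)),
    shock_intensity_mA = round(stats::runif(nrow(rats), 0.4, 0.7), 2),
    saccharin_g_s1 = rtrunc_norm(nrow(rats), 12, 3),
    saccharin_g_s2 = rtrunc_norm(nrow(rats), 14, 3),
    water_g_s1 = rtrunc_norm(nrow(rats), 6, 2),
    water_g_s2 = rtrunc_norm(nrow(rats), 5, 2),
    latency_s_t1 = step_through_latency(rtrunc_norm(nrow(rats), 30, 15)),
    latency_s_t2 = step_through_latency(rtrunc_norm(nrow(rats), 25, 15)),
    latency_s_t3 = step_through_latency(rtrunc_norm(nrow(rats), 25, 15)),
    stringsAsFactors = FALSE)
  names(ann)[names(ann) == "group"] <- "group_label"

  manifest <- list(n_per_group = n_per_group, n_freezers = as.list(
    n_freezers), seed = seed, duration_s = duration_s, dt_s = dt_s,
    sessions_per_phase = sessions_per_phase, missing_rate = missing_rate,
    thigmotaxis = as.list(thigmotaxis),
    phenotypes = stats::setNames(rats$phenotype, rats$rat_id))
  out <- list(metrics = metrics, annotations = ann, manifest = manifest)
  if (keep_tracks) out$tracks <- tracks
  out
}

#' Metric-level cohort simulator
#'
#' Draws the session metrics table directly (no trajectories): each
#' metric's values are normal with a session-specific day mean and SD
#' (emulating performance drift across days) plus a planted group shift in
#' SD units, optionally phase-specific. Used for Monte-Carlo studies of the
#' statistical pipeline (type-I error, power), where trajectory simulation
#' would add nothing but cost.
#'
#' @param n_per_group rats per group, default 9.
#' @param effects named list: metric -> either a single shift (SD units,
#'   knockdown minus control) or a named vector by phase, default none.
#' @param metrics metric column names to generate.
#' @param sessions_per_phase default 5; phases acquisition and reversal.
#' @param missing_rate planted missingness, default 0.
#' @param seed integer seed.
#' @return session metrics table (long by rat x session).
#' @export
simulate_cohort_metrics <- function(n_per_group = 9, effects = list(),
                                    metrics = c("max_time_avoided_s",
                                                "total_distance_m",
                                                "mean_dist_center_cm"),
                                    sessions_per_phase = 5,
                                    missing_rate = 0, seed = 1) {
  set.seed(seed)
  groups <- c("knockdown", "control")
  phases <- c("acquisition", "reversal")
  rat_id <- sprintf("%s%02d", rep(substr(groups, 1, 1), each = n_per_group),
                    rep(seq_len(n_per_group), 2))
  grid <- expand.grid(rat = seq_len(2 * n_per_group),
                      phase = phases,
                      session_index = seq_len(sessions_per_phase),
                      stringsAsFactors = FALSE)
  out <- data.frame(rat_id = rat_id[grid$rat],
                    group = rep(groups, each = n_per_group)[grid$rat],
                    phase = grid$phase, session_index = grid$session_index,
                    stringsAsFactors = FALSE)
  key <- interaction(out$phase, out$session_index)
  for (m in metrics) {
    day_mean <- stats::setNames(stats::rnorm(nlevels(key), 0, 0.5),
                                levels(key))
    day_sd <- stats::setNames(stats::runif(nlevels(key), 0.8, 1.2),
                              levels(key))
    eff <- effects[[m]]
    shift <- numeric(nrow(out))
    if (!is.null(eff)) {
      per_phase <- if (length(eff) == 1 && is.null(names(eff)))
        stats::setNames(rep(eff, 2), phases) else eff
      shift <- ifelse(out$group == "knockdown",
                      unname(per_phase[out$phase]), 0)
      shift[is.na(shift)] <- 0
    }
    v <- stats::rnorm(nrow(out), day_mean[as.character(key)] + shift,
                      day_sd[as.character(key)])
    if (missing_rate > 0) v[stats::runif(length(v)) < missing_rate] <- NA
    out[[m]] <- v
  }
  out
}

#' Circadian simulator configuration
#'
#' @param tau_h free-running period in hours, in (20, 28); default 24.2.
#' @param waveform `"square"` (default) or `"sinusoid"`.
#' @param mesor,amplitude counts per bin: midline level and swing; the
#'   subjective-night level is `mesor + amplitude`, the day level
#'   `max(0, mesor - amplitude)`. Defaults 10 and 8.
#' @param masking in [0,1]: fraction of activity suppressed by light
#'   under LD, default 0.3.
#' @param ld_days,dd_days schedule, defaults 29 and 16.
#' @param onset_h clock time of activity (dark) onset under LD, default 12
#'   (lights on at 0, dark at 12).
#' @param bin_width_min default 1.
#' @return list of class `circadian_sim_config`.
#' @export
circadian_sim_config <- function(tau_h = 24.2, waveform = c("square",
                                                            "sinusoid"),
                                 mesor = 10, amplitude = 8, masking = 0.3,
                                 ld_days = 29, dd_days = 16, onset_h = 12,
                                 bin_width_min = 1) {
  waveform <- match.arg(waveform)
  stopifnot(tau_h > 20, tau_h < 28, amplitude >= 0, mesor >= 0,
            masking >= 0, masking <= 1, ld_days >= 0, dd_days >= 0)
  structure(as.list(environment()), class = "circadian_sim_config")
}

#' Simulate an activity recording
#'
#' Poisson counts about a circadian waveform. Under LD the rhythm is
#' entrained (24-h period, activity onset at dark onset) and light
#' additionally suppresses activity by the masking coefficient; under DD
#' the rhythm free-runs at tau, phase-continuous with the last entrained
#' onset.
#'
#' @param config a [circadian_sim_config()].
#' @param seed integer seed.
#' @return an [activity_series()] with the LD/DD schedule attached.
#' @export
simulate_activity <- function(config = circadian_sim_config(), seed = 1) {
  stopifnot(inherits(config, "circadian_sim_config"))
  set.seed(seed)
  bw <- config$bin_width_min
  bpd <- as.integer(1440 / bw)
  n <- (config$ld_days + config$dd_days) * bpd
  t_h <- ((seq_len(n) - 0.5) * bw) / 60     # bin centers, hours
  ld_end_h <- config$ld_days * 24

  # hours since the most recent activity onset
  since_onset <- ifelse(
    t_h < ld_end_h,
    (t_h - config$onset_h) %% 24,
    (t_h - (ld_end_h - 24 + config$onset_h)) %% config$tau_h)
  period <- ifelse(t_h < ld_end_h, 24, config$tau_h)
  frac <- since_onset / period
  rate <- if (config$waveform == "square") {
    ifelse(frac < 0.5, config$mesor + config$amplitude,
           max(0, config$mesor - config$amplitude))
  } else {
    pmax(0, config$mesor + config$amplitude * cos(2 * pi * (frac - 0.25)))
  }

  light <- t_h < ld_end_h & (t_h %% 24) < 12
  rate <- ifelse(light, rate * (1 - config$masking), rate)
  counts <- stats::rpois(n, rate)

  sched <- list()
  for (d in seq_len(config$ld_days)) {
    sched[[length(sched) + 1L]] <- data.frame(
      start_min = (d - 1) * 1440, end_min = (d - 1) * 1440 + 720,
      state = "light", stringsAsFactors = FALSE)
    sched[[length(sched) + 1L]] <- data.frame(
      start_min = (d - 1) * 1440 + 720, end_min = d * 1440,
      state = "dark", stringsAsFactors = FALSE)
  }
  if (config$dd_days > 0)
    sched[[length(sched) + 1L]] <- data.frame(
      start_min = config$ld_days * 1440,
      end_min = (config$ld_days + config$dd_days) * 1440,
      state = "dark", stringsAsFactors = FALSE)
  activity_series(counts, start_timestamp = "2000-01-01 00:00",
                  bin_width_min = bw, schedule = do.call(rbind, sched))
}

#' Split an activity recording into its LD and DD portions
#'
#' @param x an [activity_series()].
#' @return list with elements `LD` and `DD` (either may be NULL).
#' @export
split_regimes <- function(x) {
  stopifnot(inherits(x, "activity_series"))
  ld <- ld_day_index(x)
  bpd <- bins_per_day(x)
  take <- function(days) {
    if (!length(days)) return(NULL)
    idx <- as.vector(vapply(days, function(d)
      ((d - 1) * bpd + 1):(d * bpd), integer(bpd)))
    st <- bin_light_state(x)[idx]
    r <- rle(st)
    ends <- cumsum(r$lengths) * x$bin_width_min
    starts <- c(0, utils::head(ends, -1))
    activity_series(x$counts[idx], start_timestamp = x$start_timestamp,
                    bin_width_min = x$bin_width_min,
                    schedule = data.frame(start_min = starts,
                                          end_min = ends, state = r$values))
  }
  list(LD = take(which(ld)), DD = take(which(!ld)))
}
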
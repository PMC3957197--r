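# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

basic_header <- function(duration_s = 60, omega = 6, phase = "habituation",
                         center = 0, width = 60) {
  list(arena_diameter_cm = 82, rotation_speed_deg_per_s = omega,
       sector_center_deg = center, sector_width_deg = width,
       session_duration_s = duration_s, phase_label = phase,
       rat_id = "r1", group_label = "control", session_index = 1)
}

make_track <- function(t_s, x_cm, y_cm, shock_flag = 0, ...) {
  track(basic_header(duration_s = max(t_s), ...),
        data.frame(t_s = t_s, x_cm = x_cm, y_cm = y_cm,
                   shock_flag = shock_flag))
}

# stationary point in the ROOM frame
parked_track <- function(radius_cm, angle_deg, duration_s = 60, dt_s = 1,
                         ...) {
  t_s <- seq(0, duration_s, by = dt_s)
  make_track(t_s, rep(radius_cm * cos(angle_deg * pi / 180), length(t_s)),
             rep(radius_cm * sin(angle_deg * pi / 180), length(t_s)), ...)
}

# random valid trajectory (uniform angles / sqrt-uniform radii), 1 Hz
random_track <- function(duration_s = 120, seed = 1, ...) {
  set.seed(seed)
  t_s <- 0:duration_s
  r <- sqrt(runif(length(t_s))) * 40
  a <- runif(length(t_s), 0, 2 * pi)
  make_track(t_s, r * cos(a), r * sin(a), ...)
}

# brute-force per-sample scan oracle for max_time_avoided: walks the
# samples once, accumulating sample-and-hold time outside the sector
brute_force_mta <- function(tr, sector = header_sector(tr)) {
  p <- to_polar(tr)
  member <- in_sector(p$theta_room_deg, sector)
  end_s <- max(tr$header$session_duration_s, max(p$t_s))
  hold <- c(diff(p$t_s), end_s - p$t_s[length(p$t_s)])
  best <- 0; cur <- 0
  for (i in seq_along(member)) {
    if (!member[i]) cur <- cur + hold[i] else cur <- 0
    if (cur > best) best <- cur
  }
  best
}

# brute-force mixed-ANOVA sums-of-squares decomposition for one between
# factor (2 groups) x one within factor, balanced or not
brute_force_mixed_anova <- function(d) {
  # d: rat_id, group, phase, score
  mu <- mean(d$score)
  subj_mean <- tapply(d$score, d$rat_id, mean)
  grp_of <- tapply(d$group, d$rat_id, function(g) g[1])
  grp_mean <- tapply(d$score, d$group, mean)
  ph_mean <- tapply(d$score, d$phase, mean)
  cell_mean <- tapply(d$score, list(d$group, d$phase), mean)
  n_w <- length(unique(d$phase))
  ss_group <- n_w * sum((tapply(subj_mean, grp_of, length)) *
                          (tapply(subj_mean, grp_of, mean) - mu)^2)
  ss_subj <- n_w * sum((subj_mean - grp_mean[grp_of])^2)
  ss_phase <- length(unique(d$rat_id)) * sum((ph_mean - mu)^2)
  # interaction SS via cell means (balanced within rat: each rat has all
  # phases once)
  n_g <- tapply(subj_mean, grp_of, length)
  ss_int <- sum(vapply(rownames(cell_mean), function(g) {
    sum(n_g[[g]] * (cell_mean[g, ] - grp_mean[[g]] - ph_mean +
                      mu)^2)
  }, numeric(1)))
  ss_tot <- sum((d$score - mu)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_phase - ss_int
  df_g <- length(unique(d$group)) - 1
  df_s <- length(unique(d$rat_id)) - length(unique(d$group))
  df_w <- n_w - 1
  df_err <- df_s * df_w
  list(
    F_group = (ss_group / df_g) / (ss_subj / df_s),
    F_phase = (ss_phase / df_w) / (ss_err / df_err),
    F_int = (ss_int / (df_g * df_w)) / (ss_err / df_err),
    ges_group = ss_group / (ss_group + ss_subj + ss_err),
    ges_int = ss_int / (ss_int + ss_subj + ss_err),
    df = c(df_g, df_s, df_w, df_err))
}

# exhaustive Mann-Whitney: exact two-sided p by enumerating all
# assignments of ranks to the first group
brute_force_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}
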
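ld_sched <- function(days) {
  do.call(rbind, lapply(seq_len(days), function(d)
    data.frame(start_min = (d - 1) * 1440 + c(0, 720),
               end_min = (d - 1) * 1440 + c(720, 1440),
               state = c("light", "dark"))))
}
dd_sched <- function(days)
  data.frame(start_min = 0, end_min = days * 1440, state = "dark")

square_series <- function(days, period_min = 1440, high = 20, low = 0,
                          onset_min = 720, sched = dd_sched(days)) {
  t <- seq_len(days * 1440) - 0.5
  phase <- (t - onset_min) %% period_min
  activity_series(ifelse(phase < period_min / 2, high, low),
                  schedule = sched)
}

test_that("double-plotted actogram: row d second half equals row d+1 first half", {
  act <- square_series(3, onset_min = 700)
  ag <- build_actogram(act)
  bpd <- 1440
  expect_equal(dim(ag$mat), c(3, 2 * bpd))
  for (d in 1:2)
    expect_equal(ag$mat[d, (bpd + 1):(2 * bpd)], ag$mat[d + 1, 1:bpd])
  # final row single-plotted with NA padding
  expect_true(all(is.na(ag$mat[3, (bpd + 1):(2 * bpd)])))
  # constant series: identical double rows
  const <- activity_series(rep(3, 3 * 1440), schedule = dd_sched(3))
  agc <- build_actogram(const)
  expect_equal(agc$mat[1, ], agc$mat[2, ])
  expect_error(build_actogram(activity_series(rep(0, 1440),
                                              schedule = dd_sched(1))),
               "2 full days")
})

test_that("a 24.5-h rhythm drifts 30 min rightward per actogram row", {
  act <- square_series(8, period_min = 1470, onset_min = 720)
  ag <- build_actogram(act)
  onset_col <- apply(ag$mat[, 1:1440], 1, function(v)
    which(diff(v) > 10)[1] + 1)
  expect_equal(diff(onset_col), rep(30, 7))
})

test_that("LD profile aligns to lights-on and recovers the waveform", {
  # nocturnal square wave: dark bins at the planted level, light bins 0
  act <- square_series(4, onset_min = 720, high = 15, low = 0,
                       sched = ld_sched(4))
  prof <- ld_profile(act)
  expect_equal(nrow(prof), 1440)
  expect_true(all(prof$mean[prof$time_h < 12] == 0))
  expect_true(all(prof$mean[prof$time_h >= 12] == 15))
  # constant series -> flat profile
  const <- activity_series(rep(7, 2 * 1440), schedule = ld_sched(2))
  expect_true(all(ld_profile(const)$mean == 7))
  expect_error(ld_profile(square_series(2)), "no LD days")
  # Poisson noise: profile within a few SE of the generating waveform
  act <- simulate_activity(circadian_sim_config(ld_days = 14, dd_days = 0,
                                                masking = 0), seed = 51)
  prof <- ld_profile(act)
  dark_mean <- mean(prof$mean[prof$time_h >= 12.5 & prof$time_h < 23.5])
  expect_equal(dark_mean, 18, tolerance = 0.05)
})

test_that("chi-square periodogram recovers planted periods", {
  # pure 24-h sinusoid + offset over 16 days
  t <- seq_len(16 * 1440) - 0.5
  x <- round(50 + 40 * sin(2 * pi * t / 1440))
  act <- activity_series(x, schedule = dd_sched(16))
  pg <- chi2_periodogram(act)
  expect_equal(pg$tau_hat, 24, tolerance = 1 / 60 + 1e-9)
  expect_true(all(pg$table$period_h >= 20 & pg$table$period_h <= 28))
  expect_true(all(pg$table$Q >= 0, na.rm = TRUE))
  # planted free-running 24.2 h under Poisson noise
  act <- simulate_activity(circadian_sim_config(tau_h = 24.2, ld_days = 0,
                                                dd_days = 16), seed = 52)
  expect_equal(chi2_periodogram(act)$tau_hat, 24.2, tolerance = 1 / 60)
  # white noise: nothing significant
  set.seed(53)
  noise <- activity_series(rpois(16 * 1440, 10), schedule = dd_sched(16))
  expect_true(is.na(chi2_periodogram(noise)$tau_hat))
  # all-zero series: no-significant-period marker, not an error
  zero <- activity_series(rep(0, 16 * 1440), schedule = dd_sched(16))
  expect_true(is.na(chi2_periodogram(zero)$tau_hat))
})

test_that("onset estimation finds square-wave onsets and rejects flat series", {
  act <- square_series(6, onset_min = 300)
  on <- onset_estimate(act, tau_h = 24)
  expect_equal(on$onset_min, 300 + (0:5) * 1440)
  # noisy square wave: within 30 min of the planted onset
  act <- simulate_activity(circadian_sim_config(tau_h = 24.2, ld_days = 0,
                                                dd_days = 10), seed = 54)
  on <- onset_estimate(act, 24.2)
  # generator plants onsets at 732 min + k * 1452 (tau = 24.2 h)
  got <- on$onset_min - (on$cycle - 1) * 1452
  expect_true(all(abs(got - 732) <= 30))
  # constant series: no onsets
  const <- activity_series(rep(5, 3 * 1440), schedule = dd_sched(3))
  expect_true(all(is.na(onset_estimate(const, 24)$onset_min)))
})

test_that("activity summary computes totals and activity/rest ratios", {
  # equal day/night activity -> ratio 1
  flat <- activity_series(rep(4, 2 * 1440), schedule = ld_sched(2))
  s <- activity_summary(flat)
  expect_equal(s$activity_rest_ratio, 1)
  expect_equal(s$total_activity_per_24h, 4 * 1440)
  expect_equal(s$regime, "LD")
  # purely nocturnal: zero light counts -> undefined marker
  noct <- square_series(2, onset_min = 720, high = 10, low = 0,
                        sched = ld_sched(2))
  expect_true(is.na(activity_summary(noct)$activity_rest_ratio))
  # with a 1-count light baseline the ratio equals the level ratio
  base <- square_series(2, onset_min = 720, high = 10, low = 1,
                        sched = ld_sched(2))
  expect_equal(activity_summary(base)$activity_rest_ratio, 10)
  # LD summary depends only on the schedule, not absolute clock time:
  # relabeling which day is which leaves it unchanged
  shuf <- activity_series(c(base$counts[1441:2880], base$counts[1:1440]),
                          schedule = ld_sched(2))
  expect_equal(activity_summary(shuf), activity_summary(base))
  # DD recovery: ratio close to the generating night/day contrast
  act <- simulate_activity(circadian_sim_config(tau_h = 24.2, ld_days = 0,
                                                dd_days = 16, mesor = 10,
                                                amplitude = 8), seed = 55)
  pg <- chi2_periodogram(act)
  s <- activity_summary(act, tau_h = pg$tau_hat)
  expect_equal(s$regime, "DD")
  expect_equal(s$activity_rest_ratio, 9, tolerance = 0.15)
})

test_that("exact Mann-Whitney matches enumeration and the stats reference", {
  set.seed(56)
  # tie-free data: agree with wilcox.test's exact distribution
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(8, 0.5)
    got <- mann_whitney_exact(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_true(got$exact)
    # and with the brute-force enumeration helper
    orc <- brute_force_mann_whitney(x, y)
    expect_equal(got$U, orc$U)
    expect_equal(got$p, orc$p)
  }
  # tied data (tau printed to 0.1 h): enumeration still exact
  x <- c(24.1, 24.1, 24.2, 24.0, 24.1)
  y <- c(24.2, 24.2, 24.3, 24.1, 24.2, 24.3, 24.2, 24.2)
  got <- mann_whitney_exact(x, y)
  orc <- brute_force_mann_whitney(x, y)
  expect_equal(got$U, orc$U)
  expect_equal(got$p, orc$p)
  # extreme ranking: all of group 1 below group 2 -> U = 0
  expect_equal(mann_whitney_exact(1:5, 6:13)$U, 0)
})

test_that("group comparison table uses Student t and exact Mann-Whitney", {
  set.seed(57)
  summ <- data.frame(
    group = rep(c("kd", "wt"), c(5, 8)),
    total_activity_per_24h = c(rnorm(5, 900, 50), rnorm(8, 1000, 50)),
    activity_rest_ratio = c(rnorm(5, 3, .5), rnorm(8, 2.5, .5)),
    tau_h = c(24.1, 24.1, 24.2, 24.0, 24.1,
              24.2, 24.2, 24.3, 24.1, 24.2, 24.3, 24.2, 24.2))
  cmp <- compare_circadian_groups(summ)
  expect_setequal(cmp$measure,
                  c("total_activity_per_24h", "activity_rest_ratio",
                    "tau_h"))
  # Student t rows have the pooled df
  expect_equal(cmp$df[cmp$measure == "total_activity_per_24h"], 11)
  ref <- t.test(summ$total_activity_per_24h[summ$group == "kd"],
                summ$total_activity_per_24h[summ$group == "wt"],
                var.equal = TRUE)
  expect_equal(cmp$statistic[cmp$measure == "total_activity_per_24h"],
               unname(ref$statistic))
  # identical groups: U at its null mean, p ~ 1
  same <- summ; same$tau_h <- rep(c(24.0, 24.1, 24.2, 24.3), length.out = 13)
  g1 <- same$tau_h[same$group == "kd"]; g2 <- same$tau_h[same$group == "wt"]
  mw <- mann_whitney_exact(g1, g2)
  expect_gt(mw$p, 0.5)
})
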
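metrics_from_values <- function(values) {
  # values: list phase -> matrix rats x sessions
  rows <- list()
  for (ph in names(values)) {
    m <- values[[ph]]
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        rat_id = sprintf("r%02d", i),
        group = if (i <= nrow(m) / 2) "knockdown" else "control",
        phase = ph, session_index = j, value = m[i, j],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- "total_distance_m"
  out
}

test_that("session standardization yields z-scores and is affine invariant", {
  m <- metrics_from_values(list(acquisition = cbind(c(1, 2, 3, 4))))
  z <- standardize_sessions(m, "total_distance_m")
  expect_equal(mean(z$z), 0)
  expect_equal(sd(z$z), 1)
  expect_equal(standardize_sessions(
    metrics_from_values(list(acquisition = cbind(c(1, 2, 3)))),
    "total_distance_m")$z, c(-1, 0, 1))
  # affine transform of the inputs leaves z-scores unchanged
  set.seed(31)
  vals <- matrix(rnorm(40), 8, 5)
  m1 <- metrics_from_values(list(acquisition = vals))
  m2 <- metrics_from_values(list(acquisition = 3.7 * vals - 11))
  expect_equal(standardize_sessions(m1, "total_distance_m")$z,
               standardize_sessions(m2, "total_distance_m")$z)
  # degenerate sessions are named errors
  expect_error(standardize_sessions(
    metrics_from_values(list(acquisition = cbind(c(2, 2, 2)))),
    "total_distance_m"), "zero variance")
  expect_error(standardize_sessions(
    metrics_from_values(list(acquisition = cbind(c(2, NA, NA)))),
    "total_distance_m"), "fewer than 2")
})

test_that("phase scores have mean 0 / SD 1 and respect missingness", {
  set.seed(32)
  m <- metrics_from_values(list(acquisition = matrix(rnorm(30, 50, 9), 6),
                                reversal = matrix(rnorm(30, 30, 5), 6)))
  ph <- phase_average(standardize_sessions(m, "total_distance_m"))
  for (p in unique(ph$phase)) {
    expect_equal(mean(ph$score[ph$phase == p]), 0, tolerance = 1e-12)
    expect_equal(sd(ph$score[ph$phase == p]), 1, tolerance = 1e-12)
  }
  # identical sessions: same ranking as a single-session z-score
  v <- c(3, 9, 1, 7, 5, 8)
  m1 <- metrics_from_values(list(
    acquisition = matrix(rep(v, 5), 6, 5)))
  ph1 <- phase_average(standardize_sessions(m1, "total_distance_m"))
  expect_equal(order(ph1$score), order(v))
  # random missingness never changes a complete rat's score sign vs a
  # brute-force recomputation over the non-missing entries
  set.seed(33)
  for (rep in 1:5) {
    vals <- matrix(rnorm(40), 8, 5)
    mask <- matrix(runif(40) < 0.15, 8, 5)
    mask[1, ] <- FALSE  # rat 1 complete
    vals[mask] <- NA
    mm <- metrics_from_values(list(acquisition = vals))
    z <- standardize_sessions(mm, "total_distance_m")
    ph <- phase_average(z)
    # oracle: direct column z-scores, row means over observed, re-z
    zo <- apply(vals, 2, function(col) (col - mean(col, na.rm = TRUE)) /
                  sd(col, na.rm = TRUE))
    sc <- rowMeans(zo, na.rm = TRUE)
    sc <- (sc - mean(sc)) / sd(sc)
    expect_equal(sort(ph$score), sort(sc), tolerance = 1e-12)
  }
})

test_that("plot imputation follows the closest-value rule", {
  mk <- function(v) metrics_from_values(list(acquisition = matrix(v, 1)))
  imp <- function(v) impute_for_plot(mk(v), "total_distance_m")
  # missing first session -> copy of second
  expect_equal(imp(c(NA, 7, 8, 9, 10))$total_distance_m[1], 7)
  # mid-phase with both neighbors valid -> their average
  expect_equal(imp(c(5, 6, NA, 10, 11))$total_distance_m[3], 8)
  # neighbor also missing -> nearest valid, tie toward the earlier session
  expect_equal(imp(c(5, 6, NA, NA, 11))$total_distance_m[3], 6)
  # imputation always works from the ORIGINAL pattern: both originally
  # valid neighbors -> average, even when another cell is also missing
  expect_equal(imp(c(5, NA, 7, NA, 11))$total_distance_m[4], 9)
  got <- imp(c(5, 4, NA, NA, 11))
  expect_equal(got$total_distance_m[4], 11)   # distance 1 beats distance 2
  expect_true(all(got$imputed[3:4]))
  # fully missing phase stays missing
  expect_true(all(is.na(imp(c(NA, NA, NA, NA, NA))$total_distance_m)))
  # analysis tables are untouched apart from the filled cells
  expect_equal(imp(c(5, 6, NA, 10, 11))$total_distance_m[c(1, 2, 4, 5)],
               c(5, 6, 10, 11))
})

test_that("non-solver flagging needs BOTH low distance and no shock response", {
  set.seed(34)
  n <- 9
  base <- function() matrix(rnorm(n * 2 * 5, 40, 6), n * 2, 5)
  acq <- base(); rev <- base()
  acq[1:3, ] <- rnorm(15, 8, 1); rev[1:3, ] <- rnorm(15, 6, 1)  # freezers
  m <- metrics_from_values(list(acquisition = acq, reversal = rev))
  m$median_abs_speed_after_shock_deg_s <- ifelse(
    m$rat_id %in% c("r01", "r02", "r03"), 0.5, 20)
  fl <- flag_nonsolvers(m)
  expect_equal(sort(fl$rat_id[fl$flagged]), c("r01", "r02", "r03"))
  # an active avoider is never flagged however poor its distance
  m2 <- m
  m2$median_abs_speed_after_shock_deg_s <- 20  # everyone responds
  expect_false(any(flag_nonsolvers(m2)$flagged))
  # all-active, homogeneous cohort: empty set
  m3 <- metrics_from_values(list(acquisition = base(), reversal = base()))
  m3$median_abs_speed_after_shock_deg_s <- 15
  expect_false(any(flag_nonsolvers(m3)$flagged))
})

test_that("matched exclusion removes equal counts, lowest avoiders first", {
  set.seed(35)
  n <- 9
  acq <- matrix(rnorm(n * 2 * 5, 40, 6), n * 2, 5)
  rev <- matrix(rnorm(n * 2 * 5, 40, 6), n * 2, 5)
  acq[10:12, ] <- rnorm(15, 8, 1); rev[10:12, ] <- rnorm(15, 6, 1)
  m <- metrics_from_values(list(acquisition = acq, reversal = rev))
  m$median_abs_speed_after_shock_deg_s <-
    ifelse(m$rat_id %in% c("r10", "r11", "r12"), 0.5, 20)
  # avoidance ranking metric
  mta_a <- matrix(rnorm(n * 2 * 5, 600, 100), n * 2, 5)
  mta_a[1:3, ] <- rnorm(15, 100, 10)  # worst knockdown avoiders
  mta_r <- matrix(rnorm(n * 2 * 5, 600, 100), n * 2, 5)
  mta_r[1:3, ] <- rnorm(15, 100, 10)
  m$max_time_avoided_s <- metrics_from_values(
    list(acquisition = mta_a, reversal = mta_r))$total_distance_m
  fl <- flag_nonsolvers(m)
  expect_equal(sort(fl$rat_id[fl$flagged]), c("r10", "r11", "r12"))
  ex <- matched_exclusion(fl, m)
  expect_equal(sort(ex$matched), c("r01", "r02", "r03"))
  expect_equal(length(ex$analysis_rats), 12)  # 6 vs 6
  # no flags -> identity
  fl0 <- fl; fl0$flagged <- FALSE
  ex0 <- matched_exclusion(fl0, m)
  expect_equal(ex0$excluded, character(0))
  expect_equal(length(ex0$analysis_rats), 18)
})

test_that("mixed ANOVA matches the brute-force sums-of-squares oracle", {
  # hand-computable 2x2 toy: 4 rats
  toy <- data.frame(rat_id = rep(c("a", "b", "c", "d"), each = 2),
                    group = rep(c("g1", "g2"), each = 4),
                    phase = rep(c("p1", "p2"), 4),
                    score = c(1, 2, 2, 4, 5, 4, 7, 5))
  got <- mixed_anova(toy)
  orc <- brute_force_mixed_anova(toy)
  expect_equal(got$F[got$effect == "group"], orc$F_group)
  expect_equal(got$F[got$effect == "group:phase"], orc$F_int)
  expect_equal(got$ges[got$effect == "group"], orc$ges_group)
  expect_equal(got$ges[got$effect == "group:phase"], orc$ges_int)
  # random cohorts, balanced and unbalanced, n <= 6 per group
  set.seed(36)
  for (n1 in 2:6) for (n2 in c(n1, min(n1 + 1, 6))) {
    d <- data.frame(
      rat_id = rep(sprintf("r%02d", seq_len(n1 + n2)), each = 2),
      group = rep(c("g1", "g2"), times = 2 * c(n1, n2)),
      phase = rep(c("p1", "p2"), n1 + n2),
      score = rnorm(2 * (n1 + n2)))
    got <- mixed_anova(d)
    orc <- brute_force_mixed_anova(d)
    expect_equal(got$F[got$effect == "group"], orc$F_group,
                 tolerance = 1e-10)
    expect_equal(got$F[got$effect == "phase"], orc$F_phase,
                 tolerance = 1e-10)
    expect_equal(got$F[got$effect == "group:phase"], orc$F_int,
                 tolerance = 1e-10)
    expect_true(all(got$ges >= 0 & got$ges <= 1))
  }
})

test_that("degenerate inputs and invariants of the mixed ANOVA", {
  # groups identical by construction: F(group) ~ 0
  d <- data.frame(rat_id = rep(sprintf("r%d", 1:6), each = 2),
                  group = rep(c("g1", "g2"), each = 6),
                  phase = rep(c("p1", "p2"), 6),
                  score = rep(c(1, 2, 3, 1, 2, 3), each = 2))
  got <- mixed_anova(d)
  expect_equal(got$F[got$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(got$ges[got$effect == "group"], 0, tolerance = 1e-12)
  # phase-score input (mean 0 both phases) suppresses the phase effect
  set.seed(37)
  m <- metrics_from_values(list(acquisition = matrix(rnorm(40), 8),
                                reversal = matrix(rnorm(40), 8)))
  ph <- phase_average(standardize_sessions(m, "total_distance_m"))
  res <- mixed_anova_group_by_phase(ph)
  expect_false("phase" %in% res$effect)
  expect_setequal(res$effect, c("group", "group:phase"))
  # incomplete within data is an error
  expect_error(mixed_anova(d[-1, ]), "within level")
})

test_that("planted group-by-phase interaction is detected with good power", {
  set.seed(38)
  hits <- 0; n_rep <- 60
  for (r in 1:n_rep) {
    m <- simulate_cohort_metrics(
      n_per_group = 6,
      effects = list(max_time_avoided_s = c(acquisition = 1.5,
                                            reversal = 0)),
      seed = 1000 + r)
    ph <- phase_average(standardize_sessions(m, "max_time_avoided_s"))
    res <- mixed_anova_group_by_phase(ph)
    if (res$p[res$effect == "group:phase"] < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.5)
})

test_that("Welch test matches the closed form and its contracts", {
  got <- welch_t(c(1, 2, 3), c(4, 5, 6))
  # textbook hand computation: equal variances 1, se = sqrt(2/3)
  expect_equal(got$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(got$df, 4, tolerance = 1e-12)
  expect_equal(got$r, -sqrt(got$t^2 / (got$t^2 + got$df)))
  # identical groups -> t = 0, r = 0
  same <- welch_t(c(2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$r, 0); expect_equal(same$p, 1)
  # Welch df never exceeds the pooled df
  set.seed(39)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(9, 1, 3)
    expect_lte(welch_t(x, y)$df, 13)
  }
})

test_that("polynomial trial contrasts have the stated signs and dfs", {
  # 9 vs 9 rats, 3 trials
  set.seed(40)
  mk <- function(trend_kd, trend_ct, noise = 3) {
    do.call(rbind, lapply(1:18, function(i) {
      g <- if (i <= 9) "knockdown" else "control"
      tr <- if (g == "knockdown") trend_kd else trend_ct
      data.frame(rat_id = sprintf("r%02d", i), group = g, trial = 1:3,
                 latency_s = tr + rnorm(3, 0, noise))
    }))
  }
  # deterministic single-rat sanity: (10,20,30) -> positive linear, zero quad
  one <- data.frame(rat_id = rep(c("a", "b"), each = 3),
                    group = rep(c("g1", "g2"), each = 3), trial = rep(1:3, 2),
                    latency_s = c(10, 20, 30, 10, 30, 10))
  sc <- trial_contrasts(rbind(one, transform(one, rat_id = paste0(
    rat_id, "2"), latency_s = latency_s + rnorm(6, 0, .1))))$contrast_scores
  expect_gt(sc$linear[sc$rat_id == "a"], 0)
  expect_equal(sc$quadratic[sc$rat_id == "a"], 0, tolerance = 1e-12)
  expect_equal(sc$linear[sc$rat_id == "b"], 0, tolerance = 1e-12)
  expect_lt(sc$quadratic[sc$rat_id == "b"], 0)  # peaked -> negative quad
  # planted increasing knockdown vs decreasing control: interaction sign
  lat <- mk(c(10, 20, 30), c(30, 20, 10))
  res <- trial_contrasts(lat)
  int_row <- res$main[res$main$effect == "linear:group", ]
  expect_lt(int_row$p, 0.01)
  # groups in sorted order: control (decreasing, negative linear) first,
  # so control - knockdown is negative
  expect_lt(int_row$t, 0)
  expect_equal(unique(res$main$df), 2 * (18 - 2))     # t(32) structure
  expect_equal(unique(res$by_group$df), 2 * (9 - 1))  # t(16) follow-ups
  expect_equal(res$group_effect$df, 16)
  expect_equal(nrow(res$per_trial), 3)
  # a rat missing a trial is dropped with a message
  expect_message(trial_contrasts(lat[-1, ]), "dropping")
})

test_that("preference ratio and its ANOVA behave as specified", {
  cons <- data.frame(rat_id = c("a", "a", "b", "b"),
                     group = c("g1", "g1", "g2", "g2"),
                     session_index = c(1, 2, 1, 2),
                     saccharin_g = c(5, 0, 10, 3),
                     water_g = c(5, 10, 0, 3))
  pr <- preference_ratio(cons)
  expect_equal(pr$preference, c(0.5, 0, 1, 0.5))
  zero <- preference_ratio(data.frame(rat_id = "a", group = "g",
                                      session_index = 1, saccharin_g = 0,
                                      water_g = 0))
  expect_true(is.na(zero$preference))
  # ANOVA runs on a small simulated cohort
  set.seed(41)
  cons <- do.call(rbind, lapply(1:12, function(i)
    data.frame(rat_id = sprintf("r%02d", i),
               group = if (i <= 6) "g1" else "g2", session_index = 1:2,
               saccharin_g = rnorm(2, 12, 2), water_g = rnorm(2, 5, 1))))
  res <- preference_anova(cons)
  expect_true("group" %in% res$effect)
  expect_true(all(res$ges >= 0 & res$ges <= 1))
})

test_that("metric correlations are symmetric with unit diagonal", {
  set.seed(42)
  ps <- data.frame(rat_id = sprintf("r%02d", 1:20), phase = "acquisition",
                   m1 = rnorm(20))
  ps$m2 <- -ps$m1
  ps$m3 <- rnorm(20)
  cc <- metric_correlations(ps)
  expect_equal(diag(cc), c(m1 = 1, m2 = 1, m3 = 1))
  expect_equal(cc["m1", "m2"], -1)
  expect_equal(cc, t(cc))
  expect_lt(abs(cc["m1", "m3"]), 0.5)  # independent -> near zero
  # constant column -> NA off-diagonal cells
  ps$m4 <- 1
  cc <- metric_correlations(ps)
  expect_true(is.na(cc["m4", "m1"]))
  expect_equal(cc["m4", "m4"], 1)
})
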
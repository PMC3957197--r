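# Cohort statistics: the session-standardization / phase-averaging scheme,
# non-solver exclusion with matched removal, mixed ANOVA with generalized
# eta squared, Welch tests, polynomial trial contrasts and the saccharin
# preference ratio. All standardizations use the sample SD (n-1).
#
# Why standardize per session before averaging: performance drifts across
# days, so a plain mean over available sessions would depend on WHICH
# sessions a rat happens to miss. z-scoring each session first removes the
# day effect; averaging the z-values then re-standardizing yields one
# comparable score per rat and phase. Missing values stay missing in the
# analysis; imputation exists only for plotting.

zscore <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)

#' Standardize a metric within each session
#'
#' Within every phase x session, converts the metric to z-scores across
#' rats ((x - mean)/SD, sample SD). Missing values are preserved.
#'
#' @param metrics session-level metrics table (one row per rat x session,
#'   as from [compute_session_metrics()] / [batch_session_metrics()]), with
#'   columns `rat_id`, `group`, `phase`, `session_index` and the metric.
#' @param metric name of the metric column.
#' @param phases phases to include, default acquisition and reversal.
#' @return data frame `rat_id`, `group`, `phase`, `session_index`, `z`.
#' @export
standardize_sessions <- function(metrics, metric,
                                 phases = c("acquisition", "reversal")) {
  if (!metric %in% names(metrics)) stop("no such metric column: ", metric)
  d <- metrics[metrics$phase %in% phases,
               c("rat_id", "group", "phase", "session_index")]
  d$value <- metrics[[metric]][metrics$phase %in% phases]
  key <- interaction(d$phase, d$session_index, drop = TRUE)
  d$z <- NA_real_
  for (k in levels(key)) {
    sel <- key == k
    v <- d$value[sel]
    ok <- !is.na(v)
    if (sum(ok) < 2)
      stop("session ", k, " has fewer than 2 non-missing values for ",
           metric)
    if (stats::sd(v[ok]) == 0)
      stop("zero variance in session ", k, " for ", metric)
    d$z[sel] <- zscore(v)
  }
  d[, c("rat_id", "group", "phase", "session_index", "z")]
}

#' Phase scores: average session z-values, then re-standardize
#'
#' Per rat and phase, the mean of available session z-values; the means are
#' then z-scored again across rats within each phase, giving one score per
#' rat per phase. With no exclusions each phase's scores have mean 0 and
#' sample SD 1 by construction. A rat with no valid session in a phase is
#' dropped from that phase with a message.
#'
#' @param z_table output of [standardize_sessions()].
#' @return data frame `rat_id`, `group`, `phase`, `score`.
#' @export
phase_average <- function(z_table) {
  sp <- split(z_table, list(z_table$rat_id, z_table$phase), drop = TRUE)
  rows <- lapply(sp, function(g) {
    data.frame(rat_id = g$rat_id[1], group = g$group[1], phase = g$phase[1],
               mean_z = mean(g$z, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  drop <- is.nan(out$mean_z)
  if (any(drop)) {
    message("dropping rat(s) with no valid session in a phase: ",
            paste(unique(out$rat_id[drop]), collapse = ", "))
    out <- out[!drop, , drop = FALSE]
  }
  out$score <- stats::ave(out$mean_z, out$phase, FUN = zscore)
  rownames(out) <- NULL
  out[order(out$phase, out$rat_id), c("rat_id", "group", "phase", "score")]
}

#' Impute missing sessions for plotting only
#'
#' Fills each missing value with the closest valid value from the same
#' phase for the same rat; if the missing value sits mid-phase with both
#' adjacent sessions valid, their average is used. Equidistant valid values
#' farther away are resolved toward the earlier session. The result is for
#' plotting; the analysis never consumes imputed values.
#'
#' @param metrics session-level metrics table.
#' @param metric metric column name.
#' @return `metrics` with the metric column imputed and a logical
#'   `imputed` column added.
#' @export
impute_for_plot <- function(metrics, metric) {
  out <- metrics
  out$imputed <- FALSE
  key <- interaction(metrics$rat_id, metrics$phase, drop = TRUE)
  for (k in levels(key)) {
    sel <- which(key == k)
    sel <- sel[order(metrics$session_index[sel])]
    v <- out[[metric]][sel]
    miss <- which(is.na(v))
    valid <- which(!is.na(v))
    if (length(valid) == 0 || length(miss) == 0) next
    for (i in miss) {
      if (i > 1 && i < length(v) &&
          !is.na(v[i - 1]) && !is.na(v[i + 1])) {
        out[[metric]][sel[i]] <- (v[i - 1] + v[i + 1]) / 2
      } else {
        dmin <- min(abs(valid - i))
        cand <- valid[abs(valid - i) == dmin]
        out[[metric]][sel[i]] <- v[min(cand)]
      }
      out$imputed[sel[i]] <- TRUE
    }
  }
  out
}

#' Flag freezing non-solvers
#'
#' A rat is a non-solver when it reacted to the task with immobility
#' rather than active escape, making its avoidance scores uninterpretable.
#' Operationalized as BOTH (a) a combined-phase standardized total-distance
#' z-score below `z_cut` (phase scores for acquisition and reversal are
#' averaged per rat and the averages re-standardized across rats) and (b) a
#' mean median absolute post-shock arena-frame speed below `speed_cut`
#' (freezing animals show no shock reaction; active escapers move at well
#' over 8 deg/s).
#'
#' @param metrics session-level metrics table including
#'   `total_distance_m` and `median_abs_speed_after_shock_deg_s`.
#' @param z_cut combined z-score guard, default -1.
#' @param speed_cut post-shock speed criterion in deg/s, default 2.
#' @return data frame per rat: `rat_id`, `group`, `z_combined`,
#'   `post_shock_speed`, `flagged`.
#' @export
flag_nonsolvers <- function(metrics, z_cut = -1, speed_cut = 2) {
  ph <- phase_average(standardize_sessions(metrics, "total_distance_m"))
  comb <- stats::aggregate(score ~ rat_id + group, ph, mean)
  comb$z_combined <- zscore(comb$score)
  av <- metrics[metrics$phase %in% c("acquisition", "reversal"), ]
  spd <- stats::aggregate(
    median_abs_speed_after_shock_deg_s ~ rat_id, av, mean,
    na.rm = TRUE, na.action = stats::na.pass)
  names(spd)[2] <- "post_shock_speed"
  out <- merge(comb[, c("rat_id", "group", "z_combined")], spd,
               by = "rat_id", all.x = TRUE)
  out$flagged <- !is.na(out$z_combined) & out$z_combined < z_cut &
    !is.na(out$post_shock_speed) & out$post_shock_speed < speed_cut
  out[order(out$rat_id), ]
}

#' Matched exclusion of low-performing rats from the other group
#'
#' Non-solvers are excluded; to keep the design balanced, the same number
#' of rats is removed from the other group, choosing those with the lowest
#' mean (acquisition, reversal) standardized maximum time avoided. Ties are
#' broken by rat id order and logged. Both groups shrink by the same count.
#'
#' @param flags output of [flag_nonsolvers()].
#' @param metrics session-level metrics table (for the avoidance ranking).
#' @return list with `excluded` (rat ids: flagged plus matched removals),
#'   `matched` (the performance-matched removals only) and `analysis_rats`
#'   (ids retained for analysis).
#' @export
matched_exclusion <- function(flags, metrics) {
  flagged <- flags$rat_id[flags$flagged]
  groups <- unique(flags$group)
  n_flag <- vapply(groups, function(g)
    sum(flags$flagged[flags$group == g]), integer(1))
  target <- max(n_flag, 0L)
  matched <- character(0)
  if (target > 0) {
    ph <- phase_average(standardize_sessions(metrics, "max_time_avoided_s"))
    perf <- stats::aggregate(score ~ rat_id + group, ph, mean)
    for (g in groups) {
      need <- target - n_flag[[g]]
      if (need == 0) next
      pool <- perf[perf$group == g & !perf$rat_id %in% flagged, ]
      if (nrow(pool) < need)
        stop("group '", g, "' too small for matched removal of ", need)
      pool <- pool[order(pool$score, pool$rat_id), ]
      if (need < nrow(pool) && pool$score[need] == pool$score[need + 1])
        message("tie in matched-exclusion ranking broken by rat_id order")
      matched <- c(matched, pool$rat_id[seq_len(need)])
    }
  }
  excluded <- c(flagged, matched)
  list(excluded = excluded, matched = matched,
       analysis_rats = setdiff(flags$rat_id, excluded))
}

anova_strata_ss <- function(fit) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1]]
    for (i in seq_len(nrow(tab))) {
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, term = trimws(rownames(tab)[i]),
        df = tab$Df[i], ss = tab$`Sum Sq`[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mixed ANOVA with a between-subject group and a within-subject factor
#'
#' Univariate mixed ANOVA via `stats::aov` with an `Error(subject/within)`
#' stratum: the group effect is tested against between-subject error, the
#' within-factor main effect and the group x within interaction against the
#' subject x within error. With a two-level within factor no sphericity
#' correction is needed (the F tests are exact). Effect sizes are
#' generalized eta squared: each effect's SS divided by that SS plus the
#' sum of ALL error SS (Bakeman's formulation with no observed factors).
#'
#' When the within factor's main effect is degenerate by construction --
#' e.g. phase scores re-standardized to mean 0 in both phases -- its row is
#' suppressed and only the group effect and the interaction are reported.
#'
#' @param scores long data frame.
#' @param dv,between,within,subject column names; defaults `score`,
#'   `group`, `phase`, `rat_id`.
#' @return data frame of class `anova_result`: `effect`, `F`, `df1`,
#'   `df2`, `p`, `ges`.
#' @export
mixed_anova <- function(scores, dv = "score", between = "group",
                        within = "phase", subject = "rat_id") {
  d <- data.frame(y = scores[[dv]],
                  g = factor(scores[[between]]),
                  w = factor(scores[[within]]),
                  s = factor(scores[[subject]]))
  if (any(is.na(d$y)))
    stop("mixed ANOVA requires complete data (all within levels per subject)")
  counts <- table(d$s, d$w)
  if (any(counts != 1))
    stop("each subject needs exactly one value per within level")
  fit <- stats::aov(y ~ g * w + Error(s / w), data = d)
  ss <- anova_strata_ss(fit)
  pick <- function(term) ss[ss$term == term, , drop = FALSE]
  ss_g <- pick("g"); ss_w <- pick("w"); ss_gw <- pick("g:w")
  err_b <- ss[grepl("Residuals", ss$term) & grepl("Error: s$", ss$stratum), ]
  err_w <- ss[grepl("Residuals", ss$term) & grepl("s:w", ss$stratum), ]
  ss_err_total <- err_b$ss + err_w$ss
  row_for <- function(eff, term_ss, err) {
    mse <- err$ss / err$df
    f <- (term_ss$ss / term_ss$df) / mse
    data.frame(effect = eff, F = f, df1 = term_ss$df, df2 = err$df,
               p = stats::pf(f, term_ss$df, err$df, lower.tail = FALSE),
               ges = term_ss$ss / (term_ss$ss + ss_err_total),
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_for(between, ss_g, err_b),
               row_for(within, ss_w, err_w),
               row_for(paste0(between, ":", within), ss_gw, err_w))
  tot <- ss_g$ss + ss_w$ss + ss_gw$ss + ss_err_total
  if (ss_w$ss <= 1e-9 * tot) out <- out[out$effect != within, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("anova_result", class(out))
  out
}

#' @rdname mixed_anova
#' @param phases the two phases analyzed, default acquisition and reversal.
#' @param scores data frame from [phase_average()].
#' @export
mixed_anova_group_by_phase <- function(scores,
                                       phases = c("acquisition",
                                                  "reversal")) {
  mixed_anova(scores[scores$phase %in% phases, , drop = FALSE])
}

#' @export
print.anova_result <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("%s: F(%d, %d) = %.2f, p = %.4g, ges = %.3f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i], x$ges[i]))
  invisible(x)
}

#' Welch's t-test with correlation effect size
#'
#' Unequal-variance t with Welch--Satterthwaite degrees of freedom, plus
#' the effect size r = sqrt(t^2 / (t^2 + df)) carrying the sign of t. When
#' both groups are constant with equal means the statistic is 0 by
#' contract.
#'
#' @param x,y numeric samples (NA dropped), each of length >= 2.
#' @return data frame of class `welch_result`: `t`, `df`, `p`, `r`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t needs at least 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      out <- data.frame(t = 0, df = length(x) + length(y) - 2, p = 1, r = 0)
      class(out) <- c("welch_result", class(out))
      return(out)
    }
    stop("both groups constant with different means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  t <- unname(ht$statistic); df <- unname(ht$parameter)
  out <- data.frame(t = t, df = df, p = ht$p.value,
                    r = sign(t) * sqrt(t^2 / (t^2 + df)))
  class(out) <- c("welch_result", class(out))
  out
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t(%.2f) = %.3f, p = %.4g, r = %.2f\n",
              x$df, x$t, x$p, x$r))
  invisible(x)
}

#' Polynomial trial contrasts for ordered repeated trials
#'
#' For a design with one ordered within-subject trial factor (e.g. two
#' habituation step-through trials followed by the acquisition trial),
#' computes per-rat orthonormal linear and quadratic contrast scores and
#' tests: each contrast's main effect (against the pooled within-subject
#' error), its interaction with group, per-group follow-up contrasts
#' (against each group's own within error), the group main effect
#' (equal-variance t on subject means), and per-trial Welch tests. A rat
#' missing any trial is dropped with a message.
#'
#' @param latencies long data frame with columns `rat_id`, `group`,
#'   `trial` (ordered integer) and `latency_s`.
#' @return list of data frames: `contrast_scores` (per rat),
#'   `main` (linear/quadratic main effects and interactions with group),
#'   `by_group` (per-group contrasts), `group_effect`, `per_trial` (Welch
#'   per trial).
#' @export
trial_contrasts <- function(latencies) {
  need <- c("rat_id", "group", "trial", "latency_s")
  stopifnot(all(need %in% names(latencies)))
  wide <- stats::reshape(latencies[, need], idvar = c("rat_id", "group"),
                         timevar = "trial", direction = "wide")
  ycols <- order(as.integer(sub("latency_s\\.", "",
                                grep("^latency_s", names(wide),
                                     value = TRUE))))
  ymat <- as.matrix(wide[, grep("^latency_s", names(wide))[ycols]])
  keep <- stats::complete.cases(ymat)
  if (!all(keep)) {
    message("dropping rat(s) with missing trial(s): ",
            paste(wide$rat_id[!keep], collapse = ", "))
    wide <- wide[keep, , drop = FALSE]; ymat <- ymat[keep, , drop = FALSE]
  }
  k <- ncol(ymat)
  if (k < 3) stop("trial contrasts need at least 3 ordered trials")
  cp <- stats::contr.poly(k)  # orthonormal columns
  scores <- data.frame(rat_id = wide$rat_id, group = wide$group,
                       linear = as.numeric(ymat %*% cp[, 1]),
                       quadratic = as.numeric(ymat %*% cp[, 2]),
                       stringsAsFactors = FALSE)
  groups <- sort(unique(scores$group))
  if (length(groups) != 2) stop("trial_contrasts expects exactly 2 groups")
  n_g <- table(factor(scores$group, groups))
  ncontr <- k - 1
  cmat <- as.matrix(ymat %*% cp)  # all k-1 orthonormal contrasts
  gm <- apply(cmat, 2, function(v) tapply(v, scores$group, mean))[groups, ,
                                                                  drop = FALSE]
  ss_w <- sum(vapply(seq_len(ncontr), function(j)
    sum((cmat[, j] - gm[scores$group, j])^2), numeric(1)))
  df_w <- ncontr * (nrow(scores) - 2)
  ms_w <- ss_w / df_w

  contrast_rows <- function(j, name) {
    est_main <- mean(gm[, j])  # unweighted mean of group means
    se_main <- sqrt(ms_w * sum(1 / n_g) / 4)
    t_main <- est_main / se_main
    est_int <- gm[1, j] - gm[2, j]
    se_int <- sqrt(ms_w * sum(1 / n_g))
    t_int <- est_int / se_int
    data.frame(
      effect = c(name, paste0(name, ":group")),
      t = c(t_main, t_int), df = df_w,
      p = 2 * stats::pt(-abs(c(t_main, t_int)), df_w),
      r = sign(c(t_main, t_int)) *
        sqrt(c(t_main, t_int)^2 / (c(t_main, t_int)^2 + df_w)),
      stringsAsFactors = FALSE)
  }
  main <- rbind(contrast_rows(1, "linear"), contrast_rows(2, "quadratic"))

  by_group <- do.call(rbind, lapply(groups, function(g) {
    sub <- cmat[scores$group == g, , drop = FALSE]
    n <- nrow(sub)
    ms_g <- sum(sweep(sub, 2, colMeans(sub))^2) / (ncontr * (n - 1))
    df_g <- ncontr * (n - 1)
    tt <- colMeans(sub)[1:2] / sqrt(ms_g / n)
    data.frame(group = g, effect = c("linear", "quadratic"), t = tt,
               df = df_g, p = 2 * stats::pt(-abs(tt), df_g),
               r = sign(tt) * sqrt(tt^2 / (tt^2 + df_g)),
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL

  m_subj <- rowMeans(ymat)
  ge <- stats::t.test(m_subj[scores$group == groups[1]],
                      m_subj[scores$group == groups[2]], var.equal = TRUE)
  tg <- unname(ge$statistic); dfg <- unname(ge$parameter)
  group_effect <- data.frame(t = tg, df = dfg, p = ge$p.value,
                             r = sign(tg) * sqrt(tg^2 / (tg^2 + dfg)))

  per_trial <- do.call(rbind, lapply(seq_len(k), function(j) {
    w <- welch_t(ymat[scores$group == groups[1], j],
                 ymat[scores$group == groups[2], j])
    cbind(trial = j, as.data.frame(w))
  }))

  list(contrast_scores = scores, main = main, by_group = by_group,
       group_effect = group_effect, per_trial = per_trial)
}

#' Step-through latency measurement rule
#'
#' The recorded latency is the time to enter the dark compartment, capped
#' at the trial ceiling; a subject that never crosses within the trial
#' scores the ceiling itself (300 s by default).
#'
#' @param cross_time_s time of crossing in seconds; NA if the subject
#'   never crossed.
#' @param cap_s trial ceiling, default 300 s.
#' @return capped latency vector.
#' @export
step_through_latency <- function(cross_time_s, cap_s = 300) {
  ifelse(is.na(cross_time_s), cap_s, pmin(cross_time_s, cap_s))
}

#' Saccharin preference ratio
#'
#' Ratio of consumed saccharin solution to total liquid consumed per rat
#' and session; undefined (NA) when nothing was drunk. Using the ratio
#' rather than raw mass removes differences in total intake between
#' groups.
#'
#' @param consumption data frame with `rat_id`, `group`, `session_index`,
#'   `saccharin_g`, `water_g`.
#' @return the input with a `preference` column in [0, 1] appended.
#' @export
preference_ratio <- function(consumption) {
  tot <- consumption$saccharin_g + consumption$water_g
  consumption$preference <-
    ifelse(!is.na(tot) & tot > 0, consumption$saccharin_g / tot, NA_real_)
  consumption
}

#' @rdname preference_ratio
#' @export
preference_anova <- function(consumption) {
  pr <- preference_ratio(consumption)
  mixed_anova(pr, dv = "preference", within = "session_index")
}

#' Correlations between phase-level metrics
#'
#' Pearson correlation matrix of phase scores across rats, one column per
#' metric (pairwise-complete); cells for constant columns are NA.
#'
#' @param phase_scores data frame with `rat_id`, `phase` and one column
#'   per metric (wide), or a long table with `metric` and `score` columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
metric_correlations <- function(phase_scores) {
  if (all(c("metric", "score") %in% names(phase_scores))) {
    phase_scores <- stats::reshape(
      phase_scores[, c("rat_id", "phase", "metric", "score")],
      idvar = c("rat_id", "phase"), timevar = "metric",
      direction = "wide")
    names(phase_scores) <- sub("^score\\.", "", names(phase_scores))
  }
  cols <- setdiff(names(phase_scores), c("rat_id", "group", "phase"))
  m <- as.matrix(phase_scores[, cols, drop = FALSE])
  if (nrow(m) < 3) stop("metric correlations need at least 3 rats")
  suppressWarnings(cc <- stats::cor(m, use = "pairwise.complete.obs"))
  diag(cc) <- 1
  cc
}
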
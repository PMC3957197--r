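# Actigraphy: double-plotted actograms, light-dark activity profiles, the
# chi-square periodogram (Sokolove-Bushell) with the free-running period
# tau, activity/rest summaries under LD and DD, and the group comparison
# (Student t for activity measures, exact Mann-Whitney for tau).

bins_per_day <- function(x) {
  bpd <- 1440 / x$bin_width_min
  if (bpd != round(bpd)) stop("bin width must divide 24 h")
  as.integer(bpd)
}

#' Double-plotted actogram matrix
#'
#' Raster of daily activity in which row d shows days d and d+1 side by
#' side, so a free-running period different from 24 h appears as a drifting
#' activity onset. The final day's row is single-plotted, right-padded with
#' NA.
#'
#' @param x an [activity_series()] covering at least 2 full days.
#' @return object of class `actogram`: list with `mat` (days x 2*bins/day),
#'   `bin_width_min`, `light` (matching matrix of light states).
#' @export
build_actogram <- function(x) {
  stopifnot(inherits(x, "activity_series"))
  bpd <- bins_per_day(x)
  n_days <- length(x$counts) %/% bpd
  if (n_days < 2) stop("actogram needs at least 2 full days of data")
  day <- function(d) x$counts[((d - 1) * bpd + 1):(d * bpd)]
  mat <- t(vapply(seq_len(n_days), function(d) {
    if (d < n_days) c(day(d), day(d + 1)) else c(day(d), rep(NA_real_, bpd))
  }, numeric(2 * bpd)))
  st <- bin_light_state(x)
  stday <- function(d) st[((d - 1) * bpd + 1):(d * bpd)]
  light <- t(vapply(seq_len(n_days), function(d) {
    if (d < n_days) c(stday(d), stday(d + 1)) else
      c(stday(d), rep(NA_character_, bpd))
  }, character(2 * bpd)))
  structure(list(mat = mat, bin_width_min = x$bin_width_min, light = light),
            class = "actogram")
}

ld_day_index <- function(x) {
  bpd <- bins_per_day(x)
  st <- bin_light_state(x)
  n_days <- length(x$counts) %/% bpd
  vapply(seq_len(n_days), function(d) {
    s <- st[((d - 1) * bpd + 1):(d * bpd)]
    any(s == "light") && any(s == "dark")
  }, logical(1))
}

#' Mean 24-h activity profile under LD
#'
#' Per-bin mean (and SD) of activity across all light-dark days, with the
#' time axis aligned so that lights-on is time 0.
#'
#' @param x an [activity_series()] with at least one LD day.
#' @return data frame `time_h` (hours since lights-on), `mean`, `sd`, `n`.
#' @export
ld_profile <- function(x) {
  stopifnot(inherits(x, "activity_series"))
  bpd <- bins_per_day(x)
  ld <- which(ld_day_index(x))
  if (length(ld) == 0) stop("no LD days in the recording")
  sched <- x$schedule
  light_on <- sched$start_min[sched$state == "light"]
  offset_bin <- if (length(light_on) == 0) 0L else
    as.integer((light_on[1] %% 1440) / x$bin_width_min)
  rows <- t(vapply(ld, function(d) {
    v <- x$counts[((d - 1) * bpd + 1):(d * bpd)]
    v[((seq_len(bpd) - 1 + offset_bin) %% bpd) + 1]
  }, numeric(bpd)))
  data.frame(time_h = (seq_len(bpd) - 1) * x$bin_width_min / 60,
             mean = colMeans(rows),
             sd = apply(rows, 2, stats::sd),
             n = length(ld))
}

#' Chi-square periodogram and free-running period
#'
#' Sokolove-Bushell periodogram: for each candidate period of P bins the
#' series is folded at P over the first K*P bins (K = number of complete
#' cycles) and
#' \deqn{Q_P = K \sum_h (M_h - \bar M)^2 / \hat\sigma^2,}
#' where M_h are the column means of the folded series, K the number of
#' complete cycles and \eqn{\hat\sigma^2} the variance of the points used
#' (each column mean has variance \eqn{\sigma^2/K} under the null, which
#' is what makes the scaled column-mean scatter chi-square). Under the
#' no-rhythm null Q_P is approximately chi-square with P-1 degrees of
#' freedom. The significance line is the chi-square quantile at
#' `alpha / n_candidates` (Bonferroni across the candidate periods, the
#' convention of standard actigraphy software), so a rhythm-free series
#' crosses it anywhere in the search range with probability about `alpha`.
#' The period estimate `tau_hat` is the candidate with the largest
#' significant Q_P inside the search range; NA when nothing exceeds the
#' line.
#'
#' @param x an [activity_series()] (typically the DD portion).
#' @param period_range_h search range in hours, default c(20, 28).
#' @param step_min candidate step in minutes; default one bin.
#' @param alpha familywise significance level for the line, default 0.001.
#' @return object of class `periodogram`: list with `table` (data frame
#'   `period_h`, `Q`, `sig_line`), `tau_hat`, `alpha`, `method`.
#' @export
chi2_periodogram <- function(x, period_range_h = c(20, 28),
                             step_min = NULL, alpha = 0.001) {
  stopifnot(inherits(x, "activity_series"))
  bw <- x$bin_width_min
  if (is.null(step_min)) step_min <- bw
  if (step_min %% bw != 0)
    stop("periodogram step must be a multiple of the bin width")
  counts <- x$counts
  n <- length(counts)
  if (n * bw < 7 * 1440)
    warning("fewer than 7 days of data; period estimate will be unstable")
  p_bins <- seq(ceiling(period_range_h[1] * 60 / bw),
                floor(period_range_h[2] * 60 / bw),
                by = step_min / bw)
  p_bins <- p_bins[p_bins <= n %/% 2]
  if (length(p_bins) == 0)
    stop("period range lies outside the data span")
  qp <- vapply(p_bins, function(P) {
    K <- n %/% P
    use <- counts[seq_len(K * P)]
    m <- colMeans(matrix(use, nrow = K, byrow = TRUE))
    mbar <- mean(use)
    denom <- sum((use - mbar)^2)
    if (denom == 0) return(NA_real_)
    K * sum((m - mbar)^2) / (denom / (K * P))
  }, numeric(1))
  sig <- stats::qchisq(1 - alpha / length(p_bins), df = p_bins - 1)
  tab <- data.frame(period_h = p_bins * bw / 60, Q = qp, sig_line = sig)
  ok <- !is.na(qp) & qp > sig
  tau_hat <- if (any(ok)) tab$period_h[ok][which.max(qp[ok])] else NA_real_
  structure(list(table = tab, tau_hat = tau_hat, alpha = alpha,
                 method = "chi-square (Sokolove-Bushell)"),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("%s periodogram, %d candidate periods %.2f-%.2f h\n",
              x$method, nrow(x$table), min(x$table$period_h),
              max(x$table$period_h)))
  if (is.na(x$tau_hat)) {
    cat(sprintf("  no period significant at alpha = %g\n", x$alpha))
  } else {
    cat(sprintf("  tau_hat = %.3f h (alpha = %g)\n", x$tau_hat, x$alpha))
  }
  invisible(x)
}

moving_average <- function(v, width) {
  if (width %% 2 != 1) stop("smoothing window must be odd")
  half <- (width - 1) / 2
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Activity-onset estimate per circadian cycle
#'
#' The recording is divided into consecutive cycles of length `tau_h`; per
#' cycle, the onset is the first bin where the smoothed activity (centered
#' moving average) rises strictly above the cycle mean and stays above it
#' for at least `sustain_min` minutes. Arrhythmic (e.g. constant) series
#' yield no onsets.
#'
#' @param x an [activity_series()].
#' @param tau_h cycle length in hours (e.g. `tau_hat` from
#'   [chi2_periodogram()]).
#' @param smooth_min odd moving-average width in minutes, default 29.
#' @param sustain_min minimum time above the mean, default 30.
#' @return data frame `cycle`, `onset_min` (absolute minutes from the
#'   recording start; NA for cycles without a detectable onset).
#' @export
onset_estimate <- function(x, tau_h, smooth_min = 29, sustain_min = 30) {
  stopifnot(inherits(x, "activity_series"))
  bw <- x$bin_width_min
  sm_bins <- max(1L, as.integer(round(smooth_min / bw)))
  if (sm_bins %% 2 == 0) sm_bins <- sm_bins + 1L
  sus_bins <- max(1L, as.integer(round(sustain_min / bw)))
  smooth <- moving_average(x$counts, sm_bins)
  cyc_bins <- as.integer(round(tau_h * 60 / bw))
  n_cycles <- length(x$counts) %/% cyc_bins
  if (n_cycles < 1) stop("recording shorter than one cycle")
  out <- data.frame(cycle = seq_len(n_cycles), onset_min = NA_real_)
  for (cyc in seq_len(n_cycles)) {
    idx <- ((cyc - 1) * cyc_bins + 1):(cyc * cyc_bins)
    s <- smooth[idx]
    above <- s > mean(s)
    r <- rle(above)
    stops <- cumsum(r$lengths)
    starts <- c(1L, utils::head(stops, -1) + 1L)
    hit <- which(r$values & r$lengths >= sus_bins)
    if (length(hit))
      out$onset_min[cyc] <- (idx[starts[hit[1]]] - 1) * bw
  }
  out
}

#' Total activity and activity/rest ratio
#'
#' Under LD, the ratio is dark-phase counts over light-phase counts per
#' day, averaged over days; under DD, the subjective night is
#' `[onset, onset + tau/2)` for each cycle's own estimated onset, advancing
#' by tau per cycle, and the ratio is subjective-night over subjective-day
#' counts averaged over complete cycles. Total activity is mean counts per
#' 24 h in both regimes. A zero denominator in any day/cycle makes the
#' ratio undefined (NA).
#'
#' @param x an [activity_series()].
#' @param tau_h free-running period (required for DD).
#' @param onsets optional output of [onset_estimate()]; computed when
#'   missing.
#' @param config a [rotarena_config()] (onset-detection settings).
#' @return data frame `regime`, `total_activity_per_24h`,
#'   `activity_rest_ratio`.
#' @export
activity_summary <- function(x, tau_h = NULL, onsets = NULL,
                             config = rotarena_config()) {
  stopifnot(inherits(x, "activity_series"))
  st <- bin_light_state(x)
  regime <- if (any(st == "light")) "LD" else "DD"
  total <- sum(x$counts) * 1440 / (length(x$counts) * x$bin_width_min)
  if (regime == "LD") {
    bpd <- bins_per_day(x)
    days <- which(ld_day_index(x))
    ratios <- vapply(days, function(d) {
      idx <- ((d - 1) * bpd + 1):(d * bpd)
      lgt <- sum(x$counts[idx][st[idx] == "light"])
      drk <- sum(x$counts[idx][st[idx] == "dark"])
      if (lgt == 0) NA_real_ else drk / lgt
    }, numeric(1))
    ratio <- if (any(is.na(ratios))) NA_real_ else mean(ratios)
  } else {
    if (is.null(tau_h)) stop("DD summary needs tau_h")
    if (is.null(onsets))
      onsets <- onset_estimate(x, tau_h, config$onset_smooth_min,
                               config$onset_sustain_min)
    bw <- x$bin_width_min
    half_bins <- as.integer(round(tau_h * 30 / bw))  # tau/2 in bins
    n <- length(x$counts)
    ratios <- vapply(seq_len(nrow(onsets)), function(i) {
      if (is.na(onsets$onset_min[i])) return(NA_real_)
      s <- as.integer(onsets$onset_min[i] / bw) + 1L
      night <- s:(s + half_bins - 1L)
      day <- (s + half_bins):(s + 2L * half_bins - 1L)
      if (max(day) > n) return(NA_real_)  # incomplete final cycle
      num <- sum(x$counts[night]); den <- sum(x$counts[day])
      if (den == 0) NA_real_ else num / den
    }, numeric(1))
    ratios <- ratios[!is.na(ratios)]
    ratio <- if (length(ratios) == 0) NA_real_ else mean(ratios)
  }
  data.frame(regime = regime, total_activity_per_24h = total,
             activity_rest_ratio = ratio, stringsAsFactors = FALSE)
}

#' Exact-permutation Mann-Whitney test
#'
#' The U statistic of the first sample with a two-sided p-value computed by
#' complete enumeration of all assignments of the pooled ranks to the
#' groups (so ties are handled exactly). The rejection region is
#' symmetric about the null mean n1*n2/2. Enumeration is feasible at
#' actigraphy sample sizes; larger problems fall back to the normal
#' approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param max_enum largest number of group assignments to enumerate
#'   exactly, default 5e5.
#' @return list with `U`, `p`, `exact` (logical).
#' @export
mann_whitney_exact <- function(x, y, max_enum = 5e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= max_enum) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    return(list(U = u_obs, p = p, exact = TRUE))
  }
  ties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - mu) / sqrt(sigma2)
  list(U = u_obs, p = 2 * stats::pnorm(-abs(z)), exact = FALSE)
}

#' Group comparison of circadian measures
#'
#' Total 24-h activity and activity/rest ratio are compared with Student's
#' (equal-variance) t-test; the free-running period tau with the exact
#' Mann-Whitney test (exact permutation null, appropriate at these sample
#' sizes).
#'
#' @param summaries data frame with columns `group`,
#'   `total_activity_per_24h`, `activity_rest_ratio`, `tau_h`.
#' @return data frame `measure`, `test`, `statistic`, `df`, `p`.
#' @export
compare_circadian_groups <- function(summaries) {
  groups <- sort(unique(summaries$group))
  if (length(groups) != 2) stop("exactly 2 groups required")
  g1 <- summaries$group == groups[1]
  trow <- function(measure) {
    v1 <- summaries[[measure]][g1]; v2 <- summaries[[measure]][!g1]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    ht <- stats::t.test(v1, v2, var.equal = TRUE)
    data.frame(measure = measure, test = "student_t",
               statistic = unname(ht$statistic),
               df = unname(ht$parameter), p = ht$p.value,
               stringsAsFactors = FALSE)
  }
  mw <- mann_whitney_exact(summaries$tau_h[g1], summaries$tau_h[!g1])
  rbind(trow("total_activity_per_24h"),
        trow("activity_rest_ratio"),
        data.frame(measure = "tau_h", test = "mann_whitney_exact",
                   statistic = mw$U, df = NA_real_,
                   p = mw$p, stringsAsFactors = FALSE))
}
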
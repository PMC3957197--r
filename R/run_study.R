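# End-to-end runner: io -> session metrics -> cohort statistics ->
# circadian summaries, writing a results bundle with a reproducibility
# manifest. Stages with missing inputs are skipped with a logged warning.

#' Run the complete analysis over a directory of input files
#'
#' Reads every track file in `track_dir`, computes session metrics, runs
#' the cohort pipeline (standardization, phase averaging, non-solver
#' flagging with matched exclusion, mixed ANOVAs for the avoidance metrics,
#' metric correlations), the annotation analyses (step-through trial
#' contrasts, saccharin preference ANOVA) when an annotation table is
#' given, and the actigraphy pipeline (periodogram, tau, activity
#' summaries, group comparison) over every activity file in `activity_dir`.
#' All tables are written as CSV next to a JSON manifest (configuration,
#' seeds, package version, input hashes) sufficient to regenerate the
#' bundle.
#'
#' @param track_dir directory of track CSV files (`*.csv`), or NULL.
#' @param annotations path to an annotation CSV, a data frame, or NULL.
#' @param activity_dir directory of activity CSV files, or NULL. File names
#'   must encode rat and group as `<group>_<rat>.csv`.
#' @param out_dir output directory (created if needed).
#' @param config a [rotarena_config()], or path to a YAML file of
#'   overrides.
#' @return (invisibly) a list of every result table, also written to
#'   `out_dir`.
#' @export
run_full_study <- function(track_dir = NULL, annotations = NULL,
                           activity_dir = NULL, out_dir = "results",
                           config = rotarena_config()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- do.call(rotarena_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "rotarena_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if (!is.null(track_dir)) {
    paths <- sort(list.files(track_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    note("carousel stage: %d track files", length(paths))
    metrics <- batch_session_metrics(paths, config = config)
    res$metrics <- metrics
    utils::write.csv(metrics, file.path(out_dir, "session_metrics.csv"),
                     row.names = FALSE)

    flags <- flag_nonsolvers(metrics, config$nonsolver_z_cut,
                             config$nonsolver_speed_cut_deg_s)
    excl <- matched_exclusion(flags, metrics)
    res$nonsolver_flags <- flags
    res$exclusion <- excl
    utils::write.csv(flags, file.path(out_dir, "nonsolver_flags.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("flagged: %s",
                         paste(flags$rat_id[flags$flagged],
                               collapse = ", ")),
                 sprintf("matched removals: %s",
                         paste(excl$matched, collapse = ", ")),
                 sprintf("analysis set: %s",
                         paste(excl$analysis_rats, collapse = ", "))),
               file.path(out_dir, "exclusion_log.txt"))
    keep <- metrics$rat_id %in% excl$analysis_rats

    carousel_metrics <- c("max_time_avoided_s", "total_distance_m",
                          "mean_dist_center_cm", "defecation")
    anova_rows <- list(); score_tables <- list()
    for (m in carousel_metrics) {
      if (all(is.na(metrics[[m]]))) next
      for (setname in c("all", "excluded")) {
        d <- if (setname == "all") metrics else metrics[keep, ]
        ph <- phase_average(standardize_sessions(d, m))
        a <- mixed_anova_group_by_phase(ph)
        a$metric <- m; a$subjects <- setname
        anova_rows[[paste(m, setname)]] <- a
        if (setname == "all") {
          ph$metric <- m
          score_tables[[m]] <- ph
        }
      }
    }
    res$anova <- do.call(rbind, anova_rows)
    utils::write.csv(res$anova, file.path(out_dir, "anova_results.csv"),
                     row.names = FALSE)
    scores_long <- do.call(rbind, score_tables)
    res$correlations <- metric_correlations(scores_long)
    utils::write.csv(res$correlations,
                     file.path(out_dir, "metric_correlations.csv"))
    res$plot_table <- impute_for_plot(metrics, "max_time_avoided_s")
    utils::write.csv(res$plot_table,
                     file.path(out_dir, "plot_table_imputed.csv"),
                     row.names = FALSE)
  } else note("no track directory: carousel stage skipped")

  if (!is.null(annotations)) {
    ann <- if (is.character(annotations))
      read_annotations(annotations, config$latency_cap_s) else annotations
    res$annotations <- ann
    lat_cols <- grep("^latency_s_t", names(ann), value = TRUE)
    if (length(lat_cols) >= 3) {
      lat <- do.call(rbind, lapply(seq_along(lat_cols), function(k)
        data.frame(rat_id = ann$rat_id, group = ann$group_label, trial = k,
                   latency_s = ann[[lat_cols[k]]],
                   stringsAsFactors = FALSE)))
      res$step_through <- trial_contrasts(lat)
      utils::write.csv(res$step_through$main,
                       file.path(out_dir, "step_through_contrasts.csv"),
                       row.names = FALSE)
    }
    sac_cols <- grep("^saccharin_g_s", names(ann), value = TRUE)
    if (length(sac_cols) >= 2) {
      cons <- do.call(rbind, lapply(seq_along(sac_cols), function(k)
        data.frame(rat_id = ann$rat_id, group = ann$group_label,
                   session_index = k,
                   saccharin_g = ann[[sprintf("saccharin_g_s%d", k)]],
                   water_g = ann[[sprintf("water_g_s%d", k)]],
                   stringsAsFactors = FALSE)))
      res$preference <- preference_anova(cons)
      utils::write.csv(res$preference,
                       file.path(out_dir, "preference_anova.csv"),
                       row.names = FALSE)
    }
  } else note("no annotations: step-through/preference stage skipped")

  if (!is.null(activity_dir)) {
    apaths <- sort(list.files(activity_dir, pattern = "\\.csv$",
                              full.names = TRUE))
    note("circadian stage: %d activity files", length(apaths))
    summ <- do.call(rbind, lapply(apaths, function(p) {
      act <- read_activity(p)
      id <- sub("\\.csv$", "", basename(p))
      grp <- sub("_.*$", "", id)
      parts <- split_regimes(act)
      rows <- list()
      if (!is.null(parts$LD)) {
        s <- activity_summary(parts$LD, config = config)
        rows$ld <- cbind(rat_id = id, group = grp, s, tau_h = NA_real_)
      }
      if (!is.null(parts$DD)) {
        pg <- chi2_periodogram(parts$DD, config$period_range_h,
                               alpha = config$periodogram_alpha)
        s <- activity_summary(parts$DD, tau_h = pg$tau_hat, config = config)
        rows$dd <- cbind(rat_id = id, group = grp, s, tau_h = pg$tau_hat)
      }
      do.call(rbind, rows)
    }))
    res$circadian_summaries <- summ
    utils::write.csv(summ, file.path(out_dir, "circadian_summaries.csv"),
                     row.names = FALSE)
    dd <- summ[summ$regime == "DD", ]
    if (length(unique(dd$group)) == 2 && nrow(dd) >= 4) {
      res$circadian_comparison <- compare_circadian_groups(dd)
      utils::write.csv(res$circadian_comparison,
                       file.path(out_dir, "circadian_comparison.csv"),
                       row.names = FALSE)
    }
  } else note("no activity directory: circadian stage skipped")

  manifest <- list(
    package_version = as.character(utils::packageVersion("rotarena")),
    r_version = R.version.string,
    timestamp_utc = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    inputs = list(track_dir = track_dir,
                  annotations = if (is.character(annotations)) annotations
                  else if (!is.null(annotations)) "<data frame>" else NULL,
                  activity_dir = activity_dir),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
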
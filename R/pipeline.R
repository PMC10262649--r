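#' Analysis run configuration
#'
#' Bundles the maze spec, analysis toggles and every threshold the
#' pipeline uses, so one object documents a run; all thresholds are
#' echoed into the output metadata for provenance.
#'
#' @param spec A [maze_spec()].
#' @param conventional,strategy,network Logical toggles for the three
#'   feature families.
#' @param theta_direct,theta_serial Strategy thresholds, see
#'   [classify_strategy()].
#' @param stop_threshold,stop_window,merge_radius Network parameters,
#'   see [detect_stops()] and [cca_cluster()].
#' @param probe_window Probe scoring window, seconds.
#' @param latency_cap Trial duration cap, seconds.
#' @param fit_days Training days entering the learning-curve fit
#'   (default 1:6).
#' @param out_dir Output directory for CSVs, or `NULL` to skip writing.
#' @param seed Seed recorded for provenance.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec, conventional = TRUE, strategy = TRUE,
                       network = TRUE, theta_direct = 0.75,
                       theta_serial = 0.8, stop_threshold = 40,
                       stop_window = 20L, merge_radius = 40,
                       probe_window = 150, latency_cap = 600,
                       fit_days = 1:6, out_dir = NULL, seed = 1L) {
  stopifnot(inherits(spec, "maze_spec"))
  structure(list(spec = spec, conventional = conventional,
                 strategy = strategy, network = network,
                 theta_direct = theta_direct,
                 theta_serial = theta_serial,
                 stop_threshold = stop_threshold,
                 stop_window = stop_window,
                 merge_radius = merge_radius,
                 probe_window = probe_window,
                 latency_cap = latency_cap, fit_days = fit_days,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

config_string <- function(config) {
  keep <- setdiff(names(config), c("spec", "out_dir"))
  vals <- vapply(config[keep], function(x) paste(format(x), collapse = ";"), "")
  paste0(config$spec$name, "|",
         paste(keep, vals, sep = "=", collapse = "|"))
}

#' Compute the full feature set for one trial
#'
#' Normalizes the trajectory to the target, then computes the enabled
#' feature families (conventional, strategy, network) for one trial.
#'
#' @param traj A raw-frame [bm_trajectory()].
#' @param config A [run_config()]; its spec's `target_index` must match
#'   the trial's goal.
#' @return One-row data frame of features (canonical columns).
#' @export
trial_features <- function(traj, config) {
  norm <- normalize_to_target(traj, config$spec)
  tr <- norm$traj; sp <- norm$spec
  meta <- traj$meta
  row <- data.frame(
    mouse_id = if (!is.null(meta)) meta$mouse_id else NA,
    cohort = if (!is.null(meta)) meta$cohort else NA,
    phase = if (!is.null(meta)) meta$phase else "training",
    day = if (!is.null(meta)) meta$day else NA,
    trial_in_day = if (!is.null(meta)) meta$trial_in_day else NA,
    maze = sp$name, goal_reached = NA, goal_time = NA_real_,
    n_errors = NA_integer_, latency = NA_real_,
    travel_distance = NA_real_, strategy = NA_character_,
    path_efficiency = NA_real_, n_nontarget_visits = NA_integer_,
    n_quadrant_crossings = NA_integer_, serial_consistency = NA_real_,
    n_stops = NA_integer_, order = NA_integer_, degree = NA_real_,
    density = NA_real_, clustering = NA_real_,
    shortest_path = NA_real_, betweenness = NA_real_,
    closeness = NA_real_)
  if (config$conventional) {
    ld <- latency_and_distance(tr, sp, cap = config$latency_cap)
    row$n_errors <- count_errors(tr, sp, window = config$probe_window)
    row$latency <- ld$latency
    row$travel_distance <- ld$travel_distance
    row$goal_reached <- ld$goal_reached
    row$goal_time <- if (ld$goal_reached) ld$latency else NA_real_
  }
  if (config$strategy &&
      (is.null(meta) || meta$phase == "training")) {
    sc <- classify_strategy(tr, sp, theta_direct = config$theta_direct,
                            theta_serial = config$theta_serial)
    row$strategy <- sc$label
    row$path_efficiency <- sc$evidence$path_efficiency
    row$n_nontarget_visits <- sc$evidence$n_nontarget_visits
    row$n_quadrant_crossings <- sc$evidence$n_quadrant_crossings
    row$serial_consistency <- sc$evidence$serial_consistency
  }
  if (config$network) {
    nm <- trial_network_features(tr, sp,
                                 threshold = config$stop_threshold,
                                 window = config$stop_window,
                                 merge_radius = config$merge_radius)
    row$n_stops <- nm$n_stops
    row$order <- nm$order
    row$degree <- nm$degree
    row$density <- nm$density
    row$clustering <- nm$clustering
    row$shortest_path <- nm$shortest_path
    row$betweenness <- nm$betweenness
    row$closeness <- nm$closeness
  }
  row
}

#' Run the full analysis over a cohort manifest
#'
#' Orchestrates manifest -> per-trial features -> per-day aggregates ->
#' per-mouse exponential learning-curve fits. Failures are isolated per
#' trial: a corrupt file is logged and skipped while the run continues.
#' Outputs are deterministic given the config and inputs; every output
#' CSV carries a `# config:` provenance header.
#'
#' @param manifest Data frame from [read_manifest()] (or a manifest CSV
#'   path), or the in-memory result of [generate_cohort()]. Each row's
#'   `target_index` (if present) overrides the config spec's target for
#'   that trial.
#' @param config A [run_config()].
#' @param features Which feature column(s) to fit learning curves on
#'   (default `"n_errors"`).
#' @return List with `features` (per-trial data frame), `daily`
#'   (per-mouse per-day means, long format), `fits` (per-mouse curve
#'   fits), `skipped` (character log of skipped trials).
#' @export
run_pipeline <- function(manifest, config, features = "n_errors") {
  trials_mem <- NULL
  if (is.list(manifest) && !is.data.frame(manifest) &&
      !is.null(manifest$manifest)) {
    trials_mem <- manifest$trials
    manifest <- manifest$manifest
  } else if (is.character(manifest)) {
    manifest <- read_manifest(manifest)
  }
  if (is.null(manifest) || nrow(manifest) == 0L)
    stop("run_pipeline: empty manifest", call. = FALSE)
  rows <- list()
  skipped <- character(0)
  for (k in seq_len(nrow(manifest))) {
    row <- tryCatch({
      cfg <- config
      if (!is.null(manifest$target_index))
        cfg$spec$target_index <- as.integer(manifest$target_index[k])
      traj <- if (!is.null(trials_mem)) trials_mem[[k]]
              else read_trial(manifest$path[k], cfg$spec)
      if (!is.null(manifest$mouse_id) &&
          (is.null(traj$meta) || is.na(traj$meta$mouse_id))) {
        traj$meta <- trial_meta(
          mouse_id = manifest$mouse_id[k],
          phase = manifest$phase[k], day = manifest$day[k],
          trial_in_day = manifest$trial_in_day[k],
          maze = manifest$maze[k])
      }
      trial_features(traj, cfg)
    }, error = function(e) {
      skipped <<- c(skipped,
                    sprintf("trial %d (%s): %s", k,
                            if (!is.null(manifest$path))
                              manifest$path[k] else "<memory>",
                            conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    stop("run_pipeline: no trial could be processed", call. = FALSE)
  feat <- do.call(rbind, rows)
  train <- feat[feat$phase == "training", , drop = FALSE]
  daily <- do.call(rbind, lapply(split(train, train$mouse_id),
                                 function(df) {
    do.call(rbind, lapply(intersect(features, names(df)), function(f) {
      dm <- suppressWarnings(daily_average(df[[f]], df$day))
      data.frame(mouse_id = df$mouse_id[1], feature = f,
                 day = as.integer(names(dm)), value = as.numeric(dm))
    }))
  }))
  rownames(daily) <- NULL
  fits <- do.call(rbind, lapply(split(train, train$mouse_id),
                                function(df) {
    df <- df[df$day %in% config$fit_days, , drop = FALSE]
    df <- df[order(df$day, df$trial_in_day), , drop = FALSE]
    do.call(rbind, lapply(intersect(features, names(df)), function(f) {
      y <- df[[f]]
      t <- (df$day - 1L) * 3L + df$trial_in_day
      fit <- tryCatch(fit_learning_curve(y, t = t),
                      error = function(e) NULL)
      data.frame(mouse_id = df$mouse_id[1], feature = f,
                 alpha = if (!is.null(fit)) fit$alpha else NA_real_,
                 beta = if (!is.null(fit)) fit$beta else NA_real_,
                 residual_norm = if (!is.null(fit)) fit$residual_norm
                                 else NA_real_,
                 n_trials_fit = if (!is.null(fit)) fit$n_trials_fit
                                else 0L)
    }))
  }))
  rownames(fits) <- NULL
  out <- list(features = feat, daily = daily, fits = fits,
              skipped = skipped)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("# config: ", config_string(config))
    wr <- function(df, name) {
      p <- file.path(config$out_dir, name)
      writeLines(hdr, p)
      suppressWarnings(
        utils::write.table(df, p, append = TRUE, sep = ",",
                           row.names = FALSE, quote = FALSE))
    }
    wr(feat, "features.csv")
    wr(daily, "daily.csv")
    wr(fits, "fits.csv")
    if (length(skipped))
      writeLines(skipped, file.path(config$out_dir, "skipped.log"))
  }
  out
}
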
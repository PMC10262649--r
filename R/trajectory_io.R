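#' Construct a trial trajectory
#'
#' A trajectory is one trial's uniformly sampled 2-D path in arena
#' coordinates (mm), with its frame times (s) and trial metadata.
#'
#' @param times Numeric vector of frame times, seconds, strictly
#'   increasing and uniform at `1/sampling_rate`.
#' @param x,y Numeric position coordinates, mm, same length as `times`.
#' @param meta A [trial_meta()] (may be `NULL` for ad-hoc paths).
#' @param sampling_rate Frames per second.
#' @param validate Check uniform sampling and monotone time.
#' @return An object of class `bm_trajectory`.
#' @export
bm_trajectory <- function(times, x, y, meta = NULL, sampling_rate = 20,
                          validate = TRUE) {
  stopifnot(length(times) == length(x), length(x) == length(y))
  if (length(times) < 2L)
    stop("bm_trajectory: need at least 2 samples", call. = FALSE)
  if (validate) {
    dt <- diff(times)
    if (any(dt <= 0))
      stop("bm_trajectory: non-monotone time", call. = FALSE)
    if (abs(stats::median(dt) - 1 / sampling_rate) >
        0.01 / sampling_rate)
      stop("bm_trajectory: median inter-sample interval deviates from ",
           "1/sampling_rate by more than 1%", call. = FALSE)
  }
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), meta = meta,
                 sampling_rate = sampling_rate),
            class = "bm_trajectory")
}

#' @export
print.bm_trajectory <- function(x, ...) {
  cat(sprintf("<bm_trajectory> %d samples, %.1f s at %g Hz\n",
              length(x$times), diff(range(x$times)), x$sampling_rate))
  if (!is.null(x$meta))
    cat(sprintf("  mouse %s, %s day %s trial %s, maze %s\n",
                x$meta$mouse_id, x$meta$phase, x$meta$day,
                x$meta$trial_in_day, x$meta$maze))
  invisible(x)
}

#' @export
length.bm_trajectory <- function(x) length(x$times)

#' Trial metadata
#'
#' @param mouse_id,cohort Labels.
#' @param phase One of `"habituation"`, `"training"`, `"probe"`.
#' @param day Integer day (>= 0; training days >= 1).
#' @param trial_in_day Integer in 1..3 (three trials per training day).
#' @param maze Maze label (e.g. `"BM1"`).
#' @param goal_reached Logical, or `NA` if unknown.
#' @param goal_time Seconds at which the goal was reached, `NA` if
#'   unknown or not reached.
#' @return An object of class `trial_meta` (a named list).
#' @export
trial_meta <- function(mouse_id = "m0", cohort = "c0",
                       phase = c("training", "habituation", "probe"),
                       day = 1L, trial_in_day = 1L, maze = "BM1",
                       goal_reached = NA, goal_time = NA_real_) {
  phase <- match.arg(phase)
  day <- as.integer(day)
  trial_in_day <- as.integer(trial_in_day)
  if (day < 0L) stop("trial_meta: day must be >= 0", call. = FALSE)
  if (phase == "training" && day < 1L)
    stop("trial_meta: training days are positive", call. = FALSE)
  if (trial_in_day < 1L || trial_in_day > 3L)
    stop("trial_meta: trial_in_day must lie in 1..3", call. = FALSE)
  structure(list(mouse_id = as.character(mouse_id),
                 cohort = as.character(cohort), phase = phase,
                 day = day, trial_in_day = trial_in_day,
                 maze = as.character(maze),
                 goal_reached = goal_reached, goal_time = goal_time),
            class = "trial_meta")
}

meta_fields <- c("mouse_id", "cohort", "phase", "day", "trial_in_day",
                 "maze", "goal_reached", "goal_time")

#' Read one trial trajectory from a CSV file
#'
#' The file is a comma-delimited table with header columns `frame`, `t`,
#' `x`, `y` (mm, pre-calibrated), optionally preceded by `#`-prefixed
#' metadata header lines of the form `# key: value`. Missing samples
#' (`NA` x/y) inside gaps of at most `max_gap` seconds are filled by
#' linear interpolation; leading/trailing missing samples are trimmed.
#'
#' Validation fails (with the violated rule named) when time is
#' non-monotone, more than 5% of samples remain missing after gap
#' interpolation, or more than 10% of points lie off the arena.
#'
#' @param path Path to the trial CSV.
#' @param spec A [maze_spec()] (for the off-arena check and frame rate).
#' @param max_gap Longest interpolatable internal gap, seconds.
#' @return A [bm_trajectory()] with metadata from the header lines.
#' @export
read_trial <- function(path, spec, max_gap = 0.5) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_meta_header(hdr)
  tab <- utils::read.csv(text = lines, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("frame", "t", "x", "y")
  if (!all(need %in% names(tab)))
    stop("read_trial: missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "),
         call. = FALSE)
  if (any(diff(tab$t) <= 0))
    stop("read_trial: non-monotone time", call. = FALSE)
  miss <- is.na(tab$x) | is.na(tab$y)
  # trim leading/trailing missing samples
  keep <- which(!miss)
  if (length(keep) < 2L)
    stop("read_trial: fewer than 2 valid samples", call. = FALSE)
  tab <- tab[keep[1]:keep[length(keep)], , drop = FALSE]
  miss <- is.na(tab$x) | is.na(tab$y)
  if (any(miss)) {
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    dt <- stats::median(diff(tab$t))
    long <- runs$values & runs$lengths * dt > max_gap
    still_missing <- sum(runs$lengths[long])
    if (still_missing / nrow(tab) > 0.05)
      stop("read_trial: more than 5% missing samples after gap ",
           "interpolation", call. = FALSE)
    if (any(long))
      stop(sprintf(
        "read_trial: internal gap longer than max_gap (%.2f s)",
        max_gap), call. = FALSE)
    for (i in which(runs$values)) {
      idx <- starts[i]:ends[i]
      tab$x[idx] <- stats::approx(tab$t[-idx], tab$x[-idx],
                                  xout = tab$t[idx])$y
      tab$y[idx] <- stats::approx(tab$t[-idx], tab$y[-idx],
                                  xout = tab$t[idx])$y
    }
  }
  r <- sqrt(tab$x^2 + tab$y^2)
  off <- mean(r > spec$arena_radius + spec$rim_tolerance)
  if (off > 0.10)
    stop(sprintf(
      "read_trial: off-arena fraction %.1f%% exceeds 10%%", 100 * off),
      call. = FALSE)
  bm_trajectory(tab$t, tab$x, tab$y, meta = meta,
                sampling_rate = spec$sampling_rate)
}

parse_meta_header <- function(hdr) {
  if (!length(hdr)) return(NULL)
  kv <- sub("^#\\s*", "", hdr)
  kv <- kv[grepl(":", kv)]
  if (!length(kv)) return(NULL)
  keys <- trimws(sub(":.*$", "", kv))
  vals <- trimws(sub("^[^:]*:", "", kv))
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  trial_meta(
    mouse_id = get("mouse_id", "m0"),
    cohort = get("cohort", "c0"),
    phase = get("phase", "training"),
    day = as.integer(get("day", "1")),
    trial_in_day = as.integer(get("trial_in_day", "1")),
    maze = get("maze", "BM1"),
    goal_reached = as.logical(get("goal_reached", NA)),
    goal_time = {
      v <- get("goal_time", NA)
      if (is.na(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
    }
  )
}

#' Write a trial trajectory to CSV
#'
#' Inverse of [read_trial()]: metadata as `# key: value` header lines,
#' then a `frame,t,x,y` table.
#'
#' @param traj A [bm_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(traj, path) {
  stopifnot(inherits(traj, "bm_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$meta)) {
    m <- traj$meta
    for (k in meta_fields)
      writeLines(sprintf("# %s: %s", k, as.character(m[[k]])), con)
  }
  tab <- data.frame(frame = seq_along(traj$times) - 1L,
                    t = traj$times, x = traj$x, y = traj$y)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

feature_columns <- c(meta_fields, "n_errors", "latency",
                     "travel_distance", "strategy", "path_efficiency",
                     "n_nontarget_visits", "n_quadrant_crossings",
                     "serial_consistency", "n_stops", "order", "degree",
                     "density", "clustering", "shortest_path",
                     "betweenness", "closeness")

#' Write a per-trial feature table
#'
#' One row per trial, stable column order; round-trips losslessly
#' through [read_features()]. Missing feature families are written as
#' `NA`.
#'
#' @param records Data frame of per-trial features (any subset of the
#'   canonical columns), or an empty data frame / `NULL` for a
#'   header-only file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(records, path) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    writeLines(paste(feature_columns, collapse = ","), path)
    return(invisible(path))
  }
  records <- as.data.frame(records)
  for (col in setdiff(feature_columns, names(records)))
    records[[col]] <- NA
  records <- records[, feature_columns]
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-trial feature table written by [write_features()]
#'
#' @param path Path to the CSV.
#' @return Data frame with the canonical feature columns.
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#'
#' A manifest drives batch runs: one row per trial with a `path` column
#' (trajectory CSV, relative paths resolved against the manifest's
#' directory) plus the [trial_meta()] fields.
#'
#' @param path Manifest CSV path.
#' @return Data frame with absolute trajectory paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"path" %in% names(man))
    stop("read_manifest: manifest needs a 'path' column", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(normalizePath(path)), man$path[rel])
  man
}
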
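#' Hole-visit events along a trajectory
#'
#' A visit is a maximal run of consecutive samples inside one hole's
#' scoring circle; leaving and re-entering starts a new visit. Runs
#' shorter than `min_visit_duration` samples are dropped (default 1: no
#' debouncing).
#'
#' @param traj A normalized [bm_trajectory()].
#' @param spec A [maze_spec()].
#' @param min_visit_duration Minimum run length, samples.
#' @return Data frame with columns `hole` (index), `t_entry`, `t_exit`
#'   (seconds, times of the first and last sample of the run),
#'   `n_samples`, in temporal order.
#' @export
hole_visit_events <- function(traj, spec, min_visit_duration = 1L) {
  stopifnot(inherits(traj, "bm_trajectory"))
  code <- region_of(cbind(traj$x, traj$y), spec)
  runs <- rle(unclass(code))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values >= 0L & runs$lengths >= min_visit_duration
  data.frame(hole = runs$values[keep],
             t_entry = traj$times[starts[keep]],
             t_exit = traj$times[ends[keep]],
             n_samples = runs$lengths[keep])
}

first_target_entry <- function(traj, spec) {
  code <- region_of(cbind(traj$x, traj$y), spec)
  idx <- which(unclass(code) == spec$target_index)
  if (length(idx)) idx[1] else NA_integer_
}

#' Count errors (nontarget hole visits)
#'
#' The number of errors is the number of visit events to nontarget hole
#' areas; re-entries recount. In training trials counting stops at the
#' first entry into the target hole area ("until they goaled"); in probe
#' trials it runs over the scoring `window` from trial start.
#'
#' @param traj A normalized [bm_trajectory()].
#' @param spec A [maze_spec()].
#' @param phase `"training"` or `"probe"`; defaults to the trajectory's
#'   metadata, else `"training"`.
#' @param window Probe scoring window, seconds.
#' @param min_visit_duration Passed to [hole_visit_events()].
#' @return Integer error count.
#' @export
count_errors <- function(traj, spec, phase = NULL, window = 150,
                         min_visit_duration = 1L) {
  if (is.null(phase))
    phase <- if (!is.null(traj$meta)) traj$meta$phase else "training"
  ev <- hole_visit_events(traj, spec, min_visit_duration)
  if (phase == "probe") {
    t_cut <- traj$times[1] + window
  } else {
    i <- first_target_entry(traj, spec)
    t_cut <- if (is.na(i)) Inf else traj$times[i]
  }
  sum(ev$hole != spec$target_index & ev$t_entry <= t_cut)
}

#' Latency and travel distance to the goal
#'
#' Latency is the time from trial start to the first sample inside the
#' target hole area, capped at `cap` seconds (10-min trial limit) when
#' the goal is never reached; travel distance is the summed
#' consecutive-sample Euclidean path length from start to that moment
#' (to trial end when not reached).
#'
#' @param traj A normalized [bm_trajectory()].
#' @param spec A [maze_spec()].
#' @param cap Latency cap when the goal is not reached, seconds.
#' @return List with `latency` (s), `travel_distance` (mm), and
#'   `goal_reached` (logical).
#' @export
latency_and_distance <- function(traj, spec, cap = 600) {
  i <- first_target_entry(traj, spec)
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  if (is.na(i)) {
    list(latency = cap, travel_distance = sum(steps),
         goal_reached = FALSE)
  } else {
    list(latency = traj$times[i] - traj$times[1],
         travel_distance = if (i > 1L) sum(steps[seq_len(i - 1L)]) else 0,
         goal_reached = TRUE)
  }
}

path_length <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Average a per-trial feature over the trials of each day
#'
#' Arithmetic mean across the (up to three) trials of each day; days
#' with missing trials are averaged over the available ones with a
#' warning; empty days yield `NA`.
#'
#' @param values Per-trial feature values.
#' @param day Integer day of each trial.
#' @return Named numeric vector of per-day means, ordered by day.
#' @export
daily_average <- function(values, day) {
  stopifnot(length(values) == length(day))
  n <- tapply(!is.na(values), day, sum)
  if (any(n < 3 & n > 0))
    warning("daily_average: day(s) with fewer than 3 trials averaged ",
            "over available ones", call. = FALSE)
  out <- tapply(values, day, mean, na.rm = TRUE)
  out[n == 0] <- NA_real_
  stats::setNames(as.numeric(out), names(out))
}

#' Normalize a learning-curve series to unit sum
#'
#' Divides a nonnegative per-trial series by its sum so that, within an
#' individual, the values across trials sum to 1 (unitless learning
#' curves comparable across maze scales).
#'
#' @param values Nonnegative numeric series with positive sum.
#' @return Series summing to 1.
#' @export
normalize_series <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("normalize_series: negative values", call. = FALSE)
  s <- sum(values, na.rm = TRUE)
  if (!is.finite(s) || s <= 0)
    stop("normalize_series: series sum must be positive", call. = FALSE)
  values / s
}

#' Fit an exponential learning curve y = alpha * exp(-beta * t)
#'
#' Nonlinear least squares over the trial index `t` (global trial
#' number, by default 1-based). Initialization is deterministic:
#' `alpha0` is the first observed value and `beta` is multistarted over
#' a fixed 5-point grid; the best converged candidate (lowest residual
#' sum of squares) wins. A lower `beta` means the curve takes longer to
#' converge.
#'
#' @param values Per-trial feature values (>= 4 finite points).
#' @param t Trial indices; default `trial_index_base + 0:(n-1)`.
#' @param trial_index_base First trial index (default 1).
#' @return An object of class `learning_curve_fit`: list with `alpha`,
#'   `beta`, `residual_norm` (sqrt RSS), `n_trials_fit`, `converged`.
#' @export
#' @examples
#' t <- 1:18
#' y <- 5 * exp(-0.3 * t)
#' fit_learning_curve(y)  # recovers alpha = 5, beta = 0.3
fit_learning_curve <- function(values, t = NULL, trial_index_base = 1L) {
  ok <- is.finite(values)
  if (is.null(t)) t <- trial_index_base + seq_along(values) - 1L
  stopifnot(length(t) == length(values))
  t <- t[ok]; y <- values[ok]
  if (length(y) < 4L)
    stop("fit_learning_curve: need at least 4 finite points",
         call. = FALSE)
  a0 <- max(y[1], 1e-8)
  best <- NULL
  for (b0 in c(0.01, 0.05, 0.1, 0.3, 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * tt),
                        data = list(y = y, tt = t),
                        start = list(a = a0, b = b0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # flat/degenerate series: fall back to beta = 0, alpha = mean
    return(structure(list(alpha = mean(y), beta = 0,
                          residual_norm = sqrt(sum((y - mean(y))^2)),
                          n_trials_fit = length(y), converged = FALSE),
                     class = "learning_curve_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(alpha = unname(cf["a"]), beta = unname(cf["b"]),
                 residual_norm = sqrt(best$rss),
                 n_trials_fit = length(y), converged = TRUE),
            class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<learning_curve_fit> alpha = %.4g, beta = %.4g (n = %d, |r| = %.3g)\n",
    x$alpha, x$beta, x$n_trials_fit, x$residual_norm))
  invisible(x)
}

#' Probe-test dwell profile
#'
#' Time spent around each hole during the probe scoring window (default
#' the first 150 s of the 300-s probe), keyed by the hole's angular
#' offset from the target in 30-degree steps (offset 0 is the target).
#' Dwell is the number of in-area samples times the frame interval, so
#' the summed dwell never exceeds the window. Probe errors over the same
#' window are included.
#'
#' @param traj A normalized probe [bm_trajectory()].
#' @param spec A [maze_spec()] (normalized: target is hole 0 at 90
#'   degrees).
#' @param window Scoring window, seconds (150 default; 90 for
#'   adjusted-duration comparisons).
#' @return An object of class `probe_profile`: list with
#'   `dwell_by_offset` (named numeric, names the signed offsets in
#'   degrees from -150 to 180), `probe_latency` (s or `NA` if the
#'   10-s-stay rule is never met), `n_errors_probe`, `window`.
#' @export
probe_profile <- function(traj, spec, window = 150) {
  stopifnot(inherits(traj, "bm_trajectory"))
  dur <- traj$times[length(traj$times)] - traj$times[1]
  if (dur < window) {
    warning(sprintf(
      "probe_profile: trial (%.1f s) shorter than window (%g s); using full trial",
      dur, window), call. = FALSE)
    window <- dur
  }
  dt <- 1 / traj$sampling_rate
  inwin <- traj$times < traj$times[1] + window
  sub <- bm_trajectory(traj$times[inwin], traj$x[inwin], traj$y[inwin],
                       meta = traj$meta,
                       sampling_rate = traj$sampling_rate,
                       validate = FALSE)
  code <- unclass(region_of(cbind(sub$x, sub$y), spec))
  nh <- spec$n_holes
  step <- 360 / nh
  # counterclockwise hole i sits at +i*step from the target; fold to (-150, 180]
  offs <- ((seq_len(nh) - 1L) * step + 150) %% 360 - 150
  shifted <- (seq_len(nh) - 1L + spec$target_index) %% nh  # hole index per offset slot
  dwell <- vapply(shifted, function(h) sum(code == h) * dt, 0)
  names(dwell) <- offs
  o <- order(offs)
  structure(list(dwell_by_offset = dwell[o],
                 probe_latency = probe_latency(traj, spec),
                 n_errors_probe = count_errors(traj, spec,
                                               phase = "probe",
                                               window = window),
                 window = window),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat(sprintf("<probe_profile> window %g s, %d probe errors, latency %s\n",
              x$window, x$n_errors_probe,
              if (is.na(x$probe_latency)) "not reached"
              else sprintf("%.2f s", x$probe_latency)))
  print(round(x$dwell_by_offset, 2))
  invisible(x)
}

#' Probe latency by the sustained-stay rule
#'
#' The probe has no escape, so latency is the start time (relative to
#' trial start) of the first maximal run inside the target hole area
#' lasting longer than `min_stay` seconds; `NA` if no run qualifies.
#'
#' @param traj A normalized probe [bm_trajectory()].
#' @param spec A [maze_spec()].
#' @param min_stay Required continuous stay, seconds (default 10).
#' @return Seconds, or `NA_real_` if never reached.
#' @export
probe_latency <- function(traj, spec, min_stay = 10) {
  ev <- hole_visit_events(traj, spec)
  ev <- ev[ev$hole == spec$target_index, , drop = FALSE]
  dt <- 1 / traj$sampling_rate
  dur <- ev$n_samples * dt
  hit <- which(dur > min_stay)
  if (!length(hit)) return(NA_real_)
  ev$t_entry[hit[1]] - traj$times[1]
}
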
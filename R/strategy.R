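#' Discard the initial stay in the start area
#'
#' The wobbly trajectory around the lift is removed from strategy
#' analysis: all samples from trial start until the first exit of the
#' start radius are dropped. Later passages through the center are
#' retained. If the animal begins outside the start area the trajectory
#' is unchanged.
#'
#' @param traj A normalized [bm_trajectory()].
#' @param spec A [maze_spec()].
#' @return A [bm_trajectory()] (possibly empty: `NULL` with attribute
#'   when the animal never leaves the start area — callers classify such
#'   trials random with a flag). The returned object carries attribute
#'   `excluded_prefix` (seconds discarded).
#' @export
strip_start_area <- function(traj, spec) {
  stopifnot(inherits(traj, "bm_trajectory"))
  r <- sqrt(traj$x^2 + traj$y^2)
  if (r[1] >= spec$start_area_radius) {
    attr(traj, "excluded_prefix") <- 0
    return(traj)
  }
  out_idx <- which(r >= spec$start_area_radius)
  if (length(out_idx) < 2L) return(NULL)  # never (usably) leaves
  i <- out_idx[1]
  out <- bm_trajectory(traj$times[i:length(traj$times)],
                       traj$x[i:length(traj$x)],
                       traj$y[i:length(traj$y)],
                       meta = traj$meta,
                       sampling_rate = traj$sampling_rate,
                       validate = FALSE)
  attr(out, "excluded_prefix") <- traj$times[i] - traj$times[1]
  out
}

#' Path efficiency of the approach to the goal
#'
#' Ratio of the straight-line distance from the first post-strip point
#' to the target hole center over the length of the path actually
#' traveled until the goal is first entered. Because the path formally
#' ends at the scoring-circle boundary, the residual straight distance
#' from the entry point to the hole center is added to the denominator,
#' so a perfectly straight approach scores 1. If the goal is never
#' reached, net progress toward the goal over the full path length is
#' reported instead and the result carries attribute
#' `goal_reached = FALSE`.
#'
#' @param traj A stripped, normalized [bm_trajectory()].
#' @param spec A [maze_spec()].
#' @return Ratio in (0, 1].
#' @export
path_efficiency <- function(traj, spec) {
  stopifnot(inherits(traj, "bm_trajectory"))
  target <- hole_positions(spec)[spec$target_index + 1L, ]
  p0 <- c(traj$x[1], traj$y[1])
  chord <- sqrt(sum((p0 - target)^2))
  i <- first_target_entry(traj, spec)
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  if (is.na(i)) {
    # goal never reached: net progress toward the goal over path length
    len <- sum(steps)
    p_end <- c(traj$x[length(traj$x)], traj$y[length(traj$y)])
    progress <- chord - sqrt(sum((p_end - target)^2))
    eff <- if (len > 0) min(1, max(0, progress) / len) else 0
    attr(eff, "goal_reached") <- FALSE
    return(eff)
  }
  len <- if (i > 1L) sum(steps[seq_len(i - 1L)]) else 0
  residual <- sqrt((traj$x[i] - target[1])^2 + (traj$y[i] - target[2])^2)
  denom <- len + residual
  eff <- if (denom > 0) min(1, chord / denom) else 1
  attr(eff, "goal_reached") <- TRUE
  eff
}

#' Count quadrant crossings
#'
#' Number of transitions between distinct 90-degree sectors (anchored to
#' the target, see [quadrant_of()]) across consecutive samples. Samples
#' inside the start radius are ignored; the previous quadrant is carried
#' forward across them.
#'
#' @param traj A stripped, normalized [bm_trajectory()].
#' @param spec A [maze_spec()].
#' @return Integer count.
#' @export
quadrant_crossings <- function(traj, spec) {
  stopifnot(inherits(traj, "bm_trajectory"))
  r <- sqrt(traj$x^2 + traj$y^2)
  keep <- r >= spec$start_area_radius
  if (sum(keep) < 2L) return(0L)
  q <- quadrant_of(cbind(traj$x[keep], traj$y[keep]), spec)
  q <- q[!is.na(q)]
  if (length(q) < 2L) return(0L)
  sum(diff(q) != 0L)
}

#' Serial-scan consistency of a hole-visit sequence
#'
#' Fraction of consecutive visit pairs that step to the circularly
#' adjacent hole in a single dominant rotational direction: 1.0 is a
#' perfect one-directional scan of neighboring holes. Adjacent steps
#' occurring in both directions contradict a single scan direction and
#' score 0, as do sequences with fewer than two visits.
#'
#' @param visits Ordered integer vector of visited hole indices
#'   (typically `hole_visit_events()$hole`, ending at the target).
#' @param n_holes Number of holes on the ring.
#' @return Ratio in \[0, 1\].
#' @export
#' @examples
#' serial_consistency(c(4, 3, 2, 1, 0))  # 1: clockwise scan
#' serial_consistency(c(4, 8, 1, 0))     # 1/3: one adjacent pair
serial_consistency <- function(visits, n_holes = 12L) {
  if (length(visits) < 2L) return(0)
  d <- diff(visits) %% n_holes
  fwd <- sum(d == 1L)                 # counterclockwise neighbor steps
  bwd <- sum(d == (n_holes - 1L))     # clockwise neighbor steps
  n_pairs <- length(visits) - 1L
  if (fwd > 0L && bwd > 0L) return(0)
  max(fwd, bwd) / n_pairs
}

#' Classify a trial's navigation strategy
#'
#' Rule hierarchy over the start-stripped trajectory:
#' \describe{
#'   \item{spatial}{moved directly toward the target (path efficiency at
#'     least `theta_direct`) with fewer than 3 visits to nontarget
#'     ("dummy") holes;}
#'   \item{serial}{sequentially approached neighboring holes until the
#'     target (serial consistency at least `theta_serial`) with fewer
#'     than 3 quadrant crossings and the target reached;}
#'   \item{random}{everything else.}
#' }
#' Spatial is tested first (a direct run trivially has few crossings).
#' The evidence behind the call is always reported.
#'
#' @param traj A normalized training-trial [bm_trajectory()] (not yet
#'   stripped; stripping is applied here).
#' @param spec A [maze_spec()].
#' @param theta_direct Path-efficiency threshold for "spatial"
#'   (default 0.75).
#' @param theta_serial Serial-consistency threshold for "serial"
#'   (default 0.8).
#' @param max_nontarget_visits Spatial rule cap (default 3: "fewer than
#'   three").
#' @param max_quadrant_crossings Serial rule cap (default 3).
#' @return An object of class `strategy_call`: list with `label`
#'   (`"spatial"`, `"serial"` or `"random"`), `evidence` (named list:
#'   `n_nontarget_visits`, `path_efficiency`, `n_quadrant_crossings`,
#'   `serial_consistency`, `goal_reached`), `excluded_prefix` (s),
#'   `thresholds`, and `flag` (e.g. `"never_left_start"`).
#' @export
classify_strategy <- function(traj, spec, theta_direct = 0.75,
                              theta_serial = 0.8,
                              max_nontarget_visits = 3L,
                              max_quadrant_crossings = 3L) {
  thresholds <- list(theta_direct = theta_direct,
                     theta_serial = theta_serial,
                     max_nontarget_visits = max_nontarget_visits,
                     max_quadrant_crossings = max_quadrant_crossings)
  stripped <- strip_start_area(traj, spec)
  if (is.null(stripped)) {
    return(structure(list(
      label = "random",
      evidence = list(n_nontarget_visits = NA_integer_,
                      path_efficiency = NA_real_,
                      n_quadrant_crossings = NA_integer_,
                      serial_consistency = NA_real_,
                      goal_reached = FALSE),
      excluded_prefix = diff(range(traj$times)),
      thresholds = thresholds, flag = "never_left_start"),
      class = "strategy_call"))
  }
  i_goal <- first_target_entry(stripped, spec)
  reached <- !is.na(i_goal)
  # evidence is computed on the approach (up to first goal entry)
  approach <- if (reached && i_goal >= 2L)
    bm_trajectory(stripped$times[1:i_goal], stripped$x[1:i_goal],
                  stripped$y[1:i_goal], meta = stripped$meta,
                  sampling_rate = stripped$sampling_rate,
                  validate = FALSE)
  else stripped
  ev <- hole_visit_events(approach, spec)
  n_nt <- sum(ev$hole != spec$target_index)
  eff <- path_efficiency(stripped, spec)
  qx <- quadrant_crossings(approach, spec)
  sc <- serial_consistency(ev$hole, spec$n_holes)
  evidence <- list(n_nontarget_visits = as.integer(n_nt),
                   path_efficiency = as.numeric(eff),
                   n_quadrant_crossings = as.integer(qx),
                   serial_consistency = sc,
                   goal_reached = reached)
  label <- if (n_nt < max_nontarget_visits && eff >= theta_direct)
    "spatial"
  else if (reached && sc >= theta_serial && qx < max_quadrant_crossings)
    "serial"
  else
    "random"
  structure(list(label = label, evidence = evidence,
                 excluded_prefix = attr(stripped, "excluded_prefix"),
                 thresholds = thresholds, flag = NA_character_),
            class = "strategy_call")
}

#' @export
print.strategy_call <- function(x, ...) {
  e <- x$evidence
  cat(sprintf(
    "<strategy_call> %s (visits %s, efficiency %.3f, crossings %s, serial %.2f)\n",
    x$label, e$n_nontarget_visits,
    ifelse(is.na(e$path_efficiency), NaN, e$path_efficiency),
    e$n_quadrant_crossings,
    ifelse(is.na(e$serial_consistency), NaN, e$serial_consistency)))
  invisible(x)
}
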
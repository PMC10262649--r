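#' Parameters of the synthetic trajectory agent
#'
#' Defines how simulated trials are generated: which navigation strategy
#' is used on each day, locomotion speed, pausing behavior, optional
#' home-base roundtrips, and the programmed learning schedule governing
#' the expected number of nontarget visits per trial,
#' `alpha * exp(-beta * t)` with `t` the global trial number.
#'
#' @param strategy_mix Either a named numeric vector of probabilities
#'   over `c("spatial", "serial", "random")` (constant across days), or
#'   a `function(day, trial_global)` returning one.
#' @param speed_mean,speed_sd Locomotion speed, mm/s.
#' @param stop_rate Spontaneous pause rate, pauses per minute of
#'   locomotion.
#' @param stop_duration_meanlog,stop_duration_sdlog Log-normal pause
#'   duration parameters, seconds (median 2 s by default, comfortably
#'   above the 1-s stop-detection window).
#' @param heading_noise Angular sd of the heading of goal-directed
#'   pursuit, radians.
#' @param crw_sd Heading-increment sd of wandering segments, radians.
#' @param learning Named numeric `c(alpha =, beta =)`: expected
#'   nontarget visits in a random-strategy trial is
#'   `alpha * exp(-beta * t)`.
#' @param home_base `NULL`, or a list with `n_roundtrips` (and
#'   optionally `radius_frac`, radial position of the base as a fraction
#'   of the arena radius) to generate home-base roundtrip trials.
#' @param seed Integer RNG seed; identical seed, identical output.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(strategy_mix = c(spatial = 1/3, serial = 1/3,
                                          random = 1/3),
                         speed_mean = 150, speed_sd = 40,
                         stop_rate = 4,
                         stop_duration_meanlog = log(2),
                         stop_duration_sdlog = 0.5,
                         heading_noise = 0.15, crw_sd = 0.6,
                         learning = c(alpha = 10, beta = 0.30),
                         home_base = NULL, seed = 1L) {
  if (!is.function(strategy_mix)) {
    stopifnot(is.numeric(strategy_mix), length(strategy_mix) == 3L)
    if (abs(sum(strategy_mix) - 1) > 1e-8)
      stop("agent_params: strategy_mix must sum to 1", call. = FALSE)
  }
  stopifnot(speed_mean > 0, stop_rate >= 0,
            all(learning >= 0), length(learning) == 2L)
  structure(list(strategy_mix = strategy_mix, speed_mean = speed_mean,
                 speed_sd = speed_sd, stop_rate = stop_rate,
                 stop_duration_meanlog = stop_duration_meanlog,
                 stop_duration_sdlog = stop_duration_sdlog,
                 heading_noise = heading_noise, crw_sd = crw_sd,
                 learning = learning, home_base = home_base,
                 seed = as.integer(seed)),
            class = "agent_params")
}

mix_for <- function(params, day, trial_global) {
  m <- params$strategy_mix
  if (is.function(m)) m <- m(day, trial_global)
  m <- m[c("spatial", "serial", "random")]
  if (any(is.na(m)) || abs(sum(m) - 1) > 1e-6)
    stop("agent_params: strategy mix must be probabilities over ",
         "spatial/serial/random summing to 1", call. = FALSE)
  m
}

derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) * 104729) %% 2147483629
  as.integer(s) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# Noisy pursuit from `pos` toward `to`; returns a matrix of positions
# (excluding `pos` itself), terminating within `tol` of the goal.
gen_pursuit <- function(pos, to, params, dt, noise_sd, tol = 15,
                        arena_radius = Inf, max_steps = 30000L) {
  out <- matrix(NA_real_, max_steps, 2)
  k <- 0L
  while (k < max_steps) {
    dx <- to[1] - pos[1]; dy <- to[2] - pos[2]
    dist <- sqrt(dx^2 + dy^2)
    if (dist < tol) break
    heading <- atan2(dy, dx) + stats::rnorm(1, 0, noise_sd)
    step <- max(params$speed_mean * 0.2,
                stats::rnorm(1, params$speed_mean, params$speed_sd)) * dt
    step <- min(step, dist)
    pos <- pos + step * c(cos(heading), sin(heading))
    r <- sqrt(sum(pos^2))
    if (r > arena_radius - 5) pos <- pos * (arena_radius - 5) / r
    k <- k + 1L
    out[k, ] <- pos
  }
  out[seq_len(k), , drop = FALSE]
}

# Splice stationary (jittered) pause blocks into a motion path.
insert_pauses <- function(path, params, fs, at = NULL, durations = NULL) {
  n <- nrow(path)
  if (is.null(at)) {
    dur_min <- n / fs / 60
    n_pauses <- stats::rpois(1, params$stop_rate * dur_min)
    if (n_pauses == 0L) return(path)
    at <- sort(sample.int(n, min(n_pauses, n)))
  }
  if (is.null(durations))
    durations <- pmax(1.2, stats::rlnorm(length(at),
                                         params$stop_duration_meanlog,
                                         params$stop_duration_sdlog))
  pieces <- list()
  prev <- 1L
  for (j in seq_along(at)) {
    i <- at[j]
    pieces[[length(pieces) + 1L]] <- path[prev:i, , drop = FALSE]
    k <- max(25L, round(durations[j] * fs))
    jitter <- matrix(stats::rnorm(2L * k, 0, 1), k, 2)
    pieces[[length(pieces) + 1L]] <-
      cbind(path[i, 1] + jitter[, 1], path[i, 2] + jitter[, 2])
    prev <- min(i + 1L, n)
  }
  pieces[[length(pieces) + 1L]] <- path[prev:n, , drop = FALSE]
  do.call(rbind, pieces)
}

random_interior_point <- function(spec, rmin = 0.25, rmax = 0.6) {
  r <- spec$arena_radius * stats::runif(1, rmin, rmax)
  a <- stats::runif(1, 0, 2 * pi)
  c(r * cos(a), r * sin(a))
}

#' Generate one synthetic trial trajectory
#'
#' Produces a 20-Hz path starting at the arena center. A strategy is
#' sampled from that day's mix: spatial runs near-straight to the
#' target; serial moves to a start hole a few positions away and steps
#' hole-to-hole in one direction until the target; random wanders
#' between interior points and a Poisson-distributed number of nontarget
#' holes (expectation `alpha * exp(-beta * t)`, `t` the global trial
#' number) before heading to the target. Log-normal pauses (median 2 s)
#' are inserted at a Poisson rate so stop detection is exercised. With
#' `home_base` set in the parameters the trial is instead a set of
#' roundtrips arriving at and departing from one base site. Probe trials
#' alternate target-area dwell with brief excursions for 300 s and the
#' trial is capped at 600 s (the 10-min limit) otherwise.
#'
#' @param params An [agent_params()].
#' @param spec A [maze_spec()] (the trial is generated in its raw frame;
#'   the target is hole `spec$target_index`).
#' @param day Training day (>= 1), or probe day.
#' @param trial Trial within day (1..3).
#' @param phase `"training"` or `"probe"`.
#' @param mouse_id,cohort Labels for the trial metadata.
#' @param trials_per_day Used to form the global trial index.
#' @return A [bm_trajectory()]; attribute `strategy` records the
#'   generating strategy label.
#' @export
generate_trial <- function(params, spec, day = 1L, trial = 1L,
                           phase = c("training", "probe"),
                           mouse_id = "m0", cohort = "c0",
                           trials_per_day = 3L) {
  stopifnot(inherits(params, "agent_params"), inherits(spec, "maze_spec"))
  phase <- match.arg(phase)
  t_global <- (day - 1L) * trials_per_day + trial
  seed <- derive_seed(params$seed, day, trial,
                      if (phase == "probe") 777L else 0L)
  with_seed(seed, {
    fs <- spec$sampling_rate
    dt <- 1 / fs
    hp <- hole_positions(spec)
    target <- hp[spec$target_index + 1L, ]
    R <- spec$arena_radius
    if (!is.null(params$home_base)) {
      path <- gen_home_base_path(params, spec, dt)
      strategy <- "home_base"
    } else if (phase == "probe") {
      path <- gen_probe_path(params, spec, dt)
      strategy <- "probe"
    } else {
      m <- mix_for(params, day, t_global)
      strategy <- sample(names(m), 1L, prob = m)
      pos <- c(0, 0)
      # expected nontarget visits follow the programmed learning decay
      lam <- params$learning["alpha"] *
        exp(-params$learning["beta"] * t_global)
      if (strategy == "spatial") {
        path <- gen_pursuit(pos, target, params, dt,
                            noise_sd = params$heading_noise,
                            arena_radius = R)
      } else if (strategy == "serial") {
        # start-hole offset shrinks with training so serial errors track
        # the same learning schedule as random-strategy visits
        dir <- sample(c(-1L, 1L), 1L)
        m_off <- max(2L, min(6L, 1L + stats::rpois(1, lam / 2)))
        idx <- spec$target_index + dir * (m_off:0)
        idx <- idx %% spec$n_holes
        segs <- list()
        for (h in idx) {
          segs[[length(segs) + 1L]] <-
            gen_pursuit(pos, hp[h + 1L, ], params, dt,
                        noise_sd = params$heading_noise,
                        arena_radius = R, tol = 10)
          pos <- segs[[length(segs)]][nrow(segs[[length(segs)]]), ]
        }
        path <- do.call(rbind, segs)
      } else {  # random
        K <- stats::rpois(1, lam)
        nontarget <- setdiff(seq_len(spec$n_holes) - 1L,
                             spec$target_index)
        visits <- if (K > 0) sample(nontarget, K, replace = TRUE)
                  else integer(0)
        segs <- list()
        go <- function(to, noise) {
          seg <- gen_pursuit(pos, to, params, dt, noise_sd = noise,
                             arena_radius = R, tol = 12)
          pos <<- if (nrow(seg)) seg[nrow(seg), ] else pos
          segs[[length(segs) + 1L]] <<- seg
        }
        for (h in visits) {
          go(random_interior_point(spec), params$crw_sd)
          go(hp[h + 1L, ], params$heading_noise * 2)
        }
        # meander before the final approach so the path is tortuous
        go(random_interior_point(spec), params$crw_sd)
        go(random_interior_point(spec), params$crw_sd)
        go(target, params$heading_noise * 2)
        path <- do.call(rbind, segs)
      }
      path <- insert_pauses(path, params, fs)
    }
    path <- rbind(c(0, 0), path)
    max_samples <- as.integer(600 * fs)
    if (nrow(path) > max_samples)
      path <- path[seq_len(max_samples), , drop = FALSE]
    times <- (seq_len(nrow(path)) - 1L) * dt
    goal <- region_of(path, spec)
    g_idx <- which(unclass(goal) == spec$target_index)
    meta <- trial_meta(mouse_id = mouse_id, cohort = cohort,
                       phase = phase, day = day, trial_in_day = trial,
                       maze = spec$name,
                       goal_reached = length(g_idx) > 0,
                       goal_time = if (length(g_idx)) times[g_idx[1]]
                                   else NA_real_)
    out <- bm_trajectory(times, path[, 1], path[, 2], meta = meta,
                         sampling_rate = fs)
    attr(out, "strategy") <- strategy
    out
  })
}

gen_probe_path <- function(params, spec, dt) {
  fs <- 1 / dt
  hp <- hole_positions(spec)
  target <- hp[spec$target_index + 1L, ]
  R <- spec$arena_radius
  pos <- c(0, 0)
  segs <- list()
  n_total <- 0L
  while (n_total < 300 * fs) {
    aim <- target + stats::rnorm(2, 0, spec$hole_area_radius / 4)
    seg <- gen_pursuit(pos, aim, params, dt,
                       noise_sd = params$heading_noise,
                       arena_radius = R, tol = 10)
    pos <- if (nrow(seg)) seg[nrow(seg), ] else pos
    k <- round(stats::runif(1, 6, 14) * fs)
    dwell <- cbind(pos[1] + stats::rnorm(k, 0, 1),
                   pos[2] + stats::rnorm(k, 0, 1))
    # occasional check of another hole, otherwise an interior excursion
    away <- if (stats::runif(1) < 0.3)
      hp[sample(setdiff(seq_len(spec$n_holes), spec$target_index + 1L),
                1L), ]
    else random_interior_point(spec, 0.3, 0.6)
    seg2 <- gen_pursuit(pos, away, params, dt,
                        noise_sd = params$crw_sd, arena_radius = R,
                        tol = 20)
    pos <- if (nrow(seg2)) seg2[nrow(seg2), ] else pos
    segs <- c(segs, list(seg, dwell, seg2))
    n_total <- n_total + nrow(seg) + k + nrow(seg2)
  }
  path <- do.call(rbind, segs)
  path[seq_len(min(nrow(path), as.integer(300 * fs))), , drop = FALSE]
}

gen_home_base_path <- function(params, spec, dt) {
  hb <- params$home_base
  n_rt <- if (!is.null(hb$n_roundtrips)) hb$n_roundtrips else 6L
  rfrac <- if (!is.null(hb$radius_frac)) hb$radius_frac else 0.55
  R <- spec$arena_radius
  a <- stats::runif(1, 0, 2 * pi)
  base <- rfrac * R * c(cos(a), sin(a))
  pause_at <- function(p, secs) {
    k <- max(25L, round(secs / dt))
    cbind(p[1] + stats::rnorm(k, 0, 1), p[2] + stats::rnorm(k, 0, 1))
  }
  pos <- c(0, 0)
  segs <- list()
  go <- function(to, noise = params$heading_noise) {
    seg <- gen_pursuit(pos, to, params, dt, noise_sd = noise,
                       arena_radius = R, tol = 10)
    pos <<- if (nrow(seg)) seg[nrow(seg), ] else pos
    segs[[length(segs) + 1L]] <<- seg
  }
  go(base)
  segs[[length(segs) + 1L]] <- pause_at(pos, 2.5)
  for (i in seq_len(n_rt)) {
    # excursion endpoints well away from the base
    repeat {
      out_pt <- random_interior_point(spec, 0.3, 0.9)
      if (sqrt(sum((out_pt - base)^2)) > 0.25 * R) break
    }
    go(out_pt, params$crw_sd / 2)
    segs[[length(segs) + 1L]] <- pause_at(pos, 2)
    go(base)
    segs[[length(segs) + 1L]] <- pause_at(pos, 2.5)
  }
  do.call(rbind, segs)
}

#' Generate a synthetic cohort
#'
#' Simulates `n_mice` animals for `n_days` days of `trials_per_day`
#' trials each, with a randomized goal hole per mouse and per-mouse
#' seeds derived from the master seed. With `dir` set, writes one
#' trajectory CSV per trial plus a `manifest.csv` consumable by
#' [read_manifest()]; otherwise the trajectories are returned in memory.
#'
#' @param n_mice Number of animals.
#' @param params_template An [agent_params()]; its `seed` is replaced by
#'   the derived per-mouse seed.
#' @param spec A [maze_spec()] (its `target_index` is re-randomized per
#'   mouse).
#' @param n_days Training days.
#' @param trials_per_day Trials per day (default 3).
#' @param seed Master seed.
#' @param dir Output directory, or `NULL` for in-memory trials.
#' @param cohort Cohort label.
#' @param probe_day If not `NULL`, also generate one probe trial per
#'   mouse on this day.
#' @return List with `manifest` (data frame) and, when `dir` is `NULL`,
#'   `trials` (list of trajectories parallel to the manifest rows).
#' @export
generate_cohort <- function(n_mice, params_template, spec, n_days,
                            trials_per_day = 3L, seed = 1L, dir = NULL,
                            cohort = "sim", probe_day = NULL) {
  stopifnot(n_days >= 1L, n_mice >= 1L)
  targets <- with_seed(derive_seed(seed, 555L),
                       sample.int(spec$n_holes, n_mice,
                                  replace = TRUE) - 1L)
  rows <- list()
  trials <- list()
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (m in seq_len(n_mice)) {
    mouse_id <- sprintf("%s_m%02d", cohort, m)
    mspec <- spec
    mspec$target_index <- targets[m]
    mparams <- params_template
    mparams$seed <- derive_seed(seed, m)
    sched <- expand.grid(trial = seq_len(trials_per_day),
                         day = seq_len(n_days))
    for (k in seq_len(nrow(sched))) {
      tr <- generate_trial(mparams, mspec, day = sched$day[k],
                           trial = sched$trial[k], phase = "training",
                           mouse_id = mouse_id, cohort = cohort,
                           trials_per_day = trials_per_day)
      fn <- sprintf("%s_d%02d_t%d.csv", mouse_id, sched$day[k],
                    sched$trial[k])
      rows[[length(rows) + 1L]] <- data.frame(
        path = fn, mouse_id = mouse_id, cohort = cohort,
        phase = "training", day = sched$day[k],
        trial_in_day = sched$trial[k], maze = spec$name,
        target_index = targets[m],
        strategy_true = attr(tr, "strategy"))
      if (is.null(dir)) trials[[length(trials) + 1L]] <- tr
      else write_trial(tr, file.path(dir, fn))
    }
    if (!is.null(probe_day)) {
      tr <- generate_trial(mparams, mspec, day = probe_day, trial = 1L,
                           phase = "probe", mouse_id = mouse_id,
                           cohort = cohort,
                           trials_per_day = trials_per_day)
      fn <- sprintf("%s_probe.csv", mouse_id)
      rows[[length(rows) + 1L]] <- data.frame(
        path = fn, mouse_id = mouse_id, cohort = cohort,
        phase = "probe", day = probe_day, trial_in_day = 1L,
        maze = spec$name, target_index = targets[m],
        strategy_true = "probe")
      if (is.null(dir)) trials[[length(trials) + 1L]] <- tr
      else write_trial(tr, file.path(dir, fn))
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest$path <- file.path(normalizePath(dir), manifest$path)
    list(manifest = manifest)
  } else {
    list(manifest = manifest, trials = trials)
  }
}

#' BM1-like and BM3-like cohort parameter templates
#'
#' Study-condition presets for the two maze scales: the 1-m-scale
#' template learns fast (visit schedule `10 * exp(-0.30 t)`, random-mix
#' weight decaying quickly), the 3-m-scale template learns slowly
#' (`12 * exp(-0.08 t)`, heavier and more persistent random mix).
#'
#' @param scale `"BM1"` or `"BM3"`.
#' @param seed RNG seed.
#' @return An [agent_params()].
#' @export
cohort_template <- function(scale = c("BM1", "BM3"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "BM1") {
    mix <- function(day, t) {
      pr <- 0.80 * exp(-0.25 * (t - 1))
      ps <- (1 - pr) * 0.35
      c(spatial = 1 - pr - ps, serial = ps, random = pr)
    }
    agent_params(strategy_mix = mix,
                 learning = c(alpha = 10, beta = 0.30), seed = seed)
  } else {
    mix <- function(day, t) {
      pr <- 0.90 * exp(-0.05 * (t - 1))
      ps <- (1 - pr) * 0.55
      c(spatial = 1 - pr - ps, serial = ps, random = pr)
    }
    agent_params(strategy_mix = mix,
                 learning = c(alpha = 12, beta = 0.08), seed = seed)
  }
}
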
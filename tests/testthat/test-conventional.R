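sp <- bm1_norm()
hp <- hole_positions(sp)

test_that("hole visits are maximal runs with re-entries counted anew", {
  # path that never enters a hole area
  tr0 <- make_traj(seg_points(c(0, 0), c(200, 0), 50))
  expect_equal(nrow(hole_visit_events(tr0, sp)), 0L)
  # enter hole 3, leave, re-enter: two events for hole 3
  h3 <- hp[4, ]
  out <- h3 * (400 - 150) / 400  # radially inside, outside the area
  xy <- rbind(seg_points(out, h3, 20), seg_points(h3, out, 20),
              seg_points(out, h3, 20))
  ev <- hole_visit_events(make_traj(xy), sp)
  expect_equal(ev$hole, c(3L, 3L))
  expect_lt(ev$t_exit[1], ev$t_entry[2])
  # a sweep along the hole ring (starting midway between holes 0 and 1)
  # touches all 12 holes once, in angular order
  sweep <- make_traj(arc_points(400, 105, 105 + 360 - 1e-6, 2000))
  ev2 <- hole_visit_events(sweep, sp)
  expect_equal(ev2$hole, c(1:11, 0L))
  # per-sample oracle: counts agree with direct region labeling
  lab <- unclass(region_of(arc_points(400, 105, 105 + 360 - 1e-6, 2000), sp))
  runs <- rle(lab)
  expect_equal(nrow(ev2), sum(runs$values >= 0))
})

test_that("error counting stops at the goal in training and re-entries recount", {
  # straight center-to-target path: no errors
  straight <- make_traj(seg_points(c(0, 0), hp[1, ], 100))
  expect_equal(count_errors(straight, sp), 0L)
  # visit holes 1, 2, 3 then the target: 3 errors
  via <- rbind(seg_points(c(0, 0), hp[2, ], 40),
               seg_points(hp[2, ], hp[3, ], 40),
               seg_points(hp[3, ], hp[4, ], 40),
               seg_points(hp[4, ], hp[1, ], 40))
  expect_equal(count_errors(make_traj(via), sp), 3L)
  # hole 5 visited twice then target: 2 errors
  h5 <- hp[6, ]
  out <- h5 * 0.6
  xy <- rbind(seg_points(c(0, 0), h5, 40), seg_points(h5, out, 20),
              seg_points(out, h5, 20), seg_points(h5, hp[1, ], 60))
  expect_equal(count_errors(make_traj(xy), sp), 2L)
  # visits after goal entry are not counted in training
  after <- rbind(seg_points(c(0, 0), hp[1, ], 60),
                 seg_points(hp[1, ], hp[2, ], 40))
  expect_equal(count_errors(make_traj(after), sp), 0L)
})

test_that("latency and travel distance measure the approach to the goal", {
  # constant-speed straight run: 400 mm over 10 s
  n <- 201
  tr <- make_traj(seg_points(c(0, 0), hp[1, ], n))  # 10 s at 20 Hz
  ld <- latency_and_distance(tr, sp)
  expect_true(ld$goal_reached)
  # goal area entered at 320 mm of 400 mm, i.e. at 8 s
  expect_equal(ld$latency, 8, tolerance = 0.05)
  expect_equal(ld$travel_distance, 320, tolerance = 2)
  # stationary trajectory: distance 0, latency = cap
  still <- make_traj(matrix(rep(c(200, 0), each = 50), ncol = 2))
  ld2 <- latency_and_distance(still, sp)
  expect_false(ld2$goal_reached)
  expect_equal(ld2$latency, 600)
  expect_equal(ld2$travel_distance, 0)
  # triangle inequality: distance >= net displacement
  set.seed(7)
  wob <- make_traj(cbind(cumsum(rnorm(200, 1, 4)),
                         cumsum(rnorm(200, 0, 4))))
  ld3 <- latency_and_distance(wob, sp)
  net <- sqrt((wob$x[200] - wob$x[1])^2 + (wob$y[200] - wob$y[1])^2)
  expect_gte(ld3$travel_distance, net)
})

test_that("daily averages pool the three trials of each day", {
  expect_equal(unname(daily_average(c(3, 6, 9), c(1, 1, 1))), 6)
  expect_warning(one <- daily_average(c(5), c(2)), "fewer than 3")
  expect_equal(unname(one), 5)
  v <- rep(4, 12); d <- rep(1:4, each = 3)
  expect_equal(unname(daily_average(v, d)), rep(4, 4))
})

test_that("series normalization maps to unit sum preserving proportions", {
  expect_equal(normalize_series(c(2, 2, 2, 2)), rep(0.25, 4))
  expect_equal(normalize_series(c(1, 3)), c(0.25, 0.75))
  set.seed(1)
  v <- rexp(18)
  expect_equal(sum(normalize_series(v)), 1, tolerance = 1e-12)
  expect_error(normalize_series(rep(0, 5)), "positive")
  expect_error(normalize_series(c(1, -1, 2)), "negative")
})

test_that("exponential curve fits recover noiseless parameters exactly", {
  t <- 1:18
  y <- 5 * exp(-0.3 * t)
  fit <- fit_learning_curve(y)
  expect_equal(fit$alpha, 5, tolerance = 1e-6)
  expect_equal(fit$beta, 0.3, tolerance = 1e-6)
  # constant series degenerates to beta ~ 0, alpha ~ c
  fitc <- fit_learning_curve(rep(4, 10))
  expect_equal(fitc$beta, 0, tolerance = 1e-6)
  expect_equal(fitc$alpha, 4, tolerance = 1e-6)
  expect_error(fit_learning_curve(c(1, 2, 3)), "at least 4")
})

test_that("beta is recovered without material bias under noise", {
  # Monte-Carlo parameter recovery: y_t = 5 exp(-0.3 t) + N(0, 0.1)
  set.seed(42)
  bhat <- replicate(200, {
    y <- 5 * exp(-0.3 * (1:18)) + rnorm(18, 0, 0.1)
    fit_learning_curve(y)$beta
  })
  expect_lt(abs(mean(bhat) - 0.3), 0.05)
})

test_that("probe profiles conserve dwell and key offsets to the target", {
  # parked in the target area for the whole window
  n <- 150 * 20 + 10
  park <- make_traj(matrix(rep(hp[1, ], each = n), ncol = 2))
  pp <- expect_silent(probe_profile(park, sp, window = 150))
  expect_equal(unname(pp$dwell_by_offset["0"]), 150, tolerance = 0.1)
  expect_equal(sum(pp$dwell_by_offset) - pp$dwell_by_offset[["0"]], 0)
  expect_lte(sum(pp$dwell_by_offset), 150 + 1e-9)
  # constant-speed ring sweep covering one full turn inside the window:
  # near-equal dwell across the 12 offsets
  sweep2 <- make_traj(arc_points(400, 90, 90 + 420, 3501), fs = 20)
  pp2 <- probe_profile(sweep2, sp, window = 150)
  dw <- pp2$dwell_by_offset
  expect_lte(sum(dw), 150 + 1e-9)
  expect_lt(diff(range(dw)) / mean(dw), 0.35)
  # offsets are exactly the 12 hole positions in 30-degree steps
  expect_equal(sort(as.numeric(names(dw))), seq(-150, 180, by = 30))
  # short trial falls back to the full duration with a warning
  short <- make_traj(matrix(rep(hp[1, ], each = 200), ncol = 2))
  expect_warning(pps <- probe_profile(short, sp, window = 150),
                 "shorter")
  expect_lt(pps$window, 150)
})

test_that("probe latency requires a sustained stay over 10 s", {
  fs <- 20
  h0 <- hp[1, ]
  out <- h0 * 0.5
  blocks <- function(stay_s) rbind(
    matrix(rep(out, each = 10 * fs), ncol = 2),
    matrix(rep(h0, each = round(stay_s * fs)), ncol = 2))
  # enters at t = 30 s (after three 10-s out-blocks... construct directly)
  xy <- rbind(matrix(rep(out, each = 30 * fs), ncol = 2),
              matrix(rep(h0, each = 12 * fs), ncol = 2),
              matrix(rep(out, each = 5 * fs), ncol = 2))
  tr <- make_traj(xy, fs = fs)
  expect_equal(probe_latency(tr, sp), 30, tolerance = 0.1)
  # repeated 5-s visits never qualify
  xy2 <- do.call(rbind, replicate(6, rbind(
    matrix(rep(out, each = 5 * fs), ncol = 2),
    matrix(rep(h0, each = 5 * fs), ncol = 2)), simplify = FALSE))
  expect_true(is.na(probe_latency(make_traj(xy2, fs = fs), sp)))
  # two qualifying stays: the first one counts
  xy3 <- rbind(matrix(rep(out, each = 40 * fs), ncol = 2),
               matrix(rep(h0, each = 11 * fs), ncol = 2),
               matrix(rep(out, each = 28 * fs), ncol = 2),
               matrix(rep(h0, each = 15 * fs), ncol = 2))
  expect_equal(probe_latency(make_traj(xy3, fs = fs), sp), 40,
               tolerance = 0.1)
})
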
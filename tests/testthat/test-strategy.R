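sp <- bm1_norm()
hp <- hole_positions(sp)

test_that("only the initial stay in the start area is discarded", {
  fs <- 20
  # 36 samples inside the start radius, then out to the rim
  inside <- seg_points(c(0, 0), c(0, 79), 37)[-37, , drop = FALSE]
  outpath <- seg_points(c(0, 80), c(0, 350), 60)
  tr <- make_traj(rbind(inside, outpath), fs = fs)
  st <- strip_start_area(tr, sp)
  expect_equal(length(st$times), 60)
  expect_equal(attr(st, "excluded_prefix"), 36 / fs)
  # re-entry of the center is retained
  back <- rbind(inside, outpath, seg_points(c(0, 350), c(0, 0), 60),
                seg_points(c(0, 0), c(200, 0), 40))
  st2 <- strip_start_area(make_traj(back, fs = fs), sp)
  r <- sqrt(st2$x^2 + st2$y^2)
  expect_gt(sum(r < sp$start_area_radius), 0)
  # starting outside the start area leaves the trajectory unchanged
  tr3 <- make_traj(outpath, fs = fs)
  expect_equal(length(strip_start_area(tr3, sp)$times), 60)
  # never leaving yields NULL (classified random downstream)
  never <- make_traj(matrix(rep(c(10, 10), each = 50), ncol = 2))
  expect_null(strip_start_area(never, sp))
  expect_equal(classify_strategy(never, sp)$label, "random")
  expect_equal(classify_strategy(never, sp)$flag, "never_left_start")
})

test_that("path efficiency is 1 for straight approaches and ratio-correct otherwise", {
  straight <- make_traj(seg_points(c(0, 85), hp[1, ], 200))
  expect_equal(as.numeric(path_efficiency(straight, sp)), 1,
               tolerance = 0.01)
  # semicircle along the hole ring from the antipodal point: 2/pi
  semi <- make_traj(arc_points(400, 270, 450, 2000))
  expect_equal(as.numeric(path_efficiency(semi, sp)), 2 / pi,
               tolerance = 0.01)
  # doubling back: path of length ~2d for straight distance d
  far <- c(0, 100)
  mid <- c(0, 250)
  xy <- rbind(seg_points(far, mid, 50), seg_points(mid, far, 50),
              seg_points(far, hp[1, ], 120))
  d <- sqrt(sum((hp[1, ] - far)^2))
  len <- 2 * sqrt(sum((mid - far)^2)) + d
  expect_equal(as.numeric(path_efficiency(make_traj(xy), sp)), d / len,
               tolerance = 0.02)
})

test_that("quadrant crossings count sector transitions outside the start area", {
  # confined to one quadrant
  one <- make_traj(seg_points(c(0, 100), c(30, 380), 80))
  expect_equal(quadrant_crossings(one, sp), 0L)
  # full ring sweep returns to its start quadrant: 4 crossings
  ring <- make_traj(arc_points(400, 90, 450 - 1e-9, 3000))
  expect_equal(quadrant_crossings(ring, sp), 4L)
  # oscillating across one boundary 5 times
  a <- 100 * c(cos(130 * pi / 180), sin(130 * pi / 180))
  b <- 100 * c(cos(140 * pi / 180), sin(140 * pi / 180))
  zig <- do.call(rbind, lapply(1:5, function(i) {
    if (i %% 2) seg_points(a, b, 10) else seg_points(b, a, 10)
  }))
  expect_equal(quadrant_crossings(make_traj(zig), sp), 5L)
})

test_that("serial consistency follows the dominant-direction adjacency rule", {
  expect_equal(serial_consistency(c(4, 3, 2, 1, 0)), 1.0)
  expect_equal(serial_consistency(c(4, 8, 1, 0)), 1 / 3)
  expect_equal(serial_consistency(c(2, 3, 2, 3)), 0)
  expect_equal(serial_consistency(c(5)), 0)          # < 2 visits
  expect_equal(serial_consistency(c(11, 0, 1, 2)), 1)  # wraps the ring
})

test_that("the rule hierarchy labels constructed paths as designed", {
  # straight path, no nontarget visits: spatial
  straight <- make_traj(seg_points(c(0, 0), hp[1, ], 150))
  call1 <- classify_strategy(straight, sp)
  expect_equal(call1$label, "spatial")
  expect_equal(call1$evidence$n_nontarget_visits, 0L)
  # ring-following path via holes 5,4,3,2,1 to the target: serial
  ringpath <- rbind(
    seg_points(c(0, 0), hp[6, ], 80),
    arc_points(400, 90 + 5 * 30, 90, 1200))
  call2 <- classify_strategy(make_traj(ringpath), sp)
  expect_equal(call2$label, "serial")
  expect_equal(call2$evidence$serial_consistency, 1.0)
  expect_lt(call2$evidence$n_quadrant_crossings, 3L)
  # wandering path with many scattered visits and crossings: random
  set.seed(9)
  holes <- c(2, 7, 4, 10, 6, 9, 3, 8) + 1
  wander <- do.call(rbind, lapply(holes, function(h)
    rbind(seg_points(c(0, 120), hp[h, ], 40),
          seg_points(hp[h, ], c(0, 120), 40))))
  wander <- rbind(wander, seg_points(c(0, 120), hp[1, ], 40))
  call3 <- classify_strategy(make_traj(wander), sp)
  expect_equal(call3$label, "random")
  expect_gte(call3$evidence$n_quadrant_crossings, 3L)
})

test_that("labels are invariant under rotation and joint scaling", {
  paths <- list(
    spatial = seg_points(c(0, 0), hp[1, ], 150),
    serial = rbind(seg_points(c(0, 0), hp[4, ], 80),
                   arc_points(400, 180, 90, 800)),
    random = {
      set.seed(11)
      do.call(rbind, lapply(c(3, 9, 5, 11, 7), function(h)
        rbind(seg_points(c(0, 150), hp[h, ], 40),
              seg_points(hp[h, ], c(0, 150), 40))))
    })
  for (nm in names(paths)) {
    tr <- make_traj(paths[[nm]])
    lab0 <- classify_strategy(tr, sp)$label
    # whole-scene rotation: rotate trajectory and the maze frame together
    spr <- sp; spr$hole0_angle <- (sp$hole0_angle + 120) %% 360
    trr <- rotate_traj(tr, 120)
    expect_equal(classify_strategy(trr, spr)$label, lab0)
    # joint x3 scaling
    expect_equal(classify_strategy(scale_traj(tr, 3),
                                   scale_spec(sp, 3))$label, lab0)
  }
})

test_that("extra nontarget visits never move a trial toward spatial", {
  straight <- seg_points(c(0, 0), hp[1, ], 150)
  lab0 <- classify_strategy(make_traj(straight), sp)$label
  expect_equal(lab0, "spatial")
  # prepend detours to three distinct nontarget holes
  detour <- do.call(rbind, lapply(c(4, 7, 10), function(h)
    rbind(seg_points(c(0, 120), hp[h, ], 40),
          seg_points(hp[h, ], c(0, 120), 40))))
  aug <- classify_strategy(make_traj(rbind(detour, straight)), sp)
  expect_gte(aug$evidence$n_nontarget_visits, 3L)
  expect_false(aug$label == "spatial")
})
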
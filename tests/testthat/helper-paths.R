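# Trajectory constructors used across tests. All are built from first
# principles (explicit coordinates), independent of the package's
# synthetic generator.

make_traj <- function(xy, fs = 20, meta = NULL) {
  bm_trajectory(times = (seq_len(nrow(xy)) - 1) / fs,
                x = xy[, 1], y = xy[, 2], meta = meta,
                sampling_rate = fs, validate = FALSE)
}

# straight segment from a to b with n samples (inclusive)
seg_points <- function(a, b, n) {
  cbind(seq(a[1], b[1], length.out = n), seq(a[2], b[2], length.out = n))
}

# arc on radius r from angle a1 to a2 (degrees), n samples
arc_points <- function(r, a1, a2, n) {
  th <- seq(a1, a2, length.out = n) * pi / 180
  cbind(r * cos(th), r * sin(th))
}

# canonical BM1 spec normalized so the target (hole 0) is at 90 degrees
bm1_norm <- function() bm_spec("BM1", target_index = 0L)

target_center <- function(spec) hole_positions(spec)[spec$target_index + 1L, ]

rotate_xy <- function(xy, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy %*% t(R)
}

scale_spec <- function(spec, k) {
  maze_spec(paste0(spec$name, "_x", k),
            arena_radius = spec$arena_radius * k,
            n_holes = spec$n_holes,
            hole_ring_radius = spec$hole_ring_radius * k,
            hole_area_radius = spec$hole_area_radius * k,
            start_area_radius = spec$start_area_radius * k,
            target_index = spec$target_index,
            sampling_rate = spec$sampling_rate,
            hole0_angle = spec$hole0_angle,
            rim_tolerance = spec$rim_tolerance * k)
}

scale_traj <- function(traj, k) {
  bm_trajectory(traj$times, traj$x * k, traj$y * k, meta = traj$meta,
                sampling_rate = traj$sampling_rate, validate = FALSE)
}

rotate_traj <- function(traj, deg) {
  xy <- rotate_xy(cbind(traj$x, traj$y), deg)
  bm_trajectory(traj$times, xy[, 1], xy[, 2], meta = traj$meta,
                sampling_rate = traj$sampling_rate, validate = FALSE)
}
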
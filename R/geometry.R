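#' Maze geometry specification
#'
#' Describes the circular-arena geometry of a Barnes maze at one scale:
#' arena radius, the ring of equally spaced peripheral holes, the scoring
#' circle around each hole, the central start area, which hole is the
#' goal, and the tracking frame rate. All lengths are millimeters.
#'
#' @param name Label for the maze (e.g. `"BM1"`).
#' @param arena_radius Arena radius, mm.
#' @param n_holes Number of peripheral holes (equally spaced).
#' @param hole_ring_radius Distance of hole centers from the arena
#'   center, mm.
#' @param hole_area_radius Radius of the scoring circle around each hole
#'   center, mm. Entering a nontarget circle is an "error"; dwell inside
#'   the target circle drives probe scoring.
#' @param start_area_radius Radius of the central start area around the
#'   lift, mm. The initial stay inside it is discarded from strategy
#'   analysis.
#' @param target_index Index of the goal hole, in `0:(n_holes - 1)`.
#' @param sampling_rate Tracking frame rate, Hz.
#' @param hole0_angle Angular position of hole 0 in the raw coordinate
#'   frame, degrees counterclockwise from +x. Holes are indexed
#'   counterclockwise. After [normalize_to_target()] the target sits at
#'   the canonical angle of 90 degrees ("north").
#' @param rim_tolerance Allowed protrusion of hole scoring circles past
#'   the arena rim, mm.
#'
#' @return An object of class `maze_spec`.
#' @seealso [bm_spec()] for the built-in 1-m and 3-m parameterizations.
#' @export
#' @examples
#' sp <- maze_spec("toy", arena_radius = 500, hole_ring_radius = 400,
#'                 hole_area_radius = 80, start_area_radius = 80)
#' hole_positions(sp)
maze_spec <- function(name, arena_radius, n_holes = 12L,
                      hole_ring_radius, hole_area_radius,
                      start_area_radius, target_index = 0L,
                      sampling_rate = 20, hole0_angle = 90,
                      rim_tolerance = 150) {
  stopifnot(is.numeric(arena_radius), arena_radius > 0,
            is.numeric(hole_ring_radius), hole_ring_radius > 0,
            is.numeric(hole_area_radius), hole_area_radius > 0,
            is.numeric(start_area_radius),
            is.numeric(sampling_rate), sampling_rate > 0)
  n_holes <- as.integer(n_holes)
  target_index <- as.integer(target_index)
  if (n_holes < 2L)
    stop("maze_spec: need at least 2 holes", call. = FALSE)
  if (target_index < 0L || target_index >= n_holes)
    stop("maze_spec: target_index must lie in [0, n_holes)", call. = FALSE)
  if (start_area_radius <= 0 ||
      start_area_radius >= hole_ring_radius - hole_area_radius)
    stop("maze_spec: start area must be disjoint from hole areas ",
         "(0 < start_area_radius < hole_ring_radius - hole_area_radius)",
         call. = FALSE)
  if (hole_ring_radius + hole_area_radius > arena_radius + rim_tolerance)
    stop("maze_spec: hole areas protrude past the arena rim by more than ",
         "rim_tolerance", call. = FALSE)
  structure(list(name = as.character(name),
                 arena_radius = arena_radius,
                 n_holes = n_holes,
                 hole_ring_radius = hole_ring_radius,
                 hole_area_radius = hole_area_radius,
                 start_area_radius = start_area_radius,
                 target_index = target_index,
                 sampling_rate = sampling_rate,
                 hole0_angle = hole0_angle,
                 rim_tolerance = rim_tolerance),
            class = "maze_spec")
}

#' Built-in maze parameterizations
#'
#' Returns the geometry of the 1-m ("BM1") or 3-m ("BM3") Barnes maze.
#' BM1: 98-cm arena, 12 holes 40 cm from the centroid, ~80-mm scoring
#' circles, 8-cm start area. BM3: 300-cm arena, 270-mm scoring circles,
#' 27-cm start area. The BM3 hole-ring radius is not a published number
#' (its holes are slotted along the rim segments); the default of
#' 1350 mm (rim minus half a slot length) approximately triples the BM1
#' layout and can be overridden.
#'
#' @param name `"BM1"` or `"BM3"`.
#' @param target_index Goal hole index, default 0.
#' @param bm3_hole_ring_radius Hole-ring radius used for BM3, mm.
#' @return A [maze_spec()].
#' @export
#' @examples
#' bm_spec("BM1")$hole_area_radius  # 80
#' bm_spec("BM3")$start_area_radius # 270
bm_spec <- function(name, target_index = 0L, bm3_hole_ring_radius = 1350) {
  switch(as.character(name),
    BM1 = maze_spec("BM1", arena_radius = 490, n_holes = 12L,
                    hole_ring_radius = 400, hole_area_radius = 80,
                    start_area_radius = 80, target_index = target_index,
                    sampling_rate = 20),
    BM3 = maze_spec("BM3", arena_radius = 1500, n_holes = 12L,
                    hole_ring_radius = bm3_hole_ring_radius,
                    hole_area_radius = 270, start_area_radius = 270,
                    target_index = target_index, sampling_rate = 20),
    stop("bm_spec: unknown maze name '", name,
         "' (expected \"BM1\" or \"BM3\")", call. = FALSE)
  )
}

#' Read a maze specification from a key-value config file
#'
#' Plain-text config, one `key: value` per line, `#` comments allowed.
#' Recognized keys match the [maze_spec()] arguments; an optional
#' `unit: cm` line rescales all length fields from centimeters.
#'
#' @param path Path to the config file.
#' @return A [maze_spec()].
#' @export
read_maze_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad))
    stop("read_maze_config: malformed line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  cfg <- stats::setNames(as.list(vals), keys)
  num <- function(k, default = NULL) {
    if (!is.null(cfg[[k]])) as.numeric(cfg[[k]]) else default
  }
  unit <- if (!is.null(cfg$unit)) cfg$unit else "mm"
  scale <- switch(unit, mm = 1, cm = 10,
                  stop("read_maze_config: unit must be mm or cm",
                       call. = FALSE))
  maze_spec(
    name = if (!is.null(cfg$name)) cfg$name else "custom",
    arena_radius = num("arena_radius") * scale,
    n_holes = if (!is.null(cfg$n_holes)) as.integer(cfg$n_holes) else 12L,
    hole_ring_radius = num("hole_ring_radius") * scale,
    hole_area_radius = num("hole_area_radius") * scale,
    start_area_radius = num("start_area_radius") * scale,
    target_index = if (!is.null(cfg$target_index))
      as.integer(cfg$target_index) else 0L,
    sampling_rate = num("sampling_rate", 20)
  )
}

#' @export
print.maze_spec <- function(x, ...) {
  cat(sprintf(
    "<maze_spec '%s'> arena %g mm, %d holes on ring %g mm,\n",
    x$name, x$arena_radius, x$n_holes, x$hole_ring_radius))
  cat(sprintf(
    "  hole area %g mm, start area %g mm, target hole %d, %g Hz\n",
    x$hole_area_radius, x$start_area_radius, x$target_index,
    x$sampling_rate))
  invisible(x)
}

hole_angles <- function(spec) {
  (spec$hole0_angle + (seq_len(spec$n_holes) - 1L) *
     360 / spec$n_holes) %% 360
}

#' Hole center coordinates
#'
#' Positions of the hole centers on the hole ring, indexed
#' counterclockwise with hole 0 at the spec's `hole0_angle`.
#'
#' @param spec A [maze_spec()].
#' @return Numeric matrix with `n_holes` rows and columns `x`, `y` (mm).
#' @export
hole_positions <- function(spec) {
  stopifnot(inherits(spec, "maze_spec"))
  a <- hole_angles(spec) * pi / 180
  cbind(x = spec$hole_ring_radius * cos(a),
        y = spec$hole_ring_radius * sin(a))
}

#' Classify points into maze scoring regions
#'
#' Each point is labeled `start_area` (inside the start radius),
#' `hole_<i>` (inside hole i's scoring circle, nearest hole on ties) or
#' `open_field`. The start area takes precedence over hole areas; under
#' the [maze_spec()] invariants the two cannot overlap, but precedence is
#' enforced for malformed configs. Points far outside the arena raise a
#' data-quality warning and are labeled `open_field`.
#'
#' @param points Numeric matrix (n x 2) or length-2 vector of positions,
#'   mm.
#' @param spec A [maze_spec()].
#' @return Integer vector of region codes: `-1` start area, `-2` open
#'   field, `0:(n_holes-1)` hole index; with class `maze_regions` and a
#'   `labels` attribute carrying the printable names.
#' @export
region_of <- function(points, spec) {
  stopifnot(inherits(spec, "maze_spec"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  r <- sqrt(points[, 1]^2 + points[, 2]^2)
  far <- r > spec$arena_radius + spec$rim_tolerance
  if (any(far))
    warning(sprintf(
      "region_of: %d point(s) beyond the arena rim; labeled open_field",
      sum(far)), call. = FALSE)
  hp <- hole_positions(spec)
  # squared distance of every point to every hole center
  d2 <- outer(points[, 1], hp[, 1], "-")^2 +
        outer(points[, 2], hp[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first") - 1L
  ndist <- sqrt(d2[cbind(seq_len(nrow(points)), nearest + 1L)])
  code <- rep.int(-2L, nrow(points))
  code[ndist < spec$hole_area_radius] <-
    nearest[ndist < spec$hole_area_radius]
  code[r < spec$start_area_radius] <- -1L
  code[far] <- -2L
  structure(code, class = "maze_regions")
}

#' Human-readable labels for region codes
#'
#' @param code Integer codes as returned by [region_of()].
#' @return Character vector: `"start_area"`, `"open_field"`, `"hole_<i>"`.
#' @export
region_label <- function(code) {
  out <- paste0("hole_", unclass(code))
  out[code == -1L] <- "start_area"
  out[code == -2L] <- "open_field"
  out
}

#' Quadrant index of points
#'
#' The arena is split into four 90-degree sectors anchored to the target
#' direction: the target ray bisects sector 0 and sectors are numbered
#' counterclockwise. Points at the exact origin have no angle; they get
#' `NA` and consumers carry the previous quadrant forward.
#'
#' @param points Numeric matrix (n x 2) or length-2 vector, mm.
#' @param spec A [maze_spec()].
#' @return Integer vector in `0:3`, `NA` at the origin.
#' @export
quadrant_of <- function(points, spec) {
  stopifnot(inherits(spec, "maze_spec"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  target_angle <- hole_angles(spec)[spec$target_index + 1L]
  ang <- atan2(points[, 2], points[, 1]) * 180 / pi
  off <- (ang - target_angle + 45) %% 360
  q <- as.integer(off %/% 90) %% 4L
  q[points[, 1] == 0 & points[, 2] == 0] <- NA_integer_
  q
}

#' Rotate a trajectory so the target hole sits at the canonical angle
#'
#' Applies a rigid rotation about the arena center that moves the target
#' hole to 90 degrees ("north"), so goal locations coincide across
#' animals; hole indexing is relabeled so the target becomes hole 0.
#' Rotation is an isometry: path length and all pairwise distances are
#' preserved.
#'
#' @param traj A [bm_trajectory()].
#' @param spec A [maze_spec()] describing the raw frame (its
#'   `target_index` and `hole0_angle` locate the goal).
#' @return List with elements `traj` (rotated trajectory) and `spec`
#'   (same geometry with `target_index = 0`, `hole0_angle = 90`).
#' @export
normalize_to_target <- function(traj, spec) {
  stopifnot(inherits(traj, "bm_trajectory"), inherits(spec, "maze_spec"))
  target_angle <- hole_angles(spec)[spec$target_index + 1L]
  delta <- (90 - target_angle) * pi / 180
  R <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2, 2)
  xy <- cbind(traj$x, traj$y) %*% t(R)
  out <- traj
  out$x <- xy[, 1]
  out$y <- xy[, 2]
  nspec <- spec
  nspec$hole0_angle <- 90
  nspec$target_index <- 0L
  list(traj = out, spec = nspec)
}
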
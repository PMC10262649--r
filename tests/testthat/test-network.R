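test_that("stop detection finds sustained low-movement epochs", {
  fs <- 20
  set.seed(3)
  dash <- function(a, b, n) seg_points(a, b, n)
  still <- function(p, k) cbind(p[1] + rnorm(k, 0, 0.5),
                                p[2] + rnorm(k, 0, 0.5))
  # stationary 40-frame segment amid fast motion: exactly one stop there
  xy <- rbind(dash(c(-300, 0), c(0, 0), 60), still(c(0, 0), 40),
              dash(c(0, 0), c(300, 0), 60))
  st <- detect_stops(make_traj(xy, fs = fs))
  expect_equal(nrow(st), 1L)
  expect_lt(abs(st$x[1]), 2)
  expect_gte(st$n_frames[1], 20L)
  # constant-speed motion at 100 mm/s never stops
  run <- make_traj(seg_points(c(-400, 0), c(400, 0), 161), fs = fs)
  expect_equal(nrow(detect_stops(run)), 0L)
  # sliding-window oracle agreement on the qualifying frames
  steps <- sqrt(diff(run$x)^2 + diff(run$y)^2)
  qual <- vapply(seq_len(161 - 19), function(i)
    sum(steps[i:(i + 18)]) < 40, TRUE)
  expect_false(any(qual))
  # two stationary segments separated by a dash: two stops
  xy2 <- rbind(still(c(-200, 0), 50), dash(c(-200, 0), c(200, 0), 40),
               still(c(200, 0), 50))
  st2 <- detect_stops(make_traj(xy2, fs = fs))
  expect_equal(nrow(st2), 2L)
  expect_lt(st2$t_end[1], st2$t_start[2])
})

test_that("CCA merges nearby stops and reaches an exact fixed point", {
  mkstops <- function(xy) data.frame(x = xy[, 1], y = xy[, 2],
                                     t_start = seq_len(nrow(xy)),
                                     t_end = seq_len(nrow(xy)) + 0.5,
                                     n_frames = 20L)
  # two stops 30 mm apart merge at their midpoint
  cl <- cca_cluster(mkstops(rbind(c(0, 0), c(30, 0))))
  expect_equal(nrow(cl$nodes), 1L)
  expect_equal(cl$nodes$x, 15)
  expect_true(cl$converged)
  # two stops 100 mm apart stay distinct at the stop locations
  cl2 <- cca_cluster(mkstops(rbind(c(0, 0), c(100, 0))))
  expect_equal(nrow(cl2$nodes), 2L)
  expect_equal(sort(cl2$nodes$x), c(0, 100))
  # collinear 0/35/70: fixed-point properties hold regardless of merges
  cl3 <- cca_cluster(mkstops(rbind(c(0, 0), c(35, 0), c(70, 0))))
  expect_true(cl3$converged)
  for (j in seq_len(nrow(cl3$nodes))) {
    members <- which(cl3$assignment == j)
    expect_equal(cl3$nodes$x[j], mean(c(0, 35, 70)[members]))
    expect_equal(cl3$nodes$y[j], 0)
  }
  # every stop lies nearest to its own node among all nodes
  d2all <- outer(c(0, 35, 70), cl3$nodes$x, "-")^2
  expect_equal(apply(d2all, 1, which.min), cl3$assignment)
  # empty input
  cl0 <- cca_cluster(data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(nrow(cl0$nodes), 0L)
})

test_that("one further CCA pass changes nothing after convergence", {
  set.seed(21)
  for (rep in 1:10) {
    xy <- cbind(runif(30, -300, 300), runif(30, -300, 300))
    stops <- data.frame(x = xy[, 1], y = xy[, 2])
    cl <- cca_cluster(stops)
    expect_true(cl$converged)
    # independent re-implementation of one assignment pass
    nx <- cl$nodes$x; ny <- cl$nodes$y
    assign2 <- integer(30)
    for (i in 1:30) {
      d <- sqrt((nx - xy[i, 1])^2 + (ny - xy[i, 2])^2)
      j <- which.min(d)
      assign2[i] <- if (d[j] < 40) j else NA_integer_
    }
    expect_equal(assign2, cl$assignment)
    # centroid exactness
    for (j in seq_along(nx)) {
      expect_equal(nx[j], mean(xy[cl$assignment == j, 1]))
      expect_equal(ny[j], mean(xy[cl$assignment == j, 2]))
    }
  }
})

test_that("well-separated planted clusters are recovered exactly", {
  set.seed(5)
  centers <- rbind(c(-300, -300), c(300, -300), c(0, 300), c(-250, 250))
  xy <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(rnorm(2 * 8, 0, 5), ncol = 2), 2, centers[k, ], "+")))
  truth <- rep(seq_len(nrow(centers)), each = 8)
  cl <- cca_cluster(data.frame(x = xy[, 1], y = xy[, 2]))
  expect_equal(nrow(cl$nodes), 4L)
  expect_equal(length(unique(paste(truth, cl$assignment))), 4L)
})

test_that("links are undirected, deduplicated and self-link free", {
  stops3 <- data.frame(x = c(0, 100, 0, 100), y = c(0, 0, 0, 0))
  net <- build_network(stops3)  # sequence A,B,A,B
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$links), 1L)
  netAAA <- build_network(data.frame(x = c(0, 1, 0), y = c(0, 0, 0)))
  expect_equal(nrow(netAAA$nodes), 1L)
  expect_equal(nrow(netAAA$links), 0L)
  tri <- build_network(data.frame(x = c(0, 100, 50, 0),
                                  y = c(0, 0, 90, 0)))
  expect_equal(nrow(tri$nodes), 3L)
  expect_equal(nrow(tri$links), 3L)
})

test_that("hand-computable graphs give the textbook measure values", {
  # triangle: complete graph
  tri <- net_from_adjacency(matrix(c(F, T, T, T, F, T, T, T, F), 3, 3))
  m <- network_measures(tri)
  expect_equal(m$density, 1)
  expect_equal(m$clustering, 1)
  expect_equal(m$shortest_path, 1)
  expect_equal(m$betweenness, 0)
  # path graph A-B-C
  A <- matrix(FALSE, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- TRUE
  mp <- network_measures(net_from_adjacency(A))
  expect_equal(mp$degree, 4 / 3)
  expect_equal(mp$density, 2 / 3)
  expect_equal(mp$per_node$betweenness, c(0, 1, 0))
  expect_equal(mp$betweenness, 1 / 3)
  # star with 4 leaves
  S <- matrix(FALSE, 5, 5); S[1, 2:5] <- S[2:5, 1] <- TRUE
  ms <- network_measures(net_from_adjacency(S))
  expect_equal(ms$density, 0.4)
  expect_equal(ms$per_node$closeness, c(1 / 4, rep(1 / 7, 4)))
  # order-0 network: all measures missing
  m0 <- network_measures(build_network(data.frame(x = numeric(0),
                                                  y = numeric(0))))
  expect_equal(m0$order, 0L)
  expect_true(is.na(m0$degree) && is.na(m0$density))
})

test_that("measures agree with igraph on random connected graphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  done <- 0
  while (done < 20) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n, runif(1, 0.4, 0.9))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (!igraph::is_connected(g)) next
    done <- done + 1
    m <- network_measures(net_from_adjacency(A))
    expect_equal(m$degree, mean(igraph::degree(g)))
    expect_equal(m$density, igraph::edge_density(g))
    expect_equal(m$clustering,
                 mean(igraph::transitivity(g, type = "localundirected",
                                           isolates = "zero")))
    expect_equal(m$shortest_path,
                 mean(rowSums(igraph::distances(g)) / (n - 1)))
    expect_equal(m$betweenness,
                 mean(igraph::betweenness(g) / ((n - 1) * (n - 2) / 2)))
    expect_equal(m$closeness, mean(igraph::closeness(g)))
  }
})

test_that("measures are invariant under node relabeling", {
  set.seed(13)
  A <- random_adjacency(7, 0.5)
  perm <- sample(7)
  Ap <- A[perm, perm]
  m1 <- network_measures(net_from_adjacency(A))
  m2 <- network_measures(net_from_adjacency(Ap))
  for (f in c("degree", "density", "clustering", "shortest_path",
              "betweenness", "closeness"))
    expect_equal(m1[[f]], m2[[f]], label = f)
})

test_that("trial-level composition matches the per-stage path", {
  fs <- 20
  set.seed(31)
  still <- function(p, k) cbind(p[1] + rnorm(k, 0, 0.5),
                                p[2] + rnorm(k, 0, 0.5))
  sites <- list(c(-200, -200), c(200, -200), c(0, 250))
  # pause at 3 well-separated sites in a cycle: triangle network
  xy <- do.call(rbind, lapply(c(1, 2, 3, 1), function(k)
    rbind(still(sites[[k]], 45),
          seg_points(sites[[k]], sites[[(k %% 3) + 1]], 30))))
  tr <- make_traj(xy, fs = fs)
  m <- trial_network_features(tr)
  expect_equal(m$order, 3L)
  expect_equal(m$density, 1)
  expect_equal(m$clustering, 1)
  expect_equal(m$betweenness, 0)
  expect_equal(m$n_stops, 4L)
  # no-stop trajectory: zero stops and missing measures
  fast <- make_traj(seg_points(c(-400, 0), c(400, 0), 100), fs = fs)
  m0 <- trial_network_features(fast)
  expect_equal(m0$n_stops, 0L)
  expect_true(is.na(m0$degree))
  # home-base style roundtrips: base node has maximal betweenness
  base <- c(0, 0)
  leaves <- list(c(250, 0), c(-250, 0), c(0, 250), c(0, -250))
  xy2 <- do.call(rbind, lapply(leaves, function(p)
    rbind(still(base, 45), seg_points(base, p, 30), still(p, 45),
          seg_points(p, base, 30))))
  m2 <- trial_network_features(make_traj(xy2, fs = fs))
  net2 <- attr(m2, "network")
  base_node <- net2$stop_sequence[1]
  expect_equal(m2$per_node$betweenness[base_node],
               max(m2$per_node$betweenness))
  expect_gt(m2$per_node$betweenness[base_node], 0)
})

test_that("a scaled-up stop pattern yields at least as many nodes", {
  set.seed(41)
  xy <- cbind(runif(40, -200, 200), runif(40, -200, 200))
  n1 <- nrow(cca_cluster(data.frame(x = xy[, 1], y = xy[, 2]))$nodes)
  n3 <- nrow(cca_cluster(data.frame(x = 3 * xy[, 1],
                                    y = 3 * xy[, 2]))$nodes)
  expect_gte(n3, n1)
})
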
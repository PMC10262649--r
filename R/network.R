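#' Detect stops in a trajectory
#'
#' A stop is a sustained low-movement epoch: whenever the traveling
#' distance over at least `window` successive frames stays below
#' `threshold` (4 cm, about half a mouse body length), one stopping
#' coordinate is generated at the centroid of the frames involved.
#' Concretely, every `window`-frame window whose cumulative step length
#' is below the threshold qualifies, overlapping qualifying windows are
#' merged into one maximal run, and runs separated by at least one
#' non-qualifying frame are distinct. Set `mode = "displacement"` to
#' test net displacement across the window instead of path length.
#'
#' @param traj A [bm_trajectory()].
#' @param spec A [maze_spec()] (frame rate; may be `NULL` to use the
#'   trajectory's own rate).
#' @param threshold Distance threshold, mm (default 40).
#' @param window Window length, frames (default 20, i.e. 1 s at 20 Hz).
#' @param mode `"path"` (cumulative step length, default) or
#'   `"displacement"` (net start-to-end distance).
#' @return Data frame of stop events: `x`, `y` (centroid, mm),
#'   `t_start`, `t_end` (s), `n_frames`.
#' @export
detect_stops <- function(traj, spec = NULL, threshold = 40,
                         window = 20L, mode = c("path", "displacement")) {
  stopifnot(inherits(traj, "bm_trajectory"))
  mode <- match.arg(mode)
  n <- length(traj$times)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      t_start = numeric(0), t_end = numeric(0),
                      n_frames = integer(0))
  if (n < window) return(empty)
  if (mode == "path") {
    steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
    cs <- c(0, cumsum(steps))
    # wlen[i] = path length over frames i .. i+window-1
    wlen <- cs[window:n] - cs[seq_len(n - window + 1L)]
  } else {
    idx <- seq_len(n - window + 1L)
    wlen <- sqrt((traj$x[idx + window - 1L] - traj$x[idx])^2 +
                 (traj$y[idx + window - 1L] - traj$y[idx])^2)
  }
  qual <- wlen < threshold
  if (!any(qual)) return(empty)
  covered <- logical(n)
  for (i in which(qual)) covered[i:(i + window - 1L)] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(
    x = vapply(keep, function(k) mean(traj$x[starts[k]:ends[k]]), 0),
    y = vapply(keep, function(k) mean(traj$y[starts[k]:ends[k]]), 0),
    t_start = traj$times[starts[keep]],
    t_end = traj$times[ends[keep]],
    n_frames = runs$lengths[keep])
}

#' Cluster stops into network nodes (City Clustering Algorithm)
#'
#' Iterates three steps to a fixed point: (1) take the stopping
#' coordinates in temporal order and integrate each into the nearest
#' existing node when its distance to that node is below `merge_radius`,
#' otherwise spawn a new node at the stop; (2) recompute every node as
#' the centroid of its constituent stops; (3) if the assignment of stops
#' to nodes is unchanged from the previous pass, terminate, else clear
#' assignments and return to step 1 (keeping the current centroids as
#' candidate nodes).
#'
#' @param stops Data frame from [detect_stops()] (columns `x`, `y`; rows
#'   in temporal order).
#' @param merge_radius Integration radius, mm (default 40).
#' @param max_iter Iteration cap; non-convergence raises a warning and
#'   returns the last state.
#' @return List with `nodes` (data frame `x`, `y`, `n_stops`),
#'   `assignment` (node index, 1-based, per stop), `converged`,
#'   `iterations`.
#' @export
cca_cluster <- function(stops, merge_radius = 40, max_iter = 100L) {
  m <- nrow(stops)
  if (is.null(m) || m == 0L)
    return(list(nodes = data.frame(x = numeric(0), y = numeric(0),
                                   n_stops = integer(0)),
                assignment = integer(0), converged = TRUE,
                iterations = 0L))
  sx <- stops$x; sy <- stops$y
  prev_assign <- NULL
  nodes_x <- numeric(0); nodes_y <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    assign <- integer(m)
    for (i in seq_len(m)) {
      if (length(nodes_x)) {
        d2 <- (nodes_x - sx[i])^2 + (nodes_y - sy[i])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) < merge_radius) {
          assign[i] <- j
          next
        }
      }
      nodes_x <- c(nodes_x, sx[i])
      nodes_y <- c(nodes_y, sy[i])
      assign[i] <- length(nodes_x)
    }
    # drop nodes that attracted no stops this pass, recompute centroids
    used <- sort(unique(assign))
    assign <- match(assign, used)
    nodes_x <- vapply(seq_along(used),
                      function(j) mean(sx[assign == j]), 0)
    nodes_y <- vapply(seq_along(used),
                      function(j) mean(sy[assign == j]), 0)
    if (!is.null(prev_assign) && identical(assign, prev_assign)) {
      converged <- TRUE
      break
    }
    prev_assign <- assign
  }
  if (!converged)
    warning(sprintf(
      "cca_cluster: no fixed point after %d iterations", max_iter),
      call. = FALSE)
  list(nodes = data.frame(
         x = nodes_x, y = nodes_y,
         n_stops = tabulate(assign, nbins = length(nodes_x))),
       assignment = assign, converged = converged, iterations = iter)
}

#' Build the exploration network from clustered stops
#'
#' Nodes are the clustered stop sites; each temporal transition between
#' consecutive stops mapped to distinct nodes adds an undirected link.
#' Self-links are excluded and repeated transitions collapse to a single
#' link.
#'
#' @param stops Data frame from [detect_stops()].
#' @param clusters Result of [cca_cluster()] on those stops; computed
#'   here if `NULL`.
#' @param merge_radius Passed to [cca_cluster()] when `clusters` is
#'   `NULL`.
#' @return An object of class `exploration_network`: list with `nodes`
#'   (data frame `x`, `y`, `n_stops`), `links` (2-column matrix of node
#'   index pairs, `i < j`), `stop_sequence` (node index per stop in
#'   time).
#' @export
build_network <- function(stops, clusters = NULL, merge_radius = 40) {
  if (is.null(clusters)) clusters <- cca_cluster(stops, merge_radius)
  seqn <- clusters$assignment
  links <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (length(seqn) >= 2L) {
    u <- seqn[-length(seqn)]
    v <- seqn[-1]
    keep <- u != v
    if (any(keep)) {
      pr <- cbind(pmin(u[keep], v[keep]), pmax(u[keep], v[keep]))
      links <- unique(pr)
      colnames(links) <- c("i", "j")
    }
  }
  structure(list(nodes = clusters$nodes, links = links,
                 stop_sequence = seqn),
            class = "exploration_network")
}

#' @export
print.exploration_network <- function(x, ...) {
  cat(sprintf("<exploration_network> %d nodes, %d links, %d stops\n",
              nrow(x$nodes), nrow(x$links), length(x$stop_sequence)))
  invisible(x)
}

adjacency_matrix <- function(net) {
  n <- nrow(net$nodes)
  A <- matrix(FALSE, n, n)
  if (nrow(net$links)) {
    A[net$links] <- TRUE
    A[net$links[, c(2, 1), drop = FALSE]] <- TRUE
  }
  A
}

# All-pairs shortest-path lengths and shortest-path counts by BFS from
# every source on an unweighted undirected graph. Returns list(d, sigma);
# d is Inf for unreachable pairs.
bfs_paths <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ])
        for (w in nb) {
          if (!is.finite(d[s, w])) {
            d[s, w] <- d[s, v] + 1
            nxt <- c(nxt, w)
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          } else if (d[s, w] == d[s, v] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(d = d, sigma = sigma)
}

#' Graph measures of an exploration network
#'
#' Computes the seven structural measures: order (node count), mean
#' degree, density, mean local clustering coefficient, mean shortest
#' path, mean betweenness centrality, mean closeness centrality.
#' Per-node measures are averaged over the nodes of the network.
#'
#' Conventions: betweenness of node i is the fraction of shortest s-t
#' paths through i, summed over unordered pairs \{s, t\} not containing
#' i and divided by the number of such pairs, so it lies in \[0, 1\];
#' clustering of a node with degree < 2 is 0; on disconnected graphs,
#' shortest-path and closeness averages use reachable pairs only and
#' betweenness counts reachable s-t pairs, with `n_isolated` reported.
#'
#' @param net An [build_network()] result (or any list with `nodes` and
#'   `links`).
#' @return An object of class `network_measures`: list with `n_stops`,
#'   `order`, `degree`, `density`, `clustering`, `shortest_path`,
#'   `betweenness`, `closeness`, `n_isolated`, plus the per-node vectors
#'   in `$per_node`. All measures are `NA` for an empty network.
#' @export
network_measures <- function(net) {
  n <- nrow(net$nodes)
  na_m <- structure(list(n_stops = length(net$stop_sequence), order = 0L,
                         degree = NA_real_, density = NA_real_,
                         clustering = NA_real_, shortest_path = NA_real_,
                         betweenness = NA_real_, closeness = NA_real_,
                         n_isolated = 0L, per_node = NULL),
                    class = "network_measures")
  if (n == 0L) return(na_m)
  A <- adjacency_matrix(net)
  deg <- rowSums(A)
  L <- nrow(net$links)
  density <- if (n >= 2L) 2 * L / (n * (n - 1)) else NA_real_
  # local clustering: realized fraction of links among neighbors
  clust <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, 0)
  bp <- bfs_paths(A)
  d <- bp$d; sigma <- bp$sigma
  sp <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di)) mean(di) else NA_real_
  }, 0)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) && sum(di) > 0) 1 / sum(di) else NA_real_
  }, 0)
  btw <- vapply(seq_len(n), function(i) {
    if (n < 3L) return(0)
    tot <- 0
    others <- setdiff(seq_len(n), i)
    for (a in seq_along(others)) {
      s <- others[a]
      for (b in seq_len(a - 1L)) {
        t <- others[b]
        if (!is.finite(d[s, t])) next
        if (is.finite(d[s, i]) && is.finite(d[i, t]) &&
            d[s, i] + d[i, t] == d[s, t])
          tot <- tot + sigma[s, i] * sigma[i, t] / sigma[s, t]
      }
    }
    tot / ((n - 1) * (n - 2) / 2)
  }, 0)
  isolated <- deg == 0
  structure(list(
    n_stops = length(net$stop_sequence),
    order = n,
    degree = mean(deg),
    density = density,
    clustering = mean(clust),
    shortest_path = if (all(isolated)) NA_real_
                    else mean(sp[!isolated]),
    betweenness = mean(btw),
    closeness = if (all(isolated)) NA_real_ else mean(clo[!isolated]),
    n_isolated = sum(isolated),
    per_node = list(degree = deg, clustering = clust,
                    shortest_path = sp, betweenness = btw,
                    closeness = clo)),
    class = "network_measures")
}

#' @export
print.network_measures <- function(x, ...) {
  cat(sprintf(
    paste0("<network_measures> order %d, degree %.2f, density %.2f,\n",
           "  clustering %.2f, shortest path %.2f, betweenness %.3f, ",
           "closeness %.3f (%d stops)\n"),
    x$order, x$degree, x$density, x$clustering, x$shortest_path,
    x$betweenness, x$closeness, x$n_stops))
  invisible(x)
}

#' End-to-end network features for one trial
#'
#' Composes [detect_stops()], [cca_cluster()], [build_network()] and
#' [network_measures()].
#'
#' @param traj A [bm_trajectory()].
#' @param spec A [maze_spec()] (unused beyond the frame rate; kept for a
#'   uniform module surface).
#' @param threshold,window Stop-detection parameters, see
#'   [detect_stops()].
#' @param merge_radius CCA integration radius, mm.
#' @return A `network_measures` object; the network itself is attached
#'   as attribute `network`.
#' @export
trial_network_features <- function(traj, spec = NULL, threshold = 40,
                                   window = 20L, merge_radius = 40) {
  stops <- detect_stops(traj, spec, threshold = threshold,
                        window = window)
  net <- build_network(stops, merge_radius = merge_radius)
  m <- network_measures(net)
  attr(m, "network") <- net
  m
}

#' Export a network as plain-text node and edge lists
#'
#' @param net An [build_network()] result.
#' @param node_path,edge_path Output CSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_network <- function(net, node_path, edge_path) {
  nodes <- cbind(node = seq_len(nrow(net$nodes)), net$nodes)
  utils::write.csv(nodes, node_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(net$links), edge_path,
                   row.names = FALSE, quote = FALSE)
  invisible(list(nodes = node_path, edges = edge_path))
}
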
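# Exhaustive graph-measure oracle for small graphs (n <= 8): enumerates
# every simple path between every node pair by depth-first search, takes
# the shortest ones, and derives distances, shortest-path counts,
# betweenness, closeness and clustering from that enumeration. Entirely
# independent of the package's BFS implementation.

enumerate_simple_paths <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ])) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

oracle_measures <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  spaths <- vector("list", n * n)  # shortest paths, keyed s < t
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    ps <- enumerate_simple_paths(A, s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, 1L) - 1L
    d[s, t] <- d[t, s] <- min(lens)
    spaths[[(s - 1L) * n + t]] <- ps[lens == min(lens)]
  }
  deg <- rowSums(A)
  clust <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2L) return(0)
    pairs <- utils::combn(nb, 2)
    mean(A[t(pairs)])
  }, 0)
  sp <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]; di <- di[is.finite(di)]
    if (length(di)) mean(di) else NA_real_
  }, 0)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]; di <- di[is.finite(di)]
    if (length(di) && sum(di) > 0) 1 / sum(di) else NA_real_
  }, 0)
  btw <- vapply(seq_len(n), function(i) {
    if (n < 3L) return(0)
    others <- setdiff(seq_len(n), i)
    tot <- 0
    cmb <- utils::combn(others, 2)
    for (k in seq_len(ncol(cmb))) {
      s <- cmb[1, k]; t <- cmb[2, k]
      ps <- spaths[[(s - 1L) * n + t]]
      if (is.null(ps)) next
      through <- vapply(ps, function(p) i %in% p, TRUE)
      tot <- tot + mean(through)
    }
    tot / (length(others) * (length(others) - 1) / 2)
  }, 0)
  nE <- sum(A) / 2
  isolated <- deg == 0
  list(order = n, degree = mean(deg),
       density = if (n >= 2) 2 * nE / (n * (n - 1)) else NA_real_,
       clustering = mean(clust),
       shortest_path = if (all(isolated)) NA_real_
                       else mean(sp[!isolated]),
       betweenness = mean(btw),
       closeness = if (all(isolated)) NA_real_ else mean(clo[!isolated]),
       per_node = list(degree = deg, clustering = clust,
                       shortest_path = sp, betweenness = btw,
                       closeness = clo))
}

random_adjacency <- function(n, p) {
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- TRUE
  }
  A
}

net_from_adjacency <- function(A) {
  n <- nrow(A)
  links <- which(upper.tri(A) & A, arr.ind = TRUE)
  colnames(links) <- c("i", "j")
  structure(list(nodes = data.frame(x = seq_len(n), y = 0,
                                    n_stops = 1L),
                 links = links, stop_sequence = integer(0)),
            class = "exploration_network")
}
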
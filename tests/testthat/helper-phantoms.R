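# Shared fixtures: all built in code, sized for fast unit tests.

dice_coef <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

# small analytic scene: bright tube along z inside a dark lung
small_tube_scene <- function(dims = c(48, 48, 48), spacing = 1, radius = 2,
                             lung_hu = -850, vessel_hu = 300) {
  d <- dims
  X <- array(seq_len(d[1]), d)
  Y <- array(rep(seq_len(d[2]), each = d[1]), d)
  a <- array(lung_hu, d)
  ctr <- (d[1] + 1) / 2
  a[(X - ctr)^2 + (Y - ctr)^2 <= radius^2] <- vessel_hu
  volume3d(a, rep(spacing, 3))
}

full_roi <- function(v) mask3d(array(1, dim(v$data)), v$spacing, v$origin)

# candidate table sampled from ground-truth tree polylines at `step` arc
# spacing (emulates ideal NMS output for topology tests)
tree_candidates <- function(tr, step = 0.6) {
  pts <- lapply(tr$segments, function(s) {
    d <- c(0, cumsum(sqrt(rowSums(diff(s)^2))))
    ss <- seq(0, max(d), by = step)
    cbind(approx(d, s[, 1], ss)$y, approx(d, s[, 2], ss)$y,
          approx(d, s[, 3], ss)$y)
  })
  P <- unique(round(do.call(rbind, pts), 6))
  df <- data.frame(x_mm = P[, 1], y_mm = P[, 2], z_mm = P[, 3],
                   response = 1, scale = step, dx = 0, dy = 0, dz = 1,
                   i = 1L, j = 1L, k = 1L)
  attr(df, "spacing") <- rep(step, 3)
  df
}

link_tree <- function(tr, step = 0.6, prune = 2) {
  g <- link_candidates(tree_candidates(tr, step), adjacency_radius = 1.3 * step)
  prune_spurs(g, prune)
}

# build a centerline_graph directly from an edge list over given points
graph_from_edges <- function(P, edges, response = NULL) {
  n <- nrow(P)
  if (is.null(response)) response <- rep(1, n)
  nodes <- data.frame(x_mm = P[, 1], y_mm = P[, 2], z_mm = P[, 3],
                      response = response)
  len <- sqrt(rowSums((P[edges[, 1], , drop = FALSE] -
                         P[edges[, 2], , drop = FALSE])^2))
  te <- data.frame(i = edges[, 1], j = edges[, 2], length = len,
                   cost = len)
  structure(list(nodes = nodes, edges = te, tree = te, spacing = c(1, 1, 1)),
            class = "centerline_graph")
}

# random labelled tree on n nodes (Pruefer-like attachment), points in 3D
random_tree_graph <- function(n, seed) {
  withr::with_seed(seed, {
    P <- matrix(runif(3 * n, 0, 100), ncol = 3)
    edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1),
                               integer(1)))
    graph_from_edges(P, edges, response = runif(n))
  })
}

# independent segment-count oracle: maximal degree-2 chains in a forest
oracle_segment_count <- function(edges, n) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], r)
    adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], r)
  }
  used <- rep(FALSE, nrow(edges))
  count <- 0
  for (v in which(deg != 2 & deg > 0)) {
    for (r0 in adj[[v]]) {
      if (used[r0]) next
      count <- count + 1
      cur <- v; r <- r0
      repeat {
        used[r] <- TRUE
        nxt <- setdiff(c(edges[r, 1], edges[r, 2]), cur)
        if (deg[nxt] != 2) break
        cur <- nxt
        r <- setdiff(adj[[nxt]], r)[1]
      }
    }
  }
  count
}
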
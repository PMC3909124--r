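# Centerline linking and segment decomposition. Candidate points from
# non-maxima suppression are connected within an adjacency radius; per
# connected component a Dijkstra shortest-path tree rooted at the
# highest-response candidate gives connected, acyclic centerlines, which are
# decomposed into vessel segments between branch/end points.

#' Link centerline candidates into a graph
#'
#' Builds adjacency among candidate points within `adjacency_radius` (edge
#' cost = Euclidean length scaled by an inverse-response factor) and extracts
#' per connected component the Dijkstra shortest-path tree from the
#' highest-response node, yielding connected acyclic centerlines.
#'
#' @param cands candidate data frame from [non_maxima_suppression()].
#' @param vv the `vesselness` object (supplies the working voxel spacing);
#'   may be `NULL` if `adjacency_radius` is given.
#' @param adjacency_radius linking radius in mm; default twice the working
#'   voxel spacing.
#' @return An object of class `centerline_graph`: `nodes` (data frame),
#'   `edges` (all adjacency edges), `tree` (shortest-path forest edges),
#'   `spacing`.
#' @export
link_candidates <- function(cands, vv = NULL, adjacency_radius = NULL) {
  spacing <- if (!is.null(vv)) vv$response$spacing else attr(cands, "spacing")
  if (is.null(adjacency_radius)) {
    if (is.null(spacing)) stop("supply `vv` or `adjacency_radius`")
    adjacency_radius <- 2 * min(spacing)
  }
  n <- nrow(cands)
  empty <- structure(list(nodes = cands,
                          edges = data.frame(i = integer(0), j = integer(0),
                                             length = numeric(0), cost = numeric(0)),
                          tree = data.frame(i = integer(0), j = integer(0),
                                            length = numeric(0), cost = numeric(0)),
                          spacing = spacing),
                     class = "centerline_graph")
  if (n == 0) return(empty)
  P <- as.matrix(cands[, c("x_mm", "y_mm", "z_mm")])
  resp <- cands$response
  # neighbour search by cell hashing
  cell <- floor(sweep(P, 2, adjacency_radius, "/"))
  cr <- apply(cell, 2, range)
  nx <- cr[2, 1] - cr[1, 1] + 2; ny <- cr[2, 2] - cr[1, 2] + 2
  key <- (cell[, 1] - cr[1, 1]) + nx * ((cell[, 2] - cr[1, 2]) +
                                          ny * (cell[, 3] - cr[1, 3]))
  buckets <- split(seq_len(n), key)
  keyset <- as.numeric(names(buckets))
  ei <- integer(0); ej <- integer(0)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  okey <- offs$dx + nx * (offs$dy + ny * offs$dz)
  for (b in seq_along(buckets)) {
    ids <- buckets[[b]]
    nb <- unlist(buckets[as.character(keyset[b] + okey)], use.names = FALSE)
    if (is.null(nb)) nb <- integer(0)
    for (i in ids) {
      js <- nb[nb > i]
      if (length(js) == 0) next
      dd <- (P[js, 1] - P[i, 1])^2 + (P[js, 2] - P[i, 2])^2 +
        (P[js, 3] - P[i, 3])^2
      js <- js[dd <= adjacency_radius^2 & dd > 0]
      if (length(js) > 0) { ei <- c(ei, rep(i, length(js))); ej <- c(ej, js) }
    }
  }
  if (length(ei) == 0) {
    g <- empty; g$nodes$component <- seq_len(n); return(g)
  }
  len <- sqrt(rowSums((P[ei, , drop = FALSE] - P[ej, , drop = FALSE])^2))
  cost <- len / (1e-6 + (resp[ei] + resp[ej]) / 2)
  ig <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  comp <- igraph::components(ig)$membership
  tree_i <- integer(0); tree_j <- integer(0)
  for (cid in unique(comp)) {
    vs <- which(comp == cid)
    if (length(vs) < 2) next
    sub <- which(ei %in% vs) # edges stay within a component
    # reindex to 0-based local ids
    loc <- match(seq_len(n), vs)
    root <- vs[which.max(resp[vs])]
    dt <- dijkstra_tree_cpp(length(vs), loc[ei[sub]] - 1L, loc[ej[sub]] - 1L,
                            cost[sub], loc[root] - 1L)
    par <- dt$parent
    ch <- which(par >= 0)
    tree_i <- c(tree_i, vs[par[ch] + 1L])
    tree_j <- c(tree_j, vs[ch])
  }
  tlen <- sqrt(rowSums((P[tree_i, , drop = FALSE] - P[tree_j, , drop = FALSE])^2))
  tcost <- tlen / (1e-6 + (resp[tree_i] + resp[tree_j]) / 2)
  nodes <- cands
  nodes$component <- comp
  structure(list(nodes = nodes,
                 edges = data.frame(i = ei, j = ej, length = len, cost = cost),
                 tree = data.frame(i = tree_i, j = tree_j, length = tlen,
                                   cost = tcost),
                 spacing = spacing),
            class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat(sprintf("<centerline_graph> %d nodes, %d adjacency edges, %d tree edges\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$tree)))
  invisible(x)
}

# adjacency list over tree edges
tree_adjacency <- function(g) {
  n <- nrow(g$nodes)
  adj <- vector("list", n)
  te <- g$tree
  for (r in seq_len(nrow(te))) {
    adj[[te$i[r]]] <- c(adj[[te$i[r]]], r)
    adj[[te$j[r]]] <- c(adj[[te$j[r]]], r)
  }
  adj
}

#' Prune short terminal spurs from a centerline graph
#'
#' Iteratively removes leaf branches (segments with one free end) shorter
#' than `min_length_mm`, a standard cleanup for single-voxel side branches
#' produced by non-maxima suppression. Interior structure is untouched.
#'
#' @param g a `centerline_graph`.
#' @param min_length_mm spur length threshold in mm.
#' @return The pruned `centerline_graph`.
#' @export
prune_spurs <- function(g, min_length_mm = 2) {
  stopifnot(inherits(g, "centerline_graph"))
  repeat {
    segs <- decompose_segments(g, warn_cycles = FALSE)
    if (length(segs) == 0) break
    drop_nodes <- integer(0)
    for (s in segs) {
      et <- s$endpoint_types
      if (sum(et == "end") == 1 && s$length_mm < min_length_mm) {
        ids <- s$node_ids
        keep_branch <- ids[which(et == "branch")]
        drop_nodes <- c(drop_nodes, setdiff(ids, keep_branch))
      }
    }
    drop_nodes <- unique(drop_nodes)
    if (length(drop_nodes) == 0) break
    keep <- !(g$tree$i %in% drop_nodes | g$tree$j %in% drop_nodes)
    g$tree <- g$tree[keep, , drop = FALSE]
    keepe <- !(g$edges$i %in% drop_nodes | g$edges$j %in% drop_nodes)
    g$edges <- g$edges[keepe, , drop = FALSE]
  }
  g
}

#' Decompose centerlines into vessel segments
#'
#' A vessel segment is the path between either two branching points or
#' between a branching point and an end point: nodes of tree degree >= 3 are
#' branch points, degree-1 nodes are end points, and every maximal path whose
#' interior nodes have degree 2 becomes one segment. Every tree edge belongs
#' to exactly one segment. Cyclic components are broken at their
#' lowest-response edge first (with a warning).
#'
#' @param g a `centerline_graph`.
#' @param warn_cycles emit a warning when a cycle is broken.
#' @return A list of `vessel_segment` objects: `points` (ordered polyline,
#'   mm), `endpoint_types` (`"branch"`/`"end"`), `length_mm`, `chord_mm`,
#'   `node_ids`.
#' @export
decompose_segments <- function(g, warn_cycles = TRUE) {
  stopifnot(inherits(g, "centerline_graph"))
  te <- g$tree
  n <- nrow(g$nodes)
  if (nrow(te) == 0) return(list())
  # enforce acyclicity: drop lowest-response edges not in a maximum spanning
  # forest (weighting edges by endpoint response)
  ig <- igraph::graph_from_edgelist(cbind(te$i, te$j), directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  ncomp <- igraph::components(ig)$no
  if (nrow(te) > n - ncomp) {
    if (warn_cycles) warning("cyclic component: broken at lowest-response edges")
    resp <- g$nodes$response
    w <- (resp[te$i] + resp[te$j]) / 2
    msf <- igraph::mst(igraph::set_edge_attr(ig, "weight", value = -w))
    el <- igraph::as_edgelist(msf)
    te <- data.frame(i = el[, 1], j = el[, 2])
    P <- as.matrix(g$nodes[, c("x_mm", "y_mm", "z_mm")])
    te$length <- sqrt(rowSums((P[te$i, , drop = FALSE] -
                                 P[te$j, , drop = FALSE])^2))
    g$tree <- te
  }
  adj <- tree_adjacency(g)
  deg <- lengths(adj)
  P <- as.matrix(g$nodes[, c("x_mm", "y_mm", "z_mm")])
  seg_list <- list()
  used <- rep(FALSE, nrow(g$tree))
  other_end <- function(r, v) if (g$tree$i[r] == v) g$tree$j[r] else g$tree$i[r]
  walk_from <- function(v0, r0) {
    # walk from special node v0 through edge r0 until the next special node
    ids <- v0; rs <- r0; v <- other_end(r0, v0); prev_r <- r0
    while (deg[v] == 2) {
      ids <- c(ids, v)
      nxt <- setdiff(adj[[v]], prev_r)
      if (length(nxt) == 0) break
      rs <- c(rs, nxt[1]); prev_r <- nxt[1]
      v <- other_end(nxt[1], v)
    }
    list(ids = c(ids, v), edges = rs)
  }
  special <- which(deg != 2 & deg > 0)
  for (v0 in special) {
    for (r0 in adj[[v0]]) {
      if (used[r0]) next
      w <- walk_from(v0, r0)
      used[w$edges] <- TRUE
      ids <- w$ids
      et <- ifelse(deg[c(ids[1], ids[length(ids)])] >= 3, "branch", "end")
      seg_list[[length(seg_list) + 1]] <- new_vessel_segment(
        P[ids, , drop = FALSE], et, ids)
    }
  }
  # pure cycles have no special node; after the MSF step above they cannot
  # remain, but guard against isolated degree-2 rings
  if (!all(used | nrow(g$tree) == 0)) {
    left <- which(!used)
    if (length(left) > 0) {
      v0 <- g$tree$i[left[1]]
      w <- walk_from(v0, left[1])
      used[w$edges] <- TRUE
      seg_list[[length(seg_list) + 1]] <- new_vessel_segment(
        P[w$ids, , drop = FALSE], c("end", "end"), w$ids)
    }
  }
  seg_list
}

new_vessel_segment <- function(points, endpoint_types, node_ids = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a vessel segment needs at least 2 points")
  dl <- sqrt(rowSums((points[-1, , drop = FALSE] -
                        points[-nrow(points), , drop = FALSE])^2))
  structure(list(points = points, endpoint_types = endpoint_types,
                 length_mm = sum(dl),
                 chord_mm = sqrt(sum((points[nrow(points), ] - points[1, ])^2)),
                 node_ids = node_ids),
            class = "vessel_segment")
}

#' Smooth vessel-segment polylines
#'
#' Endpoint-preserving binomial smoothing of the segment points (weights
#' `(1,2,1)/4` for window 3, `(1,4,6,4,1)/16` for window 5), removing the
#' sub-voxel zig-zag left by discrete candidate positions before tortuosity
#' is measured while attenuating genuine vessel curvature as little as
#' possible.
#'
#' @param segs list of `vessel_segment` objects (or a single one).
#' @param window odd window (1 = no smoothing, default 3).
#' @return The smoothed segment list.
#' @export
smooth_segments <- function(segs, window = 3) {
  single <- inherits(segs, "vessel_segment")
  if (single) segs <- list(segs)
  if (window < 3 || window %% 2 == 0) {
    if (window != 1) stop("`window` must be odd and >= 1")
    return(if (single) segs[[1]] else segs)
  }
  half <- (window - 1) / 2
  wts <- choose(window - 1, 0:(window - 1))
  out <- lapply(segs, function(s) {
    p <- s$points
    n <- nrow(p)
    if (n <= 2) return(s)
    sm <- p
    for (i in 2:(n - 1)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      w <- wts[(lo - i + half + 1):(hi - i + half + 1)]
      sm[i, ] <- colSums(p[lo:hi, , drop = FALSE] * w) / sum(w)
    }
    new_vessel_segment(sm, s$endpoint_types, s$node_ids)
  })
  if (single) out[[1]] else out
}

#' Correct the scale-space curvature bias of centerline points
#'
#' Gaussian smoothing at scale sigma displaces the intensity ridge of a
#' curved tube toward the centre of curvature by approximately
#' `sigma^2 * kappa / 2` (kappa = local curvature). This step estimates the
#' local curvature of each interior segment point from the circumcircle
#' through its neighbours `span` points away and moves the point outward by
#' the predicted displacement (clamped to half a working voxel). Straight
#' segments are unchanged.
#'
#' The curvature is estimated on a strongly smoothed copy of the polyline so
#' residual point jitter does not masquerade as curvature.
#'
#' @param segs list of `vessel_segment` objects.
#' @param scales per-candidate detection scale in mm (indexed by the
#'   segments' `node_ids`), or a single scale for all points.
#' @param span neighbour distance used for the curvature estimate.
#' @param max_shift_mm clamp on the correction.
#' @return The corrected segment list.
#' @export
debias_segments <- function(segs, scales, span = 3, max_shift_mm = 0.3) {
  heavy_smooth <- function(p) {
    for (pass in 1:2) {
      n <- nrow(p)
      if (n < 5) return(p)
      q <- p
      for (i in 3:(n - 2))
        q[i, ] <- colSums(p[(i - 2):(i + 2), , drop = FALSE] *
                            c(1, 4, 6, 4, 1)) / 16
      p <- q
    }
    p
  }
  lapply(segs, function(s) {
    p <- s$points
    n <- nrow(p)
    if (n < 2 * span + 1) return(s)
    sig <- if (length(scales) == 1) rep(scales, n) else scales[s$node_ids]
    ref <- heavy_smooth(p)
    out <- p
    for (i in (span + 1):(n - span)) {
      A <- ref[i - span, ]; B <- ref[i, ]; C <- ref[i + span, ]
      ab <- B - A; cb <- B - C; ac <- C - A
      cr <- c(ab[2] * cb[3] - ab[3] * cb[2], ab[3] * cb[1] - ab[1] * cb[3],
              ab[1] * cb[2] - ab[2] * cb[1])
      area2 <- sqrt(sum(cr^2)) # twice the triangle area
      la <- sqrt(sum(ab^2)); lb <- sqrt(sum(cb^2)); lc <- sqrt(sum(ac^2))
      if (area2 < 1e-12 || la * lb * lc < 1e-12) next
      kappa <- 2 * area2 / (la * lb * lc)
      # unit vector from the curvature centre towards B: component of
      # (2B - A - C) orthogonal to the chord AC
      m <- B - (A + C) / 2
      chord <- ac / lc
      m <- m - sum(m * chord) * chord
      nm <- sqrt(sum(m^2))
      if (nm < 1e-12) next
      ds <- (la + lb) / (2 * span) # local point spacing
      # sigma^2 kappa / 2 from the Gaussian ridge displacement, plus the
      # curvature attenuation of the binomial(1,2,1)/4 polyline smoothing
      shift <- min(kappa * (sig[i]^2 / 2 + ds^2 / 4), max_shift_mm)
      out[i, ] <- p[i, ] + shift * m / nm
    }
    new_vessel_segment(out, s$endpoint_types, s$node_ids)
  })
}

#' Construct a vessel segment from an ordered polyline
#'
#' @param points `n x 2+` matrix of ordered 3D coordinates in mm.
#' @param endpoint_types character length-2, each `"branch"` or `"end"`.
#' @return A `vessel_segment` with `length_mm` and `chord_mm` precomputed.
#' @export
vessel_segment <- function(points, endpoint_types = c("end", "end")) {
  new_vessel_segment(points, endpoint_types)
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> %d points, length %.3f mm, chord %.3f mm (%s-%s)\n",
              nrow(x$points), x$length_mm, x$chord_mm,
              x$endpoint_types[1], x$endpoint_types[2]))
  invisible(x)
}

# admissibility filter shared by counting and mean-DM: degenerate segments
# (too few points or sub-voxel chord) are excluded
admissible_segments <- function(segs, min_points = 3, min_chord_mm = 0) {
  Filter(function(s) nrow(s$points) >= min_points && s$chord_mm > min_chord_mm,
         segs)
}

#' Count admissible vessel segments
#'
#' @param segs list of `vessel_segment` objects.
#' @param min_points minimum polyline points (default 3).
#' @param min_chord_mm minimum chord length in mm (default 0; the pipeline
#'   uses one working voxel).
#' @return Integer count.
#' @export
count_segments <- function(segs, min_points = 3, min_chord_mm = 0) {
  length(admissible_segments(segs, min_points, min_chord_mm))
}

#' Export vessel segments as VTK legacy ASCII polylines
#'
#' @param segs list of `vessel_segment` objects.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_segments_vtk <- function(segs, path) {
  pts <- do.call(rbind, lapply(segs, function(s) s$points))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel centerlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(pts))), con)
  write(t(pts), con, ncolumns = 3)
  sizes <- vapply(segs, function(s) nrow(s$points), integer(1))
  writeLines(sprintf("LINES %d %d", length(segs), sum(sizes + 1)), con)
  off <- 0L
  for (s in seq_along(segs)) {
    writeLines(paste(c(sizes[s], off + seq_len(sizes[s]) - 1L), collapse = " "),
               con)
    off <- off + sizes[s]
  }
  invisible(path)
}
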
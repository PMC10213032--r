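#' Planar spatial graph of a hyphal network
#'
#' A `network_graph` stores a snapshot of a mycelium as a planar spatial
#' graph: nodes carry continuous 2-D coordinates in micrometres, a birth
#' time in hours, and (for simulated networks) the provenance of the branch
#' that created them; edges are straight segments between nodes, labelled by
#' branch type. Hyphal curvature is represented by chains of degree-2
#' nodes, so every edge is a short straight polyline piece.
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (µm) and optionally
#'   `birth_time` (h), `class`, `provenance`. Missing optional columns are
#'   filled with `NA` / 0.
#' @param edges data.frame with columns `a`, `b` (node ids) and optionally
#'   `branch_type` (one of `"germination"`, `"exploratory"`, `"operating"`,
#'   `"lateral"`).
#' @param snapshot_time time of the snapshot in hours; must be at least the
#'   largest node birth time.
#'
#' @return An object of class `network_graph`.
#' @examples
#' g <- network_graph(
#'   nodes = data.frame(id = 1:3, x = c(0, 1, 2), y = c(0, 0, 0)),
#'   edges = data.frame(a = c(1, 2), b = c(2, 3))
#' )
#' total_length(g)
#' @export
network_graph <- function(nodes, edges, snapshot_time = NULL) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)))
  if (nrow(edges) > 0) stopifnot(all(c("a", "b") %in% names(edges)))
  if (is.null(nodes$birth_time)) nodes$birth_time <- 0
  if (is.null(nodes$class)) nodes$class <- NA_character_
  if (is.null(nodes$provenance)) nodes$provenance <- NA_character_
  if (is.null(edges$branch_type)) edges$branch_type <- rep(NA_character_, nrow(edges))

  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y)))
    stop("node coordinates must be finite")
  if (nrow(edges) > 0 && !all(c(edges$a, edges$b) %in% nodes$id))
    stop("edge endpoints must reference existing node ids")
  if (is.null(snapshot_time)) snapshot_time <- max(nodes$birth_time, 0)
  if (any(nodes$birth_time > snapshot_time + 1e-9))
    stop("snapshot_time must be >= every node birth_time")

  structure(
    list(nodes = nodes, edges = edges, snapshot_time = snapshot_time),
    class = "network_graph"
  )
}

#' @export
print.network_graph <- function(x, ...) {
  deg <- vertex_degrees(x)
  cat(sprintf(
    "network_graph: %d nodes, %d edges, t = %.2f h (degrees: %s)\n",
    nrow(x$nodes), nrow(x$edges), x$snapshot_time,
    paste(names(table(deg)), table(deg), sep = ":", collapse = " ")
  ))
  invisible(x)
}

#' Degree of every stored node
#'
#' @param graph a [network_graph()].
#' @return Integer vector of degrees, named by node id, in node-table order.
#' @export
vertex_degrees <- function(graph) {
  ids <- graph$nodes$id
  deg <- integer(length(ids))
  names(deg) <- as.character(ids)
  if (nrow(graph$edges) > 0) {
    tab <- table(c(as.character(graph$edges$a), as.character(graph$edges$b)))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

# segment endpoint coordinate matrix: one row per edge (x1,y1,x2,y2,a,b)
segment_table <- function(graph) {
  n <- graph$nodes
  idx <- match(graph$edges$a, n$id)
  jdx <- match(graph$edges$b, n$id)
  cbind(
    x1 = n$x[idx], y1 = n$y[idx], x2 = n$x[jdx], y2 = n$y[jdx],
    a = idx, b = jdx
  )
}

#' Count transversal hyphal crossings
#'
#' Counts the geometric intersection points between pairs of non-adjacent
#' edge segments. Because the mycelium is not constrained vertically, hyphae
#' can overrun one another; these overlaps are geometric crossings, not
#' biological fusions (anastomosis is not modelled). Crossings are computed
#' on demand and never stored as graph nodes, so the degree invariant of the
#' stored graph is untouched. Pairs sharing an endpoint are excluded, and
#' collinear overlaps count zero (a measure-zero configuration under
#' continuous coordinates).
#'
#' @param graph a [network_graph()].
#' @return Number of transversal crossing points (integer).
#' @examples
#' x_graph <- network_graph(
#'   nodes = data.frame(id = 1:4, x = c(-1, 1, -1, 1), y = c(-1, 1, 1, -1)),
#'   edges = data.frame(a = c(1, 3), b = c(2, 4))
#' )
#' count_crossings(x_graph) # 1
#' @export
count_crossings <- function(graph) {
  seg <- segment_table(graph)
  m <- nrow(seg)
  if (is.null(m) || m < 2) return(0L)
  pairs <- candidate_segment_pairs(seg)
  if (nrow(pairs) == 0) return(0L)
  i <- pairs[, 1]; j <- pairs[, 2]
  # exclude adjacent segments (shared endpoint)
  shared <- seg[i, "a"] == seg[j, "a"] | seg[i, "a"] == seg[j, "b"] |
    seg[i, "b"] == seg[j, "a"] | seg[i, "b"] == seg[j, "b"]
  i <- i[!shared]; j <- j[!shared]
  if (length(i) == 0) return(0L)
  sum(segments_cross(seg[i, , drop = FALSE], seg[j, , drop = FALSE]))
}

# candidate pairs via uniform grid binning on segment bounding boxes;
# falls back to all pairs for small graphs
candidate_segment_pairs <- function(seg) {
  m <- nrow(seg)
  if (m <= 200) {
    idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    return(unname(idx))
  }
  len <- sqrt((seg[, "x2"] - seg[, "x1"])^2 + (seg[, "y2"] - seg[, "y1"])^2)
  cell <- max(stats::median(len), 1e-6) * 2
  xlo <- floor(pmin(seg[, "x1"], seg[, "x2"]) / cell)
  xhi <- floor(pmax(seg[, "x1"], seg[, "x2"]) / cell)
  ylo <- floor(pmin(seg[, "y1"], seg[, "y2"]) / cell)
  yhi <- floor(pmax(seg[, "y1"], seg[, "y2"]) / cell)
  # enumerate (cell, segment) incidences
  nx <- xhi - xlo + 1L
  ny <- yhi - ylo + 1L
  reps <- as.integer(nx * ny)
  sid <- rep.int(seq_len(m), reps)
  off <- sequence(reps) - 1L
  cx <- xlo[sid] + off %% nx[sid]
  cy <- ylo[sid] + off %/% nx[sid]
  key <- paste(cx, cy)
  pairs_list <- lapply(split(sid, key), function(s) {
    if (length(s) < 2) return(NULL)
    idx <- which(upper.tri(matrix(0, length(s), length(s))), arr.ind = TRUE)
    cbind(s[idx[, 1]], s[idx[, 2]])
  })
  pairs <- do.call(rbind, pairs_list)
  if (is.null(pairs)) return(matrix(integer(0), 0, 2))
  pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
  pairs
}

# strict transversal crossing test, vectorised over rows of s1/s2
segments_cross <- function(s1, s2) {
  o <- function(ax, ay, bx, by, cx, cy) {
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  }
  d1 <- o(s1[, 1], s1[, 2], s1[, 3], s1[, 4], s2[, 1], s2[, 2])
  d2 <- o(s1[, 1], s1[, 2], s1[, 3], s1[, 4], s2[, 3], s2[, 4])
  d3 <- o(s2[, 1], s2[, 2], s2[, 3], s2[, 4], s1[, 1], s1[, 2])
  d4 <- o(s2[, 1], s2[, 2], s2[, 3], s2[, 4], s1[, 3], s1[, 4])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Classify vertices of a hyphal network
#'
#' Vertex classes follow the standard nomenclature for a mycelial graph:
#' `V1` are growing tips (apexes), `V1l` tips of lateral branches, `V3`
#' three-way junctions from apical branching, `V3l` junctions from lateral
#' branching, `internal` the degree-2 nodes tracing curvature, and `V3i`
#' geometric crossing points of two hyphae (overlaps, not fusions). `V3i`
#' are synthesised from segment intersections, never stored as nodes.
#'
#' Separating `V1`/`V1l` and `V3`/`V3l` requires branch provenance, which
#' only simulated graphs carry; without it, only the degree-based classes
#' are filled and `subclasses_known` is `FALSE`.
#'
#' @param graph a [network_graph()].
#' @param count_v3i if `TRUE` (default) also count crossings as `V3i`.
#' @return A list with `counts` (named integer vector over
#'   `V1, V1l, V3, V3l, internal, V3i`) and `subclasses_known` (logical).
#' @export
classify_vertices <- function(graph, count_v3i = TRUE) {
  deg <- vertex_degrees(graph)
  if (any(deg > 3))
    stop("malformed graph: stored node with degree > 3")
  prov <- graph$nodes$provenance
  known <- !all(is.na(prov))
  lat <- known & !is.na(prov) & prov == "lateral"
  counts <- c(
    V1 = sum(deg == 1 & !lat),
    V1l = sum(deg == 1 & lat),
    V3 = sum(deg == 3 & !lat),
    V3l = sum(deg == 3 & lat),
    internal = sum(deg == 2),
    V3i = if (count_v3i) as.integer(count_crossings(graph)) else 0L
  )
  list(counts = counts, subclasses_known = known)
}

#' Total and pruned network length, and tortuosity
#'
#' `total_length()` sums the Euclidean lengths of all edge segments.
#' `pruned_length()` replaces every maximal chain of degree-2 nodes by the
#' straight chord between its flanking degree-1/3 nodes, i.e. measures the
#' network pruned of its curvature. `tortuosity()` combines the two into
#' the normalised arc-chord ratio
#' \eqn{\alpha = (L_{tot} - L_p) / (L_{tot} + L_p)}, a global measure of how
#' far hyphal growth deviates from straight lines; 0 for an all-straight
#' network, approaching 1 for extremely wiggly paths.
#'
#' @param graph a [network_graph()] with at least one edge.
#' @return `total_length()` and `pruned_length()` return lengths in µm;
#'   `tortuosity()` returns a list with `L_tot`, `L_p` and `alpha_tort`.
#' @examples
#' elbow <- network_graph(
#'   nodes = data.frame(id = 1:3, x = c(0, 1, 1), y = c(0, 0, 1)),
#'   edges = data.frame(a = c(1, 2), b = c(2, 3))
#' )
#' tortuosity(elbow)$alpha_tort # (2 - sqrt(2)) / (2 + sqrt(2))
#' @export
total_length <- function(graph) {
  if (nrow(graph$edges) == 0) stop("empty graph: length undefined")
  seg <- segment_table(graph)
  sum(sqrt((seg[, "x2"] - seg[, "x1"])^2 + (seg[, "y2"] - seg[, "y1"])^2))
}

#' @rdname total_length
#' @export
pruned_length <- function(graph) {
  if (nrow(graph$edges) == 0) stop("empty graph: length undefined")
  deg <- vertex_degrees(graph)
  n <- graph$nodes
  ids <- n$id
  # adjacency as list of (neighbour index, edge index)
  ea <- match(graph$edges$a, ids)
  eb <- match(graph$edges$b, ids)
  adj <- vector("list", length(ids))
  for (k in seq_along(ea)) {
    adj[[ea[k]]] <- rbind(adj[[ea[k]]], c(eb[k], k))
    adj[[eb[k]]] <- rbind(adj[[eb[k]]], c(ea[k], k))
  }
  anchors <- which(deg != 2)
  visited <- logical(nrow(graph$edges))
  lp <- 0
  for (v in anchors) {
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      e0 <- nb[r, 2]
      if (visited[e0]) next
      # walk along the chain of degree-2 nodes to the next anchor
      prev_edge <- e0; cur <- nb[r, 1]; visited[e0] <- TRUE
      while (deg[cur] == 2) {
        nb2 <- adj[[cur]]
        take <- if (nb2[1, 2] == prev_edge) 2L else 1L
        prev_edge <- nb2[take, 2]
        visited[prev_edge] <- TRUE
        cur <- nb2[take, 1]
      }
      lp <- lp + sqrt((n$x[v] - n$x[cur])^2 + (n$y[v] - n$y[cur])^2)
    }
  }
  lp
}

#' @rdname total_length
#' @export
tortuosity <- function(graph) {
  lt <- total_length(graph)
  lp <- pruned_length(graph)
  res <- list(L_tot = lt, L_p = lp, alpha_tort = (lt - lp) / (lt + lp))
  class(res) <- "tortuosity_result"
  res
}

#' @export
print.tortuosity_result <- function(x, ...) {
  cat(sprintf("tortuosity: L_tot = %.1f um, L_p = %.1f um, alpha = %.4f\n",
              x$L_tot, x$L_p, x$alpha_tort))
  invisible(x)
}

#' Ratio of one-body vertices to junction vertices
#'
#' The ratio (V1 + V1l) / (V3 + V3l + V3i) compares the number of growing
#' ends to the number of junctions, a simple consistency observable between
#' simulated and imaged networks. Crossings (`V3i`) appear in experimental
#' images where overlaps cannot be told apart from junctions, so they are
#' included in the denominator by default; set `include_crossings = FALSE`
#' for the purely biological junction count.
#'
#' @param graph a [network_graph()].
#' @param include_crossings include geometric crossings in the denominator.
#' @return The dimensionless ratio.
#' @export
one_body_ratio <- function(graph, include_crossings = TRUE) {
  cl <- classify_vertices(graph, count_v3i = include_crossings)$counts
  num <- cl[["V1"]] + cl[["V1l"]]
  den <- cl[["V3"]] + cl[["V3l"]] + if (include_crossings) cl[["V3i"]] else 0L
  if (den == 0) stop("degenerate early graph: no junction vertices")
  num / den
}
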
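# shared test helpers: tiny graph builders and independent oracles

# polyline chain graph through a matrix of points
chain_graph <- function(pts, branch_type = "germination") {
  n <- nrow(pts)
  network_graph(
    nodes = data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2]),
    edges = data.frame(a = seq_len(n - 1), b = 2:n, branch_type = branch_type)
  )
}

# brute-force O(n^2) transversal crossing counter, written independently
# of the package internals (orientation-sign test per segment pair)
brute_crossings <- function(graph) {
  nd <- graph$nodes
  ia <- match(graph$edges$a, nd$id)
  ib <- match(graph$edges$b, nd$id)
  m <- length(ia)
  cr <- 0L
  orient <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (length(intersect(c(ia[i], ib[i]), c(ia[j], ib[j]))) > 0) next
    p1 <- c(nd$x[ia[i]], nd$y[ia[i]]); p2 <- c(nd$x[ib[i]], nd$y[ib[i]])
    p3 <- c(nd$x[ia[j]], nd$y[ia[j]]); p4 <- c(nd$x[ib[j]], nd$y[ib[j]])
    d1 <- orient(p1, p2, p3); d2 <- orient(p1, p2, p4)
    d3 <- orient(p3, p4, p1); d4 <- orient(p3, p4, p2)
    if (d1 * d2 < 0 && d3 * d4 < 0) cr <- cr + 1L
  }
  cr
}

# quick small-run configuration for simulator tests
small_config <- function(t_end = 6, seed = 1, ...) {
  growth_config(t_end = t_end, seed = seed, ...)
}

# apex-count series of a trajectory
apex_counts <- function(traj) {
  data.frame(
    t = vapply(traj$snapshots, function(s) s$t_h[1], numeric(1)),
    N = vapply(traj$snapshots, nrow, integer(1))
  )
}
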
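test_that("vertex classification matches hand-built topologies", {
  # straight germination filament: both ends are tips
  fil <- generate_fixture("toy_graph", shape = "filament")
  cl <- classify_vertices(fil)
  expect_equal(unname(cl$counts["V1"]), 2L)
  expect_equal(unname(cl$counts["internal"]), 1L)
  expect_equal(unname(cl$counts["V3"]), 0L)

  # Y-shaped apical branching: three tips, one junction
  y <- generate_fixture("toy_graph", shape = "Y")
  cl <- classify_vertices(y)
  expect_equal(unname(cl$counts["V1"]), 3L)
  expect_equal(unname(cl$counts["V3"]), 1L)
  expect_true(cl$subclasses_known)

  # two disjoint crossing filaments: four tips plus one geometric crossing
  x <- generate_fixture("toy_graph", shape = "X")
  cl <- classify_vertices(x)
  expect_equal(unname(cl$counts["V1"]), 4L)
  expect_equal(unname(cl$counts["V3i"]), 1L)
  expect_false(cl$subclasses_known)
  # counts over stored nodes sum to the node count
  expect_equal(sum(cl$counts) - cl$counts[["V3i"]], nrow(x$nodes))
})

test_that("lateral provenance separates V1l/V3l from V1/V3", {
  g <- network_graph(
    nodes = data.frame(
      id = 1:5, x = c(0, 1, 2, 1, 1), y = c(0, 0, 0, 1, 2),
      provenance = c(NA, "lateral", NA, "lateral", "lateral")
    ),
    edges = data.frame(a = c(1, 2, 2, 4), b = c(2, 3, 4, 5),
                       branch_type = c("germination", "germination",
                                       "lateral", "lateral"))
  )
  cl <- classify_vertices(g)
  expect_equal(unname(cl$counts["V3l"]), 1L)
  expect_equal(unname(cl$counts["V1l"]), 1L)  # only the lateral tip
  expect_equal(unname(cl$counts["V1"]), 2L)
})

test_that("degree above three is a malformed graph", {
  g <- network_graph(
    nodes = data.frame(id = 1:5, x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1)),
    edges = data.frame(a = rep(1, 4), b = 2:5)
  )
  expect_error(classify_vertices(g), "degree > 3")
})

test_that("crossing counts match simple layouts and the brute-force oracle", {
  expect_equal(count_crossings(generate_fixture("toy_graph", shape = "X")), 1L)

  par <- network_graph(
    nodes = data.frame(id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
    edges = data.frame(a = c(1, 3), b = c(2, 4))
  )
  expect_equal(count_crossings(par), 0L)

  # three long segments crossing pairwise
  tri <- network_graph(
    nodes = data.frame(id = 1:6,
                       x = c(-2, 2, -1, 2, 2, -2),
                       y = c(0, 1, -2, 2, -1, 2)),
    edges = data.frame(a = c(1, 3, 5), b = c(2, 4, 6))
  )
  expect_equal(brute_crossings(tri), 3L)
  expect_equal(count_crossings(tri), 3L)

  # property: random segment soup agrees with the independent oracle
  set.seed(42)
  for (rep in 1:5) {
    m <- 60
    nd <- data.frame(id = seq_len(2 * m),
                     x = runif(2 * m, 0, 10), y = runif(2 * m, 0, 10))
    eg <- data.frame(a = seq(1, 2 * m, by = 2), b = seq(2, 2 * m, by = 2))
    g <- network_graph(nd, eg)
    expect_equal(count_crossings(g), brute_crossings(g))
  }
})

test_that("shared endpoints are never counted as crossings", {
  y <- generate_fixture("toy_graph", shape = "Y")
  expect_equal(count_crossings(y), 0L)
})

test_that("tortuosity follows the arc-chord definition", {
  # L-shaped elbow: L_tot = 2, L_p = sqrt(2)
  elbow <- chain_graph(rbind(c(0, 0), c(1, 0), c(1, 1)))
  res <- tortuosity(elbow)
  expect_equal(res$L_tot, 2)
  expect_equal(res$L_p, sqrt(2))
  expect_equal(res$alpha_tort, (2 - sqrt(2)) / (2 + sqrt(2)), tolerance = 1e-9)

  # straight chain: zero tortuosity
  straight <- chain_graph(cbind(0:5, 0))
  expect_equal(tortuosity(straight)$alpha_tort, 0)

  expect_error(total_length(network_graph(
    nodes = data.frame(id = 1, x = 0, y = 0),
    edges = data.frame(a = integer(0), b = integer(0))
  )), "empty")
})

test_that("tortuosity is invariant under rigid motions", {
  set.seed(7)
  for (rep in 1:5) {
    pts <- cbind(cumsum(runif(20, 0.5, 2)), cumsum(rnorm(20, 0, 0.3)))
    g <- chain_graph(pts)
    a0 <- tortuosity(g)$alpha_tort
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- pts %*% t(R) + matrix(rnorm(2, 0, 50), nrow(pts), 2, byrow = TRUE)
    expect_equal(tortuosity(chain_graph(moved))$alpha_tort, a0,
                 tolerance = 1e-9)
  }
})

test_that("pruned length collapses degree-2 chains between junctions", {
  # Y with a bent arm: arm 2-5-6 has a kink at node 5
  g <- network_graph(
    nodes = data.frame(id = 1:6,
                       x = c(0, 1, 2, 2, 1.5, 2.5),
                       y = c(0, 0, 1, -1, 1, 1.5)),
    edges = data.frame(a = c(1, 2, 2, 2, 5), b = c(2, 3, 4, 5, 6))
  )
  # chords: 1-2 (1), 2-3 (sqrt2), 2-4 (sqrt2), 2-6 (sqrt(1.5^2+1.5^2))
  expect_equal(pruned_length(g), 1 + sqrt(2) + sqrt(2) + sqrt(4.5),
               tolerance = 1e-9)
})

test_that("one-body ratio counts tips over junctions", {
  expect_equal(one_body_ratio(generate_fixture("toy_graph", shape = "Y")), 3)
  expect_equal(one_body_ratio(generate_fixture("toy_graph", shape = "X")), 4)
  expect_error(one_body_ratio(generate_fixture("toy_graph", shape = "filament")),
               "degenerate")
  # crossings can be excluded from the denominator
  expect_error(one_body_ratio(generate_fixture("toy_graph", shape = "X"),
                              include_crossings = FALSE), "degenerate")
})

test_that("pure binary tree with k junctions has ratio (k+2)/k", {
  # build by successively splitting tips: each junction adds one tip
  set.seed(1)
  nodes <- data.frame(id = 1:2, x = c(0, 1), y = c(0, 0))
  edges <- data.frame(a = 1, b = 2)
  tips <- c(1L, 2L)
  next_id <- 3L
  for (k in 1:6) {
    tip <- tips[1]
    for (dy in c(0.3, -0.3)) {
      nodes <- rbind(nodes, data.frame(id = next_id,
                                       x = nodes$x[tip] + 1 + 0.01 * next_id,
                                       y = nodes$y[tip] + dy * k))
      edges <- rbind(edges, data.frame(a = nodes$id[tip], b = next_id))
      tips <- c(tips, next_id)
      next_id <- next_id + 1L
    }
    tips <- tips[-1]
    g <- network_graph(nodes, edges)
    cl <- classify_vertices(g)$counts
    if (cl[["V3i"]] == 0) {
      expect_equal(one_body_ratio(g), (k + 2) / k)
      # tip/junction bookkeeping of a crossing-free binary tree
      expect_equal(unname(cl["V1"]), unname(cl["V3"]) + 2L)
    }
  }
})

test_that("graph constructor validates its invariants", {
  expect_error(network_graph(
    nodes = data.frame(id = 1:2, x = c(0, Inf), y = c(0, 0)),
    edges = data.frame(a = 1, b = 2)
  ), "finite")
  expect_error(network_graph(
    nodes = data.frame(id = 1:2, x = c(0, 1), y = c(0, 0)),
    edges = data.frame(a = 1, b = 3)
  ), "existing node")
  expect_error(network_graph(
    nodes = data.frame(id = 1:2, x = c(0, 1), y = c(0, 0), birth_time = c(0, 5)),
    edges = data.frame(a = 1, b = 2), snapshot_time = 1
  ), "birth_time")
})
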
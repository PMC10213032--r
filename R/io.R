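#' Read and write network graph snapshots
#'
#' A graph snapshot is stored as two CSV tables with units declared in
#' the headers: `nodes.csv` (`id,x_um,y_um,birth_h,class,provenance`) and
#' `edges.csv` (`a,b,branch_type`). The round trip is lossless for ids,
#' coordinates, times, classes and provenance. Parsers validate the
#' schema and report the offending row for dangling edge references.
#'
#' @param graph a [network_graph()].
#' @param dir directory receiving / holding `nodes.csv` and `edges.csv`.
#' @return `write_graph()` returns `dir` invisibly; `read_graph()`
#'   returns a [network_graph()].
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "network_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- graph$nodes
  utils::write.csv(
    data.frame(id = n$id, x_um = n$x, y_um = n$y, birth_h = n$birth_time,
               class = n$class, provenance = n$provenance),
    file.path(dir, "nodes.csv"), row.names = FALSE
  )
  utils::write.csv(
    data.frame(a = graph$edges$a, b = graph$edges$b,
               branch_type = graph$edges$branch_type),
    file.path(dir, "edges.csv"), row.names = FALSE
  )
  jsonlite::write_json(list(snapshot_h = graph$snapshot_time),
                       file.path(dir, "graph_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_graph
#' @export
read_graph <- function(dir) {
  nodes_path <- file.path(dir, "nodes.csv")
  edges_path <- file.path(dir, "edges.csv")
  if (!file.exists(nodes_path) || !file.exists(edges_path))
    stop("expected nodes.csv and edges.csv under ", dir)
  nd <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  ed <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  need_n <- c("id", "x_um", "y_um", "birth_h")
  if (!all(need_n %in% names(nd)))
    stop("nodes.csv schema error: need unit-bearing columns ",
         paste(setdiff(need_n, names(nd)), collapse = ", "))
  need_e <- c("a", "b")
  if (nrow(ed) > 0 && !all(need_e %in% names(ed)))
    stop("edges.csv schema error: need columns a, b")
  bad <- which(!(ed$a %in% nd$id) | !(ed$b %in% nd$id))
  if (length(bad) > 0)
    stop("edges.csv: dangling node reference at row ", bad[1])
  meta_path <- file.path(dir, "graph_meta.json")
  snap <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path)$snapshot_h else NULL
  network_graph(
    nodes = data.frame(id = nd$id, x = nd$x_um, y = nd$y_um,
                       birth_time = nd$birth_h,
                       class = if ("class" %in% names(nd)) nd$class else NA,
                       provenance = if ("provenance" %in% names(nd))
                         nd$provenance else NA),
    edges = data.frame(a = ed$a, b = ed$b,
                       branch_type = if ("branch_type" %in% names(ed))
                         ed$branch_type else NA),
    snapshot_time = snap
  )
}

#' Read and write trajectories
#'
#' A trajectory directory contains `snapshots/snap_0001.csv, ...` (apex
#' clouds per cadence with columns `t_h,x_um,y_um,apex_class`),
#' `events.csv` (the branch-event log), the final graph tables
#' (`nodes.csv`, `edges.csv`) and `meta.json`.
#'
#' @param trajectory a `growth_trajectory`.
#' @param dir target / source directory.
#' @return `write_trajectory()` returns `dir` invisibly;
#'   `read_trajectory()` returns a `growth_trajectory` (with `config`
#'   reduced to the recorded metadata).
#' @export
write_trajectory <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "growth_trajectory"))
  snap_dir <- file.path(dir, "snapshots")
  if (!dir.exists(snap_dir)) dir.create(snap_dir, recursive = TRUE)
  for (k in seq_along(trajectory$snapshots)) {
    utils::write.csv(trajectory$snapshots[[k]],
                     file.path(snap_dir, sprintf("snap_%04d.csv", k)),
                     row.names = FALSE)
  }
  utils::write.csv(trajectory$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  write_graph(trajectory$graph, dir)
  cfg <- trajectory$config
  jsonlite::write_json(
    list(t_end_h = cfg$t_end, dt_h = cfg$dt, seed = cfg$seed,
         snapshot_cadence_h = cfg$snapshot_cadence,
         n_apexes = trajectory$n_apexes),
    file.path(dir, "meta.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  snap_dir <- file.path(dir, "snapshots")
  files <- sort(list.files(snap_dir, pattern = "^snap_.*\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no snapshot tables under ", snap_dir)
  snaps <- lapply(files, function(f) {
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!all(c("t_h", "x_um", "y_um") %in% names(d)))
      stop("snapshot schema error in ", basename(f),
           ": need unit-bearing columns t_h, x_um, y_um")
    d
  })
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  graph <- read_graph(dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(
    list(config = meta, snapshots = snaps, events = events, graph = graph,
         n_apexes = meta$n_apexes),
    class = "growth_trajectory"
  )
}

#' Generate synthetic test fixtures
#'
#' Deterministic (seeded) generators for the small synthetic datasets the
#' package is tested against: point clouds with prescribed inertia
#' eigenvalues, exponentially growing count series with Poisson noise,
#' apical branch-spacing samples, lateral spacing mixtures (burst
#' exponential plus uniform), and toy graphs.
#'
#' @param kind one of `"point_cloud"`, `"count_series"`,
#'   `"branching_samples"`, `"mixture_samples"`, `"toy_graph"`.
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param ... kind-specific parameters:
#'   * `point_cloud`: `lambda1`, `lambda2` (µm²), `n`, `angle` (rad,
#'     orientation of the major axis).
#'   * `count_series`: `C`, `omega` (h^-1), `t` (vector of hours).
#'   * `branching_samples`: `n`, `L0` (µm), `alpha_rate` (µm^-1).
#'   * `mixture_samples`: `n`, `gamma1` (µm^-1), `uniform_fraction`,
#'     `range_um` (support of the uniform component).
#'   * `toy_graph`: `shape` (`"filament"`, `"Y"`, `"X"`).
#' @return The fixture: a matrix (point cloud), data.frame (count
#'   series), numeric vector (samples) or [network_graph()].
#' @examples
#' cloud <- generate_fixture("point_cloud", lambda1 = 2, lambda2 = 0.5,
#'                           n = 1000, seed = 1)
#' @export
generate_fixture <- function(kind, ..., seed = 1L) {
  kind <- match.arg(kind, c("point_cloud", "count_series",
                            "branching_samples", "mixture_samples",
                            "toy_graph"))
  set.seed(seed)
  args <- list(...)
  switch(kind,
    point_cloud = {
      l1 <- args$lambda1 %||% 2
      l2 <- args$lambda2 %||% 0.5
      n <- args$n %||% 1e4
      ang <- args$angle %||% 0
      pts <- cbind(stats::rnorm(n, 0, sqrt(l1)), stats::rnorm(n, 0, sqrt(l2)))
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      pts %*% t(R)
    },
    count_series = {
      C <- args$C %||% 4
      omega <- args$omega %||% 0.48
      t <- args$t %||% seq(0, 15, by = 0.3)
      data.frame(t_h = t, N = stats::rpois(length(t), C * 2^(omega * t)))
    },
    branching_samples = {
      n <- args$n %||% 1e4
      L0 <- args$L0 %||% 180
      a <- args$alpha_rate %||% 10.4e-3
      L0 + stats::rexp(n, rate = a * log(2))
    },
    mixture_samples = {
      n <- args$n %||% 1e4
      g1 <- args$gamma1 %||% 2.3e-3
      uf <- args$uniform_fraction %||% 0.22
      rng <- args$range_um %||% 5600
      iso <- stats::runif(n) < uf
      x <- numeric(n)
      x[iso] <- stats::runif(sum(iso), 0, rng)
      x[!iso] <- stats::rexp(sum(!iso), rate = g1 * log(2))
      x[x > rng] <- x[x > rng] %% rng   # keep burst tail inside the window
      x
    },
    toy_graph = {
      shape <- args$shape %||% "Y"
      toy_graph(shape)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_graph <- function(shape) {
  switch(shape,
    filament = network_graph(
      nodes = data.frame(id = 1:3, x = c(0, 1, 2), y = c(0, 0, 0)),
      edges = data.frame(a = c(1, 2), b = c(2, 3),
                         branch_type = "germination")
    ),
    Y = network_graph(
      nodes = data.frame(id = 1:4, x = c(0, 1, 2, 2), y = c(0, 0, 1, -1),
                         provenance = c(NA, "apical", NA, NA)),
      edges = data.frame(a = c(1, 2, 2), b = c(2, 3, 4),
                         branch_type = c("germination", "exploratory",
                                         "operating"))
    ),
    X = network_graph(
      nodes = data.frame(id = 1:4, x = c(-1, 1, -1, 1), y = c(-1, 1, 1, -1)),
      edges = data.frame(a = c(1, 3), b = c(2, 4),
                         branch_type = "germination")
    ),
    stop("unknown toy graph shape: ", shape)
  )
}

#' Read and write flat configuration files
#'
#' The simulator configuration serialises to a flat YAML map whose keys
#' are `block.parameter` (e.g. `apical.L0`, `lateral.gamma1`,
#' `curvature.operating.theta0`), in the units documented in
#' [apical_params()] and friends.
#'
#' @param config a [growth_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a [growth_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "growth_config"))
  flat <- list()
  for (blk in c("apical", "lateral", "germination")) {
    for (nm in names(unclass(config[[blk]])))
      flat[[paste(blk, nm, sep = ".")]] <- config[[blk]][[nm]]
  }
  for (ty in names(config$curvature)) {
    for (nm in names(unclass(config$curvature[[ty]])))
      flat[[paste("curvature", ty, nm, sep = ".")]] <- config$curvature[[ty]][[nm]]
  }
  for (nm in c("dt", "t_end", "seed", "snapshot_cadence", "lateral_enabled"))
    flat[[nm]] <- config[[nm]]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  pick <- function(prefix, ctor) {
    keys <- grep(paste0("^", prefix, "\\."), names(flat), value = TRUE)
    args <- flat[keys]
    names(args) <- sub(paste0("^", prefix, "\\."), "", keys)
    do.call(ctor, args)
  }
  growth_config(
    apical = pick("apical", apical_params),
    lateral = pick("lateral", lateral_params),
    curvature = list(
      exploratory = pick("curvature.exploratory", curvature_params),
      operating = pick("curvature.operating", curvature_params),
      lateral = pick("curvature.lateral", curvature_params)
    ),
    germination = pick("germination", germination_params),
    dt = flat$dt, t_end = flat$t_end, seed = flat$seed,
    snapshot_cadence = flat$snapshot_cadence,
    lateral_enabled = flat$lateral_enabled
  )
}
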
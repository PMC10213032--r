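#' Distances between consecutive apical branch points
#'
#' For a simulated trajectory, returns the along-hypha arc distances
#' between successive apical branch points on the same hypha (the
#' statistic whose distribution is the apical dominance length plus a
#' base-2 exponential tail). For a plain numeric vector of branch-point
#' arc positions along one hypha, returns the successive differences.
#'
#' @param x a `growth_trajectory` or a sorted numeric vector of
#'   branch-point arc positions (µm).
#' @return Numeric vector of inter-branch distances (µm).
#' @examples
#' inter_apical_lengths(c(0, 250, 600)) # 250, 350
#' @export
inter_apical_lengths <- function(x) {
  if (inherits(x, "growth_trajectory")) {
    ev <- x$events
    return(ev$inter_branch[ev$type == "apical" & !is.na(ev$inter_branch)])
  }
  stopifnot(is.numeric(x), length(x) >= 2)
  diff(sort(x))
}

#' Spacing between chronologically successive lateral branches
#'
#' Orders lateral branch events in time and returns, for each
#' consecutive pair, the spatial distance \eqn{\Delta L} and the waiting
#' time \eqn{\Delta t}. The spatial distance is planar (Euclidean)
#' between the two branch points by default; `metric = "arc"` instead
#' differences the along-hypha positions (only meaningful for pairs on
#' the same hypha; other pairs get `NA`).
#'
#' @param events data.frame of branch events with columns `type`, `time`
#'   (h), `x`, `y` (µm), and for `metric = "arc"` also `L_hypha`, `L_lat`
#'   and `apex`; typically `trajectory$events`.
#' @param metric `"euclidean"` (default) or `"arc"`.
#' @return data.frame with columns `delta_L` (µm) and `delta_t` (min).
#' @export
successive_lateral_spacing <- function(events, metric = c("euclidean", "arc")) {
  metric <- match.arg(metric)
  lat <- events[events$type == "lateral", , drop = FALSE]
  if (nrow(lat) < 2) stop("need at least two lateral events")
  lat <- lat[order(lat$time), , drop = FALSE]
  n <- nrow(lat)
  dl <- if (metric == "euclidean") {
    sqrt(diff(lat$x)^2 + diff(lat$y)^2)
  } else {
    arc <- lat$L_hypha - lat$L_lat
    ifelse(lat$apex[-1] == lat$apex[-n], abs(diff(arc)), NA_real_)
  }
  data.frame(delta_L = dl, delta_t = diff(lat$time) * 60)
}

#' Orientation and curvature-side fractions of branch events
#'
#' For each branch type, the fraction of clockwise events and the
#' fraction of events emerging on the side opposite the local hyphal
#' curvature, each with its exact binomial confidence interval.
#'
#' @param events data.frame with columns `type`, `side` (`"cw"`/`"ccw"`)
#'   and `side_vs_curvature` (`"same"`/`"opposite"`).
#' @param conf_level confidence level of the binomial intervals.
#' @return data.frame with one row per branch type: `n`, `cw_fraction`,
#'   `cw_lo`, `cw_hi`, `opposite_fraction`, `opp_lo`, `opp_hi`.
#' @export
chirality_fractions <- function(events, conf_level = 0.95) {
  stopifnot(nrow(events) >= 1)
  types <- unique(events$type)
  out <- lapply(types, function(ty) {
    e <- events[events$type == ty, , drop = FALSE]
    n <- nrow(e)
    k_cw <- sum(e$side == "cw")
    k_opp <- sum(e$side_vs_curvature == "opposite")
    bc <- stats::binom.test(k_cw, n, conf.level = conf_level)$conf.int
    bo <- stats::binom.test(k_opp, n, conf.level = conf_level)$conf.int
    data.frame(type = ty, n = n,
               cw_fraction = k_cw / n, cw_lo = bc[1], cw_hi = bc[2],
               opposite_fraction = k_opp / n, opp_lo = bo[1], opp_hi = bo[2])
  })
  do.call(rbind, out)
}

#' One-dimensional Gaussian kernel density estimate
#'
#' Gaussian KDE with Scott's bandwidth rule \eqn{h = \sigma n^{-1/5}} by
#' default, evaluated on a regular grid and normalised so the trapezoid
#' integral is 1.
#'
#' @param samples numeric sample, at least 2 values.
#' @param bandwidth either `"scott"` or a positive number (same units as
#'   the sample).
#' @param n_grid number of grid points.
#' @return List with `x` (grid), `y` (density) and `bandwidth`.
#' @export
kde_1d <- function(samples, bandwidth = "scott", n_grid = 512) {
  stopifnot(length(samples) >= 2)
  s <- stats::sd(samples)
  if (!is.finite(s) || s == 0)
    stop("degenerate (constant) sample: density is a point mass")
  bw <- if (identical(bandwidth, "scott")) s * length(samples)^(-1 / 5)
        else as.numeric(bandwidth)
  stopifnot(bw > 0)
  d <- stats::density(samples, bw = bw, kernel = "gaussian", n = n_grid)
  z <- trapezoid(d$x, d$y)
  list(x = d$x, y = d$y / z, bandwidth = bw)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
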
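#' Inertia-tensor summary of an apex point cloud
#'
#' Builds the second-moment (inertia) tensor of a planar point cloud from
#' centred coordinates, normalised by the number of points so that the
#' eigenvalues \eqn{\lambda_1 \ge \lambda_2} are per-point dispersions
#' with units µm² and their roots \eqn{r_i = \sqrt{\lambda_i}} are
#' characteristic lengths of the cloud's principal axes. The sphericity
#' \eqn{2\lambda_2 / (\lambda_1 + \lambda_2)} is 1 for an isotropic cloud
#' and tends to 0 for a degenerate (collinear) one. The product
#' \eqn{r_1 r_2} serves as the characteristic-surface proxy of the cloud.
#'
#' @param points two-column matrix or data.frame of coordinates (µm).
#' @return List of class `inertia_summary`: `centroid`, `lambda1`,
#'   `lambda2`, `r1`, `r2`, `sphericity`, `axes` (eigenvector matrix,
#'   columns = principal axes) and `n_points`.
#' @examples
#' inertia_summary(rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1)))
#' @export
inertia_summary <- function(points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2)
  n <- nrow(pts)
  if (n < 2) stop("degenerate cloud: need at least 2 points")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  M <- crossprod(cen) / n
  if (sum(diag(M)) <= 0) stop("degenerate cloud: zero variance")
  eg <- eigen(M, symmetric = TRUE)
  l1 <- eg$values[1]; l2 <- max(eg$values[2], 0)
  structure(list(
    centroid = ctr, lambda1 = l1, lambda2 = l2,
    r1 = sqrt(l1), r2 = sqrt(l2),
    sphericity = 2 * l2 / (l1 + l2),
    axes = eg$vectors, n_points = n
  ), class = "inertia_summary")
}

#' @export
print.inertia_summary <- function(x, ...) {
  cat(sprintf(
    "inertia_summary: n = %d, r1 = %.3g um, r2 = %.3g um, sphericity = %.3f\n",
    x$n_points, x$r1, x$r2, x$sphericity
  ))
  invisible(x)
}

#' Apex density time series of a trajectory
#'
#' For every snapshot, counts the one-body vertices \eqn{N_1} (tips of
#' both apical and lateral branches) and summarises the spatial spread of
#' their locations by the inertia-tensor lengths \eqn{r_1, r_2}. The
#' density observable is \eqn{\rho_o(t) = N_1(t) / (r_1(t) r_2(t))},
#' apex count over the characteristic surface of the apex cloud.
#' Uncertainty per snapshot comes from a bootstrap: apex locations are
#' resampled with replacement (`B` replicates) and the count receives
#' Poisson error, reflecting the counting-process nature of \eqn{N_1}.
#' Degenerate snapshots (fewer than 2 distinct apex positions, or a
#' collinear cloud with \eqn{r_2 = 0}) are dropped with a warning.
#'
#' @param trajectory a `growth_trajectory`, or a list of data.frames with
#'   columns `t_h`, `x_um`, `y_um` (one per snapshot).
#' @param B number of bootstrap replicates.
#' @param conf_level confidence level of the bootstrap interval.
#' @return data.frame of class `density_series` with columns `t_h`, `N1`,
#'   `r1_um`, `r2_um`, `sphericity`, `rho` (µm^-2), `rho_lo`, `rho_hi`.
#' @export
density_series <- function(trajectory, B = 500, conf_level = 0.95) {
  snaps <- if (inherits(trajectory, "growth_trajectory")) trajectory$snapshots
           else trajectory
  stopifnot(is.list(snaps), length(snaps) >= 1)
  alpha <- (1 - conf_level) / 2
  rows <- vector("list", length(snaps))
  n_dropped <- 0L
  for (k in seq_along(snaps)) {
    sn <- snaps[[k]]
    pts <- cbind(sn$x_um, sn$y_um)
    n1 <- nrow(pts)
    summ <- tryCatch(inertia_summary(pts), error = function(e) NULL)
    if (is.null(summ) || n1 < 3 || summ$lambda2 <= 1e-6 * summ$lambda1) {
      n_dropped <- n_dropped + 1L
      next
    }
    rho <- n1 / (summ$r1 * summ$r2)
    boot <- vapply(seq_len(B), function(b) {
      res <- pts[sample.int(n1, n1, replace = TRUE), , drop = FALSE]
      s <- tryCatch(inertia_summary(res), error = function(e) NULL)
      if (is.null(s) || s$lambda2 <= 1e-6 * s$lambda1) return(NA_real_)
      stats::rpois(1, n1) / (s$r1 * s$r2)
    }, numeric(1))
    qs <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    rows[[k]] <- data.frame(
      t_h = sn$t_h[1], N1 = n1, r1_um = summ$r1, r2_um = summ$r2,
      sphericity = summ$sphericity, rho = rho,
      rho_lo = qs[1], rho_hi = qs[2]
    )
  }
  if (n_dropped > 0)
    warning(sprintf("dropped %d degenerate snapshot(s)", n_dropped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("no non-degenerate snapshots")
  class(out) <- c("density_series", class(out))
  out
}

#' Locate the minimum of a density time series
#'
#' The density is expected to diverge at both short and long growth times
#' with a minimum in between separating the extension and densification
#' phases. The minimum is located on a local-quadratic smooth of
#' \eqn{\log \rho} against \eqn{t} (window of `window` points; the
#' counting noise on \eqn{\rho} is multiplicative, hence the log scale),
#' with sub-grid refinement by the vertex of the quadratic fitted around
#' the discrete argmin. If the smoothed series is monotone (argmin at
#' either end), no interior minimum exists and `has_minimum` is `FALSE`.
#' A bootstrap CI is produced by re-noising the smoothed log-density with
#' resampled residuals and relocating the minimum.
#'
#' @param series a [density_series()] data.frame (columns `t_h`, `rho`),
#'   at least 5 points.
#' @param window odd number of points of the local-quadratic smoother.
#' @param B bootstrap replicates for the CI.
#' @return List with `t_min` (h), `has_minimum`, `ci` and the smoothed
#'   log-density (`t`, `log_rho_smooth`).
#' @export
detect_density_minimum <- function(series, window = 5, B = 200) {
  t <- series$t_h
  y <- log(series$rho)
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (n < 5) stop("need at least 5 finite time points")
  stopifnot(window >= 3, window %% 2 == 1)

  sm <- quad_smooth(t, y, window)
  k <- which.min(sm)
  if (k == 1 || k == n) {
    return(list(t_min = NA_real_, has_minimum = FALSE, ci = c(NA_real_, NA_real_),
                t = t, log_rho_smooth = sm))
  }
  tmin <- quad_vertex(t, sm, k, window)

  res <- y - sm
  boots <- vapply(seq_len(B), function(b) {
    yb <- sm + sample(res, n, replace = TRUE)
    smb <- quad_smooth(t, yb, window)
    kb <- which.min(smb)
    if (kb == 1 || kb == n) return(NA_real_)
    quad_vertex(t, smb, kb, window)
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)

  list(t_min = tmin, has_minimum = TRUE, ci = ci, t = t, log_rho_smooth = sm)
}

# local quadratic smoother: refit a parabola on a sliding window
quad_smooth <- function(t, y, window) {
  n <- length(t)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    tt <- t[lo:hi]; yy <- y[lo:hi]
    if (length(tt) < 3) return(yy[which(tt == t[i])[1]])
    cf <- stats::coef(stats::lm(yy ~ tt + I(tt^2)))
    unname(cf[1] + cf[2] * t[i] + cf[3] * t[i]^2)
  }, numeric(1))
}

# sub-grid minimum: vertex of the parabola fitted around index k
quad_vertex <- function(t, y, k, window) {
  n <- length(t)
  half <- max((window - 1) / 2, 1)
  lo <- max(1, k - half); hi <- min(n, k + half)
  tt <- t[lo:hi]; yy <- y[lo:hi]
  cf <- stats::coef(stats::lm(yy ~ tt + I(tt^2)))
  if (!is.finite(cf[3]) || cf[3] <= 0) return(t[k])
  vx <- -cf[2] / (2 * cf[3])
  if (vx < min(tt) || vx > max(tt)) t[k] else unname(vx)
}
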
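#' Fit a base-2 exponential growth law
#'
#' Fits counts \eqn{y(t) = C \, 2^{\omega t}} by ordinary least squares on
#' the linearised form \eqn{\log_2 y = \log_2 C + \omega t}. All exponential
#' laws in this package are written in base 2, so \eqn{\omega} is a doubling
#' frequency (per hour for apex counts). R-squared is reported on the
#' linearised scale, as \eqn{R^2 = 1 - SS_r/SS_t}.
#'
#' @param t numeric vector of times (h).
#' @param y positive counts or magnitudes, same length as `t`.
#' @return List of class `base2_fit`: `C`, `omega` (h^-1), `se_omega`,
#'   `R2`.
#' @examples
#' t <- 0:10
#' fit_base2_exponential(t, 3 * 2^(0.4 * t))
#' @export
fit_base2_exponential <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 3)
  if (any(!is.finite(y)) || any(y <= 0)) stop("y must be positive and finite")
  fit <- stats::lm(log2(y) ~ t)
  cf <- stats::coef(fit)
  structure(list(
    C = unname(2^cf[1]),
    omega = unname(cf[2]),
    se_omega = unname(suppressWarnings(summary(fit))$coefficients[2, 2]),
    R2 = r_squared(stats::fitted(fit), log2(y))
  ), class = "base2_fit")
}

# R^2 = 1 - SS_r/SS_t
r_squared <- function(fitted, observed) {
  ssr <- sum((observed - fitted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(if (ssr == 0) 1 else -Inf)
  1 - ssr / sst
}

#' Fit the shifted base-2 exponential law of inter-apical branch distances
#'
#' The distance between consecutive apical branch points is modelled as a
#' latency length (apical dominance) followed by a memoryless tail: the
#' cumulative law is \eqn{1 - 2^{-\alpha (L - L_0)}} for \eqn{L > L_0}.
#' Following the estimation procedure used on the imaging data, the onset
#' is located at the maximum slope of the binned empirical CDF (default bin
#' width 10 µm), and the tail beyond it is fitted by least squares on the
#' linearised survival \eqn{\log_2(1 - F) = -\alpha (L - L_0)}.
#'
#' @param lengths inter-branch distances (µm), at least 20 values.
#' @param bin_width histogram bin width used to locate the maximum slope
#'   (µm).
#' @param L0 optional fixed latency length; if `NULL` the max-slope
#'   estimate is used as the shift.
#' @return List of class `shifted_exp_fit`: `L0_maxslope`, `alpha_rate`
#'   (µm^-1), `se_alpha`, `R2`, `n_tail`.
#' @export
fit_shifted_exponential_cdf <- function(lengths, bin_width = 10, L0 = NULL) {
  stopifnot(length(lengths) >= 20)
  breaks <- seq(0, max(lengths) + bin_width, by = bin_width)
  h <- graphics::hist(lengths, breaks = breaks, plot = FALSE)
  L0_maxslope <- h$mids[which.max(h$counts)]
  shift <- if (is.null(L0)) L0_maxslope else L0
  tail_x <- sort(lengths[lengths > shift])
  if (length(tail_x) < 10) stop("too few tail points beyond the latency length")
  n <- length(tail_x)
  # empirical survival of the tail sample (exclude the last point, S = 0)
  surv <- 1 - seq_len(n) / n
  keep <- surv > 0
  xs <- tail_x[keep] - shift
  ys <- log2(surv[keep])
  fit <- stats::lm(ys ~ 0 + xs)
  alpha <- -unname(stats::coef(fit)[1])
  structure(list(
    L0_maxslope = L0_maxslope,
    alpha_rate = alpha,
    se_alpha = unname(suppressWarnings(summary(fit))$coefficients[1, 2]),
    R2 = r_squared(stats::fitted(fit), ys),
    n_tail = n
  ), class = "shifted_exp_fit")
}

#' Two-step fit of the lateral spacing mixture (burst + uniform)
#'
#' The spacing \eqn{\Delta L} between chronologically successive lateral
#' branches mixes a burst population clustered near existing branches and an
#' isolated population uniform in position. The histogram is fitted in the
#' two-step procedure used for the experimental data: first a pure base-2
#' exponential \eqn{\Gamma_1 2^{-\gamma_1 \Delta L}} (linearised least
#' squares on positive bins) to estimate the decay \eqn{\gamma_1}; then,
#' with \eqn{\gamma_1} fixed, the mixture
#' \eqn{\Gamma_1 2^{-\gamma_1 \Delta L} + r} by linear least squares in
#' \eqn{(\Gamma_1, r)}.
#'
#' The uniform fraction is reported as `r * n_bins / n`, i.e. the share of
#' the sample attributed to a flat level `r` counts per bin across the
#' fitted range; this definition is stored in the result.
#'
#' @param delta_L spacings (µm), at least 30 values.
#' @param n_bins number of histogram bins across the data range.
#' @param step1_min_frac step 1 uses only bins whose count is at least
#'   this fraction of the modal count, i.e. the region dominated by the
#'   exponential component; the flat uniform floor would otherwise bias
#'   the decay estimate.
#' @return List of class `mixture_fit`: `Gamma1`, `gamma1` (µm^-1),
#'   `se_gamma1`, `r_uniform` (counts per bin), `uniform_fraction`,
#'   `R2_step1`, `R2_step2`, `step1_failed`,
#'   `uniform_fraction_definition`.
#' @export
fit_mixture_exponential_uniform <- function(delta_L, n_bins = 34,
                                            step1_min_frac = 0.1) {
  n <- length(delta_L)
  stopifnot(n >= 30)
  breaks <- seq(0, max(delta_L) * (1 + 1e-9), length.out = n_bins + 1)
  h <- graphics::hist(delta_L, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  range_L <- max(delta_L)
  # the two printed steps, re-applied to the floor-subtracted histogram
  # until the flat level stabilises (the uniform floor would otherwise
  # bias the log-linear decay estimate at large sample sizes)
  r_uniform <- 0
  gamma1 <- NA_real_; se_gamma1 <- NA_real_
  R2_step1 <- NA_real_; R2_step2 <- NA_real_
  Gamma1 <- 0
  step1_failed <- FALSE
  for (pass in 1:3) {
    adj <- counts - r_uniform
    # step 1: pure exponential on the log2 scale, over the steep region
    steep <- adj >= step1_min_frac * max(adj) & adj > 0
    if (sum(steep) < 3 || stats::sd(adj[steep]) == 0) {
      if (pass == 1) stop("flat histogram: exponential step cannot be fitted")
      break
    }
    f1 <- stats::lm(log2(adj[steep]) ~ mids[steep])
    gamma1 <- -unname(stats::coef(f1)[2])
    se_gamma1 <- unname(suppressWarnings(summary(f1))$coefficients[2, 2])
    R2_step1 <- r_squared(stats::fitted(f1), log2(adj[steep]))
    # a decay of less than a factor 2 across the range is
    # indistinguishable from the uniform component
    step1_failed <- !is.finite(gamma1) || gamma1 * range_L < 1
    if (step1_failed) {
      Gamma1 <- 0
      r_uniform <- mean(counts)
      R2_step2 <- NA_real_
      break
    }
    # step 2: gamma1 fixed, fit Gamma1 and flat level r linearly
    basis <- 2^(-gamma1 * mids)
    f2 <- stats::lm(counts ~ basis)
    Gamma1 <- unname(stats::coef(f2)[2])
    r_uniform <- max(unname(stats::coef(f2)[1]), 0)
    R2_step2 <- r_squared(stats::fitted(f2), counts)
  }
  structure(list(
    Gamma1 = Gamma1,
    gamma1 = gamma1,
    se_gamma1 = se_gamma1,
    r_uniform = r_uniform,
    uniform_fraction = min(r_uniform * n_bins / n, 1),
    R2_step1 = R2_step1,
    R2_step2 = R2_step2,
    step1_failed = step1_failed,
    uniform_fraction_definition =
      "r (counts/bin) * n_bins / n: share of sample under the flat component over the fitted range"
  ), class = "mixture_fit")
}

#' Closed-form density model and the time of the density minimum
#'
#' With an exponentially growing apex count \eqn{N_1(t) = C 2^{\omega t}}
#' and inertia-eigenvalue lengths growing linearly, \eqn{r_i = B_i t}, the
#' apex density follows \eqn{\rho(t) = D \, 2^{\omega t} / t^n} with
#' \eqn{D = C/(B_1 B_2)} and \eqn{n = 2}. The density diverges at both
#' ends and reaches its minimum at \eqn{t_{min} = n / (\omega \ln 2)},
#' which depends only on the growth rate.
#'
#' @param C initial apex count scale.
#' @param omega doubling frequency of the apex count (h^-1).
#' @param B1,B2 linear growth slopes of the eigenvalue lengths (mm h^-1).
#' @param n polynomial order of the surface growth (2 for linear
#'   eigenvalue lengths).
#' @return `density_model()` returns a list with `D` (h^2 mm^-2), `omega`,
#'   `n` and `t_min` (h); `t_min()` returns the minimum time in hours.
#' @examples
#' t_min(0.59, 2) # about 4.9 h
#' @export
density_model <- function(C, omega, B1, B2, n = 2) {
  stopifnot(C > 0, omega > 0, B1 > 0, B2 > 0, n > 0)
  list(D = C / (B1 * B2), omega = omega, n = n, t_min = t_min(omega, n))
}

#' @rdname density_model
#' @export
t_min <- function(omega, n = 2) {
  stopifnot(omega > 0, n > 0)
  n / (omega * log(2))
}

#' Hyphal length giving even odds of an isolated lateral branch
#'
#' Isolated lateral branches appear at a rate `p` per µm of hypha within a
#' 90-min activity window. Under linear accumulation, the probability of
#' observing at least one isolated branch reaches 1/2 over a length
#' \eqn{L = (1/2)/p}.
#'
#' @param p isolated-branch probability per µm per activity window.
#' @return Length in µm.
#' @examples
#' isolated_halflength(6e-3) # about 80 um
#' @export
isolated_halflength <- function(p) {
  stopifnot(p > 0)
  0.5 / p
}

#' Early-time power-law fit of the density
#'
#' In the initial growth period (before the density minimum), the apex
#' count is nearly constant while the cloud spreads, so the density is
#' expected to fall as \eqn{\rho = \beta t^{-\alpha}} with \eqn{\alpha}
#' near 2. The fit is log-log linear on the window
#' \eqn{t \in (0, 0.9\,t_{min}]}. With `fix_alpha = TRUE` the exponent is
#' pinned at 2 and only \eqn{\beta} is estimated (nested model; its
#' R-squared can never exceed the free fit's).
#'
#' @param t times (h).
#' @param rho densities (must be positive on the window).
#' @param t_min time of the density minimum (h), defining the window.
#' @param fix_alpha pin the exponent at 2.
#' @return List of class `early_power_fit`: `beta`, `alpha_early`,
#'   `R2`, `n_window`.
#' @export
fit_early_power <- function(t, rho, t_min, fix_alpha = FALSE) {
  keep <- t > 0 & t <= 0.9 * t_min & is.finite(rho) & rho > 0
  if (sum(keep) < 4) stop("fewer than 4 points in the early window")
  lt <- log(t[keep]); lr <- log(rho[keep])
  if (fix_alpha) {
    beta <- exp(mean(lr + 2 * lt))
    fitted <- log(beta) - 2 * lt
    alpha <- 2
  } else {
    f <- stats::lm(lr ~ lt)
    beta <- exp(unname(stats::coef(f)[1]))
    alpha <- -unname(stats::coef(f)[2])
    fitted <- stats::fitted(f)
  }
  structure(list(
    beta = beta, alpha_early = alpha,
    R2 = r_squared(fitted, lr), n_window = sum(keep)
  ), class = "early_power_fit")
}

#' Exact binomial orientation test with Bonferroni correction
#'
#' Tests whether an observed branch orientation frequency (e.g. clockwise
#' vs counterclockwise) deviates from a null probability, by the exact
#' two-sided binomial test; when several conditions are compared against a
#' reference, p-values are Bonferroni-adjusted for the number of
#' comparisons.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p0 null probability (default 0.5).
#' @param m_comparisons number of simultaneous comparisons.
#' @return List with `p_raw`, `p_adjusted`, `estimate` (k/n) and the exact
#'   binomial confidence interval `ci`.
#' @examples
#' binomial_orientation_test(107, 198) # p about 0.29
#' @export
binomial_orientation_test <- function(k, n, p0 = 0.5, m_comparisons = 1) {
  stopifnot(k >= 0, k <= n, m_comparisons >= 1)
  bt <- stats::binom.test(k, n, p = p0)
  list(
    p_raw = bt$p.value,
    p_adjusted = min(1, m_comparisons * bt$p.value),
    estimate = k / n,
    ci = unname(bt$conf.int)
  )
}

#' One-way ANOVA and mean-centred Levene test
#'
#' `one_way_anova()` performs the standard one-way fixed-effects analysis
#' of variance across groups. `levene_mean_centered()` tests equality of
#' variances by running a one-way ANOVA on the absolute deviations from
#' the group means (mean centring, not median centring).
#'
#' @param groups list of numeric vectors, one per group (at least two
#'   groups with at least two observations each).
#' @return `one_way_anova()`: list with `F`, `df1`, `df2`, `p`,
#'   `group_means`. `levene_mean_centered()`: list with `W` (the F
#'   statistic of the deviation ANOVA), `df1`, `df2`, `p`.
#' @examples
#' one_way_anova(list(c(194, 266, 207), c(416, 489, 420)))
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  tab <- stats::anova(stats::lm(y ~ g))
  list(
    F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
    p = tab$`Pr(>F)`[1],
    group_means = vapply(groups, mean, numeric(1))
  )
}

#' @rdname one_way_anova
#' @export
levene_mean_centered <- function(groups) {
  check_groups(groups)
  dev <- lapply(groups, function(x) abs(x - mean(x)))
  res <- one_way_anova(dev)
  list(W = res$F, df1 = res$df1, df2 = res$df2, p = res$p)
}

check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 observations")
  invisible(TRUE)
}
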
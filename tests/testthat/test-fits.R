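test_that("base-2 exponential fit is exact on noise-free input", {
  t <- 0:10
  fit <- fit_base2_exponential(t, 3 * 2^(0.4 * t))
  expect_equal(fit$C, 3, tolerance = 1e-9)
  expect_equal(fit$omega, 0.4, tolerance = 1e-9)
  expect_equal(fit$R2, 1, tolerance = 1e-9)

  flat <- fit_base2_exponential(t, rep(5, 11))
  expect_equal(flat$omega, 0, tolerance = 1e-12)

  expect_error(fit_base2_exponential(t, c(rep(2, 10), 0)), "positive")
})

test_that("base-2 fit recovers the rate from Poisson-noised counts", {
  set.seed(11)
  t <- seq(0, 15, by = 0.3)
  est <- replicate(50, {
    y <- rpois(length(t), 4 * 2^(0.48 * t))
    keep <- y > 0
    fit_base2_exponential(t[keep], y[keep])$omega
  })
  # the log-linearised estimator carries a small (~1%) transformation
  # bias from low early counts; require recovery to 2% of the rate
  expect_lt(abs(mean(est) - 0.48), 0.02 * 0.48)
  expect_lt(sd(est), 0.03)
})

test_that("shifted-exponential CDF fit recovers the branching law", {
  x <- generate_fixture("branching_samples", n = 1e4, seed = 5)
  fit <- fit_shifted_exponential_cdf(x)
  # the latency onset is located near the modal bin, and the memoryless
  # tail makes the rate estimate insensitive to the exact shift
  expect_lt(abs(fit$L0_maxslope - 180), 30)
  expect_lt(abs(fit$alpha_rate - 10.4e-3), 0.5e-3)

  # noise-free quantile sample: near-perfect linearised fit
  p <- (1:500 - 0.5) / 500
  exact <- 180 + qexp(p, rate = 10.4e-3 * log(2))
  fit2 <- fit_shifted_exponential_cdf(exact, L0 = 180)
  expect_gt(fit2$R2, 0.999)
  expect_lt(abs(fit2$alpha_rate - 10.4e-3), 2e-4)
})

test_that("experiment-sized samples give rates within the printed spread", {
  set.seed(21)
  hits <- replicate(200, {
    x <- 180 + rexp(109, rate = 10.4e-3 * log(2))
    fit <- tryCatch(fit_shifted_exponential_cdf(x), error = function(e) NULL)
    if (is.null(fit)) return(NA)
    abs(fit$alpha_rate - 10.4e-3) <= 3.9e-3
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("mixture fit separates burst and uniform populations", {
  # pure exponential: no flat component
  x <- generate_fixture("mixture_samples", n = 1e4, uniform_fraction = 0,
                        seed = 3)
  fit <- fit_mixture_exponential_uniform(x)
  expect_lt(fit$uniform_fraction, 0.05)

  # pure uniform: step 1 fails, everything attributed to the flat law
  x <- generate_fixture("mixture_samples", n = 1e4, uniform_fraction = 1,
                        seed = 3)
  fit <- fit_mixture_exponential_uniform(x)
  expect_true(fit$step1_failed)
  expect_gt(fit$uniform_fraction, 0.9)

  # the measured 78/22 mixture at n = 1e4
  x <- generate_fixture("mixture_samples", n = 1e4, seed = 7)
  fit <- fit_mixture_exponential_uniform(x)
  expect_lt(abs(fit$gamma1 - 2.3e-3), 2.5e-4)
  expect_lt(abs(fit$uniform_fraction - 0.22), 0.05)
})

test_that("density model closed forms", {
  expect_equal(t_min(0.59, 2), 2 / (0.59 * log(2)), tolerance = 1e-12)
  expect_equal(t_min(0.59, 2), 4.89, tolerance = 1e-2)
  expect_equal(t_min(mean(c(0.48, 0.46, 0.49)), 2), 6.05, tolerance = 1e-2)
  expect_equal(t_min(0.4, 4), 2 * t_min(0.4, 2), tolerance = 1e-12)
  dm <- density_model(C = 4.5, omega = 0.59, B1 = 0.1, B2 = 0.1)
  expect_equal(dm$D, 450, tolerance = 1e-9)
  expect_equal(dm$t_min, t_min(0.59, 2))
})

test_that("isolated-branch half-length", {
  expect_equal(isolated_halflength(6e-3), 83.33, tolerance = 1e-3)
  expect_equal(signif(isolated_halflength(6e-3), 1), 80)
  expect_equal(isolated_halflength(0.5), 1)
  expect_equal(isolated_halflength(3e-3), 2 * isolated_halflength(6e-3))
})

test_that("early power-law fit and its nested-model property", {
  t <- seq(0.5, 10, by = 0.25)
  rho <- 300 * t^-2
  fit <- fit_early_power(t, rho, t_min = 6)
  expect_equal(fit$alpha_early, 2, tolerance = 1e-9)
  expect_equal(fit$beta, 300, tolerance = 1e-6)
  expect_equal(fit$R2, 1, tolerance = 1e-9)

  # density model curve: exponential factor flattens the early decay
  rho2 <- 300 * 2^(0.5 * t) / t^2
  fit2 <- fit_early_power(t, rho2, t_min = t_min(0.5, 2))
  expect_lt(fit2$alpha_early, 2)
  expect_gt(fit2$alpha_early, 1)

  # fixing alpha at 2 can never beat the free fit
  set.seed(31)
  for (rep in 1:10) {
    noisy <- rho2 * exp(rnorm(length(t), 0, 0.2))
    free <- fit_early_power(t, noisy, t_min = 6)
    fixed <- fit_early_power(t, noisy, t_min = 6, fix_alpha = TRUE)
    expect_gte(free$R2, fixed$R2)
  }
})

test_that("binomial orientation test matches full enumeration", {
  # independent oracle: two-sided exact p as the sum of outcome
  # probabilities no larger than the observed one
  enum_p <- function(k, n, p0 = 0.5) {
    d <- dbinom(0:n, n, p0)
    sum(d[d <= dbinom(k, n, p0) * (1 + 1e-7)])
  }
  expect_equal(binomial_orientation_test(99, 198)$p_raw, 1, tolerance = 1e-9)
  bt <- binomial_orientation_test(107, 198)
  expect_equal(bt$p_raw, enum_p(107, 198), tolerance = 1e-9)
  expect_gt(bt$p_raw, 0.27); expect_lt(bt$p_raw, 0.29)
  expect_lt(binomial_orientation_test(163, 198)$p_raw, 1e-5)
  # Bonferroni adjustment
  expect_equal(binomial_orientation_test(107, 198, m_comparisons = 3)$p_adjusted,
               3 * bt$p_raw, tolerance = 1e-9)
  expect_equal(binomial_orientation_test(99, 198, m_comparisons = 4)$p_adjusted, 1)
})

test_that("ANOVA and Levene agree with explicit-sum oracles", {
  groups <- list(c(194, 266, 207), c(416, 489, 420))
  res <- one_way_anova(groups)
  # brute-force decomposition
  y <- unlist(groups); gm <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(res$F, f_oracle, tolerance = 1e-9)
  expect_equal(res$p, pf(f_oracle, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(res$group_means), c(222.3333, 441.6667), tolerance = 1e-4)

  lev <- levene_mean_centered(groups)
  dev <- lapply(groups, function(g) abs(g - mean(g)))
  yd <- unlist(dev); gmd <- mean(yd)
  md <- vapply(dev, mean, numeric(1))
  ssb_d <- sum(lengths(dev) * (md - gmd)^2)
  ssw_d <- sum(unlist(lapply(dev, function(g) (g - mean(g))^2)))
  expect_equal(lev$W, (ssb_d / 1) / (ssw_d / 4), tolerance = 1e-9)

  ident <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)
})

test_that("mean-centred Levene matches car::leveneTest with mean centring", {
  skip_if_not_installed("car")
  groups <- list(c(194, 266, 207), c(416, 489, 420))
  y <- unlist(groups)
  g <- factor(rep(1:2, each = 3))
  ref <- car::leveneTest(y, g, center = mean)
  lev <- levene_mean_centered(groups)
  expect_equal(lev$W, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(lev$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
})
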
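test_that("closed-form expected divergence matches matrix-power enumeration", {
  rates <- c(1e-5, 1e-3, 0.05, 0.2, 0.4)
  grid <- expand.grid(alpha = rates, beta = rates,
                      p0 = c(0.1, 0.5, 0.9))
  grid <- grid[grid$alpha + grid$beta < 1, ]
  for (r in seq_len(nrow(grid))) {
    a <- grid$alpha[r]; b <- grid$beta[r]; p0 <- grid$p0[r]
    for (t in 0:6) {
      expect_lt(abs(expected_divergence(a, b, p0, t, t) -
                      brute_force_divergence(a, b, p0, t, t)), 1e-12)
    }
    # asymmetric times and internal ancestors
    expect_lt(abs(expected_divergence(a, b, p0, 2, 5, t_anc = 3) -
                    brute_force_divergence(a, b, p0, 2, 5, t_anc = 3)), 1e-12)
  }
})

test_that("expected divergence limits and monotonicity", {
  expect_equal(expected_divergence(0.1, 0.2, 0.3, 0, 0), 0)
  # independence limit at equilibrium start: 2 pi (1 - pi)
  pi_ <- 0.1 / 0.3
  expect_equal(expected_divergence(0.1, 0.2, pi_, 1e6, 1e6),
               2 * pi_ * (1 - pi_), tolerance = 1e-10)
  expect_equal(expected_divergence(0.25, 0.25, 0.5, 1e6, 1e6), 0.5)
  # monotone non-decreasing in t at p0 = pi, bounded by 2 pi (1 - pi)
  d <- expected_divergence(1.6e-5, 8.5e-5, 1.6e-5 / 10.1e-5,
                           0:50 * 100, 0:50 * 100)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d <= 2 * pi_ * (1 - pi_) + 1e-12))
  expect_error(expected_divergence(0, 0, 0.5, 1, 1), "alpha \\+ beta")
})

test_that("noiseless closed-form points are inverted to the generating rates", {
  truth <- list(alpha = 3e-4, beta = 1.2e-3, p0 = 0.4, D0 = 0.004)
  tpts <- expand.grid(t_i = c(0, 125, 500, 1000), t_j = c(0, 125, 500, 1000))
  pts <- data.frame(t_i = tpts$t_i, t_j = tpts$t_j, t_anc = 0)
  pts$delta_t <- pts$t_i + pts$t_j
  pts$d <- truth$D0 + expected_divergence(truth$alpha, truth$beta, truth$p0,
                                          pts$t_i, pts$t_j)
  fit <- fit_neutral(pts, n_starts = 60L, seed = 5L)
  expect_lt(abs(fit$alpha - truth$alpha) / truth$alpha, 1e-3)
  expect_lt(abs(fit$beta - truth$beta) / truth$beta, 1e-3)
  expect_lt(abs(fit$p0 - truth$p0), 1e-3)
  expect_lt(abs(fit$D0 - truth$D0), 1e-4)
})

test_that("constant divergence pins rates to the boundary and favours the null", {
  tpts <- expand.grid(t_i = c(0, 125, 500, 1000), t_j = c(0, 125, 500, 1000))
  pts <- data.frame(t_i = tpts$t_i, t_j = tpts$t_j, t_anc = 0,
                    delta_t = tpts$t_i + tpts$t_j, d = 0.02)
  expect_warning(fit <- fit_neutral(pts, n_starts = 30L, seed = 2L),
                 "boundary")
  nul <- fit_null(pts)
  cmp <- compare_models(nul, fit)
  expect_gt(cmp$p_value, 0.9)
})

test_that("model comparison follows the F formula and rejects misuse", {
  f0 <- structure(list(rss = 2.0, n = 50L, k = 1L, model = "null"),
                  class = "epimutation_fit")
  f1 <- structure(list(rss = 1.0, n = 50L, k = 4L, model = "neutral"),
                  class = "epimutation_fit")
  cmp <- compare_models(f0, f1)
  expect_equal(cmp$statistic, ((2 - 1) / 3) / (1 / 46))
  expect_equal(cmp$p_value, pf(cmp$statistic, 3, 46, lower.tail = FALSE))
  # equal RSS: F = 0, p = 1
  f1b <- f1; f1b$rss <- 2.0
  cmp0 <- compare_models(f0, f1b)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)
  expect_error(compare_models(f1, f0), "nested")
  f2 <- f1; f2$n <- 49L
  expect_error(compare_models(f0, f2), "different numbers")
})

test_that("logistic fit beats the null on saturating data and errors when under-determined", {
  set.seed(16)
  dt <- rep(c(0, 125, 250, 500, 1000, 2000), each = 4)
  d <- 0.05 / (1 + exp(-0.01 * (dt - 300))) + rnorm(length(dt), 0, 1e-3)
  pts <- data.frame(t_i = dt / 2, t_j = dt / 2, delta_t = dt, d = d)
  lf <- fit_logistic(pts, n_starts = 40L, seed = 3L)
  nul <- fit_null(pts)
  expect_lt(lf$rss, nul$rss)
  cmp <- compare_models(nul, lf)
  expect_lt(cmp$p_value, 1e-6)
  expect_error(fit_logistic(pts[1:2, ]), "under-determined")
})

test_that("cluster bootstrap produces sane intervals", {
  # noiseless data: interval collapses onto the point estimate
  truth <- list(alpha = 3e-4, beta = 1.2e-3, p0 = 0.4, D0 = 0.002)
  lines <- paste0("L", 1:5)
  combos <- expand.grid(i = seq_along(lines), j = seq_along(lines))
  combos <- combos[combos$i < combos$j, ]
  tvals <- c(125, 500, 1000, 250, 750)
  pts <- data.frame(
    line_i = lines[combos$i], line_j = lines[combos$j],
    t_i = tvals[combos$i], t_j = tvals[combos$j], t_anc = 0)
  anc <- data.frame(line_i = "ancestor", line_j = lines,
                    t_i = 0, t_j = tvals, t_anc = 0)
  pts <- rbind(pts, anc)
  pts$delta_t <- pts$t_i + pts$t_j
  pts$d <- truth$D0 + expected_divergence(truth$alpha, truth$beta,
                                          truth$p0, pts$t_i, pts$t_j)
  fit <- fit_neutral(pts, n_starts = 40L, seed = 6L)
  bs <- bootstrap_rates(fit, n_boot = 20L, seed = 7L, n_starts = 3L)
  expect_lt(bs$ci["alpha", "upper"] / bs$ci["alpha", "lower"], 1.2)
  expect_true(bs$ci["alpha", "lower"] <= fit$alpha * 1.05 &&
                bs$ci["alpha", "upper"] >= fit$alpha * 0.95)
  # n_boot = 1 degenerates to a single refit
  bs1 <- bootstrap_rates(fit, n_boot = 2L, seed = 8L, n_starts = 2L)
  expect_equal(nrow(bs1$boot), bs1$n_boot_ok)
  # too few lines
  few <- pts[pts$line_i %in% c("ancestor", "L1", "L2") &
               pts$line_j %in% c("L1", "L2"), ]
  fitf <- structure(list(model = "neutral", points = few),
                    class = "epimutation_fit")
  expect_error(bootstrap_rates(fitf, n_boot = 2L), ">= 4 MA lines")
})

test_that("equilibrium fractions reproduce the published table arithmetic", {
  pub <- published_rate_estimates()
  ss <- pub[pub$site_class == "single_site", ]
  eq <- setNames(vapply(seq_len(nrow(ss)), function(i)
    equilibrium_fraction(ss$alpha[i], ss$beta[i])$percent, numeric(1)),
    ss$context)
  expect_equal(eq[["CG"]], 16)
  expect_equal(eq[["CHG"]], 16)
  expect_equal(eq[["CHH"]], 23)
  expect_equal(equilibrium_fraction(2e-5, 2e-5)$fraction, 0.5)
  expect_error(equilibrium_fraction(0, 0), "undefined")
})

test_that("rate ratios reproduce the published table arithmetic", {
  pub <- published_rate_estimates()
  chh_ss <- pub[pub$context == "CHH" & pub$site_class == "single_site", ]
  chh_dmr <- pub[pub$context == "CHH" & pub$site_class == "dmr_bin", ]
  expect_equal(rate_ratio(chh_ss$alpha, chh_ss$beta), 3.31)
  expect_equal(rate_ratio(chh_dmr$alpha, chh_dmr$beta), 2.39)
  expect_equal(rate_ratio(2e-5, 2e-5), 1.00)
  expect_error(rate_ratio(0, 1e-5), "alpha")
})
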
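test_that("closed-form multi-mitosis transition equals the looped chain", {
  grid <- expand.grid(alpha = c(1e-5, 1e-3, 0.05, 0.4),
                      beta = c(1e-5, 1e-2, 0.2, 0.4))
  for (r in seq_len(nrow(grid))) {
    a <- grid$alpha[r]; b <- grid$beta[r]
    for (t in 0:6) {
      P <- brute_force_transition(a, b, t)
      expect_lt(abs(transition_prob(a, b, t, from = 0) - P["u", "m"]), 1e-12)
      expect_lt(abs(transition_prob(a, b, t, from = 1) - P["m", "m"]), 1e-12)
    }
  }
})

test_that("degenerate chains behave as expected", {
  # no process: child identical to root in expectation and realisation
  sim <- small_recovery_sim(seed = 3L, n_sites = 400L, alpha = 0, beta = 0,
                            tau = 0)
  out <- simulate_pedigree(sim$cfg)
  root <- out$truth$latent[, "P1_root"]
  for (id in colnames(out$truth$latent))
    expect_equal(out$truth$latent[, id], root)

  # alpha = beta = 0.5: child independent of parent, divergence 0.5
  expect_equal(transition_prob(0.5, 0.5, 1, from = 0), 0.5)
  expect_equal(transition_prob(0.5, 0.5, 5, from = 1), 0.5)
})

test_that("brute-force edge evolution matches closed form statistically", {
  lay <- tiny_layout()
  ped <- pedigree(data.frame(
    sample_id = c("r", "s"), line_id = c("ancestor", "L1"),
    transfer = c(0L, 1L), parent_id = c(NA, "r"),
    sampled = c(TRUE, TRUE)))
  sites <- synthesize_sites(
    lay, counts = data.frame(domain = "centromere", context = "CG",
                             n = 20000L), seed = 5L)
  rates <- data.frame(domain = "centromere", context = "CG",
                      alpha = 0.02, beta = 0.05, tau = 0, p0 = 0.3)
  cfg <- sim_config(layout = lay, pedigree = ped, sites = sites,
                    rates = rates, seed = 21L)
  out_cf <- simulate_pedigree(cfg)
  out_bf <- simulate_pedigree(cfg, brute_force = TRUE)
  # 25 mitoses from p0 = 0.3: expected methylated fraction
  p_expect <- 0.3 * transition_prob(0.02, 0.05, 25, 1) +
    0.7 * transition_prob(0.02, 0.05, 25, 0)
  se <- sqrt(p_expect * (1 - p_expect) / 20000)
  expect_lt(abs(mean(out_cf$truth$latent[, "s"]) - p_expect), 4 * se)
  expect_lt(abs(mean(out_bf$truth$latent[, "s"]) - p_expect), 4 * se)
})

test_that("centromeric CG divergence at 2000 mitoses matches the closed form", {
  # two lines 2000 mitoses apart at the published CG rates, equilibrium start
  pub <- published_rate_estimates()
  pub <- pub[pub$context == "CG" & pub$site_class == "single_site", ]
  lay <- synthetic_layout()
  ped <- ma_pedigree(n_lines = 2L, transfers = 40L, n_pedigrees = 1L,
                     ancestor_replicates = 0L)
  sites <- synthesize_sites(
    lay, counts = data.frame(domain = "centromere", context = "CG",
                             n = 50000L), seed = 8L)
  p0 <- pub$alpha / (pub$alpha + pub$beta)
  rates <- data.frame(domain = "centromere", context = "CG",
                      alpha = pub$alpha, beta = pub$beta, tau = 0, p0 = p0)
  cfg <- sim_config(layout = lay, pedigree = ped, sites = sites,
                    rates = rates, seed = 13L)
  out <- simulate_pedigree(cfg)
  d_latent <- mean(out$truth$latent[, "L1_t40"] != out$truth$latent[, "L2_t40"])
  D <- expected_divergence(pub$alpha, pub$beta, p0, 1000, 1000)
  se <- sqrt(D * (1 - D) / 50000)
  expect_lt(abs(d_latent - D), 4 * se)
})

test_that("stationarity holds at every node when starting at equilibrium", {
  sim <- small_recovery_sim(seed = 9L, n_sites = 30000L,
                            alpha = 2e-4, beta = 8e-4, tau = 0)
  out <- simulate_pedigree(sim$cfg)
  pi_ <- 2e-4 / (2e-4 + 8e-4)
  se <- sqrt(pi_ * (1 - pi_) / 30000)
  for (id in colnames(out$truth$latent))
    expect_lt(abs(mean(out$truth$latent[, id]) - pi_), 3 * se)
})

test_that("counts conserve depth and respect meth <= total", {
  sim <- small_recovery_sim(seed = 2L, n_sites = 500L)
  out <- simulate_pedigree(sim$cfg)
  expect_true(all(out$mset$meth <= out$mset$total))
  expect_true(all(out$mset$meth >= 0))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(rates = data.frame(
    domain = "centromere", context = "CG", alpha = 0.6, beta = 0.5,
    tau = 0, p0 = 0.5)), "alpha \\+ beta")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  cfg <- sim_config(seed = 1L)
  cfg$pedigree <- cfg$pedigree[0, ]
  expect_error(simulate_pedigree(cfg), "empty pedigree")
})

test_that("stable ChIP simulation keeps per-bin means identical across samples", {
  lay <- tiny_layout()
  ped <- ma_pedigree(n_lines = 3L, transfers = c(5L, 20L), n_pedigrees = 1L,
                     ancestor_replicates = 1L)
  cfg <- sim_config(layout = lay, pedigree = ped, chip_drift_sd = 0,
                    seed = 4L)
  chip <- simulate_chip_bins(cfg)
  expect_true(all(apply(chip$truth_means, 1, function(z)
    max(z) - min(z) < 1e-12)))
  # normalized-count divergence shrinks as counts grow (sampling noise only)
  cfg_big <- sim_config(layout = lay, pedigree = ped, chip_drift_sd = 0,
                        chip_mean_enriched = 2e4,
                        chip_mean_background = 2e3, seed = 4L)
  chip_big <- simulate_chip_bins(cfg_big)
  d_small <- count_divergence(normalize_counts(chip$counts)[, 1],
                              normalize_counts(chip$counts)[, 2])
  d_big <- count_divergence(normalize_counts(chip_big$counts)[, 1],
                            normalize_counts(chip_big$counts)[, 2])
  expect_lt(d_big / mean(normalize_counts(chip_big$counts)),
            d_small / mean(normalize_counts(chip$counts)))
})

test_that("drift-mode ChIP divergence increases with separation time", {
  lay <- tiny_layout()
  ped <- ma_pedigree(n_lines = 4L, transfers = c(5L, 20L, 40L),
                     n_pedigrees = 1L, ancestor_replicates = 2L)
  cfg <- sim_config(layout = lay, pedigree = ped, chip_drift_sd = 0.05,
                    seed = 6L)
  chip <- simulate_chip_bins(cfg)
  pts <- count_divergence_points(chip$counts, ped)
  fitl <- stats::lm(d ~ delta_t, data = pts)
  expect_gt(coef(fitl)[["delta_t"]], 0)
})

test_that("peak dropout creates presence/absence divergence of the right size", {
  lay <- tiny_layout()
  ped <- ma_pedigree(n_lines = 2L, transfers = 40L, n_pedigrees = 1L,
                     ancestor_replicates = 0L)
  cfg <- sim_config(layout = lay, pedigree = ped, seed = 14L)
  chip <- simulate_chip_bins(cfg, peak_dropout = 0)
  # concordant peak sets: divergence 0 for every pair
  pm <- build_peak_matrix(chip$peaks)
  pts <- peak_divergence(pm, ped, variable_only = FALSE)
  expect_true(all(pts$d == 0))
})

test_that("mutation counts are Poisson with the configured mean", {
  lay <- tiny_layout()
  ped <- ma_pedigree(n_lines = 30L, transfers = 40L, n_pedigrees = 1L,
                     ancestor_replicates = 0L)
  # expected 33 mutations per line over 1000 mitoses
  cfg <- sim_config(layout = lay, pedigree = ped, mutation_rate = 33 / 1000,
                    seed = 10L)
  mut <- simulate_mutations(cfg)
  per_line <- tapply(mut$counts$n_mutations, mut$counts$line_id, sum)
  se <- sqrt(33 / 30)
  expect_lt(abs(mean(per_line) - 33), 4 * se)

  cfg0 <- sim_config(layout = lay, pedigree = ped, mutation_rate = 0,
                     seed = 10L)
  expect_true(all(simulate_mutations(cfg0)$counts$n_mutations == 0))
})

test_that("methylation changes occur in intervals without mutations", {
  # joint property: with transient noise and zero mutation rate, intervals
  # with zero mutations still show state changes
  sim <- small_recovery_sim(seed = 12L, n_sites = 2000L, n_lines = 4L,
                            tau = 0.01)
  sim$cfg$mutation_rate <- 0.002  # rare: most intervals mutation-free
  out <- simulate_pedigree(sim$cfg)
  mset <- call_methylation_states(out$mset)
  ch <- interval_change_counts(mset, sim$pedigree, domain_split = "none")
  mut <- simulate_mutations(sim$cfg)
  key <- function(df) paste(df$line_id, df$from_transfer, df$to_transfer)
  m <- mut$counts$n_mutations[match(key(ch), key(mut$counts))]
  expect_true(any(m == 0))
  expect_true(all(ch$n_changes[m == 0] > 0))
})
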
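test_that("state divergence handles toys, masking and degenerate input", {
  expect_equal(state_divergence(c(1, 0, 1, 0), c(1, 0, 1, 0))$d, 0)
  expect_equal(state_divergence(c(1, 0, 1, 0), c(1, 1, 0, 0))$d, 0.5)
  sd_ <- state_divergence(c(1, NA, 0), c(0, 1, 0))
  expect_equal(sd_$d, 0.5)
  expect_equal(sd_$n, 2L)
  expect_warning(out <- state_divergence(c(NA, NA), c(1, 0)), "undefined")
  expect_true(is.na(out$d))
  expect_error(state_divergence(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("state divergence is a normalized Hamming distance", {
  set.seed(7)
  for (r in 1:20) {
    n <- sample(5:50, 1)
    a <- sample(c(0L, 1L, NA), n, replace = TRUE)
    b <- sample(c(0L, 1L, NA), n, replace = TRUE)
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    d_ab <- state_divergence(a, b)$d
    expect_equal(d_ab, state_divergence(b, a)$d)     # symmetry
    expect_gte(d_ab, 0); expect_lte(d_ab, 1)          # bounds
    expect_equal(d_ab, sum(a[ok] != b[ok]) / sum(ok)) # direct loop
    expect_equal(state_divergence(a, a)$d, 0)         # identity
  }
})

test_that("count divergence equals the elementwise L1 mean and is a metric", {
  expect_equal(count_divergence(c(1, 2), c(3, 2)), 1.0)
  expect_equal(count_divergence(1:5, 1:5), 0)
  expect_error(count_divergence(1:3, 1:4), "equal length")
  set.seed(8)
  for (r in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    brute <- 0
    for (i in seq_len(n)) brute <- brute + abs(x[i] - y[i])
    expect_equal(count_divergence(x, y), brute / n)
    expect_equal(count_divergence(x, y), count_divergence(y, x))
    expect_lte(count_divergence(x, z),
               count_divergence(x, y) + count_divergence(y, z) + 1e-12)
  }
})

test_that("pairwise divergence matrix agrees with per-pair computation", {
  set.seed(9)
  states <- matrix(sample(c(0L, 1L, NA), 200, replace = TRUE,
                          prob = c(.45, .45, .1)), 50, 4)
  dm <- divergence_matrix(states)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    expect_equal(dm[i, j], state_divergence(states[, i], states[, j])$d)
  }
})

test_that("assembled divergence points carry pedigree delta_t", {
  ped <- ma_pedigree(n_lines = 2L, transfers = c(5L, 20L), n_pedigrees = 1L,
                     ancestor_replicates = 2L)
  set.seed(10)
  n <- 60L
  ids <- ped$sample_id[ped$sampled]
  states <- matrix(sample(c(0L, 1L), n * length(ids), replace = TRUE),
                   n, length(ids))
  sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L, strand = "+",
                      context = "CG", domain = "centromere")
  mset <- methylome_set(sites, states * 10L, matrix(10L, n, length(ids)),
                        data.frame(sample_id = ids,
                                   line_id = ped$line_id[ped$sampled],
                                   transfer = ped$transfer[ped$sampled]),
                        state = states)
  pts <- assemble_divergence(mset, ped)
  # same line transfers 5 and 20: 375; different lines at 20: 1000
  expect_equal(pts$delta_t[pts$sample_i == "L1_t5" &
                             pts$sample_j == "L1_t20"], 375)
  expect_equal(pts$delta_t[pts$sample_i == "L1_t20" &
                             pts$sample_j == "L2_t20"], 1000)
  # ancestor replicate pair at delta 0
  expect_true(0 %in% pts$delta_t)
  pts_nz <- assemble_divergence(mset, ped, include_zero_dt = FALSE)
  expect_false(0 %in% pts_nz$delta_t)
  # unknown sample is an error
  mset2 <- mset; mset2$samples$sample_id[1] <- "ghost"
  colnames(mset2$state) <- mset2$samples$sample_id
  expect_error(assemble_divergence(mset2, ped), "absent from pedigree")
})

test_that("interval changes count flips and reversions per interval", {
  ped <- pedigree(data.frame(
    sample_id = c("r", "t5", "t7", "t8"), line_id = c("ancestor", rep("L1", 3)),
    transfer = c(0L, 5L, 7L, 8L), parent_id = c(NA, "r", "t5", "t7"),
    sampled = c(FALSE, TRUE, TRUE, TRUE)))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                      context = "CG", domain = "centromere")
  st <- cbind(t5 = c(1L, 0L), t7 = c(0L, 0L), t8 = c(1L, 0L))
  mset <- methylome_set(sites, st * 10L, matrix(10L, 2, 3),
                        data.frame(sample_id = colnames(st), line_id = "L1",
                                   transfer = c(5L, 7L, 8L)), state = st)
  ch <- interval_change_counts(mset, ped, domain_split = "none")
  # site 1 flips 1->0 in 5-7 and back 0->1 in 7-8: both intervals count 1
  expect_equal(ch$n_changes[ch$from_transfer == 5], 1L)
  expect_equal(ch$n_changes[ch$from_transfer == 7], 1L)

  # identical consecutive methylomes: zero changes
  st0 <- cbind(t5 = c(1L, 0L), t7 = c(1L, 0L), t8 = c(1L, 0L))
  mset0 <- methylome_set(sites, st0 * 10L, matrix(10L, 2, 3),
                         mset$samples, state = st0)
  expect_true(all(interval_change_counts(mset0, ped,
                                         domain_split = "none")$n_changes == 0L))
})

test_that("mutation association test behaves at the extremes", {
  set.seed(12)
  mk <- function(changes, muts) {
    ch <- data.frame(line_id = "L1", from_transfer = seq_along(changes),
                     to_transfer = seq_along(changes) + 1L,
                     domain = "all", n_changes = changes,
                     n_compared = 100L)
    mu <- data.frame(line_id = "L1", from_transfer = seq_along(changes),
                     to_transfer = seq_along(changes) + 1L,
                     n_mutations = muts)
    list(ch = ch, mu = mu)
  }
  # perfect coupling: changes = 10 x mutations
  muts <- c(0L, 2L, 0L, 3L, 0L, 1L, 0L, 4L, 0L, 2L)
  x <- mk(10L * muts, muts)
  res <- mutation_association_test(x$ch, x$mu, n_perm = 2000L, seed = 1L)
  expect_lt(res$p_value, 0.01)
  # zero changes everywhere: statistic 0, p = 1
  x0 <- mk(rep(0L, 10), muts)
  res0 <- mutation_association_test(x0$ch, x0$mu, n_perm = 500L, seed = 1L)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # one-group degenerate case warns
  x1 <- mk(rep(1L, 10), rep(1L, 10))
  expect_warning(r1 <- mutation_association_test(x1$ch, x1$mu,
                                                 n_perm = 100L, seed = 1L),
                 "one mutation group")
  expect_true(is.na(r1$p_value))
})

test_that("mutation association test is calibrated under the null", {
  set.seed(13)
  pv <- replicate(200, {
    changes <- rpois(12, 20)
    muts <- rpois(12, 1)
    if (all(muts > 0) || all(muts == 0)) return(NA_real_)
    ch <- data.frame(line_id = "L1", from_transfer = 1:12,
                     to_transfer = 2:13, domain = "all",
                     n_changes = changes, n_compared = 100L)
    mu <- data.frame(line_id = "L1", from_transfer = 1:12,
                     to_transfer = 2:13, n_mutations = muts)
    mutation_association_test(ch, mu, n_perm = 200L,
                              seed = sample.int(1e6, 1))$p_value
  })
  pv <- pv[!is.na(pv)]
  rate <- mean(pv < 0.05)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / length(pv)))
})

test_that("peak matrices merge overlaps and drive Eq.-style divergence", {
  ped <- two_line_pedigree()
  # two half-overlapping peaks in different samples merge into one union
  # peak present in both -> concordant
  peaks <- list(
    anc1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)),
    anc2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)),
    a = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500),
                                                        c(100, 600))),
    b = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)))
  pm <- build_peak_matrix(peaks)
  expect_equal(length(pm$peaks), 2L)
  pts <- peak_divergence(pm, ped)
  # one variable peak (chr1:500-600, private to a)
  expect_equal(unique(pts$n), 1L)
  d_ab <- pts$d[pts$sample_i == "a" & pts$sample_j == "b"]
  expect_equal(d_ab, 1)
  d_anc <- pts$d[pts$sample_i == "anc1" & pts$sample_j == "anc2"]
  expect_equal(d_anc, 0)

  # identical peak sets: all divergences zero over all peaks
  same <- list(a = peaks$a, b = peaks$a)
  pm2 <- build_peak_matrix(same)
  pts2 <- peak_divergence(pm2, ped, variable_only = FALSE)
  expect_true(all(pts2$d == 0))

  # a private peak among many variable peaks contributes 1/n
  set.seed(14)
  starts <- seq(1000L, by = 500L, length.out = 270L)
  vp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts + 99L))
  pa <- sample(c(TRUE, FALSE), 270, replace = TRUE)
  private <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9e5, 9e5 + 99))
  sets <- list(a = c(vp[pa], private), b = vp[!pa])
  pm3 <- build_peak_matrix(sets)
  pts3 <- peak_divergence(pm3, ped[ped$sample_id %in% c("root", "a", "b"), ])
  expect_equal(pts3$n, 271L)

  expect_warning(empty <- build_peak_matrix(
    list(a = GenomicRanges::GRanges(), b = GenomicRanges::GRanges())),
    "no peaks")
  expect_equal(nrow(empty$presence), 0L)
})

test_that("trend test finds drift and stays quiet on flat clouds", {
  ped <- ma_pedigree(n_lines = 6L, transfers = c(5L, 20L, 40L),
                     n_pedigrees = 1L, ancestor_replicates = 2L)
  ids <- ped$sample_id[ped$sampled]
  # flat cloud: d constant
  pairs <- t(combn(ids, 2))
  flat <- data.frame(sample_i = pairs[, 1], sample_j = pairs[, 2])
  tt <- lapply(seq_len(nrow(flat)), function(i)
    pair_times(ped, flat$sample_i[i], flat$sample_j[i]))
  flat$delta_t <- vapply(tt, `[[`, numeric(1), "delta_t")
  flat$d <- 0.02
  res_flat <- divergence_trend_test(flat, n_perm = 500L, seed = 2L)
  expect_equal(res_flat$slope, 0)
  expect_gt(res_flat$p_value, 0.5)
  # increasing cloud
  inc <- flat
  set.seed(15)
  inc$d <- 0.01 + 1e-5 * inc$delta_t + rnorm(nrow(inc), 0, 1e-4)
  res_inc <- divergence_trend_test(inc, n_perm = 500L, seed = 2L)
  expect_gt(res_inc$slope, 0)
  expect_lt(res_inc$p_value, 0.05)
  # degenerate: constant delta_t
  con <- flat[flat$delta_t == 2000, ]
  expect_error(divergence_trend_test(con, n_perm = 10L), "constant")
})

test_that("DMR/H3K9me3 overlap fraction counts any-bp overlaps", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    seq(1000, 1900, by = 200), seq(1099, 1999, by = 200)))
  outside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    seq(5000, 5900, by = 200), seq(5099, 5999, by = 200)))
  expect_equal(dmr_h3k9_overlap(inside, regions)$fraction, 1.0)
  expect_equal(dmr_h3k9_overlap(outside, regions)$fraction, 0.0)
  half <- c(inside[1:5], outside[1:5])
  expect_equal(dmr_h3k9_overlap(half, regions)$fraction, 0.5)
  expect_warning(res <- dmr_h3k9_overlap(GenomicRanges::GRanges(), regions),
                 "empty DMR set")
  expect_true(is.na(res$fraction))
})
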
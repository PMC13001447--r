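# Shared fixtures, built in code at test time.

tiny_layout <- function() synthetic_layout(n_chrom = 1L, chrom_length = 2e5)

# A methylome set with hand-chosen counts; states optionally precalled.
toy_mset <- function(states = NULL) {
  sites <- data.frame(
    chrom = "chr1", pos = c(10L, 30L, 50L, 120L, 140L, 210L),
    strand = "+", context = c("CG", "CG", "CHH", "CG", "CHG", "CG"),
    domain = "euchromatin", stringsAsFactors = FALSE)
  meth <- cbind(a = c(9L, 8L, 0L, 0L, 1L, 9L),
                b = c(0L, 1L, 0L, 9L, 8L, 9L))
  total <- cbind(a = c(10L, 10L, 10L, 10L, 10L, 10L),
                 b = c(10L, 10L, 10L, 10L, 10L, 10L))
  samples <- data.frame(sample_id = c("a", "b"), line_id = c("L1", "L2"),
                        transfer = c(40L, 40L))
  methylome_set(sites, meth, total, samples, state = states)
}

two_line_pedigree <- function() {
  pedigree(data.frame(
    sample_id = c("root", "anc1", "anc2", "a", "b"),
    line_id = c("ancestor", "ancestor", "ancestor", "L1", "L2"),
    transfer = c(0L, 0L, 0L, 40L, 40L),
    parent_id = c(NA, "root", "root", "root", "root"),
    sampled = c(FALSE, TRUE, TRUE, TRUE, TRUE)))
}

# Small recovery-grade simulation shared by several tests.
small_recovery_sim <- function(seed = 1L, n_sites = 5000L, n_lines = 6L,
                               alpha = 1.62e-5, beta = 8.55e-5,
                               tau = 0.001) {
  lay <- synthetic_layout()
  ped <- ma_pedigree(n_lines = n_lines, transfers = c(5L, 20L, 40L),
                     n_pedigrees = 1L, ancestor_replicates = 3L)
  sites <- synthesize_sites(
    lay, counts = data.frame(domain = "centromere", context = "CG",
                             n = n_sites),
    seed = seed + 17L)
  p0 <- if (alpha + beta > 0) alpha / (alpha + beta) else 0.16
  rates <- data.frame(domain = "centromere", context = "CG",
                      alpha = alpha, beta = beta, tau = tau, p0 = p0)
  cfg <- sim_config(layout = lay, pedigree = ped, sites = sites,
                    rates = rates, seed = seed)
  list(cfg = cfg, layout = lay, pedigree = ped,
       truth = c(alpha = alpha, beta = beta))
}
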
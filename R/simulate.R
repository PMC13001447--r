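#' Default per-domain, per-context epimutation process parameters
#'
#' Heritable gain (`alpha`) and loss (`beta`) rates per site per mitosis are
#' nonzero only in centromeres, where they default to the published
#' centromeric single-site estimates for each sequence context; the
#' ancestral methylated fraction `p0` defaults to the implied equilibrium
#' alpha/(alpha+beta) there. Outside centromeres methylation changes are not
#' heritable: interspersed H3K9me3 regions start methylated at a moderate
#' level but carry zero heritable rates, and euchromatin/H3K27me3 are nearly
#' unmethylated with a higher transient (non-heritable, per-observation)
#' flip probability `tau`, reproducing transient euchromatic DMR formation.
#'
#' @return data.frame with columns domain, context, alpha, beta, tau, p0
#' @export
default_rates <- function() {
  pub <- published_rate_estimates()
  pub <- pub[pub$site_class == "single_site", ]
  cen <- data.frame(domain = "centromere", context = pub$context,
                    alpha = pub$alpha, beta = pub$beta, tau = 0.001,
                    p0 = pub$alpha / (pub$alpha + pub$beta))
  other <- expand.grid(domain = c("h3k9me3", "h3k27me3", "euchromatin"),
                       context = contexts, stringsAsFactors = FALSE)
  other$alpha <- 0; other$beta <- 0
  other$tau <- c(h3k9me3 = 0.001, h3k27me3 = 0.002,
                 euchromatin = 0.005)[other$domain]
  other$p0 <- c(h3k9me3 = 0.3, h3k27me3 = 0.02,
                euchromatin = 0.005)[other$domain]
  rbind(cen, other[, names(cen)])
}

#' Simulation configuration
#'
#' Collects everything the forward simulator needs: a genome layout, a site
#' table (or a recipe to make one), a pedigree, the per-domain/per-context
#' heritable and transient rates, the coverage model, bisulfite conversion
#' error rates, and the genetic mutation rate. All stochastic components are
#' governed by the single integer `seed`.
#'
#' @param layout a [genome_layout()]; default [synthetic_layout()]
#' @param pedigree a [pedigree()]; default [ma_pedigree()]
#' @param sites site table as from [synthesize_sites()], or `NULL` to
#'   synthesize one at `site_density`
#' @param site_density sites per bp when `sites` is `NULL`
#' @param rates data.frame with columns domain, context, alpha, beta, tau,
#'   p0 (rows may use context "all"); default [default_rates()]
#' @param mean_depth,depth_dispersion negative-binomial coverage model
#'   (mean reads per site and NB size parameter)
#' @param eps_fail probability an unmethylated cytosine escapes conversion
#'   and reads as methylated (bisulfite conversion failure)
#' @param eps_over probability a methylated cytosine reads as unmethylated
#'   (over-conversion)
#' @param mutation_rate genetic mutations per mitosis per line
#' @param chip_bin_size,chip_centromere_bin_size ChIP count bin widths (bp)
#' @param chip_mean_enriched,chip_mean_background mean ChIP fragment counts
#'   per genome-wide bin inside/outside H3K9me3-marked heterochromatin
#' @param chip_drift_sd per-transfer s.d. of log enrichment drift
#'   (0 = stable H3K9me3, the condition the data support)
#' @param seed master integer seed
#' @return an object of class `sim_config`
#' @export
sim_config <- function(layout = NULL, pedigree = NULL, sites = NULL,
                       site_density = 0.05, rates = NULL,
                       mean_depth = 20, depth_dispersion = 5,
                       eps_fail = 0.005, eps_over = 0.01,
                       mutation_rate = 33 / 1015,
                       chip_bin_size = 5000L,
                       chip_centromere_bin_size = 500L,
                       chip_mean_enriched = 200,
                       chip_mean_background = 20,
                       chip_drift_sd = 0,
                       seed = 1L) {
  layout <- layout %||% synthetic_layout()
  ped <- pedigree %||% ma_pedigree()
  rates <- rates %||% default_rates()
  stopifnot(all(c("domain", "context", "alpha", "beta", "tau", "p0") %in%
                  names(rates)))
  if (any(rates$alpha + rates$beta > 1))
    stopf("alpha + beta must be <= 1")
  if (any(rates$alpha < 0 | rates$beta < 0)) stopf("negative rates")
  assert_prob(rates$tau, "tau"); assert_prob(rates$p0, "p0")
  assert_prob(c(eps_fail, eps_over), "conversion error rates")
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  if (mutation_rate < 0) stopf("mutation_rate must be >= 0")
  structure(list(layout = layout, pedigree = ped, sites = sites,
                 site_density = site_density, rates = rates,
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 eps_fail = eps_fail, eps_over = eps_over,
                 mutation_rate = mutation_rate,
                 chip_bin_size = chip_bin_size,
                 chip_centromere_bin_size = chip_centromere_bin_size,
                 chip_mean_enriched = chip_mean_enriched,
                 chip_mean_background = chip_mean_background,
                 chip_drift_sd = chip_drift_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# per-site (alpha, beta, tau, p0) resolved from the rates table
resolve_rates <- function(rates, domain, context) {
  key <- paste(domain, context)
  rkey <- paste(rates$domain, rates$context)
  idx <- match(key, rkey)
  allkey <- paste(rates$domain, "all")
  idx2 <- match(paste(domain, "all"), allkey)
  idx[is.na(idx)] <- idx2[is.na(idx)]
  if (anyNA(idx))
    stopf("no rates for domain/context: %s",
          paste(unique(key[is.na(idx)]), collapse = ", "))
  rates[idx, c("alpha", "beta", "tau", "p0")]
}

#' Closed-form t-step transition probabilities of the two-state chain
#'
#' For the haploid gain/loss chain with per-mitosis gain rate `alpha`
#' (unmethylated -> methylated) and loss rate `beta`, the probability of
#' being methylated after `t` mitoses is
#' `pi + (s - pi) * c^t` with `pi = alpha/(alpha+beta)`, `c = 1-alpha-beta`,
#' and `s` the starting state (0 or 1). `t` may be real-valued via the
#' continuous extension of `c^t`.
#'
#' @param alpha,beta per-mitosis gain and loss rates (`alpha + beta <= 1`;
#'   at the boundary every mitosis redraws the state)
#' @param t number of mitoses (vectorised)
#' @param from starting state, 0 (unmethylated) or 1 (methylated)
#' @return probability of the methylated state after `t` mitoses
#' @export
transition_prob <- function(alpha, beta, t, from) {
  if (any(alpha < 0) || any(beta < 0) || any(alpha + beta > 1))
    stopf("need alpha, beta >= 0 and alpha + beta <= 1")
  s <- alpha + beta
  ifelse(s == 0, as.numeric(from),
         alpha / ifelse(s == 0, 1, s) +
           (from - alpha / ifelse(s == 0, 1, s)) * (1 - s)^t)
}

#' One-step transition matrix of the gain/loss chain
#' @inheritParams transition_prob
#' @return 2x2 matrix with rows = from (u, m), columns = to (u, m)
#' @export
transition_matrix <- function(alpha, beta) {
  matrix(c(1 - alpha, alpha, beta, 1 - beta), 2, 2, byrow = TRUE,
         dimnames = list(c("u", "m"), c("u", "m")))
}

#' Brute-force t-step transition matrix (repeated multiplication)
#'
#' Independent oracle for [transition_prob()]: multiplies the one-step
#' matrix `t` times.
#' @inheritParams transition_prob
#' @return 2x2 t-step transition matrix
#' @export
brute_force_transition <- function(alpha, beta, t) {
  P <- transition_matrix(alpha, beta)
  out <- diag(2)
  for (i in seq_len(t)) out <- out %*% P
  dimnames(out) <- dimnames(P)
  out
}

#' Forward-simulate methylomes along an MA pedigree
#'
#' Latent binary methylation states evolve independently per site along each
#' pedigree edge under the domain/context-specific two-state chain; the root
#' state is Bernoulli(`p0`). Multi-mitosis edges use the closed-form
#' transition by default (`brute_force = TRUE` loops single mitoses, for
#' oracle tests). Observed counts at each sampled node are drawn per site:
#' depth from a negative binomial, then the methylated read count from a
#' binomial whose success probability folds in the latent state, a
#' per-observation transient flip (probability `tau`), and the conversion
#' error rates.
#'
#' @param config a [sim_config()]
#' @param brute_force evolve edges one mitosis at a time (slow; oracle mode)
#' @return list with `mset` (a [methylome_set()] of counts for sampled
#'   nodes) and `truth` (latent state matrix for every pedigree node, the
#'   per-site rates, and the config)
#' @export
simulate_pedigree <- function(config, brute_force = FALSE) {
  stopifnot(is(config, "sim_config"))
  ped <- config$pedigree
  if (nrow(ped) == 0L) stopf("empty pedigree")
  with_seed(derive_seed(config$seed, 1L), {
    sites <- config$sites %||%
      synthesize_sites(config$layout, density = config$site_density,
                       seed = derive_seed(config$seed, 2L))
    if (is.null(sites$domain))
      sites$domain <- lookup_domain(config$layout, sites$chrom, sites$pos)
    n <- nrow(sites)
    rr <- resolve_rates(config$rates, sites$domain, sites$context)

    idx <- match(ped$parent_id, ped$sample_id)
    latent <- matrix(NA_integer_, n, nrow(ped),
                     dimnames = list(NULL, ped$sample_id))
    done <- rep(FALSE, nrow(ped))
    roots <- which(is.na(ped$parent_id))
    for (r in roots) {
      latent[, r] <- rbinom(n, 1L, rr$p0)
      done[r] <- TRUE
    }
    while (!all(done)) {
      ready <- which(!done & done[idx])
      for (k in ready) {
        t_edge <- ped$edge_mitoses[k]
        par <- latent[, idx[k]]
        if (brute_force) {
          st <- par
          for (m in seq_len(t_edge)) {
            p <- ifelse(st == 1L, 1 - rr$beta, rr$alpha)
            st <- rbinom(n, 1L, p)
          }
          latent[, k] <- st
        } else {
          p <- transition_prob(rr$alpha, rr$beta, t_edge, par)
          latent[, k] <- rbinom(n, 1L, p)
        }
        done[k] <- TRUE
      }
    }

    sampled <- which(ped$sampled)
    meth <- matrix(0L, n, length(sampled))
    total <- matrix(0L, n, length(sampled))
    for (j in seq_along(sampled)) {
      depth <- rnbinom(n, size = config$depth_dispersion,
                       mu = config$mean_depth)
      flip <- rbinom(n, 1L, rr$tau)
      s_obs <- ifelse(flip == 1L, 1L - latent[, sampled[j]],
                      latent[, sampled[j]])
      p_read <- ifelse(s_obs == 1L, 1 - config$eps_over, config$eps_fail)
      meth[, j] <- rbinom(n, depth, p_read)
      total[, j] <- depth
    }
    samples <- as.data.frame(ped)[sampled,
      c("sample_id", "line_id", "transfer", "pedigree_id")]
    rownames(samples) <- NULL
    mset <- methylome_set(sites, meth, total, samples)
    list(mset = mset,
         truth = list(latent = latent, rates = rr, sites = sites,
                      config = config))
  })
}

#' Simulate H3K9me3 ChIP read counts in genomic bins, plus per-sample peaks
#'
#' Per-bin expected counts are high in H3K9me3-marked heterochromatin
#' (centromeres and interspersed H3K9me3 blocks) and low elsewhere. In the
#' default stable mode the per-bin means are identical across samples and
#' only library size and Poisson sampling noise differ — the regime the MA
#' data support. With `chip_drift_sd > 0` the log-mean performs a random
#' walk along the pedigree (variance proportional to edge length in
#' transfers), giving a heritable-drift alternative for power analyses.
#' Peaks are contiguous runs of enriched bins; `peak_dropout` removes whole
#' peaks at random per sample to create presence/absence variation.
#'
#' @param config a [sim_config()]
#' @param centromeric use 500-bp bins restricted to centromeres instead of
#'   genome-wide bins
#' @param peak_dropout per-sample probability of losing each peak
#' @return list with `bins` (`GRanges`), `counts` (bins x samples),
#'   `peaks` (list of `GRanges` per sample), `samples`, `truth_means`
#' @export
simulate_chip_bins <- function(config, centromeric = FALSE,
                               peak_dropout = 0) {
  stopifnot(is(config, "sim_config"))
  if (config$chip_mean_background <= 0 || config$chip_mean_enriched <= 0)
    stopf("library/bin means must be positive")
  ped <- config$pedigree
  with_seed(derive_seed(config$seed, 3L), {
    dom <- config$layout$domains
    het <- dom[S4Vectors::mcols(dom)$domain %in% c("centromere", "h3k9me3")]
    if (centromeric) {
      cen <- dom[S4Vectors::mcols(dom)$domain == "centromere"]
      bins <- genome_bins(config$layout, config$chip_centromere_bin_size, cen)
    } else {
      bins <- genome_bins(config$layout, config$chip_bin_size)
    }
    enriched <- GenomicRanges::countOverlaps(bins, het) > 0
    scale <- GenomicRanges::width(bins) /
      (if (centromeric) config$chip_centromere_bin_size else config$chip_bin_size)
    base_mu <- ifelse(enriched, config$chip_mean_enriched,
                      config$chip_mean_background) * scale
    # bin-to-bin enrichment heterogeneity, shared by all samples
    base_mu <- base_mu * rlnorm(length(bins), 0, 0.2)

    idx <- match(ped$parent_id, ped$sample_id)
    mpt <- attr(ped, "mitoses_per_transfer")
    logmu <- matrix(NA_real_, length(bins), nrow(ped),
                    dimnames = list(NULL, ped$sample_id))
    done <- rep(FALSE, nrow(ped))
    for (r in which(is.na(ped$parent_id))) {
      logmu[, r] <- log(base_mu); done[r] <- TRUE
    }
    while (!all(done)) {
      ready <- which(!done & done[idx])
      for (k in ready) {
        dt_transfers <- ped$edge_mitoses[k] / mpt
        drift <- if (config$chip_drift_sd > 0 && dt_transfers > 0)
          rnorm(length(bins), 0, config$chip_drift_sd * sqrt(dt_transfers))
        else 0
        logmu[, k] <- logmu[, idx[k]] + drift
        done[k] <- TRUE
      }
    }

    sampled <- which(ped$sampled)
    counts <- matrix(0, length(bins), length(sampled),
                     dimnames = list(NULL, ped$sample_id[sampled]))
    peaks <- vector("list", length(sampled))
    names(peaks) <- ped$sample_id[sampled]
    truth_peaks <- GenomicRanges::reduce(bins[enriched])
    for (j in seq_along(sampled)) {
      lib <- rlnorm(1, 0, 0.1)
      counts[, j] <- rpois(length(bins), lib * exp(logmu[, sampled[j]]))
      keep <- runif(length(truth_peaks)) >= peak_dropout
      peaks[[j]] <- truth_peaks[keep]
    }
    list(bins = bins, counts = counts, peaks = peaks,
         samples = as.data.frame(ped)[sampled, , drop = FALSE],
         truth_means = exp(logmu))
  })
}

#' Simulate genetic mutations per MA line and transfer interval
#'
#' Mutation counts in each interval between consecutively sampled transfers
#' of a line are Poisson with mean `mutation_rate x interval mitoses`;
#' positions are uniform over the genome. The process is independent of the
#' methylation process (the null hypothesis of no genetic control of
#' methylation changes).
#'
#' @param config a [sim_config()]
#' @return list with `events` (one row per mutation: line_id, from_transfer,
#'   to_transfer, chrom, pos) and `counts` (one row per line x interval)
#' @export
simulate_mutations <- function(config) {
  stopifnot(is(config, "sim_config"))
  ped <- config$pedigree
  with_seed(derive_seed(config$seed, 4L), {
    lens <- config$layout$chrom_lengths
    cum <- cumsum(as.numeric(lens))
    rows <- list(); events <- list()
    for (line in setdiff(unique(ped$line_id), "ancestor")) {
      tr <- sort(unique(ped$transfer[ped$line_id == line]))
      tr <- c(0L, tr)
      for (i in seq_len(length(tr) - 1L)) {
        mit <- (tr[i + 1L] - tr[i]) * attr(ped, "mitoses_per_transfer")
        k <- rpois(1, config$mutation_rate * mit)
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = line, from_transfer = tr[i], to_transfer = tr[i + 1L],
          mitoses = mit, n_mutations = k)
        if (k > 0) {
          gpos <- runif(k) * cum[length(cum)]
          ci <- findInterval(gpos, c(0, cum), rightmost.closed = TRUE)
          events[[length(events) + 1L]] <- data.frame(
            line_id = line, from_transfer = tr[i], to_transfer = tr[i + 1L],
            chrom = names(lens)[ci],
            pos = ceiling(gpos - c(0, cum)[ci]))
        }
      }
    }
    list(events = if (length(events)) do.call(rbind, events) else
           data.frame(line_id = character(), from_transfer = integer(),
                      to_transfer = integer(), chrom = character(),
                      pos = numeric()),
         counts = do.call(rbind, rows))
  })
}
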
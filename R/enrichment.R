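assign_midpoint <- function(query, target, label_col) {
  mid <- floor((GenomicRanges::start(query) + GenomicRanges::end(query)) / 2)
  q <- GenomicRanges::GRanges(GenomicRanges::seqnames(query),
                              IRanges::IRanges(mid, mid))
  hit <- GenomicRanges::findOverlaps(q, target, select = "first")
  as.character(S4Vectors::mcols(target)[[label_col]])[hit]
}

#' DMR enrichment across chromatin domains
#'
#' Counts DMRs per chromatin domain (each DMR assigned by its midpoint) and
#' compares the observed counts with the expectation under placement
#' proportional to domain length: `expected_d = N * length_d / genome
#' length`. Rate ratios (observed/expected) come with Wald intervals on the
#' log scale (equivalent to a Poisson count model with a log-length
#' offset), and per-domain p-values from exact Poisson tails against the
#' expected count.
#'
#' @param dmrs `GRanges` of DMRs
#' @param domains `GRanges` with a `domain` column tiling the genome (e.g.
#'   `layout$domains`)
#' @return data.frame of class `enrichment_result`: domain, length_bp,
#'   observed, expected, rate_ratio, ci_lower, ci_upper, p_value
#' @export
domain_enrichment <- function(dmrs, domains) {
  if (length(dmrs) == 0L) stopf("empty DMR set: enrichment undefined")
  lab <- as.character(S4Vectors::mcols(domains)$domain)
  len <- tapply(GenomicRanges::width(domains), lab, sum)
  if (any(len <= 0)) stopf("zero-length domain")
  asg <- assign_midpoint(dmrs, domains, "domain")
  if (anyNA(asg)) stopf("DMR midpoint outside the domain tiling")
  obs <- table(factor(asg, levels = names(len)))
  N <- length(dmrs); L <- sum(len)
  expected <- N * len / L
  ratio <- as.numeric(obs) / expected
  se <- ifelse(obs > 0, 1 / sqrt(as.numeric(obs)), NA_real_)
  p <- vapply(seq_along(len), function(i)
    poisson.test(as.numeric(obs[i]), T = expected[[i]])$p.value, numeric(1))
  out <- data.frame(domain = names(len), length_bp = as.numeric(len),
                    observed = as.numeric(obs), expected = as.numeric(expected),
                    rate_ratio = as.numeric(ratio),
                    ci_lower = as.numeric(exp(log(ratio) - 1.96 * se)),
                    ci_upper = as.numeric(exp(log(ratio) + 1.96 * se)),
                    p_value = p, row.names = NULL)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' DMR enrichment across domain x annotation cells
#'
#' Crosses the chromatin domains with the sequence annotations (gene,
#' promoter, TE, intergenic), computes each cell's base-pair length, and
#' compares observed DMR counts (midpoint assignment) with expectation
#' proportional to cell length. The interaction column reports the cell's
#' rate ratio divided by the product of its marginal domain and annotation
#' ratios (1 = no interaction).
#'
#' @param dmrs `GRanges` of DMRs
#' @param domains `GRanges` with a `domain` column tiling the genome
#' @param annotations `GRanges` with a `class` column partitioning the
#'   genome; overlapping classes are an error (apply a precedence rule
#'   upstream)
#' @return data.frame of class `enrichment_result` with one row per
#'   non-empty cell: domain, annotation, length_bp, observed, expected,
#'   rate_ratio, ci_lower, ci_upper, p_value, interaction
#' @export
domain_annotation_enrichment <- function(dmrs, domains, annotations) {
  if (length(dmrs) == 0L) stopf("empty DMR set: enrichment undefined")
  red <- GenomicRanges::reduce(annotations)
  if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(annotations)))
    stopf("overlapping annotation classes; apply a precedence rule upstream")
  dom_lab <- assign_midpoint(dmrs, domains, "domain")
  ann_lab <- assign_midpoint(dmrs, annotations, "class")
  if (anyNA(dom_lab) || anyNA(ann_lab))
    stopf("DMR midpoint outside the domain/annotation partition")
  doms <- unique(as.character(S4Vectors::mcols(domains)$domain))
  anns <- unique(as.character(S4Vectors::mcols(annotations)$class))
  N <- length(dmrs)
  L <- sum(GenomicRanges::width(GenomicRanges::reduce(domains)))

  rows <- list()
  dom_len <- tapply(GenomicRanges::width(domains),
                    as.character(S4Vectors::mcols(domains)$domain), sum)
  ann_len <- tapply(GenomicRanges::width(annotations),
                    as.character(S4Vectors::mcols(annotations)$class), sum)
  dom_obs <- table(factor(dom_lab, levels = doms))
  ann_obs <- table(factor(ann_lab, levels = anns))
  dom_ratio <- as.numeric(dom_obs) / (N * dom_len[doms] / L)
  names(dom_ratio) <- doms
  ann_ratio <- as.numeric(ann_obs) / (N * ann_len[anns] / L)
  names(ann_ratio) <- anns

  for (dm in doms) for (an in anns) {
    cell <- GenomicRanges::intersect(
      domains[S4Vectors::mcols(domains)$domain == dm],
      annotations[S4Vectors::mcols(annotations)$class == an])
    clen <- sum(GenomicRanges::width(cell))
    if (clen == 0) next  # empty cell: zero expected, skipped
    obs <- sum(dom_lab == dm & ann_lab == an)
    expected <- N * clen / L
    ratio <- obs / expected
    se <- if (obs > 0) 1 / sqrt(obs) else NA_real_
    inter <- ratio / (dom_ratio[[dm]] * ann_ratio[[an]])
    rows[[length(rows) + 1L]] <- data.frame(
      domain = dm, annotation = an, length_bp = clen, observed = obs,
      expected = expected, rate_ratio = ratio,
      ci_lower = exp(log(ratio) - 1.96 * se),
      ci_upper = exp(log(ratio) + 1.96 * se),
      p_value = poisson.test(obs, T = expected)$p.value,
      interaction = inter, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' TE-proximity permutation test for a set of query intervals
#'
#' Tests whether the query intervals (e.g. euchromatic DMRs) lie closer to
#' transposable elements than random background features (e.g. genes and
#' promoters). Distance is base pairs from interval edge to the nearest TE
#' edge (0 when overlapping). The null distribution of the median distance
#' is built by drawing `length(query)` background features without
#' replacement, `n_perm` times; `p` is the fraction of permutations with a
#' median distance at most the observed one.
#'
#' @param query `GRanges` of intervals under test
#' @param te `GRanges` of transposable elements
#' @param background `GRanges` of background features
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list with `observed_median`, `null_medians`, `p_value`, `n_query`
#' @export
te_proximity_test <- function(query, te, background, n_perm = 1000L,
                              seed = 1L) {
  if (length(query) == 0L || length(te) == 0L || length(background) == 0L)
    stopf("query, TE and background sets must be nonempty")
  nearest_dist <- function(q) {
    hit <- GenomicRanges::distanceToNearest(q, te)
    # features on chromosomes without TEs have no nearest hit; treat as
    # uninformative and drop them
    S4Vectors::mcols(hit)$distance
  }
  obs <- median(nearest_dist(query))
  # per-feature distances are fixed, so the permutation null only needs
  # them once
  bg_dist <- nearest_dist(background)
  replace <- length(bg_dist) < length(query)
  if (replace)
    warnf("background smaller than query; sampling with replacement")
  null <- with_seed(derive_seed(seed, 11L), {
    vapply(seq_len(n_perm), function(i)
      median(bg_dist[sample.int(length(bg_dist), length(query),
                                replace = replace)]),
      numeric(1))
  })
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  list(observed_median = obs, null_medians = null, p_value = p,
       n_query = length(query))
}
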
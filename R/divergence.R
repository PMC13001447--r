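#' State divergence between two samples (normalized Hamming distance)
#'
#' The fraction of units (cytosines, DMR bins, or peaks) in different
#' states between two samples, computed over the units observed in both;
#' units missing in either sample are excluded and `n` reduced accordingly.
#'
#' @param states_i,states_j equal-length vectors of 0/1 states with `NA`
#'   for missing
#' @return list with `d` (divergence in `[0, 1]`, `NA` if no unit is
#'   observed in both) and `n` (number of informative units)
#' @export
state_divergence <- function(states_i, states_j) {
  if (length(states_i) != length(states_j))
    stopf("state vectors must have equal length")
  ok <- !is.na(states_i) & !is.na(states_j)
  n <- sum(ok)
  if (n == 0L) {
    warnf("no units observed in both samples; divergence undefined")
    return(list(d = NA_real_, n = 0L))
  }
  list(d = sum(states_i[ok] != states_j[ok]) / n, n = n)
}

#' Count divergence between two samples (mean absolute difference)
#'
#' Mean over bins of the absolute difference of normalized read counts.
#'
#' @param x_i,x_j equal-length numeric vectors of normalized counts
#' @return non-negative divergence
#' @export
count_divergence <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) stopf("count vectors must have equal length")
  mean(abs(x_i - x_j))
}

#' Normalize a bin-count matrix to counts per million per sample
#' @param counts bins x samples matrix
#' @return matrix of the same shape on a common library scale
#' @export
normalize_counts <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stopf("nonpositive library size")
  sweep(counts, 2, lib / 1e6, "/")
}

# all pairwise state divergences at once via cross-products
pairwise_state_divergence <- function(states) {
  O <- (!is.na(states)) + 0
  M <- (states == 1L & !is.na(states)) + 0
  U <- (states == 0L & !is.na(states)) + 0
  disc <- crossprod(M, U) + crossprod(U, M)
  n <- crossprod(O, O)
  d <- disc / n
  d[n == 0] <- NA_real_
  list(d = d, n = n)
}

#' Full pairwise divergence matrix over samples
#' @param states units x samples matrix of 0/1/NA states
#' @return symmetric matrix of divergences (diagonal 0)
#' @export
divergence_matrix <- function(states) {
  pairwise_state_divergence(states)$d
}

#' Assemble a divergence-vs-mitoses dataset from a pedigree
#'
#' Forms every unordered within-pedigree pair of samples, computes its
#' divergence (normalized Hamming distance over the requested site class)
#' and the number of mitoses `delta_t = t_i + t_j` separating the pair
#' through their most recent common ancestor. Ancestor replicate pairs
#' appear at `delta_t = 0` and measure the technical baseline.
#'
#' @param x a [methylome_set()] with called states (site class
#'   `single_site`) or a [segment_dmr_bins()] result (site class `dmr_bin`)
#' @param pedigree a [pedigree()] covering all samples of `x`
#' @param context restrict to one sequence context ("all" = no filter)
#' @param domain restrict to one chromatin domain ("all" = no filter; for
#'   DMR bins the bin midpoint decides membership, via `layout`)
#' @param layout [genome_layout()], needed for `domain` filtering of bins
#' @param drop_outliers remove samples flagged by [flag_outlier_samples()]
#' @param include_zero_dt keep replicate pairs at `delta_t = 0`
#' @return data.frame of class `divergence_points` with columns sample_i,
#'   sample_j, line_i, line_j, delta_t, t_i, t_j, t_anc, d, n, context,
#'   site_class, domain
#' @export
assemble_divergence <- function(x, pedigree, context = "all", domain = "all",
                                layout = NULL, drop_outliers = FALSE,
                                include_zero_dt = TRUE) {
  if (is(x, "methylome_set")) {
    if (is.null(x$state)) stopf("states must be called first")
    keep <- rep(TRUE, nrow(x$sites))
    if (!identical(context, "all")) keep <- keep & x$sites$context %in% context
    if (!identical(domain, "all")) {
      if (is.null(x$sites$domain)) stopf("sites carry no domain labels")
      keep <- keep & x$sites$domain %in% domain
    }
    states <- x$state[keep, , drop = FALSE]
    samples <- x$samples
    site_class <- "single_site"
  } else if (is(x, "dmr_bins")) {
    keep <- rep(TRUE, length(x$bins))
    if (!identical(domain, "all")) {
      if (is.null(layout)) stopf("layout needed for domain filtering of bins")
      mid <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(x$bins),
        IRanges::IRanges(floor((GenomicRanges::start(x$bins) +
                                  GenomicRanges::end(x$bins)) / 2), width = 1))
      keep <- lookup_domain(layout, as.character(GenomicRanges::seqnames(mid)),
                            GenomicRanges::start(mid)) %in% domain
    }
    states <- x$state[keep, , drop = FALSE]
    samples <- x$samples
    site_class <- "dmr_bin"
    context <- x$context
  } else stopf("unsupported input for assemble_divergence")

  missing_ped <- setdiff(samples$sample_id, pedigree$sample_id)
  if (length(missing_ped))
    stopf("sample absent from pedigree: %s", paste(missing_ped, collapse = ", "))

  pd <- pairwise_state_divergence(states)
  ids <- samples$sample_id
  if (drop_outliers && length(ids) >= 4L) {
    dm <- pd$d; dimnames(dm) <- list(ids, ids)
    out <- flag_outlier_samples(dm)
    keep_s <- !ids %in% out
    ids <- ids[keep_s]
    pd$d <- pd$d[keep_s, keep_s, drop = FALSE]
    pd$n <- pd$n[keep_s, keep_s, drop = FALSE]
    samples <- samples[keep_s, , drop = FALSE]
  }

  ped_of <- pedigree$pedigree_id[match(ids, pedigree$sample_id)]
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    if (ped_of[i] != ped_of[j]) next
    tt <- pair_times(pedigree, ids[j], ids[i])
    if (!include_zero_dt && tt$delta_t == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      sample_i = ids[j], sample_j = ids[i],
      line_i = samples$line_id[j], line_j = samples$line_id[i],
      delta_t = tt$delta_t, t_i = tt$t_i, t_j = tt$t_j, t_anc = tt$t_anc,
      d = pd$d[j, i], n = pd$n[j, i],
      context = paste(context, collapse = "/"), site_class = site_class,
      domain = paste(domain, collapse = "/"), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_i = character(), sample_j = character(),
               line_i = character(), line_j = character(),
               delta_t = numeric(), t_i = numeric(), t_j = numeric(),
               t_anc = numeric(), d = numeric(), n = numeric(),
               context = character(), site_class = character(),
               domain = character())
  class(out) <- c("divergence_points", "data.frame")
  out
}

#' Divergence points from a normalized bin-count matrix
#'
#' Applies the mean-absolute-difference divergence to every within-pedigree
#' sample pair of a (normalized) bin-count matrix.
#'
#' @param counts bins x samples matrix (already normalized, or set
#'   `normalize = TRUE`)
#' @param pedigree a [pedigree()]
#' @param normalize apply [normalize_counts()] first
#' @return a `divergence_points` data.frame (site class `count_bin`)
#' @export
count_divergence_points <- function(counts, pedigree, normalize = TRUE) {
  if (normalize) counts <- normalize_counts(counts)
  ids <- colnames(counts)
  missing_ped <- setdiff(ids, pedigree$sample_id)
  if (length(missing_ped))
    stopf("sample absent from pedigree: %s", paste(missing_ped, collapse = ", "))
  ped_of <- pedigree$pedigree_id[match(ids, pedigree$sample_id)]
  line_of <- pedigree$line_id[match(ids, pedigree$sample_id)]
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    if (ped_of[i] != ped_of[j]) next
    tt <- pair_times(pedigree, ids[j], ids[i])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_i = ids[j], sample_j = ids[i],
      line_i = line_of[j], line_j = line_of[i],
      delta_t = tt$delta_t, t_i = tt$t_i, t_j = tt$t_j, t_anc = tt$t_anc,
      d = count_divergence(counts[, j], counts[, i]), n = nrow(counts),
      context = "all", site_class = "count_bin", domain = "all",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("divergence_points", "data.frame")
  out
}

#' Per-interval methylation change counts along each MA line
#'
#' For every MA line with at least two sampled time points, counts the
#' units (single sites or DMR bins) whose state differs between consecutive
#' sampled transfers, split by chromatin domain class. Reversions count as
#' changes in each interval where they occur.
#'
#' @param x a [methylome_set()] with called states, or a
#'   [segment_dmr_bins()] result
#' @param pedigree a [pedigree()]
#' @param layout [genome_layout()] for domain lookup of DMR bins (optional
#'   for methylome sets with domain-labelled sites)
#' @param domain_split split counts by domain (`"centromere_vs_rest"` or
#'   `"none"`)
#' @return data.frame: line_id, from_transfer, to_transfer, domain,
#'   n_changes, n_compared
#' @export
interval_change_counts <- function(x, pedigree, layout = NULL,
                                   domain_split = c("centromere_vs_rest",
                                                    "none")) {
  domain_split <- match.arg(domain_split)
  if (is(x, "methylome_set")) {
    if (is.null(x$state)) stopf("states must be called first")
    states <- x$state; samples <- x$samples
    dom <- x$sites$domain
  } else if (is(x, "dmr_bins")) {
    states <- x$state; samples <- x$samples
    dom <- if (!is.null(layout))
      lookup_domain(layout,
                    as.character(GenomicRanges::seqnames(x$bins)),
                    floor((GenomicRanges::start(x$bins) +
                             GenomicRanges::end(x$bins)) / 2))
    else rep(NA_character_, length(x$bins))
  } else stopf("unsupported input")

  dom_class <- if (domain_split == "none") rep("all", length(dom))
               else ifelse(dom == "centromere", "centromere", "rest")
  rows <- list()
  for (line in setdiff(unique(samples$line_id), "ancestor")) {
    sub <- samples[samples$line_id == line, , drop = FALSE]
    sub <- sub[order(sub$transfer), , drop = FALSE]
    sub <- sub[!duplicated(sub$transfer), , drop = FALSE]  # one rep per time
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      a <- states[, match(sub$sample_id[i], samples$sample_id)]
      b <- states[, match(sub$sample_id[i + 1L], samples$sample_id)]
      ok <- !is.na(a) & !is.na(b)
      for (dc in unique(dom_class)) {
        sel <- ok & dom_class == dc
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = line, from_transfer = sub$transfer[i],
          to_transfer = sub$transfer[i + 1L], domain = dc,
          n_changes = sum(a[sel] != b[sel]), n_compared = sum(sel))
      }
    }
  }
  if (!length(rows)) return(data.frame(line_id = character(),
    from_transfer = integer(), to_transfer = integer(), domain = character(),
    n_changes = integer(), n_compared = integer()))
  do.call(rbind, rows)
}

#' Test association between methylation changes and genetic mutations
#'
#' Compares per-interval methylation change counts between intervals that
#' carry at least one genetic mutation and mutation-free intervals, using a
#' seeded permutation test of the difference in mean change counts
#' (one-sided: more changes in mutation-bearing intervals). A rank-sum
#' (Wilcoxon) alternative is reported alongside.
#'
#' @param changes data.frame from [interval_change_counts()] (one row per
#'   line x interval; pooled over domains beforehand if desired)
#' @param mutations data.frame with line_id, from_transfer, to_transfer,
#'   n_mutations (as from [simulate_mutations()]`$counts`)
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list with `statistic` (difference in means), `p_value`,
#'   `rank_sum_p`, `n_with`, `n_without`
#' @export
mutation_association_test <- function(changes, mutations, n_perm = 10000L,
                                      seed = 1L) {
  key <- function(df) paste(df$line_id, df$from_transfer, df$to_transfer)
  m <- mutations$n_mutations[match(key(changes), key(mutations))]
  if (anyNA(m)) stopf("mutation counts missing for some intervals")
  if (nrow(changes) < 5L) stopf("need at least 5 intervals")
  grp <- m > 0
  if (all(grp) || !any(grp)) {
    warnf("all intervals in one mutation group; test undefined")
    return(list(statistic = NA_real_, p_value = NA_real_,
                rank_sum_p = NA_real_, n_with = sum(grp),
                n_without = sum(!grp)))
  }
  y <- changes$n_changes
  obs <- mean(y[grp]) - mean(y[!grp])
  perm <- with_seed(derive_seed(seed, 5L), {
    vapply(seq_len(n_perm), function(i) {
      g <- sample(grp)
      mean(y[g]) - mean(y[!g])
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  rs <- suppressWarnings(wilcox.test(y[grp], y[!grp],
                                     alternative = "greater")$p.value)
  list(statistic = obs, p_value = p, rank_sum_p = rs,
       n_with = sum(grp), n_without = sum(!grp))
}

#' Build a nonredundant peak presence/absence matrix
#'
#' Overlapping peaks across samples are union-merged into nonredundant
#' peaks; a union peak is present in a sample when any of that sample's
#' peaks overlaps it.
#'
#' @param peak_sets named list of `GRanges`, one per sample
#' @return list with `peaks` (merged `GRanges`) and `presence` (peaks x
#'   samples logical matrix)
#' @export
build_peak_matrix <- function(peak_sets) {
  if (length(peak_sets) < 2L) stopf("need peak calls for at least 2 samples")
  nonempty <- vapply(peak_sets, length, integer(1)) > 0
  if (!any(nonempty)) {
    warnf("no peaks in any sample")
    return(list(peaks = GenomicRanges::GRanges(),
                presence = matrix(FALSE, 0, length(peak_sets),
                                  dimnames = list(NULL, names(peak_sets)))))
  }
  union <- GenomicRanges::reduce(
    suppressWarnings(do.call(c, unname(peak_sets[nonempty]))))
  presence <- vapply(peak_sets, function(p)
    GenomicRanges::countOverlaps(union, p) > 0, logical(length(union)))
  presence <- matrix(presence, nrow = length(union),
                     dimnames = list(NULL, names(peak_sets)))
  list(peaks = union, presence = presence)
}

#' Peak presence/absence divergence between sample pairs
#'
#' Applies the state divergence to the presence/absence matrix over
#' variable peaks (present in at least one sample and absent in at least
#' one).
#'
#' @param peak_matrix result of [build_peak_matrix()]
#' @param pedigree a [pedigree()]
#' @param variable_only restrict to variable peaks (default)
#' @return a `divergence_points` data.frame (site class `peak`)
#' @export
peak_divergence <- function(peak_matrix, pedigree, variable_only = TRUE) {
  pres <- peak_matrix$presence + 0L
  if (variable_only) {
    v <- rowSums(pres) > 0 & rowSums(pres) < ncol(pres)
    pres <- pres[v, , drop = FALSE]
  }
  ids <- colnames(pres)
  ped_of <- pedigree$pedigree_id[match(ids, pedigree$sample_id)]
  line_of <- pedigree$line_id[match(ids, pedigree$sample_id)]
  if (anyNA(ped_of))
    stopf("sample absent from pedigree: %s",
          paste(ids[is.na(ped_of)], collapse = ", "))
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    if (ped_of[i] != ped_of[j]) next
    tt <- pair_times(pedigree, ids[j], ids[i])
    sd_ <- if (nrow(pres)) state_divergence(pres[, j], pres[, i])
           else list(d = NA_real_, n = 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_i = ids[j], sample_j = ids[i],
      line_i = line_of[j], line_j = line_of[i],
      delta_t = tt$delta_t, t_i = tt$t_i, t_j = tt$t_j, t_anc = tt$t_anc,
      d = sd_$d, n = sd_$n, context = "all", site_class = "peak",
      domain = "all", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("divergence_points", "data.frame")
  out
}

#' Permutation trend test: does divergence increase with mitoses?
#'
#' Least-squares slope of divergence on `delta_t`, with significance from a
#' permutation null that relabels samples across the pedigree: pair
#' divergences are re-indexed through a random permutation of sample
#' identities while the pedigree's `delta_t` structure stays fixed, which
#' respects the pair structure of the data. One-sided (positive slope).
#'
#' @param points a `divergence_points` data.frame holding all pairs of a
#'   set of samples
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list with `slope`, `p_value`, `n_points`, `n_perm`
#' @export
divergence_trend_test <- function(points, n_perm = 10000L, seed = 1L) {
  points <- points[!is.na(points$d), , drop = FALSE]
  if (nrow(points) < 5L) stopf("need at least 5 divergence points")
  if (length(unique(points$delta_t)) < 2L)
    stopf("delta_t is constant; trend undefined")
  ids <- unique(c(points$sample_i, points$sample_j))
  k <- length(ids)
  ii <- match(points$sample_i, ids)
  jj <- match(points$sample_j, ids)
  D <- matrix(NA_real_, k, k)
  D[cbind(ii, jj)] <- points$d
  D[cbind(jj, ii)] <- points$d
  dt <- points$delta_t
  slope_of <- function(dvec) {
    ok <- !is.na(dvec)
    if (sum(ok) < 3L || sd(dt[ok]) == 0) return(NA_real_)
    stats::cov(dvec[ok], dt[ok]) / stats::var(dt[ok])
  }
  obs <- slope_of(points$d)
  perm <- with_seed(derive_seed(seed, 6L), {
    vapply(seq_len(n_perm), function(r) {
      sig <- sample.int(k)
      slope_of(D[cbind(sig[ii], sig[jj])])
    }, numeric(1))
  })
  perm <- perm[!is.na(perm)]
  p <- (1 + sum(perm >= obs)) / (length(perm) + 1)
  list(slope = obs, p_value = p, n_points = nrow(points), n_perm = n_perm)
}

#' Fraction of DMRs overlapping H3K9me3-enriched regions
#'
#' Reports the fraction of DMRs with at least 1 bp overlap with the region
#' set, and classifies the non-overlapping DMRs by methylation direction
#' (when the DMR `GRanges` carries a `direction` column) and annotation
#' class (when a layout is supplied).
#'
#' @param dmrs `GRanges` of DMRs (e.g. from [dmr_granges()])
#' @param regions `GRanges` of stable H3K9me3-enriched regions
#' @param layout optional [genome_layout()] for annotation breakdown
#' @return list with `fraction`, `n_dmrs`, `n_overlapping`,
#'   `nonoverlap_direction` (table), `nonoverlap_annotation` (table)
#' @export
dmr_h3k9_overlap <- function(dmrs, regions, layout = NULL) {
  if (length(dmrs) == 0L) {
    warnf("empty DMR set; overlap fraction undefined")
    return(list(fraction = NA_real_, n_dmrs = 0L, n_overlapping = 0L,
                nonoverlap_direction = table(character()),
                nonoverlap_annotation = table(character())))
  }
  hit <- GenomicRanges::countOverlaps(dmrs, regions) > 0
  non <- dmrs[!hit]
  dir_tab <- if (!is.null(S4Vectors::mcols(non)$direction))
    table(S4Vectors::mcols(non)$direction) else table(character())
  ann_tab <- if (!is.null(layout) && length(non)) {
    mid <- floor((GenomicRanges::start(non) + GenomicRanges::end(non)) / 2)
    table(lookup_domain(layout, as.character(GenomicRanges::seqnames(non)),
                        mid, track = "annotations"))
  } else table(character())
  list(fraction = mean(hit), n_dmrs = length(dmrs),
       n_overlapping = sum(hit), nonoverlap_direction = dir_tab,
       nonoverlap_annotation = ann_tab)
}
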
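#' Segment the genome into 100-bp bins and call per-sample bin states
#'
#' Bins tile each chromosome without overlap. Within a bin, the qualifying
#' cytosines of a sample are the sites of the requested context with called
#' (non-missing) state and read depth at least `min_depth`; the bin is
#' eligible for that sample when it holds at least `min_cytosines`
#' qualifying cytosines. An eligible bin is called methylated when the
#' fraction of its qualifying cytosines in the methylated state reaches
#' `meth_fraction`, otherwise unmethylated. A bin is a DMR when at least two
#' samples are eligible and their bin states differ.
#'
#' @param mset a [methylome_set()] with called states
#' @param context sequence context (or "all" to pool contexts)
#' @param bin_size bin width in bp (100 by default)
#' @param min_cytosines minimum qualifying cytosines for eligibility
#' @param min_depth minimum read depth for a cytosine to qualify
#' @param meth_fraction methylated-call threshold on the qualifying fraction
#' @return object of class `dmr_bins`: list with `bins` (`GRanges`, all bins
#'   eligible in >= 1 sample), `state` (bins x samples matrix, `NA` where
#'   ineligible), `n_cytosines`, `is_dmr` (logical), `samples`
#' @export
segment_dmr_bins <- function(mset, context = "all", bin_size = 100L,
                             min_cytosines = 5L, min_depth = 5L,
                             meth_fraction = 0.5) {
  if (is.null(mset$state)) stopf("states must be called before segmentation")
  keep <- if (identical(context, "all")) rep(TRUE, nrow(mset$sites))
          else mset$sites$context %in% context
  sites <- mset$sites[keep, , drop = FALSE]
  state <- mset$state[keep, , drop = FALSE]
  total <- mset$total[keep, , drop = FALSE]

  bin_start <- (sites$pos - 1L) %/% bin_size * bin_size + 1L
  key <- paste(sites$chrom, bin_start, sep = ":")
  fkey <- factor(key, levels = unique(key))

  qual <- (total >= min_depth) & !is.na(state)
  n_qual <- rowsum(qual + 0, fkey)
  n_meth <- rowsum((qual & state == 1L) + 0, fkey)
  eligible <- n_qual >= min_cytosines
  bstate <- ifelse(eligible, (n_meth / pmax(n_qual, 1) >= meth_fraction) + 0L,
                   NA_integer_)

  keep_bins <- rowSums(eligible) >= 1L
  if (!any(keep_bins)) {
    warnf("no eligible bins")
    keep_bins <- logical(nrow(bstate))
  }
  bstate <- bstate[keep_bins, , drop = FALSE]
  n_qual <- n_qual[keep_bins, , drop = FALSE]
  ids <- rownames(bstate) %||% character()
  chrom <- sub(":.*", "", ids)
  st <- as.integer(sub(".*:", "", ids))
  bins <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(st, st + bin_size - 1L))
  n_obs <- rowSums(!is.na(bstate))
  if (nrow(bstate) > 0L) {
    any_m <- rowSums(bstate == 1L, na.rm = TRUE) > 0
    any_u <- rowSums(bstate == 0L, na.rm = TRUE) > 0
    is_dmr <- n_obs >= 2L & any_m & any_u
  } else is_dmr <- logical(0)
  colnames(bstate) <- mset$samples$sample_id
  structure(list(bins = bins, state = bstate, n_cytosines = n_qual,
                 is_dmr = is_dmr, samples = mset$samples,
                 context = context, bin_size = bin_size),
            class = "dmr_bins")
}

#' @export
print.dmr_bins <- function(x, ...) {
  cat(sprintf("dmr_bins: %d bins with data (%d-bp, context %s), %d DMRs, %d samples\n",
              length(x$bins), x$bin_size, paste(x$context, collapse = "/"),
              sum(x$is_dmr), nrow(x$samples)))
  invisible(x)
}

#' Extract DMRs as a `GRanges`
#'
#' Each DMR carries a `direction` column: `gain` when the reference sample
#' (the first ancestor replicate if present, else the majority state) is
#' unmethylated and some sample is methylated, `loss` in the opposite case.
#'
#' @param dbins a [segment_dmr_bins()] result
#' @return `GRanges` of DMR bins with per-bin `direction`
#' @export
dmr_granges <- function(dbins) {
  gr <- dbins$bins[dbins$is_dmr]
  st <- dbins$state[dbins$is_dmr, , drop = FALSE]
  anc <- which(dbins$samples$line_id == "ancestor")[1]
  ref <- if (!is.na(anc)) st[, anc] else NA_integer_
  maj <- apply(st, 1, function(z) {
    z <- z[!is.na(z)]
    as.integer(mean(z) >= 0.5)
  })
  ref <- ifelse(is.na(ref), maj, ref)
  S4Vectors::mcols(gr)$direction <- ifelse(ref == 0L, "gain", "loss")
  gr
}

#' Flag outlier samples from a pairwise divergence matrix
#'
#' A sample is flagged when the median of its pairwise divergences to all
#' other samples exceeds the grand median (the median of those per-sample
#' medians) by more than `k` median absolute deviations.
#'
#' @param divmat symmetric numeric matrix of pairwise divergences with
#'   sample names on both dimensions
#' @param k MAD multiplier (default 3)
#' @return character vector of flagged sample ids (possibly empty)
#' @export
flag_outlier_samples <- function(divmat, k = 3) {
  stopifnot(is.matrix(divmat), nrow(divmat) == ncol(divmat))
  n <- nrow(divmat)
  if (n < 4L) stopf("outlier statistic undefined for fewer than 4 samples")
  med <- vapply(seq_len(n), function(i)
    median(divmat[i, -i], na.rm = TRUE), numeric(1))
  grand <- median(med)
  spread <- mad(med, center = grand)
  flagged <- med > grand + k * spread
  flagged[!is.finite(flagged)] <- FALSE
  (rownames(divmat) %||% as.character(seq_len(n)))[flagged]
}
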
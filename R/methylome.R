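#' Methylome sample set
#'
#' Container for per-cytosine methylation data across one or more sequenced
#' cultures that share a common site table: a data.frame of sites
#' (chrom, pos, strand, context, domain) plus matrices of methylated read
#' counts, total read counts, and (after calling) binary methylation states
#' (1 = methylated, 0 = unmethylated, `NA` = missing). Sample metadata
#' records the MA line, transfer and replicate of each column.
#'
#' @param sites data.frame with columns chrom, pos, strand, context and
#'   optionally domain; must be sorted by chromosome then position
#' @param meth,total integer matrices (sites x samples); `meth <= total`
#' @param samples data.frame with columns sample_id, line_id, transfer and
#'   optionally replicate; one row per column of `meth`
#' @param state optional integer matrix of called states
#' @return an object of class `methylome_set`
#' @export
methylome_set <- function(sites, meth, total, samples, state = NULL) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (is.null(dim(meth)) || nrow(meth) != nrow(sites) ||
      !all(dim(meth) == dim(total)))
    stopf("meth/total must be sites x samples matrices")
  if (nrow(samples) != ncol(meth))
    stopf("samples metadata must have one row per sample column")
  if (any(meth > total)) stopf("meth_count exceeds total_count")
  if (any(meth < 0) || any(total < 0)) stopf("negative counts")
  if (!identical(order(sites$chrom, sites$pos), seq_len(nrow(sites))))
    stopf("sites must be sorted by chromosome and position")
  bad <- setdiff(unique(sites$context), contexts)
  if (length(bad)) stopf("unknown context token: %s", paste(bad, collapse = ", "))
  colnames(meth) <- colnames(total) <- samples$sample_id
  if (!is.null(state)) {
    state <- as.matrix(state)
    stopifnot(all(dim(state) == dim(meth)))
    colnames(state) <- samples$sample_id
  }
  structure(list(sites = sites, meth = meth, total = total,
                 samples = as.data.frame(samples), state = state),
            class = "methylome_set")
}

#' @export
print.methylome_set <- function(x, ...) {
  cat(sprintf("methylome_set: %d sites x %d samples (%s)\n",
              nrow(x$sites), nrow(x$samples),
              paste(names(table(x$sites$context)),
                    table(x$sites$context), sep = ":", collapse = " ")))
  cat(sprintf("states called: %s\n", !is.null(x$state)))
  invisible(x)
}

#' @export
dim.methylome_set <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a methylome set by site context and/or chromatin domain
#' @param mset a [methylome_set()]
#' @param context one of CG/CHG/CHH or "all"
#' @param domain a domain label or "all"
#' @return a filtered [methylome_set()]
#' @export
filter_sites <- function(mset, context = "all", domain = "all") {
  keep <- rep(TRUE, nrow(mset$sites))
  if (!identical(context, "all")) keep <- keep & mset$sites$context %in% context
  if (!identical(domain, "all")) keep <- keep & mset$sites$domain %in% domain
  methylome_set(mset$sites[keep, , drop = FALSE],
                mset$meth[keep, , drop = FALSE],
                mset$total[keep, , drop = FALSE],
                mset$samples,
                if (!is.null(mset$state)) mset$state[keep, , drop = FALSE])
}
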
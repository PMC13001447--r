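#' Genome layout: chromosome lengths, chromatin domains, annotations
#'
#' A `genome_layout` bundles chromosome lengths with two interval tracks:
#' chromatin domains (centromere, interspersed H3K9me3, H3K27me3,
#' euchromatin), which must tile each chromosome without gaps or overlaps,
#' and sequence annotations (gene, promoter, TE, intergenic), which must
#' partition each chromosome as well.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp)
#' @param domains `GRanges` with a `domain` metadata column taking values
#'   `centromere`, `h3k9me3`, `h3k27me3`, `euchromatin`
#' @param annotations `GRanges` with a `class` metadata column taking values
#'   `gene`, `promoter`, `TE`, `intergenic`, or `NULL` if unused
#' @return an object of class `genome_layout`
#' @export
genome_layout <- function(chrom_lengths, domains, annotations = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stopf("chrom_lengths must be a named vector")
  if (any(chrom_lengths < 1)) stopf("chromosome lengths must be positive")
  validate_partition(domains, "domain", domain_levels, chrom_lengths,
                     track = "domains")
  if (!is.null(annotations))
    validate_partition(annotations, "class", annotation_levels, chrom_lengths,
                       track = "annotations")
  structure(list(chrom_lengths = chrom_lengths, domains = domains,
                 annotations = annotations),
            class = "genome_layout")
}

validate_partition <- function(gr, col, levels, chrom_lengths, track) {
  if (!is(gr, "GRanges")) stopf("%s must be a GRanges", track)
  if (is.null(S4Vectors::mcols(gr)[[col]]))
    stopf("%s must carry a '%s' metadata column", track, col)
  lab <- as.character(S4Vectors::mcols(gr)[[col]])
  bad <- setdiff(unique(lab), levels)
  if (length(bad))
    stopf("%s has unknown %s label(s): %s", track, col,
          paste(bad, collapse = ", "))
  for (chr in names(chrom_lengths)) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    if (length(sub) == 0L) stopf("%s missing chromosome %s", track, chr)
    sub <- GenomicRanges::sort(sub)
    st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
    if (st[1] != 1L || en[length(en)] != chrom_lengths[[chr]] ||
        (length(sub) > 1L && any(st[-1] != en[-length(en)] + 1L)))
      stopf("%s do not tile chromosome %s without gaps/overlaps", track, chr)
  }
  invisible(gr)
}

#' Construct a desk-scale synthetic genome layout
#'
#' Builds a compact layout mimicking the organisation of a fungal genome
#' with heterochromatic islands: a central centromere block on each
#' chromosome, interspersed H3K9me3 and H3K27me3 blocks on the arms, and the
#' remainder euchromatin. Annotation classes are interleaved deterministically
#' within each domain using domain-specific composition (centromeres are
#' TE-rich and gene-poor, euchromatin the opposite).
#'
#' @param n_chrom number of chromosomes
#' @param chrom_length length of each chromosome (bp)
#' @param centromere_fraction fraction of each chromosome in the central
#'   centromere block
#' @param h3k9me3_fraction,h3k27me3_fraction fractions in interspersed
#'   heterochromatin blocks (two blocks per chromosome each)
#' @return a [genome_layout()]
#' @export
synthetic_layout <- function(n_chrom = 2L, chrom_length = 1e6,
                             centromere_fraction = 0.2,
                             h3k9me3_fraction = 0.05,
                             h3k27me3_fraction = 0.05) {
  stopifnot(centromere_fraction + h3k9me3_fraction + h3k27me3_fraction < 1)
  chrom_length <- as.integer(chrom_length)
  chroms <- paste0("chr", seq_len(n_chrom))
  lens <- setNames(rep(chrom_length, n_chrom), chroms)

  dom_list <- list(); ann_list <- list()
  for (chr in chroms) {
    L <- chrom_length
    cen_len <- round(L * centromere_fraction)
    cen_start <- round((L - cen_len) / 2) + 1L
    cen_end <- cen_start + cen_len - 1L
    k9_len <- round(L * h3k9me3_fraction / 2)
    k27_len <- round(L * h3k27me3_fraction / 2)
    # arm blocks at fixed relative positions; remainder euchromatin
    blocks <- data.frame(
      start = c(1L,
                round(L * 0.10), round(L * 0.10) + k9_len,
                round(L * 0.25), round(L * 0.25) + k27_len,
                cen_start, cen_end + 1L,
                round(L * 0.75), round(L * 0.75) + k9_len,
                round(L * 0.90), round(L * 0.90) + k27_len),
      end   = c(round(L * 0.10) - 1L,
                round(L * 0.10) + k9_len - 1L, round(L * 0.25) - 1L,
                round(L * 0.25) + k27_len - 1L, cen_start - 1L,
                cen_end, round(L * 0.75) - 1L,
                round(L * 0.75) + k9_len - 1L, round(L * 0.90) - 1L,
                round(L * 0.90) + k27_len - 1L, L),
      domain = c("euchromatin", "h3k9me3", "euchromatin", "h3k27me3",
                 "euchromatin", "centromere", "euchromatin", "h3k9me3",
                 "euchromatin", "h3k27me3", "euchromatin"))
    blocks <- blocks[blocks$end >= blocks$start, ]
    blocks$chrom <- chr
    dom_list[[chr]] <- blocks
    ann_list[[chr]] <- annotate_domains(chr, blocks)
  }
  dom <- do.call(rbind, dom_list)
  ann <- do.call(rbind, ann_list)
  domains <- GenomicRanges::GRanges(dom$chrom,
                                    IRanges::IRanges(dom$start, dom$end),
                                    domain = dom$domain)
  annotations <- GenomicRanges::GRanges(ann$chrom,
                                        IRanges::IRanges(ann$start, ann$end),
                                        class = ann$class)
  genome_layout(lens, domains, annotations)
}

# Deterministic annotation interleaving: within each domain block, repeat a
# 10-kb unit split into TE / gene / promoter / intergenic stretches whose
# sizes reflect the domain's composition.
annotate_domains <- function(chr, blocks) {
  comp <- list(
    centromere  = c(TE = 0.70, gene = 0.08, promoter = 0.02, intergenic = 0.20),
    h3k9me3     = c(TE = 0.60, gene = 0.18, promoter = 0.02, intergenic = 0.20),
    h3k27me3    = c(TE = 0.10, gene = 0.50, promoter = 0.05, intergenic = 0.35),
    euchromatin = c(TE = 0.05, gene = 0.55, promoter = 0.05, intergenic = 0.35))
  out_start <- integer(); out_end <- integer(); out_class <- character()
  unit <- 10000L
  for (b in seq_len(nrow(blocks))) {
    fr <- comp[[blocks$domain[b]]]
    pos <- blocks$start[b]
    while (pos <= blocks$end[b]) {
      u_end <- min(pos + unit - 1L, blocks$end[b])
      u_len <- u_end - pos + 1L
      widths <- round(u_len * fr)
      widths[4] <- u_len - sum(widths[1:3])
      cur <- pos
      for (k in seq_along(widths)) {
        if (widths[k] > 0) {
          out_start <- c(out_start, cur)
          out_end <- c(out_end, cur + widths[k] - 1L)
          out_class <- c(out_class, names(fr)[k])
          cur <- cur + widths[k]
        }
      }
      pos <- u_end + 1L
    }
  }
  data.frame(chrom = chr, start = out_start, end = out_end,
             class = out_class, stringsAsFactors = FALSE)
}

#' Look up the chromatin domain (or annotation class) of genomic positions
#' @param layout a [genome_layout()]
#' @param chrom,pos character/integer vectors of equal length
#' @param track `"domains"` or `"annotations"`
#' @return character vector of labels
#' @export
lookup_domain <- function(layout, chrom, pos, track = c("domains", "annotations")) {
  track <- match.arg(track)
  gr <- layout[[track]]
  col <- if (track == "domains") "domain" else "class"
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(q, gr, select = "first")
  as.character(S4Vectors::mcols(gr)[[col]])[hit]
}

#' Generate a cytosine site table over a genome layout
#'
#' Sites are placed uniformly at random within the requested regions, with
#' strand and sequence context drawn independently per site. Either a
#' genome-wide density or an explicit per-(domain, context) count
#' specification can be given; the latter is used to construct site sets of
#' exact size (e.g. a fixed number of centromeric CG sites).
#'
#' @param layout a [genome_layout()]
#' @param density sites per bp when `counts` is `NULL`
#' @param context_probs named probabilities for CG/CHG/CHH assignment
#' @param counts optional data.frame with columns `domain`, `context`, `n`
#' @param seed integer seed
#' @return data.frame with columns chrom, pos, strand, context, domain,
#'   sorted by chromosome and position
#' @export
synthesize_sites <- function(layout, density = 0.05,
                             context_probs = c(CG = 0.25, CHG = 0.25, CHH = 0.5),
                             counts = NULL, seed = 1L) {
  with_seed(seed, {
    if (is.null(counts)) {
      res <- lapply(names(layout$chrom_lengths), function(chr) {
        n <- round(layout$chrom_lengths[[chr]] * density)
        pos <- sort(sample.int(layout$chrom_lengths[[chr]], n))
        data.frame(chrom = chr, pos = pos,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   context = sample(contexts, n, replace = TRUE,
                                    prob = context_probs[contexts]),
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, res)
      out$domain <- lookup_domain(layout, out$chrom, out$pos)
    } else {
      stopifnot(all(c("domain", "context", "n") %in% names(counts)))
      res <- lapply(seq_len(nrow(counts)), function(i) {
        dom <- counts$domain[i]
        gr <- layout$domains[S4Vectors::mcols(layout$domains)$domain == dom]
        if (length(gr) == 0L) stopf("layout has no '%s' intervals", dom)
        w <- GenomicRanges::width(gr)
        idx <- sample.int(length(gr), counts$n[i], replace = TRUE, prob = w)
        off <- floor(runif(counts$n[i]) * w[idx])
        data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[idx],
                   pos = GenomicRanges::start(gr)[idx] + off,
                   strand = sample(c("+", "-"), counts$n[i], replace = TRUE),
                   context = counts$context[i], domain = dom,
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, res)
    }
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Tile a genome (or a restricted set of regions) into fixed-width bins
#' @param layout a [genome_layout()]
#' @param bin_size bin width in bp
#' @param restrict optional `GRanges`; only bins overlapping it are kept
#' @return `GRanges` of bins
#' @export
genome_bins <- function(layout, bin_size = 5000L, restrict = NULL) {
  pieces <- lapply(names(layout$chrom_lengths), function(chr) {
    L <- layout$chrom_lengths[[chr]]
    st <- seq(1L, L, by = bin_size)
    data.frame(chrom = chr, start = st, end = pmin(st + bin_size - 1L, L))
  })
  df <- do.call(rbind, pieces)
  bins <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  if (!is.null(restrict))
    bins <- bins[GenomicRanges::countOverlaps(bins, restrict) > 0]
  bins
}
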
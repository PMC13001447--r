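#' Read a Bismark-style cytosine report
#'
#' Parses a tab-separated cytosine report with columns chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context
#' (CG/CHG/CHH). An optional seventh trinucleotide column is ignored.
#'
#' @param path file path
#' @return data.frame with columns chrom, pos, strand, context, meth_count,
#'   total_count
#' @export
read_cx_report <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth_count = integer(), total_count = integer()))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6))
    stopf("malformed cytosine report row at line %d (expected >= 6 fields)",
          which(nf < 6)[1])
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 4]))
  unmeth <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stopf("malformed cytosine report row at line %d (non-numeric field)", bad[1])
  if (any(pos < 1)) stopf("positions must be 1-based (>= 1)")
  badctx <- which(!m[, 6] %in% contexts)
  if (length(badctx))
    stopf("unknown context token '%s' at line %d", m[badctx[1], 6], badctx[1])
  badstr <- which(!m[, 3] %in% c("+", "-"))
  if (length(badstr))
    stopf("unknown strand '%s' at line %d", m[badstr[1], 3], badstr[1])
  data.frame(chrom = m[, 1], pos = pos, strand = m[, 3], context = m[, 6],
             meth_count = meth, total_count = meth + unmeth,
             stringsAsFactors = FALSE)
}

#' Write a Bismark-style cytosine report
#' @param x data.frame as returned by [read_cx_report()]
#' @param path output file path
#' @export
write_cx_report <- function(x, path) {
  out <- data.frame(x$chrom, x$pos, x$strand, x$meth_count,
                    x$total_count - x$meth_count, x$context)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pedigree definition table
#'
#' Tab-separated with a header line; columns `sample_id`, `line_id`,
#' `transfer`, `parent_id` and optionally `edge_mitoses`, `pedigree_id`.
#' Missing edge lengths default to transfer difference times
#' `mitoses_per_transfer`.
#'
#' @param path file path
#' @param mitoses_per_transfer mitoses per culture transfer
#' @return a [pedigree()]
#' @export
read_pedigree <- function(path, mitoses_per_transfer = 25) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  pedigree(df, mitoses_per_transfer = mitoses_per_transfer)
}

#' Write a pedigree definition table
#' @param ped a [pedigree()]
#' @param path output file path
#' @export
write_pedigree <- function(ped, path) {
  write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read genomic intervals (BED or GFF)
#'
#' BED input (0-based half-open) and GFF input (1-based closed) are both
#' returned as `GRanges` in the usual Bioconductor 1-based closed
#' convention; `rtracklayer` performs the coordinate conversion at the
#' boundary. For `kind = "domains"` the intervals must be non-overlapping;
#' the BED name column (or GFF type) is carried as the label column.
#'
#' @param path file path (.bed or .gff/.gff3)
#' @param kind one of `domains`, `annotations`, `peaks`, `dmrs`, `genes`
#' @param layout optional [genome_layout()] used to check coordinate bounds
#' @return a `GRanges`
#' @export
read_intervals <- function(path,
                           kind = c("peaks", "domains", "annotations",
                                    "dmrs", "genes"),
                           layout = NULL) {
  kind <- match.arg(kind)
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff") {
    lab <- as.character(S4Vectors::mcols(gr)$type)
  } else {
    lab <- S4Vectors::mcols(gr)$name
  }
  S4Vectors::mcols(gr) <- NULL
  if (!is.null(lab)) {
    if (kind == "domains") S4Vectors::mcols(gr)$domain <- lab
    else if (kind == "annotations") S4Vectors::mcols(gr)$class <- lab
    else S4Vectors::mcols(gr)$name <- lab
  }
  if (kind %in% c("domains", "annotations")) {
    red <- GenomicRanges::reduce(gr)
    if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(gr)))
      stopf("overlapping intervals not allowed for kind '%s'", kind)
  }
  if (!is.null(layout)) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    bad <- !chr %in% names(layout$chrom_lengths) |
      GenomicRanges::end(gr) > layout$chrom_lengths[chr]
    if (any(bad, na.rm = TRUE))
      stopf("interval beyond chromosome bounds at record %d", which(bad)[1])
  }
  gr
}

#' Write intervals as BED (0-based half-open on disk)
#' @param gr a `GRanges`
#' @param path output path ending in .bed
#' @export
write_intervals <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  lab <- mc$name %||% mc$domain %||% mc$class %||% mc$direction
  S4Vectors::mcols(gr) <- NULL
  if (!is.null(lab)) S4Vectors::mcols(gr)$name <- lab
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a bin-count table (chrom, start, end, sample, count; TSV with header)
#' @param path file path
#' @return list with `bins` (`GRanges`) and `counts` (bins x samples matrix)
#' @export
read_bin_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "sample", "count") %in% names(df)))
  key <- paste(df$chrom, df$start, df$end, sep = ":")
  ukey <- unique(key)
  samples <- unique(df$sample)
  counts <- matrix(NA_real_, length(ukey), length(samples),
                   dimnames = list(ukey, samples))
  counts[cbind(match(key, ukey), match(df$sample, samples))] <- df$count
  first <- match(ukey, key)
  bins <- GenomicRanges::GRanges(df$chrom[first],
                                 IRanges::IRanges(df$start[first] + 1L,
                                                  df$end[first]))
  list(bins = bins, counts = counts)
}

#' Write a bin-count matrix as a long TSV (BED-style 0-based starts)
#' @param bins `GRanges` of bins
#' @param counts bins x samples matrix
#' @param path output file path
#' @export
write_bin_counts <- function(bins, counts, path) {
  long <- data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(bins)), ncol(counts)),
    start = rep(GenomicRanges::start(bins) - 1L, ncol(counts)),
    end = rep(GenomicRanges::end(bins), ncol(counts)),
    sample = rep(colnames(counts), each = length(bins)),
    count = as.vector(counts))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation/analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are rejected.
#' @param path YAML file path
#' @return a [sim_config()]
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(vals$rates)) vals$rates <- as.data.frame(vals$rates)
  do.call(sim_config, vals)
}
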
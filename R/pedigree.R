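#' Mutation accumulation pedigree
#'
#' A pedigree is a table of nodes (sampled cultures plus unsampled internal
#' ancestors) with directed parent -> child edges whose lengths are measured
#' in mitoses. One root (parent `NA`) is required per pedigree; a table may
#' hold several independent pedigrees distinguished by `pedigree_id`, and
#' divergence times are only defined within a pedigree. When `edge_mitoses`
#' is absent it is filled in as (transfer difference) x `mitoses_per_transfer`
#' (default 25 mitoses per culture transfer).
#'
#' @param nodes data.frame with columns `sample_id`, `line_id`, `transfer`,
#'   `parent_id` (NA for the root) and optionally `edge_mitoses`,
#'   `pedigree_id`, `sampled`
#' @param mitoses_per_transfer mitoses elapsing per culture transfer
#' @return an object of class `pedigree` (a validated data.frame)
#' @export
pedigree <- function(nodes, mitoses_per_transfer = 25) {
  req <- c("sample_id", "line_id", "transfer", "parent_id")
  if (!all(req %in% names(nodes)))
    stopf("pedigree table needs columns: %s", paste(req, collapse = ", "))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$sample_id <- as.character(nodes$sample_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[nodes$parent_id %in% c("", "NA", ".")] <- NA_character_
  if (anyDuplicated(nodes$sample_id))
    stopf("duplicated sample_id in pedigree")
  if (is.null(nodes$pedigree_id)) nodes$pedigree_id <- "P1"
  if (is.null(nodes$sampled)) nodes$sampled <- TRUE

  idx <- match(nodes$parent_id, nodes$sample_id)
  missing_parent <- !is.na(nodes$parent_id) & is.na(idx)
  if (any(missing_parent))
    stopf("parent_id not found in pedigree: %s",
          paste(unique(nodes$parent_id[missing_parent]), collapse = ", "))
  if (any(!is.na(nodes$parent_id) & nodes$parent_id == nodes$sample_id))
    stopf("self-referencing parent in pedigree")

  for (ped in unique(nodes$pedigree_id)) {
    sub <- nodes$pedigree_id == ped
    if (sum(sub & is.na(nodes$parent_id)) != 1L)
      stopf("pedigree %s must have exactly one root", ped)
  }
  child <- which(!is.na(idx))
  if (any(nodes$pedigree_id[child] != nodes$pedigree_id[idx[child]]))
    stopf("edge crosses pedigrees")

  # cycle check: follow parents from every node, must reach a root
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    seen <- 0L; j <- i
    while (!is.na(nodes$parent_id[j])) {
      j <- idx[j]; seen <- seen + 1L
      if (seen > n) stopf("cycle detected in pedigree")
    }
  }

  if (is.null(nodes$edge_mitoses)) nodes$edge_mitoses <- NA_real_
  fill <- is.na(nodes$edge_mitoses) & !is.na(nodes$parent_id)
  nodes$edge_mitoses[fill] <-
    (nodes$transfer[fill] - nodes$transfer[idx[fill]]) * mitoses_per_transfer
  nodes$edge_mitoses[is.na(nodes$parent_id)] <- 0
  if (any(nodes$edge_mitoses < 0))
    stopf("negative edge_mitoses (child transfer before parent?)")

  structure(nodes, class = c("pedigree", "data.frame"),
            mitoses_per_transfer = mitoses_per_transfer)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("MA pedigree: %d nodes, %d pedigree(s), %d line(s), %g mitoses/transfer\n",
              nrow(x), length(unique(x$pedigree_id)),
              length(unique(x$line_id[!is.na(x$parent_id)])),
              attr(x, "mitoses_per_transfer")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more nodes\n", nrow(x) - 10))
  invisible(x)
}

# mitoses from the pedigree root to each node
node_depths <- function(ped) {
  idx <- match(ped$parent_id, ped$sample_id)
  depth <- rep(NA_real_, nrow(ped))
  depth[is.na(ped$parent_id)] <- 0
  while (anyNA(depth)) {
    ready <- is.na(depth) & !is.na(depth[idx])
    if (!any(ready)) stopf("unreachable nodes in pedigree")
    depth[ready] <- depth[idx[ready]] + ped$edge_mitoses[ready]
  }
  setNames(depth, ped$sample_id)
}

ancestor_path <- function(ped, id) {
  idx <- match(ped$parent_id, ped$sample_id)
  i <- match(id, ped$sample_id)
  path <- i
  while (!is.na(ped$parent_id[i])) { i <- idx[i]; path <- c(path, i) }
  ped$sample_id[path]
}

#' Divergence time between two pedigree nodes
#'
#' Returns the number of mitoses separating two nodes through their most
#' recent common ancestor (MRCA): `delta_t = t_i + t_j`, where `t_i` and
#' `t_j` are the mitoses from the MRCA down to each node. `t_anc` is the
#' number of mitoses from the pedigree root to the MRCA.
#'
#' @param ped a [pedigree()]
#' @param a,b sample ids (must belong to the same pedigree)
#' @return list with `delta_t`, `t_i`, `t_j`, `t_anc`, `mrca`
#' @export
pair_times <- function(ped, a, b) {
  if (!a %in% ped$sample_id || !b %in% ped$sample_id)
    stopf("sample absent from pedigree: %s",
          paste(setdiff(c(a, b), ped$sample_id), collapse = ", "))
  pa <- ped$pedigree_id[match(c(a, b), ped$sample_id)]
  if (pa[1] != pa[2])
    stopf("samples %s and %s are in different pedigrees", a, b)
  depth <- node_depths(ped)
  path_a <- ancestor_path(ped, a)
  path_b <- ancestor_path(ped, b)
  common <- intersect(path_a, path_b)
  mrca <- common[which.max(depth[common])]
  t_i <- depth[[a]] - depth[[mrca]]
  t_j <- depth[[b]] - depth[[mrca]]
  list(delta_t = t_i + t_j, t_i = t_i, t_j = t_j,
       t_anc = depth[[mrca]], mrca = mrca)
}

#' Build the standard MA sampling design as a pedigree
#'
#' Emulates the sampling layout of the MA experiment: `n_lines` MA lines
#' split across `n_pedigrees` independent pedigrees, each line propagated by
#' serial transfer and sampled at the given transfer numbers (later samples
#' descend from earlier ones within a line). Each pedigree root carries
#' `ancestor_replicates` replicate observations (zero-mitosis edges), and
#' `replicated_lines` get two replicates per time point.
#'
#' @param n_lines total number of MA lines
#' @param transfers transfer numbers at which lines are sampled
#' @param n_pedigrees number of independent pedigrees the lines split across
#' @param ancestor_replicates replicate samples of each pedigree ancestor
#' @param replicated_lines character vector of line ids with duplicate
#'   samples per time point (default none)
#' @param mitoses_per_transfer mitoses per transfer
#' @return a [pedigree()]
#' @export
ma_pedigree <- function(n_lines = 10L, transfers = c(5L, 20L, 40L),
                        n_pedigrees = 2L, ancestor_replicates = 3L,
                        replicated_lines = character(),
                        mitoses_per_transfer = 25) {
  rows <- list()
  ped_of_line <- rep(seq_len(n_pedigrees), length.out = n_lines)
  for (p in seq_len(n_pedigrees)) {
    root <- sprintf("P%d_root", p)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = root, line_id = "ancestor", transfer = 0L,
      parent_id = NA_character_, pedigree_id = sprintf("P%d", p),
      sampled = FALSE)
    for (r in seq_len(ancestor_replicates))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("P%d_anc_r%d", p, r), line_id = "ancestor",
        transfer = 0L, parent_id = root, pedigree_id = sprintf("P%d", p),
        sampled = TRUE)
  }
  for (l in seq_len(n_lines)) {
    p <- ped_of_line[l]
    line <- sprintf("L%d", l)
    parent <- sprintf("P%d_root", p)
    for (tr in sort(transfers)) {
      node <- sprintf("%s_t%d", line, tr)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = node, line_id = line, transfer = as.integer(tr),
        parent_id = parent, pedigree_id = sprintf("P%d", p), sampled = TRUE)
      if (line %in% replicated_lines)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_r2", node), line_id = line,
          transfer = as.integer(tr), parent_id = node,
          pedigree_id = sprintf("P%d", p), sampled = TRUE)
      parent <- node
    }
  }
  pedigree(do.call(rbind, rows), mitoses_per_transfer = mitoses_per_transfer)
}
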
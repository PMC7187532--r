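# ---- Multiple Conservation Score and companion expression metrics ----
#
# MCS = N_s + N_t x N_i.  The integer part N_s counts a circRNA's orthologs
# across species; the decimal part is read off a two-layer hierarchical
# expression tree (tissue layer over individual layer):
#   N_t = (# tissue-layer nodes expressing the circRNA) / (# tissues)
#   N_i = (# expressing nodes in both layers)
#         / (2 x # individuals in the tissues expressing the circRNA)

#' Build the hierarchical expression tree
#'
#' One node per tissue, one node per (tissue, individual); a circRNA marks an
#' individual node iff any sample of that (tissue, individual) exceeds the
#' expression threshold, and marks a tissue node iff any of its individual
#' nodes is marked.
#'
#' @param expr FPM matrix, loci x samples (see [expression_matrix()])
#' @param samples sample sheet with `tissue` and `individual` columns
#' @param threshold a node is "expressing" when FPM strictly exceeds this
#'   (default 0: any supported BSJ read)
#' @return object of class `expression_tree` with the node tables and the
#'   per-circRNA mark matrices
#' @export
build_expression_tree <- function(expr, samples, threshold = 0) {
  if (threshold < 0) stop("build_expression_tree: threshold must be >= 0")
  miss <- setdiff(colnames(expr), samples$sample_id)
  if (length(miss)) stop("build_expression_tree: samples missing for ", paste(miss, collapse = ", "))
  s <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (any(is.na(s$tissue)) || any(is.na(s$individual)))
    stop("build_expression_tree: samples lack tissue/individual labels")
  ind_key <- paste(s$tissue, s$individual, sep = "\r")
  individuals <- unique(data.frame(tissue = samples$tissue,
                                   individual = samples$individual,
                                   stringsAsFactors = FALSE))
  individuals <- individuals[order(individuals$tissue, individuals$individual), , drop = FALSE]
  rownames(individuals) <- NULL
  ikeys <- paste(individuals$tissue, individuals$individual, sep = "\r")
  tissues <- sort(unique(samples$tissue))
  on <- expr > threshold
  ind_mark <- matrix(FALSE, nrow(expr), length(ikeys),
                     dimnames = list(rownames(expr), ikeys))
  for (k in seq_along(ikeys)) {
    cols <- which(ind_key == ikeys[k])
    if (length(cols)) ind_mark[, k] <- rowSums(on[, cols, drop = FALSE]) > 0
  }
  tissue_mark <- matrix(FALSE, nrow(expr), length(tissues),
                        dimnames = list(rownames(expr), tissues))
  for (t in seq_along(tissues)) {
    cols <- which(individuals$tissue == tissues[t])
    tissue_mark[, t] <- rowSums(ind_mark[, cols, drop = FALSE]) > 0
  }
  structure(list(tissues = tissues, individuals = individuals,
                 ind_mark = ind_mark, tissue_mark = tissue_mark,
                 threshold = threshold),
            class = "expression_tree")
}

#' @export
print.expression_tree <- function(x, ...) {
  cat(sprintf("<expression_tree> %d tissue node(s), %d individual node(s), %d circRNA(s)\n",
              length(x$tissues), nrow(x$individuals), nrow(x$ind_mark)))
  invisible(x)
}

tree_locus <- function(tree, locus) {
  if (!locus %in% rownames(tree$ind_mark))
    stop("unknown circRNA locus: ", locus)
  locus
}

#' Tissue-layer conservation component N_t
#'
#' Fraction of tissue-layer nodes expressing the circRNA.
#'
#' @param tree an [build_expression_tree()] result
#' @param locus circRNA locus key (row of the expression matrix)
#' @return value in \[0, 1\]
#' @export
compute_Nt <- function(tree, locus) {
  locus <- tree_locus(tree, locus)
  if (length(tree$tissues) == 0L) stop("compute_Nt: tree has no tissues")
  sum(tree$tissue_mark[locus, ]) / length(tree$tissues)
}

#' Individual-layer conservation component N_i
#'
#' `(# expressing nodes in both layers) / (2 x # individuals belonging to the
#' expressing tissues)`.  Undefined (error) for a circRNA expressed nowhere;
#' [compute_mcs()] sets the decimal part to 0 upstream in that case.
#'
#' @inheritParams compute_Nt
#' @return value in \[0, 1\]
#' @export
compute_Ni <- function(tree, locus) {
  locus <- tree_locus(tree, locus)
  marked_t <- tree$tissues[tree$tissue_mark[locus, ]]
  if (!length(marked_t))
    stop("compute_Ni: circRNA expressed in no tissue; N_i undefined")
  in_marked <- tree$individuals$tissue %in% marked_t
  n_marked_nodes <- length(marked_t) + sum(tree$ind_mark[locus, in_marked])
  n_marked_nodes / (2 * sum(in_marked))
}

#' Multiple Conservation Score
#'
#' `MCS = N_s + N_t x N_i`.  `N_s` comes from the ortholog groups (group size
#' minus one).  For a circRNA expressed nowhere the decimal part is 0 and
#' `N_i` is reported as `NA`.  The degenerate case `N_t x N_i = 1` is kept as
#' is (components are always reported, so the integer/decimal reading stays
#' recoverable).
#'
#' @param n_s ortholog count (non-negative integer)
#' @inheritParams compute_Nt
#' @return list with `n_s`, `n_t`, `n_i`, `mcs`
#' @export
compute_mcs <- function(n_s, tree, locus) {
  if (n_s < 0) stop("compute_mcs: n_s must be >= 0")
  n_t <- compute_Nt(tree, locus)
  if (n_t == 0) return(list(n_s = n_s, n_t = 0, n_i = NA_real_, mcs = n_s + 0))
  n_i <- compute_Ni(tree, locus)
  list(n_s = n_s, n_t = n_t, n_i = n_i, mcs = n_s + n_t * n_i)
}

#' MCS profiles for a whole record table
#'
#' @param records records with a `locus_key` column
#' @param tree expression tree covering the records
#' @param groups ortholog group table from [build_ortholog_groups()] (or NULL:
#'   all `n_s = 0`); matched on `locus_key` within `records$species_code`
#' @return `records` with added columns `n_s`, `n_t`, `n_i`, `mcs`
#' @export
mcs_profiles <- function(records, tree, groups = NULL) {
  n_s <- rep(0L, nrow(records))
  if (!is.null(groups) && nrow(groups)) {
    key <- paste(groups$species, groups$locus_key)
    idx <- match(paste(records$species_code, records$locus_key), key)
    n_s[!is.na(idx)] <- groups$n_s[idx[!is.na(idx)]]
  }
  prof <- lapply(seq_len(nrow(records)), function(i)
    compute_mcs(n_s[i], tree, records$locus_key[i]))
  records$n_s <- n_s
  records$n_t <- vapply(prof, `[[`, 0, "n_t")
  records$n_i <- vapply(prof, `[[`, 0, "n_i")
  records$mcs <- vapply(prof, `[[`, 0, "mcs")
  records
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i(1 - x_i / x_max) / (N - 1)` over per-tissue mean expression:
#' 0 for a perfectly uniform profile, 1 for single-tissue expression.
#'
#' @param x numeric vector of >= 2 non-negative per-tissue means, max > 0
#' @return value in \[0, 1\]
#' @export
tissue_specificity_tau <- function(x) {
  if (length(x) < 2L) stop("tissue_specificity_tau: need >= 2 tissues")
  if (any(x < 0)) stop("tissue_specificity_tau: negative expression")
  if (max(x) == 0) stop("tissue_specificity_tau: all-zero profile")
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' Junction ratio
#'
#' Fraction of junction-spanning evidence that is circular:
#' `2 * bsj / (2 * bsj + linear)`.  A BSJ read testifies to one junction
#' while the two linear splice junctions flanking the back-splice each
#' contribute, hence the factor 2.  Returns `NA` when both counts are 0.
#'
#' @param bsj_reads back-splice junction read count(s)
#' @param linear_reads linear junction read count(s) at the same boundaries
#' @return value(s) in \[0, 1\], or `NA` where both inputs are 0
#' @export
junction_ratio <- function(bsj_reads, linear_reads) {
  if (any(bsj_reads < 0) || any(linear_reads < 0))
    stop("junction_ratio: counts must be >= 0")
  out <- 2 * bsj_reads / (2 * bsj_reads + linear_reads)
  out[bsj_reads == 0 & linear_reads == 0] <- NA_real_
  out
}

#' Rank circRNAs for prioritization
#'
#' Stable sort by MCS descending; ties by `n_s` descending, then `locus_key`
#' ascending.
#'
#' @param records records carrying `mcs` and `n_s`
#' @return reordered records
#' @export
prioritize <- function(records) {
  if (nrow(records) == 0L) return(records)
  out <- records[order(-records$mcs, -records$n_s, records$locus_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
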
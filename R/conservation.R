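# ---- cross-species orthologous circRNA detection ----
#
# Workflow: restrict candidate pairs to orthologous host genes, verify
# cirexon boundary correspondence through whole-genome-alignment coordinate
# maps (advisory), represent each BSJ by up-to-50-bp flanks drawn from its
# terminal cirexons, align all-vs-all within the candidate universe with an
# optimal local aligner, keep reciprocal best hits, and integrate pairwise
# hits into multi-species ortholog groups.

#' Restrict the candidate universe to orthologous host genes
#'
#' Only orthologous gene pairs in which both members host circRNAs are
#' retained; the candidate set is, per retained gene pair, the cross product
#' of the hosted circRNAs.
#'
#' @param circs_a,circs_b classified record tables (must carry `host_gene`)
#' @param pairs data.frame with columns `gene_a`, `gene_b` (ortholog gene ids)
#' @return data.frame with columns `gene_a`, `gene_b`, `locus_a`, `locus_b`
#' @export
restrict_to_ortholog_genes <- function(circs_a, circs_b, pairs) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      locus_a = character(), locus_b = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  if (anyDuplicated(pairs[c("gene_a", "gene_b")])) pairs <- unique(pairs)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    la <- circs_a$locus_key[!is.na(circs_a$host_gene) & circs_a$host_gene == pairs$gene_a[i]]
    lb <- circs_b$locus_key[!is.na(circs_b$host_gene) & circs_b$host_gene == pairs$gene_b[i]]
    if (!length(la) || !length(lb)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
      locus_a = rep(la, each = length(lb)), locus_b = rep(lb, length(la)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Map an interval through a pairwise coordinate map
#'
#' Each endpoint is mapped through its containing ungapped block with offset
#' arithmetic (strand-aware).  Returns `NULL` if either endpoint falls in no
#' block, or if the endpoints land on different target chromosomes or
#' strands.
#'
#' @param chrom,start,end source interval (0-based half-open)
#' @param map a [coordinate_map()]
#' @return list with `chrom`, `start`, `end`, `strand`, or `NULL`
#' @export
liftover_interval <- function(chrom, start, end, map) {
  map_point <- function(p) {
    b <- map[map$src_chrom == chrom & map$src_start <= p & p < map$src_end, , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    b <- b[1L, ]
    off <- p - b$src_start
    q <- if (b$dst_strand == "+") b$dst_start + off else b$dst_end - 1L - off
    list(chrom = b$dst_chrom, pos = q, strand = b$dst_strand)
  }
  q1 <- map_point(start)
  q2 <- map_point(end - 1L)
  if (is.null(q1) || is.null(q2)) return(NULL)
  if (q1$chrom != q2$chrom || q1$strand != q2$strand) return(NULL)
  lo <- min(q1$pos, q2$pos); hi <- max(q1$pos, q2$pos)
  list(chrom = q1$chrom, start = as.integer(lo), end = as.integer(hi + 1L),
       strand = q1$strand)
}

# cirexons of a record: exons of the best-agreeing host transcript clipped to
# the circle interval; NULL when the host is unknown or has no exon overlap
record_cirexons <- function(chrom, start, end, host_gene, genes) {
  if (is.na(host_gene)) return(NULL)
  gene <- genes[[host_gene]]
  bt <- best_transcript(gene, start, end)
  if (is.null(bt)) return(NULL)
  clip <- data.frame(start = pmax(bt$start, start), end = pmin(bt$end, end))
  clip <- clip[clip$start < clip$end, , drop = FALSE]
  if (!nrow(clip)) return(NULL)
  rownames(clip) <- NULL
  clip
}

#' Extract the BSJ-flank sequence of a circRNA
#'
#' The BSJ of a mature circle joins the 3' end of its last cirexon to the 5'
#' start of its first.  Its sequence representation is the last
#' `min(k, exon length)` nt of the 3'-terminal cirexon followed by the first
#' `min(k, exon length)` nt of the 5'-terminal cirexon, read 5'->3' on the
#' mature transcript (reverse-complemented for minus-strand circles).
#'
#' @param chrom,start,end,strand circRNA coordinates
#' @param genome [genome_ref]
#' @param cirexons data.frame of cirexon intervals (`start`, `end`), e.g. from
#'   classification; required
#' @param k flank length per side (default 50)
#' @return list with `seq` (character), `len3`, `len5` (actual side lengths,
#'   3'-side first in mature orientation)
#' @export
extract_bsj_flanks <- function(chrom, start, end, strand, genome, cirexons, k = 50L) {
  if (is.null(cirexons) || nrow(cirexons) == 0L)
    stop("extract_bsj_flanks: cirexons unknown; classify the record first ",
         "(host gene and exon overlap define the cirexons)")
  cirexons <- cirexons[order(cirexons$start), , drop = FALSE]
  left <- cirexons[1L, ]
  right <- cirexons[nrow(cirexons), ]
  if (strand == "+") {
    l3 <- min(k, right$end - right$start)
    l5 <- min(k, left$end - left$start)
    s3 <- genome_slice(genome, chrom, right$end - l3, right$end)
    s5 <- genome_slice(genome, chrom, left$start, left$start + l5)
  } else {
    l3 <- min(k, left$end - left$start)
    l5 <- min(k, right$end - right$start)
    s3 <- revcomp(genome_slice(genome, chrom, left$start, left$start + l3))
    s5 <- revcomp(genome_slice(genome, chrom, right$end - l5, right$end))
  }
  list(seq = paste0(s3, s5), len3 = as.integer(l3), len5 = as.integer(l5))
}

#' Extract BSJ flanks for a whole record table
#'
#' @param records classified records (`host_gene` present)
#' @param genome [genome_ref]
#' @param genes gene model list (to derive cirexons)
#' @param k flank length per side
#' @param fallback_whole_circle when a hosted record has no exon overlap (or
#'   no host), use the circle interval itself as a single cirexon instead of
#'   dropping the record (default TRUE; dropped records are reported in the
#'   `skipped` attribute when FALSE)
#' @return named character vector of flank sequences, names = locus keys
#' @export
extract_flanks <- function(records, genome, genes, k = 50L,
                           fallback_whole_circle = TRUE) {
  seqs <- character(0)
  skipped <- character(0)
  for (i in seq_len(nrow(records))) {
    ce <- record_cirexons(records$chrom[i], records$start[i], records$end[i],
                          records$host_gene[i], genes)
    if (is.null(ce)) {
      if (!fallback_whole_circle) { skipped <- c(skipped, records$locus_key[i]); next }
      ce <- data.frame(start = records$start[i], end = records$end[i])
    }
    fl <- extract_bsj_flanks(records$chrom[i], records$start[i], records$end[i],
                             records$strand[i], genome, ce, k)
    seqs[records$locus_key[i]] <- fl$seq
  }
  attr(seqs, "skipped") <- skipped
  seqs
}

#' Optimal local alignment of two BSJ flank sequences
#'
#' Smith--Waterman with affine gaps; default scoring `match = +1`,
#' `mismatch = -1`, gap open/extend `-2`/`-1` (the opening penalty covers the
#' first gap base).  The returned score is optimal under the scheme.
#'
#' @param a,b non-empty nucleotide sequences
#' @param match,mismatch,gap_open,gap_ext scoring parameters (penalties
#'   negative)
#' @return list with `score`, `identity` (matches / alignment columns),
#'   `aln_len` (alignment columns)
#' @export
align_flanks <- function(a, b, match = 1, mismatch = -1, gap_open = -2, gap_ext = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("align_flanks: empty sequence")
  r <- .sw_align_cpp(a, b, match, mismatch, -gap_open, -gap_ext)
  list(score = r$score, identity = r$identity, aln_len = r$aln_len)
}

#' Reciprocal best hits between two species' circRNA flank sets
#'
#' Aligns every candidate pair (from [restrict_to_ortholog_genes()]), finds
#' each locus's unique top-scoring partner, and reports a pair iff the choice
#' is mutual and passes the identity and alignment-length thresholds.  Ties
#' for the top score disqualify the locus (conservative: no pair).
#'
#' @param universe candidate pairs (`locus_a`, `locus_b`)
#' @param flanks_a,flanks_b named character vectors of flank sequences
#' @param min_identity minimum identity fraction (default 0.7)
#' @param min_aln_len minimum alignment length in columns (default 60)
#' @param match,mismatch,gap_open,gap_ext scoring, see [align_flanks()]
#' @return data.frame with `locus_a`, `locus_b`, `score`, `identity`, `aln_len`
#' @export
reciprocal_best_hits <- function(universe, flanks_a, flanks_b,
                                 min_identity = 0.7, min_aln_len = 60L,
                                 match = 1, mismatch = -1, gap_open = -2, gap_ext = -1) {
  empty <- data.frame(locus_a = character(), locus_b = character(),
                      score = numeric(), identity = numeric(), aln_len = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(universe) == 0L) return(empty)
  miss_a <- setdiff(universe$locus_a, names(flanks_a))
  miss_b <- setdiff(universe$locus_b, names(flanks_b))
  if (length(miss_a) || length(miss_b))
    stop("reciprocal_best_hits: flank sequence missing for ",
         paste(c(miss_a, miss_b), collapse = ", "))
  uni <- unique(universe[c("locus_a", "locus_b")])
  hits <- .sw_align_batch_cpp(unname(flanks_a[uni$locus_a]),
                              unname(flanks_b[uni$locus_b]),
                              match, mismatch, -gap_open, -gap_ext)
  uni$score <- hits$score
  uni$identity <- hits$identity
  uni$aln_len <- hits$aln_len
  best_of <- function(keys, by) {
    # unique top-scoring partner per key; NA when tied
    out <- setNames(rep(NA_character_, length(unique(keys))), unique(keys))
    for (k in names(out)) {
      rows <- uni[keys == k, , drop = FALSE]
      top <- max(rows$score)
      winners <- rows[[by]][rows$score == top]
      if (length(winners) == 1L) out[k] <- winners
    }
    out
  }
  best_a <- best_of(uni$locus_a, "locus_b")
  best_b <- best_of(uni$locus_b, "locus_a")
  keep <- !is.na(best_a[uni$locus_a]) & best_a[uni$locus_a] == uni$locus_b &
    !is.na(best_b[uni$locus_b]) & best_b[uni$locus_b] == uni$locus_a &
    uni$identity >= min_identity & uni$aln_len >= min_aln_len
  out <- uni[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate pairwise RBH sets into multi-species ortholog groups
#'
#' Builds the graph whose nodes are `species:locus` circRNAs and whose edges
#' are RBH pairs weighted by alignment score, then partitions each connected
#' component into species-consistent groups (at most one member per species,
#' every multi-member group internally RBH-connected) maximizing the summed
#' within-group edge score.  Components of up to `max_exact` nodes are solved
#' exactly by exhaustive partition search; larger components use a greedy
#' descending-score edge merge.  Each member's `n_s` is its group size minus
#' one (the number of orthologs), or the group size when
#' `ns_counts = "species"`.
#'
#' @param rbh data.frame with columns `species_a`, `locus_a`, `species_b`,
#'   `locus_b`, `score` (rbind of per-species-pair RBH tables)
#' @param all_members optional data.frame (`species`, `locus_key`) of every
#'   circRNA considered, so edge-less circRNAs appear as singleton groups
#' @param ns_counts `"orthologs"` (group size - 1, default) or `"species"`
#' @param max_exact component size up to which the exact search runs
#' @return data.frame with columns `group_id`, `species`, `locus_key`, `n_s`
#' @export
build_ortholog_groups <- function(rbh, all_members = NULL,
                                  ns_counts = c("orthologs", "species"),
                                  max_exact = 8L) {
  ns_counts <- match.arg(ns_counts)
  node_id <- function(sp, lk) paste0(sp, ":", lk)
  nodes <- character(0)
  if (nrow(rbh)) {
    nodes <- unique(c(node_id(rbh$species_a, rbh$locus_a),
                      node_id(rbh$species_b, rbh$locus_b)))
  }
  if (!is.null(all_members))
    nodes <- unique(c(nodes, node_id(all_members$species, all_members$locus_key)))
  if (!length(nodes)) {
    return(data.frame(group_id = integer(), species = character(),
                      locus_key = character(), n_s = integer(),
                      stringsAsFactors = FALSE))
  }
  nodes <- sort(nodes)
  spec_of <- sub(":.*$", "", nodes)
  ed <- if (nrow(rbh)) {
    data.frame(a = match(node_id(rbh$species_a, rbh$locus_a), nodes),
               b = match(node_id(rbh$species_b, rbh$locus_b), nodes),
               score = rbh$score)
  } else data.frame(a = integer(), b = integer(), score = numeric())
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$a, to = ed$b),
    directed = FALSE,
    vertices = data.frame(name = seq_along(nodes)))
  comp <- igraph::components(g)$membership[as.character(seq_along(nodes))]
  assignment <- integer(length(nodes))
  next_gid <- 0L
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    sub_ed <- ed[ed$a %in% idx & ed$b %in% idx, , drop = FALSE]
    blocks <- if (length(idx) <= max_exact) {
      partition_component_exact(idx, spec_of[idx], sub_ed)
    } else {
      partition_component_greedy(idx, spec_of[idx], sub_ed)
    }
    for (b in blocks) {
      next_gid <- next_gid + 1L
      assignment[b] <- next_gid
    }
  }
  size <- table(assignment)
  n_s <- as.integer(size[as.character(assignment)]) -
    if (ns_counts == "orthologs") 1L else 0L
  out <- data.frame(group_id = assignment, species = spec_of,
                    locus_key = sub("^[^:]*:", "", nodes),
                    n_s = n_s, stringsAsFactors = FALSE)
  out <- out[order(out$group_id, out$species, out$locus_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact maximum-score species-consistent partition of one small component;
# returns a list of integer vectors (blocks of global node indices)
partition_component_exact <- function(idx, species, ed) {
  n <- length(idx)
  if (n == 1L) return(list(idx))
  # adjacency and score lookup on local indices
  la <- match(ed$a, idx); lb <- match(ed$b, idx)
  smat <- matrix(0, n, n)
  adj <- matrix(FALSE, n, n)
  for (e in seq_along(la)) {
    smat[la[e], lb[e]] <- smat[la[e], lb[e]] + ed$score[e]
    smat[lb[e], la[e]] <- smat[la[e], lb[e]]
    adj[la[e], lb[e]] <- adj[lb[e], la[e]] <- TRUE
  }
  block_connected <- function(b) {
    if (length(b) < 2L) return(TRUE)
    seen <- b[1L]
    repeat {
      frontier <- setdiff(b[vapply(b, function(x) any(adj[x, seen]), TRUE)], seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
    length(seen) == length(b)
  }
  best_score <- -1
  best_blocks <- NULL
  recurse <- function(k, blocks, block_species, score) {
    if (k > n) {
      if (score > best_score && all(vapply(blocks, block_connected, TRUE))) {
        best_score <<- score
        best_blocks <<- blocks
      }
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      if (species[k] %in% block_species[[b]]) next
      gain <- sum(smat[k, blocks[[b]]])
      blocks2 <- blocks; blocks2[[b]] <- c(blocks2[[b]], k)
      bs2 <- block_species; bs2[[b]] <- c(bs2[[b]], species[k])
      recurse(k + 1L, blocks2, bs2, score + gain)
    }
    recurse(k + 1L, c(blocks, list(k)), c(block_species, list(species[k])), score)
  }
  recurse(2L, list(1L), list(species[1L]), 0)
  lapply(best_blocks, function(b) idx[b])
}

# greedy descending-score edge merge for large components
partition_component_greedy <- function(idx, species, ed) {
  grp <- seq_along(idx)
  spset <- as.list(species)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  if (nrow(ed)) {
    la <- match(ed$a, idx); lb <- match(ed$b, idx)
    for (e in order(-ed$score, la, lb)) {
      ia <- find(la[e]); ib <- find(lb[e])
      if (ia == ib) next
      if (!any(spset[[ia]] %in% spset[[ib]])) {
        grp[ib] <- ia
        spset[[ia]] <- c(spset[[ia]], spset[[ib]])
      }
    }
  }
  root <- vapply(seq_along(idx), find, 0L)
  lapply(split(seq_along(idx), root), function(b) idx[b])
}
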
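# Independent oracles and tiny in-code fixtures shared across the suite.

# ---- exhaustive-recursion local alignment oracle (memoized, top-down) ----
# Scores the best local alignment under match/mismatch scoring with affine
# gaps where a gap of length g costs |open| + (g-1)*|ext|.  States: M (column
# aligns a[i] with b[j]), X (gap column consuming a[i]), Y (gap column
# consuming b[j]).  Local: any prefix may be discarded for free; the best
# alignment never ends in a gap column under negative gap costs, but X/Y ends
# are included for completeness.
oracle_local_align <- function(a, b, match = 1, mismatch = -1, open = -2, ext = -1) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  memo <- new.env(parent = emptyenv())
  M <- function(i, j) {
    if (i < 1L || j < 1L) return(-Inf)
    key <- paste0("M", i, ".", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- if (av[i] == bv[j]) match else mismatch
    v <- s + max(0, M(i - 1L, j - 1L), X(i - 1L, j - 1L), Y(i - 1L, j - 1L))
    memo[[key]] <- v
    v
  }
  X <- function(i, j) {
    if (i < 1L || j < 0L) return(-Inf)
    key <- paste0("X", i, ".", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- max(M(i - 1L, j) + open, X(i - 1L, j) + ext, Y(i - 1L, j) + open)
    memo[[key]] <- v
    v
  }
  Y <- function(i, j) {
    if (i < 0L || j < 1L) return(-Inf)
    key <- paste0("Y", i, ".", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- max(M(i, j - 1L) + open, Y(i, j - 1L) + ext, X(i, j - 1L) + open)
    memo[[key]] <- v
    v
  }
  best <- 0
  for (i in seq_along(av)) for (j in seq_along(bv)) {
    best <- max(best, M(i, j), X(i, j), Y(i, j))
  }
  best
}

# ---- literal consensus-filter oracle ----
# Applies "detected by >= min_tools tools AND supported by >= min_reads BSJ
# reads" by plain enumeration over unique loci.
oracle_consensus <- function(calls, min_tools = 2L, min_reads = 2L) {
  if (nrow(calls) == 0L) return(character(0))
  keys <- paste(calls$chrom, calls$start, calls$end, calls$strand, sep = "|")
  survivors <- character(0)
  for (k in unique(keys)) {
    rows <- calls[keys == k, , drop = FALSE]
    n_tools <- length(unique(rows$tool))
    total <- 0
    for (s in unique(rows$sample_id)) {
      total <- total + max(rows$bsj_reads[rows$sample_id == s])
    }
    if (n_tools >= min_tools && total >= min_reads) survivors <- c(survivors, k)
  }
  sort(survivors)
}

# key in the oracle's format for a merge_calls record table
consensus_keys <- function(records) {
  sort(paste(records$chrom, records$start, records$end, records$strand, sep = "|"))
}

# ---- literal MCS component oracle ----
# marks: list(tissue -> character vector of expressing individuals);
# design: list(tissue -> character vector of all individuals)
oracle_nt_ni <- function(marks, design) {
  expressing_tissues <- names(marks)[vapply(marks, length, 1L) > 0L]
  n_t <- length(expressing_tissues) / length(design)
  if (length(expressing_tissues) == 0L) return(list(n_t = 0, n_i = NA_real_))
  marked_nodes <- length(expressing_tissues) +
    sum(vapply(marks[expressing_tissues], length, 1L))
  denom <- 2 * sum(vapply(design[expressing_tissues], length, 1L))
  list(n_t = n_t, n_i = marked_nodes / denom)
}

# ---- brute-force circular ORF oracle ----
# Scans the tripled sequence from every in-circle ATG, walking codons to the
# first stop (cap 3 laps), then applies the maximality definition: a start is
# suppressed by any ORF holding it as an interior codon that is longer, or
# equally long with an earlier start.
oracle_circular_orfs <- function(seq) {
  L <- nchar(seq)
  s4 <- paste(rep(seq, 4L), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  cand <- data.frame(start = integer(), length = integer(), has_stop = logical())
  for (p in seq_len(L) - 1L) {
    if (substr(s4, p + 1L, p + 3L) != "ATG") next
    q <- p; len <- 3L * L; has_stop <- FALSE
    while (q + 3L <= p + 3L * L) {
      cod <- substr(s4, q + 1L, q + 3L)
      if (cod %in% stops) { len <- q + 3L - p; has_stop <- TRUE; break }
      q <- q + 3L
    }
    cand <- rbind(cand, data.frame(start = p, length = len, has_stop = has_stop))
  }
  if (nrow(cand) == 0L) return(cand)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$length[i] < 6L) next
    interior <- (cand$start[i] + seq(3L, cand$length[i] - 3L, by = 3L)) %% L
    for (j in seq_len(nrow(cand))) {
      if (j == i) next
      if (cand$start[j] %in% interior &&
          (cand$length[j] < cand$length[i] ||
           (cand$length[j] == cand$length[i] && cand$start[j] > cand$start[i])))
        keep[j] <- FALSE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# ---- exhaustive ortholog-group assignment oracle ----
# Enumerates all set partitions of a component's nodes (n <= 6), keeps
# partitions whose blocks are species-consistent and edge-connected, and
# returns the maximum total within-block edge score.
oracle_best_partition_score <- function(nodes, species, edges) {
  n <- length(nodes)
  parts <- list(list())
  for (i in seq_len(n)) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_along(p)) {
        q <- p; q[[b]] <- c(q[[b]], i); nxt[[length(nxt) + 1L]] <- q
      }
      p[[length(p) + 1L]] <- i
      nxt[[length(nxt) + 1L]] <- p
    }
    parts <- nxt
  }
  edge_score <- function(block) {
    if (length(block) < 2L) return(0)
    s <- 0
    for (e in seq_len(nrow(edges))) {
      ia <- match(edges$a[e], nodes); ib <- match(edges$b[e], nodes)
      if (!is.na(ia) && !is.na(ib) && ia %in% block && ib %in% block)
        s <- s + edges$score[e]
    }
    s
  }
  connected <- function(block) {
    if (length(block) < 2L) return(TRUE)
    seen <- block[1L]
    repeat {
      grew <- FALSE
      for (e in seq_len(nrow(edges))) {
        ia <- match(edges$a[e], nodes); ib <- match(edges$b[e], nodes)
        if (is.na(ia) || is.na(ib)) next
        if (ia %in% seen && ib %in% block && !(ib %in% seen)) { seen <- c(seen, ib); grew <- TRUE }
        if (ib %in% seen && ia %in% block && !(ia %in% seen)) { seen <- c(seen, ia); grew <- TRUE }
      }
      if (!grew) break
    }
    length(seen) == length(block)
  }
  best <- 0
  for (p in parts) {
    ok <- all(vapply(p, function(b) !anyDuplicated(species[b]) && connected(b), TRUE))
    if (!ok) next
    best <- max(best, sum(vapply(p, edge_score, 0)))
  }
  best
}

# achieved within-group score of a build_ortholog_groups() result
achieved_group_score <- function(groups, rbh) {
  gid_of <- setNames(groups$group_id, paste(groups$species, groups$locus_key))
  s <- 0
  for (e in seq_len(nrow(rbh))) {
    ga <- gid_of[paste(rbh$species_a[e], rbh$locus_a[e])]
    gb <- gid_of[paste(rbh$species_b[e], rbh$locus_b[e])]
    if (!is.na(ga) && !is.na(gb) && ga == gb) s <- s + rbh$score[e]
  }
  s
}

# build an expression tree directly from a marks specification
# design: list(tissue -> individuals); marks: list(tissue -> expressing inds)
tree_from_marks <- function(marks, design, locus = "circA") {
  samples <- do.call(rbind, lapply(names(design), function(t)
    data.frame(sample_id = paste(t, design[[t]], sep = "_"),
               species_code = "hsa", tissue = t, individual = design[[t]],
               mapped_fragments = 1e6, stringsAsFactors = FALSE)))
  expr <- matrix(0, 1L, nrow(samples), dimnames = list(locus, samples$sample_id))
  for (t in names(marks)) for (ind in marks[[t]])
    expr[locus, paste(t, ind, sep = "_")] <- 2.0
  build_expression_tree(expr, samples)
}

# ---- tiny in-code gene fixture ----
# Three-exon gene on chr1 with UTRs carved from the terminal exons:
#   exons [100,200) [300,400) [500,600); 5'UTR [100,150); 3'UTR [550,600)
make_toy_gene <- function(gene_id = "g1", strand = "+", chrom = "chr1") {
  ex <- data.frame(start = c(100L, 300L, 500L), end = c(200L, 400L, 600L))
  utr5 <- data.frame(start = 100L, end = 150L)
  utr3 <- data.frame(start = 550L, end = 600L)
  if (strand == "-") { tmp <- utr5; utr5 <- utr3; utr3 <- tmp }
  structure(list(gene_id = gene_id, symbol = toupper(gene_id), chrom = chrom,
                 strand = strand,
                 transcripts = setNames(list(ex), paste0(gene_id, "_t1")),
                 utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

make_toy_genome <- function(len = 2000L, seed = 42L, species = "hsa") {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  genome_ref(c(chr1 = seq), species)
}

random_calls <- function(n, n_loci = 6L, tools = c("CIRI2", "DCC", "find_circ", "CIRCexplorer2"),
                         samples = c("s1", "s2", "s3")) {
  loci <- data.frame(chrom = "chr1",
                     start = sample.int(1000L, n_loci) * 10L,
                     strand = sample(c("+", "-"), n_loci, replace = TRUE))
  loci$end <- loci$start + sample(100:400, n_loci, replace = TRUE)
  idx <- sample.int(n_loci, n, replace = TRUE)
  data.frame(sample_id = sample(samples, n, replace = TRUE),
             tool = sample(tools, n, replace = TRUE),
             chrom = loci$chrom[idx], start = loci$start[idx],
             end = loci$end[idx], strand = loci$strand[idx],
             bsj_reads = sample(0:6, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

toy_samples <- function(ids = c("s1", "s2", "s3"), species = "hsa",
                        mapped = 1e6) {
  data.frame(sample_id = ids, species_code = species,
             tissue = paste0("t", seq_along(ids)),
             individual = "ind1", mapped_fragments = mapped,
             stringsAsFactors = FALSE)
}
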
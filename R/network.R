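# ---- integrated circRNA / mRNA / miRNA / RBP annotation network ----

#' Aggregate a per-sample expression matrix to per-tissue means
#'
#' @param expr matrix, rows = loci/genes, cols = sample ids
#' @param samples sample sheet mapping samples to tissues
#' @return matrix rows x tissues of mean expression
#' @export
aggregate_by_tissue <- function(expr, samples) {
  s <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (any(is.na(s$sample_id))) stop("aggregate_by_tissue: unknown sample columns")
  tissues <- sort(unique(s$tissue))
  out <- vapply(tissues, function(t)
    rowMeans(expr[, s$tissue == t, drop = FALSE]), numeric(nrow(expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(expr), dimnames = list(rownames(expr), tissues))
  out
}

#' Co-expression edges between circRNAs and mRNAs
#'
#' Nodes expressed in fewer than `min_tissues` tissues are removed first, so
#' the breadth filter and the correlation act on the same (per-tissue) axis.
#' Pearson correlation over per-tissue means is then computed for every pair
#' containing at least one circRNA, and the weak-correlation filter keeps
#' edges with correlation at or above `r_min` (absolute value with
#' `keep_anticorrelated = TRUE`).  Constant profiles have undefined
#' correlation and are skipped with a warning.
#'
#' @param tissue_expr joint circRNA + mRNA matrix aggregated per tissue (>= 3
#'   tissue columns)
#' @param circ_ids which row names are circRNAs
#' @param r_min correlation threshold (default 0.5)
#' @param min_tissues minimum expressed-tissue breadth for a node (default 3)
#' @param keep_anticorrelated also keep strong negative correlations
#' @return data.frame with `node_a`, `node_b`, `r` (node_a is the circRNA)
#' @export
coexpression_edges <- function(tissue_expr, circ_ids, r_min = 0.5,
                               min_tissues = 3L, keep_anticorrelated = FALSE) {
  if (ncol(tissue_expr) < 3L) stop("coexpression_edges: need >= 3 tissue columns")
  breadth <- rowSums(tissue_expr > 0)
  kept <- tissue_expr[breadth >= min_tissues, , drop = FALSE]
  empty <- data.frame(node_a = character(), node_b = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  circs <- intersect(rownames(kept), circ_ids)
  if (!length(circs) || nrow(kept) < 2L) return(empty)
  sds <- apply(kept, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant profile(s) skipped (undefined correlation)")
    kept <- kept[sds > 0, , drop = FALSE]
    circs <- intersect(rownames(kept), circ_ids)
    if (!length(circs) || nrow(kept) < 2L) return(empty)
  }
  cm <- stats::cor(t(kept))
  out <- list()
  for (ci in circs) {
    partners <- setdiff(rownames(kept), ci)
    r <- cm[ci, partners]
    keep <- if (keep_anticorrelated) abs(r) >= r_min else r >= r_min
    if (any(keep)) {
      out[[ci]] <- data.frame(node_a = ci, node_b = partners[keep],
                              r = unname(r[keep]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  ed <- do.call(rbind, out)
  # de-duplicate circ-circ pairs reported in both directions
  pair_key <- ifelse(ed$node_b %in% circs & ed$node_b < ed$node_a,
                     paste(ed$node_b, ed$node_a), paste(ed$node_a, ed$node_b))
  ed <- ed[!duplicated(pair_key), , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

# target-site strings (5'->3' DNA) for a miRNA's canonical seed classes
seed_patterns <- function(mirna) {
  mir <- toupper(gsub("U", "T", mirna))
  if (nchar(mir) < 8L) stop("mirna_seed_sites: miRNA shorter than 8 nt")
  rc28 <- revcomp(substr(mir, 2L, 8L))   # 7 nt, matches miRNA positions 2-8
  rc27 <- revcomp(substr(mir, 2L, 7L))   # 6 nt, matches positions 2-7
  list(`8mer` = paste0(rc28, "A"), `7mer-m8` = rc28,
       `7mer-A1` = paste0(rc27, "A"), `6mer` = rc27)
}

#' Scan circRNA sequences for canonical miRNA seed sites
#'
#' Reports 6mer, 7mer-A1, 7mer-m8 and 8mer matches of each miRNA's seed
#' (reverse complement of miRNA positions 2-7/2-8, with the site-type "A"
#' opposite position 1 where applicable) on each circular sequence.  The scan
#' runs on the circular context (sequence extended by its first 7 nt), so
#' sites straddling the back-splice junction are found.  Overlapping matches
#' of one miRNA at the same seed register are reported once, as the most
#' specific type.
#'
#' @param circ_seqs named character vector of circRNA sequences (DNA or RNA)
#' @param mirnas named character vector of mature miRNA sequences (>= 8 nt)
#' @return data.frame with `circ_id`, `mirna`, `position` (0-based site start
#'   on the circle), `type`, `spans_bsj`
#' @export
mirna_seed_sites <- function(circ_seqs, mirnas) {
  empty <- data.frame(circ_id = character(), mirna = character(),
                      position = integer(), type = character(),
                      spans_bsj = logical(), stringsAsFactors = FALSE)
  if (!length(mirnas) || !length(circ_seqs)) return(empty)
  out <- list()
  for (cid in names(circ_seqs)) {
    seq <- toupper(gsub("U", "T", circ_seqs[[cid]]))
    L <- nchar(seq)
    ctx <- paste0(seq, substr(seq, 1L, min(7L, L)))
    for (mid in names(mirnas)) {
      pats <- seed_patterns(mirnas[[mid]])
      seen_register <- integer(0)  # 6mer-core start positions already typed
      for (ty in names(pats)) {
        p <- pats[[ty]]
        hits <- gregexpr(p, ctx, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (h in as.integer(hits)) {
          site_start <- h - 1L                       # 0-based on ctx
          core <- if (ty %in% c("8mer", "7mer-m8")) site_start + 1L else site_start
          if (site_start >= L) next                  # second-lap duplicate
          if (core %% L %in% seen_register) next
          seen_register <- c(seen_register, core %% L)
          out[[length(out) + 1L]] <- data.frame(
            circ_id = cid, mirna = mid, position = site_start, type = ty,
            spans_bsj = site_start + nchar(p) > L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$circ_id, res$mirna, res$position), , drop = FALSE]
}

#' circRNA--RBP edges from CLIP peaks near back-splice junctions
#'
#' An RBP is linked to a circRNA when any of its CLIP peaks overlaps the
#' 1-kb (default) windows on both sides of either BSJ coordinate, i.e.
#' `[start - window, start + window)` or `[end - window, end + window)` on
#' the circle's chromosome (strand-agnostic).
#'
#' @param records circRNA records (`chrom`, `start`, `end`, `locus_key`)
#' @param peaks CLIP peak BED data.frame; the `name` column carries the RBP
#' @param window half-window in bp around each BSJ coordinate (default 1000)
#' @return data.frame with `locus_key`, `rbp`, `peak_count`, `min_dist`
#'   (minimum distance from a supporting peak to the nearest BSJ coordinate)
#' @export
rbp_edges <- function(records, peaks, window = 1000L) {
  empty <- data.frame(locus_key = character(), rbp = character(),
                      peak_count = integer(), min_dist = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L || nrow(peaks) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(records))) {
    p <- peaks[peaks$chrom == records$chrom[i], , drop = FALSE]
    if (!nrow(p)) next
    s <- records$start[i]; e <- records$end[i]
    hit <- (p$start < s + window & p$end > s - window) |
           (p$start < e + window & p$end > e - window)
    if (!any(hit)) next
    p <- p[hit, , drop = FALSE]
    # distance from a peak to a BSJ point (0 when the peak covers it)
    dist_to <- function(q) ifelse(p$start <= q & q < p$end, 0L,
                                  pmin(abs(p$start - q), abs(q - (p$end - 1L))))
    d <- pmin(dist_to(s), dist_to(e))
    agg <- tapply(d, p$name, function(v) c(n = length(v), dmin = min(v)))
    for (rbp in names(agg)) {
      out[[length(out) + 1L]] <- data.frame(
        locus_key = records$locus_key[i], rbp = rbp,
        peak_count = as.integer(agg[[rbp]]["n"]),
        min_dist = as.integer(agg[[rbp]]["dmin"]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the typed annotation network
#'
#' Builds an \pkg{igraph} graph over circRNA, mRNA, miRNA and RBP nodes with
#' evidence-tagged edges: `coexpression` (weight = r), `mirna_binding`
#' (site count, site types) and `rbp_binding` (peak count, min distance).
#'
#' @param coexp [coexpression_edges()] output (may be NULL)
#' @param seed_sites [mirna_seed_sites()] output (may be NULL)
#' @param rbp [rbp_edges()] output (may be NULL)
#' @param circ_ids character vector of all circRNA node names
#' @return igraph object with vertex attribute `type` and edge attributes
#'   `etype`, `weight`, `sites`, `site_types`, `peaks`, `min_dist`
#' @export
build_annotation_network <- function(coexp = NULL, seed_sites = NULL, rbp = NULL,
                                     circ_ids = character()) {
  edges <- list()
  if (!is.null(coexp) && nrow(coexp)) {
    edges$co <- data.frame(from = coexp$node_a, to = coexp$node_b,
                           etype = "coexpression", weight = coexp$r,
                           sites = NA_integer_, site_types = NA_character_,
                           peaks = NA_integer_, min_dist = NA_integer_,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(seed_sites) && nrow(seed_sites)) {
    agg <- stats::aggregate(type ~ circ_id + mirna, data = seed_sites,
                            FUN = function(x) paste(sort(unique(x)), collapse = ","))
    cnt <- stats::aggregate(position ~ circ_id + mirna, data = seed_sites, FUN = length)
    agg$sites <- cnt$position[match(paste(agg$circ_id, agg$mirna),
                                    paste(cnt$circ_id, cnt$mirna))]
    edges$mir <- data.frame(from = agg$circ_id, to = agg$mirna,
                            etype = "mirna_binding", weight = NA_real_,
                            sites = agg$sites, site_types = agg$type,
                            peaks = NA_integer_, min_dist = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(rbp) && nrow(rbp)) {
    edges$rbp <- data.frame(from = rbp$locus_key, to = rbp$rbp,
                            etype = "rbp_binding", weight = NA_real_,
                            sites = NA_integer_, site_types = NA_character_,
                            peaks = rbp$peak_count, min_dist = rbp$min_dist,
                            stringsAsFactors = FALSE)
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), etype = character(),
               weight = numeric(), sites = integer(), site_types = character(),
               peaks = integer(), min_dist = integer(), stringsAsFactors = FALSE)
  mirna_nodes <- unique(ed$to[ed$etype == "mirna_binding"])
  rbp_nodes <- unique(ed$to[ed$etype == "rbp_binding"])
  all_nodes <- unique(c(circ_ids, ed$from, ed$to))
  vtype <- ifelse(all_nodes %in% circ_ids, "circRNA",
                  ifelse(all_nodes %in% mirna_nodes, "miRNA",
                         ifelse(all_nodes %in% rbp_nodes, "RBP", "mRNA")))
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = all_nodes, type = vtype, stringsAsFactors = FALSE))
  g
}

#' Propagate GO/KEGG terms to circRNAs from their network neighbors
#'
#' For each circRNA, the gene set of its annotated neighbors is tested per
#' term with the hypergeometric upper tail `P(X >= k)` against the universe of
#' all annotated genes in the network, followed by Benjamini--Hochberg
#' correction across terms within the circRNA.
#'
#' @param network igraph from [build_annotation_network()]
#' @param terms data.frame with columns `gene_id`, `term_id`
#' @param universe optional character vector of universe genes (default: all
#'   annotated genes present in the network)
#' @return data.frame with `circ_id`, `term_id`, `support`, `n_neighbors`,
#'   `p`, `q`, sorted by `q` within circRNA
#' @export
propagate_function <- function(network, terms, universe = NULL) {
  if (nrow(terms) == 0L) stop("propagate_function: empty term table")
  vnames <- igraph::V(network)$name
  vtype <- igraph::V(network)$type
  if (is.null(universe))
    universe <- intersect(unique(terms$gene_id), vnames)
  terms <- terms[terms$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  term_genes <- split(terms$gene_id, terms$term_id)
  circs <- vnames[vtype == "circRNA"]
  out <- list()
  for (ci in circs) {
    nb <- igraph::neighbors(network, ci)$name
    genes <- intersect(nb, universe)
    n <- length(genes)
    if (n == 0L) next
    rows <- list()
    for (tid in names(term_genes)) {
      tg <- unique(term_genes[[tid]])
      K <- length(tg)
      k <- length(intersect(genes, tg))
      if (k == 0L) next
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[tid]] <- data.frame(circ_id = ci, term_id = tid, support = k,
                                n_neighbors = n, p = p, stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df$q <- stats::p.adjust(df$p, method = "BH")
    out[[ci]] <- df[order(df$q, df$p, df$term_id), , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(circ_id = character(), term_id = character(),
                      support = integer(), n_neighbors = integer(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank RBPs and miRNAs by the number of interacting circRNAs
#'
#' @param network igraph from [build_annotation_network()]
#' @return data.frame with `node`, `type`, `n_circ` sorted descending
#'   (ties lexicographic)
#' @export
rank_interactors <- function(network) {
  vnames <- igraph::V(network)$name
  vtype <- igraph::V(network)$type
  targets <- vnames[vtype %in% c("RBP", "miRNA")]
  if (!length(targets)) {
    return(data.frame(node = character(), type = character(),
                      n_circ = integer(), stringsAsFactors = FALSE))
  }
  n_circ <- vapply(targets, function(v) {
    nb <- igraph::neighbors(network, v)$name
    length(unique(nb[nb %in% vnames[vtype == "circRNA"]]))
  }, 0L)
  out <- data.frame(node = targets, type = vtype[match(targets, vnames)],
                    n_circ = n_circ, stringsAsFactors = FALSE)
  out <- out[order(-out$n_circ, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import external miRNA-target predictions and combine with seed scans
#'
#' External predictor output (any tool) supplied as a TSV with columns
#' `circ_id`, `mirna` can be unioned (default) or intersected with the
#' internal canonical-seed calls, standing in for a multi-tool ensemble.
#'
#' @param seed_sites internal [mirna_seed_sites()] calls
#' @param external data.frame (or TSV path) with `circ_id`, `mirna`
#' @param mode `"union"` or `"intersect"`
#' @return data.frame of (circ_id, mirna) interaction pairs with a `source`
#'   column (`internal`, `external` or `both`)
#' @export
combine_mirna_predictions <- function(seed_sites, external, mode = c("union", "intersect")) {
  mode <- match.arg(mode)
  if (is.character(external) && length(external) == 1L)
    external <- data.table::fread(external, sep = "\t", header = TRUE, data.table = FALSE)
  int_pairs <- unique(seed_sites[c("circ_id", "mirna")])
  ext_pairs <- unique(external[c("circ_id", "mirna")])
  ik <- paste(int_pairs$circ_id, int_pairs$mirna)
  ek <- paste(ext_pairs$circ_id, ext_pairs$mirna)
  if (mode == "intersect") {
    keep <- int_pairs[ik %in% ek, , drop = FALSE]
    if (nrow(keep)) keep$source <- "both"
    else keep$source <- character(0)
    return(keep)
  }
  all <- rbind(int_pairs, ext_pairs)
  keys <- c(ik, ek)
  out <- all[!duplicated(keys), , drop = FALSE]
  uk <- keys[!duplicated(keys)]
  out$source <- ifelse(uk %in% ik & uk %in% ek, "both",
                       ifelse(uk %in% ik, "internal", "external"))
  rownames(out) <- NULL
  out
}
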
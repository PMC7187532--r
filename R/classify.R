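# ---- host-gene assignment and subclass classification ----

# exonic overlap (bp) between [start,end) and a gene's exon union
exonic_overlap <- function(gene, start, end) {
  ex <- gene_exon_union(gene)
  if (!nrow(ex)) return(0L)
  sum(pmax(0L, pmin(ex$end, end) - pmax(ex$start, start)))
}

#' Assign a host gene to a circRNA locus
#'
#' The host is the same-strand gene whose exon/intron span contains both BSJ
#' coordinates.  If no same-strand gene contains the locus, a containing gene
#' on the opposite strand is returned with orientation `"antisense"`;
#' otherwise the locus is intergenic (`NULL` host).  Among multiple candidate
#' genes, the one with the largest exonic overlap with `[start, end)` wins;
#' ties break lexicographically by `gene_id`.
#'
#' @param chrom,start,end,strand circRNA BSJ coordinates (0-based half-open)
#' @param genes named list of gene models ([parse_gtf()])
#' @return list with `gene_id` (or `NA`), `orientation` (`"sense"`,
#'   `"antisense"` or `NA`)
#' @export
assign_host_gene <- function(chrom, start, end, strand, genes) {
  cand_ids <- names(genes)[vapply(genes, function(g) {
    if (g$chrom != chrom || !length(g$transcripts)) return(FALSE)
    sp <- gene_span(g)
    sp[1L] <= start && end <= sp[2L]
  }, TRUE)]
  if (!length(cand_ids)) return(list(gene_id = NA_character_, orientation = NA_character_))
  pick <- function(ids) {
    ov <- vapply(genes[ids], exonic_overlap, 0L, start = start, end = end)
    ids[order(-ov, ids)][1L]
  }
  same <- cand_ids[vapply(genes[cand_ids], function(g) g$strand == strand, TRUE)]
  if (length(same)) return(list(gene_id = pick(same), orientation = "sense"))
  list(gene_id = pick(cand_ids), orientation = "antisense")
}

in_intervals <- function(p, iv) {
  if (is.null(iv) || !nrow(iv)) return(FALSE)
  any(iv$start <= p & p < iv$end)
}

intervals_overlap <- function(s1, e1, iv) {
  if (is.null(iv) || !nrow(iv)) return(FALSE)
  any(pmax(s1, iv$start) < pmin(e1, iv$end))
}

# transcript of a gene maximizing exonic agreement with [start,end)
best_transcript <- function(gene, start, end) {
  if (!length(gene$transcripts)) return(NULL)
  ov <- vapply(gene$transcripts, function(ex)
    sum(pmax(0L, pmin(ex$end, end) - pmax(ex$start, start))), 0L)
  gene$transcripts[[order(-ov, names(gene$transcripts))[1L]]]
}

# introns of an exon table (gaps between consecutive exons)
transcript_introns <- function(ex) {
  if (nrow(ex) < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
}

# the intron immediately upstream of `start` / downstream of `end` (genomic)
flanking_introns <- function(ex, start, end) {
  introns <- transcript_introns(ex)
  up <- introns[introns$end <= start, , drop = FALSE]
  up <- if (nrow(up)) up[which.max(up$end), ] else NULL
  down <- introns[introns$start >= end, , drop = FALSE]
  down <- if (nrow(down)) down[which.min(down$start), ] else NULL
  if (!is.null(up)) rownames(up) <- NULL
  if (!is.null(down)) rownames(down) <- NULL
  list(upstream = up, downstream = down)
}

#' Classify a circRNA into its genomic subclass
#'
#' Decision cascade on a single locus, given its host-gene assignment:
#' intergenic (no host) -> antisense (opposite-strand host) -> then, on the
#' sense host: `5utr` if either BSJ coordinate lies in an annotated 5'-UTR,
#' else `3utr` likewise, else `exonic` (lenient mode, the default: both BSJ
#' coordinates lie within exons), else `intronic` if the circle lies entirely
#' inside one intron.  A locus matching none of these (one junction in an
#' exon, the other in an intron) is labelled `exonic` when it overlaps any
#' exon and `intronic` otherwise, so classification is total.  In strict mode
#' `exonic` instead requires the circle's start and end to coincide with
#' annotated exon boundaries (splice sites), and every non-matching circle on
#' the sense host is pooled as intron-derived (`intronic`).
#'
#' The orthogonal `non_repeat` flag is defined only when both flanking introns
#' (on the transcript with the greatest exonic agreement) exist: it is `TRUE`
#' iff neither intron overlaps a repeat interval, and `NA` otherwise.
#'
#' @param chrom,start,end,strand BSJ coordinates
#' @param host result of [assign_host_gene()]
#' @param genes gene model list
#' @param repeats optional repeat annotation (data.frame from [read_bed()])
#' @param exonic_mode `"lenient"` (default) or `"strict"` boundary matching
#' @return list with `subclass`, `non_repeat`, `flank_upstream`,
#'   `flank_downstream` (intron intervals or NULL)
#' @export
classify_subclass <- function(chrom, start, end, strand, host, genes,
                              repeats = NULL, exonic_mode = c("lenient", "strict")) {
  exonic_mode <- match.arg(exonic_mode)
  res <- list(subclass = NA_character_, non_repeat = NA,
              flank_upstream = NULL, flank_downstream = NULL)
  if (is.na(host$gene_id)) { res$subclass <- "intergenic"; return(res) }
  if (identical(host$orientation, "antisense")) { res$subclass <- "antisense"; return(res) }
  gene <- genes[[host$gene_id]]
  p1 <- start; p2 <- end - 1L   # the two BSJ base positions
  ex_union <- gene_exon_union(gene)
  if (in_intervals(p1, gene$utr5) || in_intervals(p2, gene$utr5)) {
    res$subclass <- "5utr"
  } else if (in_intervals(p1, gene$utr3) || in_intervals(p2, gene$utr3)) {
    res$subclass <- "3utr"
  } else {
    all_ex <- do.call(rbind, gene$transcripts)
    exonic <- if (exonic_mode == "strict") {
      any(all_ex$start == start) && any(all_ex$end == end)
    } else {
      in_intervals(p1, ex_union) && in_intervals(p2, ex_union)
    }
    if (exonic) {
      res$subclass <- "exonic"
    } else if (exonic_mode == "strict") {
      # strict mode reserves "exonic" for splice-site-matching circles and
      # pools everything else on the sense host as intron-derived
      res$subclass <- "intronic"
    } else {
      inside_intron <- any(vapply(gene$transcripts, function(ex) {
        introns <- transcript_introns(ex)
        nrow(introns) > 0L && any(introns$start <= start & end <= introns$end)
      }, TRUE))
      if (inside_intron) res$subclass <- "intronic"
      else res$subclass <- if (intervals_overlap(start, end, ex_union)) "exonic" else "intronic"
    }
  }
  bt <- best_transcript(gene, start, end)
  if (!is.null(bt)) {
    fl <- flanking_introns(bt, start, end)
    res$flank_upstream <- fl$upstream
    res$flank_downstream <- fl$downstream
    if (!is.null(fl$upstream) && !is.null(fl$downstream)) {
      hit <- FALSE
      if (!is.null(repeats) && nrow(repeats)) {
        rp <- repeats[repeats$chrom == chrom, , drop = FALSE]
        hit <- intervals_overlap(fl$upstream$start, fl$upstream$end, rp) ||
          intervals_overlap(fl$downstream$start, fl$downstream$end, rp)
      }
      res$non_repeat <- !hit
    }
  }
  res
}

#' Classify a table of consensus records
#'
#' Vectorized wrapper: assigns host gene, orientation, subclass and the
#' non-repeat flag to every record.
#'
#' @param records consensus record data.frame ([merge_calls()])
#' @param genes gene model list
#' @param repeats optional repeat BED data.frame
#' @param exonic_mode passed to [classify_subclass()]
#' @return `records` with added columns `host_gene`, `host_symbol`,
#'   `orientation`, `subclass`, `non_repeat`
#' @export
classify_records <- function(records, genes, repeats = NULL,
                             exonic_mode = c("lenient", "strict")) {
  exonic_mode <- match.arg(exonic_mode)
  n <- nrow(records)
  host_gene <- character(n); orientation <- character(n)
  subclass <- character(n); non_repeat <- rep(NA, n); host_symbol <- character(n)
  for (i in seq_len(n)) {
    h <- assign_host_gene(records$chrom[i], records$start[i], records$end[i],
                          records$strand[i], genes)
    s <- classify_subclass(records$chrom[i], records$start[i], records$end[i],
                           records$strand[i], h, genes, repeats, exonic_mode)
    host_gene[i] <- h$gene_id
    host_symbol[i] <- if (is.na(h$gene_id)) NA_character_ else genes[[h$gene_id]]$symbol
    orientation[i] <- h$orientation
    subclass[i] <- s$subclass
    non_repeat[i] <- s$non_repeat
  }
  records$host_gene <- host_gene
  records$host_symbol <- host_symbol
  records$orientation <- orientation
  records$subclass <- subclass
  records$non_repeat <- non_repeat
  records
}

#' Assign atlas-style circRNA identifiers
#'
#' Gene-hosted records get `"<species>-<symbol>_<ordinal>"` with a 4-digit
#' zero-padded ordinal ranked by MCS descending within the host gene (so
#' `_0001` is the most conserved circRNA of that gene); ties break by
#' `(chrom, start, end)`.  Intergenic records, and antisense records without a
#' host symbol, fall back to `"<species>-<locus_key>"`.  IDs are unique within
#' a species.
#'
#' @param records classified records carrying an `mcs` column (and
#'   `host_symbol`); duplicate locus keys abort
#' @return `records` with an added `circ_id` column
#' @export
assign_ids <- function(records) {
  if (anyDuplicated(records$locus_key)) stop("assign_ids: duplicate locus_key")
  if (is.null(records$mcs)) stop("assign_ids: records lack an mcs column; compute MCS first")
  id <- character(nrow(records))
  hosted <- !is.na(records$host_symbol)
  for (sym in unique(records$host_symbol[hosted])) {
    idx <- which(hosted & records$host_symbol == sym)
    o <- idx[order(-records$mcs[idx], records$chrom[idx],
                   records$start[idx], records$end[idx])]
    id[o] <- sprintf("%s-%s_%04d", records$species_code[o], sym, seq_along(o))
  }
  id[!hosted] <- sprintf("%s-%s", records$species_code[!hosted],
                         records$locus_key[!hosted])
  records$circ_id <- id
  records
}

# ---- circular ORF search ----

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames on a circular sequence
#'
#' Translation on a circular template can run past the back-splice junction
#' and, when the circle length is not a multiple of 3, shift frame on each
#' lap.  The search therefore scans the tripled sequence from every in-circle
#' ATG and extends to the first stop codon, capping at 3 laps (rolling-circle
#' bound): an ORF that never meets a stop is reported with length `3 * L` and
#' flagged.  Only maximal ORFs are reported (an ATG that is an internal codon
#' of a longer reported ORF is suppressed).
#'
#' @param seq circular nucleotide sequence (A/C/G/T), length >= 3
#' @return data.frame with columns `start` (0-based offset on the circle),
#'   `length` (nt, multiple of 3, stop included), `spans_bsj`, `has_stop`,
#'   `peptide_length` (aa, stop excluded)
#' @export
find_circular_orfs <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("find_circular_orfs: sequence shorter than 3 nt")
  if (grepl("[^ACGT]", seq)) stop("find_circular_orfs: non-ACGT characters")
  L <- nchar(seq)
  s4 <- strrep(seq, 4L)
  codon_at <- function(p) substr(s4, p + 1L, p + 3L)  # p 0-based
  cand <- list()
  for (p in 0:(L - 1L)) {
    if (codon_at(p) != "ATG") next
    len <- NA_integer_; has_stop <- FALSE
    q <- p
    while (q + 3L <= p + 3L * L) {
      if (codon_at(q) %in% STOP_CODONS) { len <- q + 3L - p; has_stop <- TRUE; break }
      q <- q + 3L
    }
    if (!has_stop) len <- 3L * L  # capped at 3 laps, flagged via has_stop
    cand[[length(cand) + 1L]] <- list(start = p, length = len, has_stop = has_stop)
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), length = integer(), spans_bsj = logical(),
                      has_stop = logical(), peptide_length = integer()))
  }
  # suppress ORFs whose start ATG is an internal codon of another ORF
  starts <- vapply(cand, `[[`, 0L, "start")
  lens <- vapply(cand, `[[`, 0L, "length")
  internal <- rep(FALSE, length(cand))
  for (i in seq_along(cand)) {
    li <- lens[i]
    if (li < 6L) next
    interior <- (starts[i] + seq(3L, li - 3L, by = 3L)) %% L
    # suppress strictly shorter ORFs starting at an interior codon of i;
    # among equal-length rotations of one circular ORF keep the earliest start
    sup <- starts %in% interior &
      (lens < li | (lens == li & starts > starts[i]))
    internal <- internal | sup
  }
  keep <- which(!internal)
  out <- data.frame(
    start = starts[keep],
    length = lens[keep],
    spans_bsj = starts[keep] + lens[keep] > L,
    has_stop = vapply(cand[keep], `[[`, TRUE, "has_stop")
  )
  out$peptide_length <- (out$length - ifelse(out$has_stop, 3L, 0L)) %/% 3L
  out[order(out$start), , drop = FALSE]
}
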
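#' Canonical circRNA locus key
#'
#' A circRNA is identified by its back-splice junction: chromosome, 0-based
#' half-open interval, and strand, encoded as `"chrom:start|end:strand"`.
#' The encoding is bijective with its inputs (see [parse_locus_key()]).
#'
#' @param chrom chromosome name(s)
#' @param start 0-based start (first base of the circle)
#' @param end exclusive end (one past the last base); must exceed `start`
#' @param strand `"+"` or `"-"`
#' @return character vector of keys
#' @examples
#' locus_key("chr1", 100, 500, "+")
#' @export
locus_key <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("locus_key: non-integer coordinates")
  if (any(start >= end)) stop("locus_key: start must be < end")
  if (!all(strand %in% c("+", "-"))) stop("locus_key: strand must be '+' or '-'")
  sprintf("%s:%d|%d:%s", chrom, start, end, strand)
}

#' Parse a locus key back into its components
#'
#' @param key character vector of keys produced by [locus_key()]
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`
#' @export
parse_locus_key <- function(key) {
  m <- regmatches(key, regexec("^(.+):([0-9]+)\\|([0-9]+):([+-])$", key))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("parse_locus_key: malformed key(s): ", paste(key[bad], collapse = ", "))
  data.frame(
    chrom  = vapply(m, `[`, "", 2L),
    start  = as.integer(vapply(m, `[`, "", 3L)),
    end    = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

#' Construct a genome reference
#'
#' Bundles a species code (3-letter prefix such as `hsa` or `mmu`) with its
#' chromosome sequences.  The alphabet is restricted to A, C, G, T, N.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet]
#' @param species_code 3-letter species prefix
#' @return object of class `genome_ref` with elements `species_code`, `seqs`
#' @export
genome_ref <- function(sequences, species_code) {
  if (!methods::is(sequences, "DNAStringSet")) sequences <- Biostrings::DNAStringSet(sequences)
  nm <- names(sequences)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("genome_ref: chromosome names must be present and unique")
  if (!grepl("^[a-z]{3}$", species_code))
    stop("genome_ref: species_code must be a 3-letter lowercase prefix")
  freq <- Biostrings::alphabetFrequency(sequences)
  allowed <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(other > 0)) stop("genome_ref: sequence alphabet restricted to A/C/G/T/N")
  structure(list(species_code = species_code, seqs = sequences), class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %s: %d sequence(s), %s bp total\n",
              x$species_code, length(x$seqs),
              format(sum(Biostrings::width(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Read a genome FASTA into a genome_ref
#' @param path FASTA file
#' @param species_code 3-letter species prefix
#' @export
read_genome <- function(path, species_code) {
  genome_ref(Biostrings::readDNAStringSet(path), species_code)
}

# slice [start, end) 0-based half-open out of a genome chromosome
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seqs)) stop("genome_slice: unknown chromosome ", chrom)
  as.character(Biostrings::subseq(genome$seqs[[chrom]], start + 1L, end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Parse a GTF annotation into gene models
#'
#' Reads a GTF2.2-style annotation (via \pkg{rtracklayer}) and groups exon and
#' UTR features into one gene model per `gene_id`.  Coordinates are converted
#' from GTF 1-based closed to the package-wide 0-based half-open convention.
#' Records with unknown strand are rejected with a warning; lines whose
#' attribute column lacks `gene_id` abort with the offending line number.
#'
#' @param path GTF file
#' @return named list of `gene_model` objects, each with elements `gene_id`,
#'   `symbol`, `chrom`, `strand`, `transcripts` (named list of exon
#'   data.frames with `start`/`end`), `utr5`, `utr3`
#' @export
parse_gtf <- function(path) {
  raw <- readLines(path)
  body <- which(!grepl("^#", raw) & nzchar(raw))
  if (length(body) == 0L) return(structure(list(), names = character()))
  nfield <- vapply(strsplit(raw[body], "\t", fixed = TRUE), length, 1L)
  if (any(nfield < 9L))
    stop("GTF parse error at line ", body[which(nfield < 9L)[1L]],
         ": expected 9 tab-separated fields")
  no_gid <- !grepl("gene_id", raw[body])
  if (any(no_gid))
    stop("GTF parse error at line ", body[which(no_gid)[1L]],
         ": attribute string lacks gene_id")
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  type <- tolower(as.character(df$type))
  is_exon <- type == "exon"
  is_u5 <- type %in% c("five_prime_utr", "5utr", "utr5")
  is_u3 <- type %in% c("three_prime_utr", "3utr", "utr3")
  keep <- is_exon | is_u5 | is_u3
  df <- df[keep, , drop = FALSE]
  type <- type[keep]
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  bad_strand <- !(df$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    warning(sum(bad_strand), " GTF record(s) with unknown strand rejected")
    df <- df[!bad_strand, , drop = FALSE]
    type <- type[!bad_strand]
  }
  # 1-based closed -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  out <- list()
  for (gid in unique(df$gene_id)) {
    g <- df[df$gene_id == gid, , drop = FALSE]
    gt <- type[df$gene_id == gid]
    ex <- g[gt == "exon", , drop = FALSE]
    symbol <- gid
    if ("gene_name" %in% names(g)) {
      sy <- g$gene_name[!is.na(g$gene_name)]
      if (length(sy)) symbol <- sy[1L]
    }
    transcripts <- list()
    if (nrow(ex)) {
      for (tid in unique(ex$transcript_id)) {
        e <- ex[ex$transcript_id == tid, , drop = FALSE]
        e <- e[order(e$start0), , drop = FALSE]
        ivs <- data.frame(start = e$start0, end = e$end0)
        if (nrow(ivs) > 1L && any(ivs$start[-1L] < ivs$end[-nrow(ivs)]))
          stop("parse_gtf: overlapping exons in transcript ", tid)
        transcripts[[tid]] <- ivs
      }
    }
    iv_of <- function(sel) {
      u <- g[sel, , drop = FALSE]
      if (!nrow(u)) return(NULL)
      u <- u[order(u$start0), , drop = FALSE]
      unique(data.frame(start = u$start0, end = u$end0))
    }
    out[[gid]] <- structure(list(
      gene_id = gid, symbol = symbol,
      chrom = ex$seqnames[1L] %||% g$seqnames[1L],
      strand = ex$strand[1L] %||% g$strand[1L],
      transcripts = transcripts,
      utr5 = iv_of(gt %in% c("five_prime_utr", "5utr", "utr5")),
      utr3 = iv_of(gt %in% c("three_prime_utr", "3utr", "utr3"))
    ), class = "gene_model")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s%s, %d transcript(s)\n",
              x$gene_id, x$symbol, x$chrom, x$strand, length(x$transcripts)))
  invisible(x)
}

# union of exon intervals across transcripts of one gene, as a data.frame
gene_exon_union <- function(gene) {
  if (!length(gene$transcripts)) return(data.frame(start = integer(), end = integer()))
  all <- do.call(rbind, gene$transcripts)
  ir <- IRanges::reduce(IRanges::IRanges(all$start + 1L, all$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

gene_span <- function(gene) {
  ex <- do.call(rbind, gene$transcripts)
  c(min(ex$start), max(ex$end))
}

#' Read normalized BSJ call tables
#'
#' The interchange format for detector output is a headered TSV with columns
#' `sample_id`, `tool`, `chrom`, `start`, `end`, `strand`, `bsj_reads`
#' (0-based half-open coordinates).  Native dialects of individual detectors
#' are not parsed; convert them to this layout first (see
#' [convert_detector_output()]).
#'
#' Rows violating `start < end` or lacking a `+`/`-` strand are rejected and
#' tallied in the `rejects` attribute (a data.frame with the source row number
#' and reason); negative read counts abort.  If a [genome_ref] is supplied,
#' rows on unknown chromosomes or beyond chromosome ends are also rejected.
#'
#' @param path TSV file
#' @param genome optional [genome_ref] for coordinate validation
#' @param tools optional character vector restricting the accepted tool set
#' @return data.frame of calls with attribute `rejects`
#' @export
read_bsj_calls <- function(path, genome = NULL, tools = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = "chrom"))
  req <- c("sample_id", "tool", "chrom", "start", "end", "strand", "bsj_reads")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("read_bsj_calls: missing column(s): ", paste(miss, collapse = ", "))
  dt <- dt[req]
  validate_bsj_calls(dt, genome = genome, tools = tools)
}

# shared validation for in-memory call tables; attaches a rejects report
validate_bsj_calls <- function(dt, genome = NULL, tools = NULL) {
  if (nrow(dt) == 0L) {
    attr(dt, "rejects") <- data.frame(row = integer(), reason = character())
    return(dt)
  }
  if (any(dt$bsj_reads < 0)) stop("read_bsj_calls: negative bsj_reads")
  reason <- rep(NA_character_, nrow(dt))
  reason[dt$start >= dt$end] <- "start >= end"
  reason[is.na(reason) & !(dt$strand %in% c("+", "-"))] <- "strand not +/-"
  if (!is.null(tools))
    reason[is.na(reason) & !(dt$tool %in% tools)] <- "unknown tool"
  if (!is.null(genome)) {
    known <- dt$chrom %in% names(genome$seqs)
    reason[is.na(reason) & !known] <- "unknown chromosome"
    lens <- setNames(Biostrings::width(genome$seqs), names(genome$seqs))
    inb <- known & dt$end <= lens[dt$chrom] & dt$start >= 0
    reason[is.na(reason) & known & !inb] <- "coordinates out of bounds"
  }
  rej <- which(!is.na(reason))
  out <- dt[setdiff(seq_len(nrow(dt)), rej), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- data.frame(row = rej, reason = reason[rej])
  out
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `species_code`, `tissue`, `individual`,
#' `mapped_fragments` (> 0).  `(tissue, individual)` identifies a node path in
#' the hierarchical expression tree used for the MCS.
#'
#' @param path TSV file
#' @return data.frame of samples
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("sample_id", "species_code", "tissue", "individual", "mapped_fragments")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("read_sample_sheet: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(dt$sample_id)) stop("read_sample_sheet: duplicate sample_id")
  if (any(dt$mapped_fragments <= 0)) stop("read_sample_sheet: mapped_fragments must be > 0")
  dt[req]
}

#' Read a BED file of intervals (repeats, CLIP peaks)
#'
#' BED coordinates are already 0-based half-open and pass through unchanged.
#' Three columns are required; `name`, `score`, `strand` are optional and
#' filled with defaults.  Strand `"."` is tolerated here (overlap queries on
#' repeats and peaks are strand-agnostic).
#'
#' @param path BED file
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`, `strand`
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("read_bed: need at least 3 columns")
  names(dt)[1:3] <- c("chrom", "start", "end")
  dt$name <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else "."
  dt$score <- if (ncol(dt) >= 5L) dt[[5L]] else 0
  dt$strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "."
  if (any(dt$start >= dt$end)) stop("read_bed: start must be < end")
  dt[c("chrom", "start", "end", "name", "score", "strand")]
}

#' Read a chain-like pairwise coordinate map
#'
#' Ungapped alignment blocks between two assemblies, one block per row:
#' `src_chrom`, `src_start`, `src_end`, `dst_chrom`, `dst_start`, `dst_end`,
#' `dst_strand` (0-based half-open; gaps fall between blocks).  Within a
#' block, source and target lengths must match; source blocks must not
#' overlap.
#'
#' @param path TSV file with header
#' @return data.frame of class `coordinate_map`
#' @export
read_coordinate_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  coordinate_map(dt)
}

#' Construct (and validate) a coordinate map from a data.frame
#' @param blocks data.frame with the chain-like columns (see [read_coordinate_map()])
#' @export
coordinate_map <- function(blocks) {
  req <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start", "dst_end", "dst_strand")
  miss <- setdiff(req, names(blocks))
  if (length(miss)) stop("coordinate_map: missing column(s): ", paste(miss, collapse = ", "))
  blocks <- blocks[req]
  if (any((blocks$src_end - blocks$src_start) != (blocks$dst_end - blocks$dst_start)))
    stop("coordinate_map: source/target length mismatch within a block")
  if (!all(blocks$dst_strand %in% c("+", "-")))
    stop("coordinate_map: dst_strand must be '+' or '-'")
  blocks <- blocks[order(blocks$src_chrom, blocks$src_start), , drop = FALSE]
  for (ch in unique(blocks$src_chrom)) {
    b <- blocks[blocks$src_chrom == ch, , drop = FALSE]
    if (nrow(b) > 1L && any(b$src_start[-1L] < b$src_end[-nrow(b)]))
      stop("coordinate_map: overlapping source blocks on ", ch)
  }
  rownames(blocks) <- NULL
  structure(blocks, class = c("coordinate_map", "data.frame"))
}

#' Read an expression matrix (rows = circRNA locus keys or gene ids)
#' @param path TSV; first column holds row ids, remaining columns samples/tissues
#' @return numeric matrix
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  if (any(m < 0)) stop("read_expression_matrix: negative values")
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with row and column names
#' @param path output file
#' @param id_col name for the row-id column
#' @export
write_expression_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Extension point for native detector dialects
#'
#' Native output dialects of individual BSJ detectors are version-unstable and
#' deliberately not parsed; the normalized TSV of [read_bsj_calls()] is the
#' interchange format.  This stub documents where a per-tool converter would
#' plug in.
#'
#' @param path native detector output
#' @param tool detector name
#' @export
convert_detector_output <- function(path, tool) {
  stop("convert_detector_output: no converter registered for '", tool,
       "'; supply calls in the normalized TSV interchange format ",
       "(sample_id, tool, chrom, start, end, strand, bsj_reads)")
}

# write a tiny GTF from simulator gene models (GTF 1-based closed on write)
write_gtf <- function(genes, path) {
  lines <- character()
  for (g in genes) {
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      for (i in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\tcirckit\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
          g$chrom, ex$start[i] + 1L, ex$end[i], g$strand, g$gene_id, tid, g$symbol))
      }
    }
    utr_lines <- function(iv, kind) {
      if (is.null(iv)) return(character())
      tid <- names(g$transcripts)[1L]
      sprintf("%s\tcirckit\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
              g$chrom, kind, iv$start + 1L, iv$end, g$strand, g$gene_id, tid, g$symbol)
    }
    lines <- c(lines, utr_lines(g$utr5, "five_prime_utr"), utr_lines(g$utr3, "three_prime_utr"))
  }
  writeLines(lines, path)
  invisible(path)
}
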
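#' Consensus-filter configuration
#'
#' Controls how per-tool, per-sample BSJ calls are merged into consensus
#' circRNA records.  The defaults encode the atlas filter: a circRNA is kept
#' only if it was detected by at least two tools and supported by at least two
#' independent BSJ reads.
#'
#' Read counts from different tools within one sample are aggregated with the
#' maximum by default (`read_agg = "max"`): two detectors seeing the same
#' junction in the same library see the same fragments, so summing would
#' double-count.  `min_reads` applies to the total across samples
#' (`min_reads_scope = "total"`); set `"per_sample"` to require the support
#' within a single sample instead.  `coordinate_slack` (bp) clusters calls
#' whose start and end each differ by at most that much; the default 0
#' requires exact coordinate agreement between detectors.
#'
#' @param min_tools minimum number of distinct detection tools (default 2)
#' @param min_reads minimum supporting BSJ read count (default 2)
#' @param coordinate_slack clustering slack in bp (default 0)
#' @param read_agg per-sample cross-tool aggregation, `"max"` or `"sum"`
#' @param min_reads_scope `"total"` (across samples) or `"per_sample"`
#' @return object of class `consensus_config`
#' @export
consensus_config <- function(min_tools = 2L, min_reads = 2L, coordinate_slack = 0L,
                             read_agg = c("max", "sum"),
                             min_reads_scope = c("total", "per_sample")) {
  read_agg <- match.arg(read_agg)
  min_reads_scope <- match.arg(min_reads_scope)
  if (min_tools < 1L) stop("consensus_config: min_tools must be >= 1")
  if (min_reads < 0L) stop("consensus_config: min_reads must be >= 0")
  if (coordinate_slack < 0L) stop("consensus_config: coordinate_slack must be >= 0")
  structure(list(min_tools = as.integer(min_tools), min_reads = as.integer(min_reads),
                 coordinate_slack = as.integer(coordinate_slack),
                 read_agg = read_agg, min_reads_scope = min_reads_scope),
            class = "consensus_config")
}

# cluster calls within +/- slack bp at both junction ends; coordinates of a
# cluster are taken from its highest-read call (ties: smallest coordinates)
cluster_calls <- function(calls, slack) {
  if (slack == 0L || nrow(calls) == 0L) return(calls)
  o <- order(calls$chrom, calls$strand, calls$start, calls$end)
  calls <- calls[o, , drop = FALSE]
  cl <- integer(nrow(calls))
  cur <- 0L
  for (i in seq_len(nrow(calls))) {
    assigned <- FALSE
    if (i > 1L) {
      for (j in (i - 1L):max(1L, i - 50L)) {
        same <- calls$chrom[j] == calls$chrom[i] && calls$strand[j] == calls$strand[i]
        if (same && abs(calls$start[j] - calls$start[i]) <= slack &&
            abs(calls$end[j] - calls$end[i]) <= slack) {
          cl[i] <- cl[j]; assigned <- TRUE; break
        }
        if (!same || calls$start[i] - calls$start[j] > slack) break
      }
    }
    if (!assigned) { cur <- cur + 1L; cl[i] <- cur }
  }
  for (k in unique(cl)) {
    idx <- which(cl == k)
    rep_i <- idx[order(-calls$bsj_reads[idx], calls$start[idx], calls$end[idx])[1L]]
    calls$start[idx] <- calls$start[rep_i]
    calls$end[idx] <- calls$end[rep_i]
  }
  calls
}

#' Merge per-tool BSJ calls into consensus circRNA records
#'
#' Applies the two atlas filters to raw detector evidence: a locus survives
#' iff it was called by at least `min_tools` distinct tools (across all
#' samples) and its summed per-sample read support reaches `min_reads`.
#' Within a sample, reads from different tools are aggregated per
#' [consensus_config()] (default: maximum).
#'
#' @param calls data.frame of BSJ calls (see [read_bsj_calls()])
#' @param samples sample sheet covering every `sample_id` in `calls`; all
#'   samples must belong to one species (merge one species at a time)
#' @param cfg a [consensus_config()]
#' @return data.frame of consensus records (one row per surviving locus) with
#'   columns `species_code`, `chrom`, `start`, `end`, `strand`, `locus_key`,
#'   `tools` (comma-joined), `n_tools`, `total_bsj_reads`, and attribute
#'   `sample_reads`: a long data.frame (`locus_key`, `sample_id`, `reads`) of
#'   per-sample aggregated read counts
#' @export
merge_calls <- function(calls, samples, cfg = consensus_config()) {
  empty <- data.frame(species_code = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      locus_key = character(), tools = character(),
                      n_tools = integer(), total_bsj_reads = integer(),
                      stringsAsFactors = FALSE)
  attr(empty, "sample_reads") <- data.frame(locus_key = character(),
                                            sample_id = character(), reads = integer())
  if (nrow(calls) == 0L) return(empty)
  unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(unknown)) stop("merge_calls: unknown sample_id: ", paste(unknown, collapse = ", "))
  sp <- unique(samples$species_code[samples$sample_id %in% calls$sample_id])
  if (length(sp) != 1L) stop("merge_calls: calls span multiple species; merge per species")
  calls <- cluster_calls(calls, cfg$coordinate_slack)
  dt <- data.table::as.data.table(calls)
  dt[, locus_key := locus_key(chrom, start, end, strand)]
  agg <- if (cfg$read_agg == "max") max else sum
  per_sample <- dt[, .(reads = as.integer(agg(bsj_reads))), by = .(locus_key, sample_id)]
  per_locus <- dt[, .(chrom = chrom[1L], start = start[1L], end = end[1L],
                      strand = strand[1L],
                      tools = paste(sort(unique(tool)), collapse = ","),
                      n_tools = length(unique(tool))), by = locus_key]
  totals <- per_sample[, .(total_bsj_reads = sum(reads), max_sample_reads = max(reads)),
                       by = locus_key]
  rec <- merge(per_locus, totals, by = "locus_key")
  keep <- rec$n_tools >= cfg$min_tools &
    (if (cfg$min_reads_scope == "total") rec$total_bsj_reads else rec$max_sample_reads) >= cfg$min_reads
  rec <- rec[keep]
  rec <- rec[order(chrom, start, end, strand)]
  out <- data.frame(species_code = rep(sp, nrow(rec)),
                    chrom = rec$chrom, start = rec$start, end = rec$end,
                    strand = rec$strand, locus_key = rec$locus_key,
                    tools = rec$tools, n_tools = rec$n_tools,
                    total_bsj_reads = rec$total_bsj_reads,
                    stringsAsFactors = FALSE)
  sr <- as.data.frame(per_sample[per_sample$locus_key %in% out$locus_key])
  attr(out, "sample_reads") <- sr[order(sr$locus_key, sr$sample_id), , drop = FALSE]
  out
}

#' Back-spliced reads per million mapped fragments
#'
#' FPM is the expression unit for circRNAs:
#' `FPM = bsj_reads / (mapped_fragments / 1e6)`.
#'
#' @param bsj_reads non-negative BSJ read count(s)
#' @param mapped_fragments positive library size(s) in fragments
#' @return numeric FPM value(s)
#' @examples
#' compute_fpm(10, 2e6)  # 5
#' @export
compute_fpm <- function(bsj_reads, mapped_fragments) {
  if (any(mapped_fragments <= 0)) stop("compute_fpm: mapped_fragments must be > 0")
  if (any(bsj_reads < 0)) stop("compute_fpm: bsj_reads must be >= 0")
  bsj_reads / (mapped_fragments / 1e6)
}

#' Assemble the per-sample FPM expression matrix from consensus records
#'
#' Cells for (locus, sample) pairs without a call are 0.
#'
#' @param records output of [merge_calls()] (carries `sample_reads`)
#' @param samples sample sheet (defines columns and library sizes)
#' @return numeric matrix, loci x samples, of FPM values
#' @export
expression_matrix <- function(records, samples) {
  sr <- attr(records, "sample_reads")
  if (is.null(sr)) stop("expression_matrix: records lack per-sample read counts; use merge_calls() output")
  m <- matrix(0, nrow = nrow(records), ncol = nrow(samples),
              dimnames = list(records$locus_key, samples$sample_id))
  if (nrow(sr)) {
    mf <- setNames(samples$mapped_fragments, samples$sample_id)
    m[cbind(match(sr$locus_key, rownames(m)), match(sr$sample_id, colnames(m)))] <-
      compute_fpm(sr$reads, mf[sr$sample_id])
  }
  m
}
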
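# ---- deterministic synthetic fixtures with planted ground truth ----
#
# The generator emulates the atlas study design: six vertebrate species, 19
# normal tissues, four BSJ detectors.  Genomes of the non-reference species
# are derived from species 1 by per-base substitution with coordinates
# preserved, so ortholog gene pairs and coordinate maps are exact by
# construction, and planted circRNA loci are orthologous across species.

#' Fixture generator configuration
#'
#' Defaults mirror the atlas study design where it is stated (six species,
#' 19 tissues, the four detectors); remaining sizes are desk-scale choices
#' documented in the methods vignette.  Every downstream draw is fixed by
#' `seed`.
#'
#' @param seed integer seed fixing all draws
#' @param species species codes (3-letter); species 1 is the reference
#' @param genes_per_species,exons_per_gene,exon_len,intron_len,intergenic_len
#'   gene layout on the single simulated chromosome
#' @param utr_len length of the 5'-/3'-UTR carved from the terminal exons
#' @param tissues tissue names
#' @param individuals_per_tissue individuals sampled per tissue (one RNA-seq
#'   sample per individual)
#' @param n_circ planted circRNA loci
#' @param divergence per-base substitution rate between species 1 and every
#'   other species (warning above 0.5: RBH recovery not guaranteed)
#' @param tools detector names
#' @param tool_sensitivity per-tool detection probability for an expressed
#'   circRNA in a sample
#' @param mean_bsj_reads mean BSJ reads of a detected call (Poisson, >= 1)
#' @param decoy_rate single-tool false-positive calls per truth circRNA
#' @param repeat_density fraction of introns carrying a repeat element
#' @param mean_mapped_fragments mean library size (fragments)
#' @param n_mirnas,n_coexpr_pairs,n_mrnas annotation-layer sizes
#' @return object of class `fixture_config`
#' @export
fixture_config <- function(seed = 1L,
                           species = c("hsa", "mml", "mmu", "rno", "ssc", "gga"),
                           genes_per_species = 20L, exons_per_gene = 4L,
                           exon_len = 150L, intron_len = 120L, intergenic_len = 300L,
                           utr_len = 50L,
                           tissues = c("brain", "cerebellum", "cortex", "heart",
                                       "liver", "lung", "kidney", "spleen",
                                       "muscle", "testis", "ovary", "stomach",
                                       "intestine", "colon", "skin", "thymus",
                                       "adrenal", "pancreas", "blood"),
                           individuals_per_tissue = 3L,
                           n_circ = 30L, divergence = 0.05,
                           tools = c("CIRI2", "CIRCexplorer2", "DCC", "find_circ"),
                           tool_sensitivity = c(0.95, 0.90, 0.90, 0.85),
                           mean_bsj_reads = 8, decoy_rate = 0.2,
                           repeat_density = 0.5,
                           mean_mapped_fragments = 2e7,
                           n_mirnas = 5L, n_coexpr_pairs = 5L, n_mrnas = 20L) {
  stopifnot(length(tool_sensitivity) == length(tools))
  rates <- c(divergence, tool_sensitivity, decoy_rate, repeat_density)
  if (any(rates < 0 | rates > 1)) stop("fixture_config: rates must lie in [0, 1]")
  if (divergence > 0.5) warning("fixture_config: divergence > 0.5; RBH recovery not guaranteed")
  cfg <- list(seed = as.integer(seed), species = species,
              genes_per_species = genes_per_species, exons_per_gene = exons_per_gene,
              exon_len = exon_len, intron_len = intron_len,
              intergenic_len = intergenic_len, utr_len = utr_len,
              tissues = tissues, individuals_per_tissue = individuals_per_tissue,
              n_circ = n_circ, divergence = divergence, tools = tools,
              tool_sensitivity = tool_sensitivity, mean_bsj_reads = mean_bsj_reads,
              decoy_rate = decoy_rate, repeat_density = repeat_density,
              mean_mapped_fragments = mean_mapped_fragments,
              n_mirnas = n_mirnas, n_coexpr_pairs = n_coexpr_pairs, n_mrnas = n_mrnas)
  structure(cfg, class = "fixture_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

mutate_dna <- function(seq, rate) {
  if (rate == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    subst <- vapply(bases[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    bases[hit] <- subst
  }
  paste(bases, collapse = "")
}

#' Simulate the species set: genomes, gene models, ortholog pairs, maps
#'
#' Species 1 gets a random genome with a regular gene layout; every other
#' species inherits the same coordinates with per-base substitutions at the
#' divergence rate, yielding identity coordinate maps and exact ortholog gene
#' pairs.
#'
#' @param cfg a [fixture_config()]
#' @return list with `genomes` (named list of [genome_ref]), `genes` (named
#'   list of gene-model lists), `ortholog_pairs` (data.frame `species_a`,
#'   `gene_a`, `species_b`, `gene_b`), `maps` (named list `"spA.spB"` of
#'   [coordinate_map()]s)
#' @export
simulate_species_set <- function(cfg) {
  set.seed(cfg$seed)
  ng <- cfg$genes_per_species; ne <- cfg$exons_per_gene
  gene_span <- ne * cfg$exon_len + (ne - 1L) * cfg$intron_len
  chrom_len <- ng * (gene_span + cfg$intergenic_len) + cfg$intergenic_len
  ref_seq <- random_dna(chrom_len)
  strands <- rep(c("+", "-"), length.out = ng)
  layout <- list()
  cursor <- cfg$intergenic_len
  for (i in seq_len(ng)) {
    ex_start <- cursor + (seq_len(ne) - 1L) * (cfg$exon_len + cfg$intron_len)
    layout[[i]] <- data.frame(start = ex_start, end = ex_start + cfg$exon_len)
    cursor <- cursor + gene_span + cfg$intergenic_len
  }
  genomes <- list(); genes <- list()
  for (s in seq_along(cfg$species)) {
    sp <- cfg$species[s]
    seq <- if (s == 1L) ref_seq else mutate_dna(ref_seq, cfg$divergence)
    genomes[[sp]] <- genome_ref(setNames(Biostrings::DNAStringSet(seq), "chr1"), sp)
    gl <- list()
    for (i in seq_len(ng)) {
      ex <- layout[[i]]
      gid <- sprintf("%s_g%02d", sp, i)
      u <- cfg$utr_len
      if (strands[i] == "+") {
        utr5 <- data.frame(start = ex$start[1L], end = ex$start[1L] + u)
        utr3 <- data.frame(start = ex$end[ne] - u, end = ex$end[ne])
      } else {
        utr5 <- data.frame(start = ex$end[ne] - u, end = ex$end[ne])
        utr3 <- data.frame(start = ex$start[1L], end = ex$start[1L] + u)
      }
      gl[[gid]] <- structure(list(
        gene_id = gid, symbol = sprintf("GENE%02d", i), chrom = "chr1",
        strand = strands[i],
        transcripts = setNames(list(ex), sprintf("%s_t1", gid)),
        utr5 = utr5, utr3 = utr3), class = "gene_model")
    }
    genes[[sp]] <- gl
  }
  pairs <- list()
  for (a in seq_along(cfg$species)) for (b in seq_along(cfg$species)) {
    if (a >= b) next
    pairs[[paste(a, b)]] <- data.frame(
      species_a = cfg$species[a], gene_a = sprintf("%s_g%02d", cfg$species[a], seq_len(ng)),
      species_b = cfg$species[b], gene_b = sprintf("%s_g%02d", cfg$species[b], seq_len(ng)),
      stringsAsFactors = FALSE)
  }
  maps <- list()
  for (a in seq_along(cfg$species)) for (b in seq_along(cfg$species)) {
    if (a == b) next
    maps[[paste0(cfg$species[a], ".", cfg$species[b])]] <- coordinate_map(data.frame(
      src_chrom = "chr1", src_start = 0L, src_end = chrom_len,
      dst_chrom = "chr1", dst_start = 0L, dst_end = chrom_len, dst_strand = "+"))
  }
  list(genomes = genomes, genes = genes,
       ortholog_pairs = do.call(rbind, pairs), maps = maps,
       layout = layout, strands = strands, chrom_len = chrom_len)
}

#' Plant ground-truth circRNA loci on the simulated gene set
#'
#' Circles cycle through the subclasses with an exon-dominated composition
#' (exonic, exonic, exonic, 5utr, 3utr, intronic, antisense, intergenic, ...),
#' are present in species 1..k (k cycling over the species count, so ortholog
#' group sizes vary), and receive a planted expression pattern (housekeeping,
#' random-breadth, or single-tissue) over tissues and individuals.
#'
#' @param cfg a [fixture_config()]
#' @param ss a [simulate_species_set()] result
#' @return list with `circs` (data.frame of loci and truth labels),
#'   `presence` (circ x species long table) and `patterns` (per-circ list of
#'   expressing (tissue, individual) pairs)
#' @export
plant_truth_circs <- function(cfg, ss) {
  set.seed(cfg$seed + 1L)
  ng <- cfg$genes_per_species; ne <- cfg$exons_per_gene
  cls_cycle <- c("exonic", "exonic", "exonic", "5utr", "3utr",
                 "intronic", "antisense", "intergenic")
  n_ind <- cfg$individuals_per_tissue
  circs <- list(); patterns <- list(); presence <- list()
  for (j in seq_len(cfg$n_circ)) {
    gi <- ((j - 1L) %% ng) + 1L
    ex <- ss$layout[[gi]]
    strand <- ss$strands[gi]
    cls <- cls_cycle[((j - 1L) %% length(cls_cycle)) + 1L]
    if (cls == "exonic") {
      # exon 2 .. exon (ne-1): interior exons, clear of the UTRs
      start <- ex$start[2L]; end <- ex$end[min(3L, ne)]
    } else if (cls == "5utr") {
      if (strand == "+") { start <- ex$start[1L]; end <- ex$end[2L] }
      else { start <- ex$start[ne - 1L]; end <- ex$end[ne] }
    } else if (cls == "3utr") {
      if (strand == "+") { start <- ex$start[ne - 1L]; end <- ex$end[ne] }
      else { start <- ex$start[1L]; end <- ex$end[2L] }
    } else if (cls == "intronic") {
      start <- ex$end[1L] + 10L; end <- ex$start[2L] - 10L
    } else if (cls == "antisense") {
      start <- ex$start[2L]; end <- ex$end[2L]
      strand <- if (strand == "+") "-" else "+"
    } else { # intergenic: in the gap upstream of the gene
      start <- ex$start[1L] - cfg$intergenic_len + 20L
      end <- ex$start[1L] - 20L
    }
    k <- ((j - 1L) %% length(cfg$species)) + 1L  # present in species 1..k
    n_t <- length(cfg$tissues)
    mode <- c("housekeeping", "random", "single")[((j - 1L) %% 3L) + 1L]
    tis <- switch(mode,
                  housekeeping = cfg$tissues,
                  random = sort(sample(cfg$tissues, sample(2:max(2L, n_t - 1L), 1L))),
                  single = sample(cfg$tissues, 1L))
    pat <- list()
    for (t in tis) {
      inds <- sort(sample(seq_len(n_ind), sample(seq_len(n_ind), 1L)))
      pat[[t]] <- sprintf("ind%d", inds)
    }
    circs[[j]] <- data.frame(
      circ_idx = j, chrom = "chr1", start = start, end = end, strand = strand,
      locus_key = locus_key("chr1", start, end, strand),
      gene_index = if (cls == "intergenic") NA_integer_ else gi,
      class_truth = cls, n_species = k, group_id = j,
      expr_mode = mode, stringsAsFactors = FALSE)
    patterns[[j]] <- pat
    presence[[j]] <- data.frame(circ_idx = j,
                                species_code = cfg$species[seq_len(k)],
                                stringsAsFactors = FALSE)
  }
  list(circs = do.call(rbind, circs), presence = do.call(rbind, presence),
       patterns = patterns)
}

#' Simulate the sample sheet for one species
#' @param cfg a [fixture_config()]
#' @param species_code which species
#' @return sample sheet data.frame
#' @export
simulate_samples <- function(cfg, species_code) {
  set.seed(cfg$seed + 2L + match(species_code, cfg$species))
  grid <- expand.grid(individual = sprintf("ind%d", seq_len(cfg$individuals_per_tissue)),
                      tissue = cfg$tissues, stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%s", species_code, grid$tissue, grid$individual),
    species_code = species_code, tissue = grid$tissue, individual = grid$individual,
    mapped_fragments = round(cfg$mean_mapped_fragments * runif(nrow(grid), 0.8, 1.2)),
    stringsAsFactors = FALSE)
}

#' Simulate per-tool BSJ calls for one species
#'
#' Each tool detects each expressed (circ, sample) combination independently
#' with its sensitivity; detected calls draw `1 + Poisson(mean - 1)` BSJ
#' reads.  Decoy single-tool, single-read calls are injected at
#' `decoy_rate` per truth circRNA, modelling detector false positives (the
#' failure mode the two-tool consensus filter targets).  The returned truth
#' table records, by literal enumeration of the generated evidence, which
#' loci satisfy the >= 2 tools / >= 2 reads consensus.
#'
#' @param cfg a [fixture_config()]
#' @param truth [plant_truth_circs()] result
#' @param species_code which species
#' @param samples optional pre-built sample sheet ([simulate_samples()])
#' @return list with `calls` (data.frame), `samples`, and `truth_detected`
#'   (data.frame `locus_key`, `is_truth`, `consensus_truth`)
#' @export
simulate_circ_calls <- function(cfg, truth, species_code, samples = NULL) {
  if (is.null(samples)) samples <- simulate_samples(cfg, species_code)
  set.seed(cfg$seed + 100L + match(species_code, cfg$species))
  present <- truth$presence$circ_idx[truth$presence$species_code == species_code]
  calls <- list()
  for (j in present) {
    ci <- truth$circs[truth$circs$circ_idx == j, ]
    pat <- truth$patterns[[j]]
    for (t in names(pat)) for (ind in pat[[t]]) {
      sid <- sprintf("%s_%s_%s", species_code, t, ind)
      if (!sid %in% samples$sample_id) next
      for (k in seq_along(cfg$tools)) {
        if (runif(1L) > cfg$tool_sensitivity[k]) next
        reads <- 1L + rpois(1L, max(0, cfg$mean_bsj_reads - 1))
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = sid, tool = cfg$tools[k], chrom = ci$chrom,
          start = ci$start, end = ci$end, strand = ci$strand,
          bsj_reads = reads, stringsAsFactors = FALSE)
      }
    }
  }
  n_decoy <- round(cfg$decoy_rate * length(present))
  decoy_keys <- character(0)
  if (n_decoy > 0L) {
    for (d in seq_len(n_decoy)) {
      repeat {
        s0 <- sample.int(2000L, 1L) * 7L
        e0 <- s0 + sample(100:400, 1L)
        st <- sample(c("+", "-"), 1L)
        lk <- locus_key("chr1", s0, e0, st)
        if (!lk %in% truth$circs$locus_key && !lk %in% decoy_keys) break
      }
      decoy_keys <- c(decoy_keys, lk)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sample(samples$sample_id, 1L),
        tool = sample(cfg$tools, 1L), chrom = "chr1",
        start = s0, end = e0, strand = st, bsj_reads = 1L,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), tool = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               bsj_reads = integer(), stringsAsFactors = FALSE)
  # literal enumeration of the consensus rule over the generated evidence
  truth_detected <- NULL
  if (nrow(calls)) {
    keys <- locus_key(calls$chrom, calls$start, calls$end, calls$strand)
    uk <- unique(keys)
    cons <- vapply(uk, function(k) {
      rows <- calls[keys == k, , drop = FALSE]
      ntools <- length(unique(rows$tool))
      tot <- sum(vapply(split(rows$bsj_reads, rows$sample_id), max, 0))
      ntools >= 2L && tot >= 2
    }, TRUE)
    truth_detected <- data.frame(locus_key = uk,
                                 is_truth = uk %in% truth$circs$locus_key,
                                 consensus_truth = unname(cons),
                                 stringsAsFactors = FALSE)
  }
  list(calls = calls, samples = samples, truth_detected = truth_detected)
}

#' Simulate a repeat annotation (BED) over the simulated introns
#'
#' A fraction `repeat_density` of introns receives one repeat interval.
#'
#' @param cfg a [fixture_config()]
#' @param ss a [simulate_species_set()] result
#' @return data.frame in BED layout (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`)
#' @export
simulate_repeats <- function(cfg, ss) {
  set.seed(cfg$seed + 3L)
  out <- list()
  for (gi in seq_along(ss$layout)) {
    ex <- ss$layout[[gi]]
    if (nrow(ex) < 2L) next
    for (ii in seq_len(nrow(ex) - 1L)) {
      if (runif(1L) > cfg$repeat_density) next
      istart <- ex$end[ii]; iend <- ex$start[ii + 1L]
      w <- min(30L, iend - istart - 4L)
      if (w < 5L) next
      s0 <- istart + sample.int(iend - istart - w, 1L) - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = "chr1", start = s0, end = s0 + w,
        name = sprintf("SINE_g%02d_i%d", gi, ii), score = 0, strand = ".",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Simulate a joint circRNA + mRNA per-tissue expression matrix
#'
#' Plants (i) housekeeping circRNAs with a near-uniform profile
#' (tau near 0), (ii) single-tissue circRNAs (tau = 1), and (iii) circ--mRNA
#' pairs sharing a latent tissue profile with small independent noise
#' (population r >= 0.9); remaining mRNAs draw independent profiles.
#'
#' @param cfg a [fixture_config()]
#' @return list with `tissue_expr` (matrix rows x tissues), `circ_ids`,
#'   `mrna_ids`, `truth_pairs` (planted co-expressed circ--mRNA pairs),
#'   `housekeeping_ids`, `single_tissue` (data.frame circ, tissue)
#' @export
simulate_coexpression <- function(cfg) {
  set.seed(cfg$seed + 4L)
  nt <- length(cfg$tissues)
  rows <- list(); circ_ids <- character(0); mrna_ids <- character(0)
  truth_pairs <- list(); hk <- character(0); single <- list()
  for (b in seq_len(cfg$n_coexpr_pairs)) {
    z <- runif(nt, 1, 10)
    ci <- sprintf("circ_co%02d", b); mi <- sprintf("mRNA_co%02d", b)
    rows[[ci]] <- pmax(0, z + rnorm(nt, sd = 0.2))
    rows[[mi]] <- pmax(0, z + rnorm(nt, sd = 0.2))
    circ_ids <- c(circ_ids, ci); mrna_ids <- c(mrna_ids, mi)
    truth_pairs[[b]] <- data.frame(circ = ci, mrna = mi, stringsAsFactors = FALSE)
  }
  for (h in seq_len(3L)) {
    ci <- sprintf("circ_hk%02d", h)
    rows[[ci]] <- 5 * runif(nt, 0.97, 1.03)  # housekeeping: tau near 0
    circ_ids <- c(circ_ids, ci); hk <- c(hk, ci)
  }
  for (s in seq_len(3L)) {
    ci <- sprintf("circ_st%02d", s)
    t <- sample(cfg$tissues, 1L)
    v <- numeric(nt); v[match(t, cfg$tissues)] <- 8
    rows[[ci]] <- v                        # single tissue: tau = 1
    circ_ids <- c(circ_ids, ci)
    single[[s]] <- data.frame(circ = ci, tissue = t, stringsAsFactors = FALSE)
  }
  n_extra <- max(0L, cfg$n_mrnas - length(mrna_ids))
  for (e in seq_len(n_extra)) {
    mi <- sprintf("mRNA_bg%02d", e)
    rows[[mi]] <- runif(nt, 0.5, 10)
    mrna_ids <- c(mrna_ids, mi)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cfg$tissues
  list(tissue_expr = m, circ_ids = circ_ids, mrna_ids = mrna_ids,
       truth_pairs = do.call(rbind, truth_pairs), housekeeping_ids = hk,
       single_tissue = do.call(rbind, single))
}

#' Simulate miRNAs and circRNA sequences with planted seed sites
#'
#' Random 22-nt miRNAs; each planted site writes the miRNA's 8mer target
#' sequence into a random circRNA sequence at a known offset, with one site
#' per circRNA placed across the back-splice junction (starting 4 nt before
#' the junction) to exercise the circular scan.
#'
#' @param cfg a [fixture_config()]
#' @param n_circ number of circRNA sequences (default 8)
#' @param circ_len circRNA sequence length (default 300)
#' @return list with `mirnas`, `circ_seqs` (named character vectors) and
#'   `truth_sites` (data.frame `circ_id`, `mirna`, `position`, `spans_bsj`)
#' @export
simulate_mirna_truth <- function(cfg, n_circ = 8L, circ_len = 300L) {
  set.seed(cfg$seed + 5L)
  mirnas <- setNames(vapply(seq_len(cfg$n_mirnas), function(i) random_dna(22L), ""),
                     sprintf("sim-miR-%02d", seq_len(cfg$n_mirnas)))
  circ_seqs <- setNames(vapply(seq_len(n_circ), function(i) random_dna(circ_len), ""),
                        sprintf("circ_mir%02d", seq_len(n_circ)))
  truth <- list()
  for (i in seq_len(n_circ)) {
    mid <- names(mirnas)[((i - 1L) %% length(mirnas)) + 1L]
    site <- seed_patterns(mirnas[[mid]])[["8mer"]]
    cross <- i %% 2L == 0L
    pos <- if (cross) circ_len - 4L else sample(10:(circ_len - 20L), 1L)
    s <- circ_seqs[[i]]
    if (cross) {
      # last 4 nt of the circle + first 4 nt hold the site
      s <- paste0(substr(s, 1L, pos), substr(site, 1L, 4L))
      s <- paste0(substr(site, 5L, 8L), substr(s, 5L, circ_len))
    } else {
      s <- paste0(substr(s, 1L, pos), site, substr(s, pos + 9L, circ_len))
    }
    circ_seqs[[i]] <- s
    truth[[i]] <- data.frame(circ_id = names(circ_seqs)[i], mirna = mid,
                             position = pos, spans_bsj = cross,
                             stringsAsFactors = FALSE)
  }
  list(mirnas = mirnas, circ_seqs = circ_seqs, truth_sites = do.call(rbind, truth))
}

#' Simulate CLIP peaks around circRNA back-splice junctions
#'
#' Plants one peak per record within the 1-kb BSJ window, plus decoy peaks
#' far from any BSJ and on a decoy chromosome.
#'
#' @param cfg a [fixture_config()]
#' @param records circRNA records (`chrom`, `start`, `end`, `locus_key`)
#' @param rbps RBP names to cycle through
#' @return list with `peaks` (BED-layout data.frame) and `truth_edges`
#'   (data.frame `locus_key`, `rbp`)
#' @export
simulate_clip_truth <- function(cfg, records,
                                rbps = c("U2AF2", "PTBP1", "ELAVL1", "FUS")) {
  set.seed(cfg$seed + 6L)
  peaks <- list(); truth <- list()
  for (i in seq_len(nrow(records))) {
    rbp <- rbps[((i - 1L) %% length(rbps)) + 1L]
    off <- sample(50:900, 1L) * sample(c(-1L, 1L), 1L)
    anchor <- if (i %% 2L == 0L) records$start[i] else records$end[i]
    s0 <- max(0L, anchor + off)
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = records$chrom[i], start = s0, end = s0 + 30L, name = rbp,
      score = 0, strand = ".", stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      locus_key = records$locus_key[i], rbp = rbp, stringsAsFactors = FALSE)
  }
  for (d in seq_len(nrow(records))) {
    s0 <- 10000000L + d * 5000L
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = "chrDecoy", start = s0, end = s0 + 30L,
      name = rbps[((d - 1L) %% length(rbps)) + 1L], score = 0, strand = ".",
      stringsAsFactors = FALSE)
  }
  list(peaks = do.call(rbind, peaks), truth_edges = unique(do.call(rbind, truth)))
}

#' Simulate a GO/KEGG-style term table over the mRNA universe
#'
#' Co-expressed partner mRNAs share a planted term; background terms are
#' scattered over the remaining genes.
#'
#' @param cfg a [fixture_config()]
#' @param mrna_ids mRNA universe
#' @param planted_genes genes carrying the planted term
#' @return data.frame with `gene_id`, `term_id`
#' @export
simulate_term_table <- function(cfg, mrna_ids, planted_genes = character()) {
  set.seed(cfg$seed + 7L)
  rows <- list()
  if (length(planted_genes))
    rows$planted <- data.frame(gene_id = planted_genes, term_id = "GO:PLANTED",
                               stringsAsFactors = FALSE)
  for (t in 1:3) {
    g <- sample(mrna_ids, max(2L, length(mrna_ids) %/% 3L))
    rows[[paste0("bg", t)]] <- data.frame(gene_id = g,
                                          term_id = sprintf("GO:BG%04d", t),
                                          stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, rows))
}

#' Write a complete fixture bundle to disk
#'
#' Emits every external format the toolkit reads: genome FASTA and GTF per
#' species, ortholog gene pair TSV, coordinate map TSVs, repeats BED, per-
#' species BSJ call TSVs and sample sheets, miRNA FASTA, CLIP peak BED and a
#' term table.  Output is byte-identical for identical configs.
#'
#' @param cfg a [fixture_config()]
#' @param dir output directory (created)
#' @return invisibly, the list of generated objects
#' @export
write_fixture_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- simulate_species_set(cfg)
  truth <- plant_truth_circs(cfg, ss)
  for (sp in cfg$species) {
    Biostrings::writeXStringSet(ss$genomes[[sp]]$seqs,
                                file.path(dir, sprintf("%s.genome.fa", sp)))
    write_gtf(ss$genes[[sp]], file.path(dir, sprintf("%s.genes.gtf", sp)))
    sim <- simulate_circ_calls(cfg, truth, sp)
    data.table::fwrite(sim$calls, file.path(dir, sprintf("%s.calls.tsv", sp)), sep = "\t")
    data.table::fwrite(sim$samples, file.path(dir, sprintf("%s.samples.tsv", sp)), sep = "\t")
  }
  data.table::fwrite(ss$ortholog_pairs, file.path(dir, "ortholog_genes.tsv"), sep = "\t")
  for (nm in names(ss$maps))
    data.table::fwrite(as.data.frame(ss$maps[[nm]]),
                       file.path(dir, sprintf("map_%s.tsv", nm)), sep = "\t")
  rep_bed <- simulate_repeats(cfg, ss)
  data.table::fwrite(rep_bed, file.path(dir, "repeats.bed"), sep = "\t", col.names = FALSE)
  co <- simulate_coexpression(cfg)
  write_expression_matrix(co$tissue_expr, file.path(dir, "tissue_expr.tsv"))
  mt <- simulate_mirna_truth(cfg)
  writeLines(as.character(rbind(paste0(">", names(mt$mirnas)), unname(mt$mirnas))),
             file.path(dir, "mirnas.fa"))
  data.table::fwrite(truth$circs, file.path(dir, "truth_circs.tsv"), sep = "\t")
  invisible(list(species_set = ss, truth = truth, coexpr = co, mirna = mt))
}
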
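test_that("co-expression edges keep strong positive correlations over tissue means", {
  m <- rbind(circ1 = c(1, 2, 3, 4, 5),
             geneA = c(2, 4, 6, 8, 10),   # r = 1 with circ1
             geneB = c(5, 4, 3, 2, 1),    # r = -1 with circ1
             geneC = c(1, 0, 0, 2, 0))
  colnames(m) <- paste0("t", 1:5)
  ed <- coexpression_edges(m, circ_ids = "circ1", min_tissues = 2L)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$node_b, "geneA")
  expect_equal(ed$r, 1.0)
  # anticorrelated edges come back with the flag
  ed2 <- coexpression_edges(m, "circ1", min_tissues = 2L, keep_anticorrelated = TRUE)
  expect_setequal(ed2$node_b, c("geneA", "geneB"))
})

test_that("nodes expressed in fewer than 3 tissues are excluded before correlation", {
  m <- rbind(circ1 = c(3, 2, 0, 0, 0),    # 2 tissues only
             circ2 = c(1, 2, 3, 4, 5),
             geneA = c(1, 2, 3, 4, 5))
  colnames(m) <- paste0("t", 1:5)
  ed <- coexpression_edges(m, circ_ids = c("circ1", "circ2"))
  expect_false("circ1" %in% c(ed$node_a, ed$node_b))
  expect_equal(nrow(ed), 1L)
  expect_error(coexpression_edges(m[, 1:2], "circ2"), ">= 3 tissue")
  expect_warning(
    coexpression_edges(rbind(m, flat = rep(4, 5)), c("circ1", "circ2")),
    "constant")
})

test_that("let-7-style 8mer seed sites are found, typed, and reverse-complement sound", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  # CTACCTCA = rc(positions 2-8) + A
  circ <- paste0("GGGGGGGGGG", "CTACCTCA", "GGGGGGGGGG")
  sites <- mirna_seed_sites(c(c1 = circ), c(`let-7` = let7))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$type, "8mer")
  expect_equal(sites$position, 10L)
  expect_false(sites$spans_bsj)
  # soundness: the site sequence reverse-complements to miRNA positions 2-8
  mir_dna <- gsub("U", "T", let7)
  site_seq <- substr(circ, sites$position + 1L, sites$position + 7L)
  expect_equal(as.character(Biostrings::reverseComplement(Biostrings::DNAString(site_seq))),
               substr(mir_dna, 2L, 8L))

  expect_equal(nrow(mirna_seed_sites(c(c1 = circ), character(0))), 0L)
  expect_error(mirna_seed_sites(c(c1 = circ), c(short = "ACGUACG")), "shorter")
})

test_that("seed sites straddling the back-splice junction are found via circular context", {
  let7 <- "TGAGGTAGTAGGTTGTATAGTT"
  site <- "CTACCTCA"
  L <- 40L
  # place the site across the junction: last 3 nt + first 5 nt
  tail_part <- substr(site, 1L, 3L)
  head_part <- substr(site, 4L, 8L)
  circ <- paste0(head_part, strrep("G", L - 8L), tail_part)
  sites <- mirna_seed_sites(c(c1 = circ), c(`let-7` = let7))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, L - 3L)
  expect_true(sites$spans_bsj)
  expect_equal(sites$type, "8mer")
  # brute-force check on the rotated sequence: rotating the circle so the site
  # is interior must recover the same site
  rot <- paste0(substr(circ, 11L, L), substr(circ, 1L, 10L))
  rot_sites <- mirna_seed_sites(c(c1 = rot), c(`let-7` = let7))
  expect_equal(nrow(rot_sites), 1L)
  expect_equal(rot_sites$type, "8mer")
})

test_that("weaker seed classes are typed by their most specific match", {
  mir <- "TGAGGTAGTAGGTTGTATAGTT"   # rc(2-8) = CTACCTC
  mk <- function(core) paste0(strrep("G", 12), core, strrep("G", 12))
  expect_equal(mirna_seed_sites(c(x = mk("CTACCTCA")), c(m = mir))$type, "8mer")
  expect_equal(mirna_seed_sites(c(x = mk("CTACCTCG")), c(m = mir))$type, "7mer-m8")
  expect_equal(mirna_seed_sites(c(x = mk("GTACCTCA")), c(m = mir))$type, "7mer-A1")
  expect_equal(mirna_seed_sites(c(x = mk("GTACCTCG")), c(m = mir))$type, "6mer")
})

test_that("RBP edges require a CLIP peak within the BSJ windows", {
  rec <- data.frame(chrom = "chr1", start = 5000L, end = 9000L,
                    locus_key = "chr1:5000|9000:+", stringsAsFactors = FALSE)
  peak <- function(s, e, name = "PTBP1", chrom = "chr1")
    data.frame(chrom = chrom, start = s, end = e, name = name, score = 0,
               strand = ".", stringsAsFactors = FALSE)
  # peak at start + 200 -> edge
  ed <- rbp_edges(rec, peak(5200L, 5230L))
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$rbp, "PTBP1")
  expect_equal(ed$min_dist, 200L)  # nearest BSJ base is start (5000)
  # peaks inside the circle but > 1 kb from both BSJs -> no edge
  expect_equal(nrow(rbp_edges(rec, rbind(peak(6500L, 6530L), peak(7500L, 7530L)))), 0L)
  # other chromosome -> no edge
  expect_equal(nrow(rbp_edges(rec, peak(5200L, 5230L, chrom = "chr2"))), 0L)
  # two peaks of one RBP aggregate with the closest distance
  ed2 <- rbp_edges(rec, rbind(peak(4000L, 4030L), peak(9500L, 9530L)))
  expect_equal(ed2$peak_count, 2L)
  expect_equal(ed2$min_dist, 500L)  # 9500 is 500 bp past the end BSJ
})

test_that("hypergeometric function propagation matches the closed form and Monte Carlo", {
  # universe of 10 genes, term covers 5, circ has 2 neighbors, both in term
  universe <- sprintf("g%02d", 1:10)
  terms <- data.frame(gene_id = universe[1:5], term_id = "GO:X",
                      stringsAsFactors = FALSE)
  coexp <- data.frame(node_a = "circ1", node_b = universe[1:2], r = 0.9,
                      stringsAsFactors = FALSE)
  net <- build_annotation_network(coexp, NULL, NULL, circ_ids = "circ1")
  calls <- propagate_function(net, terms, universe = universe)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, 2L)
  expect_equal(calls$p, 10 / 45, tolerance = 1e-12)
  # Monte-Carlo estimate within 3 standard errors
  set.seed(8)
  draws <- replicate(1e5, sum(sample(10, 2) <= 5) >= 2)
  mc <- mean(draws); se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(calls$p - mc), 3 * se)
  # all universe genes carry the term -> p = 1
  terms_all <- data.frame(gene_id = universe, term_id = "GO:ALL")
  p_all <- propagate_function(net, terms_all, universe = universe)
  expect_equal(p_all$p[p_all$term_id == "GO:ALL"], 1.0)
})

test_that("BH q-values are monotone in p-rank and never below p", {
  universe <- sprintf("g%02d", 1:20)
  set.seed(31)
  terms <- do.call(rbind, lapply(1:6, function(i)
    data.frame(gene_id = sample(universe, sample(4:12, 1L)),
               term_id = sprintf("GO:%d", i), stringsAsFactors = FALSE)))
  coexp <- data.frame(node_a = "circ1", node_b = sample(universe, 6L), r = 0.8,
                      stringsAsFactors = FALSE)
  net <- build_annotation_network(coexp, NULL, NULL, circ_ids = "circ1")
  calls <- propagate_function(net, terms, universe = universe)
  expect_true(all(calls$q >= calls$p))
  o <- order(calls$p)
  expect_true(all(diff(calls$q[o]) >= -1e-12))
  # a circRNA with no neighbors yields no calls
  lonely <- build_annotation_network(NULL, NULL, NULL, circ_ids = "circZ")
  expect_equal(nrow(propagate_function(lonely, terms, universe = universe)), 0L)
})

test_that("interactor ranking counts distinct circRNA partners", {
  sites <- data.frame(circ_id = c("c1", "c2", "c3", "c1"),
                      mirna = c("miR-1", "miR-1", "miR-1", "miR-2"),
                      position = c(1L, 2L, 3L, 4L), type = "8mer",
                      spans_bsj = FALSE, stringsAsFactors = FALSE)
  rbp <- data.frame(locus_key = "c1", rbp = "U2AF2", peak_count = 1L,
                    min_dist = 10L, stringsAsFactors = FALSE)
  net <- build_annotation_network(NULL, sites, rbp, circ_ids = c("c1", "c2", "c3"))
  rk <- rank_interactors(net)
  expect_equal(rk$node[1L], "miR-1")
  expect_equal(rk$n_circ[1L], 3L)
  # degree equals a brute-force recount of incident circRNA edges
  for (i in seq_len(nrow(rk))) {
    nb <- igraph::neighbors(net, rk$node[i])$name
    expect_equal(rk$n_circ[i], length(unique(intersect(nb, c("c1", "c2", "c3")))))
  }
  empty <- build_annotation_network(NULL, NULL, NULL, circ_ids = character())
  expect_equal(nrow(rank_interactors(empty)), 0L)
})

test_that("external miRNA predictions union or intersect with internal calls", {
  internal <- data.frame(circ_id = c("c1", "c2"), mirna = c("m1", "m2"),
                         position = 1L, type = "8mer", spans_bsj = FALSE,
                         stringsAsFactors = FALSE)
  external <- data.frame(circ_id = c("c2", "c3"), mirna = c("m2", "m3"),
                         stringsAsFactors = FALSE)
  u <- combine_mirna_predictions(internal, external)
  expect_equal(nrow(u), 3L)
  expect_setequal(u$source, c("internal", "both", "external"))
  i <- combine_mirna_predictions(internal, external, mode = "intersect")
  expect_equal(nrow(i), 1L)
  expect_equal(i$circ_id, "c2")
})

test_that("planted co-expression blocks are recovered with a low false-edge rate", {
  cfg <- fixture_config(seed = 99L)
  co <- simulate_coexpression(cfg)
  ed <- suppressWarnings(coexpression_edges(co$tissue_expr, co$circ_ids))
  got <- paste(ed$node_a, ed$node_b)
  want <- paste(co$truth_pairs$circ, co$truth_pairs$mrna)
  expect_true(all(want %in% got))  # every planted pair recovered
  # null calibration: planted-uncorrelated pairs produce edges in < 10% of
  # seeded replicates
  set.seed(1000)
  false_edges <- 0L; trials <- 0L
  for (s in 1:100) {
    nt <- length(cfg$tissues)
    a <- runif(nt, 0.5, 10); b <- runif(nt, 0.5, 10)
    m <- rbind(circX = a, geneY = b); colnames(m) <- cfg$tissues
    e <- coexpression_edges(m, "circX")
    trials <- trials + 1L
    if (nrow(e) > 0L) false_edges <- false_edges + 1L
  }
  expect_lt(false_edges / trials, 0.10)
})
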
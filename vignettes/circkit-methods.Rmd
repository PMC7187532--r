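---
title: "circkit: methods and design notes"
author: "circkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circkit)
```

## What circkit computes

Circular RNAs (circRNAs) are covalently closed transcripts formed by
back-splicing; each is identified by its back-splice junction (BSJ): a
chromosome, a 0-based half-open interval, and a strand.  circkit implements
the analytical chain used to assemble a multi-species circRNA atlas from the
output of several BSJ detectors:

1. **Consensus calling** — merge per-tool, per-sample BSJ call tables and keep
   loci detected by at least two tools and supported by at least two BSJ
   reads; quantify expression in FPM (BSJ reads per million mapped
   fragments).
2. **Classification** — assign each circRNA a host gene and one of six
   subclasses (exonic, intronic, 5'-UTR, 3'-UTR, antisense, intergenic), plus
   an orthogonal *non-repeat* flag when neither flanking intron carries a
   repeat element.
3. **Conservation** — detect orthologous circRNAs across species by
   restricting candidates to orthologous host genes, representing each BSJ by
   up to 50 bp of flanking cirexon sequence per side, aligning all candidates
   with an optimal local aligner, keeping reciprocal best hits (RBH), and
   integrating pairwise hits into multi-species ortholog groups.
4. **MCS** — score each circRNA's conservation as
   $\mathrm{MCS} = N_s + N_t \times N_i$, where $N_s$ is the ortholog count
   and the decimal part reads tissue and individual expression breadth off a
   two-layer hierarchical expression tree.
5. **Annotation network** — a typed graph over circRNAs, mRNAs, miRNAs and
   RNA-binding proteins (RBPs), from which GO/KEGG terms are propagated to
   circRNAs by hypergeometric enrichment over network neighbors.

A deterministic synthetic-fixture generator plants ground truth for every
stage, so the whole chain is testable with no external data.

## Coordinate and identity conventions

All internal coordinates are 0-based half-open.  GTF input (1-based closed)
is converted on read; BED input passes through unchanged.  A circRNA's
identity is its locus key `chrom:start|end:strand`; strand is part of the
identity, so calls with strand `"."` are rejected (repeats and CLIP peaks,
whose overlap queries are strand-agnostic, may carry `"."`).

Native output dialects of individual detectors are deliberately not parsed:
they are version-unstable, and the analysis starts after detection.  The
normalized TSV of `read_bsj_calls()` is the interchange format, with
`convert_detector_output()` left as the documented extension point.

## Consensus model

The filter keeps a locus iff it was called by $\ge$ 2 distinct tools (over
all samples) and its total read support is $\ge$ 2.  Two interpretation
choices were genuinely open:

* **Cross-tool aggregation within a sample is the maximum, not the sum.**
  Two detectors that see the same junction in the same library see the same
  sequencing fragments; summing would double-count them.  "Independent BSJ
  reads" is therefore read as *distinct fragments*.  A `read_agg = "sum"`
  switch exists.
* **The read threshold applies to the total across samples** (the filter is
  phrased at dataset level); `min_reads_scope = "per_sample"` demands the
  support within a single sample instead.
* **Detectors must agree on exact coordinates** (`coordinate_slack = 0`).  A
  ±1 bp clustering mode exists (cluster representative = highest-read call)
  but is off by default because no slack rule is part of the filter.

FPM is linear in reads: `fpm = reads / (mapped_fragments / 1e6)`.

## Classification cascade

Host assignment: the same-strand gene whose exon/intron span contains the
circle, largest exonic overlap winning, ties broken lexicographically by
gene id; failing that, an opposite-strand containing gene (antisense);
failing that, intergenic.  On the sense host the cascade is
5'-UTR → 3'-UTR → exonic → intronic, testing the two BSJ base positions
(`start` and `end - 1`).  UTR classes take precedence over exonic so that
UTR-derived circles are counted separately from body-exon circles.

Two modes answer an open question — must an "exonic" circle match annotated
splice sites, or merely lie in exons?

* **lenient (default)**: both BSJ bases inside exons.  A circle matching
  neither this rule nor the single-intron rule (one junction in an exon, the
  other in an intron) is labelled exonic when it overlaps any exon, else
  intronic, keeping classification total.
* **strict**: exonic requires the circle's start and end to coincide with
  annotated exon boundaries; every other sense-host circle is pooled as
  intron-derived.

Flanking introns are taken from the transcript with the greatest exonic
agreement with the circle; `non_repeat` is defined only when both exist and
is `TRUE` iff neither overlaps a repeat interval — adding repeats can only
flip it `TRUE → FALSE`.

IDs follow the atlas scheme `<species>-<host symbol>_<ordinal>` with the
ordinal ranked by MCS descending within the gene (`_0001` = most conserved),
ties broken by coordinates; hostless records fall back to
`<species>-<locus key>`.

The circular ORF search scans the tripled sequence in all frames from every
in-circle ATG: translation may cross the BSJ and, when the circle length is
not a multiple of 3, shift frame on each lap.  ORFs are capped at three laps
(rolling-circle bound); an ORF that never meets a stop is reported at
`3 * L` and flagged.  Only maximal ORFs are reported; among equal-length
rotations of one circular ORF the earliest start is kept.  IRES prediction
is out of scope (it requires externally trained models).

## Conservation workflow

Candidates are restricted to orthologous gene pairs in which **both** genes
host circRNAs; the candidate set is the per-gene-pair cross product.
Cirexon boundary correspondence can be verified through chain-like pairwise
coordinate maps (`liftover_interval()`, ungapped blocks, strand-aware offset
arithmetic); this verification is advisory rather than a hard filter, since
the alignments are used to ensure accuracy, not as a stated rejection rule.

Each BSJ is represented by the last $\min(50, \text{exon length})$ nt of the
3'-terminal cirexon followed by the first $\min(50, \text{exon length})$ nt
of the 5'-terminal cirexon, read 5'→3' on the mature transcript; minus-strand
extraction is exactly the reverse complement of the plus-strand slice, so
circles compare correctly across strands.  For hosted circles without exon
overlap (e.g. intronic) the circle interval itself serves as the single
cirexon (`fallback_whole_circle = TRUE`), so they remain comparable.

Alignment uses an internal optimal Smith–Waterman (affine gaps; match +1,
mismatch −1, gap open −2 covering the first gap base, extension −1),
implemented in C++ — at ≤ 100 nt queries optimality is affordable and removes
any external aligner binary.  Its optimality is tested against an
exhaustive-recursion oracle and cross-checked against
`Biostrings::pairwiseAlignment`.  RBH requires a mutual, *unique* top score
(ties disqualify — conservative), identity ≥ 0.7 and alignment length ≥ 60
columns; these thresholds are explicit defaults, config-exposed, since no
published cutoffs exist for this step.

Pairwise RBH sets are integrated into groups on the RBH graph: within each
connected component, a species-consistent partition (≤ 1 member per species,
multi-member groups internally RBH-connected) maximizing the summed edge
score is chosen — exactly, by exhaustive partition search, for components of
up to 8 nodes, and by greedy descending-score edge merging above that.  This
graph integration replaces genome-scale gene-family machinery that the
toolkit does not need.  $N_s$ = group size − 1 ("number of orthologs"); a
`ns_counts = "species"` flag reports group size instead, since the axis could
also be read as a species count.

## MCS

The hierarchical expression tree has one node per tissue and one per
(tissue, individual); an individual node is marked when any of its samples
exceeds the expression threshold (default FPM > 0, i.e. any supported BSJ
read; config-exposed), and a tissue node when any of its individuals is
marked.  Then

$$N_t = \frac{\#\text{marked tissue nodes}}{\#\text{tissues}}, \qquad
  N_i = \frac{\#\text{marked nodes in both layers}}
             {2 \times \#\text{individuals in marked tissues}},$$

and $\mathrm{MCS} = N_s + N_t N_i$.  "Marked nodes in both layers" sums the
marked tissue nodes and the marked individual nodes; with every individual of
every marked tissue expressing, $N_i = 1$ and the decimal part degenerates to
$N_t$.  The degenerate case $N_t N_i = 1$ is not clamped; components are
always reported alongside the composite so the integer/decimal reading stays
recoverable.  For a circRNA expressed nowhere, $N_i$ is undefined and the
decimal part is 0.

Companion metrics: the tissue-specificity index is $\tau$
($\sum_i (1 - x_i/x_{\max}) / (N-1)$ over per-tissue means, the
field-standard index, adopted because only the index's name is given
elsewhere), and the junction ratio is $2b/(2b + l)$ — a BSJ read testifies to
one junction while the two flanking linear splice junctions each contribute,
matching the convention of the CIRI detector family that anchors the
detection stack.  Linear junction reads are an input column, not recomputed.

Prioritization sorts by MCS descending, ties by $N_s$ descending then locus
key.

## Annotation network

Co-expression is computed on per-tissue mean expression so that the
"expressed in ≥ 3 tissues" node restriction and the correlation act on the
same axis.  After removing nodes expressed in fewer than 3 tissues, Pearson
correlation is computed for pairs containing a circRNA, and the
weak-correlation filter keeps edges with $r \ge 0.5$.  The filter is
one-sided: strongly negative pairs are also "not weak", so a
`keep_anticorrelated` flag restores $|r| \ge 0.5$.  Constant profiles have
undefined correlation and are skipped with a warning.

miRNA sites use the canonical seed classes (6mer, 7mer-A1, 7mer-m8, 8mer:
reverse complement of miRNA positions 2–7/2–8, with the site-type A opposite
position 1), scanned on the circular context (sequence ⊕ its first 7 nt) so
sites spanning the BSJ are found; each match is typed by its most specific
class.  This internal scan stands in for an ensemble of external target
predictors; external prediction TSVs can be unioned (default) or intersected
with it via `combine_mirna_predictions()`, since it is unknown whether a
multi-predictor consensus was required.

RBP edges connect a circRNA to an RBP when a CLIP peak overlaps the ±1 kb
windows around either BSJ coordinate (strand-agnostic), recording peak count
and the minimum distance to a BSJ.

Function propagation tests, per circRNA and term, the neighbor gene set with
the hypergeometric upper tail $P(X \ge k)$ against the universe of annotated
genes in the network, then applies Benjamini–Hochberg across terms within the
circRNA.  The enrichment statistic is a design choice; no statistic is
prescribed for this step.

## Synthetic fixtures

The generator emulates the atlas study design where that design is stated:
six species (`hsa mml mmu rno ssc gga`), 19 normal tissues, four detectors
(CIRI2, CIRCexplorer2, DCC, find_circ).  Sizes the study does not pin down
are desk-scale choices made once: 3 individuals per tissue (one RNA-seq
sample each), 20 genes per species with 4 exons of 150 bp and 120 bp introns,
30 planted circRNAs, 5% inter-species substitution rate, tool sensitivities
0.95/0.90/0.90/0.85, mean BSJ read count 8, decoy (single-tool, single-read)
calls at 0.2 per truth circRNA, repeats on half the introns, mean library
size 2×10⁷ fragments.

Species 1 receives a random genome; every other species inherits identical
coordinates with per-base substitutions at the divergence rate, so ortholog
gene pairs and identity coordinate maps are exact by construction and planted
circRNA loci are orthologous across species.  Planted circles cycle through
the subclasses with an exon-dominated composition, are present in species
1..k with k cycling over the species count (varying $N_s$), and carry planted
expression patterns (housekeeping ≈ uniform, random breadth, single-tissue).
Decoy calls model detector false positives — the failure mode the two-tool
filter targets.  Coordinate maps are identity by default so liftover truth is
exact.

What the fixtures do **not** emulate: read-level sequencing noise (evidence
is simulated at the call level), indels and rearrangements between genomes,
alternative splicing and overlapping genes, expression count noise beyond
Poisson reads, and biased detector error profiles.  Passing tests therefore
demonstrate correctness of the algorithms under their stated models, not
robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

* Ties are broken deterministically everywhere (lexicographic ids or
  coordinates), so identical inputs give identical outputs.
* RBH top-score ties disqualify the locus rather than picking arbitrarily.
* `junction_ratio(0, 0)` is undefined and returns `NA`; `tau` errors on
  all-zero profiles; `compute_Ni` errors for unexpressed circRNAs (handled
  upstream by `compute_mcs`).
* The exact group solver enumerates species-consistent, edge-connected
  partitions (Bell-number bounded; ≤ 4140 partitions at 8 nodes); the greedy
  fallback above that is not guaranteed optimal.
* Every simulation entry point seeds the RNG explicitly from the fixture
  config, making the full pipeline byte-reproducible.

## Problem sizes used by the test-suite

The suite runs the consensus oracle on 200 random call sets, the aligner
oracle on 200 pairs of length ≤ 12, MCS brute force on 50 random trees, the
ortholog-recovery sweep on two-species fixtures of 24 planted circles at 5%,
15% and 30% divergence, the group-builder oracle on components of ≤ 6 nodes,
and the end-to-end demo twice at the default configuration (6 species ×
19 tissues × 3 individuals).  These sizes keep the default `devtools::test()`
run around a minute while exercising every code path.

## Known limitations

* Full-length isoform reconstruction, IRES scoring, disease-database
  integration and detector re-execution are out of scope; detector output
  tables are the entry point.
* The subclass cascade resolves multi-category loci by fixed precedence;
  genes with heavily overlapping annotation may be sensitive to the
  host-gene tie-break.
* $N_s$ depends on RBH quality; at high divergence (> 0.5 substitution rate)
  recovery is not guaranteed, and the generator warns accordingly.
* The co-expression filter is correlation-based and therefore blind to
  non-linear relationships.
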
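---
title: "Methods: miRNA-centered regulatory network analysis at desk scale"
author: "mircascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-centered regulatory network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mircascade` implements, end to end and at desk scale, the computational
stages of a plant miRNA-centered regulatory-network study: small-RNA read
preparation, criteria-based annotation of miRNA hairpin loci, conservation
and family classification, genomic clusters and synteny anchoring, target
prediction with two scoring families, degradome (PARE) confirmation,
RPM/FPKM quantification and expression-pattern classification, miRNA-target
correlation, weighted co-expression modules, promoter PWM scanning, and
enumeration of TF→miRNA→target cascade and feed-forward-loop (FFL) motifs.
A fully specified synthetic-data generator emulates the study design — seven
tissues (root, stem, leaf at the shooting stage; root, stem, flag leaf,
panicle at grain filling), two small-RNA replicates, three mRNA replicates
and one PARE library per tissue — and writes machine-checkable truth tables
so every stage is testable without any download.

# Small-RNA preparation

Reads arrive pre-trimmed (adapter removal is a vendor step upstream of this
package; a pass-through accepts any pre-trimmed FASTQ). Cleaning trims
homopolymer-A tails of at least 8 terminal As (the polyA constant is
configurable; only "polyA removal" is specified by convention, not a
threshold) and then keeps reads of 18–30 nt. The miRNA prediction set is
the 19–25 nt fraction. Reads matching structural ncRNAs (tRNA, rRNA,
snRNA, snoRNA) full-length, ungapped, on either strand with at most one
mismatch are discarded; this filter is implemented as exact set membership
against the 1-mismatch neighborhood of every ncRNA window, which is both
fast and exactly equivalent to per-read alignment at this allowance.
Genome mapping is exact (all occurrences, both strands) through
Biostrings `PDict`/`matchPDict`; mature-miRNA quantification uses exact
reads, so mismatch tolerance exists only in the ncRNA filter. The mapping
mismatch allowance is exposed (`max_mm`) because upstream read mappers are
commonly run with small nonzero allowances.

# Locus annotation

Candidate regions are read stacks: overlapping same-strand alignments of
prediction-set reads, kept when their summed count reaches
`min_stack_count` (default 10 — at the default background depth, chance
read pile-ups essentially never reach this). Each stack is extended by
250 nt of flanking sequence on both sides (enough to host any precursor up
to the 300-nt cap) and evaluated:

1. **Mature arm.** The most abundant 19–25 nt read in the window; ties go
   to the 5′-most read for determinism.
2. **Star arm search.** A Watson–Crick complementarity scan locates
   candidate duplex partners within the maximum precursor span.
   Candidates are ranked by match count, then smaller precursor span, and
   candidates whose arm has read support are tried first — the
   read-supported duplex is the biologically meaningful one.
3. **Folding.** The duplex-anchored precursor subsequence (both arms plus
   10-nt pads) is folded by the internal maximum-base-pairing folder, a
   Nussinov dynamic program over {G:C, A:U, G:U} pairs with a minimum
   hairpin loop of 3. Folding the anchored subsequence rather than the
   entire 520-nt window is deliberate: a maximum-pairing objective on a
   long window has massively degenerate optima that scatter the mature
   arm's partners over flanking sequence. The folder is pluggable;
   externally computed dot-bracket structures (e.g. from a thermodynamic
   folder) can be passed through `precomputed`.
4. **Criteria.** The miRNA* is the duplex partner implied by the
   structure with 2-nt 3′ overhangs. Because an antiparallel duplex has a
   constant frame (position + partner), the star interval is pinned by
   the modal frame of the mature arm's partners, which is robust to
   single wobble-shifted pairings. Duplex mismatches are the duplex
   positions (mature minus its own 2-nt 3′ overhang) not paired within
   3 nt of the modal frame — pairs further off-frame belong to
   alternative helices the maximum-pairing objective can invent, not to
   the mature:star duplex. The asymmetric bulge is the largest asymmetry
   between consecutive partner gaps. A locus passes when: duplex
   mismatches ≤ 5; asymmetric bulge ≤ 3 nt; precursor ≤ 300 nt; mature
   length 19–25 nt (20–24 nt flagged high-confidence); at least one star
   read at the expected coordinates (±1 nt — stricter than the 2-nt
   mature anchoring rule, since the star call is the decisive evidence);
   and read precision (mature + star reads over all reads overlapping
   the precursor) ≥ 0.75. Rejections log the first failing criterion in
   this order.

Conservation is classified against a reference catalogue carrying species
and lineage tags: matching allows ≤ 2 mismatches and ≤ 2 nt of terminal
shift (the catalogue-matching shift tolerance is an interpretation of the
"2 nt contiguous nucleotides" matching convention); any hit in a
non-Poaceae species → conserved, hits confined to Poaceae →
Poaceae-specific, no hit → species-specific. Catalogued loci inherit the
reference family; novel loci are grouped into `miRN` families by
single-linkage at ≤ 2 mismatches and lettered in genomic order. Genomic
clusters chain loci with start-to-start distances strictly below 10 kb.
Synteny anchoring takes precomputed collinearity blocks as paired
intervals (computing collinearity itself is out of scope); two
same-family loci anchored to the two sides of one block pair are a
syntenic pair.

# Target prediction and degradome confirmation

Two computational scoring families run behind one alignment engine
(ungapped or one single-nucleotide bulge on either strand, exact optimum):

* **Expectation penalty** (psRNATarget-style): mismatch 1.0, G:U 0.5,
  bulged nucleotide 2.0, all doubled at miRNA positions 2–13; sites with
  E < 3.0 (strict) are kept.
* **Duplex energy ratio** (RNAhybrid-style): simplified pair energies
  G:C −3, A:U −2, G:U −1 (arbitrary units; monotone and auditable rather
  than a nearest-neighbor table — the ratio semantics are preserved).
  MDE is the perfectly paired miRNA energy, MFE the best pairing of the
  candidate site; sites with MFE/MDE ≥ 0.75 are kept.

The original study ran four external predictors; implementing two
representative scoring families preserves the integration rule — which is
the actual computation — without duplicating near-identical scorers. The
overall dataset is the union of all methods plus degradome evidence; the
overlap dataset keeps every degradome-confirmed pair plus pairs predicted
by at least two computational methods.

Degradome tags (≥ 15 nt, exact matching, multi-transcript tags counted
once per hit) build per-transcript 5′-end depth profiles. With d the
depth at the queried position, M the maximum and med the median over
positions with at least one read (zero positions excluded, following the
cleavage-classifier convention and avoiding zero inflation): category 0 =
unique maximum, 1 = tied maximum, 2 = above the median, 3 = above 1, 4 =
depth 1. The expected cleavage position is the transcript nucleotide
paired to miRNA position 10 (`cut_pos` exposes the off-by-one convention);
categories {0, 1} confirm by default.

# Quantification, patterns, correlation

RPM counts a read toward a mature miRNA when it maps to the same strand
with both end offsets within 2 nt (inclusive; "less than 2-nt shift" is
ambiguous between < 2 and ≤ 2, so the anchor is configurable), divided by
all genome-mapped reads in the library. FPKM is count / (kb × million
fragments). Tissue matrices are replicate means. Pattern classes cut the
tissue matrix at RPM ≥ 100 ("high") and < 10 ("low"): housekeeping = high
everywhere, tissue-specific = high in exactly one tissue, low = low
everywhere, intermediate = the rest; the four predicates are the minimal
partition consistent with those cutoffs and are config-driven.

Pearson correlation between each miRNA and target uses the 7
tissue-averaged points (replicate-level correlation would mix biological
and technical variation; the averaging convention also fixes the t-test
at 5 degrees of freedom). Constant profiles yield undefined r and are
excluded from the negative-fraction denominator. Enrichment is the exact
upper-tail hypergeometric per term (equivalently Fisher's one-sided
test — one implementation serves both names) with optional
Benjamini–Hochberg adjustment; raw correlation p-values are reported
without correction.

# Co-expression modules

The weighted network is unsigned: adjacency |cor|^β with β = 8 (the soft
power is fixed rather than estimated by scale-free fit). The topological
overlap matrix is TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 −
a_ij). Modules come from average-linkage clustering of 1 − TOM with a
static cut at height 0.9; clusters below 5 genes (a desk-scale minimum)
pool into the unassigned "grey" module. The static cut replaces dynamic
tree cutting: it is deterministic, dependency-free and sufficient for
planted-block recovery; the height is configurable. Module eigengenes are
the first principal component of the standardized module submatrix,
sign-oriented to correlate positively with the module's mean profile —
this makes module–trait signs deterministic. Traits are one-hot tissue
indicators over samples (the module analysis runs on the 21-sample
matrix, since sample-level replication is what gives the trait
correlations their p-values); modules with |r| ≥ 0.75 and p < 0.01 are
retained (the threshold is read inclusively). kME is the correlation of a
gene with its own module eigengene; the top 9 hubs per module are
reported with ties broken by gene id.

# Promoter scanning and the network

Promoters are the 2,000 nt upstream of the strand-aware feature start
(precursor start for miRNA loci), truncated at chromosome edges with the
realized length recorded (truncation is recorded rather than padded so
scan statistics stay honest near contig edges). PWMs (JASPAR-style tab or
MEME minimal input; columns normalized, pseudocount 1e-3 applied when a
probability is zero) score windows on both strands by log2 odds against a
0-order background. Scores are quantized to a 1e-4-bit grid so the exact
score distribution — and hence every p-value — is computed by dynamic
programming over per-column score distributions; a window is a hit at
p ≤ 1e-4, mirroring the common promoter-scan default. TMI edges are TF
motif hits on pre-miRNA promoters, TTI edges hits on target-gene
promoters (the scan is restricted to target-gene promoters by default,
configurable), MTI edges come from the selected interaction dataset
(overlap by default; overall selectable). Duplicate edges collapse with
evidence counts; TF self-edges are dropped so the enumerated motifs stay
acyclic. Cascades are TMI∘MTI chains; FFLs are cascades whose (TF,
target) pair is also a TTI edge. Exports: SIF, node attributes,
GraphML (round-trips through igraph).

# The synthetic-data generator

The generator is first-class, tested code. It plants:

* **Hairpin loci** whose mature:star duplex satisfies every criterion by
  construction: exact-complement arms with 0–2 planted C:C facing
  mismatches, 2-nt 3′ overhangs, all-A loops (12–18 nt) and 10-nt all-A
  buffers. Letter constraints (loop-adjacent duplex positions G/C,
  overhangs A/C) make the planted duplex the unique maximum-pairing
  structure, so the annotation criteria are machine-checkable. Hairpins
  alternate strands to exercise strand handling.
* **Decoys**, each violating exactly one named criterion: 7 facing
  mismatches, a 5-nt asymmetric star bulge, no star reads, or read
  precision below 0.75. Decoy duplex arms are G-skewed G/C with A:A
  mismatches and A-bulges — an A can pair nothing in a G/C arm, so the
  planted defect cannot be refolded away.
* **Reads**: negative-binomial counts (variance μ + μ²·d, dispersion
  d = 0.2) with per-tissue means from the planted pattern class
  (housekeeping ≈ 12 reads/library everywhere; tissue-specific 30 in the
  peak tissue; intermediate 12 in two tissues; low 0.02 — i.e. expected
  RPM below 10, which is the realistic price of a low class: such loci
  are not recoverable from reads and two of the 30 true loci carry it).
  Mature reads dominate star reads 4:1 in expectation; 80% of reads sit
  at the exact coordinates, 15% shift 1 nt, 5% shift 2 nt. Background
  reads (2,000 per library) are drawn uniformly from the non-locus
  genome with a designed 24-nt length peak, plus a small fraction of
  polyA-tailed and out-of-range reads to exercise cleaning, and 5%
  ncRNA-derived reads to exercise the filter.
* **Target sites**: perfect-complement sites inside dedicated target
  transcripts; the PARE libraries put a dominant 5′ tag at the position
  opposite miRNA position 10 (category 0/1 by construction) over sparse
  single-tag background.
* **Expression**: the direct miRNA RPM matrix follows the pattern
  classes with log-normal tissue and replicate noise; the transcript
  FPKM matrix carries three co-expression blocks (panicle-high,
  root-high, leaf-high; within-block correlation ≥ 0.8 by construction)
  and repressed targets with expected level base × (1 − s·m), where m is
  the miRNA tissue mean normalized to its maximum and s the repression
  strength (default 0.9).
* **Promoter motifs**: consensus words of 5 PWMs planted into 40% of
  promoters at masked positions (never overwriting hairpins or target
  sites), on either strand.

Every output file draws from its own RNG stream derived from the master
seed by a stable label hash (with avalanche mixing so that labels
differing in one character give unrelated streams), which makes each file
individually reproducible and the whole dataset byte-identical under a
fixed seed.

What the generator does *not* emulate: sequencing error, adapter
contamination, expression isoforms, multi-mapping ambiguity beyond planted
family paralogs, GC or positional biases, and genome repeat structure.
Passing tests therefore demonstrate the correctness of the computations
under the stated model, not performance on real sequencing data.

# Problem sizes and numerical choices

Default desk-scale sizes, chosen once as a realistic miniature of the
study design: 2 chromosomes × 200 kb, 30 true + 10 decoy loci, 80
transcripts (12 TFs, 20 repressed targets, 3 × 15 block genes), 2,000
background reads per small-RNA library; the repression-structure analysis
uses 260 transcripts and 200 planted pairs on 450-kb chromosomes. All
numeric ties are broken deterministically (5′-most mature, smallest
length histogram mode, gene-id order for kME ties, smallest-span star
candidate). PWM scores are exact on a quantized grid; TOM and adjacency
are plain dense matrix algebra, adequate below a few thousand genes.

# Known limitations

* The maximum-base-pairing folder is not thermodynamic; precursor
  structures with large internal loops fold differently than under an
  MFE model. The backend is pluggable for that reason.
* The duplex-energy model is a three-value pair table, not a
  nearest-neighbor stack model; only the MFE/MDE *ratio* semantics are
  preserved.
* The static tree cut does not merge close modules; on real data the
  cut height would need tuning where dynamic cutting is standard.
* Synteny blocks are consumed, never computed.
* Expression-pattern recovery from reads is limited by count
  granularity at desk-scale depth (1 read ≈ 400 RPM); the direct
  expression matrices are the right route for pattern-level analyses.
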
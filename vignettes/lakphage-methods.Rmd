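---
title: "Methods: alternative genetic codes, CRISPR host linkage and population structure of Lak-type megaphages"
author: "lakphage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternative genetic codes, CRISPR host linkage and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakphage)
```

This vignette explains the models and procedures implemented in
`lakphage`, their assumptions, the parameters that matter, and the design
decisions taken where the design was genuinely open. The package targets a
specific discovery scenario: very large (>540 kb), AT-rich phage genomes
assembled from gut metagenomes, whose genes are translated with a
reassigned stop codon and whose host must be established indirectly.

## Coordinates and containers

All internal coordinates are 0-based, half-open; conversions to the
1-based inclusive GFF3 convention happen only at the format boundary in
`write_features()` / `read_features()`. A `genome` is a named sequence over
{A,C,G,T,N} plus a circularity flag. Features on circular genomes may wrap
the origin (`wrap = TRUE`, `end` beyond the genome length); windowed
statistics assume the genome was rotated to a feature-free origin, and
drop wrapped ORFs rather than guessing. Windows or fragments with more
than 10% N are excluded from density and identity statistics, which
defines behaviour for uncurated input.

## ORF model and genetic-code inference

`find_orfs()` scans all six frames. Within a frame, each stop-to-stop
segment yields at most one ORF, from the segment's first ATG/GTG/TTG to
its terminating stop (the stop codon is included in the reported
interval); stop-less segments at the ends of linear sequences are reported
`partial`. This is deliberately not a Prodigal-style gene finder — no
RBS model, no start scoring. The decision statistic built on top of it is
robust to that simplification: removing a codon from the stop set can only
merge or extend stop-to-stop segments, so the coding density under
table 15 is never below the density under table 11, and the *gain* is the
signal. A genuinely recoded genome, called with table 11, fragments every
TAG-containing gene and loses tens of percentage points of density; an
unrecoded genome gains almost nothing because TAG simply stops occurring
in-frame within real genes.

`infer_genetic_code()` therefore calls an alternative table only when its
density exceeds the table-11 density by `delta = 0.10` (absolute). The
threshold is configurable; 0.10 sits well clear of both the gains we
observe on unrecoded synthetic genomes (≲ 0.03, from chance segment
merging in non-coding frames) and well below the gains on recoded ones
(≈ 0.18 at the default 1% TAG rate). Table 4 (TGA → Trp) is carried as a
third candidate so the procedure is a genuine model selection rather than
a binary switch; ties resolve to table 11, the conservative call.

`codon_usage_windows()` reports, per consecutive 1 kb window, the
percentage of a target codon among all codons of all ORFs whose first
base lies in the window — windows without coding sequence are missing
(`NA`), never zero, because "no data" and "zero usage" mean different
things for a codon-avoidance signal. `tag_free_regions()` returns maximal
intervals longer than 5 kb with no in-frame TAG of any *primary* ORF.
The primary reduction (`primary_orfs()`, greedy longest-first with ≤ 30 bp
mutual overlap) exists because six-frame calling reports short antisense
ORFs nested inside real genes; their incidental TAG codons are calling
artifacts, not codon usage.

## tRNA detection

`scan_trnas()` is a simplified cloverleaf matcher, not a covariance-model
search, and is validated on synthetic tRNAs only — a deliberate scope
decision, since the observations it supports (a CTA-anticodon suppressor;
introns 3′ of the anticodon) are testable without full covariance models.
The template is a canonical 75-nt layout: 7-bp acceptor stem (≥ 6 pairs
required, G·U allowed), 4-bp D stem (≥ 3), 5-bp anticodon stem (≥ 4) with
a 7-nt loop, 5-bp T stem (≥ 3); the score is the total number of paired
bases (max 21). Candidates whose downstream arms pair only after inserting
5–60 nt immediately 3′ of the anticodon are reported with that insertion
as an intron. The default `min_score` is 20 of 21: with a plain
pairing-count score and an intron grid, a cutoff of 18 admits more than
ten spurious hits per 10 kb on AT-rich random sequence (measured on seeded
nulls), whereas 20 keeps the empirical false-positive rate below one hit
per 10 kb at both 26% and 50% GC while leaving recall of canonical
(perfect-stem) tRNAs at 100%. Suppressors are the hits whose anticodon is
CTA — the anticodon that pairs with TAG. `detect_intron_by_offset()`
locates an intron as the unmatched middle between the maximal exact prefix
and suffix shared by intron-bearing and intron-free loci; amid repeated
flanking bases the placement is ambiguous, the leftmost placement is
chosen (the standard alignment convention) and flagged.

## CRISPR arrays, spacer matching and host taxonomy

`detect_arrays()` seeds on 11-mers recurring with a spacing compatible
with repeat+spacer periodicity, extends seeds to maximal repeat units by
column-majority agreement, and accepts an array when ≥ 3 repeat copies
match the majority consensus at ≥ 90% identity with all spacer lengths in
15–70 bp. One boundary column of ambiguity against a planted truth is
possible whenever every repeat copy happens to be flanked by the same
base; any majority-rule detector must include such a column.

`match_spacers()` emulates a short-sequence nucleotide search: exact
11-mer seeds, ungapped full-length extension, both strands. A hit is
accepted iff the aligned length **exceeds 24 bp** with **at most one
mismatch** — the filter that defines "targets the phage" throughout the
package. The ungapped, ≤ 1-mismatch model subsumes every hit that filter
can accept, so a gapped aligner would change nothing. Repeats are screened
identically and any repeat hit voids the scaffold's spacer evidence, since
it indicates the target carries related repeat sequence itself. All
qualifying positions are reported; summaries count spacers, not hits, so
multi-target spacers are not double-counted. No protospacer-adjacent-motif
analysis is attempted.

Scaffold taxonomy (`assign_taxonomy()`) walks ranks species → domain and
returns the most specific rank at which one name is shared by **at least
50%** of the scaffold's genes, unannotated genes counting in the
denominator. `compare_arrays()` clusters spacers across arrays at 95%
identity (either orientation) and reports shared-cluster counts plus order
conservation as the longest common subsequence of cluster ids, computed in
both relative orientations — arrays diversify at one end, so the better
orientation is the meaningful one.

## Comparative genomics

`pairwise_ani()` follows the classic fragment-recruitment definition: the
query is cut into consecutive 1 kb fragments; each is placed by exact
15-mer seeding (modal diagonal, both strands) and aligned globally within
the fragment, locally in the target; fragments with ≥ 70% identity over
≥ 70% of their length are retained; ANI is the mean retained identity.
Under an i.i.d. substitution model the retained-fragment identity is
Binomial(1000, 1−e)/1000, which gives the calibration check its closed
form. Fragmenting makes the measure slightly asymmetric; the package
asserts |ANI(a,b) − ANI(b,a)| ≤ 1 percentage point empirically rather than
pretending symmetry.

`find_rearrangements()` chains k-mers unique in, and shared by, all
genomes into collinear blocks (breaks at orientation flips, order
violations, or > 2 kb anchor gaps) and counts rearrangement *events*:
blocks inverted in place plus blocks displaced out of the longest
conserved order. This event count matches how a person counts "large
rearrangements" on a dot plot (one inversion = 1, three transpositions
= 3); it is a heuristic, not a minimal breakpoint distance, and is
documented as such.

`segment_identity_blocks()` operates on equal-length, gaplessly aligned
genomes. Every polymorphic column induces a partition of the genomes into
identical-character classes; maximal runs of columns with the same
partition become blocks, so monomorphic stretches never split a block —
the reasoning is SNP-pattern-based throughout. Runs shorter than
`min_block` are absorbed into their longer flank (preserving the exact
tiling) but retained, flagged, in the `runs` attribute, because at
realistic breakpoint densities the raw runs *are* the recombination
signal and the absorbed micro-runs matter for minor-variant analysis.
Breakpoint resolution is intrinsically limited to one informative-site
spacing: the recovered boundary is the first polymorphic column after the
true breakpoint.

`screen_metagenome()` keeps contig alignments of **≥ 2 kb and ≥ 70%
identity** and calls a sample positive when one alignment survives.
`marker_profile()` clusters marker genes greedily (longest first) at 90%
identity, maps reads to centroids, and reports breadth of coverage
normalised by total sample bases; the relative abundance across clusters
is invariant to sequencing depth, which the tests exercise by sample
duplication.

## Read mapping and population structure

`map_reads()` is an exact-seed (21-mer), ungapped, ≤ `max_mm`-mismatch
mapper with wrap-aware placement on circular references; best placement
wins, ties resolve leftmost and are flagged multi-mapping. Ungapped
mapping is a scope decision, not a limitation of the analyses: the
synthetic data are indel-free by construction, which keeps the mapper an
exactly testable oracle, and placements from standard mappers can be
imported as a data frame with the same columns. "SNP" is used in the
read-level sense — a read-versus-reference mismatch — so the zero-SNP
fraction of a clonal population with error rate e and read length L has
expectation (1−e)^L, and values near 1 on real data argue the assembled
genome is not a chimera of population variants.

`call_variants()` reports sites with coverage ≥ 10 and a non-reference
allele at frequency ≥ 5% in any sample. `variant_trajectories()` joins
sites across ordered samples and reports two-locus linkage from reads
co-covering site pairs (≥ 20 reads): the package operationalises
"unlinked" as |D′| < 0.5 at ≥ 90% of pairs — thresholds configurable,
chosen to turn a qualitative claim into a checkable rule.
`find_recombinant_reads()` paints each read's alleles at the panel's
diagnostic sites and flags reads that no single panel genome can explain
(minimal-switch parsimony ≥ 2 donors), localising the switch between the
flanking diagnostic sites. Read- and pair-level evidence are reported
separately rather than combined.

## The synthetic-data generator

The generator *defines the study conditions*; all stochastic behaviour is
a pure function of the arguments plus one integer seed.

* **Phage genomes** default to 26% GC, table 15, ~90% gene density with
  50–200 bp intergenic gaps, a 1% per-codon TAG rate in TAG-permitted
  genes, two planted TAG-free spans (at 10–20% and 55–65% of the genome),
  and a planted suppressor tRNA plus one intron-bearing tRNA. Gene length
  is uniform over 200–550 codons — the source genomes show many long
  genes and large intergenic regions but report no distributions, so both
  are configurable single choices. Genes touching a TAG-free span avoid
  the TAG motif *in every frame and on both strands* (CTA being a
  minus-strand TAG), via draw-time codon exclusion plus a GC-balanced
  motif scrub (TAG→TAA, CTA→CCA); without this, ORF calls legitimately
  sweeping through intergenic sequence or neighbouring frames would pick
  up incidental TAGs and no planted span could ever be recovered cleanly.
  tRNAs are never planted inside TAG-free spans (the suppressor's CTA
  anticodon is itself a TAG mirror).
* **Host scaffolds** carry one repeat–spacer array (default repeat: the
  30-mer of the Lak-targeting *Prevotella* arrays) whose true spacers are
  copied from recorded phage intervals on either strand; spacer lengths
  are uniform 25–40 bp — an explicit assumption, the source arrays'
  empirical length distribution being unavailable. Decoy spacers are
  random sequence.
* **Mosaic populations** are substitution-only: ancestors are built by
  i.i.d. substitution at `snp_rate` (default 0.02) from a reference, and
  each output genome concatenates ancestor blocks with exponential lengths
  (mean 5 kb), consecutive blocks always switching donor. Substitution-only
  keeps the population aligned by construction, so segmentation needs no
  gapped aligner and the truth channel stays exact. The default of two
  ancestors matches the pairwise-sharing structure the block analysis
  reads; with more ancestors the per-column partitions within one block
  differ between sites and the segmentation reports finer runs.
* **Reads** have uniform start positions (wrapping on circular genomes),
  i.i.d. substitutions (default 0.004 per base, Illumina-like), optional
  pairs with a fixed outer insert.

What the generator does **not** emulate: indels and structural errors,
quality-score structure, coverage bias, chimeric assembly artifacts, and
real tRNA sequence diversity (planted tRNAs have perfect stems in the
package's own canonical geometry — the scanner's recall on real tRNAs is
untested and expected to be lower). Passing tests therefore demonstrate
correctness of the algorithms under the stated models, not performance on
real sequencing data.

## Numerical choices and problem sizes

Ties in ORF selection (first start per segment), intron placement
(leftmost), code inference (standard table), and read placement
(leftmost, flagged) are all deterministic, so every pipeline output is
byte-identical under a fixed seed. The bundled verification
(`tests/testthat/test-acceptance.R`, `scripts/acceptance.R`) runs at desk
scale, chosen to exercise every stage in a few minutes of one CPU:
20 genomes per code at 50 kb for code recovery; 1,000 (tests) / 200
(script) random sequences up to 10 kb against the exhaustive ORF oracle;
20 seeded host scaffolds with 5 true + 5 decoy spacers; mosaic populations
of 6 × 50 kb; 10,000 reads per error rate; 25 constructed chimeric reads;
and a 15-cell length × divergence screen grid. The headline genome-scale
quantities (density gain ≈ 0.18, code-11 density ≈ 74%, zero-SNP fractions,
ANI calibration) are stable across seeds at these sizes.

## Known limitations

The gene caller over-extends ORFs 5′ of the true start (no start-site
model); tRNA isotypes are assigned from the anticodon alone; the
rearrangement count is a heuristic event count; D′ from pooled reads
ignores sample structure; and the CRISPR detector reports one consensus
per array without internal repeat variants. Each is a deliberate trade
for testability at this scale.
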
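---
title: "Methods: small RNA profiling at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`srnapipe` re-implements, at desk scale, the analysis chain used for deep
small-RNA sequencing surveys of tissues such as adult testis: read cleaning,
unique-tag annotation through a priority cascade, rule-based novel miRNA
hairpin discovery, piRNA ping-pong characterization, seed-based miRNA target
prediction, and GO/pathway enrichment. Everything runs against a seeded
synthetic genome with planted features, so all behaviour is testable without
downloads. This vignette explains each model, its assumptions, and the
numerical and design choices behind it.

## Read model and cleaning

Reads emulate a Solexa-era protocol: an 18–28 nt insert ligated between a 5'
adapter (`GTTCAGAGTTCTACAGTCCGACGATC`) and a 3' adapter
(`TCGTATGCCGTCTTCTGCTTG`), sequenced to a fixed 36 nt. Qualities use the
offset-64 encoding, Q = ASCII − 64, and a read is low quality when any base
has Q < 10 (`max_bad_fraction = 0`, the strictest reading of the rule; the
fraction is configurable). Filters run in a fixed order — quality, adapter
stripping, N rejection, the 11–33 nt length window — and each read is charged
to the first filter it fails, so accounting is exact: total = clean +
rejected, and clean equals the sum of collapsed tag counts.

Adapter matching is exact with a minimum overlap of 6 nt: a read prefix
matching a 5'-adapter suffix is removed, and the read is truncated at the
leftmost occurrence of a 3'-adapter prefix. Reads without a detectable 3'
adapter are rejected rather than kept whole: a genuine small-RNA insert in a
36-nt read must run into the adapter. "Contaminated reads", undefined in the
original protocol descriptions, are modelled as adapter dimers (no insert)
and N-containing reads — the two standard failure modes a cleaning stage must
reject.

With a 36-nt read and a 6-nt minimum adapter overlap, the longest fully
recoverable insert is 30 nt. Longer planted piRNAs (up to 31 nt) therefore
shed a terminal base in their reads — conveniently mirroring the published
pattern in which the most abundant tag of a 31-nt piRNA is its 30-nt
sub-fragment.

## Mapping and the annotation cascade

Unique tags are mapped to both genome strands allowing at most one
substitution and no indels, via `Biostrings::matchPattern` behind the
`genome_index()`/`map_tag()` surface; every reported hit is re-verified by
direct comparison, and tests hold the mapper to an independent brute-force
scan. Categories are assigned by a priority cascade — miRNA, piRNA, rRNA,
tRNA, snRNA, snoRNA, scRNA, srpRNA, repeat, mRNA, else unannotated — where a
"match" means the tag aligns within a catalog sequence with at most one
mismatch in the same orientation. The order of the non-miRNA/piRNA block
follows the conventional category-table row order; the cascade makes the
result independent of reference load order. Each tag is counted once, in its
single category; per-chromosome read counts instead split multi-mapping tags
fractionally across their hits so chromosome totals still sum to the mapped
read count.

Editing candidates are called per catalog miRNA by pooling exact and
single-mismatch tags and reporting positions where mismatch reads exceed 10%
of the pool. The first and last two positions are excluded because 5'/3' end
heterogeneity produces apparent end mismatches that are length variants, not
edits.

## Secondary structure: a stacking-energy folder

Novel-miRNA discovery needs a fully specified, oracle-testable folding
engine, so `fold_rna()` implements a nearest-neighbour stacking model rather
than a full thermodynamic parameter set: G:C, A:U and G:U pairs are allowed;
unpaired bases and isolated pairs are free; a stack of two adjacent pairs
contributes −3.0 kcal/mol when both are G:C, −2.0 when the weakest pair is
A:U, and −1.0 when it is G:U (weakest-pair-wins is the tie-break when a stack
mixes A:U and G:U). Hairpin loops hold at least 3 unpaired bases; pseudoknots
are excluded. The dynamic program minimizes total stack energy over
non-crossing structures and is checked against exhaustive structure
enumeration on short sequences. All energy thresholds in the package (−18
for precursors, −20 for miRNA/target duplexes) are interpreted on this
model's scale, and the synthetic generator plants hairpins and target sites
calibrated to it. Consequences of the simplification: absolute energies are
not comparable to Turner-parameter folders, loop sizes carry no penalty, and
ties between isostable structures are resolved toward fewer pairs.

`duplex_free_energy()` applies the same stack table to intermolecular,
antiparallel, non-crossing pairing of two sequences (two-sequence dynamic
program, symmetric in its arguments, 0 when no pair forms).

## Novel miRNA discovery

Unannotated tags with at least 45 reads are discovery-eligible. The read
cutoff is stated both as "greater than 45" and "at least 45" in the source
protocol; the inclusive reading (≥ 45) is adopted and configurable. Around
each genomic hit two windows are excised — `[start−100, end+20]` and
`[start−20, end+100]` — covering a mature arm on either side of the hairpin;
windows are folded and evaluated against five rules, all inclusive on the
passing side: mature length 18–26 nt, precursor energy ≤ −18 kcal/mol,
mature/star spacing ≤ 35 nt, largest bulge in the mature/star duplex ≤ 4 nt,
and count ≥ 45. The star arm is the region pairing with at least 60% of
mature bases; candidates whose mature arm pairs more diffusely fail the
spacing/bulge rules by construction. Because the two arms of a perfect stem
are mutual reverse complements, the same locus surfaces on both strands;
deduplication is therefore strand-blind, keeping the highest-count mature per
overlapping locus. Occasionally (about one planted hairpin in eighty across
seeds) the window-wide minimum-energy structure reorganizes a planted stem
together with its flanks and the bulge rule rejects the locus — recovery is
therefore assessed as sensitivity at least 0.9 over seeds, with zero decoy
accepts, rather than as exact recovery. A 5'-nucleotide U/A preference is reported, not enforced:
published novels show it in most but not all cases, so it cannot be a hard
filter.

## piRNA characterization

The piRNA stage matches tags within a catalog (≤ 1 mismatch, same
orientation; RNA-alphabet catalogs are mapped U→T), reports each entry's most
abundant tag, and measures abundance concentration as the top-n read share.
The ping-pong signature is computed from opposite-strand mapped read pairs:
for every overlapping pair the distance between 5' ends (plus-strand start to
minus-strand end, inclusive) is histogrammed over 1–30 nt, and the 10-nt bin
is summarized as z10 = (h[10] − mean(h[≠10])) / sd(h[≠10]). The z10 statistic
is this package's quantification of a signature that the source literature
reports qualitatively; simulated ping-pong libraries give z10 well above 3
while position-shuffled nulls stay below 2 in ≥ 95% of trials (calibrated in
the test suite). The analysis window for the piRNA size class is 24–32 nt, an
inclusive superset of the commonly quoted 24–31 ranges, configurable.
In the end-to-end pipeline the signature is computed over reads overlapping
catalog-matched regions, oriented by the annotation (regions whose
catalog-matched reads map to the minus strand are mirrored), so that "sense"
means sense relative to the piRNA transcript rather than the genome's plus
strand; the 1U/10A conventions assume that orientation.

piRNA target classes are assigned by antisense alignment of the full piRNA
against a labeled repeat/transcript reference at ≥ 90% identity,
best-(fewest-mismatch)-hit wins; the identity cutoff is a declared stand-in
for unstated BLAST parameters.

## Target prediction

Three filters, in order. (1) Seed: a perfect Watson–Crick match of miRNA
positions 2–8 in the UTR (no G:U in the seed). (2) Duplex energy below −20
kcal/mol on the package's stacking scale. (3) A miRanda-style local alignment
score above 140: match +5, G:U wobble +2, mismatch −3, gap open −9, gap
extend −4 (a length-L gap costs 9 + 4(L−1)), with miRNA positions 2–8 double
weighted. The parameterization is calibrated so a perfect complement of a
22-nt miRNA scores 7·5·2 + 15·5 = 145 — just above threshold — while a
seed-only partial duplex falls well short; all five parameters are exposed.
The candidate site window runs from 4 nt upstream of the pairing region of
the miRNA 3' end to the base pairing miRNA position 1. Scores are per-site;
a gene is a predicted target when any site passes.

## Enrichment

With N annotated genes in the universe, n carrying a term, M annotated genes
among predicted targets and m of them carrying the term, the fold enrichment
(E-ratio) is (m/M)/(n/N) and the p-value is the hypergeometric upper tail
P(X ≥ m) (equivalently one-sided Fisher; the identity is tested on a dense
grid). Background counts are taken over annotated genes only. Significance
thresholds are strict, as printed: E-ratio > 2 and p < 0.05 for GO terms,
E-ratio > 1.5 and p < 0.05 for pathways. No multiple-testing correction is
applied by default, mirroring the original analysis; `adjust = "BH"` enables
Benjamini–Hochberg. Ties in the E-ratio ordering break by ascending p, then
term id.

## The synthetic study

`synth_config()` fixes the study conditions. A 90-kb three-chromosome genome
hosts non-overlapping planted features: six known miRNA hairpins (22-nt
matures, perfect stems, 12-nt loops, abundances 1200…80 reads), four novel
hairpins and four decoy loci (all with main-tag stacks ≥ 45 reads), 25
piRNAs over five loci (lengths 24–31 nt with a 26–27 mode, 1U bias 0.9), the
standard non-coding classes, repeats and LINE1/LTR retrotransposons, and
thirty 400-nt 3'UTRs of which eight carry perfect-complement target sites
for the top known miRNAs and four carry seed-only decoy sites. piRNA counts
are set so the ten most abundant hold exactly 61% of piRNA reads, and piRNA
sequences derive antisense from the repeat classes in proportions 17:2:4:2
(LINE1 : LTR : repeat : mRNA), i.e. 76% retrotransposon-derived with LINE1
dominating — mirroring the reported concentration and target-class breakdown.
Two known miRNAs carry a planted editing event (position 10, 15% of reads).

Decoy loci are the one deliberately artificial construct: 262-nt A/C-only
regions. With no G, no T, no base pairing is possible, so every excised
window folds to exactly 0 kcal/mol and fails the energy rule decisively —
the decoys isolate the energy rule, while their read stacks pass the count
rule. Real false candidates would fail more gradually; the negative control
here is sharp by design.

End heterogeneity is modelled as 1-nt 5'/3' trims (probabilities 0.08 and
0.18 — more 3' variation, as reported for hairpin products); extensions are
not generated because a tag longer than its catalog entry cannot align
within it and would (correctly) leave the miRNA category. Expected counts
are exact by default — `simulate_library()` emits precisely the planted read
counts, so conservation checks are sharp; passing `n_reads` switches to a
multinomial draw. Default noise levels are modest (per-base error 0.002,
contamination 0.03, low-quality fraction 0.02). All read-generating
sequences avoid adapter-derived 6-mers on both strands so that trimming is
exact on noise-free data; sequencing errors can still create spurious
adapter hits, at a rate too low to disturb the summaries.

What the generator does not emulate: position-dependent error profiles,
ligation bias, isomiR tailing, genuine repeat copy families (each repeat is
a single exemplar), GO term correlation structure, and genome-scale
multi-mapping. Passing tests therefore demonstrate correctness of the
algorithms under clean, known-truth conditions, not performance on real
libraries.

Problem sizes throughout (90-kb genome, ~8,000 reads per run, 100-kb mapping
oracle, N ≤ 60 enrichment grids, ≤ 14-nt folding enumerations) are chosen so
the full suite runs comfortably on a laptop while every oracle stays
exhaustive at its scale.

## Numerical and boundary conventions

* All rule thresholds are inclusive on the passing side (energy ≤ −18 passes;
  spacing 35 passes; bulge 4 passes; lengths 18 and 26 pass; count 45
  passes), except the target rules and enrichment thresholds, which are
  strict (< −20, > 140, > 2/1.5, < 0.05) as printed.
* Coordinates in R-facing tables are 1-based inclusive (the R/Bioconductor
  convention).
* z10 is undefined (NA) when no opposite-strand pairs exist.
* Tag ordering breaks count ties lexicographically; expression tables break
  read ties by name; enrichment breaks E-ratio ties by p then term id — all
  outputs are deterministic under a fixed seed.
* `e_ratio()` errors on zero denominators rather than returning Inf; m = 0
  yields 0 and p = 1.

## Limitations

The folder is not a thermodynamic model; energies are comparable only within
this package. The mapper is exact but not indexed for genome-scale data. The
piRNA target search uses full-length antisense identity, not local
alignment. Enrichment ignores the GO DAG. These are scope decisions: the
package's purpose is a faithful, fully testable reconstruction of the
analysis logic at a size where every step can be checked against an
independent oracle.
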
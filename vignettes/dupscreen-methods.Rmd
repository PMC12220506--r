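---
title: "Screening a chromosome-scale genome for duplication signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a chromosome-scale genome for duplication signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dupscreen)
```

## The problem

Chromosome-scale assemblies of non-model invertebrates go through a set of
bespoke curation and screening stages between scaffolding and biological
interpretation: contaminant scaffolds must be removed, gene models from
heterogeneous evidence must be reconciled into one non-redundant
annotation, conserved gene clusters (above all the Hox cluster) must be
assessed for integrity and gene loss, and the genome must be screened for
the footprint of a whole-genome duplication (WGD).  `dupscreen` implements
these four stages as tested, reusable functions, together with a synthetic
genome/evidence simulator so every stage can be validated against known
ground truth without any external data.

The motivating use case is the chelicerate WGD debate: horseshoe crabs and
arachnopulmonates carry WGD signatures while several other lineages do
not, so a marine outgroup genome that shows *no* duplication signal
anchors the non-duplicated state as ancestral.  The package's screening
logic operationalizes what "no duplication signal" means: no strong
off-diagonal block structure in a self-synteny contribution matrix, and
single-copy conserved gene clusters.

## Coordinates and containers

All coordinates are 1-based inclusive, the native convention of GFF3 and
of the IRanges/GenomicRanges stack the package is built on.  Using the
on-disk convention internally means there is no conversion layer at the
file boundary at all, which removes the usual class of off-by-one
defects; interval lengths are `end - start + 1` everywhere.

An `annotation_set` couples an ordered chromosome `assembly_layout`
(names, lengths, cumulative offsets) with a gene table (id, chromosome,
span, strand, source class, exon list).  Chromosome order is assembly
order and is preserved by every operation; the cumulative offsets define
the linearized axis used by the Oxford grid.

## Scaffold decontamination

Scaffolds are screened by taxonomic majority vote: per-scaffold hits are
aggregated into a metazoan fraction and a scaffold is removed when it has
at least one hit and *strictly less than* 90% of its hits are metazoan
(`flag_contaminant_scaffolds`, threshold exposed).  Three choices the
vote does not determine by itself:

* **Zero-hit scaffolds are kept.**  The rule is phrased over hits;
  absence of evidence is not evidence of contamination.
* **Lineage reduction is conservative.**  A lineage string counts as
  metazoan only if its path contains the metazoan clade label;
  unresolved or unclassified hits count as non-metazoan.
* **Hits are unweighted.**  Each hit counts once regardless of score;
  the score is retained for reporting only.

Surviving pseudochromosomes are renumbered consecutively in assembly
order (`renumber_scaffolds`), so removing, say, numbers 52 and 53 from a
59-scaffold assembly renames 54–59 to 52–57; names without a numeric
suffix pass through unchanged.

Suspicious reads are triaged by repeat-masked fraction
(`classify_repeat_reads`): more than 50% of the read length is *high*,
more than 25% *mild*, the rest *low*; both boundaries are strict, so a
read at exactly 25% is low.

The calibration of the vote is exactly binomial: a clean scaffold with
per-hit metazoan probability $p$ and $n$ hits is falsely removed with
probability $P(\mathrm{Bin}(n, p) < \lceil 0.9 n \rceil)$.  The test
suite and the acceptance script verify the empirical false-removal rate
against this closed form (for $n = 50$, $p = 0.95$ the tail is
`pbinom(44, 50, 0.95)` ≈ 0.038).

## Gene-model reconciliation

The annotation is assembled in three rounds from four evidence classes,
with a strict priority ordering `iso > braker1 > braker2 > denovo` — a
lower-priority model never displaces a higher-priority gene.

**Round 1** treats every full-length transcript cluster as a gene and
drops ab initio models that significantly overlap a cluster on the same
strand.  Significance uses two rules: when a model overlaps transcripts
from exactly one cluster, it is merged if at least 40% of that cluster's
transcripts fully contain the model or are fully contained in it;
failing that (and always, when several clusters are overlapped), it is
merged if the mean per-transcript overlap fraction exceeds 50%.  These
cutoffs deliberately leave partial, end-on overlaps unmerged.  Two
numerical choices:

* **Overlap denominator.**  The overlap fraction divides the
  intersection length by the *shorter* of the two intervals, making
  containment the limiting case of fraction 1.0 and keeping the measure
  symmetric.
* **Rule order.**  The containment rule is evaluated only in the
  single-cluster case; the mean-overlap rule is the fallback.  A model
  spanning two clusters (a fusion artifact) therefore always faces the
  mean-overlap test against each cluster, fails to be "merged" into
  either in a containment sense, and is dropped, while both clusters are
  retained.

Round 1 obeys an exact conservation law, asserted on every run:
`genes out = clusters + models with no significant overlap`.

**Round 2** (`incorporate_novel_models`) admits a new model only if none
of its exons overlaps a same-strand exon of an existing gene — an
exon-level test, so a model inside an intron is accepted.  Accepted ids
are prefixed (`r2_`).

**Round 3** (`reconcile_denovo`) rescues loci from per-stage de novo
transcript mappings: mappings overlapping the annotation (any strand,
mirroring `bedtools intersect -v`) are discarded, the rest are grouped
into same-strand overlapping loci across stages, and a locus becomes a
gene (`at_DN<n>`) when the anchor stage supports it or at least two
non-anchor stages agree.  The latter clause is a deliberate loosening of
a strict pairwise-anchor intersection: discarding all anchor-free loci
would silence genes expressed only in other stages, while requiring two
independent stages controls spurious mappings.  It is exposed as a flag
(`keep_nonanchor_loci`).  Residual same-strand overlaps among new models
are resolved by keeping the longer model, ties by lexicographically
smaller id.

`finalize_annotation` sorts by (chromosome order, start, id) and *warns*,
listing pairs, when same-strand overlapping genes remain: merging such
residuals is a manual curation step, deliberately out of scope.

## Conserved cluster assessment

`assign_members_from_hits` maps member-query alignments (e.g. homeobox
queries against the genome) onto gene models: hits below the e-value
cutoff (default 1e-20, with a relaxed second pass at 1e-10 for rapidly
diverging families) are assigned to the overlapping gene model, keeping
the best e-value per member/model; hits over no model are reported as
unmapped rather than silently dropped.

`assess_cluster` reports copy numbers, missing members, chromosomes,
order, strand uniformity and span.  Two conventions matter:

* **Order tolerates uniform reversal.**  A cluster ascending on the
  minus strand is ordered; orientation is reported separately.  Order is
  evaluated over single-copy members only, so tandem-expanded members
  (four Msx-like copies, say) do not break it; the breakpoint count is
  the number of adjacent order violations under the better orientation.
* **Syntenic blocks are permissive.**  A block is co-location on one
  chromosome, regardless of intervening non-member genes or strand, with
  members listed in coordinate order; there is no maximum-gap parameter.

`find_intervening_models` lists non-member genes inside a single-
chromosome cluster span with their flanking members (the pattern behind
"a putative gene between two adjacent Hox genes"), and
`flag_identical_duplicates` flags same-chromosome gene pairs with
byte-identical nucleotide sequences as misassembly candidates — the
same-chromosome restriction reflects that the misassembly suspicion is
positional; a flag widens it.  `completeness_score` computes presence
fractions for expected label sets (used for conserved microRNA families),
reported to one decimal percent.

## The self-synteny screen

The screen starts from a 13-column all-vs-all protein self-alignment
table.  `filter_self_hits` reduces it in four steps: collapse
sequence-level rows to directed gene pairs keeping the best bitscore
(so isoforms are not counted twice); drop self-pairs; apply the e-value
threshold; and per query gene and target chromosome keep only the best
e-value.  The last step prevents two chromosomes that each carry several
members of one gene family from appearing strongly connected: at
paralog-detection thresholds, all members match all members, which would
otherwise inflate the cell.  An e-value of exactly 0 is the most
significant value; ties break by higher bitscore, then lexicographic
target id, making the filter fully deterministic.  "Best-scoring" uses
the bitscore column by default (`best_by` switches to e-value).

Genes are placed on a single linear axis,
$\mathrm{coord}(g) = \sum_{n<k} L_n + (start_g + end_g)/2$
for a gene on chromosome $k$, and each surviving pair becomes one Oxford
grid point (target on x, query on y).  Because the per-chromosome best
step is direction-dependent, the grid built from the fully filtered
pairs need not be symmetric even for a symmetric input table; the exact
symmetry property holds for the collapse-only pair set, which
`per_chromosome_best = FALSE` exposes (and the test suite checks).

The grid is summarized as a K×K **contribution matrix**: cell $(x, y)$
is the percentage of genes on chromosome $x$ with a surviving pair to a
gene on chromosome $y$, normalized by the gene count of $x$ (cells count
distinct genes, not pairs).  The normalization direction is ambiguous in
informal descriptions ("donor" vs "acceptor"); the default follows the
percentage-of-genes-on-x reading, and `mode = "donor"` switches the
denominator to the source chromosome.  Under a WGD one expects strong
off-diagonal cells connecting duplicated chromosome pairs;
`score_duplication_signal` operationalizes this as the per-chromosome
arg-max off-diagonal cell (suppressed below `min_cell`, default 5%) plus
a greedy mutual-best matching.  `summarize_contributions` reports
off-diagonal mean/min/max, the diagonal mean, and their contrast ratio
(infinite when the off-diagonal mean is 0, as in a pure tandem genome
without noise).

## The simulator and what it does (not) emulate

All simulator draws use R's Mersenne-Twister generator, seeded once per
operation call (via `withr::local_seed`), so identical configurations
give identical output.  `simulate_base_genome` packs genes left to right
with at least 1 bp between neighbours and randomly apportioned slack —
the simplest scheme satisfying non-overlap.  `apply_wgd` appends one
homolog per chromosome (suffix `_B`, after all originals, keeping
original linear coordinates stable) and retains each gene's duplicate
independently with the retention probability.  `apply_tandem` inserts
adjacent copies and shifts downstream genes right, extending the
chromosome — duplication adds sequence, so adjacency is always
satisfiable by construction.

`emit_self_hits` models detectability directly as a probability rather
than through a sequence-evolution model: retained pairs yield reciprocal
hits with log10 e-values uniform on [−80, −20], spurious pairs on
[−10, −4], which separates signal from noise at the 1e-5 and 1e-60
analysis thresholds by construction.  A fraction of recovered pairs also
emits a second isoform-level row to exercise gene-level collapsing.
`emit_annotation_evidence` produces transcript clusters (1–5 transcripts
jittered within the gene), fused/split ab initio models, and withholds
`p_novel` of genes from round-1 evidence, routing them to round-2 models
or de novo maps.  `emit_tax_hits` and `emit_read_repeat_profiles`
complete the input set.

The defaults describe the standard screening scenario used throughout
validation: 10 chromosomes × 200 genes of 1–4 kb on 1 Mb chromosomes,
WGD retention 0.5, detectability 0.9, tandem rate 0.2 with arrays of up
to 3 copies, 0.05 spurious hits per gene.  The retention/detectability/
rate values are the recovery-scenario parameters the screening claims
are calibrated against; the genome dimensions are chosen so that
per-chromosome statistics are stable (≈100 retained duplicates per
chromosome) while a full 20-replicate recovery experiment runs in about
a minute on one CPU.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: sequence evolution (substitutions, indels,
alignment-score landscapes), repeat structure along sequences, read-level
errors, assembly artifacts other than the identical-duplicate pattern,
unequal chromosome sizes, and gene-family expansions beyond simple WGD +
tandem scenarios.  Recovery rates measured here are properties of the
stated generative model, not of any particular real genome.

## Validation summary

The test suite validates each stage against independent oracles: the
pair filter against a naive exhaustive reimplementation on random tables
(100 seeds); threshold monotonicity of pair sets and per-chromosome
paralog fractions; the round-1 conservation law on random evidence
fixtures; decontamination error against the exact binomial tail;
boundary semantics at 0.90/0.50/0.25; noise-free end-to-end closure
(every stage recovers ground truth exactly when noise is off); WGD
partner recovery ≥ 90% under the standard scenario and zero partner
calls with contrast ratio > 5 for tandem-only genomes; and planted
cluster reports (deleted member, multi-copy member, reversed order)
recovered exactly across 50 seeds.  `scripts/acceptance.R` recomputes
the headline quantities from scratch; the reanalysis of the deposited
real-data alignment table is implemented but runs only when those files
are supplied locally, as they are not redistributable with the package.

## Known limitations

* The reconciliation intentionally stops short of manual curation:
  residual same-strand overlaps are warned about, not merged.
* Cluster member assignment is by best alignment hit; phylogenetic
  confirmation of member identity is out of scope, and reports should be
  read as "putative" assignments.
* The coverage columns of the hit table are carried but not filtered on
  by default; a target-length column would be needed to apply a
  both-sequences coverage rule exactly.
* `run_pipeline` wires the stages together for simulated inputs; real
  assemblies should call the stage functions directly on their own
  files.
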
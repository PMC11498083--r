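---
title: "Methods: post-detection viromics processing and vOTU clustering"
author: "viromics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-detection viromics processing and vOTU clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromics)
```

# Overview

This package implements the computational stages of a viromics workflow
that sit *between* the external tools: after a virus classifier and a
genome-quality estimator have produced their summary tables, and before
ecological analysis of the final abundance matrices. The stages are (1)
post-detection processing, including the two-round handling of trimmed
proviruses; (2) gene-content filtration; (3) merging of local nucleotide
alignments into per-pair global ANI and greedy clustering into
species-level vOTUs; (4) coverage statistics and vOTU-by-sample matrices
with horizontal-coverage filtering; and (5) post-processing of viral
genome bins. A deterministic fixture generator emulates every input with
known ground truth, so the whole pipeline is testable without external
binaries, databases, or downloads.

# Post-detection processing

## Detection records and presets

A *detection record* joins, per predicted viral or proviral sequence, the
classifier's outputs (virus score in [0,1], hallmark-gene count, taxonomy
lineage) with the quality estimator's (gene counts split into viral and
host, quality tier, completeness). Two post-classification presets gate
these records:

| preset | min score | min length | min hallmarks |
|---|---|---|---|
| conservative | 0.8 | 2500 bp | 1 |
| relaxed | 0.7 | 2500 bp | 0 |

All three thresholds are applied inclusively (`>=`), matching how the
cutoffs are conventionally stated; `passesPreset()` is monotone in all
three inputs, a property the test suite asserts on randomized records. A
record with a missing score, length, or hallmark count raises an error
rather than silently passing — filtration failures in this domain are
usually schema drift in upstream tables, and silence would propagate them
into published counts.

## Provirus reconciliation

When the quality estimator trims a host region off a predicted provirus,
all of the metrics attached to the original prediction (score, gene
counts, completeness) describe a sequence that no longer exists. The
workflow therefore re-scores the trimmed sequences in a second detection
round, and `reconcileProvirusRounds()` substitutes the round-2 records
for their parents: a parent with *k* ≥ 1 trimmed children contributes
exactly its *k* children and is dropped; every other round-1 record
passes through bit-identical. Child IDs follow
`<parent>|provirus_<start>_<end>` — parseable, collision-free, and
carrying the 1-based inclusive trimmed region. Overlapping trimmed
regions from one parent are kept (both may be real prophages) with a
warning. The conservation law `n_out = n1 - p + k` is asserted over
randomized fixtures.

For proviruses, the preset's length test applies to the trimmed-region
length, which is what the record's `length` field holds from round 2 —
judging a provirus by its host contig's length would defeat the purpose
of trimming.

## Genome type and host domain

Genome type (dsDNA/ssDNA/RNA) and host domain (prokaryotic/eukaryotic)
are inferred from the taxonomy lineage by scanning ranks right-to-left
(most specific first) against a bundled, user-overridable mapping table;
e.g. *Caudoviricetes* maps to dsDNA/prokaryotic. Unmapped lineages give
`(unknown, unknown)` rather than a guess.

## Gene-content filtration

Records are kept iff `viral_genes >= 1` and `host_genes / viral_genes
<= 1` (both defaults overridable; ratio inclusive at exactly 1.0, reading
the default "ratio = 1" as a maximum). These filters live in their own
stage so cutoffs can be re-applied without re-running detection. When the
minimum viral-gene count is lowered to 0 the ratio becomes undefined at
`viral_genes == 0`; the documented convention keeps such a record iff it
also has zero host genes, on the grounds that a contig with host genes
and no viral genes is host material. The 2×2 zero/nonzero grid is tested
exhaustively.

# vOTU clustering

## Pairwise global ANI

`computePairwiseANI()` merges BLAST-style local alignments per sequence
pair: ANI is the alignment-length-weighted mean of percent identities
across all HSPs, while the query/target aligned fractions are computed on
the *union* of aligned intervals (via IRanges) so overlapping HSPs are
not double-counted. The deliberate asymmetry — identity weighting does
not de-overlap, coverage does — follows the established
anicalc convention of averaging across all aligned regions. Self-hits
are removed; reverse-strand coordinates are normalized; when an aligner
reports both orientations of a pair, the orientation with the greater
total aligned length wins (ties broken lexicographically), which is
invisible on symmetric inputs but makes the output well-defined on real
BLAST output. Correctness is checked against an exact-arithmetic oracle
(integer-scaled identity sums, position-wise coverage masks) on hundreds
of fuzzed tables, to 1e-9.

## Greedy centroid clustering

`greedyCluster()` sorts sequences by length descending (ties: ID
ascending — the tie-break must be total for determinism) and scans: each
unassigned sequence becomes a representative; every later unassigned
sequence whose pair with the representative reaches ANI ≥ 95 and aligned
fraction ≥ 0.85 joins it, where the AF of a pair is the coverage of the
shorter sequence (on a length tie, the larger of the two coverages, so
the test is the most permissive reading consistent with "coverage of the
shorter"). A sequence joins the *first* qualifying representative — the
standard greedy centroid behavior — not the best-scoring one; the
alternative "best representative" rule was considered and rejected
because it changes results only in the rare multi-qualifying case while
breaking the single-scan structure shared with the reference
implementations users know. Both thresholds are inclusive (`>=`),
following the flag semantics (`min_ani`, `min_tcov`) rather than the
looser prose convention of "> 95%".

The result is a `VOTUClusterSet` whose validity method enforces the
partition property and the longest-member-representative invariant.
Equivalence with a naive reference that literally follows the sorted-scan
definition is asserted on 500 random instances, including all-tie length
cases.

# Coverage and abundance matrices

`coveredStats()` computes, from read placements (aligned spans standing
in for sorted BAM content — base qualities and MAPQ weighting belong to
the upstream mapper), the horizontal covered fraction |∪ spans|/length,
mean depth Σ span lengths / length, and read count; it matches
position-wise counting exactly. `buildCoverageMatrix()` completes
observed per-sample rows into a full representatives-by-samples
`VOTUCoverage` (a SummarizedExperiment with `depth`, `coveredFraction`,
and `readCount` assays), filling absent cells with zero and conserving
total observed depth.

`applyHorizontalCoverage()` implements the standard viromics guard
against spurious detections: at each threshold *t* ∈ {0.1, 0.5, 0.9} by
default, abundance cells with covered fraction below *t* are zeroed and
rows left all-zero are dropped. Zero-then-drop (rather than row deletion
alone) keeps each thresholded table a complete matrix directly usable in
ecology software; dropping empty rows is reversible via
`dropEmptyRows = FALSE`. Row sets are provably nested across rising
thresholds, which the tests assert.

The final-table sequence filter keeps, in conservative mode, sequences
longer than 5 kb or longer than 1 kb with Complete/High/Medium quality —
both comparisons strict, as "longer than" reads — in contrast to the
inclusive detection presets; both inclusivity choices are deliberate and
documented where they apply. Relaxed mode re-applies the default
gene-content filters instead.

# Viral-bin post-processing

Bins are filtered on protein redundancy: conservative keeps redundancy
< 2; relaxed rejects only > 5, keeping the ambiguous 2–5 band. Giant
viruses (NCLDVs) can carry ~10 redundant proteins legitimately, so the
exemption is per-bin (`overrideBins`) rather than a global loosening.
Multi-scaffold bins are concatenated in membership order with 10-N
linkers (length Σ members + 10·(k−1)) for single-sequence quality
estimation. Combined tables carry one row per kept bin plus one per
unbinned representative; a bin row's depth and covered fraction are the
length-weighted means over its members — chosen over the unweighted mean
because depth is a per-base quantity, so the weighted mean equals the
depth of the concatenated genome (up to linkers) — and its read count is
the member sum.

# The fixture generator

`generateCommunity()` plants species-level structure analytically: each
cluster has a random ancestor; members are prefix-truncations of the
ancestor mutated at divergence d ≤ `dWithin` (substitutions only, exact
count `round(d·len)` — no indels, so identity and divergence stay in
closed form). Truncation makes the ancestor the unique longest member,
hence the representative; truncate-then-mutate makes each member's
identity against it exactly `100·(1 − round(d·len)/len)` ≥ 97 for
`dWithin = 0.03`, clearing the 95% threshold by construction. Member–
member identities may fall below the threshold (~2d divergence), which is
harmless: the greedy scan only ever compares members to representatives.
Ancestors are independent random sequences (expected mutual divergence
0.75); their divergence is verified against `dBetween` and no
between-cluster alignments are emitted, as a local aligner would find
none at 25% divergence. The alignment table is emitted directly from the
sequences rather than by running an aligner — that keeps truth analytic;
real BLAST output can be substituted wherever a table is accepted.

Detection, gene-filter, quality-filter, and placement fixtures plant
their outcomes the same way: parameters are drawn from the qualifying or
disqualifying region for each rule, so expected counts are exact by
construction. Placement generation tiles non-overlapping spans from
position 1, making the realized covered fraction exact whenever
`target · length` rounds to an integer and within 1/length otherwise.
All generators are pure functions of (parameters, seed); the RNG state of
the caller is restored.

What the fixtures do *not* emulate: sequencing error models, indels,
chimeric contigs, compositional bias, or alignment noise. Passing tests
therefore demonstrate the correctness of the bookkeeping and the
algorithms under their stated definitions — not the robustness of the
upstream detectors, which are outside the package.

# The command-line interface

Each stage is a subcommand (`simulate`, `validate`, `detect-post`,
`filter-genes`, `cluster`, `coverage`, `votu-table`, `bin-post`,
`summarize`) writing a numbered folder under `--workdir` plus a
plain-text summary report (command line, counts, runtime). The metadata
file fixes the columns `sample`, `group`, `assembly`, and optionally
`genomad`, `checkv`, `placements`; paths may be workdir-relative, which
keeps a working directory relocatable and repeated seeded runs
byte-identical. Existing outputs are never overwritten without
`--force`; no subcommand mutates its inputs. Missing-value cells are
written as `NA` in every table; coordinates are stored 1-based inclusive
throughout (the BLAST/detector convention), converting to half-open only
inside the interval algebra.

# Problem sizes and numerical choices

The test and acceptance workloads use desk-scale sizes chosen to exercise
every code path with analytic expectations: fuzzing at ≤ 50 sequences per
ANI table and ≤ 12 per clustering instance (small enough for the literal
reference to stay obviously correct), a 20 × 5 planted community, and an
8-cluster two-sample fixture pipeline. Agreement tolerances are 1e-9
where two floating-point routes are compared and exact where the oracle
is integer counting. Degenerate inputs — empty alignment sets, header-only
tables, zero placements, zero kept bins — all have defined, tested
behavior.

# Known limitations

The coverage module consumes placements or precomputed coverage tables,
not BAM; the clustering module consumes alignment tables, not raw
sequences (the expected BLASTN invocation is `blastn -outfmt 6` all-vs-all
against the filtered sequences). Protein-level or genus-rank clustering,
normalization beyond mean depth (TPM/RPKM), functional annotation, and
host prediction are out of scope. The greedy clustering is O(n·k) in
sequences × representatives with an in-memory edge map, adequate for
tens of thousands of sequences but not engineered beyond that.
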
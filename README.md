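# viromics

Post-detection processing, species-level vOTU clustering, and abundance
tables for viral metagenomics.

## What this package is for

A typical viromics study detects putative viral contigs in metagenome
assemblies with a virus classifier, estimates genome quality and trims
host regions off proviruses with a quality estimator, dereplicates the
survivors into species-level viral operational taxonomic units (vOTUs),
maps reads back to the representatives, and builds per-sample abundance
tables. The detection, alignment, and mapping steps are served by mature
external tools; everything between them — reconciling trimmed provirus
predictions, applying the layered filtration rules, merging local
alignments into global identities, greedy centroid clustering, coverage
matrices with horizontal-coverage guards, and viral-bin post-processing —
is bespoke glue that every lab rewrites. This package implements that
glue as a tested R library with a subcommand CLI, operating purely on the
standard intermediate file formats (detector/quality-summary TSVs, FASTA,
BLAST tabular, per-sample coverage tables), so none of the external
binaries or databases are needed to run or test it.

It is aimed at microbiome researchers who already run geNomad/CheckV-class
tools and want reproducible, scriptable post-processing, and at method
developers who need a deterministic fixture generator with analytic ground
truth.

## The core computations

**Global ANI from local alignments.** For a pair of sequences with local
alignments (HSPs) *i* of length *L<sub>i</sub>* and percent identity
*p<sub>i</sub>*:

> ANI = Σ *p<sub>i</sub>* *L<sub>i</sub>* / Σ *L<sub>i</sub>*

and the aligned fraction of each sequence is |∪ aligned intervals| /
sequence length, computed on interval unions so overlapping HSPs are not
double-counted.

**Greedy vOTU clustering.** Sequences are sorted by length (descending;
ties by ID) and scanned: each unassigned sequence becomes a
representative, and every later unassigned sequence whose pair with it has
ANI ≥ 95 and aligned fraction ≥ 0.85 — the fraction evaluated on the
shorter sequence — joins it. Representatives are therefore always the
longest member of their cluster.

**Filtration tiers.** Detection presets (conservative: score ≥ 0.8,
≥ 2500 bp, ≥ 1 hallmark gene; relaxed: score ≥ 0.7, ≥ 0 hallmarks), gene
content filters (viral genes ≥ 1, host/viral ratio ≤ 1), the
sequence-quality rule for final tables (> 5 kb, or > 1 kb and
Complete/High/Medium quality), horizontal-coverage thresholds
(0.1/0.5/0.9), and bin protein-redundancy cutoffs (conservative < 2,
relaxed ≤ 5).

## Worked example

Generate a planted community of 20 species-level clusters with 5 members
each (members ≤ 3% diverged from their cluster ancestor), merge the
synthetic alignment table into pairwise global ANI, and cluster:

```r
library(viromics)

comm  <- generateCommunity(nClusters = 20, membersPerCluster = 5, seed = 7)
lens  <- setNames(Biostrings::width(comm$sequences), names(comm$sequences))
pairs <- computePairwiseANI(comm$alignments, lens)
head(pairs, 3)
#>   query_id target_id n_alns      ani      qcov tcov
#> 1 cl01_m01  cl01_m02      1 99.04580 0.9993189    1
#> 2 cl01_m01  cl01_m03      1 99.39981 0.9986378    1
#> 3 cl01_m01  cl01_m04      1 99.24242 0.9979567    1

cl <- greedyCluster(pairs, lens)
cl
#> VOTUClusterSet with 20 clusters over 100 sequences
#>   singletons: 0 | largest cluster: 5 members
#>   representatives: cl01_m01, cl20_m01, cl18_m01 ...
```

The pairwise rows show each pair's alignment-weighted mean identity
(`ani`, here ≈ 99% within a planted cluster) and the merged aligned
fraction of query and target. The 100 sequences collapse back to exactly
the 20 planted clusters, each represented by its longest member (the
ancestor), and `memberStats(cl)` records the ANI/AF of every member
against its representative.

The same operations are available from a shell via the launcher script
(`system.file("scripts", "viromics-cli", package = "viromics")`), with
subcommands `simulate`, `validate`, `detect-post`, `filter-genes`,
`cluster`, `coverage`, `votu-table`, `bin-post`, and `summarize` that
write numbered stage folders under a working directory:

```sh
viromics-cli simulate    --workdir run1 --seed 7
viromics-cli detect-post --workdir run1
viromics-cli filter-genes --workdir run1
viromics-cli cluster     --workdir run1
...
```

## Scope

The package does not run geNomad, CheckV, BLAST, read mappers, CoverM, or
vRhyme, and does not recompute their scores — it consumes and produces
their file formats. Annotation searches, host prediction, and ecology
statistics are out of scope.
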
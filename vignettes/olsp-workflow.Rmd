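---
title: "Multi-primer COI metabarcoding: filtering model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-primer COI metabarcoding: filtering model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olspr)
library(dplyr)
```

## The problem

Diet metabarcoding amplifies a barcode locus (here the 5' region of the
mitochondrial COI gene) from degraded environmental DNA — feces, spider
webs — and sequences the amplicons to identify prey. Two error classes
dominate such data. *False positives* arise from tag jumps, cross-sample
contamination and PCR point errors, and appear as low-frequency occurrences
of sequences in samples where they do not belong. *False negatives* arise
when a primer set fails to amplify a taxon; no bioinformatic step can
recover them afterwards. This package implements a workflow that attacks
both at once: several primer sets on the *same* locus (so their amplicons
overlap and can be merged into directly comparable contigs), combined with a
stringent, control-calibrated, variant-centred (clustering-free) filtering
procedure.

The default marker set is three COI primer pairs (MFZR, ZFZR, LFCR) whose
~150 bp amplicons overlap over roughly 130 bp of the barcode. Every sample
is amplified in triplicate with every marker — nine PCRs per sample — and
PCRs are demultiplexed by combinations of 11–13 nt tags on both primers,
with every pair of tags in a set at Hamming distance at least 3.

## The filtering model

Let `N_ijk` be the read count of variant *i* in sample *j*, PCR replicate
*k* (after demultiplexing by exact tag pairs and dereplication of identical
trimmed reads). An occurrence is kept iff all of:

* `N_ijk >= t_abs` — an absolute floor;
* `N_ijk / N_i.. >= t_var` — its share of the variant's run-wide total,
  which removes tag-jump leakage of abundant variants into other PCRs;
* `N_ijk / N_.jk >= t_rep` — its share of the replicate's total reads.

Both denominators are computed **once on the input table** and never
recomputed between sub-filters. This makes `lfn_filter()` order-independent
and idempotent, two properties the test suite asserts directly. Each
sub-filter can be disabled by setting its threshold to zero.

### Calibration on controls

The thresholds are not user guesses: `calibrate_lfn()` chooses them per run
and per marker from the controls sequenced alongside the samples. Mock
communities of known composition (two mocks of seven prey taxa at 0.2
relative concentration plus the predator at 0.8) define occurrences that
*must survive*; occurrences in the four kinds of negative control
(extraction, aerosol, PCR, tag) and unexpected occurrences inside mocks
define occurrences that *should be removed*. Mock retention is a hard
constraint and elimination is the objective: among all threshold triples
that keep every expected mock occurrence, calibration maximises the number
of unwanted occurrences removed, and among the maximisers returns the
lexicographically smallest `(t_abs, t_var, t_rep)`. Because the removal
region is a union over the three statistics, the optimum can be found in
closed form by a separable cover argument; the test suite checks it against
an exhaustive grid search on hundreds of random tables. The search grid is
the finite set of observed occurrence statistics (plus an epsilon step):
thresholds between observed values are behaviourally identical, so nothing
is lost. Unwanted occurrences that no feasible threshold can remove —
stronger than the weakest expected mock occurrence on all three statistics —
are reported as `unremovable` instead of silently sacrificing mock
retention; real datasets do produce such survivors, and they belong in the
report, not under the carpet.

If an expected mock occurrence has zero reads it is reported as a mock
dropout, not raised as an error: an absent positive control is a finding.

### Replicate reproducibility

Two further rules exploit the triplicate design. First, within each
(sample, marker), each replicate's variant profile is normalised to
frequencies and replicates whose mean Renkonen distance
(`1 - sum(pmin(p, q))`) to the others exceeds a cutoff (default 0.5; the
choice is a package default, documented, not a measured constant) are
dropped entirely. Replicates that the design expects but that carry no
reads are dropped with reason `"empty"`. Second, a variant is validated in
a sample only if present in at least two surviving replicates
(`min_replicates = 2`); replicates removed by the Renkonen screen cannot
support validation — the rule counts replicates *after* screening, which is
the stricter of the two possible readings and the one implemented here.

### The second pass

After a first pass of filtering and taxonomic assignment, detections that
are incompatible with their sample's habitat (a freshwater-only taxon in a
brackish sample, say) are residual noise that slipped through. Their
occurrences join the must-drop set, thresholds are recalibrated on the
original dereplicated table, and the whole filter chain is re-run. Taxa
absent from the habitat-compatibility table are treated as compatible
everywhere — the rule can only ever be tightened by explicit knowledge —
and are logged. With an empty habitat map the second pass is a fixed point
of the first.

## Contigs and MOTUs

Validated variants from different markers that are identical over a perfect
ungapped overlap of at least `min_overlap = 100` bases (the amplicons share
~130 bp by design) are combined into contigs. The merge is run-global and
graph-based: components of the perfect-overlap graph become contigs only if
they contain at most one variant per marker and their implied base layout
is conflict-free at every position; otherwise the whole component stays
unmerged and is logged as ambiguous. This conservative no-merge rule for
conflicting components is this package's choice — merging nothing is always
safe, merging wrongly fabricates haplotypes. Contig identifiers are
assigned on members sorted by id, so results are independent of input
order, and contigs plus leftover variants are treated uniformly as
"validated items" downstream.

Items are clustered into MOTUs by agglomerative complete linkage at 3%
divergence: no merge is performed that would put two members at distance
above the threshold in one cluster, so the intra-MOTU distance bound holds
by construction. Distance is a gaps-counted p-distance
(`(mismatches + internal gap bases) / aligned overlap length`) on a
semi-global alignment: end gaps are free because items span different
windows of the same locus, so terminal overhangs reflect primer geometry,
not divergence. Whether the canonical 3% is meant on a raw or gaps-counted
p-distance is ambiguous in the field; gaps-counted is implemented and
documented here. Agglomeration ties are broken by merging the
lexicographically smallest pair of cluster labels, making the partition
reproducible and permutation-invariant; the implementation is checked
against `stats::hclust(..., "complete")` on a thousand random instances.

## Taxonomic assignment and resolution

Items are assigned by the lowest-taxonomic-group rule over semi-global
alignment hits against a reference database (identity floor 80% over at
least 80% of the item length). The highest identity band of the ladder
(97, 95, 90, 85, 80) containing a hit is selected; within the band the
deepest rank at which a single taxon holds at least 90% of the hits is
awarded, capped per band (97 → species, 95 → genus, 90 → family,
85 → order, 80 → class). The ladder, caps and inclusion fraction are
configurable defaults surfaced in the function signature — the exact values
used by predecessor implementations of this rule are not published, so
these defaults are explicit package parameters rather than hidden
constants. Curated assignments (from manual database searches or
phylogenetic arbitration, which are human steps outside this package) can
be supplied as overrides that supersede the automatic calls.

Resolution is summarised by the IR index: Species = 6, Genus = 5,
Family = 4, Order = 3, Class = 2, Phylum = 1, Kingdom or unassigned = 0,
averaged over a sample's validated items.

The analyses target "Macrometazoans" — macroinvertebrate and vertebrate
prey. Items whose assigned path touches the exclusion list
(microinvertebrates such as Amoebozoa, Acari, Tardigrada, Rotifera;
diatoms, algae and plants; parasite groups such as Acanthocephala and
Nematoda) are removed; unassigned items are retained conservatively and
flagged.

## Metrics

All comparative statistics run at six aggregation levels: Phylum, Class,
Order, Family, MOTU, variant. An item with no name at a taxonomic rank
falls back to its MOTU id, so every item maps to exactly one bin at every
level and per-sample item totals are conserved under aggregation (asserted
in the tests). Per (sample, level):

* **MNI** — the number of distinct validated items per taxon, a
  semiquantitative abundance proxy;
* **Bc** — coverage of a primer set: taxa it detected over taxa detected by
  all sets together;
* **Com** — complementarity: taxa detected by exactly one set over the
  union;
* **Wsd** — within-sample Bray–Curtis dissimilarity
  (`1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`) between the per-primer-set
  MNI vectors; **Bsd** — the same between samples on pooled MNI vectors.

A contig counts as detected by a primer set in a sample only when that
set's own member variant was validated there — contig presence alone would
hide exactly the primer-set differences these statistics measure. Bc and
Com are computed both per sample (the primary output, since the
distributions are what gets compared) and pooled globally; group dispersion
of MNI uses the sample standard deviation (n − 1), a documented assumption
since a bare "±" does not define its estimator. Cells whose detection union
is empty are excluded rather than scored 0.

## What the simulator emulates — and what it does not

`simulate_run()` generates a complete run with ground truth: a reference of
COI-like templates (~300 nt) embedding binding sites for all three markers
in a nested layout, so the three amplicon windows overlap over a shared
120 bp core; a design with 12 forward and 8 reverse tags (rejection-sampled
to pairwise distance ≥ 3), triplicate PCRs of eDNA samples drawn from the
packaged 107-sample census, two mocks and four negative kinds per run; and
reads with point substitutions, tag jumps and cross-habitat contamination.
Primer-specific taxon dropout — the motivation for using several primer
sets — is emulated two ways: per-taxon marker compatibility drawn from
per-marker success probabilities (0.50 / 0.70 / 0.64 for MFZR / ZFZR /
LFCR, matching the relative per-marker detection fractions the three sets
show on real data), conditioned on every taxon keeping at least one
compatible marker (mirroring that every mock member was recoverable by some
set); and three planted binding-site mismatches on incompatible
marker–taxon pairs, so dropout also emerges mechanistically at
demultiplexing.

Defaults chosen once and kept: 8 simulated eDNA samples with reads (the
full census is used for design-level checks; read simulation scales
linearly and 8 samples exercise every code path), 300 reads per PCR,
24 reference taxa (the 12 mock taxa plus 12 background taxa, 2 of them
reserved as marine-habitat contaminant sources), substitution rate
5 × 10⁻⁴ per base, tag-switch rate 10⁻³ per read, contamination at 0.3% of
eDNA/mock reads and a mean of 2 reads per negative PCR. Property tests that
loop over many seeds shrink the size knobs (3 samples, 60–150 reads per
PCR, 14–16 taxa) but never the noise rates: sizes are runtime choices,
rates are the conditions under test.

The simulator does **not** model realistic Illumina error profiles
(substitutions are uniform), chimeras, indel errors, length variation
among taxa, PCR abundance biases beyond the multinomial draw, or quality
scores (emitted constant; the pipeline ignores quality beyond parsing). A
passing noiseless-identity test therefore shows the machinery is lossless
and consistent, not that real data would filter this cleanly; the
default-noise mock-retention tests show robustness to the modelled noise
classes only.

## Numerical and degenerate-input choices

* Tags are matched exactly (they carry sample identity; one error must not
  reassign a read), primers IUPAC-aware with ≤ 2 substitutions and no
  indels; both bounds are arguments. The primer tolerance is a documented
  default — no published value exists for this step.
* Both ends must match; one-sided rescue is a known tag-jump vector and is
  never attempted. Reads matching zero or multiple constructs, or with no
  insert left after trimming, go to the unassigned bin with a reason code.
* Tag sets of unequal length are compared over the shorter, read-proximal
  prefix, where tags anchor on the primer construct.
* Two replicates at Renkonen distance 1 both exceed any cutoff ≤ 1 and are
  both dropped — the degenerate case is flagged rather than arbitrated.
* Sequences with no alignable overlap of at least 50 bases get distance 1
  (the defined ceiling) in MOTU clustering.
* Empty tables pass through every filter unchanged; an empty item set
  clusters to an empty MOTU list.
* The run-design table makes the tag layout fully explicit instead of
  assuming a combinatorial scheme, and the replicate count is a design
  property (default 3), so degraded designs are expressible.

## Known limitations

Chimera detection, abundance-bias correction and read-pair merging are out
of scope (the pipeline starts from merged reads). Kruskal–Wallis testing of
the metric distributions is left to the analyst — the package emits the
long-format tables those tests consume. The contig merge is same-locus by
construction and cannot (and should not) merge across loci. Taxonomic
assignment quality is bounded by reference completeness; the automatic rule
makes no probabilistic claim.
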
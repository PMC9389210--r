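---
title: "Composite SAG construction: models, parameters and design choices"
author: "cosagr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite SAG construction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-genome amplification of single bacterial cells (multiple displacement
amplification, MDA) yields single-amplified genomes (SAGs) that are
individually incomplete and artifact-ridden: coverage is extremely skewed,
whole loci drop out, and a fraction of reads are chimeric joins of
non-contiguous genomic segments. Because many cells of the *same strain* are
usually captured from one host sample, the losses are complementary: pooling
reads from SAGs identified as the same strain and co-assembling them yields a
composite SAG (CoSAG) of much higher completeness — provided the pooled
reads really come from one strain and the chimeric molecules are removed
first. `cosagr` implements that construction:

1. **Read QC** — Phred-style right-end trimming and length / N-count /
   mean-quality filters, plus host-read removal against a decoy genome.
2. **Genome metrics** — contig-length filtering, single-copy-marker
   completeness and contamination, MIMAG-style quality tiers.
3. **Similarity** — three pairwise measures: fragment-based two-way ANI,
   canonical tetranucleotide-frequency (TNF) correlation, and single-copy
   marker homology.
4. **Strain clustering** — same-strain groups as connected components of the
   three-way-threshold graph; dereplication at 99% ANI.
5. **Chimera splitting** — iterative cross-reference mapping of each
   member's reads against the other members' assemblies, cutting partially
   aligned reads at alignment boundaries.
6. **Pipeline** — orchestration with provenance hashing and co-assembler
   handoff (the assembler itself is external, by design).

A ground-truthed synthetic SAG generator is part of the package, so every
stage is testable against known truth.

## Decision rules

Quality tiers follow the printed single-copy-marker definitions, with the
inequalities taken literally:

* HQ: completeness > 90 and contamination < 5;
* MQ: completeness >= 50 and contamination < 10;
* LQ: completeness < 50 and contamination < 10;
* excluded: contamination >= 10.

SAGs enter strain grouping when completeness >= 20 and contamination < 10.
A pair of SAGs is same-strain when it *strictly* exceeds all three
thresholds: ANI > 99, TNF correlation > 0.90, and marker homology above the
marker threshold. The marker threshold deserves a note: the strain-grouping
rule is quoted in two variants in the literature this design follows — 99%
and 99.9% — and both are genuinely in use. `strain_grouping_params()`
defaults to 99.9 (the stricter, figure-caption variant) and exposes 99.0 as
a configuration. The choice matters when same-strain cells are simulated
with explicit microdiversity: at a pairwise within-strain identity of
0.999, the *expected* marker homology is exactly 99.9, and a strict
`> 99.9` cut then behaves like a coin flip per pair. The package's test
fixtures therefore exercise grouping with the 99.0 variant, which is the
rule that remains discriminative under that generative model (between-strain
homology sits near 97).

Undefined similarities — too few qualifying ANI fragments, an undefined TNF
profile, or fewer than `min_shared_markers` comparable markers — are treated
as *below threshold*, never as missing-at-random. This is conservative: a
pair with insufficient shared signal is not merged. A practical consequence
is that the marker set must be large enough relative to SAG completeness;
with `n` markers and completeness `c` in both genomes, roughly `n * c^2`
markers are shared, and that number must clear `min_shared_markers`
(default 10).

## The three similarity measures

**Fragment ANI.** The query assembly is chopped into non-overlapping
1,000-bp fragments; each fragment's best local alignment in the target is
found with the internal aligner; fragments passing 70% identity *and* 70%
coverage contribute their percent identity; one-way ANI is their mean, and
the reported ANI averages both directions. Fewer than `min_fragments`
(default 5) qualifying fragments gives an undefined result ("insufficient
homologous fraction"). Self-comparison returns exactly 100.

**TNF correlation.** The profile counts each 4-mer together with its
reverse complement over all contigs — windows never span contig boundaries
and windows containing N are skipped — collapsed to the 136 canonical
(strand-symmetric) bins and normalized to sum to 1. Canonical collapsing
makes the profile orientation-invariant, which clustering requires because
assembly contig orientation is arbitrary. Pearson correlation is used, the
field convention for TNF similarity. Assemblies shorter than 5 kb give an
undefined profile (too noisy a composition estimate).

**Marker homology.** Markers found single-copy in both assemblies (the
genome-metrics hit rule: identity >= 0.90 over >= 0.80 of the marker) are
extracted in marker orientation; each pair is globally aligned over its
*common marker interval* (banded Needleman–Wunsch, band 16), and homology is
the mean percent identity. Restricting to the common interval keeps
dropout-truncated marker copies from masquerading as divergence: without
it, a marker cut at a contig edge would contribute missing sequence as
mismatch. Overlaps shorter than 200 bp are skipped.

## The internal aligner

All read- and fragment-level mapping uses one deterministic seed-and-extend
core (C++): exact 15-mer seeding against a hash index of the target,
clustering of seed hits per (contig, strand) with a ±3 diagonal tolerance
(the small-indel allowance), and X-drop extension along the cluster's
modal diagonal (match +1, mismatch −2, drop threshold 20). The aligner is
substitution-oriented by construction: at the identity levels where
grouping and cleaning decisions live (>= 90%), substitutions dominate, and
the generator emits no indels (an explicit non-goal), so diagonal extension
is exact for every contract in the package. The gapped banded aligner is
reserved for marker-pair global identity.

Two numerical choices matter downstream:

* **Seed sampling stride.** Query k-mer positions are sampled with a small
  stride (4 for 1,000-bp ANI fragments, 2 for reads and markers). Seeds
  only anchor clusters; segment boundaries and identity come from the
  extension, so the stride does not change results at these densities — it
  only cuts index-lookup cost.
* **Minimum segment evidence for splitting: 30 bp (two seed lengths).** A
  single random 15-mer match extends to a ~16-bp spurious "segment" about
  once per hundred reads against a 50-kb genome; accepting it as evidence of
  partial alignment would wrongly split reads whose true locus is absent in
  the partner. Requiring 30 bp makes spurious evidence vanishingly rare
  while keeping every simulated chimera segment detectable (junctions lie
  in the central half of the read, so true segments are >= 37 bp at 150-bp
  reads).

## Chimera splitting

Within a strain group, each member's current read pool is mapped against
every *other* member's assembly. A read with one segment covering >= 95% of
its length is clean; a read with no segments is retained whole — absence of
alignment is dropout evidence, not chimerism evidence, and discarding such
reads would delete exactly the strain-specific sequence co-assembly is
meant to recover. Otherwise the read is partially aligned: it is cut at
segment boundaries into aligned and interstitial fragments (qualities
sliced in register), fragments shorter than 20 bp are discarded, and when
several partners flag the read, the most fragmenting partner's split is
applied — a junction is evidence wherever it is visible, and partner
dropout can hide it. When two aligned segments overlap by up to one seed
length (seed-edge ambiguity) the boundary is placed at the overlap
midpoint, tie broken toward the longer segment. Cycles of mapping and
splitting repeat until no read is split (a fixpoint, typically 2–3 cycles)
or `max_cycles = 5` is reached; only newly created fragments need remapping
in later cycles, since decisions are deterministic in (read, partner).
Total output bases never exceed input bases and the deficit reconciles
exactly with the discarded-fragment report.

## The synthetic generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, with every artifact recorded in a truth manifest:

* **Strain structure.** One ancestral genome per cohort; strains derived by
  uniform per-site substitution at rate `(1 − ANI)/2` each, so a strain
  pair meets its target identity. SAG genomes of one strain add
  microdiversity the same way (`within_strain_identity`, default 0.999).
  No indels or rearrangements (non-goals).
* **Markers.** `n_markers` unique 900-bp tags are planted at uniform
  non-overlapping loci *before* strain derivation and written to a marker
  FASTA — a fully known stand-in for universal single-copy marker genes,
  so completeness/contamination truth needs no external HMM database.
* **Dropout.** Whole 5,000-bp windows are removed until the retained
  fraction matches the target completeness; the retained windows, merged
  into contigs, *are* the SAG assembly (assembling simulated reads is out
  of scope, and truncation makes true completeness exact). The window is
  the MDA amplification-locus unit: per-window depth is lognormal
  (mean `mean_depth`, shape `lognormal_sigma`), and reads are sampled
  wholly within windows. Locus-scale dropout is also why windows (5 kb)
  exceed the 1,000-bp contig filter — sub-filter windows would vanish
  silently.
* **Artifacts.** Reads carry uniform substitution errors; a `chimera_rate`
  fraction are junctions of two uniformly chosen retained loci (split point
  uniform in the central half of the read, random strand for the second
  segment, junction recorded); `host_decoy_rate` and `contam_rate`
  fractions are replaced by reads from a simulated host decoy (GC 0.41)
  and an unrelated species (GC 0.60). Qualities are constant Q30 with an
  optional degraded-tail fraction to exercise QC.

Defaults are chosen as realistic study conditions for Illumina-era
single-cell sequencing: 150-bp reads, 20× mean depth, 0.5% substitution
error, completeness spread 0.5–1.0, between-strain ANI 0.97 (within the
94.9–98.8% intra-species band the similarity module must resolve),
lognormal σ = 0.8 (moderate MDA skew; the true value is not identifiable
from published completeness spreads, so it is exposed as configuration
rather than claimed). The default genome length (200 kb) and marker count
(100) are scaled-down stand-ins for a ~2–5 Mb genome with ~100 marker
genes; tests use 40–120 kb genomes with proportionally fewer markers so the
full suite runs in about two minutes.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: indel and rearrangement divergence (real strain
pairs would stress the substitution-oriented aligner more), gene-content
differences and mobile elements, sequence-dependent MDA bias and chimera
hotspots, paired-end structure, and assembly errors in the input SAG
contigs (real SAG assemblies contribute their own misassemblies, which the
truncation model cannot represent).

## Degenerate inputs and determinism

Empty read sets, empty assemblies after the contig filter, singleton strain
groups (reads pass through unchanged) and members without assemblies
(excluded as mapping targets, with a message) are all handled explicitly.
All randomness flows through R's RNG from explicit seeds; identical
configurations give byte-identical FASTA/FASTQ/TSV outputs, and
`run_pipeline()` with an output directory records a configuration hash and
per-file checksums, returning the cached report when re-run unchanged.

## Known limitations

* The aligner's indel support is limited to the ±3 diagonal tolerance; it
  is not a general gapped mapper and is not meant to reproduce minimap2 or
  BBMap output bit-for-bit — the contracts are at the level of decisions
  (remove / keep / split), not alignments.
* Marker-based contamination only sees duplicated markers; contamination by
  a genome fragment that carries no markers is invisible, as it is for any
  single-copy-marker estimator.
* Connected-component grouping can chain through intermediate genomes in
  principle; at the stringent default thresholds this did not occur in any
  fixture, and the threshold-monotonicity property (raising any threshold
  only refines the partition) bounds the behavior.
* The dereplication score is the two-term `completeness − 5 ×
  contamination` (the dominant terms of the standard dRep-style weighting);
  strain-heterogeneity and N50 terms are deliberately dropped because the
  package's own quality estimator does not produce them.
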
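---
title: "Homoeolog-specific assembly of polyploid transcriptomes: models and methods"
author: "homoeoasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homoeolog-specific assembly of polyploid transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeoasm)
```

## The problem

Bread wheat is an allohexaploid: each gene is typically present as three
homoeologous copies contributed by the A, B and D parental genomes. The
copies diverge at only ~97.2% nucleotide identity (about one SNP per 71
bases per pairwise comparison, i.e. ~1.4% divergence per sequence from the
common ancestor). A conventional de novo assembler treats this divergence
as sequencing noise and collapses the copies into a single consensus — a
*chimeric* contig whose sequence mixes alleles from different genomes and
is useless for genome-specific marker design or expression analysis.

`homoeoasm` implements a two-stage strategy that keeps the copies apart:

1. **Stage 1 (permissive):** a rough overlap assembly, deliberately
   homoeolog-*insensitive*, whose only purpose is to group reads. Its
   contigs are transitively clustered whenever they share a 32-base word,
   reads are assigned to clusters by the same criterion, and the rough
   contigs are then discarded.
2. **Stage 2 (strict):** each read cluster is re-assembled independently
   by a greedy overlap–layout–consensus (OLC) assembler whose
   overlap-acceptance threshold — the *relative score*, alignment score
   divided by the maximum attainable score for the overlap length — is
   raised to 0.97. A full-length dovetail between reads from two
   homoeologs at 97% identity scores ~0.91 under the default
   match/mismatch weights (+1/−2) and is rejected, while within-copy
   overlaps (relative score ≈ 1) are kept.

The split into two stages exists because a strict assembler applied to a
whole transcriptome is expensive, and because the clusters can be
assembled independently: the pipeline guarantees that the final output is
identical whatever order (or concurrency) the clusters are processed in.

## The overlap model and its consequences

Overlaps are **gapless** dovetails scored `m·match + mm·mismatch`, with
`relative_score = score / (match · overlap_length)`; a 100-base overlap
with two mismatches scores `(100 − 2 − 2·2)/100 = 0.94`. This
substitution-only model matches how homoeolog divergence is quantified in
wheat (SNP frequencies — indel divergence is not part of the model) and
makes the layout exactly consistent: every read has an integer offset and
orientation in its contig frame, maintained by a union–find structure with
offset/orientation transforms. Conflicting placements are skipped;
paired-end insert bounds (1–500 bases by default) are enforced only as an
advisory check whose violating merges are deferred, since the bound is
loose by design.

Reads carrying *sequencing* indels (the long-read platform's homopolymer
errors) fail this gapless model gracefully: either their overlaps score
below threshold and they stay unplaced, or they are **evicted** after
consensus when they no longer realign to the contig at the relative-score
threshold. Evicted and unplaced reads become singleton layouts that the
final filters remove (a single read's consensus error equals its base
error probability, above the 10⁻⁴ filter for any realistic quality). This
is a deliberate simplification relative to production OLC assemblers,
which gap-realign reads into a padded consensus; its cost is a small tail
of short redundant contigs assembled from indel-bearing read pairs.

## Consensus and conflict splitting

The consensus is quality-weighted: per column, each base's support is
`Σ (1 − 10^(−q/10))` over supporting reads and the heaviest base wins
(ties alphabetically). Column error estimates:

* **contested columns** (at least two disagreeing reads): `losing weight /
  total weight`;
* **unanimous columns**, and columns with a single dissenting read (one
  read is indistinguishable from a sequencing error — the same logic
  behind the conflict-support threshold below): the product of the
  supporting reads' error probabilities, floored at `10^(−quality_cap/10)`
  (`quality_cap` = 90 by default, i.e. never below 10⁻⁹).

A contig's `mean_error` is the arithmetic mean over columns; the
stage-2 filters keep contigs strictly longer than 250 bases with mean
error strictly below 10⁻⁴.

Because short SNP-free dovetails between homoeologs *do* pass the 0.97
threshold (a 50-base clean overlap has relative score 1 regardless of
which copies the reads came from), merged layouts can still arise. The
assembler therefore runs up to `max_passes` (default 3) **conflict
rounds**: a column is a conflict when a minority base is supported by at
least 2 reads with quality ≥ 30. Reads are then bipartitioned by their
alleles across linked conflict columns — the minority part is seeded from
the best-supported conflict column and greedily recruits reads that agree
more with its emerging allele profile than with the consensus — and each
part is re-assembled. Two rounds suffice to peel a three-copy mixture
apart one copy at a time.

This machinery also reproduces the **resolution limit**: when the average
SNP spacing exceeds the effective read length (e.g. 99.9% identity with
100-base reads), homoeologs merge at the overlap stage and the conflict
columns are isolated — the minority part consists only of the reads
physically covering one SNP, assembles into a fragment shorter than the
250-base filter, and is removed. The family then yields a single merged
contig, which is the correct behaviour: no assembler can phase variants
that no read pair connects.

The **permissive mode** used for stage 1 (relative score 0.90, no
conflict rounds, no quality filter, and a two-read minimum per reported
contig — a rough assembler does not emit unassembled single reads)
deliberately reproduces homoeolog-blind behaviour, which is also what the
package's benchmark uses as the chimera-prone comparator.

## Alignment engine

Every percent-identity in the package comes from one local aligner:
exact-seed screening (word size 11, the classic nucleotide-search default)
followed by *exhaustive* Smith–Waterman with affine gaps (gap of length L
costs `gap_open + L·gap_extend`; defaults +1/−2/−3/−2). At the scale this
package operates (transcripts of a few kilobases) the full dynamic
programming matrix is affordable, so no banding heuristic is used and the
reported alignment is provably the local optimum — the test suite verifies
score equality against an independent dynamic-programming implementation
on hundreds of random instances. Percent identity counts identical columns
over *all* alignment columns, gaps included; this convention is fixed and
tested rather than inherited from any external tool. Database-style
E-value thresholds are replaced by explicit minimum aligned length /
minimum identity / minimum seed-cluster requirements, which are
reproducible and independent of database size. Pairs of sequences that
share no exact seed word report no hit — standard seed-and-extend
semantics.

For set-vs-set searches, a pair becomes an alignment candidate when at
least 8 seed words cluster within one diagonal band of 64; chance 12–14
base matches between unrelated sequences produce only 2–4 clustered seeds,
while any hit long enough to qualify (100+ columns) produces dozens.

## The synthetic transcriptome generator

All evaluation rests on a ground-truthed simulator of a hexaploid
transcriptome:

* **Families.** Each family is an ancestral transcript (log-normal length,
  median ~1.1 kb, clamped to 0.5–5 kb) plus 1–3 genome copies (triplet /
  doublet / singlet mix 0.7/0.2/0.1 by default). A per-family target
  identity is drawn from Normal(97.2, 1.8), truncated to (85, 100] — draws
  above 100 clip to 100, representing genuinely undiverged copies. Each
  copy is mutated independently from the ancestor at half the implied
  pairwise rate, so pairwise identity ≈ target. By default all divergence
  is substitutional (wheat homoeolog divergence is reported as SNP rates);
  a 1-base-indel layer and an optional cultivar-polymorphism layer
  (`cultivar_snp_spacing`, e.g. 300 bases between the sequenced cultivar
  and the reference set) are available. Realized pairwise identities are
  re-measured by alignment and stored with the truth.
* **Reads.** Long reads are single-ended, length Normal(363.2, 60) clipped
  to [50, transcript length], constant Q38 with substitutions injected at
  the matching error probability plus homopolymer 1-base indels at
  10⁻³/base. Short reads are inward-facing 108-base pairs with inserts
  uniform on [250, 300]; their per-base error ramps linearly 4-fold from
  5′ to 3′ around a 2×10⁻³ mean, with PHRED qualities consistent with the
  injected rates by construction. Every read carries its origin (family,
  genome, 0-based half-open coordinates, strand); coordinates are one
  convention used everywhere.
* **Expression.** Coverage is uniform per copy by default — the idealized
  outcome of the library normalization step such experiments use; a
  log-normal expression skew with a median-multiple coverage cap is
  available to emulate incomplete normalization.
* **Artifacts.** Adapter append (with optional mismatches), ambiguous-base
  runs and low-quality tails can be injected for QC testing; truth labels
  are preserved.

What the simulator does **not** model: splice isoforms, rRNA or
inter-molecular library chimeras, base-composition bias, and realistic
quality-score miscalibration. Passing the benchmarks here therefore
demonstrates the pipeline's homoeolog-separation logic under the stated
divergence model, not robustness to every artefact of real libraries.

## Read QC

The trimming rules are applied in a fixed order so each later rule sees
the final retained bases: (adapter) the longest read suffix matching an
adapter prefix with at most one mismatch per 10 matched bases (minimum 8)
is removed, iterated to a fixed point with (a); (a) the read is truncated
immediately before the first run of more than 3 consecutive ambiguous
bases (any non-ACGT symbol) or more than 3 consecutive bases under Q20,
scanning 5′→3′ — the interpretation of "trimmed back" for 3′-degrading
chemistry; (b) reads whose median retained quality is below Q20 are
discarded; (c) reads shorter than 50 bases are discarded. When one mate of
a pair dies, the survivor is demoted to a single. The
adapter/run-trimming fixed point is what makes the whole QC pass
idempotent, which the tests assert.

## Evaluation machinery

* **Allocation.** Contigs are matched to reference homoeologs by
  iteratively taking the globally best percent identity and removing its
  row and column — one-to-one within a family, accepted identities
  non-increasing, ties broken lexicographically.
* **Chimera detection.** Each reference homoeolog is split into three
  equal pieces (remainder to the last) and allocation is repeated per
  piece; a contig whose winning homoeolog differs between informative
  pieces is chimeric. Pieces with no qualifying hit, or where two
  homoeologs tie exactly (no clear decision possible, e.g. a locally
  undiverged region), are ignored — partial contigs are not auto-flagged.
* **Benchmark.** Fraction of reference homoeologs identified (allocated at
  >98% identity), fraction of assigned contigs chimeric, and fraction
  whose alignment spans more than half the homoeolog.
* **Identity distribution.** All-vs-all best-hit-per-pair search (minimum
  aligned length 400), identity histogram in 0.5% bins, flat background
  estimated as the median bin height over 85–92% (a parameter — the
  background model is this package's choice), excess mass at ≥93%
  summarized as a homoeolog peak (weighted mean/sd). Dividing the excess
  hit count by three gives a lower bound on expressed homoeolog triplets.
* **SNP conversions.** `snp_stats()` exposes both conventions explicitly:
  per-sequence frequency `(100 − identity)/2` (e.g. 97.2% → 1.4%, one SNP
  per 71 bases) and pairwise spacing `100/(100 − identity)` (e.g. 99.67% →
  one mismatch per ~300 bases), because the two are easy to conflate.
* **Coverage.** Per identity cutoff (90/98/99 by default), the average
  covered fraction along a 100-bin relative-position axis, the fraction of
  references matched at all, and the fraction whose best single alignment
  spans >80% of the reference.

## Numerical and design choices

* Tie-breaks are lexicographic everywhere (read ids in overlap ordering,
  bases in consensus, contig/homoeolog ids in allocation) — determinism is
  a contract, verified by byte-identical outputs under permuted inputs and
  permuted cluster order.
* Stage-1 contigs shorter than the 32-base clustering word form singleton
  clusters and are logged rather than dropped silently.
* Multi-assigned reads (sharing 32-mers with several clusters) are
  duplicated into each cluster; the resulting duplicate contigs are
  removed afterwards by exact containment between contigs sharing a member
  read. Exact (not approximate) containment is used because the
  deduplication rule must never merge genuinely distinct homoeolog
  contigs.
* Clusters larger than a configurable read cap (20,000) are subsampled
  with a warning, seeded from the pipeline seed and the cluster index.
* The degenerate inputs are all defined: empty read sets error at QC; a
  single read assembles to a singleton contig subject to filters; an
  identity matrix with all `NA` yields an empty allocation; identity = 100
  gives infinite SNP spacings.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to exercise every code path
with comfortable statistical margins: oracle equivalence of the aligner on
200 random instances up to 1 kb; clustering versus brute-force connected
components on 100 random sets of up to 200 contigs; identity-peak recovery
on 300 simulated triplet families; the strict-versus-permissive
separation contrast on 50 triplet families at 97% identity, 30× coverage
and 300-base reads; and the resolution-limit demonstration on 20 families
at 99.9% identity with 100-base reads.

## Known limitations

* The gapless overlap/consensus model cannot reconcile layouts across
  inter-homoeolog indels; enabling the generator's indel layer degrades
  the *permissive* (rough) assembly first, which in practice only affects
  stage-1 clustering granularity but is the main reason the indel layer is
  off by default.
* Conflict bipartition phases one haplotype per round; pathological
  mixtures of many near-identical paralogs may need more rounds than the
  default 3.
* The background model under the identity peak is a flat median over
  85–92%; a sloped background would bias the excess-hit count slightly.
* Expression skew, isoforms and library chimeras are out of the
  simulator's scope, as noted above.
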
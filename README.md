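# homoeoasm

Homoeolog-specific de novo transcriptome assembly for polyploids, with a
ground-truthed synthetic hexaploid simulator and a full evaluation suite.

## The problem

In an allopolyploid such as bread wheat (genomes A, B, D), each gene is
present as up to three *homoeologous* copies that differ at only ~97.2%
nucleotide identity (mean pairwise divergence ≈ 2.8%, i.e. a per-sequence
SNP frequency of (100 − 97.2)/2 = 1.4%, one SNP per 71 bases). Ordinary
assemblers read this divergence as noise and collapse the copies into
chimeric consensus contigs. `homoeoasm` implements a two-stage strategy
that separates them:

1. a **permissive rough assembly** groups reads into clusters: rough
   contigs are transitively clustered whenever they share a 32-base word
   (canonical 32-mers), reads are assigned by the same criterion, and the
   rough contigs are discarded;
2. each cluster is re-assembled by a **strict greedy
   overlap–layout–consensus** assembler whose overlap acceptance uses the
   *relative score* `score / (match × overlap_length)` with threshold
   0.97. Under the default +1/−2 scoring, a full-length dovetail between
   reads from 97%-diverged homoeologs scores ≈ 0.91 and is rejected;
   within-copy overlaps (≈ 1.0) are kept. Quality-weighted consensus,
   conflict-column phasing, and the final filters (mean base error
   < 10⁻⁴, length > 250) follow.

The evaluation suite implements iterative highest-identity contig→
homoeolog allocation, tripartite chimera detection (split each reference
homoeolog into three pieces, allocate per piece, flag inconsistency),
identity-distribution statistics with background subtraction, SNP-rate
conversions, and positional coverage profiling.

## Worked example

Simulate a small hexaploid transcriptome, run the two-stage pipeline, and
evaluate against the known truth:

```r
library(homoeoasm)

cfg   <- sim_config(n_families = 12, seed = 101,
                    long_read_coverage = 8, short_read_coverage = 25)
fam   <- generate_families(cfg)
reads <- simulate_reads(fam, cfg)
run   <- run_two_stage(reads, pipeline_config(seed = 101))
report(run, fam)
```

which prints (exact numbers for this seed):

```
== assembly report ==
<qc_summary> input 9,429, kept 9,429 (4,307 pairs + 815 singles), ...
total kept reads: 9,429
clusters: 13; reads assigned: 100.0%
contigs: 26 (9 over 1 kb; longest 1455)
<benchmark_metrics> identified 25/33 homoeologs (75.8%); chimeric 1/25
assigned contigs (4.0%); half-length fraction 0.76
chimera rate: 4.0%
homoeolog identity peak: 95.6% (sd 1.8%)
implied per-sequence SNP rate: 2.20% (1 SNP/46 bases)
```

Reading this: 12 families yielded 33 reference homoeologs (triplet/
doublet/singlet mix); the pipeline grouped all reads into 13 clusters and
assembled 26 filtered contigs. 25 of the 33 homoeologs are matched by a
dedicated contig at >98% identity, and only one assigned contig shows
piece-wise evidence of mixing two homoeologs. The identity histogram over
the contigs recovers the divergence peak the simulation planted (the
configured mean identity of this particular draw of 12 families is
96.6%). At higher coverage and with triplets only, identification rises
above 95% and the chimera rate stays near zero, while the same reads
assembled in permissive mode are almost all chimeric — the contrast the
two-stage design exists to demonstrate (see
`tests/testthat/test-acceptance.R`).

A thin command-line front end with `simulate`, `qc`, `pipeline` and
`evaluate` subcommands is installed at `inst/scripts/homoeoasm.R`:

```sh
Rscript inst/scripts/homoeoasm.R simulate --out sim --families 50 --seed 7
Rscript inst/scripts/homoeoasm.R pipeline --single sim.fastq \
    --mate1 sim_1.fastq --mate2 sim_2.fastq --out run1
Rscript inst/scripts/homoeoasm.R evaluate --contigs run1/contigs.fasta \
    --refs sim_refs.fasta
```

## Package layout

| Piece | What it does |
|---|---|
| `sim_config`, `generate_families`, `simulate_reads`, `inject_artifacts` | synthetic hexaploid transcriptome + reads with full truth labels |
| `qc_params`, `trim_and_filter_read`, `trim_adapter`, `qc_readset` | read trimming/filtering rules and accounting |
| `align_params`, `local_align`, `all_vs_all` | seed-screened exact Smith–Waterman local alignment |
| `cluster_contigs`, `assign_reads`, `cluster_stats` | canonical 32-mer transitive clustering |
| `asm_params`, `compute_overlaps`, `assemble_cluster`, `call_consensus`, `filter_contigs` | strict/permissive greedy OLC assembler |
| `iterative_allocation`, `detect_chimera`, `benchmark_assembly`, `identity_histogram`, `snp_stats`, `triplet_lower_bound`, `coverage_profile` | evaluation machinery |
| `pipeline_config`, `run_two_stage`, `report` | two-stage orchestration and reporting |

The methods vignette (`vignettes/homoeolog-assembly.Rmd`) documents the
models, parameter choices, numerical conventions and known limitations.
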
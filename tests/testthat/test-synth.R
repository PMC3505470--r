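test_that("zero divergence yields identical genome copies", {
  cfg <- sim_config(n_families = 5, ploidy_mix = c(triplet = 1, doublet = 0,
                                                   singlet = 0),
                    homoeolog_identity_mean = 100, homoeolog_identity_sd = 0,
                    transcript_min = 400, transcript_max = 600, seed = 2)
  fam <- generate_families(cfg)
  for (f in unique(fam$transcripts$family_id)) {
    seqs <- fam$transcripts$sequence[fam$transcripts$family_id == f]
    expect_length(seqs, 3)
    expect_length(unique(seqs), 1)
  }
  expect_true(all(fam$identities$realized_identity == 100))
})

test_that("fixed 97% target on 1000-base transcripts gives ~30 pairwise differences", {
  cfg <- sim_config(n_families = 10,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    homoeolog_identity_mean = 97, homoeolog_identity_sd = 0,
                    indel_fraction = 0, transcript_meanlog = log(1000),
                    transcript_sdlog = 0, transcript_min = 1000,
                    transcript_max = 1000, seed = 3)
  fam <- generate_families(cfg)
  # substitution-only divergence on equal-length copies: Hamming distance
  diffs <- numeric(0)
  for (f in unique(fam$transcripts$family_id)) {
    seqs <- fam$transcripts$sequence[fam$transcripts$family_id == f]
    for (pair in utils::combn(3, 2, simplify = FALSE)) {
      a <- strsplit(seqs[pair[1]], "")[[1]]
      b <- strsplit(seqs[pair[2]], "")[[1]]
      diffs <- c(diffs, sum(a != b))
    }
  }
  expect_true(all(abs(diffs - 30) <= 8)) # 2x15 mutations minus collisions
  expect_true(all(abs(fam$identities$realized_identity - 97) <= 0.3))
})

test_that("realized identities match the configured 97.2/1.8 distribution", {
  cfg <- sim_config(n_families = 300,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    seed = 42)
  fam <- generate_families(cfg)
  ids <- fam$identities$realized_identity
  expect_lt(abs(mean(ids) - 97.2), 0.2)
  expect_lt(abs(stats::sd(ids) - 1.8), 0.3)
})

test_that("error-free reads are exact substrings of their transcript", {
  cfg <- sim_config(n_families = 1,
                    ploidy_mix = c(triplet = 0, doublet = 0, singlet = 1),
                    homoeolog_identity_sd = 0, transcript_meanlog = log(1000),
                    transcript_sdlog = 0, transcript_min = 1000,
                    transcript_max = 1000, long_read_coverage = 10,
                    short_read_coverage = 0,
                    long_error = list(indel_rate = 0, quality = 60),
                    seed = 4)
  fam <- generate_families(cfg)
  reads <- simulate_reads(fam, cfg)
  tx <- fam$transcripts$cultivar[1]
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    if (reads$strand[i] == "-") s <- revcomp(s)
    expect_identical(s, substr(tx, reads$start[i] + 1, reads$end[i]))
  }
})

test_that("long-read lengths follow the 363.2-base model", {
  cfg <- sim_config(n_families = 4,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    transcript_meanlog = log(2500), transcript_sdlog = 0,
                    transcript_min = 2000, transcript_max = 3000,
                    long_read_coverage = 120, short_read_coverage = 0,
                    long_read_length_sd = 60, seed = 5)
  fam <- generate_families(cfg)
  reads <- simulate_reads(fam, cfg)
  expect_gt(nrow(reads), 5000)
  expect_lt(abs(mean(nchar(reads$sequence)) - 363.2), 2)
})

test_that("paired short reads respect the configured insert range", {
  cfg <- sim_config(n_families = 3,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    long_read_coverage = 0, short_read_coverage = 15,
                    insert_min = 250, insert_max = 300, seed = 6)
  fam <- generate_families(cfg)
  reads <- simulate_reads(fam, cfg)
  r1 <- reads[endsWith(reads$read_id, "_1"), ]
  r2 <- reads[match(r1$mate_id, reads$read_id), ]
  inserts <- r2$end - r1$start
  expect_true(all(inserts >= 250 & inserts <= 300))
  # mate links are symmetric: the mate of my mate is me
  linked <- reads[!is.na(reads$mate_id), ]
  back <- reads$mate_id[match(linked$mate_id, reads$read_id)]
  expect_identical(back, linked$read_id)
})

test_that("transcripts shorter than the minimum insert emit only long reads", {
  cfg <- sim_config(n_families = 2,
                    ploidy_mix = c(triplet = 0, doublet = 0, singlet = 1),
                    transcript_meanlog = log(200), transcript_sdlog = 0,
                    transcript_min = 200, transcript_max = 200,
                    long_read_coverage = 5, short_read_coverage = 20,
                    insert_min = 250, insert_max = 300, seed = 7)
  fam <- generate_families(cfg)
  expect_message(reads <- simulate_reads(fam, cfg), "minimum")
  expect_true(all(reads$platform == "long"))
})

test_that("simulation and file outputs are byte-identical under a fixed seed", {
  cfg <- sim_config(n_families = 3, seed = 8, long_read_coverage = 3,
                    short_read_coverage = 6)
  fam1 <- generate_families(cfg); r1 <- simulate_reads(fam1, cfg)
  fam2 <- generate_families(cfg); r2 <- simulate_reads(fam2, cfg)
  expect_identical(fam1$transcripts, fam2$transcripts)
  expect_identical(r1, r2)
  d <- tempfile(); dir.create(d)
  for (run in c("a", "b")) {
    write_transcripts_fasta(fam1, file.path(d, paste0(run, ".fasta")))
    write_reads_fastq(r1, file.path(d, run))
    write_truth_tsv(r1, file.path(d, paste0(run, ".tsv")))
  }
  for (ext in c(".fasta", "_1.fastq", "_2.fastq", ".fastq", ".tsv"))
    expect_identical(readLines(file.path(d, paste0("a", ext))),
                     readLines(file.path(d, paste0("b", ext))))
})

test_that("artifact injection behaves per rule and preserves truth", {
  cfg <- sim_config(n_families = 2, long_read_coverage = 4,
                    short_read_coverage = 0, seed = 9)
  fam <- generate_families(cfg)
  reads <- simulate_reads(fam, cfg)
  adapter <- "ACGTACGTGGCCTTAA"
  same <- inject_artifacts(reads, adapter, list(), seed = 1)
  expect_identical(same, reads)
  withad <- inject_artifacts(reads, adapter, list(adapter_rate = 1), seed = 1)
  expect_true(all(endsWith(withad$sequence, adapter)))
  expect_identical(withad[, c("family_id", "start", "end", "strand")],
                   reads[, c("family_id", "start", "end", "strand")])
  withn <- inject_artifacts(reads, adapter,
                            list(n_run_rate = 1, n_run_length = 5), seed = 1)
  expect_true(all(grepl("N{5,}", withn$sequence)))
  expect_error(inject_artifacts(reads, "ACGT"), "adapter")
})

test_that("fastq round-trip preserves sequences, qualities and pairing", {
  cfg <- sim_config(n_families = 2, long_read_coverage = 3,
                    short_read_coverage = 8, seed = 10)
  reads <- simulate_reads(generate_families(cfg), cfg)
  d <- tempfile(); dir.create(d)
  write_reads_fastq(reads, file.path(d, "rr"))
  back <- read_reads_fastq(single = file.path(d, "rr.fastq"),
                           mate1 = file.path(d, "rr_1.fastq"),
                           mate2 = file.path(d, "rr_2.fastq"))
  m <- match(reads$read_id, back$read_id)
  expect_false(anyNA(m))
  expect_identical(back$sequence[m], reads$sequence)
  expect_identical(back$quality[m], reads$quality)
  expect_identical(is.na(back$mate_id[m]), is.na(reads$mate_id))
})
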
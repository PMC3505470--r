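strict <- asm_params("strict")
perm <- asm_params("permissive")

test_that("relative scores follow score / (match x overlap length)", {
  set.seed(1)
  x <- rand_dna(200)
  r1 <- substr(x, 1, 140)
  r2 <- substr(x, 41, 200) # 100-base overlap with r1
  # perfect overlap: relative score 1
  ov <- compute_overlaps(mk_reads(c(r1, r2)), perm)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$relative_score, 1)
  expect_equal(ov$overlap_length, 100L)
  # two substitutions inside the overlap: (100 - 2 - 2*2)/100 = 0.94
  ch <- strsplit(r2, "")[[1]]
  for (p in c(30, 60))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  r2m <- paste(ch, collapse = "")
  ovp <- compute_overlaps(mk_reads(c(r1, r2m)), perm)
  expect_equal(ovp$relative_score, 0.94)
  # strict mode (0.97) rejects that same overlap
  ovs <- compute_overlaps(mk_reads(c(r1, r2m)), strict)
  expect_equal(nrow(ovs), 0L)
})

test_that("reads from ~97%-diverged homoeologs do not overlap in strict mode", {
  set.seed(2)
  a <- rand_dna(300)
  b <- sub_mutate(a, 9)$seq # ~97% identity, full-length dovetail
  ov <- compute_overlaps(mk_reads(c(a, b)), strict)
  expect_equal(nrow(ov), 0L)
  ovp <- compute_overlaps(mk_reads(c(a, b)), perm)
  expect_equal(nrow(ovp), 1L)
  expect_lt(ovp$relative_score, 0.97)
})

test_that("error-free tiling reads assemble into the exact transcript", {
  set.seed(3)
  tx <- rand_dna(800)
  reads <- tile_reads(tx, read_len = 100, step = 40)
  cs <- assemble_cluster(reads, strict, cluster_id = 7)
  expect_equal(nrow(cs), 1L)
  expect_identical(cs$consensus, tx)
  expect_identical(cs$name, "C7_1")
  expect_equal(cs$n_reads, nrow(reads))
})

test_that("strict mode separates a 97% homoeolog pair; permissive merges it", {
  cfg <- sim_config(n_families = 1,
                    ploidy_mix = c(triplet = 0, doublet = 1, singlet = 0),
                    homoeolog_identity_mean = 97, homoeolog_identity_sd = 0,
                    transcript_meanlog = log(1000), transcript_sdlog = 0,
                    transcript_min = 1000, transcript_max = 1000,
                    long_read_length_mean = 300, long_read_length_sd = 30,
                    long_read_coverage = 30, short_read_coverage = 0,
                    long_error = list(indel_rate = 0, quality = 38),
                    seed = 21)
  fam <- generate_families(cfg)
  reads <- simulate_reads(fam, cfg)
  cs <- filter_contigs(assemble_cluster(reads, strict), strict)
  expect_gte(nrow(cs), 2L)
  # each strict contig matches one truth homoeolog near-perfectly
  refs <- setNames(fam$transcripts$sequence, fam$transcripts$genome_label)
  for (i in seq_len(nrow(cs))) {
    best <- max(vapply(refs, function(r) {
      h <- local_align(cs$consensus[i], r)
      if (is.null(h)) 0 else h$pct_id
    }, numeric(1)))
    expect_gte(best, 99.9)
  }
  # member reads are never mixed across homoeologs (truth audit)
  for (m in cs$members) {
    labs <- reads$genome_label[match(m$read_id, reads$read_id)]
    expect_length(unique(labs), 1L)
  }
  cp <- filter_contigs(assemble_cluster(reads, perm), perm)
  expect_equal(nrow(cp), 1L)
  both <- vapply(refs, function(r)
    local_align(cp$consensus[1], r)$pct_id, numeric(1))
  expect_true(all(both > 97.5 & both < 99.9)) # blended consensus
})

test_that("consensus calls are quality-weighted with calibrated errors", {
  # five agreeing Q30 reads: tiny error, well under 1e-3
  lay <- list(sequences = rep("ACGT", 5), qualities = rep(qual_str(30L, 4), 5),
              starts = rep(0L, 5))
  cc <- call_consensus(lay, strict)
  expect_identical(cc$consensus, "ACGT")
  expect_true(all(cc$per_base_error <= 1e-3))
  # 3 x Q40 'A' against 1 x Q10 'G'
  lay2 <- list(sequences = c("A", "A", "A", "G"),
               qualities = c(rep(qual_str(40L, 1), 3), qual_str(10L, 1)),
               starts = rep(0L, 4))
  cc2 <- call_consensus(lay2, strict)
  expect_identical(cc2$consensus, "A")
  # single-read column: the consensus is the read base
  lay3 <- list(sequences = "TTGCA", qualities = qual_str(38L, 5),
               starts = 0L)
  expect_identical(call_consensus(lay3, strict)$consensus, "TTGCA")
})

test_that("contig filters apply strict thresholds on length and error", {
  mk_cs <- function(len, err, n_reads = 5) {
    out <- data.frame(name = "c", consensus = strrep("A", len),
                      length = len, mean_error = err, n_reads = n_reads,
                      stringsAsFactors = FALSE)
    out$per_base_error <- list(rep(err, len))
    out$members <- list(data.frame(read_id = sprintf("r%d", seq_len(n_reads))))
    class(out) <- c("contig_set", "data.frame")
    out
  }
  expect_equal(nrow(filter_contigs(mk_cs(251, 5e-5), strict)), 1L)
  expect_equal(nrow(filter_contigs(mk_cs(250, 5e-5), strict)), 0L)
  expect_equal(nrow(filter_contigs(mk_cs(1000, 2e-4), strict)), 0L)
  expect_equal(nrow(filter_contigs(mk_cs(1000, 2e-4), perm)), 1L)
  expect_equal(nrow(filter_contigs(mk_cs(300, 5e-5, n_reads = 1), perm)), 0L)
})

test_that("member reads realign to their contig at the strict threshold", {
  cfg <- sim_config(n_families = 2,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    homoeolog_identity_mean = 97, homoeolog_identity_sd = 0,
                    long_read_length_mean = 300, long_read_length_sd = 30,
                    long_read_coverage = 25, short_read_coverage = 0,
                    seed = 22)
  fam <- generate_families(cfg)
  reads <- simulate_reads(fam, cfg)
  cs <- assemble_cluster(reads, strict)
  for (i in seq_len(nrow(cs))) {
    m <- cs$members[[i]]
    cons <- cs$consensus[i]
    for (j in seq_len(nrow(m))) {
      r <- reads[reads$read_id == m$read_id[j], ]
      s <- if (m$ori[j] == -1) revcomp(r$sequence) else r$sequence
      span <- substr(cons, m$start[j] + 1, m$start[j] + nchar(s))
      a <- strsplit(s, "")[[1]]; b <- strsplit(span, "")[[1]]
      mm <- sum(a != b)
      rs <- ((length(a) - mm) * 1 + mm * (-2)) / length(a)
      expect_gte(rs, strict$min_relative_score)
    }
  }
})

test_that("assembly output is invariant to read input order", {
  cfg <- sim_config(n_families = 1,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    long_read_coverage = 15, short_read_coverage = 0,
                    seed = 23)
  reads <- simulate_reads(generate_families(cfg), cfg)
  set.seed(9)
  c1 <- assemble_cluster(reads, strict)
  c2 <- assemble_cluster(reads[sample(nrow(reads)), ], strict)
  expect_identical(c1$consensus, c2$consensus)
  expect_identical(c1$name, c2$name)
})
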
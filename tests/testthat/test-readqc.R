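mk_one <- function(sequence, quality) {
  list(sequence = sequence, quality = quality)
}

test_that("clean high-quality reads pass unchanged", {
  set.seed(1)
  r <- mk_one(rand_dna(100), qual_str(40L, 100))
  res <- trim_and_filter_read(r, qc_params())
  expect_identical(res$verdict, "kept")
  expect_identical(res$sequence, r$sequence)
  expect_false(res$trimmed)
})

test_that("a run of four ambiguous bases truncates the read before the run", {
  set.seed(2)
  s <- rand_dna(100)
  substr(s, 61, 64) <- "NNNN" # 0-based positions 60-63
  r <- mk_one(s, qual_str(40L, 100))
  res <- trim_and_filter_read(r, qc_params())
  expect_identical(res$verdict, "kept")
  expect_identical(nchar(res$sequence), 60L)
  expect_identical(res$sequence, substr(s, 1, 60))
  # a run of exactly three is tolerated
  s3 <- rand_dna(100); substr(s3, 61, 63) <- "NNN"
  res3 <- trim_and_filter_read(mk_one(s3, qual_str(40L, 100)), qc_params())
  expect_identical(res3$verdict, "kept")
  expect_identical(nchar(res3$sequence), 100L)
})

test_that("rule order is a (run trim) then b (median) then c (length)", {
  set.seed(3)
  # 49 x Q40 then 51 x Q10: rule (a) truncates at the Q10 run, leaving 49
  # clean bases, so the length rule fires — not the median rule
  r <- mk_one(rand_dna(100), qual_str(c(rep(40L, 49), rep(10L, 51))))
  res <- trim_and_filter_read(r, qc_params())
  expect_identical(res$verdict, "length")
  # median rule: low quality without any run longer than three
  q <- rep(c(10L, 10L, 10L, 40L), 25)
  res2 <- trim_and_filter_read(mk_one(rand_dna(100), qual_str(q)), qc_params())
  expect_identical(res2$verdict, "median")
  # empty read discards under the length rule
  res3 <- trim_and_filter_read(mk_one(NA_character_, NA_character_),
                               qc_params())
  expect_identical(res3$verdict, "length")
})

test_that("adapter trimming removes the longest matching suffix", {
  set.seed(4)
  adapter <- "ACGGTTACCAGGTTAACC"
  params <- qc_params(adapter = adapter, adapter_max_mismatch = 0)
  body <- rand_dna(80)
  r <- mk_one(paste0(body, adapter), qual_str(40L, 80 + nchar(adapter)))
  res <- trim_adapter(r, params)
  expect_identical(res$sequence, body)
  # one substitution within the adapter, two mismatches allowed
  ad2 <- adapter; substr(ad2, 5, 5) <- "T"
  params2 <- qc_params(adapter = adapter, adapter_max_mismatch = 2)
  res2 <- trim_adapter(mk_one(paste0(body, ad2),
                              qual_str(40L, 80 + nchar(ad2))), params2)
  expect_identical(res2$sequence, body)
  # internal adapter occurrence (not a suffix) stays untouched
  r3 <- mk_one(paste0(substr(body, 1, 40), adapter, rand_dna(40)),
               qual_str(40L, 40 + nchar(adapter) + 40))
  res3 <- trim_adapter(r3, params)
  expect_identical(res3$sequence, r3$sequence)
  # a partial adapter prefix (>= 8 bases) at the 3' end is removed too
  r4 <- mk_one(paste0(body, substr(adapter, 1, 10)), qual_str(40L, 90))
  res4 <- trim_adapter(r4, params)
  expect_identical(res4$sequence, body)
})

test_that("qc_readset demotes widowed mates and keeps its accounting invariant", {
  set.seed(5)
  n <- 10
  s1 <- vapply(rep(100, n), rand_dna, character(1))
  s2 <- vapply(rep(100, n), rand_dna, character(1))
  q <- qual_str(40L, 100)
  reads <- homoeoasm:::new_read_set(data.frame(
    read_id = c(sprintf("p%02d_1", 1:n), sprintf("p%02d_2", 1:n)),
    sequence = c(s1, s2), quality = q, platform = "short",
    mate_id = c(sprintf("p%02d_2", 1:n), sprintf("p%02d_1", 1:n)),
    stringsAsFactors = FALSE))
  # force one mate to fail the median rule
  reads$quality[reads$read_id == "p03_2"] <-
    qual_str(rep(c(10L, 10L, 10L, 40L), 25))
  out <- qc_readset(reads, qc_params())
  expect_equal(out$summary$n_pairs_kept, 9)
  expect_equal(out$summary$n_singles_kept, 1)
  expect_equal(out$summary$n_kept +
                 out$summary$n_discarded_median +
                 out$summary$n_discarded_length,
               out$summary$n_input)
  expect_equal(qc_total_reads(out$summary), out$summary$n_kept)
  # empty input gives all-zero counts
  empty <- qc_readset(reads[0, ], qc_params())
  expect_equal(empty$summary$n_input, 0)
})

test_that("qc is idempotent and never lengthens or under-trims reads", {
  cfg <- sim_config(n_families = 3, long_read_coverage = 4,
                    short_read_coverage = 8, seed = 6)
  reads <- simulate_reads(generate_families(cfg), cfg)
  reads <- inject_artifacts(reads, "ACGGTTACCAGGTTAACC",
                            list(adapter_rate = 0.3, n_run_rate = 0.2,
                                 n_run_length = 6, lowq_tail_rate = 0.3,
                                 tail_length = 12), seed = 7)
  params <- qc_params(adapter = "ACGGTTACCAGGTTAACC")
  once <- qc_readset(reads, params)
  twice <- qc_readset(once$reads, params)
  expect_identical(twice$reads, once$reads)
  expect_identical(twice$summary$n_kept, once$summary$n_kept)
  lens_in <- nchar(reads$sequence[match(once$reads$read_id, reads$read_id)])
  expect_true(all(nchar(once$reads$sequence) <= lens_in))
  expect_true(all(nchar(once$reads$sequence) >= params$min_length))
  meds <- vapply(once$reads$quality,
                 function(q) stats::median(utf8ToInt(q) - 33L), numeric(1))
  expect_true(all(meds >= params$min_median_phred))
})

test_that("asymmetric mate links are rejected with the offending read named", {
  reads <- mk_reads(c("ACGTACGTACGT", "ACGTACGTACGT"),
                    read_id = c("a", "b"),
                    mate_id = c("b", "zzz"))
  expect_error(qc_readset(reads, qc_params()), "a")
})
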
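test_that("iterative allocation reproduces the worked 3x3 example", {
  m <- matrix(c(99, 98, 97,
                99, 100, 98,
                97, 97, 98), nrow = 3, byrow = TRUE,
              dimnames = list(c("1", "2", "3"), c("A", "B", "D")))
  al <- iterative_allocation(m)
  expect_identical(al$contig_id, c("2", "1", "3"))
  expect_identical(al$homoeolog_id, c("B", "A", "D"))
  expect_equal(al$pct_id, c(100, 99, 98))
  # accepted identities are non-increasing by construction
  expect_true(all(diff(al$pct_id) <= 0))
})

test_that("allocation handles single cells, NA gaps and non-square matrices", {
  one <- matrix(97.5, 1, 1, dimnames = list("c", "A"))
  expect_equal(iterative_allocation(one)$pct_id, 97.5)
  m <- matrix(runif(12, 90, 100), nrow = 4,
              dimnames = list(paste0("c", 1:4), c("A", "B", "D")))
  al <- iterative_allocation(m)
  expect_equal(nrow(al), 3L) # one per column at most
  expect_false(anyDuplicated(al$contig_id) > 0)
  withna <- matrix(c(99, NA, NA, 95), 2, 2,
                   dimnames = list(c("c1", "c2"), c("A", "B")))
  alna <- iterative_allocation(withna)
  expect_identical(alna$homoeolog_id, c("A", "B"))
})

test_that("allocation agrees with an independent repeated-argmax oracle", {
  oracle_alloc <- function(m) {
    out <- NULL
    while (any(!is.na(m))) {
      idx <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)
      idx <- idx[order(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]]), ,
                 drop = FALSE]
      out <- rbind(out, data.frame(contig_id = rownames(m)[idx[1, 1]],
                                   homoeolog_id = colnames(m)[idx[1, 2]],
                                   pct_id = m[idx[1, 1], idx[1, 2]]))
      m <- m[-idx[1, 1], -idx[1, 2], drop = FALSE]
      if (nrow(m) == 0 || ncol(m) == 0) break
    }
    out
  }
  set.seed(11)
  for (i in 1:20) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    m <- matrix(round(runif(nr * nc, 85, 100), 2), nr,
                dimnames = list(sprintf("c%d", 1:nr),
                                sprintf("h%d", 1:nc)))
    m[sample(length(m), nr)] <- NA
    if (all(is.na(m))) next
    mine <- iterative_allocation(m)
    orc <- oracle_alloc(m)
    expect_equal(mine$contig_id, orc$contig_id)
    expect_equal(mine$pct_id, orc$pct_id)
  }
})

test_that("allocation is stable under row and column permutation", {
  set.seed(12)
  m <- matrix(round(runif(12, 90, 100), 3), 4,
              dimnames = list(paste0("c", 1:4), c("A", "B", "D")))
  a1 <- iterative_allocation(m)
  a2 <- iterative_allocation(m[sample(4), sample(3)])
  expect_equal(a1, a2)
})

test_that("tripartite matching flags spliced contigs and tolerates partial ones", {
  set.seed(13)
  anc <- rand_dna(900)
  A <- sub_mutate(anc, 14)$seq
  B <- sub_mutate(anc, 14)$seq
  refs <- c(A = A, B = B)
  expect_identical(as.character(detect_chimera(A, refs)), "consistent")
  # first two thirds of A spliced to the last third of B
  splice <- paste0(substr(A, 1, 600), substr(B, 601, 900))
  v <- detect_chimera(splice, refs)
  expect_identical(as.character(v), "chimeric")
  expect_identical(attr(v, "piece_winners"), c("A", "A", "B"))
  # a contig covering only the middle third is informative on one piece
  mid <- substr(A, 320, 580)
  vm <- detect_chimera(mid, refs)
  expect_identical(as.character(vm), "consistent")
  expect_equal(sum(!is.na(attr(vm, "piece_winners"))), 1L)
  # no qualifying hit at all
  expect_identical(as.character(detect_chimera(rand_dna(300), refs)),
                   "unassigned")
})

test_that("benchmark metrics are exact on a perfect toy assembly", {
  cfg <- sim_config(n_families = 5,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    transcript_min = 600, transcript_max = 900,
                    transcript_meanlog = log(700), seed = 14)
  fam <- generate_families(cfg)
  contigs <- setNames(fam$transcripts$sequence,
                      sprintf("tig%02d", seq_len(nrow(fam$transcripts))))
  bm <- benchmark_assembly(contigs, fam)
  expect_equal(bm$frac_identified, 1)
  expect_equal(bm$frac_chimeric, 0)
  expect_equal(bm$frac_half_length, 1)
  expect_equal(bm$n_refs, 15L)
})

test_that("chimera-rate and read-accounting arithmetic match the printed figures", {
  expect_equal(chimera_rate(27, 186), 14.5)
  expect_equal(qc_total_reads(qc_summary(6913826, 736096)), 14563748)
  expect_equal(qc_total_reads(qc_summary(6913826, 736096)) + 1495941,
               16059689)
})

test_that("snp conversions reproduce the per-sequence and pairwise figures", {
  s <- snp_stats(97.2)
  expect_equal(s$per_sequence_snp_freq, 1.4)
  expect_equal(s$per_sequence_spacing, 71)
  expect_equal(snp_stats(99.67)$pairwise_mismatch_spacing, 303)
  s100 <- snp_stats(100)
  expect_equal(s100$per_sequence_snp_freq, 0)
  expect_identical(s100$per_sequence_spacing, Inf)
  # round-trip: the inverse map recovers the identity exactly
  for (id in c(90, 95.5, 97.2, 99.67))
    expect_equal(100 - 2 * snp_stats(id)$per_sequence_snp_freq, id)
  expect_error(snp_stats(0), "identity")
})

test_that("triplet lower bound divides excess hits by three", {
  tb <- triplet_lower_bound(83600)
  expect_equal(tb$raw, 83600 / 3, tolerance = 1e-12)
  expect_equal(tb$rounded, 27900)
  expect_equal(triplet_lower_bound(0)$raw, 0)
  expect_equal(triplet_lower_bound(6)$raw, 2)
  expect_error(triplet_lower_bound(-1), ">= 0")
})

test_that("identity histograms behave on degenerate inputs", {
  set.seed(15)
  a <- rand_dna(600)
  ih <- identity_histogram(c(x = a, y = a))
  top <- ih$histogram[ih$histogram$bin_start == 99.5, ]
  expect_equal(top$count, 1L)
  expect_equal(sum(ih$histogram$count), 1L)
  # unrelated sequences: no qualifying pairs, zero excess
  un <- vapply(rep(600, 6), rand_dna, character(1))
  names(un) <- paste0("u", 1:6)
  ih2 <- identity_histogram(un)
  expect_equal(sum(ih2$histogram$count), 0L)
  expect_null(ih2$estimate)
})

test_that("coverage profiles track where contigs align", {
  set.seed(16)
  cfg <- sim_config(n_families = 4,
                    ploidy_mix = c(triplet = 0, doublet = 0, singlet = 1),
                    transcript_min = 800, transcript_max = 1000,
                    transcript_meanlog = log(900), seed = 17)
  fam <- generate_families(cfg)
  full <- setNames(fam$transcripts$sequence, paste0("f", 1:4))
  cp <- coverage_profile(fam, full, pct_id_cutoffs = c(90, 99))
  expect_true(all(cp[["90"]]$profile == 1))
  expect_equal(cp[["99"]]$matched_fraction, 1)
  expect_equal(cp[["99"]]$long_alignment_fraction, 1)
  # contigs covering only the first half: front bins covered, back not
  half <- setNames(substr(fam$transcripts$sequence, 1,
                          floor(fam$transcripts$length / 2)),
                   paste0("h", 1:4))
  cph <- coverage_profile(fam, half, pct_id_cutoffs = 90)
  expect_true(all(cph[["90"]]$profile[1:45] > 0.95))
  expect_true(all(cph[["90"]]$profile[55:100] < 0.05))
  expect_equal(cph[["90"]]$matched_fraction, 1)
  expect_equal(cph[["90"]]$long_alignment_fraction, 0)
  # raising the identity cutoff never increases the matched fraction
  noisy <- setNames(vapply(fam$transcripts$sequence, function(s)
    sub_mutate(s, round(nchar(s) * 0.03))$seq, character(1)), paste0("n", 1:4))
  cpn <- coverage_profile(fam, noisy, pct_id_cutoffs = c(90, 98, 99))
  expect_true(cpn[["99"]]$matched_fraction <= cpn[["98"]]$matched_fraction)
  expect_true(cpn[["98"]]$matched_fraction <= cpn[["90"]]$matched_fraction)
})

test_that("identity matrices hold best qualifying hits with NA elsewhere", {
  set.seed(18)
  cfg <- sim_config(n_families = 2,
                    ploidy_mix = c(triplet = 1, doublet = 0, singlet = 0),
                    transcript_min = 600, transcript_max = 800,
                    transcript_meanlog = log(700), seed = 19)
  fam <- generate_families(cfg)
  tigs <- setNames(fam$transcripts$sequence[fam$transcripts$family_id ==
                                            "F0001"], paste0("t", 1:3))
  m <- homoeolog_identity_matrix(tigs, fam)
  expect_equal(dim(m), c(3L, 6L))
  own <- m[, grep("F0001", colnames(m))]
  expect_true(all(diag(own) == 100))
  other <- m[, grep("F0002", colnames(m))]
  expect_true(all(is.na(other)))
})
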
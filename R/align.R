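# Local alignment engine: exact-seed screening followed by exact
# Smith-Waterman with affine gaps (full dynamic programming; at desk scale
# no banding is needed, so the reported alignment is the true local
# optimum). Percent identity counts identical columns over all alignment
# columns, gap columns included. E-value thresholds of database search tools
# are replaced by (min_aligned_length, min_pct_id, min_score) triples.

#' Alignment parameters
#'
#' @param match,mismatch match/mismatch scores (match > 0 > mismatch).
#' @param gap_open,gap_extend gap scores (negative); a gap of length L
#'   scores `gap_open + L * gap_extend`.
#' @param min_aligned_length minimum alignment columns for a reported hit.
#' @param min_pct_id minimum percent identity for a reported hit.
#' @param seed_length exact-match word size used to screen sequence pairs
#'   (>= 11).
#' @return object of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = -3,
                         gap_extend = -2, min_aligned_length = 0,
                         min_pct_id = 0, seed_length = 11) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (seed_length < 11) stop("seed_length must be >= 11")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_aligned_length = min_aligned_length,
                 min_pct_id = min_pct_id,
                 seed_length = as.integer(seed_length)),
            class = "align_params")
}

sw_hit <- function(a, b, params, strand) {
  bq <- if (strand == "-") revcomp(b) else b
  res <- cpp_sw_align(a, bq, params$match, params$mismatch,
                      -params$gap_open, -params$gap_extend)
  if (res$score <= 0 || res$columns == 0) return(NULL)
  b0 <- res$b0; b1 <- res$b1
  if (strand == "-") {
    len <- nchar(b)
    tmp <- b0
    b0 <- len - b1
    b1 <- len - tmp
  }
  list(score = res$score,
       pct_id = 100 * res$identities / res$columns,
       aligned_length = res$columns,
       query_interval = c(res$a0, res$a1),
       target_interval = c(b0, b1), strand = strand)
}

#' Best local alignment of two sequences
#'
#' Both strands of `b` are considered; strands without a shared exact seed
#' word are skipped (seed-and-extend semantics: pairs with no exact
#' `seed_length`-mer in common report no hit). The surviving strand is
#' aligned by exhaustive Smith-Waterman, so the returned alignment is the
#' highest-scoring local alignment.
#'
#' @param a,b sequences (character scalars); both non-empty.
#' @param params an [align_params()].
#' @param query_id,target_id optional identifiers stored on the hit.
#' @return an `alignment_hit` (list with score, pct_id, aligned_length,
#'   query_interval, target_interval — 0-based half-open — and strand), or
#'   `NULL` when no alignment meets the thresholds.
#' @export
local_align <- function(a, b, params = align_params(), query_id = NULL,
                        target_id = NULL) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  strands <- cpp_shared_seed_strands(a, b, params$seed_length)
  best <- NULL
  if (strands[1]) best <- sw_hit(a, b, params, "+")
  if (strands[2]) {
    h <- sw_hit(a, b, params, "-")
    if (!is.null(h) && (is.null(best) || h$score > best$score)) best <- h
  }
  if (is.null(best)) return(NULL)
  if (best$aligned_length < params$min_aligned_length ||
      best$pct_id < params$min_pct_id) return(NULL)
  best$query_id <- query_id
  best$target_id <- target_id
  class(best) <- "alignment_hit"
  best
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("<alignment_hit> score %.1f, %.2f%% id over %d cols, strand %s\n",
              x$score, x$pct_id, x$aligned_length, x$strand))
  invisible(x)
}

hit_row <- function(hit, qid, tid) {
  data.frame(query_id = qid, target_id = tid, pct_id = hit$pct_id,
             aligned_length = hit$aligned_length, score = hit$score,
             q_start = hit$query_interval[1], q_end = hit$query_interval[2],
             t_start = hit$target_interval[1], t_end = hit$target_interval[2],
             strand = hit$strand, stringsAsFactors = FALSE)
}

# Seed-screened best hits between two sequence sets (or within one set when
# `targets` is NULL). Candidate pairs need >= min_seeds seed words clustered
# on one diagonal band before the exact alignment runs; chance 12-14 base
# matches between unrelated sequences produce only 2-4 clustered seeds,
# while any qualifying hit produces dozens.
seeded_hits <- function(queries, targets = NULL, params = align_params(),
                        min_seeds = 8, band = 64) {
  self <- is.null(targets)
  qn <- names(queries) %||% as.character(seq_along(queries))
  seqs <- if (self) queries else c(queries, targets)
  tn <- if (self) qn else
    (names(targets) %||% as.character(seq_along(targets)))
  cand <- cpp_seed_candidates(unname(seqs), params$seed_length,
                              as.integer(min_seeds), as.integer(band), 200L)
  nq <- length(queries)
  rows <- list(); key_best <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (self) {
      qi <- min(i, j); ti <- max(i, j)
      if (qi == ti) next
    } else {
      # keep only query-vs-target pairs
      if ((i <= nq) == (j <= nq)) next
      qi <- min(i, j); ti <- max(i, j) - nq
    }
    strand <- if (cand$strand[r] == 1) "+" else "-"
    a <- if (self) seqs[[qi]] else queries[[qi]]
    b <- if (self) seqs[[ti]] else targets[[ti]]
    h <- sw_hit(a, b, params, strand)
    if (is.null(h)) next
    key <- paste0(qi, "_", ti)
    prev <- key_best[[key]]
    if (is.null(prev) || h$score > prev$score) {
      h$qi <- qi; h$ti <- ti
      key_best[[key]] <- h
    }
  }
  hits <- ls(key_best)
  rows <- lapply(hits, function(k) {
    h <- key_best[[k]]
    hit_row(h, qn[h$qi], tn[h$ti])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), target_id = character(),
               pct_id = numeric(), aligned_length = integer(),
               score = numeric(), q_start = integer(), q_end = integer(),
               t_start = integer(), t_end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  out[order(out$query_id, out$target_id), , drop = FALSE]
}

#' All-vs-all best hits within a sequence set
#'
#' For each unordered pair of sequences at most one hit — the highest
#' scoring — is retained; self-hits are excluded. The default minimum
#' aligned length of 400 columns mirrors the identity-distribution analysis
#' this operation feeds.
#'
#' @param seqs named character vector of sequences (>= 2).
#' @param params an [align_params()]; when omitted,
#'   `align_params(min_aligned_length = 400)`.
#' @return data.frame of hits (query_id, target_id, pct_id, aligned_length,
#'   score, coordinates, strand).
#' @export
all_vs_all <- function(seqs, params = align_params(min_aligned_length = 400)) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  hits <- seeded_hits(seqs, NULL, params)
  keep <- hits$aligned_length >= params$min_aligned_length &
    hits$pct_id >= params$min_pct_id
  hits[keep, , drop = FALSE]
}

#' Write hits in 12-column tabular (BLAST outfmt-6 compatible) order
#'
#' Columns: query, target, pct_id, aligned length, mismatches, gap
#' openings (reported as 0; gaps are folded into the column count), query
#' start/end, target start/end (1-based inclusive, target reversed on
#' minus-strand hits), e-value placeholder (`NA`) and score.
#'
#' @param hits data.frame from [all_vs_all()] or internal hit tables.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  mm <- round(hits$aligned_length * (1 - hits$pct_id / 100))
  ts <- ifelse(hits$strand == "-", hits$t_end, hits$t_start + 1)
  te <- ifelse(hits$strand == "-", hits$t_start + 1, hits$t_end)
  out <- data.frame(hits$query_id, hits$target_id,
                    sprintf("%.2f", hits$pct_id), hits$aligned_length, mm,
                    0L, hits$q_start + 1, hits$q_end, ts, te, NA, hits$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
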
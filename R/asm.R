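# Greedy overlap-layout-consensus assembler with homoeolog-aware strictness.
# Overlaps are gapless dovetails scored match/mismatch; the relative score
# of an overlap is score / (match * overlap_length), and the strict default
# of 0.97 rejects overlaps between reads drawn from homoeologs at ~97%
# identity while accepting within-copy overlaps. Indel-bearing reads fail
# their overlaps or are evicted after consensus rather than gap-realigned.
# Conflict rounds split layouts whose consensus shows well-supported
# minority alleles (the multi-pass "learning" behaviour); the permissive
# mode used for stage-1 clustering disables them.

#' Assembler parameters
#'
#' @param mode `"strict"` (homoeolog-separating; relative score 0.97, up to
#'   3 conflict-splitting passes) or `"permissive"` (stage-1 rough
#'   assembly; relative score 0.90, no conflict passes, relaxed error
#'   filter since its contigs are only used to cluster reads).
#' @param min_relative_score overlap acceptance threshold in (0, 1].
#' @param min_overlap minimum overlap length (bases).
#' @param insert_min,insert_max advisory paired-end insert bounds during
#'   layout.
#' @param max_passes maximum conflict-splitting rounds.
#' @param min_contig_length contigs must be strictly longer than this.
#' @param max_mean_error contigs must have mean per-base error strictly
#'   below this (permissive mode: 1, i.e. no quality filter — rough
#'   contigs only group reads).
#' @param min_reads minimum reads per reported contig (permissive mode: 2,
#'   since a rough assembler does not report unassembled single reads).
#' @param conflict_min_support,conflict_min_qual a consensus column is a
#'   conflict when a minority base is supported by at least
#'   `conflict_min_support` reads each with quality >=
#'   `conflict_min_qual`.
#' @param match,mismatch overlap scoring.
#' @param overlap_seed exact word size used to propose overlap candidates.
#' @param quality_cap maximum trusted PHRED score; unanimous consensus
#'   columns are floored at error `10^(-quality_cap/10)`.
#' @return object of class `asm_params`.
#' @export
asm_params <- function(mode = c("strict", "permissive"),
                       min_relative_score = NULL, min_overlap = 40,
                       insert_min = 1, insert_max = 500, max_passes = NULL,
                       min_contig_length = 250, max_mean_error = NULL,
                       min_reads = NULL,
                       conflict_min_support = 2, conflict_min_qual = 30,
                       match = 1, mismatch = -2, overlap_seed = 14,
                       quality_cap = 90) {
  mode <- match.arg(mode)
  strict <- mode == "strict"
  p <- list(mode = mode,
            min_relative_score = min_relative_score %||%
              (if (strict) 0.97 else 0.90),
            min_overlap = as.integer(min_overlap),
            insert_min = as.integer(insert_min),
            insert_max = as.integer(insert_max),
            max_passes = max_passes %||% (if (strict) 3L else 0L),
            min_contig_length = as.integer(min_contig_length),
            max_mean_error = max_mean_error %||%
              (if (strict) 1e-4 else 1),
            min_reads = as.integer(min_reads %||% (if (strict) 1L else 2L)),
            conflict_min_support = as.integer(conflict_min_support),
            conflict_min_qual = as.integer(conflict_min_qual),
            match = match, mismatch = mismatch,
            overlap_seed = as.integer(overlap_seed),
            quality_cap = quality_cap)
  if (p$min_relative_score <= 0 || p$min_relative_score > 1)
    stop("min_relative_score must lie in (0, 1]")
  if (p$insert_min > p$insert_max) stop("insert_min must be <= insert_max")
  class(p) <- "asm_params"
  p
}

#' Compute dovetail overlaps between reads
#'
#' All gapless dovetail overlaps of at least `min_overlap` bases with
#' relative score `score / (match * overlap_length)` at or above
#' `min_relative_score`, both orientations considered; at most one (the
#' best-scoring) overlap per read pair. Ordering is deterministic: score
#' descending, then lexicographic read ids.
#'
#' @param reads a `read_set` (quality-filtered).
#' @param params an [asm_params()].
#' @return data.frame with read_i, read_j, strand, offset (start of the
#'   oriented j in i's forward frame), overlap_length, score and
#'   relative_score.
#' @export
compute_overlaps <- function(reads, params = asm_params()) {
  ov <- cpp_overlaps(reads$sequence, params$match, params$mismatch,
                     params$min_overlap, params$min_relative_score,
                     params$overlap_seed, 500L)
  out <- data.frame(read_i = reads$read_id[ov$i], read_j = reads$read_id[ov$j],
                    strand = ifelse(ov$strand == 1, "+", "-"),
                    offset = ov$offset, overlap_length = ov$olen,
                    score = ov$score, relative_score = ov$rs,
                    i = ov$i, j = ov$j, s = ov$strand,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$read_i, out$read_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call a quality-weighted consensus over a layout
#'
#' Per column, each base's support weight is the sum of `1 - 10^(-q/10)`
#' over the reads supporting it; the heaviest base is called (ties broken
#' alphabetically). Contested columns get error `losing weight / total
#' weight`; unanimous columns get the product of the supporting reads'
#' error probabilities, floored at `10^(-quality_cap/10)`.
#'
#' @param layout list with `sequences` (oriented read sequences),
#'   `qualities` (PHRED+33 strings) and `starts` (0-based column offsets).
#' @param params an [asm_params()].
#' @return list with `consensus` and `per_base_error`.
#' @export
call_consensus <- function(layout, params = asm_params()) {
  if (!length(layout$sequences)) stop("empty layout")
  res <- cpp_consensus(layout$sequences, layout$qualities,
                       as.integer(layout$starts), params$quality_cap,
                       params$conflict_min_support, params$conflict_min_qual,
                       params$match, params$mismatch)
  list(consensus = res$consensus, per_base_error = res$per_base_error)
}

orient_reads <- function(reads, ori) {
  s <- reads$sequence
  q <- reads$quality
  flip <- ori == -1
  if (any(flip)) {
    s[flip] <- revcomp(s[flip])
    q[flip] <- vapply(q[flip], function(x)
      intToUtf8(rev(utf8ToInt(x))), character(1))
  }
  list(sequence = s, quality = q)
}

# One assembled layout: reads (data.frame rows), ori, start, consensus, err
finish_layout <- function(reads, ori, starts, params) {
  o <- orient_reads(reads, ori)
  res <- cpp_consensus(o$sequence, o$quality, as.integer(starts),
                       params$quality_cap, params$conflict_min_support,
                       params$conflict_min_qual, params$match,
                       params$mismatch)
  list(reads = reads, ori = ori, starts = starts, oriented = o, cons = res)
}

# Split a layout at zero-coverage columns (arises only after evictions).
split_by_coverage <- function(lay) {
  cov <- lay$cons$coverage
  if (all(cov > 0)) return(list(lay))
  runs <- rle(cov > 0)
  ends <- cumsum(runs$lengths)
  starts_run <- ends - runs$lengths + 1
  segs <- which(runs$values)
  lens <- nchar(lay$oriented$sequence)
  out <- list()
  for (sg in segs) {
    lo <- starts_run[sg] - 1; hi <- ends[sg] # 0-based half-open
    inside <- lay$starts >= lo & (lay$starts + lens) <= hi
    if (!any(inside)) next
    out[[length(out) + 1]] <- list(reads = lay$reads[inside, , drop = FALSE],
                                   ori = lay$ori[inside],
                                   starts = lay$starts[inside] - lo)
  }
  out
}

# Seeded haplotype bipartition over linked conflict columns. Starting from
# the reads carrying the minority allele at the best-supported conflict
# column, the minority part greedily recruits reads that agree more with
# its emerging allele profile than with the consensus at shared conflict
# columns. Returns a logical vector (TRUE = minority part) or NULL when no
# proper split exists.
phase_bipartition <- function(fl) {
  confs <- fl$cons$conflict_pos
  alle <- fl$cons$alleles
  minor <- fl$cons$conflict_minor
  consb <- match(strsplit(fl$cons$consensus, "")[[1]],
                 c("A", "C", "G", "T")) - 1L
  consb <- consb[confs + 1L]
  support <- vapply(seq_along(confs), function(ci)
    sum(alle[, ci] == minor[ci]), integer(1))
  c0 <- which.max(support)
  B <- alle[, c0] == minor[c0]
  if (!any(B) || all(B)) return(NULL)
  repeat {
    bcons <- vapply(seq_along(confs), function(ci) {
      v <- alle[B, ci]
      v <- v[v >= 0]
      if (!length(v)) return(-1L)
      which.max(tabulate(v + 1L, 5L)) - 1L
    }, integer(1))
    changed <- FALSE
    for (r in which(!B)) {
      cols <- which(alle[r, ] >= 0 & bcons >= 0 & bcons != consb)
      if (!length(cols)) next
      agree_b <- sum(alle[r, cols] == bcons[cols])
      agree_c <- sum(alle[r, cols] == consb[cols])
      if (agree_b > agree_c) { B[r] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  if (all(B)) return(NULL)
  B
}

# Recursive assembly of a read subset; returns list of finished layouts.
assemble_set <- function(reads, params, passes) {
  n <- nrow(reads)
  if (n == 0) return(list())
  if (n == 1) {
    return(list(finish_layout(reads, 1L, 0L, params)))
  }
  ov <- compute_overlaps(reads, params)
  mate <- match(reads$mate_id, reads$read_id)
  mate[is.na(mate)] <- 0L
  lay <- cpp_greedy_layout(n, nchar(reads$sequence), ov$i, ov$j, ov$s,
                           ov$offset, seq_len(nrow(ov)), mate,
                           params$insert_min, params$insert_max,
                           any(mate > 0))
  results <- list()
  for (root in unique(lay$root)) {
    idx <- which(lay$root == root)
    queue <- list(list(reads = reads[idx, , drop = FALSE],
                       ori = lay$ori[idx],
                       starts = lay$start[idx] - min(lay$start[idx])))
    while (length(queue)) {
      item <- queue[[1]]; queue <- queue[-1]
      if (nrow(item$reads) == 1) {
        results[[length(results) + 1]] <-
          finish_layout(item$reads, 1L, 0L, params)
        next
      }
      fl <- finish_layout(item$reads, item$ori, item$starts, params)
      pieces <- split_by_coverage(fl)
      if (length(pieces) > 1 ||
          (length(pieces) == 1 && nrow(pieces[[1]]$reads) < nrow(fl$reads))) {
        queue <- c(queue, pieces)
        next
      }
      # conflict rounds come first: a merged-homoeolog layout must be
      # phased apart, not eroded read by read
      if (passes > 0 && length(fl$cons$conflict_pos) > 0) {
        partB <- phase_bipartition(fl)
        if (!is.null(partB)) {
          results <- c(results,
                       assemble_set(fl$reads[!partB, , drop = FALSE],
                                    params, passes - 1),
                       assemble_set(fl$reads[partB, , drop = FALSE],
                                    params, passes - 1))
          next
        }
      }
      # eviction: reads that no longer realign to the consensus (typically
      # indel-bearing) drop out as singletons and the rest is re-examined
      bad <- which(fl$cons$read_rs < params$min_relative_score)
      if (length(bad) && length(bad) < nrow(fl$reads)) {
        for (b in bad)
          results[[length(results) + 1]] <-
            finish_layout(fl$reads[b, , drop = FALSE], 1L, 0L, params)
        keep <- setdiff(seq_len(nrow(fl$reads)), bad)
        queue <- c(queue,
                   list(list(reads = fl$reads[keep, , drop = FALSE],
                             ori = fl$ori[keep],
                             starts = fl$starts[keep] -
                               min(fl$starts[keep]))))
        next
      }
      results[[length(results) + 1]] <- fl
    }
  }
  results
}

#' Assemble one read cluster
#'
#' Greedy layout (best overlaps merged first, with consistent-placement
#' checks and advisory pair-insert bounds), quality-weighted consensus,
#' post-consensus eviction of reads that no longer realign at
#' `min_relative_score`, and up to `max_passes` conflict rounds in which
#' reads are bipartitioned by their alleles at well-supported conflict
#' columns and re-assembled. Unplaced reads become singleton layouts
#' (subject to the final filters). Deterministic given the read set;
#' invariant to input read order.
#'
#' @param reads a `read_set`.
#' @param params an [asm_params()].
#' @param cluster_id integer used in the `C{cluster}_{index}` contig names.
#' @return a `contig_set` data.frame: name, consensus, length, mean_error,
#'   n_reads, plus list columns `per_base_error` and `members`
#'   (data.frame read_id/start/ori per contig).
#' @export
assemble_cluster <- function(reads, params = asm_params(), cluster_id = 0) {
  stopifnot(nrow(reads) >= 1)
  reads <- reads[order(reads$read_id), , drop = FALSE]
  layouts <- assemble_set(reads, params, params$max_passes)
  if (!length(layouts)) return(empty_contig_set())
  key <- vapply(layouts, function(l) min(l$reads$read_id), character(1))
  layouts <- layouts[order(key)]
  rows <- lapply(seq_along(layouts), function(i) {
    l <- layouts[[i]]
    data.frame(name = sprintf("C%s_%d", cluster_id, i),
               consensus = l$cons$consensus,
               length = nchar(l$cons$consensus),
               mean_error = mean(l$cons$per_base_error),
               n_reads = nrow(l$reads), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$per_base_error <- lapply(layouts, function(l) l$cons$per_base_error)
  out$members <- lapply(layouts, function(l)
    data.frame(read_id = l$reads$read_id, start = l$starts, ori = l$ori,
               stringsAsFactors = FALSE))
  class(out) <- c("contig_set", "data.frame")
  out
}

empty_contig_set <- function() {
  out <- data.frame(name = character(), consensus = character(),
                    length = integer(), mean_error = numeric(),
                    n_reads = integer(), stringsAsFactors = FALSE)
  out$per_base_error <- list()
  out$members <- list()
  class(out) <- c("contig_set", "data.frame")
  out
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs, total %d bases, longest %s\n",
              nrow(x), sum(x$length),
              if (nrow(x)) max(x$length) else 0))
  invisible(x)
}

#' Filter contigs on length and consensus quality
#'
#' Keeps contigs strictly longer than `min_contig_length` with mean
#' per-base error strictly below `max_mean_error`.
#'
#' @param contigs a `contig_set`.
#' @param params an [asm_params()].
#' @return the filtered `contig_set`.
#' @export
filter_contigs <- function(contigs, params = asm_params()) {
  keep <- contigs$length > params$min_contig_length &
    contigs$mean_error < params$max_mean_error &
    contigs$n_reads >= params$min_reads
  out <- contigs[keep, , drop = FALSE]
  class(out) <- c("contig_set", "data.frame")
  out
}
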
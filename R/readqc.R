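# Read quality trimming and filtering. Rule order is fixed:
# adapter -> run-trim (a) -> median filter (b) -> length filter (c),
# so each later rule sees the final retained bases. "Trimmed back" is
# truncation at the start of the first offending run, scanning 5'->3'.

#' QC parameters
#'
#' @param max_run maximum tolerated run length of ambiguous or low-quality
#'   bases; a run of *more than* `max_run` such bases triggers truncation.
#' @param min_phred per-base PHRED threshold defining a low-quality base.
#' @param min_median_phred minimum median PHRED of the retained read.
#' @param min_length minimum retained read length (bases).
#' @param adapter optional adapter to trim from read 3' ends.
#' @param adapter_max_mismatch mismatches tolerated in the adapter match.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(max_run = 3, min_phred = 20, min_median_phred = 20,
                      min_length = 50, adapter = NULL,
                      adapter_max_mismatch = 2) {
  if (any(c(max_run, min_phred, min_median_phred, min_length) <= 0))
    stop("all thresholds must be positive")
  structure(list(max_run = as.integer(max_run),
                 min_phred = as.integer(min_phred),
                 min_median_phred = as.integer(min_median_phred),
                 min_length = as.integer(min_length), adapter = adapter,
                 adapter_max_mismatch = as.integer(adapter_max_mismatch)),
            class = "qc_params")
}

# 0-based cut position (retained length) applying rule (a) to one read;
# Inf-like len when no offending run. Ambiguous = any non-ACGT symbol.
run_trim_pos <- function(sequence, quality, params) {
  len <- nchar(sequence)
  pat_n <- sprintf("[^ACGTacgt]{%d,}", params$max_run + 1L)
  pos_n <- regexpr(pat_n, sequence)
  # PHRED+33: q < min_phred <=> ASCII in [33, 32 + min_phred]
  hi <- 32L + params$min_phred
  pat_q <- sprintf("[\\x21-\\x%02x]{%d,}", hi, params$max_run + 1L)
  pos_q <- regexpr(pat_q, quality, perl = TRUE)
  cuts <- c(if (pos_n > 0) pos_n - 1L, if (pos_q > 0) pos_q - 1L)
  if (length(cuts)) min(cuts) else len
}

#' Trim and filter a single read
#'
#' Applies, in order: (a) truncation immediately before the first run of
#' more than `max_run` consecutive ambiguous bases or more than `max_run`
#' consecutive bases with quality below `min_phred`; (b) discard if the
#' median quality of the retained bases is below `min_median_phred`;
#' (c) discard if the retained length is below `min_length`.
#'
#' @param read one-row `read_set` (or list with `sequence` and `quality`).
#' @param params a [qc_params()].
#' @return list with `verdict` (`"kept"`, `"median"`, or `"length"`),
#'   `sequence`, `quality` and `trimmed` (logical).
#' @export
trim_and_filter_read <- function(read, params = qc_params()) {
  s <- read$sequence; q <- read$quality
  if (is.na(s) || nchar(s) == 0)
    return(list(verdict = "length", sequence = "", quality = "",
                trimmed = FALSE))
  cut <- run_trim_pos(s, q, params)
  trimmed <- cut < nchar(s)
  if (trimmed) {
    s <- substr(s, 1L, cut)
    q <- substr(q, 1L, cut)
  }
  if (nchar(s) == 0)
    return(list(verdict = "length", sequence = s, quality = q,
                trimmed = trimmed))
  med <- median(utf8ToInt(q) - 33L)
  if (med < params$min_median_phred)
    return(list(verdict = "median", sequence = s, quality = q,
                trimmed = trimmed))
  if (nchar(s) < params$min_length)
    return(list(verdict = "length", sequence = s, quality = q,
                trimmed = trimmed))
  list(verdict = "kept", sequence = s, quality = q, trimmed = trimmed)
}

#' Trim an adapter from the 3' end of a read
#'
#' Removes the longest read suffix matching a prefix of the adapter with at
#' most `adapter_max_mismatch` mismatches (minimum match 8 bases; at most
#' one mismatch is tolerated per 10 matched bases, so short chance matches
#' never trigger trimming); qualities are trimmed in lockstep. Reads
#' without a qualifying match are returned unchanged.
#'
#' @param read one-row `read_set` (or list with `sequence` and `quality`).
#' @param params a [qc_params()] with a configured `adapter`.
#' @return list with `sequence` and `quality`.
#' @export
trim_adapter <- function(read, params) {
  if (is.null(params$adapter)) stop("no adapter configured")
  s <- read$sequence; q <- read$quality
  repeat { # to a fixed point, so adapter dimers are fully removed
    keep <- cpp_trim_adapter(s, params$adapter,
                             params$adapter_max_mismatch, 8L)
    if (all(keep == nchar(s))) break
    s <- substr(s, 1L, keep)
    q <- substr(q, 1L, keep)
  }
  list(sequence = s, quality = q)
}

#' QC a full read set
#'
#' Applies adapter trimming (when configured) then [trim_and_filter_read()]
#' to every read. When one mate of a pair is discarded, the surviving mate
#' is demoted to a single (its `mate_id` cleared).
#'
#' @param reads a `read_set`; paired reads must carry symmetric mate links.
#' @param params a [qc_params()].
#' @return list with `reads` (kept `read_set`) and `summary`
#'   (a `qc_summary`).
#' @export
qc_readset <- function(reads, params = qc_params()) {
  n_input <- nrow(reads)
  if (n_input) {
    m <- reads$mate_id
    linked <- !is.na(m)
    back <- reads$mate_id[match(m[linked], reads$read_id)]
    if (any(is.na(back)) || any(back != reads$read_id[linked]))
      stop("asymmetric mate link at read ",
           reads$read_id[linked][which(is.na(back) | back != reads$read_id[linked])[1]])
  }
  if (n_input == 0) {
    summary <- new_qc_summary(0, 0, 0, 0, 0, 0, 0)
    return(list(reads = reads, summary = summary))
  }
  # adapter trimming and run-truncation are iterated to a joint fixed
  # point (truncating at a bad run can expose a fresh adapter suffix, and
  # vice versa) so the median/length rules see the final retained bases
  lens0 <- nchar(reads$sequence)
  repeat {
    before <- nchar(reads$sequence)
    if (!is.null(params$adapter)) {
      res <- trim_adapter(reads, params)
      reads$sequence <- res$sequence
      reads$quality <- res$quality
    }
    cuts <- vapply(seq_len(n_input), function(i)
      run_trim_pos(reads$sequence[i], reads$quality[i], params), numeric(1))
    reads$sequence <- substr(reads$sequence, 1L, cuts)
    reads$quality <- substr(reads$quality, 1L, cuts)
    if (all(nchar(reads$sequence) == before)) break
  }
  trimmed <- nchar(reads$sequence) < lens0
  verdicts <- character(n_input)
  for (i in seq_len(n_input)) {
    res <- trim_and_filter_read(reads[i, ], params)
    verdicts[i] <- res$verdict
    reads$sequence[i] <- res$sequence
    reads$quality[i] <- res$quality
  }
  kept <- verdicts == "kept"
  out <- reads[kept, , drop = FALSE]
  # demote widowed mates to singles
  lost <- !is.na(out$mate_id) & !(out$mate_id %in% out$read_id)
  out$mate_id[lost] <- NA_character_
  n_pairs_kept <- sum(!is.na(out$mate_id)) / 2
  n_singles_kept <- sum(is.na(out$mate_id))
  summary <- new_qc_summary(n_input = n_input, n_kept = nrow(out),
                            n_discarded_median = sum(verdicts == "median"),
                            n_discarded_length = sum(verdicts == "length"),
                            n_trimmed = sum(trimmed & kept),
                            n_pairs_kept = n_pairs_kept,
                            n_singles_kept = n_singles_kept)
  list(reads = new_read_set(out), summary = summary)
}

new_qc_summary <- function(n_input, n_kept, n_discarded_median,
                           n_discarded_length, n_trimmed, n_pairs_kept,
                           n_singles_kept) {
  structure(list(n_input = n_input, n_kept = n_kept,
                 n_discarded_median = n_discarded_median,
                 n_discarded_length = n_discarded_length,
                 n_trimmed = n_trimmed, n_pairs_kept = n_pairs_kept,
                 n_singles_kept = n_singles_kept),
            class = "qc_summary")
}

#' Build a QC summary from counts
#'
#' Useful for read accounting over externally produced counts (e.g. the
#' pairs/singles bookkeeping of a sequencing run).
#'
#' @param n_pairs_kept,n_singles_kept kept pair and single counts.
#' @param n_input total input reads (defaults to all kept).
#' @param n_discarded_median,n_discarded_length,n_trimmed discard/trim counts.
#' @return a `qc_summary`.
#' @export
qc_summary <- function(n_pairs_kept, n_singles_kept,
                       n_input = 2 * n_pairs_kept + n_singles_kept,
                       n_discarded_median = 0, n_discarded_length = 0,
                       n_trimmed = 0) {
  new_qc_summary(n_input, 2 * n_pairs_kept + n_singles_kept,
                 n_discarded_median, n_discarded_length, n_trimmed,
                 n_pairs_kept, n_singles_kept)
}

#' Total kept reads implied by a QC summary
#'
#' `2 * n_pairs_kept + n_singles_kept`.
#'
#' @param summary a `qc_summary`.
#' @return integer-valued numeric.
#' @export
qc_total_reads <- function(summary) {
  2 * summary$n_pairs_kept + summary$n_singles_kept
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(paste0("<qc_summary> input %s, kept %s ",
                     "(%s pairs + %s singles), trimmed %s, ",
                     "discarded median %s / length %s\n"),
              format(x$n_input, big.mark = ","),
              format(x$n_kept, big.mark = ","),
              format(x$n_pairs_kept, big.mark = ","),
              format(x$n_singles_kept, big.mark = ","),
              format(x$n_trimmed, big.mark = ","),
              format(x$n_discarded_median, big.mark = ","),
              format(x$n_discarded_length, big.mark = ",")))
  invisible(x)
}

#' Write a QC summary as TSV
#' @param summary a `qc_summary`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(summary, path) {
  write.table(as.data.frame(unclass(summary)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
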
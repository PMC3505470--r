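# Small shared helpers. All interval fields in this package are 0-based,
# half-open; strand is "+"/"-".

#' Reverse-complement character sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(x)
}

phred_to_int <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(pmin(pmax(v, 0L), 60L) + 33L), character(1))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_read_set <- function(df) {
  needed <- c("read_id", "sequence", "quality", "platform", "mate_id",
              "family_id", "genome_label", "start", "end", "strand")
  for (col in setdiff(needed, names(df))) df[[col]] <- NA
  df <- df[, needed]
  rownames(df) <- NULL
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads (%d long, %d short)\n", nrow(x),
              sum(x$platform == "long"), sum(x$platform == "short")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}
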
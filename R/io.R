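# File interfaces. FASTA/FASTQ through Biostrings; truth tables and reports
# as TSV. Reference family FASTA headers follow the `family|genome`
# convention (genome in A/B/D).

#' Write family transcripts as FASTA
#'
#' Headers follow the `family|genome` convention.
#'
#' @param families a [generate_families()] result.
#' @param path output FASTA path.
#' @param which `"reference"` (evaluation set) or `"cultivar"` (the copies
#'   reads were sequenced from; identical unless a cultivar SNP layer was
#'   configured).
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(families, path, which = "reference") {
  tx <- families$transcripts
  seqs <- if (which == "cultivar") tx$cultivar else tx$sequence
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- tx$seq_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read reference homoeolog families from FASTA
#'
#' Headers must follow `family|genome`.
#'
#' @param path FASTA file.
#' @return data.frame with seq_id, family_id, genome_label, sequence, length.
#' @export
read_families_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("FASTA headers must follow 'family|genome': ", ids[bad][1])
  data.frame(seq_id = ids,
             family_id = vapply(parts, `[`, character(1), 1),
             genome_label = vapply(parts, `[`, character(1), 2),
             sequence = as.character(x), length = Biostrings::width(x),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' Unpaired reads go to `<prefix>.fastq`; paired reads to synchronized
#' `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#'
#' @param reads a `read_set`.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_reads_fastq <- function(reads, prefix) {
  written <- character()
  emit <- function(df, path) {
    x <- Biostrings::DNAStringSet(df$sequence)
    names(x) <- df$read_id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(df$quality))
    path
  }
  # reads whose mate is not part of this set are written as unpaired
  widow <- !is.na(reads$mate_id) & !(reads$mate_id %in% reads$read_id)
  reads$mate_id[widow] <- NA_character_
  unpaired <- reads[is.na(reads$mate_id), , drop = FALSE]
  paired <- reads[!is.na(reads$mate_id), , drop = FALSE]
  if (nrow(unpaired))
    written <- c(written, emit(unpaired, paste0(prefix, ".fastq")))
  if (nrow(paired)) {
    m1 <- paired[endsWith(paired$read_id, "_1"), , drop = FALSE]
    m2 <- paired[match(m1$mate_id, paired$read_id), , drop = FALSE]
    written <- c(written, emit(m1, paste0(prefix, "_1.fastq")),
                 emit(m2, paste0(prefix, "_2.fastq")))
  }
  invisible(written)
}

#' Read FASTQ files into a read set
#'
#' @param single optional FASTQ of unpaired (long) reads.
#' @param mate1,mate2 optional synchronized paired FASTQ files.
#' @return a `read_set` (truth columns `NA`); mate links are rebuilt from
#'   file synchronization.
#' @export
read_reads_fastq <- function(single = NULL, mate1 = NULL, mate2 = NULL) {
  load1 <- function(path, platform, mate_ids = NA_character_) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quals <- as.character(S4Vectors::mcols(x)$qualities)
    S4Vectors::mcols(x) <- NULL
    new_read_set(data.frame(read_id = sub("\\s.*$", "", names(x)),
                            sequence = as.character(x),
                            quality = quals,
                            platform = platform, mate_id = mate_ids,
                            stringsAsFactors = FALSE))
  }
  out <- list()
  if (!is.null(single)) out <- c(out, list(load1(single, "long")))
  if (!is.null(mate1) != !is.null(mate2))
    stop("mate1 and mate2 must be given together")
  if (!is.null(mate1)) {
    r1 <- load1(mate1, "short")
    r2 <- load1(mate2, "short")
    if (nrow(r1) != nrow(r2))
      stop("mismatched pair files: ", basename(mate1), " vs ", basename(mate2))
    r1$mate_id <- r2$read_id
    r2$mate_id <- r1$read_id
    out <- c(out, list(r1, r2))
  }
  if (!length(out)) stop("no input files given")
  new_read_set(do.call(rbind, out))
}

#' Write the read truth table as TSV
#'
#' Columns: read_id, family_id, genome_label, start, end, strand
#' (0-based half-open coordinates on the sequenced copy).
#'
#' @param reads a `read_set` with truth columns.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  write.table(reads[, c("read_id", "family_id", "genome_label",
                        "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write contigs as FASTA plus a TSV sidecar
#'
#' @param contigs a `contig_set`.
#' @param fasta_path,tsv_path output paths (either may be `NULL`).
#' @param members_path optional TSV of per-contig member read placements
#'   (contig, read_id, start, ori).
#' @return invisibly, the paths written.
#' @export
write_contigs <- function(contigs, fasta_path, tsv_path = NULL,
                          members_path = NULL) {
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(contigs$consensus)
    names(x) <- contigs$name
    Biostrings::writeXStringSet(x, fasta_path)
  }
  if (!is.null(tsv_path)) {
    write.table(data.frame(name = contigs$name, length = contigs$length,
                           mean_error = contigs$mean_error,
                           n_reads = contigs$n_reads),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(members_path)) {
    mem <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i)
      cbind(contig = contigs$name[i], contigs$members[[i]])))
    write.table(mem, members_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(fasta_path, tsv_path, members_path))
}
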
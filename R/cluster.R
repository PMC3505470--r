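# Transitive clustering of rough contigs by shared canonical 32-mers and
# read-to-cluster assignment. "Common subsequence of at least 32 bases" is
# implemented as ">= 1 shared exact canonical 32-mer": a contiguous shared
# 32-base substring is exactly a shared 32-mer, and canonicalization
# (lexicographic min of a word and its reverse complement) handles the
# unknown strand of rough contigs.

#' Cluster contigs by shared canonical k-mers
#'
#' Two contigs sharing at least one canonical k-mer land in the same
#' cluster; closure is transitive (union-find). Contigs shorter than `k`
#' form singletons. Cluster numbering is deterministic: clusters are
#' ordered by their smallest member contig id.
#'
#' @param contigs named character vector of contig sequences.
#' @param k word size (default 32).
#' @return object of class `cluster_partition`: list with `clusters`
#'   (named list: cluster id -> character vector of contig ids) and
#'   `membership` (named character: contig id -> cluster id).
#' @export
cluster_contigs <- function(contigs, k = 32) {
  if (length(contigs) < 1) stop("need at least one contig")
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%05d", seq_along(contigs))
  short <- nchar(contigs) < k
  if (any(short))
    message(sum(short), " contig(s) shorter than k form singleton clusters")
  comp <- cpp_kmer_components(unname(contigs), as.integer(k))
  ids <- names(contigs)
  groups <- split(ids, comp)
  # deterministic numbering by smallest member contig id
  mins <- vapply(groups, function(g) min(g), character(1))
  groups <- groups[order(mins)]
  names(groups) <- sprintf("CL%05d", seq_along(groups))
  membership <- setNames(rep(names(groups), lengths(groups)),
                         unlist(groups, use.names = FALSE))
  membership <- membership[ids]
  structure(list(clusters = groups, membership = membership, k = k),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d contigs in %d clusters (k = %d)\n",
              length(x$membership), length(x$clusters), x$k))
  invisible(x)
}

#' Assign reads to clusters by shared canonical k-mers
#'
#' A read joins every cluster with which it shares at least one canonical
#' k-mer (via any member contig); reads sharing none remain unassigned.
#'
#' @param reads a `read_set` or named character vector of read sequences.
#' @param contigs the named contig sequences the partition was built over.
#' @param partition a [cluster_contigs()] result over `contigs`.
#' @param k word size (must match the partition).
#' @return object of class `read_assignment`: named list read_id ->
#'   character vector of cluster ids (possibly empty, possibly > 1).
#' @export
assign_reads <- function(reads, contigs, partition, k = 32) {
  if (k != partition$k) stop("k must match the partition")
  if (!setequal(names(contigs), names(partition$membership)))
    stop("partition was built over a different contig set")
  seqs <- if (inherits(reads, "read_set")) reads$sequence else unname(reads)
  ids <- if (inherits(reads, "read_set")) reads$read_id else
    (names(reads) %||% sprintf("read%06d", seq_along(reads)))
  hits <- cpp_kmer_assign(seqs, unname(contigs), as.integer(k))
  memb <- partition$membership[names(contigs)]
  out <- lapply(hits, function(ix) sort(unique(unname(memb[ix]))))
  names(out) <- ids
  structure(out, class = "read_assignment")
}

#' Per-cluster read counts and cumulative curve
#'
#' @param assignment a [assign_reads()] result.
#' @return list with `per_cluster` (data.frame: cluster_id, n_reads,
#'   cumulative_fraction — ordered by descending cluster size) and
#'   `assigned_fraction` (fraction of reads assigned to >= 1 cluster;
#'   multi-assigned reads count once).
#' @export
cluster_stats <- function(assignment) {
  n_reads <- length(assignment)
  assigned <- lengths(assignment) > 0
  tab <- table(unlist(assignment, use.names = FALSE))
  if (length(tab) == 0) {
    per <- data.frame(cluster_id = character(), n_reads = integer(),
                      cumulative_fraction = numeric())
  } else {
    per <- data.frame(cluster_id = names(tab), n_reads = as.integer(tab),
                      stringsAsFactors = FALSE)
    per <- per[order(-per$n_reads, per$cluster_id), , drop = FALSE]
    per$cumulative_fraction <- cumsum(per$n_reads) / sum(per$n_reads)
    rownames(per) <- NULL
  }
  list(per_cluster = per,
       assigned_fraction = if (n_reads) mean(assigned) else NA_real_)
}

#' Write a partition and read assignment as TSV
#'
#' @param partition a `cluster_partition` (or `NULL`).
#' @param assignment a `read_assignment` (or `NULL`); multi-cluster
#'   assignments are comma-joined.
#' @param partition_path,assignment_path output paths.
#' @return invisibly, the paths written.
#' @export
write_cluster_tsv <- function(partition = NULL, assignment = NULL,
                              partition_path = NULL, assignment_path = NULL) {
  if (!is.null(partition) && !is.null(partition_path))
    write.table(data.frame(contig_id = names(partition$membership),
                           cluster_id = unname(partition$membership)),
                partition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(assignment) && !is.null(assignment_path))
    write.table(data.frame(read_id = names(assignment),
                           cluster_ids = vapply(assignment, paste,
                                                character(1), collapse = ",")),
                assignment_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(partition_path, assignment_path))
}

#' Write per-cluster FASTQ files for stage-2 assembly
#'
#' Emits one FASTQ (or pair of synchronized FASTQ files) per cluster under
#' `dir`, duplicating multi-assigned reads into every cluster they belong
#' to.
#'
#' @param reads the `read_set` the assignment was computed over.
#' @param assignment a [assign_reads()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the cluster ids written.
#' @export
write_cluster_fastq <- function(reads, assignment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_cluster <- split(rep(names(assignment), lengths(assignment)),
                      unlist(assignment, use.names = FALSE))
  for (cl in names(by_cluster)) {
    sub <- reads[reads$read_id %in% by_cluster[[cl]], , drop = FALSE]
    write_reads_fastq(sub, file.path(dir, cl))
  }
  invisible(names(by_cluster))
}
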
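# Two-stage assembly orchestration: QC -> permissive rough assembly ->
# 32-mer transitive clustering -> per-cluster strict assembly -> filtering,
# containment deduplication and reports. Stage-1 contigs are used only to
# group reads and are then discarded. Cluster results are independent of
# the order in which clusters are processed (the parallelism contract).

#' Pipeline configuration
#'
#' @param qc a [qc_params()].
#' @param stage1 permissive [asm_params()] for the rough assembly.
#' @param stage2 strict [asm_params()] for per-cluster assembly; its
#'   `min_relative_score` must exceed stage 1's.
#' @param cluster_k word size for transitive clustering (default 32).
#' @param cluster_read_cap clusters with more reads are subsampled (with
#'   warning) before stage-2 assembly.
#' @param seed integer seed (used only for such subsampling).
#' @param outdir optional output directory; when set, FASTA/TSV artifacts
#'   are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_params(),
                            stage1 = asm_params("permissive"),
                            stage2 = asm_params("strict"),
                            cluster_k = 32, cluster_read_cap = 20000,
                            seed = 1, outdir = NULL) {
  if (stage1$min_relative_score >= stage2$min_relative_score)
    stop("stage1 min_relative_score must be below stage2's")
  structure(list(qc = qc, stage1 = stage1, stage2 = stage2,
                 cluster_k = as.integer(cluster_k),
                 cluster_read_cap = as.integer(cluster_read_cap),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the two-stage homoeolog-specific assembly
#'
#' Reads are QC'd, rough-assembled permissively, and the rough contigs are
#' transitively clustered by shared canonical 32-mers; reads are assigned
#' to clusters by the same criterion (multi-assigned reads join every
#' matching cluster) and each cluster is strictly re-assembled. Final
#' contigs are filtered (length and mean error), deduplicated (a contig
#' 100% contained in another contig that shares a member read is dropped)
#' and named `C{cluster}_{index}`. The output is identical regardless of
#' cluster processing order.
#'
#' @param reads a `read_set` (or FASTQ paths via [read_reads_fastq()]
#'   upstream).
#' @param config a [pipeline_config()].
#' @param .cluster_order optional permutation of cluster ids (verification
#'   hook for the order-independence contract).
#' @return object of class `homoeoasm_run`: list with `contigs`
#'   (filtered `contig_set`), `qc_summary`, `partition`, `assignment`,
#'   `cluster_stats`, `n_stage1_contigs` and `unassigned_reads`.
#' @export
run_two_stage <- function(reads, config = pipeline_config(),
                          .cluster_order = NULL) {
  t0 <- Sys.time()
  qc <- qc_readset(reads, config$qc)
  if (nrow(qc$reads) == 0) stop("no reads survive QC")
  log_stage("qc", t0)
  # stage 1: permissive rough assembly, contigs used only for clustering
  t1 <- Sys.time()
  rough <- assemble_cluster(qc$reads, config$stage1, cluster_id = "rough")
  rough <- rough[rough$length >= config$cluster_k, , drop = FALSE]
  log_stage("stage1", t1)
  t2 <- Sys.time()
  rough_seqs <- setNames(rough$consensus, rough$name)
  partition <- cluster_contigs(rough_seqs, config$cluster_k)
  assignment <- assign_reads(qc$reads, rough_seqs, partition,
                             config$cluster_k)
  cstats <- cluster_stats(assignment)
  log_stage("cluster", t2)
  # stage 2: strict per-cluster assembly (order-independent)
  t3 <- Sys.time()
  cluster_ids <- names(partition$clusters)
  if (!is.null(.cluster_order)) cluster_ids <- .cluster_order
  by_cluster <- split(rep(names(assignment), lengths(assignment)),
                      unlist(assignment, use.names = FALSE))
  pieces <- list()
  for (cl in cluster_ids) {
    rids <- by_cluster[[cl]]
    if (is.null(rids) || !length(rids)) next
    sub <- qc$reads[qc$reads$read_id %in% rids, , drop = FALSE]
    if (nrow(sub) > config$cluster_read_cap) {
      warning(sprintf("cluster %s subsampled from %d to %d reads", cl,
                      nrow(sub), config$cluster_read_cap))
      set.seed(config$seed + match(cl, names(partition$clusters)))
      sub <- sub[sort(sample.int(nrow(sub), config$cluster_read_cap)), ,
                 drop = FALSE]
    }
    cl_num <- sub("^CL0*", "", cl)
    pieces[[cl]] <- assemble_cluster(sub, config$stage2, cluster_id = cl_num)
  }
  pieces <- pieces[order(names(pieces))] # order-independence of output
  contigs <- if (length(pieces)) do.call(rbind, unname(pieces)) else
    empty_contig_set()
  class(contigs) <- c("contig_set", "data.frame")
  contigs <- filter_contigs(contigs, config$stage2)
  contigs <- dedup_contained(contigs)
  log_stage("stage2", t3)
  run <- structure(list(contigs = contigs, qc_summary = qc$summary,
                        partition = partition, assignment = assignment,
                        cluster_stats = cstats,
                        n_stage1_contigs = nrow(rough),
                        unassigned_reads = names(assignment)[
                          lengths(assignment) == 0]),
                   class = "homoeoasm_run")
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

log_stage <- function(stage, t_start) {
  message(sprintf("[%s] %.1fs", stage,
                  as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
}

# Drop contigs whose consensus is fully contained in another contig that
# shares a (multi-assigned) member read; containment on either strand.
dedup_contained <- function(contigs) {
  n <- nrow(contigs)
  if (n < 2) return(contigs)
  member_sets <- lapply(contigs$members, function(m) m$read_id)
  drop <- logical(n)
  ord <- order(-contigs$length, contigs$name)
  for (ai in seq_len(n - 1)) {
    for (bi in seq((ai + 1), n)) {
      a <- ord[ai]; b <- ord[bi] # length(a) >= length(b)
      if (drop[a] || drop[b]) next
      if (!length(intersect(member_sets[[a]], member_sets[[b]]))) next
      if (grepl(contigs$consensus[b], contigs$consensus[a], fixed = TRUE) ||
          grepl(revcomp(contigs$consensus[b]), contigs$consensus[a],
                fixed = TRUE))
        drop[b] <- TRUE
    }
  }
  out <- contigs[!drop, , drop = FALSE]
  class(out) <- c("contig_set", "data.frame")
  out
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_contigs(run$contigs, file.path(outdir, "contigs.fasta"),
                file.path(outdir, "contigs.tsv"))
  write_qc_summary(run$qc_summary, file.path(outdir, "qc_summary.tsv"))
  write_cluster_tsv(run$partition, run$assignment,
                    file.path(outdir, "clusters.tsv"),
                    file.path(outdir, "assignments.tsv"))
  invisible(outdir)
}

#' @export
print.homoeoasm_run <- function(x, ...) {
  cat("<homoeoasm_run>\n  ")
  print(x$qc_summary)
  cat(sprintf("  %d clusters; %.1f%% of reads assigned\n",
              length(x$partition$clusters),
              100 * x$cluster_stats$assigned_fraction))
  cat("  ")
  print(x$contigs)
  invisible(x)
}

#' Summary report of an assembly run
#'
#' Collects read accounting, cluster statistics and the contig length
#' distribution; when a reference family set is supplied, adds benchmark
#' metrics, the chimera rate, the identity histogram with its homoeolog
#' peak estimate, the implied SNP statistics and a coverage profile.
#'
#' @param run a `homoeoasm_run` object, or a directory written by
#'   [run_two_stage()] (artifacts are re-read from TSV/FASTA).
#' @param references optional `homoeolog_families` or
#'   [read_families_fasta()] data.frame.
#' @return list of class `homoeoasm_report`; printing it renders the
#'   summary.
#' @export
report <- function(run, references = NULL) {
  if (is.character(run)) run <- read_run(run)
  qs <- run$qc_summary
  contigs <- run$contigs
  lens <- sort(contigs$length, decreasing = TRUE)
  out <- list(
    qc = qs,
    total_kept_reads = qc_total_reads(qs),
    n_clusters = length(run$partition$clusters),
    assigned_fraction = run$cluster_stats$assigned_fraction,
    n_contigs = nrow(contigs),
    n_contigs_over_1kb = sum(contigs$length > 1000),
    longest_contig = if (nrow(contigs)) max(contigs$length) else 0L,
    length_distribution = data.frame(
      rank = seq_along(lens), length = lens,
      cumulative_fraction = if (length(lens))
        cumsum(as.numeric(lens)) / sum(as.numeric(lens)) else numeric()))
  if (!is.null(references)) {
    bm <- benchmark_assembly(contigs, references)
    out$benchmark <- bm
    out$chimera_rate_pct <- if (bm$n_assigned)
      chimera_rate(bm$n_chimeric, bm$n_assigned) else NA_real_
    ih <- tryCatch(identity_histogram(contigs), error = function(e) NULL)
    out$identity_peak <- ih$estimate
    if (!is.null(ih$estimate))
      out$snp_stats <- snp_stats(ih$estimate$mean_identity)
    out$coverage <- coverage_profile(references, contigs)
  }
  class(out) <- "homoeoasm_report"
  out
}

read_run <- function(dir) {
  need <- c("contigs.fasta", "contigs.tsv", "qc_summary.tsv",
            "clusters.tsv", "assignments.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing run artifact(s): ", paste(missing, collapse = ", "))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fasta"))
  meta <- read.delim(file.path(dir, "contigs.tsv"), stringsAsFactors = FALSE)
  contigs <- data.frame(name = sub("\\s.*$", "", names(fa)),
                        consensus = as.character(fa),
                        length = Biostrings::width(fa),
                        stringsAsFactors = FALSE)
  contigs$mean_error <- meta$mean_error[match(contigs$name, meta$name)]
  contigs$n_reads <- meta$n_reads[match(contigs$name, meta$name)]
  contigs$per_base_error <- rep(list(NULL), nrow(contigs))
  contigs$members <- rep(list(data.frame(read_id = character())),
                         nrow(contigs))
  class(contigs) <- c("contig_set", "data.frame")
  qs <- read.delim(file.path(dir, "qc_summary.tsv"))
  qsl <- as.list(qs)
  class(qsl) <- "qc_summary"
  cl <- read.delim(file.path(dir, "clusters.tsv"), stringsAsFactors = FALSE)
  asg <- read.delim(file.path(dir, "assignments.tsv"),
                    stringsAsFactors = FALSE)
  assignment <- lapply(strsplit(asg$cluster_ids, ",", fixed = TRUE),
                       function(x) x[nzchar(x)])
  names(assignment) <- asg$read_id
  class(assignment) <- "read_assignment"
  partition <- structure(list(clusters = split(cl$contig_id, cl$cluster_id),
                              membership = setNames(cl$cluster_id,
                                                    cl$contig_id), k = NA),
                         class = "cluster_partition")
  structure(list(contigs = contigs, qc_summary = qsl, partition = partition,
                 assignment = assignment,
                 cluster_stats = cluster_stats(assignment),
                 n_stage1_contigs = NA_integer_,
                 unassigned_reads = names(assignment)[
                   lengths(assignment) == 0]),
            class = "homoeoasm_run")
}

#' @export
print.homoeoasm_report <- function(x, ...) {
  cat("== assembly report ==\n")
  print(x$qc)
  cat(sprintf("total kept reads: %s\n",
              format(x$total_kept_reads, big.mark = ",")))
  cat(sprintf("clusters: %d; reads assigned: %.1f%%\n", x$n_clusters,
              100 * x$assigned_fraction))
  cat(sprintf("contigs: %d (%d over 1 kb; longest %d)\n", x$n_contigs,
              x$n_contigs_over_1kb, x$longest_contig))
  if (!is.null(x$benchmark)) {
    print(x$benchmark)
    cat(sprintf("chimera rate: %.1f%%\n", x$chimera_rate_pct))
    if (!is.null(x$identity_peak))
      cat(sprintf("homoeolog identity peak: %.1f%% (sd %.1f%%)\n",
                  x$identity_peak$mean_identity,
                  x$identity_peak$sd_identity))
    if (!is.null(x$snp_stats))
      cat(sprintf("implied per-sequence SNP rate: %.2f%% (1 SNP/%d bases)\n",
                  x$snp_stats$per_sequence_snp_freq,
                  x$snp_stats$per_sequence_spacing))
  }
  invisible(x)
}
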
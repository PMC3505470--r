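# Fixture builders shared across test files. All fixtures are generated in
# code under explicit seeds.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent substitution mutator (test-side oracle for divergence)
sub_mutate <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  list(seq = paste(ch, collapse = ""), pos = sort(pos))
}

qual_str <- function(q, len = length(q)) {
  if (length(q) == 1) q <- rep(q, len)
  intToUtf8(q + 33L)
}

mk_reads <- function(sequence, quality = NULL, read_id = NULL,
                     platform = "long", mate_id = NA_character_) {
  n <- length(sequence)
  if (is.null(quality))
    quality <- vapply(nchar(sequence), function(l) qual_str(40L, l),
                      character(1))
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  homoeoasm:::new_read_set(data.frame(
    read_id = read_id, sequence = sequence, quality = quality,
    platform = platform, mate_id = mate_id, stringsAsFactors = FALSE))
}

# error-free reads tiling a transcript (plus strand), constant quality
tile_reads <- function(transcript, read_len = 100, step = 40, q = 40) {
  L <- nchar(transcript)
  starts <- seq(1, max(1, L - read_len + 1), by = step)
  if (starts[length(starts)] + read_len - 1 < L)
    starts <- c(starts, L - read_len + 1)
  mk_reads(substring(transcript, starts, starts + read_len - 1), quality =
             rep(qual_str(q, read_len), length(starts)))
}

# Biostrings local-alignment oracle score under the package's default
# scoring (match 1, mismatch -2, gap open -3, gap extend -2; a gap of
# length L costs open + L*extend in both conventions).
oracle_local_score <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  fwd <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 3, gapExtension = 2)
  rev <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a),
    Biostrings::reverseComplement(Biostrings::DNAString(b)),
    type = "local", substitutionMatrix = sm,
    gapOpening = 3, gapExtension = 2)
  max(Biostrings::score(fwd), Biostrings::score(rev))
}

# brute-force shared-k-mer connected components via substring enumeration
# and igraph (independent of the package's union-find / bit-packed k-mers)
oracle_components <- function(seqs, k) {
  n <- length(seqs)
  revc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character())
    fw <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rv <- rev(substring(revc(s), 1:(nchar(s) - k + 1), k:nchar(s)))
    unique(pmin(fw, rv)) # canonical form (rv[i] = revcomp of fw[i])
  })
  edges <- matrix(integer(), ncol = 2)
  tab <- split(rep(seq_len(n), lengths(kmers)),
               unlist(kmers, use.names = FALSE))
  for (g in tab) {
    g <- unique(g)
    if (length(g) > 1)
      edges <- rbind(edges, cbind(g[1], g[-1]))
  }
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) gr <- igraph::add_edges(gr, t(edges))
  igraph::components(gr)$membership
}

# canonical form of a partition: sorted list of sorted member vectors
canonical_partition <- function(groups) {
  out <- lapply(groups, sort)
  out[order(vapply(out, `[`, character(1), 1))]
}
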
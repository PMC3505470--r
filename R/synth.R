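# Synthetic hexaploid transcriptome and read simulator. Families consist of
# an ancestral transcript plus 1-3 diverged genome copies (A/B/D); divergence
# is applied independently per copy from the shared ancestor, so the pairwise
# homoeolog identity is approximately 100 - 2 * per-copy rate.

#' Simulation configuration
#'
#' Parameters describing the synthetic polyploid transcriptome and the
#' sequencing platforms. Defaults mirror the statistics of the wheat study
#' this package emulates: homoeolog identity 97.2 +/- 1.8 percent, long
#' reads of mean length 363.2 bases, paired 108-base short reads with
#' 250-300 base inserts.
#'
#' @param n_families number of homoeologous families to simulate.
#' @param ploidy_mix named proportions of triplet/doublet/singlet families;
#'   must sum to 1.
#' @param transcript_meanlog,transcript_sdlog log-normal parameters of
#'   transcript length (bases).
#' @param transcript_min,transcript_max clamp for transcript lengths.
#' @param homoeolog_identity_mean,homoeolog_identity_sd mean and sd (percent)
#'   of the per-family target pairwise homoeolog identity; the mean must lie
#'   in (85, 100].
#' @param indel_fraction fraction of divergence variants realized as 1-base
#'   indels (the rest are substitutions). The default of 0 mirrors how
#'   homoeolog divergence is quantified in hexaploid wheat (as SNP
#'   frequencies); an indel layer can be enabled for robustness studies.
#' @param cultivar_snp_spacing optional bases-per-SNP spacing of an extra
#'   cultivar polymorphism layer applied to the sequenced (but not the
#'   reference) copies; `NA` disables the layer.
#' @param long_read_length_mean,long_read_length_sd normal model of long-read
#'   lengths (bases), clipped to `[50, transcript length]`.
#' @param short_read_length short-read length (bases).
#' @param insert_min,insert_max paired-end insert range (bases).
#' @param long_read_coverage,short_read_coverage fold coverage per genome
#'   copy for each platform (0 disables a platform).
#' @param long_error list with `indel_rate` (per-base homopolymer indel
#'   probability) and `quality` (constant PHRED score; substitutions are
#'   injected at the matching error probability).
#' @param short_error list with `rate` (mean per-base substitution
#'   probability) and `decay` (fold increase of the error rate from 5' to 3',
#'   realized as a linear error-rate ramp with matching PHRED qualities).
#' @param expression_sdlog log-normal sd of per-family expression weights
#'   (0 = uniform coverage, emulating fully effective library
#'   normalization).
#' @param coverage_cap_multiple cap on per-transcript coverage as a multiple
#'   of the median (emulates duplex-specific-nuclease normalization when
#'   expression skew is enabled).
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 100,
                       ploidy_mix = c(triplet = 0.7, doublet = 0.2, singlet = 0.1),
                       transcript_meanlog = log(1100), transcript_sdlog = 0.35,
                       transcript_min = 500, transcript_max = 5000,
                       homoeolog_identity_mean = 97.2,
                       homoeolog_identity_sd = 1.8,
                       indel_fraction = 0,
                       cultivar_snp_spacing = NA,
                       long_read_length_mean = 363.2,
                       long_read_length_sd = 60,
                       short_read_length = 108,
                       insert_min = 250, insert_max = 300,
                       long_read_coverage = 10, short_read_coverage = 30,
                       long_error = list(indel_rate = 0.001, quality = 38),
                       short_error = list(rate = 0.002, decay = 4),
                       expression_sdlog = 0, coverage_cap_multiple = 3,
                       seed = 1) {
  cfg <- list(n_families = n_families, ploidy_mix = ploidy_mix,
              transcript_meanlog = transcript_meanlog,
              transcript_sdlog = transcript_sdlog,
              transcript_min = transcript_min, transcript_max = transcript_max,
              homoeolog_identity_mean = homoeolog_identity_mean,
              homoeolog_identity_sd = homoeolog_identity_sd,
              indel_fraction = indel_fraction,
              cultivar_snp_spacing = cultivar_snp_spacing,
              long_read_length_mean = long_read_length_mean,
              long_read_length_sd = long_read_length_sd,
              short_read_length = short_read_length,
              insert_min = insert_min, insert_max = insert_max,
              long_read_coverage = long_read_coverage,
              short_read_coverage = short_read_coverage,
              long_error = long_error, short_error = short_error,
              expression_sdlog = expression_sdlog,
              coverage_cap_multiple = coverage_cap_multiple,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$ploidy_mix) - 1) > 1e-9)
    stop("ploidy_mix proportions must sum to 1")
  if (cfg$homoeolog_identity_mean <= 85 || cfg$homoeolog_identity_mean > 100)
    stop("homoeolog_identity_mean must lie in (85, 100]")
  if (cfg$insert_min > cfg$insert_max)
    stop("insert_min must be <= insert_max")
  rates <- c(cfg$indel_fraction, cfg$long_error$indel_rate, cfg$short_error$rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$n_families < 1) stop("n_families must be positive")
  invisible(cfg)
}

# Apply n_mut mutations (substitutions / 1-base indels) to a sequence vector
# of single characters; returns the mutated character vector.
mutate_chars <- function(chars, n_mut, indel_fraction) {
  L <- length(chars)
  if (n_mut <= 0 || L == 0) return(chars)
  n_mut <- min(n_mut, L)
  pos <- sort(sample.int(L, n_mut), decreasing = TRUE)
  is_indel <- runif(n_mut) < indel_fraction
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_mut)) {
    p <- pos[i]
    if (is_indel[i]) {
      if (runif(1) < 0.5) {
        chars <- chars[-p] # deletion
      } else {
        chars <- append(chars, sample(bases, 1), after = p) # insertion
      }
    } else {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
  }
  chars
}

#' Generate homoeologous transcript families
#'
#' Draws a per-family target identity from
#' `Normal(homoeolog_identity_mean, homoeolog_identity_sd)` truncated to
#' (85, 100], creates an ancestral transcript, and diverges each genome copy
#' independently at half the implied pairwise rate. Mutations are placed
#' uniformly at random; `indel_fraction` of them are 1-base indels, the rest
#' substitutions. Realized pairwise identities are measured by local
#' alignment and stored alongside the targets. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `homoeolog_families`: list with `transcripts`
#'   (data.frame: seq_id, family_id, genome_label, sequence, cultivar
#'   sequence, length), `identities` (data.frame of target and realized
#'   pairwise identities per label pair) and the config.
#' @export
generate_families <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_families
  kinds <- sample(names(config$ploidy_mix), n, replace = TRUE,
                  prob = config$ploidy_mix)
  lens <- pmin(pmax(round(rlnorm(n, config$transcript_meanlog,
                                 config$transcript_sdlog)),
                    config$transcript_min), config$transcript_max)
  targets <- numeric(n)
  for (i in seq_len(n)) {
    if (config$homoeolog_identity_sd == 0) {
      targets[i] <- config$homoeolog_identity_mean
    } else {
      # truncated to (85, 100]: draws above 100 clip to 100 (undiverged
      # copies); draws at or below 85 are redrawn (far tail)
      repeat {
        t <- min(rnorm(1, config$homoeolog_identity_mean,
                       config$homoeolog_identity_sd), 100)
        if (t > 85) break
      }
      targets[i] <- t
    }
  }
  rows <- list(); idrows <- list()
  for (i in seq_len(n)) {
    fam <- sprintf("F%04d", i)
    labels <- switch(kinds[i],
                     triplet = c("A", "B", "D"),
                     doublet = sort(sample(c("A", "B", "D"), 2)),
                     singlet = sample(c("A", "B", "D"), 1))
    L <- lens[i]
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    d <- (100 - targets[i]) / 2 / 100
    n_mut <- round(L * d)
    copies <- lapply(labels, function(lab)
      mutate_chars(anc, n_mut, config$indel_fraction))
    names(copies) <- labels
    refs <- vapply(copies, paste, character(1), collapse = "")
    cult <- refs
    if (!is.na(config$cultivar_snp_spacing)) {
      for (lab in labels) {
        ch <- copies[[lab]]
        n_snp <- round(length(ch) / config$cultivar_snp_spacing)
        cult[lab] <- paste(mutate_chars(ch, n_snp, 0), collapse = "")
      }
    }
    rows[[i]] <- data.frame(seq_id = paste0(fam, "|", labels),
                            family_id = fam, genome_label = labels,
                            sequence = unname(refs), cultivar = unname(cult),
                            length = nchar(unname(refs)),
                            stringsAsFactors = FALSE)
    if (length(labels) > 1) {
      prs <- utils::combn(labels, 2)
      idrows[[i]] <- data.frame(family_id = fam, label_a = prs[1, ],
                                label_b = prs[2, ],
                                target_identity = targets[i],
                                realized_identity = NA_real_,
                                stringsAsFactors = FALSE)
    }
  }
  transcripts <- do.call(rbind, rows)
  identities <- if (length(idrows)) do.call(rbind, idrows) else
    data.frame(family_id = character(), label_a = character(),
               label_b = character(), target_identity = numeric(),
               realized_identity = numeric())
  # measure realized pairwise identity with the package aligner
  ap <- align_params()
  for (r in seq_len(nrow(identities))) {
    fam <- identities$family_id[r]
    sa <- transcripts$sequence[transcripts$family_id == fam &
                               transcripts$genome_label == identities$label_a[r]]
    sb <- transcripts$sequence[transcripts$family_id == fam &
                               transcripts$genome_label == identities$label_b[r]]
    hit <- local_align(sa, sb, ap)
    identities$realized_identity[r] <- if (is.null(hit)) NA_real_ else hit$pct_id
  }
  out <- list(transcripts = transcripts, identities = identities,
              config = config)
  class(out) <- "homoeolog_families"
  out
}

#' @export
print.homoeolog_families <- function(x, ...) {
  cat(sprintf("<homoeolog_families> %d families, %d transcripts\n",
              length(unique(x$transcripts$family_id)), nrow(x$transcripts)))
  if (nrow(x$identities))
    cat(sprintf("  realized pairwise identity: mean %.2f%%, sd %.2f%%\n",
                mean(x$identities$realized_identity, na.rm = TRUE),
                stats::sd(x$identities$realized_identity, na.rm = TRUE)))
  invisible(x)
}

# Build a linear per-base error profile with mean `rate` and 3'/5' fold
# `decay`, and the matching PHRED qualities.
short_quality_profile <- function(len, rate, decay) {
  e1 <- 2 * rate / (1 + decay)
  e <- seq(e1, e1 * decay, length.out = len)
  q <- pmin(40L, pmax(3L, as.integer(round(-10 * log10(pmax(e, 1e-6))))))
  q
}

inject_substitutions <- function(seq_chars, q) {
  p <- 10^(-q / 10)
  hit <- which(runif(length(seq_chars)) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (h in hit) seq_chars[h] <- sample(setdiff(bases, seq_chars[h]), 1)
  }
  seq_chars
}

# Homopolymer 1-base indels at per-base rate; only positions inside a
# homopolymer run (neighbour equality) are eligible.
inject_homopolymer_indels <- function(seq_chars, q, rate) {
  if (rate <= 0 || length(seq_chars) < 2) return(list(s = seq_chars, q = q))
  n <- length(seq_chars)
  cand <- which(runif(n) < rate)
  cand <- cand[cand > 1 & seq_chars[cand] == seq_chars[pmax(cand - 1, 1)]]
  for (p in rev(cand)) {
    if (p > length(seq_chars)) next
    if (runif(1) < 0.5) {
      seq_chars <- seq_chars[-p]; q <- q[-p]
    } else {
      seq_chars <- append(seq_chars, seq_chars[p], after = p)
      q <- append(q, q[p], after = p)
    }
  }
  list(s = seq_chars, q = q)
}

#' Simulate sequencing reads from homoeolog families
#'
#' Long reads are single-ended with lengths drawn from
#' `Normal(long_read_length_mean, long_read_length_sd)` clipped to
#' `[50, transcript length]`; short reads come as inward-facing pairs with
#' inserts drawn uniformly from the configured range. Platform error models
#' are applied with base qualities consistent with the injected error rates,
#' and every read carries its ground-truth origin (family, genome label,
#' 0-based half-open coordinates on the sequenced copy, strand).
#' Transcripts shorter than the smallest insert emit only long/unpaired
#' reads (reported via `message()`). Deterministic given `config$seed`.
#'
#' @param families a [generate_families()] result.
#' @param config the [sim_config()] used (coverages must be >= 0, at least
#'   one positive).
#' @return a `read_set` data.frame.
#' @export
simulate_reads <- function(families, config) {
  stopifnot(inherits(families, "homoeolog_families"))
  if (config$long_read_coverage <= 0 && config$short_read_coverage <= 0)
    stop("at least one platform coverage must be positive")
  set.seed(config$seed + 1L)
  tx <- families$transcripts
  fams <- unique(tx$family_id)
  # per-family expression weights, optionally capped at a multiple of median
  w <- if (config$expression_sdlog > 0)
    rlnorm(length(fams), 0, config$expression_sdlog) else rep(1, length(fams))
  w <- pmin(w, config$coverage_cap_multiple * median(w))
  w <- w / mean(w)
  names(w) <- fams
  out <- vector("list", nrow(tx) * 2)
  k <- 0
  short_skipped <- character()
  for (r in seq_len(nrow(tx))) {
    src <- tx$cultivar[r]
    L <- nchar(src)
    fam <- tx$family_id[r]; lab <- tx$genome_label[r]
    weight <- w[[fam]]
    src_chars_full <- strsplit(src, "", fixed = TRUE)[[1]]
    # ---- long reads ----
    covL <- config$long_read_coverage * weight
    if (covL > 0) {
      nL <- max(0L, as.integer(round(covL * L / config$long_read_length_mean)))
      if (nL > 0) {
        rl <- pmin(pmax(round(rnorm(nL, config$long_read_length_mean,
                                    config$long_read_length_sd)), 50), L)
        st <- floor(runif(nL, 0, L - rl + 1))
        strand <- sample(c("+", "-"), nL, replace = TRUE)
        q0 <- as.integer(config$long_error$quality)
        seqs <- character(nL); quals <- character(nL)
        for (i in seq_len(nL)) {
          ch <- src_chars_full[(st[i] + 1):(st[i] + rl[i])]
          if (strand[i] == "-") ch <- rev(chartr_chars(ch))
          q <- rep(q0, rl[i])
          ch <- inject_substitutions(ch, q)
          hp <- inject_homopolymer_indels(ch, q, config$long_error$indel_rate)
          seqs[i] <- paste(hp$s, collapse = "")
          quals[i] <- intToUtf8(hp$q + 33L)
        }
        k <- k + 1
        out[[k]] <- new_read_set(data.frame(
          read_id = sprintf("%s_%s_L%05d", fam, lab, seq_len(nL)),
          sequence = seqs, quality = quals, platform = "long",
          mate_id = NA_character_, family_id = fam, genome_label = lab,
          start = st, end = st + rl, strand = strand,
          stringsAsFactors = FALSE))
      }
    }
    # ---- short read pairs ----
    covS <- config$short_read_coverage * weight
    if (covS > 0) {
      if (L < config$insert_min) {
        short_skipped <- c(short_skipped, tx$seq_id[r])
      } else {
        rl <- config$short_read_length
        nP <- max(0L, as.integer(round(covS * L / (2 * rl))))
        if (nP > 0) {
          ins <- sample(seq(config$insert_min, min(config$insert_max, L)),
                        nP, replace = TRUE)
          st <- floor(runif(nP, 0, L - ins + 1))
          rl1 <- pmin(rl, ins); rl2 <- pmin(rl, ins)
          qprof <- short_quality_profile(rl, config$short_error$rate,
                                         config$short_error$decay)
          id1 <- sprintf("%s_%s_S%05d_1", fam, lab, seq_len(nP))
          id2 <- sprintf("%s_%s_S%05d_2", fam, lab, seq_len(nP))
          s1 <- character(nP); s2 <- character(nP)
          q1 <- character(nP); q2 <- character(nP)
          for (i in seq_len(nP)) {
            a <- src_chars_full[(st[i] + 1):(st[i] + rl1[i])]
            bpos <- st[i] + ins[i] - rl2[i]
            b <- rev(chartr_chars(src_chars_full[(bpos + 1):(bpos + rl2[i])]))
            qa <- qprof[seq_len(rl1[i])]; qb <- qprof[seq_len(rl2[i])]
            a <- inject_substitutions(a, qa)
            b <- inject_substitutions(b, qb)
            s1[i] <- paste(a, collapse = ""); s2[i] <- paste(b, collapse = "")
            q1[i] <- intToUtf8(qa + 33L); q2[i] <- intToUtf8(qb + 33L)
          }
          k <- k + 1
          out[[k]] <- new_read_set(data.frame(
            read_id = c(id1, id2), sequence = c(s1, s2),
            quality = c(q1, q2), platform = "short",
            mate_id = c(id2, id1), family_id = fam, genome_label = lab,
            start = c(st, st + ins - rl2), end = c(st + rl1, st + ins),
            strand = c(rep("+", nP), rep("-", nP)),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (length(short_skipped))
    message(sprintf(paste0("%d transcript(s) shorter than the minimum ",
                           "insert emit only long/unpaired reads"),
                    length(short_skipped)))
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res)) stop("no reads generated; increase coverage")
  new_read_set(res)
}

# complement a character vector of bases (used with rev() for revcomp)
chartr_chars <- function(ch) {
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- m[ch]
  out[is.na(out)] <- "N"
  unname(out)
}

#' Inject library/sequencing artifacts into reads
#'
#' Appends adapter sequence (optionally with mismatches) to the 3' end of a
#' configured fraction of reads, introduces runs of ambiguous bases and
#' low-quality 3' tails. Truth labels are preserved.
#'
#' @param reads a `read_set`.
#' @param adapter adapter sequence (length >= 8).
#' @param rates list with any of `adapter_rate`, `adapter_mismatches`,
#'   `n_run_rate`, `n_run_length`, `lowq_tail_rate`, `tail_length`.
#' @param seed integer seed.
#' @return the modified `read_set`.
#' @export
inject_artifacts <- function(reads, adapter,
                             rates = list(adapter_rate = 0,
                                          adapter_mismatches = 0,
                                          n_run_rate = 0, n_run_length = 5,
                                          lowq_tail_rate = 0,
                                          tail_length = 10),
                             seed = 1) {
  if (nchar(adapter) < 8) stop("adapter length must be >= 8")
  set.seed(seed)
  n <- nrow(reads)
  r <- function(x, d) rates[[x]] %||% d
  pick <- function(rate) which(runif(n) < rate)
  for (i in pick(r("adapter_rate", 0))) {
    ad <- strsplit(adapter, "")[[1]]
    mm <- r("adapter_mismatches", 0)
    if (mm > 0) {
      pos <- sample(length(ad), mm)
      for (p in pos) ad[p] <- sample(setdiff(c("A", "C", "G", "T"), ad[p]), 1)
    }
    reads$sequence[i] <- paste0(reads$sequence[i], paste(ad, collapse = ""))
    reads$quality[i] <- paste0(reads$quality[i],
                               intToUtf8(rep(25L + 33L, length(ad))))
  }
  for (i in pick(r("n_run_rate", 0))) {
    len <- nchar(reads$sequence[i])
    run <- r("n_run_length", 5)
    if (len < run) next
    p <- sample(len - run + 1, 1)
    s <- strsplit(reads$sequence[i], "")[[1]]
    q <- utf8ToInt(reads$quality[i]) - 33L
    s[p:(p + run - 1)] <- "N"
    q[p:(p + run - 1)] <- 2L
    reads$sequence[i] <- paste(s, collapse = "")
    reads$quality[i] <- intToUtf8(q + 33L)
  }
  for (i in pick(r("lowq_tail_rate", 0))) {
    len <- nchar(reads$quality[i])
    tl <- min(r("tail_length", 10), len)
    q <- utf8ToInt(reads$quality[i]) - 33L
    q[(len - tl + 1):len] <- 8L
    reads$quality[i] <- intToUtf8(q + 33L)
  }
  reads
}
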
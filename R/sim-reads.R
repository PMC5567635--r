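revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# inject per-base sequencing errors into a character vector of reads
add_seq_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), nerr[i])
    ch[pos] <- BASES[((match(ch[pos], BASES) - 1L +
                         sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L]
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate paired-end reads for one sample
#'
#' Fragments are drawn per gene from the same multinomial-with-replicate-noise
#' model as [simulate_counts()]; each fragment's two mates are read from its
#' ends (mate 2 reverse-complemented) with per-base substitution errors.
#' Accession variants are first applied to the AT-subgenome transcripts, so the
#' reads carry the accession's genotype. Fragments shorter than the read length
#' (only possible on transcripts shorter than `read_len`) yield two fully
#' overlapping mates covering the whole fragment. Read names carry no truth;
#' the true origin of every fragment is returned separately.
#'
#' @param truth A study truth object from [simulate_study()], or a list with
#'   elements `subgenomes`, `variants`, `expression`.
#' @param accession `"acc1"` or `"acc2"`.
#' @param replicate Replicate number (1-based).
#' @param config A [sim_config()].
#' @return List with `reads` (tibble `read_id`, `mate1`, `mate2`) and `origin`
#'   (tibble `read_id`, `subgenome`, `gene`).
#' @export
simulate_reads <- function(truth, accession, replicate, config) {
  stopifnot(inherits(config, "sim_config"), accession %in% c("acc1", "acc2"))
  acc_i <- match(accession, c("acc1", "acc2"))
  # counts reuse the simulate_counts() stream so the two agree per sample
  set.seed(stage_seed(config$seed, "counts", i = acc_i * 100L + replicate))
  et <- truth$expression
  expr <- if (accession == "acc1") et$expr_acc1 else et$expr_acc2
  noise <- rlnorm(length(expr), 0, config$rep_noise_sdlog)
  w <- expr * noise * et$length
  n <- config$reads_per_sample
  cnt <- if (n > 0L && sum(w) > 0) as.integer(rmultinom(1L, n, w)) else integer(length(w))

  set.seed(stage_seed(config$seed, "reads", i = acc_i * 100L + replicate))
  snps <- truth$variants[[accession]]
  hap_at <- apply_snps(truth$subgenomes$at, snps)
  seqs <- c(setNames(hap_at$seq, hap_at$gene),
            setNames(truth$subgenomes$aa$seq, truth$subgenomes$aa$gene))

  idx <- rep(seq_along(cnt), cnt)
  total <- length(idx)
  if (total == 0L) {
    return(list(
      reads = tibble(read_id = character(), mate1 = character(), mate2 = character()),
      origin = tibble(read_id = character(), subgenome = character(), gene = character())
    ))
  }
  glen <- et$length[idx]
  flen <- pmin(pmax(round(rnorm(total, config$fragment_len_mean,
                                config$fragment_len_sd)), config$read_len), glen)
  start <- floor(runif(total) * (glen - flen + 1)) + 1L
  gseq <- seqs[et$gene[idx]]
  frag <- substr(gseq, start, start + flen - 1L)
  rl <- pmin(config$read_len, flen)
  mate1 <- substr(frag, 1L, rl)
  mate2 <- revcomp_chr(substr(frag, flen - rl + 1L, flen))
  mate1 <- add_seq_errors(mate1, config$seq_error_rate)
  mate2 <- add_seq_errors(mate2, config$seq_error_rate)

  ids <- sprintf("%s_rep%d_f%07d", accession, replicate, seq_len(total))
  list(
    reads = tibble(read_id = ids, mate1 = unname(mate1), mate2 = unname(mate2)),
    origin = tibble(read_id = ids, subgenome = et$subgenome[idx], gene = et$gene[idx])
  )
}

#' Write simulated paired reads as two FASTQ files
#'
#' Four-line FASTQ records, Phred+33, constant quality (the assigner is
#' quality-agnostic).
#'
#' @param reads Tibble from [simulate_reads()] (`read_id`, `mate1`, `mate2`).
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  wr <- function(ids, seqs, path) {
    if (length(seqs)) {
      qual <- strrep("I", nchar(seqs))
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
    } else {
      writeLines(character(), path)
    }
  }
  wr(reads$read_id, reads$mate1, path1)
  wr(reads$read_id, reads$mate2, path2)
  invisible(c(path1, path2))
}

#' Read a pair of FASTQ files into the reads tibble used by the assigner
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2 (same order and IDs).
#' @return Tibble with `read_id`, `mate1`, `mate2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2)) abort("mate files differ in read count")
  tibble(
    read_id = sub("\\s.*$", "", names(r1)),
    mate1 = unname(as.character(r1)),
    mate2 = unname(as.character(r2))
  )
}
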
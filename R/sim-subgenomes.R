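BASES <- c("A", "C", "G", "T")

random_seq_vec <- function(n_bases) sample(BASES, n_bases, replace = TRUE)

# Per-copy substitution rate m such that two copies mutated independently at
# rate m (uniform choice among the three alternative bases) differ at an
# expected fraction d of sites: P(differ) = 2m - (4/3) m^2.
divergence_to_copy_rate <- function(d) {
  if (d == 0) return(0)
  (3 / 4) * (1 - sqrt(1 - 4 * d / 3))
}

# substitute bases of a character vector at per-site rate `rate`
mutate_bases <- function(bases, rate) {
  if (rate <= 0) return(bases)
  hit <- which(runif(length(bases)) < rate)
  if (length(hit) == 0L) return(bases)
  idx <- match(bases[hit], BASES)
  bases[hit] <- BASES[((idx - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
  bases
}

#' Simulate two diverged subgenome transcript sets and their homoeolog map
#'
#' Draws one ancestral transcript per homoeologous pair and mutates the two
#' copies independently (substitutions only, uniform over sites and over the
#' three alternative bases) so that the expected pairwise identity between
#' homoeologs is `1 - subgenome_divergence`. Unpaired genes receive novel
#' unrelated sequences. Gene IDs carry the subgenome label as a prefix, so IDs
#' are unique across the concatenated reference.
#'
#' @param config A [sim_config()].
#' @param k Smallest k-mer length any downstream index will use; transcripts
#'   shorter than `k` are rejected up front.
#' @return A list with elements `at` and `aa` (tibbles `gene`, `subgenome`,
#'   `length`, `seq`) and `map` (tibble `pair_id`, `at_gene`, `aa_gene`).
#' @examples
#' sg <- simulate_subgenomes(sim_config(n_pairs = 5, n_unpaired_per_subgenome = 2,
#'                                      transcript_len_range = c(300, 400)))
#' sg$map
#' @export
simulate_subgenomes <- function(config, k = 21L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$transcript_len_range[1] < k) {
    abort(sprintf(
      "transcript_len_range lower bound (%d) is below the downstream k-mer size (%d)",
      config$transcript_len_range[1], k
    ))
  }
  set.seed(stage_seed(config$seed, "subgenomes"))
  np <- config$n_pairs
  nu <- config$n_unpaired_per_subgenome
  m <- divergence_to_copy_rate(config$subgenome_divergence)

  lens <- sample(config$transcript_len_range[1]:config$transcript_len_range[2],
                 np + 2L * nu, replace = TRUE)
  pair_lens <- lens[seq_len(np)]

  make_pair <- function(len) {
    anc <- random_seq_vec(len)
    list(at = paste(mutate_bases(anc, m), collapse = ""),
         aa = paste(mutate_bases(anc, m), collapse = ""))
  }
  pairs <- lapply(pair_lens, make_pair)

  pair_ids <- sprintf("P%05d", seq_len(np))
  at_pair_genes <- paste0("AT_", pair_ids)
  aa_pair_genes <- paste0("AA_", pair_ids)

  unpaired_seq <- function(len) paste(random_seq_vec(len), collapse = "")
  at_un_lens <- lens[np + seq_len(nu)]
  aa_un_lens <- lens[np + nu + seq_len(nu)]

  at <- tibble(
    gene = c(at_pair_genes, if (nu) sprintf("AT_U%05d", seq_len(nu))),
    subgenome = "AT",
    length = c(pair_lens, at_un_lens),
    seq = c(map_chr(pairs, "at"), map_chr(at_un_lens, unpaired_seq))
  )
  aa <- tibble(
    gene = c(aa_pair_genes, if (nu) sprintf("AA_U%05d", seq_len(nu))),
    subgenome = "AA",
    length = c(pair_lens, aa_un_lens),
    seq = c(map_chr(pairs, "aa"), map_chr(aa_un_lens, unpaired_seq))
  )
  map <- tibble(pair_id = pair_ids, at_gene = at_pair_genes, aa_gene = aa_pair_genes)
  list(at = at, aa = aa, map = map)
}

#' Observed identity between homoeologous pairs
#'
#' Site-wise identity of each pair in a simulated subgenome set; used to check
#' that realised divergence matches the configured expectation.
#'
#' @param subgenomes Result of [simulate_subgenomes()].
#' @return Tibble with `pair_id`, `length`, `identity` (fraction of matching
#'   sites).
#' @export
pair_identity <- function(subgenomes) {
  at <- subgenomes$at[match(subgenomes$map$at_gene, subgenomes$at$gene), ]
  aa <- subgenomes$aa[match(subgenomes$map$aa_gene, subgenomes$aa$gene), ]
  ident <- map_dbl(seq_len(nrow(subgenomes$map)), function(i) {
    a <- strsplit(at$seq[i], "", fixed = TRUE)[[1]]
    b <- strsplit(aa$seq[i], "", fixed = TRUE)[[1]]
    mean(a == b)
  })
  tibble(pair_id = subgenomes$map$pair_id, length = at$length, identity = ident)
}

#' Write a transcriptome tibble to FASTA
#'
#' @param transcriptome Tibble with `gene` and `seq` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  x <- Biostrings::DNAStringSet(setNames(transcriptome$seq, transcriptome$gene))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a transcriptome FASTA into the tibble form used throughout
#'
#' @param path FASTA path.
#' @param subgenome Subgenome label to attach ("AT" or "AA").
#' @return Tibble with `gene`, `subgenome`, `length`, `seq`.
#' @export
read_transcriptome_fasta <- function(path, subgenome) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    gene = sub("\\s.*$", "", names(x)),
    subgenome = subgenome,
    length = Biostrings::width(x),
    seq = unname(as.character(x))
  )
}
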
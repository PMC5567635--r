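# Shared fixtures; heavier objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_pairs = 30, n_unpaired_per_subgenome = 6,
         transcript_len_range = c(300L, 600L),
         n_de_genes = 6, n_coordinated_pairs = 2,
         reads_per_sample = 600, seed = 101),
    list(...)
  )
  do.call(sim_config, args)
}

# a small error-free study with reads, used across assignment/SNP tests
fix_study <- function() {
  cached("study", {
    cfg <- sim_config(
      n_pairs = 60, n_unpaired_per_subgenome = 10,
      transcript_len_range = c(400L, 800L),
      n_de_genes = 10, n_coordinated_pairs = 3,
      reads_per_sample = 1500, seq_error_rate = 0,
      accession_snp_rate = 0.003, seed = 42
    )
    simulate_study(cfg, reads = TRUE)
  })
}

fix_indices <- function() {
  cached("indices", {
    truth <- fix_study()
    list(at = build_kmer_index(truth$subgenomes$at, 21),
         aa = build_kmer_index(truth$subgenomes$aa, 21))
  })
}

fix_assignments <- function() {
  cached("assignments", {
    truth <- fix_study()
    idx <- fix_indices()
    out <- lapply(unique(truth$reads$sample_id), function(s) {
      r <- truth$reads[truth$reads$sample_id == s, ]
      a <- assign_fragments(r, idx$at, idx$aa)
      a$sample_id <- s
      a
    })
    dplyr::bind_rows(out)
  })
}

# tiny homoeolog map helper for constructed examples
toy_map <- function(P) {
  tibble::tibble(
    pair_id = sprintf("p%02d", seq_len(P)),
    at_gene = sprintf("AT_%02d", seq_len(P)),
    aa_gene = sprintf("AA_%02d", seq_len(P))
  )
}

# brute-force enumeration of the pair-count tail over all draws
enum_pair_tail <- function(universe, map, n_draw, obs) {
  cmb <- utils::combn(length(universe), n_draw)
  cnt <- apply(cmb, 2, function(ix) {
    g <- universe[ix]
    sum(map$at_gene %in% g & map$aa_gene %in% g)
  })
  list(tail = mean(cnt >= obs), mean = mean(cnt))
}

# random SNP tibble on synthetic transcript names
random_snps <- function(n, transcripts = sprintf("t%02d", 1:5), qual = 50) {
  tibble::tibble(
    transcript = sample(transcripts, n, replace = TRUE),
    pos = sample.int(500, n, replace = TRUE),
    ref = "A", alt = "C",
    qual = qual, is_indel = FALSE
  ) |> dplyr::distinct(transcript, pos, .keep_all = TRUE)
}

# SNP tibble from explicit integer keys (transcript fixed), for set algebra
snps_from_keys <- function(keys, transcript = "tx", qual = 50) {
  tibble::tibble(
    transcript = transcript, pos = as.integer(keys),
    ref = "A", alt = "C", qual = qual, is_indel = FALSE
  )
}
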
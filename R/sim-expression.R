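#' Simulate per-gene expression truth for two accessions
#'
#' Baseline expression is drawn from a log-normal distribution (heavy tail,
#' FPKM-like), once per homoeologous pair — the two members share the
#' ancestral baseline, mirroring the strong expression correlation of
#' homoeologs — and once per unpaired gene. The AT subgenome's baseline is
#' then multiplied by `2^dominance_log2` (subgenome expression dominance). `n_de_genes` genes are
#' then made truly differentially expressed between the accessions with
#' absolute log2 fold change `de_log2fc`; `n_coordinated_pairs` homoeologous
#' pairs contribute two DE genes each, with both members shifted in the same
#' direction. The remaining DE genes are drawn so that no further pair has both
#' members DE, keeping the planted coordinated-pair count exact.
#'
#' @param subgenomes Result of [simulate_subgenomes()].
#' @param config A [sim_config()].
#' @return Tibble with one row per gene: `gene`, `subgenome`, `pair_id`
#'   (`NA` for unpaired genes), `length`, `base_expr`, `expr_acc1`,
#'   `expr_acc2`, `is_de`, `direction` (`"up_in_acc1"`/`"up_in_acc2"`/`NA`)
#'   and `coordinated`.
#' @export
simulate_expression_truth <- function(subgenomes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "expression"))
  genes <- bind_rows(
    subgenomes$at[, c("gene", "subgenome", "length")],
    subgenomes$aa[, c("gene", "subgenome", "length")]
  )
  map_ <- subgenomes$map
  pid_at <- map_$pair_id[match(genes$gene, map_$at_gene)]
  pid_aa <- map_$pair_id[match(genes$gene, map_$aa_gene)]
  genes$pair_id <- dplyr::coalesce(pid_at, pid_aa)

  n <- nrow(genes)
  if (config$n_de_genes > n) abort("`n_de_genes` exceeds the number of genes")

  pair_base <- rlnorm(nrow(map_), config$expr_meanlog, config$expr_sdlog)
  names(pair_base) <- map_$pair_id
  genes$base_expr <- unname(pair_base[genes$pair_id])
  unpaired <- is.na(genes$pair_id)
  genes$base_expr[unpaired] <- rlnorm(sum(unpaired), config$expr_meanlog,
                                      config$expr_sdlog)
  genes$base_expr[genes$subgenome == "AT"] <-
    genes$base_expr[genes$subgenome == "AT"] * 2^config$dominance_log2

  genes$is_de <- FALSE
  genes$direction <- NA_character_
  genes$coordinated <- FALSE

  fc <- config$de_log2fc
  ncp <- config$n_coordinated_pairs
  nde_single <- config$n_de_genes - 2L * ncp

  if (fc != 0 && config$n_de_genes > 0L) {
    coord_pairs <- if (ncp > 0L) sample(map_$pair_id, ncp) else character()
    coord_genes <- c(map_$at_gene[map_$pair_id %in% coord_pairs],
                     map_$aa_gene[map_$pair_id %in% coord_pairs])
    # one sampling unit per remaining pair (a random member) plus every
    # unpaired gene, so no non-coordinated pair can end up fully DE
    rest_pairs <- map_[!(map_$pair_id %in% coord_pairs), , drop = FALSE]
    unit_genes <- c(
      ifelse(runif(nrow(rest_pairs)) < 0.5, rest_pairs$at_gene, rest_pairs$aa_gene),
      genes$gene[is.na(genes$pair_id)]
    )
    if (nde_single > length(unit_genes)) {
      abort("`n_de_genes` too large for the number of available genes/pairs")
    }
    single_genes <- if (nde_single > 0L) sample(unit_genes, nde_single) else character()

    dir_pairs <- sample(c("up_in_acc1", "up_in_acc2"), max(ncp, 1L), replace = TRUE)
    pd <- setNames(dir_pairs[seq_len(ncp)], coord_pairs)
    i_coord <- match(coord_genes, genes$gene)
    genes$is_de[i_coord] <- TRUE
    genes$coordinated[i_coord] <- TRUE
    genes$direction[i_coord] <- pd[genes$pair_id[i_coord]]

    i_single <- match(single_genes, genes$gene)
    genes$is_de[i_single] <- TRUE
    genes$direction[i_single] <- sample(c("up_in_acc1", "up_in_acc2"),
                                        length(i_single), replace = TRUE)
  }

  shift <- ifelse(genes$is_de,
                  ifelse(genes$direction == "up_in_acc2", fc, -fc), 0)
  genes$expr_acc1 <- genes$base_expr
  genes$expr_acc2 <- genes$base_expr * 2^shift
  genes[, c("gene", "subgenome", "pair_id", "length", "base_expr",
            "expr_acc1", "expr_acc2", "is_de", "direction", "coordinated")]
}

#' Simulate fragment counts for every sample without generating sequences
#'
#' The count-level core of the read simulator: per sample, per-gene biological
#' replicate noise (log-normal) is applied to the accession's expression truth
#' and `reads_per_sample` fragments are drawn from a multinomial with
#' probabilities proportional to expression times transcript length, exactly
#' the model under which FPKM is proportional to expression.
#'
#' @param expression_truth Result of [simulate_expression_truth()].
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `accession`, `replicate`, `gene`, `count`.
#' @export
simulate_counts <- function(expression_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sample_sheet(config)
  out <- map(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    set.seed(stage_seed(config$seed, "counts",
                        i = match(s$accession, c("acc1", "acc2")) * 100L + s$replicate))
    expr <- if (s$accession == "acc1") expression_truth$expr_acc1 else expression_truth$expr_acc2
    noise <- rlnorm(length(expr), 0, config$rep_noise_sdlog)
    w <- expr * noise * expression_truth$length
    n <- config$reads_per_sample
    cnt <- if (n > 0L && sum(w) > 0) as.integer(rmultinom(1L, n, w)) else integer(length(w))
    tibble(sample_id = s$sample_id, accession = s$accession,
           replicate = s$replicate, gene = expression_truth$gene, count = cnt)
  })
  bind_rows(out)
}

#' Sample sheet for a configured study
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `accession` (`"acc1"`/`"acc2"`),
#'   `replicate`.
#' @export
sample_sheet <- function(config) {
  tidyr::expand_grid(accession = c("acc1", "acc2"),
                     replicate = seq_len(config$n_replicates)) |>
    mutate(sample_id = sprintf("%s_rep%d", accession, replicate)) |>
    select(sample_id, accession, replicate)
}
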
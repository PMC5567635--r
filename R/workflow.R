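#' Run the full subgenome-aware study pipeline on a simulated dataset
#'
#' End-to-end orchestration: simulate the study (subgenomes, variants,
#' expression, reads), assign every sample's fragments to subgenome and gene,
#' quantify FPKM, test differential expression between the two accessions,
#' join DEGs against the homoeolog map, run the pair-enrichment permutation
#' test and the direction-concordance sign test, compute per-accession
#' subgenome dominance ratios, call and filter SNPs per accession from the
#' assigned reads, partition them pairwise and against the panel, and test
#' SNP density in DEG transcripts. The same seed and configuration reproduce
#' the report exactly.
#'
#' @param config A [sim_config()].
#' @param k K-mer length for indexing/assignment.
#' @param min_margin Assignment margin threshold.
#' @param de_alpha DE significance level (BH q).
#' @param perm_replicates Permutation draws for the pair-enrichment test.
#' @param snp_min_depth,snp_min_alt_frac SNP caller thresholds.
#' @param snp_min_quality Strict quality filter threshold applied before the
#'   partitions.
#' @param annotations,categories Optional term annotation and term-category
#'   tibbles; when supplied, Fisher term enrichment and gene categorization
#'   run on the DEG set.
#' @return Object of class `study_report` (a list; see [verify_report()] for
#'   the identities it satisfies).
#' @export
run_study <- function(config, k = 21L, min_margin = 2L, de_alpha = 0.05,
                      perm_replicates = 1e5, snp_min_depth = 4L,
                      snp_min_alt_frac = 0.9, snp_min_quality = 30,
                      annotations = NULL, categories = NULL) {
  truth <- simulate_study(config, reads = TRUE, k = k)
  idx_at <- build_kmer_index(truth$subgenomes$at, k = k)
  idx_aa <- build_kmer_index(truth$subgenomes$aa, k = k)
  gene_info <- bind_rows(truth$subgenomes$at, truth$subgenomes$aa)[
    , c("gene", "subgenome", "length")]

  samples <- truth$samples
  asg_list <- list()
  counts_all <- list()
  totals_all <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]
    r <- truth$reads[truth$reads$sample_id == s, ]
    a <- assign_fragments(r, idx_at, idx_aa, min_margin = min_margin)
    a$sample_id <- s
    asg_list[[s]] <- a
    cf <- count_fragments(a)
    tot <- attr(cf, "totals")
    cf$sample_id <- s
    counts_all[[s]] <- cf
    totals_all[[s]] <- tibble(sample_id = s, mapped_total = tot$mapped,
                              at = tot$at, aa = tot$aa,
                              ambiguous = tot$ambiguous, unmapped = tot$unmapped)
  }
  counts <- bind_rows(counts_all)
  totals <- bind_rows(totals_all)

  if (sum(totals$mapped_total) > 0) {
    expr <- compute_fpkm(counts, gene_info,
                         totals[, c("sample_id", "mapped_total")])
    de <- differential_expression(expr, samples, "acc1", "acc2",
                                  alpha = de_alpha)
  } else {
    # a libraryless run (e.g. zero reads) still yields a structured report
    expr <- tidyr::expand_grid(sample_id = samples$sample_id,
                               gene = gene_info$gene) |>
      left_join(gene_info, by = "gene") |>
      mutate(count = 0L, fpkm = 0)
    de <- tibble(gene = character(), subgenome = character(),
                 mean_fpkm_1 = numeric(), mean_fpkm_2 = numeric(),
                 log2fc = numeric(), p = numeric(), q = numeric(),
                 significant = logical(), direction = character())
  }
  degs <- de |> filter(significant)
  dirsum <- direction_summary(degs)

  pj <- join_pairs(degs, truth$subgenomes$map)
  universe <- de$gene
  perm <- NULL
  if (pj$total > 0L && pj$total <= length(universe)) {
    perm <- pair_enrichment_permutation(
      universe, truth$subgenomes$map, n_draw = pj$total,
      observed_pairs = pj$pairs, replicates = perm_replicates,
      seed = stage_seed(config$seed, "permutation")
    )
  }
  conc <- direction_concordance(pj)

  ratios <- list(
    acc1 = subgenome_ratio(expr, truth$subgenomes$map, samples, "acc1"),
    acc2 = subgenome_ratio(expr, truth$subgenomes$map, samples, "acc2")
  )

  # SNP stage: pool each accession's assigned reads, call on the AT reference
  snps <- list()
  for (acc in c("acc1", "acc2")) {
    ids <- samples$sample_id[samples$accession == acc]
    asg <- bind_rows(asg_list[ids]) |> filter(call == "AT")
    reads_acc <- truth$reads[truth$reads$sample_id %in% ids, ]
    pl <- pileup_assignments(asg, reads_acc, truth$subgenomes$at, k = k)
    called <- call_snps(pl, truth$subgenomes$at, min_depth = snp_min_depth,
                        min_alt_frac = snp_min_alt_frac)
    snps[[acc]] <- filter_snps(called, remove_indels = TRUE,
                               min_quality = snp_min_quality)
  }
  pairwise <- partition_pairwise(snps$acc1, snps$acc2)
  panel_part <- partition_with_panel(snps$acc1, snps$acc2, truth$variants$panel)

  # SNPs differing between the accessions, placed in DEG vs non-DEG bp
  diff_keys <- c(setdiff(snp_key(snps$acc1), snp_key(snps$acc2)),
                 setdiff(snp_key(snps$acc2), snp_key(snps$acc1)))
  diff_tr <- sub(":.*$", "", diff_keys)
  at_info <- truth$subgenomes$at
  deg_at <- degs$gene[degs$subgenome == "AT"]
  deg_bp <- sum(at_info$length[at_info$gene %in% deg_at])
  total_bp <- sum(at_info$length)
  chisq <- NULL
  if (length(diff_keys) > 0L && deg_bp > 0L) {
    chisq <- snp_deg_enrichment(
      total_snps = length(diff_keys),
      snps_in_degs = sum(diff_tr %in% deg_at),
      deg_bp = deg_bp, total_bp = total_bp
    )
  }

  enr <- NULL
  gene_cats <- NULL
  if (!is.null(annotations) && nrow(degs) > 0L) {
    enr <- fisher_enrichment(degs$gene, universe, annotations)
    if (!is.null(categories)) {
      gene_cats <- categorize_genes(filter_terms(enr), annotations, categories,
                                    deg = degs$gene)
    }
  }

  structure(list(
    config = config,
    truth = truth,
    totals = totals,
    expression = expr,
    de = de,
    degs = degs,
    direction_summary = dirsum,
    pair_join = pj,
    permutation = perm,
    concordance = conc,
    ratios = ratios,
    snps = snps,
    pairwise_partition = pairwise,
    panel_partition = panel_part,
    chisq = chisq,
    enrichment = enr,
    gene_categories = gene_cats,
    seed = config$seed
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$pair_join)
  if (!is.null(x$permutation)) print(x$permutation)
  cat(sprintf("  concordant pairs: %d/%d\n", x$concordance$concordant,
              x$concordance$concordant + x$concordance$discordant))
  print(x$ratios$acc1)
  print(x$pairwise_partition)
  invisible(x)
}

#' Verify the arithmetic identities a study report must satisfy
#'
#' Checks the pair-join identities (`total = at_only + aa_only + 2 * pairs`,
#' subgenome totals), the SNP partition marginal sums, the ratio-summary
#' bookkeeping (analyzed + excluded = total pairs) and that direction
#' percentages sum to about 100. An empty report section passes vacuously
#' with a warning-style note in `detail`.
#'
#' @param report A `study_report`, or any list exposing the same components.
#' @return Tibble with `check`, `ok`, `detail`.
#' @export
verify_report <- function(report) {
  checks <- list()
  add <- function(name, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = name, ok = ok, detail = detail)
  }
  pj <- report$pair_join
  if (!is.null(pj)) {
    add("deg_total_identity", pj$total == pj$at_only + pj$aa_only + 2L * pj$pairs,
        sprintf("%d = %d + %d + 2*%d", pj$total, pj$at_only, pj$aa_only, pj$pairs))
    add("at_total_identity", pj$at_total == pj$at_only + pj$pairs)
    add("aa_total_identity", pj$aa_total == pj$aa_only + pj$pairs)
  } else add("deg_total_identity", TRUE, "no pair join (vacuous)")
  ds <- report$direction_summary
  if (!is.null(ds) && nrow(ds) > 0L) {
    add("direction_pct_sums_100", abs(sum(ds$pct) - 100L) <= 1L,
        sprintf("sum pct = %d", sum(ds$pct)))
    add("direction_counts_sum", sum(ds$n) == pj$total)
  } else add("direction_pct_sums_100", TRUE, "no DEGs (vacuous)")
  pp <- report$panel_partition
  if (!is.null(pp)) {
    add("partition_a_margin",
        pp$a_total == pp$shared_in_panel + pp$shared_not_panel +
          pp$a_only_in_panel + pp$a_only_not_panel)
    add("partition_b_margin",
        pp$b_total == pp$shared_in_panel + pp$shared_not_panel +
          pp$b_only_in_panel + pp$b_only_not_panel)
    add("partition_a_not_in_panel",
        pp$a_not_in_panel == pp$shared_not_panel + pp$a_only_not_panel)
    add("partition_b_not_in_panel",
        pp$b_not_in_panel == pp$shared_not_panel + pp$b_only_not_panel)
  }
  for (acc in names(report$ratios %||% list())) {
    rs <- report$ratios[[acc]]
    add(paste0("ratio_bookkeeping_", acc),
        rs$analyzed + rs$excluded == rs$total_pairs)
  }
  if (!is.null(report$permutation)) {
    h <- report$permutation$histogram
    add("perm_histogram_mass", sum(h$n) == report$permutation$replicates)
    add("perm_null_max", report$permutation$null_max == max(h$pairs[h$n > 0L]))
  }
  bind_rows(checks)
}
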
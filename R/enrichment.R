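#' Fisher exact over-representation test per annotation term
#'
#' One-sided hypergeometric tail per term: the probability of seeing at least
#' the observed number of term-annotated genes in a DEG set of the given size
#' drawn from the universe. P-values are deliberately left uncorrected; the
#' conventional reporting filter (`p < 0.05` and at least two annotated DEGs)
#' is recorded in the `reported` flag and applied by [filter_terms()]. Terms
#' with no annotated gene in the universe are skipped with a message.
#'
#' @param deg Character vector of DEG IDs (must be a subset of `universe`).
#' @param universe Character vector of all quantified gene IDs.
#' @param annotations Tibble with `term`, `gene` (one row per annotation),
#'   optionally `term_name`.
#' @return Tibble with `term`, `in_deg`, `deg_size`, `in_universe`,
#'   `universe_size`, `p`, `reported` (and `term_name` when provided), sorted
#'   by `p`.
#' @examples
#' ann <- tibble::tibble(term = "T1", gene = c("g1", "g2"))
#' fisher_enrichment(c("g1", "g2"), c("g1", "g2", "g3", "g4"), ann)$p  # 1/6
#' @export
fisher_enrichment <- function(deg, universe, annotations) {
  if (!all(deg %in% universe)) abort("`deg` must be a subset of `universe`")
  universe <- unique(universe)
  deg <- unique(deg)
  ann <- annotations |>
    filter(gene %in% universe) |>
    distinct(term, gene, .keep_all = TRUE)
  dropped <- setdiff(unique(annotations$term), unique(ann$term))
  if (length(dropped)) {
    inform(sprintf("%d term(s) with no universe-annotated gene skipped", length(dropped)))
  }
  if (nrow(ann) == 0L) {
    return(tibble(term = character(), in_deg = integer(), deg_size = integer(),
                  in_universe = integer(), universe_size = integer(),
                  p = numeric(), reported = logical()))
  }
  N <- length(universe)
  n <- length(deg)
  res <- ann |>
    group_by(term) |>
    summarise(in_deg = sum(gene %in% deg), in_universe = dplyr::n(),
              .groups = "drop") |>
    mutate(
      deg_size = n,
      universe_size = N,
      p = phyper(in_deg - 1L, in_universe, N - in_universe, n,
                 lower.tail = FALSE),
      reported = p < 0.05 & in_deg >= 2L
    ) |>
    select(term, in_deg, deg_size, in_universe, universe_size, p, reported) |>
    arrange(p)
  if ("term_name" %in% names(annotations)) {
    nm <- distinct(annotations, term, term_name)
    res <- left_join(res, nm, by = "term")
  }
  res
}

#' Apply the reporting filter to an enrichment table
#'
#' Keeps terms with `p` strictly below 0.05 and at least two annotated genes
#' in the DEG set. Idempotent.
#'
#' @param rows Tibble from [fisher_enrichment()].
#' @param p_cut Strict upper bound on p.
#' @param min_genes Minimum annotated DEG count.
#' @return The reported subset of `rows`.
#' @export
filter_terms <- function(rows, p_cut = 0.05, min_genes = 2L) {
  rows[rows$p < p_cut & rows$in_deg >= min_genes, , drop = FALSE]
}

STRESS_CATEGORIES <- c("not_stress", "abiotic", "biotic", "general")

#' Assign stress-response categories to genes from their reported terms
#'
#' Each reported term carries a category (`not_stress`, `abiotic`, `biotic`,
#' or `general`; terms missing from `categories` default to `not_stress`). A
#' gene annotated with a single stress category takes it; a gene whose terms
#' mix two or more distinct stress categories collapses to `general`; a gene
#' with only `not_stress` terms stays `not_stress`. Genes with no reported
#' term are absent from the output.
#'
#' @param reported Tibble of reported terms (e.g. [filter_terms()] output).
#' @param annotations Tibble with `term`, `gene`.
#' @param categories Tibble with `term`, `category`.
#' @param deg Optional DEG ID vector; when given, only DEGs are categorized.
#' @return Tibble with `gene`, `category`.
#' @export
categorize_genes <- function(reported, annotations, categories, deg = NULL) {
  if (!all(categories$category %in% STRESS_CATEGORIES)) {
    abort(sprintf("categories must be one of: %s",
                  paste(STRESS_CATEGORIES, collapse = ", ")))
  }
  ann <- annotations |> filter(term %in% reported$term)
  if (!is.null(deg)) ann <- ann |> filter(gene %in% deg)
  ann <- ann |>
    left_join(categories, by = "term") |>
    mutate(category = dplyr::coalesce(category, "not_stress"))
  ann |>
    group_by(gene) |>
    summarise(category = {
      stress <- setdiff(unique(category), "not_stress")
      if (length(stress) == 0L) "not_stress"
      else if (length(stress) == 1L) stress
      else "general"
    }, .groups = "drop")
}
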
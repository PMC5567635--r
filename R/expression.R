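#' FPKM quantification from per-sample fragment counts
#'
#' Computes Fragments Per Kilobase of transcript per Million mapped fragments:
#' `fpkm = count * 1e9 / (length * mapped_total)`, where `mapped_total` is the
#' whole-library mapped fragment total of the sample — both subgenomes plus
#' ambiguous fragments — not the per-subgenome total. By construction the
#' identity `sum(fpkm * length * mapped_total) / 1e9 == sum(count)` holds per
#' sample.
#'
#' @param counts Long tibble with `sample_id`, `gene`, `count` (genes absent
#'   from a sample are treated as zero).
#' @param gene_info Tibble with `gene`, `subgenome`, `length` (bp) covering
#'   every gene of the universe; genes without counts get count 0.
#' @param totals Tibble with `sample_id`, `mapped_total`. If `NULL`, the sum
#'   of counts per sample is used.
#' @return Long tibble with `sample_id`, `gene`, `subgenome`, `length`,
#'   `count`, `fpkm`.
#' @examples
#' counts <- tibble::tibble(sample_id = "s1", gene = "g", count = 10)
#' gi <- tibble::tibble(gene = "g", subgenome = "AT", length = 1000)
#' tot <- tibble::tibble(sample_id = "s1", mapped_total = 1e6)
#' compute_fpkm(counts, gi, tot)$fpkm  # 10
#' @export
compute_fpkm <- function(counts, gene_info, totals = NULL) {
  if (any(gene_info$length <= 0)) abort("zero-length gene in `gene_info`")
  grid <- tidyr::expand_grid(sample_id = unique(counts$sample_id),
                             gene = gene_info$gene)
  x <- grid |>
    left_join(counts[, c("sample_id", "gene", "count")],
              by = c("sample_id", "gene")) |>
    mutate(count = dplyr::coalesce(count, 0L)) |>
    left_join(gene_info[, c("gene", "subgenome", "length")], by = "gene")
  if (is.null(totals)) {
    totals <- x |> group_by(sample_id) |> summarise(mapped_total = sum(count))
  }
  x <- left_join(x, totals, by = "sample_id")
  if (any(x$mapped_total <= 0)) abort("library mapped total must be > 0")
  x |>
    mutate(fpkm = count * 1e9 / (length * mapped_total)) |>
    select(sample_id, gene, subgenome, length, count, fpkm)
}

#' Differential expression between two accession groups
#'
#' Per gene, a two-sample t-test on `log2(FPKM + 1)` across the replicates of
#' the two groups, with Benjamini-Hochberg adjustment over all tested genes.
#' The default pools the two group variances (Student t): with a balanced
#' design and a common per-gene noise model the pooled test has exact size,
#' whereas the Welch-Satterthwaite approximation is measurably conservative
#' at three replicates per group (true size about 0.035 at nominal 0.05);
#' `var_equal = FALSE` switches to Welch for unbalanced or
#' heteroskedastic designs. Genes with zero counts in every sample are
#' skipped. A gene whose replicate values are constant within both groups
#' gets `p = 1` when the group means agree and `p = 0` when they differ (a
#' degenerate zero-variance contrast).
#'
#' @param expr Long FPKM tibble from [compute_fpkm()].
#' @param samples Tibble with `sample_id`, `accession` mapping samples to
#'   groups.
#' @param group1,group2 The two accession labels to contrast.
#' @param alpha Significance level on the BH-adjusted q-value.
#' @param var_equal Pool the group variances (default) or use Welch's
#'   unequal-variance test.
#' @return Tibble of class `homeo_de`: `gene`, `subgenome`, `mean_fpkm_1`,
#'   `mean_fpkm_2`, `log2fc` (group 2 over group 1 on the pseudocounted log
#'   scale), `p`, `q`, `significant`, `direction` (`"up_in_<group>"`).
#' @export
differential_expression <- function(expr, samples, group1 = "acc1",
                                    group2 = "acc2", alpha = 0.05,
                                    var_equal = TRUE) {
  x <- expr |>
    inner_join(samples[, c("sample_id", "accession")], by = "sample_id") |>
    filter(accession %in% c(group1, group2)) |>
    mutate(y = log2(fpkm + 1))
  n_rep <- x |> distinct(accession, sample_id) |> count(accession)
  if (nrow(n_rep) < 2L || any(n_rep$n < 2L)) {
    abort("need at least two replicates in each group")
  }
  st <- x |>
    group_by(gene, subgenome) |>
    summarise(
      any_count = any(count > 0),
      m1 = mean(y[accession == group1]),
      m2 = mean(y[accession == group2]),
      v1 = var(y[accession == group1]),
      v2 = var(y[accession == group2]),
      n1 = sum(accession == group1),
      n2 = sum(accession == group2),
      mean_fpkm_1 = mean(fpkm[accession == group1]),
      mean_fpkm_2 = mean(fpkm[accession == group2]),
      .groups = "drop"
    ) |>
    filter(any_count)
  if (var_equal) {
    sp2 <- ((st$n1 - 1) * st$v1 + (st$n2 - 1) * st$v2) / (st$n1 + st$n2 - 2)
    se2 <- sp2 * (1 / st$n1 + 1 / st$n2)
    df <- st$n1 + st$n2 - 2
  } else {
    se2 <- st$v1 / st$n1 + st$v2 / st$n2
    df <- se2^2 / ((st$v1 / st$n1)^2 / (st$n1 - 1) +
                     (st$v2 / st$n2)^2 / (st$n2 - 1))
  }
  tstat <- (st$m2 - st$m1) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(st$m1[degenerate] == st$m2[degenerate], 1, 0)
  out <- st |>
    mutate(
      log2fc = m2 - m1,
      p = p,
      q = p.adjust(p, method = "BH"),
      significant = q <= alpha,
      direction = ifelse(log2fc >= 0, paste0("up_in_", group2),
                         paste0("up_in_", group1))
    ) |>
    select(gene, subgenome, mean_fpkm_1, mean_fpkm_2, log2fc, p, q,
           significant, direction) |>
    arrange(p)
  attr(out, "groups") <- c(group1, group2)
  attr(out, "alpha") <- alpha
  class(out) <- c("homeo_de", class(out))
  out
}

#' Summarise DEG directions as counts and rounded percentages
#'
#' @param degs A `homeo_de` tibble (or any tibble with a `direction` column),
#'   typically pre-filtered to significant genes.
#' @return Tibble with `direction`, `n`, `pct` (percent of DEGs, rounded to
#'   the nearest integer). Zero rows in, zero rows out.
#' @examples
#' degs <- tibble::tibble(direction = rep(c("up_in_acc2", "up_in_acc1"),
#'                                        c(90, 58)))
#' direction_summary(degs)  # 61% / 39%
#' @export
direction_summary <- function(degs) {
  if (nrow(degs) == 0L) {
    return(tibble(direction = character(), n = integer(), pct = integer()))
  }
  degs |>
    count(direction) |>
    mutate(pct = as.integer(round(100 * n / sum(n)))) |>
    arrange(desc(n))
}

#' Subgenome expression-dominance ratio over homoeologous pairs
#'
#' For one accession group, averages each gene's FPKM across the group's
#' replicates, then forms `log2(AT FPKM / AA FPKM)` per homoeologous pair.
#' The ratio uses the ratio of average FPKMs (not the average of per-replicate
#' ratios). Pairs with a zero average on either side — including pairs with a
#' member absent from the matrix — are excluded and counted.
#'
#' @param expr Long FPKM tibble from [compute_fpkm()].
#' @param map Homoeolog map tibble (`pair_id`, `at_gene`, `aa_gene`).
#' @param samples Sample sheet (`sample_id`, `accession`).
#' @param group Accession whose replicates are averaged.
#' @return Object of class `ratio_summary`: list with `pairs` (tibble
#'   `pair_id`, `at_fpkm`, `aa_fpkm`, `log2_ratio`), `analyzed`, `excluded`,
#'   `total_pairs`, `mean_log2`, `median_log2`, `group`.
#' @export
subgenome_ratio <- function(expr, map, samples, group) {
  ids <- samples$sample_id[samples$accession == group]
  avg <- expr |>
    filter(sample_id %in% ids) |>
    group_by(gene) |>
    summarise(mean_fpkm = mean(fpkm), .groups = "drop")
  look <- setNames(avg$mean_fpkm, avg$gene)
  at_f <- unname(look[map$at_gene]); at_f[is.na(at_f)] <- 0
  aa_f <- unname(look[map$aa_gene]); aa_f[is.na(aa_f)] <- 0
  keep <- at_f > 0 & aa_f > 0
  pairs <- tibble(
    pair_id = map$pair_id[keep],
    at_fpkm = at_f[keep],
    aa_fpkm = aa_f[keep],
    log2_ratio = log2(at_f[keep] / aa_f[keep])
  )
  structure(list(
    pairs = pairs,
    analyzed = sum(keep),
    excluded = sum(!keep),
    total_pairs = nrow(map),
    mean_log2 = if (nrow(pairs)) mean(pairs$log2_ratio) else NA_real_,
    median_log2 = if (nrow(pairs)) median(pairs$log2_ratio) else NA_real_,
    group = group
  ), class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf(
    "<ratio_summary> %s: %d pairs analyzed, %d excluded (zero FPKM); mean log2(AT/AA) %.3f, median %.3f\n",
    x$group, x$analyzed, x$excluded, x$mean_log2, x$median_log2
  ))
  invisible(x)
}
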
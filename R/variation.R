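snp_key <- function(x) paste(x$transcript, x$pos, x$alt, sep = ":")

check_ref_consistency <- function(sets) {
  refs <- bind_rows(lapply(sets, function(s) s[, c("transcript", "pos", "ref")]))
  bad <- refs |>
    distinct(transcript, pos, ref) |>
    count(transcript, pos, name = "n_ref") |>
    filter(n_ref > 1L)
  if (nrow(bad)) {
    abort(sprintf("reference allele mismatch across sets at %s:%d",
                  bad$transcript[1], bad$pos[1]))
  }
  invisible(TRUE)
}

#' Filter a SNP set by indel status and quality
#'
#' Drops indel records (when `remove_indels`) and records whose quality does
#' not strictly exceed `min_quality`. A record with quality exactly equal to
#' the threshold is dropped.
#'
#' @param snps SNP tibble (`transcript`, `pos`, `ref`, `alt`, `qual`,
#'   `is_indel`).
#' @param remove_indels Drop `is_indel` records?
#' @param min_quality Retain only `qual > min_quality`.
#' @return Filtered SNP tibble.
#' @export
filter_snps <- function(snps, remove_indels = TRUE, min_quality = 30) {
  out <- snps
  if (remove_indels) out <- out[!out$is_indel, , drop = FALSE]
  out[out$qual > min_quality, , drop = FALSE]
}

#' Pairwise shared/private partition of two SNP sets
#'
#' Variants are identified by their `(transcript, position, alt)` key; a
#' reference-allele disagreement at a shared key is an error.
#'
#' @param a,b SNP tibbles.
#' @return List of class `pairwise_partition` with counts `shared`, `a_only`,
#'   `b_only` and totals `a_total`, `b_total`.
#' @examples
#' a <- tibble::tibble(transcript = "t", pos = 1:3, ref = "A", alt = "C",
#'                     qual = 50, is_indel = FALSE)
#' b <- dplyr::mutate(a, pos = 2:4)
#' partition_pairwise(a, b)
#' @export
partition_pairwise <- function(a, b) {
  check_ref_consistency(list(a, b))
  ka <- snp_key(a); kb <- snp_key(b)
  structure(list(
    shared = length(intersect(ka, kb)),
    a_only = length(setdiff(ka, kb)),
    b_only = length(setdiff(kb, ka)),
    a_total = length(unique(ka)),
    b_total = length(unique(kb))
  ), class = "pairwise_partition")
}

#' @export
print.pairwise_partition <- function(x, ...) {
  cat(sprintf("<pairwise_partition> shared %d | A-only %d | B-only %d (A total %d, B total %d)\n",
              x$shared, x$a_only, x$b_only, x$a_total, x$b_total))
  invisible(x)
}

#' Six-cell partition of two accessions' SNPs against a reference panel
#'
#' Splits each pairwise category (shared between the accessions, private to
#' each) by presence in the panel, where "in panel" means present in at least
#' one panel member. The `a_only_not_panel` and `b_only_not_panel` cells are
#' the private variants of each accession in the strict population-genetic
#' sense: found in one accession and in no panel member.
#'
#' @param a,b Accession SNP tibbles.
#' @param panel A SNP tibble of the panel union, or a list of per-member SNP
#'   tibbles (union taken internally).
#' @return List of class `panel_partition` with the six cell counts and
#'   derived totals (`a_total`, `b_total`, `a_not_in_panel`,
#'   `b_not_in_panel`).
#' @export
partition_with_panel <- function(a, b, panel) {
  if (is.data.frame(panel)) panel <- list(panel)
  check_ref_consistency(c(list(a, b), panel))
  ka <- unique(snp_key(a)); kb <- unique(snp_key(b))
  kp <- unique(unlist(lapply(panel, snp_key)))
  sh <- intersect(ka, kb); ao <- setdiff(ka, kb); bo <- setdiff(kb, ka)
  cells <- list(
    shared_in_panel = sum(sh %in% kp),
    shared_not_panel = sum(!(sh %in% kp)),
    a_only_in_panel = sum(ao %in% kp),
    a_only_not_panel = sum(!(ao %in% kp)),
    b_only_in_panel = sum(bo %in% kp),
    b_only_not_panel = sum(!(bo %in% kp))
  )
  cells$a_total <- length(ka)
  cells$b_total <- length(kb)
  cells$a_not_in_panel <- cells$shared_not_panel + cells$a_only_not_panel
  cells$b_not_in_panel <- cells$shared_not_panel + cells$b_only_not_panel
  structure(cells, class = "panel_partition")
}

#' @export
print.panel_partition <- function(x, ...) {
  cat("<panel_partition>\n")
  cat(sprintf("  shared:  %d in panel, %d not (total %d)\n",
              x$shared_in_panel, x$shared_not_panel,
              x$shared_in_panel + x$shared_not_panel))
  cat(sprintf("  A-only:  %d in panel, %d private (A total %d, not-in-panel %d)\n",
              x$a_only_in_panel, x$a_only_not_panel, x$a_total, x$a_not_in_panel))
  cat(sprintf("  B-only:  %d in panel, %d private (B total %d, not-in-panel %d)\n",
              x$b_only_in_panel, x$b_only_not_panel, x$b_total, x$b_not_in_panel))
  invisible(x)
}

#' Chi-square test for SNP enrichment in a gene set, bp-normalized
#'
#' Tests whether `snps_in_degs` of `total_snps` variants falling inside a gene
#' set spanning `deg_bp` of `total_bp` transcript space departs from a uniform
#' per-bp distribution. The default is a two-cell goodness-of-fit: expected
#' in-set count `total_snps * deg_bp / total_bp`, chi-square summed over the
#' in-set and out-of-set cells, 1 df. `method = "contingency"` instead builds
#' the 2x2 table of SNP/non-SNP bp by in/out of the set (no continuity
#' correction).
#'
#' @param total_snps,snps_in_degs Total variants and variants inside the set.
#' @param deg_bp,total_bp Transcript bp inside the set and overall.
#' @param method `"goodness_of_fit"` (default) or `"contingency"`.
#' @return Tibble with `statistic`, `df`, `p`, `expected_in`.
#' @examples
#' snp_deg_enrichment(100, 20, 100, 1000)
#' @export
snp_deg_enrichment <- function(total_snps, snps_in_degs, deg_bp, total_bp,
                               method = c("goodness_of_fit", "contingency")) {
  method <- match.arg(method)
  if (deg_bp > total_bp) abort("deg_bp exceeds total_bp")
  if (snps_in_degs > total_snps) abort("snps_in_degs exceeds total_snps")
  if (method == "goodness_of_fit") {
    p_in <- deg_bp / total_bp
    exp_in <- total_snps * p_in
    exp_out <- total_snps * (1 - p_in)
    if (exp_in == 0 || exp_out == 0) abort("an expected cell is zero")
    obs_out <- total_snps - snps_in_degs
    stat <- (snps_in_degs - exp_in)^2 / exp_in + (obs_out - exp_out)^2 / exp_out
  } else {
    m <- matrix(c(snps_in_degs, total_snps - snps_in_degs,
                  deg_bp - snps_in_degs,
                  (total_bp - deg_bp) - (total_snps - snps_in_degs)),
                nrow = 2L)
    if (any(m < 0)) abort("contingency cells must be non-negative")
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(e == 0)) abort("an expected cell is zero")
    stat <- sum((m - e)^2 / e)
    exp_in <- e[1, 1]
  }
  tibble(statistic = stat, df = 1L, p = pchisq(stat, df = 1L, lower.tail = FALSE),
         expected_in = exp_in)
}

#' Rank panel members by genotype similarity to a query SNP set
#'
#' Scores every panel member by the Jaccard similarity of its variant keys
#' with the query's, after the query has been quality-filtered. Ties are
#' broken lexicographically by member name and flagged.
#'
#' @param query Query SNP tibble (apply [filter_snps()] first for the
#'   conventional `qual > 30` filter).
#' @param panel Named list of panel-member SNP tibbles.
#' @return Tibble with `member`, `score`, `rank`, `tied`, sorted by
#'   descending score.
#' @export
match_accessions <- function(query, panel) {
  kq <- unique(snp_key(query))
  scores <- map_dbl(panel, function(m) {
    km <- unique(snp_key(m))
    u <- length(union(kq, km))
    if (u == 0L) 0 else length(intersect(kq, km)) / u
  })
  out <- tibble(member = names(panel) %||% as.character(seq_along(panel)),
                score = unname(scores)) |>
    arrange(desc(score), member) |>
    mutate(rank = dplyr::min_rank(desc(score)),
           tied = duplicated(score) | duplicated(score, fromLast = TRUE))
  out
}
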
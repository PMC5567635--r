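#' Join a DEG list against the homoeolog map
#'
#' Splits the differentially expressed genes into complete homoeologous pairs
#' (both members DE), AT-only and AA-only genes, with the arithmetic
#' identities `total = at_only + aa_only + 2 * pairs`,
#' `at_total = at_only + pairs` and `aa_total = aa_only + pairs` holding by
#' construction.
#'
#' @param degs Tibble with `gene`, `subgenome` and (optionally) `direction`
#'   columns — typically the significant rows of
#'   [differential_expression()].
#' @param map Homoeolog map tibble (`pair_id`, `at_gene`, `aa_gene`).
#' @return Object of class `pair_join`: list with the counts (`total`,
#'   `at_total`, `aa_total`, `at_only`, `aa_only`, `pairs`) and `pair_rows`
#'   (tibble `pair_id`, `at_gene`, `aa_gene`, `dir_at`, `dir_aa`).
#' @examples
#' # the canonical 68 + 38 + 2*21 layout
#' map <- tibble::tibble(pair_id = sprintf("P%03d", 1:21),
#'                       at_gene = sprintf("AT_%03d", 1:21),
#'                       aa_gene = sprintf("AA_%03d", 1:21))
#' degs <- tibble::tibble(
#'   gene = c(map$at_gene, map$aa_gene, sprintf("AT_x%02d", 1:68),
#'            sprintf("AA_x%02d", 1:38)),
#'   subgenome = rep(c("AT", "AA", "AT", "AA"), c(21, 21, 68, 38)),
#'   direction = "up_in_acc2")
#' join_pairs(degs, map)
#' @export
join_pairs <- function(degs, map) {
  deg_genes <- degs$gene
  dirs <- if ("direction" %in% names(degs)) degs$direction else rep(NA_character_, nrow(degs))
  dir_of <- setNames(dirs, deg_genes)
  complete <- map$at_gene %in% deg_genes & map$aa_gene %in% deg_genes
  pair_rows <- tibble(
    pair_id = map$pair_id[complete],
    at_gene = map$at_gene[complete],
    aa_gene = map$aa_gene[complete],
    dir_at = unname(dir_of[map$at_gene[complete]]),
    dir_aa = unname(dir_of[map$aa_gene[complete]])
  )
  at_total <- sum(degs$subgenome == "AT")
  aa_total <- sum(degs$subgenome == "AA")
  n_pairs <- nrow(pair_rows)
  structure(list(
    total = nrow(degs),
    at_total = at_total,
    aa_total = aa_total,
    at_only = at_total - n_pairs,
    aa_only = aa_total - n_pairs,
    pairs = n_pairs,
    pair_rows = pair_rows
  ), class = "pair_join")
}

#' @export
print.pair_join <- function(x, ...) {
  cat(sprintf("<pair_join> %d DEGs = %d AT-only + %d AA-only + 2 x %d pairs\n",
              x$total, x$at_only, x$aa_only, x$pairs))
  cat(sprintf("  subgenome totals: AT %d, AA %d\n", x$at_total, x$aa_total))
  invisible(x)
}

# integer pair labels over a universe: 0 = cannot complete a pair
universe_pair_ids <- function(universe, map) {
  pid <- integer(length(universe))
  at_i <- match(universe, map$at_gene)
  aa_i <- match(universe, map$aa_gene)
  pid[!is.na(at_i)] <- at_i[!is.na(at_i)]
  pid[!is.na(aa_i)] <- aa_i[!is.na(aa_i)]
  # a pair can only complete if both members are present in the universe
  tab <- tabulate(pid, nbins = nrow(map))
  pid[pid > 0L & tab[pmax(pid, 1L)] < 2L] <- 0L
  pid
}

#' Permutation test for enrichment of homoeologous pairs among DEGs
#'
#' Draws `replicates` random gene sets of size `n_draw` uniformly without
#' replacement from the quantified universe (paired and unpaired genes alike),
#' counts the complete homoeologous pairs in each, and reports the empirical
#' tail probability of the observed pair count with the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + replicates)`, together with the
#' full null histogram and its maximum. With the add-one estimator, a p-value
#' below `1/replicates` is only reportable when no null draw reaches the
#' observed count.
#'
#' @param universe Character vector of gene IDs (the full quantified gene
#'   list, unpaired genes included).
#' @param map Homoeolog map tibble.
#' @param n_draw Number of genes per draw (the DEG count).
#' @param observed_pairs Observed complete-pair count among the DEGs.
#' @param replicates Number of permutation draws.
#' @param seed Integer seed.
#' @return Object of class `pair_permutation`: list with `observed`,
#'   `replicates`, `p`, `null_max`, `null_mean`, `histogram` (tibble `pairs`,
#'   `n`), `seed`.
#' @export
pair_enrichment_permutation <- function(universe, map, n_draw, observed_pairs,
                                        replicates = 1e6, seed = 1L) {
  n <- length(universe)
  if (n_draw > n) abort("n_draw exceeds the universe size")
  if (observed_pairs > floor(n_draw / 2)) {
    abort("observed_pairs exceeds floor(n_draw / 2): impossible")
  }
  pid <- universe_pair_ids(universe, map)
  set.seed(seed)
  replicates <- as.integer(replicates)
  counts <- integer(replicates)
  for (i in seq_len(replicates)) {
    s <- pid[sample.int(n, n_draw)]
    s <- s[s > 0L]
    counts[i] <- length(s) - length(unique(s))
  }
  hist_ <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  structure(list(
    observed = observed_pairs,
    replicates = replicates,
    p = (1 + sum(counts >= observed_pairs)) / (1 + replicates),
    null_max = max(counts),
    null_mean = mean(counts),
    histogram = tibble(pairs = seq_along(hist_) - 1L, n = hist_),
    seed = seed
  ), class = "pair_permutation")
}

#' @export
print.pair_permutation <- function(x, ...) {
  cat(sprintf("<pair_permutation> observed %d pairs; %d draws; null max %d; p = %.3g\n",
              x$observed, x$replicates, x$null_max, x$p))
  invisible(x)
}

#' Exact tail probability of the pair count under uniform draws
#'
#' Closed-form distribution of the number of complete homoeologous pairs in a
#' uniform draw of `n_draw` genes without replacement from a universe holding
#' `P` complete pairs and `U` unpaired (or partner-less) genes:
#' `P(K = j) = C(P, j) * sum_m C(P - j, m) 2^m C(U, n - 2j - m) / C(N, n)`
#' (choose the `j` complete pairs, then `m` half-pairs, then singletons).
#' Serves as the independent oracle for the permutation test and scales to
#' arbitrarily large universes through log-space binomial coefficients.
#'
#' @inheritParams pair_enrichment_permutation
#' @param observed_pairs Tail threshold: returns `P(K >= observed_pairs)`.
#' @return Tibble with `p_tail`, `expected`, and the full `distribution`
#'   tibble (`pairs`, `prob`) as a list-column.
#' @export
pair_enrichment_exact <- function(universe, map, n_draw, observed_pairs) {
  n <- length(universe)
  if (n_draw > n) abort("n_draw exceeds the universe size")
  pid <- universe_pair_ids(universe, map)
  P <- length(unique(pid[pid > 0L]))
  U <- sum(pid == 0L)
  jmax <- min(P, floor(n_draw / 2))
  lgN <- lchoose(n, n_draw)
  probs <- map_dbl(0:jmax, function(j) {
    m <- 0:min(P - j, n_draw - 2 * j)
    terms <- lchoose(P - j, m) + m * log(2) + lchoose(U, n_draw - 2 * j - m)
    sum(exp(lchoose(P, j) + terms - lgN))
  })
  dist <- tibble(pairs = 0:jmax, prob = probs)
  tibble(
    p_tail = sum(probs[dist$pairs >= observed_pairs]),
    expected = sum(dist$pairs * dist$prob),
    distribution = list(dist)
  )
}

#' Direction concordance of complete DE homoeologous pairs
#'
#' Counts pairs whose two members moved in the same direction and tests
#' departure from coin-flip concordance with a two-sided exact sign test:
#' `p = min(1, 2 * P(X >= max(c, n - c)))`, `X ~ Binomial(n, 1/2)`.
#'
#' @param pairjoin A [join_pairs()] result whose `pair_rows` carry both
#'   directions.
#' @return Tibble with `concordant`, `discordant`, `p`.
#' @examples
#' # 21 of 21 concordant: p = 2 * 0.5^21 = 0.5^20
#' @export
direction_concordance <- function(pairjoin) {
  pr <- pairjoin$pair_rows
  n <- nrow(pr)
  if (n == 0L) return(tibble(concordant = 0L, discordant = 0L, p = NA_real_))
  if (any(is.na(pr$dir_at) | is.na(pr$dir_aa))) {
    abort("pair rows lack directions; build the pair join from a DEG table with a `direction` column")
  }
  conc <- sum(pr$dir_at == pr$dir_aa)
  k <- max(conc, n - conc)
  p <- min(1, 2 * pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
  tibble(concordant = conc, discordant = n - conc, p = p)
}
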
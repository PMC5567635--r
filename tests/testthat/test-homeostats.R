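make_degs <- function(map, n_pairs_de, n_at_only, n_aa_only,
                      dir = "up_in_acc2") {
  tibble::tibble(
    gene = c(map$at_gene[seq_len(n_pairs_de)], map$aa_gene[seq_len(n_pairs_de)],
             sprintf("AT_x%03d", seq_len(n_at_only)),
             sprintf("AA_x%03d", seq_len(n_aa_only))),
    subgenome = rep(c("AT", "AA", "AT", "AA"),
                    c(n_pairs_de, n_pairs_de, n_at_only, n_aa_only)),
    direction = dir
  )
}

test_that("the canonical DEG layout joins into its printed identities", {
  map <- toy_map(30)
  pj <- join_pairs(make_degs(map, 21, 68, 38), map)
  expect_equal(pj$total, 148)
  expect_equal(pj$at_total, 89)
  expect_equal(pj$aa_total, 59)
  expect_equal(pj$at_only, 68)
  expect_equal(pj$aa_only, 38)
  expect_equal(pj$pairs, 21)
  g <- glance(pj)
  expect_equal(g$total, g$at_only + g$aa_only + 2 * g$pairs)
})

test_that("degenerate joins behave", {
  map <- toy_map(5)
  empty <- tibble::tibble(gene = character(), subgenome = character(),
                          direction = character())
  pj <- join_pairs(empty, map)
  expect_equal(unlist(pj[c("total", "at_only", "aa_only", "pairs")]),
               c(total = 0L, at_only = 0L, aa_only = 0L, pairs = 0L))
  degs <- make_degs(map, 2, 1, 1)
  pj2 <- join_pairs(degs, map[0, ])
  expect_equal(pj2$pairs, 0)
  expect_equal(pj2$at_only, pj2$at_total)
})

test_that("join identities hold on fuzzed random DEG sets", {
  set.seed(77)
  map <- toy_map(40)
  all_genes <- c(map$at_gene, map$aa_gene,
                 sprintf("AT_u%02d", 1:15), sprintf("AA_u%02d", 1:15))
  sub_of <- ifelse(startsWith(all_genes, "AT"), "AT", "AA")
  for (i in 1:25) {
    take <- sample(length(all_genes), sample(0:60, 1))
    degs <- tibble::tibble(gene = all_genes[take], subgenome = sub_of[take],
                           direction = sample(c("up_in_acc1", "up_in_acc2"),
                                              length(take), replace = TRUE))
    pj <- join_pairs(degs, map)
    expect_equal(pj$total, pj$at_only + pj$aa_only + 2 * pj$pairs)
    expect_equal(pj$at_total, pj$at_only + pj$pairs)
    expect_equal(pj$aa_total, pj$aa_only + pj$pairs)
  }
})

test_that("two-pair universe gives the enumerated tail probability 1/3", {
  map <- toy_map(2)
  universe <- c(map$at_gene, map$aa_gene)
  ex <- pair_enrichment_exact(universe, map, 2, 1)
  expect_equal(ex$p_tail, 1 / 3, tolerance = 1e-12)
  pr <- pair_enrichment_permutation(universe, map, 2, 1,
                                    replicates = 1e5, seed = 3)
  se <- sqrt((1 / 3) * (2 / 3) / 1e5)
  expect_lt(abs(pr$p - 1 / 3), 3 * se)
})

test_that("single-gene draws can never contain a pair", {
  map <- toy_map(3)
  universe <- c(map$at_gene, map$aa_gene)
  pr <- pair_enrichment_permutation(universe, map, 1, 0,
                                    replicates = 2000, seed = 1)
  expect_equal(pr$null_max, 0)
  expect_equal(pr$p, 1)
  expect_error(pair_enrichment_permutation(universe, map, 3, 2, 100, 1),
               "impossible")
})

test_that("permutation agrees with the exact oracle on small universes", {
  set.seed(31)
  for (trial in 1:8) {
    P <- sample(1:4, 1)
    U <- sample(0:4, 1)
    map <- toy_map(P)
    universe <- c(map$at_gene, map$aa_gene,
                  if (U) sprintf("U%02d", seq_len(U)))
    n <- length(universe)
    n_draw <- sample(2:n, 1)
    obs <- sample(0:min(P, n_draw %/% 2), 1)
    ex <- pair_enrichment_exact(universe, map, n_draw, obs)
    reps <- 2e4
    pr <- pair_enrichment_permutation(universe, map, n_draw, obs,
                                      replicates = reps, seed = trial)
    se <- sqrt(max(ex$p_tail * (1 - ex$p_tail), 0) / reps)
    expect_lt(abs(pr$p - ex$p_tail), 3 * se + 2 / reps)
    # histogram mean matches the closed-form expectation
    em <- sum(pr$histogram$pairs * pr$histogram$n) / reps
    sd_null <- sqrt(max(sum(ex$distribution[[1]]$pairs^2 * ex$distribution[[1]]$prob) -
                          ex$expected^2, 0))
    expect_lt(abs(em - ex$expected), 3 * sd_null / sqrt(reps) + 1e-9)
  }
})

test_that("exact distribution matches full enumeration on tiny universes", {
  set.seed(55)
  for (trial in 1:6) {
    P <- sample(0:3, 1); U <- sample(0:3, 1)
    if (2 * P + U < 2) next
    map <- toy_map(max(P, 1))[seq_len(P), ]
    universe <- c(map$at_gene, map$aa_gene, if (U) sprintf("U%02d", seq_len(U)))
    n_draw <- sample(seq_len(length(universe)), 1)
    for (obs in 0:min(P, n_draw %/% 2)) {
      br <- enum_pair_tail(universe, map, n_draw, obs)
      ex <- pair_enrichment_exact(universe, map, n_draw, obs)
      expect_equal(ex$p_tail, br$tail, tolerance = 1e-12)
      expect_equal(ex$expected, br$mean, tolerance = 1e-12)
    }
  }
})

test_that("fixed seeds reproduce the permutation result exactly", {
  map <- toy_map(10)
  universe <- c(map$at_gene, map$aa_gene, sprintf("U%02d", 1:5))
  a <- pair_enrichment_permutation(universe, map, 6, 1, 5000, seed = 99)
  b <- pair_enrichment_permutation(universe, map, 6, 1, 5000, seed = 99)
  expect_identical(a, b)
  expect_equal(sum(a$histogram$n), a$replicates)
  expect_equal(a$null_max, max(a$histogram$pairs[a$histogram$n > 0]))
})

test_that("direction concordance follows the exact binomial sign test", {
  mk <- function(n, conc) {
    pr <- tibble::tibble(
      pair_id = sprintf("p%d", seq_len(n)), at_gene = "x", aa_gene = "y",
      dir_at = "up_in_acc2",
      dir_aa = rep(c("up_in_acc2", "up_in_acc1"), c(conc, n - conc))
    )
    structure(list(pair_rows = pr), class = "pair_join")
  }
  expect_equal(direction_concordance(mk(21, 21))$p, 0.5^20, tolerance = 1e-12)
  expect_equal(direction_concordance(mk(1, 1))$p, 1)
  expect_equal(direction_concordance(mk(20, 10))$p, 1)
  r <- direction_concordance(mk(12, 9))
  expect_equal(r$concordant, 9)
  expect_equal(r$p, min(1, 2 * pbinom(8, 12, 0.5, lower.tail = FALSE)))
})
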
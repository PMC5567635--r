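test_that("FPKM follows its defining formula", {
  counts <- tibble::tibble(sample_id = "s1", gene = c("g1", "g2"),
                           count = c(10L, 0L))
  gi <- tibble::tibble(gene = c("g1", "g2"), subgenome = "AT",
                       length = c(1000L, 500L))
  tot <- tibble::tibble(sample_id = "s1", mapped_total = 1e6)
  x <- compute_fpkm(counts, gi, tot)
  expect_equal(x$fpkm[x$gene == "g1"], 10)
  expect_equal(x$fpkm[x$gene == "g2"], 0)
  expect_error(compute_fpkm(counts, dplyr::mutate(gi, length = c(1000L, 0L)), tot),
               "zero-length")
  expect_error(compute_fpkm(counts, gi,
                            tibble::tibble(sample_id = "s1", mapped_total = 0)),
               "> 0")
})

test_that("the FPKM conservation identity holds to 1e-9 on simulated samples", {
  cfg <- tiny_config(reads_per_sample = 20000)
  sg <- simulate_subgenomes(cfg)
  et <- simulate_expression_truth(sg, cfg)
  cnt <- simulate_counts(et, cfg)
  gi <- dplyr::bind_rows(sg$at, sg$aa)[, c("gene", "subgenome", "length")]
  x <- compute_fpkm(cnt, gi)
  chk <- x |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(
      lhs = sum(fpkm * length) * sum(count) / 1e9,
      rhs = sum(count)
    )
  expect_true(all(abs(chk$lhs - chk$rhs) / chk$rhs < 1e-9))
})

test_that("ambiguous fragments enter the FPKM denominator but no gene count", {
  a <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    call = c("AT", "AT", "ambiguous"),
    gene = c("g1", "g1", NA), score = 5L, margin = c(5L, 5L, 0L)
  )
  cf <- count_fragments(a)
  tot <- attr(cf, "totals")
  expect_equal(cf$count[cf$gene == "g1"], 2L)
  expect_equal(tot$at, 2L)
  expect_equal(tot$mapped, 3L)
})

test_that("identical groups produce no significant genes", {
  cfg <- tiny_config(de_log2fc = 0, reads_per_sample = 20000)
  sg <- simulate_subgenomes(cfg)
  et <- simulate_expression_truth(sg, cfg)
  x <- compute_fpkm(simulate_counts(et, cfg),
                    dplyr::bind_rows(sg$at, sg$aa)[, c("gene", "subgenome", "length")])
  de <- differential_expression(x, sample_sheet(cfg))
  expect_equal(sum(de$significant), 0)
  expect_true(all(de$q >= de$p - 1e-12))
  expect_true(all(de$q <= 1))
  # BH q monotone in p rank
  expect_true(all(diff(de$q[order(de$p)]) >= -1e-12))
})

test_that("degenerate zero-variance genes get the conventional p", {
  expr <- tidyr::expand_grid(sample_id = sprintf("s%d", 1:6), gene = c("g1", "g2")) |>
    dplyr::mutate(
      subgenome = "AT", length = 1000L,
      count = ifelse(gene == "g1", 10L, ifelse(sample_id %in% sprintf("s%d", 1:3), 10L, 20L)),
      fpkm = count / 10
    )
  samples <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                            accession = rep(c("acc1", "acc2"), each = 3))
  de <- differential_expression(expr, samples)
  expect_equal(de$p[de$gene == "g1"], 1)  # constant, equal means
  expect_equal(de$p[de$gene == "g2"], 0)  # constant within, means differ
  expect_error(differential_expression(expr, samples[c(1, 4), ]), "two replicates")
})

test_that("per-gene p-values agree with t.test on the same data", {
  cfg <- tiny_config(reads_per_sample = 5000)
  sg <- simulate_subgenomes(cfg)
  et <- simulate_expression_truth(sg, cfg)
  x <- compute_fpkm(simulate_counts(et, cfg),
                    dplyr::bind_rows(sg$at, sg$aa)[, c("gene", "subgenome", "length")])
  ss <- sample_sheet(cfg)
  for (ve in c(TRUE, FALSE)) {
    de <- differential_expression(x, ss, var_equal = ve)
    for (g in de$gene[c(1, 10, 25)]) {
      y <- log2(x$fpkm[x$gene == g][match(ss$sample_id, x$sample_id[x$gene == g])] + 1)
      ref <- stats::t.test(y[ss$accession == "acc2"], y[ss$accession == "acc1"],
                           var.equal = ve)
      expect_equal(de$p[de$gene == g], unname(ref$p.value), tolerance = 1e-10)
    }
  }
})

test_that("true DE genes are recovered with correct directions", {
  # regime with a DE fraction large enough for BH to have power
  res <- lapply(1:4, function(s) {
    cfg <- sim_config(n_pairs = 150, n_unpaired_per_subgenome = 20,
                      transcript_len_range = c(400L, 800L),
                      n_de_genes = 20, n_coordinated_pairs = 5, de_log2fc = 3,
                      reads_per_sample = 3e5, seed = s)
    sg <- simulate_subgenomes(cfg)
    et <- simulate_expression_truth(sg, cfg)
    x <- compute_fpkm(simulate_counts(et, cfg),
                      dplyr::bind_rows(sg$at, sg$aa)[, c("gene", "subgenome", "length")])
    de <- differential_expression(x, sample_sheet(cfg))
    tp <- de[de$significant & de$gene %in% et$gene[et$is_de], ]
    list(tp = nrow(tp), nde = sum(et$is_de),
         dir_ok = all(tp$direction == et$direction[match(tp$gene, et$gene)]))
  })
  sens <- sum(vapply(res, `[[`, numeric(1), "tp")) /
    sum(vapply(res, `[[`, numeric(1), "nde"))
  expect_gte(sens, 0.9)
  expect_true(all(vapply(res, `[[`, logical(1), "dir_ok")))
})

test_that("null genes stay unflagged at the study-like small DE fraction", {
  # composition effects are negligible when DE genes hold ~1% of the library;
  # there, practically no truly-null gene should reach significance
  counts <- vapply(1:4, function(s) {
    cfg <- sim_config(n_pairs = 400, n_unpaired_per_subgenome = 40,
                      transcript_len_range = c(400L, 800L),
                      n_de_genes = 8, n_coordinated_pairs = 2, de_log2fc = 3,
                      reads_per_sample = 3e5, seed = s + 50)
    sg <- simulate_subgenomes(cfg)
    et <- simulate_expression_truth(sg, cfg)
    x <- compute_fpkm(simulate_counts(et, cfg),
                      dplyr::bind_rows(sg$at, sg$aa)[, c("gene", "subgenome", "length")])
    de <- differential_expression(x, sample_sheet(cfg))
    c(fp = sum(de$significant & !(de$gene %in% et$gene[et$is_de])),
      null = sum(!(de$gene %in% et$gene[et$is_de])))
  }, numeric(2))
  expect_lte(sum(counts["fp", ]) / sum(counts["null", ]), 0.01)
})

test_that("direction summaries reproduce the canonical percentages", {
  d1 <- tibble::tibble(direction = rep(c("up_in_acc2", "up_in_acc1"), c(90, 58)))
  s1 <- direction_summary(d1)
  expect_equal(s1$pct[s1$direction == "up_in_acc2"], 61L)
  expect_equal(s1$pct[s1$direction == "up_in_acc1"], 39L)
  expect_equal(sum(s1$n), 148L)

  d2 <- tibble::tibble(direction = rep(c("up_in_acc2", "up_in_acc1"), c(32, 10)))
  s2 <- direction_summary(d2)
  expect_equal(s2$pct, c(76L, 24L))

  expect_equal(nrow(direction_summary(d1[0, ])), 0)
})

test_that("subgenome ratios recover the planted dominance and bookkeeping", {
  cfg <- sim_config(n_pairs = 500, n_unpaired_per_subgenome = 0,
                    transcript_len_range = c(400L, 800L),
                    n_de_genes = 0, n_coordinated_pairs = 0,
                    dominance_log2 = 1, reads_per_sample = 5e5, seed = 8)
  sg <- simulate_subgenomes(cfg)
  et <- simulate_expression_truth(sg, cfg)
  x <- compute_fpkm(simulate_counts(et, cfg),
                    dplyr::bind_rows(sg$at, sg$aa)[, c("gene", "subgenome", "length")])
  rs <- subgenome_ratio(x, sg$map, sample_sheet(cfg), "acc1")
  expect_lt(abs(rs$mean_log2 - 1), 0.1)
  expect_equal(rs$analyzed + rs$excluded, rs$total_pairs)

  # equal expression: median ratio zero, nothing excluded
  expr_eq <- tidyr::expand_grid(sample_id = sprintf("acc1_rep%d", 1:3),
                                gene = c(sg$map$at_gene[1:5], sg$map$aa_gene[1:5])) |>
    dplyr::mutate(subgenome = ifelse(startsWith(gene, "AT"), "AT", "AA"),
                  length = 500L, count = 10L, fpkm = 7)
  rs_eq <- subgenome_ratio(expr_eq, sg$map[1:5, ],
                           tibble::tibble(sample_id = sprintf("acc1_rep%d", 1:3),
                                          accession = "acc1"), "acc1")
  expect_equal(rs_eq$median_log2, 0)
  expect_equal(rs_eq$excluded, 0)

  # planting zeros on one side excludes exactly those pairs
  expr_z <- expr_eq |>
    dplyr::mutate(fpkm = ifelse(gene %in% sg$map$aa_gene[1:2], 0, fpkm))
  rs_z <- subgenome_ratio(expr_z, sg$map[1:5, ],
                          tibble::tibble(sample_id = sprintf("acc1_rep%d", 1:3),
                                         accession = "acc1"), "acc1")
  expect_equal(rs_z$excluded, 2)
  expect_equal(rs_z$analyzed, 3)
})
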
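test_that("quality filtering is strict and indel removal exact", {
  snps <- tibble::tibble(
    transcript = "t1", pos = 1:5, ref = "A",
    alt = c("C", "G", "T", "AC", "C"),
    qual = c(30, 30.0001, 45, 50, 12),
    is_indel = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  out <- filter_snps(snps, remove_indels = TRUE, min_quality = 30)
  expect_equal(out$pos, c(2L, 3L))  # qual == 30 dropped, indel dropped
  expect_equal(nrow(filter_snps(snps[0, ])), 0)

  planted <- dplyr::bind_rows(
    random_snps(100, qual = 50),
    dplyr::mutate(random_snps(20, transcripts = "t9", qual = 50),
                  alt = "CC", is_indel = TRUE)
  )
  expect_equal(nrow(filter_snps(planted, remove_indels = TRUE)),
               sum(!planted$is_indel))
})

test_that("pairwise partition is a disjoint decomposition", {
  a <- snps_from_keys(c(1, 2, 3))
  b <- snps_from_keys(c(2, 3, 4))
  pw <- partition_pairwise(a, b)
  expect_equal(pw$shared, 2)
  expect_equal(pw$a_only, 1)
  expect_equal(pw$b_only, 1)
  expect_equal(pw$a_total, pw$shared + pw$a_only)

  same <- partition_pairwise(a, a)
  expect_equal(same$a_only, 0)
  expect_equal(same$b_only, 0)

  # sets built to the published marginals reproduce them
  big_a <- snps_from_keys(seq_len(46223 + 17580))
  big_b <- snps_from_keys(c(seq_len(46223), 63803 + seq_len(11797)))
  pw2 <- partition_pairwise(big_a, big_b)
  expect_equal(pw2$shared, 46223)
  expect_equal(pw2$a_only, 17580)
  expect_equal(pw2$b_only, 11797)
  expect_equal(pw2$a_total, 63803)
  expect_equal(pw2$b_total, 58020)
})

test_that("ref mismatches across sets are an error", {
  a <- snps_from_keys(1:3)
  b <- snps_from_keys(2:4)
  b$ref[1] <- "G"
  expect_error(partition_pairwise(a, b), "mismatch")
})

test_that("panel partition matches hand enumeration and marginals", {
  a <- snps_from_keys(c(1, 2, 3))
  b <- snps_from_keys(c(2, 3, 4))
  panel <- snps_from_keys(c(3, 4, 5))
  pp <- partition_with_panel(a, b, panel)
  expect_equal(pp$shared_not_panel, 1)   # {2}
  expect_equal(pp$shared_in_panel, 1)    # {3}
  expect_equal(pp$a_only_not_panel, 1)   # {1}
  expect_equal(pp$b_only_in_panel, 1)    # {4}
  expect_equal(pp$a_only_in_panel, 0)
  expect_equal(pp$b_only_not_panel, 0)

  # published-cell construction: private counts and the shared-not-panel set
  a2 <- snps_from_keys(seq_len(46223 + 17580))
  b2 <- snps_from_keys(c(seq_len(46223), 63803 + seq_len(11797)))
  shared_not_panel <- seq_len(11648)
  a_private <- 46223 + seq_len(8447)
  b_private <- 63803 + seq_len(5943)
  panel_keys <- setdiff(c(seq_len(63803), 63803 + seq_len(11797)),
                        c(shared_not_panel, a_private, b_private))
  pp2 <- partition_with_panel(a2, b2, snps_from_keys(panel_keys))
  expect_equal(pp2$a_only_not_panel, 8447)
  expect_equal(pp2$b_only_not_panel, 5943)
  expect_equal(pp2$shared_not_panel, 11648)
  expect_equal(pp2$a_not_in_panel, 20095)
  expect_equal(pp2$b_not_in_panel, 17591)
})

test_that("panel partition marginalizes to the pairwise partition on fuzzed sets", {
  set.seed(14)
  for (i in 1:20) {
    a <- snps_from_keys(sample(50, sample(0:30, 1)))
    b <- snps_from_keys(sample(50, sample(0:30, 1)))
    panel <- snps_from_keys(sample(50, sample(0:30, 1)))
    pw <- partition_pairwise(a, b)
    pp <- partition_with_panel(a, b, panel)
    expect_equal(pp$shared_in_panel + pp$shared_not_panel, pw$shared)
    expect_equal(pp$a_only_in_panel + pp$a_only_not_panel, pw$a_only)
    expect_equal(pp$b_only_in_panel + pp$b_only_not_panel, pw$b_only)
    expect_equal(pp$a_total, nrow(a))
  }
})

test_that("the chi-square enrichment matches hand and library oracles", {
  r0 <- snp_deg_enrichment(100, 10, 100, 1000)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  r1 <- snp_deg_enrichment(100, 20, 100, 1000)
  expect_equal(r1$statistic, (20 - 10)^2 / 10 + (80 - 90)^2 / 90,
               tolerance = 1e-12)
  expect_equal(r1$p, stats::pchisq(100 / 9, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(r1$p - 0.00086), 2e-5)

  set.seed(6)
  for (i in 1:100) {
    tot_bp <- sample(5000:50000, 1)
    deg_bp <- sample(100:(tot_bp %/% 2), 1)
    n_snp <- sample(50:2000, 1)
    in_deg <- rbinom(1, n_snp, deg_bp / tot_bp)
    mine <- snp_deg_enrichment(n_snp, in_deg, deg_bp, tot_bp)
    oracle <- suppressWarnings(
      stats::chisq.test(c(in_deg, n_snp - in_deg),
                        p = c(deg_bp / tot_bp, 1 - deg_bp / tot_bp))
    )
    expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(mine$p, unname(oracle$p.value), tolerance = 1e-9)
  }

  # the 2x2 alternative agrees with chisq.test without correction
  m <- matrix(c(30, 470, 170, 9330), nrow = 2)
  mine2 <- snp_deg_enrichment(500, 30, 200, 10000, method = "contingency")
  oracle2 <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(mine2$statistic, unname(oracle2$statistic), tolerance = 1e-9)
  expect_error(snp_deg_enrichment(10, 11, 100, 1000), "exceeds")
})

test_that("panel matching ranks the planted closest member first", {
  q <- snps_from_keys(1:100)
  panel <- list(
    near = snps_from_keys(c(1:50, 201:250)),      # Jaccard 50/150
    far1 = snps_from_keys(c(1:8, 301:390)),
    far2 = snps_from_keys(401:500),               # disjoint
    same = snps_from_keys(1:100)                  # identical
  )
  r <- match_accessions(q, panel)
  expect_equal(r$member[1], "same")
  expect_equal(r$score[1], 1)
  expect_equal(r$member[2], "near")
  expect_equal(r$score[r$member == "far2"], 0)
  expect_equal(r$score[r$member == "near"], 50 / 150)
})

test_that("the consensus caller calls obvious sites and respects depth", {
  ref <- tibble::tibble(gene = "t1", subgenome = "AT", length = 30L,
                        seq = strrep("A", 30))
  pile <- tibble::tibble(transcript = "t1",
                         pos = c(rep(5L, 10), rep(9L, 2)),
                         base = "G")
  out <- call_snps(pile, ref, min_depth = 4)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 5L)
  expect_equal(out$ref, "A")
  expect_equal(out$alt, "G")
  expect_gt(out$qual, 30)
  expect_error(call_snps(dplyr::mutate(pile, transcript = "nope"), ref),
               "missing")
})

test_that("error-free study recovers exactly the coverable planted SNPs", {
  truth <- fix_study()
  asg <- fix_assignments()
  acc1_ids <- truth$samples$sample_id[truth$samples$accession == "acc1"]
  a <- asg[asg$sample_id %in% acc1_ids & asg$call == "AT", ]
  a <- a[, setdiff(names(a), "sample_id")]
  reads <- truth$reads[truth$reads$sample_id %in% acc1_ids, ]
  pl <- pileup_assignments(a, reads, truth$subgenomes$at, k = 21)
  called <- call_snps(pl, truth$subgenomes$at, min_depth = 4)
  planted <- truth$variants$acc1
  key <- function(x) paste(x$transcript, x$pos, x$alt)
  # no false positives at all
  expect_equal(setdiff(key(called), key(planted)), character(0))
  # every planted site with adequate depth is recovered
  depth <- pl |> dplyr::count(transcript, pos, name = "depth")
  pd <- dplyr::left_join(planted, depth, by = c("transcript", "pos")) |>
    dplyr::mutate(depth = dplyr::coalesce(depth, 0L))
  covered <- pd[pd$depth >= 4, ]
  expect_true(all(key(covered) %in% key(called)))
  expect_gt(nrow(covered), 20)  # the check is not vacuous
})
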
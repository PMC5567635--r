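other_base <- function(ref) {
  idx <- match(ref, BASES)
  BASES[((idx - 1L + sample.int(3L, length(ref), replace = TRUE)) %% 4L) + 1L]
}

snp_tbl <- function(transcript = character(), pos = integer(), ref = character(),
                    alt = character(), qual = numeric(),
                    is_indel = logical(length(transcript))) {
  tibble(transcript = transcript, pos = as.integer(pos), ref = ref, alt = alt,
         qual = as.numeric(qual), is_indel = is_indel)
}

#' Simulate accession and panel variant sets on the maternal subgenome
#'
#' Plants substitution variants on the AT-subgenome transcripts of two
#' accessions, mirroring variants called for the maternal subgenome against its
#' parental reference. Each accession's set has a shared core (identical
#' position and allele in both accessions; expected fraction
#' `shared_snp_fraction`) and a private remainder. Configured fractions of the
#' shared and private categories are additionally planted into one or more
#' members of a reference panel, so that every cell of the
#' shared/private-by-panel partition is populated with counts recorded in the
#' returned truth table. Panel members also carry their own background
#' variants absent from both accessions.
#'
#' @param subgenomes Result of [simulate_subgenomes()].
#' @param config A [sim_config()].
#' @return List with `acc1`, `acc2` (SNP tibbles: `transcript`, `pos`, `ref`,
#'   `alt`, `qual`, `is_indel`), `panel` (named list of SNP tibbles), and
#'   `cells`, the planted counts of the six partition cells
#'   (`shared_in_panel`, `shared_not_panel`, `a_only_in_panel`,
#'   `a_only_not_panel`, `b_only_in_panel`, `b_only_not_panel`).
#' @export
simulate_variants <- function(subgenomes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "variants"))
  at <- subgenomes$at
  r <- config$accession_snp_rate
  sf <- config$shared_snp_fraction

  if (r <= 0 || nrow(at) == 0L) {
    empty <- snp_tbl()
    panel <- rep(list(empty), config$panel_size)
    names(panel) <- sprintf("panel%02d", seq_len(config$panel_size))
    cells <- setNames(rep(0L, 6L), c(
      "shared_in_panel", "shared_not_panel", "a_only_in_panel",
      "a_only_not_panel", "b_only_in_panel", "b_only_not_panel"
    ))
    return(list(acc1 = empty, acc2 = empty, panel = panel, cells = as.list(cells)))
  }

  # per transcript, draw disjoint site sets for the three categories
  draw_sites <- function(len, gene, seqchars) {
    n_sh <- rbinom(1L, len, r * sf)
    n_pa <- rbinom(1L, len, r * (1 - sf))
    n_pb <- rbinom(1L, len, r * (1 - sf))
    n_tot <- min(n_sh + n_pa + n_pb, len)
    if (n_tot == 0L) return(NULL)
    pos <- sort(sample.int(len, n_tot))
    cat_ <- rep(c("shared", "a_only", "b_only"), c(n_sh, n_pa, n_pb))[seq_len(n_tot)]
    ref <- seqchars[pos]
    tibble(transcript = gene, pos = pos, ref = ref, alt = other_base(ref),
           category = cat_)
  }
  sites <- map(seq_len(nrow(at)), function(i) {
    draw_sites(at$length[i], at$gene[i], strsplit(at$seq[i], "", fixed = TRUE)[[1]])
  })
  sites <- bind_rows(sites)
  if (nrow(sites) == 0L) sites <- tibble(transcript = character(), pos = integer(),
                                         ref = character(), alt = character(),
                                         category = character())

  # panel membership per category
  ovl <- ifelse(sites$category == "shared",
                config$panel_overlap_shared, config$panel_overlap_private)
  sites$in_panel <- runif(nrow(sites)) < ovl & config$panel_size > 0L

  qdraw <- function(n) runif(n, config$qual_range[1], config$qual_range[2])
  as_snps <- function(d) snp_tbl(d$transcript, d$pos, d$ref, d$alt, qdraw(nrow(d)))

  acc1 <- as_snps(sites[sites$category != "b_only", ])
  acc2 <- as_snps(sites[sites$category != "a_only", ])

  # distribute panel-borne sites over members (each to >= 1 member)
  panel <- vector("list", config$panel_size)
  names(panel) <- sprintf("panel%02d", seq_len(config$panel_size))
  panel_sites <- sites[sites$in_panel, , drop = FALSE]
  member_hits <- vector("list", config$panel_size)
  if (config$panel_size > 0L) {
    for (j in seq_len(nrow(panel_sites))) {
      members <- which(runif(config$panel_size) < 0.3)
      if (length(members) == 0L) members <- sample.int(config$panel_size, 1L)
      for (mm in members) member_hits[[mm]] <- c(member_hits[[mm]], j)
    }
    # background variants unique to each panel member
    for (mm in seq_len(config$panel_size)) {
      own <- panel_sites[member_hits[[mm]], c("transcript", "pos", "ref", "alt")]
      bg_n <- rbinom(1L, sum(at$length), r * 0.25)
      if (bg_n > 0L) {
        tr_idx <- sample.int(nrow(at), bg_n, replace = TRUE, prob = at$length)
        bp <- map_int(tr_idx, function(i) sample.int(at$length[i], 1L))
        refb <- map_chr(seq_len(bg_n), function(i) {
          substr(at$seq[tr_idx[i]], bp[i], bp[i])
        })
        bg <- tibble(transcript = at$gene[tr_idx], pos = bp, ref = refb,
                     alt = other_base(refb))
        # background sites must not collide with accession sites
        bg <- anti_join(bg, sites, by = c("transcript", "pos"))
        own <- bind_rows(own, bg)
      }
      own <- distinct(own, transcript, pos, alt, .keep_all = TRUE)
      panel[[mm]] <- as_snps(own)
    }
  }

  cells <- list(
    shared_in_panel   = sum(sites$category == "shared" & sites$in_panel),
    shared_not_panel  = sum(sites$category == "shared" & !sites$in_panel),
    a_only_in_panel   = sum(sites$category == "a_only" & sites$in_panel),
    a_only_not_panel  = sum(sites$category == "a_only" & !sites$in_panel),
    b_only_in_panel   = sum(sites$category == "b_only" & sites$in_panel),
    b_only_not_panel  = sum(sites$category == "b_only" & !sites$in_panel)
  )
  list(acc1 = acc1, acc2 = acc2, panel = panel, cells = cells)
}

# apply a substitution-only SNP set to a transcriptome, returning the
# accession haplotype sequences
apply_snps <- function(transcriptome, snps) {
  if (nrow(snps) == 0L) return(transcriptome)
  snps <- snps[!snps$is_indel, , drop = FALSE]
  out <- transcriptome
  by_tr <- split(snps, snps$transcript)
  idx <- match(names(by_tr), out$gene)
  for (i in seq_along(by_tr)) {
    j <- idx[i]
    if (is.na(j)) abort(sprintf("SNP transcript '%s' not in transcriptome", names(by_tr)[i]))
    ch <- strsplit(out$seq[j], "", fixed = TRUE)[[1]]
    d <- by_tr[[i]]
    if (any(d$pos > length(ch))) abort("SNP position beyond transcript length")
    ch[d$pos] <- d$alt
    out$seq[j] <- paste(ch, collapse = "")
  }
  out
}
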
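# Locate one set of mates on a single gene: try both orientations, take the
# modal (gene position - read position) offset supported by the most k-mer
# matches. Returns NA offset when no k-mer of either orientation matches
# (e.g. a read consisting entirely of errors).
locate_on_gene <- function(mates, gene_fwd_codes, k) {
  out_off <- integer(length(mates))
  out_rc <- logical(length(mates))
  for (i in seq_along(mates)) {
    b <- base_ints(mates[i])
    fwd <- roll_codes(b, k)
    rc <- roll_codes(rev(3L - b), k)
    mf <- match(fwd, gene_fwd_codes)
    mr <- match(rc, gene_fwd_codes)
    sup_f <- sum(!is.na(mf)); sup_r <- sum(!is.na(mr))
    if (sup_f == 0L && sup_r == 0L) {
      out_off[i] <- NA_integer_
      next
    }
    if (sup_f >= sup_r) {
      offs <- mf - seq_along(mf)          # gene start - read start
      out_rc[i] <- FALSE
    } else {
      offs <- mr - seq_along(mr)          # offsets of the reverse-complemented read
      out_rc[i] <- TRUE
    }
    offs <- offs[!is.na(offs)]
    out_off[i] <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
  }
  tibble(offset = out_off, is_rc = out_rc)
}

#' Build a per-base pileup from assigned fragments
#'
#' Places each mate of every unambiguously assigned fragment on its gene by
#' exact k-mer anchoring (modal offset over matching k-mers, both
#' orientations tried) and emits one row per covered base. Alignment is
#' ungapped, matching the substitution-only read model. Mates whose k-mers all
#' miss the gene are dropped.
#'
#' @param assignments Tibble from [assign_fragments()].
#' @param reads Tibble with `read_id`, `mate1`, `mate2`.
#' @param transcriptome Combined transcriptome tibble (`gene`, `seq`) covering
#'   every assigned gene.
#' @param k K-mer length for anchoring (same as the assignment k by default).
#' @return Tibble with `transcript`, `pos` (1-based), `base`.
#' @export
pileup_assignments <- function(assignments, reads, transcriptome, k = 21L) {
  asg <- assignments |>
    filter(call %in% c("AT", "AA")) |>
    inner_join(reads, by = "read_id")
  if (nrow(asg) == 0L) {
    return(tibble(transcript = character(), pos = integer(), base = character()))
  }
  out <- vector("list", 2L * length(unique(asg$gene)))
  oi <- 0L
  for (g in unique(asg$gene)) {
    gseq <- transcriptome$seq[match(g, transcriptome$gene)]
    if (is.na(gseq)) abort(sprintf("reference transcript '%s' missing", g))
    glen <- nchar(gseq)
    gcodes <- roll_codes(base_ints(gseq), k)
    sub_ <- asg[asg$gene == g, ]
    for (mate_col in c("mate1", "mate2")) {
      mates <- sub_[[mate_col]]
      loc <- locate_on_gene(mates, gcodes, k)
      keep <- which(!is.na(loc$offset))
      if (length(keep) == 0L) next
      seqs <- ifelse(loc$is_rc[keep], revcomp_chr(mates[keep]), mates[keep])
      lens <- nchar(seqs)
      starts <- loc$offset[keep] + 1L
      ridx <- rep(seq_along(seqs), lens)
      ppos <- starts[ridx] + sequence(lens) - 1L
      bases <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
      ok <- ppos >= 1L & ppos <= glen
      oi <- oi + 1L
      out[[oi]] <- tibble(transcript = g, pos = ppos[ok], base = bases[ok])
    }
  }
  bind_rows(out[seq_len(oi)])
}

#' Call SNPs from a pileup against a reference transcriptome
#'
#' A homozygous-consensus caller for inbred-line transcript-space data: a site
#' is called when its depth reaches `min_depth` and one non-reference base
#' accounts for at least `min_alt_frac` of the coverage. The quality score is
#' the Phred-scaled probability of seeing that many non-reference bases from
#' sequencing error alone, `-10 log10 P(X >= alt_depth)` with
#' `X ~ Binomial(depth, error_rate)`, capped at 99.
#'
#' @param pileup Tibble from [pileup_assignments()] (`transcript`, `pos`,
#'   `base`).
#' @param reference Transcriptome tibble (`gene`, `seq`) for the reference
#'   alleles.
#' @param min_depth Minimum site depth.
#' @param min_alt_frac Minimum fraction of reads supporting the alternate
#'   base.
#' @param error_rate Assumed per-base error rate for the quality model.
#' @return SNP tibble (`transcript`, `pos`, `ref`, `alt`, `qual`, `is_indel`),
#'   `is_indel` all `FALSE` (the caller is substitution-only).
#' @export
call_snps <- function(pileup, reference, min_depth = 4L, min_alt_frac = 0.9,
                      error_rate = 0.01) {
  if (nrow(pileup) == 0L) return(snp_tbl())
  missing_tr <- setdiff(unique(pileup$transcript), reference$gene)
  if (length(missing_tr)) {
    abort(sprintf("reference transcript '%s' missing", missing_tr[1]))
  }
  site <- pileup |>
    count(transcript, pos, base, name = "n_base") |>
    group_by(transcript, pos) |>
    mutate(depth = sum(n_base)) |>
    ungroup()
  refch <- map2_chr_safe(site$transcript, site$pos, reference)
  site$ref <- refch
  cand <- site |>
    filter(base != ref, depth >= min_depth, n_base / depth >= min_alt_frac) |>
    group_by(transcript, pos) |>
    slice_max(n_base, n = 1L, with_ties = FALSE) |>
    ungroup()
  if (nrow(cand) == 0L) return(snp_tbl())
  qual <- -10 * log10(pmax(
    pbinom(cand$n_base - 1L, cand$depth, error_rate, lower.tail = FALSE),
    1e-12
  ))
  snp_tbl(cand$transcript, cand$pos, cand$ref, cand$base, pmin(qual, 99))
}

# vectorized reference-base lookup
map2_chr_safe <- function(transcripts, pos, reference) {
  idx <- match(transcripts, reference$gene)
  substr(reference$seq[idx], pos, pos)
}
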
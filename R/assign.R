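#' Assign read pairs to subgenome and gene by shared canonical k-mers
#'
#' Scores every fragment (read pair) against the two subgenome indices: the
#' score of a gene is the number of distinct canonical k-mers the fragment
#' shares with it (both mates pooled; canonical k-mers make scoring
#' strand-agnostic). Each subgenome's score is the maximum over its genes; the
#' winning subgenome takes the fragment when its lead over the other subgenome
#' (the margin) is at least `min_margin`, otherwise the fragment is
#' `"ambiguous"`. Fragments sharing no k-mer with either index are
#' `"unmapped"`.
#'
#' @param reads Tibble with `read_id`, `mate1`, `mate2`.
#' @param index_at,index_aa [build_kmer_index()] results for the two
#'   subgenomes (built with the same `k`).
#' @param min_margin Minimum score lead for an unambiguous call (shared
#'   k-mers).
#' @return Tibble with `read_id`, `call` (`"AT"`/`"AA"`/`"ambiguous"`/
#'   `"unmapped"`), `gene` (`NA` unless called), `score`, `margin`.
#' @export
assign_fragments <- function(reads, index_at, index_aa, min_margin = 2L) {
  if (index_at$k != index_aa$k) abort("the two indices use different k")
  k <- index_at$k
  n <- nrow(reads)
  if (n == 0L) {
    return(tibble(read_id = character(), call = character(),
                  gene = character(), score = integer(), margin = integer()))
  }
  # distinct canonical codes per fragment, mates pooled
  c1 <- batch_canonical_codes(reads$mate1, k)
  c2 <- batch_canonical_codes(reads$mate2, k)
  frag <- distinct(bind_rows(
    tibble(rid = c1$item, code = c1$code),
    tibble(rid = c2$item, code = c2$code)
  ), rid, code)

  score_side <- function(index, label) {
    inner_join(frag, index$score_table, by = "code") |>
      count(rid, gene, name = "score") |>
      group_by(rid) |>
      slice_max(score, n = 1L, with_ties = TRUE) |>
      arrange(gene, .by_group = TRUE) |>
      slice(1L) |>
      ungroup() |>
      mutate(side = label)
  }
  best <- bind_rows(score_side(index_at, "AT"), score_side(index_aa, "AA"))

  wide <- best |>
    select(rid, side, gene, score) |>
    tidyr::pivot_wider(names_from = side, values_from = c(gene, score),
                       values_fill = list(score = 0L))
  for (col in c("gene_AT", "gene_AA")) if (!col %in% names(wide)) wide[[col]] <- NA_character_
  for (col in c("score_AT", "score_AA")) if (!col %in% names(wide)) wide[[col]] <- 0L

  res <- tibble(rid = seq_len(n)) |>
    left_join(wide, by = "rid") |>
    mutate(
      score_AT = dplyr::coalesce(score_AT, 0L),
      score_AA = dplyr::coalesce(score_AA, 0L),
      best = pmax(score_AT, score_AA),
      margin = abs(score_AT - score_AA),
      call = dplyr::case_when(
        best == 0L ~ "unmapped",
        margin < min_margin ~ "ambiguous",
        score_AT > score_AA ~ "AT",
        TRUE ~ "AA"
      ),
      gene = dplyr::case_when(
        call == "AT" ~ gene_AT,
        call == "AA" ~ gene_AA,
        TRUE ~ NA_character_
      )
    )
  tibble(read_id = reads$read_id, call = res$call, gene = res$gene,
         score = as.integer(res$best), margin = ifelse(res$call == "unmapped",
                                                       0L, as.integer(res$margin)))
}

#' Tally assigned fragments into per-gene counts with library totals
#'
#' Ambiguous fragments are excluded from per-gene counts and from the
#' subgenome totals but included in the library-wide mapped total (they were
#' mapped, just not attributable to one homoeolog), which is the denominator
#' FPKM uses. Unmapped fragments count in neither.
#'
#' @param assignments Tibble from [assign_fragments()]; read IDs must be
#'   unique.
#' @return Tibble `gene`, `subgenome`, `count` with attribute `totals`: a list
#'   with `at`, `aa`, `ambiguous`, `unmapped`, `mapped` (= at + aa +
#'   ambiguous) and `input`.
#' @export
count_fragments <- function(assignments) {
  if (anyDuplicated(assignments$read_id)) {
    abort("duplicate read IDs in assignments")
  }
  counts <- assignments |>
    filter(call %in% c("AT", "AA")) |>
    count(gene, call, name = "count") |>
    rename(subgenome = call) |>
    arrange(gene)
  tot <- list(
    at = sum(assignments$call == "AT"),
    aa = sum(assignments$call == "AA"),
    ambiguous = sum(assignments$call == "ambiguous"),
    unmapped = sum(assignments$call == "unmapped"),
    input = nrow(assignments)
  )
  tot$mapped <- tot$at + tot$aa + tot$ambiguous
  attr(counts, "totals") <- tot
  counts
}

#' Route pre-aligned SAM-dialect records by the subgenome of their reference
#'
#' Reads a text SAM stream (header lines starting with `@`; alignment columns
#' 1-4 honoured: QNAME, FLAG, RNAME, POS), drops unmapped records (FLAG bit
#' 0x4 or RNAME `*`) with a count, and routes every mapped record to the
#' stream of its reference's subgenome, preserving order. `@SQ` header lines
#' are routed to the stream owning their sequence; other header lines go to
#' both.
#'
#' @param lines Character vector of SAM lines, or a file path.
#' @param ref_map Tibble with `ref` and `subgenome` ("AT"/"AA") assigning every
#'   reference sequence to a subgenome.
#' @return List with `at` and `aa` (character vectors of SAM lines) and
#'   `summary` (tibble `n_at`, `n_aa`, `n_unmapped`).
#' @export
separate_alignments <- function(lines, ref_map) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  is_header <- startsWith(lines, "@")
  headers <- lines[is_header]
  records <- lines[!is_header]

  sq <- startsWith(headers, "@SQ")
  sq_name <- vapply(strsplit(headers[sq], "\t", fixed = TRUE), function(f) {
    hit <- f[startsWith(f, "SN:")]
    if (length(hit) == 0L) NA_character_ else substring(hit[1], 4L)
  }, character(1))
  sq_side <- ref_map$subgenome[match(sq_name, ref_map$ref)]
  if (any(is.na(sq_side))) {
    abort(sprintf("@SQ reference '%s' absent from the subgenome map",
                  sq_name[which(is.na(sq_side))[1]]))
  }
  head_at <- c(headers[!sq], headers[sq][sq_side == "AT"])
  head_aa <- c(headers[!sq], headers[sq][sq_side == "AA"])

  if (length(records)) {
    f <- str_split(records, "\t", simplify = TRUE)
    flag <- suppressWarnings(as.integer(f[, 2]))
    rname <- f[, 3]
    unmapped <- bitwAnd(flag, 4L) > 0L | rname == "*"
    side <- ref_map$subgenome[match(rname, ref_map$ref)]
    bad <- !unmapped & is.na(side)
    if (any(bad)) {
      abort(sprintf("reference '%s' absent from the subgenome map",
                    rname[which(bad)[1]]))
    }
    at <- records[!unmapped & side == "AT"]
    aa <- records[!unmapped & side == "AA"]
    n_unmapped <- sum(unmapped)
  } else {
    at <- aa <- character()
    n_unmapped <- 0L
  }
  list(
    at = c(head_at, at),
    aa = c(head_aa, aa),
    summary = tibble(n_at = length(at), n_aa = length(aa),
                     n_unmapped = n_unmapped)
  )
}
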
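# K-mers are encoded as base-4 integers stored in doubles (exact up to
# 4^26 < 2^53). The rolling code of the window ending at position i is
# sum_j 4^j * base[i - j]; it is computed for a whole sequence in one
# stats::filter() pass. Windows containing a non-ACGT base get code NA and are
# dropped. The canonical code of a k-mer is the elementwise minimum of its
# forward code and the code of its reverse complement, which makes scoring
# strand-agnostic without alignment.

base_ints <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], BASES) - 1L
}

# codes by window *start* position for one integer base vector
roll_codes <- function(b, k) {
  n <- length(b)
  if (n < k) return(numeric(0))
  y <- stats::filter(b, 4^(0:(k - 1)), sides = 1, method = "convolution")
  as.numeric(y[k:n])
}

# forward and canonical codes for one sequence string
seq_codes <- function(seq, k) {
  b <- base_ints(seq)
  fwd <- roll_codes(b, k)
  rc <- rev(roll_codes(rev(3L - b), k))
  list(fwd = fwd, canon = pmin(fwd, rc))
}

# canonical codes for many sequences in one filter pass (NA separators)
batch_canonical_codes <- function(seqs, k) {
  if (length(seqs) == 0L) {
    return(tibble(item = integer(), pos = integer(), code = numeric()))
  }
  lens <- nchar(seqs)
  joined <- paste(seqs, collapse = "N")
  b <- match(strsplit(joined, "", fixed = TRUE)[[1]], BASES) - 1L
  n <- length(b)
  fwd_end <- as.numeric(stats::filter(b, 4^(0:(k - 1)), sides = 1))
  rcv <- rev(3L - b)            # NA separators survive complementation
  rc_end <- as.numeric(stats::filter(rcv, 4^(0:(k - 1)), sides = 1))
  # window starting at i (1-based) ends at i + k - 1; in the reversed vector
  # its reverse complement ends at n - i + 1
  starts_all <- seq_len(n - k + 1L)
  fwd <- fwd_end[starts_all + k - 1L]
  rc <- rc_end[n - starts_all + 1L]
  canon <- pmin(fwd, rc)
  # map global start positions back to (item, within-item pos)
  offs <- cumsum(c(0L, head(lens, -1L) + 1L))
  item <- rep(seq_along(seqs), pmax(lens - k + 1L, 0L))
  pos_in <- sequence(pmax(lens - k + 1L, 0L))
  glob <- offs[item] + pos_in
  tibble(item = item, pos = pos_in, code = canon[glob]) |>
    filter(!is.na(code))
}

#' Build a canonical k-mer index over a transcriptome
#'
#' Maps every canonical k-mer of every transcript to the genes and positions
#' where it occurs. Duplicated k-mers (within or across genes) are retained
#' with all locations; downstream scoring collapses them per gene.
#'
#' @param transcriptome Tibble with `gene`, `seq` (and `subgenome`) columns.
#' @param k K-mer length; must be at least 11 and no longer than the shortest
#'   transcript (and at most 26 so codes stay exact in doubles).
#' @return A list of class `kmer_index` with the location tibble (`code`,
#'   `gene`, `pos`), the distinct `(code, gene)` scoring table, `k` and the
#'   subgenome `label`.
#' @examples
#' tx <- tibble::tibble(gene = "g1", subgenome = "AT", seq = "ACGTACGTACGTACGT")
#' idx <- build_kmer_index(tx, k = 12)
#' nrow(idx$locations)
#' @export
build_kmer_index <- function(transcriptome, k = 21L) {
  k <- as.integer(k)
  if (k < 11L) abort("k must be at least 11")
  if (k > 26L) abort("k must be at most 26 (codes are exact only up to 4^26)")
  minlen <- min(nchar(transcriptome$seq))
  if (k > minlen) {
    abort(sprintf("k (%d) exceeds the shortest transcript length (%d)", k, minlen))
  }
  codes <- batch_canonical_codes(transcriptome$seq, k)
  locations <- tibble(
    code = codes$code,
    gene = transcriptome$gene[codes$item],
    pos = codes$pos
  )
  structure(
    list(
      locations = locations,
      score_table = distinct(locations, code, gene),
      k = k,
      label = transcriptome$subgenome[1] %||% NA_character_
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> %s: %d locations, %d distinct (k-mer, gene), k = %d\n",
              x$label, nrow(x$locations), nrow(x$score_table), x$k))
  invisible(x)
}
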
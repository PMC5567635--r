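#' Configuration for a synthetic allopolyploid study
#'
#' Bundles every tunable of the synthetic data generator. The defaults describe
#' the study design the package is built around: two accessions of an
#' allotetraploid whose two parental subgenomes ("AT" and "AA") have diverged to
#' roughly 83% transcript identity, 13,394 homoeologous gene pairs, three
#' biological replicates per accession sequenced as 2 x 150 bp paired-end
#' fragments, an accession SNP structure with a shared core and private
#' remainders partly mirrored in a reference panel, a small set of truly
#' differentially expressed genes of which a subset forms coordinately
#' regulated homoeologous pairs, and a two-fold subgenome expression dominance.
#'
#' @param n_pairs Number of homoeologous gene pairs (one member per subgenome).
#' @param n_unpaired_per_subgenome Number of genes per subgenome without a
#'   homoeologous partner.
#' @param transcript_len_range Length range (bp) for simulated transcripts,
#'   sampled uniformly.
#' @param subgenome_divergence Expected per-site substitution divergence
#'   between homoeologs, in (0, 1). The two copies of each ancestral transcript
#'   are mutated independently at a per-copy rate solved so that the expected
#'   pairwise identity is `1 - subgenome_divergence`.
#' @param accession_snp_rate Expected substitutions per bp per accession on the
#'   AT subgenome (variants are called against the AT reference, mirroring
#'   calling the maternal subgenome against its parental reference).
#' @param shared_snp_fraction Fraction of each accession's SNPs that are shared
#'   (identical position and allele) with the other accession.
#' @param panel_size Number of reference-panel accessions.
#' @param panel_overlap_shared,panel_overlap_private Fraction of shared
#'   (respectively accession-private) SNPs that are also planted into at least
#'   one panel member. Together these populate all cells of the
#'   shared/private-by-panel partition with known counts.
#' @param n_de_genes Number of truly differentially expressed genes between the
#'   accessions (counting both members of a coordinated pair).
#' @param n_coordinated_pairs Number of homoeologous pairs whose two members
#'   are both DE, in the same direction. Must satisfy
#'   `2 * n_coordinated_pairs <= n_de_genes`.
#' @param de_log2fc Absolute log2 fold change applied to DE genes.
#' @param dominance_log2 Subgenome-wide expression offset: the AT subgenome's
#'   baseline expression is multiplied by `2^dominance_log2`. Negative values
#'   favour the AA subgenome.
#' @param expr_meanlog,expr_sdlog Parameters of the log-normal baseline
#'   expression distribution (natural-log scale).
#' @param rep_noise_sdlog Per-replicate, per-gene biological noise (log-normal,
#'   natural-log scale standard deviation).
#' @param read_len Read length (bp) of each mate.
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution (bp).
#' @param seq_error_rate Per-base sequencing error probability.
#' @param n_replicates Biological replicates per accession.
#' @param reads_per_sample Fragments (read pairs) per sample.
#' @param qual_range Range from which planted variant quality scores are drawn.
#' @param seed Integer seed; identical seeds give bit-identical studies.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_pairs = 50, reads_per_sample = 1000)
#' cfg$subgenome_divergence
#' @export
sim_config <- function(n_pairs = 13394,
                       n_unpaired_per_subgenome = 1500,
                       transcript_len_range = c(500L, 2500L),
                       subgenome_divergence = 0.17,
                       accession_snp_rate = 0.002,
                       shared_snp_fraction = 0.72,
                       panel_size = 10L,
                       panel_overlap_shared = 0.75,
                       panel_overlap_private = 0.5,
                       n_de_genes = 148L,
                       n_coordinated_pairs = 21L,
                       de_log2fc = 2,
                       dominance_log2 = 1,
                       expr_meanlog = 3,
                       expr_sdlog = 1.2,
                       rep_noise_sdlog = 0.2,
                       read_len = 150L,
                       fragment_len_mean = 300,
                       fragment_len_sd = 50,
                       seq_error_rate = 0.001,
                       n_replicates = 3L,
                       reads_per_sample = 5e5,
                       qual_range = c(20, 60),
                       seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    n_unpaired_per_subgenome = as.integer(n_unpaired_per_subgenome),
    transcript_len_range = as.integer(transcript_len_range),
    subgenome_divergence = subgenome_divergence,
    accession_snp_rate = accession_snp_rate,
    shared_snp_fraction = shared_snp_fraction,
    panel_size = as.integer(panel_size),
    panel_overlap_shared = panel_overlap_shared,
    panel_overlap_private = panel_overlap_private,
    n_de_genes = as.integer(n_de_genes),
    n_coordinated_pairs = as.integer(n_coordinated_pairs),
    de_log2fc = de_log2fc,
    dominance_log2 = dominance_log2,
    expr_meanlog = expr_meanlog,
    expr_sdlog = expr_sdlog,
    rep_noise_sdlog = rep_noise_sdlog,
    read_len = as.integer(read_len),
    fragment_len_mean = fragment_len_mean,
    fragment_len_sd = fragment_len_sd,
    seq_error_rate = seq_error_rate,
    n_replicates = as.integer(n_replicates),
    reads_per_sample = as.integer(reads_per_sample),
    qual_range = qual_range,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$subgenome_divergence < 0 || cfg$subgenome_divergence >= 1) {
    abort("`subgenome_divergence` must lie in [0, 1)")
  }
  if (cfg$shared_snp_fraction < 0 || cfg$shared_snp_fraction > 1) {
    abort("`shared_snp_fraction` must lie in [0, 1].")
  }
  counts <- c(
    cfg$n_pairs, cfg$n_unpaired_per_subgenome, cfg$panel_size,
    cfg$n_de_genes, cfg$n_coordinated_pairs, cfg$n_replicates,
    cfg$reads_per_sample
  )
  if (any(counts < 0)) abort("all counts in a `sim_config` must be >= 0")
  if (2L * cfg$n_coordinated_pairs > cfg$n_de_genes) {
    abort("`n_coordinated_pairs` must satisfy 2 * n_coordinated_pairs <= n_de_genes")
  }
  if (cfg$n_coordinated_pairs > cfg$n_pairs) {
    abort("`n_coordinated_pairs` cannot exceed `n_pairs`")
  }
  if (diff(cfg$transcript_len_range) < 0 || cfg$transcript_len_range[1] < 1) {
    abort("`transcript_len_range` must be an increasing positive interval")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d homoeolog pairs + %d unpaired genes/subgenome, divergence %.3f\n",
    x$n_pairs, x$n_unpaired_per_subgenome, x$subgenome_divergence
  ))
  cat(sprintf(
    "  %d DE genes (%d coordinated pairs), |log2FC| %.2f, dominance %.2f\n",
    x$n_de_genes, x$n_coordinated_pairs, x$de_log2fc, x$dominance_log2
  ))
  cat(sprintf(
    "  2 accessions x %d replicates, %d x 2 x %d bp fragments/sample, seed %d\n",
    x$n_replicates, x$reads_per_sample, x$read_len, x$seed
  ))
  invisible(x)
}

# deterministic per-stage seed derived from the study seed; kept < 2^31
stage_seed <- function(seed, stage, i = 0L) {
  base <- (as.numeric(seed) * 1103 + sum(utf8ToInt(stage)) * 7919 + i * 104729)
  as.integer(base %% 2147483629)
}
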
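#' Generate a complete synthetic allopolyploid study with ground truth
#'
#' Runs the full generator: diverged subgenomes and homoeolog map, accession
#' and panel variant sets, expression truth (including DE genes and
#' coordinated pairs), and — optionally — the paired reads of every sample.
#' Identical configurations (including the seed) give bit-identical studies.
#'
#' @param config A [sim_config()].
#' @param reads If `TRUE`, simulate the reads of all samples and store them in
#'   the result; if `FALSE`, only the truth tables are produced (reads can be
#'   generated later per sample with [simulate_reads()]).
#' @param k Smallest downstream k-mer size (transcript length guard).
#' @return An object of class `homeo_truth`: a list with `config`,
#'   `subgenomes` (`$at`, `$aa`, `$map`), `variants` (`$acc1`, `$acc2`,
#'   `$panel`, `$cells`), `expression`, `samples`, and (with `reads = TRUE`)
#'   `reads` and `origin` tibbles covering all samples.
#' @examples
#' cfg <- sim_config(n_pairs = 30, n_unpaired_per_subgenome = 5,
#'                   transcript_len_range = c(300, 600),
#'                   n_de_genes = 6, n_coordinated_pairs = 2,
#'                   reads_per_sample = 500, seed = 7)
#' truth <- simulate_study(cfg)
#' truth$subgenomes$map
#' @export
simulate_study <- function(config, reads = FALSE, k = 21L) {
  stopifnot(inherits(config, "sim_config"))
  subgenomes <- simulate_subgenomes(config, k = k)
  variants <- simulate_variants(subgenomes, config)
  expression <- simulate_expression_truth(subgenomes, config)
  samples <- sample_sheet(config)
  truth <- structure(
    list(config = config, subgenomes = subgenomes, variants = variants,
         expression = expression, samples = samples),
    class = "homeo_truth"
  )
  if (reads) {
    sim <- map(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      r <- simulate_reads(truth, s$accession, s$replicate, config)
      r$reads$sample_id <- s$sample_id
      r$origin$sample_id <- s$sample_id
      r
    })
    truth$reads <- bind_rows(map(sim, "reads"))
    truth$origin <- bind_rows(map(sim, "origin"))
  }
  truth
}

#' @export
print.homeo_truth <- function(x, ...) {
  cat("<homeo_truth>\n")
  cat(sprintf("  %d homoeolog pairs, %d genes total\n",
              nrow(x$subgenomes$map), nrow(x$expression)))
  cat(sprintf("  truly DE genes: %d (%d coordinated pairs)\n",
              sum(x$expression$is_de), sum(x$expression$coordinated) %/% 2L))
  cat(sprintf("  accession SNPs: %d (acc1), %d (acc2); panel of %d\n",
              nrow(x$variants$acc1), nrow(x$variants$acc2),
              length(x$variants$panel)))
  if (!is.null(x$reads)) {
    cat(sprintf("  reads: %d fragments over %d samples\n",
                nrow(x$reads), nrow(x$samples)))
  }
  invisible(x)
}

#' Write the truth tables of a simulated study to plain-text files
#'
#' Emits FASTA transcriptomes, the homoeolog map, the expression/DE truth, the
#' read-origin table (if reads were simulated), FASTQ read pairs per sample,
#' and one VCF per accession and panel member.
#'
#' @param truth A `homeo_truth` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcriptome_fasta(truth$subgenomes$at, file.path(dir, "subgenome_AT.fasta"))
  write_transcriptome_fasta(truth$subgenomes$aa, file.path(dir, "subgenome_AA.fasta"))
  readr::write_tsv(truth$subgenomes$map, file.path(dir, "homoeolog_map.tsv"))
  readr::write_tsv(truth$expression, file.path(dir, "expression_truth.tsv"))
  write_snp_vcf(truth$variants$acc1, file.path(dir, "acc1.vcf"), sample = "acc1")
  write_snp_vcf(truth$variants$acc2, file.path(dir, "acc2.vcf"), sample = "acc2")
  for (nm in names(truth$variants$panel)) {
    write_snp_vcf(truth$variants$panel[[nm]], file.path(dir, paste0(nm, ".vcf")),
                  sample = nm)
  }
  if (!is.null(truth$reads)) {
    readr::write_tsv(truth$origin, file.path(dir, "read_origin.tsv"))
    for (s in unique(truth$reads$sample_id)) {
      r <- truth$reads[truth$reads$sample_id == s, ]
      write_fastq_pair(r, file.path(dir, paste0(s, "_1.fastq")),
                       file.path(dir, paste0(s, "_2.fastq")))
    }
  }
  invisible(dir)
}
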
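#' Write a SNP tibble as a VCF file
#'
#' Emits VCF 4.x with the transcript ID as CHROM, 1-based POS, and the record
#' quality in QUAL. Indel records keep their multi-base alleles. Writing goes
#' through `vcfR`; a `.gz` suffix is appended by `vcfR::write.vcf` when not
#' present in `path`, so pass the intended final name.
#'
#' @param snps SNP tibble (`transcript`, `pos`, `ref`, `alt`, `qual`,
#'   `is_indel`).
#' @param path Output path (`.vcf.gz` recommended; `vcfR` writes gzip).
#' @param sample Sample name recorded in the header.
#' @return The path written, invisibly.
#' @export
write_snp_vcf <- function(snps, path, sample = "sample") {
  n <- nrow(snps)
  fix <- cbind(
    CHROM = as.character(snps$transcript),
    POS = as.character(snps$pos),
    ID = rep(".", n),
    REF = as.character(snps$ref),
    ALT = as.character(snps$alt),
    QUAL = sprintf("%.2f", snps$qual),
    FILTER = rep("PASS", n),
    INFO = rep(".", n)
  )
  if (n == 0L) fix <- matrix(character(), ncol = 8L,
                             dimnames = list(NULL, colnames(fix)))
  gt <- cbind(FORMAT = rep("GT", n), rep("1/1", n))
  colnames(gt) <- c("FORMAT", sample)
  if (n == 0L) gt <- matrix(character(), ncol = 2L,
                            dimnames = list(NULL, c("FORMAT", sample)))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=homeopipe",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  v <- methods::new(cls, meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a VCF file into the SNP tibble used throughout
#'
#' Accepts plain-text or gzipped VCF. Records whose REF or ALT allele is not
#' a single base are flagged `is_indel`. Multi-allelic ALT fields are split
#' into one record per alternate allele.
#'
#' @param path VCF path.
#' @return SNP tibble (`transcript`, `pos`, `ref`, `alt`, `qual`,
#'   `is_indel`).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(snp_tbl())
  d <- tibble(
    transcript = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  ) |>
    tidyr::separate_longer_delim(alt, delim = ",") |>
    mutate(is_indel = nchar(ref) != 1L | nchar(alt) != 1L,
           qual = dplyr::coalesce(qual, 0))
  snp_tbl(d$transcript, d$pos, d$ref, d$alt, d$qual, d$is_indel)
}
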
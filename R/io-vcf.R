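## VCF input/output. Reading is delegated to VariantAnnotation; only
## biallelic SNPs survive, and the outgroup allele is pulled either from a
## designated haploid sample column or from an INFO key. Writing emits a
## minimal VCF 4.2 dialect that round-trips through read_vcf().

## Map GT strings ("0/1", "1|1", "1", "./.", ...) to ALT dosages.
gt_to_dosage <- function(gt) {
  u <- unique(gt)
  dos <- vapply(u, function(g) {
    if (is.na(g) || grepl("\\.", g) || g == "") return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (!all(alleles %in% c("0", "1"))) return(NA_integer_)
    sum(alleles == "1")
  }, integer(1))
  unname(dos[match(gt, u)])
}

## Haploid outgroup allele from a GT column: "0"/"0/0" -> 0, "1"/"1/1" -> 1,
## anything else (missing, heterozygous) -> NA.
gt_to_haploid <- function(gt) {
  d <- gt_to_dosage(gt)
  ploidy <- ifelse(grepl("[/|]", gt), 2L, 1L)
  out <- rep(NA_integer_, length(gt))
  out[!is.na(d) & d == 0L] <- 0L
  out[!is.na(d) & d == ploidy & d > 0L] <- 1L
  out
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Only biallelic SNP records are retained; multiallelic records, indels and
#' records with no called genotype are dropped and counted. The outgroup
#' allele is read from a designated haploid sample column (default sample ID
#' `"outgroup"`) or, alternatively, from an INFO key holding the ancestral
#' base (e.g. `AA`).
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `list(chrom, start, end)` with 0-based half-open
#'   coordinates; only records inside the region are returned.
#' @param outgroup_sample sample column holding the haploid outgroup allele;
#'   set to `NA` to read no outgroup information.
#' @param outgroup_info INFO key holding the outgroup base; overrides
#'   `outgroup_sample` when non-`NULL`.
#' @return A [genotype_matrix()]. Attribute `dropped` counts discarded
#'   records by reason.
#' @export
read_vcf <- function(path, region = NULL, outgroup_sample = "outgroup",
                     outgroup_info = NULL) {
  ms_assert(file.exists(path), "VCF not found: %s", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) ms_stop("malformed VCF %s: %s", path, conditionMessage(e))
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  is_multi <- n_alt != 1
  is_snp <- !is_multi & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) ms_stop("VCF %s has no GT field", path)
  samples <- colnames(gt)

  og_col <- NULL
  if (is.null(outgroup_info) && !is.na(outgroup_sample)) {
    if (!outgroup_sample %in% samples)
      ms_stop("configured outgroup sample '%s' absent from VCF", outgroup_sample)
    og_col <- outgroup_sample
    samples <- setdiff(samples, og_col)
  }
  if (length(samples) == 0) ms_stop("VCF has no analysis samples")

  dos <- apply(gt[, samples, drop = FALSE], 2, gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, ncol = length(samples))
  colnames(dos) <- samples
  no_call <- rowSums(!is.na(dos)) == 0

  keep <- is_snp & !no_call
  dropped <- c(multiallelic = sum(is_multi),
               not_snp = sum(is_multi == FALSE & !is_snp),
               no_calls = sum(is_snp & no_call))

  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      ref = ref, alt = alt1, stringsAsFactors = FALSE)[keep, ]
  dos <- dos[keep, , drop = FALSE]

  outgroup <- rep(NA_integer_, nrow(sites))
  if (!is.null(outgroup_info)) {
    info <- VariantAnnotation::info(vcf)
    if (!outgroup_info %in% names(info))
      ms_stop("configured outgroup INFO key '%s' absent from VCF", outgroup_info)
    aa <- toupper(as.character(info[[outgroup_info]]))[keep]
    outgroup <- ifelse(aa == sites$ref, 0L, ifelse(aa == sites$alt, 1L, NA_integer_))
  } else if (!is.null(og_col)) {
    outgroup <- gt_to_haploid(gt[keep, og_col])
  }

  G <- genotype_matrix(sites, dos, outgroup)
  if (!is.null(region)) {
    ms_assert(all(c("chrom", "start", "end") %in% names(region)),
              "region must be list(chrom, start, end)")
    G <- subset_region(G, region$chrom, region$start, region$end)
  }
  attr(G, "dropped") <- dropped
  G
}

#' Write a genotype matrix as VCF
#'
#' Emits the dialect read back by [read_vcf()]: diploid GT columns for the
#' analysis samples plus a haploid outgroup column.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @param outgroup_sample name for the haploid outgroup column.
#' @param chrom_lengths optional named vector; when given, `##contig` header
#'   lines are written.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path, outgroup_sample = "outgroup",
                      chrom_lengths = NULL) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[G$geno + 1L], nrow = nrow(G$geno))
  gt[is.na(G$geno)] <- "./."
  og <- as.character(G$outgroup)
  og[is.na(og)] <- "."
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mosaicscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", G$samples, outgroup_sample),
                      collapse = "\t"))
  body <- paste(G$sites$chrom, G$sites$pos, ".", G$sites$ref, G$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), og, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
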
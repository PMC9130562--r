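## GenotypeMatrix: the package's core container. Sites are biallelic SNPs
## ordered by (chrom, pos); genotypes are diploid ALT-allele dosages in
## {0, 1, 2, NA}; the outgroup carries one haploid allele per site
## (0 = REF, 1 = ALT, NA = unknown) used to polarize derived states.

#' Construct a genotype matrix
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`. Rows must be sorted by chromosome (order of appearance) and
#'   position, and every record must be a biallelic SNP.
#' @param geno integer matrix, one row per site and one column per sample,
#'   holding ALT-allele dosages 0/1/2 or `NA` for missing calls.
#' @param outgroup integer vector of haploid outgroup alleles per site
#'   (0 = REF, 1 = ALT, `NA` = unknown). Defaults to all-`NA`.
#'
#' @return An object of class `genotype_matrix` with fields `sites`,
#'   `geno`, `samples`, `outgroup`.
#' @export
genotype_matrix <- function(sites, geno, outgroup = NULL) {
  ms_assert(is.data.frame(sites) &&
              all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            "sites needs columns chrom, pos, ref, alt")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ms_assert(nrow(geno) == nrow(sites), "geno rows must match sites rows")
  ms_assert(!is.null(colnames(geno)), "geno must have sample column names")
  if (is.null(outgroup)) outgroup <- rep(NA_integer_, nrow(sites))
  outgroup <- as.integer(outgroup)
  ms_assert(length(outgroup) == nrow(sites), "outgroup length must match sites")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  ## strict (chrom, pos) sort within chromosome blocks
  lev <- chrom_levels(sites$chrom)
  key <- order(match(sites$chrom, lev), sites$pos)
  ms_assert(all(key == seq_along(key)), "sites must be sorted by (chrom, pos)")
  dup <- duplicated(sites[c("chrom", "pos")])
  ms_assert(!any(dup), "duplicate site positions are not allowed")
  bad <- geno < 0L | geno > 2L
  ms_assert(!any(bad, na.rm = TRUE), "genotype dosages must be 0, 1 or 2")
  rownames(sites) <- NULL
  structure(
    list(sites = sites, geno = geno, samples = colnames(geno),
         outgroup = outgroup),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d biallelic SNPs x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(chrom_levels(x$sites$chrom), collapse = ",")))
  cat(sprintf("  outgroup allele known at %d/%d sites\n",
              sum(!is.na(x$outgroup)), nrow(x$sites)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

n_sites <- function(G) nrow(G$sites)

#' Subset a genotype matrix to a genomic region
#'
#' @param G a [genotype_matrix()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_region <- function(G, chrom, start, end) {
  check_interval(start, end)
  keep <- G$sites$chrom == chrom & (G$sites$pos - 1L) >= start &
    (G$sites$pos - 1L) < end
  genotype_matrix(G$sites[keep, , drop = FALSE],
                  G$geno[keep, , drop = FALSE],
                  G$outgroup[keep])
}

## --- group maps ------------------------------------------------------------

GROUP_LABELS <- c("P1", "P2", "P3", "OUT")

#' Construct a sample-to-group map
#'
#' Groups follow the four-taxon convention used throughout: P1 and P2 are
#' the two putative parental lineages, P3 the focal (test) lineage and OUT
#' the outgroup. Display names default to the macaque species groups the
#' scan was designed around.
#'
#' @param samples character vector of sample IDs.
#' @param groups matching character vector of labels in
#'   `c("P1","P2","P3","OUT")`.
#' @param display named character vector mapping group labels to display
#'   names.
#' @return An object of class `group_map`.
#' @export
group_map <- function(samples, groups,
                      display = c(P1 = "sinica", P2 = "fascicularis",
                                  P3 = "arctoides", OUT = "outgroup")) {
  ms_assert(length(samples) == length(groups),
            "samples and groups must have equal length")
  ms_assert(!anyDuplicated(samples), "duplicate sample in group map")
  bad <- setdiff(unique(groups), GROUP_LABELS)
  ms_assert(length(bad) == 0, "unknown group label(s): %s",
            paste(bad, collapse = ", "))
  structure(list(sample = as.character(samples), group = as.character(groups),
                 display = display),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  tab <- table(factor(x$group, GROUP_LABELS))
  cat("<group_map>", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Samples belonging to one group
#' @param map a [group_map()].
#' @param label group label (`"P1"`, `"P2"`, `"P3"` or `"OUT"`).
#' @return character vector of sample IDs.
#' @export
group_samples <- function(map, label) {
  map$sample[map$group == label]
}

## Column indices in G for a group's samples; errors when a needed group
## has no genotyped member.
group_cols <- function(G, map, label, required = TRUE) {
  idx <- which(G$samples %in% group_samples(map, label))
  if (required && length(idx) == 0)
    ms_stop("group %s has no samples present in the genotype matrix", label)
  idx
}

## --- allele frequency machinery -------------------------------------------

## Per-site called allele count and ALT dosage sum for one set of columns.
alt_counts <- function(G, cols) {
  sub <- G$geno[, cols, drop = FALSE]
  called <- 2L * rowSums(!is.na(sub))
  list(called = called, alt = rowSums(sub, na.rm = TRUE))
}

## ALT allele frequencies per group (NaN when no called alleles).
group_alt_freq <- function(G, map, label) {
  ac <- alt_counts(G, group_cols(G, map, label))
  list(p = ac$alt / ac$called, n = ac$called)
}

## Derived allele frequency: the non-outgroup allele is taken as derived,
## so the outgroup's own derived frequency is identically 0. NA where the
## outgroup allele is unknown.
polarize <- function(alt_freq, outgroup) {
  ifelse(is.na(outgroup), NA_real_,
         ifelse(outgroup == 0L, alt_freq, 1 - alt_freq))
}
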
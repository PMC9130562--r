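## Readers/writers for the remaining plain-text inputs: sample-to-group
## maps, bedGraph recombination maps, BED12/GFF3 gene models and one-ID-per-
## line gene lists; plus the per-sample heterozygosity intersections.

#' Read a two-column sample-to-group map
#'
#' @param path TSV with columns sample, group (no header). Group labels must
#'   be `P1`, `P2`, `P3` or `OUT`.
#' @return A [group_map()]; empty files give an empty map.
#' @export
read_group_map <- function(path) {
  ms_assert(file.exists(path), "group map not found: %s", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0)
    return(group_map(character(), character()))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("sample", "group"))
  group_map(df$sample, df$group)
}

#' Write a group map
#' @param map a [group_map()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(map, path) {
  write.table(data.frame(map$sample, map$group), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## --- interval maps (recombination rate) ------------------------------------

#' Construct an interval map (piecewise-constant genomic track)
#'
#' Used for the recombination-rate track (values in cM/Mb). Intervals are
#' 0-based half-open, per-chromosome sorted and non-overlapping.
#'
#' @param chrom,start,end,value parallel vectors describing the intervals.
#' @return An object of class `interval_map` (a data.frame).
#' @export
interval_map <- function(chrom, start, end, value) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  check_interval(df$start, df$end)
  ms_assert(all(df$value >= 0, na.rm = TRUE), "interval map values must be >= 0")
  df <- df[order(match(df$chrom, chrom_levels(df$chrom)), df$start), ]
  by_chr <- split(df, df$chrom)
  for (d in by_chr) {
    if (nrow(d) > 1)
      ms_assert(all(d$start[-1] >= d$end[-nrow(d)]),
                "interval map has overlapping intervals on %s", d$chrom[1])
  }
  rownames(df) <- NULL
  class(df) <- c("interval_map", "data.frame")
  df
}

#' Read a bedGraph track into an interval map
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @return An [interval_map()].
#' @export
read_bedgraph <- function(path) {
  ms_assert(file.exists(path), "bedGraph not found: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  interval_map(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               gr$score)
}

#' Write an interval map as bedGraph
#' @param map an [interval_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(map, path) {
  write.table(data.frame(map$chrom, as.integer(map$start), as.integer(map$end),
                         map$value),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Length-weighted mean track value over an interval
#'
#' @param map an [interval_map()].
#' @param chrom chromosome.
#' @param start,end 0-based half-open query interval.
#' @return The length-weighted mean of overlapping interval values, or `NA`
#'   when the query overlaps no interval (including absent chromosomes).
#' @export
mean_rate_in_interval <- function(map, chrom, start, end) {
  check_interval(start, end)
  d <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) return(NA_real_)
  ov_start <- pmax(d$start, start)
  ov_end <- pmin(d$end, end)
  w <- pmax(0, ov_end - ov_start)
  if (sum(w) == 0) return(NA_real_)
  sum(w * d$value) / sum(w)
}

## --- gene models ------------------------------------------------------------

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param transcripts data.frame with 0-based half-open `start`, `end` spans,
#'   one row per transcript.
#' @param cds optional data.frame of CDS segments (`start`, `end`, 0-based
#'   half-open) on the same chromosome; total length must be divisible by 3.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts, cds = NULL) {
  ms_assert(nrow(transcripts) >= 1, "gene %s has no transcripts", gene_id)
  check_interval(transcripts$start, transcripts$end)
  ms_assert(strand %in% c("+", "-"), "gene %s: strand must be + or -", gene_id)
  if (!is.null(cds) && nrow(cds)) {
    cds <- cds[order(cds$start), , drop = FALSE]
    check_interval(cds$start, cds$end)
    tot <- sum(cds$end - cds$start)
    ms_assert(tot %% 3 == 0, "gene %s: CDS length %d not divisible by 3",
              gene_id, tot)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts, cds = cds),
            class = "gene_model")
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 rows sharing a `name` are treated as transcripts of one gene, with
#' the thick region taken as CDS. GFF3 files are assembled from
#' gene/mRNA/CDS records via `Parent` attributes.
#'
#' @param path annotation file; format chosen by extension (`.bed` vs
#'   `.gff`/`.gff3`) unless `format` is given.
#' @param format `"bed"` or `"gff3"`.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, format = NULL) {
  ms_assert(file.exists(path), "annotation not found: %s", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") read_gene_models_bed12(path) else read_gene_models_gff3(path)
}

read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  ids <- gr$name
  out <- lapply(split(seq_along(gr), ids), function(ix) {
    g <- gr[ix]
    chr <- unique(as.character(GenomicRanges::seqnames(g)))
    ms_assert(length(chr) == 1, "gene %s spans multiple chromosomes", ids[ix[1]])
    tx <- data.frame(start = GenomicRanges::start(g) - 1L,
                     end = GenomicRanges::end(g))
    cds <- NULL
    if (!is.null(g$thick)) {
      th <- g$thick[1]
      if (IRanges::width(th) > 0)
        cds <- data.frame(start = IRanges::start(th) - 1L, end = IRanges::end(th))
    }
    strand <- as.character(GenomicRanges::strand(g))[1]
    if (strand == "*") strand <- "+"
    gene_model(ids[ix[1]], chr, strand, tx, cds)
  })
  out[order(names(out))]
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mrna <- gr[gr$type %in% c("mRNA", "transcript")]
  cds <- gr[gr$type == "CDS"]
  gene_of <- setNames(as.character(mrna$Parent), mrna$ID)
  out <- lapply(split(seq_along(mrna), unname(gene_of)), function(ix) {
    m <- mrna[ix]
    gid <- as.character(m$Parent[[1]])
    chr <- unique(as.character(GenomicRanges::seqnames(m)))
    ms_assert(length(chr) == 1, "gene %s spans multiple chromosomes", gid)
    tx <- data.frame(start = GenomicRanges::start(m) - 1L,
                     end = GenomicRanges::end(m))
    cd <- cds[as.character(cds$Parent) %in% m$ID]
    cd_df <- NULL
    if (length(cd)) {
      cd_df <- unique(data.frame(start = GenomicRanges::start(cd) - 1L,
                                 end = GenomicRanges::end(cd)))
    }
    strand <- as.character(GenomicRanges::strand(m))[1]
    if (strand == "*") strand <- "+"
    gene_model(gid, chr, strand, tx, cd_df)
  })
  out[order(names(out))]
}

#' Write gene models as BED12
#'
#' One row per transcript; block structure is a single exon spanning the
#' transcript, and the thick region marks the CDS span.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  rows <- lapply(models, function(m) {
    cds0 <- if (!is.null(m$cds)) min(m$cds$start) else m$transcripts$start[1]
    cds1 <- if (!is.null(m$cds)) max(m$cds$end) else m$transcripts$start[1]
    data.frame(chrom = m$chrom, start = m$transcripts$start,
               end = m$transcripts$end, name = m$gene_id, score = 0,
               strand = m$strand, thickStart = cds0, thickEnd = cds1,
               rgb = "0,0,0", blockCount = 1,
               blockSizes = paste0(m$transcripts$end - m$transcripts$start, ","),
               blockStarts = "0,")
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read/write a one-ID-per-line gene list
#' @param path text file.
#' @return character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  ms_assert(file.exists(path), "gene list not found: %s", path)
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_list
#' @param ids character vector of gene IDs to write.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

## --- heterozygous-site intersections ---------------------------------------

#' Heterozygous-site intersections across samples
#'
#' For every sample, the set of sites with a heterozygous genotype is
#' formed; the function reports per-sample totals plus the sizes of all
#' exclusive intersections (UpSet-style: each site is counted once, under
#' the exact subset of samples heterozygous there).
#'
#' @param G a [genotype_matrix()].
#' @param samples samples to include (default: all).
#' @return list with `totals` (named integer vector) and `exclusive`
#'   (data.frame with `members` -- sample names joined by `&` -- and
#'   `count`).
#' @export
het_intersections <- function(G, samples = NULL) {
  samples <- samples %||% G$samples
  ms_assert(length(samples) >= 1, "need at least one sample")
  het <- !is.na(G$geno[, samples, drop = FALSE]) &
    G$geno[, samples, drop = FALSE] == 1L
  totals <- colSums(het)
  key <- apply(het, 1, function(r) paste(samples[r], collapse = "&"))
  key <- key[nzchar(key)]
  tab <- table(key)
  excl <- data.frame(members = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  excl <- excl[order(-excl$count, excl$members), ]
  rownames(excl) <- NULL
  list(totals = totals, exclusive = excl)
}
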
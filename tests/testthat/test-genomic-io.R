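# genomic_io: VCF round trips and filters, group maps, interval maps,
# gene models, heterozygosity intersections.

make_toy_G <- function() {
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), c(3, 2)),
                      pos = c(100L, 250L, 900L, 50L, 60L),
                      ref = c("A", "C", "G", "T", "A"),
                      alt = c("T", "G", "A", "C", "G"))
  geno <- matrix(c(0L, 1L, 2L, NA, 1L,
                   2L, 1L, 0L, 0L, 0L,
                   1L, NA, 1L, 2L, 1L), ncol = 3,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  genotype_matrix(sites, geno, c(0L, 1L, NA, 0L, 1L))
}

test_that("VCF writing and reading round-trips sites, genotypes and outgroup", {
  G <- make_toy_G()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(G, f, chrom_lengths = c(chr1 = 1000, chr2 = 100))
  G2 <- read_vcf(f)
  expect_identical(G2$sites, G$sites)
  expect_identical(unname(G2$geno), unname(G$geno))
  expect_identical(G2$samples, G$samples)
  expect_identical(G2$outgroup, G$outgroup)
})

test_that("multiallelic and indel records are dropped and counted", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", "outgroup", sep = "\t"),
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1\t0",
    "chr1\t20\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t1/2\t0",   # multiallelic
    "chr1\t30\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t0",    # indel
    "chr1\t40\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t./.\t1",     # no called genotype
    "chr1\t50\t.\tG\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t."
  ), f)
  G <- read_vcf(f)
  expect_equal(nrow(G$sites), 2L)
  expect_equal(G$sites$pos, c(10L, 50L))
  dropped <- attr(G, "dropped")
  expect_equal(unname(dropped["multiallelic"]), 1)
  expect_equal(unname(dropped["not_snp"]), 1)
  expect_equal(unname(dropped["no_calls"]), 1)
  expect_true(is.na(G$outgroup[2]))
})

test_that("region queries match a linear scan over the toy VCF", {
  G <- make_toy_G()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(G, f)
  for (reg in list(list(chrom = "chr1", start = 0, end = 300),
                   list(chrom = "chr1", start = 99, end = 100),
                   list(chrom = "chr2", start = 0, end = 60),
                   list(chrom = "chr1", start = 500, end = 2000))) {
    got <- read_vcf(f, region = reg)
    keep <- G$sites$chrom == reg$chrom & (G$sites$pos - 1) >= reg$start &
      (G$sites$pos - 1) < reg$end
    expect_equal(got$sites$pos, G$sites$pos[keep])
    expect_equal(unname(got$geno), unname(G$geno[keep, , drop = FALSE]))
  }
})

test_that("unknown outgroup configuration raises a configuration error", {
  G <- make_toy_G()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(G, f, outgroup_sample = "baboon")
  expect_error(read_vcf(f), "outgroup")
  expect_silent(G2 <- read_vcf(f, outgroup_sample = "baboon"))
  expect_identical(G2$outgroup, G$outgroup)
})

test_that("group maps validate labels, duplicates and emptiness", {
  f <- withr::local_tempfile()
  # mirrors the published sample table: 3 focal, 4 + 2 parental, 1 outgroup
  writeLines(sprintf("%s\t%s",
                     c("XH1", "TibetanNO3", "BGI-CE-4", "CR-5", "BGI",
                       "BGI-96346", "Malaya", "SM1", "SM2", "baboon"),
                     c("P1", "P1", "P2", "P2", "P2", "P2",
                       "P3", "P3", "P3", "OUT")), f)
  m <- read_group_map(f)
  expect_equal(length(group_samples(m, "P1")), 2L)
  expect_equal(length(group_samples(m, "P2")), 4L)
  expect_equal(length(group_samples(m, "P3")), 3L)
  expect_equal(length(group_samples(m, "OUT")), 1L)

  writeLines(character(), f)
  empty <- read_group_map(f)
  expect_equal(length(empty$sample), 0L)
  G <- make_toy_G()
  expect_error(window_stats(G, empty,
                            data.frame(chrom = "chr1", start = 0, end = 1000)),
               "no samples")

  writeLines(c("a\tP1", "a\tP2"), f)
  expect_error(read_group_map(f), "duplicate")
  writeLines(c("a\tP1", "b\tP9"), f)
  expect_error(read_group_map(f), "unknown group")
})

test_that("length-weighted interval means follow hand calculations", {
  uniform <- interval_map("chr1", seq(0, 900, 100), seq(100, 1000, 100),
                          rep(1, 10))
  expect_equal(mean_rate_in_interval(uniform, "chr1", 123, 777), 1.0)
  two <- interval_map("chr1", c(0, 500), c(500, 1000), c(0.5, 1.5))
  expect_equal(mean_rate_in_interval(two, "chr1", 0, 1000), 1.0)
  expect_equal(mean_rate_in_interval(two, "chr1", 250, 750), 1.0)
  expect_equal(mean_rate_in_interval(two, "chr1", 400, 600), 1.0)
  expect_equal(mean_rate_in_interval(two, "chr1", 0, 750),
               (500 * 0.5 + 250 * 1.5) / 750)
  expect_true(is.na(mean_rate_in_interval(two, "chrX", 0, 10)))
  expect_true(is.na(mean_rate_in_interval(
    interval_map("chr1", 0, 10, 1), "chr1", 20, 30)))
  expect_error(mean_rate_in_interval(two, "chr1", 100, 100), "inverted")
})

test_that("interval means are invariant to splitting intervals", {
  withr::with_seed(7, {
    for (k in 1:20) {
      v <- runif(3, 0, 5)
      whole <- interval_map("chr1", c(0, 300, 600), c(300, 600, 900), v)
      cuts <- sort(sample(1:899, 5))
      edges <- unique(sort(c(0, cuts, 300, 600, 900)))
      vals <- vapply(head(edges, -1), function(s) {
        v[findInterval(s, c(0, 300, 600))]
      }, numeric(1))
      split_map <- interval_map("chr1", head(edges, -1), edges[-1], vals)
      q <- sort(sample(0:900, 2))
      if (q[1] == q[2]) next
      expect_equal(mean_rate_in_interval(split_map, "chr1", q[1], q[2]),
                   mean_rate_in_interval(whole, "chr1", q[1], q[2]))
    }
  })
})

test_that("bedGraph round trip preserves the interval map", {
  m <- interval_map(rep(c("chr1", "chr2"), each = 2),
                    c(0, 100, 0, 50), c(100, 300, 50, 80),
                    c(0.2, 1.7, 3.0, 0.0))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(m, f)
  m2 <- read_bedgraph(f)
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)
  expect_equal(m2$value, m$value)
})

test_that("heterozygous-site intersections match a set-algebra oracle", {
  fx <- random_genotype_matrix(60, c(2, 2, 1), miss = 0.1, seed = 11)
  res <- het_intersections(fx$G)
  # naive per-sample sets
  sets <- lapply(fx$G$samples, function(s) {
    which(!is.na(fx$G$geno[, s]) & fx$G$geno[, s] == 1)
  })
  names(sets) <- fx$G$samples
  expect_equal(unname(res$totals), vapply(sets, length, integer(1)),
               ignore_attr = TRUE)
  # each exclusive intersection: sites het in exactly that member set
  for (i in seq_len(nrow(res$exclusive))) {
    members <- strsplit(res$exclusive$members[i], "&", fixed = TRUE)[[1]]
    inside <- Reduce(intersect, sets[members])
    outside <- Reduce(union, c(sets[setdiff(fx$G$samples, members)],
                               list(integer())))
    expect_equal(res$exclusive$count[i], length(setdiff(inside, outside)))
  }
  # exclusive counts containing a sample sum to its total
  for (s in fx$G$samples) {
    has <- vapply(strsplit(res$exclusive$members, "&", fixed = TRUE),
                  function(m) s %in% m, logical(1))
    expect_equal(sum(res$exclusive$count[has]), unname(res$totals[s]))
  }
})

test_that("samples without heterozygous calls give empty intersections", {
  sites <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "T")
  geno <- cbind(a = c(0L, 2L, 0L, 2L), b = c(1L, 1L, 0L, 0L),
                c = c(1L, 0L, 0L, 0L))
  G <- genotype_matrix(sites, geno)
  res <- het_intersections(G)
  expect_equal(unname(res$totals), c(0L, 2L, 1L))
  expect_false(any(grepl("a", res$exclusive$members)))
  # two samples heterozygous at the same single site -> pairwise entry 1
  expect_equal(res$exclusive$count[res$exclusive$members == "b&c"], 1L)
})

test_that("gene models survive a BED12 round trip and read from GFF3", {
  m1 <- gene_model("gA", "chr1", "+",
                   data.frame(start = c(1000, 1200), end = c(5000, 6000)),
                   cds = data.frame(start = 2000, end = 2900))
  m2 <- gene_model("gB", "chr2", "-",
                   data.frame(start = 100, end = 700),
                   cds = data.frame(start = 200, end = 500))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(list(gA = m1, gB = m2), f)
  back <- read_gene_models(f)
  expect_setequal(names(back), c("gA", "gB"))
  expect_equal(back$gA$transcripts$start, m1$transcripts$start)
  expect_equal(back$gA$cds$start, 2000)
  expect_equal(back$gB$strand, "-")

  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\tID=gC",
    "chr1\tsrc\tmRNA\t1001\t5000\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr1\tsrc\tCDS\t2001\t2900\t.\t+\t0\tID=gC.c1;Parent=gC.t1"
  ), g)
  mg <- read_gene_models(g)
  expect_equal(mg$gC$transcripts$start, 1000)
  expect_equal(mg$gC$cds$start, 2000)
  expect_equal(mg$gC$cds$end, 2900)
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("x", "chr1", "+",
                          data.frame(start = 10, end = 100),
                          cds = data.frame(start = 20, end = 90)),
               "divisible by 3")
  expect_error(gene_model("x", "chr1", "+", data.frame(start = numeric(),
                                                       end = numeric())),
               "no transcripts")
})
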
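# windows_stats: window construction, the minimum-site rule, and the five
# per-window statistics against naive oracles.

test_that("sliding windows follow the containment and step conventions", {
  w <- make_sliding_windows(c(chr1 = 1e5), 5e4, 0.2)
  expect_equal(w$start, seq(0, 5e4, by = 1e4))
  expect_equal(unique(w$end - w$start), 5e4)
  # chromosome shorter than the window yields nothing
  expect_equal(nrow(make_sliding_windows(c(chr1 = 4e4), 5e4)), 0L)
  # step fraction 1 tiles without overlap
  t1 <- make_sliding_windows(c(chr1 = 1e5), 2e4, 1)
  expect_equal(t1$start, seq(0, 8e4, by = 2e4))
  expect_equal(nrow(make_sliding_windows(numeric()[0], 1e4)), 0L)
  expect_error(make_sliding_windows(c(chr1 = 1e5), -1), "positive")
})

test_that("gene windows are the flanked transcript union, clipped", {
  m <- gene_model("g", "chr1", "+",
                  data.frame(start = c(10000, 12000), end = c(15000, 20000)))
  expect_equal(gene_window(m, flank = 5000),
               data.frame(chrom = "chr1", start = 5000, end = 25000))
  m2 <- gene_model("g2", "chr1", "+", data.frame(start = 2000, end = 3000))
  expect_equal(gene_window(m2, flank = 5000)$start, 0)
  expect_equal(gene_window(m2, flank = 5000, chrom_length = 7500)$end, 7500)
  expect_equal(gene_window(m, flank = 0),
               data.frame(chrom = "chr1", start = 10000, end = 20000))
})

test_that("the minimum-site ladder masks windows below threshold", {
  expect_equal(min_sites_for_size(5000), 10L)
  expect_equal(min_sites_for_size(50000), 100L)
  expect_equal(min_sites_for_size(1e6), 2000L)
  expect_error(min_sites_for_size(123), "threshold")
  st <- data.frame(chrom = "chr1", start = 0, end = 5e4,
                   n_sites = c(99L, 100L), n_pol = c(99L, 100L),
                   pi_P3 = 0.1, dxy_P3_P1 = 0.2, dxy_P3_P2 = 0.2,
                   fst_P3_P1 = 0.3, fst_P3_P2 = 0.3, D = 0.1, f_dM = 0.1)
  out <- apply_min_sites(st, window_size = 5e4)
  expect_true(all(is.na(out[1, 6:12])))
  expect_equal(out[2, ], st[2, ])
})

win_all <- function(G) data.frame(chrom = "chr1", start = 0,
                                  end = max(G$sites$pos) + 1)

make_hap_G <- function(geno_by_group, og = NULL) {
  # geno_by_group: list(P1 = matrix, P2 = ..., P3 = ...) rows = sites
  geno <- do.call(cbind, geno_by_group)
  n <- vapply(geno_by_group, ncol, integer(1))
  samples <- sprintf("s%02d", seq_len(sum(n)))
  colnames(geno) <- samples
  sites <- data.frame(chrom = "chr1", pos = seq_len(nrow(geno)) * 10L,
                      ref = "A", alt = "T")
  G <- genotype_matrix(sites, geno, og %||% rep(0L, nrow(geno)))
  map <- group_map(samples, rep(names(n), times = n))
  list(G = G, map = map)
}

test_that("diversity and divergence match hand-built cases", {
  # monomorphic window: pi = 0
  fx <- make_hap_G(list(P1 = matrix(0L, 10, 2), P2 = matrix(0L, 10, 2),
                        P3 = matrix(0L, 10, 2)))
  expect_equal(nucleotide_diversity(fx$G, fx$map, win_all(fx$G)), 0)
  # one diploid P3 sample het at 1 of 10 usable sites -> pi = 0.1
  p3 <- matrix(0L, 10, 1); p3[4, 1] <- 1L
  fx <- make_hap_G(list(P1 = matrix(0L, 10, 2), P2 = matrix(0L, 10, 2),
                        P3 = p3))
  expect_equal(nucleotide_diversity(fx$G, fx$map, win_all(fx$G)), 0.1)
  # identical fixed sequences: dxy = 0
  fx <- make_hap_G(list(P1 = matrix(2L, 10, 2), P2 = matrix(2L, 10, 2),
                        P3 = matrix(2L, 10, 2)))
  expect_equal(dxy(fx$G, fx$map, win_all(fx$G), "P1"), 0)
  # alternate fixation at 2 of 10 sites -> dxy = 0.2
  p1 <- matrix(0L, 10, 2); p3 <- matrix(0L, 10, 2)
  p3[c(3, 7), ] <- 2L
  fx <- make_hap_G(list(P1 = p1, P2 = matrix(0L, 10, 2), P3 = p3))
  expect_equal(dxy(fx$G, fx$map, win_all(fx$G), "P1"), 0.2)
})

test_that("Hudson F_ST matches closed forms", {
  # equal sample frequencies in both groups: the unbiased within-group
  # heterozygosity is inflated by n/(n-1), so the estimator sits exactly at
  # 1 - n/(n-1) (slightly negative, -1/3 at n = 4), approaching 0 as n grows
  g <- rbind(c(0, 1, 0, 1), c(1, 1, 1, 1), c(2, 0, 2, 0))
  fx <- make_hap_G(list(P1 = matrix(as.integer(g[, 1:2]), 3),
                        P2 = matrix(0L, 3, 2),
                        P3 = matrix(as.integer(g[, 3:4]), 3)))
  expect_equal(fst(fx$G, fx$map, win_all(fx$G), "P1"), 1 - 4 / 3)
  big <- matrix(rep(c(0L, 2L), each = 20), 1)  # 40 diploids = 80 haplotypes
  fx_big <- make_hap_G(list(P1 = big, P2 = matrix(0L, 1, 2), P3 = big))
  expect_equal(fst(fx_big$G, fx_big$map, win_all(fx_big$G), "P1"),
               1 - 80 / 79)
  # alternate fixation at all variable sites -> 1
  fx <- make_hap_G(list(P1 = matrix(0L, 5, 2), P2 = matrix(0L, 5, 2),
                        P3 = matrix(2L, 5, 2)))
  expect_equal(fst(fx$G, fx$map, win_all(fx$G), "P1"), 1)
  # 10 haplotypes per group at frequencies 0.2 / 0.8: closed form
  p1 <- matrix(c(2L, 2L, 2L, 2L, 0L), 1)  # 8/10 alt
  p3 <- matrix(c(2L, 0L, 0L, 0L, 0L), 1)  # 2/10 alt
  fx <- make_hap_G(list(P1 = p1, P2 = matrix(0L, 1, 2), P3 = p3))
  hw <- (2 * 0.2 * 0.8 * 10 / 9 + 2 * 0.8 * 0.2 * 10 / 9) / 2
  hb <- 0.2 * 0.2 + 0.8 * 0.8
  expect_equal(fst(fx$G, fx$map, win_all(fx$G), "P1"), 1 - hw / hb)
})

test_that("site-pattern sums follow the polarized per-site formulas", {
  # p1 = p2 = p3 = 0: contributes nothing
  fx <- make_hap_G(list(P1 = matrix(0L, 1, 2), P2 = matrix(0L, 1, 2),
                        P3 = matrix(0L, 1, 2)))
  s <- site_pattern_sums(fx$G, fx$map, win_all(fx$G))
  expect_equal(s$sum_abba, 0); expect_equal(s$sum_baba, 0)
  expect_equal(s$n_sites, 1)
  # (p1, p2, p3) = (0, 0.5, 0.5): ABBA 0.25, BABA 0
  fx <- make_hap_G(list(P1 = matrix(0L, 1, 2), P2 = matrix(1L, 1, 2),
                        P3 = matrix(1L, 1, 2)))
  s <- site_pattern_sums(fx$G, fx$map, win_all(fx$G))
  expect_equal(s$sum_abba, 0.25)
  expect_equal(s$sum_baba, 0)
  # missing outgroup allele: skipped entirely
  fx <- make_hap_G(list(P1 = matrix(0L, 2, 2), P2 = matrix(2L, 2, 2),
                        P3 = matrix(2L, 2, 2)), og = c(0L, NA))
  s <- site_pattern_sums(fx$G, fx$map, win_all(fx$G))
  expect_equal(s$n_sites, 1)
  expect_equal(s$sum_abba, 1)
  # outgroup carrying ALT flips polarization
  fx <- make_hap_G(list(P1 = matrix(2L, 1, 2), P2 = matrix(0L, 1, 2),
                        P3 = matrix(0L, 1, 2)), og = 1L)
  s <- site_pattern_sums(fx$G, fx$map, win_all(fx$G))
  expect_equal(s$sum_abba, 1)  # derived = REF here
})

test_that("Patterson's D and f_dM behave on constructed sums", {
  expect_equal(patterson_D(list(sum_abba = 3, sum_baba = 3)), 0)
  expect_equal(patterson_D(list(sum_abba = 5, sum_baba = 0)), 1)
  expect_true(is.na(patterson_D(list(sum_abba = 0, sum_baba = 0))))
  # single site (0, 1, 1): numerator equals denominator -> f_dM = 1
  fx <- make_hap_G(list(P1 = matrix(0L, 1, 2), P2 = matrix(2L, 1, 2),
                        P3 = matrix(2L, 1, 2)))
  expect_equal(fdm(site_pattern_sums(fx$G, fx$map, win_all(fx$G))), 1)
  # p1 = p2 at every site -> numerator vanishes
  g12 <- matrix(sample(0:2, 20, replace = TRUE), 10, 2)
  fx <- make_hap_G(list(P1 = matrix(as.integer(g12), 10),
                        P2 = matrix(as.integer(g12), 10),
                        P3 = matrix(1L, 10, 2)))
  expect_equal(fdm(site_pattern_sums(fx$G, fx$map, win_all(fx$G))), 0)
})

test_that("swapping P1 and P2 negates f_dM", {
  for (seed in 1:10) {
    fx <- random_genotype_matrix(30, c(3, 3, 3), seed = seed)
    swapped <- group_map(fx$map$sample,
                         c(P1 = "P2", P2 = "P1", P3 = "P3")[fx$map$group])
    f1 <- fdm(site_pattern_sums(fx$G, fx$map, win_all(fx$G)))
    f2 <- fdm(site_pattern_sums(fx$G, swapped, win_all(fx$G)))
    if (is.na(f1)) expect_true(is.na(f2) || f2 == 0)
    else expect_equal(f1, -f2, tolerance = 1e-12)
  }
})

test_that("all five statistics match the naive oracles on random matrices", {
  for (seed in 1:12) {
    fx <- random_genotype_matrix(20, c(3, 4, 3), miss = 0.1, seed = seed)
    w <- win_all(fx$G)
    expect_equal(nucleotide_diversity(fx$G, fx$map, w),
                 oracle_pi(fx$G, fx$map), tolerance = 1e-12)
    expect_equal(dxy(fx$G, fx$map, w, "P1"), oracle_dxy(fx$G, fx$map, "P1"),
                 tolerance = 1e-12)
    expect_equal(dxy(fx$G, fx$map, w, "P2"), oracle_dxy(fx$G, fx$map, "P2"),
                 tolerance = 1e-12)
    expect_equal(fst(fx$G, fx$map, w, "P1"), oracle_fst(fx$G, fx$map, "P1"),
                 tolerance = 1e-12)
    o <- oracle_D_fdm(fx$G, fx$map)
    s <- site_pattern_sums(fx$G, fx$map, w)
    expect_equal(patterson_D(s), o$D, tolerance = 1e-12)
    expect_equal(fdm(s), o$fdm, tolerance = 1e-12)
  }
})

test_that("window_stats agrees with single-window operations and bounds hold", {
  fx <- random_genotype_matrix(200, c(3, 4, 3), miss = 0.08, seed = 99)
  wins <- data.frame(chrom = "chr1",
                     start = seq(0, 9000, by = 500),
                     end = seq(1000, 10000, by = 500))
  st <- window_stats(fx$G, fx$map, wins)
  for (i in c(1, 5, 9)) {
    expect_equal(st$pi_P3[i],
                 nucleotide_diversity(fx$G, fx$map, wins[i, ]))
    expect_equal(st$dxy_P3_P2[i], dxy(fx$G, fx$map, wins[i, ], "P2"))
    expect_equal(st$fst_P3_P1[i], fst(fx$G, fx$map, wins[i, ], "P1"))
    expect_equal(st$f_dM[i], fdm(site_pattern_sums(fx$G, fx$map, wins[i, ])))
  }
  expect_true(all(st$D >= -1 & st$D <= 1, na.rm = TRUE))
  expect_true(all(st$f_dM >= -1 & st$f_dM <= 1, na.rm = TRUE))
  expect_true(all(st$pi_P3 >= 0, na.rm = TRUE))
  expect_true(all(st$dxy_P3_P1 >= 0 & st$dxy_P3_P2 >= 0, na.rm = TRUE))
  expect_true(all(st$fst_P3_P1 <= 1 & st$fst_P3_P2 <= 1, na.rm = TRUE))
  # D and f_dM share sign (or one is zero) on the same sums
  sgn <- sign(st$D) * sign(st$f_dM)
  expect_true(all(sgn >= 0 | st$D == 0 | st$f_dM == 0, na.rm = TRUE))
})
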
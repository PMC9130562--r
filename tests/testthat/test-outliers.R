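# outlier_scan: regression diagnostics, outlier rules, enrichment and
# permutation inference.

test_that("perfect fits have zero residuals and zero Cook's distance", {
  x <- 1:10
  fit <- fit_rate_regression(2 + 0.5 * x, x, statistic = "pi_P3")
  expect_equal(fit$points$residual, rep(0, 10))
  expect_equal(fit$points$cooksd, rep(0, 10), tolerance = 1e-20)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 2)
})

test_that("mirror-symmetric duplicated points share Cook's distance", {
  x <- c(1, 1, 2, 2, 3, 3)
  y <- c(1.1, 0.9, 2.2, 1.8, 3.1, 2.9)
  fit <- fit_rate_regression(y, x)
  cd <- fit$points$cooksd
  expect_equal(cd[1], cd[2]); expect_equal(cd[3], cd[4])
  expect_equal(cd[5], cd[6])
})

test_that("Cook's distance equals the leave-one-out refit definition", {
  withr::with_seed(14, {
    x <- runif(5, 0, 3)
    y <- 1 + 0.4 * x + rnorm(5, sd = 0.3)
    fit <- fit_rate_regression(y, x)
    expect_equal(fit$points$cooksd, oracle_cooksd(x, y), tolerance = 1e-10)
    # and on larger random datasets
    x <- runif(50, 0, 5)
    y <- 2 - 0.3 * x + rnorm(50)
    fit <- fit_rate_regression(y, x)
    expect_equal(fit$points$cooksd, oracle_cooksd(x, y), tolerance = 1e-10)
  })
})

test_that("regression preconditions are enforced", {
  expect_error(fit_rate_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_rate_regression(1:5, rep(2, 5)), "zero rate variance")
})

test_that("cooksd outlier calls respect threshold and direction", {
  withr::with_seed(3, {
    x <- runif(40, 0, 4)
    y <- 0.2 + 0.1 * x + rnorm(40, sd = 0.01)
  })
  # uniform influence (balanced design, equal |residual|): all Cook's
  # distances are equal, so nobody exceeds 3x the mean
  fit0 <- fit_rate_regression(c(1, 2, 1, 2) + c(0.1, 0.1, -0.1, -0.1),
                              c(1, 2, 1, 2), statistic = "fst_P3_P1")
  expect_equal(diff(range(fit0$points$cooksd)), 0, tolerance = 1e-12)
  expect_false(any(call_cooksd_outliers(fit0, k = 3)$is_outlier))
  # a planted high point above the line in an F_ST scan is flagged
  y_hi <- c(y, 0.2 + 0.1 * 2 + 0.5); x_hi <- c(x, 2)
  fit_hi <- fit_rate_regression(y_hi, x_hi, statistic = "fst_P3_P1")
  calls <- call_cooksd_outliers(fit_hi)
  expect_true(calls$is_outlier[41])
  expect_equal(calls$direction[41], "above")
  # the same point below the line is not flagged (wrong side for F_ST)
  y_lo <- c(y, 0.2 + 0.1 * 2 - 0.5)
  fit_lo <- fit_rate_regression(y_lo, x_hi, statistic = "fst_P3_P1")
  expect_false(call_cooksd_outliers(fit_lo)$is_outlier[41])
  # ... but is flagged for a below-tail statistic (pi) and for both-tails
  fit_pi <- fit_rate_regression(y_lo, x_hi, statistic = "pi_P3")
  expect_true(call_cooksd_outliers(fit_pi)$is_outlier[41])
  fit_fd <- fit_rate_regression(y_lo, x_hi, statistic = "f_dM")
  expect_true(call_cooksd_outliers(fit_fd)$is_outlier[41])
  # unknown statistic without a tail errors
  fit_uk <- fit_rate_regression(y, x, statistic = "mystery")
  expect_error(call_cooksd_outliers(fit_uk), "tail")
})

test_that("outlier calls are invariant to joint affine rescaling", {
  withr::with_seed(9, {
    x <- runif(30, 0, 2)
    y <- 0.1 + 0.3 * x + rnorm(30, sd = 0.05)
  })
  f1 <- call_cooksd_outliers(fit_rate_regression(y, x, statistic = "f_dM"))
  f2 <- call_cooksd_outliers(fit_rate_regression(10 * y - 3, 5 * x + 1,
                                                 statistic = "f_dM"))
  expect_equal(f1$is_outlier, f2$is_outlier)
})

test_that("quantile outliers flag the empirical top tail", {
  omega <- setNames(seq(0.01, 1, length.out = 100), sprintf("g%03d", 1:100))
  calls <- call_quantile_outliers(omega, 0.05)
  expect_equal(sum(calls$is_outlier), 5L)
  # full-sort oracle: the flagged set is exactly the top five
  expect_setequal(calls$gene[calls$is_outlier],
                  names(sort(omega, decreasing = TRUE))[1:5])
  # ties at the cutoff are all flagged
  omega2 <- setNames(c(rep(0.1, 90), rep(0.9, 10)), sprintf("h%03d", 1:100))
  calls2 <- call_quantile_outliers(omega2, 0.05)
  expect_equal(sum(calls2$is_outlier), 10L)
  expect_error(call_quantile_outliers(omega[1:10], 0.05), "too few")
})

test_that("chi-square enrichment matches the closed form", {
  # equal outlier proportions: statistic 0, p = 1
  cand <- rep(c(TRUE, FALSE), c(100, 900))
  outl <- c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(90, 810)))
  enr <- enrichment_chisq(outl, cand)
  expect_equal(enr$statistic, 0, tolerance = 1e-12)
  expect_equal(enr$p, 1)
  # printed toy table: candidates 10/100 outliers, background 40/900
  outl2 <- c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(40, 860)))
  enr2 <- enrichment_chisq(outl2, cand)
  tab <- matrix(c(860, 90, 40, 10), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / 1000
  by_hand <- sum((tab - expected)^2 / expected)
  expect_equal(enr2$statistic, by_hand, tolerance = 1e-12)
  expect_equal(enr2$p, pchisq(by_hand, 1, lower.tail = FALSE))
  # low expected counts warn; degenerate margins error
  expect_warning(enrichment_chisq(c(TRUE, rep(FALSE, 30)),
                                  c(TRUE, TRUE, rep(FALSE, 29))),
                 "below 5")
  expect_error(enrichment_chisq(rep(FALSE, 10), rep(c(TRUE, FALSE), 5)),
               "margin")
})

test_that("permutation tests: degenerate input, planted effects, seeds", {
  vals <- rep(1, 50)
  cand <- rep(c(TRUE, FALSE), c(10, 40))
  pr <- permutation_mean_diff(vals, cand, n_perm = 50, tail = "two-sided",
                              seed = 1)
  expect_equal(pr$observed, 0)
  expect_equal(pr$p, 1)
  # planted 3-sd shift: p = 0 with raw counting, add-one stays positive
  withr::with_seed(2, {
    vals <- c(rnorm(20, mean = 3), rnorm(180))
  })
  cand <- rep(c(TRUE, FALSE), c(20, 180))
  pr2 <- permutation_mean_diff(vals, cand, n_perm = 100, tail = "upper",
                               seed = 7)
  expect_equal(pr2$p, 0)
  expect_equal(pr2$p_add_one, 1 / 101)
  # bit-exact reproducibility under a fixed seed
  pr3 <- permutation_mean_diff(vals, cand, n_perm = 100, tail = "upper",
                               seed = 7)
  expect_identical(pr2$perms, pr3$perms)
  expect_error(permutation_mean_diff(vals, rep(FALSE, 200)), "candidate")
  expect_error(permutation_mean_diff(rep(NA_real_, 10), rep(TRUE, 10)),
               "candidate|background")
})

test_that("male/female contrast is symmetric and handles identical sets", {
  withr::with_seed(8, {
    recs <- data.frame(gene = sprintf("g%03d", 1:100),
                       pi_P3 = rnorm(100), f_dM = rnorm(100))
  })
  set1 <- recs$gene[1:20]
  set2 <- recs$gene[15:40]
  a <- male_female_contrast(recs, set1, set2,
                            statistics = c("pi_P3", "f_dM"),
                            n_perm = 200, seed = 5)
  b <- male_female_contrast(recs, set2, set1,
                            statistics = c("pi_P3", "f_dM"),
                            n_perm = 200, seed = 5)
  expect_equal(a$observed, -b$observed)
  expect_equal(a$p, b$p)
  # identical sets: difference 0, p = 1
  same <- male_female_contrast(recs, set1, set1, statistics = "pi_P3",
                               n_perm = 50, seed = 2)
  expect_equal(same$observed, 0)
  expect_equal(same$p, 1)
})

test_that("a planted shift appears only in the affected statistic", {
  withr::with_seed(11, {
    recs <- data.frame(gene = sprintf("g%03d", 1:200),
                       pi_P3 = rnorm(200), f_dM = rnorm(200))
    male <- sample(recs$gene, 30)
    female <- sample(setdiff(recs$gene, male), 30)
    recs$f_dM[recs$gene %in% male] <- recs$f_dM[recs$gene %in% male] + 3
  })
  res <- male_female_contrast(recs, male, female,
                              statistics = c("pi_P3", "f_dM"),
                              n_perm = 100, seed = 3)
  expect_lt(res$p[res$statistic == "f_dM"], 0.05)
  expect_gt(res$p[res$statistic == "pi_P3"], 0.05)
})

test_that("gene_scan assembles the per-gene record", {
  cfg <- test_sim_config(seed = 6L)
  ann <- simulate_annotation(cfg)
  gen <- simulate_genome(cfg, annotation = ann)
  scan <- gene_scan(gen$G, gen$map, ann$models, ann$rate_map,
                    candidates = ann$candidates,
                    chrom_lengths = as.list(cfg$chrom_lengths))
  expect_equal(nrow(scan), cfg$n_genes)
  expect_equal(sum(scan$candidate), length(ann$candidates))
  expect_false(any(is.na(scan$r)))
  # spot-check one gene against direct single-window computation
  m <- ann$models[[5]]
  w <- gene_window(m, 5000, cfg$chrom_lengths[[m$chrom]])
  i <- which(scan$gene == m$gene_id)
  expect_equal(scan$pi_P3[i], nucleotide_diversity(gen$G, gen$map, w))
  expect_equal(scan$r[i],
               mean_rate_in_interval(ann$rate_map, w$chrom, w$start, w$end))
})
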
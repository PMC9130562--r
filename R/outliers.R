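## Gene-centered outlier scan: assemble the seven per-gene statistics,
## regress each on local recombination rate, flag influential genes by
## Cook's distance with statistic-specific tails, apply the empirical
## quantile rule to dN/dS, and run enrichment / permutation inference
## against the candidate gene set.

## Which side of the fitted line counts as "outlying" for each statistic.
## Diversity outliers sit below the line (selection removes variation);
## divergence outliers above; the introgression statistic is two-tailed.
DEFAULT_TAILS <- c(pi_P3 = "below",
                   fst_P3_P1 = "above", fst_P3_P2 = "above",
                   dxy_P3_P1 = "above", dxy_P3_P2 = "above",
                   f_dM = "both")

## Tail conventions for the candidate-vs-background permutation tests.
DEFAULT_PERM_TAILS <- c(pi_P3 = "lower", omega = "upper",
                        fst_P3_P1 = "two-sided", fst_P3_P2 = "two-sided",
                        dxy_P3_P1 = "two-sided", dxy_P3_P2 = "two-sided",
                        f_dM = "two-sided")

#' Assemble the per-gene scan table
#'
#' For every gene model a gene-anchored window (transcript union plus
#' flank) is formed and the window statistics are recomputed on it; the
#' length-weighted mean recombination rate, the topology-weighted dN/dS
#' and the candidate flag are joined in.
#'
#' @param G a [genotype_matrix()].
#' @param map a [group_map()].
#' @param models named list of [gene_model()] objects.
#' @param rate_map an [interval_map()] of recombination rates (cM/Mb).
#' @param omega optional named vector of per-gene topology-weighted dN/dS.
#' @param candidates character vector of candidate gene IDs.
#' @param flank gene window flank in bp (default 5000).
#' @param chrom_lengths optional named vector for right-clipping windows.
#' @return data.frame with one row per gene: window coordinates,
#'   `n_sites`, mean rate `r`, the seven statistics and `candidate`.
#' @export
gene_scan <- function(G, map, models, rate_map, omega = NULL,
                      candidates = character(), flank = 5000,
                      chrom_lengths = NULL) {
  ms_assert(length(models) > 0, "no gene models")
  wins <- do.call(rbind, lapply(models, function(m) {
    gene_window(m, flank = flank,
                chrom_length = chrom_lengths[[m$chrom]] %||% NULL)
  }))
  ids <- vapply(models, `[[`, character(1), "gene_id")
  ## window_stats expects windows grouped by chromosome in G's order
  ord <- order(match(wins$chrom, chrom_levels(G$sites$chrom)), wins$start)
  st <- window_stats(G, map, wins[ord, ])[order(ord), ]
  r <- vapply(seq_along(models), function(i) {
    mean_rate_in_interval(rate_map, wins$chrom[i], wins$start[i], wins$end[i])
  }, numeric(1))
  data.frame(
    gene = ids, chrom = wins$chrom, start = wins$start, end = wins$end,
    n_sites = st$n_sites, r = r,
    pi_P3 = st$pi_P3, fst_P3_P1 = st$fst_P3_P1, fst_P3_P2 = st$fst_P3_P2,
    dxy_P3_P1 = st$dxy_P3_P1, dxy_P3_P2 = st$dxy_P3_P2, f_dM = st$f_dM,
    omega = if (is.null(omega)) NA_real_ else unname(omega[ids]),
    candidate = ids %in% candidates,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Ordinary least squares of a statistic on recombination rate
#'
#' Fits `value ~ rate` and records, per gene, the fitted value, residual,
#' leverage and Cook's distance.
#'
#' @param values per-gene statistic.
#' @param rates per-gene mean recombination rate.
#' @param ids gene IDs (defaults to names of `values` or indices).
#' @param statistic statistic name carried into the output.
#' @return object of class `regression_fit`: coefficients, `sigma2`, `n`
#'   and data.frame `points`.
#' @export
fit_rate_regression <- function(values, rates, ids = NULL, statistic = "stat") {
  ids <- ids %||% names(values) %||% as.character(seq_along(values))
  ok <- !is.na(values) & !is.na(rates)
  ms_assert(sum(ok) >= 3, "need at least 3 complete (value, rate) pairs")
  v <- values[ok]; r <- rates[ok]; id <- ids[ok]
  ms_assert(sd(r) > 0, "regression undefined: zero rate variance")
  fit <- lm(v ~ r)
  cd <- unname(cooks.distance(fit))
  ## an exact fit makes Cook's distance 0/0; define it as zero influence
  if (max(abs(resid(fit))) < 1e-10 * max(1, max(abs(v)))) cd[] <- 0
  pts <- data.frame(
    id = id, value = v, rate = r,
    fitted = unname(fitted(fit)), residual = unname(resid(fit)),
    leverage = unname(hatvalues(fit)), cooksd = cd,
    stringsAsFactors = FALSE
  )
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  structure(list(statistic = statistic,
                 intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
                 sigma2 = sm$sigma^2, n = nrow(pts), points = pts,
                 p_slope = sm$coefficients[2, 4]),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s ~ rate: slope %.4g (p = %.3g), n = %d\n",
              x$statistic, x$slope, x$p_slope, x$n))
  invisible(x)
}

#' Cook's-distance outlier calls
#'
#' A gene is flagged when its Cook's distance exceeds `k` times the mean
#' Cook's distance of the fit *and* its residual lies on the configured
#' side of the fitted value.
#'
#' @param fit a [fit_rate_regression()] result.
#' @param direction `"above"`, `"below"` or `"both"`; defaults to the
#'   statistic's configured tail (see `DEFAULT_TAILS`), errors for unknown
#'   statistics without an explicit direction.
#' @param k multiplier on the mean Cook's distance (default 3).
#' @return data.frame with `gene`, `statistic`, `value`, `fitted`,
#'   `cooksd`, `direction` (side of the line) and `is_outlier`.
#' @export
call_cooksd_outliers <- function(fit, direction = NULL, k = 3) {
  if (is.null(direction)) {
    direction <- DEFAULT_TAILS[fit$statistic]
    if (is.na(direction))
      ms_stop("no tail configured for statistic '%s'; pass direction=",
              fit$statistic)
  }
  ms_assert(direction %in% c("above", "below", "both"),
            "direction must be above, below or both")
  p <- fit$points
  thr <- k * mean(p$cooksd)
  side <- ifelse(p$residual >= 0, "above", "below")
  side_ok <- switch(direction,
                    above = side == "above",
                    below = side == "below",
                    both = TRUE)
  data.frame(gene = p$id, statistic = fit$statistic, value = p$value,
             fitted = p$fitted, cooksd = p$cooksd, direction = side,
             rule = "cooksd", is_outlier = p$cooksd > thr & side_ok,
             stringsAsFactors = FALSE)
}

#' Upper-quantile outlier calls for dN/dS
#'
#' Flags genes at or above the empirical `(1 - q)` quantile: the cutoff is
#' the `floor(q * n)`-th largest value, and ties at the cutoff are all
#' flagged.
#'
#' @param omega named per-gene topology-weighted dN/dS.
#' @param q upper-tail fraction (default 0.05).
#' @return data.frame with `gene`, `statistic`, `value`, `rule`,
#'   `direction`, `is_outlier`.
#' @export
call_quantile_outliers <- function(omega, q = 0.05) {
  x <- omega[!is.na(omega)]
  ms_assert(length(x) >= 1 / q, "too few genes (%d) for a %g quantile rule",
            length(x), q)
  n_flag <- max(1L, floor(q * length(x)))
  cutoff <- sort(x, decreasing = TRUE)[n_flag]
  data.frame(gene = names(x), statistic = "omega", value = unname(x),
             fitted = NA_real_, cooksd = NA_real_, direction = "above",
             rule = "quantile", is_outlier = unname(x >= cutoff),
             stringsAsFactors = FALSE)
}

#' Chi-square enrichment of outliers in the candidate set
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 candidate-by-outlier table.
#'
#' @param outlier logical per-gene outlier flags.
#' @param candidate logical per-gene candidate flags.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `table`, `statistic`, `p`, `expected` and
#'   `low_expected` (TRUE when any expected cell is below 5).
#' @export
enrichment_chisq <- function(outlier, candidate, correct = FALSE) {
  ms_assert(length(outlier) == length(candidate), "flag lengths differ")
  tab <- table(candidate = factor(candidate, c(FALSE, TRUE)),
               outlier = factor(outlier, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    ms_stop("degenerate 2x2 table: a row or column margin is zero")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  low <- any(expected < 5)
  if (low) warning("chi-square approximation: expected cell count below 5")
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
       expected = expected, low_expected = low)
}

#' Permutation test on the candidate-vs-background mean difference
#'
#' The test statistic is `mean(candidates) - mean(background)`. Labels are
#' shuffled `n_perm` times; the p-value is the raw fraction of replicates
#' at least as extreme under the configured tail (which can be exactly 0),
#' with the add-one estimator `(k + 1) / (n_perm + 1)` reported alongside.
#'
#' @param values per-gene statistic (NAs dropped).
#' @param candidate logical flags, same length.
#' @param n_perm number of permutations (default 100).
#' @param tail `"two-sided"`, `"lower"` or `"upper"`.
#' @param seed RNG seed.
#' @return object of class `permutation_result`: `observed`, `perms`,
#'   `n_perm`, `tail`, `p`, `p_add_one`.
#' @export
permutation_mean_diff <- function(values, candidate, n_perm = 100,
                                  tail = "two-sided", seed = 1L) {
  ms_assert(tail %in% c("two-sided", "lower", "upper"), "unknown tail %s", tail)
  ok <- !is.na(values)
  v <- values[ok]; cand <- candidate[ok]
  ms_assert(sum(cand) > 0, "empty candidate set after missing-value removal")
  ms_assert(sum(!cand) > 0, "empty background set after missing-value removal")
  obs <- mean(v[cand]) - mean(v[!cand])
  n_c <- sum(cand)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(length(v), n_c)
      mean(v[ix]) - mean(v[-ix])
    }, numeric(1))
  })
  k <- switch(tail,
              lower = sum(perms <= obs),
              upper = sum(perms >= obs),
              `two-sided` = sum(abs(perms) >= abs(obs)))
  structure(list(observed = obs, perms = perms, n_perm = n_perm, tail = tail,
                 p = k / n_perm, p_add_one = (k + 1) / (n_perm + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4g, %s p = %.3g (add-one %.3g, %d perms)\n",
              x$observed, x$tail, x$p, x$p_add_one, x$n_perm))
  invisible(x)
}

#' Male-set versus female-set permutation contrast
#'
#' Two-sided permutation test of the mean difference between two candidate
#' sub-lists (e.g. male versus female genital-development genes) for each
#' requested statistic. Genes present in both sets are kept in both by
#' default. The permutation draws two sets of the observed sizes from the
#' union; the computation is canonicalized on set size so that swapping
#' the two input sets negates the observed difference but leaves the
#' p-value unchanged.
#'
#' @param records gene scan table from [gene_scan()].
#' @param male_ids,female_ids gene ID vectors.
#' @param statistics statistic columns to test.
#' @param n_perm permutations per statistic (default 100).
#' @param seed RNG seed.
#' @param drop_shared drop genes present in both sets (default FALSE).
#' @return data.frame with one row per statistic: `observed`
#'   (male - female), `p`, `n_male`, `n_female`.
#' @export
male_female_contrast <- function(records, male_ids, female_ids,
                                 statistics = c("pi_P3", "fst_P3_P1",
                                                "fst_P3_P2", "dxy_P3_P1",
                                                "dxy_P3_P2", "f_dM", "omega"),
                                 n_perm = 100, seed = 1L,
                                 drop_shared = FALSE) {
  if (drop_shared) {
    shared <- intersect(male_ids, female_ids)
    male_ids <- setdiff(male_ids, shared)
    female_ids <- setdiff(female_ids, shared)
  }
  ms_assert(length(male_ids) > 0 && length(female_ids) > 0,
            "both gene sets must be non-empty")
  ## canonical order: smaller set first (ties broken by first ID) so the
  ## test is exactly symmetric under swapping the inputs
  swap <- (length(female_ids) < length(male_ids)) ||
    (length(female_ids) == length(male_ids) &&
       min(female_ids) < min(male_ids))
  setA <- if (swap) female_ids else male_ids
  setB <- if (swap) male_ids else female_ids
  rows <- lapply(seq_along(statistics), function(si) {
    stat <- statistics[si]
    vals <- setNames(records[[stat]], records$gene)
    vA <- vals[intersect(setA, names(vals))]
    vB <- vals[intersect(setB, names(vals))]
    vA <- vA[!is.na(vA)]; vB <- vB[!is.na(vB)]
    ms_assert(length(vA) > 0 && length(vB) > 0,
              "no usable %s values in one of the sets", stat)
    obs <- mean(vA) - mean(vB)
    pool <- vals[union(names(vA), names(vB))]
    perms <- with_seed(derive_seed(seed, si), {
      vapply(seq_len(n_perm), function(i) {
        a <- sample(pool, length(vA))
        b <- sample(pool, length(vB))
        mean(a) - mean(b)
      }, numeric(1))
    })
    p <- sum(abs(perms) >= abs(obs)) / n_perm
    data.frame(statistic = stat, observed = if (swap) -obs else obs, p = p,
               n_male = length(if (swap) vB else vA),
               n_female = length(if (swap) vA else vB),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
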
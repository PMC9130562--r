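## Sliding/gene-anchored windows and the per-window statistics.
##
## Conventions (documented in the methods vignette):
##  * a site is *usable* when each of P1, P2, P3 has at least two called
##    alleles there; usable-site counts are the per-window denominators for
##    the per-site statistics and for the minimum-site rule;
##  * a site is *polarizable* when additionally the outgroup allele is
##    known; only polarizable sites enter the ABBA/BABA pattern sums;
##  * all window coordinates are 0-based half-open.

#' Sliding windows over chromosomes
#'
#' Windows start at 0 with a step equal to `round(size * step_fraction)`;
#' only windows fully contained in a chromosome are emitted.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step_fraction step as a fraction of `size` (default 0.2, i.e.
#'   80% overlap); 1 gives a non-overlapping tiling.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
make_sliding_windows <- function(chrom_lengths, size, step_fraction = 0.2) {
  ms_assert(size > 0, "window size must be positive")
  ms_assert(step_fraction > 0 && step_fraction <= 1,
            "step_fraction must be in (0, 1]")
  step <- max(1L, as.integer(round(size * step_fraction)))
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < size) return(NULL)
    starts <- seq.int(0L, as.integer(L - size), by = step)
    data.frame(chrom = ch, start = starts, end = starts + as.integer(size))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer())
  out
}

#' Gene-anchored window
#'
#' The smallest span containing all transcripts of a gene, extended by a
#' flank on both sides (to capture proximal regulatory sequence) and
#' clipped at the chromosome bounds.
#'
#' @param model a [gene_model()].
#' @param flank flank size in bp (default 5000).
#' @param chrom_length optional chromosome length for right clipping.
#' @return data.frame row with `chrom`, `start`, `end`.
#' @export
gene_window <- function(model, flank = 5000, chrom_length = NULL) {
  s <- max(0, min(model$transcripts$start) - flank)
  e <- max(model$transcripts$end) + flank
  if (!is.null(chrom_length)) e <- min(e, chrom_length)
  data.frame(chrom = model$chrom, start = s, end = e)
}

#' Minimum usable sites required for a window size
#'
#' The supported ladder pairs window sizes 5, 25, 50, 100, 500 and 1000 kb
#' with thresholds 10, 50, 100, 200, 1000 and 2000 usable sites.
#'
#' @param size window size in bp.
#' @return integer threshold.
#' @export
min_sites_for_size <- function(size) {
  ladder <- c(`5000` = 10L, `25000` = 50L, `50000` = 100L, `1e+05` = 200L,
              `5e+05` = 1000L, `1e+06` = 2000L)
  key <- as.character(as.numeric(size))
  if (!key %in% names(ladder))
    ms_stop("no minimum-site threshold configured for window size %s", size)
  ladder[[key]]
}

#' Apply the minimum-site rule to a window statistics table
#'
#' Every statistic column is set missing for windows whose usable-site
#' count falls below the threshold (strictly fewer than `min_sites`).
#'
#' @param stats data.frame from [window_stats()].
#' @param window_size window size in bp, used to look up the ladder
#'   threshold when `min_sites` is not given.
#' @param min_sites explicit threshold overriding the ladder.
#' @return the filtered data.frame.
#' @export
apply_min_sites <- function(stats, window_size = NULL, min_sites = NULL) {
  if (is.null(min_sites)) {
    ms_assert(!is.null(window_size), "need window_size or explicit min_sites")
    min_sites <- min_sites_for_size(window_size)
  }
  statcols <- intersect(c("pi_P3", "dxy_P3_P1", "dxy_P3_P2", "fst_P3_P1",
                          "fst_P3_P2", "D", "f_dM"), names(stats))
  low <- stats$n_sites < min_sites
  stats[low, statcols] <- NA_real_
  stats
}

## Per-site ingredient table used by every window statistic. Contributions
## from non-usable sites are zeroed so windows can be aggregated by
## cumulative sums.
site_stat_table <- function(G, map) {
  f1 <- group_alt_freq(G, map, "P1")
  f2 <- group_alt_freq(G, map, "P2")
  f3 <- group_alt_freq(G, map, "P3")
  usable <- f1$n >= 2L & f2$n >= 2L & f3$n >= 2L
  og_ok <- !is.na(G$outgroup)
  pol <- usable & og_ok

  ## unbiased per-site heterozygosity 2p(1-p) n/(n-1)
  hz <- function(f) 2 * f$p * (1 - f$p) * f$n / pmax(f$n - 1L, 1L)
  pi1 <- hz(f1); pi2 <- hz(f2); pi3 <- hz(f3)
  dxy31 <- f3$p * (1 - f1$p) + f1$p * (1 - f3$p)
  dxy32 <- f3$p * (1 - f2$p) + f2$p * (1 - f3$p)
  hw31 <- (pi3 + pi1) / 2
  hw32 <- (pi3 + pi2) / 2

  d1 <- polarize(f1$p, G$outgroup)
  d2 <- polarize(f2$p, G$outgroup)
  d3 <- polarize(f3$p, G$outgroup)
  abba <- (1 - d1) * d2 * d3
  baba <- d1 * (1 - d2) * d3
  ## dynamic-donor denominators of f_dM (donor substituted in both slots)
  pdG <- pmax(d2, d3)
  dpos <- (1 - d1) * pdG * pdG - d1 * (1 - pdG) * pdG
  pdD <- pmax(d1, d3)
  dneg <- -((1 - pdD) * d2 * pdD - pdD * (1 - d2) * pdD)

  z <- function(x, keep) ifelse(keep & !is.na(x), x, 0)
  data.frame(
    chrom = G$sites$chrom, pos0 = G$sites$pos - 1L,
    usable = usable, pol = pol,
    pi1 = z(pi1, usable), pi2 = z(pi2, usable), pi3 = z(pi3, usable),
    dxy31 = z(dxy31, usable), dxy32 = z(dxy32, usable),
    hw31 = z(hw31, usable), hw32 = z(hw32, usable),
    abba = z(abba, pol), baba = z(baba, pol),
    dpos = z(dpos, pol), dneg = z(dneg, pol)
  )
}

## Sum site-table columns over many (possibly overlapping) windows via
## cumulative sums: O(sites + windows).
aggregate_windows <- function(tab, windows) {
  num_cols <- setdiff(names(tab), c("chrom", "pos0"))
  out <- matrix(0, nrow = nrow(windows), ncol = length(num_cols),
                dimnames = list(NULL, num_cols))
  for (ch in chrom_levels(windows$chrom)) {
    w_ix <- which(windows$chrom == ch)
    s_ix <- which(tab$chrom == ch)
    pos <- tab$pos0[s_ix]
    cs <- vapply(num_cols, function(cn) c(0, cumsum(as.numeric(tab[[cn]][s_ix]))),
                 numeric(length(s_ix) + 1L))
    lo <- findInterval(windows$start[w_ix] - 0.5, pos)
    hi <- findInterval(windows$end[w_ix] - 0.5, pos)
    out[w_ix, ] <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  as.data.frame(out)
}

#' Window statistics table
#'
#' Computes, for each window, nucleotide diversity of P3, absolute
#' divergence D_XY and Hudson-type F_ST of P3 against P1 and P2,
#' Patterson's D and the symmetric introgression statistic f_dM
#' (positive = excess P2/P3 sharing, negative = excess P1/P3 sharing).
#'
#' @param G a [genotype_matrix()].
#' @param map a [group_map()] with non-empty P1, P2, P3.
#' @param windows data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [make_sliding_windows()].
#' @param min_sites optional minimum usable sites; windows below it have
#'   all statistics set missing.
#' @return data.frame with window coordinates, `n_sites` (usable),
#'   `n_pol` (polarizable) and the seven statistic columns.
#' @export
window_stats <- function(G, map, windows, min_sites = NULL) {
  tab <- site_stat_table(G, map)
  agg <- aggregate_windows(tab, windows)
  n_sites <- agg$usable
  n_pol <- agg$pol
  res <- data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    n_sites = as.integer(n_sites), n_pol = as.integer(n_pol),
    pi_P3 = ifelse(n_sites > 0, agg$pi3 / n_sites, NA_real_),
    dxy_P3_P1 = ifelse(n_sites > 0, agg$dxy31 / n_sites, NA_real_),
    dxy_P3_P2 = ifelse(n_sites > 0, agg$dxy32 / n_sites, NA_real_),
    fst_P3_P1 = ifelse(agg$dxy31 > 0, 1 - agg$hw31 / agg$dxy31, NA_real_),
    fst_P3_P2 = ifelse(agg$dxy32 > 0, 1 - agg$hw32 / agg$dxy32, NA_real_),
    D = patterson_D(list(sum_abba = agg$abba, sum_baba = agg$baba)),
    f_dM = fdm(list(sum_abba = agg$abba, sum_baba = agg$baba,
                    sum_denom_pos = agg$dpos, sum_denom_neg = agg$dneg,
                    n_sites = n_pol))
  )
  if (!is.null(min_sites)) res <- apply_min_sites(res, min_sites = min_sites)
  res
}

## --- single-window operations ----------------------------------------------

window_site_table <- function(G, map, window) {
  Gw <- subset_region(G, window$chrom, window$start, window$end)
  site_stat_table(Gw, map)
}

#' Nucleotide diversity of one group in one window
#'
#' Average pairwise difference per usable site, using the unbiased
#' n/(n-1)-corrected per-site heterozygosity.
#'
#' @param G a [genotype_matrix()].
#' @param map a [group_map()].
#' @param window one-row data.frame (`chrom`, `start`, `end`).
#' @param group group whose diversity is measured (default `"P3"`).
#' @return per-site diversity, or `NA` with no usable sites.
#' @export
nucleotide_diversity <- function(G, map, window, group = "P3") {
  tab <- window_site_table(G, map, window)
  n <- sum(tab$usable)
  if (n == 0) return(NA_real_)
  col <- c(P1 = "pi1", P2 = "pi2", P3 = "pi3")[[group]]
  sum(tab[[col]]) / n
}

#' Absolute divergence D_XY between P3 and a parental group in one window
#' @inheritParams nucleotide_diversity
#' @param other `"P1"` or `"P2"`.
#' @return per-site divergence, or `NA` with no usable sites.
#' @export
dxy <- function(G, map, window, other = "P1") {
  tab <- window_site_table(G, map, window)
  n <- sum(tab$usable)
  if (n == 0) return(NA_real_)
  col <- c(P1 = "dxy31", P2 = "dxy32")[[other]]
  sum(tab[[col]]) / n
}

#' Hudson-type F_ST between P3 and a parental group in one window
#'
#' Ratio of averages 1 - mean(Hw)/mean(Hb) with sample-size-corrected
#' within-group heterozygosities.
#'
#' @inheritParams dxy
#' @return F_ST, or `NA` when mean between-group heterozygosity is zero.
#' @export
fst <- function(G, map, window, other = "P1") {
  tab <- window_site_table(G, map, window)
  hw <- c(P1 = "hw31", P2 = "hw32")[[other]]
  hb <- c(P1 = "dxy31", P2 = "dxy32")[[other]]
  den <- sum(tab[[hb]])
  if (den <= 0) return(NA_real_)
  1 - sum(tab[[hw]]) / den
}

#' ABBA/BABA site-pattern sums for one window
#'
#' Sites are polarized on the outgroup allele (derived = non-outgroup
#' allele, so the outgroup's derived frequency is identically zero); sites
#' with unknown outgroup allele are skipped.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `sum_abba`, `sum_baba`, `sum_denom_pos`,
#'   `sum_denom_neg` (the dynamic-donor f_dM denominators) and `n_sites`
#'   (polarizable usable sites).
#' @export
site_pattern_sums <- function(G, map, window) {
  tab <- window_site_table(G, map, window)
  list(sum_abba = sum(tab$abba), sum_baba = sum(tab$baba),
       sum_denom_pos = sum(tab$dpos), sum_denom_neg = sum(tab$dneg),
       n_sites = sum(tab$pol))
}

#' Patterson's D from site-pattern sums
#' @param s list with `sum_abba`, `sum_baba` (vectors allowed).
#' @return (ABBA - BABA) / (ABBA + BABA); `NA` for zero denominators.
#' @export
patterson_D <- function(s) {
  den <- s$sum_abba + s$sum_baba
  ifelse(den > 0, (s$sum_abba - s$sum_baba) / den, NA_real_)
}

#' f_dM from site-pattern sums
#'
#' The symmetric dynamic-donor introgression fraction: the numerator is
#' ABBA - BABA; the denominator substitutes the higher of (p2, p3) as donor
#' when the numerator is non-negative and the higher of (p1, p3) when it is
#' negative. Values are clamped to `[-1, 1]` (degenerate frequency
#' configurations can push the raw ratio marginally outside).
#'
#' @param s list as returned by [site_pattern_sums()] (vectors allowed).
#' @return f_dM in `[-1, 1]`; `NA` when the matching denominator is zero or
#'   no polarizable site exists.
#' @export
fdm <- function(s) {
  num <- s$sum_abba - s$sum_baba
  den <- ifelse(num >= 0, s$sum_denom_pos, s$sum_denom_neg)
  ok <- s$n_sites > 0 & den > 0
  ifelse(ok, pmin(1, pmax(-1, num / den)), NA_real_)
}
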
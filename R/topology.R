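## Window trees and topology weighting.
##
## Diploid genotypes are pseudo-haploidized (two pseudo-haplotypes per
## sample; heterozygous sites resolved by a seeded draw), neighbor-joining
## trees are built in non-overlapping windows of a fixed number of SNPs,
## and each tree's weight on the three rooted species topologies is
## computed by exact enumeration of one-tip-per-group combinations:
##   topo1  (arc,(fas,sin))  -- P3 alone outside (P1,P2)
##   topo2  (fas,(arc,sin))  -- P3 sister to P1
##   topo3  ((arc,fas),sin)  -- P3 sister to P2

TOPO_LABELS <- c("topo1", "topo2", "topo3")

#' Pseudo-haploidize a genotype matrix
#'
#' Each diploid sample contributes two pseudo-haplotypes. Homozygous
#' genotypes fill both haplotypes; heterozygous sites assign the ALT allele
#' to one of the two haplotypes by a seeded per-sample-per-site draw. The
#' haploid outgroup allele becomes a tip named `"outgroup"`.
#'
#' @param G a [genotype_matrix()].
#' @param map a [group_map()].
#' @param seed integer seed making the heterozygote resolution
#'   deterministic.
#' @return list with `haps` (sites x tips 0/1/NA matrix) and `tips`
#'   (data.frame `tip`, `sample`, `group`).
#' @export
pseudo_haplotypes <- function(G, map, seed = 1L) {
  keep <- G$samples[G$samples %in% map$sample[map$group %in% c("P1", "P2", "P3")]]
  ms_assert(length(keep) > 0, "no P-group samples present")
  geno <- G$geno[, keep, drop = FALSE]
  n <- length(keep)
  hapA <- matrix(NA_integer_, nrow(geno), n)
  hapB <- hapA
  hapA[geno == 0L] <- 0L; hapB[geno == 0L] <- 0L
  hapA[geno == 2L] <- 1L; hapB[geno == 2L] <- 1L
  het <- which(geno == 1L)
  with_seed(seed, {
    pick <- runif(length(het)) < 0.5
    hapA[het] <- as.integer(pick)
    hapB[het] <- as.integer(!pick)
  })
  haps <- matrix(NA_integer_, nrow(geno), 2L * n + 1L)
  haps[, seq(1L, 2L * n, by = 2L)] <- hapA
  haps[, seq(2L, 2L * n, by = 2L)] <- hapB
  haps[, 2L * n + 1L] <- G$outgroup
  tip_names <- c(rbind(paste0(keep, "_a"), paste0(keep, "_b")), "outgroup")
  colnames(haps) <- tip_names
  grp <- map$group[match(keep, map$sample)]
  tips <- data.frame(tip = tip_names,
                     sample = c(rbind(keep, keep), "outgroup"),
                     group = c(rbind(grp, grp), "OUT"),
                     stringsAsFactors = FALSE)
  list(haps = haps, tips = tips)
}

## Pairwise p-distances among haplotype columns; NA when no shared called
## site.
hap_pdist <- function(H) {
  C <- !is.na(H)
  X <- H; X[!C] <- 0L
  storage.mode(X) <- "double"; storage.mode(C) <- "double"
  shared <- crossprod(C)
  diffs <- crossprod(X, C) + crossprod(C, X) - 2 * crossprod(X)
  d <- diffs / shared
  d[shared == 0] <- NA_real_
  d
}

#' Neighbor-joining trees in SNP windows
#'
#' @param G a [genotype_matrix()].
#' @param map a [group_map()]; every P group must have at least one sample.
#' @param snps_per_window SNPs per window (default 50).
#' @param step window step in SNPs; defaults to `snps_per_window`
#'   (non-overlapping). Trailing windows with fewer SNPs are skipped.
#' @param seed seed for the heterozygote resolution.
#' @return list of `window_tree` objects: `chrom`, `start`, `end` (genomic
#'   span of the window's SNPs, half-open), `n_snps`, `tree` (ape phylo),
#'   `newick`, `tips`, `star` (TRUE when all haplotypes were identical).
#' @export
window_trees <- function(G, map, snps_per_window = 50L, step = NULL,
                         seed = 1L) {
  for (g in c("P1", "P2", "P3")) group_cols(G, map, g)
  step <- as.integer(step %||% snps_per_window)
  ph <- pseudo_haplotypes(G, map, seed = seed)
  out <- list()
  for (ch in chrom_levels(G$sites$chrom)) {
    ix <- which(G$sites$chrom == ch)
    if (length(ix) < snps_per_window) next
    starts <- seq.int(1L, length(ix) - snps_per_window + 1L, by = step)
    for (s in starts) {
      rows <- ix[s:(s + snps_per_window - 1L)]
      wt <- build_window_tree(ph$haps[rows, , drop = FALSE], ph$tips)
      if (is.null(wt)) next
      wt$chrom <- ch
      wt$start <- G$sites$pos[rows[1]] - 1L
      wt$end <- G$sites$pos[rows[length(rows)]]
      wt$n_snps <- snps_per_window
      out[[length(out) + 1L]] <- wt
    }
  }
  out
}

build_window_tree <- function(H, tips) {
  called <- colSums(!is.na(H))
  use <- called >= max(1, nrow(H) * 0.5)
  H <- H[, use, drop = FALSE]
  tips <- tips[use, , drop = FALSE]
  if (ncol(H) < 4L) return(NULL)
  d <- hap_pdist(H)
  ## tips without pairwise overlap cannot be placed; drop greedily
  while (anyNA(d)) {
    worst <- which.max(rowSums(is.na(d)))
    d <- d[-worst, -worst, drop = FALSE]
    tips <- tips[-worst, , drop = FALSE]
  }
  if (nrow(d) < 4L) return(NULL)
  if (!all(c("P1", "P2", "P3") %in% tips$group)) return(NULL)
  star <- all(d == 0)
  tree <- ape::nj(stats::as.dist(d))
  structure(list(tree = tree, newick = ape::write.tree(tree), tips = tips,
                 star = star),
            class = "window_tree")
}

#' Exact topology weights of a window tree
#'
#' Enumerates every combination of one tip per group (P1, P2, P3, outgroup)
#' and classifies the quartet each combination induces, using the
#' four-point condition on the tree's path distances: the pairing with the
#' smallest sum of within-pair distances is the displayed split. Ties
#' (polytomies) split the vote equally among compatible topologies.
#'
#' @param wt a `window_tree` from [window_trees()], or an ape `phylo` (then
#'   `tips` must be supplied).
#' @param tips optional tip data.frame (`tip`, `group`).
#' @return list with `w` (named weights summing to 1), `n_combos`, and
#'   `majority` left `NA` (see [majority_topology()]).
#' @export
topology_weights <- function(wt, tips = NULL) {
  if (inherits(wt, "window_tree")) {
    tree <- wt$tree; tips <- wt$tips
  } else {
    tree <- wt
    ms_assert(!is.null(tips), "tips required when passing a bare tree")
  }
  d <- ape::cophenetic.phylo(tree)
  ord <- match(tips$tip, rownames(d))
  idx <- split(ord, tips$group)
  for (g in c("P1", "P2", "P3", "OUT"))
    ms_assert(length(idx[[g]] %||% integer()) > 0, "no tip for group %s", g)
  combos <- expand.grid(i1 = idx$P1, i2 = idx$P2, i3 = idx$P3, io = idx$OUT,
                        KEEP.OUT.ATTRS = FALSE)
  s1 <- d[cbind(combos$i3, combos$io)] + d[cbind(combos$i1, combos$i2)]
  s2 <- d[cbind(combos$i3, combos$i1)] + d[cbind(combos$i2, combos$io)]
  s3 <- d[cbind(combos$i3, combos$i2)] + d[cbind(combos$i1, combos$io)]
  S <- cbind(s1, s2, s3)
  tol <- 1e-8 * (1 + max(d))
  m <- pmin(s1, s2, s3)
  votes <- S <= m + tol
  w <- colSums(votes / rowSums(votes)) / nrow(S)
  list(w = setNames(as.numeric(w), TOPO_LABELS), n_combos = nrow(S))
}

#' Majority topology under the two-thirds rule
#'
#' @param w named weight vector (`topo1`, `topo2`, `topo3`) summing to 1.
#' @param threshold majority threshold (default 2/3); the label with weight
#'   `>= threshold` wins, otherwise `"unresolved"`.
#' @return a label string.
#' @export
majority_topology <- function(w, threshold = 2 / 3) {
  ms_assert(abs(sum(w) - 1) < 1e-6, "weights must sum to 1")
  hit <- which(w >= threshold - 1e-9)
  if (length(hit) == 1) names(w)[hit] else "unresolved"
}

#' Topology weight table for a set of window trees
#'
#' @param trees list from [window_trees()].
#' @param threshold majority threshold (default 2/3).
#' @return data.frame with window span, `n_snps`, `w1`..`w3` and
#'   `majority`.
#' @export
topology_weight_table <- function(trees, threshold = 2 / 3) {
  rows <- lapply(trees, function(wt) {
    tw <- topology_weights(wt)
    data.frame(chrom = wt$chrom, start = wt$start, end = wt$end,
               n_snps = wt$n_snps,
               w1 = tw$w[["topo1"]], w2 = tw$w[["topo2"]], w3 = tw$w[["topo3"]],
               majority = majority_topology(tw$w, threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), w1 = numeric(), w2 = numeric(),
                      w3 = numeric(), majority = character())
}

#' Collapse adjacent same-label segments
#'
#' Run-length merge of consecutive windows/segments on the same chromosome
#' carrying the same majority label; supports are summed.
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `label` and
#'   optionally `support`; must be sorted and non-overlapping.
#' @return collapsed data.frame; adjacent rows differ in label.
#' @export
collapse_adjacent <- function(segments) {
  if (nrow(segments) == 0) return(segments)
  if (is.null(segments$support)) segments$support <- 1
  out <- list()
  for (ch in chrom_levels(segments$chrom)) {
    d <- segments[segments$chrom == ch, , drop = FALSE]
    ms_assert(!is.unsorted(d$start), "segments must be sorted")
    if (nrow(d) > 1)
      ms_assert(all(d$start[-1] >= d$end[-nrow(d)]), "segments overlap on %s", ch)
    r <- rle(d$label)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    out[[ch]] <- data.frame(
      chrom = ch, start = d$start[lo], end = d$end[hi], label = r$values,
      support = vapply(seq_along(lo),
                       function(k) sum(d$support[lo[k]:hi[k]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide topology proportions with block-bootstrap CIs
#'
#' Point estimates are the span-weighted shares of each majority label
#' (topo1/2/3/unresolved, in percent, summing to 100). Confidence
#' intervals come from resampling fixed-size genomic blocks with
#' replacement and taking percentile quantiles.
#'
#' @param wt weight table from [topology_weight_table()].
#' @param block block size in bp (default 1 Mb); partial terminal blocks
#'   are kept.
#' @param reps bootstrap replicates (default 10000).
#' @param seed RNG seed (results are deterministic given the seed).
#' @param conf confidence level (default 0.95).
#' @return data.frame with `label`, `estimate`, `lower`, `upper` (percent).
#' @export
genome_proportions_bootstrap <- function(wt, block = 1e6, reps = 10000,
                                         seed = 1L, conf = 0.95) {
  ms_assert(nrow(wt) > 0, "no windows to bootstrap")
  labels <- c(TOPO_LABELS, "unresolved")
  span <- wt$end - wt$start
  lab <- factor(wt$majority, labels)
  block_id <- paste0(wt$chrom, ":", floor((wt$start + wt$end) / 2 / block))
  blocks <- unique(block_id)
  ms_assert(length(blocks) >= 1, "zero blocks")
  ## per-block span per label
  M <- rowsum(outer(as.integer(lab), seq_along(labels), `==`) * span,
              group = block_id)
  colnames(M) <- labels
  est <- 100 * colSums(M) / sum(M)
  qs <- with_seed(seed, {
    draws <- matrix(sample.int(nrow(M), nrow(M) * reps, replace = TRUE),
                    nrow = reps)
    shares <- t(apply(draws, 1, function(ix) {
      cs <- colSums(M[ix, , drop = FALSE])
      100 * cs / sum(cs)
    }))
    apply(shares, 2, quantile, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
          names = FALSE)
  })
  data.frame(label = labels, estimate = as.numeric(est),
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}

#' Per-topology divergence between sister lineages
#'
#' Windows whose maximum topology weight reaches `purity` are labeled and
#' collapsed; D_XY is then computed on each segment between the focal
#' lineage (P3) and the class-appropriate group: P1 for topo2 segments
#' (P3's sister there), P2 for topo3 segments, and P2 for topo1 segments.
#'
#' @param G a [genotype_matrix()].
#' @param map a [group_map()].
#' @param wt weight table from [topology_weight_table()].
#' @param purity minimum weight for a window to count (default 1.0, i.e.
#'   unanimous windows only).
#' @return data.frame with `label`, `chrom`, `start`, `end`, `dxy`.
#' @export
dxy_by_topology <- function(G, map, wt, purity = 1.0) {
  ms_assert(purity > 2 / 3 && purity <= 1, "purity must be in (2/3, 1]")
  W <- as.matrix(wt[, c("w1", "w2", "w3")])
  top <- max.col(W, ties.method = "first")
  keep <- W[cbind(seq_len(nrow(W)), top)] >= purity - 1e-9
  if (!any(keep)) {
    return(data.frame(label = character(), chrom = character(),
                      start = integer(), end = integer(), dxy = numeric()))
  }
  seg <- data.frame(chrom = wt$chrom[keep], start = wt$start[keep],
                    end = wt$end[keep], label = TOPO_LABELS[top[keep]],
                    stringsAsFactors = FALSE)
  seg <- collapse_adjacent(seg)
  partner <- c(topo1 = "P2", topo2 = "P1", topo3 = "P2")
  seg$dxy <- vapply(seq_len(nrow(seg)), function(i) {
    dxy(G, map, seg[i, ], other = partner[[seg$label[i]]])
  }, numeric(1))
  seg[, c("label", "chrom", "start", "end", "dxy")]
}
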
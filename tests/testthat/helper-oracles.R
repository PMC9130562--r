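# Independent oracles: deliberately naive re-implementations (per-site /
# per-pair loops, leave-one-out refits, textbook algorithms) used to check
# the package's vectorized code paths. They share only the documented
# conventions (usable site = >=2 called alleles in each P group; polarized
# site additionally needs a known outgroup allele).

# -- random fixtures ---------------------------------------------------------

random_genotype_matrix <- function(n_sites = 20, n_per_group = c(3, 4, 3),
                                   miss = 0.05, og_miss = 0.1, seed = 1) {
  withr::with_seed(seed, {
    n <- sum(n_per_group)
    geno <- matrix(sample(0:2, n_sites * n, replace = TRUE), n_sites, n)
    geno[matrix(runif(n_sites * n) < miss, n_sites, n)] <- NA
    samples <- sprintf("s%02d", seq_len(n))
    colnames(geno) <- samples
    og <- sample(c(0L, 1L), n_sites, replace = TRUE)
    og[runif(n_sites) < og_miss] <- NA
    sites <- data.frame(chrom = "chr1", pos = sort(sample.int(n_sites * 50, n_sites)),
                        ref = "A", alt = "T")
    G <- genotype_matrix(sites, geno, og)
    map <- group_map(samples, rep(c("P1", "P2", "P3"), times = n_per_group))
    list(G = G, map = map)
  })
}

# -- window statistics -------------------------------------------------------

oracle_site_freqs <- function(G, map, group) {
  cols <- which(G$samples %in% group_samples(map, group))
  t(vapply(seq_len(nrow(G$sites)), function(i) {
    g <- G$geno[i, cols]
    g <- g[!is.na(g)]
    c(alt = sum(g), n = 2 * length(g))
  }, numeric(2)))
}

oracle_usable <- function(G, map) {
  f1 <- oracle_site_freqs(G, map, "P1")
  f2 <- oracle_site_freqs(G, map, "P2")
  f3 <- oracle_site_freqs(G, map, "P3")
  f1[, "n"] >= 2 & f2[, "n"] >= 2 & f3[, "n"] >= 2
}

# mean pairwise allele difference within one group, looped over all allele
# pairs site by site
oracle_pi <- function(G, map, group = "P3") {
  f <- oracle_site_freqs(G, map, group)
  usable <- oracle_usable(G, map)
  if (!any(usable)) return(NA_real_)
  per_site <- vapply(which(usable), function(i) {
    alt <- f[i, "alt"]; n <- f[i, "n"]
    if (n < 2) return(0)
    diff_pairs <- alt * (n - alt)
    diff_pairs / (n * (n - 1) / 2)
  }, numeric(1))
  sum(per_site) / sum(usable)
}

oracle_dxy <- function(G, map, other = "P1") {
  fA <- oracle_site_freqs(G, map, "P3")
  fB <- oracle_site_freqs(G, map, other)
  usable <- oracle_usable(G, map)
  if (!any(usable)) return(NA_real_)
  per_site <- vapply(which(usable), function(i) {
    pa <- fA[i, "alt"] / fA[i, "n"]
    pb <- fB[i, "alt"] / fB[i, "n"]
    pa * (1 - pb) + pb * (1 - pa)  # all between-group allele pairs
  }, numeric(1))
  sum(per_site) / sum(usable)
}

oracle_fst <- function(G, map, other = "P1") {
  fA <- oracle_site_freqs(G, map, "P3")
  fB <- oracle_site_freqs(G, map, other)
  usable <- oracle_usable(G, map)
  hw <- 0; hb <- 0
  for (i in which(usable)) {
    pa <- fA[i, "alt"] / fA[i, "n"]; na <- fA[i, "n"]
    pb <- fB[i, "alt"] / fB[i, "n"]; nb <- fB[i, "n"]
    hw <- hw + (2 * pa * (1 - pa) * na / (na - 1) +
                  2 * pb * (1 - pb) * nb / (nb - 1)) / 2
    hb <- hb + pa * (1 - pb) + pb * (1 - pa)
  }
  if (hb <= 0) return(NA_real_)
  as.numeric(1 - hw / hb)
}

# per-site ABBA/BABA loop with published dynamic-donor denominators
oracle_D_fdm <- function(G, map) {
  f1 <- oracle_site_freqs(G, map, "P1")
  f2 <- oracle_site_freqs(G, map, "P2")
  f3 <- oracle_site_freqs(G, map, "P3")
  usable <- oracle_usable(G, map)
  abba <- baba <- dpos <- dneg <- 0
  n_pol <- 0
  for (i in seq_len(nrow(G$sites))) {
    if (!usable[i] || is.na(G$outgroup[i])) next
    n_pol <- n_pol + 1
    pol <- function(f) {
      p <- f[i, "alt"] / f[i, "n"]
      if (G$outgroup[i] == 0) p else 1 - p
    }
    p1 <- pol(f1); p2 <- pol(f2); p3 <- pol(f3)
    abba <- abba + (1 - p1) * p2 * p3
    baba <- baba + p1 * (1 - p2) * p3
    pd <- max(p2, p3)
    dpos <- dpos + (1 - p1) * pd * pd - p1 * (1 - pd) * pd
    pd <- max(p1, p3)
    dneg <- dneg - ((1 - pd) * p2 * pd - pd * (1 - p2) * pd)
  }
  D <- as.numeric(if (abba + baba > 0) (abba - baba) / (abba + baba) else NA_real_)
  num <- abba - baba
  den <- if (num >= 0) dpos else dneg
  fdm <- as.numeric(if (n_pol > 0 && den > 0) min(1, max(-1, num / den)) else NA_real_)
  list(D = D, fdm = fdm)
}

# -- regression --------------------------------------------------------------

# Cook's distance by its definition: refit without point i and compare the
# fitted values, sum((yhat - yhat_(i))^2) / (p * s^2)
oracle_cooksd <- function(x, y) {
  fit <- lm(y ~ x)
  s2 <- summary(fit)$sigma^2
  yhat <- fitted(fit)
  vapply(seq_along(x), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    yhat_i <- coef(fit_i)[1] + coef(fit_i)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

# -- neighbor joining (textbook Saitou-Nei loop) -----------------------------

oracle_nj <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  nodes <- as.list(labels)
  D <- d
  while (length(nodes) > 2) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    new_node <- sprintf("(%s,%s)", nodes[[i]], nodes[[j]])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, dk), c(dk, 0))
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    nodes <- c(nodes[-c(i, j)], new_node)
    rownames(D) <- colnames(D) <- NULL
  }
  newick <- sprintf("(%s,%s);", nodes[[1]], nodes[[2]])
  ape::read.tree(text = newick)
}

# -- quartet classification via tree manipulation (independent of the
#    four-point-distance route used by the package) --------------------------

oracle_quartet_class <- function(tree, t1, t2, t3, to) {
  sub <- ape::keep.tip(tree, c(t1, t2, t3, to))
  sub <- ape::unroot(sub)
  if (!ape::is.binary(sub)) return(c(1, 1, 1) / 3)
  rooted <- ape::root(sub, outgroup = to, resolve.root = TRUE)
  mono <- function(pair) ape::is.monophyletic(rooted, pair)
  w <- c(topo1 = 0, topo2 = 0, topo3 = 0)
  if (mono(c(t1, t2))) w["topo1"] <- 1
  else if (mono(c(t3, t1))) w["topo2"] <- 1
  else if (mono(c(t3, t2))) w["topo3"] <- 1
  else return(c(1, 1, 1) / 3)
  w
}

# random tree with group-labelled tips
random_group_tree <- function(n_per_group = c(3, 3, 3), seed = 1) {
  withr::with_seed(seed, {
    n <- sum(n_per_group) + 1
    tree <- ape::rtree(n)
    tips <- tree$tip.label
    grp <- sample(c(rep("P1", n_per_group[1]), rep("P2", n_per_group[2]),
                    rep("P3", n_per_group[3]), "OUT"))
    list(tree = tree, tips = data.frame(tip = tips, sample = tips,
                                        group = grp))
  })
}

# run-length-encoding oracle for segment collapsing
oracle_rle_collapse <- function(labels) {
  out <- list()
  cur <- labels[1]; count <- 1
  for (x in labels[-1]) {
    if (x == cur) count <- count + 1
    else { out[[length(out) + 1]] <- c(cur, count); cur <- x; count <- 1 }
  }
  out[[length(out) + 1]] <- c(cur, count)
  out
}

read_tsv2 <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}

# small helper: fast scaled-down simulation config for tests (explicit
# arguments override the scaled-down defaults)
test_sim_config <- function(...) {
  args <- utils::modifyList(list(chrom_lengths = c(chr1 = 1e6),
                                 n_genes = 40L, mu = 3e-3),
                            list(...))
  do.call(simulation_config, args)
}
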
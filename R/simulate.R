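## Synthetic genomes with known truth.
##
## The generator plants a mosaic of local genealogies along the genome:
## each chromosome is partitioned into tracts labeled topo1/topo2/topo3
## (fixed rooted four-taxon trees with class-specific split depths) or
## "mixed" (genealogies interleaved at the kb scale, yielding genuinely
## unresolved windows). Every SNP is placed by drawing a branch of its
## tract's tree with probability proportional to branch length, giving
## exact truth labels at desk scale without a full coalescent. Within-
## group polymorphism comes from a single scaled depth per group with a
## neutral-like 1/k frequency spectrum. Candidate genes can carry planted
## effects: deflated P3 polymorphism and an inflated P3 external branch.

#' Default simulation configuration
#'
#' Returns the full parameter list; any element can be overridden via
#' `...`. Defaults state a world with the focal-lineage mosaic proportions
#' reported for the bear macaque (topo2 52.64%, topo3 15.70%, topo1
#' 11.07%, unresolved/mixed 20.59%), species-split depths in scaled time
#' units (recent minority introgression younger than the majority class),
#' and within-group diversity in the empirical primate range.
#'
#' @param ... named overrides.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    chrom_lengths = setNames(rep(5e6, 4), paste0("chr", 1:4)),
    samples_per_group = c(P1 = 3L, P2 = 4L, P3 = 3L),
    proportions = c(topo1 = 0.1107, topo2 = 0.5264, topo3 = 0.1570,
                    mixed = 0.2059),
    tract_mean = 2e5,        # mean genealogy tract length (bp)
    mixed_tile = 1000,       # interleaving scale inside mixed tracts (bp)
    ils_fraction = 0.1,      # per-SNP chance of a random genealogy inside
                             # resolved tracts (incomplete lineage sorting)
    mu = 4e-3,               # expected SNPs per bp at baseline tree length
    eps = 0.15,              # within-group coalescent depth (time units)
    t_inner = c(topo1 = 1.68, topo2 = 0.8, topo3 = 1.4),
    t_outer = c(topo1 = 3.5, topo2 = 3.0, topo3 = 3.0),
    t_root = 6.0,
    tile = 1e5,              # tile size for diversity/recombination tracks
    theta_sd = 0.5,          # lognormal sd of regional diversity multiplier
    rate_sd = 0.7,           # lognormal sd of recombination rate (cM/Mb)
    rate_correlation = 0.5,  # corr(log rate, log diversity multiplier)
    n_genes = 600L,
    candidate_fraction = 0.1,
    codons_range = c(100L, 400L),
    pi_deflation = 0.3,      # multiplier on P3 polymorphism in candidates
    div_inflation = 1.5,     # multiplier on P3 external branch in candidates
    omega_meanlog = log(0.2),
    omega_sdlog = 0.5,
    omega_bg = 0.2,          # dN/dS on non-focal branches
    coding_rate = 0.03,      # proposal rate per nt per unit branch length
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  ms_assert(length(bad) == 0, "unknown config field(s): %s",
            paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  ms_assert(abs(sum(cfg$proportions) - 1) < 1e-8, "proportions must sum to 1")
  ms_assert(all(cfg$chrom_lengths > 0), "chromosome lengths must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

sim_sample_names <- function(cfg) {
  list(P1 = paste0("sin", seq_len(cfg$samples_per_group[["P1"]])),
       P2 = paste0("fas", seq_len(cfg$samples_per_group[["P2"]])),
       P3 = paste0("arc", seq_len(cfg$samples_per_group[["P3"]])))
}

#' Group map matching a simulation configuration
#' @param cfg a [simulation_config()].
#' @return a [group_map()] including the haploid `outgroup` sample.
#' @export
sim_group_map <- function(cfg) {
  nm <- sim_sample_names(cfg)
  group_map(c(nm$P1, nm$P2, nm$P3, "outgroup"),
            c(rep("P1", length(nm$P1)), rep("P2", length(nm$P2)),
              rep("P3", length(nm$P3)), "OUT"))
}

## Partition one chromosome into genealogy tracts.
draw_tracts <- function(len, cfg) {
  lens <- numeric()
  while (sum(lens) < len)
    lens <- c(lens, max(1000, rexp(1, 1 / cfg$tract_mean)))
  edges <- unique(pmin(round(cumsum(lens)), len))
  edges <- edges[edges > 0]
  if (tail(edges, 1) < len) edges <- c(edges, len)
  start <- c(0, head(edges, -1))
  cls <- sample(names(cfg$proportions), length(start), replace = TRUE,
                prob = cfg$proportions)
  data.frame(start = start, end = edges, class = cls,
             stringsAsFactors = FALSE)
}

## Genealogy roles per class: the two lineages joining at t_inner and the
## one joining at t_outer.
class_roles <- function(class) {
  switch(class,
         topo1 = list(inner = c("P1", "P2"), outer = "P3"),
         topo2 = list(inner = c("P3", "P1"), outer = "P2"),
         topo3 = list(inner = c("P3", "P2"), outer = "P1"))
}

## harmonic number: relative total length of a coalescent-like within-group
## tree with n haplotypes
harmonic <- function(n) if (n <= 1) 0 else sum(1 / seq_len(n - 1))

#' Simulate a mosaic genome
#'
#' @param cfg a [simulation_config()].
#' @param annotation optional result of [simulate_annotation()]; when
#'   given, reference alleles inside CDS match the annotation's reference
#'   sequences, regional diversity multipliers follow its tiles, and
#'   candidate genes carry the configured planted effects.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list with `G` (a [genotype_matrix()]), `truth` (tract table
#'   with `chrom`, `start`, `end`, `class`) and `map` (the group map).
#' @export
simulate_genome <- function(cfg, annotation = NULL, seed = NULL) {
  seed <- seed %||% cfg$seed
  nm <- sim_sample_names(cfg)
  samples <- c(nm$P1, nm$P2, nm$P3)
  grp_of <- c(rep("P1", length(nm$P1)), rep("P2", length(nm$P2)),
              rep("P3", length(nm$P3)))
  n_hap <- 2L * c(P1 = length(nm$P1), P2 = length(nm$P2), P3 = length(nm$P3))
  if (cfg$mu == 0) warning("mutation scale 0: no variant records will be produced")

  with_seed(derive_seed(seed, 11L), {
    truth <- list(); all_sites <- list(); all_geno <- list(); all_og <- list()
    for (ch in names(cfg$chrom_lengths)) {
      len <- cfg$chrom_lengths[[ch]]
      tr <- draw_tracts(len, cfg)
      truth[[ch]] <- data.frame(chrom = ch, tr, stringsAsFactors = FALSE)
      ## expand mixed tracts into interleaved tiles
      pieces <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
        if (tr$class[i] != "mixed") {
          data.frame(start = tr$start[i], end = tr$end[i], class = tr$class[i],
                     soft = FALSE)
        } else {
          edges <- unique(c(seq(tr$start[i], tr$end[i], by = cfg$mixed_tile),
                            tr$end[i]))
          data.frame(start = head(edges, -1), end = edges[-1],
                     class = sample(TOPO_LABELS, length(edges) - 1L,
                                    replace = TRUE),
                     soft = TRUE)
        }
      }))
      sim <- simulate_piece_snps(pieces, cfg, ch, annotation, n_hap, grp_of)
      all_sites[[ch]] <- sim$sites
      all_geno[[ch]] <- sim$geno
      all_og[[ch]] <- sim$og
    }
    sites <- do.call(rbind, all_sites)
    geno <- do.call(rbind, all_geno)
    colnames(geno) <- samples
    G <- genotype_matrix(sites, geno, do.call(c, all_og))
    list(G = G, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
         map = sim_group_map(cfg))
  })
}

## SNP generation for the piece table of one chromosome (runs inside the
## caller's seeded context).
simulate_piece_snps <- function(pieces, cfg, chrom, annotation, n_hap, grp_of) {
  groups <- c("P1", "P2", "P3")
  cand_win <- NULL; cds_idx <- NULL
  if (!is.null(annotation)) {
    cand_win <- annotation$windows[annotation$windows$chrom == chrom &
                                     annotation$windows$candidate, , drop = FALSE]
    cds_idx <- annotation$cds_genome[annotation$cds_genome$chrom == chrom, ,
                                     drop = FALSE]
  }
  theta_of <- function(pos) {
    if (is.null(annotation)) return(rep(1, length(pos)))
    th <- annotation$theta[annotation$theta$chrom == chrom, , drop = FALSE]
    ix <- findInterval(pos, th$start)
    ifelse(ix >= 1 & ix <= nrow(th), th$m[pmax(ix, 1)], 1)
  }
  planted_of <- function(pos) {
    if (is.null(cand_win) || nrow(cand_win) == 0) return(rep(FALSE, length(pos)))
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(cand_win)))
      hit <- hit | (pos >= cand_win$start[i] & pos < cand_win$end[i])
    hit
  }

  sites <- list(); geno <- list(); og <- list()
  for (i in seq_len(nrow(pieces))) {
    p_len <- pieces$end[i] - pieces$start[i]
    cls <- pieces$class[i]
    roles <- class_roles(cls)
    base_w <- sum(cfg$t_inner[[cls]] - cfg$eps, cfg$t_inner[[cls]] - cfg$eps,
                  cfg$t_outer[[cls]] - cfg$eps,
                  cfg$t_outer[[cls]] - cfg$t_inner[[cls]],
                  cfg$t_root - cfg$t_outer[[cls]], cfg$t_root,
                  cfg$eps * sum(vapply(n_hap, harmonic, numeric(1))))
    n <- rpois(1, p_len * cfg$mu * base_w / 12)
    if (n == 0) next
    ## 0-based positions within [start, end)
    pos <- sort(unique(pieces$start[i] +
                         sample.int(as.integer(p_len), min(n, p_len)) - 1L))
    n <- length(pos)
    m <- theta_of(pos)
    planted <- planted_of(pos)
    ## per-SNP genealogy: tract class, with an ILS fraction of random trees
    snp_cls <- rep(cls, n)
    ils <- runif(n) < cfg$ils_fraction
    snp_cls[ils] <- sample(TOPO_LABELS, sum(ils), replace = TRUE)

    gmat <- matrix(0L, n, sum(n_hap) / 2)
    ogv <- integer(n)
    for (sc in unique(snp_cls)) {
      sel <- which(snp_cls == sc)
      r <- class_roles(sc)
      ti <- cfg$t_inner[[sc]]; to <- cfg$t_outer[[sc]]; tr <- cfg$t_root
      infl <- ifelse(planted[sel], cfg$div_inflation, 1)
      defl <- ifelse(planted[sel], cfg$pi_deflation, 1)
      ## in soft (mixed) tracts the genealogy-informative categories behave
      ## as standing polymorphism, so a planted sweep deflates them too
      soft_defl <- if (pieces$soft[i]) defl else 1
      W <- cbind(
        ext_i1 = (ti - cfg$eps) * soft_defl *
          (if (r$inner[1] == "P3") infl else 1),
        ext_i2 = (ti - cfg$eps) * soft_defl *
          (if (r$inner[2] == "P3") infl else 1),
        ext_out = (to - cfg$eps) * soft_defl *
          (if (r$outer == "P3") infl else 1),
        internal = (to - ti) * soft_defl,
        stem = tr - to,
        outg = tr,
        poly_P1 = cfg$eps * harmonic(n_hap[["P1"]]) * m[sel],
        poly_P2 = cfg$eps * harmonic(n_hap[["P2"]]) * m[sel],
        poly_P3 = cfg$eps * harmonic(n_hap[["P3"]]) * m[sel] * defl
      )
      cw <- W / rowSums(W)
      u <- runif(length(sel))
      branch <- max.col(t(apply(cw, 1, cumsum)) >= u, ties.method = "first")
      bnames <- colnames(W)[branch]
      ## in "mixed" (soft) tracts, genealogy-informative mutations are
      ## deeply unsorted: the derived allele segregates across the whole
      ## species complex with a neutral-like 1/k frequency spectrum,
      ## ignoring group boundaries. Group monophyly then breaks in window
      ## trees and one-tip-per-group subsamples disagree -- these windows
      ## come out unresolved -- while per-site diversity stays at
      ## polymorphism (not fixed-difference) scale.
      soft <- pieces$soft[i]
      nh_tot <- 2L * ncol(gmat)
      fill <- function(row, members) {
        if (soft) {
          k <- sample.int(nh_tot - 1L, 1L, prob = 1 / seq_len(nh_tot - 1L))
          haps <- sample.int(nh_tot, k)
          gmat[row, ] <<- as.integer(tabulate((haps + 1L) %/% 2L,
                                              nbins = ncol(gmat)))
        } else {
          gmat[row, members] <<- 2L
        }
      }
      for (j in seq_along(sel)) {
        row <- sel[j]
        b <- bnames[j]
        if (b == "ext_i1") fill(row, grp_of == r$inner[1])
        else if (b == "ext_i2") fill(row, grp_of == r$inner[2])
        else if (b == "ext_out") fill(row, grp_of == r$outer)
        else if (b == "internal") fill(row, grp_of %in% r$inner)
        else if (b == "stem") gmat[row, ] <- 2L
        else if (b == "outg") ogv[row] <- 1L
        else {
          g <- sub("poly_", "", b)
          nh <- n_hap[[g]]
          k <- sample.int(nh - 1L, 1L, prob = 1 / seq_len(nh - 1L))
          haps <- sample.int(nh, k)
          dos <- tabulate((haps + 1L) %/% 2L, nbins = nh / 2L)
          gmat[row, grp_of == g] <- as.integer(dos)
        }
      }
    }
    ## reference = ancestral base; inside CDS it must match the annotation
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    if (!is.null(cds_idx) && nrow(cds_idx)) {
      for (k in seq_len(nrow(cds_idx))) {
        inside <- which(pos >= cds_idx$start[k] & pos < cds_idx$end[k])
        if (length(inside))
          anc[inside] <- substring(cds_idx$seq[k],
                                   pos[inside] - cds_idx$start[k] + 1L,
                                   pos[inside] - cds_idx$start[k] + 1L)
      }
    }
    der <- vapply(anc, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    sites[[i]] <- data.frame(chrom = chrom, pos = pos + 1L, ref = anc,
                             alt = unname(der), stringsAsFactors = FALSE)
    geno[[i]] <- gmat
    og[[i]] <- ogv
  }
  list(sites = do.call(rbind, sites) %||%
         data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character()),
       geno = do.call(rbind, geno) %||% matrix(0L, 0, sum(n_hap) / 2),
       og = do.call(c, og) %||% integer())
}

#' Simulate gene annotation, candidate lists and recombination map
#'
#' Places non-overlapping gene models (1-3 transcripts, one CDS segment)
#' along the genome, samples a candidate subset, and draws a piecewise-
#' constant recombination map whose log-rate correlates with the regional
#' diversity multiplier by `cfg$rate_correlation`.
#'
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list with `models`, `cds_ancestral` (named coding-strand CDS
#'   reference sequences), `cds_genome` (genome-strand CDS segments with
#'   sequences), `windows` (gene windows with candidate flags), `rate_map`,
#'   `theta` (diversity tiles), `candidates`, `male`, `female`,
#'   `truth_genes`.
#' @export
simulate_annotation <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$seed
  ms_assert(cfg$n_genes >= 1, "n_genes must be >= 1")
  with_seed(derive_seed(seed, 23L), {
    ## regional diversity multiplier and correlated recombination rate
    theta <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
      edges <- unique(c(seq(0, cfg$chrom_lengths[[ch]], by = cfg$tile),
                        cfg$chrom_lengths[[ch]]))
      z <- rnorm(length(edges) - 1L)
      data.frame(chrom = ch, start = head(edges, -1), end = edges[-1], z = z,
                 m = exp(cfg$theta_sd * z), stringsAsFactors = FALSE)
    }))
    rho <- cfg$rate_correlation
    z_r <- rho * theta$z + sqrt(1 - rho^2) * rnorm(nrow(theta))
    rate_map <- interval_map(theta$chrom, theta$start, theta$end,
                             exp(cfg$rate_sd * z_r))

    ## gene placement: proportional share of genes per chromosome
    total_len <- sum(cfg$chrom_lengths)
    genes_per_chr <- round(cfg$n_genes * cfg$chrom_lengths / total_len)
    genes_per_chr[length(genes_per_chr)] <-
      cfg$n_genes - sum(head(genes_per_chr, -1))
    models <- list(); cds_anc <- character(); cds_gen <- list()
    gid <- 0L
    for (ch in names(cfg$chrom_lengths)) {
      ng <- genes_per_chr[[ch]]
      if (ng == 0) next
      len <- cfg$chrom_lengths[[ch]]
      slot <- len / ng
      ms_assert(slot > 3 * cfg$codons_range[2] + 16000,
                "genome too small for %d genes on %s", ng, ch)
      for (k in seq_len(ng)) {
        gid <- gid + 1L
        id <- sprintf("gene%04d", gid)
        n_cod <- sample(cfg$codons_range[1]:cfg$codons_range[2], 1)
        cds_len <- 3L * n_cod
        margin <- sample(500:2000, 2)
        g_start <- round((k - 1) * slot + runif(1, 2000, slot / 4))
        cds_start <- g_start + margin[1]
        cds_end <- cds_start + cds_len
        tx_end <- cds_end + margin[2]
        strand <- sample(c("+", "-"), 1)
        n_tx <- sample(1:3, 1)
        tx <- data.frame(
          start = pmax(0, g_start - sample(0:1000, n_tx, replace = TRUE)),
          end = pmin(len, tx_end + sample(0:1000, n_tx, replace = TRUE)))
        cds <- data.frame(start = cds_start, end = cds_end)
        models[[id]] <- gene_model(id, ch, strand, tx, cds)
        codons <- sample(setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS),
                         n_cod, replace = TRUE)
        coding <- paste(codons, collapse = "")
        genome_seq <- if (strand == "+") coding else revcomp(coding)
        cds_anc[[id]] <- coding
        cds_gen[[id]] <- data.frame(gene = id, chrom = ch, start = cds_start,
                                    end = cds_end, strand = strand,
                                    seq = genome_seq, stringsAsFactors = FALSE)
      }
    }
    cds_genome <- do.call(rbind, cds_gen)

    n_cand <- round(cfg$n_genes * cfg$candidate_fraction)
    candidates <- sort(sample(names(models), n_cand))
    male <- sort(sample(candidates, max(1, round(0.45 * n_cand))))
    female <- sort(sample(candidates, max(1, round(0.45 * n_cand))))

    windows <- do.call(rbind, lapply(models, function(m) {
      w <- gene_window(m, flank = 5000,
                       chrom_length = cfg$chrom_lengths[[m$chrom]])
      w$gene <- m$gene_id
      w
    }))
    windows$candidate <- windows$gene %in% candidates
    rownames(windows) <- NULL

    truth_genes <- data.frame(gene = names(models),
                              candidate = names(models) %in% candidates,
                              planted = names(models) %in% candidates,
                              stringsAsFactors = FALSE)
    list(models = models, cds_ancestral = cds_anc, cds_genome = cds_genome,
         windows = windows, rate_map = rate_map, theta = theta,
         candidates = candidates, male = male, female = female,
         truth_genes = truth_genes)
  })
}

## Evolve a codon sequence along one branch: point-mutation proposals at
## rate `rate` per nt per time unit, accepted so the realized nonsyn/syn
## rate ratio equals `omega`; proposals creating stop codons are rejected.
evolve_branch <- function(codons, t, omega, rate) {
  n_nt <- 3L * length(codons)
  n_prop <- rpois(1, t * rate * n_nt)
  if (n_prop == 0) return(codons)
  acc_n <- min(omega, 1)
  acc_s <- min(1 / omega, 1)
  for (i in seq_len(n_prop)) {
    p <- sample.int(n_nt, 1)
    ci <- (p - 1L) %/% 3L + 1L
    cp <- (p - 1L) %% 3L + 1L
    old <- codons[ci]
    b <- sample(setdiff(c("A", "C", "G", "T"), substr(old, cp, cp)), 1)
    new <- old
    substr(new, cp, cp) <- b
    if (new %in% STOP_CODONS) next
    syn <- identical(translate_codon(old), translate_codon(new))
    if (runif(1) < (if (syn) acc_s else acc_n)) codons[ci] <- new
  }
  codons
}

#' Simulate codon alignments with a controlled focal-branch dN/dS
#'
#' Evolves one CDS per gene down the rooted four-taxon tree of its
#' topology class; the focal (P3) terminal branch uses the gene's omega,
#' all other branches the background omega.
#'
#' @param cfg a [simulation_config()].
#' @param genes data.frame with columns `gene`, `topology`
#'   (`topo1`/`topo2`/`topo3`), `omega` (> 0) and `n_codons`; or NULL to
#'   draw `cfg$n_genes` genes from the config's distributions.
#' @param anc optional named vector of ancestral coding sequences (from
#'   [simulate_annotation()]).
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list with `alignments` (named list of [codon_alignment()]) and
#'   `truth` (the genes table).
#' @export
simulate_coding <- function(cfg, genes = NULL, anc = NULL, seed = NULL) {
  seed <- seed %||% cfg$seed
  with_seed(derive_seed(seed, 37L), {
    if (is.null(genes)) {
      genes <- data.frame(
        gene = sprintf("gene%04d", seq_len(cfg$n_genes)),
        topology = sample(TOPO_LABELS, cfg$n_genes, replace = TRUE,
                          prob = cfg$proportions[TOPO_LABELS] /
                            sum(cfg$proportions[TOPO_LABELS])),
        omega = exp(rnorm(cfg$n_genes, cfg$omega_meanlog, cfg$omega_sdlog)),
        n_codons = sample(cfg$codons_range[1]:cfg$codons_range[2],
                          cfg$n_genes, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    ms_assert(all(genes$omega > 0), "omega values must be > 0")
    alns <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      root <- if (!is.null(anc) && g$gene %in% names(anc)) {
        split_codons(anc[[g$gene]])
      } else {
        sample(setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS),
               g$n_codons, replace = TRUE)
      }
      r <- class_roles(g$topology)
      ti <- cfg$t_inner[[g$topology]]
      to <- cfg$t_outer[[g$topology]]
      om <- function(gr) if (gr == "P3") g$omega else cfg$omega_bg
      rate <- cfg$coding_rate
      out_seq <- evolve_branch(root, cfg$t_root, cfg$omega_bg, rate)
      stem <- evolve_branch(root, cfg$t_root - to, cfg$omega_bg, rate)
      outer_seq <- evolve_branch(stem, to, om(r$outer), rate)
      inner_anc <- evolve_branch(stem, to - ti, cfg$omega_bg, rate)
      i1 <- evolve_branch(inner_anc, ti, om(r$inner[1]), rate)
      i2 <- evolve_branch(inner_anc, ti, om(r$inner[2]), rate)
      seqs <- setNames(character(4), c("P1", "P2", "P3", "OUT"))
      seqs[["OUT"]] <- paste(out_seq, collapse = "")
      seqs[[r$outer]] <- paste(outer_seq, collapse = "")
      seqs[[r$inner[1]]] <- paste(i1, collapse = "")
      seqs[[r$inner[2]]] <- paste(i2, collapse = "")
      alns[[g$gene]] <- codon_alignment(g$gene, seqs)
    }
    list(alignments = alns, truth = genes)
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Produces the full set of pipeline inputs with known truth: a mosaic
#' genome VCF (with a haploid outgroup column), group map, BED12 gene
#' models, bedGraph recombination map, candidate gene lists (overall plus
#' male/female sublists), per-gene codon alignments and reference CDS
#' FASTA, and truth tables.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; the bundle is byte-identical for a given seed.
#' @param cfg a [simulation_config()]; defaults to the paper-scale world
#'   (4 chromosomes x 5 Mb, 10 samples, ~600 genes, ~60 candidates with
#'   planted effects).
#' @return named list of file paths, plus `truth` (tract and gene truth
#'   tables) and `cfg`.
#' @export
paperlike_dataset <- function(dir, seed = 1L, cfg = simulation_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(cfg, seed = seed)
  gen <- simulate_genome(cfg, annotation = ann, seed = seed)

  ## per-gene topology class from the tract overlapping the gene midpoint
  mid <- (ann$windows$start + ann$windows$end) / 2
  topo_of <- vapply(seq_len(nrow(ann$windows)), function(i) {
    tr <- gen$truth[gen$truth$chrom == ann$windows$chrom[i], ]
    hit <- tr$class[tr$start <= mid[i] & mid[i] < tr$end]
    if (length(hit) == 0 || hit[1] == "mixed") "random" else hit[1]
  }, character(1))
  genes <- with_seed(derive_seed(seed, 53L), {
    n_cod <- nchar(ann$cds_ancestral[ann$windows$gene]) / 3
    data.frame(gene = ann$windows$gene,
               topology = ifelse(topo_of == "random",
                                 sample(TOPO_LABELS, nrow(ann$windows),
                                        replace = TRUE),
                                 topo_of),
               omega = exp(rnorm(nrow(ann$windows), cfg$omega_meanlog,
                                 cfg$omega_sdlog)),
               n_codons = as.integer(n_cod), stringsAsFactors = FALSE)
  })
  cod <- simulate_coding(cfg, genes = genes, anc = ann$cds_ancestral,
                         seed = seed)

  paths <- list(
    vcf = file.path(dir, "genome.vcf"),
    groups = file.path(dir, "groups.tsv"),
    genes_bed = file.path(dir, "genes.bed"),
    rate_bedgraph = file.path(dir, "recomb.bedgraph"),
    candidates = file.path(dir, "candidates.txt"),
    candidates_male = file.path(dir, "candidates_male.txt"),
    candidates_female = file.path(dir, "candidates_female.txt"),
    cds_alignments = file.path(dir, "cds_alignments.fa"),
    cds_reference = file.path(dir, "cds_reference.fa"),
    truth_tracts = file.path(dir, "truth_tracts.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  write_vcf(gen$G, paths$vcf, chrom_lengths = cfg$chrom_lengths)
  write_group_map(gen$map, paths$groups)
  write_bed12(ann$models, paths$genes_bed)
  write_bedgraph(ann$rate_map, paths$rate_bedgraph)
  write_gene_list(ann$candidates, paths$candidates)
  write_gene_list(ann$male, paths$candidates_male)
  write_gene_list(ann$female, paths$candidates_female)
  fa <- unlist(lapply(names(cod$alignments), function(g) {
    a <- cod$alignments[[g]]
    as.vector(rbind(sprintf(">%s|%s", g, names(a$seqs)), unname(a$seqs)))
  }))
  writeLines(fa, paths$cds_alignments)
  writeLines(as.vector(rbind(sprintf(">%s", names(ann$cds_ancestral)),
                             unname(ann$cds_ancestral))),
             paths$cds_reference)
  write_tsv(gen$truth, paths$truth_tracts)
  truth_genes <- merge(ann$truth_genes, cod$truth, by = "gene")
  write_tsv(truth_genes, paths$truth_genes)

  c(paths, list(truth = list(tracts = gen$truth, genes = truth_genes),
                cfg = cfg))
}
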
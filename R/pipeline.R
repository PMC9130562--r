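## End-to-end orchestration: load inputs, run the window scan, topology
## weighting, dN/dS, the gene-centered outlier scan and the permutation
## analyses, writing one TSV per stage plus a run manifest. Every stage is
## a pure function of (inputs, config, seed), so identical runs produce
## byte-identical outputs.

#' Pipeline configuration with field-standard defaults
#'
#' All tunables default to the scan's canonical parameterization: 50 kb
#' windows with a 20% step and 100 usable sites minimum, 50-SNP tree
#' windows, 2/3 majority threshold, unanimous-window per-topology
#' divergence, Cook's distance multiplier 3, 5% dN/dS quantile, 100
#' permutations, and 10,000 block-bootstrap replicates on 1 Mb blocks.
#'
#' @param inputs named list of input paths (`vcf`, `groups`, `genes_bed`,
#'   `rate_bedgraph`, `candidates`, optionally `candidates_male`,
#'   `candidates_female`, `cds_alignments`).
#' @param ... overrides for any tunable.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), ...) {
  cfg <- list(
    inputs = inputs,
    window_size = 50000, step_fraction = 0.2, min_sites = NULL,
    snps_per_tree = 50L, majority_threshold = 2 / 3,
    dxy_purity = 1.0,
    gene_flank = 5000,
    cooksd_k = 3, dnds_q = 0.05,
    n_perm = 100,
    bootstrap_reps = 10000, bootstrap_block = 1e6,
    chisq_correct = FALSE,
    seed = 1L
  )
  cfg <- modifyList(cfg, list(...))
  if (is.null(cfg$min_sites))
    cfg$min_sites <- min_sites_for_size(cfg$window_size)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write a pipeline configuration (JSON)
#' @param path file path.
#' @return a `pipeline_config` (reader) or `path` (writer).
#' @export
read_pipeline_config <- function(path) {
  ms_assert(file.exists(path), "config not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(list(inputs = as.list(raw$inputs)),
                             raw[setdiff(names(raw), "inputs")]))
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

## Read the per-gene codon alignment FASTA written by paperlike_dataset():
## headers are "gene|TAXON" with TAXON in P1/P2/P3/OUT.
read_cds_alignments <- function(path) {
  ms_assert(file.exists(path), "codon alignment FASTA not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1)
  taxa <- vapply(parts, `[[`, character(1), 2)
  out <- lapply(split(seq_along(seqs), genes), function(ix) {
    codon_alignment(genes[ix[1]],
                    setNames(as.character(seqs[ix]), taxa[ix]))
  })
  out[order(names(out))]
}

## Topology weights for each gene window: average of the weights of tree
## windows overlapping the window, renormalized; equal weights when no
## tree window overlaps.
gene_topology_weights <- function(wt, windows) {
  t(vapply(seq_len(nrow(windows)), function(i) {
    sel <- wt$chrom == windows$chrom[i] & wt$end > windows$start[i] &
      wt$start < windows$end[i]
    if (!any(sel)) return(c(1, 1, 1) / 3)
    w <- colMeans(wt[sel, c("w1", "w2", "w3"), drop = FALSE])
    as.numeric(w / sum(w))
  }, numeric(3)))
}

#' Topology-weighted dN/dS for a set of genes
#'
#' @param alignments named list of [codon_alignment()] objects.
#' @param weights matrix (genes x 3) of topology weights, rows matching
#'   `alignments` order.
#' @return data.frame with per-topology estimates, exclusion reasons and
#'   the weighted `omega`.
#' @export
gene_dnds_table <- function(alignments, weights) {
  rows <- lapply(seq_along(alignments), function(i) {
    aln <- alignments[[i]]
    ests <- lapply(TOPO_LABELS, function(tp) branch_dnds(aln, tp))
    ob <- weighted_dnds(ests, weights[i, ])
    data.frame(gene = aln$gene_id,
               dn1 = ests[[1]]$dn, ds1 = ests[[1]]$ds, omega1 = ests[[1]]$omega,
               dn2 = ests[[2]]$dn, ds2 = ests[[2]]$ds, omega2 = ests[[2]]$omega,
               dn3 = ests[[3]]$dn, ds3 = ests[[3]]$ds, omega3 = ests[[3]]$omega,
               w1 = weights[i, 1], w2 = weights[i, 2], w3 = weights[i, 3],
               excluded1 = ests[[1]]$excluded, excluded2 = ests[[2]]$excluded,
               excluded3 = ests[[3]]$excluded,
               omega = ob, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Stages: load inputs, sliding-window statistics, window trees and
#' topology weighting (with collapsed segments and block-bootstrap genome
#' proportions), per-topology divergence, branch dN/dS, the gene-centered
#' scan, recombination-aware outlier calling with chi-square enrichment,
#' candidate permutation tests and the male/female contrast, and variant
#' consequence classification for outlier candidate genes.
#'
#' @param cfg a [pipeline_config()] whose `inputs` paths exist.
#' @param outdir output directory for the report bundle.
#' @return named list of outputs (also written as TSV under `outdir`),
#'   including the `manifest`.
#' @export
run_pipeline <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- character()
  log_stage <- function(name, rows) {
    stages <<- c(stages, sprintf("%s:%d", name, rows))
    message(sprintf("[%s] stage %s complete (%d rows)",
                    format(Sys.time(), "%H:%M:%S"), name, rows))
  }
  need <- function(key) {
    p <- cfg$inputs[[key]]
    if (is.null(p) || !file.exists(p))
      ms_stop("missing required input '%s'%s", key,
              if (is.null(p)) "" else sprintf(" (%s)", p))
    p
  }

  ## stage 1: load
  G <- read_vcf(need("vcf"))
  map <- read_group_map(need("groups"))
  models <- read_gene_models(need("genes_bed"))
  candidates <- read_gene_list(need("candidates"))
  chrom_lengths <- vapply(split(G$sites$pos, G$sites$chrom), max, numeric(1))
  log_stage("load", n_sites(G))

  ## stage 2: sliding-window statistics
  wins <- make_sliding_windows(chrom_lengths, cfg$window_size,
                               cfg$step_fraction)
  winstats <- window_stats(G, map, wins, min_sites = cfg$min_sites)
  write_tsv(winstats, file.path(outdir, "window_stats.tsv"))
  log_stage("winstats", nrow(winstats))

  ## stage 3: topology weighting
  trees <- window_trees(G, map, snps_per_window = cfg$snps_per_tree,
                        seed = derive_seed(cfg$seed, 101L))
  writeLines(vapply(trees, `[[`, character(1), "newick"),
             file.path(outdir, "window_trees.nwk"))
  wt <- topology_weight_table(trees, threshold = cfg$majority_threshold)
  write_tsv(wt, file.path(outdir, "topology_weights.tsv"))
  seg <- collapse_adjacent(data.frame(chrom = wt$chrom, start = wt$start,
                                      end = wt$end, label = wt$majority,
                                      stringsAsFactors = FALSE))
  write_tsv(seg, file.path(outdir, "topology_segments.tsv"))
  props <- genome_proportions_bootstrap(wt, block = cfg$bootstrap_block,
                                        reps = cfg$bootstrap_reps,
                                        seed = derive_seed(cfg$seed, 103L))
  write_tsv(props, file.path(outdir, "topology_proportions.tsv"))
  dxy_topo <- dxy_by_topology(G, map, wt, purity = cfg$dxy_purity)
  write_tsv(dxy_topo, file.path(outdir, "dxy_by_topology.tsv"))
  log_stage("topology", nrow(wt))

  ## stage 4: branch dN/dS
  omega <- NULL
  dnds_tab <- NULL
  if (!is.null(cfg$inputs$cds_alignments)) {
    alns <- read_cds_alignments(need("cds_alignments"))
    gwins <- do.call(rbind, lapply(models[names(alns)], function(m) {
      gene_window(m, flank = cfg$gene_flank,
                  chrom_length = chrom_lengths[[m$chrom]] %||% NULL)
    }))
    gw <- gene_topology_weights(wt, gwins)
    dnds_tab <- gene_dnds_table(alns, gw)
    write_tsv(dnds_tab, file.path(outdir, "gene_dnds.tsv"))
    omega <- setNames(dnds_tab$omega, dnds_tab$gene)
    log_stage("dnds", nrow(dnds_tab))
  }

  ## stage 5: gene-centered scan (the recombination track is read here, so
  ## a missing map aborts at this stage with a missing-input error)
  rate_map <- read_bedgraph(need("rate_bedgraph"))
  scan <- gene_scan(G, map, models, rate_map, omega = omega,
                    candidates = candidates, flank = cfg$gene_flank,
                    chrom_lengths = as.list(chrom_lengths))
  write_tsv(scan, file.path(outdir, "gene_scan.tsv"))
  log_stage("genescan", nrow(scan))

  ## stage 6: outlier calling
  calls <- list()
  for (stat in names(DEFAULT_TAILS)) {
    fit <- fit_rate_regression(setNames(scan[[stat]], scan$gene), scan$r,
                               statistic = stat)
    calls[[stat]] <- call_cooksd_outliers(fit, k = cfg$cooksd_k)
  }
  if (!is.null(omega))
    calls$omega <- call_quantile_outliers(setNames(scan$omega, scan$gene),
                                          q = cfg$dnds_q)
  outliers <- do.call(rbind, c(calls, make.row.names = FALSE))
  write_tsv(outliers, file.path(outdir, "outliers.tsv"))
  out_any <- tapply(outliers$is_outlier, outliers$gene, any)
  scan$outlier <- unname(out_any[scan$gene]) %in% TRUE
  enr <- enrichment_chisq(scan$outlier, scan$candidate,
                          correct = cfg$chisq_correct)
  write_tsv(data.frame(statistic = enr$statistic, p = enr$p,
                       low_expected = enr$low_expected),
            file.path(outdir, "enrichment_chisq.tsv"))
  log_stage("outliers", nrow(outliers))

  ## stage 7: permutation tests
  perm_rows <- lapply(names(DEFAULT_PERM_TAILS), function(stat) {
    if (stat == "omega" && is.null(omega)) return(NULL)
    pr <- permutation_mean_diff(scan[[stat]], scan$candidate,
                                n_perm = cfg$n_perm,
                                tail = DEFAULT_PERM_TAILS[[stat]],
                                seed = derive_seed(cfg$seed,
                                                   match(stat, names(DEFAULT_PERM_TAILS))))
    data.frame(statistic = stat, observed = pr$observed, tail = pr$tail,
               p = pr$p, p_add_one = pr$p_add_one, n_perm = pr$n_perm)
  })
  perms <- do.call(rbind, perm_rows)
  write_tsv(perms, file.path(outdir, "permutations.tsv"))
  mf <- NULL
  if (!is.null(cfg$inputs$candidates_male) &&
      !is.null(cfg$inputs$candidates_female)) {
    stats_mf <- setdiff(names(DEFAULT_PERM_TAILS),
                        if (is.null(omega)) "omega" else character())
    mf <- male_female_contrast(scan, read_gene_list(need("candidates_male")),
                               read_gene_list(need("candidates_female")),
                               statistics = stats_mf, n_perm = cfg$n_perm,
                               seed = derive_seed(cfg$seed, 211L))
    write_tsv(mf, file.path(outdir, "male_female_contrast.tsv"))
  }
  log_stage("permutations", nrow(perms))

  ## stage 8: consequence classification for outlier candidate genes
  cons <- NULL
  if (!is.null(cfg$inputs$cds_reference)) {
    refs <- Biostrings::readDNAStringSet(need("cds_reference"))
    ocg <- scan$gene[scan$outlier & scan$candidate]
    cons <- classify_gene_variants(G, models[intersect(ocg, names(models))],
                                   setNames(as.character(refs), names(refs)))
    write_tsv(cons, file.path(outdir, "consequences.tsv"))
    log_stage("consequences", nrow(cons))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mosaicscan")),
    config_hash = unname(tools::md5sum(write_pipeline_config(
      cfg, file.path(outdir, "config.json")))),
    seed = cfg$seed,
    stages = stages,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(winstats = winstats, weights = wt, segments = seg,
                 proportions = props, dxy_by_topology = dxy_topo,
                 dnds = dnds_tab, scan = scan, outliers = outliers,
                 enrichment = enr, permutations = perms,
                 male_female = mf, consequences = cons, manifest = manifest))
}

#' Classify consequences of all SNPs falling in a set of genes
#'
#' @param G a [genotype_matrix()].
#' @param models named list of [gene_model()] objects.
#' @param cds_refs named vector of coding-strand reference CDS sequences.
#' @return data.frame with `gene`, `chrom`, `pos`, `ref`, `alt`, `class`.
#' @export
classify_gene_variants <- function(G, models, cds_refs) {
  rows <- lapply(models, function(m) {
    if (is.null(m$cds) || !m$gene_id %in% names(cds_refs)) return(NULL)
    lo <- min(m$transcripts$start); hi <- max(m$transcripts$end)
    sel <- which(G$sites$chrom == m$chrom & G$sites$pos - 1L >= lo &
                   G$sites$pos - 1L < hi)
    if (!length(sel)) return(NULL)
    cls <- vapply(sel, function(i) {
      classify_consequence(m, cds_refs[[m$gene_id]], G$sites$pos[i],
                           G$sites$ref[i], G$sites$alt[i])
    }, character(1))
    data.frame(gene = m$gene_id, chrom = m$chrom, pos = G$sites$pos[sel],
               ref = G$sites$ref[sel], alt = G$sites$alt[sel], class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out %||% data.frame(gene = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(), class = character())
}
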
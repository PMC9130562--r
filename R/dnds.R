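## Branch-specific dN/dS on the focal (P3) lineage by parsimony counting.
##
## For each codon the ancestral state of the focal terminal branch is
## inferred on the given rooted four-taxon topology; a substitution is
## assigned to the focal branch only when every most-parsimonious
## assignment requires it (ambiguous codons contribute sites but no
## changes; codons whose ancestral state is unknowable are skipped).
## Counts are converted to rates with Nei-Gojobori-style synonymous /
## nonsynonymous site counting on the ancestral codon, averaging multi-hit
## codons over minimal stop-free pathways.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- local({
  env <- new.env()
  function() {
    if (is.null(env$aa)) {
      gc <- Biostrings::GENETIC_CODE
      env$aa <- setNames(as.character(gc), names(gc))
    }
    env$aa
  }
})

translate_codon <- function(codon) {
  unname(codon_table()[codon])
}

split_codons <- function(seq) {
  n <- nchar(seq)
  ms_assert(n %% 3 == 0, "sequence length %d not divisible by 3", n)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## NG86 site counts for one codon: at each position, the fraction of the
## three possible changes that are synonymous (changes to stop codons count
## as nonsynonymous, so syn + nonsyn = 3 per codon).
ng_site_counts <- local({
  cache <- new.env()
  function(codon) {
    hit <- cache[[codon]]
    if (!is.null(hit)) return(hit)
    aa0 <- translate_codon(codon)
    syn <- 0
    for (p in 1:3) {
      base <- substr(codon, p, p)
      for (b in setdiff(c("A", "C", "G", "T"), base)) {
        alt <- codon
        substr(alt, p, p) <- b
        if (identical(translate_codon(alt), aa0)) syn <- syn + 1 / 3
      }
    }
    res <- c(syn = syn, nonsyn = 3 - syn)
    cache[[codon]] <- res
    res
  }
})

## Average synonymous/nonsynonymous substitution counts over minimal
## pathways between two codons, excluding pathways through stop codons
## (all pathways are used if every one passes a stop).
pathway_counts <- function(from, to) {
  diffs <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(diffs) == 1) list(diffs) else {
    if (length(diffs) == 2) {
      list(diffs, rev(diffs))
    } else {
      ix <- list()
      for (a in 1:3) for (b in setdiff(1:3, a))
        ix[[length(ix) + 1]] <- diffs[c(a, b, setdiff(1:3, c(a, b)))]
      ix
    }
  }
  walk <- function(order) {
    cur <- from
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      if (nxt %in% STOP_CODONS && nxt != to) blocked <- TRUE
      if (identical(translate_codon(cur), translate_codon(nxt))) {
        syn <- syn + 1
      } else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
  }
  paths <- t(vapply(perms, walk, numeric(3)))
  ok <- paths[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(paths))
  c(syn = mean(paths[ok, "syn"]), nonsyn = mean(paths[ok, "nonsyn"]))
}

#' Construct a codon alignment
#'
#' One coding-strand, frame-0 CDS sequence per group consensus (P1, P2,
#' P3) plus the outgroup.
#'
#' @param gene_id gene identifier.
#' @param seqs named character vector with elements `P1`, `P2`, `P3`,
#'   `OUT`; equal lengths divisible by 3.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene_id, seqs) {
  ms_assert(all(c("P1", "P2", "P3", "OUT") %in% names(seqs)),
            "codon alignment needs P1, P2, P3, OUT sequences")
  lens <- nchar(seqs)
  ms_assert(length(unique(lens)) == 1, "gene %s: unequal sequence lengths",
            gene_id)
  ms_assert(lens[[1]] %% 3 == 0, "gene %s: frame violation (length %d)",
            gene_id, lens[[1]])
  structure(list(gene_id = gene_id, seqs = toupper(seqs)),
            class = "codon_alignment")
}

## Focal-branch ancestral inference for one codon under a rooted topology.
## Returns list(skip, change, anc).
focal_codon_ancestor <- function(topology, f, p1, p2, o) {
  if (topology == "topo1") {
    if (p1 == p2 && p1 == o) return(list(skip = FALSE, change = f != p1, anc = p1))
    if (p1 != p2 && p1 != o && p2 != o) return(list(skip = TRUE))
    return(list(skip = FALSE, change = FALSE, anc = f))
  }
  if (topology == "topo2") { s <- p1; x <- p2 } else { s <- p2; x <- p1 }
  if (s == x || s == o) return(list(skip = FALSE, change = f != s, anc = s))
  if (x == o) return(list(skip = FALSE, change = FALSE, anc = f))
  list(skip = TRUE)
}

#' Branch-specific dN/dS for the focal lineage under one topology
#'
#' @param aln a [codon_alignment()].
#' @param topology `"topo1"`, `"topo2"` or `"topo3"` (which lineage is
#'   P3's sister: none, P1, or P2).
#' @param focal focal group (fixed to `"P3"`).
#' @return list of class `dnds_estimate`: `dn`, `ds`, `omega`,
#'   `n_codons_used`, `n_changes`, `topology`, `excluded`, `reason`.
#' @export
branch_dnds <- function(aln, topology = "topo2", focal = "P3") {
  ms_assert(topology %in% TOPO_LABELS, "unknown topology %s", topology)
  ms_assert(identical(focal, "P3"), "focal branch must be P3")
  cf <- split_codons(aln$seqs[["P3"]])
  c1 <- split_codons(aln$seqs[["P1"]])
  c2 <- split_codons(aln$seqs[["P2"]])
  co <- split_codons(aln$seqs[["OUT"]])
  valid <- grepl("^[ACGT]{3}$", cf) & grepl("^[ACGT]{3}$", c1) &
    grepl("^[ACGT]{3}$", c2) & grepl("^[ACGT]{3}$", co)
  syn_sites <- 0; nonsyn_sites <- 0
  syn_subs <- 0; nonsyn_subs <- 0
  used <- 0L; changes <- 0L
  for (i in which(valid)) {
    res <- focal_codon_ancestor(topology, cf[i], c1[i], c2[i], co[i])
    if (res$skip) next
    anc <- res$anc
    if (anc %in% STOP_CODONS || cf[i] %in% STOP_CODONS) next
    sc <- ng_site_counts(anc)
    syn_sites <- syn_sites + sc[["syn"]]
    nonsyn_sites <- nonsyn_sites + sc[["nonsyn"]]
    used <- used + 1L
    if (res$change) {
      pc <- pathway_counts(anc, cf[i])
      syn_subs <- syn_subs + pc[["syn"]]
      nonsyn_subs <- nonsyn_subs + pc[["nonsyn"]]
      changes <- changes + 1L
    }
  }
  dn <- if (nonsyn_sites > 0) nonsyn_subs / nonsyn_sites else 0
  ds <- if (syn_sites > 0) syn_subs / syn_sites else 0
  omega <- if (ds > 0) dn / ds else NA_real_
  excl <- dnds_exclusion(dn, ds, omega)
  structure(list(dn = dn, ds = ds, omega = omega, n_codons_used = used,
                 n_changes = changes, topology = topology,
                 excluded = !excl$keep, reason = excl$reason),
            class = "dnds_estimate")
}

#' Exclusion rule for dN/dS estimates
#'
#' Estimates with no synonymous divergence (`dS = 0`) or implausibly large
#' ratios (`omega > 10`) carry too little signal and are dropped.
#'
#' @param dn,ds,omega components of an estimate.
#' @return list with `keep` (logical) and `reason` (`NA` when kept).
#' @export
dnds_exclusion <- function(dn, ds, omega) {
  if (is.na(ds) || ds == 0) return(list(keep = FALSE, reason = "dS=0"))
  if (!is.na(omega) && omega > 10) return(list(keep = FALSE, reason = "omega>10"))
  list(keep = TRUE, reason = NA_character_)
}

#' Topology-weighted mean dN/dS
#'
#' Combines the three per-topology estimates with the gene window's
#' topology weights; excluded estimates have their weight redistributed
#' proportionally among the rest.
#'
#' @param estimates list of three `dnds_estimate` objects in
#'   topo1/topo2/topo3 order.
#' @param w numeric weights (same order), summing to 1.
#' @return weighted mean omega, or `NA` when every usable weight is zero
#'   or every estimate is excluded.
#' @export
weighted_dnds <- function(estimates, w) {
  ms_assert(length(estimates) == 3 && length(w) == 3,
            "need three estimates and three weights")
  omega <- vapply(estimates, function(e) e$omega %||% NA_real_, numeric(1))
  keep <- !vapply(estimates, `[[`, logical(1), "excluded") & !is.na(omega) & w > 0
  if (!any(keep)) return(NA_real_)
  sum(w[keep] * omega[keep]) / sum(w[keep])
}

#' Classify the coding consequence of a SNP
#'
#' Standard-code translation of the reference versus alternate codon on the
#' coding strand. Variants outside the CDS are `"noncoding"`; changes that
#' keep the amino acid are `"silent"`, changes creating a premature stop
#' are `"nonsense"`, and all other amino-acid changes (including stop
#' losses) are `"missense"`. `"unknown"` flags inconsistent inputs
#' (reference mismatch, incomplete codon).
#'
#' @param model a [gene_model()] with CDS segments.
#' @param cds_seq the gene's reference CDS on the coding strand.
#' @param pos 1-based genomic position of the SNP.
#' @param ref,alt reference/alternate bases (genome strand).
#' @return one of `"silent"`, `"missense"`, `"nonsense"`, `"noncoding"`,
#'   `"unknown"`.
#' @export
classify_consequence <- function(model, cds_seq, pos, ref, alt) {
  if (is.null(model$cds) || nrow(model$cds) == 0) return("noncoding")
  pos0 <- pos - 1L
  seg <- which(model$cds$start <= pos0 & pos0 < model$cds$end)
  if (length(seg) == 0) return("noncoding")
  prior <- 0L
  if (seg > 1) prior <- sum(model$cds$end[1:(seg - 1)] - model$cds$start[1:(seg - 1)])
  off_plus <- prior + (pos0 - model$cds$start[seg])
  total <- sum(model$cds$end - model$cds$start)
  if (nchar(cds_seq) != total) return("unknown")
  if (model$strand == "+") {
    off <- off_plus
    r <- toupper(ref); a <- toupper(alt)
  } else {
    off <- total - 1L - off_plus
    r <- chartr("ACGT", "TGCA", toupper(ref))
    a <- chartr("ACGT", "TGCA", toupper(alt))
  }
  cod_i <- off %/% 3L
  in_cod <- off %% 3L
  codon <- toupper(substr(cds_seq, cod_i * 3L + 1L, cod_i * 3L + 3L))
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) return("unknown")
  if (substr(codon, in_cod + 1L, in_cod + 1L) != r) return("unknown")
  alt_codon <- codon
  substr(alt_codon, in_cod + 1L, in_cod + 1L) <- a
  aa0 <- translate_codon(codon)
  aa1 <- translate_codon(alt_codon)
  if (identical(aa0, aa1)) return("silent")
  if (identical(aa1, "*")) return("nonsense")
  "missense"
}
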
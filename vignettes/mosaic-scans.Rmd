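---
title: "Genome mosaicism scans: models, conventions, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome mosaicism scans: models, conventions, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The setting

`mosaicscan` analyzes a four-taxon design: a focal lineage P3 whose
genome may be a mosaic of ancestry shared with two candidate parental
lineages P1 and P2, polarized by an outgroup. The motivating biology is
a putative hybrid primate lineage tested against the two species groups
it overlaps, but nothing in the package is primate-specific: any
multi-sample biallelic SNP callset with an outgroup allele column, a
gene annotation, a recombination map and a candidate gene list can be
run through the same pipeline.

Two layers of inference are combined. The *genome layer* localizes
ancestry: windowed introgression statistics (Patterson's D and the
symmetric f_dM) and topology weighting of neighbor-joining trees built
in 50-SNP windows, summarized into majority-topology segments and
genome-wide proportions with block-bootstrap confidence intervals. The
*gene layer* asks whether a candidate gene set is unusual: seven
statistics per gene (π of P3; F_ST and D_XY of P3 against each parental
group; f_dM; topology-weighted branch dN/dS), a linear regression of
each statistic on local recombination rate with Cook's-distance outlier
calls, chi-square enrichment, and permutation tests of mean differences.

## Window statistics and their conventions

All internal coordinates are 0-based half-open; VCF positions are
1-based; BED is read as-is and GFF3 converted.

A site is **usable** when each of P1, P2 and P3 has at least two called
alleles; it is additionally **polarizable** when the outgroup allele is
known and equals REF or ALT. Usable-site counts are the per-window
denominators for the per-site statistics and the quantity the
minimum-site rule thresholds; only polarizable sites enter the
ABBA/BABA sums. This resolves the open question of what the min-site
ladder should count: informative sites, not raw VCF records. Requiring
two alleles in every group (slightly stricter than D_XY alone needs)
keeps a single usable-site definition for all statistics; with the
2-4-sample groups this analysis targets, the cost is negligible.

Window sizes 5, 25, 50, 100, 500 and 1000 kb pair with minimum usable
sites 10, 50, 100, 200, 1000 and 2000; windows step by 20% of their
size and only fully contained windows are emitted. The 50 kb/100-site
combination is the default working size. Because the input carries only
variant sites, π and D_XY are reported **per usable variant site**, not
per base pair; they are comparable across windows of one callset, which
is all the downstream outlier machinery needs.

Statistic definitions:

- π (group g): Σ 2p(1−p)·n/(n−1) over usable sites, divided by the
  usable-site count. The n/(n−1) correction matters at these tiny
  sample sizes.
- D_XY(A, B): Σ [p_A(1−p_B) + p_B(1−p_A)] / usable sites.
- F_ST: Hudson's ratio of averages, 1 − ΣH_w/ΣH_b, with H_w the mean of
  the two groups' corrected heterozygosities and H_b the D_XY site
  term. A consequence of the unbiased H_w worth knowing: at *equal*
  sample frequencies the estimator sits at 1 − n/(n−1) (slightly
  negative), approaching 0 from below as n grows. This is the standard
  behavior of the estimator, and why F_ST is documented as lying in
  [−small, 1].
- Patterson's D: (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA) with ABBA =
  (1−p₁)p₂p₃ and BABA = p₁(1−p₂)p₃ on outgroup-polarized derived
  frequencies (the outgroup's derived frequency is identically 0).
- f_dM: numerator ΣABBA − ΣBABA; the denominator substitutes the
  higher of (p₂, p₃) as donor into both the P2 and P3 slots when the
  numerator is non-negative, and the higher of (p₁, p₃) into the P1 and
  P3 slots when it is negative. Positive values mean excess P2↔P3
  sharing, negative excess P1↔P3 sharing.

**Numerical choice — clamping f_dM.** With the dynamic-donor
denominator, degenerate sites (high p₁, intermediate p₂, p₃ = 0) can
contribute *negative* denominator terms while contributing nothing to
the numerator, so the raw window ratio can land marginally outside
[−1, 1] in small windows. The package clamps to [−1, 1]; the
independent per-site oracle used in the tests applies the same
documented convention.

## Topology weighting

Diploids are pseudo-haploidized: two pseudo-haplotypes per sample,
heterozygous sites resolved by a seeded per-sample-per-site draw. This
uses all allele information and is exactly reproducible given the seed.
Distances are proportions of differing alleles among sites called in
both tips; trees are neighbor-joining (ape); windows are
**non-overlapping** 50-SNP blocks (the step is configurable, but the
default mirrors the non-overlapping convention of the script family
this reimplements), and trailing sub-windows are skipped.

Weights are exact: every combination of one tip per group is
enumerated, and its induced quartet is classified by the four-point
condition on the tree's path distances — the pairing with the smallest
within-pair distance sum is the displayed split; ties within a relative
tolerance of 1e−8 (polytomies, zero-length branches) split the vote
equally among the tied topologies. The unit tests check this route
against an independent classification by tree surgery
(`keep.tip`/`root`/`is.monophyletic`).

A window's majority topology is any topology with weight ≥ 2/3
(inclusive at the boundary); otherwise the window is unresolved.
Same-label neighbors are collapsed run-length style. Genome proportions
are span-weighted shares of the majority labels; confidence intervals
resample fixed 1 Mb blocks (partial terminal blocks kept) with
replacement, 10,000 replicates by default, percentile bounds.

Per-topology divergence raises the bar to unanimous windows (purity
1.0 by default, configurable down to just above 2/3) and computes D_XY
between P3 and its within-class sister: P1 in topo2 segments, P2 in
topo3 segments, and P2 in topo1 segments (where either choice is
equivalent by construction; one is reported).

## Branch dN/dS

The estimator is a deterministic counting method, not a codeml-style
likelihood fit — adequate for the ranking/outlier role it plays here,
and declared in the output. For each codon, the ancestral state of the
focal (P3) terminal branch is inferred on the given rooted four-taxon
topology, and a substitution is charged to the focal branch **only when
every most-parsimonious assignment requires it**:

- sister state corroborated by the other taxon or the outgroup →
  ancestral = sister; a differing focal codon is a focal change;
- other taxon and outgroup agree but the sister differs → the
  focal-parent state is parsimony-ambiguous; no focal change is
  counted (the codon still contributes sites);
- all three non-focal states distinct → the codon is skipped entirely.

Counts convert to rates with Nei–Gojobori site counting on the
ancestral codon (stop-codon changes counted as nonsynonymous, so
synonymous + nonsynonymous sites = 3 per codon) and multi-hit codons
average over minimal stop-free pathways. No multiple-hit (Jukes–Cantor)
correction is applied; at the within-genus divergences targeted here
the proportions are close enough to rates for ranking, and the
recovery tests quantify exactly what the estimator delivers.

Estimates with dS = 0 or ω > 10 are excluded — read as two independent
drop rules (dS = 0 leaves ω undefined regardless of the other clause).
Per-gene ω̄ re-normalizes the gene window's topology weights over the
non-excluded estimates. Genes whose gene window overlaps no tree window
fall back to equal weights (logged; rare in practice). Group sequences
are per-group consensus CDS, as the upstream methodology assumes.

## The outlier scan

Mean recombination rate per gene window is the length-weighted mean of
the bedGraph track; genes with no overlapping track interval are
excluded from regressions. Each statistic is regressed on rate by OLS;
a gene is an outlier when its Cook's distance exceeds 3× the mean Cook's
distance **and** its residual lies on the statistic's tail: π below the
fitted line, both F_STs and both D_XYs above, f_dM either side. The
directional condition is configurable (`direction = "both"` disables
it), since the source description is ambiguous on whether direction was
part of the rule; the directional reading is the default because it
matches the stated per-statistic expectations. ω̄ uses a 5% empirical
upper-quantile rule instead (its regression on recombination rate is
typically non-significant): the cutoff is the ⌊0.05·n⌋-th largest value
and ties at the cutoff are all flagged.

**Numerical choice.** On an exactly collinear fit the textbook Cook's
distance is 0/0; the package defines it as zero influence.

Permutation tests report the raw fraction of `n_perm` label shuffles at
least as extreme as the observed candidate-minus-background mean
difference — so p can be exactly 0 — with the add-one estimator
(k+1)/(n+1) alongside. Tails: π lower, ω̄ upper, all others two-sided.
The male/female contrast is always two-sided; genes in both sets stay
in both by default (a `drop_shared` option exists), and the computation
is canonicalized on set size so swapping the inputs negates the
observed difference but leaves p unchanged. The chi-square enrichment
test is Pearson's without continuity correction (configurable) and
warns when an expected cell is below 5.

## The synthetic world

The generator plants a **genealogy mosaic** rather than simulating an
ancestral recombination graph: each chromosome is partitioned into
tracts (exponential lengths, mean 200 kb) labeled topo1/topo2/topo3 or
"mixed" in configured proportions, and every SNP draws a branch of its
tract's fixed tree with probability proportional to branch length. This
trades demographic realism for exact truth labels, which is what the
recovery tests need.

Defaults state one world, chosen once:

- proportions (topo2, topo3, topo1, mixed) = (52.64%, 15.70%, 11.07%,
  20.59%) — the mosaic composition reported for the bear macaque;
- split depths in scaled time units: inner joins at 0.8 (topo2 — the
  majority class is the *younger*, introgression-like ancestry), 1.4
  (topo3) and 1.68 (topo1's P1–P2 join, with P3 attaching at 3.5);
  remaining lineage at 3.0; outgroup at 6.0. These echo the relative
  ages in the macaque literature (species-group split ~3 Mya, recent
  gene flow < 1.7 Mya, baboon outgroup ~6 Mya) without claiming
  calibrated units;
- within-group coalescent depth ε = 0.15 with a 1/k frequency spectrum
  and exchangeable carriers — polymorphism-to-outgroup-divergence
  ratios in the primate range;
- SNP density 4e−3 per bp (≈ 80k SNPs on the 4×5 Mb default genome),
  matching the variants-per-bp scale of a multi-species macaque
  callset;
- 10 samples in groups of 3 (P1), 4 (P2), 3 (P3) plus a haploid
  outgroup column — the sample structure of the motivating study;
- recombination map: piecewise-constant 100 kb tiles, lognormal around
  ~1 cM/Mb (sd 0.7 on the log scale), with log-rate correlated 0.5 with
  the regional diversity multiplier — diversity-recombination coupling
  is the empirical pattern the outlier scan exists to control for;
- 600 genes, 10% candidates; planted candidate effects: P3 polymorphism
  × 0.3 and P3 external branch × 1.5;
- 10% of SNPs inside resolved tracts draw a random topology
  (incomplete lineage sorting), so windows are strong but not pure.

**Mixed tracts** are the one non-obvious design decision. Interleaving
clean class-trees at the kb scale does *not* produce unresolved
windows: within-group cohesion keeps every group monophyletic in the NJ
tree, and one-tip-per-group subsamples then vote unanimously for
whichever class dominates the window. What real unresolved windows look
like is broken group monophyly, so mixed tracts emit *deeply unsorted*
variants: the derived allele segregates across all P haplotypes with a
neutral-like 1/k spectrum, ignoring group boundaries. Window trees in
those tracts scramble the groups and the vote splits — and per-site
diversity stays at polymorphism scale rather than fixed-difference
scale. A planted sweep (candidate π-deflation) suppresses this unsorted
variation too, as a real sweep would.

What the generator does **not** emulate — and therefore what a green
test does not establish: no linkage-disequilibrium decay within tracts
(sites are exchangeable given their branch), no missing genotypes or
sequencing error, no mutation-rate heterogeneity beyond the diversity
tiles, no indels or multiallelic sites, single-segment CDS gene models,
and coding alignments decoupled from the genome SNPs except for shared
reference bases and topology labels. Green recovery tests establish
that the estimators measure what they claim on data where the answer is
known; they do not validate robustness to alignment artifacts or
callset quality, which real inputs must bring under control upstream.

## Determinism and budgets

Every random step takes a seed; a pipeline run is a pure function of
(inputs, config, seed), and identical runs produce byte-identical
tables (the manifest records wall-clock timing and is the one file
excluded from that statement). Seeds for internal stages derive from
the master seed by a fixed linear-congruential fan-out, so stage
results do not depend on execution order.

The acceptance suite scales simulation sizes to a single-CPU budget:
mosaic recovery uses 20 replicate genomes of 2 × 3 Mb at density 2e−3
with 500 bootstrap replicates; the determinism criterion runs the full
pipeline twice on a 2 × 3 Mb bundle; ω recovery uses 200 seeds at 500
codons in a stated higher-divergence coding world (proposal rate
0.1/nt/unit, outer branches at 2.5, root at 4) chosen by power analysis
*before* the test was first run, so that synonymous counts are
estimable at ω = 5 — with the default coding rate, ~16% of genes are
dS = 0-excluded per topology, which is itself a realistic property the
pipeline handles (matching the real analysis, where most genes lack a
usable dN/dS).

## Known limitations

- π/D_XY are per-variant-site, not per-bp; comparisons across callsets
  with different site densities are not meaningful.
- The dN/dS counting estimator underestimates long-branch rates
  (no saturation correction) and discards parsimony-ambiguous codons;
  it is a ranking tool, not a substitution-rate measurement.
- Block-bootstrap CIs assume tract lengths well below the block size;
  with few blocks (small genomes) the percentile intervals are coarse.
- The unresolved class in the generator is a stylized model of deep
  incomplete lineage sorting, not a calibrated coalescent.
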
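---
title: "From metagenomic read counts to eCAGs: models and design choices"
author: "ecag package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From metagenomic read counts to eCAGs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The marine picocyanobacteria *Prochlorococcus* and *Synechococcus* dominate
phytoplankton communities over most of the surface ocean. Within each genus,
genetically coherent groups occupying distinct ecological niches — ESTUs,
ecologically significant taxonomic units, delineated from the single-copy
core marker gene *petB* (cytochrome b6) — partition the ocean along
temperature, iron and nutrient gradients. The question this package
addresses is how the *flexible* (non-core) gene repertoire maps onto those
niches: which accessory genes travel together across the ocean, which
environmental gradients they track, and which of them are also physically
clustered in reference genomes. Gene sets that are both co-distributed in
situ and adjacent in genomes — eCAGs, environmental clusters of adjacent
genes — are strong candidates for operons or pathways under niche-specific
selection.

The pipeline takes four inputs: a gene-family-by-station table of
metagenomic read counts (families are CLOGs, clusters of likely orthologous
genes, pre-assigned upstream), ordered per-genome gene annotations, a
per-station environmental table, and per-station ESTU relative abundances.
Read recruitment, ortholog calling and ESTU delineation are upstream of
this package and are taken as given.

## Normalization and filtering

Counts are converted to fold-coverage by gene and read length,
$\mathrm{cov}(g,s) = n(g,s)\, L_{\mathrm{read}}(s) / L_g$, so a gene
carried in single copy by every sampled cell reads as the sequencing depth
of the genus regardless of its length. Three filters follow, all with
strict inequalities:

1. **Samples**: keep stations detecting *more* families than a reference
   count (by default the mean gene count of the reference genomes) — a
   station that cannot account for one genome's worth of genes is too
   shallow for repertoire analysis.
2. **Genes**: keep families with coverage above 1x in at least 2 retained
   stations.
3. **Core removal**: only flexible genes carry niche information; core
   genes track total genus abundance.

Relative abundance is then
$\mathrm{rel}(g,s) = \mathrm{cov}(g,s) / \mathrm{cov}(petB, s)$, the
fraction of the genus population carrying $g$ at $s$ (it may exceed 1 and
is not clipped). Stations whose *petB* coverage falls below
`min_marker_cov` (default 0.1x; the display threshold behind blacked-out
stations on distribution maps) are masked as all-missing columns, and that
missingness propagates: masked stations are excluded from distances,
correlations and profiles rather than imputed. A station with *petB*
coverage exactly 0 is always masked, so no ratio is ever infinite.

## Station clustering and congruence

Stations are compared by Bray–Curtis dissimilarity on flexible-gene
relative abundances, and independently on ESTU relative abundances, then
clustered with Ward's minimum-variance criterion. We use the Ward.D2
variant (the Lance–Williams update on squared dissimilarities); the
literature on this method family rarely states the variant, so it is a
config key (`cluster$linkage`). Congruence between the gene-content and
taxonomic views is quantified by a Mantel test: Pearson correlation of the
lower triangles, with a one-sided permutation p-value using the add-one
correction $p = (1 + \#\{r^\ast \ge r\})/(1 + n_{\mathrm{perm}})$. The
default 10,000 permutations make $p < 10^{-4}$ resolvable, and the add-one
form makes the test exact at nominal level under exchangeability (the
test suite verifies the 5% type-I rate against a binomial 99% CI).

## Co-abundance modules

The module machinery is this package's own implementation of weighted
correlation network analysis; nothing is delegated.

**Adjacency.** Unsigned: $a_{ij} = |r_{ij}|^\beta$, Pearson over
pairwise-complete unmasked stations; pairs with fewer than 4 complete
observations get $r = 0$ and are counted in the log. The unsigned form is
the cited tool's default and a config choice.

**Marker-noise control.** Relative abundances share a common noisy
denominator (the marker's sampled coverage), and ratios with a shared
divisor are spuriously correlated — Pearson's classic artifact. At desk
scale this is material: a 645 bp marker at 5x depth is ~32 reads, an 18%
sampling CV common to every gene at that station, enough to weld genes
with flat carriage into an artifactual module whose eigengene simply
tracks the inverse marker coverage. The network therefore uses, by default
(`modules$marker_control`), first-order *partial* correlations controlling
for the observed log marker coverage. The same controlled correlation
space is used for the cohesion screen and eigengene merging below. On
deeply sequenced data the control variable is nearly constant and the
correction is a no-op (it is skipped entirely when the control has no
variance, e.g. in noiseless simulations). The trade-off: genuine modules
whose carriage tracks total genus abundance would be dampened; disable the
control if that signal matters.

**Soft threshold.** For each candidate power 1–20 the signed scale-free
fit of the connectivity distribution is computed: $R^2$ of
$\log_{10} p(k)$ on $\log_{10} k$, signed by the negative regression
slope. Two estimator details matter. Bins are equal-occupancy (quantile)
with a proper density normalisation — equal-width bins on these heavily
skewed distributions gave fit values noisy enough to select absurd powers.
And a fit is only reported when the connectivity distribution has real
dispersion (sd(k) at least 10% of mean(k)): a power law fitted to a
spread-less distribution is vacuous, which otherwise happens on noiseless
data where every gene has near-identical connectivity. The smallest power
reaching `target_fit = 0.8` is selected. When no power qualifies — typical
for strongly modular, block-structured co-abundance data, which simply is
not scale-free — the fallback prefers the largest candidate power whose
mean connectivity stays at least 1: the strongest suppression of
background correlation that keeps the average gene connected. (Taking the
argmax of the fit curve instead would not be robust: the fit values are
uninformative exactly when the primary rule fails.)

**Topological overlap and detection.**
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$; genes are clustered by average linkage on $1 - \mathrm{TOM}$ and
the tree is cut statically at `cut_height` (0.995) times the highest
merge. The cut is implemented directly on the merge list because
average-linkage heights can carry tiny floating-point inversions that the
stock cutters reject. Branches with at least `min_module_size` (10) genes
become modules, colored by decreasing size with the conventional color
sequence. Two refinements follow:

* a **cohesion screen**: members whose own-module eigengene correlation
  (in the controlled space) falls below `min_gene_kme` (0.5) return to
  grey, and modules that shrink below the minimum size dissolve. A static
  height cut inevitably gathers an incoherent "leftover" branch near the
  top of the tree; this screen is the same concern the kME refinement
  stage of dynamic tree cutting addresses, in a simpler form;
* **eigengene merging**: modules whose eigengenes correlate above
  `1 - merge_height` (0.75) merge iteratively, then colors are reassigned
  by final size.

This is deliberately simpler than the dynamic hybrid cut of the reference
tool; the supported claim is recovery of planted modules under the study
conditions below, not replication of any particular module count on real
data.

**Eigengenes and representatives.** A module eigengene is the first right
singular vector of the gene-standardized module submatrix over unmasked
stations — a unit-norm per-station profile, sign-oriented to correlate
positively with the mean member profile (so the arbitrary SVD sign never
leaks). kME is the correlation of any gene with any module eigengene;
"most representative" genes are members with own-module kME at least
`min_kme` (0.7). Module–trait association uses Pearson correlation against
environmental parameters and Spearman against ESTU abundances, both with
the Student asymptotic p-value $t = r\sqrt{(n-2)/(1-r^2)}$ on
pairwise-complete stations; parameters with fewer than 3 paired values are
reported missing. No multiple-testing correction is applied in these
tables, matching the conventional raw $p > \alpha$ masking of module-trait
heatmaps ($\alpha = 0.01$); the per-gene enrichment output additionally
carries a Benjamini–Hochberg column for users who want it.

## Synteny and eCAG delineation

Gene-gap distance between two families in a genome is the minimal rank
distance over occurrence pairs: 1 for immediate neighbours, circularly
wrapped on circular replicons ($\min(|p-q|, m-|p-q|)$), undefined across
replicons — a pair split across replicons counts among the genomes
possessing both but can never count as close, a conservative choice given
incomplete (SAG/MAG) assemblies with many short contigs. Strand is kept in
annotations but ignored for distance.

Two edge rules are implemented because the field uses both phrasings:

* **support mode** (default for the eCAG inventory): families at distance
  at most `D_support = 5` ("less than 6 genes apart") in at least 80% of
  the genomes possessing both;
* **any-genome mode** (the display rule of synteny network figures):
  distance at most `D_any = 4` ("less than five genes apart") in at least
  one genome.

"Genomes possessing them" is read as genomes containing *both* families.
Both D values and the support fraction are config keys.

eCAGs are the connected components, of size at least `min_size = 2`, of
the edge graph induced within each module (grey genes excluded) — so no
eCAG ever spans modules. Ids are assigned per genus by decreasing size,
ties broken by the lexicographically smallest member; the ordering rule of
published inventories is unstated, so this convention is the package's
own. Per-station eCAG profiles are member means (or medians) with masked
stations propagated. Niche enrichment between user-supplied station groups
uses Welch's unequal-variance t-test per gene, with an "all members
individually significant in the same direction" flag per eCAG; groups are
inputs, not auto-derived, because published niche groups come from prior
ESTU work. Degenerate units follow fixed conventions: both groups constant
and equal gives $p = 1$; constant but different gives $p = 0$; a group
with fewer than 2 unmasked stations skips the unit with a warning.

## The synthetic generator and what passing tests mean

Real read recruitment at ocean scale is out of reach on a desk, so every
stage is exercised against a generator with recorded ground truth
(`truth.json`): planted niche modules, planted eCAGs with their
placements, ESTU niche parameters, genome-ESTU assignments.

The reference study conditions are 24 genomes in 6 ESTUs, 60 core + 240
flexible families (120 niche-labelled, 120 neutral), 6 planted eCAGs of
3–7 genes, 40 stations, read length 100 bp, gene lengths 800–2500 bp
(*petB* fixed at its real 645 bp), and Poisson counts at 5x single-copy
depth — small enough that the whole study runs in seconds. Design choices
a user should know:

* **One niche per ESTU**, with Gaussian responses on three gradients
  (temperature, phosphate, and the satellite iron-limitation proxy);
  optima are placed on spread permutations of evenly spaced levels so no
  two ESTUs are close on every gradient at once, with niche width 1/6 of
  each gradient range. Two distractor parameters (PAR30, DCM) have no
  planted effect.
* **Stations**: half are drawn around niche optima (cycling over ESTUs),
  half uniformly. Purely uniform draws over a 3-gradient space leave some
  niche unsampled in roughly a third of realisations at 40 stations, which
  would make that niche's module unobservable by construction; transects
  that cross each assemblage's habitat are also the realistic sampling
  design.
* **Neutral families** are carried by exactly half the genomes of *every*
  ESTU, so their expected relative abundance is flat across stations: they
  test the pipeline's ability to leave niche-neutral genes unassigned, and
  they are the worst case for the marker-noise artifact discussed above.
* **Genome layout**: core genes keep a conserved circular order; each
  planted eCAG is a contiguous block in every carrier genome; non-eCAG
  same-niche genes are kept at least 6 ranks apart in every genome (when
  the spacer budget allows), so conserved adjacency is unique to planted
  eCAGs by construction and recovered precision is interpretable.
* **Noise**: Poisson by default, negative binomial through one
  overdispersion knob, or exactly the expected counts in noiseless mode.
  Carriage is binary per genome.

What the generator does *not* emulate: lateral gene transfer, copy-number
variation, within-ESTU genome heterogeneity beyond the neutral class,
read-mapping ambiguity, compositional coupling between genera, or real
spatial autocorrelation structure. Recovery results on this generator
therefore demonstrate that the machinery is correct and calibrated — not
that real ocean-scale data would yield any particular module count or eCAG
inventory, which is why headline quantities from the original ocean-scale
analyses (read totals, genus splits, four/five modules, specific named
eCAGs) are explicitly not reproduction targets.

## Numerical conventions

* Genes constant up to floating point (relative sd below $10^{-10}$) are
  excluded from the network with a logged count — noiseless ratios are
  constant only to ~$10^{-16}$, which would otherwise produce garbage
  correlations.
* Correlations are clamped to $[-1, 1]$ after the partialling formula;
  control correlations are clamped away from $\pm 1$ before it.
* `cut_k` resolves ties at the cut height by merge order and logs the
  event; run manifests contain no timestamps, so identical inputs give
  byte-identical manifests.
* Every stochastic step (simulation, Mantel permutations, graph layout)
  takes an explicit seed; the test suite asserts bit-reproducibility of
  the whole pipeline under a fixed seed.

## Known limitations

The static cut plus cohesion screen can split one true module into two
when its internal correlation structure is heterogeneous; the eigengene
merge step recovers most such cases but is bounded by `merge_height`.
Partial-correlation control assumes the log marker coverage enters gene
profiles approximately linearly, which holds to first order for moderate
marker CV. The support-mode synteny rule undercounts adjacency in heavily
fragmented assemblies (split pairs inflate the denominator); this is the
conservative direction. Welch tests on relative abundances inherit the
denominators' dependence across genes at the same station, so the per-eCAG
"all members significant" flag is a reporting convention rather than a
joint test.
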
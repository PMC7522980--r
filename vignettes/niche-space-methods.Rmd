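---
title: "Methods: diffusion-map coordinates for metabolic niche space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-map coordinates for metabolic niche space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemap)
```

## The model

`nichemap` represents each bacterial genome as a binary vector over metabolic
*traits*: a trait is a directed substrate → product edge in the genome's
metabolic network, labelled `"substrate->product"`. Trait columns are the
lexicographically sorted union of edges over all genomes, so the matrix is a
deterministic function of the input networks regardless of edge order. Only
edge sets enter the trait matrix; metabolite node sets are kept separately
and feed the enrichment stage. Constant columns are retained by default —
they do not change any pairwise Euclidean distance, and
`drop_constant_traits()` is offered as an explicit, provably
distance-preserving opt-in.

The embedding follows the nearly parameter-free kNN diffusion-map recipe:

1. Pairwise Euclidean distances d between trait rows.
2. Each genome is linked to its k nearest rows (k = 10 by default) with
   weight w = 1/d; the directed relation is symmetrized by union,
   w_ij = max(w_ij, w_ji).
3. From the weighted adjacency W with degree matrix D, the row-normalized
   Laplacian L = I − D⁻¹W is diagonalized. Its eigenvalues are real and lie
   in [0, 2]; the constant eigenvector at eigenvalue 0 is discarded, and the
   eigenvector of the smallest non-zero eigenvalue is diffusion variable 1,
   the next smallest variable 2, and so on. Small eigenvalues correspond to
   slow diffusive modes, i.e. the most important axes of variation.

Assumptions worth stating: genomes with identical trait rows have d = 0 and
an undefined inverse-distance weight, so they are rejected with instructions
to merge duplicates and re-expand afterwards (an arbitrary large-weight cap
would make results depend on that cap). The similarity kernel is only
constrained to be monotone decreasing in distance; w = 1/d is the
parameter-free default, and a Gaussian kernel exp(−d²/σ²) with σ set to the
median kNN distance is available through `weight_mode = "gaussian"`. Union
symmetrization (rather than mutual-kNN) guarantees every node keeps at least
k neighbors and preserves connectivity better.

## Numerical choices

Eigenpairs are computed through the symmetric conjugate
L_sym = I − D^(−1/2) W D^(−1/2), which shares the spectrum of L, using the
dense symmetric solver; eigenvectors are back-transformed by D^(−1/2). This
guarantees a real spectrum and stable results for the non-symmetric
row-normalized operator. Each variable is normalized to unit Euclidean norm.
The sign of an eigenvector is mathematically arbitrary; it is fixed so that
the largest-magnitude entry is negative (first such entry on exact ties),
which makes the whole pipeline bit-reproducible and places extremal clusters
at low values. Zero-eigenvalue detection and residual checks
(‖Lv − λv‖∞) use tol = 1e-8.

A disconnected kNN graph produces additional (near-)zero eigenvalues whose
eigenvectors merely indicate connected components. By default this is an
error suggesting a larger k; with `allow_disconnected = TRUE` the extra
modes are kept but flagged in `component_indicator`, because for planted
discrete clusters the component indicator *is* the cluster contrast and
discarding it would hide exactly the structure of interest. The test suite
and acceptance script use this flag for fixtures whose clusters are so well
separated that no k below the cluster size connects them.

kNN ties among equidistant candidates are broken by input row order (stable
sort); extremal-taxon ties on entry values are broken lexicographically by
genome id. `extremal_taxa()` refuses n > N/2 so the two extrema cannot
overlap.

Diffusion distances default to the unweighted ("flat") Euclidean distance
over the retained variables; an `inverse_eigenvalue` mode divides coordinate
l by λ_l first, emphasizing slow modes in the spirit of the diffusion-
distance literature. The flat default is used wherever results are compared
across fixtures because it does not magnify near-zero eigenvalue noise.

The inverse participation ratio IPR = Σᵢ vᵢ⁴ of a unit-norm variable
quantifies localization: 1/N for a perfectly flat vector, 1 for a delta
vector. It is reported per variable so localized variables (discrete
clusters of unique capabilities) can be screened without inspecting plots.

## Enrichment

For a chosen variable, genomes are ranked by entry (descending, id-ordered
on ties) and each metabolite's genome set is scored with the classic
running-sum statistic: up-steps |stat|^exponent normalized over member hits,
down-steps 1/(N − |S|), ES = the extreme deviation, signed. The exponent
defaults to 1 (stat-weighted, as in mainstream GSEA implementations);
exponent 0 gives the unweighted Kolmogorov–Smirnov walk used in the analytic
worked examples. The null distribution draws `n_perm` random same-size
genome sets — a gene-set permutation, feasible without phenotype labels —
and the sign-matched add-one estimator gives p ≥ 1/(n_perm + 1).
Benjamini–Hochberg correction is applied across the metabolites tested for
one variable: the per-variable family matches how variables are interrogated
one at a time; testing several variables against a global family can be had
by pooling tables and re-running `bh_adjust()`. Set-size bounds default to
[5, N − 5] since near-empty or near-full sets carry no ranking information.
Enrichment toward either extremum is of interest, so ES keeps its sign and
the permutation p is computed in the matching tail.

## Phylogeny comparison

`mantel()` correlates the condensed upper triangles of two distance
matrices (Pearson) and permutes rows/columns of the second jointly for the
null. The default alternative is one-sided positive — the directional
question is whether metabolically similar genomes are phylogenetically
close — with a two-sided option. Genome/leaf alignment is by explicit id
intersection; unmatched ids raise an error (or a message under
`partial = TRUE`) — silent subsetting is never performed. Note the Mantel
statistic is not rank-based: a strictly monotone transform of one matrix
changes r, so no invariance of that kind is claimed or tested.

## Community fingerprints

Niches are operationally the 10 most-negative and 10 most-positive genomes
along each of the first 50 variables (100 niches). A census occupies a niche
if at least one of its taxa maps, through the match table filtered at ≥ 97%
identity (inclusive), to one of the niche's genomes; abundances are ignored
(presence-based occupancy). The fingerprint entry for (ecosystem, niche) is
the fraction of that ecosystem's samples occupying the niche. Fingerprint
rows are clustered with Ward's minimum-variance criterion on Euclidean
distances (`hclust(method = "ward.D2")`, the algorithm that implements Ward
for Euclidean input); given a fixed row order the procedure is
deterministic, with merge-candidate ties resolved by the underlying
implementation's stable pair ordering. The match table is an input contract
(one top-hit genome per taxon with a percent identity): 16S extraction and
BLAST searching are published tools outside this package's scope, and
treating their output as data keeps the module testable without sequence
databases. A taxon's single top-hit genome, if at or above the threshold,
determines its niche membership.

## What the generators emulate — and what they do not

* `make_clustered_traits()`: discrete yes-or-no strategy clusters — a shared
  core block, one unique block per cluster, optional background genomes, and
  independent Bernoulli bit-flip noise (`flip_prob`). At low noise,
  within-cluster rows can be identical; `force_unique` adds one private
  trait per genome so fixtures satisfy the no-duplicate-rows contract
  without materially changing geometry.
* `make_branching_traits()`: quasi one-dimensional branches rising from a
  common core; step s on branch b carries s·`traits_per_step` cumulative
  branch traits, so within-branch Hamming distance is exactly
  |s − t|·`traits_per_step` and one shared root genome sits at every
  branch's origin.
* `make_random_tree()`: a Yule (pure-birth) tree grown with per-lineage
  unit-mean exponential waiting times; the final waiting period is appended
  to pendant edges so all branch lengths are positive.
* `simulate_traits_on_tree()`: each trait evolves independently as a
  two-state continuous-time Markov chain (gain/loss rates per unit branch
  length) using the exact closed-form transition probabilities per edge.
* `make_communities()`: each sample occupies each niche independently with
  its ecosystem's probability, contributing the pseudo-taxon of one member
  genome; the match table links pseudo-taxa to genomes at a stated identity.

Noise is deliberately independent (Bernoulli flips, independent CTMC
traits): it keeps every oracle analytic (Hamming arithmetic, binomial
bounds, 2-state closed forms). Real genome collections violate this in ways
the generators do not emulate — correlated trait gain/loss (operons,
horizontal transfer of pathway cassettes), heterogeneous trait frequencies,
annotation noise that is systematic rather than independent, and uneven
taxon sampling. Passing the recovery tests therefore shows the algorithms
are correct on the geometry they assume, not that real data satisfy that
geometry. Fingerprint round-trip bounds additionally assume niche genome
sets are disjoint; extremal sets from a real diffusion result can overlap
between variables, in which case occupancy is correlated across niches and
entries exceed their single-niche generating probabilities.

## Problem sizes and tolerances used in validation

The shipped tests and acceptance script run on fixtures of 20–61 genomes,
70–300 traits, 40–60 tree leaves, 400 evolved traits, and 40 samples per
ecosystem — sizes at which every planted structure is comfortably
recoverable and the full suite completes in seconds. Closed-form spectral
checks are asserted at 1e-8; Monte-Carlo quantities use 3-sigma binomial
bounds; permutation tests use 199–999 permutations with seeded RNG
throughout. Phylogenetic-signal fixtures rescale the Yule tree to unit
depth before applying gain = loss = 0.5, giving about one expected
transition per trait per root-to-leaf path — enough divergence to avoid
duplicate leaves, far from saturation; at rates two orders of magnitude
higher the same test confirms the association collapses.

## Known limitations

* Dense eigendecomposition is O(N³); for collections beyond a few thousand
  genomes a sparse/iterative solver would be the natural extension.
* Eigenvector orderings, not magnitudes, are the operative quantities;
  unit-norm scaling is a convention and entry magnitudes should not be
  compared across datasets with different N.
* The per-variable BH family and the gene-set permutation scheme are
  documented choices, not the only defensible ones.
* Two-dimensional re-embeddings of the diffusion variables, abundance-
  weighted occupancy, and partial Mantel tests are out of scope.
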
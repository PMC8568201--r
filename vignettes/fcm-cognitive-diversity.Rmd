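---
title: "Measuring cognitive diversity from fuzzy cognitive maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cognitive diversity from fuzzy cognitive maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmdiv)
```

# The problem

Participatory studies of common-pool resources elicit one fuzzy cognitive
map (FCM) per stakeholder: a directed graph whose nodes are system concepts
and whose edges carry weights in $[-1, +1]$ giving the sign and strength of
a perceived causal influence.  Surface-level ("identity") diversity —
whether a sample mixes fishers, managers, NGO staff, tourism operators and
scientists — is easy to measure.  Deep-level ("cognitive") diversity —
whether those people actually hold different mental models — needs a
distance between graphs.  This package implements such a distance, the
group statistics built on it, a Monte-Carlo generator of virtual
stakeholders, entropy-based identity-diversity indices, and a micro-motif
clustering pipeline, together with a synthetic-population generator used to
test every stage.

# The cognitive distance

## Homogenization

Maps are compared only after two preprocessing steps:

* **Qualitative homogenization** — synonymous concept labels are merged.
  The package applies a user-supplied synonym table mechanically
  (`apply_synonym_table()`); deciding which terms are synonymous is the
  analyst's job.  When a rename merges two concepts, parallel edges are
  combined by the mean of their weights (clipped to $[-1,1]$; a merged
  weight of exactly 0 encodes absence, so the edge is dropped and
  reported), or by `max_abs` if selected.
* **Quantitative homogenization** — `homogenize_collection()` pads every
  map to the union concept set with isolated nodes, so all adjacency
  matrices share one universe.  No edge is added, removed or reweighted,
  and padding is designed to be *exactly* neutral for the distance (see
  the isolated-node convention below).

Concept labels are matched after trimming, whitespace collapsing and case
folding; node order everywhere is the locale-independent lexicographic
order of these canonical labels, so every matrix the package builds is
reproducible bit for bit.

## The two channels

For maps $G_1, G_2$ over a shared universe:

* **Structure channel.** The dichotomized adjacency matrix $A^d$ records
  edge presence only.  Viewing the matrices as directed edge sets,
  $d_J = 1 - |E_1 \cap E_2| / |E_1 \cup E_2|$.  Two empty maps get
  $d_J = 0$ (maximally similar) by convention.
* **Weight channel.**  The directed, signed map is first symmetrized to a
  nonnegative matrix $A_w$; the default (`sum_abs`) sets
  $a_{ij} = |w_{i\to j}| + |w_{j\to i}|$, preserving the total causal
  intensity of a dyad.  `max_abs` and `mean_abs` (mean over the directed
  edges actually present) are selectable.  Absolute values are not
  optional: they guarantee the normalized Laplacian
  $L^{sym} = D^{-1/2}(D - A_w)D^{-1/2}$ has a real, nonnegative spectrum.
  The spectral distance is
  $d_s = \sqrt{\sum_{i \le k^*} (\lambda_{1i} - \lambda_{2i})^2}$ over
  eigenvalues sorted in decreasing order, where each map's $k$ is the
  *smallest* number of leading eigenvalues reaching 90% of its total
  spectral mass and $k^* = \min(k_1, k_2)$.

The combined **cognitive distance** is
$CD = \phi \cdot d_s / (1 - d_J)$, capped at 1: agreeing on which edges
exist ($d_J$ small) leaves $CD$ driven by the weight structure; including
largely different edges inflates it.

## The standardization coefficient $\phi$

How $\phi$ maps $CD$ into $[0,1]$ was genuinely open; the package defines
it as the reciprocal of the largest finite raw value
$d_s/(1-d_J)$ in the analyzed collection.  Consequences worth knowing:

* at least one pair in every collection attains $CD = 1$;
* $CD$ values are comparable **within** one collection, not across
  collections, unless a fixed $\phi$ is supplied (`phi =` argument);
* structurally disjoint pairs ($d_J = 1$, raw $= \infty$) get $CD = 1$:
  maps sharing no edge are maximally distant.

## Numerical conventions and degenerate inputs

* Isolated nodes get a zero row/column in $L^{sym}$ and hence eigenvalue
  0 at the tail of the spectrum; total mass and the 90% index are
  unaffected, which makes padding invariance exact rather than
  approximate.
* Eigenvalues are accepted down to $-10^{-9}$ (numerical noise) and then
  clipped to 0; anything lower signals an invalid matrix and errors.
* An all-zero spectrum has $k = 0$; a pair with $k^* = 0$ has $d_s = 0$
  and is flagged as degenerate rather than erroring, since padded real
  collections can contain near-empty maps.
* A collection in which *all* pairs are identical (every raw 0) or *all*
  pairs disjoint (every raw $\infty$) has no usable $\phi$ and errors
  with an explanation.
* Useful invariances (all property-tested): $CD(a,a) = 0$; symmetry;
  appending the same isolated concepts to both maps changes nothing;
  multiplying one map's weights by $c > 0$ changes nothing (the
  normalized Laplacian cancels scale — the spectral channel sees
  *relative* weight structure); flipping one weight's sign changes
  nothing (a documented information loss of the absolute-value
  symmetrization).

# Group statistics

`partition_distances()` splits pairwise distances into intra-group
(both members share the label) and inter-group (exactly one member in the
group) sets; for the pooled `"ALL"` partition these cover all
$\binom{N}{2}$ pairs.  `compare_groups_report()` then runs

* Welch's $t$ test (default; group sizes such as 11 vs 4 make the
  pooled-variance form fragile, though it is selectable), and
* the Wilcoxon–Mann–Whitney $U$ test: exact enumeration of all subset
  assignments for combined $n \le 12$ (valid under ties), otherwise a
  normal approximation with tie and continuity corrections.

Both default to two-sided alternatives; the directional question "are
inter-group distances longer?" is available via `alternative = "greater"`.
A caveat is attached and printed: pairwise distances share individuals and
are not independent, so these $p$-values are approximate in a way the
tests cannot see.  At study scale (33 individuals) the measured two-sided
false-positive rate on label-free synthetic data stays near the nominal
5% (the test suite checks 2–8% over 200 seeds), so the dependence
is tolerable there, but it should not be assumed harmless for much larger
collections of pairs.

# Identity and cognitive diversity

Identity diversity uses Shannon entropy with natural logarithms
($0 \ln 0 = 0$): $D = e^H / \max(r)$, where $\max(r)$ is the maximum
possible richness — 5 types by default in the synthetic study design.
$D \in (0, 1]$ is 1 exactly for a uniform sample over all possible types,
and is Schur-concave: any transfer making counts less even decreases it.
Cognitive diversity is the mean of all pairwise $CD$ values.

# The Monte-Carlo generator

`fit_group_edge_model()` estimates, per group: the union edge set of the
members' maps, each edge's inclusion frequency $\pi_e$ (exact fraction of
member maps containing it), and the mean $\mu_e$ and standard deviation
$\sigma_e$ of its signed weights over those maps.  $\sigma$ uses the
population convention (divide by the count) so single-observation edges
are well defined with $\sigma = 0$; the sample convention is selectable.

`sample_virtual_map()` draws each union edge independently
(Bernoulli($\pi_e$)) and gives included edges weights from
$N(\mu_e, \sigma_e)$, clipped to $[-1, 1]$ with magnitude floored at
$0.01$ preserving the sign of the draw (sign of $\mu_e$ if the draw is
exactly 0).  The floor keeps Bernoulli-decided presence consistent with
"zero weight = absent".  Two knock-on effects are worth documenting:

* **Truncation bias.** For $|\mu_e|$ near 1 the clipped draw is no longer
  Gaussian and its mean shrinks toward 0 (about 0.05 at $\mu = 0.95$,
  $\sigma = 0.15$), so fitting a model to maps sampled from it recovers
  $\mu_e$ exactly only away from the bounds; the recovery test uses
  $|\mu| \le 0.7$, where clipping is inactive.
* **Edge independence.** Edges are drawn independently; the generator does
  not model the co-occurrence of edges sharing a source node.  A
  Markov-style generator with memory would need far larger samples than
  interview studies provide and is out of scope.

## The diversity experiment

`run_diversity_experiment()` builds (by default) 100 virtual samples of
$N = 33$ agents.  Each replicate draws an identity composition, generates
the agents' maps, computes $D$ and the mean pairwise $CD$, and attaches a
95% percentile bootstrap interval (1000 resamples of individuals;
resampled duplicate pairs contribute $CD = 0$).  The output includes the
Pearson correlation between $D$ and mean $CD$ across replicates.

Two design choices were open and are resolved as follows:

* **Composition sampling.** "A random combination of agents" is made
  concrete as: proportions from a symmetric Dirichlet whose concentration
  is drawn log-uniformly over $[0.05, 20]$, converted to counts by
  largest-remainder rounding (total preserved exactly).  Small
  concentrations give lopsided samples ($D$ near $1/\max(r)$), large ones
  near-uniform samples ($D$ near 1), so replicate sets span the whole
  evenness axis — which is precisely what the correlation needs.
* **Standardization across replicates.** The experiment's default fits
  **one global $\phi$** from a balanced reference sample drawn from the
  same models and applies it to every replicate.  Normalizing each
  replicate by its own maximum raw distance (`phi = "per-replicate"`) is
  also available but not recommended for the experiment: each replicate's
  mean $CD$ then equals mean(raw)/max(raw), and because the maximum grows
  with diversity alongside the mean, the ratio cancels most of the
  between-replicate signal the correlation is supposed to measure.

# Micro-motif clustering

Seven directed graphlets on 2–3 distinct nodes serve as the elementary
patterns of perceived causation: direct link, reciprocal dyad, chain,
fork (common cause), collider (common effect), feedback 3-cycle, and
transitive triangle.  The exact catalog in the source material was not
enumerable from the text, so this canonical set from the
perceived-causation literature is the default and the catalog is
JSON-configurable (`read_motif_catalog()`).

Counting uses *pattern-occurrence* (non-induced) semantics — motifs are
building blocks, so extra edges are allowed — with each occurrence counted
once per automorphism class; weights, signs and self-loops are ignored.
The default catalog is counted in closed form with matrix algebra and
verified against an exhaustive pair/triple enumerator; custom catalogs use
a generic enumerator.  Frequencies are counts over total counts; a map
with no occurrences gets a flagged all-zero profile.

Profiles are embedded with 2-component PCA.  **Standardization default:**
the embedding uses the raw frequency covariance (`standardize = FALSE`).
Z-scoring the seven dimensions spreads variance nearly evenly and leaves
two components carrying only about half of it, while the raw covariance
concentrates most of the variance on two components and gives markedly
more stable downstream clustering; both options are exposed.  Component
signs are fixed (largest-magnitude loading positive) for reproducibility,
and zero-variance columns are left at zero rather than producing NaNs.
K-means (best of 10 restarts, Euclidean, seeded) assigns cognitive
clusters, relabeled in order of first appearance; `concurrency_matrix()`
reports, per cluster, the fraction of members carrying each identity and
the dominant identity with its probability.

# The synthetic population generator

`population_spec()` + `generate_population()` stand in for interview data
throughout testing.  Defaults describe an interview-scale study: 5 social
groups over 40 concepts, 40 union edges per group, inclusion frequencies
uniform in $[0.3, 0.9]$, signed mean weights uniform in $[-1, 1]$, weight
noise $\sigma = 0.15$, and a default composition of 33 agents split
11/4/6/6/6 (the shape of a typical stakeholder sample; 200 per group for
clustering-scale runs).

The separation knob is `overlap`: a common core of
$\mathrm{round}(\mathrm{overlap} \times 40)$ edges shared by all groups
with identical parameters, the remainder private and pairwise disjoint
across groups.  At `overlap = 1` the groups are statistically identical
and the labels carry no information (the null configuration); at
`overlap = 0` they share nothing.

**Private-edge placement is styled, not uniform.**  Uniformly random
private edges would separate groups in Jaccard space but *not* in motif
space: all groups would live in the same random-graph ensemble with
near-identical expected motif frequencies.  Separation is supposed to be
visible to both channels, so each group's private edges are laid down in
a distinctive causal topology — fork hubs (common-cause reasoning),
collider hubs (common-effect reasoning), chains (linear reasoning), and
two alternating mixtures.  Building all five styles from three primitives
keeps the five group centroids in a two-dimensional plane of
motif-frequency space, which a 2-component PCA retains essentially in
full; with five unrelated styles the centroids span four dimensions and
the 2-component projection collapses some of them.

What the generator does **not** emulate about real interview data:
concept vocabularies and their meanings, hub concepts shared across all
stakeholders, correlated edge inclusion (people mention a concept's edges
together), weight distributions with interviewer-induced rounding, or
systematically different map sizes per stakeholder type.  Passing tests
on this generator therefore demonstrates that the *machinery* behaves as
specified under controlled separation — not that any particular empirical
effect size will reappear in a real study.

# Problem sizes used in the test suite

The shipped tests run the pipeline at the scales the analyses are
designed for: 33-map collections (528 pairs) for the group statistics,
100-replicate experiments of $N = 33$ with 1000-resample bootstraps for
the diversity correlation, 1000-map populations (200 per group) for the
clustering stage, and 10,000 sampled maps for model recovery; oracle
comparisons use exhaustive enumeration on graphs of up to 8 nodes and
compositions of up to $N = 8$.

# Known limitations

* The spectral channel is blind to edge direction and sign, and spectra
  can be sensitive to small structural changes; users comparing very
  sparse or near-empty maps should watch the degenerate-pair flags.
* $\phi$ makes $CD$ collection-relative; cross-study comparisons need a
  shared reference $\phi$.
* The group tests inherit the pairwise-dependence caveat above.
* The $U$ test's exact path enumerates subsets and is limited to small
  combined samples (configurable, default $n \le 12$).
* The generator's independence and truncation properties are as
  documented; fitted $\sigma_e$ of single-observation edges is 0 by
  convention, which underestimates real dispersion for rare edges.
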
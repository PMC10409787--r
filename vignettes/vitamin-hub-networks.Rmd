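---
title: "Predicting vitamin-provisioning hubs from co-occurrence networks"
author: "vitnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting vitamin-provisioning hubs from co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitnet)
```

## The problem

Genome-resolved metagenomics of a microbial community yields (i) a relative
abundance for every recovered genome (MAG) in every sample and (ii) each
genome's gene content. Organisms that persistently co-occur across samples
are candidates for ecological interaction, and one concrete, testable
mechanism of interaction is B-vitamin cross-feeding: many community members
lack the biosynthetic pathway for a vitamin they require (auxotrophs) and
must obtain it from organisms that encode the full pathway (producers).

`vitnet` implements this analysis as a pipeline: a compositional
co-occurrence network is inferred from the abundance table, pathway
completeness is called per genome from KEGG ortholog (KO) annotations, and a
node-level *vitamin-hubness* score with a label-randomization null
identifies producers that correlated auxotrophs plausibly depend on.

## The co-occurrence network

Relative abundances are compositional: they sum to (at most) one per sample,
so naive correlation of fractions produces spurious negative dependence.
`sparccCorrelations()` therefore estimates *basis* correlations from
log-ratio variances $t_{ij} = \mathrm{Var}\,\log(x_i / x_j)$, which are
invariant to per-sample totals. Under a sparsity assumption (most pairs
uncorrelated) the basis variances $\omega_i^2$ solve the linear system
$\sum_{j \in \mathrm{inc}(i)} t_{ij} = d_i\,\omega_i^2 +
\sum_{j \in \mathrm{inc}(i)} \omega_j^2$, and

$$\rho_{ij} = \frac{\omega_i^2 + \omega_j^2 - t_{ij}}{2\,\omega_i\,\omega_j}.$$

Pairs whose estimated $|\rho|$ exceeds `exclusionThreshold` (default 0.1)
violate the sparsity assumption and are excluded from the system one at a
time, up to `nExclusionRounds` (default 10) times. Because the input may be
fractions rather than counts, zeros are handled with a pseudocount (default
$10^{-6}$, added before the log transform) rather than by posterior count
resampling alone; estimation round 1 uses the observed compositions, rounds
2..`nIterations` (default 20) Dirichlet-resample them at concentration
`resampleDepth` (default 1000, playing the role of a per-sample count
depth), and the reported matrix is the element-wise median. With
`nIterations = 1` the estimate is fully deterministic; that deterministic
path is also the one for which exact label equivariance holds, since
resampling noise attaches to row positions.

The network keeps an edge wherever $\rho_{ij} \ge 0.35$; negative
correlations are never used. Permutation p-values (each genome's sample
order shuffled independently, add-one estimator) are available through
`permutationPvalues()` and an optional `pMax` filter, but the filter is off
by default: the canonical construction thresholds the correlation only.
Genomes with no retained edge are dropped from the network (and logged);
entries absent from the input table are read as abundance zero.

## Topology

Node importance for overall connectivity is unweighted betweenness
centrality,

$$b(v) = \sum_{s \ne t \ne v} \frac{\sigma(s,t \mid v)}{\sigma(s,t)},$$

summed over unordered pairs; correlation weights are similarities, not path
lengths, so shortest paths ignore them. Network density is
$d = 2m / (n(n-1))$ and is reported alongside the mean degree $2m/n$ — the
two summarize the same edge set differently and both are emitted without
attempting to reconcile them into a single connectivity figure. Hubs are
delineated from the betweenness distribution; because no universal criterion
exists, both a `top_k` rule (default $k = \max(1, \mathrm{round}(0.07 n))$,
the hub fraction typical of bioreactor networks of ~120 nodes with 8 hubs)
and a `mean_plus_sd` rule are exposed, with ties broken by degree then node
id. Modules come from Louvain maximization of weighted modularity
(resolution 1, seeded tie-breaking) and can be cross-checked with
Girvan–Newman edge removal, selecting the cut of maximal weighted
modularity along the removal hierarchy; on well-separated module structure
the two agree (tested at adjusted Rand index $\ge 0.9$).

## Pathway calls and roles

A `PathwayCatalog` defines, per vitamin, an ordered list of stages, each a
set of alternative KOs; a stage is satisfied when the genome carries any of
its KOs. A pathway is `complete` when every stage is satisfied;
`near_complete` when the union of missing KOs lies entirely within the
catalog's exempt set; `absent` otherwise. For the shipped thiamine
definition — stages thiazole production, pyrimidine synthesis, moiety
linking, and the kinases, with exempt set {K03147 (thiC)} — this reduces to
the familiar tier rule: a genome lacking only thiC is near-complete. The
rule is monotone: adding a KO can only promote a status. The shipped catalog
covers thiamine, biotin, tetrahydrofolate, riboflavin, NAD and pantothenate;
the published KO tables behind such analyses live in supplementary material
rather than in any machine-readable registry, so the shipped lists follow
the standard KEGG biosynthesis steps and are deliberately user-editable
config (JSON), not code.

Role labels dichotomize each vitamin: `producer` = complete (by default
also near-complete, since near-complete genomes are conventionally counted
toward capability; the stricter `auxotroph` policy is one switch away) and
`auxotroph` = everything else. The genomic definition of auxotrophy — lacks
the pathway — is weaker than the physiological one (requires the compound
for growth), which cannot be decided from a genome; the labels should be
read accordingly. `vitaminCountVsSize()` relates synthesis breadth (number
of complete pathways; near-complete counting is optional and off) to genome
length in the bins {0–1, 2, 3, 4, 5–6} with pairwise Welch t-tests.

## The vitamin-hubness metric

For a producer $v$ with degree $D_{\mathrm{total}}$ and $N$
auxotroph-labeled neighbors,

$$h(v) = \frac{D_{\mathrm{total}}(v) \cdot D_{\mathrm{auxotroph}}(v)}
{\frac{1}{N} \sum_{a} D_{\mathrm{producer}}(a)},$$

where the sum runs over $v$'s auxotroph neighbors $a$ and
$D_{\mathrm{producer}}(a)$ counts producer-labeled nodes adjacent to $a$
anywhere in the network, $v$ itself included. Three conventions were open
and are fixed as follows:

* $N$ is the number of $v$'s auxotroph neighbors, so the denominator is the
  *mean* producer-degree over that set — this is the reading under which the
  score has interpretable magnitude (a node of degree ~10 whose dependents
  have no alternatives scores ~100, not ~$10^4$).
* $D_{\mathrm{producer}}(a)$ counts producers globally, not only within
  $v$'s module: an auxotroph with a producer neighbor in another module
  still has an alternative source.
* $N = 0 \Rightarrow h = 0$: a producer with no correlated auxotrophs has no
  provisioning evidence. Because $v$ counts toward every neighbor's producer
  links, the denominator is $\ge 1$ and $0 \le h \le D_{\mathrm{total}}
  \cdot D_{\mathrm{auxotroph}}$, with equality exactly when no auxotroph
  neighbor has an alternative producer.

The significance of an observed score is assessed against a
label-randomization null (`randomizationNull()`): producer labels are
redrawn uniformly at random with the observed producer count preserved, all
other nodes relabeled auxotroph, and the focal node's score recomputed,
1000 times by default. The focal node's own label under randomization is a
genuine ambiguity; the default `focal_forced_producer` policy keeps the
focal node in every drawn producer set (its score is then always
well-defined), while `free_relabel` draws the whole set freely and records
draws in which the score is undefined (focal unlabeled as producer and some
auxotroph neighbor without any producer neighbor) as $h = 0$, with a
counter, for sensitivity analysis. The null preserves the edge set — it
asks whether the *labeling* explains the score, not the topology, so it is
a label-permutation null rather than a degree-preserving rewiring null.

## The synthetic study

`simulateCommunity()` generates the study conditions the analysis assumes,
with ground truth: by default 120 genomes in 92 samples, four correlated
modules of 30 genomes, within-module basis correlation 0.7 on the log
scale, a planted hub in module 1 whose 8 dependent module-mates correlate
with it at 0.8, and 38 thiamine producers drawn outside the hub's module so
that the hub is its module's only producer — the provisioning phenotype
(a producer correlated almost exclusively with auxotrophs) the metric is
designed to flag. Latent log abundances are multivariate normal
($\mu = 0$, $\sigma = 1$) with that block correlation (verified positive
semidefinite, hard error otherwise), exponentiated, and observed through
per-sample multinomial sampling at depth $10^5$ — deep enough that counting
noise does not mask a 0.7 latent correlation at 92 samples. Producer
fractions for the other five vitamins (0.35–0.70) were chosen once as
plausible community-level prevalences of B-vitamin prototrophy; 10% of each
vitamin's producers (where the catalog allows it) are planted near-complete.
Genome lengths are $2.5\,\mathrm{Mbp} + 0.4\,\mathrm{Mbp} \times
(\text{pathways encoded})$ with 8% lognormal noise, so the breadth–size
association is recoverable but not deterministic. Two modules respond to
the sample conditions (a factor-2 abundance shift for the
planktonic/high-thiocyanate and planktonic/low-thiocyanate axes), giving
the stratified comparisons something to find. `simulateAnnotations()` emits
KO sets consistent with the planted roles under the shipped catalog, plus
decoy KOs, so the full pipeline can be validated end to end.

What the simulation does *not* emulate: temporal autocorrelation of a
reactor time series, strain-level variation within a genome bin, read-level
noise and binning error, unmapped-read mass (per-sample totals are exactly
1), and vitamin concentrations themselves. A pipeline that passes the
recovery tests is therefore validated for the statistical structure assumed
here — modular compositional abundances with a planted dependency hub — not
for every failure mode of real metagenomes.

## Numerical choices and test design

Edge cases are fixed as follows: correlations are clamped to $[-1, 1]$ and
matrices exactly symmetrized; zero-variance genomes correlate 0 with
everything (warning); the basis system requires $\ge 4$ genomes (hard
error below); a pair is not excluded from the basis system if that would
leave a genome with fewer than two partners; hub-score ties rank by more
auxotroph neighbors then node id; Welch tests return `NA` (not-computable)
when a group has fewer than 2 observations or is constant; the presence
threshold for frequency is 0 (any nonzero abundance); modularity of an
edgeless graph is 0 by convention; thiocyanate high/low is a user-supplied
label, not a concentration cutoff.

The test suite checks every metric against an independent oracle: a
simple-path-enumeration betweenness (exhaustive over all labeled graphs on
up to 5 nodes, sampled up to 8), an adjacency-matrix hub-score counter on
1000 random labeled graphs, exhaustive enumeration of all star labelings
for the null mean, and a stage-subset oracle for pathway tiers. End-to-end
recovery runs the default 120-genome study over 20 seeds and requires the
planted hub to rank first among the 38 producers in at least 18 of them,
with a null z-score above 1; these problem sizes keep the whole suite
around two minutes while leaving the per-seed statistics far from their
thresholds.

## Limitations

Correlation networks from relative abundances cannot distinguish direct
interaction from shared habitat preference, and a high hubness score is a
hypothesis generator, not a demonstration of cross-feeding — the natural
follow-up is isolation and co-culture. Pathway calls inherit annotation
error (a missed gene demotes a genome to auxotroph; transporter annotation
in particular is poor, so salvage routes are invisible). The null
randomizes labels only; a score driven purely by degree structure will also
stand out under label permutation and should be read together with the raw
components that `hubScore()` reports.
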
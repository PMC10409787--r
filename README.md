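# vitnet

Vitamin-informed microbial co-occurrence network analysis.

## What it does

Microbial communities are full of B-vitamin auxotrophs — organisms that
lack the biosynthetic pathway for a vitamin they need and must obtain it
from neighbors. `vitnet` turns genome-resolved metagenomic data into
testable cross-feeding hypotheses:

1. **Compositional correlation.** A SparCC-style basis-correlation
   estimator infers genome–genome association from relative abundances via
   log-ratio variances (invariant to per-sample totals), with iterative
   exclusion of strongly correlated pairs and optional permutation
   p-values.
2. **Co-occurrence network.** Edges are correlations ≥ 0.35 (positive
   only). Topology comes with unweighted betweenness centrality
   b(v) = Σ σ(s,t|v)/σ(s,t), density d = 2m/(n(n−1)), hub delineation, and
   Louvain / Girvan–Newman modules.
3. **Vitamin pathway calls.** Per-genome pathway completeness from KEGG
   ortholog (KO) sets against an editable JSON catalog of staged pathway
   definitions (shipped: thiamine, biotin, tetrahydrofolate, riboflavin,
   NAD, pantothenate). A thiamine pathway lacking only thiC (K03147) is
   called near-complete.
4. **Vitamin-hubness.** For a producer v with N auxotroph neighbors,

   ```
   h(v) = D_total(v) · D_auxotroph(v) / [ (1/N) Σ_a D_producer(a) ]
   ```

   where D_producer(a) counts producer-labeled nodes adjacent to auxotroph
   neighbor a. High h flags well-connected producers whose correlated
   auxotrophs have few alternative sources. A label-randomization null
   (producer count preserved, 1000 draws) yields mean, sd, z and an
   empirical p for any focal node.
5. **Ecology and simulation.** Condition-stratified (biofilm/planktonic,
   high/low thiocyanate) frequency and Welch-test comparisons, and a
   synthetic-community generator with planted correlation modules, a
   planted provisioning hub and ground truth for end-to-end validation.

Audience: microbial ecologists and bioinformaticians working with MAG
abundance tables (e.g. CoverM output) and KO annotations.

## Worked example

The score is easiest to read on a five-node graph: producer `v` is
correlated with auxotrophs `a1`–`a3` and producer `p1`; `a1` is also
correlated with `p1`.

```r
library(vitnet)
g <- igraph::graph_from_edgelist(cbind(
  c("v", "v", "v", "v", "a1"), c("a1", "a2", "a3", "p1", "p1")),
  directed = FALSE)
net <- CooccurrenceNetwork(
  igraph::set_edge_attr(g, "weight", value = 0.5), threshold = 0.35)
lab <- new("RoleLabels", vitamin = "thiamine", policy = "producer",
           roleVec = c(v = "producer", p1 = "producer", a1 = "auxotroph",
                       a2 = "auxotroph", a3 = "auxotroph"))
hubScore(net, lab, "v")
#> HubnessScore: v  h = 9.000  (degree = 4, auxotroph neighbors = 3, mean producer links = 1.333)
```

`v` has degree 4 and three auxotroph neighbors; those auxotrophs see on
average 4/3 producers (`a1` sees both `v` and `p1`), so
h = 4·3 / (4/3) = 9. `p1` scores 1 — its one auxotroph neighbor has an
alternative source.

The same machinery runs end to end on a simulated community:

```r
spec <- SyntheticSpec()                 # 120 genomes, 92 samples, 38 producers
sim  <- simulateCommunity(spec, seed = 1)
corr <- sparccCorrelations(sim$abundance, seed = 1)
net  <- buildNetwork(corr, threshold = 0.35)
lab  <- restrictRoles(
  new("RoleLabels", vitamin = "thiamine", policy = "producer",
      roleVec = sim$truth@rolesByVitamin$thiamine), net)
head(rankHubScores(net, lab), 3)
#> DataFrame with 3 rows and 5 columns
#>          node    dTotal dAuxotroph     denom     score
#>   <character> <integer>  <integer> <numeric> <numeric>
#> 1        G001        24         24         1    576.00
#> 2        G034        29         22         8     79.75
#> 3        G036        29         22         8     79.75
randomizationNull(net, lab, "G001", nSim = 1000, seed = 1)
#> NullDistribution (focal_forced_producer): focal G001, 1000 simulations
#>   observed h = 576.00, null mean = 48.84, sd = 17.41, z = 30.29, empirical p = 0.000999
```

The planted hub `G001` ranks first by a wide margin: all 24 of its
retained correlations are with auxotrophs whose only producer neighbor is
`G001` itself (denominator 1, so h collapses to 24 × 24), and its observed
score sits ~30 null standard deviations above the mean score obtained when
38 producers are assigned at random. `runPipeline()` chains
all stages and writes `report.json` plus per-stage TSVs.

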
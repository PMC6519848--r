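# regmetnet

Analysis of **integrated gene-regulatory / metabolic networks** in R.

Genome-scale reconstructions usually treat metabolism and gene regulation
separately, although most cellular programs — sugar uptake by the
phosphotransferase system, nucleotide supply, nitrogen starvation response —
run through both at once. When the two systems are merged into one directed,
typed graph (reactions, compounds, genes, and four protein classes; encoding,
reaction-association and regulation edges), a natural question is whether the
result is organised as two domains — a metabolic domain (MD) and a regulatory
domain (RD) — or as three, with an explicit **protein interface (PI)**
bridging them in a bow-tie-like architecture. `regmetnet` is for systems
biologists and network scientists who want to build such graphs (from
BioCyc-style flat files or GraphML), partition them, and quantify the
interface.

## What it computes

Let `G = (V, E)` be the directed typed graph. The package provides:

* **Functional partitions** MD–PI–RD and MD–RD: an iterative affiliation
  fixed point seeded from vertex biology (pure-compound reactions are
  metabolic; regulation-incident genes are regulatory; proteins with no
  regulatory involvement are metabolic) and propagated synchronously — a
  vertex pulled by both sides *is* interface. **Vertex-driven partitions**
  (types only) for comparison.
* **Partition quality**: inter-module edge fraction
  `c_D = external / (external + internal)` and Newman modularity
  `M = Σ_j [ L(M_j,M_j)/L_G − (deg(M_j)/2L_G)² ]` with per-module summands.
* **Vertex statistics**: degree centrality `DC(v) = k_in + k_out`, hubs
  (`DC > 50`), embeddedness `ξ_D(v) = k_v^intra / k_v`, unnormalized
  Brandes betweenness `BC(v) = Σ σ_st(v)/σ_st`, a random-subset betweenness
  null, and top-k rank reports with domain labels.
* **Domain-traversing paths**: complete enumeration of directed paths
  `u → v_1 → … → v_{k−1} → w` with endpoints in RD/MD (downwards) or MD/RD
  (upwards) and distinct interior vertices confined to PI; length
  histograms, per-vertex / pair / triple participation fractions, SCC
  containment, direct-link counts, and **regulatory–metabolic feedback
  loops** (upwards + downwards path pairs closed in both domains).
* **Reconstruction**: a reduced-fidelity parser for BioCyc attribute-value
  flat files (`regulation.dat`, `reactions.dat`, …) that validates vertex
  candidates, substitutes generic class terms, decodes aliases, splits
  reversible reactions, multiplies regulation per transcription-unit gene,
  and assembles the largest weakly connected component.
* **Synthetic data**: a seeded generator of grammar-respecting networks
  with planted domain labels (and matching miniature flat files), plus the
  hand-checkable 8-vertex fixture `toy8_graph()`.

## Worked example

The TOY-8 fixture wires the two canonical interface motifs — an enzyme
whose gene is regulated, and a metabolic transcription factor formed by
metabolite binding:

```r
library(regmetnet)
toy <- toy8_graph()
affiliate_functional(toy, 3)
#> <domain_partition> functional, 3 domains, 8 vertices
#>   MD=3, PI=3, RD=2
#>   unresolved at fixed point: 0
```

Genes `g1`, `g2` are regulatory; enzyme `p1`, apo-regulator `p2` and the
regulator–metabolite complex `pc1` form the interface; reaction `r1` and
compounds `c1`, `c2` are metabolic, and every vertex resolved without
ambiguity. The interface carries exactly one downwards path
(`g1 → p1 → r1`: regulated gene to catalysed reaction) and two upwards
paths (`c2 → pc1 → g1/g2`: effector metabolite to regulated gene), which
close into one regulatory–metabolic feedback loop:

```r
p3   <- affiliate_functional(toy, 3)
down <- enumerate_traversing_paths(toy, p3, "downwards")  # 1 path
up   <- enumerate_traversing_paths(toy, p3, "upwards")    # 2 paths
length(find_feedback_loops(toy, p3, up, down))            # 1
```

At scale, the `ecoli-like` synthetic preset (~780 vertices) reproduces the
qualitative architecture:

```r
sim <- generate_network(preset_params("ecoli-like", seed = 1))
p   <- affiliate_functional(sim$graph, 3)
modularity_partition(sim$graph, p)$total                  # 0.273 (vs 0.216 for MD-RD)
inter_module_edge_fraction(sim$graph, p)
#>   domain internal external       c_d
#> 1     MD      816      129 0.1365079
#> 2     PI       71      215 0.7517483
#> 3     RD      129      122 0.4860558
```

The three-domain modularity exceeds the two-domain one, and the interface
shows by far the highest inter-module edge fraction (0.75 against 0.14 and
0.49) — the signature of a bridging module rather than an entangled one.

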
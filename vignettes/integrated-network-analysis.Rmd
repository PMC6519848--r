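---
title: "Methods: partitioning and interface analysis of integrated regulatory–metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning and interface analysis of integrated regulatory-metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmetnet)
```

## The model

Cellular metabolism and gene regulation are usually reconstructed and
analysed separately, yet most cellular programs run through both: enzymes
couple genes to reactions, and metabolite-binding transcription factors
couple reactions back to genes. `regmetnet` works with an *integrated*
network in which both systems and their couplings are one directed, typed
graph:

* **seven vertex classes** — reaction, compound, gene, protein monomer,
  protein–protein complex, protein–compound complex, protein–RNA complex;
* **seven edge classes** — transcription- and translation-encoding, educt,
  product, catalysis, complex formation, and regulation (with mode +1
  activation, −1 inhibition, 0 combined);
* edge **logic** marks Boolean semantics: *conjunct* (all inputs required:
  reaction educts, complex subunits) versus *disjunct* (any input
  suffices: isoenzymes, products).

Reversible reactions are split into a forward vertex and a `_REV` twin
with swapped educt/product edges, so every reaction vertex has a single
direction. Compartments (`c`, `e`, `p`, `i`, `o`, `m`) annotate all
non-gene, non-reaction vertices.

The central question the package addresses is architectural: is the
integrated system best described as two domains — metabolic (MD) and
regulatory (RD) — or as three, with an explicit **protein interface (PI)**
bridging them? The package computes both *functional* partitions (from
the wiring) and *vertex-driven* partitions (from vertex types alone), in
two- and three-domain variants, and quantifies interface structure with
partition-aware graph statistics.

## The functional affiliation algorithm

`affiliate_functional()` assigns every vertex to MD, PI or RD by a
deterministic fixed-point computation.

**Seeds.**

* A reaction whose educts and products are all compounds is purely
  metabolic (MD); all-protein participation makes it a protein-conversion
  step and hence interface-related (PI); mixed participation is deferred.
* A gene is regulatory (RD) when it takes part in a regulation edge or
  encodes — directly or through complex assembly — a regulation source
  (a transcription-factor gene is a regulatory gene even when the factor
  acts only as a complex). All other genes are metabolic (MD).
* A protein with no *regulatory involvement* is metabolic. Involvement is
  a closure: a protein is involved if it touches a regulation edge, is
  encoded by a regulation-incident gene, or shares a complex-formation
  edge with an involved protein. This closure matters: an enzyme itself
  touches no regulation edge, but if its gene is regulated it belongs to
  the machinery that couples regulation to metabolism.
* A compound with no influential neighbours (below) defaults to MD —
  small molecules are metabolic by nature.

**Influential neighbours.** Deferred vertices resolve from a fixed,
declarative scope per vertex class (`influence_table()`): mixed reactions
wait on their protein educt/product participants; compounds look at the
reactions they take part in plus regulators targeting them (deliberately
*not* at complexes they bind into — being the ligand of a
transcription-factor complex does not make a metabolite an interface
element); proteins look at all non-regulation neighbours plus regulation
sources acting on them.

**Rounds.** Resolution proceeds in synchronous rounds: every deferred
vertex inspects the labels of its scope *from the previous round*, so the
fixed point cannot depend on vertex iteration order (verified by a
20-permutation test). A vertex whose scope agrees on MD or on RD adopts
that label. A vertex pulled by both MD and RD becomes PI — a conflicting
pull *is* the definition of an interface element, and since additional
labels cannot un-conflict it, this resolution fires as soon as the
conflict is certain. PI neighbours exert no directional pull. Labels are
written once and never change; a safety cap of |V| rounds guards the loop.

**Residual clusters.** Mutually deferred vertices (e.g. a complex waiting
on its subunits while the subunits wait on the complex) are resolved as
clusters at the round fixed point: the labels on the cluster's boundary
decide (one-sided boundary → that side; two-sided → PI for the whole
cluster). Clusters with *no* labelled boundary at all are genuinely
ambiguous: they are assigned PI and counted by `count_unresolved()`.
This separation — conflict-PI as a resolution, empty-boundary-PI as
ambiguity — is what makes the interface a positive finding rather than a
bucket of leftovers.

**Two-domain merge.** For the MD–RD scheme, PI vertices fall to the side
holding the majority of their non-regulation edges into domain-labelled
neighbours; ties and isolated interface vertices fall to RD (the
conservative choice: an unattached protein intermediate is treated as
part of the control system, not of material flow).

On the eight-vertex worked fixture the fixed point is reached in full:

```{r toy}
toy <- toy8_graph()
p3 <- affiliate_functional(toy, 3)
p3$labels
count_unresolved(toy)
```

## Partition quality and vertex statistics

* **Inter-module edge fraction** `c_D` = external / (external + internal)
  edges of domain *D*, direction ignored. A bridging interface shows a
  high `c_D` while the outer domains stay low.
* **Modularity** *M* is computed on the undirected simple view (each
  directed edge one link; reciprocal and parallel duplicates collapse,
  self-links drop): per module, internal links over total links minus the
  squared degree share. Per-module summands are reported alongside the
  total; the implementation is cross-checked against igraph's modularity
  in the tests.
* **Degree centrality** DC = in + out degree on the directed multigraph.
  **Hubs** are vertices with DC strictly greater than 50 (the threshold is
  a parameter; 50 is the conventional cut for this network family).
* **Embeddedness** ξ_D(v) is the fraction of a vertex's degree that stays
  inside domain *D* (its own domain by default). Zero-degree vertices are
  reported as missing, not zero. Across all domains the fractions sum to
  one per vertex — a tested invariant.
* **Betweenness centrality** is unnormalized Brandes betweenness over
  ordered vertex pairs, computed on the directed graph by default (the
  network *is* directed); an undirected option collapses the graph but
  keeps ordered-pair counting, so conventions stay comparable.
  `betweenness_null()` draws random vertex subsets of a given size and
  records mean BC per draw, the null model against which the interface's
  mean betweenness is placed (`null_quantile()`).

## Domain-traversing paths and feedback loops

A *traversing path* is a directed path whose endpoints lie in RD and MD
("downwards") or MD and RD ("upwards") and whose interior vertices are
pairwise distinct members of PI. Single RD–MD edges are *direct links*,
tallied separately by `count_direct_links()`; the minimum traversing-path
length is therefore 2 edges. Endpoints cannot repeat (they lie in
different domains), so traversing paths are simple overall.

Enumeration (`enumerate_traversing_paths()`) is a depth-first search
seeded at the boundary edges from the source domain into the interface,
extended only through unvisited interface vertices and closed at the
first successor in the target domain. It is complete, deterministic
(output sorted lexicographically by id sequence under C collation), and
guarded by a configurable path-count cap with a hard error — worst-case
enumeration is exponential even though realistic interfaces are thin.

`path_statistics()` summarises a path set: length histogram and the
fraction of paths whose interior contains each vertex, unordered pair and
unordered triple — the triple level is where dominant interface
subsystems become visible. `scc_containment()` reports the fraction of
paths fully inside a vertex set (typically the largest strongly connected
component).

`find_feedback_loops()` pairs upwards with downwards paths and keeps
pairs closed at both ends. Regulatory closure: the regulator ending the
upwards path is the gene starting the downwards path (`identity`), or
reaches it by a directed path inside RD of at most `rd_max_len` edges
(`path`; length 0 reduces to identity). Metabolic closure: a direct edge
from the downwards end to the upwards start (`edge`, the default, i.e.
path length 1) or a directed path inside MD of bounded length. The
paper-family phrase "a direct path" is ambiguous between these readings,
so both are exposed and both results should be reported when the bound
exceeds 1.

## The synthetic generator

`generate_network()` builds type-grammar-respecting networks with planted
ground-truth domains so that every stage of the pipeline is testable
without any database download. The default parameters describe a
~200-vertex miniature; the `ecoli-like` preset scales to ~780 vertices.
What it emulates:

* a compound/reaction core with a reversible fraction (split twins) and
  enzyme catalysis by monomers or disjoint-membership complexes;
* genes split between enzyme-encoding, transcription-factor and other
  roles; one monomer per gene;
* metabolic transcription factors active only as protein–compound
  complexes; pure factors regulating directly; optional protein–RNA
  regulator complexes;
* transcriptional regulation with a Pareto-tailed regulator out-degree
  (exponent 2 by default) mimicking global regulators — a documented
  default, not a claim about *E. coli*;
* sparse direct cross-domain regulation in both directions (factors
  acting on reaction activity; metabolites acting on genes) and
  allosteric-like compound-on-reaction inhibition.

Ground truth is planted by construction role (regulated genes and
regulator-encoding genes RD; enzymes of regulated genes, their complexes
and metabolite-bound regulator complexes PI; pure regulators RD;
everything else MD). Vertices whose wiring makes the intended role
ambiguous — regulators that end up with no realised target, proteins
recruited as connectivity bridges — are flagged, and recovery claims are
made only on unflagged vertices. Weak connectivity is enforced by minimal
grammar-respecting bridge edges (with mirrored edges on reversible
twins). Identical parameters and seed reproduce the identical graph.

What the generator does *not* emulate, hence what passing tests do not
show about real data: currency metabolites and the resulting degree
inflation, multi-compartment transport chains, the joint degree structure
of the deposited reconstruction, and — notably — the betweenness
enrichment of the interface (synthetic interfaces are thin and
peripheral, so their mean betweenness typically falls *below* the random
null, unlike the published network's).

`emit_flat_files()` writes any grammar-respecting graph as a miniature
BioCyc-dialect fixture directory such that `reconstruct_network()`
round-trips to a graph identical (ids and attributes) to its largest weak
component. The reduced dialect makes explicit choices where full database
semantics are out of scope: transcription units appear as multi-valued
`REGULATED-ENTITY` attributes (one line per gene, so regulation
"multiplies per gene" on reconstruction); complex composition lives in
`protcplxs.col`; double annotations are `ALIAS-OF` records; generic class
terms list their `MEMBERS` and are substituted away; RNA components
surface as synthesised `<gene>-RNA` accessions and reconstruct as
gene→complex transcription-encoding edges (an implementation-defined
choice pinned by fixture tests). Records without a compartment default to
the cytosol, logged per vertex; stoichiometry defaults to 0 where not
applicable; reactions outside periplasm / inner membrane / cytosol are
dropped with a report entry.

## Numerical and design choices

* All tie-breaks are deterministic and documented: component ties go to
  the component holding the lexicographically smallest id; ranking ties
  order by id; the two-domain merge ties to RD. String order is C
  collation (radix) everywhere, independent of locale.
* The affiliation iteration is synchronous specifically to buy
  order-independence; a sequential sweep would be faster but
  nondeterministic under reordering.
* Betweenness is directed by default and unnormalized; normalisation is
  presentation only.
* Modularity needs at least one link (the formula divides by the link
  count); an empty edge set is an error, not a zero.
* GraphML input/output keeps optional attributes optional (absent
  `<data>` elements rather than sentinel values), so round-trips are
  exact. The deposited-graph dialect maps attribute names through the
  versioned table `s1_key_map()` — in that dialect the stoichiometry
  attribute of regulation edges carries the regulation mode, and the
  two-domain affiliation is a 0/1 `metabolic` flag.
* Problem sizes in the test-suite were chosen so the whole suite runs in
  well under a minute: brute-force oracles (betweenness, components,
  Eq-2 path enumeration) run on 50 random graphs of 6–15 vertices per
  operation; label-recovery uses the ~200-vertex default at a fixed seed;
  the pipeline demonstrations use the ~780-vertex `ecoli-like` preset.

## Limitations

* The affiliation rule set reconstructs a procedure whose original is
  published only as algorithm figures; where the text underdetermines a
  rule (mixed-educt reactions, protein–RNA complexes, the two-domain
  merge) the package makes one documented choice and exposes the
  machinery — the per-class influence table, the trace, and the
  disagreement report against stored labels — to audit it rather than
  hide it.
* The flat-file parser is reduced-fidelity by design: promoters,
  terminators, sigma factors and attenuation are out of scope; unknown
  attributes pass through opaquely.
* Feedback-loop search is quadratic in the two path-set sizes; for large
  path sets pre-filter by endpoint.
* The deposited *E. coli* graph itself is an external artifact; analyses
  of it require a local copy (`REGMETNET_S1_FILE`), and the package's
  claims about it are limited to what its acceptance checks recompute.
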
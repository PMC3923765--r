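---
title: "Models and methods behind bionetviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bionetviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionetviz)
```

This vignette explains what the package computes and why it is built the
way it is: the hierarchical visualization model, the three-step rendering
pipeline and its incremental contract, the layout engines, the projection
framework, the flattening semantics behind the analysis algorithms, and
the synthetic generators used throughout the tests — including what those
generators do and do not emulate about real data.

## The hierarchical model

A drawable biological network mixes constructs with different semantics:

* **Entities** are the molecules (protein, gene, RNA, compound, plus
  complex/family/pathway used as entity kinds where a source file models
  them that way). Each carries external accessions (xrefs) and free-text
  subcellular-location terms.
* **Groups** are compound nodes: complexes, protein families, pathways,
  the auto-created co-factor satellites of a reaction, and radial "stars"
  (a degenerate group whose members orbit its first member, the hub, at
  layout time — a reading chosen because hub-plus-satellites is the one
  drawing that distinguishes a star from an ordinary group; it is isolated
  behind `add_star()` so the interpretation can be revised without
  touching anything else). The membership tree is unbounded in depth;
  cycles are rejected at construction, and each component has at most one
  parent.
* **Reaction hyperedges** hold substrates and products with
  stoichiometry, catalysts, a reversibility flag, and a subset of
  participants flagged as co-factors. Because a currency metabolite (ATP,
  NADH) participates in many reactions but a component can have only one
  parent, `add_reaction()` materialises co-factors as *alias instances*
  inside a per-reaction `reaction_cofactors` group: the same entity can
  orbit any number of reactions, the group can be collapsed to hide the
  clutter, and expanding it re-integrates the co-factors into the
  surrounding layout.
* **Alias instances** more generally let one entity appear in several
  pathway contexts; `merge_aliases()` folds them back, re-attaching edges
  and collapsing duplicates into multiplicity counts.

Collapse state is *not* destructive: collapsing a group only flips a flag
and marks the component topologically dirty; the re-attachment of member
edges to the group node (and the merging of parallel re-attached edges
into one aggregate edge carrying an integer multiplicity) happens when the
render topology is built. That makes expand trivially exact and the
collapse/expand round trip an identity by construction rather than by
bookkeeping. When aggregated member edges disagree on their relation type
the aggregate is labelled `generic` — the alternative (keeping an
arbitrary member's type) would assert a relation the drawing cannot
support.

### Property layers

Every visual attribute (label, shape, size, fill, stroke, line width,
font, visibility, plus the extended projection targets glyph and
compartments) resolves through four stacked layers:

```
built-in defaults < visual style < user override < data projection
```

The projection layer deliberately sits on top of user overrides: the
purpose of projecting data is to *see the data*, so it must not be
silently masked by an earlier manual colour choice; clearing the
projection restores the override exactly. The resolution is total — any
(component, property) query yields a value — which the tests assert for
every layer combination.

## The rendering pipeline and its incremental contract

Rendering is split into three steps — (1) topology construction, (2)
attribute assignment, (3) layout — because edits rarely invalidate all
three. Each model edit records per-component dirty flags of one of three
kinds. `incremental_update()` re-resolves attributes only for components
with visual dirt (leaving the step-1 result untouched), re-runs only the
layout step for layout dirt, and rebuilds everything on topological dirt.
Visibility changes are classified as topological even though `visible` is
a property, because they change *what exists* in the drawable graph.

The defining contract is behavioural, not structural: **an incremental
update must equal a from-scratch render**, deep-equality on nodes, edges
and bands. The test suite replays 1000 randomized edit scripts (style
changes, overrides, visibility toggles, collapses/expands, projection
set/clear) across both the force and layered engines and requires
equality after every single step. Dirty granularity is per component with
propagation to the outermost collapsed ancestor; for topological dirt the
affected subtree is rebuilt via a full step-1 pass — correctness first,
since step 1 is cheap relative to layout.

SVG emission sorts elements by id and formats all coordinates with two
decimals, so a fixed input and seed give byte-identical output — which is
also how the determinism invariants are tested. Reaction arrows are drawn
as quadratic Bézier paths (the textbook curved-arrow convention); glyph
nodes replace the node shape by a fixed 48×32 px bar or line chart with
min/max tick labels; aggregate edges print their multiplicity; and after
a layered run the compartment bands appear as labelled background strips.
Output validity is asserted by parsing (well-formed XML, `svg` root,
version 1.1) — no offline SVG DTD is assumed.

## Layouts

All engines share one convention: pixels, origin top-left, y growing
downward, node (x, y) at the centre, ties broken by lexicographic node id.

**Layered (Sugiyama).** Layers are *given*, not computed: the compartment
model maps location terms to an ordered list of cell layers
(extracellular at the top through nucleus at the bottom). A node with
several mapped terms takes the topmost layer — a membrane-associated
kinase is drawn at the membrane — and reports its ambiguity count; a node
with none falls to a configurable fallback (cytoplasm). Edges spanning
more than one band get dummy nodes; within-band order starts
lexicographic and is improved by barycenter sweeps, fixed at 8 (4 down, 4
up) — enough for desk-scale graphs and deterministic — keeping the best
ordering seen so the final crossing count never exceeds the initial one.
Band height grows to fit the tallest node, so strict band separation
(layer(u) < layer(v) ⇒ y(u) < y(v)) holds by construction.

**Force-directed.** A seeded Fruchterman–Reingold run (igraph's
implementation under a fixed RNG seed) rescaled to an ideal edge length
of 80 px, followed by the package's co-factor pass: per reaction, the
flow direction is the vector from the mean position of its inputs to the
mean of its outputs; consumed co-factors are re-placed on a 90° arc on
the incoming side, produced ones on the outgoing side, at the configured
orbit radius (default 40 px). A final minimum-separation pass pushes
overlapping node bodies apart along the axis of least penetration,
visiting pairs in id order. The pass is vectorised but still quadratic in
node count, so it is skipped above 1200 nodes: a 100,000-edge hairball is
an overview drawing, and node-body separation is meaningless at that
scale anyway.

**KEGG.** Hinted nodes take their KGML coordinates verbatim — treated as
top-left-anchored pixel coordinates with y increasing downward, matching
KEGG maps — and are never moved afterwards (the separation pass only
moves un-hinted nodes, which are force-placed and clamped into the hinted
bounding box). KGML carries no edge routes, so the layouter computes
them: straight segments, replaced by a 2-bend orthogonal route (x-first
or y-first, then a bounded offset search) whenever the straight segment
would pass through a third node's body, tested by Liang–Barsky clipping.
With no hints at all the engine falls back to force layout with a
warning.

## Projection

A series is a numeric matrix with identifier-*sets* per row (one
measurement may carry several accessions) and named sample groups
(replicate structure, time points). Rows match entities whose id or
xrefs intersect the row's identifiers, case-sensitively and exactly —
ambiguity-free and testable; fuzzy matching belongs in the id-mapping
table, which is applied first and may be many-to-many.

Selected samples are averaged per row over non-missing values (a row
missing everywhere stays missing); a formula may derive a temporary
sample instead. The evaluator parses the formula with R's own parser but
whitelists tokens: only sample names, numeric literals, the arithmetic
operators, and the built-ins mean/log2/log10/abs/min/max/zscore (zscore
normalising over the rows of its argument) are allowed, so an unknown
token is a parse error naming it rather than an arbitrary code path.
`register_sample_function()` is the hook through which an external
statistical backend can add functions. Division by zero and domain
errors become missing values with a warning. The cross-operation
equivalence `derive_sample("mean(…)") ≡ mean_sample(…)` is asserted on
random series.

Scales: the colour scale interpolates linearly per RGB channel between
three anchors, default blue `#0000FF` – white – red `#FF0000` symmetric
about 0 — the conventional down/neutral/up diverging palette; anchors are
exact and channels monotone between them. Values outside the domain
clamp. Unmapped entities follow the spec's missing policy, defaulting to
*default appearance* (an absent measurement should not invent a colour).
Several rows mapping to one entity are averaged before scaling, matching
the multi-sample convention. Ambiguity colouring uses red/rose
(`#FFC0CB`)/white for one/several/no location annotations; the exact hues
are arguments, since only the colour names are conventional. A signed
value bound to the reaction-direction target flips the rendered direction
of *reversible* reactions only — an irreversible reaction's direction is
a fact about chemistry, not a display choice.

## Flattening and analysis

Classical graph algorithms are not valid on a compound graph with
hyperedges and aliases, so analyses run on an explicit flattening whose
policy has **no implicit defaults at call sites**: families split into
members (each inheriting every family edge) or fold to one node;
complexes fold, star to their members, or expand to a binding clique
(emitted as two directed edges per pair — an approximation, documented as
such); reactions stay bipartite or become substrate→product edges with
the reaction recorded in the edge origin; aliases merge or stay; and
co-factors can be dropped, since paths through ATP are rarely the paths a
biologist means. Undirected edges become two directed edges; parallels
fold their multiplicity into the edge weight. Every flat node and edge
carries an invertible origin map back to model components, and a
fingerprint of the model guards against back-projecting onto an edited
model (a staleness error rather than silently wrong highlights).

`k_shortest_paths()` is Yen's algorithm over a deterministic Dijkstra,
with one refinement for exactness under ties: candidates are popped by
(weight, hops, lexicographic sequence), extraction continues until the
next candidate is strictly heavier than the k-th accepted path, and the
accepted set is finally sorted by the full key and truncated — so the
result equals exhaustive simple-path enumeration under the same ordering,
which the suite verifies on 500 random graphs of up to 8 nodes. BFS hop
distances come from igraph on the flat graph (directed by default, with
an undirected option, since interaction sources disagree on direction
semantics) and are checked against unit-weight Dijkstra. Path results
back-project as a single highlight colour on every origin component —
both a family member on the path and its family group light up — and
distance maps through a sequential scale, darkest at distance 0.

## Synthetic generators, and what passing tests do not show

All fixtures are generated in code, deterministic per seed, and emitted
in exactly the dialects the readers parse:

* `gen_ppi_sif()` grows a connected preferential-attachment graph with an
  exact edge count — the heavy-tailed, connected shape of large PPI data
  sets. The scale tests use 20,000 proteins and 100,000 interactions.
* `gen_metabolic_kgml()` emits a chain-with-branches pathway on an 80-px
  grid with an ATP/ADP-like currency pair on every third reaction and a
  side list naming it, so co-factor strategies are exercised end to end.
* `gen_regulatory_model()` emulates a signalling cascade: ~25% receptors
  (plasma membrane), ~50% kinases (cytoplasm), ~25% transcription factors
  (nucleus), edges oriented membrane→nucleus; 10% of entities get a
  second location term and 10% none, covering the red/rose/white
  annotation cases.
* `gen_omics_series()` draws log-normal baselines (meanlog 3, sdlog 0.8),
  applies a log2 effect ramping linearly across groups to a 20% subset of
  rows, multiplies log-normal replicate noise (sd 0.15), and blanks 5% of
  cells; a truth table records each row's effect. These rates are fixed
  generator defaults chosen as ordinary magnitudes for a designed
  time-course experiment.

What these generators do **not** emulate: real identifier messiness
(synonyms, versioned accessions, cross-species mappings), correlated
missingness and batch effects in omics data, hub-specific degree
corrections of curated interactomes, or the irregular hand-tuned
geometry of curated KEGG maps. Tests passing on these fixtures therefore
demonstrate the machinery — parsing, layering, layout invariants,
algorithmic correctness, round-trip fidelity — not biological validity of
any particular drawing.

## Numerical and engineering choices

* Determinism everywhere: lexicographic tie-breaks, fixed sweep counts,
  seeded force iterations, two-decimal SVG coordinates, id-sorted
  emission. Identical input and seed give byte-identical SVG.
* Degenerate inputs: empty models render valid empty SVG; single nodes
  centre in their band; graphs with no edges lay out on a seeded scatter;
  an unreachable path query returns an empty list, not an error.
* The project JSON writer serialises doubles at 17 significant digits so
  the save/load round trip is bit-lossless.
* Problem sizes in the routine suite are desk-scale (tens of nodes,
  hundreds of cases) with one full-scale run at 100,000 edges and a
  30-iteration force smoke pass at that size; the acceptance script uses
  the same sizes.
* Out of scope by design: interactive editing and GUI concerns, BioPAX,
  full SBML (rules, events), live database or web-service access, raster
  export (standard SVG converters do this), and statistical normalisation
  methods themselves — the formula evaluator's registration hook is the
  seam where an external engine plugs in.
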
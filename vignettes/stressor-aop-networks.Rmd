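---
title: "Building stressor-centric AOP networks from toxicogenomic evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building stressor-centric AOP networks from toxicogenomic evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressorAOP)
```

## The problem

Adverse outcome pathways (AOPs) organize toxicological knowledge as a
directed chain of key events (KEs): a molecular initiating event (MIE) —
the chemical's first biological interaction — propagates through
intermediate KEs at increasing levels of biological organization until it
reaches an adverse outcome (AO) of regulatory relevance. Directed,
evidence-graded links between KEs are key event relationships (KERs).
AOPs are authored stressor-agnostically, so connecting a chemical of
interest to the AOPs it can plausibly perturb requires independent
evidence that the chemical affects specific KEs.

`stressorAOP` implements that connection end to end: it curates
high-confidence AOPs from an AOP-Wiki XML release, derives
chemical-to-KE associations from five heterogeneous evidence channels,
and assembles a bipartite *stressor–AOP network* in which each link
carries a quantitative coverage score and a qualitative five-level
relevance class. Downstream analytics (AOP projection graphs, directed KE
union networks, centrality, cumulative weight of evidence) support
per-chemical interpretation.

## High-confidence AOP curation

AOP-Wiki entries are living documents of very uneven completeness. The
filter in `filterHighConfidence()` accepts an AOP only if, in order:

1. its SAAOP status is not *archived*;
2. no member KE is titled "unknown" (whole-title, case-insensitive
   match — a title merely *containing* the word is not a defect), and it
   has at least one KE and one KER;
3. the KER graph over its KE set is **weakly connected** and covers every
   listed KE — an isolated KE counts as a disconnected component;
4. it has at least one MIE, at least one AO, and a **directed path** from
   some MIE to some AO over its KERs.

The first failing rule becomes the rejection reason, so accepted and
rejected AOPs partition the release and the decision is independent of
input order. Two genuinely open readings are settled as follows. The path
check uses *all* KERs, adjacent and non-adjacent, because the source
workflow extracts adjacency but states no restriction; `pathEdges =
"adjacent"` exposes the stricter mode. Empty KE titles are not treated as
"unknown" (they fall under rule 2's missing-KE arm only when the KE list
itself is empty). Manual curation steps that cannot be computed are
represented by an explicit override table (`force_accept` /
`force_reject` with a note), keeping the workflow reproducible while
admitting expert judgment.

## Evidence channels

Five channels produce `(chemical, KE)` associations; their union, keyed
by the pair with every evidence record retained, is the association
table. Chemical identifiers are canonicalized first
(`normalizeCas()`), resolving superseded CAS registry numbers
transitively and failing loudly on cycles.

**Assay channel (`toxcastChannel()`).** High-throughput screening hit
calls are kept when the winning-model hit call satisfies `hitc >= 0.9`
(inclusive, as published); the sign of the winning model's `top`
parameter labels the response activatory or inhibitory — metadata that is
carried but never used in scoring. Activity near a chemical's cytotoxic
concentration range is non-specific, so each hit receives a
cytotoxicity-burst Z-score

$$Z = \frac{-\log AC_{50}(\text{chem, assay}) -
\operatorname{median}[-\log AC_{50}(\text{chem, cytotox})]}
{\text{global cytotoxicity MAD}}$$

and hits with $-3 < Z < 3$ are discarded as bursts. The interval is
open: "lying between" is read strictly, so $Z = \pm 3$ exactly is kept
as target-specific. A chemical lacking a cytotoxicity profile cannot be
evidence of a burst, so its hits are kept with a warning. Surviving
endpoints map to KEs by gene-set overlap (case-insensitive symbols, no
orthology expansion), restricted to KEs at the molecular or cellular
level, and then filtered by a curated endpoint-to-KE whitelist — the
reproducible stand-in for manual review of assay descriptions. An empty
whitelist retains all candidates, with a prominent warning.

**CTD-like channels (`buildCgpdTetramers()`, `mapCtdToKes()`).**
Chemical–gene–phenotype–disease (CGPD) tetramers are the four-way join of
pairwise association tables: curated chemical–gene, curated
chemical–phenotype, direct-evidence chemical–disease, direct-evidence
gene–disease. The exact evidence requirements live in prior curation
practice, so each table's flag requirement is configurable. Tetramer
phenotypes (GO terms) are expanded to their immediate ontology
neighborhood — the term, its direct parents and direct children over
`is_a` and `part_of` edges (whether the published expansion included
`part_of` is not stated; it is on by default and switchable) — and
matched against KE process annotations, gated by a curated
phenotype-to-KE whitelist. Tetramer diseases map to KEs through a curated
disease-to-KE table.

**Curated endpoint channels (`mapCuratedEndpoints()`).** Endocrine and
neurotoxicity endpoint resources contribute associations through
two-column endpoint-to-KE maps; unmapped endpoints are counted so the
funnel is auditable.

**Stressor channel (`aopwikiStressorChannel()`).** When the release
itself documents a chemical as a stressor of an AOP, the chemical is
associated with every KE of that AOP.

## The bipartite network

`buildNetwork()` links a chemical to every accepted AOP with which it
shares at least one associated KE. Each link carries:

* **coverage** — shared KEs divided by the AOP's total KE count (MIEs and
  AOs included in the denominator), in $(0, 1]$; and
* **relevance level**, evaluated top-down so the five levels are mutually
  exclusive and exhaustive:
  5 — an associated MIE reaches an associated AO by a directed path over
  the AOP's KERs (the path may traverse unassociated KEs; its endpoints
  must be associated);
  4 — associated MIE and AO, but no such path;
  3 — associated MIE, no associated AO;
  2 — associated AO, no associated MIE;
  1 — only intermediate KEs associated.

The top-down reading resolves the textual ambiguity in the level
definitions: a link satisfying the level-2 wording might also satisfy
level 1's, but each link receives exactly one label, the highest that
applies. `filterLinks()` applies inclusive thresholds (the defaults,
level 5 and coverage 0.4, select "highly relevant" links — at least 40%
of the AOP's KEs covered). Sector membership for chemicals and disease
classes for AOPs are table-driven inputs: their content comes from
external compilations that are not computable here, but their structure
is reproducible and replaceable.

## Per-stressor analytics

`buildAopProjection()` joins two AOPs when they share a KE and reports
connected components (size-sorted, ties broken by the lexicographically
smallest id set, for determinism). `buildKeUnionGraph()` unions the KEs
and KERs of a component; a KE that is an MIE in one member and an AO in
another takes the MIE role (figures depict one role per node; conflicts
are logged). `centralityReport()` computes in/out-degree and betweenness
on the directed graph — raw, unnormalized path counts with endpoints
excluded, the variant that is directly checkable against brute-force
enumeration; rankings are unaffected by normalization — and eccentricity
on the undirected projection within each node's component, because
directed eccentricity is undefined when pairs are mutually unreachable,
which KER graphs routinely are.

Cumulative weight of evidence for an AOP aggregates its KERs' evidence
grades. The published rule lives in earlier work and is not fully
specified, so the default here encodes High = 3, Moderate = 2, Low = 1
(unspecified ignored) and bins the mean at 2.5 and 1.5; a weakest-link
(`min`) rule and a majority rule are provided as alternatives, and all
three are permutation-invariant. All-unspecified KER sets yield
*undetermined*.

## The synthetic world generator

`generateWorld()` writes every input the pipeline consumes — a miniature
AOP-Wiki-dialect XML, assay hit and cytotoxicity tables, CTD-like
association tables, a GO subset in OBO format, curated maps, sector and
disease tables — plus a manifest of the planted truth. One integer seed
drives the whole world, so identical seeds give byte-identical files.

Defaults define the study conditions for testing: 12 AOPs of 4 chain KEs
each, 15 chemicals, one planted defect of each kind (archived,
unknown-titled KE, disconnected component, no MIE-to-AO path), planted
links at counts L1=3, L2=2, L3=2, L4=1, L5=2 plus one full-coverage
stressor-channel link, and a planted burst. These sizes keep a full
generate-and-recover cycle under a second while exercising every rule at
least once; recovery tests run 50 such worlds. Design choices worth
noting:

* **Level-4 plants.** A level-4 link needs an associated MIE and AO with
  no directed path between them, inside an AOP that still passes the
  filter. The generator builds a dedicated five-node structure
  (`M1 -> K -> A1` as the accepted backbone, `M2 -> K` joining in, `A2`
  hanging off `M1`) and associates the chemical with `{M2, A2}`: no
  route, yet the AOP is accepted via `M1 -> K -> A1`.
* **Private KEs.** Each AOP's KEs are unique to it, so a planted
  association produces exactly one link and the manifest is exact.
  Consequently generated projection graphs are edgeless; shared-KE
  analytics are tested on purpose-built fixtures instead. This is the
  main respect in which the generator is *less* real than AOP-Wiki,
  where KE reuse is pervasive — recovery tests therefore validate the
  scoring logic, not the combinatorics of heavily overlapping releases.
* **Burst margin.** Planted Z-scores keep at least 0.5 from the
  $\pm 3$ boundary in both directions, so recovery never hinges on
  boundary semantics — those are pinned by their own unit tests.
* **Realism limits.** AC50 values are placed to realize chosen Z-scores,
  not drawn from realistic potency distributions; CTD evidence
  vocabularies are reduced to `curated`/`direct` flags; gene symbols are
  synthetic. Passing recovery tests demonstrates correct plumbing and
  scoring under controlled truth, not performance on real releases.

## Numerical and degenerate-input choices

Thresholds are inclusive where the source says "at least" (`hitc`,
level, coverage) and exclusive where it says "between" (burst interval).
Coverage denominators count unique KEs. All tabular outputs are sorted
(chemical, AOP id, KE id) before writing, making reruns byte-identical
and diffs meaningful. Empty inputs degrade explicitly: empty whitelists
warn; a missing cytotoxicity profile warns and keeps the hit; a
single-node graph reports zero for every centrality; an empty AOP KE set
cannot occur after filtering and is an error if forced.

## A worked run

```{r, eval = FALSE}
w <- generateWorld(worldConfig(seed = 1), dir = tempfile())
res <- runPipeline(w)
res$network
#> StressorAopNetwork: 11 links between 6 chemicals and 5 AOPs
#>   links per relevance level: L1=3 L2=2 L3=2 L4=1 L5=3
summarizeNetwork(res$network, by = "level")
links(filterLinks(res$network, minLevel = 5, minCoverage = 0.4))
```

The same stages are scriptable from a shell through the thin wrapper in
`inst/scripts/aopnet.R` (`simulate`, `ingest`, `associate`, `network`,
`analyze`, `report`), which adds run manifests with configuration hashes
and input checksums.

## Known limitations

Reproducing published network counts requires the original curated
inputs (the AOP-Wiki release of 1 January 2024 and the published
association tables); the package ships loaders (`loadCuratedRelease()`,
`loadAssociationTable()`) but not the data. Manual curation steps —
endpoint whitelists, disease mappings, sector membership — are consumed
as tables, so results are only as good as the supplied curation. The
GO expansion is a single-step neighborhood, not a semantic-similarity
measure. Direction labels (activatory/inhibitory) are recorded but do
not influence scoring, mirroring the published workflow.
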
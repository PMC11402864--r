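# stressorAOP

Stressor-centric adverse outcome pathway (AOP) networks from
heterogeneous toxicogenomic evidence.

Chemical risk assessors increasingly organize mechanistic knowledge as
AOPs: directed chains in which a molecular initiating event (MIE)
propagates through key events (KEs) to an adverse outcome (AO), with
directed, evidence-graded key event relationships (KERs) between them.
AOPs are written without reference to any particular chemical, so linking
a stressor — here, typically a plastic additive identified by its CAS
registry number — to the AOPs it can perturb requires independent
evidence that the chemical affects specific KEs. `stressorAOP` builds
that bridge as a reproducible pipeline:

1. **Ingest** an AOP-Wiki XML release into typed records and keep only
   *high-confidence* AOPs: not archived, no KE titled "unknown", at
   least one KE and KER, a weakly connected KER graph covering every
   listed KE, and a directed MIE-to-AO path. The first failing rule is
   the recorded rejection reason.
2. **Associate** chemicals with KEs through five evidence channels:
   high-throughput assay hit calls (`hitc >= 0.9`, response direction
   from the winning model's `top` sign) with cytotoxicity-burst
   filtering by the Z-score

   *Z* = (−log AC₅₀(chem, assay) − median[−log AC₅₀(chem, cytotox)]) / global cytotoxicity MAD,

   discarding hits with −3 < *Z* < 3; chemical–gene–phenotype–disease
   (CGPD) tetramers joined from curated/direct-evidence association
   tables, mapped to KEs via immediate-neighbor GO expansion and curated
   whitelists; two curated endpoint resources (endocrine, neurotoxicity);
   and stressors documented in AOP-Wiki itself.
3. **Network**: a bipartite stressor–AOP graph linking a chemical to
   every accepted AOP sharing at least one associated KE. Each link
   carries a *coverage score* (fraction of the AOP's KEs associated, in
   (0, 1]) and a *relevance level* 1–5 — level 5 means an associated MIE
   reaches an associated AO along the AOP's KERs. "Highly relevant"
   links satisfy level 5 and coverage ≥ 0.4.
4. **Analyze** per stressor: undirected AOP–AOP projections (edges =
   shared KEs), directed KE/KER union networks of components, in/out
   degree, betweenness, eccentricity, and cumulative weight-of-evidence
   labels aggregated from KER evidence grades.

A seeded synthetic-data generator emits every input the pipeline reads,
together with a ground-truth manifest of planted filter defects,
cytotoxicity bursts and link levels, so the entire pipeline is testable
offline, end to end.

## A worked example

```r
library(stressorAOP)

w   <- generateWorld(worldConfig(seed = 1), dir = tempfile())
res <- runPipeline(w)
res$network
#> StressorAopNetwork: 11 links between 6 chemicals and 5 AOPs
#>   links per relevance level: L1=3 L2=2 L3=2 L4=1 L5=3

res$counters[c("aops_parsed", "aops_accepted", "bursts_discarded")]
#>      aops_parsed    aops_accepted bursts_discarded
#>               12                8                2

links(filterLinks(res$network, minLevel = 5, minCoverage = 0.4))[, 1:5]
#>   chemical aop_id n_shared coverage level
#> 1 128-22-4  AOP:7        2      0.5     5
#> 2 135-25-5  AOP:8        2      0.5     5
#> 3 205-55-5  AOP:6        4      1.0     5
```

Twelve synthetic AOPs were parsed; four were rejected (one archived, one
with an "unknown" KE title, one disconnected, one without an MIE-to-AO
path) and two planted cytotoxicity bursts were discarded before KE
mapping. Of the eleven stressor–AOP links, three are highly relevant at
the default thresholds; chemical `205-55-5` covers all four KEs of
`AOP:6` (coverage 1.0) because AOP-Wiki documents it as that AOP's
stressor. The link table, the per-level/sector/disease summaries
(`summarizeNetwork()`), and GraphML/SIF exports (`exportNetwork()`) are
Cytoscape-ready.

The same stages run from a shell via the thin wrapper script:

```sh
Rscript inst/scripts/aopnet.R simulate --seed 7 --out-dir world
Rscript inst/scripts/aopnet.R network  --world-dir world --out-dir out
Rscript inst/scripts/aopnet.R report   --world-dir world --out-dir out
```

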
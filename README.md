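# pgxvis

Graph-based visualization of pharmacogenomic (PGx) plausibility-check
reports, for the people who have to act on them at prescribing time.

## The problem

Clinical decision support systems can already screen a prescription against
a patient's pharmacogene diplotypes and emit evidence-based dosing
guidelines (PharmGKB, DPWG). The output is prose, one paragraph per
drug–gene pair — and because the enzymes of a metabolic pathway vary
independently, those paragraphs can contradict each other: a CYP2D6 poor
metabolizer (PM) guideline may say *lower the dose to 70 % of standard*
while a CYP2C19 ultrarapid metabolizer (UM) guideline for the same drug
says *avoid it altogether*. pgxvis renders the drug's metabolism pathway as
a directed network, attaches each guideline to the enzyme it concerns,
encodes the metabolizer phenotype as a node symbol (PM ↓, IM ↘, NM →,
UM ↑, variant-without-status ○), and flags diverging recommendation
categories explicitly, so the shape of the problem is visible at a glance.

Core model, in brief: a pathway is a set of reactions
*substrate → product* with catalyst genes; `buildGraph()` interposes one
enzyme node per (gene, reaction) incidence (a gene in *m* reactions appears
*m* times, keeping the drawing a chain instead of a hub-cluster), attaches
guidelines keyed by gene symbol, and computes a contradiction report: two
guidelines conflict iff their categories are distinct members of
{`increase_dose`, `decrease_dose`, `avoid`}. A deterministic spring
embedder (edge springs of rest length *k* plus soft-core pairwise repulsion
of radius *k*; two connected nodes equilibrate at distance exactly *k*)
lays the graph out as a pure function of `(graph, seed)`.

## Worked example

The package ships a complete clomipramine case (pathway TSV + patient
report JSON under `inst/extdata/`):

```r
library(pgxvis)

we <- makeWorkedExample()
we$pathway
#> Pathway for clomipramine: 6 entities, 5 reactions
we$record
#> PatientRecord: John Doe (male, 54 y)
#>   2 prescription(s), 3 variant call(s), 3 guideline(s)

g <- buildGraph(we$pathway,
                matchGuidelines(we$record, "clomipramine"),
                variantCalls(we$record))
g
#> AnnotatedGraph for clomipramine: 13 nodes (7 gene), 14 edges
#>   1 contradictory guideline pair(s), 2 varying categories

subset(graphNodes(g), role == "gene",
       c(node_id, label, occurrence, symbol))
#>           node_id   label occurrence                   symbol
#> 7   CYP1A2#rxn001  CYP1A2          1                    plain
#> 8  CYP2C19#rxn001 CYP2C19          1              arrow_up_um
#> 9   CYP3A4#rxn001  CYP3A4          1 circle_variant_no_status
#> 10  CYP2D6#rxn002  CYP2D6          1            arrow_down_pm
#> 11  CYP2D6#rxn003  CYP2D6          2            arrow_down_pm
#> 12 CYP2C19#rxn004 CYP2C19          2              arrow_up_um
#> 13 UGT2B10#rxn005 UGT2B10          1                    plain

conflictPairs(contradictions(g))
#>   guideline_id_1 guideline_id_2    category_1 category_2
#> 1            gl1            gl2 decrease_dose      avoid
```

Reading the output: the demethylation step is mediated by three enzymes
(CYP1A2, CYP2C19, CYP3A4, all suffixed `#rxn001`); CYP2D6 catalyzes two
hydroxylation steps and is therefore duplicated, both nodes drawn as the PM
down-arrow; CYP3A4 has a variant call but no metabolizer status (circle
symbol); and the patient's two clomipramine guidelines point in opposite
directions — the `decrease_dose` vs `avoid` pair in the contradiction
report, which the rendered document shows as a banner.

Render and export:

```r
lay <- forceLayout(g, seed = 1)
renderDocument(g, we$record, lay, file = "clomipramine_report.html")
renderSvg(g, lay, file = "clomipramine_pathway.svg")
exportGraph(g, "clomipramine.graphml", "graphml")
```

Or from a shell, via the installed CLI wrapper
(`system.file("scripts", "pgxvis", package = "pgxvis")`):

```sh
pgxvis demo --out demo_dir
pgxvis render --pathway pathway.tsv --report report.json \
       --drug clomipramine --format html --out report.html
pgxvis validate --pathway pathway.tsv --report report.json
```

Exit codes: 0 success, 1 domain error (e.g. drug not in the report, with
the available drugs listed), 2 I/O or parse failure.

Synthetic cases for experimentation come from the seeded generator:

```r
case <- generateCase(syntheticSpec(seed = 1, nMetabolites = 6, nGenes = 4))
```

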
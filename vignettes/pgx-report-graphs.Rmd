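---
title: "Visualizing pharmacogenomic check reports as annotated pathway graphs"
author: "pgxvis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing pharmacogenomic check reports as annotated pathway graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxvis)
```

## The problem

Polymorphic drug-metabolizing enzymes (most prominently the cytochrome P450
family) change how fast a patient clears a drug. A *poor metabolizer* (PM)
diplotype of an enzyme leaves more active drug in the blood — a risk of side
effects or overdose — while an *ultrarapid metabolizer* (UM) can clear the
drug so fast that therapy fails. Evidence-based dosing guidelines (PharmGKB,
DPWG) exist per drug–gene-variant pair, and rule-based medication-check
systems already emit them as text during prescribing. The practical problem
is volume and shape: a single prescription can trigger several guidelines,
the enzymes are independent of each other, and the recommendations can
genuinely contradict (one enzyme says "lower the dose", another says "avoid
the drug"). Reading that off a stack of prose paragraphs is slow and
error-prone.

pgxvis turns one drug's check report into a picture: the drug's metabolism
pathway as a directed network, with the patient's enzyme phenotypes drawn
as symbols on the enzyme nodes and diverging recommendations flagged
explicitly.

## Inputs and their quirks

Two inputs drive everything:

1. **A pathway table** (tab-separated, one reaction per row: substrate,
   product, reaction type, controller genes) in the dialect used by curated
   pathway resources. These tables do not follow one rigid schema, so the
   parser is deliberately lenient: headers are matched case- and
   punctuation-insensitively under synonym sets
   ({From, Source, Substrate}, {To, Target, Product},
   {Controller, Genes, Enzymes}, {Reaction Type, Type}), columns may appear
   in any order, and multi-enzyme cells are split on commas or semicolons.
   Rows that share substrate, product and reaction type are merged into one
   reaction with the union of their catalysts — one metabolic step drawn
   once, even if the source lists each enzyme on its own row. The merge key
   includes the reaction type on purpose: a transport row between the same
   two chemicals is a different relationship than a biochemical one and must
   not be absorbed into it. Unrecognized reaction types (inhibition,
   transport, complex assembly) are retained as `other` and later drawn with
   dashed edges rather than silently dropped. Rows missing a substrate or
   product are rejected into an issue table, never a crash, and every input
   row is accounted for either as (part of) a reaction or as an issue.

2. **A patient report document** (JSON; schema shipped at
   `inst/schema/patient-report.schema.json`) with demographics,
   prescriptions, star-allele diplotype calls, and one guideline entry per
   drug–gene pair: metabolizer status, recommendation text and category,
   severity, evidence level, source URL, effect text. Sources use two status
   vocabularies (PM/IM/NM/UM vs. "poor metabolizer", with NM and the older
   "extensive metabolizer" treated as the same phenotype), so statuses are
   normalized through an explicit synonym table that is total over its
   domain and raises on anything outside it; the parser catches that and
   degrades to `UNKNOWN` with a warning issue. Recommendation categories are
   normalized onto a closed set (`increase_dose`, `decrease_dose`, `avoid`,
   `standard`, `other`) because the contradiction logic needs a finite
   alphabet; the verbatim label is kept alongside. A percentage quoted in
   the recommendation text ("lower the dose to 70 percent ...") is parsed
   into a numeric `dose_percent` so the headline number of a guideline is
   machine-readable. CAS registry numbers are validated by their check
   digit; a failure is a warning, not an error, since upstream data quality
   varies. Brand names are resolved through a small explicit alias table
   (shipped with `anafranil → clomipramine`) rather than any external
   service — determinism over coverage.

Severity uses three levels (1 = informational, 2 = warning, 3 = critical),
matching the alert tiers typical of clinical decision support systems.

## The graph model

`buildGraph()` joins the two inputs. Enzymes are *interposed as nodes* on
the substrate → product path: a reaction with three catalysts becomes three
parallel substrate → enzyme → product chains. Crucially, a gene that
catalyzes several reactions gets a **fresh node per reaction** (node id
`<gene>#<reaction_id>`). Without duplication, shared enzymes act as hubs and
pull the drawing into a tight cluster; with it, the pathway reads as the
chain of metabolic steps it is. The per-gene `occurrence` counter and the
invariant *number of nodes labelled g = number of reactions catalyzed by g*
are oracle-checked over seeded random cases in the test suite.

Each gene node carries a symbol class, assigned by the total mapping
`assignSymbol()`: PM → blue ↓, IM → light-blue ↘, NM → green →, UM → red ↑,
variant-without-status → blue circle with yellow border, otherwise plain.
Shapes are contractual and injective over the four phenotypes; colors are
configuration defaults (shape carries the meaning for color-blind readers).
When one gene has several guidelines from different sources, all are
attached, the displayed severity is the maximum (fail-safe), and a
`multi_source` flag is set when the sources disagree in category. A gene
with multiple guidelines displays the status of its highest-severity
guideline (first on ties).

Guidelines whose gene does not occur in the pathway are never dropped: they
land in `orphanGuidelines()`, and the conservation law |attached| +
|orphaned| = |matched| is tested.

### Contradictions

Two guidelines conflict when their categories fall in opposing groups:
`increase_dose` × `decrease_dose`, `increase_dose` × `avoid`, and
`decrease_dose` × `avoid`. `standard` and `other` never conflict — "no
action" cannot oppose an action without clinical semantics the category
alone does not carry. Whether "avoid" truly opposes "decrease dose" is a
judgment call (one says less drug, the other says none); we flag it by
default because a prescriber facing both must actively choose. The report
counts the distinct actionable categories present (`varyingCategories`) and
lists every opposing pair once; the implementation is verified against an
independent exhaustive enumeration for all category multisets up to size 4.
Contradictions are computed over the guidelines attached to pathway genes:
a conflict involving a gene that is absent from the drawn pathway would not
be visible in the graph and is left to the orphan list.

### Collapsing unaffected steps

For larger pathways, `collapseUnaffected()` reduces visual complexity: a
reaction is *affected* iff one of its gene nodes carries a non-plain
symbol; maximal chains of unaffected reactions between two retained
chemicals are replaced by a single dashed edge labelled with the number of
elided reactions. The root chemical, all nodes of affected reactions, and
all terminal metabolites are always retained. The operation is idempotent,
never removes an annotated node, and preserves reachability among retained
nodes — all three properties are tested against a graph-library oracle on
seeded cases.

## Layout

The original tool delegates layout to a charting runtime's force layout;
this package implements its own deterministic spring embedder so that
positions are a pure, testable function of `(graph, seed, maxIter)`. The
force law is chosen for an analyzable equilibrium and a non-negative
stress:

* every edge is a spring with rest length $k$ (`springLength`, default 1
  canvas unit), energy $(d-k)^2$;
* every node pair repels within distance $k$, energy $(k-d)^2$ for $d<k$
  (soft-core repulsion, zero beyond one spring length).

Two connected nodes therefore minimize their energy at distance exactly
$k$ — the closed form the layout tests assert to $10^{-6}$. Optimization is
damped gradient descent with a per-node displacement cap (the temperature):
a step that would increase the stress is rejected and the temperature
halved, so the recorded stress trace is non-increasing *by construction*
and the final stress never exceeds that of the seeded random
initialization. Convergence stops when the largest displacement falls below
`tol` ($10^{-10}$) or after `maxIter` epochs (default 600, ample for the
tens-of-nodes graphs this tool draws). Coincident initial points get a
deterministic separation axis derived from their indices; the global RNG
state is saved and restored around the seeded initialization.

## Outputs

* `renderSvg()` — static SVG, one glyph per node and one path per edge
  (count-conserving; collapsed edges get a distinct dash pattern and an
  elided-count label).
* `renderDocument()` — one self-contained HTML file: patient panel, graph,
  a legend enumerating all five non-plain symbol classes, hover tooltips on
  gene nodes (status, recommendation, activity score, severity; truncated
  at a character budget with a click-to-expand affordance), an expandable
  full-text guideline section with source links, a contradiction banner
  when recommendations diverge, and a drug selector when the record holds
  more than one prescription. A static file cannot re-run the pipeline, so
  switching drugs means re-rendering (e.g. via the CLI); the selector
  documents what else is prescribed.
* `exportGraph()` / `importGraph()` — GraphML (via igraph) and node-link
  JSON, lossless for nodes, edges, symbols and attached guideline ids.

## The packaged worked example

`makeWorkedExample()` loads a clomipramine case shipped as the same file
formats the parsers consume, so tests exercise parsing end to end. The
pathway encodes demethylation of clomipramine to desmethylclomipramine by
three enzymes (CYP1A2, CYP2C19, CYP3A4), CYP2D6-mediated hydroxylation of
both clomipramine and desmethylclomipramine (so CYP2D6 is duplicated), a
further CYP2C19 demethylation step and a UGT2B10 glucuronidation step. The
exact reaction-level topology of the public clomipramine pathway cannot be
re-verified offline; the fixture is a faithful synthetic encoding of the
described structure, which is what the invariants need. The patient record
is a fictitious 54-year-old man with ADHD and depression, prescribed
clomipramine and atomoxetine, with variants CYP2D6\*4/\*6 (PM for
clomipramine; guideline: lower the dose to 70% of standard),
CYP2C19\*17/\*17 (UM; guideline: avoid tertiary amines) and CYP3A4\*1A/\*1B
(variant present, no status). The two clomipramine guidelines carry
diverging categories — the contradiction the visualization exists to
surface. The fixture reproduces the published case literally, including its
internal oddity that the PM guideline's effect text describes *increased*
metabolism; flagging semantic mismatches inside guideline prose is out of
scope, and the fixture's fidelity matters more than its clinical polish.

```{r worked-example}
we <- makeWorkedExample()
g <- buildGraph(we$pathway,
                matchGuidelines(we$record, "clomipramine"),
                variantCalls(we$record))
g
contradictions(g)
```

## The synthetic case generator

`generateCase()` produces seeded random (pathway, record) pairs for
property testing. The pathway is a random spanning tree over the
metabolites (each new metabolite attaches to a uniformly chosen earlier
entity), which guarantees root-connectivity by construction; `branching`
above 1 adds shortcut reactions at rate `branching − 1`. Defaults (6
metabolites, 4 genes, branching 1.2) mirror the size of the drug pathways
the tool is meant for — clomipramine-like graphs of a dozen-odd nodes.
Statuses are drawn per gene from `statusProbs` (default weighted toward NM
with a 20% UNKNOWN mass, the shape of a typical pharmacogene panel);
`conflictRate` controls the probability that a case contains an
opposing-category guideline pair, and the construction makes conflicts
occur *exactly* when scheduled (a conflicting case gets a forced
decrease/avoid pair; a non-conflicting case draws all actionable categories
from a single group), so the empirical conflict frequency is a direct check
of the generator. What the generator does **not** emulate: real allele
frequencies, real guideline prose, correlated phenotypes across genes, or
the schema noise of real pathway exports. Passing property suites on
synthetic cases therefore demonstrates structural correctness of the graph
algebra, not robustness to every real-world data artifact — the lenient
parser and its issue lists carry that burden.

Test and acceptance problem sizes (200 seeded cases for the duplication
invariant, 100 for collapse safety, multisets up to size 4 for the
contradiction oracle, 1000 generator draws for the conflict-rate check) are
the package's chosen trade-off between coverage and a suite that runs in
well under a minute.

## Known limitations

* Only reaction-level pathway semantics: inhibition, transport and complex
  assembly are preserved and drawn dashed but carry no special edge-tip
  glyphs.
* Genotype → phenotype translation is taken as given from the upstream
  system; the package never derives a metabolizer status from a diplotype.
* One drug per graph; merged multi-drug pathways and interaction checks are
  out of scope.
* Very metabolite-rich pathways will still crowd even with collapsing;
  highlighting duplicate nodes on hover is a natural next step.
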
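#' @import methods
NULL

## Issue data.frames are the common diagnostic currency of the package:
## one row per finding, severity in {"error","warning","info"}.

#' Create an empty issue table
#'
#' Issue tables are plain data.frames with columns \code{severity}
#' (\code{"error"}, \code{"warning"} or \code{"info"}), \code{message} and
#' \code{location}. All validators and parsers in the package return them.
#'
#' @return A zero-row issue data.frame.
#' @export
emptyIssues <- function() {
    data.frame(severity = character(0), message = character(0),
               location = character(0), stringsAsFactors = FALSE)
}

newIssue <- function(severity, message, location = NA_character_) {
    data.frame(severity = severity, message = message, location = location,
               stringsAsFactors = FALSE)
}

bindIssues <- function(...) {
    parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
    if (!length(parts)) return(emptyIssues())
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
}

.METABOLIZER_STATUSES <- c("PM", "IM", "NM", "UM", "UNKNOWN")
.RECOMMENDATION_CATEGORIES <- c("increase_dose", "decrease_dose", "avoid",
                                "standard", "other")
.NODE_SYMBOLS <- c("arrow_down_pm", "arrow_lowerright_im", "arrow_right_nm",
                   "arrow_up_um", "circle_variant_no_status", "plain")
.EDGE_STYLES <- c("solid_biochemical", "dashed_other", "collapsed")
.EVIDENCE_LEVELS <- c("1A", "1B", "2A", "2B", "3", "4", "NONE")

.checkCols <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
        sprintf("%s is missing column(s): %s", what,
                paste(missing, collapse = ", "))
    else
        NULL
}

emptyEntities <- function() {
    data.frame(entity_id = character(0), label = character(0),
               kind = character(0), compartment = character(0),
               stringsAsFactors = FALSE)
}

emptyReactions <- function() {
    df <- data.frame(reaction_id = character(0), substrate_id = character(0),
                     product_id = character(0), reaction_type = character(0),
                     type_label = character(0), stringsAsFactors = FALSE)
    df$catalysts <- list()
    df
}

#' Pathway: a drug's metabolism network
#'
#' A \code{Pathway} holds the chemical entities (the drug and its metabolites)
#' and the reactions between them, each reaction optionally catalyzed by one
#' or more enzymes identified by gene symbol. Structural validity (column
#' shapes, identifier types) is enforced by the class; semantic checks
#' (reference resolution, reachability from the drug root) live in
#' \code{\link{validatePathway}} so that defective objects can be constructed
#' and diagnosed.
#'
#' @slot drugName Display name of the drug at the pathway root.
#' @slot drugCas Optional CAS registry number of the drug (\code{NA} if unknown).
#' @slot entities data.frame with columns \code{entity_id}, \code{label},
#'   \code{kind} (\code{"drug"} or \code{"metabolite"}), \code{compartment}.
#' @slot reactions data.frame with columns \code{reaction_id},
#'   \code{substrate_id}, \code{product_id}, \code{reaction_type}
#'   (\code{"biochemical"} or \code{"other"}), \code{type_label} (verbatim
#'   input label) and list-column \code{catalysts} (character vectors of gene
#'   symbols).
#' @slot issues Parse-time diagnostics (see \code{\link{emptyIssues}}).
#'
#' @seealso \code{\link{parsePathway}}, \code{\link{validatePathway}},
#'   \code{\link{writePathwayTable}}
#' @export
setClass("Pathway",
         representation(drugName = "character", drugCas = "character",
                        entities = "data.frame", reactions = "data.frame",
                        issues = "data.frame"))

setValidity("Pathway", function(object) {
    msgs <- c(
        if (length(object@drugName) != 1L || is.na(object@drugName) ||
            !nzchar(object@drugName)) "drugName must be a single non-empty string",
        if (length(object@drugCas) != 1L) "drugCas must be length 1",
        .checkCols(object@entities, c("entity_id", "label", "kind", "compartment"),
                   "entities"),
        .checkCols(object@reactions,
                   c("reaction_id", "substrate_id", "product_id",
                     "reaction_type", "type_label", "catalysts"),
                   "reactions"),
        .checkCols(object@issues, c("severity", "message", "location"), "issues")
    )
    if (is.null(msgs)) TRUE else msgs
})

newPathway <- function(drugName, drugCas = NA_character_,
                       entities = emptyEntities(),
                       reactions = emptyReactions(),
                       issues = emptyIssues()) {
    rownames(entities) <- NULL
    rownames(reactions) <- NULL
    if (!is.null(reactions$catalysts))
        reactions$catalysts <- lapply(unclass(reactions$catalysts), as.character)
    new("Pathway", drugName = drugName, drugCas = drugCas,
        entities = entities, reactions = reactions, issues = issues)
}

emptyPrescriptions <- function() {
    data.frame(drug_name = character(0), drug_cas = character(0),
               brand_name = character(0), stringsAsFactors = FALSE)
}

emptyVariants <- function() {
    data.frame(gene = character(0), diplotype = character(0),
               activity_score = numeric(0), stringsAsFactors = FALSE)
}

emptyGuidelines <- function() {
    data.frame(guideline_id = character(0), gene = character(0),
               diplotype = character(0), metabolizer_status = character(0),
               drug_name = character(0), drug_cas = character(0),
               recommendation_text = character(0),
               recommendation_category = character(0),
               category_label = character(0), severity = integer(0),
               evidence_level = character(0), source_url = character(0),
               effect_text = character(0), activity_score = numeric(0),
               dose_percent = numeric(0), source = character(0),
               stringsAsFactors = FALSE)
}

#' PatientRecord: demographics, prescriptions, variant calls and guidelines
#'
#' The second input of the visualization pipeline: what an upstream clinical
#' decision support system exports after a pharmacogenomic plausibility check.
#' Demographics are display-only; the guidelines table is the scientific
#' payload (one row per evidence-based drug--gene-variant recommendation).
#'
#' @slot name,sex Patient display fields.
#' @slot age Age in years.
#' @slot bmi Body-mass index (kg/m^2), \code{NA} when not reported.
#' @slot diagnoses Character vector of diagnosis labels.
#' @slot prescriptions data.frame: \code{drug_name}, \code{drug_cas},
#'   \code{brand_name}.
#' @slot variants data.frame of gene-variant calls: \code{gene},
#'   \code{diplotype} (star-allele pair, e.g. \code{"*4/*6"}),
#'   \code{activity_score}.
#' @slot guidelines data.frame, one row per guideline; see
#'   \code{\link{parseReport}} for the column contract. The
#'   \code{dose_percent} column is parsed out of the recommendation text when
#'   it quotes a percentage of the standard dose.
#' @slot issues Parse-time diagnostics.
#'
#' @seealso \code{\link{parseReport}}, \code{\link{validateReport}},
#'   \code{\link{matchGuidelines}}
#' @export
setClass("PatientRecord",
         representation(name = "character", age = "numeric", sex = "character",
                        bmi = "numeric", diagnoses = "character",
                        prescriptions = "data.frame", variants = "data.frame",
                        guidelines = "data.frame", issues = "data.frame"))

setValidity("PatientRecord", function(object) {
    msgs <- c(
        if (length(object@name) != 1L) "name must be length 1",
        if (length(object@age) != 1L) "age must be length 1",
        if (length(object@sex) != 1L) "sex must be length 1",
        if (length(object@bmi) != 1L) "bmi must be length 1",
        .checkCols(object@prescriptions, names(emptyPrescriptions()),
                   "prescriptions"),
        .checkCols(object@variants, names(emptyVariants()), "variants"),
        .checkCols(object@guidelines, names(emptyGuidelines()), "guidelines"),
        .checkCols(object@issues, c("severity", "message", "location"), "issues")
    )
    if (is.null(msgs)) TRUE else msgs
})

newPatientRecord <- function(name, age, sex, bmi = NA_real_,
                             diagnoses = character(0),
                             prescriptions = emptyPrescriptions(),
                             variants = emptyVariants(),
                             guidelines = emptyGuidelines(),
                             issues = emptyIssues()) {
    rownames(prescriptions) <- NULL
    rownames(variants) <- NULL
    rownames(guidelines) <- NULL
    new("PatientRecord", name = name, age = as.numeric(age), sex = sex,
        bmi = as.numeric(bmi), diagnoses = as.character(diagnoses),
        prescriptions = prescriptions, variants = variants,
        guidelines = guidelines, issues = issues)
}

#' ContradictionReport: diverging recommendation categories for one drug
#'
#' Summarizes whether the guidelines attached to a drug's pathway disagree:
#' \code{varying} counts the distinct actionable recommendation categories
#' (\code{increase_dose}, \code{decrease_dose}, \code{avoid}) present, and
#' \code{conflicts} lists every pair of guidelines whose categories belong to
#' opposing groups. \code{standard} and \code{other} never conflict.
#'
#' @slot drugLabel Drug the report refers to.
#' @slot varying Integer count of distinct actionable categories.
#' @slot conflicts data.frame with columns \code{guideline_id_1},
#'   \code{guideline_id_2}, \code{category_1}, \code{category_2}; each
#'   unordered pair appears once.
#'
#' @seealso \code{\link{detectContradictions}}
#' @export
setClass("ContradictionReport",
         representation(drugLabel = "character", varying = "integer",
                        conflicts = "data.frame"))

setValidity("ContradictionReport", function(object) {
    msgs <- c(
        if (length(object@varying) != 1L || is.na(object@varying) ||
            object@varying < 0L) "varying must be a single non-negative integer",
        .checkCols(object@conflicts,
                   c("guideline_id_1", "guideline_id_2", "category_1",
                     "category_2"), "conflicts"),
        if (nrow(object@conflicts) > 0 && object@varying < 2L)
            "varying must be >= 2 when conflicts are present"
    )
    if (is.null(msgs)) TRUE else msgs
})

emptyConflicts <- function() {
    data.frame(guideline_id_1 = character(0), guideline_id_2 = character(0),
               category_1 = character(0), category_2 = character(0),
               stringsAsFactors = FALSE)
}

newContradictionReport <- function(drugLabel = NA_character_,
                                   varying = 0L, conflicts = emptyConflicts()) {
    rownames(conflicts) <- NULL
    new("ContradictionReport", drugLabel = drugLabel,
        varying = as.integer(varying), conflicts = conflicts)
}

emptyGraphNodes <- function() {
    df <- data.frame(node_id = character(0), role = character(0),
                     label = character(0), occurrence = integer(0),
                     symbol = character(0), variant_gene = character(0),
                     variant_diplotype = character(0),
                     activity_score = numeric(0), severity_max = integer(0),
                     multi_source = logical(0), stringsAsFactors = FALSE)
    df$guideline_ids <- list()
    df
}

emptyGraphEdges <- function() {
    data.frame(from_id = character(0), to_id = character(0),
               reaction_id = character(0), style = character(0),
               collapsed_count = integer(0), stringsAsFactors = FALSE)
}

#' AnnotatedGraph: the renderable patient-specific pathway network
#'
#' Product of \code{\link{buildGraph}}: chemical nodes plus one gene node per
#' (gene, reaction) incidence — a gene catalyzing two reactions appears twice,
#' keeping the pathway a readable chain rather than a tight cluster. Gene
#' nodes carry a symbol class encoding the patient's metabolizer status, the
#' attached guideline ids, and the patient's variant call for that gene.
#'
#' @slot drugLabel Drug whose pathway is annotated.
#' @slot rootId node_id of the root chemical (the drug).
#' @slot nodes data.frame; columns \code{node_id}, \code{role}
#'   (\code{"chemical"}/\code{"gene"}), \code{label}, \code{occurrence}
#'   (per-gene instance counter), \code{symbol} (see
#'   \code{\link{assignSymbol}}), \code{variant_gene}, \code{variant_diplotype},
#'   \code{activity_score}, \code{severity_max}, \code{multi_source} and
#'   list-column \code{guideline_ids}.
#' @slot edges data.frame; columns \code{from_id}, \code{to_id},
#'   \code{reaction_id}, \code{style} (\code{solid_biochemical},
#'   \code{dashed_other} or \code{collapsed}) and \code{collapsed_count}
#'   (number of elided reactions, \code{NA} unless collapsed).
#' @slot orphanGuidelines Guidelines matching the drug but no pathway gene
#'   (same columns as \code{guidelines(x)} on a \code{PatientRecord}).
#' @slot guidelineTable All guidelines used to annotate the graph (attached
#'   and orphaned), for tooltip/detail rendering.
#' @slot contradictions A \code{\linkS4class{ContradictionReport}}.
#'
#' @seealso \code{\link{buildGraph}}, \code{\link{collapseUnaffected}},
#'   \code{\link{forceLayout}}, \code{\link{exportGraph}}
#' @export
setClass("AnnotatedGraph",
         representation(drugLabel = "character", rootId = "character",
                        nodes = "data.frame", edges = "data.frame",
                        orphanGuidelines = "data.frame",
                        guidelineTable = "data.frame",
                        contradictions = "ContradictionReport"))

setValidity("AnnotatedGraph", function(object) {
    msgs <- c(
        if (length(object@drugLabel) != 1L) "drugLabel must be length 1",
        if (length(object@rootId) != 1L) "rootId must be length 1",
        .checkCols(object@nodes, names(emptyGraphNodes()), "nodes"),
        .checkCols(object@edges, names(emptyGraphEdges()), "edges")
    )
    if (!is.null(msgs)) return(msgs)
    ids <- object@nodes$node_id
    msgs <- c(
        if (anyDuplicated(ids)) "node_id values must be unique",
        if (nrow(object@nodes) && !(object@rootId %in% ids))
            "rootId must be a node_id",
        if (nrow(object@edges) &&
            !all(c(object@edges$from_id, object@edges$to_id) %in% ids))
            "edge endpoints must resolve to node_ids",
        if (length(bad <- setdiff(object@nodes$symbol, .NODE_SYMBOLS)))
            sprintf("unknown symbol(s): %s", paste(bad, collapse = ", ")),
        if (length(bad <- setdiff(object@edges$style, .EDGE_STYLES)))
            sprintf("unknown edge style(s): %s", paste(bad, collapse = ", ")),
        if (nrow(object@edges) &&
            any(object@edges$style == "collapsed" &
                is.na(object@edges$collapsed_count)))
            "collapsed edges must carry collapsed_count"
    )
    if (is.null(msgs)) TRUE else msgs
})

newAnnotatedGraph <- function(drugLabel, rootId, nodes = emptyGraphNodes(),
                              edges = emptyGraphEdges(),
                              orphanGuidelines = emptyGuidelines(),
                              guidelineTable = emptyGuidelines(),
                              contradictions = newContradictionReport(drugLabel)) {
    rownames(nodes) <- NULL
    rownames(edges) <- NULL
    rownames(orphanGuidelines) <- NULL
    rownames(guidelineTable) <- NULL
    if (!is.null(nodes$guideline_ids))
        nodes$guideline_ids <- lapply(unclass(nodes$guideline_ids), as.character)
    new("AnnotatedGraph", drugLabel = drugLabel, rootId = rootId,
        nodes = nodes, edges = edges, orphanGuidelines = orphanGuidelines,
        guidelineTable = guidelineTable, contradictions = contradictions)
}

#' LayoutResult: deterministic node coordinates
#'
#' @slot positions Numeric matrix, one row per node (rownames are node_ids),
#'   columns \code{x}, \code{y}, in abstract canvas units.
#' @slot iterationsRun Number of optimization epochs executed.
#' @slot finalStress Final value of the layout stress (non-negative).
#' @slot stressTrace Stress of the random initialization followed by the
#'   stress after each accepted or rejected epoch; non-increasing by
#'   construction.
#' @slot seed The seed that produced the layout.
#'
#' @seealso \code{\link{forceLayout}}
#' @export
setClass("LayoutResult",
         representation(positions = "matrix", iterationsRun = "integer",
                        finalStress = "numeric", stressTrace = "numeric",
                        seed = "integer"))

setValidity("LayoutResult", function(object) {
    msgs <- c(
        if (!is.numeric(object@positions) || ncol(object@positions) != 2L)
            "positions must be a numeric matrix with two columns",
        if (nrow(object@positions) && any(!is.finite(object@positions)))
            "positions must be finite",
        if (length(object@finalStress) != 1L || is.na(object@finalStress) ||
            object@finalStress < 0) "finalStress must be a non-negative number"
    )
    if (is.null(msgs)) TRUE else msgs
})

#' SyntheticSpec: parameters of the seeded synthetic case generator
#'
#' @slot seed Integer seed; identical specs generate identical cases.
#' @slot nMetabolites Number of metabolite entities beyond the drug root (>= 1).
#' @slot nGenes Number of synthetic pharmacogenes available as catalysts (>= 0).
#' @slot branching Mean out-degree of the pathway graph (> 0); values above 1
#'   add shortcut reactions on top of the random spanning tree.
#' @slot statusProbs Probability vector over metabolizer statuses
#'   (PM, IM, NM, UM, UNKNOWN), summing to 1.
#' @slot conflictRate Probability that a generated case contains an
#'   opposing-category guideline pair.
#'
#' @seealso \code{\link{generateCase}}
#' @export
setClass("SyntheticSpec",
         representation(seed = "integer", nMetabolites = "integer",
                        nGenes = "integer", branching = "numeric",
                        statusProbs = "numeric", conflictRate = "numeric"))

setValidity("SyntheticSpec", function(object) {
    p <- object@statusProbs
    msgs <- c(
        if (length(object@nMetabolites) != 1L || object@nMetabolites < 1L)
            "nMetabolites must be >= 1",
        if (length(object@nGenes) != 1L || object@nGenes < 0L)
            "nGenes must be >= 0",
        if (length(object@branching) != 1L || !is.finite(object@branching) ||
            object@branching <= 0) "branching must be > 0",
        if (length(p) != 5L || is.null(names(p)) ||
            !identical(names(p), .METABOLIZER_STATUSES))
            "statusProbs must be named PM, IM, NM, UM, UNKNOWN",
        if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
            "statusProbs must lie in [0,1] and sum to 1 (tolerance 1e-9)",
        if (length(object@conflictRate) != 1L || object@conflictRate < 0 ||
            object@conflictRate > 1) "conflictRate must be in [0,1]"
    )
    if (is.null(msgs)) TRUE else msgs
})

#' Construct a synthetic-case specification
#'
#' @param seed Integer seed.
#' @param nMetabolites Number of metabolites (>= 1).
#' @param nGenes Number of synthetic genes (>= 0).
#' @param branching Mean out-degree (> 0).
#' @param statusProbs Probabilities over \code{c(PM, IM, NM, UM, UNKNOWN)}.
#' @param conflictRate Probability of an opposing-category guideline pair.
#' @return A \code{\linkS4class{SyntheticSpec}}.
#' @examples
#' syntheticSpec(seed = 1, nMetabolites = 5, nGenes = 3)
#' @export
syntheticSpec <- function(seed, nMetabolites = 6L, nGenes = 4L,
                          branching = 1.2,
                          statusProbs = c(PM = 0.15, IM = 0.15, NM = 0.4,
                                          UM = 0.1, UNKNOWN = 0.2),
                          conflictRate = 0.3) {
    new("SyntheticSpec", seed = as.integer(seed),
        nMetabolites = as.integer(nMetabolites), nGenes = as.integer(nGenes),
        branching = as.numeric(branching),
        statusProbs = statusProbs, conflictRate = as.numeric(conflictRate))
}
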
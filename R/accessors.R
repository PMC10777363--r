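#' Accessors for pgxvis classes
#'
#' Accessor generics for the package's S4 classes; use these instead of
#' reaching into slots.
#'
#' @param x A pgxvis object.
#' @return The slot contents (usually a data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugName", function(x) standardGeneric("drugName"))
#' @rdname accessors
#' @export
setGeneric("entities", function(x) standardGeneric("entities"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))
#' @rdname accessors
#' @export
setGeneric("prescriptions", function(x) standardGeneric("prescriptions"))
#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))
#' @rdname accessors
#' @export
setGeneric("guidelines", function(x) standardGeneric("guidelines"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("orphanGuidelines", function(x) standardGeneric("orphanGuidelines"))
#' @rdname accessors
#' @export
setGeneric("contradictions", function(x) standardGeneric("contradictions"))
#' @rdname accessors
#' @export
setGeneric("conflictPairs", function(x) standardGeneric("conflictPairs"))
#' @rdname accessors
#' @export
setGeneric("varyingCategories", function(x) standardGeneric("varyingCategories"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setMethod("drugName", "Pathway", function(x) x@drugName)
#' @rdname accessors
#' @export
setMethod("entities", "Pathway", function(x) x@entities)
#' @rdname accessors
#' @export
setMethod("reactions", "Pathway", function(x) x@reactions)
#' @rdname accessors
#' @export
setMethod("issues", "Pathway", function(x) x@issues)

#' @rdname accessors
#' @export
setMethod("prescriptions", "PatientRecord", function(x) x@prescriptions)
#' @rdname accessors
#' @export
setMethod("variantCalls", "PatientRecord", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("guidelines", "PatientRecord", function(x) x@guidelines)
#' @rdname accessors
#' @export
setMethod("issues", "PatientRecord", function(x) x@issues)

#' @rdname accessors
#' @export
setMethod("drugName", "AnnotatedGraph", function(x) x@drugLabel)
#' @rdname accessors
#' @export
setMethod("graphNodes", "AnnotatedGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("graphEdges", "AnnotatedGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("orphanGuidelines", "AnnotatedGraph", function(x) x@orphanGuidelines)
#' @rdname accessors
#' @export
setMethod("guidelines", "AnnotatedGraph", function(x) x@guidelineTable)
#' @rdname accessors
#' @export
setMethod("contradictions", "AnnotatedGraph", function(x) x@contradictions)

#' @rdname accessors
#' @export
setMethod("conflictPairs", "ContradictionReport", function(x) x@conflicts)
#' @rdname accessors
#' @export
setMethod("varyingCategories", "ContradictionReport", function(x) x@varying)

#' @rdname accessors
#' @export
setMethod("positions", "LayoutResult", function(x) x@positions)

setMethod("show", "Pathway", function(object) {
    cat(sprintf("Pathway for %s: %d entities, %d reactions\n",
                object@drugName, nrow(object@entities),
                nrow(object@reactions)))
    if (nrow(object@issues))
        cat(sprintf("  %d parse issue(s)\n", nrow(object@issues)))
    invisible(object)
})

setMethod("show", "PatientRecord", function(object) {
    cat(sprintf(paste0("PatientRecord: %s (%s, %g y)\n",
                       "  %d prescription(s), %d variant call(s), ",
                       "%d guideline(s)\n"),
                object@name, object@sex, object@age,
                nrow(object@prescriptions), nrow(object@variants),
                nrow(object@guidelines)))
    invisible(object)
})

setMethod("show", "AnnotatedGraph", function(object) {
    cat(sprintf("AnnotatedGraph for %s: %d nodes (%d gene), %d edges\n",
                object@drugLabel, nrow(object@nodes),
                sum(object@nodes$role == "gene"), nrow(object@edges)))
    cr <- object@contradictions
    if (nrow(cr@conflicts))
        cat(sprintf("  %d contradictory guideline pair(s), %d varying categories\n",
                    nrow(cr@conflicts), cr@varying))
    if (nrow(object@orphanGuidelines))
        cat(sprintf("  %d orphan guideline(s)\n", nrow(object@orphanGuidelines)))
    invisible(object)
})

setMethod("show", "ContradictionReport", function(object) {
    cat(sprintf("ContradictionReport for %s: %d varying categories, %d conflict pair(s)\n",
                object@drugLabel, object@varying, nrow(object@conflicts)))
    invisible(object)
})

setMethod("show", "LayoutResult", function(object) {
    cat(sprintf("LayoutResult: %d nodes, %d epochs, final stress %.4g (seed %d)\n",
                nrow(object@positions), object@iterationsRun,
                object@finalStress, object@seed))
    invisible(object)
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf("SyntheticSpec: seed %d, %d metabolites, %d genes, branching %.2f, conflict rate %.2f\n",
                object@seed, object@nMetabolites, object@nGenes,
                object@branching, object@conflictRate))
    invisible(object)
})
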
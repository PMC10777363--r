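## Join pathway and guidelines into the renderable annotated network.
## Design: enzymes are interposed as nodes on the substrate -> product path
## (substrate -> enzyme -> product), one fresh gene node per (gene, reaction)
## incidence. Duplicating gene nodes keeps the pathway drawn as a chain
## instead of a tight cluster around shared enzymes.

#' Map metabolizer status to a node symbol class
#'
#' Total, deterministic mapping from a gene's annotation state to its glyph:
#' PM is a blue downwards arrow (slower metabolism), IM a light-blue
#' lower-right arrow, NM a green rightwards arrow, UM a red upwards arrow
#' (faster metabolism). A gene with a variant call but no status gets a blue
#' circle with a yellow border; a gene with neither stays plain. The mapping
#' is injective on \{PM, IM, NM, UM\}.
#'
#' @param status One of \code{"PM", "IM", "NM", "UM", "UNKNOWN"}.
#' @param hasVariant Does the patient have a variant call for this gene?
#' @return A symbol class string (see \code{\linkS4class{AnnotatedGraph}}).
#' @examples
#' assignSymbol("PM", TRUE)        # "arrow_down_pm"
#' assignSymbol("UNKNOWN", TRUE)   # "circle_variant_no_status"
#' @export
assignSymbol <- function(status, hasVariant = FALSE) {
    stopifnot(length(status) == 1L, status %in% .METABOLIZER_STATUSES)
    switch(status,
           PM = "arrow_down_pm",
           IM = "arrow_lowerright_im",
           NM = "arrow_right_nm",
           UM = "arrow_up_um",
           UNKNOWN = if (isTRUE(hasVariant)) "circle_variant_no_status"
                     else "plain")
}

## opposing recommendation-category groups; standard/other never conflict
.OPPOSING_PAIRS <- matrix(c("increase_dose", "decrease_dose",
                            "increase_dose", "avoid",
                            "decrease_dose", "avoid"),
                          ncol = 2, byrow = TRUE)

.categoriesOppose <- function(a, b) {
    any((.OPPOSING_PAIRS[, 1] == a & .OPPOSING_PAIRS[, 2] == b) |
        (.OPPOSING_PAIRS[, 1] == b & .OPPOSING_PAIRS[, 2] == a))
}

#' Detect contradictory recommendations among a drug's guidelines
#'
#' Pharmacogene phenotypes are independent of each other, so the guidelines
#' for enzymes in one drug's pathway can point in opposite directions (lower
#' the dose vs. avoid the drug). Two guidelines conflict when their
#' recommendation categories fall into opposing groups:
#' \code{increase_dose} vs \code{decrease_dose}, \code{increase_dose} vs
#' \code{avoid}, and \code{decrease_dose} vs \code{avoid}. \code{standard}
#' and \code{other} never participate. Every cross-group pair is listed once
#' (unordered).
#'
#' @param guidelines A guideline data.frame (as in \code{guidelines(record)}),
#'   all referring to the same drug.
#' @param drugLabel Optional drug label for the report; defaults to the first
#'   guideline's drug name.
#' @return A \code{\linkS4class{ContradictionReport}} whose \code{varying}
#'   slot counts the distinct actionable categories present.
#' @export
detectContradictions <- function(guidelines, drugLabel = NULL) {
    cats <- guidelines$recommendation_category
    actionable <- c("increase_dose", "decrease_dose", "avoid")
    if (is.null(drugLabel))
        drugLabel <- if (nrow(guidelines)) guidelines$drug_name[1]
                     else NA_character_
    varying <- length(unique(cats[cats %in% actionable]))
    conf <- emptyConflicts()
    n <- nrow(guidelines)
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            for (j in seq((i + 1L), n)) {
                if (.categoriesOppose(cats[i], cats[j]))
                    conf <- rbind(conf, data.frame(
                        guideline_id_1 = guidelines$guideline_id[i],
                        guideline_id_2 = guidelines$guideline_id[j],
                        category_1 = cats[i], category_2 = cats[j],
                        stringsAsFactors = FALSE))
            }
        }
    }
    newContradictionReport(drugLabel, varying, conf)
}

## per-gene annotation summary used for every duplicated node of that gene
.geneAnnotation <- function(gene, guidelines, variants) {
    gl <- guidelines[guidelines$gene == gene, , drop = FALSE]
    vHit <- match(gene, variants$gene)
    hasVariant <- !is.na(vHit)
    status <- "UNKNOWN"
    sevMax <- NA_integer_
    multi <- FALSE
    if (nrow(gl)) {
        sev <- ifelse(is.na(gl$severity), 0L, gl$severity)
        status <- gl$metabolizer_status[which.max(sev)]
        sevMax <- suppressWarnings(max(gl$severity, na.rm = TRUE))
        if (!is.finite(sevMax)) sevMax <- NA_integer_
        multi <- nrow(gl) > 1L &&
            length(unique(gl$recommendation_category)) > 1L
    }
    list(status = status, hasVariant = hasVariant,
         symbol = assignSymbol(status, hasVariant),
         guideline_ids = gl$guideline_id,
         variant_diplotype = if (hasVariant) variants$diplotype[vHit]
                             else NA_character_,
         activity_score = if (hasVariant) variants$activity_score[vHit]
                          else NA_real_,
         severity_max = as.integer(sevMax), multi_source = multi)
}

#' Build the annotated patient-specific pathway graph
#'
#' Joins a \code{\linkS4class{Pathway}} with the guidelines matched to its
#' drug and the patient's variant calls. Each reaction with \eqn{k} catalysts
#' expands into \eqn{k} parallel substrate \eqn{\to} enzyme \eqn{\to} product
#' chains (the gene node is duplicated per (gene, reaction) incidence, node
#' id \code{<gene>#<reaction_id>}); a reaction without catalysts becomes a
#' direct substrate \eqn{\to} product edge. Every gene node carries the
#' guidelines for its gene (keyed by gene symbol), the patient's variant
#' call, and a symbol from \code{\link{assignSymbol}}; when several sources
#' disagree in category for one gene, the node's displayed severity is the
#' maximum and \code{multi_source} is set. Guidelines whose gene does not
#' occur in the pathway are preserved in \code{orphanGuidelines(x)};
#' contradictions are computed over the attached guidelines.
#'
#' @param p A \code{\linkS4class{Pathway}}.
#' @param guidelines Guidelines already filtered to this drug (see
#'   \code{\link{matchGuidelines}}).
#' @param variants The patient's variant-call data.frame.
#' @return An \code{\linkS4class{AnnotatedGraph}}.
#' @examples
#' we <- makeWorkedExample()
#' g <- buildGraph(we$pathway,
#'                 matchGuidelines(we$record, "clomipramine"),
#'                 variantCalls(we$record))
#' sum(graphNodes(g)$label == "CYP2D6")  # duplicated per reaction incidence
#' @export
buildGraph <- function(p, guidelines = emptyGuidelines(),
                       variants = emptyVariants()) {
    stopifnot(is(p, "Pathway"))
    ents <- p@entities
    rxn <- p@reactions
    rootId <- ents$entity_id[ents$kind == "drug"][1]

    nodes <- emptyGraphNodes()
    addNode <- function(node_id, role, label, occurrence, ann = NULL) {
        row <- data.frame(node_id = node_id, role = role, label = label,
                          occurrence = as.integer(occurrence),
                          symbol = if (is.null(ann)) "plain" else ann$symbol,
                          variant_gene = if (is.null(ann) || !ann$hasVariant)
                              NA_character_ else label,
                          variant_diplotype = if (is.null(ann))
                              NA_character_ else ann$variant_diplotype,
                          activity_score = if (is.null(ann)) NA_real_
                                           else ann$activity_score,
                          severity_max = if (is.null(ann)) NA_integer_
                                         else ann$severity_max,
                          multi_source = if (is.null(ann)) FALSE
                                         else ann$multi_source,
                          stringsAsFactors = FALSE)
        row$guideline_ids <- list(if (is.null(ann)) character(0)
                                  else ann$guideline_ids)
        nodes <<- rbind(nodes, row)
    }
    for (i in seq_len(nrow(ents)))
        addNode(ents$entity_id[i], "chemical", ents$label[i], 1L)

    genesSeen <- integer(0)
    anns <- list()
    edges <- emptyGraphEdges()
    addEdge <- function(from, to, rid, style) {
        edges <<- rbind(edges, data.frame(
            from_id = from, to_id = to, reaction_id = rid, style = style,
            collapsed_count = NA_integer_, stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(rxn))) {
        rid <- rxn$reaction_id[i]
        style <- if (rxn$reaction_type[i] == "biochemical")
            "solid_biochemical" else "dashed_other"
        cats <- rxn$catalysts[[i]]
        if (!length(cats)) {
            addEdge(rxn$substrate_id[i], rxn$product_id[i], rid, style)
            next
        }
        for (g in cats) {
            if (is.null(anns[[g]]))
                anns[[g]] <- .geneAnnotation(g, guidelines, variants)
            genesSeen[g] <- (if (is.na(genesSeen[g])) 0L else genesSeen[g]) + 1L
            gid <- paste0(g, "#", rid)
            addNode(gid, "gene", g, genesSeen[g], anns[[g]])
            addEdge(rxn$substrate_id[i], gid, rid, style)
            addEdge(gid, rxn$product_id[i], rid, style)
        }
    }

    pathwayGenes <- unique(unlist(rxn$catalysts))
    orphan <- guidelines[!(guidelines$gene %in% pathwayGenes), , drop = FALSE]
    attached <- guidelines[guidelines$gene %in% pathwayGenes, , drop = FALSE]
    rownames(orphan) <- NULL

    newAnnotatedGraph(
        drugLabel = p@drugName, rootId = rootId, nodes = nodes, edges = edges,
        orphanGuidelines = orphan, guidelineTable = guidelines,
        contradictions = detectContradictions(attached,
                                              drugLabel = p@drugName))
}

## chemical-level reaction units of an annotated graph:
## each reaction (or already-collapsed edge) as one (from, to, affected, count)
.chemicalUnits <- function(g) {
    nodes <- g@nodes; edges <- g@edges
    role <- stats::setNames(nodes$role, nodes$node_id)
    symbol <- stats::setNames(nodes$symbol, nodes$node_id)
    units <- list()
    done <- character(0)
    for (i in seq_len(nrow(edges))) {
        e <- edges[i, ]
        if (e$style == "collapsed") {
            units[[length(units) + 1L]] <- list(
                from = e$from_id, to = e$to_id, affected = FALSE,
                count = e$collapsed_count, genes = character(0))
            next
        }
        rid <- e$reaction_id
        if (rid %in% done) next
        sub <- edges[!is.na(edges$reaction_id) & edges$reaction_id == rid, ,
                     drop = FALSE]
        geneIds <- unique(c(sub$from_id, sub$to_id))
        geneIds <- geneIds[role[geneIds] == "gene"]
        chemFrom <- unique(sub$from_id[role[sub$from_id] == "chemical"])
        chemTo <- unique(sub$to_id[role[sub$to_id] == "chemical"])
        units[[length(units) + 1L]] <- list(
            from = chemFrom[1], to = chemTo[1],
            affected = any(symbol[geneIds] != "plain"),
            count = 1L, genes = geneIds, style = sub$style[1], rid = rid)
        done <- c(done, rid)
    }
    units
}

#' Collapse reactions unaffected by the patient's variants
#'
#' Reduces visual complexity by eliding pathway steps that carry no
#' patient-specific annotation. A reaction is \emph{affected} iff any of its
#' gene nodes has a non-plain symbol. Maximal chains of unaffected reactions
#' running between two retained chemicals are replaced by a single
#' \code{collapsed} edge carrying the number of elided reactions. The root
#' chemical, every chemical and gene node of an affected reaction, and all
#' terminal metabolites are always retained; the operation is idempotent and
#' never removes a node with a non-plain symbol.
#'
#' @param g An \code{\linkS4class{AnnotatedGraph}}.
#' @return A collapsed \code{\linkS4class{AnnotatedGraph}}.
#' @export
collapseUnaffected <- function(g) {
    stopifnot(is(g, "AnnotatedGraph"))
    units <- .chemicalUnits(g)
    nodes <- g@nodes
    chems <- nodes$node_id[nodes$role == "chemical"]
    if (!length(units)) return(g)
    from <- vapply(units, `[[`, "", "from")
    to <- vapply(units, `[[`, "", "to")
    affected <- vapply(units, `[[`, TRUE, "affected")
    terminals <- setdiff(chems, from)
    retainedChem <- unique(c(g@rootId, terminals,
                             from[affected], to[affected]))
    retainedGenes <- unlist(lapply(units[affected], `[[`, "genes"))

    ## walk unaffected units from each retained chemical until the next
    ## retained chemical; each such maximal chain becomes one collapsed edge
    collapsed <- emptyGraphEdges()
    walk <- function(node, count, onPath) {
        outs <- which(from == node & !affected)
        for (u in outs) {
            nxt <- to[u]
            if (nxt %in% onPath) next            # cycle guard
            total <- count + units[[u]]$count
            if (nxt %in% retainedChem) {
                collapsed <<- rbind(collapsed, data.frame(
                    from_id = start, to_id = nxt, reaction_id = NA_character_,
                    style = "collapsed", collapsed_count = as.integer(total),
                    stringsAsFactors = FALSE))
            } else {
                walk(nxt, total, c(onPath, nxt))
            }
        }
    }
    for (start in retainedChem) walk(start, 0L, start)
    collapsed <- collapsed[order(collapsed$from_id, collapsed$to_id,
                                 collapsed$collapsed_count), , drop = FALSE]
    collapsed <- collapsed[!duplicated(collapsed), , drop = FALSE]

    keepIds <- c(retainedChem, retainedGenes)
    newNodes <- nodes[nodes$node_id %in% keepIds, , drop = FALSE]
    keptEdges <- g@edges[!is.na(g@edges$reaction_id) &
                         g@edges$reaction_id %in%
                         vapply(units[affected], function(u) u$rid, ""), ,
                         drop = FALSE]
    newEdges <- rbind(keptEdges, collapsed)
    rownames(newNodes) <- NULL
    rownames(newEdges) <- NULL
    newAnnotatedGraph(
        drugLabel = g@drugLabel, rootId = g@rootId, nodes = newNodes,
        edges = newEdges, orphanGuidelines = g@orphanGuidelines,
        guidelineTable = g@guidelineTable, contradictions = g@contradictions)
}
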
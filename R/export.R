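## Machine-readable graph export. GraphML goes through igraph; node-link JSON
## through jsonlite. Both are lossless for nodes, edges, symbols and attached
## guideline ids, so export -> import round-trips to an isomorphic graph
## (guideline texts and contradiction reports live in the patient record and
## are not part of the graph serialization).

.naToEmpty <- function(x) ifelse(is.na(x), "", as.character(x))
.emptyToNa <- function(x) ifelse(!nzchar(x), NA_character_, x)

.graphToIgraph <- function(g) {
    v <- g@nodes
    vertices <- data.frame(
        name = v$node_id, role = v$role, label = v$label,
        occurrence = v$occurrence, symbol = v$symbol,
        guideline_ids = vapply(v$guideline_ids, paste, "", collapse = ","),
        variant_gene = .naToEmpty(v$variant_gene),
        variant_diplotype = .naToEmpty(v$variant_diplotype),
        activity_score = ifelse(is.na(v$activity_score), -1,
                                v$activity_score),
        severity_max = ifelse(is.na(v$severity_max), -1L, v$severity_max),
        multi_source = as.integer(v$multi_source),
        stringsAsFactors = FALSE)
    e <- g@edges
    edgesDf <- data.frame(
        from = e$from_id, to = e$to_id,
        reaction_id = .naToEmpty(e$reaction_id), style = e$style,
        collapsed_count = ifelse(is.na(e$collapsed_count), -1L,
                                 e$collapsed_count),
        stringsAsFactors = FALSE)
    ig <- igraph::graph_from_data_frame(edgesDf, directed = TRUE,
                                        vertices = vertices)
    ig <- igraph::set_graph_attr(ig, "drug_label", g@drugLabel)
    igraph::set_graph_attr(ig, "root_id", g@rootId)
}

.igraphToGraph <- function(ig) {
    v <- igraph::as_data_frame(ig, what = "vertices")
    e <- igraph::as_data_frame(ig, what = "edges")
    nodes <- data.frame(
        node_id = v$name, role = v$role, label = v$label,
        occurrence = as.integer(v$occurrence), symbol = v$symbol,
        variant_gene = .emptyToNa(v$variant_gene),
        variant_diplotype = .emptyToNa(v$variant_diplotype),
        activity_score = ifelse(v$activity_score < 0, NA_real_,
                                v$activity_score),
        severity_max = ifelse(v$severity_max < 0, NA_integer_,
                              as.integer(v$severity_max)),
        multi_source = as.logical(v$multi_source),
        stringsAsFactors = FALSE)
    nodes$guideline_ids <- lapply(strsplit(v$guideline_ids, ","),
                                  function(x) x[nzchar(x)])
    edges <- data.frame(
        from_id = e$from, to_id = e$to,
        reaction_id = .emptyToNa(e$reaction_id), style = e$style,
        collapsed_count = ifelse(e$collapsed_count < 0, NA_integer_,
                                 as.integer(e$collapsed_count)),
        stringsAsFactors = FALSE)
    newAnnotatedGraph(
        drugLabel = igraph::graph_attr(ig, "drug_label"),
        rootId = igraph::graph_attr(ig, "root_id"),
        nodes = nodes, edges = edges)
}

#' Export an annotated graph
#'
#' Serializes an \code{\linkS4class{AnnotatedGraph}} to GraphML (via igraph)
#' or node-link JSON. Node attributes (role, label, occurrence, symbol,
#' attached guideline ids, variant call) and edge attributes (reaction id,
#' style, collapsed count) survive the round trip through
#' \code{\link{importGraph}}.
#'
#' @param g An \code{\linkS4class{AnnotatedGraph}}.
#' @param file Path to write to.
#' @param format \code{"graphml"} or \code{"node_link"}.
#' @return \code{file}, invisibly.
#' @export
exportGraph <- function(g, file, format = c("graphml", "node_link")) {
    stopifnot(is(g, "AnnotatedGraph"))
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(.graphToIgraph(g), file, format = "graphml")
    } else {
        v <- g@nodes
        doc <- list(
            drug_label = g@drugLabel, root_id = g@rootId, directed = TRUE,
            nodes = lapply(seq_len(nrow(v)), function(i) list(
                id = v$node_id[i], role = v$role[i], label = v$label[i],
                occurrence = v$occurrence[i], symbol = v$symbol[i],
                guideline_ids = as.list(v$guideline_ids[[i]]),
                variant_gene = v$variant_gene[i],
                variant_diplotype = v$variant_diplotype[i],
                activity_score = v$activity_score[i],
                severity_max = v$severity_max[i],
                multi_source = v$multi_source[i])),
            links = lapply(seq_len(nrow(g@edges)), function(i) list(
                source = g@edges$from_id[i], target = g@edges$to_id[i],
                reaction_id = g@edges$reaction_id[i],
                style = g@edges$style[i],
                collapsed_count = g@edges$collapsed_count[i])))
        writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                                 pretty = TRUE, digits = NA,
                                                 null = "null", na = "null")),
                   file, useBytes = TRUE)
    }
    invisible(file)
}

#' Import a previously exported graph
#'
#' Inverse of \code{\link{exportGraph}}. Guideline texts and the
#' contradiction report are not part of the graph serialization, so the
#' imported object carries the node/edge structure, symbols and attached
#' guideline ids with an empty guideline table.
#'
#' @param file Path of the serialized graph.
#' @param format \code{"graphml"} or \code{"node_link"}.
#' @return An \code{\linkS4class{AnnotatedGraph}}.
#' @export
importGraph <- function(file, format = c("graphml", "node_link")) {
    format <- match.arg(format)
    if (format == "graphml")
        return(.igraphToGraph(igraph::read_graph(file, format = "graphml")))
    doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
    toChr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
    toNum <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    toInt <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
    nodes <- emptyGraphNodes()
    for (nd in doc$nodes) {
        row <- data.frame(
            node_id = nd$id, role = nd$role, label = nd$label,
            occurrence = toInt(nd$occurrence), symbol = nd$symbol,
            variant_gene = toChr(nd$variant_gene),
            variant_diplotype = toChr(nd$variant_diplotype),
            activity_score = toNum(nd$activity_score),
            severity_max = toInt(nd$severity_max),
            multi_source = isTRUE(nd$multi_source),
            stringsAsFactors = FALSE)
        row$guideline_ids <- list(as.character(unlist(nd$guideline_ids)))
        nodes <- rbind(nodes, row)
    }
    edges <- emptyGraphEdges()
    for (lk in doc$links)
        edges <- rbind(edges, data.frame(
            from_id = lk$source, to_id = lk$target,
            reaction_id = toChr(lk$reaction_id), style = lk$style,
            collapsed_count = toInt(lk$collapsed_count),
            stringsAsFactors = FALSE))
    newAnnotatedGraph(drugLabel = doc$drug_label, rootId = doc$root_id,
                      nodes = nodes, edges = edges)
}
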
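# Independent oracles used across the suite. They deliberately take
# different routes than the implementation: reachability goes through
# igraph, contradiction logic through a set-membership formulation, node
# counting through a brute-force sweep over the reaction list.

# reachability matrix among `ids` in the node-level directed graph
oracleReachability <- function(edges, ids) {
    if (!nrow(edges)) {
        m <- diag(TRUE, length(ids))
        dimnames(m) <- list(ids, ids)
        return(m)
    }
    vertices <- unique(c(ids, edges$from_id, edges$to_id))
    ig <- igraph::graph_from_data_frame(
        edges[, c("from_id", "to_id")], directed = TRUE,
        vertices = data.frame(name = vertices))
    d <- igraph::distances(ig, v = ids, to = ids, mode = "out")
    is.finite(d)
}

# two categories oppose iff both are actionable and differ
oracleOppose <- function(a, b) {
    actionable <- c("increase_dose", "decrease_dose", "avoid")
    (a %in% actionable) && (b %in% actionable) && a != b
}

oracleConflictPairs <- function(categories) {
    n <- length(categories)
    pairs <- list()
    if (n >= 2) {
        for (i in seq_len(n - 1)) {
            for (j in seq(i + 1, n)) {
                if (oracleOppose(categories[i], categories[j]))
                    pairs[[length(pairs) + 1]] <- c(i, j)
            }
        }
    }
    pairs
}

# per-gene reaction incidence counted by brute force over the reaction list
oracleGeneIncidence <- function(pathway) {
    counts <- integer(0)
    rx <- reactions(pathway)
    for (i in seq_len(nrow(rx))) {
        for (g in unique(rx$catalysts[[i]])) {
            counts[g] <- (if (is.na(counts[g])) 0L else counts[g]) + 1L
        }
    }
    counts
}

# all multisets of the given size over the category alphabet
categoryMultisets <- function(size) {
    alphabet <- c("increase_dose", "decrease_dose", "avoid", "standard",
                  "other")
    if (size == 0) return(list(character(0)))
    idx <- utils::combn(length(alphabet) + size - 1, size)
    lapply(seq_len(ncol(idx)), function(j) {
        k <- idx[, j] - seq_len(size) + 1
        alphabet[k]
    })
}

# minimal guideline data.frame for contradiction tests
guidelineStub <- function(categories, statuses = NULL) {
    n <- length(categories)
    data.frame(
        guideline_id = sprintf("gl%d", seq_len(n)),
        gene = sprintf("GENE%d", seq_len(n)),
        diplotype = "*1/*2",
        metabolizer_status = if (is.null(statuses)) "NM" else statuses,
        drug_name = "drugx", drug_cas = NA_character_,
        recommendation_text = "", recommendation_category = categories,
        category_label = categories, severity = 2L, evidence_level = "3",
        source_url = "", effect_text = "", activity_score = NA_real_,
        dose_percent = NA_real_, source = "TEST",
        stringsAsFactors = FALSE)
}

emptyGuidelineStub <- function() guidelineStub("standard")[0, , drop = FALSE]

workedExampleGraph <- function() {
    we <- makeWorkedExample()
    list(we = we,
         graph = buildGraph(we$pathway,
                            matchGuidelines(we$record, "clomipramine"),
                            variantCalls(we$record)))
}

# chain fixture: drug -> A -> B -> C, one gene per step; guideline on the
# gene of the first reaction only
chainCase <- function() {
    tsv <- c("From\tTo\tReaction Type\tController",
             "drugx\tmetA\tBiochemical Reaction\tGENE1",
             "metA\tmetB\tBiochemical Reaction\tGENE2",
             "metB\tmetC\tBiochemical Reaction\tGENE3")
    p <- parsePathway(tsv, "drugx")
    gl <- guidelineStub("decrease_dose", statuses = "PM")
    gl$gene <- "GENE1"
    vars <- data.frame(gene = "GENE1", diplotype = "*4/*6",
                       activity_score = 0, stringsAsFactors = FALSE)
    buildGraph(p, gl, vars)
}
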
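## Pathway table parsing -- PharmGKB-style tab-separated relationship tables.
## Upstream TSVs do not always follow one schema, so header matching is
## deliberately lenient: case-insensitive, punctuation-insensitive, with a
## synonym table per canonical column.

.HEADER_SYNONYMS <- list(
    from        = c("from", "source", "substrate"),
    to          = c("to", "target", "product"),
    controller  = c("controller", "controllers", "genes", "gene", "enzymes",
                    "controllergenes"),
    type        = c("reactiontype", "type"),
    compartment = c("compartment")
)

.normHeader <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.trimws2 <- function(x) trimws(as.character(x))

makeEntityId <- function(label) {
    id <- gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(label)))
    ifelse(nzchar(id), id, "entity")
}

.splitCatalysts <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character(0))
    parts <- toupper(trimws(strsplit(x, "[,;]")[[1]]))
    parts[nzchar(parts)]
}

.classifyReactionType <- function(label) {
    if (!nzchar(label)) return(c("biochemical", "biochemical"))
    if (grepl("biochemical", tolower(label))) c("biochemical", label)
    else c("other", label)
}

#' Parse a drug-metabolism pathway table
#'
#' Reads a tab-separated relationship table (one reaction per row: substrate,
#' product, reaction type, controller genes) into a
#' \code{\linkS4class{Pathway}}. Header matching is lenient: columns are
#' recognized case-insensitively under the synonyms
#' \{From, Source, Substrate\}, \{To, Target, Product\},
#' \{Controller, Genes, Enzymes\} and \{Reaction Type, Type\}, in any order.
#' Multi-catalyst cells are split on commas/semicolons and gene symbols are
#' upper-cased. Verbatim duplicate rows are dropped; rows sharing substrate,
#' product and reaction type merge their catalyst lists into one reaction
#' (one metabolic step, several enzymes). Rows with an unrecognized reaction
#' type are kept with \code{reaction_type = "other"}; rows missing substrate
#' or product are rejected into the issue table, not a crash.
#'
#' @param file Path, connection, or character vector of table lines.
#' @param drugName Name of the drug at the pathway root; matched
#'   case-insensitively against entity labels (exact first, then unique
#'   prefix). If the table has no rows at all, a root entity is synthesized
#'   and a warning issue recorded.
#' @return A \code{\linkS4class{Pathway}}; parse diagnostics are in
#'   \code{issues(x)}.
#' @examples
#' tsv <- c("From\tTo\tReaction Type\tController",
#'          "drugX\tmetY\tBiochemical Reaction\tCYP9Z9")
#' p <- parsePathway(tsv, "drugX")
#' reactions(p)
#' @export
parsePathway <- function(file, drugName) {
    stopifnot(is.character(drugName), length(drugName) == 1L, nzchar(drugName))
    if (is.character(file) &&
        (length(file) > 1L || grepl("[\t\n]", file[1])))
        file <- textConnection(file)
    raw <- tryCatch(
        utils::read.delim(file, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", na.strings = NULL,
                          blank.lines.skip = TRUE),
        error = function(e) stop("unreadable pathway table: ",
                                 conditionMessage(e), call. = FALSE))
    hdr <- .normHeader(names(raw))
    colFor <- function(key) {
        hit <- which(hdr %in% .HEADER_SYNONYMS[[key]])
        if (length(hit)) hit[1L] else NA_integer_
    }
    iFrom <- colFor("from"); iTo <- colFor("to")
    if (is.na(iFrom) || is.na(iTo))
        stop("pathway table: source/target columns not identifiable ",
             "(recognized synonyms: From/Source/Substrate, To/Target/Product)",
             call. = FALSE)
    iCtl <- colFor("controller"); iTyp <- colFor("type")
    iCmp <- colFor("compartment")

    issues <- emptyIssues()
    ents <- emptyEntities()
    addEntity <- function(label, compartment = NA_character_) {
        hit <- match(label, ents$label)
        if (!is.na(hit)) {
            if (is.na(ents$compartment[hit]) && !is.na(compartment))
                ents$compartment[hit] <<- compartment
            return(ents$entity_id[hit])
        }
        id <- makeEntityId(label)
        if (id %in% ents$entity_id)
            id <- paste0(id, "_", sum(startsWith(ents$entity_id, id)) + 1L)
        ents <<- rbind(ents, data.frame(entity_id = id, label = label,
                                        kind = "metabolite",
                                        compartment = compartment,
                                        stringsAsFactors = FALSE))
        id
    }

    ## accepted reactions accumulate keyed on (substrate, product, type label)
    keys <- character(0)
    rx <- list()
    seenRows <- character(0)
    for (i in seq_len(nrow(raw))) {
        from <- .trimws2(raw[[iFrom]][i])
        to <- .trimws2(raw[[iTo]][i])
        typLabel <- if (!is.na(iTyp)) .trimws2(raw[[iTyp]][i]) else ""
        ctl <- if (!is.na(iCtl)) .trimws2(raw[[iCtl]][i]) else ""
        cmp <- if (!is.na(iCmp)) .trimws2(raw[[iCmp]][i]) else ""
        if (!nzchar(from) || !nzchar(to)) {
            issues <- bindIssues(issues, newIssue(
                "error", "row rejected: missing source or target entity",
                sprintf("row %d", i)))
            next
        }
        rowSig <- paste(from, to, typLabel, ctl, sep = "\r")
        if (rowSig %in% seenRows) next   # verbatim duplicate
        seenRows <- c(seenRows, rowSig)
        typ <- .classifyReactionType(typLabel)
        fromId <- addEntity(from, if (nzchar(cmp)) cmp else NA_character_)
        toId <- addEntity(to)
        if (fromId == toId) {
            issues <- bindIssues(issues, newIssue(
                "error", sprintf("row rejected: self-reaction on '%s'", from),
                sprintf("row %d", i)))
            next
        }
        cats <- .splitCatalysts(ctl)
        key <- paste(fromId, toId, tolower(typ[2]), sep = "\r")
        hit <- match(key, keys)
        if (is.na(hit)) {
            keys <- c(keys, key)
            rx[[length(rx) + 1L]] <- list(substrate_id = fromId,
                                          product_id = toId,
                                          reaction_type = typ[1],
                                          type_label = typ[2],
                                          catalysts = cats)
        } else {
            rx[[hit]]$catalysts <- unique(c(rx[[hit]]$catalysts, cats))
        }
    }

    if (nrow(ents) == 0L) {
        ents <- data.frame(entity_id = makeEntityId(drugName),
                           label = drugName, kind = "drug",
                           compartment = NA_character_,
                           stringsAsFactors = FALSE)
        issues <- bindIssues(issues, newIssue(
            "warning", "table has no usable rows; synthesized the root entity",
            "table"))
        rootIdx <- 1L
    } else {
        rootIdx <- which(tolower(ents$label) == tolower(drugName))
        if (length(rootIdx) == 0L)
            rootIdx <- which(startsWith(tolower(ents$label), tolower(drugName)))
        if (length(rootIdx) == 0L)
            stop(sprintf("root not found: no entity matching drug '%s'",
                         drugName), call. = FALSE)
        if (length(rootIdx) > 1L)
            stop(sprintf("root ambiguous: %d entities match drug '%s'",
                         length(rootIdx), drugName), call. = FALSE)
        ents$kind[rootIdx] <- "drug"
    }

    reactionsDf <- if (length(rx)) {
        df <- data.frame(
            reaction_id = sprintf("rxn%03d", seq_along(rx)),
            substrate_id = vapply(rx, `[[`, "", "substrate_id"),
            product_id = vapply(rx, `[[`, "", "product_id"),
            reaction_type = vapply(rx, `[[`, "", "reaction_type"),
            type_label = vapply(rx, `[[`, "", "type_label"),
            stringsAsFactors = FALSE)
        df$catalysts <- lapply(rx, `[[`, "catalysts")
        df
    } else emptyReactions()

    newPathway(drugName = ents$label[rootIdx], entities = ents,
               reactions = reactionsDf, issues = issues)
}

#' Serialize a Pathway to the canonical tab-separated table
#'
#' Writes the canonical columns \code{From}, \code{To}, \code{Reaction Type},
#' \code{Controller} (plus \code{Compartment} when any substrate entity has
#' one), one reaction per row sorted by reaction id, catalysts joined with
#' \code{", "}. Output is bit-stable, and re-parsing it with
#' \code{\link{parsePathway}} reproduces the Pathway.
#'
#' @param p A \code{\linkS4class{Pathway}}.
#' @param file Optional path to write to; when \code{NULL} the lines are
#'   returned.
#' @return Invisibly (or visibly when \code{file = NULL}) the character vector
#'   of table lines.
#' @export
writePathwayTable <- function(p, file = NULL) {
    stopifnot(is(p, "Pathway"))
    rxn <- p@reactions[order(p@reactions$reaction_id), , drop = FALSE]
    lab <- function(ids) p@entities$label[match(ids, p@entities$entity_id)]
    cmp <- p@entities$compartment[match(rxn$substrate_id, p@entities$entity_id)]
    withCmp <- any(!is.na(cmp))
    header <- c("From", "To", "Reaction Type", "Controller",
                if (withCmp) "Compartment")
    rows <- vapply(seq_len(nrow(rxn)), function(i) {
        fields <- c(lab(rxn$substrate_id[i]), lab(rxn$product_id[i]),
                    rxn$type_label[i],
                    paste(rxn$catalysts[[i]], collapse = ", "),
                    if (withCmp) ifelse(is.na(cmp[i]), "", cmp[i]))
        paste(fields, collapse = "\t")
    }, "")
    lines <- c(paste(header, collapse = "\t"), rows)
    if (is.null(file)) return(lines)
    writeLines(lines, file, useBytes = TRUE)
    invisible(lines)
}

#' Validate a Pathway
#'
#' Pure semantic validation: reference resolution, identifier uniqueness,
#' exactly one drug root, no self-reactions, non-empty labels (errors), and
#' reachability of every entity from the root via the directed reaction graph
#' (warnings). Never mutates its argument.
#'
#' @param p A \code{\linkS4class{Pathway}}.
#' @return An issue data.frame (possibly zero rows); see
#'   \code{\link{emptyIssues}}.
#' @export
validatePathway <- function(p) {
    stopifnot(is(p, "Pathway"))
    ents <- p@entities; rxn <- p@reactions
    iss <- emptyIssues()
    if (anyDuplicated(ents$entity_id))
        iss <- bindIssues(iss, newIssue("error", "duplicate entity_id",
                                        "entities"))
    if (any(!nzchar(ents$label)))
        iss <- bindIssues(iss, newIssue("error", "empty entity label",
                                        "entities"))
    nDrug <- sum(ents$kind == "drug")
    if (nDrug != 1L)
        iss <- bindIssues(iss, newIssue(
            "error", sprintf("pathway must have exactly one drug root (found %d)",
                             nDrug), "entities"))
    if (anyDuplicated(rxn$reaction_id))
        iss <- bindIssues(iss, newIssue("error", "duplicate reaction_id",
                                        "reactions"))
    for (i in seq_len(nrow(rxn))) {
        loc <- rxn$reaction_id[i]
        bad <- setdiff(c(rxn$substrate_id[i], rxn$product_id[i]),
                       ents$entity_id)
        if (length(bad))
            iss <- bindIssues(iss, newIssue(
                "error", sprintf("reaction %s references unknown entity id: %s",
                                 loc, paste(bad, collapse = ", ")), loc))
        if (identical(rxn$substrate_id[i], rxn$product_id[i]))
            iss <- bindIssues(iss, newIssue(
                "error", sprintf("reaction %s is a self-reaction", loc), loc))
    }
    if (nDrug == 1L && nrow(ents)) {
        root <- ents$entity_id[ents$kind == "drug"]
        reach <- .reachableFrom(root, rxn$substrate_id, rxn$product_id)
        unreachable <- setdiff(ents$entity_id, reach)
        for (u in unreachable)
            iss <- bindIssues(iss, newIssue(
                "warning",
                sprintf("entity '%s' is not reachable from the root", u), u))
    }
    iss
}

## breadth-first reachability over a directed edge list
.reachableFrom <- function(start, from, to) {
    seen <- start
    frontier <- start
    while (length(frontier)) {
        nxt <- unique(to[from %in% frontier])
        frontier <- setdiff(nxt, seen)
        seen <- c(seen, frontier)
    }
    seen
}
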
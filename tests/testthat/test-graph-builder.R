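test_that("worked-example graph duplicates CYP2D6 per reaction and annotates symbols", {
    wg <- workedExampleGraph()
    g <- wg$graph
    n <- graphNodes(g)

    cyp2d6 <- n[n$label == "CYP2D6", ]
    expect_equal(nrow(cyp2d6), 2)           # two reaction incidences
    expect_equal(cyp2d6$occurrence, c(1L, 2L))
    expect_equal(unique(cyp2d6$symbol), "arrow_down_pm")
    # each duplicate carries the PM guideline
    pmId <- guidelines(g)$guideline_id[guidelines(g)$gene == "CYP2D6"]
    expect_true(all(vapply(cyp2d6$guideline_ids,
                           function(x) pmId %in% x, TRUE)))

    expect_equal(n$symbol[n$label == "CYP2C19"], rep("arrow_up_um", 2))
    expect_equal(n$symbol[n$label == "CYP3A4"], "circle_variant_no_status")
    expect_equal(n$symbol[n$label == "CYP1A2"], "plain")
    expect_equal(n$symbol[n$role == "chemical"],
                 rep("plain", sum(n$role == "chemical")))

    # three enzymes mediate the demethylation step
    demeth <- n[grepl("#rxn001$", n$node_id), ]
    expect_setequal(demeth$label, c("CYP1A2", "CYP2C19", "CYP3A4"))
})

test_that("guidelines are conserved: attached plus orphaned equals input", {
    we <- makeWorkedExample()
    gl <- matchGuidelines(we$record, "clomipramine")
    # add a guideline for a gene absent from the pathway
    orphan <- gl[1, ]
    orphan$guideline_id <- "gl_orphan"
    orphan$gene <- "CYP99X9"
    gl2 <- rbind(gl, orphan)
    g <- buildGraph(we$pathway, gl2, variantCalls(we$record))

    attachedIds <- unique(unlist(graphNodes(g)$guideline_ids))
    orphanIds <- orphanGuidelines(g)$guideline_id
    expect_equal(sort(c(attachedIds, orphanIds)), sort(gl2$guideline_id))
    expect_equal(orphanIds, "gl_orphan")
})

test_that("symbol assignment is total, deterministic and injective on the four statuses", {
    expect_equal(assignSymbol("PM"), "arrow_down_pm")
    expect_equal(assignSymbol("IM"), "arrow_lowerright_im")
    expect_equal(assignSymbol("NM"), "arrow_right_nm")
    expect_equal(assignSymbol("UM"), "arrow_up_um")
    expect_equal(assignSymbol("UNKNOWN", hasVariant = TRUE),
                 "circle_variant_no_status")
    expect_equal(assignSymbol("UNKNOWN", hasVariant = FALSE), "plain")
    four <- vapply(c("PM", "IM", "NM", "UM"), assignSymbol, "")
    expect_equal(anyDuplicated(four), 0L)
    expect_error(assignSymbol("XX"))
})

test_that("contradiction detection matches the worked example and trivial cases", {
    gl <- guidelineStub(c("decrease_dose", "avoid"),
                        statuses = c("PM", "UM"))
    cr <- detectContradictions(gl)
    expect_equal(varyingCategories(cr), 2L)
    expect_equal(nrow(conflictPairs(cr)), 1)
    expect_setequal(unlist(conflictPairs(cr)[, c("category_1", "category_2")]),
                    c("decrease_dose", "avoid"))

    single <- detectContradictions(guidelineStub("avoid"))
    expect_lte(varyingCategories(single), 1L)
    expect_equal(nrow(conflictPairs(single)), 0)

    agreeing <- detectContradictions(guidelineStub(c("avoid", "avoid",
                                                     "standard")))
    expect_equal(nrow(conflictPairs(agreeing)), 0)
})

test_that("contradiction detection equals exhaustive pairwise enumeration (multisets of size <= 3)", {
    for (size in 0:3) {
        for (cats in categoryMultisets(size)) {
            if (!length(cats)) next
            gl <- guidelineStub(cats)
            cr <- detectContradictions(gl)
            expected <- oracleConflictPairs(cats)
            got <- conflictPairs(cr)
            expect_equal(nrow(got), length(expected),
                         label = paste(cats, collapse = "+"))
            if (length(expected)) {
                gotIdx <- lapply(seq_len(nrow(got)), function(i)
                    match(c(got$guideline_id_1[i], got$guideline_id_2[i]),
                          gl$guideline_id))
                expect_setequal(vapply(gotIdx, paste, "", collapse = "-"),
                                vapply(expected, paste, "", collapse = "-"))
            }
        }
    }
})

test_that("gene-node duplication equals per-gene reaction incidence on seeded cases", {
    for (seed in 1:30) {
        case <- generateCase(syntheticSpec(seed = seed, nMetabolites = 6,
                                           nGenes = 4, branching = 1.3))
        g <- buildGraph(case$pathway,
                        matchGuidelines(case$record,
                                        drugName(case$pathway)),
                        variantCalls(case$record))
        counts <- table(graphNodes(g)$label[graphNodes(g)$role == "gene"])
        oracle <- oracleGeneIncidence(case$pathway)
        expect_equal(sort(names(counts)), sort(names(oracle)))
        for (gene in names(oracle))
            expect_equal(unname(counts[gene]), oracle[[gene]],
                         label = sprintf("seed %d gene %s", seed, gene))
    }
})

test_that("a pathway without guidelines or variants builds an all-plain graph", {
    we <- makeWorkedExample()
    g <- buildGraph(we$pathway)
    expect_true(all(graphNodes(g)$symbol == "plain"))
    expect_equal(nrow(conflictPairs(contradictions(g))), 0)
    expect_equal(varyingCategories(contradictions(g)), 0L)
})

test_that("a zero-catalyst reaction becomes a direct chemical-to-chemical edge", {
    tsv <- c("From\tTo\tReaction Type\tController",
             "drugx\tmetA\tBiochemical Reaction\t")
    g <- buildGraph(parsePathway(tsv, "drugx"))
    expect_equal(nrow(graphNodes(g)), 2)
    e <- graphEdges(g)
    expect_equal(nrow(e), 1)
    expect_equal(e$from_id, "drugx")
    expect_equal(e$to_id, "meta")
})

test_that("collapse elides the unaffected tail of a chain into one counted edge", {
    g <- chainCase()
    collapsed <- collapseUnaffected(g)
    n <- graphNodes(collapsed)
    # root, affected gene, its product, and the terminal metabolite remain
    expect_setequal(n$node_id, c("drugx", "GENE1#rxn001", "meta", "metc"))
    ce <- graphEdges(collapsed)
    ce <- ce[ce$style == "collapsed", ]
    expect_equal(nrow(ce), 1)
    expect_equal(ce$from_id, "meta")
    expect_equal(ce$to_id, "metc")
    expect_equal(ce$collapsed_count, 2L)
})

test_that("collapse is idempotent, keeps annotated nodes, and preserves reachability (seeded cases)", {
    for (seed in 1:20) {
        case <- generateCase(syntheticSpec(seed = seed, nMetabolites = 7,
                                           nGenes = 4, branching = 1.3))
        g <- buildGraph(case$pathway,
                        matchGuidelines(case$record,
                                        drugName(case$pathway)),
                        variantCalls(case$record))
        c1 <- collapseUnaffected(g)
        c2 <- collapseUnaffected(c1)
        expect_equal(c2, c1, label = sprintf("idempotence seed %d", seed))

        nonPlain <- graphNodes(g)$node_id[graphNodes(g)$symbol != "plain"]
        expect_true(all(nonPlain %in% graphNodes(c1)$node_id),
                    label = sprintf("non-plain retention seed %d", seed))

        retained <- intersect(
            graphNodes(g)$node_id[graphNodes(g)$role == "chemical"],
            graphNodes(c1)$node_id)
        before <- oracleReachability(graphEdges(g), retained)
        after <- oracleReachability(graphEdges(c1), retained)
        expect_equal(after, before,
                     label = sprintf("reachability seed %d", seed))
    }
})

test_that("a fully affected graph collapses to itself", {
    we <- makeWorkedExample()
    gl <- matchGuidelines(we$record, "clomipramine")
    # give every pathway gene an annotation so every reaction is affected
    genes <- unique(unlist(reactions(we$pathway)$catalysts))
    vars <- data.frame(gene = genes, diplotype = "*1/*2",
                       activity_score = 1, stringsAsFactors = FALSE)
    g <- buildGraph(we$pathway, gl, vars)
    expect_true(all(graphNodes(g)$symbol[graphNodes(g)$role == "gene"] !=
                    "plain"))
    expect_equal(collapseUnaffected(g), g)
})
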
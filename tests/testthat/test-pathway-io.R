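fixtureLines <- function() {
    readLines(workedExampleFiles()[["pathway"]])
}

test_that("clomipramine fixture parses with merged catalysts and duplicated CYP2D6", {
    p <- parsePathway(workedExampleFiles()[["pathway"]], "clomipramine")
    expect_s4_class(p, "Pathway")
    expect_equal(nrow(issues(p)), 0)

    ents <- entities(p)
    expect_equal(sum(ents$kind == "drug"), 1)
    expect_equal(ents$label[ents$kind == "drug"], "clomipramine")

    rx <- reactions(p)
    demeth <- rx[rx$substrate_id == "clomipramine" &
                 rx$product_id == "desmethylclomipramine", ]
    expect_equal(nrow(demeth), 1)
    expect_setequal(demeth$catalysts[[1]], c("CYP1A2", "CYP2C19", "CYP3A4"))

    cyp2d6In <- vapply(rx$catalysts, function(x) "CYP2D6" %in% x, TRUE)
    expect_gte(sum(cyp2d6In), 2)
})

test_that("header-only table yields a synthesized root and a warning issue", {
    p <- parsePathway("From\tTo\tReaction Type\tController", "drugx")
    expect_equal(nrow(reactions(p)), 0)
    expect_equal(nrow(entities(p)), 1)
    expect_equal(entities(p)$kind, "drug")
    expect_equal(entities(p)$label, "drugx")
    expect_equal(issues(p)$severity, "warning")
})

test_that("column order and header case do not change the parse", {
    lines <- fixtureLines()
    canonical <- parsePathway(lines, "clomipramine")

    fields <- strsplit(lines, "\t")
    perm <- c(4, 2, 5, 1, 3)   # Controller, To, Compartment, From, Type
    permuted <- vapply(fields, function(f) paste(f[perm], collapse = "\t"), "")
    permuted[1] <- toupper(permuted[1])
    reparsed <- parsePathway(permuted, "CLOMIPRAMINE")

    expect_equal(reparsed, canonical)
})

test_that("same substrate/product rows merge while different pairs stay apart", {
    tsv <- c("From\tTo\tType\tGenes",
             "drugx\tmetA\tBiochemical Reaction\tcyp1a1",
             "drugx\tmetA\tBiochemical Reaction\tCYP2B2; CYP3C3",
             "drugx\tmetA\tBiochemical Reaction\tcyp1a1",   # verbatim dup
             "drugx\tmetB\tTransport\tABCB1")
    p <- parsePathway(tsv, "drugx")
    rx <- reactions(p)
    expect_equal(nrow(rx), 2)
    merged <- rx[rx$product_id == "meta", ]
    expect_setequal(merged$catalysts[[1]], c("CYP1A1", "CYP2B2", "CYP3C3"))
    expect_equal(rx$reaction_type[rx$product_id == "metb"], "other")
    expect_equal(rx$type_label[rx$product_id == "metb"], "Transport")
})

test_that("rows missing source or target are rejected into the issue list, conserving row count", {
    tsv <- c("From\tTo\tReaction Type\tController",
             "drugx\tmetA\tBiochemical Reaction\tCYP1A1",
             "\tmetB\tBiochemical Reaction\tCYP1A1",
             "metA\t\tBiochemical Reaction\t",
             "metA\tmetC\tBiochemical Reaction\tCYP1A1")
    p <- parsePathway(tsv, "drugx")
    rejected <- sum(issues(p)$severity == "error")
    expect_equal(rejected, 2)
    expect_equal(nrow(reactions(p)) + rejected, 4)   # every row accounted for
})

test_that("serialize-then-parse is the identity on a parsed Pathway", {
    p <- parsePathway(fixtureLines(), "clomipramine")
    roundtrip <- parsePathway(writePathwayTable(p), "clomipramine")
    expect_equal(roundtrip, p)

    # and the serializer itself is stable
    expect_identical(writePathwayTable(roundtrip), writePathwayTable(p))
})

test_that("root resolution: exact beats prefix, missing and ambiguous roots are fatal", {
    tsv <- c("From\tTo\tReaction Type\tController",
             "clomipramine\tclomipramine glucuronide\tBiochemical Reaction\tUGT2B10")
    # exact case-insensitive match wins over the prefix-sharing metabolite
    p <- parsePathway(tsv, "Clomipramine")
    expect_equal(entities(p)$label[entities(p)$kind == "drug"],
                 "clomipramine")
    # prefix match used when no exact match exists, but only if unique
    tsv2 <- c("From\tTo\tReaction Type\tController",
              "warfarin alcohol\tmetA\tBiochemical Reaction\tCYP2C9")
    p2 <- parsePathway(tsv2, "warfarin")
    expect_equal(entities(p2)$label[entities(p2)$kind == "drug"],
                 "warfarin alcohol")
    expect_error(parsePathway(tsv, "clomi"), "ambiguous")
    expect_error(parsePathway(tsv, "warfarin"), "root not found")
})

test_that("validatePathway flags unknown references and unreachable entities", {
    p <- parsePathway(fixtureLines(), "clomipramine")
    expect_equal(nrow(validatePathway(p)), 0)

    broken <- p
    broken@reactions$product_id[1] <- "no_such_entity"
    iss <- validatePathway(broken)
    expect_true(any(iss$severity == "error" &
                    grepl("rxn001", iss$message) &
                    grepl("no_such_entity", iss$message)))

    tsv <- c("From\tTo\tReaction Type\tController",
             "drugx\tmetA\tBiochemical Reaction\tCYP1A1",
             "metB\tmetC\tBiochemical Reaction\tCYP1A1")
    island <- parsePathway(tsv, "drugx")
    iss2 <- validatePathway(island)
    expect_setequal(iss2$location[iss2$severity == "warning"],
                    c("metb", "metc"))
})
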
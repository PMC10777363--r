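test_that("the worked example reproduces the published case", {
    we <- makeWorkedExample()
    r <- we$record

    expect_equal(nrow(variantCalls(r)), 3)
    expect_setequal(variantCalls(r)$gene, c("CYP2D6", "CYP2C19", "CYP3A4"))
    expect_setequal(variantCalls(r)$diplotype, c("*4/*6", "*17/*17",
                                                 "*1A/*1B"))
    expect_equal(r@age, 54)
    expect_equal(r@sex, "male")
    expect_setequal(r@diagnoses, c("ADHD", "depression"))
    expect_setequal(prescriptions(r)$drug_name,
                    c("clomipramine", "atomoxetine"))

    gl <- matchGuidelines(r, "clomipramine")
    cyp2c19 <- gl[gl$gene == "CYP2C19", ]
    expect_equal(cyp2c19$recommendation_category, "avoid")
    expect_match(cyp2c19$recommendation_text, "tertiary amine")
    cyp2d6 <- gl[gl$gene == "CYP2D6", ]
    expect_equal(cyp2d6$metabolizer_status, "PM")
    expect_equal(cyp2d6$dose_percent, 70)
    expect_match(cyp2d6$effect_text,
                 "^Increased metabolism of TCAs to less active compounds compared to NMs")

    expect_equal(sum(validateReport(r)$severity == "error"), 0)
    expect_equal(sum(validatePathway(we$pathway)$severity == "error"), 0)
})

test_that("identical specs generate byte-identical cases; RNG state is preserved", {
    spec <- syntheticSpec(seed = 11, nMetabolites = 5, nGenes = 3)
    set.seed(99)
    before <- .Random.seed
    a <- generateCase(spec)
    expect_identical(.Random.seed, before)
    b <- generateCase(spec)
    expect_identical(writePathwayTable(a$pathway),
                     writePathwayTable(b$pathway))
    expect_identical(writeReport(a$record), writeReport(b$record))
})

test_that("generated cases validate cleanly and stay rooted", {
    for (seed in 1:25) {
        case <- generateCase(syntheticSpec(seed = seed, nMetabolites = 6,
                                           nGenes = 4, branching = 1.4))
        expect_equal(sum(validatePathway(case$pathway)$severity == "error"),
                     0, label = sprintf("pathway seed %d", seed))
        # spanning-tree construction keeps everything reachable
        expect_equal(sum(validatePathway(case$pathway)$severity == "warning"),
                     0, label = sprintf("reachability seed %d", seed))
        expect_equal(sum(validateReport(case$record)$severity == "error"),
                     0, label = sprintf("record seed %d", seed))
    }
})

test_that("a degenerate status distribution forces every guideline status", {
    spec <- syntheticSpec(seed = 4, nMetabolites = 6, nGenes = 4,
                          statusProbs = c(PM = 0, IM = 0, NM = 1, UM = 0,
                                          UNKNOWN = 0))
    case <- generateCase(spec)
    gl <- guidelines(case$record)
    expect_gt(nrow(gl), 0)
    expect_equal(unique(gl$metabolizer_status), "NM")
})

test_that("the empirical conflict rate tracks the configured rate", {
    n <- 1000
    hasConflict <- vapply(seq_len(n), function(seed) {
        case <- generateCase(syntheticSpec(seed = 10000 + seed,
                                           nMetabolites = 4, nGenes = 3,
                                           conflictRate = 0.3))
        g <- buildGraph(case$pathway, guidelines(case$record),
                        variantCalls(case$record))
        nrow(conflictPairs(contradictions(g))) > 0
    }, TRUE)
    expect_lt(abs(mean(hasConflict) - 0.3), 0.05)
})

test_that("empirical status frequencies follow statusProbs", {
    probs <- c(PM = 0.2, IM = 0.2, NM = 0.2, UM = 0.2, UNKNOWN = 0.2)
    statuses <- character(0)
    for (seed in 1:150) {
        case <- generateCase(syntheticSpec(seed = 20000 + seed,
                                           nMetabolites = 4, nGenes = 4,
                                           statusProbs = probs,
                                           conflictRate = 0))
        r <- case$record
        gl <- guidelines(r)
        statuses <- c(statuses, gl$metabolizer_status,
                      rep("UNKNOWN", sum(!(variantCalls(r)$gene %in%
                                           gl$gene))))
    }
    observed <- table(factor(statuses, levels = names(probs)))
    p <- stats::chisq.test(observed, p = probs)$p.value
    expect_gt(p, 1e-4)
})

test_that("invalid synthetic specs are rejected", {
    expect_error(syntheticSpec(seed = 1, nMetabolites = 0), "nMetabolites")
    expect_error(syntheticSpec(seed = 1,
                               statusProbs = c(PM = 0.5, IM = 0.5, NM = 0.5,
                                               UM = 0, UNKNOWN = 0)),
                 "sum to 1")
    expect_error(syntheticSpec(seed = 1, conflictRate = 1.5), "conflictRate")
})
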
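## Packaged worked example and seeded synthetic case generator. The worked
## example ships as data files in the same formats the parsers consume
## (pathway TSV + report JSON under inst/extdata), so tests exercise the
## parsers, not in-memory constructors.

#' Paths to the packaged worked-example input files
#'
#' @return Named character vector with elements \code{pathway} (clomipramine
#'   pathway TSV) and \code{report} (patient report JSON).
#' @export
workedExampleFiles <- function() {
    c(pathway = system.file("extdata", "clomipramine_pathway.tsv",
                            package = "pgxvis", mustWork = TRUE),
      report = system.file("extdata", "john_doe_report.json",
                           package = "pgxvis", mustWork = TRUE))
}

#' The clomipramine worked example
#'
#' Loads the packaged clomipramine case: the drug's metabolism pathway
#' (demethylation to desmethylclomipramine catalyzed by three enzymes —
#' CYP1A2, CYP2C19, CYP3A4 — plus CYP2D6-mediated hydroxylation of both
#' clomipramine and desmethylclomipramine, so CYP2D6 occurs in two reactions)
#' and the report of a fictitious 54-year-old male patient diagnosed with
#' ADHD and depression, prescribed clomipramine and atomoxetine, with variant
#' calls CYP2D6*4/*6, CYP2C19*17/*17 and CYP3A4*1A/*1B. The CYP2D6 guideline
#' marks a poor metabolizer and recommends lowering the dose to 70\% of the
#' standard dose; the CYP2C19 guideline marks an ultrarapid metabolizer and
#' recommends avoiding tertiary amines — two diverging recommendations for
#' the same drug.
#'
#' @return A list with elements \code{pathway}
#'   (\code{\linkS4class{Pathway}}) and \code{record}
#'   (\code{\linkS4class{PatientRecord}}).
#' @examples
#' we <- makeWorkedExample()
#' we$pathway
#' we$record
#' @export
makeWorkedExample <- function() {
    files <- workedExampleFiles()
    list(pathway = parsePathway(files[["pathway"]], "clomipramine"),
         record = parseReport(files[["report"]]))
}

.randomDiplotype <- function() {
    alleles <- sample(c("1", "2", "3", "4", "6", "17", "1A", "1B"), 2,
                      replace = TRUE)
    paste0("*", alleles[1], "/*", alleles[2])
}

.CATEGORY_TEXT <- c(increase_dose = "increase dose",
                    decrease_dose = "decrease dose",
                    avoid = "avoid",
                    standard = "standard dose",
                    other = "monitor plasma levels")

#' Generate a seeded synthetic case
#'
#' Builds a random but reproducible (pathway, patient record) pair for
#' property testing: the pathway is a random spanning tree over
#' \code{nMetabolites} metabolites rooted at a synthetic drug, plus shortcut
#' reactions at rate \code{branching - 1}; catalysts are drawn from
#' \code{nGenes} synthetic gene symbols; every catalyst gene gets a variant
#' call and a metabolizer status drawn from \code{statusProbs}; genes with a
#' known status get a guideline whose category is chosen so that, with
#' probability \code{conflictRate}, the case contains an opposing-category
#' pair (and otherwise provably does not). Identical specs generate
#' byte-identical serializations. The generator leaves the caller's RNG
#' state untouched.
#'
#' @param spec A \code{\linkS4class{SyntheticSpec}}.
#' @return A list with elements \code{pathway} and \code{record}.
#' @examples
#' case <- generateCase(syntheticSpec(seed = 1, nMetabolites = 5, nGenes = 3))
#' case$pathway
#' @export
generateCase <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(spec@seed)

    nMet <- spec@nMetabolites
    drugLabel <- sprintf("syndrug%d", spec@seed)
    metLabels <- sprintf("metabolite%02d", seq_len(nMet))
    geneSyms <- if (spec@nGenes > 0)
        sprintf("SYNGENE%d", seq_len(spec@nGenes)) else character(0)

    ents <- data.frame(
        entity_id = makeEntityId(c(drugLabel, metLabels)),
        label = c(drugLabel, metLabels),
        kind = c("drug", rep("metabolite", nMet)),
        compartment = NA_character_, stringsAsFactors = FALSE)

    ## random spanning tree: metabolite i attaches to a uniformly chosen
    ## earlier entity, guaranteeing root-connectivity by construction
    from <- integer(nMet)
    for (i in seq_len(nMet))
        from[i] <- if (i == 1L) 1L else sample.int(i, 1L)
    to <- seq_len(nMet) + 1L
    nExtra <- max(0L, round((spec@branching - 1) * nMet))
    if (nExtra > 0 && nMet >= 2L) {
        for (k in seq_len(nExtra)) {
            a <- sample.int(nMet + 1L, 1L)
            b <- sample.int(nMet, 1L) + 1L
            if (a != b && !any(from == a & to == b)) {
                from <- c(from, a); to <- c(to, b)
            }
        }
    }
    nRxn <- length(from)
    catalysts <- lapply(seq_len(nRxn), function(i) {
        if (!length(geneSyms)) return(character(0))
        nCat <- sample(0:2, 1L, prob = c(0.2, 0.5, 0.3))
        sort(sample(geneSyms, min(nCat, length(geneSyms))))
    })
    rxn <- data.frame(reaction_id = sprintf("rxn%03d", seq_len(nRxn)),
                      substrate_id = ents$entity_id[from],
                      product_id = ents$entity_id[to],
                      reaction_type = "biochemical",
                      type_label = "Biochemical Reaction",
                      stringsAsFactors = FALSE)
    rxn$catalysts <- catalysts
    pathway <- newPathway(drugName = drugLabel, entities = ents,
                          reactions = rxn)

    usedGenes <- sort(unique(unlist(catalysts)))
    statuses <- if (length(usedGenes))
        sample(names(spec@statusProbs), length(usedGenes), replace = TRUE,
               prob = spec@statusProbs) else character(0)
    names(statuses) <- usedGenes

    wantConflict <- length(usedGenes) > 0 &&
        stats::runif(1) < spec@conflictRate
    if (wantConflict && !any(statuses != "UNKNOWN"))
        statuses[1] <- "NM"   # guarantee at least one guideline carrier

    variants <- if (length(usedGenes)) data.frame(
        gene = usedGenes,
        diplotype = vapply(usedGenes, function(g) .randomDiplotype(), ""),
        activity_score = round(stats::runif(length(usedGenes), 0, 3), 1),
        stringsAsFactors = FALSE) else emptyVariants()

    ## guideline categories: a conflicting case gets one decrease_dose and
    ## one avoid guideline; a non-conflicting case draws every actionable
    ## category from a single group (plus standard/other), so opposing pairs
    ## occur exactly when scheduled
    carriers <- usedGenes[statuses[usedGenes] != "UNKNOWN"]
    gls <- emptyGuidelines()
    if (length(carriers)) {
        slots <- data.frame(gene = carriers,
                            source = "SYNSOURCE", stringsAsFactors = FALSE)
        if (wantConflict && nrow(slots) < 2L)
            slots <- rbind(slots, data.frame(gene = carriers[1],
                                             source = "SYNSOURCE2",
                                             stringsAsFactors = FALSE))
        cats <- if (wantConflict) {
            base <- sample(c("standard", "other", "decrease_dose"),
                           nrow(slots), replace = TRUE)
            pick <- sample.int(nrow(slots), 2L)
            base[pick] <- c("decrease_dose", "avoid")
            base
        } else {
            single <- sample(c("increase_dose", "decrease_dose", "avoid"), 1L)
            sample(c(single, "standard", "other"), nrow(slots),
                   replace = TRUE, prob = c(0.6, 0.2, 0.2))
        }
        for (i in seq_len(nrow(slots))) {
            gene <- slots$gene[i]
            sev <- sample(1:3, 1L)
            recText <- sprintf("Guideline for %s and %s: %s.", drugLabel,
                               gene, .CATEGORY_TEXT[[cats[i]]])
            gls <- rbind(gls, data.frame(
                guideline_id = sprintf("gl%d", i),
                gene = gene,
                diplotype = variants$diplotype[match(gene, variants$gene)],
                metabolizer_status = unname(statuses[gene]),
                drug_name = drugLabel, drug_cas = NA_character_,
                recommendation_text = recText,
                recommendation_category = unname(cats[i]),
                category_label = unname(.CATEGORY_TEXT[[cats[i]]]),
                severity = sev, evidence_level = "3",
                source_url = "https://example.org/synthetic",
                effect_text = sprintf("Synthetic effect of %s on %s.", gene,
                                      drugLabel),
                activity_score =
                    variants$activity_score[match(gene, variants$gene)],
                dose_percent = NA_real_, source = slots$source[i],
                stringsAsFactors = FALSE))
        }
    }

    record <- newPatientRecord(
        name = sprintf("synthetic patient %d", spec@seed),
        age = sample(18:90, 1L), sex = sample(c("female", "male"), 1L),
        bmi = round(stats::runif(1, 18, 35), 1),
        diagnoses = "synthetic diagnosis",
        prescriptions = data.frame(drug_name = drugLabel,
                                   drug_cas = NA_character_,
                                   brand_name = NA_character_,
                                   stringsAsFactors = FALSE),
        variants = variants, guidelines = gls)
    list(pathway = pathway, record = record)
}
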
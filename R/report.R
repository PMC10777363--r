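## Patient PGx report parsing. The interchange document is JSON (the format a
## rule-based medication-check system exports); the schema shipped at
## inst/schema/patient-report.schema.json documents required/optional fields.

.STATUS_SYNONYMS <- c(
    "pm" = "PM", "poor metabolizer" = "PM", "poor metaboliser" = "PM",
    "im" = "IM", "intermediate metabolizer" = "IM",
    "intermediate metaboliser" = "IM",
    "nm" = "NM", "em" = "NM", "normal metabolizer" = "NM",
    "normal metaboliser" = "NM", "extensive metabolizer" = "NM",
    "extensive metaboliser" = "NM",
    "um" = "UM", "ultrarapid metabolizer" = "UM",
    "ultra-rapid metabolizer" = "UM", "ultrarapid metaboliser" = "UM",
    "ultra-rapid metaboliser" = "UM"
)

#' Normalize a metabolizer-status label
#'
#' Maps the two vocabularies used by guideline sources (abbreviations PM, IM,
#' NM/EM, UM and the spelled-out "poor/intermediate/normal/extensive/
#' ultrarapid metabolizer" forms) onto the canonical enum \code{PM, IM, NM,
#' UM}. Absent or empty input maps to \code{UNKNOWN}; anything outside the
#' synonym table is an error.
#'
#' @param x A status label (or \code{NA}/\code{NULL}/empty for UNKNOWN).
#' @return One of \code{"PM", "IM", "NM", "UM", "UNKNOWN"}.
#' @examples
#' normalizeMetabolizerStatus("poor metabolizer")   # "PM"
#' normalizeMetabolizerStatus("Ultrarapid Metabolizer") # "UM"
#' @export
normalizeMetabolizerStatus <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(x)))
        return("UNKNOWN")
    key <- tolower(trimws(x))
    if (key == "unknown") return("UNKNOWN")
    hit <- .STATUS_SYNONYMS[key]
    if (is.na(hit))
        stop(sprintf("unrecognized metabolizer status: '%s'", x),
             call. = FALSE)
    unname(hit)
}

#' Normalize a recommendation-category label
#'
#' Dosing guidance categories form a small closed set for contradiction
#' detection: substrings "increase" map to \code{increase_dose},
#' "lower"/"decrease"/"reduce" to \code{decrease_dose}, "avoid" to
#' \code{avoid}, "standard"/"no action" to \code{standard}; anything else is
#' kept as \code{other} with its verbatim label.
#'
#' @param x Category text (or \code{NA} for \code{other}).
#' @return A list with \code{category} (the enum value) and \code{label}
#'   (verbatim input).
#' @export
normalizeRecommendationCategory <- function(x) {
    label <- if (is.null(x) || length(x) == 0L || is.na(x)) "" else trimws(x)
    key <- tolower(label)
    category <-
        if (grepl("increase", key)) "increase_dose"
        else if (grepl("lower|decrease|reduce", key)) "decrease_dose"
        else if (grepl("avoid", key)) "avoid"
        else if (grepl("standard|no action|no change", key)) "standard"
        else "other"
    list(category = category, label = label)
}

#' Validate a CAS registry number's check digit
#'
#' CAS numbers have the form \code{NNNNNNN-NN-R} where \code{R} is the
#' weighted digit sum of the preceding digits (rightmost weight 1) modulo 10.
#'
#' @param cas CAS string.
#' @return \code{TRUE}/\code{FALSE}; \code{NA} for missing input.
#' @examples
#' casCheckDigitValid("303-49-1")  # clomipramine, TRUE
#' @export
casCheckDigitValid <- function(cas) {
    if (is.null(cas) || length(cas) == 0L || is.na(cas) || !nzchar(cas))
        return(NA)
    if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", cas), "")[[1]])
    n <- length(digits)
    check <- digits[n]
    body <- digits[-n]
    sum(rev(body) * seq_along(body)) %% 10L == check
}

#' Extract a dose percentage from recommendation text
#'
#' Guideline texts often quote a fraction of the standard dose ("lower the
#' dose to 70 percent of the standard dose"); this pulls the first percentage
#' out so it is machine readable.
#'
#' @param text Recommendation text.
#' @return The percentage as a number, or \code{NA} when none is quoted.
#' @export
parseDosePercent <- function(text) {
    if (is.null(text) || length(text) == 0L || is.na(text)) return(NA_real_)
    m <- regmatches(text,
                    regexpr("[0-9]+(\\.[0-9]+)?[[:space:]]*(%|percent)", text,
                            ignore.case = TRUE))
    if (!length(m)) return(NA_real_)
    as.numeric(sub("[[:space:]]*(%|percent)$", "", m, ignore.case = TRUE))
}

.chr1 <- function(x, default = NA_character_) {
    if (is.null(x) || length(x) == 0L) return(default)
    v <- as.character(x[[1]])
    if (is.na(v) || !nzchar(trimws(v))) default else trimws(v)
}

.num1 <- function(x, default = NA_real_) {
    if (is.null(x) || length(x) == 0L) return(default)
    v <- suppressWarnings(as.numeric(x[[1]]))
    if (is.na(v)) default else v
}

.KNOWN_TOP <- c("patient", "prescriptions", "gene_variants", "guidelines")
.KNOWN_PATIENT <- c("name", "age", "sex", "bmi", "diagnoses")
.KNOWN_PRESCRIPTION <- c("drug_name", "drug_cas", "brand_name")
.KNOWN_VARIANT <- c("gene", "diplotype", "activity_score")
.KNOWN_GUIDELINE <- c("gene", "diplotype", "activity_score",
                      "metabolizer_status", "drug_name", "drug_cas",
                      "recommendation_text", "recommendation_category",
                      "severity", "evidence_level", "source_url",
                      "effect_text", "source")

.warnUnknown <- function(obj, known, where) {
    extra <- setdiff(names(obj), known)
    if (length(extra))
        newIssue("warning",
                 sprintf("ignored unknown field(s): %s",
                         paste(extra, collapse = ", ")), where)
    else emptyIssues()
}

#' Parse a patient PGx report document
#'
#' Reads the JSON interchange document exported by an upstream clinical
#' decision support system: a \code{patient} object (name, age, sex, bmi,
#' diagnoses), \code{prescriptions}, \code{gene_variants} (star-allele
#' diplotype calls with optional activity score) and \code{guidelines} (one
#' object per drug--gene-variant recommendation, carrying metabolizer status,
#' recommendation text and category, severity 1--3, evidence level, source
#' URL and effect text). Unknown fields are ignored with a warning issue;
#' metabolizer statuses and recommendation categories are normalized (see
#' \code{\link{normalizeMetabolizerStatus}},
#' \code{\link{normalizeRecommendationCategory}}); a quoted dose percentage is
#' parsed into the \code{dose_percent} column; a guideline naming neither a
#' drug name nor a CAS number is rejected into the issue table.
#'
#' @param file Path to (or JSON text of) the report document.
#' @return A \code{\linkS4class{PatientRecord}}; parse diagnostics are in
#'   \code{issues(x)}.
#' @seealso \code{\link{writeReport}} for the inverse,
#'   \code{\link{validateReport}} for semantic validation.
#' @export
parseReport <- function(file) {
    doc <- tryCatch(jsonlite::fromJSON(file, simplifyVector = FALSE),
                    error = function(e) stop("malformed report document: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    if (!is.list(doc))
        stop("malformed report document: top level must be an object",
             call. = FALSE)
    iss <- .warnUnknown(doc, .KNOWN_TOP, "document")
    pat <- doc$patient
    if (!is.null(pat)) iss <- bindIssues(iss, .warnUnknown(pat, .KNOWN_PATIENT,
                                                           "patient"))
    diagnoses <- as.character(unlist(pat$diagnoses %||% list()))

    presc <- emptyPrescriptions()
    for (i in seq_along(doc$prescriptions)) {
        pr <- doc$prescriptions[[i]]
        iss <- bindIssues(iss, .warnUnknown(pr, .KNOWN_PRESCRIPTION,
                                            sprintf("prescriptions[%d]", i)))
        nm <- .chr1(pr$drug_name)
        if (is.na(nm)) {
            iss <- bindIssues(iss, newIssue(
                "error", "prescription rejected: missing drug_name",
                sprintf("prescriptions[%d]", i)))
            next
        }
        cas <- .chr1(pr$drug_cas)
        if (!is.na(cas) && isFALSE(casCheckDigitValid(cas)))
            iss <- bindIssues(iss, newIssue(
                "warning", sprintf("CAS number '%s' fails the check-digit rule",
                                   cas), sprintf("prescriptions[%d]", i)))
        presc <- rbind(presc, data.frame(drug_name = nm, drug_cas = cas,
                                         brand_name = .chr1(pr$brand_name),
                                         stringsAsFactors = FALSE))
    }

    vars <- emptyVariants()
    for (i in seq_along(doc$gene_variants)) {
        gv <- doc$gene_variants[[i]]
        iss <- bindIssues(iss, .warnUnknown(gv, .KNOWN_VARIANT,
                                            sprintf("gene_variants[%d]", i)))
        gene <- toupper(.chr1(gv$gene, ""))
        if (!nzchar(gene)) {
            iss <- bindIssues(iss, newIssue(
                "error", "variant call rejected: missing gene symbol",
                sprintf("gene_variants[%d]", i)))
            next
        }
        vars <- rbind(vars, data.frame(
            gene = gene, diplotype = .chr1(gv$diplotype),
            activity_score = .num1(gv$activity_score),
            stringsAsFactors = FALSE))
    }

    gls <- emptyGuidelines()
    for (i in seq_along(doc$guidelines)) {
        g <- doc$guidelines[[i]]
        where <- sprintf("guidelines[%d]", i)
        iss <- bindIssues(iss, .warnUnknown(g, .KNOWN_GUIDELINE, where))
        drugNm <- .chr1(g$drug_name)
        drugCas <- .chr1(g$drug_cas)
        if (is.na(drugNm) && is.na(drugCas)) {
            iss <- bindIssues(iss, newIssue(
                "error",
                "guideline rejected: missing both drug_name and drug_cas",
                where))
            next
        }
        if (!is.na(drugCas) && isFALSE(casCheckDigitValid(drugCas)))
            iss <- bindIssues(iss, newIssue(
                "warning",
                sprintf("CAS number '%s' fails the check-digit rule", drugCas),
                where))
        status <- tryCatch(normalizeMetabolizerStatus(.chr1(g$metabolizer_status)),
                           error = function(e) {
                               iss <<- bindIssues(iss, newIssue(
                                   "warning", conditionMessage(e), where))
                               "UNKNOWN"
                           })
        cat <- normalizeRecommendationCategory(.chr1(g$recommendation_category))
        ev <- toupper(.chr1(g$evidence_level, "NONE"))
        if (!(ev %in% .EVIDENCE_LEVELS)) {
            iss <- bindIssues(iss, newIssue(
                "warning", sprintf("unrecognized evidence level '%s'", ev),
                where))
            ev <- "NONE"
        }
        recText <- .chr1(g$recommendation_text, "")
        gls <- rbind(gls, data.frame(
            guideline_id = sprintf("gl%d", nrow(gls) + 1L),
            gene = toupper(.chr1(g$gene, "")),
            diplotype = .chr1(g$diplotype),
            metabolizer_status = status,
            drug_name = drugNm, drug_cas = drugCas,
            recommendation_text = recText,
            recommendation_category = cat$category,
            category_label = cat$label,
            severity = as.integer(.num1(g$severity, NA_real_)),
            evidence_level = ev,
            source_url = .chr1(g$source_url, ""),
            effect_text = .chr1(g$effect_text, ""),
            activity_score = .num1(g$activity_score),
            dose_percent = parseDosePercent(recText),
            source = .chr1(g$source, ""),
            stringsAsFactors = FALSE))
    }

    newPatientRecord(
        name = .chr1(pat$name, "unknown"), age = .num1(pat$age),
        sex = .chr1(pat$sex, "unknown"), bmi = .num1(pat$bmi),
        diagnoses = diagnoses, prescriptions = presc, variants = vars,
        guidelines = gls, issues = iss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a PatientRecord to the report document format
#'
#' Inverse of \code{\link{parseReport}}: writing a parsed record and
#' re-parsing it reproduces the record (derived columns such as
#' \code{dose_percent} are recomputed, not stored).
#'
#' @param r A \code{\linkS4class{PatientRecord}}.
#' @param file Optional path; when \code{NULL} the JSON text is returned.
#' @return The JSON text (invisibly when written to \code{file}).
#' @export
writeReport <- function(r, file = NULL) {
    stopifnot(is(r, "PatientRecord"))
    dropNa <- function(x) x[!vapply(x, function(v)
        length(v) == 0L || (length(v) == 1L && is.na(v)), TRUE)]
    doc <- list(
        patient = dropNa(list(name = r@name, age = r@age, sex = r@sex,
                              bmi = r@bmi,
                              diagnoses = as.list(r@diagnoses))),
        prescriptions = lapply(seq_len(nrow(r@prescriptions)), function(i)
            dropNa(as.list(r@prescriptions[i, , drop = FALSE]))),
        gene_variants = lapply(seq_len(nrow(r@variants)), function(i)
            dropNa(as.list(r@variants[i, , drop = FALSE]))),
        guidelines = lapply(seq_len(nrow(r@guidelines)), function(i) {
            g <- r@guidelines[i, , drop = FALSE]
            dropNa(list(
                gene = g$gene, diplotype = g$diplotype,
                activity_score = g$activity_score,
                metabolizer_status = g$metabolizer_status,
                drug_name = g$drug_name, drug_cas = g$drug_cas,
                recommendation_text = g$recommendation_text,
                recommendation_category = g$category_label,
                severity = g$severity, evidence_level = g$evidence_level,
                source_url = g$source_url, effect_text = g$effect_text,
                source = g$source))
        }))
    txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                            null = "null")
    if (is.null(file)) return(as.character(txt))
    writeLines(as.character(txt), file, useBytes = TRUE)
    invisible(as.character(txt))
}

#' Validate a PatientRecord
#'
#' Pure semantic checks: non-empty upper-case gene symbols, star-allele
#' diplotype pattern \code{*token/*token}, severity within 1..3,
#' non-negative activity scores, known enum values, CAS check digits
#' (warning), and the cross-check that every guideline's gene has a variant
#' call (warning, not error).
#'
#' @param r A \code{\linkS4class{PatientRecord}}.
#' @return An issue data.frame.
#' @export
validateReport <- function(r) {
    stopifnot(is(r, "PatientRecord"))
    iss <- emptyIssues()
    diploOk <- function(d) !is.na(d) &
        grepl("^\\*[A-Za-z0-9]+/\\*[A-Za-z0-9]+$", d)
    v <- r@variants
    for (i in seq_len(nrow(v))) {
        loc <- sprintf("variants[%d]", i)
        if (!nzchar(v$gene[i]) || v$gene[i] != toupper(v$gene[i]))
            iss <- bindIssues(iss, newIssue(
                "error", "gene symbol must be non-empty upper-case", loc))
        if (!diploOk(v$diplotype[i]))
            iss <- bindIssues(iss, newIssue(
                "error", sprintf("diplotype '%s' does not match *token/*token",
                                 v$diplotype[i]), loc))
        if (!is.na(v$activity_score[i]) && v$activity_score[i] < 0)
            iss <- bindIssues(iss, newIssue(
                "error", "activity score must be non-negative", loc))
    }
    g <- r@guidelines
    for (i in seq_len(nrow(g))) {
        loc <- sprintf("guidelines[%d] (%s)", i, g$guideline_id[i])
        if (is.na(g$severity[i]) || !(g$severity[i] %in% 1:3))
            iss <- bindIssues(iss, newIssue(
                "error", sprintf("severity %s outside 1..3",
                                 g$severity[i]), loc))
        if (!(g$metabolizer_status[i] %in% .METABOLIZER_STATUSES))
            iss <- bindIssues(iss, newIssue(
                "error", sprintf("unknown metabolizer status '%s'",
                                 g$metabolizer_status[i]), loc))
        if (!(g$recommendation_category[i] %in% .RECOMMENDATION_CATEGORIES))
            iss <- bindIssues(iss, newIssue(
                "error", sprintf("unknown recommendation category '%s'",
                                 g$recommendation_category[i]), loc))
        if (is.na(g$drug_name[i]) && is.na(g$drug_cas[i]))
            iss <- bindIssues(iss, newIssue(
                "error", "guideline names neither drug_name nor drug_cas", loc))
        if (!is.na(g$drug_cas[i]) && isFALSE(casCheckDigitValid(g$drug_cas[i])))
            iss <- bindIssues(iss, newIssue(
                "warning", sprintf("CAS number '%s' fails the check-digit rule",
                                   g$drug_cas[i]), loc))
        if (nzchar(g$gene[i]) && !(g$gene[i] %in% v$gene))
            iss <- bindIssues(iss, newIssue(
                "warning",
                sprintf("guideline gene %s has no variant call in the record",
                        g$gene[i]), loc))
        if (nzchar(g$gene[i]) && g$gene[i] %in% v$gene &&
            !is.na(g$diplotype[i])) {
            vd <- v$diplotype[match(g$gene[i], v$gene)]
            if (!is.na(vd) && vd != g$diplotype[i])
                iss <- bindIssues(iss, newIssue(
                    "warning",
                    sprintf("guideline diplotype %s disagrees with variant call %s for %s",
                            g$diplotype[i], vd, g$gene[i]), loc))
        }
    }
    iss
}

#' Default brand-name alias table
#'
#' Maps brand names to active agents for guideline matching. Shipped with the
#' single entry \code{anafranil -> clomipramine}; extend by passing your own
#' named vector to \code{\link{matchGuidelines}}.
#'
#' @return Named character vector (names are lower-case brand names).
#' @export
defaultBrandAliases <- function() {
    c(anafranil = "clomipramine")
}

.canonDrug <- function(name, aliases) {
    key <- tolower(trimws(name))
    out <- unname(aliases[key])
    ifelse(is.na(out), key, out)
}

#' Match guidelines to a prescription
#'
#' Filters a record's guidelines to those concerning one prescribed drug.
#' When both the guideline and the prescription carry a CAS number the match
#' is by CAS; otherwise drug names are compared case-insensitively after
#' brand-name aliasing (so a prescription for "Anafranil" matches
#' clomipramine guidelines). Input order is preserved.
#'
#' @param r A validated \code{\linkS4class{PatientRecord}}.
#' @param drug Either a drug name (matched against prescription drug or brand
#'   names) or a one-row slice / list with \code{drug_name}, \code{drug_cas},
#'   \code{brand_name}.
#' @param aliases Brand-name alias table; see \code{\link{defaultBrandAliases}}.
#' @return The matching subset of \code{guidelines(r)} (possibly zero rows).
#' @export
matchGuidelines <- function(r, drug, aliases = defaultBrandAliases()) {
    stopifnot(is(r, "PatientRecord"))
    if (is.character(drug) && length(drug) == 1L) {
        p <- r@prescriptions
        canon <- .canonDrug(drug, aliases)
        hit <- which(.canonDrug(p$drug_name, aliases) == canon |
                     (!is.na(p$brand_name) &
                      .canonDrug(p$brand_name, aliases) == canon))
        drug <- if (length(hit)) as.list(p[hit[1L], , drop = FALSE])
                else list(drug_name = drug, drug_cas = NA_character_,
                          brand_name = NA_character_)
    } else {
        drug <- as.list(as.data.frame(drug, stringsAsFactors = FALSE))
    }
    g <- r@guidelines
    if (!nrow(g)) return(g)
    pCas <- .chr1(drug$drug_cas)
    pNames <- stats::na.omit(c(drug$drug_name, drug$brand_name))
    pCanon <- unique(.canonDrug(pNames, aliases))
    keep <- vapply(seq_len(nrow(g)), function(i) {
        if (!is.na(pCas) && !is.na(g$drug_cas[i]))
            return(g$drug_cas[i] == pCas)
        gCanon <- .canonDrug(stats::na.omit(g$drug_name[i]), aliases)
        length(gCanon) > 0 && any(gCanon %in% pCanon)
    }, TRUE)
    out <- g[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
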
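test_that("John Doe report parses with normalized statuses and derived dose percent", {
    r <- parseReport(workedExampleFiles()[["report"]])
    expect_s4_class(r, "PatientRecord")
    expect_equal(nrow(variantCalls(r)), 3)
    expect_setequal(prescriptions(r)$drug_name,
                    c("clomipramine", "atomoxetine"))
    expect_equal(nrow(issues(r)), 0)
    expect_equal(nrow(validateReport(r)), 0)

    gl <- matchGuidelines(r, "clomipramine")
    expect_gte(nrow(gl), 2)
    pm <- gl[gl$gene == "CYP2D6", ]
    expect_equal(pm$metabolizer_status, "PM")
    expect_equal(pm$recommendation_category, "decrease_dose")
    expect_equal(pm$dose_percent, 70)
    um <- gl[gl$gene == "CYP2C19", ]
    expect_equal(um$metabolizer_status, "UM")
    expect_equal(um$recommendation_category, "avoid")
})

test_that("metabolizer status normalization is total over the synonym table and raises outside it", {
    cases <- c("PM" = "PM", "pm" = "PM", "Poor Metabolizer" = "PM",
               "IM" = "IM", "intermediate metabolizer" = "IM",
               "NM" = "NM", "EM" = "NM", "Normal Metabolizer" = "NM",
               "extensive metabolizer" = "NM",
               "UM" = "UM", "Ultrarapid Metabolizer" = "UM",
               "ultra-rapid metabolizer" = "UM")
    for (input in names(cases))
        expect_equal(normalizeMetabolizerStatus(input), unname(cases[input]),
                     label = input)
    expect_equal(normalizeMetabolizerStatus(NA), "UNKNOWN")
    expect_equal(normalizeMetabolizerStatus(""), "UNKNOWN")
    expect_equal(normalizeMetabolizerStatus(NULL), "UNKNOWN")
    expect_error(normalizeMetabolizerStatus("hyperactive"), "unrecognized")
})

test_that("recommendation categories normalize onto the closed set", {
    expect_equal(normalizeRecommendationCategory("increase dose")$category,
                 "increase_dose")
    expect_equal(normalizeRecommendationCategory("Lower the dose")$category,
                 "decrease_dose")
    expect_equal(normalizeRecommendationCategory("reduce to 70%")$category,
                 "decrease_dose")
    expect_equal(normalizeRecommendationCategory("AVOID drug")$category,
                 "avoid")
    expect_equal(normalizeRecommendationCategory("standard dose")$category,
                 "standard")
    res <- normalizeRecommendationCategory("monitor plasma levels")
    expect_equal(res$category, "other")
    expect_equal(res$label, "monitor plasma levels")
})

test_that("CAS check-digit validation accepts real numbers and rejects corrupted ones", {
    expect_true(casCheckDigitValid("303-49-1"))     # clomipramine
    expect_true(casCheckDigitValid("83015-26-3"))   # atomoxetine
    expect_true(casCheckDigitValid("50-00-0"))      # formaldehyde
    expect_false(casCheckDigitValid("303-49-2"))
    expect_false(casCheckDigitValid("not-a-cas"))
    expect_true(is.na(casCheckDigitValid(NA)))
})

test_that("dose percentages are pulled out of recommendation text", {
    expect_equal(parseDosePercent("lower to 70 percent of the standard dose"),
                 70)
    expect_equal(parseDosePercent("give 12.5% of the dose"), 12.5)
    expect_true(is.na(parseDosePercent("avoid the drug")))
    expect_true(is.na(parseDosePercent(NA)))
})

test_that("unknown fields, bad statuses and drugless guidelines degrade to issues, not crashes", {
    doc <- '{
      "patient": {"name": "X", "age": 40, "sex": "female",
                  "favorite_color": "green"},
      "prescriptions": [{"drug_name": "drugx"}],
      "gene_variants": [{"gene": "CYP2D6", "diplotype": "*1/*1"}],
      "guidelines": [
        {"gene": "CYP2D6", "drug_name": "drugx", "severity": 2,
         "metabolizer_status": "hyperactive"},
        {"gene": "CYP2C19", "severity": 2}
      ]
    }'
    r <- parseReport(doc)
    iss <- issues(r)
    expect_true(any(iss$severity == "warning" &
                    grepl("favorite_color", iss$message)))
    expect_true(any(iss$severity == "warning" &
                    grepl("hyperactive", iss$message)))
    # guideline without either drug identifier is rejected
    expect_equal(nrow(guidelines(r)), 1)
    expect_true(any(iss$severity == "error" &
                    grepl("drug_name", iss$message)))
    # the unparseable status fell back to UNKNOWN
    expect_equal(guidelines(r)$metabolizer_status, "UNKNOWN")
    expect_error(parseReport('{"patient": '), "malformed")
})

test_that("validateReport flags out-of-range severity and unknown-gene guidelines", {
    doc <- '{
      "patient": {"name": "X", "age": 40, "sex": "female"},
      "gene_variants": [{"gene": "CYP2D6", "diplotype": "*1/*1"}],
      "guidelines": [
        {"gene": "CYP2D6", "drug_name": "drugx", "severity": 7},
        {"gene": "CYP2C19", "drug_name": "drugx", "severity": 2}
      ]
    }'
    iss <- validateReport(parseReport(doc))
    expect_true(any(iss$severity == "error" & grepl("severity 7", iss$message)))
    expect_true(any(iss$severity == "warning" &
                    grepl("CYP2C19", iss$message)))
})

test_that("guideline matching filters by CAS when available, else by aliased name", {
    r <- parseReport(workedExampleFiles()[["report"]])
    byName <- matchGuidelines(r, "clomipramine")
    byBrand <- matchGuidelines(r, "Anafranil")
    expect_equal(byBrand, byName)
    expect_setequal(byName$gene, c("CYP2D6", "CYP2C19"))
    # matching is a filter
    expect_true(all(byName$guideline_id %in% guidelines(r)$guideline_id))
    # CAS match wins when both sides carry one (name intentionally wrong)
    byCas <- matchGuidelines(r, list(drug_name = "mystery",
                                     drug_cas = "303-49-1",
                                     brand_name = NA_character_))
    expect_equal(byCas, byName)
    # atomoxetine only gets its own guideline
    ato <- matchGuidelines(r, "atomoxetine")
    expect_equal(ato$gene, "CYP2D6")
    expect_equal(ato$drug_name, "atomoxetine")
    # empty-guideline record
    empty <- parseReport('{"patient": {"name": "X"}, "guidelines": []}')
    expect_equal(nrow(matchGuidelines(empty, "drugx")), 0)
})

test_that("serialize-then-parse is the identity on a PatientRecord", {
    r <- parseReport(workedExampleFiles()[["report"]])
    roundtrip <- parseReport(writeReport(r))
    expect_equal(roundtrip, r)
})
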
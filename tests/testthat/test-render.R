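countMatches <- function(pattern, text) {
    length(gregexpr(pattern, text, fixed = TRUE)[[1]]) *
        as.integer(grepl(pattern, text, fixed = TRUE))
}

test_that("the SVG has one glyph per node and one path per edge", {
    wg <- workedExampleGraph()
    g <- wg$graph
    lay <- forceLayout(g, seed = 1)
    svg <- renderSvg(g, lay)
    expect_equal(countMatches('<g class="node', svg), nrow(graphNodes(g)))
    expect_equal(countMatches('class="edge edge-', svg), nrow(graphEdges(g)))
    # deterministic output
    expect_identical(renderSvg(g, lay), svg)
    # well-formed XML with the SVG namespace
    doc <- xml2::read_xml(svg)
    expect_equal(xml2::xml_name(doc), "svg")
})

test_that("a single-node graph renders one glyph and no edges", {
    g <- buildGraph(parsePathway("From\tTo\tReaction Type\tController",
                                 "drugx"))
    svg <- renderSvg(g, forceLayout(g, seed = 1))
    expect_equal(countMatches('<g class="node', svg), 1)
    expect_equal(countMatches('class="edge edge-', svg), 0)
})

test_that("collapsed edges get a distinct stroke pattern and an elided-count label", {
    collapsed <- collapseUnaffected(chainCase())
    svg <- renderSvg(collapsed, forceLayout(collapsed, seed = 1))
    expect_match(svg, 'class="edge edge-collapsed"')
    expect_match(svg, 'stroke-dasharray="2 5"')
    expect_match(svg, '2 elided')
})

test_that("the document shows patient panel, legend, tooltips, details and drug selector", {
    wg <- workedExampleGraph()
    g <- wg$graph
    html <- renderDocument(g, wg$we$record, forceLayout(g, seed = 1))

    expect_equal(countMatches('class="legend-entry"', html), 5)
    expect_match(html, '<select id="drug-selector">')
    expect_match(html, '<option value="clomipramine"')
    expect_match(html, '<option value="atomoxetine"')
    expect_match(html, "John Doe")
    expect_match(html, "Age: 54")
    expect_match(html, "BMI: 26.1")

    # tooltip summarizes status, recommendation, activity score, severity
    expect_match(html, "status PM; recommendation: decrease dose; activity score 0; severity 3")
    # contradiction banner lists the diverging categories
    expect_match(html, 'class="contradiction-banner"')
    expect_match(html, "avoid vs decrease_dose")
    # expandable full-text guideline section with source link
    expect_match(html, '<details class="guideline"')
    expect_match(html, "https://www.pharmgkb.org/guidelineAnnotation/PA166104959")
    expect_match(html, "70 percent of the standard dose")
})

test_that("a record without guidelines renders without banner and with plain glyphs", {
    we <- makeWorkedExample()
    g <- buildGraph(we$pathway)   # no guidelines, no variants
    bare <- parseReport('{"patient": {"name": "Nobody", "age": 30, "sex": "female"},
                          "prescriptions": [{"drug_name": "clomipramine"}]}')
    html <- renderDocument(g, bare, forceLayout(g, seed = 1))
    expect_false(grepl('class="contradiction-banner"', html))
    expect_false(grepl("symbol-arrow", html))
    expect_false(grepl("drug-selector", html))   # single prescription
    # rendering drops no node
    expect_equal(countMatches('<g class="node', html), nrow(graphNodes(g)))
})
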
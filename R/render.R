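## Static SVG and self-contained interactive HTML rendering. Everything is
## string-assembled on purpose: the outputs must be deterministic, inspectable
## in tests, and free of runtime dependencies (clinical environments are
## offline-hostile, so the HTML embeds all data and script inline).

.SYMBOL_META <- data.frame(
    symbol = c("arrow_down_pm", "arrow_lowerright_im", "arrow_right_nm",
               "arrow_up_um", "circle_variant_no_status"),
    label = c("Poor metabolizer (slower metabolism)",
              "Intermediate metabolizer",
              "Normal metabolizer",
              "Ultrarapid metabolizer (faster metabolism)",
              "Variant present, no metabolizer status"),
    color = c("#1f4e9c", "#6db3e8", "#2e8b57", "#d62728", "#1f4e9c"),
    stringsAsFactors = FALSE)

.escapeXml <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    x <- gsub("\"", "&quot;", x, fixed = TRUE)
    gsub("'", "&#39;", x, fixed = TRUE)
}

.fmt <- function(x) formatC(x, format = "f", digits = 2)

## arrow glyph path (unit arrow pointing right, centered at origin),
## rotated per symbol class
.arrowPath <- function(cx, cy, r, angleDeg) {
    a <- angleDeg * pi / 180
    pts <- matrix(c(-1, 0.45, 0.1, 0.45, 0.1, 0.95, 1, 0,
                    0.1, -0.95, 0.1, -0.45, -1, -0.45),
                  ncol = 2, byrow = TRUE) * r
    rot <- cbind(pts[, 1] * cos(a) - pts[, 2] * sin(a),
                 pts[, 1] * sin(a) + pts[, 2] * cos(a))
    paste0("M", paste(.fmt(rot[, 1] + cx), .fmt(rot[, 2] + cy),
                      sep = ",", collapse = " L"), " Z")
}

.SYMBOL_ANGLES <- c(arrow_down_pm = 90, arrow_lowerright_im = 45,
                    arrow_right_nm = 0, arrow_up_um = -90)

.nodeGlyph <- function(node, x, y, r) {
    sym <- node$symbol
    cls <- sprintf("node role-%s symbol-%s", node$role, sym)
    body <-
        if (sym %in% names(.SYMBOL_ANGLES)) {
            col <- .SYMBOL_META$color[.SYMBOL_META$symbol == sym]
            sprintf('<path d="%s" fill="%s"/>',
                    .arrowPath(x, y, 1.2 * r, .SYMBOL_ANGLES[[sym]]), col)
        } else if (sym == "circle_variant_no_status") {
            sprintf('<circle cx="%s" cy="%s" r="%s" fill="#1f4e9c" stroke="#f2c200" stroke-width="%s"/>',
                    .fmt(x), .fmt(y), .fmt(r), .fmt(r / 3))
        } else if (node$role == "chemical") {
            fill <- if (isTRUE(node$is_root)) "#8e6bbf" else "#c8c8c8"
            sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#555555"/>',
                    .fmt(x), .fmt(y), .fmt(r * 1.15), fill)
        } else {
            sprintf('<circle cx="%s" cy="%s" r="%s" fill="#e8e8e8" stroke="#888888"/>',
                    .fmt(x), .fmt(y), .fmt(r))
        }
    tooltip <- if (!is.null(node$tooltip) && nzchar(node$tooltip))
        sprintf(' data-tooltip="%s"', .escapeXml(node$tooltip)) else ""
    sprintf('<g class="%s" data-node-id="%s"%s>%s<text class="node-label" x="%s" y="%s" text-anchor="middle" font-size="%s">%s</text></g>',
            cls, .escapeXml(node$node_id), tooltip, body,
            .fmt(x), .fmt(y + 2.2 * r), .fmt(1.1 * r),
            .escapeXml(node$label))
}

.scalePositions <- function(pos, width, height, margin) {
    rng <- function(v) {
        r <- range(v)
        if (diff(r) < 1e-9) r + c(-0.5, 0.5) else r
    }
    rx <- rng(pos[, 1]); ry <- rng(pos[, 2])
    cbind(margin + (pos[, 1] - rx[1]) / diff(rx) * (width - 2 * margin),
          margin + (pos[, 2] - ry[1]) / diff(ry) * (height - 2 * margin))
}

.svgBody <- function(g, layout, width, height, nodeRadius) {
    pos <- layout@positions[g@nodes$node_id, , drop = FALSE]
    xy <- .scalePositions(pos, width, height, margin = 40)
    nodeFor <- stats::setNames(seq_len(nrow(g@nodes)), g@nodes$node_id)
    edgeTags <- vapply(seq_len(nrow(g@edges)), function(i) {
        e <- g@edges[i, ]
        p1 <- xy[nodeFor[[e$from_id]], ]
        p2 <- xy[nodeFor[[e$to_id]], ]
        dash <- switch(e$style, solid_biochemical = "",
                       dashed_other = ' stroke-dasharray="7 4"',
                       collapsed = ' stroke-dasharray="2 5"')
        lbl <- if (e$style == "collapsed")
            sprintf('<text class="collapsed-count" x="%s" y="%s" font-size="11" text-anchor="middle">%d elided</text>',
                    .fmt((p1[1] + p2[1]) / 2), .fmt((p1[2] + p2[2]) / 2 - 4),
                    e$collapsed_count)
        else ""
        sprintf('<path class="edge edge-%s" d="M%s,%s L%s,%s" stroke="#777777" stroke-width="1.6" fill="none" marker-end="url(#arrowhead)"%s/>%s',
                e$style, .fmt(p1[1]), .fmt(p1[2]), .fmt(p2[1]), .fmt(p2[2]),
                dash, lbl)
    }, "")
    nodeTags <- vapply(seq_len(nrow(g@nodes)), function(i) {
        node <- as.list(g@nodes[i, , drop = FALSE])
        node$guideline_ids <- node$guideline_ids[[1]]
        node$is_root <- identical(node$node_id, g@rootId)
        node$tooltip <- .nodeTooltip(node, g@guidelineTable)
        .nodeGlyph(node, xy[i, 1], xy[i, 2], nodeRadius)
    }, "")
    paste0(
        '<defs><marker id="arrowhead" markerWidth="8" markerHeight="8" refX="7" refY="3" orient="auto"><path d="M0,0 L7,3 L0,6 Z" fill="#777777"/></marker></defs>',
        paste(edgeTags, collapse = "\n"), "\n",
        paste(nodeTags, collapse = "\n"))
}

.nodeTooltip <- function(node, guidelineTable) {
    if (node$role != "gene") return("")
    parts <- c(sprintf("%s", node$label))
    gl <- guidelineTable[guidelineTable$guideline_id %in% node$guideline_ids, ,
                         drop = FALSE]
    if (nrow(gl)) {
        for (i in seq_len(nrow(gl)))
            parts <- c(parts, sprintf(
                "status %s; recommendation: %s; activity score %s; severity %s",
                gl$metabolizer_status[i], gl$category_label[i],
                ifelse(is.na(gl$activity_score[i]), "n/a",
                       gl$activity_score[i]),
                ifelse(is.na(gl$severity[i]), "n/a", gl$severity[i])))
    } else if (!is.na(node$variant_diplotype)) {
        parts <- c(parts, sprintf("variant %s%s, no metabolizer status",
                                  node$label, node$variant_diplotype))
    }
    paste(parts, collapse = " | ")
}

#' Render an annotated graph as a static SVG image
#'
#' One glyph per node (shape per symbol class, see \code{\link{assignSymbol}})
#' and one path per edge; collapsed edges get a distinct dash pattern and an
#' elided-reaction count label. Output is deterministic for fixed inputs.
#'
#' @param g An \code{\linkS4class{AnnotatedGraph}}.
#' @param layout A \code{\linkS4class{LayoutResult}} covering \code{g}.
#' @param file Optional path to write the SVG to.
#' @param width,height Canvas size in pixels.
#' @param nodeRadius Glyph radius in pixels.
#' @return The SVG text (invisibly when written to \code{file}).
#' @export
renderSvg <- function(g, layout, file = NULL, width = 900, height = 620,
                      nodeRadius = 14) {
    stopifnot(is(g, "AnnotatedGraph"), is(layout, "LayoutResult"))
    if (!all(g@nodes$node_id %in% rownames(layout@positions)))
        stop("layout does not cover all graph nodes", call. = FALSE)
    svg <- sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">\n<title>%s metabolism pathway</title>\n%s\n</svg>',
        width, height, width, height, .escapeXml(g@drugLabel),
        .svgBody(g, layout, width, height, nodeRadius))
    if (is.null(file)) return(svg)
    writeLines(svg, file, useBytes = TRUE)
    invisible(svg)
}

.legendHtml <- function() {
    entries <- vapply(seq_len(nrow(.SYMBOL_META)), function(i) {
        m <- .SYMBOL_META[i, ]
        glyph <- if (m$symbol == "circle_variant_no_status")
            sprintf('<svg width="26" height="26"><circle cx="13" cy="13" r="8" fill="%s" stroke="#f2c200" stroke-width="3"/></svg>', m$color)
        else
            sprintf('<svg width="26" height="26"><path d="%s" fill="%s"/></svg>',
                    .arrowPath(13, 13, 10, .SYMBOL_ANGLES[[m$symbol]]), m$color)
        sprintf('<div class="legend-entry" data-symbol="%s">%s<span>%s</span></div>',
                m$symbol, glyph, .escapeXml(m$label))
    }, "")
    sprintf('<div id="legend"><h3>Legend</h3>%s</div>',
            paste(entries, collapse = "\n"))
}

.patientPanelHtml <- function(r) {
    sprintf(paste0(
        '<div id="patient-panel"><h3>Patient</h3><ul>',
        '<li>Name: %s</li><li>Age: %s years</li><li>Sex: %s</li>',
        '<li>BMI: %s</li><li>Diagnoses: %d</li><li>Prescriptions: %d</li>',
        '</ul></div>'),
        .escapeXml(r@name), ifelse(is.na(r@age), "n/a", r@age),
        .escapeXml(r@sex), ifelse(is.na(r@bmi), "n/a", r@bmi),
        length(r@diagnoses), nrow(r@prescriptions))
}

.drugSelectorHtml <- function(r, current) {
    if (nrow(r@prescriptions) <= 1L) return("")
    opts <- vapply(r@prescriptions$drug_name, function(d)
        sprintf('<option value="%s"%s>%s</option>', .escapeXml(d),
                if (tolower(d) == tolower(current)) ' selected="selected"'
                else "", .escapeXml(d)), "")
    sprintf(paste0(
        '<label for="drug-selector">Drug:</label> ',
        '<select id="drug-selector">%s</select>',
        '<noscript>Re-render to switch drugs.</noscript>'),
        paste(opts, collapse = ""))
}

.contradictionBannerHtml <- function(cr) {
    if (!nrow(cr@conflicts)) return("")
    cats <- sort(unique(c(cr@conflicts$category_1, cr@conflicts$category_2)))
    sprintf(paste0(
        '<div class="contradiction-banner">Contradictory recommendations ',
        'for %s: %d guideline pair(s) with diverging categories (%s)</div>'),
        .escapeXml(cr@drugLabel), nrow(cr@conflicts),
        .escapeXml(paste(cats, collapse = " vs ")))
}

.guidelineDetailsHtml <- function(g) {
    gl <- g@guidelineTable
    if (!nrow(gl)) return("")
    items <- vapply(seq_len(nrow(gl)), function(i) {
        x <- gl[i, ]
        sprintf(paste0(
            '<details class="guideline" id="%s"><summary>%s %s &#8212; %s ',
            '(severity %s, evidence %s)</summary>',
            '<p class="rec-text">%s</p><p class="effect-text">%s</p>',
            '<p><a href="%s">Source</a> (%s)</p></details>'),
            .escapeXml(x$guideline_id), .escapeXml(x$gene),
            .escapeXml(ifelse(is.na(x$diplotype), "", x$diplotype)),
            .escapeXml(x$metabolizer_status),
            ifelse(is.na(x$severity), "n/a", x$severity),
            .escapeXml(x$evidence_level),
            .escapeXml(x$recommendation_text), .escapeXml(x$effect_text),
            .escapeXml(x$source_url), .escapeXml(x$source))
    }, "")
    sprintf('<div id="guideline-details"><h3>Guidelines</h3>%s</div>',
            paste(items, collapse = "\n"))
}

.TOOLTIP_SCRIPT <- paste0(
    '<script>(function(){',
    'var tip=document.getElementById("tooltip");',
    'var max=280;',
    'document.querySelectorAll("g.node[data-tooltip]").forEach(function(n){',
    'n.addEventListener("mouseenter",function(ev){',
    'var t=n.getAttribute("data-tooltip");',
    'tip.textContent=t.length>max?t.slice(0,max)+"\\u2026 (click node for full text)":t;',
    'tip.style.display="block";',
    'tip.style.left=(ev.pageX+12)+"px";tip.style.top=(ev.pageY+12)+"px";});',
    'n.addEventListener("mouseleave",function(){tip.style.display="none";});',
    'n.addEventListener("click",function(){',
    'document.querySelectorAll("#guideline-details details").forEach(',
    'function(d){d.open=true;});});});',
    '})();</script>')

#' Render a self-contained interactive report document
#'
#' Produces one standalone HTML file mirroring the visual layout of the tool:
#' a patient panel, the pathway graph with status glyphs, a legend of all
#' five non-plain symbol classes, hover tooltips on gene nodes (status,
#' recommendation, activity score, severity; truncated with an expand
#' affordance), an expandable full-text guideline section with source links,
#' a contradiction banner when recommendations diverge, and a drug selector
#' when the record holds more than one prescription (switching drugs means
#' re-rendering; the selector documents what else is prescribed). All data
#' and script are inline: the file needs no network access.
#'
#' @param g An \code{\linkS4class{AnnotatedGraph}}.
#' @param r The \code{\linkS4class{PatientRecord}} the graph was built from.
#' @param layout A \code{\linkS4class{LayoutResult}} covering \code{g}.
#' @param file Optional path to write the document to.
#' @return The HTML text (invisibly when written to \code{file}).
#' @export
renderDocument <- function(g, r, layout, file = NULL) {
    stopifnot(is(g, "AnnotatedGraph"), is(r, "PatientRecord"),
              is(layout, "LayoutResult"))
    svg <- renderSvg(g, layout)
    css <- paste0(
        "body{font-family:sans-serif;margin:0;display:grid;",
        "grid-template-columns:220px 1fr 240px;gap:12px;padding:12px}",
        "#tooltip{display:none;position:absolute;background:#fffbe6;",
        "border:1px solid #aaa;padding:6px;max-width:320px;font-size:13px}",
        ".contradiction-banner{grid-column:1/4;background:#ffe0e0;",
        "border:1px solid #c00;padding:8px}",
        "#guideline-details{grid-column:1/4}",
        ".legend-entry{display:flex;align-items:center;gap:6px}")
    html <- paste0(
        "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
        sprintf("<title>PGx report: %s</title>", .escapeXml(g@drugLabel)),
        "<style>", css, "</style></head><body>\n",
        .contradictionBannerHtml(g@contradictions),
        .patientPanelHtml(r), "\n",
        "<div id=\"graph-panel\">",
        .drugSelectorHtml(r, g@drugLabel), "\n", svg, "</div>\n",
        .legendHtml(), "\n",
        .guidelineDetailsHtml(g), "\n",
        "<div id=\"tooltip\"></div>\n", .TOOLTIP_SCRIPT,
        "\n</body></html>")
    if (is.null(file)) return(html)
    writeLines(html, file, useBytes = TRUE)
    invisible(html)
}
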
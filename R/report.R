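#' Chi-square report over a set of crosses
#'
#' Evaluates every cross table and binds the per-class results into a single
#' report mirroring the layout of a deletion-stacking screening summary:
#' one row per cross x expected class with observed/expected counts,
#' statistic, p-value, significance flag and bold marker.
#'
#' @param tables List of [ObservedCrossTable-class] objects.
#' @param config A [SignificanceConfig-class].
#' @return A data.frame with columns `gene`, `cross`, `index`, `n_screened`
#'   plus the [perClassChiSquare()] columns.
#' @export
crossReport <- function(tables, config = SignificanceConfig()) {
    do.call(rbind, lapply(tables, function(tab) {
        res <- evaluateCrossTable(tab, config = config)
        if (!nrow(res)) return(NULL)
        cbind(data.frame(gene = tab@gene, cross = tab@cross@label,
                         index = tab@cross@index, n_screened = tab@n,
                         stringsAsFactors = FALSE),
              res)
    }))
}

#' Screening summary for one gene
#'
#' Aggregates the crosses targeting a gene: total progeny screened, per-class
#' observed totals, and the per-cross significance flags from
#' [evaluateCrossTable()].
#'
#' @param tables List of [ObservedCrossTable-class] objects, all for the
#'   same gene.
#' @param gene Gene label the tables must share.
#' @param config A [SignificanceConfig-class].
#' @return A list with `gene`, `n_crosses`, `total_screened`,
#'   `class_totals` (named integer vector) and `report` (the per-cross
#'   chi-square report).
#' @export
summarizeScreening <- function(tables, gene, config = SignificanceConfig()) {
    genes <- vapply(tables, function(t) t@gene, character(1))
    if (length(tables) && !all(genes == gene))
        stop("cross tables target ", paste(unique(genes), collapse = ", "),
             " but gene = ", gene)
    classTotals <- structure(integer(length(DETECTED_CLASSES) - 1L),
                             names = setdiff(DETECTED_CLASSES, "none"))
    for (t in tables)
        classTotals[names(t@counts)] <- classTotals[names(t@counts)] +
            t@counts
    list(gene = gene,
         n_crosses = length(tables),
         total_screened = sum(vapply(tables, function(t) t@n, integer(1))),
         class_totals = classTotals,
         report = if (length(tables)) crossReport(tables, config) else NULL)
}

#' Render deletion intervals as a plain-text marker track
#'
#' One row per interval on the marker grid of the panel: `#` marks markers
#' inside the minimum deleted span, `~` markers inside the possible maximal
#' extent (up to, excluding, the bounding intact markers), `|` the bounding
#' intact markers, `>` an open end, and `.` markers outside the interval.
#'
#' @param intervals List of [DeletionInterval-class] objects.
#' @param panel The [MarkerPanel-class] the intervals refer to.
#' @return A character vector of lines (header first), printed as a side
#'   effect is left to the caller.
#' @export
renderIntervalTrack <- function(intervals, panel) {
    m <- markers(panel)
    off <- m$offset_kb
    header <- paste0(format("mutant", width = 18),
                     paste(formatC(ifelse(abs(off) >= 1000,
                                          paste0(off / 1000, "M"), off),
                                   width = 6), collapse = ""))
    lines <- vapply(intervals, function(iv) {
        upBound <- if (iv@openUp) -Inf else
            off[m$gene_id == iv@upBoundMarker]
        downBound <- if (iv@openDown) Inf else
            off[m$gene_id == iv@downBoundMarker]
        ## reconstruct the deleted run bounds from the interval arithmetic
        glyph <- rep(".", length(off))
        inside <- off > upBound & off < downBound
        glyph[inside] <- "~"
        if (!iv@openUp) glyph[off == upBound] <- "|"
        if (!iv@openDown) glyph[off == downBound] <- "|"
        if (iv@openUp) glyph[1L] <- ">"
        if (iv@openDown) glyph[length(glyph)] <- ">"
        label <- sprintf("%s [%s]", iv@mutantId, iv@subgenome)
        paste0(format(label, width = 18),
               paste(formatC(glyph, width = 6), collapse = ""),
               sprintf("  min %g kb, max %s", iv@minSize,
                       if (is.finite(iv@maxSize))
                           paste0(iv@maxSize, " kb")
                       else paste0("> ", iv@minSize, " kb (open)")))
    }, character(1))
    c(header, lines)
}
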
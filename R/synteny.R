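#' Infer a deletion interval from flanking-marker intactness
#'
#' The minimum span runs from the outermost marker called deleted on the Up
#' side to the outermost deleted marker on the Down side of the anchor. On
#' each side the deletion may extend until the nearest marker beyond the
#' deleted run carrying a definite `intact` call; markers called `unknown`
#' are skipped when locating that bound. If no intact marker exists beyond
#' the run on a side, the maximum is open (`Inf`) on that side.
#'
#' A marker called deleted beyond an intervening intact marker is excluded
#' from the interval with a non-contiguous-deletion warning (possible
#' rearrangement).
#'
#' @param profile An [IntactnessProfile-class]; the anchor gene must be
#'   called `deleted`.
#' @param panel A [MarkerPanel-class].
#' @return A [DeletionInterval-class].
#' @examples
#' panel <- pft1FlankPanel()
#' calls <- structure(rep("unknown", nrow(markers(panel))),
#'                    names = markers(panel)$gene_id)
#' calls[markers(panel)$offset_kb >= -400 & markers(panel)$offset_kb <= 100] <-
#'     "deleted"
#' calls[markers(panel)$offset_kb %in% c(-700, 200)] <- "intact"
#' inferDeletionInterval(IntactnessProfile("mut", "A", calls), panel)
#' @export
inferDeletionInterval <- function(profile, panel) {
    stopifnot(is(profile, "IntactnessProfile"), is(panel, "MarkerPanel"))
    m <- markers(panel)
    calls <- profile@calls
    if (!length(calls)) stop("empty intactness profile")
    unknownGenes <- setdiff(names(calls), m$gene_id)
    if (length(unknownGenes))
        stop("profile calls genes absent from the panel: ",
             paste(unknownGenes, collapse = ", "))
    status <- structure(rep("unknown", nrow(m)), names = m$gene_id)
    status[names(calls)] <- calls
    off <- m$offset_kb
    anchorIdx <- which(off == 0)
    if (status[anchorIdx] != "deleted")
        stop("anchor gene ", sQuote(m$gene_id[anchorIdx]),
             " is not called deleted; no deletion interval to infer")

    ## Walk outward from the anchor: the deleted run continues through
    ## deleted and unknown markers and stops at the first intact marker.
    runEnd <- function(idxSeq) {
        lastDeleted <- anchorIdx
        bound <- NA_integer_
        for (i in idxSeq) {
            if (status[i] == "intact") {
                bound <- i
                break
            }
            if (status[i] == "deleted") lastDeleted <- i
        }
        list(lastDeleted = lastDeleted, bound = bound,
             stopped = !is.na(bound))
    }
    up <- runEnd(rev(seq_len(anchorIdx - 1L)))
    down <- runEnd(seq(anchorIdx + 1L, length.out = nrow(m) - anchorIdx))

    ## deleted markers beyond an intact bound: non-contiguous, excluded
    outside <- (off < ifelse(up$stopped, off[up$bound], -Inf) |
                off > ifelse(down$stopped, off[down$bound], Inf)) &
        status == "deleted"
    if (any(outside))
        warning("non-contiguous deletion: marker(s) ",
                paste(m$gene_id[outside], collapse = ", "),
                " called deleted beyond an intact marker; excluded from the ",
                "interval (possible rearrangement)")

    minUp <- off[up$lastDeleted]
    minDown <- off[down$lastDeleted]
    minSize <- minDown - minUp
    maxSize <- (if (up$stopped) -off[up$bound] else Inf) +
        (if (down$stopped) off[down$bound] else Inf)
    new("DeletionInterval",
        minSize = minSize, maxSize = maxSize,
        upBoundMarker = if (up$stopped) m$gene_id[up$bound] else "none assayed",
        downBoundMarker = if (down$stopped) m$gene_id[down$bound]
                          else "none assayed",
        openUp = !up$stopped, openDown = !down$stopped,
        mutantId = profile@mutantId, subgenome = profile@subgenome)
}

#' Classify synteny conservation of one gene from homology hits
#'
#' With no hit on any target chromosome arm the gene is `translocated`.
#' Otherwise each arm is represented by its single best hit (smallest
#' e-value, ties by identity then alignment length): the gene is `conserved`
#' if some target-arm best hit is not matched-or-beaten by an off-target
#' best hit of equal-or-greater identity *and* length; if every target-arm
#' hit is dominated, the call is `uncertain`.
#'
#' @param hits data.frame of hits for a single query gene with columns
#'   `query_gene`, `subject_arm`, `identity` (percent), `align_length`,
#'   `e_value`.
#' @param targetArms Character vector of arms where a homoeologue is
#'   expected (e.g. `c("5AL", "5BL", "5DL")`).
#' @return A one-row data.frame: `query_gene`, `status`, `evidence_arms`
#'   (comma-separated target arms supporting conservation, or all target
#'   arms hit).
#' @export
classifySynteny <- function(hits, targetArms) {
    if (!length(targetArms)) stop("targetArms must be non-empty")
    if (!nrow(hits)) {
        warning("no hits supplied; translocation call carries zero evidence")
        return(data.frame(query_gene = NA_character_,
                          status = "translocated", evidence_arms = "",
                          stringsAsFactors = FALSE))
    }
    gene <- unique(hits$query_gene)
    if (length(gene) != 1L) stop("hits must concern a single query gene")
    bestPerArm <- do.call(rbind, lapply(split(hits, hits$subject_arm),
        function(h) {
            h <- h[order(h$e_value, -h$identity, -h$align_length), ,
                   drop = FALSE]
            h[1L, , drop = FALSE]
        }))
    onTarget <- bestPerArm[bestPerArm$subject_arm %in% targetArms, ,
                           drop = FALSE]
    offTarget <- bestPerArm[!bestPerArm$subject_arm %in% targetArms, ,
                            drop = FALSE]
    if (!nrow(onTarget))
        return(data.frame(query_gene = gene, status = "translocated",
                          evidence_arms = "", stringsAsFactors = FALSE))
    dominated <- vapply(seq_len(nrow(onTarget)), function(i)
        any(offTarget$identity >= onTarget$identity[i] &
            offTarget$align_length >= onTarget$align_length[i]),
        logical(1))
    if (all(dominated))
        data.frame(query_gene = gene, status = "uncertain",
                   evidence_arms = paste(sort(onTarget$subject_arm),
                                         collapse = ","),
                   stringsAsFactors = FALSE)
    else
        data.frame(query_gene = gene, status = "conserved",
                   evidence_arms = paste(sort(onTarget$subject_arm[!dominated]),
                                         collapse = ","),
                   stringsAsFactors = FALSE)
}

#' Total length of unique scaffolds harbouring synteny-conserved genes
#'
#' @param calls data.frame of [classifySynteny()] results (one row per
#'   gene).
#' @param scaffolds data.frame with columns `scaffold_id`, `length`, `genes`
#'   (comma-separated gene ids per scaffold).
#' @return Total bases, each scaffold counted once.
#' @export
estimateRegionSize <- function(calls, scaffolds) {
    conserved <- calls$query_gene[calls$status == "conserved"]
    if (!length(conserved)) return(0)
    geneLists <- strsplit(scaffolds$genes, ",", fixed = TRUE)
    keep <- vapply(geneLists, function(g)
        any(trimws(g) %in% conserved), logical(1))
    sum(scaffolds$length[keep & !duplicated(scaffolds$scaffold_id)])
}

#' The packaged 21-marker panel flanking PFT1
#'
#' Synteny-anchored marker panel of 20 genes flanking the PFT1 anchor at
#' regular intervals across ~4 Mb of the model-grass reference (offsets from
#' 2 Mb Up to 2 Mb Down), plus the anchor itself. The two anchor-adjacent
#' markers carry +/-10 kb placeholder offsets (no published distance),
#' configurable via `adjacentKb`.
#'
#' @param adjacentKb Absolute placeholder offset (kb) for the two
#'   anchor-adjacent markers.
#' @return A [MarkerPanel-class].
#' @export
pft1FlankPanel <- function(adjacentKb = 10) {
    path <- system.file("extdata", "pft1_flank_panel.csv",
                        package = "HomoeoDel", mustWork = TRUE)
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
    adj <- m$label %in% c("Up adjacent", "Down adjacent")
    m$offset_kb[adj] <- sign(m$offset_kb[adj]) * abs(adjacentKb)
    MarkerPanel(m$gene_id, m$offset_kb, m$label)
}
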
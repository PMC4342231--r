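snpKey <- function(tab) {
    paste(tab$gene_ID, tab$ref_position, tab$allele_variants, sep = "\r")
}

#' Wild-type consensus SNPs
#'
#' A SNP is retained only if detected in every wild-type sample: variants
#' seen in a subset of wild types are discarded as accession-specific or
#' unreliable.
#'
#' @param snpTables Named list of SNP tables (as returned by [detectSnps()]),
#'   one per sample.
#' @param design A [ControlDesign-class]; all its wild-type samples must be
#'   present in `snpTables`.
#' @return A data.frame of consensus keys with columns `gene_ID`,
#'   `ref_position`, `allele_variants`.
#' @export
selectConsensusSnps <- function(snpTables, design) {
    wt <- design@wildTypeSamples
    missing <- setdiff(wt, names(snpTables))
    if (length(missing))
        stop("missing wild-type sample table(s): ",
             paste(missing, collapse = ", "))
    keys <- lapply(snpTables[wt], snpKey)
    consensus <- Reduce(intersect, keys)
    first <- snpTables[[wt[1]]]
    sel <- first[match(consensus, snpKey(first)),
                 c("gene_ID", "ref_position", "allele_variants"),
                 drop = FALSE]
    rownames(sel) <- NULL
    sel
}

#' Assign consensus SNPs to subgenomes via nullisomic-tetrasomic controls
#'
#' A consensus SNP absent from exactly one nullisomic-tetrasomic control is
#' specific to the subgenome that control lacks. SNPs absent from zero
#' controls (shared variation) or from several (ambiguous) are reported
#' unassigned with a reason.
#'
#' @param consensus Output of [selectConsensusSnps()].
#' @param snpTables Named list of per-sample SNP tables; must contain all
#'   three nulli-tetra control tables named in `design`.
#' @param design A [ControlDesign-class].
#' @param genes Character vector of all annotated gene ids (defaults to the
#'   genes appearing in the consensus set).
#' @return A [HomoeoSnpSets-class].
#' @export
assignHomoeologueSnps <- function(consensus, snpTables, design,
                                  genes = NULL) {
    nt <- design@nullTetra
    missing <- setdiff(unname(nt), names(snpTables))
    if (length(missing))
        stop("missing nullisomic-tetrasomic control table(s): ",
             paste(missing, collapse = ", "))
    ckey <- paste(consensus$gene_ID, consensus$ref_position,
                  consensus$allele_variants, sep = "\r")
    absentFrom <- vapply(SUBGENOMES, function(s)
        !(ckey %in% snpKey(snpTables[[nt[[s]]]])), logical(length(ckey)))
    absentFrom <- matrix(absentFrom, ncol = 3L,
                         dimnames = list(NULL, SUBGENOMES))
    nAbsent <- rowSums(absentFrom)
    base <- data.frame(gene_id = consensus$gene_ID,
                       ref_position = consensus$ref_position,
                       allele_variant = consensus$allele_variants,
                       stringsAsFactors = FALSE)
    specific <- nAbsent == 1L
    assigned <- base[specific, , drop = FALSE]
    assigned$subgenome <- if (any(specific))
        SUBGENOMES[apply(absentFrom[specific, , drop = FALSE], 1L, which)]
        else character()
    unassigned <- base[!specific, , drop = FALSE]
    unassigned$reason <- ifelse(nAbsent[!specific] == 0L,
                                "present in all nulli-tetra controls",
                                "absent from multiple nulli-tetra controls")
    rownames(assigned) <- rownames(unassigned) <- NULL
    if (is.null(genes)) genes <- unique(consensus$gene_ID)
    new("HomoeoSnpSets", assigned = assigned, unassigned = unassigned,
        genes = as.character(genes))
}

#' Call gene intactness in a mutant sample
#'
#' For each gene and subgenome with at least one homoeologue-specific SNP:
#' if every such SNP is absent from the mutant's SNP table the gene is
#' called `deleted`; if every one is present, `intact`; a partial pattern is
#' conservatively `unknown` with a conflict flag. Genes with no specific SNP
#' for a subgenome are `unknown`.
#'
#' @param mutantTable SNP table of the mutant sample ([detectSnps()] output).
#' @param sets A [HomoeoSnpSets-class].
#' @param subgenome Optional subset of subgenomes to call (default all
#'   three).
#' @return A data.frame with columns `gene_id`, `subgenome`, `status`,
#'   `supporting_snps` (number of specific SNPs), `absent_snps`, `conflict`.
#' @export
callIntactness <- function(mutantTable, sets,
                           subgenome = subgenomes()) {
    stopifnot(is(sets, "HomoeoSnpSets"))
    mkey <- snpKey(mutantTable)
    asn <- assignedSnps(sets)
    akey <- paste(asn$gene_id, asn$ref_position, asn$allele_variant,
                  sep = "\r")
    present <- akey %in% mkey
    grid <- expand.grid(gene_id = sets@genes, subgenome = subgenome,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(i) {
        sel <- asn$gene_id == grid$gene_id[i] &
            asn$subgenome == grid$subgenome[i]
        k <- sum(sel)
        nPresent <- sum(present[sel])
        if (k == 0L) {
            status <- "unknown"; conflict <- FALSE
        } else if (nPresent == k) {
            status <- "intact"; conflict <- FALSE
        } else if (nPresent == 0L) {
            status <- "deleted"; conflict <- FALSE
        } else {
            status <- "unknown"; conflict <- TRUE
        }
        data.frame(gene_id = grid$gene_id[i],
                   subgenome = grid$subgenome[i], status = status,
                   supporting_snps = k, absent_snps = k - nPresent,
                   conflict = conflict, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (any(out$conflict))
        warning("partial SNP absence (conflicting evidence) for: ",
                paste(unique(paste0(out$gene_id[out$conflict], "-",
                                    out$subgenome[out$conflict])),
                      collapse = ", "))
    out
}

#' Intactness calls as a gene x subgenome matrix
#'
#' @param calls Output of [callIntactness()].
#' @return A character matrix (rows = genes, columns = subgenomes) of
#'   `intact`/`deleted`/`unknown`.
#' @export
intactnessMatrix <- function(calls) {
    genes <- unique(calls$gene_id)
    m <- matrix("unknown", nrow = length(genes), ncol = 3L,
                dimnames = list(genes, SUBGENOMES))
    m[cbind(calls$gene_id, calls$subgenome)] <- calls$status
    m
}

#' Extract an IntactnessProfile for one subgenome
#'
#' @param calls Output of [callIntactness()].
#' @param mutantId Mutant identifier to stamp on the profile.
#' @param subgenome Subgenome of interest.
#' @return An [IntactnessProfile-class].
#' @export
intactnessProfile <- function(calls, mutantId, subgenome) {
    sel <- calls[calls$subgenome == subgenome, , drop = FALSE]
    IntactnessProfile(mutantId, subgenome,
                      structure(sel$status, names = sel$gene_id))
}
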
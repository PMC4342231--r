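#' Align amplicon reads to reference sequences
#'
#' Exhaustive ungapped placement: every read is scored against every
#' reference at every offset and assigned to the placement with the fewest
#' mismatches (highest identity over the read length). Ties are broken
#' deterministically: first reference in the supplied order, then lowest
#' offset. A read maps only if its best identity reaches
#' `minIdentity(config)`; the 85% default reflects a mapping stringency that
#' accepts reads from homoeologues diverged a few percent from the reference
#' while rejecting off-target products.
#'
#' Amplicons are short and the simulator is substitution-only, so alignment
#' is gapless by design; indel-tolerant alignment is out of scope.
#'
#' @param reads A named [Biostrings::DNAStringSet] of reads (names = read
#'   ids).
#' @param refs A named [Biostrings::DNAStringSet] of reference sequences.
#' @param config A [CallerConfig-class].
#' @return A data.frame with one row per read: `read_id`, `ref_id`, `start`
#'   (1-based offset on the reference), `identity`, `mapped`.
#' @export
alignReads <- function(reads, refs, config = CallerConfig()) {
    if (length(refs) == 0L) stop("empty reference set")
    if (is.null(names(refs)) || anyDuplicated(names(refs)))
        stop("references must have unique names")
    hits <- .alignScan(as.character(reads), as.character(refs),
                       config@minIdentity)
    len <- Biostrings::width(reads)
    identity <- 1 - hits$mismatches / len
    data.frame(read_id = if (is.null(names(reads)))
                   paste0("read", seq_along(reads)) else names(reads),
               ref_id = names(refs)[hits$ref_idx],
               start = hits$start,
               identity = identity,
               mapped = hits$mapped,
               stringsAsFactors = FALSE)
}

#' Build per-reference pileups from mapped reads
#'
#' Counts, for every reference position, the read bases covering it from
#' mapped reads only.
#'
#' @param alignments Output of [alignReads()].
#' @param reads The [Biostrings::DNAStringSet] passed to [alignReads()].
#' @param refs The reference [Biostrings::DNAStringSet].
#' @return A named list (one element per reference with at least one mapped
#'   read) of 4 x L integer matrices with rows `A`, `C`, `G`, `T`; an
#'   attached attribute `coverage` holds the column sums.
#' @export
buildPileup <- function(alignments, reads, refs) {
    stopifnot(all(c("read_id", "ref_id", "start", "mapped") %in%
                  names(alignments)))
    mappedAln <- alignments[alignments$mapped, , drop = FALSE]
    if (!nrow(mappedAln)) return(structure(list(), names = character()))
    idx <- match(mappedAln$read_id, names(reads))
    if (anyNA(idx)) stop("alignments refer to unknown read ids")
    out <- list()
    for (ref in unique(mappedAln$ref_id)) {
        sel <- mappedAln$ref_id == ref
        width <- length(refs[[ref]])
        cm <- Biostrings::consensusMatrix(reads[idx[sel]],
                                          shift = mappedAln$start[sel] - 1L,
                                          width = width)
        m <- cm[c("A", "C", "G", "T"), , drop = FALSE]
        storage.mode(m) <- "integer"
        attr(m, "coverage") <- colSums(m)
        out[[ref]] <- m
    }
    out
}

#' Detect SNPs from pileups
#'
#' Reports one record per (position, non-reference allele) whose position
#' coverage reaches `minCoverage` and whose allele frequency reaches
#' `minAlleleFreq`. Frequencies are reported as percentages of coverage,
#' positions as 1-based reference coordinates.
#'
#' @param pileup Output of [buildPileup()].
#' @param refs The reference [Biostrings::DNAStringSet].
#' @param config A [CallerConfig-class].
#' @param annotation Named character vector mapping reference ids to gene
#'   ids; references absent from it keep their own id as gene id.
#' @return A data.frame in the exported SNP-table schema: `scaffold_ID`,
#'   `gene_ID`, `ref_position`, `ref_type`, `num_variants`,
#'   `allele_variants`, `frequency`, `coverage`, sorted by scaffold and
#'   position (and therefore invariant to read input order).
#' @export
detectSnps <- function(pileup, refs, config = CallerConfig(),
                       annotation = NULL) {
    rows <- lapply(names(pileup), function(ref) {
        m <- pileup[[ref]]
        cov <- attr(m, "coverage")
        refChars <- strsplit(as.character(refs[[ref]]), "")[[1]]
        freq <- sweep(m, 2L, pmax(cov, 1L), "/")
        isRef <- outer(rownames(m), refChars, "==")
        pass <- freq >= config@minAlleleFreq & !isRef &
            matrix(cov >= config@minCoverage, nrow = 4L, ncol = ncol(m),
                   byrow = TRUE) & m > 0L
        if (!any(pass)) return(NULL)
        hit <- which(pass, arr.ind = TRUE)
        pos <- hit[, "col"]
        nVar <- colSums(pass)[pos]
        gene <- if (!is.null(annotation) && ref %in% names(annotation))
            annotation[[ref]] else ref
        data.frame(scaffold_ID = ref, gene_ID = gene,
                   ref_position = as.integer(pos),
                   ref_type = refChars[pos],
                   num_variants = as.integer(nVar),
                   allele_variants = rownames(m)[hit[, "row"]],
                   frequency = 100 * freq[hit],
                   coverage = as.integer(cov[pos]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(scaffold_ID = character(), gene_ID = character(),
                          ref_position = integer(), ref_type = character(),
                          num_variants = integer(),
                          allele_variants = character(),
                          frequency = numeric(), coverage = integer(),
                          stringsAsFactors = FALSE)
    out <- out[order(out$scaffold_ID, out$ref_position, out$allele_variants),
               , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fraction of mapped reads sharing a start position with another read
#'
#' A logged stand-in for visual inspection of PCR duplication: the fraction
#' of mapped reads whose (reference, start) is shared with at least one
#' other mapped read. No filtering is performed.
#'
#' @param alignments Output of [alignReads()].
#' @return A single proportion.
#' @export
duplicateStartFraction <- function(alignments) {
    m <- alignments[alignments$mapped, , drop = FALSE]
    if (!nrow(m)) return(0)
    key <- paste(m$ref_id, m$start)
    mean(key %in% key[duplicated(key)])
}
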
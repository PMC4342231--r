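#' Read a cross-observation table from CSV
#'
#' Expected columns: `gene`, `parent_labels`, `index`, `n_screened`, then
#' one column per detected deletion class (any of `A`, `B`, `D`, `AB`, `AD`,
#' `BD`, `ABD`). An empty / missing cell means the class is not expected in
#' that cross and is omitted from the counts.
#'
#' @param path CSV file path.
#' @return A list of [ObservedCrossTable-class] objects (parental genotypes
#'   reconstructed from the `index` column via [indexToCross()]).
#' @export
readCrossTables <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    need <- c("gene", "parent_labels", "index", "n_screened")
    if (!all(need %in% names(df)))
        stop("cross table needs columns: ", paste(need, collapse = ", "))
    classCols <- intersect(setdiff(DETECTED_CLASSES, "none"), names(df))
    lapply(seq_len(nrow(df)), function(i) {
        counts <- unlist(df[i, classCols, drop = TRUE])
        counts <- counts[!is.na(counts)]
        cross <- indexToCross(df$index[i], label = df$parent_labels[i])
        ObservedCrossTable(cross, n = df$n_screened[i],
                           counts = structure(as.integer(counts),
                                              names = names(counts)),
                           gene = df$gene[i])
    })
}

#' Packaged example cross tables
#'
#' Observed F2 screening counts from a hexaploid-wheat deletion-stacking
#' experiment: `"tetra"` (25 crosses between primary mutants attempting
#' two-locus deletion lines for three genes) and `"hexa"` (4 crosses
#' attempting three-locus deletion lines).
#'
#' @param which `"tetra"` or `"hexa"`.
#' @return A list of [ObservedCrossTable-class] objects.
#' @export
exampleCrossTables <- function(which = c("tetra", "hexa")) {
    which <- match.arg(which)
    path <- system.file("extdata", paste0(which, "_crosses.csv"),
                        package = "HomoeoDel", mustWork = TRUE)
    readCrossTables(path)
}

#' Write / read per-sample SNP tables
#'
#' Tab-separated with columns `sample_id`, `scaffold_ID`, `gene_ID`,
#' `ref_position` (1-based), `ref_type`, `num_variants`, `allele_variants`,
#' `frequency` (percent), `coverage`.
#'
#' @param snpTable A SNP table from [detectSnps()].
#' @param sampleId Sample identifier written into the first column.
#' @param path Output / input TSV path.
#' @return `writeSnpTable()` returns `path` invisibly; `readSnpTable()`
#'   returns a named list of per-sample SNP tables.
#' @export
writeSnpTable <- function(snpTable, sampleId, path) {
    out <- cbind(sample_id = sampleId, snpTable)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeSnpTable
#' @export
readSnpTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "scaffold_ID", "gene_ID", "ref_position",
              "ref_type", "num_variants", "allele_variants", "frequency",
              "coverage")
    if (!all(need %in% names(df)))
        stop("SNP table needs columns: ", paste(need, collapse = ", "))
    split(df[setdiff(names(df), "sample_id")], df$sample_id)
}

#' Write an intactness call matrix
#'
#' Tab-separated gene x subgenome matrix of `intact`/`deleted`/`unknown`.
#'
#' @param m Matrix from [intactnessMatrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeIntactnessMatrix <- function(m, path) {
    utils::write.table(cbind(gene_id = rownames(m), as.data.frame(m)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a tabular homology hit table
#'
#' Tab-separated with the six columns `query_gene`, `subject_arm`,
#' `identity`, `align_length`, `e_value` (header required).
#'
#' @param path Input TSV path.
#' @return A data.frame of hits.
#' @export
readHitTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("query_gene", "subject_arm", "identity", "align_length",
              "e_value")
    if (!all(need %in% names(df)))
        stop("hit table needs columns: ", paste(need, collapse = ", "))
    df
}

#' Read a scaffold-length table
#'
#' CSV with columns `scaffold_id`, `length`, `genes` (comma-separated).
#'
#' @param path Input CSV path.
#' @return A data.frame of scaffold records.
#' @export
readScaffoldTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("scaffold_id", "length", "genes")
    if (!all(need %in% names(df)))
        stop("scaffold table needs columns: ", paste(need, collapse = ", "))
    df
}

#' Read a marker panel from CSV
#'
#' CSV with columns `gene_id`, `offset_kb`, `label`.
#'
#' @param path Input CSV path.
#' @return A [MarkerPanel-class].
#' @export
readMarkerPanelCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    MarkerPanel(df$gene_id, df$offset_kb, df$label)
}

#' Write inferred deletion intervals to CSV
#'
#' One row per interval with min/max span (kb; `max_size_kb` empty when the
#' interval is open) and the bounding markers.
#'
#' @param intervals A list of [DeletionInterval-class] objects.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
writeIntervals <- function(intervals, path) {
    df <- do.call(rbind, lapply(intervals, function(iv)
        data.frame(mutant_id = iv@mutantId, subgenome = iv@subgenome,
                   min_size_kb = iv@minSize,
                   max_size_kb = ifelse(is.finite(iv@maxSize), iv@maxSize,
                                        NA_real_),
                   open_up = iv@openUp, open_down = iv@openDown,
                   up_bound_marker = iv@upBoundMarker,
                   down_bound_marker = iv@downBoundMarker,
                   stringsAsFactors = FALSE)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(df)
}
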
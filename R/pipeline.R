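#' SNP table for one sample (align -> pileup -> detect)
#'
#' @param reads Named [Biostrings::DNAStringSet] of the sample's reads.
#' @param reference Named [Biostrings::DNAStringSet] of mapping references.
#' @param config A [CallerConfig-class].
#' @param annotation Optional named map reference id -> gene id.
#' @return A SNP table as from [detectSnps()].
#' @export
sampleSnpTable <- function(reads, reference, config = CallerConfig(),
                           annotation = NULL) {
    aln <- alignReads(reads, reference, config)
    pile <- buildPileup(aln, reads, reference)
    detectSnps(pile, reference, config, annotation)
}

#' Run the full deletion-calling pipeline on a set of samples
#'
#' Aligns each sample's reads, detects SNPs, builds the wild-type consensus,
#' assigns homoeologue-specific SNPs via the nullisomic-tetrasomic controls,
#' and calls gene intactness for every non-control sample.
#'
#' @param sampleReads Named list of [Biostrings::DNAStringSet]s, one per
#'   sample, covering all samples named in `design` plus the mutants.
#' @param reference Named [Biostrings::DNAStringSet] of mapping references.
#' @param design A [ControlDesign-class].
#' @param config A [CallerConfig-class].
#' @param annotation Optional reference id -> gene id map.
#' @return A list with `snpTables` (per sample), `consensus`, `sets` (a
#'   [HomoeoSnpSets-class]) and `calls` (named list of [callIntactness()]
#'   data.frames for each non-control sample).
#' @export
runDeletionCalling <- function(sampleReads, reference, design,
                               config = CallerConfig(), annotation = NULL) {
    snpTables <- lapply(sampleReads, sampleSnpTable, reference = reference,
                        config = config, annotation = annotation)
    consensus <- selectConsensusSnps(snpTables, design)
    sets <- assignHomoeologueSnps(consensus, snpTables, design,
                                  genes = names(reference))
    controlIds <- c(design@wildTypeSamples, unname(design@nullTetra),
                    unname(design@extraControls))
    mutants <- setdiff(names(snpTables), controlIds)
    calls <- lapply(snpTables[mutants], callIntactness, sets = sets)
    list(snpTables = snpTables, consensus = consensus, sets = sets,
         calls = calls)
}

#' Simulate a batch of deletion mutants and recover their intervals
#'
#' End-to-end parameter-recovery harness: simulates homoeologous references
#' and control samples once, then for each mutant simulates a deletion with
#' a known span, sequences it, runs the deletion-calling pipeline, and
#' infers the deletion interval from the resulting intactness profile.
#'
#' @param panel A [MarkerPanel-class].
#' @param spans Numeric matrix / data.frame with columns `up_kb` (<= 0) and
#'   `down_kb` (>= 0), one row per mutant.
#' @param subgenome Character vector (recycled) of deleted subgenomes.
#' @param simConfig A [SimulationConfig-class].
#' @param callerConfig A [CallerConfig-class].
#' @param seed Integer seed controlling references, controls and reads.
#' @return A data.frame with one row per mutant: the truth columns plus
#'   `min_size_kb`, `max_size_kb` (`Inf` when open) and `bounded`.
#' @export
recoverDeletionIntervals <- function(panel, spans,
                                     subgenome = c("A", "B", "D"),
                                     simConfig = SimulationConfig(),
                                     callerConfig = CallerConfig(),
                                     seed = 1L) {
    spans <- as.data.frame(spans)
    nMut <- nrow(spans)
    subgenome <- rep_len(subgenome, nMut)
    refs <- simulateHomoeologRefs(panel, simConfig, seed = seed)
    design <- ControlDesign(
        wildTypeSamples = c("WT_1", "WT_2"),
        nullTetra = c(A = "N5A", B = "N5B", D = "N5D"))
    controls <- list(
        WT_1 = wildTypeGenotype(panel), WT_2 = wildTypeGenotype(panel),
        N5A = nulliTetraGenotype(panel, "A"),
        N5B = nulliTetraGenotype(panel, "B"),
        N5D = nulliTetraGenotype(panel, "D"))
    controlReads <- lapply(seq_along(controls), function(i)
        simulateSampleReads(controls[[i]], refs, simConfig,
                            seed = seed + i, sampleId = names(controls)[i]))
    names(controlReads) <- names(controls)
    controlTables <- lapply(controlReads, sampleSnpTable,
                            reference = refs$reference,
                            config = callerConfig)
    consensus <- selectConsensusSnps(controlTables, design)
    sets <- assignHomoeologueSnps(consensus, controlTables, design,
                                  genes = names(refs$reference))
    out <- vector("list", nMut)
    for (i in seq_len(nMut)) {
        id <- sprintf("mut_%03d", i)
        mut <- simulateDeletionMutant(panel, subgenome[i],
                                      c(spans$up_kb[i], spans$down_kb[i]),
                                      mutantId = id)
        reads <- simulateSampleReads(mut$genotype, refs, simConfig,
                                     seed = seed + 100L + i, sampleId = id)
        tab <- sampleSnpTable(reads, refs$reference, callerConfig)
        calls <- callIntactness(tab, sets, subgenome = subgenome[i])
        profile <- intactnessProfile(calls, id, subgenome[i])
        iv <- inferDeletionInterval(profile, panel)
        out[[i]] <- cbind(mut$truth,
                          data.frame(min_size_kb = minSize(iv),
                                     max_size_kb = maxSize(iv),
                                     bounded = is.finite(maxSize(iv))))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
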
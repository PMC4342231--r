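randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## i.i.d. substitution errors over a character vector of fragments;
## positions drawn per fragment, substituted base always differs from the
## original. Vectorized over errors, not fragments.
injectErrors <- function(frag, errorRate) {
    len <- nchar(frag)
    cum <- cumsum(len)
    total <- cum[length(cum)]
    nErr <- stats::rbinom(1L, total, errorRate)
    if (nErr == 0L) return(frag)
    gpos <- sample.int(total, nErr)
    idx <- findInterval(gpos - 0.5, c(0, cum))
    pos <- gpos - c(0L, cum)[idx]
    cur <- substring(frag[idx], pos, pos)
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"),
                  nrow = 4L, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    repl <- alt[cbind(match(cur, rownames(alt)),
                      sample.int(3L, length(cur), replace = TRUE))]
    for (e in seq_along(idx))
        substr(frag[idx[e]], pos[e], pos[e]) <- repl[e]
    frag
}

#' Simulate homoeologous amplicon reference triplets
#'
#' For each marker gene an ancestral amplicon sequence is drawn and each
#' subgenome copy diverges from it by substitutions at rate `divergence/2`,
#' so realized pairwise identity between homoeologues matches the configured
#' target (default 97%, within the 96-98% regime typical of wheat
#' homoeologues). Divergence sites are drawn at distinct positions across the
#' three subgenomes (no transition/transversion bias). The ancestral
#' sequence itself serves as the mapping reference, standing in for the
#' diploid-progenitor scaffolds used as alignment references in practice.
#'
#' @param panel A [MarkerPanel-class] naming the genes, or a character
#'   vector of gene ids.
#' @param config A [SimulationConfig-class].
#' @param seed Integer seed.
#' @return A list with elements:
#'   \describe{
#'     \item{reference}{Named [Biostrings::DNAStringSet] of mapping
#'       references (one per gene).}
#'     \item{homoeologs}{Named list `A`/`B`/`D` of
#'       [Biostrings::DNAStringSet]s: the subgenome copies.}
#'     \item{sites}{data.frame of planted divergence sites: `gene_id`,
#'       `position` (1-based), `subgenome`, `allele` (derived base),
#'       `ref_base`.}
#'   }
#' @export
simulateHomoeologRefs <- function(panel, config = SimulationConfig(),
                                  seed = 1L) {
    genes <- if (is(panel, "MarkerPanel")) markers(panel)$gene_id
             else as.character(panel)
    set.seed(seed)
    L <- config@ampliconLength
    perSub <- config@divergence / 2
    refSeqs <- character(length(genes))
    homoeo <- list(A = character(length(genes)),
                   B = character(length(genes)),
                   D = character(length(genes)))
    sites <- vector("list", length(genes))
    for (i in seq_along(genes)) {
        anc <- strsplit(randomDna(L), "")[[1]]
        ## fixed per-subgenome site count keeps realized pairwise identity
        ## within 1% of the configured target on every gene
        nSites <- rep(as.integer(round(L * perSub)), 3L)
        if (sum(nSites) > L)
            stop("divergence too high for amplicon length")
        posAll <- sample.int(L, sum(nSites))
        split <- rep(SUBGENOMES, nSites)
        copies <- list(A = anc, B = anc, D = anc)
        rows <- NULL
        for (s in SUBGENOMES) {
            pos <- posAll[split == s]
            if (length(pos)) {
                derived <- vapply(anc[pos], function(b)
                    sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1))
                copies[[s]][pos] <- derived
                rows <- rbind(rows, data.frame(
                    gene_id = genes[i], position = as.integer(pos),
                    subgenome = s, allele = unname(derived),
                    ref_base = anc[pos], stringsAsFactors = FALSE))
            }
        }
        refSeqs[i] <- paste(anc, collapse = "")
        for (s in SUBGENOMES)
            homoeo[[s]][i] <- paste(copies[[s]], collapse = "")
        sites[[i]] <- rows
    }
    names(refSeqs) <- genes
    reference <- Biostrings::DNAStringSet(refSeqs)
    homoeologs <- lapply(homoeo, function(x) {
        names(x) <- genes
        Biostrings::DNAStringSet(x)
    })
    siteDf <- do.call(rbind, sites)
    if (is.null(siteDf))
        siteDf <- data.frame(gene_id = character(), position = integer(),
                             subgenome = character(), allele = character(),
                             ref_base = character(), stringsAsFactors = FALSE)
    rownames(siteDf) <- NULL
    list(reference = reference, homoeologs = homoeologs, sites = siteDf)
}

#' Hamming pairwise identity between homoeologous copies
#'
#' @param refs Output of [simulateHomoeologRefs()].
#' @return A data.frame of pairwise identities per gene.
#' @export
pairwiseIdentity <- function(refs) {
    genes <- names(refs$reference)
    pairs <- list(c("A", "B"), c("A", "D"), c("B", "D"))
    do.call(rbind, lapply(genes, function(g) {
        do.call(rbind, lapply(pairs, function(pr) {
            x <- as.character(refs$homoeologs[[pr[1]]][[g]])
            y <- as.character(refs$homoeologs[[pr[2]]][[g]])
            xs <- strsplit(x, "")[[1]]
            ys <- strsplit(y, "")[[1]]
            data.frame(gene_id = g, pair = paste(pr, collapse = "-"),
                       identity = mean(xs == ys), stringsAsFactors = FALSE)
        }))
    }))
}

#' Genotypes as gene x subgenome copy-number matrices
#'
#' `wildTypeGenotype()` gives two copies of every homoeologue.
#' `nulliTetraGenotype()` models a nullisomic-tetrasomic control: zero copies
#' of the missing subgenome genome-wide, four of the compensating one.
#'
#' @param panel A [MarkerPanel-class] or character vector of gene ids.
#' @param missing Subgenome absent in the nulli-tetra line.
#' @param compensating Subgenome present in four copies (default: the next
#'   subgenome in A->B->D->A order).
#' @return An integer matrix (rows = genes, columns `A`, `B`, `D`) of copy
#'   numbers.
#' @export
wildTypeGenotype <- function(panel) {
    genes <- if (is(panel, "MarkerPanel")) markers(panel)$gene_id
             else as.character(panel)
    matrix(2L, nrow = length(genes), ncol = 3L,
           dimnames = list(genes, SUBGENOMES))
}

#' @rdname wildTypeGenotype
#' @export
nulliTetraGenotype <- function(panel, missing,
                               compensating = NULL) {
    stopifnot(missing %in% SUBGENOMES)
    if (is.null(compensating))
        compensating <- SUBGENOMES[match(missing, SUBGENOMES) %% 3L + 1L]
    g <- wildTypeGenotype(panel)
    g[, missing] <- 0L
    g[, compensating] <- 4L
    g
}

#' Simulate a deletion mutant with a known span
#'
#' All panel markers whose offset lies inside `span` are deleted (copy
#' number 0) on the given subgenome; the true span is recorded for parameter
#' recovery.
#'
#' @param panel A [MarkerPanel-class].
#' @param subgenome Subgenome carrying the deletion.
#' @param span Numeric length-2 vector `c(up_kb, down_kb)` with
#'   `up_kb <= 0 <= down_kb`: the deletion covers offsets in
#'   `[up_kb, down_kb]` and must include the anchor.
#' @param mutantId Identifier for the simulated mutant.
#' @return A list with `genotype` (copy-number matrix) and `truth`
#'   (data.frame: `mutant_id`, `subgenome`, `deleted_genes`, `span_up_kb`,
#'   `span_down_kb`, `true_span_kb`).
#' @export
simulateDeletionMutant <- function(panel, subgenome, span,
                                   mutantId = "mutant") {
    stopifnot(is(panel, "MarkerPanel"), subgenome %in% SUBGENOMES,
              length(span) == 2L)
    if (span[1] > 0 || span[2] < 0)
        stop("span must cover the anchor (up_kb <= 0 <= down_kb)")
    m <- markers(panel)
    deleted <- m$offset_kb >= span[1] & m$offset_kb <= span[2]
    g <- wildTypeGenotype(panel)
    g[deleted, subgenome] <- 0L
    list(genotype = g,
         truth = data.frame(
             mutant_id = mutantId, subgenome = subgenome,
             deleted_genes = paste(m$gene_id[deleted], collapse = ","),
             span_up_kb = span[1], span_down_kb = span[2],
             true_span_kb = span[2] - span[1], stringsAsFactors = FALSE))
}

#' Simulate amplicon reads for one sample
#'
#' Reads are drawn from every present gene x subgenome copy in proportion to
#' copy number. Fragment starts emulate sheared amplicon pools: they may
#' overhang either amplicon end and are clipped, keeping fragments with at
#' least `minOverlap` retained bases, so coverage is close to uniform across
#' the whole amplicon (interior per-copy coverage equals
#' `coverage(config)`). Substitution errors are i.i.d. per base at
#' `errorRate(config)`. Deterministic given `seed`.
#'
#' @param genotype Copy-number matrix (genes x subgenomes), e.g. from
#'   [wildTypeGenotype()] or [simulateDeletionMutant()].
#' @param refs Output of [simulateHomoeologRefs()].
#' @param config A [SimulationConfig-class].
#' @param seed Integer seed.
#' @param sampleId Sample identifier used in read names.
#' @param minOverlap Minimum retained fragment length after clipping.
#' @return A named [Biostrings::DNAStringSet] of reads.
#' @export
simulateSampleReads <- function(genotype, refs, config = SimulationConfig(),
                                seed = 1L, sampleId = "sample",
                                minOverlap = 50L) {
    set.seed(seed)
    L <- config@ampliconLength
    rl <- config@readLength
    minOverlap <- min(minOverlap, rl)
    windows <- L + rl - 2L * minOverlap + 1L
    out <- character(0)
    nm <- character(0)
    for (s in SUBGENOMES) {
        seqs <- refs$homoeologs[[s]]
        for (g in rownames(genotype)) {
            cn <- genotype[g, s]
            if (cn == 0L) next
            nFrag <- as.integer(ceiling(cn / 2 * config@coverage *
                                        windows / rl))
            starts <- sample.int(windows, nFrag, replace = TRUE) -
                (rl - minOverlap)
            from <- pmax(starts, 1L)
            to <- pmin(starts + rl - 1L, L)
            frag <- substring(as.character(seqs[[g]]), from, to)
            if (config@errorRate > 0)
                frag <- injectErrors(frag, config@errorRate)
            out <- c(out, frag)
            nm <- c(nm, sprintf("%s:%s:%s:%d", sampleId, g, s,
                                seq_len(nFrag)))
        }
    }
    reads <- Biostrings::DNAStringSet(out)
    names(reads) <- nm
    reads
}

#' Simulate an F2 population from a cross
#'
#' Draws `n` F2 genotypes by locus-independent selfing of the F1, rejection-
#' sampling out individuals whose detected class is lethal. Detected-class
#' frequencies converge to the renormalized [f2ClassDistribution()].
#'
#' @param cross A [CrossSpec-class].
#' @param n Number of F2 individuals.
#' @param lethalClasses Character vector of detected classes removed from
#'   the population (may be empty).
#' @param seed Integer seed.
#' @return An integer matrix `n x 3` of intact-allele dosages (columns `A`,
#'   `B`, `D`).
#' @export
simulateF2Population <- function(cross, n, lethalClasses = character(),
                                 seed = 1L) {
    stopifnot(is(cross, "CrossSpec"), n >= 0L)
    f1 <- f1Genotype(cross@parent1, cross@parent2)
    p <- classProbs(f2ClassDistribution(f1))
    if (sum(p[!(names(p) %in% lethalClasses)]) <= 0)
        stop("lethal classes cover the whole F2 distribution")
    set.seed(seed)
    h <- dosage(f1)
    drawLocus <- function(hl, k) {
        if (hl == 0L) rep(0L, k)
        else if (hl == 2L) rep(2L, k)
        else sample(0:2, k, replace = TRUE, prob = c(1, 2, 1) / 4)
    }
    draw <- function(k) {
        m <- cbind(A = drawLocus(h[1], k), B = drawLocus(h[2], k),
                   D = drawLocus(h[3], k))
        storage.mode(m) <- "integer"
        m
    }
    pop <- draw(n)
    if (n > 0L && length(lethalClasses)) {
        repeat {
            bad <- detectClassMatrix(pop) %in% lethalClasses
            if (!any(bad)) break
            pop[bad, ] <- draw(sum(bad))
        }
    }
    pop
}

#' Write / read simulated reads as FASTA or FASTQ
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()]. FASTQ qualities are written as a
#' constant placeholder and ignored on input (the substitution-only error
#' model carries no quality information).
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `writeReads()` returns `path` invisibly; `readReads()` returns a
#'   [Biostrings::DNAStringSet].
#' @export
writeReads <- function(reads, path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    if (format == "fastq") {
        Biostrings::writeXStringSet(reads, path, format = "fastq",
                                    qualities = Biostrings::BStringSet(
                                        strrep("I", Biostrings::width(reads))))
    } else {
        Biostrings::writeXStringSet(reads, path)
    }
    invisible(path)
}

#' @rdname writeReads
#' @export
readReads <- function(path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    Biostrings::readDNAStringSet(path, format = format)
}
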
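# Independent brute-force oracles used to pin the implementations.

# F2 detected-class distribution by explicit gamete enumeration: each F1
# locus contributes one of its two alleles per gamete, all 4 gamete
# combinations per locus equally likely, loci independent. Kept deliberately
# separate from the closed-form implementation.
oracleF2Distribution <- function(f1) {
    gametes <- function(h) switch(as.character(h),
                                  "0" = c(0L, 0L),
                                  "1" = c(0L, 1L),
                                  "2" = c(1L, 1L))
    h <- dosage(f1)
    probs <- structure(numeric(length(detectedClasses())),
                       names = detectedClasses())
    for (gA1 in gametes(h[1])) for (gA2 in gametes(h[1]))
    for (gB1 in gametes(h[2])) for (gB2 in gametes(h[2]))
    for (gD1 in gametes(h[3])) for (gD2 in gametes(h[3])) {
        z <- HomoeoGenotype(gA1 + gA2, gB1 + gB2, gD1 + gD2)
        cls <- detectClass(z)
        probs[cls] <- probs[cls] + (1 / 64)
    }
    probs
}

# Exhaustive ungapped alignment in plain R; N on either side is a mismatch.
# First-best in (reference, offset) order wins.
bruteAlign <- function(read, refs, minIdentity = 0.85) {
    L <- nchar(read)
    rc <- strsplit(read, "")[[1]]
    best <- list(mm = floor((1 - minIdentity) * L + 1e-9) + 1L,
                 ref = NA_integer_, start = NA_integer_)
    for (j in seq_along(refs)) {
        refc <- strsplit(refs[j], "")[[1]]
        if (length(refc) < L) next
        for (o in seq_len(length(refc) - L + 1L)) {
            win <- refc[o:(o + L - 1L)]
            mm <- sum(rc != win | rc == "N" | win == "N")
            if (mm < best$mm) best <- list(mm = mm, ref = j, start = o)
        }
    }
    best
}

# Recount a pileup directly from alignment coordinates and read characters.
brutePileup <- function(alignments, reads, refs) {
    out <- list()
    aln <- alignments[alignments$mapped, , drop = FALSE]
    for (ref in unique(aln$ref_id)) {
        L <- length(refs[[ref]])
        m <- matrix(0L, nrow = 4L, ncol = L,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
        sel <- which(aln$ref_id == ref)
        for (i in sel) {
            chars <- strsplit(as.character(reads[[aln$read_id[i]]]),
                              "")[[1]]
            pos <- aln$start[i] + seq_along(chars) - 1L
            for (k in seq_along(chars)) {
                if (chars[k] %in% rownames(m))
                    m[chars[k], pos[k]] <- m[chars[k], pos[k]] + 1L
            }
        }
        attr(m, "coverage") <- colSums(m)
        out[[ref]] <- m
    }
    out
}

# Rule-table oracle for synteny classification, written as a direct
# transcription of the decision rules over per-arm best hits.
oracleSynteny <- function(hits, targetArms) {
    if (!nrow(hits)) return("translocated")
    best <- lapply(split(hits, hits$subject_arm), function(h) {
        h[order(h$e_value, -h$identity, -h$align_length), ][1, ]
    })
    on <- Filter(function(h) h$subject_arm %in% targetArms, best)
    off <- Filter(function(h) !h$subject_arm %in% targetArms, best)
    if (!length(on)) return("translocated")
    unbeaten <- vapply(on, function(h)
        !any(vapply(off, function(g)
            g$identity >= h$identity && g$align_length >= h$align_length,
            logical(1))), logical(1))
    if (any(unbeaten)) "conserved" else "uncertain"
}

# A small marker panel + profile builder shared by interval tests.
miniPanel <- function() {
    MarkerPanel(gene_id = paste0("g", 1:7),
                offset_kb = c(-300, -100, -50, 0, 50, 100, 300))
}

profileFromOffsets <- function(panel, deletedAt, intactAt,
                               mutantId = "mut", subgenome = "A") {
    m <- markers(panel)
    calls <- structure(rep("unknown", nrow(m)), names = m$gene_id)
    calls[m$offset_kb %in% deletedAt] <- "deleted"
    calls[m$offset_kb %in% intactAt] <- "intact"
    IntactnessProfile(mutantId, subgenome, calls)
}

randomDnaStr <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
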
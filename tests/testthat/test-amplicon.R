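smallSim <- function() SimulationConfig(ampliconLength = 300L,
                                        readLength = 100L, coverage = 60,
                                        errorRate = 0.01)

smallGenes <- paste0("gene", 1:4)

test_that("read placement equals the exhaustive brute-force oracle", {
    set.seed(101)
    for (t in 1:60) {
        refs <- vapply(1:2, function(i) randomDnaStr(60), "")
        L <- sample(c(15L, 30L), 1)
        if (runif(1) < 0.7) {
            j <- sample(2, 1)
            o <- sample(60 - L + 1, 1)
            read <- substring(refs[j], o, o + L - 1)
            k <- rbinom(1, L, 0.1)
            if (k > 0) {
                ch <- strsplit(read, "")[[1]]
                p <- sample(L, k)
                ch[p] <- sample(c("A", "C", "G", "T", "N"), k, TRUE)
                read <- paste(ch, collapse = "")
            }
        } else {
            read <- randomDnaStr(L)
        }
        reads <- Biostrings::DNAStringSet(structure(read, names = "r1"))
        rs <- Biostrings::DNAStringSet(structure(refs,
                                                 names = c("refA", "refB")))
        a <- alignReads(reads, rs)
        b <- bruteAlign(read, refs)
        if (is.na(b$ref)) {
            expect_false(a$mapped)
        } else {
            expect_true(a$mapped)
            expect_identical(a$ref_id, c("refA", "refB")[b$ref])
            expect_identical(a$start, b$start)
            expect_equal(a$identity, 1 - b$mm / L)
        }
    }
})

test_that("reads map at the identity threshold boundary", {
    ref <- Biostrings::DNAStringSet(structure(randomDnaStr(80),
                                              names = "ref1"))
    refStr <- as.character(ref[[1]])
    exact <- substring(refStr, 11, 50)
    reads <- Biostrings::DNAStringSet(structure(exact, names = "exact"))
    a <- alignReads(reads, ref)
    expect_true(a$mapped)
    expect_equal(a$identity, 1)
    expect_identical(a$start, 11L)

    ## 20% mismatches: below the 85% identity floor everywhere
    ch <- strsplit(exact, "")[[1]]
    flip <- seq(1, 40, by = 5)
    ch[flip] <- vapply(ch[flip], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], "")
    noisy <- Biostrings::DNAStringSet(structure(paste(ch, collapse = ""),
                                                names = "noisy"))
    b <- bruteAlign(as.character(noisy[[1]]), refStr)
    a <- alignReads(noisy, ref)
    expect_identical(a$mapped, !is.na(b$ref))
    expect_error(alignReads(noisy, Biostrings::DNAStringSet()), "empty")
})

test_that("pileup counts equal a brute-force recount", {
    set.seed(202)
    refs <- Biostrings::DNAStringSet(structure(
        c(randomDnaStr(70), randomDnaStr(70)), names = c("r1", "r2")))
    reads <- character(30)
    for (i in 1:30) {
        j <- sample(2, 1)
        o <- sample(50, 1)
        frag <- substring(as.character(refs[[j]]), o, o + 19)
        ch <- strsplit(frag, "")[[1]]
        p <- sample(20, 1)
        ch[p] <- sample(c("A", "C", "G", "T"), 1)
        reads[i] <- paste(ch, collapse = "")
    }
    reads <- Biostrings::DNAStringSet(structure(reads,
                                                names = paste0("rd", 1:30)))
    aln <- alignReads(reads, refs)
    pile <- buildPileup(aln, reads, refs)
    oracle <- brutePileup(aln, reads, refs)
    for (ref in names(pile)) {
        expect_equal(unclass(pile[[ref]])[, ], unclass(oracle[[ref]])[, ],
                     ignore_attr = TRUE)
        expect_equal(attr(pile[[ref]], "coverage"),
                     colSums(pile[[ref]]), ignore_attr = TRUE)
    }
    ## no mapped reads -> empty pileup
    none <- alignReads(Biostrings::DNAStringSet(
        structure(randomDnaStr(20), names = "x")), refs)
    none$mapped <- FALSE
    expect_length(buildPileup(none, reads, refs), 0)

    ## identical perfect reads give a single-base column at full coverage
    dup <- Biostrings::DNAStringSet(structure(
        rep(substring(as.character(refs[[1]]), 5, 34), 60),
        names = paste0("d", 1:60)))
    pile <- buildPileup(alignReads(dup, refs), dup, refs)
    expect_equal(unname(attr(pile[["r1"]], "coverage")[5:34]), rep(60L, 30))
    expect_true(all(apply(pile[["r1"]][, 5:34], 2,
                          function(col) sum(col > 0)) == 1))
})

test_that("SNP detection applies coverage and frequency thresholds", {
    mkPile <- function(counts) {
        m <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
        m[, 2] <- counts
        attr(m, "coverage") <- colSums(m)
        list(ref1 = m)
    }
    ref <- Biostrings::DNAStringSet(structure("AAA", names = "ref1"))
    ## coverage 49 with a 50% variant: below the 50x floor
    tab <- detectSnps(mkPile(c(A = 25L, C = 24L, G = 0L, T = 0L)), ref)
    expect_identical(nrow(tab), 0L)
    ## coverage 100 with 4 variant reads: below 5% frequency
    tab <- detectSnps(mkPile(c(A = 96L, C = 4L, G = 0L, T = 0L)), ref)
    expect_identical(nrow(tab), 0L)
    ## two passing variants at one position, percentages of coverage
    tab <- detectSnps(mkPile(c(A = 60L, C = 30L, G = 10L, T = 0L)), ref)
    expect_identical(nrow(tab), 2L)
    expect_setequal(tab$allele_variants, c("C", "G"))
    expect_equal(sort(tab$frequency), c(10, 30))
    expect_identical(unique(tab$num_variants), 2L)
    expect_identical(unique(tab$ref_position), 2L)
})

test_that("SNP detection is invariant to read input order", {
    cfg <- smallSim()
    refs <- simulateHomoeologRefs(smallGenes, cfg, seed = 5)
    reads <- simulateSampleReads(wildTypeGenotype(smallGenes), refs, cfg,
                                 seed = 6, sampleId = "WT")
    tab1 <- sampleSnpTable(reads, refs$reference)
    set.seed(9)
    shuffled <- reads[sample(length(reads))]
    tab2 <- sampleSnpTable(shuffled, refs$reference)
    expect_equal(tab1, tab2)
})

test_that("wild-type consensus requires presence in every wild-type sample", {
    t1 <- data.frame(scaffold_ID = "s", gene_ID = "g1",
                     ref_position = c(10L, 20L), ref_type = "A",
                     num_variants = 1L, allele_variants = c("C", "G"),
                     frequency = 30, coverage = 100L)
    t2 <- t1[1, ]
    design <- ControlDesign("WT_1",
                            nullTetra = c(A = "NA1", B = "NB1", D = "ND1"))
    ## single wild type: its full table is the consensus
    cons <- selectConsensusSnps(list(WT_1 = t1), design)
    expect_identical(nrow(cons), 2L)
    ## SNP in one of two wild types is excluded
    design2 <- ControlDesign(c("WT_1", "WT_2"),
                             nullTetra = c(A = "NA1", B = "NB1", D = "ND1"))
    cons <- selectConsensusSnps(list(WT_1 = t1, WT_2 = t2), design2)
    expect_identical(nrow(cons), 1L)
    expect_identical(cons$ref_position, 10L)
    expect_error(selectConsensusSnps(list(WT_1 = t1), design2),
                 "missing wild-type")
})

test_that("nulli-tetra subtraction assigns subgenome-specific SNPs", {
    snp <- function(pos, allele) data.frame(
        scaffold_ID = "s", gene_ID = "g1", ref_position = pos,
        ref_type = "A", num_variants = 1L, allele_variants = allele,
        frequency = 30, coverage = 100L)
    consensus <- data.frame(gene_ID = "g1", ref_position = c(1L, 2L, 3L),
                            allele_variants = c("C", "G", "T"))
    design <- ControlDesign("WT",
                            nullTetra = c(A = "N5A", B = "N5B", D = "N5D"))
    tables <- list(
        WT = rbind(snp(1L, "C"), snp(2L, "G"), snp(3L, "T")),
        ## pos 1 absent only from the A control -> A-specific
        N5A = rbind(snp(2L, "G"), snp(3L, "T")),
        ## pos 2 present everywhere -> unassigned;
        ## pos 3 absent from B and D controls -> ambiguous
        N5B = rbind(snp(1L, "C"), snp(2L, "G")),
        N5D = rbind(snp(1L, "C"), snp(2L, "G")))
    sets <- assignHomoeologueSnps(consensus, tables, design)
    asn <- assignedSnps(sets)
    expect_identical(nrow(asn), 1L)
    expect_identical(asn$subgenome, "A")
    expect_identical(asn$ref_position, 1L)
    un <- unassignedSnps(sets)
    expect_identical(nrow(un), 2L)
    expect_match(un$reason[un$ref_position == 2L], "present in all")
    expect_match(un$reason[un$ref_position == 3L], "multiple")
    expect_error(assignHomoeologueSnps(consensus, tables[-2], design),
                 "missing nullisomic")
})

test_that("intactness calls follow the consistently-deleted rule", {
    asn <- data.frame(gene_id = rep("g1", 5), ref_position = 1:5,
                      allele_variant = "C", subgenome = "A")
    sets <- new("HomoeoSnpSets", assigned = asn,
                unassigned = data.frame(gene_id = character(),
                                        ref_position = integer(),
                                        allele_variant = character(),
                                        reason = character()),
                genes = c("g1", "g2"))
    mk <- function(pos) data.frame(
        scaffold_ID = rep("s", length(pos)),
        gene_ID = rep("g1", length(pos)), ref_position = pos,
        ref_type = rep("A", length(pos)),
        num_variants = rep(1L, length(pos)),
        allele_variants = rep("C", length(pos)),
        frequency = rep(30, length(pos)),
        coverage = rep(100L, length(pos)))
    ## all five A-specific SNPs absent -> deleted
    calls <- callIntactness(mk(integer()), sets, subgenome = "A")
    expect_identical(calls$status[calls$gene_id == "g1"], "deleted")
    expect_identical(calls$absent_snps[calls$gene_id == "g1"], 5L)
    ## no specific SNPs for g2 -> unknown
    expect_identical(calls$status[calls$gene_id == "g2"], "unknown")
    ## all present -> intact
    calls <- callIntactness(mk(1:5), sets, subgenome = "A")
    expect_identical(calls$status[calls$gene_id == "g1"], "intact")
    ## 3 of 5 absent -> unknown with conflict
    expect_warning(calls <- callIntactness(mk(1:2), sets, subgenome = "A"),
                   "conflict")
    expect_identical(calls$status[calls$gene_id == "g1"], "unknown")
    expect_true(calls$conflict[calls$gene_id == "g1"])
})

test_that("error-free simulation recovers planted truth end to end", {
    cfg <- SimulationConfig(ampliconLength = 300L, readLength = 100L,
                            coverage = 60, errorRate = 0)
    refs <- simulateHomoeologRefs(smallGenes, cfg, seed = 31)
    design <- ControlDesign(c("WT_1", "WT_2"),
                            nullTetra = c(A = "N5A", B = "N5B", D = "N5D"))
    genotypes <- list(WT_1 = wildTypeGenotype(smallGenes),
                      WT_2 = wildTypeGenotype(smallGenes),
                      N5A = nulliTetraGenotype(smallGenes, "A"),
                      N5B = nulliTetraGenotype(smallGenes, "B"),
                      N5D = nulliTetraGenotype(smallGenes, "D"))
    ## a mutant missing genes 2 and 3 on B
    mut <- wildTypeGenotype(smallGenes)
    mut[2:3, "B"] <- 0L
    genotypes$mut <- mut
    sampleReads <- lapply(seq_along(genotypes), function(i)
        simulateSampleReads(genotypes[[i]], refs, cfg, seed = 40 + i,
                            sampleId = names(genotypes)[i]))
    names(sampleReads) <- names(genotypes)
    out <- runDeletionCalling(sampleReads, refs$reference, design)
    ## every planted divergence site passes the thresholds in wild type
    expect_identical(nrow(out$consensus), nrow(refs$sites))
    ## and is correctly assigned to its subgenome
    asn <- assignedSnps(out$sets)
    expect_identical(nrow(asn), nrow(refs$sites))
    key <- function(d, pos, sub) paste(d$gene_id, pos, sub)
    expect_setequal(paste(asn$gene_id, asn$ref_position, asn$subgenome),
                    paste(refs$sites$gene_id, refs$sites$position,
                          refs$sites$subgenome))
    ## intactness calls equal ground truth for every gene x subgenome
    m <- intactnessMatrix(out$calls$mut)
    expect_true(all(m[, "A"] == "intact"))
    expect_true(all(m[, "D"] == "intact"))
    expect_identical(unname(m[smallGenes[2:3], "B"]),
                     c("deleted", "deleted"))
    expect_identical(unname(m[smallGenes[c(1, 4)], "B"]),
                     c("intact", "intact"))
})

test_that("duplicate samples from one genotype give identical calls", {
    cfg <- smallSim()
    refs <- simulateHomoeologRefs(smallGenes, cfg, seed = 77)
    design <- ControlDesign("WT_1",
                            nullTetra = c(A = "N5A", B = "N5B", D = "N5D"))
    mut <- wildTypeGenotype(smallGenes)
    mut[1:2, "A"] <- 0L
    genotypes <- list(WT_1 = wildTypeGenotype(smallGenes),
                      N5A = nulliTetraGenotype(smallGenes, "A"),
                      N5B = nulliTetraGenotype(smallGenes, "B"),
                      N5D = nulliTetraGenotype(smallGenes, "D"),
                      dup_1 = mut, dup_2 = mut)
    sampleReads <- lapply(seq_along(genotypes), function(i)
        simulateSampleReads(genotypes[[i]], refs, cfg, seed = 900 + i,
                            sampleId = names(genotypes)[i]))
    names(sampleReads) <- names(genotypes)
    out <- runDeletionCalling(sampleReads, refs$reference, design)
    expect_identical(intactnessMatrix(out$calls$dup_1),
                     intactnessMatrix(out$calls$dup_2))
})
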
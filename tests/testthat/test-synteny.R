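test_that("interval inference reproduces the worked flanking-marker bracket", {
    panel <- pft1FlankPanel()
    m <- markers(panel)
    profile <- profileFromOffsets(
        panel,
        deletedAt = m$offset_kb[m$offset_kb >= -400 & m$offset_kb <= 100],
        intactAt = c(-700, 200),
        mutantId = "tapft1-616-a", subgenome = "A")
    iv <- inferDeletionInterval(profile, panel)
    expect_equal(minSize(iv), 500)
    expect_equal(maxSize(iv), 900)
    expect_identical(iv@upBoundMarker,
                     m$gene_id[m$offset_kb == -700])
    expect_identical(iv@downBoundMarker,
                     m$gene_id[m$offset_kb == 200])
    expect_false(iv@openUp || iv@openDown)
})

test_that("interval inference handles tight, open and degenerate cases", {
    panel <- miniPanel()
    ## only the anchor deleted, adjacent markers at +/-50 intact
    iv <- inferDeletionInterval(
        profileFromOffsets(panel, deletedAt = 0, intactAt = c(-50, 50)),
        panel)
    expect_equal(minSize(iv), 0)
    expect_equal(maxSize(iv), 100)

    ## deleted through the outermost Down marker: open Down
    iv <- inferDeletionInterval(
        profileFromOffsets(panel, deletedAt = c(-50, 0, 50, 100, 300),
                           intactAt = -100),
        panel)
    expect_equal(minSize(iv), 350)
    expect_true(iv@openDown)
    expect_false(iv@openUp)
    expect_identical(iv@downBoundMarker, "none assayed")
    expect_identical(maxSize(iv), Inf)

    ## anchor not deleted / empty profile are errors
    expect_error(inferDeletionInterval(
        profileFromOffsets(panel, deletedAt = -50, intactAt = 0), panel),
        "anchor")
    expect_error(inferDeletionInterval(
        IntactnessProfile("m", "A", structure(character(), names = character())),
        panel), "empty")

    ## a deleted marker beyond an intact marker is non-contiguous
    expect_warning(iv <- inferDeletionInterval(
        profileFromOffsets(panel, deletedAt = c(0, 300), intactAt = c(50, -50)),
        panel), "non-contiguous")
    expect_equal(minSize(iv), 0)
    expect_equal(maxSize(iv), 100)
})

test_that("unknown calls only widen the maximal extent", {
    panel <- pft1FlankPanel()
    m <- markers(panel)
    set.seed(33)
    for (i in 1:100) {
        up <- -sample(c(0, 50, 100, 400, 1000, 2000), 1)
        down <- sample(c(0, 50, 100, 400, 1000, 2000), 1)
        calls <- ifelse(m$offset_kb >= up & m$offset_kb <= down,
                        "deleted", "intact")
        names(calls) <- m$gene_id
        ## sprinkle unknowns over intact markers
        intactIdx <- which(calls == "intact")
        flip <- intactIdx[runif(length(intactIdx)) < 0.3]
        profile <- IntactnessProfile("m", "A", calls)
        iv1 <- inferDeletionInterval(profile, panel)
        calls2 <- calls
        calls2[flip] <- "unknown"
        iv2 <- inferDeletionInterval(IntactnessProfile("m", "A", calls2),
                                     panel)
        expect_identical(minSize(iv2), minSize(iv1))
        expect_gte(maxSize(iv2), maxSize(iv1))
    }
})

test_that("interval inference ignores call storage order", {
    panel <- pft1FlankPanel()
    m <- markers(panel)
    profile <- profileFromOffsets(
        panel, deletedAt = m$offset_kb[abs(m$offset_kb) <= 100],
        intactAt = c(-200, 200))
    set.seed(4)
    shuffled <- IntactnessProfile(
        profile@mutantId, profile@subgenome,
        profile@calls[sample(length(profile@calls))])
    expect_equal(minSize(inferDeletionInterval(profile, panel)),
                 minSize(inferDeletionInterval(shuffled, panel)))
    expect_equal(maxSize(inferDeletionInterval(profile, panel)),
                 maxSize(inferDeletionInterval(shuffled, panel)))
})

test_that("synteny classification follows the best-hit dominance rules", {
    arms <- c("5AL", "5BL", "5DL")
    hit <- function(arm, id, len, e = 1e-50)
        data.frame(query_gene = "q", subject_arm = arm, identity = id,
                   align_length = len, e_value = e)
    ## hits only on the group-4 arms: translocated
    h <- rbind(hit("4AL", 97, 500), hit("4BS", 96, 480), hit("4DS", 95, 450))
    expect_identical(classifySynteny(h, arms)$status, "translocated")
    ## a single target-arm hit: conserved
    expect_identical(classifySynteny(hit("5AL", 92, 300), arms)$status,
                     "conserved")
    ## target hit dominated on both identity and length: uncertain
    h <- rbind(hit("5BL", 95, 400), hit("2AL", 96, 450))
    expect_identical(classifySynteny(h, arms)$status, "uncertain")
    ## off-target better on one criterion only does not dominate
    h <- rbind(hit("5BL", 95, 400), hit("2AL", 96, 350))
    expect_identical(classifySynteny(h, arms)$status, "conserved")
    ## empty hit table: translocated with a zero-evidence warning
    expect_warning(res <- classifySynteny(h[0, ], arms), "zero evidence")
    expect_identical(res$status, "translocated")
})

test_that("synteny classification matches a rule-table oracle over hit orderings", {
    arms <- c("5AL", "5BL", "5DL")
    set.seed(12)
    armsPool <- c("5AL", "5BL", "5DL", "2AL", "4BS", "7DL")
    for (rep in 1:40) {
        n <- sample(1:4, 1)
        h <- data.frame(query_gene = "q",
                        subject_arm = sample(armsPool, n, replace = TRUE),
                        identity = round(runif(n, 80, 100), 1),
                        align_length = sample(100:600, n),
                        e_value = 10^-sample(5:80, n, replace = TRUE))
        want <- oracleSynteny(h, arms)
        for (perm in 1:4) {
            hp <- h[sample(n), , drop = FALSE]
            expect_identical(classifySynteny(hp, arms)$status, want)
        }
    }
})

test_that("region size sums unique scaffolds of conserved genes", {
    calls <- data.frame(query_gene = c("g1", "g2", "g3"),
                        status = c("conserved", "conserved", "translocated"),
                        evidence_arms = "")
    ## two conserved genes on one scaffold: counted once
    sc <- data.frame(scaffold_id = "s1", length = 10000,
                     genes = "g1,g2")
    expect_equal(estimateRegionSize(calls, sc), 10000)
    ## conserved on 7 kb + 5 kb, translocated gene's 9 kb excluded
    sc <- data.frame(scaffold_id = c("s1", "s2", "s3"),
                     length = c(7000, 5000, 9000),
                     genes = c("g1", "g2", "g3"))
    expect_equal(estimateRegionSize(calls, sc), 12000)
    ## no conserved genes
    expect_equal(estimateRegionSize(calls[3, , drop = FALSE], sc), 0)
})
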
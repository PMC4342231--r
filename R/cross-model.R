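#' F1 genotype of a cross between homozygous deletion lines
#'
#' Each parent must be homozygous at every homoeolocus (dosage 0 or 2); the
#' F1 receives one gamete from each, so its dosage per locus is the parental
#' mean.
#'
#' @param parent1,parent2 [HomoeoGenotype-class] objects with dosages in
#'   \{0, 2\}.
#' @return The F1 [HomoeoGenotype-class].
#' @examples
#' f1Genotype(HomoeoGenotype(0, 2, 2), HomoeoGenotype(2, 0, 2))
#' @export
f1Genotype <- function(parent1, parent2) {
    d1 <- dosage(parent1)
    d2 <- dosage(parent2)
    bad <- d1 == 1L | d2 == 1L
    if (any(bad))
        stop("parents must be homozygous at every homoeolocus for F2 ratio ",
             "derivation; hemizygous (dosage 1) at: ",
             paste(SUBGENOMES[bad], collapse = ", "))
    HomoeoGenotype(A = (d1[1] + d2[1]) / 2,
                   B = (d1[2] + d2[2]) / 2,
                   D = (d1[3] + d2[3]) / 2)
}

#' Detected class of a genotype under a hemizygote-blind assay
#'
#' The screen reports only homoeoloci at which both homoeoalleles are deleted
#' (dosage 0); hemizygous loci are indistinguishable from homozygous wild
#' type.
#'
#' @param g A [HomoeoGenotype-class].
#' @return A single string from [detectedClasses()]: the sorted subgenome
#'   labels with dosage 0, or `"none"`.
#' @examples
#' detectClass(HomoeoGenotype(0, 1, 2))  # "A"
#' detectClass(HomoeoGenotype(1, 1, 1))  # "none": hemizygotes read wild type
#' @export
detectClass <- function(g) {
    del <- SUBGENOMES[dosage(g) == 0L]
    if (!length(del)) "none" else paste(del, collapse = "")
}

## Detected classes for a dosage matrix (rows = individuals, cols A,B,D).
detectClassMatrix <- function(m) {
    cls <- rep("none", nrow(m))
    del <- m == 0L
    has <- rowSums(del) > 0L
    if (any(has)) {
        cls[has] <- apply(del[has, , drop = FALSE], 1L, function(z)
            paste(SUBGENOMES[z], collapse = ""))
    }
    cls
}

#' Detected-class distribution among F2 progeny
#'
#' Given the F1 genotype, homoeoloci assort independently; a locus of F1
#' dosage h yields an F2 dosage-0 offspring with probability (1 - h/2)^2
#' (1/4 when hemizygous, 1 when already homozygous deleted, 0 when intact).
#' Class probabilities multiply across loci.
#'
#' @param f1 The F1 [HomoeoGenotype-class].
#' @return A [ClassDistribution-class] over [detectedClasses()].
#' @examples
#' f2ClassDistribution(HomoeoGenotype(1, 1, 2))  # 3:3:1:9 / 16
#' @export
f2ClassDistribution <- function(f1) {
    h <- dosage(f1)
    pDel <- (1 - h / 2)^2
    probs <- vapply(DETECTED_CLASSES, function(cls) {
        inCls <- if (cls == "none") c(FALSE, FALSE, FALSE)
                 else SUBGENOMES %in% strsplit(cls, "")[[1]]
        prod(ifelse(inCls, pDel, 1 - pDel))
    }, numeric(1))
    new("ClassDistribution", probs = probs)
}

#' Per-class chi-square goodness of fit for an F2 deletion class
#'
#' One-degree-of-freedom goodness of fit on the two-cell split \{class, not
#' class\} with no continuity correction. For `observed = 0` the statistic
#' reduces to the closed form `n * p / (1 - p)`.
#'
#' @param observed Observed count of the class.
#' @param n Total F2 progeny screened.
#' @param expectedP Expected class probability, in (0, 1).
#' @param class Optional class label carried into the result.
#' @param config A [SignificanceConfig-class] supplying the flag thresholds.
#' @return A one-row data.frame with columns `class`, `observed`, `expected`,
#'   `statistic`, `df`, `p_value`, `flag` (`""`, `"*"` or `"**"`) and `bold`
#'   (`TRUE` when the class was never observed and the deficit is flagged).
#' @examples
#' perClassChiSquare(0, 252, 1 / 64)   # statistic 4, p ~ 0.0455, "*"
#' @export
perClassChiSquare <- function(observed, n, expectedP, class = NA_character_,
                              config = SignificanceConfig()) {
    observed <- as.integer(observed)
    n <- as.integer(n)
    if (observed < 0L || observed > n)
        stop("observed must lie in 0..n")
    if (expectedP <= 0 || expectedP >= 1) {
        if (expectedP == 0 && observed > 0L)
            stop("impossible class observed: ", class,
                 " has expected probability 0 but count ", observed)
        stop("expectedP must be in (0, 1)")
    }
    e1 <- n * expectedP
    e2 <- n * (1 - expectedP)
    statistic <- (observed - e1)^2 / e1 + ((n - observed) - e2)^2 / e2
    p <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
    flag <- if (p < config@alpha2) "**" else if (p < config@alpha1) "*" else ""
    data.frame(class = class, observed = observed, expected = e1,
               statistic = statistic, df = 1L, p_value = p, flag = flag,
               bold = observed == 0L && nzchar(flag),
               stringsAsFactors = FALSE)
}

#' Test every expected deletion class of a cross for incompatibility
#'
#' Derives the F1 and its F2 detected-class distribution from the cross
#' parents, then applies [perClassChiSquare()] to each deletion class with
#' positive expected probability, reproducing the per-cell significance
#' flags of a deletion-stacking screen.
#'
#' @param table An [ObservedCrossTable-class].
#' @param config A [SignificanceConfig-class].
#' @return A data.frame with one row per expected deletion class (columns as
#'   in [perClassChiSquare()]); empty (with a warning) when `n = 0`.
#' @examples
#' ct <- ObservedCrossTable(indexToCross(1), n = 316,
#'                          counts = c(A = 55, B = 51, AB = 0))
#' evaluateCrossTable(ct)
#' @export
evaluateCrossTable <- function(table, config = SignificanceConfig()) {
    stopifnot(is(table, "ObservedCrossTable"))
    empty <- data.frame(class = character(), observed = integer(),
                        expected = numeric(), statistic = numeric(),
                        df = integer(), p_value = numeric(),
                        flag = character(), bold = logical())
    if (table@n == 0L) {
        warning("no progeny screened for cross ", sQuote(table@cross@label))
        return(empty)
    }
    dist <- f2ClassDistribution(f1Genotype(table@cross@parent1,
                                           table@cross@parent2))
    p <- classProbs(dist)
    ## only classes the table reports are tested: screening tables omit
    ## classes that were not scored (e.g. single-locus deletions among the
    ## progeny of tetra x tetra crosses)
    listed <- names(table@counts)
    impossible <- listed[p[listed] == 0 & table@counts > 0L]
    if (length(impossible))
        stop("observed count for class(es) with zero expected probability: ",
             paste(impossible, collapse = ", "))
    testable <- listed[p[listed] > 0]
    if (!length(testable)) return(empty)
    res <- do.call(rbind, lapply(testable, function(cls)
        perClassChiSquare(table@counts[cls], table@n, p[cls], class = cls,
                          config = config)))
    rownames(res) <- NULL
    res
}

#' Parental genotypes for the standard expected-ratio indices
#'
#' Index 1: A x B primary mutants; 2: A x D; 3: B x D; 4: AD-tetra x
#' BD-tetra (all progeny carry a D deletion); 5: AB-tetra x D primary.
#'
#' @param index Integer in 1..5.
#' @param label Optional cross label.
#' @return A [CrossSpec-class].
#' @examples
#' indexToCross(5)
#' @export
indexToCross <- function(index, label = paste0("index-", index)) {
    parents <- switch(as.character(index),
        "1" = list(HomoeoGenotype(0, 2, 2), HomoeoGenotype(2, 0, 2)),
        "2" = list(HomoeoGenotype(0, 2, 2), HomoeoGenotype(2, 2, 0)),
        "3" = list(HomoeoGenotype(2, 0, 2), HomoeoGenotype(2, 2, 0)),
        "4" = list(HomoeoGenotype(0, 2, 0), HomoeoGenotype(2, 0, 0)),
        "5" = list(HomoeoGenotype(0, 0, 2), HomoeoGenotype(2, 2, 0)),
        stop("unknown expected-ratio index: ", index))
    CrossSpec(parents[[1]], parents[[2]], label = label,
              index = as.integer(index))
}

#' Monte-Carlo power to flag lethal classes as incompatible
#'
#' Simulates F2 screens of size `n` from the cross's detected-class
#' distribution with the lethal classes removed (renormalized), evaluates
#' each simulated table, and returns the proportion of replicates in which
#' every lethal class is flagged at `alpha1`. With an empty lethal set the
#' returned value is instead the per-class false-flagging rate under the
#' null (averaged over classes and replicates).
#'
#' @param cross A [CrossSpec-class].
#' @param n F2 progeny per simulated screen.
#' @param lethalClasses Character vector of detected classes (e.g. `"AB"`)
#'   removed from the population before screening; may be empty.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param config A [SignificanceConfig-class].
#' @return A proportion in [0, 1].
#' @examples
#' incompatibilityPower(indexToCross(1), n = 316, lethalClasses = "AB",
#'                      reps = 50, seed = 1)
#' @export
incompatibilityPower <- function(cross, n, lethalClasses = character(),
                                 reps = 200L, seed = 1L,
                                 config = SignificanceConfig()) {
    stopifnot(reps >= 1L)
    lethalClasses <- unique(lethalClasses)
    if (!all(lethalClasses %in% DETECTED_CLASSES))
        stop("unknown detected class in lethalClasses")
    dist <- f2ClassDistribution(f1Genotype(cross@parent1, cross@parent2))
    p <- classProbs(dist)
    keep <- !(names(p) %in% lethalClasses)
    if (sum(p[keep]) <= 0)
        stop("lethal classes cover the whole F2 distribution")
    pSim <- p
    pSim[!keep] <- 0
    pSim <- pSim / sum(pSim)
    delClasses <- setdiff(names(p)[p > 0], "none")
    set.seed(seed)
    draws <- stats::rmultinom(reps, size = n, prob = pSim)
    rownames(draws) <- names(pSim)
    hit <- logical(reps)
    falseFlags <- numeric(reps)
    for (r in seq_len(reps)) {
        counts <- draws[delClasses, r]
        tab <- ObservedCrossTable(cross, n = n, counts = counts)
        res <- evaluateCrossTable(tab, config = config)
        flagged <- res$class[res$p_value < config@alpha1]
        if (length(lethalClasses)) {
            hit[r] <- all(lethalClasses %in% flagged)
        } else {
            falseFlags[r] <- length(flagged) / nrow(res)
        }
    }
    if (length(lethalClasses)) mean(hit) else mean(falseFlags)
}
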
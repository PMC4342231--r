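#' @import methods
NULL

SUBGENOMES <- c("A", "B", "D")

## Canonical order of detectable genotype classes under a hemizygote-blind
## assay: the subset of subgenomes at which both homoeoalleles are deleted.
DETECTED_CLASSES <- c("none", "A", "B", "D", "AB", "AD", "BD", "ABD")

#' Subgenome and detected-class vocabularies
#'
#' `subgenomes()` returns the three wheat subgenome labels. `detectedClasses()`
#' returns the canonical order of the eight genotype classes a hemizygote-blind
#' deletion screen can report: the (possibly empty) set of homoeoloci at which
#' both homoeoalleles are deleted, written as a sorted string such as `"AB"`,
#' with `"none"` for the empty set.
#'
#' @return A character vector.
#' @examples
#' subgenomes()
#' detectedClasses()
#' @export
subgenomes <- function() SUBGENOMES

#' @rdname subgenomes
#' @export
detectedClasses <- function() DETECTED_CLASSES

#' HomoeoGenotype: intact-allele dosage at the three homoeoloci
#'
#' Dosage of intact alleles at the A, B and D homoeoloci of a target gene:
#' 2 = homozygous intact, 1 = hemizygous (one homoeoallele deleted),
#' 0 = homozygous deleted.
#'
#' @slot dosage Named integer vector of length 3 (names `"A"`, `"B"`, `"D"`),
#'   each element in 0..2.
#' @export
setClass("HomoeoGenotype", representation(dosage = "integer"))

setValidity("HomoeoGenotype", function(object) {
    d <- object@dosage
    if (length(d) != 3L || !identical(names(d), SUBGENOMES))
        return("dosage must be a length-3 integer vector named A, B, D")
    if (anyNA(d) || any(d < 0L | d > 2L))
        return("each dosage must be 0, 1 or 2")
    TRUE
})

#' Construct a HomoeoGenotype
#'
#' @param A,B,D Integer dosage of intact alleles (0, 1 or 2) at each
#'   homoeolocus.
#' @return A [HomoeoGenotype-class] object.
#' @examples
#' HomoeoGenotype(0, 2, 2)   # homozygous A-deletion primary mutant
#' @export
HomoeoGenotype <- function(A = 2L, B = 2L, D = 2L) {
    d <- as.integer(c(A = A, B = B, D = D))
    names(d) <- SUBGENOMES
    new("HomoeoGenotype", dosage = d)
}

#' @rdname HomoeoGenotype
#' @param object,x A `HomoeoGenotype`.
#' @export
setMethod("show", "HomoeoGenotype", function(object) {
    sym <- mapply(function(s, d) {
        paste0(rep(c(tolower(s), s), c(2L - d, d)), collapse = "")
    }, SUBGENOMES, object@dosage)
    cat("HomoeoGenotype:", paste(sym, collapse = " "), "\n")
})

#' @rdname HomoeoGenotype
#' @export
dosage <- function(x) {
    stopifnot(is(x, "HomoeoGenotype"))
    x@dosage
}

#' CrossSpec: a cross between two deletion lines
#'
#' Both parents must be homozygous at every homoeolocus (dosage 0 or 2) for
#' F2 expected-ratio derivation; the F1 is computed internally.
#'
#' @slot parent1,parent2 [HomoeoGenotype-class] parents.
#' @slot label Free-text cross label.
#' @slot index Integer index of the expected-ratio family (1: A x B primaries,
#'   2: A x D, 3: B x D, 4: AD-tetra x BD-tetra, 5: AB-tetra x D primary), or
#'   `NA`.
#' @export
setClass("CrossSpec", representation(
    parent1 = "HomoeoGenotype", parent2 = "HomoeoGenotype",
    label = "character", index = "integer"))

setValidity("CrossSpec", function(object) {
    if (length(object@label) != 1L) return("label must be a single string")
    if (length(object@index) != 1L) return("index must be a single integer or NA")
    TRUE
})

#' Construct a CrossSpec
#'
#' @param parent1,parent2 [HomoeoGenotype-class] parents, homozygous at every
#'   locus.
#' @param label Cross label.
#' @param index Optional expected-ratio index (1-5); see [indexToCross()].
#' @return A [CrossSpec-class].
#' @export
CrossSpec <- function(parent1, parent2, label = "", index = NA_integer_) {
    new("CrossSpec", parent1 = parent1, parent2 = parent2,
        label = as.character(label), index = as.integer(index))
}

setMethod("show", "CrossSpec", function(object) {
    cat("CrossSpec", if (nzchar(object@label)) sQuote(object@label) else "",
        if (!is.na(object@index)) paste0("(index ", object@index, ")") else "",
        "\n")
    show(object@parent1)
    show(object@parent2)
})

#' ClassDistribution: probability law of detected F2 classes
#'
#' Probability of each hemizygote-blind detected class among F2 progeny.
#'
#' @slot probs Named numeric vector over [detectedClasses()], non-negative,
#'   summing to 1.
#' @export
setClass("ClassDistribution", representation(probs = "numeric"))

setValidity("ClassDistribution", function(object) {
    p <- object@probs
    if (!identical(names(p), DETECTED_CLASSES))
        return("probs must be named by detectedClasses() in canonical order")
    if (any(p < 0)) return("probabilities must be non-negative")
    if (abs(sum(p) - 1) > 1e-12) return("probabilities must sum to 1")
    TRUE
})

#' @rdname ClassDistribution-class
#' @param x A `ClassDistribution`.
#' @return `classProbs()` returns the named probability vector.
#' @export
classProbs <- function(x) {
    stopifnot(is(x, "ClassDistribution"))
    x@probs
}

setMethod("show", "ClassDistribution", function(object) {
    p <- object@probs[object@probs > 0]
    frac <- vapply(p, function(q) {
        den <- 4^max(1, ceiling(log(1 / min(object@probs[object@probs > 0]), 4)))
        num <- q * den
        if (abs(num - round(num)) < 1e-9)
            paste0(round(num), "/", den) else format(q, digits = 4)
    }, character(1))
    cat("ClassDistribution over detected F2 classes:\n")
    print(noquote(frac))
})

#' ObservedCrossTable: screened F2 counts for one cross
#'
#' @slot cross A [CrossSpec-class].
#' @slot n Total number of F2 progeny screened.
#' @slot counts Named integer vector of observed counts per detected deletion
#'   class (subset of `detectedClasses()` excluding `"none"`); the `"none"`
#'   class is implicit (`n` minus the listed counts).
#' @slot gene Gene label the cross targets.
#' @export
setClass("ObservedCrossTable", representation(
    cross = "CrossSpec", n = "integer", counts = "integer",
    gene = "character"))

setValidity("ObservedCrossTable", function(object) {
    if (object@n < 0L) return("n must be non-negative")
    cn <- names(object@counts)
    if (length(object@counts) &&
        (is.null(cn) || !all(cn %in% setdiff(DETECTED_CLASSES, "none"))))
        return("counts must be named by deletion classes (A..ABD)")
    if (any(object@counts < 0L)) return("counts must be non-negative")
    if (sum(object@counts) > object@n)
        return("sum of listed class counts exceeds n")
    TRUE
})

#' Construct an ObservedCrossTable
#'
#' @param cross A [CrossSpec-class].
#' @param n Number of F2 progeny screened.
#' @param counts Named integer vector of per-class observed counts, e.g.
#'   `c(A = 55, B = 51, AB = 0)`.
#' @param gene Gene label.
#' @return An [ObservedCrossTable-class].
#' @export
ObservedCrossTable <- function(cross, n, counts = integer(), gene = "") {
    cnt <- as.integer(counts)
    names(cnt) <- names(counts)
    new("ObservedCrossTable", cross = cross, n = as.integer(n),
        counts = cnt, gene = as.character(gene))
}

setMethod("show", "ObservedCrossTable", function(object) {
    cat("ObservedCrossTable", sQuote(object@gene), "n =", object@n, "\n")
    print(object@counts)
})

#' SignificanceConfig: alpha levels for incompatibility flags
#'
#' Classes observed significantly below expectation are flagged `"*"`
#' (`alpha2 <= p < alpha1`) or `"**"` (`p < alpha2`).
#'
#' @slot alpha1,alpha2 Significance levels, `0 < alpha2 < alpha1 < 1`.
#' @export
setClass("SignificanceConfig",
         representation(alpha1 = "numeric", alpha2 = "numeric"))

setValidity("SignificanceConfig", function(object) {
    if (!(object@alpha2 > 0 && object@alpha2 < object@alpha1 &&
          object@alpha1 < 1))
        return("need 0 < alpha2 < alpha1 < 1")
    TRUE
})

#' @rdname SignificanceConfig-class
#' @param alpha1,alpha2 Significance levels (defaults 0.05 and 0.01).
#' @export
SignificanceConfig <- function(alpha1 = 0.05, alpha2 = 0.01) {
    new("SignificanceConfig", alpha1 = alpha1, alpha2 = alpha2)
}

#' CallerConfig: thresholds for amplicon alignment and SNP detection
#'
#' @slot minIdentity Minimum ungapped alignment identity for a read to map
#'   (fraction; default 0.85).
#' @slot minAlleleFreq Minimum variant allele frequency (fraction of coverage;
#'   default 0.05).
#' @slot minCoverage Minimum read coverage at a position for SNP detection
#'   (default 50).
#' @export
setClass("CallerConfig", representation(
    minIdentity = "numeric", minAlleleFreq = "numeric",
    minCoverage = "integer"))

setValidity("CallerConfig", function(object) {
    if (!(object@minIdentity > 0 && object@minIdentity <= 1))
        return("minIdentity must be in (0, 1]")
    if (!(object@minAlleleFreq > 0 && object@minAlleleFreq < 1))
        return("minAlleleFreq must be in (0, 1)")
    if (object@minCoverage < 1L) return("minCoverage must be >= 1")
    TRUE
})

#' @rdname CallerConfig-class
#' @param minIdentity,minAlleleFreq,minCoverage See slots.
#' @export
CallerConfig <- function(minIdentity = 0.85, minAlleleFreq = 0.05,
                         minCoverage = 50L) {
    new("CallerConfig", minIdentity = minIdentity,
        minAlleleFreq = minAlleleFreq, minCoverage = as.integer(minCoverage))
}

#' ControlDesign: control samples for homoeologue-specific SNP assignment
#'
#' @slot wildTypeSamples Sample ids of euploid wild-type controls (a SNP must
#'   be present in all of them to be retained).
#' @slot nullTetra Named character vector mapping each subgenome (`A`, `B`,
#'   `D`) to the sample id of the nullisomic-tetrasomic line lacking it.
#' @slot extraControls Optional named character vector of further controls
#'   (e.g. a ditelosomic line); not used for assignment.
#' @export
setClass("ControlDesign", representation(
    wildTypeSamples = "character", nullTetra = "character",
    extraControls = "character"))

setValidity("ControlDesign", function(object) {
    if (length(object@wildTypeSamples) < 1L)
        return("at least one wild-type sample is required")
    if (!identical(sort(names(object@nullTetra)), SUBGENOMES))
        return("nullTetra must name one control for each of A, B, D")
    TRUE
})

#' @rdname ControlDesign-class
#' @param wildTypeSamples,nullTetra,extraControls See slots.
#' @export
ControlDesign <- function(wildTypeSamples, nullTetra,
                          extraControls = character()) {
    new("ControlDesign", wildTypeSamples = wildTypeSamples,
        nullTetra = nullTetra[SUBGENOMES], extraControls = extraControls)
}

#' HomoeoSnpSets: homoeologue-specific SNP assignment
#'
#' @slot assigned data.frame with columns `gene_id`, `ref_position`,
#'   `allele_variant`, `subgenome`: consensus SNPs absent from exactly one
#'   nullisomic-tetrasomic control, assigned to that control's missing
#'   subgenome.
#' @slot unassigned data.frame with columns `gene_id`, `ref_position`,
#'   `allele_variant`, `reason`: consensus SNPs absent from zero or from
#'   multiple controls.
#' @slot genes Character vector of all gene ids in the annotation (so genes
#'   with no specific SNP can later be reported `unknown`).
#' @export
setClass("HomoeoSnpSets", representation(
    assigned = "data.frame", unassigned = "data.frame", genes = "character"))

setValidity("HomoeoSnpSets", function(object) {
    need <- c("gene_id", "ref_position", "allele_variant", "subgenome")
    if (!all(need %in% names(object@assigned)))
        return("assigned needs gene_id, ref_position, allele_variant, subgenome")
    key <- with(object@assigned, paste(gene_id, ref_position, allele_variant))
    if (anyDuplicated(key))
        return("subgenome sets must be disjoint as (gene, position, allele)")
    TRUE
})

setMethod("show", "HomoeoSnpSets", function(object) {
    cat("HomoeoSnpSets:", nrow(object@assigned), "homoeologue-specific SNPs",
        "across", length(object@genes), "genes;",
        nrow(object@unassigned), "unassigned\n")
    if (nrow(object@assigned))
        print(table(object@assigned$gene_id, object@assigned$subgenome))
})

#' @rdname HomoeoSnpSets-class
#' @param x A `HomoeoSnpSets`.
#' @return `assignedSnps()` / `unassignedSnps()` return the underlying
#'   data.frames.
#' @export
assignedSnps <- function(x) {
    stopifnot(is(x, "HomoeoSnpSets"))
    x@assigned
}

#' @rdname HomoeoSnpSets-class
#' @export
unassignedSnps <- function(x) {
    stopifnot(is(x, "HomoeoSnpSets"))
    x@unassigned
}

#' MarkerPanel: ordered synteny-anchored marker panel
#'
#' Markers flanking an anchor gene, placed by signed offset in kb (negative =
#' "Up", toward the distal end of the short arm; positive = "Down").
#'
#' @slot markers data.frame with columns `gene_id`, `offset_kb`, `label`,
#'   sorted by offset, containing the anchor at offset 0.
#' @export
setClass("MarkerPanel", representation(markers = "data.frame"))

setValidity("MarkerPanel", function(object) {
    m <- object@markers
    if (!all(c("gene_id", "offset_kb", "label") %in% names(m)))
        return("markers needs gene_id, offset_kb, label")
    if (anyDuplicated(m$offset_kb)) return("offsets must be unique")
    if (!any(m$offset_kb == 0)) return("panel must contain the anchor (offset 0)")
    if (is.unsorted(m$offset_kb)) return("markers must be sorted by offset")
    TRUE
})

#' Construct a MarkerPanel
#'
#' @param gene_id Character marker gene ids.
#' @param offset_kb Signed offsets in kb from the anchor.
#' @param label Optional display labels.
#' @return A [MarkerPanel-class].
#' @seealso [pft1FlankPanel()] for the packaged 21-marker panel.
#' @export
MarkerPanel <- function(gene_id, offset_kb, label = NULL) {
    if (is.null(label)) {
        label <- ifelse(offset_kb == 0, "anchor",
                        paste(ifelse(offset_kb < 0, "Up", "Down"),
                              abs(offset_kb), "kb"))
    }
    m <- data.frame(gene_id = as.character(gene_id),
                    offset_kb = as.numeric(offset_kb),
                    label = as.character(label))
    m <- m[order(m$offset_kb), , drop = FALSE]
    rownames(m) <- NULL
    new("MarkerPanel", markers = m)
}

setMethod("show", "MarkerPanel", function(object) {
    m <- object@markers
    cat("MarkerPanel with", nrow(m), "markers spanning",
        min(m$offset_kb), "to", max(m$offset_kb), "kb\n")
})

#' @rdname MarkerPanel-class
#' @param x A `MarkerPanel`.
#' @return `markers()` returns the marker data.frame.
#' @export
markers <- function(x) {
    stopifnot(is(x, "MarkerPanel"))
    x@markers
}

#' @rdname MarkerPanel-class
#' @export
anchorGene <- function(x) {
    m <- markers(x)
    m$gene_id[m$offset_kb == 0]
}

#' IntactnessProfile: per-marker intactness calls for one mutant x subgenome
#'
#' @slot mutantId Sample/mutant identifier.
#' @slot subgenome One of `"A"`, `"B"`, `"D"`.
#' @slot calls Named character vector, `gene_id -> {"intact", "deleted",
#'   "unknown"}`.
#' @export
setClass("IntactnessProfile", representation(
    mutantId = "character", subgenome = "character", calls = "character"))

setValidity("IntactnessProfile", function(object) {
    if (!object@subgenome %in% SUBGENOMES)
        return("subgenome must be one of A, B, D")
    if (!all(object@calls %in% c("intact", "deleted", "unknown")))
        return("calls must be intact/deleted/unknown")
    if (is.null(names(object@calls)))
        return("calls must be named by gene_id")
    TRUE
})

#' Construct an IntactnessProfile
#'
#' @param mutantId Mutant identifier.
#' @param subgenome Subgenome the profile describes.
#' @param calls Named character vector of `intact`/`deleted`/`unknown` calls
#'   per marker gene.
#' @return An [IntactnessProfile-class].
#' @export
IntactnessProfile <- function(mutantId, subgenome, calls) {
    new("IntactnessProfile", mutantId = as.character(mutantId),
        subgenome = as.character(subgenome), calls = calls)
}

setMethod("show", "IntactnessProfile", function(object) {
    cat("IntactnessProfile", sQuote(object@mutantId),
        paste0("[", object@subgenome, "]:"),
        sum(object@calls == "deleted"), "deleted /",
        sum(object@calls == "intact"), "intact /",
        sum(object@calls == "unknown"), "unknown\n")
})

#' DeletionInterval: inferred min/max deletion span
#'
#' The minimum span runs between the outermost markers called deleted; the
#' maximum extends to the nearest flanking markers with a definite intact
#' call (unknowns are skipped). A side with no intact marker beyond the
#' deleted run is open (`maxSize = Inf`).
#'
#' @slot minSize,maxSize Span in kb; `maxSize` is `Inf` when open on a side.
#' @slot upBoundMarker,downBoundMarker Gene ids of the nearest intact markers
#'   bounding the deletion, or `"none assayed"`.
#' @slot openUp,openDown Logical; `TRUE` when no intact marker bounds that
#'   side.
#' @slot mutantId,subgenome Provenance of the profile.
#' @export
setClass("DeletionInterval", representation(
    minSize = "numeric", maxSize = "numeric",
    upBoundMarker = "character", downBoundMarker = "character",
    openUp = "logical", openDown = "logical",
    mutantId = "character", subgenome = "character"))

setValidity("DeletionInterval", function(object) {
    if (object@minSize < 0) return("minSize must be >= 0")
    if (is.finite(object@maxSize) && object@minSize > object@maxSize)
        return("minSize must be <= maxSize when maxSize is bounded")
    TRUE
})

setMethod("show", "DeletionInterval", function(object) {
    mx <- if (is.finite(object@maxSize)) paste(object@maxSize, "kb")
          else paste0("> ", object@minSize, " kb (open)")
    cat("DeletionInterval", sQuote(object@mutantId),
        paste0("[", object@subgenome, "]:"),
        "min", object@minSize, "kb, max", mx, "\n",
        " bounds:", object@upBoundMarker, "(Up) /",
        object@downBoundMarker, "(Down)\n")
})

#' @rdname DeletionInterval-class
#' @param x A `DeletionInterval`.
#' @return `minSize()`/`maxSize()` return spans in kb.
#' @export
minSize <- function(x) {
    stopifnot(is(x, "DeletionInterval"))
    x@minSize
}

#' @rdname DeletionInterval-class
#' @export
maxSize <- function(x) {
    stopifnot(is(x, "DeletionInterval"))
    x@maxSize
}

#' SimulationConfig: parameters of the synthetic amplicon data generator
#'
#' Defaults emulate the study conditions the analysis assumes: ~800 bp
#' amplicons (within the 500-1500 bp design window), 3% pairwise divergence
#' between homoeologues (96-98% identity), 200 bp reads at 60-fold per-copy
#' coverage, and a 1% per-base substitution error rate.
#'
#' @slot ampliconLength Amplicon length in bases.
#' @slot divergence Target pairwise divergence between homoeologues
#'   (fraction).
#' @slot readLength Read length in bases.
#' @slot coverage Per-copy fold coverage.
#' @slot errorRate Per-base substitution probability.
#' @export
setClass("SimulationConfig", representation(
    ampliconLength = "integer", divergence = "numeric",
    readLength = "integer", coverage = "numeric", errorRate = "numeric"))

setValidity("SimulationConfig", function(object) {
    if (object@divergence < 0 || object@divergence >= 0.2)
        return("divergence must be in [0, 0.2)")
    if (object@coverage < 1) return("coverage must be >= 1")
    if (object@readLength > object@ampliconLength)
        return("readLength must not exceed ampliconLength")
    if (object@errorRate < 0 || object@errorRate >= 1)
        return("errorRate must be in [0, 1)")
    TRUE
})

#' @rdname SimulationConfig-class
#' @param ampliconLength,divergence,readLength,coverage,errorRate See slots.
#' @export
SimulationConfig <- function(ampliconLength = 800L, divergence = 0.03,
                             readLength = 200L, coverage = 60,
                             errorRate = 0.01) {
    new("SimulationConfig", ampliconLength = as.integer(ampliconLength),
        divergence = divergence, readLength = as.integer(readLength),
        coverage = coverage, errorRate = errorRate)
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@ampliconLength, "bp amplicons,",
        100 * object@divergence, "% divergence,",
        object@readLength, "bp reads at", object@coverage, "x per copy,",
        100 * object@errorRate, "% error\n")
})
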
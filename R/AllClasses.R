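#' Amplicon reference sequence with flanking primers
#'
#' Holds the amplicon reference in sequencing orientation together with the
#' two PCR primers. The forward primer must occur near the 5' end of the
#' reference; the reverse primer is stored as the oligo itself, i.e. its
#' reverse complement must occur near the 3' end. The sequence between the
#' two primer footprints is the reference window that reads are aligned to
#' and variant positions are reported on.
#'
#' @slot seq A [Biostrings::DNAString] with the full amplicon sequence.
#' @slot fwdPrimer,revPrimer [Biostrings::DNAString] primers (the reverse
#'   primer in its own 5'->3' orientation).
#' @slot name Character scalar naming the amplicon.
#'
#' @aliases AmpliconReference
#' @exportClass AmpliconReference
setClass("AmpliconReference",
    representation(seq = "DNAString", fwdPrimer = "DNAString",
                   revPrimer = "DNAString", name = "character"))

setValidity("AmpliconReference", function(object) {
    s <- as.character(object@seq)
    f <- as.character(object@fwdPrimer)
    r <- as.character(Biostrings::reverseComplement(object@revPrimer))
    if (nchar(s) < nchar(f) + nchar(r) + 1)
        return("reference shorter than its two primers")
    if (substr(s, 1L, nchar(f)) != f)
        return("forward primer is not a prefix of the reference")
    if (substr(s, nchar(s) - nchar(r) + 1L, nchar(s)) != r)
        return("reverse-complemented reverse primer is not a suffix of the reference")
    TRUE
})

#' Construct an AmpliconReference
#'
#' @param seq Amplicon sequence (character or DNAString), forward orientation,
#'   beginning with the forward primer and ending with the reverse complement
#'   of the reverse primer.
#' @param fwdPrimer,revPrimer Primer sequences, each in its own 5'->3'
#'   orientation (as ordered from the oligo house).
#' @param name Optional amplicon name.
#' @return An [AmpliconReference-class] object.
#' @examples
#' ref <- AmpliconReference("ACGTACGTAAATTTCCCGGGTACGCATGCA",
#'                          fwdPrimer = "ACGTACGT",
#'                          revPrimer = "TGCATGCG")
#' refWindow(ref)
#' @export
AmpliconReference <- function(seq, fwdPrimer, revPrimer, name = "amplicon") {
    new("AmpliconReference",
        seq = Biostrings::DNAString(toupper(as.character(seq))),
        fwdPrimer = Biostrings::DNAString(toupper(as.character(fwdPrimer))),
        revPrimer = Biostrings::DNAString(toupper(as.character(revPrimer))),
        name = name)
}

#' @describeIn AmpliconReference-class Full reference sequence as DNAString.
#' @param object,x An `AmpliconReference`.
#' @export
refSequence <- function(x) x@seq

#' @describeIn AmpliconReference-class Forward primer.
#' @export
fwdPrimer <- function(x) x@fwdPrimer

#' @describeIn AmpliconReference-class Reverse primer (oligo orientation).
#' @export
revPrimer <- function(x) x@revPrimer

#' @describeIn AmpliconReference-class The inter-primer reference window that
#'   alignment and variant positions refer to.
#' @export
refWindow <- function(x) {
    s <- as.character(x@seq)
    f <- nchar(as.character(x@fwdPrimer))
    r <- nchar(as.character(x@revPrimer))
    Biostrings::DNAString(substr(s, f + 1L, nchar(s) - r))
}

setMethod("show", "AmpliconReference", function(object) {
    cat("AmpliconReference '", object@name, "': ",
        length(object@seq), " bp (window ",
        length(refWindow(object)), " bp)\n", sep = "")
})

#' Cross-sample variant count container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `counts` assay
#' holds read counts with variants as rows and samples as columns (matrix C;
#' per-sample proportions, matrix P, are derived on demand). Reduced tables
#' (C') produced by [reduceCounts()] carry the reserved rows
#' `uneditedName()` and `commonSumName()`, a `role` column in `rowData`, and
#' the applied `theta_v` in `metadata`.
#'
#' @aliases BarcodeExperiment
#' @exportClass BarcodeExperiment
setClass("BarcodeExperiment", contains = "SummarizedExperiment")

setValidity("BarcodeExperiment", function(object) {
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        return("missing 'counts' assay")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) return("negative counts")
    if (is.null(rownames(cts))) return("variant names (rownames) required")
    if (anyDuplicated(rownames(cts))) return("duplicated variant names")
    TRUE
})

#' Construct a BarcodeExperiment from per-sample variant tables
#'
#' @param tables Either a named list of per-sample variant tables as returned
#'   by [tabulateSample()] (each a data.frame with `variant` and `count`
#'   columns), or a numeric count matrix with variants as rows and samples as
#'   columns.
#' @return A [BarcodeExperiment-class].
#' @examples
#' tabs <- list(
#'   s1 = tabulateSample(c("125:1I", "125:1I", "no variant")),
#'   s2 = tabulateSample(c("7:2D", "no variant")))
#' be <- BarcodeExperiment(tabs)
#' variantCounts(be)
#' @export
BarcodeExperiment <- function(tables) {
    if (is.matrix(tables)) {
        cts <- tables
    } else {
        stopifnot(is.list(tables), length(tables) >= 1L)
        if (is.null(names(tables)))
            names(tables) <- sprintf("sample%02d", seq_along(tables))
        allv <- unique(unlist(lapply(tables, function(t) t$variant)))
        cts <- matrix(0L, nrow = length(allv), ncol = length(tables),
                      dimnames = list(allv, names(tables)))
        for (j in seq_along(tables))
            cts[tables[[j]]$variant, j] <- tables[[j]]$count
    }
    role <- ifelse(rownames(cts) == UNEDITED, "unedited",
            ifelse(rownames(cts) == COMMON_SUM, "common_sum", "informative"))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cts),
        rowData = S4Vectors::DataFrame(role = role, row.names = rownames(cts)))
    new("BarcodeExperiment", se)
}

#' @describeIn BarcodeExperiment-class Read-count matrix (variants x samples).
#' @param x,object A `BarcodeExperiment`.
#' @export
variantCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn BarcodeExperiment-class Per-sample proportion matrix; each
#'   column sums to 1 over that sample's aligned reads.
#' @export
variantProportions <- function(x) {
    cts <- variantCounts(x)
    sweep(cts, 2L, colSums(cts), "/")
}

#' @describeIn BarcodeExperiment-class Aligned-read total per sample.
#' @export
sampleTotals <- function(x) colSums(variantCounts(x))

setMethod("show", "BarcodeExperiment", function(object) {
    cts <- variantCounts(object)
    th <- S4Vectors::metadata(object)$theta_v
    cat("BarcodeExperiment: ", nrow(cts), " variants x ", ncol(cts),
        " samples", if (!is.null(th)) sprintf(" (reduced, theta_V = %g)", th),
        "\n", sep = "")
    cat("  aligned reads/sample: ",
        paste(range(colSums(cts)), collapse = "-"), "\n", sep = "")
})

#' Result of a theta_V threshold sweep
#'
#' Stores, for each candidate threshold, the mean pairwise Sharing Factor
#' over informative rows (`meanS`), the same statistic over all rows
#' including the unedited and aggregated common-variant rows (`meanSAll`),
#' the mean fraction of informative reads (`meanPhi`), the Z-scores of
#' mean phi and of 1 - mean S, their element-wise product, and the selected
#' threshold (argmax of the product). See [sweepTheta()].
#'
#' @aliases SharingSweep
#' @exportClass SharingSweep
setClass("SharingSweep",
    representation(thetaValues = "numeric", meanS = "numeric",
                   meanSAll = "numeric", meanPhi = "numeric",
                   zPhi = "numeric", zOneMinusS = "numeric",
                   zProduct = "numeric", selectedTheta = "numeric",
                   commonVariants = "character", warnings = "character"))

setValidity("SharingSweep", function(object) {
    n <- length(object@thetaValues)
    if (length(object@meanS) != n || length(object@meanPhi) != n ||
        length(object@zProduct) != n)
        return("sweep vectors must share the theta grid length")
    if (!object@selectedTheta %in% object@thetaValues)
        return("selectedTheta not on the swept grid")
    TRUE
})

#' @describeIn SharingSweep-class Selected theta_V (argmax of the Z-score
#'   product).
#' @param x,object A `SharingSweep`.
#' @export
selectedTheta <- function(x) x@selectedTheta

#' @describeIn SharingSweep-class Variant names flagged common at the
#'   selected threshold.
#' @export
commonVariants <- function(x) x@commonVariants

#' @describeIn SharingSweep-class QC warnings raised during the sweep.
#' @export
sweepWarnings <- function(x) x@warnings

#' @describeIn SharingSweep-class Sweep table as a data.frame (one row per
#'   theta value).
#' @export
sweepTable <- function(x) {
    data.frame(theta_v = x@thetaValues, mean_S = x@meanS,
               mean_S_all = x@meanSAll, mean_phi = x@meanPhi,
               z_phi = x@zPhi, z_one_minus_S = x@zOneMinusS,
               z_product = x@zProduct)
}

setMethod("show", "SharingSweep", function(object) {
    cat("SharingSweep over", length(object@thetaValues), "thresholds\n")
    i <- match(object@selectedTheta, object@thetaValues)
    cat(sprintf("  selected theta_V = %g (mean S = %.4g, mean phi = %.3f)\n",
                object@selectedTheta, object@meanS[i], object@meanPhi[i]))
    cat("  common variants flagged:", length(object@commonVariants), "\n")
    if (length(object@warnings))
        cat("  warnings:\n", paste0("   - ", object@warnings, "\n"), sep = "")
})

#' Bootstrap of the mean fraction of informative reads
#'
#' Result of [bootstrapPhi()]: paired bootstrap replicates of mean phi and of
#' the standard deviation of the clone count B_0.02, the BCa confidence
#' interval for mean phi, and the Pearson correlation between the two
#' replicate series.
#'
#' @aliases BootstrapResult
#' @exportClass BootstrapResult
setClass("BootstrapResult",
    representation(nReps = "integer", repMeanPhi = "numeric",
                   repSdB = "numeric", estimate = "numeric",
                   ciLow = "numeric", ciHigh = "numeric",
                   pearsonR = "numeric", degenerate = "logical"))

setValidity("BootstrapResult", function(object) {
    if (length(object@repMeanPhi) != object@nReps)
        return("replicate vector length differs from nReps")
    if (object@ciLow > object@estimate + 1e-12 ||
        object@ciHigh < object@estimate - 1e-12)
        return("estimate outside its confidence interval")
    TRUE
})

#' @describeIn BootstrapResult-class BCa confidence interval (low, high).
#' @param x,object A `BootstrapResult`.
#' @export
phiCI <- function(x) c(x@ciLow, x@ciHigh)

#' @describeIn BootstrapResult-class Point estimate of mean phi.
#' @export
phiEstimate <- function(x) x@estimate

setMethod("show", "BootstrapResult", function(object) {
    cat(sprintf("BootstrapResult: mean phi = %.3f, 95%% BCa CI [%.3f, %.3f] (%d reps)\n",
                object@estimate, object@ciLow, object@ciHigh, object@nReps))
    cat(sprintf("  cor(replicate mean phi, replicate sd B) = %.3f\n",
                object@pearsonR))
    if (object@degenerate) cat("  NOTE: degenerate (all phi identical)\n")
})

#' Clones of one sample with diversity summaries
#'
#' The informative barcodes of one sample that pass the VAF cutoff, with
#' their allele fractions and diversity statistics (Shannon entropy on
#' natural logs, its exponential as effective clone number, and the inverse
#' Simpson index). Built by [cloneSet()].
#'
#' @aliases CloneSet
#' @exportClass CloneSet
setClass("CloneSet",
    representation(sampleId = "character", clones = "data.frame",
                   cutoff = "numeric", shannonH = "numeric",
                   invSimpson = "numeric", effectiveNumber = "numeric"))

setValidity("CloneSet", function(object) {
    if (nrow(object@clones) &&
        !all(c("variant", "vaf") %in% colnames(object@clones)))
        return("clones must have 'variant' and 'vaf' columns")
    if (nrow(object@clones) && any(object@clones$vaf <= object@cutoff))
        return("clone VAF at or below the cutoff")
    TRUE
})

#' @describeIn CloneSet-class Number of clones above the cutoff.
#' @param x,object A `CloneSet`.
#' @export
nClones <- function(x) nrow(x@clones)

#' @describeIn CloneSet-class Clone table (variant, vaf), VAF-descending.
#' @export
cloneTable <- function(x) x@clones

#' @describeIn CloneSet-class Shannon entropy H' (nats) of the renormalised
#'   clone distribution.
#' @export
shannonH <- function(x) x@shannonH

#' @describeIn CloneSet-class Inverse Simpson index of the renormalised
#'   clone distribution.
#' @export
invSimpson <- function(x) x@invSimpson

setMethod("show", "CloneSet", function(object) {
    cat(sprintf("CloneSet %s: %d clones (VAF > %g), H' = %.3f, 2D = %.3f\n",
                object@sampleId, nrow(object@clones), object@cutoff,
                object@shannonH, object@invSimpson))
})
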
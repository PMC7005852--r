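# Cross-sample variant sharing: the sharing coefficient and Sharing Factor,
# common-variant flagging at threshold theta_V, reduced per-sample tables,
# the fraction of informative reads phi, the theta_V sweep with Z-score
# product selection, and QC warnings.

# QC thresholds: chosen to separate interpretable experiments (post-selection
# mean S around 0.002-0.008, mean phi 0.75-0.92) from failed ones (S 0.012 or
# 0.51, phi 0.55 or 0.01).
S_WARN <- 0.01
PHI_WARN <- 0.6

#' Per-variant sharing coefficient
#'
#' For one variant observed with `v1` reads in one sample and `v2` in
#' another, s = 2 * min(v1, v2) / (v1 + v2). s = 0 when the variant is
#' unique to one sample of the pair and s = 1 when v1 = v2.
#'
#' @param v1,v2 Non-negative read counts, not both zero.
#' @return The sharing coefficient in `[0, 1]`.
#' @examples
#' sharingCoefficient(20225, 4073)
#' @export
sharingCoefficient <- function(v1, v2) {
    stopifnot(v1 >= 0, v2 >= 0)
    if (v1 + v2 == 0) stop("variant absent from both samples")
    2 * min(v1, v2) / (v1 + v2)
}

#' Sharing Factor for a pair of samples
#'
#' The pooled sharing statistic for two per-sample count tables: over the
#' union of their variant names (absent = 0 reads),
#' S = 2 * sum_i min(b_i1, b_i2) / sum_i (b_i1 + b_i2).
#' S = 0 for disjoint variant sets, S = 1 for identical tables, and S can be
#' read as the proportion of the pair's reads attributable to shared
#' variants.
#'
#' @param c1,c2 Named non-negative count vectors (names = variant names).
#' @return The Sharing Factor in `[0, 1]`.
#' @examples
#' sharingFactor(c(A = 10, B = 30), c(A = 10, C = 50))
#' @export
sharingFactor <- function(c1, c2) {
    tot <- sum(c1) + sum(c2)
    if (tot == 0) stop("both tables empty")
    vars <- union(names(c1), names(c2))
    b1 <- b2 <- setNames(numeric(length(vars)), vars)
    b1[names(c1)] <- c1
    b2[names(c2)] <- c2
    2 * sum(pmin(b1, b2)) / tot
}

#' Flag common variants at a threshold
#'
#' A variant whose proportional abundance strictly exceeds `thetaV` in more
#' than one sample is labelled a common variant: it recurs across animals
#' that share no cell lineage, so it is a stereotypical repair outcome, not
#' a clade-specific barcode. The unedited allele is handled separately and
#' never listed here.
#'
#' @param be A [BarcodeExperiment-class] (unreduced).
#' @param thetaV Threshold in (0, 1].
#' @return Character vector of flagged variant names (possibly empty).
#' @export
flagCommonVariants <- function(be, thetaV) {
    stopifnot(thetaV > 0, thetaV <= 1)
    P <- variantProportions(be)
    n <- rowSums(P > thetaV)
    nm <- rownames(P)[n >= 2L]
    setdiff(nm, UNEDITED)
}

#' Reduce a count table at a threshold
#'
#' Builds the reduced per-sample tables C': the unedited allele and an
#' aggregated `common variant sum` row (total reads in variants flagged by
#' [flagCommonVariants()]), followed by every remaining (informative)
#' variant. Read totals per sample are conserved.
#'
#' @param be A [BarcodeExperiment-class].
#' @param thetaV Threshold used for flagging.
#' @param common Optional pre-computed common-variant names (defaults to
#'   `flagCommonVariants(be, thetaV)`).
#' @return A reduced [BarcodeExperiment-class] with `theta_v` and
#'   `common_variants` in its metadata.
#' @export
reduceCounts <- function(be, thetaV, common = NULL) {
    if (is.null(common)) common <- flagCommonVariants(be, thetaV)
    cts <- variantCounts(be)
    uned <- if (UNEDITED %in% rownames(cts)) cts[UNEDITED, , drop = TRUE]
            else setNames(numeric(ncol(cts)), colnames(cts))
    csum <- if (length(common))
                colSums(cts[rownames(cts) %in% common, , drop = FALSE])
            else setNames(numeric(ncol(cts)), colnames(cts))
    rest <- cts[!(rownames(cts) %in% c(UNEDITED, common)), , drop = FALSE]
    red <- rbind(matrix(c(uned, csum), nrow = 2, byrow = TRUE,
                        dimnames = list(c(UNEDITED, COMMON_SUM),
                                        colnames(cts))),
                 rest)
    out <- BarcodeExperiment(red)
    S4Vectors::metadata(out)$theta_v <- thetaV
    S4Vectors::metadata(out)$common_variants <- common
    out
}

#' Fraction of informative reads
#'
#' phi = (aligned - unedited - common-variant sum) / aligned, per sample of
#' a reduced table.
#'
#' @param reduced A reduced [BarcodeExperiment-class] from [reduceCounts()].
#' @return Named numeric vector of phi per sample.
#' @export
informativeFraction <- function(reduced) {
    cts <- variantCounts(reduced)
    stopifnot(all(c(UNEDITED, COMMON_SUM) %in% rownames(cts)))
    tot <- colSums(cts)
    if (any(tot == 0)) stop("sample with zero aligned reads")
    (tot - cts[UNEDITED, ] - cts[COMMON_SUM, ]) / tot
}

# counts restricted to informative rows of a reduced table
.informativeCounts <- function(reduced) {
    cts <- variantCounts(reduced)
    cts[!(rownames(cts) %in% c(UNEDITED, COMMON_SUM)), , drop = FALSE]
}

#' Pairwise Sharing Factor matrix
#'
#' Sharing Factor for every unordered pair of samples of a count matrix.
#'
#' @param cts Count matrix (variants x samples).
#' @return Symmetric matrix of S values (diagonal 1 where a sample has
#'   reads).
#' @export
pairwiseSharing <- function(cts) {
    n <- ncol(cts)
    S <- matrix(NA_real_, n, n, dimnames = list(colnames(cts), colnames(cts)))
    tot <- colSums(cts)
    for (i in seq_len(n)) {
        for (j in i:n) {
            d <- tot[i] + tot[j]
            S[i, j] <- S[j, i] <-
                if (d == 0) 0 else 2 * sum(pmin(cts[, i], cts[, j])) / d
        }
    }
    S
}

# mean over unordered distinct pairs, excluding self-comparisons
.meanPairwiseS <- function(cts) {
    S <- pairwiseSharing(cts)
    mean(S[upper.tri(S)])
}

#' Sweep the common-variant threshold and select theta_V
#'
#' For each threshold of the grid, flags common variants, builds reduced
#' tables, and records the mean pairwise Sharing Factor and the mean
#' fraction of informative reads phi. The Sharing Factor driving selection
#' is computed over informative rows only (common-variant and unedited reads
#' are the ones being discarded); the all-row statistic is recorded
#' alongside. Mean phi and 1 - mean S are Z-standardised across the grid
#' ((x - mean) / sd) and the threshold maximising the element-wise product
#' of the two Z-score vectors is selected. A selected threshold equal to the
#' largest non-trivial grid value indicates that sharing is dominated by one
#' or a few high-frequency alleles and raises a warning.
#'
#' @param be A [BarcodeExperiment-class] with at least two samples.
#' @param thetaValues Threshold grid (default [thetaSweepDefault()]).
#' @return A [SharingSweep-class].
#' @export
sweepTheta <- function(be, thetaValues = thetaSweepDefault()) {
    stopifnot(ncol(be) >= 2L, length(thetaValues) >= 2L)
    thetaValues <- sort(thetaValues)
    meanS <- meanSAll <- meanPhi <- numeric(length(thetaValues))
    commonPer <- vector("list", length(thetaValues))
    for (k in seq_along(thetaValues)) {
        red <- reduceCounts(be, thetaValues[k])
        commonPer[[k]] <- S4Vectors::metadata(red)$common_variants
        meanS[k] <- .meanPairwiseS(.informativeCounts(red))
        meanSAll[k] <- .meanPairwiseS(variantCounts(red))
        meanPhi[k] <- mean(informativeFraction(red))
    }
    warnings <- character(0)
    zs <- function(x) (x - mean(x)) / sd(x)
    if (sd(meanPhi) == 0 || sd(1 - meanS) == 0) {
        warnings <- c(warnings,
            "degenerate sweep: all thresholds equivalent; using raw product")
        zPhi <- meanPhi
        zOneMinusS <- 1 - meanS
    } else {
        zPhi <- zs(meanPhi)
        zOneMinusS <- zs(1 - meanS)
    }
    zProduct <- zPhi * zOneMinusS
    sel <- which.max(zProduct)
    nonTrivial <- thetaValues[thetaValues < max(thetaValues)]
    if (length(nonTrivial) && thetaValues[sel] == max(nonTrivial))
        warnings <- c(warnings, sprintf(
            paste0("selected theta_V = %g is the largest non-trivial ",
                   "threshold: sharing is likely driven by one or a few ",
                   "dominant alleles"), thetaValues[sel]))
    new("SharingSweep", thetaValues = thetaValues, meanS = meanS,
        meanSAll = meanSAll, meanPhi = meanPhi, zPhi = zPhi,
        zOneMinusS = zOneMinusS, zProduct = zProduct,
        selectedTheta = thetaValues[sel],
        commonVariants = as.character(commonPer[[sel]]),
        warnings = warnings)
}

#' QC warnings for a completed analysis
#'
#' Combines the sweep-time warnings with checks on the post-selection
#' statistics: a mean Sharing Factor above `sWarn` (default 0.01) or a mean
#' phi below `phiWarn` (default 0.6) among the selected samples marks the
#' experiment as poorly barcoded or dominated by shared alleles.
#'
#' @param sweep A [SharingSweep-class].
#' @param postS Post-selection mean Sharing Factor.
#' @param postPhi Post-selection mean phi.
#' @param sWarn,phiWarn Warning thresholds.
#' @return Character vector of warnings (possibly empty).
#' @export
qcWarnings <- function(sweep, postS, postPhi, sWarn = S_WARN,
                       phiWarn = PHI_WARN) {
    w <- sweepWarnings(sweep)
    if (postS > sWarn)
        w <- c(w, sprintf(
            "post-selection mean Sharing Factor %.4g exceeds %.3g: barcodes are extensively shared across samples",
            postS, sWarn))
    if (postPhi < phiWarn)
        w <- c(w, sprintf(
            "post-selection mean phi %.3g below %.3g: few informative reads remain",
            postPhi, phiWarn))
    w
}
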
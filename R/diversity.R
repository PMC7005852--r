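# Clone enumeration and diversity statistics on informative barcodes, plus
# the group-level normality/t-test comparison.

#' Count clones above a VAF cutoff
#'
#' Number of informative variants whose allele fraction (against total
#' aligned reads of the sample) strictly exceeds the cutoff. A flat
#' VAF > 0.02 cutoff is the conventional definition of a detectable HSC
#' clone.
#'
#' @param reduced A reduced [BarcodeExperiment-class] from [reduceCounts()].
#' @param vafCutoff VAF cutoff (default 0.02).
#' @return Named integer vector of clone counts per sample.
#' @export
countClones <- function(reduced, vafCutoff = 0.02) {
    inf <- .informativeCounts(reduced)
    tot <- colSums(variantCounts(reduced))
    vaf <- sweep(inf, 2L, tot, "/")
    colSums(vaf > vafCutoff)
}

#' Shannon entropy of a clone distribution
#'
#' H' = -sum(p_i * ln(p_i)) over the included barcodes; proportions are
#' renormalised to sum to 1. The effective clone number is exp(H').
#'
#' @param proportions Positive proportions (renormalised internally).
#' @return H' in nats.
#' @examples
#' shannonEntropy(rep(0.1, 10))  # ln(10)
#' @export
shannonEntropy <- function(proportions) {
    if (length(proportions) == 0L) stop("empty proportion vector")
    stopifnot(all(proportions > 0))
    p <- proportions / sum(proportions)
    -sum(p * log(p))
}

#' Inverse Simpson diversity index
#'
#' 2D = 1 / sum(p_i^2) over the included barcodes (renormalised).
#'
#' @inheritParams shannonEntropy
#' @return The inverse Simpson index (1 for a single clone, R for a uniform
#'   distribution over R clones).
#' @export
inverseSimpson <- function(proportions) {
    if (length(proportions) == 0L) stop("empty proportion vector")
    stopifnot(all(proportions > 0))
    p <- proportions / sum(proportions)
    1 / sum(p^2)
}

#' Build the CloneSet of one sample
#'
#' Collects the informative barcodes of one sample above the VAF cutoff and
#' computes diversity summaries. By default diversity is computed on the
#' clone proportions renormalised over the retained clones; with
#' `renormalize = FALSE` the raw VAFs (against all aligned reads) are used
#' instead.
#'
#' @param reduced A reduced [BarcodeExperiment-class].
#' @param sampleId Which sample (column name).
#' @param vafCutoff VAF cutoff (default 0.02).
#' @param renormalize Renormalise over retained clones before Eq.-style
#'   diversity (default TRUE).
#' @return A [CloneSet-class]; with zero clones the diversity statistics are
#'   `NA`.
#' @export
cloneSet <- function(reduced, sampleId, vafCutoff = 0.02,
                     renormalize = TRUE) {
    inf <- .informativeCounts(reduced)
    stopifnot(sampleId %in% colnames(inf))
    tot <- sum(variantCounts(reduced)[, sampleId])
    vaf <- inf[, sampleId] / tot
    keep <- vaf > vafCutoff
    cl <- data.frame(variant = rownames(inf)[keep], vaf = unname(vaf[keep]),
                     stringsAsFactors = FALSE)
    cl <- cl[order(-cl$vaf), , drop = FALSE]
    rownames(cl) <- NULL
    if (nrow(cl)) {
        if (renormalize) {
            H <- shannonEntropy(cl$vaf)       # renormalises internally
            D2 <- inverseSimpson(cl$vaf)
        } else {
            H <- -sum(cl$vaf * log(cl$vaf))   # raw VAF weights
            D2 <- 1 / sum(cl$vaf^2)
        }
    } else {
        H <- NA_real_; D2 <- NA_real_
    }
    new("CloneSet", sampleId = sampleId, clones = cl, cutoff = vafCutoff,
        shannonH = H, invSimpson = D2,
        effectiveNumber = if (is.na(H)) NA_real_ else exp(H))
}

#' Compare clone counts between two groups
#'
#' Tests each group for normality (Shapiro-Wilk), then compares the group
#' means with a two-tailed two-sample t-test. The classical pooled-variance
#' (Student) form is the default; `welch = TRUE` drops the equal-variance
#' assumption. Zero-variance input to Shapiro-Wilk yields `NA` with a
#' warning.
#'
#' @param groupA,groupB Clone counts (each length >= 3).
#' @param welch Use the Welch t-test instead of pooled variance.
#' @return A list with `shapiro_p_a`, `shapiro_p_b`, `t_p`, and
#'   `mean_a`/`sd_a`/`mean_b`/`sd_b`.
#' @export
groupCompare <- function(groupA, groupB, welch = FALSE) {
    stopifnot(length(groupA) >= 3L, length(groupB) >= 3L)
    if (sd(groupA) == 0 && sd(groupB) == 0)
        stop("zero variance in both groups: t statistic undefined")
    swp <- function(x) {
        if (sd(x) == 0) {
            warning("zero-variance group: Shapiro-Wilk undefined")
            return(NA_real_)
        }
        shapiro.test(x)$p.value
    }
    tt <- t.test(groupA, groupB, var.equal = !welch)
    list(shapiro_p_a = swp(groupA), shapiro_p_b = swp(groupB),
         t_p = tt$p.value,
         mean_a = mean(groupA), sd_a = sd(groupA),
         mean_b = mean(groupB), sd_b = sd(groupB))
}
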
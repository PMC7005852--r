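# Bootstrap-based sample selection: paired resampling of (phi, B_0.02),
# BCa confidence interval for mean phi, classification against the lower CI
# bound, and the distributional comparison of clone counts between high- and
# low-phi samples.

# Order-statistic quantile with interpolation on the normal scale at
# positions (B+1)*alpha — the canonical convention for BCa endpoints.
.normInterQuantile <- function(reps, alpha) {
    B <- length(reps)
    st <- sort(reps)
    vapply(alpha, function(al) {
        rk <- (B + 1) * al
        k <- floor(rk)
        if (k <= 0) return(st[1])
        if (k >= B) return(st[B])
        if (rk == k) return(st[k])
        g <- (qnorm(al) - qnorm(k / (B + 1))) /
             (qnorm((k + 1) / (B + 1)) - qnorm(k / (B + 1)))
        st[k] + g * (st[k + 1] - st[k])
    }, numeric(1))
}

# BCa interval on a bootstrap replicate vector. z0 from the fraction of
# replicates below the observed statistic (standard bias correction, with
# half-weight on ties), acceleration from the jackknife skewness of the
# statistic over samples.
.bcaCI <- function(t0, reps, jackStats, conf = 0.95) {
    B <- length(reps)
    prop <- (sum(reps < t0) + 0.5 * sum(reps == t0)) / B
    if (prop <= 0 || prop >= 1)   # statistic off the replicate support
        return(.normInterQuantile(reps, c((1 - conf) / 2, (1 + conf) / 2)))
    z0 <- qnorm(prop)
    u <- mean(jackStats) - jackStats
    denom <- sum(u^2)^1.5
    a <- if (denom == 0) 0 else sum(u^3) / (6 * denom)
    zal <- qnorm(c((1 - conf) / 2, (1 + conf) / 2))
    adj <- pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
    .normInterQuantile(reps, adj)
}

#' Bootstrap mean phi and the variability of the clone count
#'
#' Resamples the sample set with replacement; each replicate records the
#' mean fraction of informative reads and the standard deviation of the
#' clone count B_0.02 over the same resampled index set (paired). The
#' confidence interval for mean phi uses the bias-corrected accelerated
#' (BCa) method with jackknife acceleration; the Pearson correlation between
#' the two replicate series quantifies whether low-phi-heavy resamples are
#' also more variable in clone count.
#'
#' @param phi Fraction of informative reads per sample (length >= 3).
#' @param b002 Clone count (barcodes with VAF > 0.02) per sample.
#' @param nReps Number of bootstrap replicates (>= 100; default 1000).
#' @param seed RNG seed (logged with the run; default 20200207).
#' @param conf Confidence level (default 0.95).
#' @return A [BootstrapResult-class].
#' @export
bootstrapPhi <- function(phi, b002, nReps = 1000L, seed = 20200207L,
                         conf = 0.95) {
    n <- length(phi)
    stopifnot(n >= 3L, length(b002) == n, nReps >= 100L)
    if (!is.null(seed)) set.seed(seed)
    idx <- matrix(sample.int(n, n * nReps, replace = TRUE), nrow = nReps)
    repPhi <- rowMeans(matrix(phi[idx], nrow = nReps))
    bmat <- matrix(b002[idx], nrow = nReps)
    repSdB <- sqrt(pmax(0, (rowSums(bmat^2) - n * rowMeans(bmat)^2) /
                           (n - 1)))
    t0 <- mean(phi)
    degenerate <- sd(phi) == 0
    if (degenerate) {
        ci <- c(t0, t0)
    } else {
        jack <- (sum(phi) - phi) / (n - 1)
        ci <- .bcaCI(t0, repPhi, jack, conf = conf)
    }
    r <- if (sd(repPhi) == 0 || sd(repSdB) == 0) NA_real_
         else cor(repPhi, repSdB)
    new("BootstrapResult", nReps = as.integer(nReps), repMeanPhi = repPhi,
        repSdB = repSdB, estimate = t0, ciLow = ci[1], ciHigh = ci[2],
        pearsonR = r, degenerate = degenerate)
}

#' Classify samples by the bootstrap lower bound
#'
#' Samples with phi at or above the lower bound of the bootstrap confidence
#' interval are classified as high-phi (informative); the rest as low-phi.
#'
#' @param phi Named numeric vector of per-sample phi.
#' @param ciLow Lower CI bound (e.g. `phiCI(boot)[1]`).
#' @return A list with `high` and `low` (named phi vectors), and the mean
#'   phi of each class.
#' @export
classifySamples <- function(phi, ciLow) {
    high <- phi[phi >= ciLow]
    low <- phi[phi < ciLow]
    list(high = high, low = low,
         mean_high = if (length(high)) mean(high) else NA_real_,
         mean_low = if (length(low)) mean(low) else NA_real_)
}

#' Compare clone-count distributions of two sample classes
#'
#' Two-sample Kolmogorov-Smirnov test of the B_0.02 distributions in high-
#' and low-phi samples. With tied (integer) clone counts the p-value is the
#' asymptotic approximation.
#'
#' @param highB,lowB Clone counts per sample in each class (each length
#'   >= 2).
#' @return A list with `D` and `p_value`.
#' @export
compareDistributions <- function(highB, lowB) {
    if (length(highB) < 2L || length(lowB) < 2L)
        stop("each class needs at least 2 samples")
    kt <- suppressWarnings(ks.test(highB, lowB))
    list(D = unname(kt$statistic), p_value = kt$p.value)
}
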
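# Sharing coefficient, Sharing Factor, common-variant flagging, reduction,
# phi, the theta_V sweep and QC warnings.

test_that("sharing coefficient obeys its boundary properties and formula", {
    expect_equal(sharingCoefficient(7, 0), 0)
    expect_equal(sharingCoefficient(13, 13), 1)
    expect_equal(sharingCoefficient(20225, 4073),
                 2 * 4073 / (20225 + 4073))
    expect_error(sharingCoefficient(0, 0), "absent from both")
    set.seed(31)
    for (k in 1:50) {
        s <- sharingCoefficient(sample.int(1000, 1), sample.int(1000, 1))
        expect_gte(s, 0); expect_lte(s, 1)
    }
})

test_that("Sharing Factor boundary cases, symmetry and hand-worked pair", {
    t1 <- c(A = 10, B = 30)
    expect_equal(sharingFactor(t1, t1), 1)
    expect_equal(sharingFactor(t1, c(X = 5, Y = 2)), 0)
    expect_equal(sharingFactor(t1, c(A = 10, C = 50)), 0.2)
    expect_equal(sharingFactor(c(A = 3, B = 9), c(B = 2, A = 11)),
                 sharingFactor(c(B = 2, A = 11), c(A = 3, B = 9)))
    expect_error(sharingFactor(setNames(numeric(0), character(0)),
                               setNames(numeric(0), character(0))),
                 "empty")
})

test_that("Sharing Factor equals the brute-force union oracle on random tables", {
    set.seed(32)
    for (k in 1:100) {
        c1 <- randTable(); c2 <- randTable()
        expect_identical(sharingFactor(c1, c2), bruteSharingFactor(c1, c2))
    }
})

test_that("common-variant flagging requires recurrence above the threshold", {
    tabs <- list(
        s1 = data.frame(variant = c("10:1I", "20:2D", uneditedName()),
                        count = c(50L, 900L, 50L)),
        s2 = data.frame(variant = c("10:1I", "30:1D"),
                        count = c(50L, 950L)),
        s3 = data.frame(variant = c("40:4D", uneditedName()),
                        count = c(600L, 400L)))
    be <- BarcodeExperiment(tabs)
    # 10:1I at VAF 0.05 in two samples
    expect_equal(flagCommonVariants(be, 0.003), "10:1I")
    # 20:2D is high-VAF in one sample only: never flagged
    expect_false("20:2D" %in% flagCommonVariants(be, 0.003))
    # nothing can exceed a threshold of 1
    expect_length(flagCommonVariants(be, 1), 0)
    # the unedited allele is never listed even when it recurs
    expect_false(uneditedName() %in% flagCommonVariants(be, 0.01))
})

test_that("reduction conserves reads and removes flagged rows", {
    be <- plantedBe(nSamples = 5, sharedProp = 0.05, seed = 33)
    red <- reduceCounts(be, 0.003)
    expect_equal(unname(colSums(variantCounts(red))),
                 unname(colSums(variantCounts(be))))
    expect_false("shared:1D" %in%
                 rownames(variantCounts(red)))
    expect_true(all(c(uneditedName(), commonSumName()) %in%
                    rownames(variantCounts(red))))
    # unedited + common sum + informative = aligned, per sample
    cts <- variantCounts(red)
    inf <- cts[!(rownames(cts) %in% c(uneditedName(), commonSumName())), ]
    expect_equal(unname(cts[uneditedName(), ] + cts[commonSumName(), ] +
                        colSums(inf)),
                 unname(colSums(cts)))
})

test_that("informative fraction follows its definition", {
    mk <- function(unedited, common, informative) {
        m <- matrix(c(unedited, common, informative), ncol = 1,
                    dimnames = list(c(uneditedName(), commonSumName(), "x:1I"),
                                    "s1"))
        be <- BarcodeExperiment(m)
        informativeFraction(be)
    }
    expect_equal(unname(mk(1000, 0, 0)), 0)
    expect_equal(unname(mk(0, 0, 1000)), 1)
    expect_equal(unname(mk(200, 100, 700)), 0.7)
})

test_that("sweep flags a planted shared variant and drives sharing to zero", {
    be <- plantedBe(nSamples = 10, total = 2000, sharedProp = 0.05,
                    seed = 34)
    sw <- sweepTheta(be)
    expect_lt(selectedTheta(sw), 0.05)
    expect_true("shared:1D" %in% commonVariants(sw))
    i <- match(selectedTheta(sw), sweepTable(sw)$theta_v)
    expect_lt(sweepTable(sw)$mean_S[i], 0.01)
    # phi is maximal when nothing is flagged
    tab <- sweepTable(sw)
    expect_true(all(tab$mean_phi[tab$theta_v == 1] >= tab$mean_phi - 1e-12))
})

test_that("an all-unique dataset has zero sharing at every threshold", {
    be <- plantedBe(nSamples = 6, sharedProp = 0, uneditedProp = 0,
                    seed = 35)
    sw <- sweepTheta(be)
    expect_equal(sweepTable(sw)$mean_S, rep(0, 8))
})

test_that("QC warnings fire on failed experiments and stay silent on good ones", {
    be <- plantedBe(nSamples = 6, sharedProp = 0.05, seed = 36)
    sw <- sweepTheta(be)
    expect_length(qcWarnings(sw, postS = 0.0024, postPhi = 0.92), 0)
    w <- qcWarnings(sw, postS = 0.51, postPhi = 0.01)
    expect_length(w, 2)
    expect_match(w[1], "Sharing Factor")
    expect_match(w[2], "phi")
    # borderline passing values from a well-run experiment
    expect_length(qcWarnings(sw, postS = 0.008, postPhi = 0.75), 0)
})

test_that("pairwise sharing matrix is symmetric with unit diagonal", {
    be <- plantedBe(nSamples = 5, sharedProp = 0.1, seed = 37)
    S <- pairwiseSharing(variantCounts(be))
    expect_equal(S, t(S))
    expect_equal(unname(diag(S)), rep(1, 5))
    expect_true(all(S >= 0 & S <= 1))
})
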
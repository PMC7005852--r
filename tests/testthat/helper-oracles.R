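# Independent oracles and small fixture builders used across the suite.

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

revcompStr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Plain-R three-state (Gotoh) global alignment score, written independently
# of the package's C++ aligner: gap of length L costs open + (L-1) * ext.
rGotohScore <- function(a, b, match = 5, mismatch = -4, open = 10,
                        ext = 0.25) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    M <- D <- I <- matrix(-Inf, n + 1, m + 1)
    M[1, 1] <- 0
    for (i in 2:(n + 1)) D[i, 1] <- -(open + (i - 2) * ext)
    for (j in 2:(m + 1)) I[1, j] <- -(open + (j - 2) * ext)
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            s <- if (A[i - 1] == B[j - 1]) match else mismatch
            M[i, j] <- s + max(M[i - 1, j - 1], D[i - 1, j - 1],
                               I[i - 1, j - 1])
            D[i, j] <- max(M[i - 1, j] - open, D[i - 1, j] - ext,
                           I[i - 1, j] - open)
            I[i, j] <- max(M[i, j - 1] - open, D[i, j - 1] - open,
                           I[i, j - 1] - ext)
        }
    }
    max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
}

# Brute-force Sharing Factor: explicit loop over the union of names.
bruteSharingFactor <- function(c1, c2) {
    vars <- union(names(c1), names(c2))
    num <- 0
    for (v in vars) {
        b1 <- if (v %in% names(c1)) c1[[v]] else 0
        b2 <- if (v %in% names(c2)) c2[[v]] else 0
        num <- num + min(b1, b2)
    }
    2 * num / (sum(c1) + sum(c2))
}

# random named count table
randTable <- function(maxVars = 12, maxCount = 100, pool = LETTERS) {
    k <- sample.int(maxVars, 1)
    nm <- sample(pool, k)
    setNames(sample.int(maxCount, k, replace = TRUE), nm)
}

# BarcodeExperiment with planted structure: each of n samples gets `unique`
# private variants plus optionally a shared variant at a given proportion.
plantedBe <- function(nSamples = 6, total = 1000, sharedProp = 0,
                      uneditedProp = 0.2, nUnique = 3, seed = 42) {
    set.seed(seed)
    tabs <- lapply(seq_len(nSamples), function(i) {
        counts <- c()
        if (uneditedProp > 0)
            counts[uneditedName()] <- round(total * uneditedProp)
        if (sharedProp > 0) counts[["shared:1D"]] <- round(total * sharedProp)
        rest <- total - sum(counts)
        per <- as.vector(stats::rmultinom(1, rest, rep(1, nUnique)))
        for (k in seq_len(nUnique))
            counts[[sprintf("s%d_u%d:1I", i, k)]] <- per[k]
        data.frame(variant = names(counts), count = as.integer(counts))
    })
    names(tabs) <- sprintf("S%02d", seq_len(nSamples))
    BarcodeExperiment(tabs)
}

# shared lazily-built fixtures for the heavier end-to-end checks
.fixtures <- new.env(parent = emptyenv())

defaultTruth <- function() {
    if (is.null(.fixtures$truth)) {
        dir <- file.path(tempdir(), "cb_default_sim")
        cfg <- simulationConfig(seed = 101L)
        .fixtures$truth <- simulateDataset(cfg, dir = dir)
    }
    .fixtures$truth
}

defaultRun <- function() {
    if (is.null(.fixtures$run)) {
        truth <- defaultTruth()
        .fixtures$run <- runPipeline(truth$sampleSheet, truth$reference,
                                     outputDir = NULL, nBoot = 1000L,
                                     seed = 5L)
    }
    .fixtures$run
}
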
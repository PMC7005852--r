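# Synthetic-data generator: config validation, truth consistency,
# reproducibility, clean-data recovery.

test_that("configuration validation rejects inconsistent fractions", {
    expect_error(simulationConfig(uneditedFraction = 1.2), "outside")
    expect_error(simulationConfig(uneditedFraction = 0.9,
                                  commonVafs = 0.2), "exceed 1")
    expect_error(simulationConfig(nSites = 20L, siteLen = 30L,
                                  windowLength = 300L), "do not fit")
    expect_error(simulationConfig(commonVafs = c(0.01, 0.01),
                                  commonInSamples = 3L), "inconsistent")
})

test_that("truth read counts equal emitted FASTQ records and seeds reproduce bytes", {
    cfg <- simulationConfig(nSamples = 2L, readsPerSample = 120L, seed = 81L)
    d1 <- file.path(tempdir(), "cb_repro_a")
    d2 <- file.path(tempdir(), "cb_repro_b")
    t1 <- simulateDataset(cfg, dir = d1)
    t2 <- simulateDataset(cfg, dir = d2)
    for (i in 1:2) {
        fq <- readLines(t1$sampleSheet$r1[i])
        expect_equal(length(fq) / 4L, t1$samples$total_reads[i])
        expect_identical(readLines(t1$sampleSheet$r1[i]),
                         readLines(t2$sampleSheet$r1[i]))
        expect_identical(readLines(t1$sampleSheet$r2[i]),
                         readLines(t2$sampleSheet$r2[i]))
    }
    # truth variant counts sum to the per-sample totals
    agg <- tapply(t1$variants$count, t1$variants$sample_id, sum)
    expect_equal(as.vector(agg[t1$samples$sample_id]),
                 t1$samples$total_reads)
})

test_that("planted alleles are left-alignment-stable so truth names match the caller", {
    cfg <- simulationConfig(nSamples = 3L, readsPerSample = 50L,
                            subErrorRate = 0, indelErrorRate = 0,
                            seed = 82L)
    truth <- simulateCounts(cfg)
    window <- as.character(refWindow(truth$reference))
    vt <- truth$variants[truth$variants$class != "unedited" &
                         truth$variants$count > 0, ]
    for (r in seq_len(nrow(vt))) {
        # rebuild the allele sequence from its name and confirm the caller
        # returns the same name
        comps <- strsplit(vt$variant[r], ",")[[1]]
        df <- do.call(rbind, lapply(comps, function(cc) {
            m <- regmatches(cc, regexec("^(\\d+):(\\d+)([ID])$", cc))[[1]]
            data.frame(pos = as.integer(m[2]), len = as.integer(m[3]),
                       kind = m[4])
        }))
        seq <- window
        for (i in order(-df$pos)) {
            if (df$kind[i] == "D")
                seq <- paste0(substr(seq, 1, df$pos[i] - 1),
                              substr(seq, df$pos[i] + df$len[i], nchar(seq)))
            else
                seq <- paste0(substr(seq, 1, df$pos[i] - 1),
                              paste(sample(c("A", "C", "G", "T"), df$len[i],
                                           replace = TRUE), collapse = ""),
                              substr(seq, df$pos[i], nchar(seq)))
        }
        # deletions are fully determined by the name; insertions are not,
        # so only check deletion-only alleles here
        if (all(df$kind == "D")) {
            v <- callVariant(nwAlign(seq, window)$cigar, seq, window)
            expect_equal(v$name, vt$variant[r])
        }
    }
})

test_that("clean fixed-VAF clones are recovered exactly end to end", {
    cfg <- simulationConfig(nSamples = 3L, readsPerSample = 200L,
                            cloneVafs = c(0.5, 0.3, 0.2),
                            uneditedFraction = 0, commonVafs = numeric(0),
                            subErrorRate = 0, indelErrorRate = 0,
                            seed = 83L)
    dir <- file.path(tempdir(), "cb_clean3")
    truth <- simulateDataset(cfg, dir = dir)
    run <- runPipeline(truth$sampleSheet, truth$reference, nBoot = 100L)
    expect_equal(unname(run$phi), rep(1, 3))
    expect_equal(unname(run$b002[truth$samples$sample_id]), rep(3L, 3))
    # exactly 3 variants per sample, matching truth names
    cts <- variantCounts(run$be)
    for (i in 1:3) {
        sid <- truth$samples$sample_id[i]
        called <- rownames(cts)[cts[, sid] > 0]
        tv <- truth$variants[truth$variants$sample_id == sid &
                             truth$variants$count > 0, ]
        expect_setequal(called, tv$variant)
    }
})

test_that("fully unedited input yields phi of zero", {
    cfg <- simulationConfig(nSamples = 2L, readsPerSample = 80L,
                            uneditedFraction = 1, commonVafs = numeric(0),
                            subErrorRate = 0, indelErrorRate = 0,
                            seed = 84L)
    truth <- simulateCounts(cfg)
    red <- reduceCounts(truth$be, 0.003)
    expect_equal(unname(informativeFraction(red)), c(0, 0))
})
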
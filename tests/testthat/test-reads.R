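# Read preprocessing: merging, trimming, primer filtering.

q <- function(qchars) paste(qchars, collapse = "")

test_that("exact-overlap pairs merge to the spanned amplicon", {
    # amplicon of 30 nt, mates of 20 nt overlapping by 10
    set.seed(11)
    amp <- randDna(30)
    r1 <- substr(amp, 1, 20)
    r2 <- revcompStr(substr(amp, 11, 30))
    m <- mergePairs(r1, strrep("I", 20), r2, strrep("I", 20))
    expect_equal(m$seq, amp)
    expect_equal(m$overlap_len, 10L)

    # no overlap of at least minOverlap exists
    m2 <- mergePairs(randDna(20), strrep("I", 20),
                     randDna(20), strrep("I", 20), minOverlap = 15L)
    expect_equal(m2$n_merged, 0L)
    expect_length(m2$seq, 0)

    expect_error(mergePairs("", "", "ACGT", "IIII"), "empty read")
})

test_that("mismatched overlap bases resolve to the higher quality and the chosen overlap maximises score", {
    set.seed(12)
    amp <- randDna(40)
    r1 <- substr(amp, 1, 25)
    over <- substr(amp, 16, 40)
    # plant a mismatch at amplicon position 20 (overlap position 5) on mate 2
    bad <- over
    orig <- substr(amp, 20, 20)
    alt <- setdiff(c("A", "C", "G", "T"), orig)[1]
    substr(bad, 5, 5) <- alt
    r2 <- revcompStr(bad)
    q1 <- strrep("I", 25)                      # Q40 everywhere on mate 1
    q2chars <- rep("I", 25); q2chars[5] <- "+" # Q10 at the mismatch
    q2 <- paste(rev(q2chars), collapse = "")   # mate-2 qualities as sequenced
    m <- mergePairs(r1, q1, r2, q2)
    expect_equal(m$seq, amp)                   # qual-40 base won
    # swap qualities: now mate 2's base must win
    q1chars <- rep("I", 25); q1chars[20] <- "+"
    m2 <- mergePairs(r1, paste(q1chars, collapse = ""), r2, strrep("I", 25))
    expected <- amp
    substr(expected, 20, 20) <- alt
    expect_equal(m2$seq, expected)

    # planted unique best overlap: brute-force enumeration confirms the
    # merger picks the maximum-score offset
    for (k in 1:20) {
        A <- randDna(12); M <- randDna(12); B <- randDna(12)
        r1 <- paste0(A, M)
        r2 <- revcompStr(paste0(M, B))
        mm <- mergePairs(r1, strrep("I", 24), r2, strrep("I", 24),
                         minOverlap = 6L, maxMismatchFrac = 0.1)
        s2 <- paste0(M, B)
        best <- -Inf; bestO <- NA
        for (o in -(24 - 6):(24 - 6)) {
            lo <- max(0, o); hi <- min(24, o + 24)
            if (hi - lo < 6) next
            x <- strsplit(substr(r1, lo + 1, hi), "")[[1]]
            y <- strsplit(substr(s2, lo - o + 1, hi - o), "")[[1]]
            mis <- sum(x != y)
            sc <- sum(x == y) - mis
            if (mis / (hi - lo) <= 0.1 && sc > best) { best <- sc; bestO <- o }
        }
        if (is.na(bestO) || best < 12) next  # planted overlap not unique max
        expect_equal(mm$n_merged, 1L)
        expect_equal(mm$overlap_len, min(24, bestO + 24) - max(0, bestO))
        if (bestO == 12) expect_equal(mm$seq, paste0(A, M, B))
    }
})

test_that("merging is symmetric under mate swap with reverse-complement", {
    set.seed(13)
    for (k in 1:10) {
        amp <- randDna(35)
        r1 <- substr(amp, 1, 22); r2 <- revcompStr(substr(amp, 10, 35))
        # plant a disagreement with unequal qualities so resolution is
        # orientation-independent
        bad <- r1
        orig <- substr(bad, 15, 15)
        substr(bad, 15, 15) <- setdiff(c("A", "C", "G", "T"), orig)[1]
        q1chars <- rep("I", 22); q1chars[15] <- "#"
        q1 <- paste(q1chars, collapse = ""); q2 <- strrep("I", 26)
        a <- mergePairs(bad, q1, r2, q2)
        b <- mergePairs(r2, q2, bad, q1)
        expect_equal(a$seq, revcompStr(b$seq))
        expect_equal(a$overlap_len, b$overlap_len)
    }
})

test_that("sliding-window trimming truncates at the first failing window", {
    # untouched high-quality read
    r <- list(id = "a", seq = randDna(150), qual = strrep("I", 150))
    t1 <- trimSlidingWindow(r, 4L, 15, 100L)
    expect_equal(nchar(t1$seq), 150L)

    # abrupt collapse to Q2 from position 91: the first failing window
    # starts at 90 (it holds three Q2 bases), so 89 nt remain - below MINLEN
    qual <- paste0(strrep("I", 90), strrep("#", 60))
    t2 <- trimSlidingWindow(list(id = "b", seq = randDna(150), qual = qual),
                            4L, 15, 100L)
    expect_equal(t2$n_kept, 0L)
    t3 <- trimSlidingWindow(list(id = "b", seq = randDna(150), qual = qual),
                            4L, 15, 50L)
    expect_equal(nchar(t3$seq), 89L)
    # gentler drop to Q12: windows stay above the mean threshold until the
    # window starting at 91 is all-Q12, leaving 90 nt
    qual2 <- paste0(strrep("I", 90), strrep("-", 60))
    t3b <- trimSlidingWindow(list(id = "b2", seq = randDna(150),
                                  qual = qual2), 4L, 15, 50L)
    expect_equal(nchar(t3b$seq), 90L)

    # full-length high-quality read below the minimum length is dropped
    t4 <- trimSlidingWindow(list(id = "c", seq = randDna(99),
                                 qual = strrep("I", 99)), 4L, 15, 100L)
    expect_equal(t4$n_kept, 0L)
})

test_that("trimming agrees with a brute-force window scan and never lengthens", {
    set.seed(14)
    for (k in 1:25) {
        L <- sample(20:80, 1)
        qv <- sample(2:40, L, replace = TRUE)
        r <- list(id = "x", seq = randDna(L), qual = intToUtf8(qv + 33L))
        t <- trimSlidingWindow(r, 4L, 15, 1L)
        cut <- L
        for (s in 1:(L - 3)) {
            if (mean(qv[s:(s + 3)]) < 15) { cut <- s - 1L; break }
        }
        if (cut == 0L) expect_equal(t$n_kept, 0L)
        else expect_equal(nchar(t$seq), cut)
        if (t$n_kept > 0) expect_lte(nchar(t$seq), L)
    }
})

test_that("primer filtering keeps exactly-one-primer-pair reads and normalises orientation", {
    set.seed(15)
    fwdP <- randDna(20); revEnd <- randDna(20)
    ref <- AmpliconReference(paste0(fwdP, randDna(60), revEnd),
                             fwdPrimer = fwdP,
                             revPrimer = revcompStr(revEnd))
    fwd <- as.character(fwdPrimer(ref))
    rcRev <- revcompStr(as.character(revPrimer(ref)))
    insert <- randDna(50)
    mk <- function(s) list(id = "r", seq = s, qual = strrep("I", nchar(s)))

    good <- paste0(fwd, insert, rcRev)
    expect_equal(filterPrimers(mk(good), ref)$seq, insert)

    # reverse-complemented read is flipped and recovered
    expect_equal(filterPrimers(mk(revcompStr(good)), ref)$seq, insert)

    # absent forward primer
    expect_equal(filterPrimers(mk(paste0(randDna(20), insert, rcRev)),
                               ref)$n_kept, 0L)
    # duplicated forward primer
    expect_equal(filterPrimers(mk(paste0(fwd, fwd, insert, rcRev)),
                               ref)$n_kept, 0L)
    # one edit in the primer is tolerated (within 10% of 20 nt)
    mut <- good
    substr(mut, 3, 3) <- chartr("ACGT", "TTAC", substr(good, 3, 3))
    expect_equal(filterPrimers(mk(mut), ref)$n_kept, 1L)
    # three edits are not
    mut3 <- good
    substr(mut3, 2, 4) <- chartr("ACGT", "GTAC", substr(good, 2, 4))
    expect_equal(filterPrimers(mk(mut3), ref)$n_kept, 0L)

    # output never contains either primer within tolerance
    out <- filterPrimers(mk(good), ref)
    hits <- Biostrings::countPattern(fwd, Biostrings::DNAString(out$seq),
                                     max.mismatch = 2)
    expect_equal(hits, 0)
})

test_that("error-free synthetic reads traverse the whole preprocessing chain intact", {
    cfg <- simulationConfig(nSamples = 2L, readsPerSample = 150L,
                            subErrorRate = 0, indelErrorRate = 0,
                            seed = 99L)
    dir <- file.path(tempdir(), "cb_clean_sim")
    truth <- simulateDataset(cfg, dir = dir)
    window <- as.character(refWindow(truth$reference))
    for (i in 1:2) {
        pre <- preprocessSample(truth$sampleSheet$r1[i],
                                truth$sampleSheet$r2[i], truth$reference)
        expect_equal(pre$fates$surviving, pre$fates$total)  # 100% survive
        vt <- truth$variants[truth$variants$sample_id ==
                             truth$sampleSheet$sample_id[i], ]
        vt <- vt[vt$count > 0, ]
        # without sequencing error the surviving inserts are exactly the
        # true allele sequences, with the true multiplicities
        expect_equal(length(unique(pre$seq)), nrow(vt))
        expect_equal(sort(as.integer(table(pre$seq))), sort(vt$count))
        # unedited reads equal the reference window exactly
        expect_equal(sum(pre$seq == window),
                     vt$count[vt$variant == uneditedName()])
    }
})
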
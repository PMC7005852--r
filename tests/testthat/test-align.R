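# Global alignment and variant naming.

test_that("alignment handles identity, deletions and rejects empty input", {
    set.seed(21)
    s <- randDna(20)
    a <- nwAlign(s, s)
    expect_equal(a$cigar, "20M")
    expect_equal(a$score, 20 * 5)

    ref <- randDna(30)
    read <- paste0(substr(ref, 1, 12), substr(ref, 16, 30))  # 3-nt deletion
    cig <- parseCigar(nwAlign(read, ref)$cigar)
    expect_equal(sum(cig$op == "D"), 1L)
    expect_equal(cig$len[cig$op == "D"], 3L)

    expect_error(nwAlign("", "ACGT"), "empty")
})

test_that("alignment score equals an independent Gotoh oracle on random pairs", {
    set.seed(22)
    for (k in 1:200) {
        a <- randDna(sample.int(12, 1))
        b <- randDna(sample.int(12, 1))
        expect_equal(nwAlign(a, b)$score, rGotohScore(b, a), tolerance = 1e-12)
    }
})

test_that("alignment score matches pairwiseAlignment under the equivalent gap parameterisation", {
    skip_if_not_installed("Biostrings")
    set.seed(23)
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = TRUE)
    for (k in 1:25) {
        a <- randDna(sample(5:30, 1)); b <- randDna(sample(5:30, 1))
        # gap of L costs open + (L-1)*ext here; gapOpening + L*gapExtension
        # there, so shift the opening by one extension
        s <- Biostrings::score(Biostrings::pairwiseAlignment(
            a, b, type = "global", substitutionMatrix = sub,
            gapOpening = 9.75, gapExtension = 0.25))
        expect_equal(nwAlign(a, b)$score, s, tolerance = 1e-9)
    }
})

test_that("variant naming reproduces the positional convention", {
    set.seed(24)
    window <- randDna(260)
    # 1-bp insertion before reference base 125, stable under left-shift
    ins <- setdiff(c("A", "C", "G", "T"), substr(window, 124, 124))[1]
    read <- paste0(substr(window, 1, 124), ins, substr(window, 125, 260))
    aln <- nwAlign(read, window)
    v <- callVariant(aln$cigar, read, window)
    expect_equal(v$name, "125:1I")
    expect_false(v$is_unedited)

    # 108-bp deletion at position 122
    window2 <- randDna(260)
    while (substr(window2, 121, 121) == substr(window2, 229, 229))
        window2 <- randDna(260)
    read2 <- paste0(substr(window2, 1, 121), substr(window2, 230, 260))
    v2 <- callVariant(nwAlign(read2, window2)$cigar, read2, window2)
    expect_equal(v2$name, "122:108D")

    # substitutions only collapse into the unedited allele
    read3 <- window
    substr(read3, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                     substr(window, 50, 50))[1]
    v3 <- callVariant(nwAlign(read3, window)$cigar, read3, window)
    expect_equal(v3$name, uneditedName())
    expect_true(v3$is_unedited)
})

test_that("indels in homopolymers are left-aligned and multi-component names sort by position", {
    # reference with an AAAA run at positions 11-14: any single-A deletion
    # in the run must be reported at position 11
    ref <- paste0("GTCGTCGTCG", "AAAA", "CGTCGTCGTC")
    for (del in 11:14) {
        read <- paste0(substr(ref, 1, del - 1), substr(ref, del + 1, 24))
        v <- callVariant(nwAlign(read, ref)$cigar, read, ref)
        expect_equal(v$name, "11:1D")
    }
    # insertion of A adjacent to the run left-aligns to position 11
    readI <- paste0(substr(ref, 1, 14), "A", substr(ref, 15, 24))
    vI <- callVariant(nwAlign(readI, ref)$cigar, readI, ref)
    expect_equal(vI$name, "11:1I")

    # two components, ascending positions, comma-joined
    set.seed(25)
    w <- randDna(120)
    while (substr(w, 29, 29) == substr(w, 32, 32)) w <- randDna(120)
    ins <- setdiff(c("A", "C", "G", "T"), substr(w, 79, 79))[1]
    read <- paste0(substr(w, 1, 29), substr(w, 33, 79), ins,
                   substr(w, 80, 120))
    v <- callVariant(nwAlign(read, w)$cigar, read, w)
    expect_equal(v$name, "30:3D,80:1I")
    expect_equal(v$components$pos, c(30L, 80L))
})

test_that("reads differing only by substitutions map to the same variant", {
    set.seed(26)
    window <- randDna(200)
    base <- paste0(substr(window, 1, 99), substr(window, 105, 200)) # 100:5D
    v0 <- callVariant(nwAlign(base, window)$cigar, base, window)
    for (k in 1:5) {
        mut <- base
        p <- sample(nchar(base), 1)
        substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(base, p, p))[1]
        v <- callVariant(nwAlign(mut, window)$cigar, mut, window)
        expect_equal(v$name, v0$name)
    }
})

test_that("tabulation counts, normalises and rejects empty input", {
    t <- tabulateSample(c("125:1I", "125:1I", "125:1I", uneditedName()))
    expect_equal(t$count[t$variant == "125:1I"], 3L)
    expect_equal(t$proportion[t$variant == "125:1I"], 0.75)
    expect_equal(sum(t$proportion), 1)
    expect_error(tabulateSample(character(0)), "no aligned reads")

    set.seed(27)
    v <- sample(c("1:1I", "5:2D", uneditedName()), 57, replace = TRUE)
    expect_equal(sum(tabulateSample(v)$proportion), 1)
})

test_that("the alignment score floor excludes unrelated sequences", {
    set.seed(28)
    window <- randDna(150)
    while (substr(window, 70, 70) == substr(window, 73, 73))
        window <- randDna(150)   # keep the planted deletion left-stable
    good <- paste0(substr(window, 1, 70), substr(window, 74, 150))
    junk <- randDna(150)
    res <- alignSample(c(good, junk, window), window)
    expect_equal(res$aligned, c(TRUE, FALSE, TRUE))
    expect_equal(res$variant, c("71:3D", uneditedName()))
})
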
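# Read preprocessing: paired-end merging, sliding-window quality trimming and
# primer-based filtering. These are bespoke re-implementations of the standard
# merge/trim/demultiplex stages so that the whole pipeline is self-contained
# and deterministic. Reads travel as plain character vectors of bases plus
# Phred+33 quality strings; FASTQ I/O goes through Biostrings.

phredToInt <- function(qual) {
    lapply(strsplit(qual, ""), function(ch) utf8ToInt(paste(ch, collapse = "")) - 33L)
}

intToPhred <- function(q) {
    vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

#' Read a FASTQ file into sequences and quality strings
#'
#' @param path FASTQ file (gzip-transparent).
#' @return A list with character vectors `id`, `seq` and `qual` (Phred+33).
#' @export
readFastq <- function(path) {
    # this Biostrings version warns about dropping its own internal mcols
    x <- withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path,
            quality.scoring = "phred"),
        warning = function(w) {
            if (grepl("metadata columns on input", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    list(id = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
}

#' Write sequences and qualities to FASTQ
#'
#' @param x A list with `id`, `seq`, `qual` as returned by [readFastq()].
#' @param path Output FASTQ path (".gz" suffix compresses).
#' @export
writeFastq <- function(x, path) {
    sset <- Biostrings::DNAStringSet(x$seq)
    qset <- Biostrings::PhredQuality(x$qual)
    names(sset) <- x$id
    names(qset) <- x$id
    qs <- Biostrings::QualityScaledDNAStringSet(sset, qset)
    Biostrings::writeQualityScaledXStringSet(qs, path,
        compress = grepl("\\.gz$", path))
}

#' Merge paired-end reads by maximum-score ungapped overlap
#'
#' Mate 2 is reverse-complemented and slid along mate 1; the overlap scoring
#' +1 per match and -1 per mismatch (N counts as a mismatch) is maximised
#' over all offsets with overlap length at least `minOverlap`. The pair is
#' merged at the best offset if the overlap mismatch fraction is at most
#' `maxMismatchFrac`, otherwise it is discarded. At positions covered by both
#' mates with disagreeing bases, the base with the higher quality is kept
#' together with its quality (quality ties keep mate 1's base); agreeing
#' positions keep the higher of the two qualities.
#'
#' @param seq1,qual1 Mate-1 bases and Phred+33 qualities (character vectors).
#' @param seq2,qual2 Mate-2 bases and qualities, as sequenced (reverse
#'   orientation).
#' @param id Optional read identifiers.
#' @param minOverlap Minimum overlap length (default 10).
#' @param maxMismatchFrac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return A list with `id`, `seq`, `qual`, `overlap_len` for the merged
#'   reads and `n_input`/`n_merged` counters. Pairs that fail to merge are
#'   dropped.
#' @examples
#' m <- mergePairs("ACGTACGTACGTACGTACGT", strrep("I", 20),
#'                 "GTCATGCAACGTACGTACGT", strrep("I", 20))
#' m$seq  # 30 nt, 10 nt overlap
#' @export
mergePairs <- function(seq1, qual1, seq2, qual2, id = NULL,
                       minOverlap = 10L, maxMismatchFrac = 0.1) {
    stopifnot(length(seq1) == length(seq2))
    if (any(nchar(seq1) == 0L) || any(nchar(seq2) == 0L))
        stop("empty read")
    if (is.null(id)) id = sprintf("read%d", seq_along(seq1))
    # amplicon libraries are duplicate-heavy: merge each distinct
    # (seq, qual) tuple once and broadcast the result
    key <- paste(seq1, qual1, seq2, qual2, sep = "\r")
    ui <- which(!duplicated(key))
    r <- .merge_pairs_batch(seq1[ui], qual1[ui], seq2[ui], qual2[ui],
                            as.integer(minOverlap), maxMismatchFrac)
    map <- match(key, key[ui])
    keep <- r$merged[map]
    list(id = id[keep], seq = r$seq[map][keep], qual = r$qual[map][keep],
         overlap_len = r$overlap_len[map][keep],
         n_input = length(seq1), n_merged = sum(keep))
}

#' Sliding-window quality trimming
#'
#' Scans each read 5'->3' with a window of `window` bases; at the first
#' window whose mean quality falls below `minQ` the read is truncated at that
#' window's start. Reads shorter than `minLen` after truncation are dropped.
#' Defaults mirror the conventional SLIDINGWINDOW:4:15 MINLEN:100 setting for
#' 2x250 bp amplicon data.
#'
#' @param reads A list with `id`, `seq`, `qual` (Phred+33).
#' @param window Window width (>= 1).
#' @param minQ Minimum mean window quality.
#' @param minLen Minimum surviving length.
#' @return A list like `reads` plus `n_input`/`n_kept`.
#' @export
trimSlidingWindow <- function(reads, window = 4L, minQ = 15, minLen = 100L) {
    stopifnot(window >= 1L)
    keep <- .sliding_window_keep(reads$qual, as.integer(window), minQ,
                                 as.integer(minLen))
    sel <- keep > 0L
    list(id = reads$id[sel],
         seq = substr(reads$seq[sel], 1L, keep[sel]),
         qual = substr(reads$qual[sel], 1L, keep[sel]),
         n_input = length(reads$seq), n_kept = sum(sel))
}

#' Filter reads by flanking primer structure
#'
#' Requires exactly one approximate occurrence of the forward primer and
#' exactly one of the reverse-complemented reverse primer in each read, with
#' the forward match upstream of the reverse match; both primer footprints
#' are removed and the insert between them is returned. Reads matching the
#' primers in reverse-complement orientation are flipped before testing.
#' Reads with absent, excessively divergent, multiple, or out-of-order primer
#' hits are discarded. Each primer tolerates
#' `floor(maxErrorRate * nchar(primer))` edits (mismatches or indels).
#'
#' @param reads A list with `id`, `seq`, `qual`.
#' @param ref An [AmpliconReference-class].
#' @param maxErrorRate Edit tolerance per primer base (default 0.1).
#' @return A list with the surviving inserts (`id`, `seq`, `qual`) and
#'   counters `n_input`, `n_kept`.
#' @export
filterPrimers <- function(reads, ref, maxErrorRate = 0.1) {
    fwd <- as.character(fwdPrimer(ref))
    rcRev <- as.character(Biostrings::reverseComplement(revPrimer(ref)))
    errF <- floor(maxErrorRate * nchar(fwd))
    errR <- floor(maxErrorRate * nchar(rcRev))
    seqs <- reads$seq
    quals <- reads$qual

    # orientation-normalise: flip reads that carry the forward primer only
    # on the reverse strand
    nf <- .primer_scan(seqs, fwd, errF)$count
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
    nfr <- .primer_scan(rc, fwd, errF)$count
    flip <- nf == 0L & nfr > 0L
    if (any(flip)) {
        seqs[flip] <- rc[flip]
        quals[flip] <- vapply(strsplit(quals[flip], ""),
                              function(x) paste(rev(x), collapse = ""),
                              character(1))
    }

    hitsF <- .primer_scan(seqs, fwd, errF)
    hitsR <- .primer_scan(seqs, rcRev, errR)
    ok <- hitsF$count == 1L & hitsR$count == 1L &
        !is.na(hitsF$end) & !is.na(hitsR$start) &
        hitsR$start > hitsF$end
    ok[is.na(ok)] <- FALSE
    ins <- substr(seqs, hitsF$end + 1L, hitsR$start - 1L)
    okLen <- ok & nchar(ins) > 0L
    list(id = reads$id[okLen],
         seq = ins[okLen],
         qual = substr(quals, hitsF$end + 1L, hitsR$start - 1L)[okLen],
         n_input = length(reads$seq), n_kept = sum(okLen))
}

#' Preprocess one sample: merge, trim, primer-filter
#'
#' Runs the full read-preprocessing chain on one FASTQ pair and reports read
#' fates. With `umiLength > 0` the UMI is split off the merged read before
#' primer matching and returned alongside.
#'
#' @param r1,r2 FASTQ paths for mates 1 and 2.
#' @param ref An [AmpliconReference-class].
#' @param minOverlap,maxMismatchFrac Passed to [mergePairs()].
#' @param window,minQ,minLen Passed to [trimSlidingWindow()].
#' @param maxErrorRate Passed to [filterPrimers()].
#' @param umiLength UMI length at the 5' end of the merged read (0 = none).
#' @return A list with the surviving inserts (`id`, `seq`, `qual`, and `umi`
#'   when enabled) and a one-row data.frame `fates` with columns `total`,
#'   `merged`, `trimmed_out`, `primer_fail`, `surviving`.
#' @export
preprocessSample <- function(r1, r2, ref, minOverlap = 10L,
                             maxMismatchFrac = 0.1, window = 4L, minQ = 15,
                             minLen = 100L, maxErrorRate = 0.1,
                             umiLength = 0L) {
    f1 <- readFastq(r1)
    f2 <- readFastq(r2)
    m <- mergePairs(f1$seq, f1$qual, f2$seq, f2$qual, id = f1$id,
                    minOverlap = minOverlap,
                    maxMismatchFrac = maxMismatchFrac)
    t <- trimSlidingWindow(m, window = window, minQ = minQ, minLen = minLen)
    trimmedOut <- t$n_input - t$n_kept
    umi <- NULL
    if (umiLength > 0L) {
        u <- extractUmi(t, umiLength)
        t <- u$reads
        umi <- u$umi
    }
    p <- filterPrimers(t, ref, maxErrorRate = maxErrorRate)
    if (!is.null(umi)) p$umi <- umi[match(p$id, t$id)]
    p$fates <- data.frame(total = m$n_input, merged = m$n_merged,
                          trimmed_out = trimmedOut,
                          primer_fail = p$n_input - p$n_kept,
                          surviving = p$n_kept)
    p
}
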
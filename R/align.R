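# Global alignment of surviving reads to the inter-primer reference window
# and conversion of alignment CIGARs into named indel variant alleles
# ("barcodes"). The aligner is a Gotoh affine-gap Needleman-Wunsch
# implemented in C++ (src/nw_align.cpp); only indel position and length feed
# the variant name, substitutions are collapsed into the unedited allele.

#' Global affine-gap alignment
#'
#' Optimal global (Needleman-Wunsch) alignment of a read against a reference
#' under affine gap penalties. A gap of length L costs
#' `gapOpen + (L - 1) * gapExt`. Default scoring follows the EDNAFULL
#' nucleotide convention (match +5, mismatch -4) with gap open 10 and gap
#' extension 0.25, the settings conventional for aligning highly divergent
#' edited amplicons to a short reference. Ties in the dynamic program prefer
#' match over deletion over insertion so the traceback is deterministic.
#'
#' @param read,ref Non-empty DNA strings.
#' @param match,mismatch Substitution scores.
#' @param gapOpen,gapExt Gap penalties (positive numbers, subtracted).
#' @return A list with `score`, `cigar` (e.g. `"120M3D97M"`, ops M/I/D on
#'   the reference), and `ref_start` (always 0: global).
#' @examples
#' nwAlign("ACGTACGT", "ACGTTTACGT")$cigar
#' @export
nwAlign <- function(read, ref, match = 5, mismatch = -4,
                    gapOpen = 10, gapExt = 0.25) {
    if (nchar(read) == 0L || nchar(ref) == 0L) stop("empty sequence")
    r <- .nw_align_batch(read, as.character(ref), match, mismatch,
                         gapOpen, gapExt, -1L)
    list(score = r$score[1], cigar = as.character(r$cigar[1]), ref_start = 0L)
}

# vectorised form over many reads against one reference; bandSlack >= 0
# restricts the DP to diagonals within slack of the net length difference
# (exact unless the optimal alignment's gap excursion exceeds the slack)
nwAlignBatch <- function(reads, ref, match = 5, mismatch = -4,
                         gapOpen = 10, gapExt = 0.25, bandSlack = -1L) {
    if (length(reads) == 0L)
        return(list(score = numeric(0), cigar = character(0)))
    .nw_align_batch(reads, as.character(ref), match, mismatch, gapOpen,
                    gapExt, as.integer(bandSlack))
}

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string with M/I/D operations.
#' @return A data.frame with `op` and `len` columns, in CIGAR order.
#' @examples
#' parseCigar("120M3D97M")
#' @export
parseCigar <- function(cigar) {
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
    data.frame(op = ops, len = lens)
}

#' Call an indel variant allele from a global alignment
#'
#' Extracts insertions and deletions from the CIGAR of a global alignment
#' and names the allele by its components. Substitutions are ignored:
#' an alignment with no indel yields the unedited allele `"no variant"`.
#' Indels are left-aligned (shifted maximally 5' within reference repeats)
#' so that equivalent alignments from different reads receive the same name.
#' Positions are 1-based on the reference window; a deletion is positioned
#' at its first deleted base, an insertion at the reference base immediately
#' after the insertion point. Components are named `"<pos>:<len><I|D>"` and
#' joined with `","` in ascending position order, e.g. `"125:1I"` or
#' `"122:108D"`.
#'
#' @param cigar CIGAR string of a global read-vs-reference alignment.
#' @param read,ref The aligned sequences (needed for left-alignment of
#'   insertions; `ref` is the reference window).
#' @return A list with `name`, `components` (data.frame pos/len/kind) and
#'   `is_unedited`.
#' @examples
#' aln <- nwAlign("ACGTACGT", "ACGTTTACGT")
#' callVariant(aln$cigar, "ACGTACGT", "ACGTTTACGT")$name
#' @export
callVariant <- function(cigar, read, ref) {
    cig <- parseCigar(cigar)
    refseq <- strsplit(as.character(ref), "")[[1]]
    readseq <- strsplit(as.character(read), "")[[1]]
    rpos <- 1L  # next reference base
    qpos <- 1L  # next read base
    comp <- list()
    for (k in seq_len(nrow(cig))) {
        op <- cig$op[k]; len <- cig$len[k]
        if (op == "M") {
            rpos <- rpos + len; qpos <- qpos + len
        } else if (op == "D") {
            p <- rpos
            # left-shift while the base before the gap equals the last
            # deleted base
            while (p > 1L && refseq[p - 1L] == refseq[p + len - 1L])
                p <- p - 1L
            comp[[length(comp) + 1L]] <- list(pos = p, len = len, kind = "D")
            rpos <- rpos + len
        } else if (op == "I") {
            p <- rpos                      # insertion sits before ref base p
            ins <- readseq[qpos:(qpos + len - 1L)]
            while (p > 1L && refseq[p - 1L] == ins[len]) {
                ins <- c(ins[len], ins[-len])  # rotate right
                p <- p - 1L
            }
            comp[[length(comp) + 1L]] <- list(pos = p, len = len, kind = "I")
            qpos <- qpos + len
        }
    }
    if (length(comp) == 0L)
        return(list(name = UNEDITED,
                    components = data.frame(pos = integer(0), len = integer(0),
                                            kind = character(0)),
                    is_unedited = TRUE))
    df <- do.call(rbind, lapply(comp, as.data.frame))
    df <- df[order(df$pos, df$kind, df$len), , drop = FALSE]
    rownames(df) <- NULL
    list(name = paste(sprintf("%d:%d%s", df$pos, df$len, df$kind),
                      collapse = ","),
         components = df, is_unedited = FALSE)
}

#' Align reads and call variant alleles for one sample
#'
#' Aligns every read globally to the reference window, discards reads whose
#' alignment score falls below `minScoreFrac` times the maximum attainable
#' score (`match * min(read length, reference length)`), and names the indel
#' allele of each surviving read. Identical read sequences are aligned once.
#'
#' @param seqs Character vector of insert sequences (primers removed).
#' @param ref An [AmpliconReference-class] or a DNA string used directly as
#'   the reference window.
#' @param minScoreFrac Alignment acceptance floor (default 0.4).
#' @param bandSlack Diagonal band slack for the batch aligner: alignments
#'   whose insertions and deletions each stay within `bandSlack` of the net
#'   read-reference length difference are scored exactly (default 48, ample
#'   for CRISPR indels at a short amplicon); set to -1 for the full matrix.
#' @param ... Scoring parameters passed to the aligner.
#' @return A list with `variant` (name per aligned read), `aligned` (logical
#'   per input read), and `alignments` (per unique sequence: seq, score,
#'   cigar, variant).
#' @export
alignSample <- function(seqs, ref, minScoreFrac = 0.4, match = 5,
                        mismatch = -4, gapOpen = 10, gapExt = 0.25,
                        bandSlack = 48L) {
    window <- if (is(ref, "AmpliconReference")) as.character(refWindow(ref))
              else as.character(ref)
    uniq <- unique(seqs)
    aln <- nwAlignBatch(uniq, window, match, mismatch, gapOpen, gapExt,
                        bandSlack = bandSlack)
    maxScore <- match * pmin(nchar(uniq), nchar(window))
    pass <- aln$score >= minScoreFrac * maxScore
    vname <- rep(NA_character_, length(uniq))
    vname[pass] <- vapply(which(pass), function(i)
        callVariant(aln$cigar[i], uniq[i], window)$name, character(1))
    idx <- match(seqs, uniq)
    list(variant = vname[idx][pass[idx]],
         aligned = pass[idx],
         alignments = data.frame(seq = uniq, score = aln$score,
                                 cigar = as.character(aln$cigar),
                                 variant = vname,
                                 stringsAsFactors = FALSE))
}

#' Tabulate variant alleles of one sample
#'
#' Counts reads per unique variant name and computes proportions against the
#' total number of aligned reads.
#'
#' @param variants Character vector of variant names, one per aligned read.
#' @return A data.frame with `variant`, `count`, `proportion`
#'   (count-descending; proportions sum to 1).
#' @examples
#' tabulateSample(c("125:1I", "125:1I", "125:1I", "no variant"))
#' @export
tabulateSample <- function(variants) {
    if (length(variants) == 0L) stop("no aligned reads")
    tab <- sort(table(variants), decreasing = TRUE)
    data.frame(variant = names(tab), count = as.integer(tab),
               proportion = as.numeric(tab) / length(variants),
               stringsAsFactors = FALSE)
}

#' Export alignments of one sample as SAM
#'
#' Minimal single-reference SAM export (ops M/I/D only) for inspection in
#' standard tools.
#'
#' @param alignments The `alignments` data.frame from [alignSample()].
#' @param ref An [AmpliconReference-class] (its window is the SAM reference).
#' @param path Output SAM path.
#' @export
writeSam <- function(alignments, ref, path) {
    window <- as.character(refWindow(ref))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", ref@name, nchar(window))), con)
    ok <- !is.na(alignments$variant)
    writeLines(sprintf("read%d\t0\t%s\t1\t255\t%s\t*\t0\t0\t%s\t*",
                       seq_len(sum(ok)), ref@name,
                       alignments$cigar[ok], alignments$seq[ok]), con)
    invisible(path)
}
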
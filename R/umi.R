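# Optional UMI handling: extraction from the merged read, grouping,
# per-position majority consensus, deduplication to one read per template
# molecule, and the standard-vs-UMI VAF regression comparison.

#' Split UMIs off merged reads
#'
#' The first `umiLength` bases of each merged read are taken as the UMI; the
#' remainder proceeds through the standard pipeline. Reads shorter than or
#' equal to the UMI length are filtered out.
#'
#' @param reads A list with `id`, `seq`, `qual`.
#' @param umiLength UMI length in bases (> 0).
#' @return A list with `umi` (character vector) and `reads` (the trimmed
#'   read list).
#' @export
extractUmi <- function(reads, umiLength) {
    stopifnot(umiLength > 0L)
    ok <- nchar(reads$seq) > umiLength
    list(umi = substr(reads$seq[ok], 1L, umiLength),
         reads = list(id = reads$id[ok],
                      seq = substr(reads$seq[ok], umiLength + 1L,
                                   nchar(reads$seq[ok])),
                      qual = substr(reads$qual[ok], umiLength + 1L,
                                    nchar(reads$qual[ok]))))
}

#' Group reads by UMI
#'
#' Groups reads with identical UMIs. With `maxEdits = 1`, each UMI observed
#' in fewer reads is absorbed into a UMI within one edit that is observed in
#' more reads (sequencing-error tolerance; off by default since template
#' tags are expected to match exactly).
#'
#' @param umi Character vector of UMIs, one per read.
#' @param maxEdits 0 (exact, default) or 1.
#' @return A list of integer vectors of read indices, named by UMI.
#' @export
groupUmis <- function(umi, maxEdits = 0L) {
    groups <- split(seq_along(umi), umi)
    if (maxEdits >= 1L && length(groups) > 1L) {
        sizes <- lengths(groups)
        ord <- order(sizes)  # absorb small into large
        nm <- names(groups)
        d <- utils::adist(nm)
        for (i in ord) {
            cand <- which(d[i, ] == 1L & lengths(groups) > lengths(groups)[i])
            if (length(cand)) {
                tgt <- cand[which.max(lengths(groups)[cand])]
                groups[[tgt]] <- c(groups[[tgt]], groups[[i]])
                groups[[i]] <- integer(0)
            }
        }
        groups <- groups[lengths(groups) > 0L]
    }
    groups
}

# majority base per position; ties broken by highest summed quality, then
# alphabetically. Consensus length = most frequent member length (ties:
# higher total quality).
.consensusOne <- function(seqs, quals) {
    if (length(seqs) == 1L) return(list(seq = seqs, qual = quals))
    lens <- nchar(seqs)
    ltab <- sort(table(lens), decreasing = TRUE)
    topLens <- as.integer(names(ltab)[ltab == ltab[1]])
    L <- if (length(topLens) == 1L) topLens else {
        qsum <- vapply(topLens, function(l)
            sum(utf8ToInt(paste(quals[lens == l], collapse = "")) - 33L),
            numeric(1))
        topLens[which.max(qsum)]
    }
    use <- lens == L
    sm <- do.call(rbind, strsplit(seqs[use], ""))
    qm <- do.call(rbind, lapply(strsplit(quals[use], ""),
                                function(x) utf8ToInt(paste(x, collapse = "")) - 33L))
    cons <- character(L); cq <- integer(L)
    for (p in seq_len(L)) {
        counts <- table(sm[, p])
        top <- names(counts)[counts == max(counts)]
        if (length(top) > 1L) {
            qs <- vapply(top, function(b) sum(qm[sm[, p] == b, p]), numeric(1))
            top <- sort(top[qs == max(qs)])[1]
        }
        cons[p] <- top
        cq[p] <- max(qm[sm[, p] == top, p])
    }
    list(seq = paste(cons, collapse = ""), qual = intToUtf8(cq + 33L))
}

#' Collapse UMI groups to consensus reads
#'
#' One consensus read per UMI group: per-position majority base over the
#' members, ties broken by the highest summed quality. Each group
#' contributes exactly one read downstream, so deduplication is idempotent.
#'
#' @param reads A list with `id`, `seq`, `qual`.
#' @param umi UMI per read (same length as `reads$seq`).
#' @param maxEdits Passed to [groupUmis()].
#' @return A read list with one entry per UMI group (ids are the UMIs).
#' @export
deduplicateUmi <- function(reads, umi, maxEdits = 0L) {
    groups <- groupUmis(umi, maxEdits = maxEdits)
    cons <- lapply(groups, function(idx)
        .consensusOne(reads$seq[idx], reads$qual[idx]))
    list(id = names(groups),
         seq = vapply(cons, `[[`, character(1), "seq"),
         qual = vapply(cons, `[[`, character(1), "qual"),
         group_size = lengths(groups))
}

#' Regress UMI-deduplicated VAFs on standard VAFs
#'
#' Ordinary least-squares regression of matched variant allele fractions
#' between a standard-PCR table and a UMI-deduplicated table of the same
#' biological sample. Variants absent from one table enter with VAF 0.
#'
#' @param tableStd,tableUmi Variant tables from [tabulateSample()].
#' @return A list with `slope`, `intercept`, `r_squared` (adjusted) and the
#'   matched VAF data.frame.
#' @export
compareVafs <- function(tableStd, tableUmi) {
    shared <- intersect(tableStd$variant, tableUmi$variant)
    if (length(shared) < 3L)
        stop("fewer than 3 shared variant names between the two tables")
    vars <- union(tableStd$variant, tableUmi$variant)
    x <- setNames(numeric(length(vars)), vars)
    y <- x
    x[tableStd$variant] <- tableStd$proportion
    y[tableUmi$variant] <- tableUmi$proportion
    fit <- stats::lm(y ~ x)
    # a perfect fit (identical tables) is a legitimate input here
    rsq <- suppressWarnings(summary(fit)$adj.r.squared)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = rsq,
         data = data.frame(variant = vars, vaf_std = unname(x),
                           vaf_umi = unname(y)))
}
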
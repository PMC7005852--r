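# Longitudinal analysis: matching samples across timepoints to individual
# animals by top-k barcode overlap, and normalised clone trajectories.

#' Match samples across timepoints by top-k barcode overlap
#'
#' For every cross-timepoint sample pair, scores the overlap of the k most
#' frequent barcodes: score = |intersection of top-k names| / k. A greedy
#' 1-to-1 assignment by descending score is proposed; the full score matrix
#' is always returned because the assignment is advisory and intended for
#' manual review, not an authoritative decision.
#'
#' @param t1Sets,t2Sets Named lists of [CloneSet-class] objects (or of
#'   data.frames with `variant` and `vaf` columns), one per sample at each
#'   timepoint.
#' @param k Number of top barcodes compared (default 5).
#' @return A list with `scores` (t1 x t2 matrix) and `assignment`
#'   (data.frame t1_id, t2_id, score; greedy, at most
#'   `min(length(t1Sets), length(t2Sets))` rows).
#' @export
matchSamples <- function(t1Sets, t2Sets, k = 5L) {
    stopifnot(k >= 1L)
    topk <- function(x) {
        tab <- if (is(x, "CloneSet")) cloneTable(x) else x
        tab <- tab[order(-tab$vaf), , drop = FALSE]
        head(tab$variant, k)
    }
    top1 <- lapply(t1Sets, topk)
    top2 <- lapply(t2Sets, topk)
    scores <- matrix(0, length(top1), length(top2),
                     dimnames = list(names(t1Sets), names(t2Sets)))
    for (i in seq_along(top1))
        for (j in seq_along(top2))
            scores[i, j] <- length(intersect(top1[[i]], top2[[j]])) / k
    # greedy assignment by descending score
    s <- scores
    assign <- data.frame(t1_id = character(0), t2_id = character(0),
                         score = numeric(0), stringsAsFactors = FALSE)
    while (nrow(s) > 0L && ncol(s) > 0L && max(s) > -Inf) {
        w <- which(s == max(s), arr.ind = TRUE)[1, ]
        assign <- rbind(assign, data.frame(
            t1_id = rownames(s)[w[1]], t2_id = colnames(s)[w[2]],
            score = s[w[1], w[2]], stringsAsFactors = FALSE))
        s <- s[-w[1], -w[2], drop = FALSE]
    }
    list(scores = scores, assignment = assign)
}

#' Normalised clone trajectory for one animal
#'
#' For a matched pair of timepoint samples, keeps the clones with VAF above
#' the cutoff at each timepoint and renormalises each timepoint to a
#' cumulative frequency of 1.0. A clone retained at only one timepoint gets
#' frequency 0 at the other (after that timepoint's renormalisation). The
#' result is ready for stacked-area plotting.
#'
#' @param cs1,cs2 [CloneSet-class] objects (or data.frames with `variant`
#'   and `vaf`) for the two timepoints of one animal.
#' @param vafCutoff VAF cutoff applied at each timepoint (default 0.02).
#' @param fishId Label for the animal.
#' @return A data.frame with `fish_id`, `clone`, `t1_freq`, `t2_freq`; each
#'   frequency column sums to 1.
#' @export
buildTrajectory <- function(cs1, cs2, vafCutoff = 0.02, fishId = "fish") {
    get <- function(x, label) {
        tab <- if (is(x, "CloneSet")) cloneTable(x) else x
        tab <- tab[tab$vaf > vafCutoff, , drop = FALSE]
        if (nrow(tab) == 0L)
            stop("no clones above cutoff at a timepoint for sample: ", label)
        setNames(tab$vaf / sum(tab$vaf), tab$variant)
    }
    f1 <- get(cs1, paste0(fishId, "/t1"))
    f2 <- get(cs2, paste0(fishId, "/t2"))
    clones <- union(names(f1), names(f2))
    out <- data.frame(fish_id = fishId, clone = clones,
                      t1_freq = unname(ifelse(clones %in% names(f1),
                                              f1[clones], 0)),
                      t2_freq = unname(ifelse(clones %in% names(f2),
                                              f2[clones], 0)),
                      stringsAsFactors = FALSE)
    out[order(-out$t1_freq, -out$t2_freq), , drop = FALSE]
}
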
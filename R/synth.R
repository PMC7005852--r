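# Synthetic amplicon-barcode datasets with full truth tables. The generator
# emulates the study conditions: per-sample clone structure with skewed
# allele fractions, a fraction of unedited alleles, stereotypical repair
# variants shared across samples, substitution/indel sequencing error, and
# optional UMI tags. Reads are emitted as standard paired FASTQ so every
# pipeline stage is exercised.

.randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulation configuration
#'
#' Validated configuration for [simulateDataset()]. Defaults model a
#' well-executed barcoding experiment: 20 animals, 5000 read pairs each,
#' about 4 clones per animal with Dirichlet-skewed allele fractions, 20% of
#' alleles unedited, one stereotypical repair variant present in every
#' sample at VAF 0.05, substitution error 1e-3 and indel error 1e-4 per
#' base, no UMIs.
#'
#' @param nSamples Number of samples (animals).
#' @param readsPerSample Read pairs per sample.
#' @param windowLength Length of the inter-primer reference window.
#' @param nSites,siteLen Number and length of evenly spaced CRISPR target
#'   sites within the window.
#' @param primerLen Primer length on each side.
#' @param readLen Mate length (paired-end, 2 x readLen).
#' @param clonesMean,clonesSd Per-sample clone-count distribution (normal,
#'   rounded, floored at 1).
#' @param dirichletAlpha Dirichlet concentration for clone VAF skew (smaller
#'   = more skewed).
#' @param cloneVafs Optional fixed clone allele fractions: when given, every
#'   sample carries exactly `length(cloneVafs)` clones at these fractions
#'   (rescaled to the probability mass left after unedited and common
#'   alleles), overriding `clonesMean`/`clonesSd`/`dirichletAlpha`.
#' @param uneditedFraction Expected fraction of unedited alleles per sample
#'   (scalar, or one value per sample).
#' @param commonVafs Numeric vector: planted stereotypical variants, one per
#'   entry, each present at this VAF in the samples selected by
#'   `commonInSamples`.
#' @param commonInSamples Number of samples carrying each planted common
#'   variant (default all).
#' @param subErrorRate,indelErrorRate Per-base sequencing error rates.
#' @param umiLength UMI length (0 disables UMI tagging).
#' @param umiMeanDup Mean PCR duplicates per template molecule when UMIs are
#'   on.
#' @param baseQ,qualDroop Base quality and linear 3' quality droop (Phred
#'   units over the read).
#' @param seed RNG seed; the same seed reproduces the dataset byte for byte.
#' @return A classed list (`SimulationConfig`).
#' @export
simulationConfig <- function(nSamples = 20L, readsPerSample = 5000L,
                             windowLength = 300L, nSites = 10L,
                             siteLen = 23L, primerLen = 20L, readLen = 250L,
                             clonesMean = 4, clonesSd = 1.8,
                             dirichletAlpha = 1, cloneVafs = NULL,
                             uneditedFraction = 0.2,
                             commonVafs = 0.05, commonInSamples = NULL,
                             subErrorRate = 1e-3, indelErrorRate = 1e-4,
                             umiLength = 0L, umiMeanDup = 4,
                             baseQ = 35L, qualDroop = 0,
                             seed = 20200207L) {
    cfg <- list(nSamples = as.integer(nSamples),
                readsPerSample = as.integer(readsPerSample),
                windowLength = as.integer(windowLength),
                nSites = as.integer(nSites), siteLen = as.integer(siteLen),
                primerLen = as.integer(primerLen),
                readLen = as.integer(readLen),
                clonesMean = clonesMean, clonesSd = clonesSd,
                dirichletAlpha = dirichletAlpha, cloneVafs = cloneVafs,
                uneditedFraction = uneditedFraction,
                commonVafs = commonVafs,
                commonInSamples = if (is.null(commonInSamples))
                    rep(as.integer(nSamples), length(commonVafs))
                    else as.integer(commonInSamples),
                subErrorRate = subErrorRate,
                indelErrorRate = indelErrorRate,
                umiLength = as.integer(umiLength), umiMeanDup = umiMeanDup,
                baseQ = as.integer(baseQ), qualDroop = qualDroop,
                seed = as.integer(seed))
    u <- cfg$uneditedFraction
    if (any(u < 0 | u > 1)) stop("uneditedFraction outside [0, 1]")
    if (length(u) != 1L && length(u) != cfg$nSamples)
        stop("uneditedFraction must be scalar or one value per sample")
    if (!is.null(cfg$cloneVafs) && any(cfg$cloneVafs <= 0))
        stop("cloneVafs must be positive")
    if (any(cfg$commonVafs < 0) ||
        max(u) + sum(cfg$commonVafs) > 1)
        stop("unedited fraction plus planted common VAFs exceed 1")
    if (cfg$nSites * cfg$siteLen > cfg$windowLength)
        stop("target sites do not fit in the reference window")
    if (length(cfg$commonInSamples) != length(cfg$commonVafs) ||
        any(cfg$commonInSamples > cfg$nSamples))
        stop("commonInSamples inconsistent with commonVafs/nSamples")
    class(cfg) <- "SimulationConfig"
    cfg
}

# target-site start positions, evenly spaced within the window
.sitePositions <- function(cfg) {
    gap <- (cfg$windowLength - cfg$nSites * cfg$siteLen) / (cfg$nSites + 1)
    starts <- round(gap * seq_len(cfg$nSites) +
                    cfg$siteLen * (seq_len(cfg$nSites) - 1L)) + 1L
    as.integer(starts)
}

#' Generate the synthetic amplicon reference
#'
#' A random amplicon with `nSites` evenly spaced target sites in the
#' reference window, flanked by two primers. Deterministic given the
#' config's seed.
#'
#' @param cfg A [simulationConfig()].
#' @return An [AmpliconReference-class].
#' @export
simulateReference <- function(cfg) {
    set.seed(cfg$seed)
    fwd <- .randDna(cfg$primerLen)
    rcRev <- .randDna(cfg$primerLen)
    window <- .randDna(cfg$windowLength)
    AmpliconReference(paste0(fwd, window, rcRev), fwdPrimer = fwd,
                      revPrimer = as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(rcRev))),
                      name = "synthetic_amplicon")
}

# Draw one indel component inside a target site that is stable under
# left-alignment against the window (so the generator's coordinates are the
# names the variant caller must produce).
.drawComponent <- function(window, siteStart, siteLen) {
    w <- strsplit(window, "")[[1]]
    for (try in 1:50) {
        if (runif(1) < 0.6) {  # deletion
            len <- sample(2:12, 1)
            pos <- siteStart + sample.int(max(1L, siteLen - len), 1) - 1L
            if (pos <= 1L || pos + len - 1L > length(w)) next
            if (w[pos - 1L] != w[pos + len - 1L])
                return(list(pos = pos, len = len, kind = "D", ins = ""))
        } else {               # insertion
            len <- sample(1:8, 1)
            pos <- siteStart + sample.int(siteLen, 1) - 1L
            if (pos <= 1L) next
            ins <- .randDna(len)
            if (substr(ins, len, len) != w[pos - 1L])
                return(list(pos = pos, len = len, kind = "I", ins = ins))
        }
    }
    NULL
}

# apply components (ref-window coordinates) to the window sequence
.applyComponents <- function(window, comps) {
    if (length(comps) == 0L) return(window)
    ord <- order(-vapply(comps, `[[`, numeric(1), "pos"))
    s <- window
    for (cmp in comps[ord]) {
        if (cmp$kind == "D") {
            s <- paste0(substr(s, 1L, cmp$pos - 1L),
                        substr(s, cmp$pos + cmp$len, nchar(s)))
        } else {
            s <- paste0(substr(s, 1L, cmp$pos - 1L), cmp$ins,
                        substr(s, cmp$pos, nchar(s)))
        }
    }
    s
}

.componentName <- function(comps) {
    if (length(comps) == 0L) return(UNEDITED)
    df <- do.call(rbind, lapply(comps, function(c)
        data.frame(pos = c$pos, len = c$len, kind = c$kind)))
    df <- df[order(df$pos, df$kind, df$len), , drop = FALSE]
    paste(sprintf("%d:%d%s", df$pos, df$len, df$kind), collapse = ",")
}

# draw a clone allele (1-3 indels at distinct sites) whose name is not in
# `used`; returns list(name, comps, seq)
.drawAllele <- function(window, sites, siteLen, used, maxIndels = 3L) {
    repeat {
        k <- sample.int(maxIndels, 1)
        at <- sample(sites, min(k, length(sites)))
        comps <- list()
        for (s in at) {
            cmp <- .drawComponent(window, s, siteLen)
            if (!is.null(cmp)) comps[[length(comps) + 1L]] <- cmp
        }
        if (length(comps) == 0L) next
        nm <- .componentName(comps)
        if (!(nm %in% used))
            return(list(name = nm, comps = comps,
                        seq = .applyComponents(window, comps)))
    }
}

# per-read sequencing errors: substitutions and (rare) 1-3 bp indels
.mutateReads <- function(seqs, subRate, indelRate) {
    if (subRate <= 0 && indelRate <= 0) return(seqs)
    L <- nchar(seqs)
    nSub <- rbinom(length(seqs), L, subRate)
    nInd <- rbinom(length(seqs), L, indelRate)
    hit <- which(nSub + nInd > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        ch <- strsplit(seqs[i], "")[[1]]
        if (nSub[i] > 0L) {
            at <- sample.int(length(ch), min(nSub[i], length(ch)))
            for (p in at) ch[p] <- sample(setdiff(bases, ch[p]), 1)
        }
        if (nInd[i] > 0L) {
            for (k in seq_len(nInd[i])) {
                p <- sample.int(length(ch), 1)
                len <- sample.int(3L, 1)
                if (runif(1) < 0.5 && length(ch) > len + 1L) {
                    ch <- ch[-(p:min(p + len - 1L, length(ch)))]
                } else {
                    ch <- append(ch, sample(bases, len, replace = TRUE), p)
                }
            }
        }
        seqs[i] <- paste(ch, collapse = "")
    }
    seqs
}

.qualString <- function(len, baseQ, droop) {
    if (len <= 0L) return("")
    q <- round(baseQ - droop * (seq_len(len) - 1L) / max(1L, len - 1L))
    intToUtf8(pmax(2L, q) + 33L)
}

# allele frequency layout for one sample: named vafs for unedited, planted
# commons present in this sample, and per-clone alleles
.sampleLayout <- function(cfg, sampleIdx, commonAlleles, commonCarriers,
                          cloneFactory) {
    u <- if (length(cfg$uneditedFraction) == 1L) cfg$uneditedFraction
         else cfg$uneditedFraction[sampleIdx]
    commons <- which(vapply(commonCarriers,
                            function(cc) sampleIdx %in% cc, logical(1)))
    commonVaf <- cfg$commonVafs[commons]
    rest <- 1 - u - sum(commonVaf)
    if (!is.null(cfg$cloneVafs)) {
        nClones <- length(cfg$cloneVafs)
        cloneVaf <- rest * cfg$cloneVafs / sum(cfg$cloneVafs)
    } else {
        nClones <- max(1L, round(rnorm(1, cfg$clonesMean, cfg$clonesSd)))
        cloneVaf <- rgamma(nClones, shape = cfg$dirichletAlpha)
        cloneVaf <- rest * cloneVaf / sum(cloneVaf)
    }
    clones <- replicate(nClones, cloneFactory(), simplify = FALSE)
    list(unedited = u, commonIdx = commons, commonVaf = commonVaf,
         clones = clones, cloneVaf = cloneVaf)
}

#' Simulate a paired-end amplicon barcode dataset with truth tables
#'
#' Draws per-sample clone structure, planted stereotypical (common)
#' variants, and unedited alleles; emits paired 2 x `readLen` FASTQ files
#' per sample plus a sample sheet, applying per-base substitution/indel
#' sequencing error and, optionally, UMI tags with PCR duplication. Truth
#' tables record every sample's true variant names, read counts, fraction
#' of informative reads, and clone count above any cutoff. The same config
#' (including seed) reproduces the dataset exactly.
#'
#' @param cfg A [simulationConfig()].
#' @param dir Output directory (created if needed); `NULL` simulates counts
#'   only (no FASTQ written).
#' @return A list with `reference` ([AmpliconReference-class]), `sampleSheet`
#'   (data.frame sample_id, r1, r2, group), `samples` (per-sample truth:
#'   totals, phi, clone counts), `variants` (per-sample per-variant truth),
#'   and `config`.
#' @export
simulateDataset <- function(cfg, dir = NULL) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    ref <- simulateReference(cfg)   # also seeds the RNG
    window <- as.character(refWindow(ref))
    fullRef <- as.character(refSequence(ref))
    sites <- .sitePositions(cfg)
    used <- character(0)

    # planted stereotypical variants, shared across the chosen samples
    commonAlleles <- list()
    for (k in seq_along(cfg$commonVafs)) {
        al <- .drawAllele(window, sites, cfg$siteLen, used, maxIndels = 2L)
        used <- c(used, al$name)
        commonAlleles[[k]] <- al
    }
    commonCarriers <- lapply(seq_along(cfg$commonVafs), function(k)
        sort(sample.int(cfg$nSamples, cfg$commonInSamples[k])))

    cloneFactory <- function() {
        al <- .drawAllele(window, sites, cfg$siteLen, used)
        used <<- c(used, al$name)
        al
    }

    ids <- sprintf("S%02d", seq_len(cfg$nSamples))
    sampleRows <- list(); variantRows <- list()
    r1Paths <- r2Paths <- rep(NA_character_, cfg$nSamples)
    if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

    toAmplicon <- function(windowSeq)
        paste0(substr(fullRef, 1L, cfg$primerLen), windowSeq,
               substr(fullRef, nchar(fullRef) - cfg$primerLen + 1L,
                      nchar(fullRef)))

    for (i in seq_len(cfg$nSamples)) {
        lay <- .sampleLayout(cfg, i, commonAlleles, commonCarriers,
                             cloneFactory)
        alleleNames <- c(UNEDITED,
                         vapply(commonAlleles[lay$commonIdx], `[[`,
                                character(1), "name"),
                         vapply(lay$clones, `[[`, character(1), "name"))
        alleleSeqs <- c(window,
                        vapply(commonAlleles[lay$commonIdx], `[[`,
                               character(1), "seq"),
                        vapply(lay$clones, `[[`, character(1), "seq"))
        probs <- c(lay$unedited, lay$commonVaf, lay$cloneVaf)
        cls <- c("unedited", rep("common", length(lay$commonVaf)),
                 rep("clone", length(lay$cloneVaf)))
        counts <- as.integer(rmultinom(1, cfg$readsPerSample, probs))
        tot <- sum(counts)
        informative <- sum(counts[cls == "clone"])
        vafs <- counts / tot
        variantRows[[i]] <- data.frame(
            sample_id = ids[i], variant = alleleNames, class = cls,
            count = counts, vaf = vafs, stringsAsFactors = FALSE)
        sampleRows[[i]] <- data.frame(
            sample_id = ids[i], total_reads = tot,
            unedited_reads = counts[1],
            common_reads = sum(counts[cls == "common"]),
            phi_true = informative / tot,
            b002_true = sum(cls == "clone" & vafs > 0.02),
            n_clones = sum(cls == "clone"), stringsAsFactors = FALSE)

        if (!is.null(dir)) {
            amp <- unname(vapply(alleleSeqs, toAmplicon, character(1),
                                 USE.NAMES = FALSE))
            tmpl <- rep(amp, counts)
            if (cfg$umiLength > 0L) {
                # carve each allele's reads into template molecules; every
                # molecule gets its own UMI (unique within the sample, as
                # expected when the tag space vastly exceeds the number of
                # template molecules) and contributes its duplicates
                sizesPer <- lapply(counts, function(n) {
                    if (n == 0L) return(integer(0))
                    if (cfg$umiMeanDup <= 1) return(rep(1L, n))
                    m <- max(1L, round(n / cfg$umiMeanDup))
                    sz <- tabulate(sample.int(m, n, replace = TRUE), m)
                    sz[sz > 0L]
                })
                nMol <- sum(lengths(sizesPer))
                umis <- character(0)
                while (length(umis) < nMol)
                    umis <- unique(c(umis, vapply(
                        seq_len(nMol - length(umis) + 8L),
                        function(z) .randDna(cfg$umiLength), character(1))))
                umis <- umis[seq_len(nMol)]
                tmpl <- character(0); m0 <- 0L
                for (a in seq_along(counts)) {
                    sizes <- sizesPer[[a]]
                    if (length(sizes) == 0L) next
                    u <- umis[m0 + seq_along(sizes)]
                    m0 <- m0 + length(sizes)
                    tmpl <- c(tmpl, paste0(rep(u, sizes), amp[a]))
                }
            }
            L <- nchar(tmpl)
            m1 <- substr(tmpl, 1L, pmin(cfg$readLen, L))
            m2raw <- substr(tmpl, pmax(1L, L - cfg$readLen + 1L), L)
            m2 <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(m2raw)))
            m1 <- .mutateReads(m1, cfg$subErrorRate, cfg$indelErrorRate)
            m2 <- .mutateReads(m2, cfg$subErrorRate, cfg$indelErrorRate)
            q1 <- vapply(nchar(m1), .qualString, character(1),
                         baseQ = cfg$baseQ, droop = cfg$qualDroop)
            q2 <- vapply(nchar(m2), .qualString, character(1),
                         baseQ = cfg$baseQ, droop = cfg$qualDroop)
            idv <- sprintf("%s_read%06d", ids[i], seq_along(m1))
            r1Paths[i] <- file.path(dir, paste0(ids[i], "_R1.fastq"))
            r2Paths[i] <- file.path(dir, paste0(ids[i], "_R2.fastq"))
            writeFastq(list(id = idv, seq = m1, qual = q1), r1Paths[i])
            writeFastq(list(id = idv, seq = m2, qual = q2), r2Paths[i])
        }
    }

    sheet <- data.frame(sample_id = ids, r1 = r1Paths, r2 = r2Paths,
                        group = "simulated", stringsAsFactors = FALSE)
    if (!is.null(dir)) {
        write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        truthS <- do.call(rbind, sampleRows)
        write.table(truthS, file.path(dir, "truth_samples.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        write.table(do.call(rbind, variantRows),
                    file.path(dir, "truth_variants.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
    }
    list(reference = ref, sampleSheet = sheet,
         samples = do.call(rbind, sampleRows),
         variants = do.call(rbind, variantRows), config = cfg)
}

#' Simulate a cross-sample count matrix directly (no reads)
#'
#' Draws the same clone/common/unedited structure as [simulateDataset()] but
#' skips read emission and sequencing error, returning the true count matrix
#' as a [BarcodeExperiment-class]. Useful for studying the sharing and
#' selection stages at scale.
#'
#' @param cfg A [simulationConfig()].
#' @return A list with `be` (the [BarcodeExperiment-class]), `samples` and
#'   `variants` truth tables, and `reference`.
#' @export
simulateCounts <- function(cfg) {
    truth <- simulateDataset(cfg, dir = NULL)
    tabs <- split(truth$variants, truth$variants$sample_id)
    tabs <- lapply(tabs, function(t) t[t$count > 0L, c("variant", "count")])
    be <- BarcodeExperiment(tabs[unique(truth$variants$sample_id)])
    list(be = be, samples = truth$samples, variants = truth$variants,
         reference = truth$reference, config = truth$config)
}

#' Preset failure-mode configurations
#'
#' Two archetypes of uninterpretable experiments. `poor_labeling`: 95-98% of
#' alleles unedited, so almost no informative reads remain (the low-phi
#' warning fires). `dominant_shared_allele`: one editing pattern present at
#' VAF about 0.5 in 14 of 16 samples plus a ladder of lesser shared repair
#' products, so threshold selection is pushed to the top of the sweep grid
#' and extensive sharing persists after selection (theta_V-at-maximum,
#' Sharing-Factor and phi warnings fire).
#'
#' @param mode `"poor_labeling"` or `"dominant_shared_allele"`.
#' @param seed RNG seed for the returned config.
#' @return A [simulationConfig()].
#' @export
failureModeConfig <- function(mode = c("poor_labeling",
                                       "dominant_shared_allele"),
                              seed = 20200207L) {
    mode <- match.arg(mode)
    if (mode == "poor_labeling") {
        simulationConfig(nSamples = 16L, readsPerSample = 2000L,
                         uneditedFraction = 0.96, commonVafs = 0.01,
                         clonesMean = 3, clonesSd = 1, seed = seed)
    } else {
        simulationConfig(nSamples = 16L, readsPerSample = 2000L,
                         uneditedFraction = 0.15,
                         commonVafs = c(0.5, 0.002, 0.005, 0.01, 0.03,
                                        0.08, 0.15),
                         commonInSamples = c(14L, rep(16L, 6)),
                         clonesMean = 3, clonesSd = 1, seed = seed)
    }
}
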
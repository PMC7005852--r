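# End-to-end orchestration: reads -> align -> [umi] -> sharing -> select ->
# diversity, with per-stage outputs, structured per-sample counters and a
# machine-readable QC JSON. Each stage is also callable on its own through
# the module functions.

#' Read an amplicon reference from FASTA
#'
#' Loads the first record of a FASTA file as the amplicon sequence and
#' attaches the primer sequences.
#'
#' @param fasta Path to a FASTA file (first record used).
#' @param fwdPrimer,revPrimer Primer sequences (each 5'->3' on its own
#'   strand).
#' @return An [AmpliconReference-class].
#' @export
readAmpliconReference <- function(fasta, fwdPrimer, revPrimer) {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (length(ss) == 0L) stop("no sequences in ", fasta)
    AmpliconReference(as.character(ss[[1]]), fwdPrimer = fwdPrimer,
                      revPrimer = revPrimer,
                      name = if (!is.null(names(ss))) names(ss)[1]
                             else "amplicon")
}

#' Run the full informative-barcode pipeline
#'
#' Processes every sample of a sample sheet through read preprocessing,
#' optional UMI deduplication, global alignment and variant calling, then
#' performs the cross-sample analysis: theta_V sweep and common-variant
#' flagging, per-sample phi and clone counts, bootstrap sample selection,
#' post-selection QC and per-sample diversity. All stage outputs are written
#' under `outputDir` as TSV plus a QC JSON reporting the three quality
#' control quantities every experiment should state: the selected theta_V,
#' the post-selection mean Sharing Factor and the post-selection mean phi.
#'
#' @param sampleSheet Data.frame (or TSV path) with columns `sample_id`,
#'   `r1`, `r2` (and optionally `group`).
#' @param ref An [AmpliconReference-class].
#' @param outputDir Output directory (`NULL` = no files written).
#' @param thetaValues Threshold sweep grid.
#' @param vafCutoff Clone-defining VAF cutoff (default 0.02).
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (logged in the QC JSON).
#' @param umiLength UMI length (0 = standard protocol).
#' @param minScoreFrac Alignment acceptance floor.
#' @param ... Further arguments to [preprocessSample()].
#' @return A list with `be` (unreduced [BarcodeExperiment-class]), `sweep`
#'   ([SharingSweep-class]), `reduced` (at the selected theta_V), `phi`,
#'   `b002`, `boot` ([BootstrapResult-class]), `classes`, `postS`,
#'   `postPhi`, `warnings`, `cloneSets`, `fates` and `qc` (the QC list).
#' @export
runPipeline <- function(sampleSheet, ref, outputDir = NULL,
                        thetaValues = thetaSweepDefault(), vafCutoff = 0.02,
                        nBoot = 1000L, seed = 20200207L, umiLength = 0L,
                        minScoreFrac = 0.4, ...) {
    if (is.character(sampleSheet))
        sampleSheet <- read.delim(sampleSheet, stringsAsFactors = FALSE)
    if (nrow(sampleSheet) == 0L) stop("empty sample sheet")
    stopifnot(all(c("sample_id", "r1", "r2") %in% colnames(sampleSheet)))

    tabs <- list(); fates <- list()
    for (i in seq_len(nrow(sampleSheet))) {
        sid <- sampleSheet$sample_id[i]
        res <- tryCatch({
            pre <- preprocessSample(sampleSheet$r1[i], sampleSheet$r2[i],
                                    ref, umiLength = umiLength, ...)
            if (umiLength > 0L) {
                dedup <- deduplicateUmi(pre[c("id", "seq", "qual")], pre$umi)
                pre$seq <- dedup$seq
            }
            aln <- alignSample(pre$seq, ref, minScoreFrac = minScoreFrac)
            list(tab = tabulateSample(aln$variant),
                 fates = cbind(sample_id = sid, pre$fates,
                               aligned = sum(aln$aligned)))
        }, error = function(e)
            stop("sample '", sid, "' failed in preprocessing/alignment: ",
                 conditionMessage(e), call. = FALSE))
        tabs[[sid]] <- res$tab
        fates[[i]] <- res$fates
    }
    fates <- do.call(rbind, fates)
    be <- BarcodeExperiment(tabs)

    sweep <- sweepTheta(be, thetaValues)
    reduced <- reduceCounts(be, selectedTheta(sweep),
                            common = commonVariants(sweep))
    phi <- informativeFraction(reduced)
    b002 <- countClones(reduced, vafCutoff)
    boot <- bootstrapPhi(phi, b002, nReps = nBoot, seed = seed)
    classes <- classifySamples(phi, phiCI(boot)[1])
    highIds <- names(classes$high)
    postS <- if (length(highIds) >= 2L)
        .meanPairwiseS(.informativeCounts(reduced)[, highIds, drop = FALSE])
        else NA_real_
    postPhi <- classes$mean_high
    warnings <- qcWarnings(sweep, postS, postPhi)
    cloneSets <- lapply(colnames(be), function(sid)
        cloneSet(reduced, sid, vafCutoff = vafCutoff))
    names(cloneSets) <- colnames(be)

    qc <- list(selected_theta_v = selectedTheta(sweep),
               mean_sharing_factor = postS, mean_phi = postPhi,
               n_samples = ncol(be), n_high_phi = length(classes$high),
               n_low_phi = length(classes$low),
               bootstrap_estimate = phiEstimate(boot),
               bootstrap_ci = phiCI(boot),
               n_common_variants = length(commonVariants(sweep)),
               vaf_cutoff = vafCutoff, n_boot = as.integer(nBoot),
               seed = as.integer(seed), warnings = warnings)

    out <- list(be = be, sweep = sweep, reduced = reduced, phi = phi,
                b002 = b002, boot = boot, classes = classes, postS = postS,
                postPhi = postPhi, warnings = warnings,
                cloneSets = cloneSets, fates = fates, qc = qc)
    if (!is.null(outputDir)) writePipelineOutputs(out, outputDir)
    out
}

#' Write all pipeline outputs to a directory
#'
#' TSVs for the sweep table, the common-variant list, per-sample reduced
#' counts, the pairwise Sharing-Factor matrix, bootstrap replicates, sample
#' classification, per-sample clone tables and read fates, plus `qc.json`.
#'
#' @param run A [runPipeline()] result.
#' @param outputDir Destination directory (created if needed).
#' @return The directory, invisibly.
#' @export
writePipelineOutputs <- function(run, outputDir) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(x, name, rn = FALSE)
        write.table(x, file.path(outputDir, name), sep = "\t",
                    quote = FALSE, row.names = rn,
                    col.names = if (rn) NA else TRUE)
    tsv(sweepTable(run$sweep), "sweep.tsv")
    writeLines(commonVariants(run$sweep),
               file.path(outputDir, "common_variants.txt"))
    tsv(as.data.frame(variantCounts(run$reduced)), "reduced_counts.tsv",
        rn = TRUE)
    tsv(pairwiseSharing(.informativeCounts(run$reduced)),
        "pairwise_sharing.tsv", rn = TRUE)
    tsv(data.frame(rep = seq_len(run$boot@nReps),
                   mean_phi = run$boot@repMeanPhi,
                   sd_b002 = run$boot@repSdB), "bootstrap_replicates.tsv")
    tsv(data.frame(sample_id = names(run$phi), phi = unname(run$phi),
                   b002 = unname(run$b002[names(run$phi)]),
                   class = ifelse(names(run$phi) %in%
                                  names(run$classes$high), "high", "low")),
        "classification.tsv")
    clones <- do.call(rbind, lapply(run$cloneSets, function(cs)
        if (nrow(cloneTable(cs)))
            cbind(sample_id = cs@sampleId, cloneTable(cs))
        else NULL))
    if (!is.null(clones)) tsv(clones, "clones.tsv")
    tsv(run$fates, "read_fates.tsv")
    jsonlite::write_json(run$qc, file.path(outputDir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outputDir)
}
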
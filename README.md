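# cloneBarcodes

Quantifying hematopoietic clonal diversity from CRISPR amplicon barcodes
sequenced across many experimental replicates.

Lineage-tracing transgenes such as the GESTALT array (ten tandem Cas9
target sites in a single amplicon) are edited in the one-cell embryo;
the indel patterns ("barcodes") inherited by adult blood cells identify the
stem-cell clones feeding hematopoiesis. Reading those barcodes reliably
requires solving two problems that raw variant calling does not: DNA-repair
produces *stereotypical* indels that recur in unrelated animals and
therefore carry no lineage information, and animals vary widely in
labelling efficiency, so poorly labelled samples distort clone counts.
`cloneBarcodes` addresses both with statistics computed *across*
experimental replicates, plus everything upstream and downstream: read
processing, alignment, variant naming, sample selection, clone enumeration,
longitudinal matching, and a fully truth-tracked synthetic-data generator.

## The core statistics

For a variant with read counts $v_1, v_2$ in a pair of samples, the
sharing coefficient is $s = 2\min(v_1,v_2)/(v_1+v_2)$; pooled over the $m$
variants of the pair, the **Sharing Factor**

$$S \;=\; \frac{2\sum_{i=1}^m \min(b_{i1}, b_{i2})}{\sum_{i=1}^m (b_{i1}+b_{i2})}$$

is the proportion of the pair's reads attributable to shared variants
($S=0$ disjoint, $S=1$ identical). A variant whose proportion exceeds a
threshold $\theta_V$ in more than one animal is flagged **common**
(stereotypical) and aggregated out of the analysis. $\theta_V$ is selected
by sweeping a grid and maximising the product of the Z-scores of mean
$\phi$ (fraction of informative reads) and $1 - \bar S$. Samples are
then selected by a BCa bootstrap of mean $\phi$: those at or above the
lower 95% bound are kept, and clones are counted as informative barcodes
with VAF > 0.02 alongside Shannon entropy and the inverse Simpson index.

## Worked example

Simulate a six-animal study (1500 read pairs each, ~4 clones per animal,
20% unedited alleles, one stereotypical variant planted at VAF 0.05 in
every sample, realistic sequencing error) and run the whole pipeline:

```r
library(cloneBarcodes)

cfg   <- simulationConfig(nSamples = 6L, readsPerSample = 1500L, seed = 7L)
truth <- simulateDataset(cfg, dir = tempfile("demo"))
run   <- runPipeline(truth$sampleSheet, truth$reference,
                     nBoot = 1000L, seed = 7L)

run$sweep
#> SharingSweep over 8 thresholds
#>   selected theta_V = 0.001 (mean S = 0.0003006, mean phi = 0.760)
#>   common variants flagged: 1

round(run$phi, 3)
#>   S01   S02   S03   S04   S05   S06
#> 0.772 0.761 0.756 0.749 0.765 0.758

run$b002
#> S01 S02 S03 S04 S05 S06
#>   5   4   4   4   5   5

run$boot
#> BootstrapResult: mean phi = 0.760, 95% BCa CI [0.754, 0.766] (1000 reps)
#>   cor(replicate mean phi, replicate sd B) = 0.014

run$cloneSets[["S01"]]
#> CloneSet S01: 5 clones (VAF > 0.02), H' = 1.433, 2D = 3.583
```

Reading this output: the sweep flagged exactly the one planted
stereotypical variant and chose $\theta_V = 0.001$, below the planted VAF
of 0.05; after removing it and the unedited alleles, ~76% of reads per
sample are informative (the generator's truth is 0.2 unedited + 0.05
common, i.e. $\phi_{\text{true}} \approx 0.75$), residual sharing is
~3×10⁻⁴, and the clone counts per sample equal the generator's truth
table (`truth$samples$b002_true`) exactly. Sample S01 carries 5 clones
with an effective clone number of $e^{1.433} \approx 4.2$.

All stage outputs (sweep table, common-variant list, reduced counts,
pairwise sharing matrix, bootstrap replicates, classification, clone
tables, read fates, QC JSON) are written as TSV/JSON when `outputDir` is
given. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --sample-sheet samples.tsv \
    --reference amplicon.fa --fwd-primer ACGT... --rev-primer TGCA... \
    --out results/
```

It exits non-zero when QC warnings fire (high Sharing Factor, low mean
$\phi$, or threshold selection at the top of the sweep grid), so failed
experiments are machine-detectable.

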
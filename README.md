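# chromfusion

Downstream analysis of dual-antibody chromatin profiling (CUT&RUN /
CUT&Tag) experiments built around the KMT2A fusion-oncoprotein design:
antibodies against the KMT2A **N terminus** see both wild-type protein
and leukemic fusion oncoproteins, antibodies against the **C terminus**
see only the wild-type protein, so fusion binding sites stand out as
wide peaks with excess N-terminal signal. The package is written for
computational biologists analyzing such experiments (or building
simulation studies of them) and implements four connected stages:

1. **Fusion-site calling** — the per-peak N-over-C ratio

   ```
   NCR_i = log10( (n_i + min(N)) / (c_i + min(C)) ) * F((n_i + c_i)/2)
   ```

   where `min(N)`, `min(C)` are the minimum counts over the sample's
   peaks and `F` is the empirical CDF of per-peak mean signals (a
   shrinkage factor pulling low-coverage peaks toward 0). Peaks are
   classified by two-component Gaussian-mixture EM on NCR *and* on peak
   width; a site is a fusion call only when it exceeds the
   component-intersection cutoff of both mixtures. A sample without
   N/C asymmetry fails the partition check and yields zero calls.
   Gene-level target assignment, recurrent targets across a cohort,
   "missing targets" per sample, genomic-category Fisher comparisons,
   NCR clustering and PCA round out the stage.

2. **Bivalent promoters** — H3K4me3 and H3K27me3 counts in 2-kb TSS
   windows, per-mark mixture fits on `log10(count + 1)`, posterior-rule
   enrichment, and bivalency-fraction comparisons between gene groups
   with Fisher exact tests.

3. **Chromatin landscape** — peak-set merging, a lognormal-ECDF count
   filter (masks entries whose empirical CDF diverges > 5% from a
   fitted lognormal, below the fitted median), log/z-score transform,
   PCA (components > 1% variance), t-SNE at perplexity `round(sqrt(n))`,
   density-peak clustering, cluster profiles, per-region lineage
   assignment, and genome-coverage fractions.

4. **Single cells** — fragment/FRiP QC (>= 300 fragments and FRiP >=
   mean - 2 sd), 5-kb genome binning, binarized TF-IDF + truncated SVD
   (LSI) with depth-component removal, UMAP, gene scores with kNN
   diffusion imputation, mean-binned normalized dispersion, and
   covariance grouping of genes into anticorrelated programs.

Every stochastic step takes an explicit seed, and a family of
`simulate_*()` generators produces all inputs with planted ground truth,
so each stage is validated end-to-end.

## Worked example

```r
library(chromfusion)

ann   <- make_annotation(400, c(chrA = 2.5e7, chrB = 2.5e7), seed = 1)
sim   <- simulate_fusion_experiment(ann, n_peaks = 1000, seed = 2)
calls <- call_fusion_sites(sim$peaks, sim$signals$n_count,
                           sim$signals$c_count, seed = 2)
calls
#> Fusion-site calls over 1000 peaks
#>   NCR mixture:   partitioned
#>   width mixture: partitioned
#>   fusion sites called: 50

calls$ncr_fit
#> Two-component Gaussian mixture fit (n = 1000 )
#>   weights: 0.950 / 0.050
#>   means:   -0.007062 / 0.5641
#>   sds:     0.04333 / 0.06778
#>   logLik 1499.093 after 3 iterations (converged: TRUE)
```

The NCR mixture separates a majority null component centered at ~0 from
a 5% fusion component centered at 0.56 ≈ log10(4) — the planted 4-fold
N-over-C enrichment. All 50 planted fusion peaks are recovered:

```r
called <- calls$table$peak_id[calls$table$is_fusion]
sum(called %in% sim$truth$fusion_peaks)
#> [1] 50

head(calls$table[calls$table$is_fusion, c("peak_id", "ncr", "width")], 3)
#>     peak_id       ncr width
#> 1 peak00001 0.5388864 16617
#> 2 peak00002 0.5240527 13031
#> 3 peak00003 0.4818967 18789

assign_targets(sim$peaks, calls$table$is_fusion, ann)[1:4]
#> [1] "gene00003" "gene00004" "gene00008" "gene00009"
```

Called peaks are wide (13–19 kb here, versus ~1.5 kb narrow peaks) with
NCR near log10(4), and map onto their host genes as fusion targets.
`run_pipeline(default_config(seed = 1))` chains all four stages on
synthetic inputs and writes TSV outputs plus a manifest of parameters,
seeds and content digests; identical configurations reproduce
byte-identical outputs.

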
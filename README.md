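# clonefate

Clone-fate analysis of DNA-barcoded tumour cells under immune selection.

## What this package is for

Cellular DNA barcoding tags every founder cell of a tumour cell line with a
heritable random nucleotide insert, so that sequencing read counts of each
barcode track the abundance of that cell's clone over time. When barcoded
leukaemic cells are co-cultured with natural killer (NK) cells in replicate
wells, the trajectory of every clone reveals how it responds to immune
pressure: most clones are killed, some are intrinsically resistant, some
are indifferent, and a few acquire resistance stochastically during the
co-culture and expand in a single well only.

`clonefate` implements the full analysis path from raw barcode-amplicon
reads to per-clone fate calls, together with a synthetic co-culture
generator that produces FASTQ reads, count matrices and ground truth, so
every stage is testable without any sequencing data:

1. **Extraction** — each 64-bp read is searched for the fixed anchors
   `GAACACTCGAGATCAG` (head) and `TGTGGTATGATGT` (tail); the 21-nt insert
   between them is the barcode. Reads with a missing anchor, an insert of
   the wrong length, or an uncalled base (`N`) are discarded (about 15% in
   practice).
2. **Reference** — barcodes with at least 100 summed reads across the
   viral-library samples form the whitelist; observed counts are
   restricted to it.
3. **Count assembly** — technical replicates are merged by summing;
   barcodes must be detected in all three tumour-alone wells at the
   reference timepoint with at least 9 reads in total; counts are
   normalized by size factors and a shifted log2 transform
   `log2(count/sf + 1)`.
4. **Statistics** — per sample, Shannon diversity `H = -Σ p log p`; per
   clone, a negative-binomial Wald test of NK vs alone abundance
   (method-of-moments dispersion, BH-adjusted p-values) and the
   variability statistic `v = log2((max(x)+1)/(min(x)+1))` across the
   replicate wells of each arm.
5. **Fate calls** — a rule-based decision tree, first match wins:
   * **primary resistant**: `padj < 0.05` and `log2FC >= 1`;
   * **eliminated**: `padj < 0.05` and `log2FC <= -1`;
   * **static**: `v <= 0.5` alone and `v < 1` under NK;
   * **secondary resistant**: `v <= 0.5` alone, `v >= 1` under NK, and
     abundance high in exactly one of the three wells;
   * **other**: none of the above.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures (category heatmap, diversity
points, secondary-resistance bubble plot).

## Worked example

```r
library(clonefate)

cfg <- generator_config(n_clones = 500, seed = 42)
run <- run_pipeline(cfg)   # synthesizes FASTQ, re-extracts, classifies
run
#> <clone_run> 500 clones simulated, 490 in reference, 490 retained (seed 42)
#>   mean discard fraction: 0.150
#>   fate proportions at TP2
#> # A tibble: 5 × 5
#>   timepoint category                n proportion proportion_excl_other
#>   <chr>     <fct>               <int>      <dbl>                 <dbl>
#> 1 TP2       eliminated            297     0.606                 0.606
#> 2 TP2       primary_resistant      82     0.167                 0.167
#> 3 TP2       static                 97     0.198                 0.198
#> 4 TP2       secondary_resistant    14     0.0286                0.0286
#> 5 TP2       other                   0     0                    NA
```

Reading this output: of the 500 simulated clones, 490 passed the library
reference and detection filters; 15.0% of synthetic reads were discarded
by the extraction filters, matching the generator's malformation rate. At
the late timepoint the decision tree calls 60.6% of clones eliminated,
16.7% primary resistant, 19.8% static and 2.9% secondary resistant — close
to the generating fate weights of this run's random draw. `glance(run)`
additionally reports a ~19% Shannon-diversity drop in the NK arm,
`tidy(run)` returns per-clone calls joined with the ground truth, and
`fate_recovery(run)` cross-tabulates calls against generating fates.

```r
autoplot(run)                # category-ordered abundance heatmap
plot_secondary_bubbles(run)  # single-well expansions
```

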
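# qsipflow

Quantitative stable isotope probing (qSIP) analysis of density-gradient 16S
rRNA amplicon data, for microbial ecologists quantifying which taxa
assimilate a ^13^C-labeled substrate — and how much — in incubation
experiments with CsCl density-gradient fractionation.

DNA built from ^13^C is denser than unlabeled DNA. After isopycnic
centrifugation, each gradient is collected as density fractions (15 per
replicate in the emulated design), and each fraction contributes a measured
buoyant density, a qPCR total of 16S copies, and an amplicon library. For
every OTU, qsipflow computes the copy-weighted average buoyant density

    W = Σ ρᵢ yᵢ / Σ yᵢ,   yᵢ = (countᵢ / depthᵢ) · total_copiesᵢ,

in the control (`W_light`) and labeled (`W_lab`) incubations, and converts
the shift into an excess atom fraction (EAF) of ^13^C through the standard
GC/molar-mass model:

    GC      = (W_light − 1.646057) / 0.083506
    M_light = 0.496·GC + 307.691
    M_lab   = (W_lab / W_light) · M_light
    ΔM_max  = 9.974564 − 0.4987282·GC
    A       = (M_lab − M_light) / ΔM_max · (1 − 0.01111233)

Bootstrap resampling of biological replicates (n = 1,000) gives each OTU a
median EAF and a 90% percentile CI; an OTU is called ^13^C-labeled when the
CI lies strictly above zero. Around this core the package provides the
per-replicate abundance filter (> 12 reads per replicate) and
blank-vs-sample contaminant rule, cross-substrate overlap categories with
min–max EAF normalization, phylum-level summaries, phylogenetic-signal
tests (Blomberg's K with permutations, Pagel's λ with a likelihood-ratio
test), a biomass back-calculation from DNA content, and a generative
simulator of the whole experiment that provides ground truth for every
stage.

## Worked example

Simulate a complete one-substrate experiment (3 labeled + 3 control
replicates, 15 fractions each) and run the full pipeline:

```r
library(qsipflow)
sim <- simulate_qsip_experiment(
  simulation_config(n_taxa = 40, depth = 5000), seed = 7)
res <- qsip_run(sim$dataset, out_dir = "qsip_out",
                contaminants = sim$contaminants, tree = sim$tree,
                n_boot = 300, seed = 7)
head(res$eaf[, c("otu_id", "boot_median", "ci_low", "ci_high", "labeled")])
#> # A tibble: 6 × 5
#>   otu_id   boot_median  ci_low ci_high labeled
#>   <chr>          <dbl>   <dbl>   <dbl> <lgl>
#> 1 OTU_0001     0.254    0.241   0.270  TRUE
#> 2 OTU_0002     0.217    0.201   0.240  TRUE
#> 3 OTU_0003     0.0557   0.0468  0.0640 TRUE
#> 4 OTU_0004     0.127    0.113   0.144  TRUE
#> 5 OTU_0005     0.110    0.100   0.118  TRUE
#> 6 OTU_0006    -0.00652 -0.0406  0.0276 FALSE
```

Each row is one OTU: `boot_median` is its bootstrap-median ^13^C excess
atom fraction (0 = unlabeled, 0.25 ≈ a quarter of its DNA carbon newly
derived from the labeled substrate), the CI bounds are the 90% percentile
interval over replicate resamples, and `labeled` is the CI-above-zero
call — OTU_0006's interval spans zero, so it is not called labeled.
Negative medians are reported as-is; they are evidence of no labeling, not
an error. Comparing against the simulator's truth table, the median
absolute recovery error here is 0.011. `res$summary` aggregates labeled
OTUs by phylum (unweighted mean of bootstrap medians, read shares), and
`res$signal` carries the Blomberg's K / Pagel's λ report for the EAF trait
on the supplied tree.

A point EAF for a single density shift:

```r
eaf_point(w_light = 1.700, w_lab = 1.706)
#> [1] 0.1113733
```

For two substrates, run the pipeline once per substrate and combine with
`assign_categories()` / `paired_overlap_scatter()`; see the methods
vignette (`vignettes/qsip-methods.Rmd`) for the model, the simulator's
noise structure, and the package's calibration limits.

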
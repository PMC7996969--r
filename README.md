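# lfq4d

Label-free quantification of ion-mobility LC–MS proteomics data in R.

Trapped-ion-mobility mass spectrometers (TIMS-TOF, PASEF acquisition)
place every MS1 peak in a four-dimensional space: retention time, m/z,
inverse reduced ion mobility (1/K₀), and intensity. `lfq4d` turns
FDR-filtered peptide identifications plus per-run MS1 peak data into
peptide-ion and protein intensity tables:

1. **4-D indexing** — peaks are binned by mobility (half-open 0.002 1/K₀
   bins), m/z-sorted per bin, and RT-gridded, so a tolerance query
   `(|Δm/z| ≤ 10 ppm, |Δ1/K₀| ≤ 0.05, RT ∈ [t₁, t₂])` touches only a
   sliver of the data.
2. **XIC tracing** — per mobility bin, an extracted ion chromatogram is
   built around each PSM's retention time and Gaussian-smoothed; the
   apex is the smoothed maximum in the seed window and boundaries walk
   outward to 1% of apex or a valley.
3. **4-D features and isotopes** — adjacent mobility bins with coherent
   RT bounds merge into one feature; up to three features are extracted
   per ion at m/z + k·1.003355/z (k = 0, 1, 2), and the ion intensity is
   the sum of their raw volumes, reported only when at least
   `min_isotope_count = 2` isotopes were traced.
4. **Piecewise normalization** — against the run with the most
   quantified ions, each run's log-intensities are split into 10
   equal-count ranges and shifted by the median of the log-ratios within
   one median absolute deviation, removing constant and
   intensity-dependent run biases.
5. **Protein roll-up and reports** — proteins keep ≥ 2 quantified ions;
   the top 3 ions present in ≥ 50% of experiments are summed per
   experiment; outputs include per-run ion CSVs, the ion matrix, an
   MSstats-compatible CSV, replicate CVs, and (for two-condition
   designs) a per-organism log2-ratio benchmark summary.

A ground-truthed synthetic generator (separable Gaussian ions on the
RT × 1/K₀ grid, log-normal abundances, isotope envelopes, decoy noise,
per-run distortions, a three-organism two-condition benchmark at mixing
ratios 1:1 / 2:1 / 1:4) makes the whole pipeline testable without
proprietary raw files. Everything is tibble-in/tibble-out and
pipe-friendly, with `tidy()`/`glance()`/`autoplot()` methods on fitted
objects.

## Worked example

Simulate a small three-organism benchmark (90/20/20 proteins × 3 ions,
two conditions × three replicates, 10% replicate noise, rotating run
biases), quantify it end to end, and read off the recovered mixing
ratios:

```r
library(lfq4d)

sim        <- make_design(n_proteins = c(90, 20, 20), seed = 42)
experiment <- simulate_experiment(sim, sim_config(seed = 42))
res        <- quantify_experiment(experiment)

res$ratio_summary
#> # A tibble: 3 × 5
#>   organism      n_proteins median_log2_ratio iqr_log2_ratio median_fold
#>   <chr>              <int>             <dbl>          <dbl>       <dbl>
#> 1 E. coli               20           -2.05            0.119       0.241
#> 2 H. sapiens            90           -0.0121          0.151       0.992
#> 3 S. cerevisiae         20            0.980           0.151       1.97

glance(res$proteins)
#> # A tibble: 1 × 3
#>   n_proteins n_experiments median_cv
#>        <int>         <int>     <dbl>
#> 1        130             6    0.0653
```

The organisms were mixed at A:B = 1:1 (H. sapiens), 2:1 (S. cerevisiae),
and 1:4 (E. coli); the recovered median folds (0.992, 1.97, 0.241)
land on the programmed ratios despite noise and per-run intensity
distortions, and the median replicate CV is ~7% at 10% ion-level noise.
`autoplot(res$ratio_summary)` draws the benchmark-style ratio scatter,
`autoplot(res$norm_model)` the per-run correction profiles.

File-based workflows use `run_simulate()` / `run_quantify()` (TSV, mzML
with ion mobility, or the package's binary peak cache), and a thin CLI
wraps them:

```sh
inst/cli/lfq4d simulate --out sim/ --seed 7
inst/cli/lfq4d quant --peaks sim/A_1.peaks.tsv,...,sim/B_3.peaks.tsv \
    --psms sim/psms.tsv --design sim/design.tsv --out out/
```

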
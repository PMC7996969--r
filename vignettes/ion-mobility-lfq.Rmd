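---
title: "Indexed 4-D label-free quantification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexed 4-D label-free quantification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

lfq4d quantifies peptide ions from trapped-ion-mobility LC-MS (TIMS/PASEF)
MS1 data. Every centroided MS1 point lives in a four-dimensional space —
retention time (RT, minutes), m/z (Th), inverse reduced ion mobility
(1/K~0~, Vs/cm²), and intensity — and quantification is
identification-directed: features are extracted only at coordinates given
by FDR-filtered peptide-spectrum matches (PSMs). This vignette documents
the model, the tunable parameters, the numerical choices, and what the
synthetic validation data do and do not establish.

## The extraction model

**Indexing.** The mobility dimension is digitized into half-open bins
`[k·w, (k+1)·w)` with `w = 0.002` 1/K~0~; a value on a bin boundary
belongs to the upper bin, so assignment is deterministic. Within each bin
peaks are sorted by m/z (stably, so ties keep file order) and carry their
ordinal on the run's scan-cycle RT grid. A tolerance query touches only
the bins overlapping the mobility window and binary-searches the sorted
m/z inside each, then applies the exact triple condition: relative m/z
deviation within the ppm tolerance, absolute mobility deviation within
the 1/K~0~ tolerance, RT inside a closed interval. The test suite holds
the index to set-equality with a brute-force linear scan on randomized
runs.

**Tracing.** For a PSM at (m/z, 1/K~0~, RT), each mobility bin in the
window yields an extracted ion chromatogram over the scan-cycle grid:
all cycles within the RT tolerance of the PSM's retention time, extended
outward cycle by cycle for as long as matching peaks continue, tolerating
up to `max_gap_cycles` consecutive empty cycles. Cycles with several
matching peaks sum their intensities; interior empty cycles are
zero-filled. The RT tolerance is thus a *seed window* for apex search;
tracing may extend beyond it to complete a peak whose apex sits near the
window edge.

**Smoothing, apex, boundaries.** Each trace is convolved with a discrete
Gaussian kernel (σ in scan cycles, truncated at ±4σ, renormalized to unit
sum; at the trace ends the kernel is renormalized over its in-range
support so a constant trace smooths to itself — the price is that mass
conservation holds only for signal at least two kernel half-widths from
the ends). The apex is the maximum smoothed point inside the seed window;
ties break toward the PSM RT, then toward earlier RT, so output is
deterministic. Boundaries walk outward from the apex until the smoothed
intensity falls below `boundary_fraction` of the apex (default 1%), rises
again after descending (a valley split between co-eluting peaks), or the
trace ends.

**Clustering and volume.** Bounded traces in adjacent mobility bins
(consecutive ordinals, one empty bin of slack) whose RT bounds contain
the seed trace's apex merge into one 4-D feature anchored at the bin
containing the precursor mobility. The feature's mobility extent is the
merged bin range; its apex mobility is the apex-intensity-weighted mean
of member bin centers. The volume is the plain sum of *raw* member
intensities inside the seed trace's RT bounds — smoothing only steers
apex and boundary placement, never the reported quantity.

**Isotopes.** Up to three features are extracted per ion at
`mz + k·1.003355/z` for k = 0, 1, 2 (the ¹³C–¹²C mass difference over
charge). The +1/+2 apexes must land within one scan cycle of the
monoisotopic apex; incoherent features are discarded as likely chimeras.
The ion intensity is the summed volume of the recovered isotope features,
reported only when at least `min_isotope_count` (default 2) of them have
positive volume — otherwise the value is missing, never zero.

## Normalization

Runs are normalized against the *reference run*, the one with the most
quantified ions (ties: first in design order). For each other run, using
only ions quantified in both, log-ratios `r = log(run) − log(ref)` are
computed; the run's own quantified log-intensities are split into
`n_ranges = 10` equal-count (quantile) ranges; per range the additive
log-space correction is the median of the log-ratios within one raw
median absolute deviation (MAD with scale constant 1, reading "one median
absolute deviation" literally) of the range median. Ranges with fewer
than three shared ions inherit the global MAD-filtered median. Applying
the model subtracts each cell's range correction in log space; the
reference run is never altered and missing cells stay missing.

Choices the underlying description leaves open, decided here:

* **Equal-count, not equal-width ranges**, defined on each run's own
  intensities: keeps per-range sample sizes balanced so range medians are
  equally stable across the intensity scale.
* **MAD filtering per range**, around the per-range median.
* **Natural log internally**; reports label corrections in log2 and range
  bounds in log10, the units practitioners read.
* **Idempotence is exact only for order-preserving corrections** (e.g. a
  constant fold): a general piecewise model can reorder ions across
  range boundaries, so refitting after applying yields corrections that
  are near zero rather than identically zero. The tests assert exact
  idempotence for the constant case and < 0.02 refit corrections for a
  smooth rank-based distortion.

Median-of-log-ratio normalization presumes that most ions shared with the
reference are unchanged. In a mixture where a regulated organism
dominates part of the intensity range, per-range medians track that
organism and its ratios compress toward zero — a real failure mode of
this family of methods, visible in any mixed-proteome benchmark when the
unchanged background is not the majority.

## Protein roll-up and reports

Proteins with fewer than `min_ions = 2` distinct quantified ions are
discarded. Eligible ions are those quantified in at least
`min_experiment_fraction = 50%` of experiments (condition × replicate
cells); the `top_n = 3` by total intensity across experiments are summed
per experiment. Ions shared by several proteins count toward each and the
protein is flagged. Replicate precision is the sample (n−1) coefficient
of variation per condition. The MSstats export writes one row per
quantified (ion, run) cell with the MS1 sentinel convention (FragmentIon
and ProductCharge empty, label type L). For two-condition designs the
ratio report gives, per organism, the count, median, and IQR of
per-protein `log2(mean_A/mean_B)` (condition means over non-missing
replicates — the usual benchmark convention).

## The synthetic generator

Real TIMS raw data are proprietary and too large for unit-scale
validation, so the generator emits ground-truthed 4-D runs with the
statistical structure the pipeline assumes:

* each ion is a **separable Gaussian** in RT (σ ∈ U(0.05, 0.10) min) and
  mobility (σ ∈ U(0.003, 0.006) 1/K~0~) on a discrete grid (0.1 min
  cycles, 0.001 1/K~0~ spacing over a 40-min gradient), per isotope, with
  envelope relatives from a crude carbon-count model of peptide mass;
* peptides are random residue strings whose m/z comes from the actual
  residue monoisotopic masses; mobility increases with m/z with a charge
  offset and scatter, mimicking the m/z–mobility correlation of real
  TIMS data;
* base abundances are log-normal (meanlog log(3e5), sdlog 2 — several
  orders of magnitude, as in a real proteome); condition mixing ratios
  scale whole organisms; one multiplicative log-normal noise factor per
  ion per run sets replicate variability (default CV 10%);
* points below a noise floor (default 50) are dropped, uniform decoy
  peaks (default 2000/run) are added, and one PSM per ion is emitted
  within ±0.2 min of the true apex, clamped into the emitted extent —
  exercising the seed-window logic without guaranteeing apex-centered
  seeds;
* per-run distortions emulate intensity-dependent experimental error:
  a constant fold, or the monotone rank multiplier
  `1 + 0.5·rank(I)/n`; the default experiment rotates
  none/constant/intensity-dependent across runs so normalization has
  real work to do.

The three-organism benchmark layout fixes A:B mixing ratios of 1:1
(H. sapiens), 2:1 (S. cerevisiae), and 1:4 (E. coli) with three
replicates per condition. The default composition is 900/200/200
proteins × 3 ions: human-majority, close to the entry shares of the
combined three-organism sequence database behind the published
benchmark, and a precondition for the normalization model (see above).
Everything is a deterministic function of (design, config, seed); the
ground-truth table carries per-isotope emitted volumes and true apex
coordinates so downstream assertions are mechanical.

What the generator does **not** model: chromatographic tailing and peak
asymmetry, mobility–RT covariance within one ion, interfering
near-isobaric ions, centroiding artifacts, missed or false
identifications, and detector saturation. Passing tests therefore
establish algorithmic correctness under the stated assumptions, not
end-to-end performance on real raw data.

## Numerical choices and degenerate inputs

* m/z windows are symmetric in ppm around the query center; mobility
  windows are absolute; RT intervals are closed (scan-cycle times are
  discrete, so half-open intervals would drop boundary cycles).
* The smoothing kernel default σ = 1 scan cycle matches peak widths of
  3–6 s sampled at ~0.1-min cycles.
* An all-zero or absent trace is a *no-feature* result, not an error;
  a missing intensity is a value (`NA`) that propagates through
  normalization and roll-up via pairwise-complete statistics.
* Within-run duplicate PSMs of one ion collapse to the first by table
  order before tracing — one traced feature per distinct ion per run.
* Doubles round-trip exactly through the TSV writers (17 significant
  digits out, `strtod` back in) and bit-exactly through the binary
  cache, which is version-tagged and refuses files from other versions.

## Validation scale

The checked-in validation uses problem sizes a laptop handles in
minutes: randomized index checks at ~10³–10⁵ peaks per run, boundary and
roll-up oracles at hundreds of randomized cases, and the full
three-organism benchmark at its default 1,300 proteins / 3,900 ions / 6
runs (~2 × 10⁶ peaks per run), which recovers the programmed organism
medians within ±0.15 log2 units under 10% replicate noise and per-run
distortions. `scripts/acceptance.R` re-runs that benchmark end to end
from a seed and writes the recovered medians as JSON.

## Known limitations

* No match-between-runs: an ion missing a confident identification in a
  run is missing from that run.
* No untargeted feature finding, charge deconvolution, or isotope-pattern
  fitting; extraction trusts the PSM coordinates.
* Protein grouping/inference is out of scope; shared ions are counted
  for every listed protein and flagged.
* The mzML reader covers the MS1 + ion-mobility subset it documents
  (spectrum-level mobility value or per-peak mobility array), not the
  full standard; the pepXML reader is similarly minimal.
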
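# ferrodecay

Normalization and mRNA decay modelling for targeted (NanoString-style)
transcript count panels from iron-limitation / iron-resupply experiments
in phytoplankton.

When iron is resupplied to an iron-starved diatom culture, transcripts for
iron-starvation proteins collapse within minutes. Whether that collapse
reflects transcriptional shut-off or mRNA degradation is resolved by
comparing the decline after iron addition with the decline after
transcription arrest (actinomycin D). This package provides the complete
analysis for that design, for anyone working with hybridization-based
count panels and time-resolved treatments:

* **Four-stage count normalization** — positive-control geometric-mean
  scaling, reference-lane probe calibration across plates, probe
  attenuation correction from a titration run, and housekeeping
  normalization with a dedicated *per-timepoint* scheme for
  transcription-inhibited samples (whose housekeeping transcript itself
  decays), with a full factor audit trail.
* **Broken-line decay modelling** — per treatment,
  `y = α + B·min(t−t₀,0) + B′·max(t−t₀,0) + e` on natural-log counts,
  with the changepoint t₀ profiled out by RSS minimization (observed-time
  candidates plus golden-section refinement on every interval); half-life
  `t½ = ln2 / k` with `k = −B`.
* **Decay-rate comparisons** — joint multi-treatment fit with fixed
  per-treatment changepoints and a likelihood-ratio test
  `n·ln(RSS₀/RSS₁) ~ χ²(1)` of slope equality (F-test variant available).
* **Summaries** — low/high fold changes with Welch tests and BH
  adjustment, Spearman correlation matrix with clustering order, PCA
  sample scores, growth rates.
* **A seeded simulator** of the full experimental design (7 treatments,
  short- and long-term sampling grids, spike-in ladder, attenuation,
  loading and lane effects) so every stage is testable against ground
  truth without instrument data.

## Worked example

```r
library(ferrodecay)

sim  <- simulate_experiment(seed = 17)          # raw counts + titration
norm <- normalize_pipeline(sim$counts, hk_probe = "NUCL_HK",
                           titration = sim$titration)

hl <- fit_decay_table(norm$matrix)              # rec, actd, actd_fe arms
subset(hl, treatment == "actd" & gene %in%
            c("FLDA1", "MNSOD", "CREGX2", "PETF", "PETE"),
       select = c(gene, changepoint_min, half_life_min))
#>     gene changepoint_min half_life_min
#>    FLDA1         30.0000       7.40071
#>    MNSOD        230.5674      87.45402
#>   CREGX2         60.0000      37.30297
#>     PETF        240.0000      93.94389
#>     PETE        240.0000      67.47607

summarize_half_lives(subset(hl, treatment == "actd"),
                     exclude = c("MNSOD", "CREGX2", "PETF", "PETE"))$average
#> [1] 7.75751
```

Fast iron-responsive transcripts decay with half-lives near 8 min under
transcription arrest; the four long-lived transcripts sit between roughly
40 and 95 min in a single simulated run (their changepoints fall near the
end of the 6-h window, so single-run estimates are noisier — medians over
replicated runs land within 15% of truth). The panel average excluding the
long-lived set is ~8 min.

```r
lrt <- compare_decay_rates(norm$matrix, c("rec", "actd"))
subset(lrt, gene == "FLDA1", select = c(gene, beta1_a, beta1_b, p_adjusted))
#>    gene     beta1_a     beta1_b   p_adjusted
#>   FLDA1  -0.1390695  -0.09365955 5.159403e-09
```

The iron-recovery decline of FLDA1 is steeper than its pure-degradation
rate — evidence that iron addition does more than stop transcription.
The control comparison (`c("actd", "actd_fe")`) shows no adjusted
significance for any gene.

The `analysis/` directory runs the same sequence as numbered scripts
(`01_simulate.R` … `05_summaries.R`), each writing its tables under
`results/` and printing a short narrative of what it found.

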
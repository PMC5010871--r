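# kinfit

Mechanistic parameterization of kinomic peptide-array time series.

Kinome peptide arrays (e.g. the PamGene PamChip platform) record the
phosphorylation of 144 peptides by the active kinases in a lysate, as
background-subtracted fluorescence over successive reaction cycles. Each
peptide yields a ~13-point progress curve, and downstream kinomic analyses
live or die by how those curves are reduced to parameters. kinfit is for
researchers analysing such arrays — or any short enzymatic progress curves —
who want mechanistic parameters with built-in quality control and an honest
account of their reproducibility.

## The models and the method

Three candidate models are fitted per peptide, with signal *y* against
cycle number *c*:

| id | model | parameters |
|----|-------|------------|
| `eq1` | y = y₀ + y_max·(1 − e^(−k·c)) | y₀, y_max, k |
| `eq2` | y = y₀ + y_max·(1 − e^(−k·(c−c₀))) | y₀, y_max, k, c₀ |
| `eq3` | y = y_max·v_i·(c−c₀) / (y_max + v_i·(c−c₀)) | y_max, v_i, c₀ |

`eq3` is linear accumulation at initial rate v_i saturating at capacity
y_max — the rational-hyperbolic alternative to first-order kinetics, and
the model this package exists to make usable. With 13 points per curve it
also buys an 11% gain in residual degrees of freedom over `eq2`
(`residual_df_gain()` returns 11.11).

Fitting is a deterministic coordinate-wise adaptive-step least-squares
search (defaults: 1000 sweeps max, initial step 1/100 of each start,
6e-5% minimum SSE improvement; accepted steps grow ×1.2, rejected steps
reverse and halve). Goodness of fit combines R² with an exact one-sided
Wald–Wolfowitz runs test on residual signs; the QC gate requires runs-test
p ≥ 0.05 — jointly, for all three models. Replicate reproducibility of any
fitted parameter (k, y_max, v_i, or the derived early slope
v_ini = y_max·k·e^(−k·(35−c₀))) is summarised as the Spearman correlation of
quantile-transformed within-set replicate pairs. A seeded synthetic-chip
generator with known ground truth makes all of this testable without
instrument data.

## Worked example

```r
library(kinfit)
set.seed(42)

cyc <- seq(5, 65, by = 5)
sig <- eval_kinetic("eq3", c(ymax = 300, vi = 8, c0 = 2), cyc) +
  rnorm(13, 0, 8)
fit <- fit_series(cyc, sig, "eq3")
fit
#> <kin_fit> model eq3
#>       ymax         vi         c0
#> 316.432802   7.891934   1.208865
#>   SSE 862.103 | R^2 0.9748 | runs p 0.9662 | 283 sweeps (SSE_CHANGE)
```

The true rate v_i = 8 is recovered as 7.89 from data with noise; the
runs-test p of 0.97 says the residual signs look random, so the model is
not systematically wrong. `tidy(fit)`, `glance(fit)`, `augment(fit)` and
`autoplot(fit)` give the parameter table, the one-row summary, the
residuals and a plot.

Whole-chip analysis is data-frame-first and pipeable:

```r
chip <- simulate_chip(chip_sim_config(n_peptides = 144, n_replicates = 6,
                                      seed = 11))
fits <- fit_kinetics(chip$data, models = c("eq2", "eq3"))
replicate_correlation(fits, "eq3", "vi")
#> # A tibble: 1 × 4
#>   model parameter n_pairs correlation
#>   <chr> <chr>       <int>       <dbl>
#> 1 eq3   vi           2136       0.962
replicate_correlation(fits, "eq2", "k")
#> # A tibble: 1 × 4
#>   model parameter n_pairs correlation
#>   <chr> <chr>       <int>       <dbl>
#> 1 eq2   k            1918       0.774
```

Across 6 technical replicates sharing true kinetics, the hyperbolic rate
v_i (q–q Spearman 0.96) is far more reproducible than the exponential rate
k fitted to the same curves (0.77) — the central practical argument for the
hyperbolic parameterization. `run_pipeline(data)` wraps fitting plus the QC
gate and prints per-model pass counts; `read_kinetics()` /
`write_kinetics()` handle wide and long CSV layouts; `inst/cli/kinfit`
exposes `fit`, `simulate`, `qc`, `repro` and `version` subcommands for
shell use.

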
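# karyobias

Karyomorphometric descriptors and inter-observer bias analysis for plant
cytogenetics.

When several people measure the chromosomes of the *same* metaphase plate
— even on the same microphotograph, with the same software — they do not
get the same karyotype descriptors. `karyobias` is a toolkit for
quantifying that problem and for probing its proposed mechanism, a
systematic overestimation of chromosome **short arms**:

* **Descriptors** (`karyotype_params()`): from per-chromosome long/short
  arm lengths \(L_i, S_i\) (with \(CL_i = L_i + S_i\),
  \(CI_i = S_i/CL_i\)) it computes
  * THL \(= \sum_i CL_i / p\) — total haploid length (ploidy \(p\)),
  * M\_CA \(= \overline{100\,(L_i - S_i)/CL_i}\) — mean centromeric
    asymmetry (%),
  * CV\_CL \(= 100\,\mathrm{sd}(CL)/\overline{CL}\) and
    CV\_CI \(= 100\,\mathrm{sd}(CI)/\overline{CI}\) (%).
* **Inter-observer analysis** (`build_study_table()`, `trait_cv()`,
  `pearson_matrix()`, `scatter_export()`): per-observer descriptor table,
  across-observer CV per trait (which descriptors are most
  observer-sensitive), and the Pearson correlation matrix with exact
  two-sided t-based p values. The diagnostic signature of short-arm
  overestimation is a *negative* r(THL, M\_CA): reading short arms too
  long inflates THL and deflates M\_CA simultaneously.
* **Observer simulator** (`make_true_karyotype()`, `simulation_config()`,
  `simulate_study()`): a forward error model with an observer-level
  lognormal calibration factor, per-arm lognormal noise, and a shared
  half-normal short-arm bias, applied either additively (outline read too
  long — THL grows) or as a length-conserving centromere-misplacement
  transfer (THL preserved). `replicate_study_correlation()` runs the
  Monte-Carlo experiment that separates the two.
* **IO and CLI**: long-format measurement CSVs in and analysis bundles
  out (`read_measurements()`, `write_study_outputs()`), YAML simulation
  configs, ggplot2 `autoplot()`/`plot_trait_*()` figures, broom-style
  `tidy()`/`glance()`, and a thin command-line wrapper
  (`inst/cli/karyobias` — subcommands `params`, `study`, `simulate`).

## Worked example

The package ships a synthetic 15-observer study of one 2n = 18 plate
(`inst/extdata/synthetic_observer_study.csv`, generated by the package's
own simulator — it is *not* real measurement data):

```r
library(karyobias)

path <- system.file("extdata", "synthetic_observer_study.csv",
                    package = "karyobias")
study <- build_study_table(read_measurements(path), ploidy = 2)

trait_cv(study) |> dplyr::select(trait, mean, sd, cv)
#> # A tibble: 4 × 4
#>   trait  mean    sd    cv
#>   <chr> <dbl> <dbl> <dbl>
#> 1 THL    40.4 2.15   5.33
#> 2 M_CA   22.0 2.08   9.45
#> 3 CV_CL  19.0 0.615  3.24
#> 4 CV_CI  16.0 0.918  5.75

tidy(pearson_matrix(study))
#> # A tibble: 6 × 5
#>   trait_x trait_y      r         p significance
#>   <chr>   <chr>    <dbl>     <dbl> <chr>
#> 1 THL     M_CA    -0.857 0.0000441 highly significant
#> 2 THL     CV_CL   -0.525 0.0445    marginally significant
#> 3 M_CA    CV_CL    0.662 0.00719   highly significant
#> 4 THL     CV_CI   -0.580 0.0235    marginally significant
#> 5 M_CA    CV_CI    0.719 0.00250   highly significant
#> 6 CV_CL   CV_CI    0.390 0.150     not significant
```

Reading the output: THL varies by 5.3% and M\_CA by 9.5% across these
simulated observers, and the THL–M\_CA correlation is strongly negative
(r = −0.86, p < 0.001) — exactly the coupling a shared short-arm
overestimation produces, since this dataset was simulated with the additive
bias switched on. `autoplot(study)` draws the per-trait boxplots with
jittered observer values; `plot_trait_scatter(study)` draws THL against
M\_CA with the fitted r in the subtitle.

To analyse real data, lay the measurements out one chromosome per row with
columns `plate_id, observer_id, chromosome_index, long_arm, short_arm`
(any consistent length unit; `col_map` renames third-party headers) and
run the same three calls — or from a shell:

```sh
Rscript inst/cli/karyobias study measurements.csv --highlight obs15 -o results/
```

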
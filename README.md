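# somspectra

Predicting **soil organic matter** (SOM, g kg⁻¹) from **Vis-NIR
reflectance spectra** (350–2500 nm) with optimal band-combination spectral
indices, PCA features, and random-forest regression.

SOM darkens soil in the visible and adds weak NIR overtone bands that
compete with much stronger water (1400/1900 nm) and clay (≈2200 nm)
absorptions. Rather than modeling all 401 preprocessed bands, the package
searches **every combination** of two or three wavelengths under ten
algebraic index forms and keeps the combination whose correlation with SOM
is both strong and stable:

* two-band forms: SI = Rᵢ+Rⱼ, DI = Rᵢ−Rⱼ, PI = Rᵢ·Rⱼ, RI = Rᵢ/Rⱼ,
  NDI = (Rᵢ−Rⱼ)/(Rᵢ+Rⱼ)
* three-band forms: TBI1 = Rᵢ/(Rⱼ+Rₖ), TBI2 = (Rᵢ+Rⱼ)/Rₖ,
  TBI3 = (Rᵢ−Rⱼ)/(Rⱼ−Rₖ), TBI4 = (Rᵢ−Rⱼ)/(Rᵢ+Rⱼ−2Rₖ),
  TBI5 = Rᵢ+Rⱼ−2Rₖ

The search scans the Pearson correlation r of every ordered wavelength
combination against calibration SOM (401² or 401³ cells; Rcpp core), keeps
the top 1 % by |r|, and selects the candidate minimizing |r_cal − r_val|.
Models are evaluated with R², RMSE and **RPIQ** = IQR(observed validation
SOM)/RMSE_val, categorized A (>4.05), B (>3.37), C (>2.70), D (≤2.70).

The pipeline is driven end-to-end by a tested synthetic-data generator that
reproduces the statistical structure of a 168-sample arid-region soil
survey (right-skewed SOM: mean 7.46, SD 8.75, range 0.26–45.71 g kg⁻¹),
including a planted SOM-linked absorption at 2200 nm so that feature
recovery is verifiable. See the methods vignette
(`vignettes/som-band-search.Rmd`) for the generative model and all design
choices.

## Worked example

```r
library(somspectra)

out <- run_som_pipeline(config = synth_config(seed = 1),
                        grid_step = 5,    # canonical 401-band preprocessing
                        search_step = 10, # exhaustive search on a 10 nm grid
                        n_trees = 1000, seed = 1)

out$selected
#>    form wl_i wl_j wl_k  r_cal  r_val      err  r_max
#> 1    SI  420  430   NA -0.575 -0.631 5.68e-02 -0.587
#> 2    DI 2210 2220   NA -0.947 -0.948 7.31e-04  0.947
#> 3    PI  410  420   NA -0.527 -0.586 5.83e-02 -0.533
#> 4    RI  900 1040   NA -0.960 -0.960 1.06e-05  0.975
#> 5   NDI  850 1050   NA -0.946 -0.946 1.85e-05  0.974
#> 6  TBI1  850 1070 1200 -0.946 -0.946 7.91e-08  0.992
#> 7  TBI2  850  890 1100 -0.951 -0.951 3.29e-08 -0.992
#> 8  TBI3  970  640  480  0.990  0.990 5.13e-07 -0.994
#> 9  TBI4  770  880  410 -0.973 -0.973 2.44e-07  0.991
#> 10 TBI5 2200  970 1150 -0.791 -0.791 4.99e-08  0.984

out$summary
#>         strategy m_try r2_cal rmse_cal r2_val rmse_val rpiq category
#> 1DV          1DV     4  0.968    1.488  0.868    2.600 2.19        D
#> 2DI          2DI     3  0.982    1.062  0.948    1.623 3.50        B
#> 3DI          3DI     4  0.989    0.848  0.986    0.909 6.25        A
#> 1DV+2DI  1DV+2DI     6  0.985    1.003  0.950    1.603 3.55        B
#> 1DV+3DI  1DV+3DI     8  0.989    0.839  0.985    0.940 6.05        A
#> 2DI+3DI  2DI+3DI     7  0.989    0.840  0.984    0.964 5.90        A
```

Reading the output: the selected difference index (DI) lands at
2210/2220 nm, on the planted SOM-linked clay-region band (the generator's
known truth); the ratio-type indices latch onto the visible/NIR darkening
slope. `r_cal`/`r_val` are the calibration/validation Pearson correlations
of the selected combination, `err` their absolute difference (the selection
objective) and `r_max` the strongest calibration correlation the form
reached anywhere on the grid. In the strategy table, validation RMSE
(g kg⁻¹) improves with variable dimension — 1DV (PCA scores, RPIQ
category D) < 2DI (B) < 3DI (A) — the study's headline ordering, and the
`m_try` column shows the out-of-bag-tuned forest hyperparameter per
strategy.

Key user-facing functions:

| step | functions |
|---|---|
| simulate | `synth_config()`, `generate_dataset()`, `write_dataset()` |
| preprocess | `trim_wavelengths()`, `gaussian_downsample()`, `savgol_smooth()`, `continuum_remove()`, `preprocess_spectra()` |
| split / describe | `rank_order_split()`, `describe_values()`, `anova_p()` |
| features | `fit_pca()`, `project_pca()`, `scan_index()`, `top_candidates()`, `select_optimal()`, `search_indices()` |
| model | `fit_linear()`, `tune_mtry()`, `fit_rf()`, `run_all_strategies()` |
| evaluate / report | `r_squared()`, `rmse()`, `rpiq()`, `rpiq_category()`, `interval_bands()`, `render_report()` |

A thin command-line driver is installed at
`inst/scripts/som_pipeline.R`; it accepts a wide spectra CSV (`--data`) or
a YAML generator config (`--config`), plus `--search-step`, `--fraction`,
`--n-trees`, `--seed`, `--out` and `--figures`.

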
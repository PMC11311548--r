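# oxishelf

Shelf-life kinetics and FTIR chemometrics for lipid oxidation in stored
foods.

`oxishelf` is for food scientists running **accelerated storage studies**:
samples (the motivating system is green coffee beans, dry- and
honey-processed) are stored at several temperatures, the lipid-oxidation
markers **PV** (peroxide value, meq/kg oil) and **TBARS** (malondialdehyde,
nmol/g) are assayed over time, and each sample is fingerprinted by
**ATR-FTIR**. The package covers the full analysis chain:

1. **Assay arithmetic** — moisture %, PV from titration volumes, TBARS/MDA
   from baseline-corrected absorbance (`moisture_percent()`,
   `peroxide_value()`, `tbars_mda()`).
2. **Kinetics** — per-temperature zero-order (`y = y0 + kt`) and
   first-order (`ln y = ln y0 + kt`) fits, Arrhenius regression
   `ln k = ln k0 − Ea/(RT)`, and closed-form shelf life
   `SL(T) = (ln y_c − ln y0) / (k0 e^{−Ea/RT})` to a stated endpoint
   (`fit_zero_order()`, `fit_first_order()`, `fit_arrhenius()`,
   `predict_shelf_life()`, `shelf_life_table()`).
3. **Spectral preprocessing** — standard normal variate and
   Savitzky–Golay first derivative on the physical wavenumber axis
   (`snv()`, `first_derivative()`, `preprocess()`).
4. **Chemometrics** — NIPALS PLS1 with leave-one-out cross-validation
   (RMSECV, R², RPD), auto-prediction, Wold VIP scores with VIP ≥ 1 band
   selection, and PCA (`pls_fit()`, `loocv()`, `auto_predict()`,
   `vip_scores()`, `select_bands()`, `pca()`).
5. **Synthetic data** — a tested generator emulating the 2-process ×
   3-temperature × 5-timepoint × 3-replicate design (78 spectra, 26
   distinct samples) with known kinetic ground truth and band-level
   spectral structure, so the whole pipeline is verifiable without any
   external data (`synthetic_config()`, `make_study()`).
6. **Pipeline & CLI** — an end-to-end runner with CSV reports and a JSON
   manifest (`run_pipeline()`, `cli_main()`; script in `inst/cli/`).

## Worked example

Simulate a study, fit the shelf-life table, and cross-validate a PLS
model linking spectra to TBARS:

```r
library(oxishelf)

study <- make_study(synthetic_config(seed = 1))
study
#> <synthetic_study> 78 spectra, 12 oxidation series (seed 1)

tab <- shelf_life_table(study$oxidation, endpoints = c(PV = 2, TBARS = 12))
subset(tab, response == "PV")
#>  process response temperature_C order r_squared shelf_life_days sd_days endpoint_used
#>       DP       PV            30 first     0.831            60.4  18.046             2
#>       DP       PV            40 first     0.956            32.7   3.136             2
#>       DP       PV            50 first     0.994            18.4   1.661             2
#>       HP       PV            30  zero     0.871            49.8   6.577             2
#>       HP       PV            40  zero     0.964            22.1   0.997             2
#>       HP       PV            50  zero     0.964            10.3   0.609             2
```

Each row is one process × temperature cell: the selected kinetic order,
its per-temperature fit R², the Arrhenius-based shelf life in days to the
stated endpoint (here PV = 2 meq/kg, echoed in `endpoint_used`), and an
SD from refitting the whole chain per replicate. Shelf life shrinks with
temperature because the generating activation energy is positive.

```r
pre <- preprocess(study$spectra)            # SNV + 1st derivative
cv <- loocv(pre$absorbance, study$truth$latents$TBARS, n_lv = 10)
cv
#> <cv_result> scheme=loocv  RMSE=2.125  R2=0.81  RPD=2.309
```

RMSECV is in the response's own units (nmol MDA/g); RPD > 2 is the
conventional "usable calibration" region.

VIP band selection is run on SNV-only spectra (a derivative is zero at a
band apex — see the methods vignette):

```r
fit <- pls_fit(snv(study$spectra)$absorbance, study$truth$latents$PV, n_lv = 10)
bands <- select_bands(vip_scores(fit), study$spectra$wavenumbers)
subset(bands, n_channels >= 8)
#>  low_cm1 high_cm1 n_channels
#>     3769     4000        121
#>     3287     3339         28
#>     2906     2944         21
#>     2827     2881         29
#>     1721     1769         26
#>     ...
```

The intervals 2827–2881 and 1721–1769 cm⁻¹ recover the two
oxidation-linked bands planted at 2854 and 1745 cm⁻¹; the remaining
intervals sit on the other (static) bands and on the signal-free grid
edges, where after SNV the residual variation is scatter-dominated —
band tables should always be read against the raw spectrum.

The full pipeline with all CSV reports and a manifest:

```r
run_pipeline(list(synthetic = list(seed = 1), seed = 1), "out/")
# out/: shelf_life.csv, pls_summary.csv, vip_scores_*.csv, vip_bands_*.csv,
#       observed_predicted_*.csv, pca_scores.csv, manifest.json
```

or from the command line:

```sh
Rscript inst/cli/oxishelf.R simulate --seed 1 --out data/
Rscript inst/cli/oxishelf.R kinetics --oxidation data/oxidation.csv --out report/
```

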
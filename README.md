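# thioltrace

Computational workflow for charge-tagged thiol metabolomics by LC-MS/MS.

Free thiols (cysteine, homocysteine, glutathione, cysteinyl-glycine,
γ-glutamyl-cysteine, N-acetyl-cysteine, cysteamine) are polar, poorly
ionizing analytes. A practical route to measuring them in serum and
cerebrospinal fluid is derivatization with a permanently charged
triphenylphosphonium probe: the tag alkylates the sulfhydryl group, boosts
electrospray response, and — because every derivative shares the tag — all
labeled thiols fragment to one common diagnostic product ion that can be
used to recognize them in MS/MS data without standards. `thioltrace`
implements the downstream computation for such an assay:

* **Mass model.** Hill-notation formula parsing and monoisotopic
  arithmetic over a packaged atomic-mass table. The derivative cation is
  strictly additive: for a probe cation **P**⁺ (default C₂₅H₂₈BrNP, m/z
  452.1137), thiol **T** and leaving group HBr,

  *m/z*(T-derivative) = [ *m*(P) + *m*(T) − *m*(HBr) − *m*ₑ ] / 1

  with the electron mass *m*ₑ always corrected. The shared diagnostic
  fragment is the sulfur-retaining tag ion C₂₅H₂₉NPS⁺ at m/z 406.1753.
* **Screening.** Detection of the diagnostic fragment in MS2 spectra
  (mzML via Bioconductor `mzR`, or MGF), inference of the native thiol
  mass from the precursor, annotation against a packaged 97-entry compound
  library (one row per candidate identity for co-eluting, mass-degenerate
  features), and (RT, m/z) deduplication.
* **Quantification.** Internal-standard calibration by OLS (optionally
  1/x-weighted), inverse prediction with range flags, LOD/LOQ at
  signal-to-noise 3:1 and 10:1 (3σ/slope, 10σ/slope), replicate CVs
  (sample SD / mean × 100) and spike recoveries
  ((spiked − unspiked)/spike × 100), assembled into a validation report.
* **Cohort statistics.** Group-mean fold changes, pooled (Student's) or
  Welch t-tests with significance stars, NIPALS PLS-DA on autoscaled data
  with S-plot (covariance vs correlation with the first score), z-scored
  average-linkage heatmap clustering, and a volcano stage for protein
  tables.
* **Classification.** Repeated stratified train/test evaluation
  (default 200 trials, 14 train / 6 test) of a 500-tree random forest and
  an L2 logistic regression, with normalized feature importances and full
  seed determinism.
* **Synthetic data.** Seeded generators for labeled MS2 runs with decoy
  spectra, calibration series, log-normal two-group cohorts with
  configured fold changes, and protein tables with planted effects.

## Worked example

```r
library(thioltrace)

# 1. The monitored-transition list from the probe model
transitions_table()
#>    analyte     formula theoretical_mz product_mz printed_mz ppm_vs_printed
#> 1       CA      C2H7NS       449.2175   406.1753   449.2172           0.63
#> 2      Cys    C3H7NO2S       493.2073   406.1753   493.2072           0.23
#> 3      Hcy    C4H9NO2S       507.2230   406.1753   507.2202           5.45
#> 4      GSH C10H17N3O6S       679.2714   406.1753   679.2752          -5.64
#> 5      Nac    C5H9NO3S       535.2179   406.1753   535.2181          -0.42
#> 6  Cys-Gly  C5H10N2O3S       550.2288   406.1753   550.2288          -0.04
#> 7 gGlu-Cys  C8H14N2O5S       622.2499   406.1753   622.2416          13.35
```

The theoretical precursor for each derivative sits next to the assay's
monitored value; Cys, Nac and Cys-Gly agree below 1 ppm, while the Hcy,
GSH and γ-Glu-Cys monitored values are recorded observations several ppm
from additive theory and are carried as such, not forced to agree.

```r
# 2. Screen a synthetic MS2 run against the packaged library
lib <- load_library()                       # 97 catalogued thiol metabolites
spectra <- gen_ms2_run(lib, seed = 1, n_decoys = 20)
ann <- screen_run(spectra, lib)
sum(!is.na(ann$record_index))
#> [1] 97                                    # every record, no decoys

# 3. Calibration with detection limits
cal <- gen_calibration_series(table2_curves(), noise_sd = 0, seed = 1)
lod_loq(fit_calibration(cal[cal$analyte == "Cys", ], analyte = "Cys"),
        noise_sd = 5.5e-6)
#> <calibration_curve> Cys: y = 0.0022x + 4e-05  (R2 = 1.0000, n = 21, unweighted)
#>   range 0.024-500 pmol  LOD 7.5 fmol  LOQ 25 fmol

# 4. Cohort comparison on a simulated serum cohort (30 + 30)
co <- gen_cohort(fig_cohort_params("serum"), seed = 1)
r <- two_sample_t(co, "gGlu-Cys")
sprintf("fold %.2f, t = %.1f, p = %.2g %s",
        r$fold_change, r$t_stat, r$p_value, r$stars)
#> [1] "fold 1.78, t = 14.4, p = 7.6e-21 ***"

# 5. Repeated-split classifier on a separable 11-protein cohort
pt <- gen_protein_table(n_features = 11, n_planted = 5, effect_size = 5,
                        n_per_group = 10, seed = 8)
repeated_eval(pt, eval_config("rf", n_trials = 200, seed = 7))
#> <thiol_eval> rf, 200 trials (train 14 / test 6, seed 7)
#>   accuracy 100.00% (SD 0.00%)
#>   top features: prot011, prot009, prot008
```

A command-line front end covering the same stages
(`screen | quant | compare | classify | simulate | transitions`) is
installed at `inst/cli/thioltrace`.

## Scope

The package operates on peak lists, peak-area tables and concentration
tables. Chromatographic peak picking, isotope-pattern deconvolution,
vendor raw-file reading, acquisition control and pathway-enrichment
analysis are out of scope. See `vignettes/thioltrace-methods.Rmd` for the
model, defaults, numerical choices and limitations.
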
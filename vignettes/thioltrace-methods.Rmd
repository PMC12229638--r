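---
title: "thioltrace: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thioltrace: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thioltrace)
```

This vignette is the package's own account of the science it implements:
the derivative-mass model, the screening and annotation logic, the
validation arithmetic, the multivariate and classification stages, what
the synthetic-data generators emulate, and the choices made where the
design was genuinely open.

## The derivative-mass model

A permanently charged triphenylphosphonium probe alkylates free
sulfhydryl groups. The probe is handled as three pieces of composition: a
cation (default C~25~H~28~BrNP, charge +1), a neutral leaving group
(HBr), and a diagnostic tag fragment. Conjugation is strictly additive on
elemental composition:

$$ \text{derivative}^+ = \text{probe cation} + \text{thiol} - \mathrm{HBr} $$

All masses are monoisotopic sums over a packaged atomic-mass table
(CODATA/NIST values, at least 7 decimals) — packaged rather than queried,
so every m/z in the package is bit-reproducible. Ion m/z always carries
the electron-mass correction ($m_e = 0.00054858$ Da); the probe's
recorded cation m/z is reproduced within 1 ppm only with the correction
applied, so it is never optional. Internally full precision is kept; 4
decimals are used for display.

Applying the model to the seven targeted thiols reproduces the monitored
precursors for cysteamine, cysteine, N-acetyl-cysteine and
cysteinyl-glycine within 1 mDa (the latter three below 1 ppm). The
monitored values for homocysteine, glutathione and γ-glutamyl-cysteine
deviate 5–14 ppm from additive theory; they are treated as recorded
experimental observations, carried alongside theory in
`transitions_table()` and never "corrected" to match.

The diagnostic fragment common to all derivatives retains the analyte's
sulfur on the tag side. Its composition (default C~25~H~29~NPS, cation
m/z 406.1753) is inferred from neutral-loss bookkeeping: for every
targeted thiol, derivative minus fragment equals the analyte residue lost,
and the test suite checks this closes below 10⁻⁶ Da. Because the
fragment's composition is an inference, it stays configurable in
`probe_spec()`, and the whole probe definition can be swapped for other
reagents.

The ppm convention is $(obs - theo)/theo \times 10^6$, signed, theory in
the denominator. Recomputing the packaged library's mass-error column
from its printed m/z and formulas agrees with the printed values within
0.5 ppm wherever the printed row is self-consistent (a long tail of
library rows shares one placeholder error value; those are carried as
printed but not used as checks).

## Screening and annotation

`screen_run()` composes four steps: find the diagnostic peak in each MS2
spectrum, infer the native thiol mass from the precursor, annotate
against a compound library, deduplicate.

*Reporter search* takes the most intense peak within tolerance of the
reporter m/z, subject to a minimum relative intensity against the base
peak. Defaults — 10 ppm reporter tolerance, 5 ppm library annotation
tolerance, 0.5 min retention-time window, 5% intensity floor — are chosen
to be loose against the library's own 4-decimal rounding (±5 ppm printed
errors occur) and tight against decoys; the source data name no values.
All are configurable.

*Annotation* compares the observed precursor against each library
record's **listed** m/z, not against theory recomputed from its formula.
The library catalogues observed, adducted features whose printed mass
errors reach ±5 ppm; matching against recomputed theory would reject
correctly measured features at the 5 ppm tolerance. The declared adduct
is metadata (it selects the displayed adduct and supports a native-mass
fallback for probe-conjugate records, for which a permanently charged
derivative would be an [M]⁺ species — the library is ambiguous on this
point, so both matching modes exist and neither is asserted as ground
truth). Records listing several adducts are expanded to one candidate per
adduct.

Annotation has two modes. `"best"` returns the single candidate
minimizing |ppm| (ties: smaller ΔRT, then lower record index). `"all"` —
what `screen_run()` uses — returns one row per candidate identity within
tolerance. The packaged library contains co-eluting, mass-degenerate
entries (four identities share RT 6.27 / m/z 209.0596); a mass
spectrometer cannot distinguish them, and the catalogue style is one row
per candidate identity, which only the `"all"` mode can reproduce.

*Deduplication* groups annotations by record and merges clusters linked
by chains of (RT, m/z) proximity — connected components of the proximity
graph, computed by union-find, with the highest-relative-intensity member
as representative. The m/z window defaults to 10 ppm, twice the
annotation tolerance: the library twice catalogues the same compound 1.1
ppm apart, and with ±3 ppm synthetic jitter two observations of one
record can sit ~7 ppm apart; a 10 ppm window keeps one row per record in
that worst case. Distinct records never merge.

## Validation arithmetic

Calibration is ordinary least squares of the analyte/IS area ratio on
amount (`stats::lm`), unweighted by default because the assay's
calibration equations are simple linear fits; 1/x weighting is a flag
(zero-amount points are dropped from a weighted fit). $R^2 = 1 -
SS_{res}/SS_{tot}$. On exact linear data the packaged equations are
reproduced to numerical precision with $R^2 = 1$.

LOD and LOQ implement the S/N 3:1 and 10:1 definitions as $3\sigma/b$ and
$10\sigma/b$ with $b$ the slope and $\sigma$ a supplied blank-ratio SD —
noise estimation from raw chromatograms is out of scope, so $\sigma$ is
an input. The ratio LOQ/LOD is 10/3 by construction; the packaged,
*printed* LOD/LOQ values do not all satisfy that ratio and are therefore
treated as experimental observations, not as targets of the formula.
Amounts are pmol throughout; LOD/LOQ are displayed in fmol (×1000).

CV uses the sample (n−1) standard deviation. Recovery is
$(\text{spiked} - \text{unspiked})/\text{spike} \times 100$ and is
invariant under common rescaling of all three inputs. Mean recovery is
the arithmetic mean of per-level recoveries, which reproduces the
packaged panel's printed means from its printed per-level values to
0.01 percentage points (recomputing per-level recoveries from the printed
*measured means* instead shifts them a few hundredths of a point — the
panel's own rounding).

## Cohort statistics

Fold change is the ratio of arithmetic group means (case/control), with
the favoured group reported so "x times higher" is well defined in either
direction. Means rather than medians: the source material does not say
which it used, and the generator's log-normal cohorts make the ratio of
means equal the configured fold in expectation, which keeps the estimator
interpretable. Serum and CSF are analysed per matrix, mirroring the
per-matrix reporting.

The two-sample test defaults to the pooled-variance Student's t (the test
the workflow names), two-sided, with Welch by flag. No multiple-testing
correction by default — the reported criterion is raw p < 0.05 —
Benjamini–Hochberg is a clearly labelled flag. Stars: \*, \*\*, \*\*\*
at 0.05, 0.01, 0.001.

PLS-DA is NIPALS on autoscaled (unit-variance) features with the class
coded ±1: weights from $X^Ty$, scores $t = Xw$, deflation of X and y
after each component. With a univariate response the inner loop converges
in one pass, but the iteration (max 500, tolerance 10⁻¹⁰) is retained for
generality. Initialization is from y, so the fit is deterministic; each
component's sign is fixed by making its largest-magnitude weight
positive. Three components mirror the 3-D score plot. Constant features
are dropped from autoscaling with a warning. Score vectors are mutually
orthogonal by construction (tested to 10⁻⁶ relative), and the test suite
checks the fit against an independent SVD-based PLS1 oracle and against
`mixOmics::pls` scores. The S-plot reports, per feature, covariance
(magnitude) and correlation (reliability, bounded in [−1, 1]) with the
first score vector on autoscaled data.

The heatmap stage z-scores each feature across samples (exactly mean 0 /
SD 1) and clusters features and samples by average-linkage agglomeration
on Euclidean distance via `stats::hclust` — the standard metabolomics
default, chosen because the source is silent. The volcano stage runs the
t-test per protein and reports log2 fold changes (natural-scale ratios
are used everywhere else); down-regulation is a negative log2 FC.

## Classifier evaluation

The repeated-split protocol mirrors a 10 + 10 sample cohort: stratified
draws of 14 training and 6 test samples (7/7 and 3/3), 200 trials,
accuracy as the single headline metric, with per-trial accuracies and
summed confusion counts retained. The split description in the source
material is internally inconsistent (80/20 of 20, "fourteen … six",
"tested on 20 maintenance samples"); the implementation makes the sizes
configurable with defaults 14/6 from the 200-trial protocol.
Standardization is fitted on the training fold only, to avoid leakage.
Models: 500-tree random forest (`randomForest`, √p features per split)
and ridge logistic regression (`glmnet`, α = 0, fixed λ = 1 — "L2, unit
regularization"). Feature importance is Gini mean decrease in impurity
(rf) or |standardized coefficient| (lr), normalized to sum to 1. The
whole evaluation is a pure function of (data, config, seed).

The headline accuracy of the original patient cohort is not reproducible
without its protein data, which is not deposited; the package instead
asserts properties on synthetic cohorts: ≥95% mean accuracy on a strongly
separated 11-feature cohort (5 SD effects on 5 features), chance level
(40–60%) under label permutation, and bit-identical reports for identical
seeds.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions for every test:

* **MS2 runs** (`gen_ms2_run`): one spectrum per library record at the
  record's listed m/z under *bounded uniform* mass error (default ±3 ppm)
  and Gaussian RT jitter (SD 0.05 min), a reporter peak at 80% of the
  base peak, 5–20 random filler peaks kept 50 ppm clear of the reporter,
  plus reporter-free decoys whose fillers are rejection-sampled away from
  the reporter window — guaranteeing a zero false-positive floor.
  Bounded rather than Gaussian m/z error is deliberate: it makes
  "jitter < tolerance/2 implies exact library recovery" a theorem rather
  than a probability, which is what the round-trip tests assert.
* **Cohorts** (`gen_cohort`): log-normal per-analyte concentrations
  (positive, right-skewed, as concentration data are), CV interpreted on
  the natural scale (sdlog = √log(1+CV²)), default 15% — a typical
  biological between-subject spread, chosen once since the source states
  none — with the case geometric mean scaled by the configured fold. The
  packaged parameter file carries the reported serum and CSF ratios with
  their directions and uses the unspiked endogenous levels of the
  recovery panel as control baselines.
* **Calibration series** (`gen_calibration_series`): the packaged
  equations plus Gaussian ratio noise, triplicates per level, 7
  geometrically spaced levels over each analyte's calibrated range.
* **Protein tables** (`gen_protein_table`): Gaussian background (mean 10,
  SD 1, so abundances stay positive) with planted case-group shifts and
  the planted indices attached for truth-aware tests.

What passing tests on these generators shows is that the *arithmetic and
algorithms* are correct under controlled conditions. They do not emulate
chromatographic peak shapes, isotope envelopes, heteroscedastic detector
noise, matrix effects, missing values, or batch drift — so the tests say
nothing about robustness to those features of real data.

Problem sizes used by the default test run were chosen to keep the suite
quick while leaving no estimator undersampled: 10,000 null cohorts for
type-I calibration, 100 seeds for fold-change recovery, 1,000 spectra for
the screening oracle, 200 classifier trials.

## Numerical and degenerate-input choices

* Composition subtraction that would go negative is an error; a
  sulfur-free "thiol" is a warning but still computed.
* `find_diagnostic` on an empty peak list returns no hit, not an error;
  an empty run screens to an empty table.
* Degenerate t-tests: both groups constant and equal gives t = 0, p = 1;
  constant and unequal floors the p-value at the smallest double rather
  than erroring.
* Inverse calibration never clips: below-/above-range amounts are flagged.
* Zero-CV cohort generation short-circuits to exact constants instead of
  exponentiating a zero-variance normal draw.
* Dedup tie-breaks are deterministic (cluster representative by highest
  relative intensity; output sorted by RT, then m/z).
* Retention times are minutes everywhere; mzML/MGF seconds are converted
  at the boundary. m/z is written with 6 decimals, intensities at full
  float precision.
* Library serum/CSF flags are carried as printed; the per-matrix
  catalogue split is typographically ambiguous in the source and is not
  asserted anywhere.

## Known limitations

Only singly charged species are handled (the packaged library is
charge 1 throughout). MS1/XIC peak picking, isotope-pattern scoring and
acquisition control are out of scope, as are GO/KEGG enrichment and
network inference downstream of the volcano stage. The ridge logistic
model uses a fixed penalty rather than tuned regularization —
hyperparameter search is deliberately excluded from the evaluation
protocol. The native-mass fallback annotation mode is provided but
unvalidated against real conjugate spectra.
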
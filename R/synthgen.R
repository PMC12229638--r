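# Seeded generators for every input the toolkit consumes: labeled-thiol
# MS2 runs with decoys, calibration series, cohort tables, protein tables.
# Every generator is a pure function of (parameters, seed).

#' Generate a synthetic MS2 run from a compound library
#'
#' One reporter-positive spectrum per library record: the precursor is the
#' record's m/z under a bounded, uniform relative mass error of up to
#' `mz_jitter_ppm` ppm (bounded rather than Gaussian, so a jitter below
#' half the matching tolerance guarantees exact library recovery);
#' retention time gets Gaussian jitter of SD `rt_jitter` minutes. Each
#' spectrum carries the jittered diagnostic reporter peak at
#' `reporter_rel_intensity` of the base peak plus 5-20 random filler
#' peaks, none of which falls within 3x the default screening tolerance of
#' the reporter. `n_decoys` additional spectra contain filler peaks only,
#' so they can never produce a reporter hit.
#'
#' @param library Compound library (see [load_library()]).
#' @param probe A [probe_spec()] providing the reporter m/z.
#' @param seed Integer seed.
#' @param mz_jitter_ppm Half-width of the uniform m/z error (ppm).
#' @param rt_jitter Retention-time jitter SD (minutes).
#' @param reporter_rel_intensity Reporter intensity as fraction of base peak.
#' @param n_decoys Number of reporter-free decoy spectra.
#' @param n_replicates Spectra per library record.
#' @return List of [ms2_spectrum()] objects.
#' @export
gen_ms2_run <- function(library, probe = probe_spec(), seed = 1L,
                        mz_jitter_ppm = 3, rt_jitter = 0.05,
                        reporter_rel_intensity = 0.8, n_decoys = 0L,
                        n_replicates = 1L) {
  stopifnot(nrow(library) >= 1L, mz_jitter_ppm >= 0, rt_jitter >= 0,
            reporter_rel_intensity > 0, reporter_rel_intensity <= 1,
            n_decoys >= 0, n_replicates >= 1)
  set.seed(seed)
  reporter <- probe$diagnostic_fragment_mz
  exclusion_ppm <- 50  # filler peaks keep well clear of the reporter window
  filler <- function() {
    k <- sample(5:20, 1L)
    mz <- numeric(0)
    while (length(mz) < k) {
      cand <- stats::runif(k, 50, 1000)
      cand <- cand[abs(cand - reporter) / reporter * 1e6 > exclusion_ppm]
      mz <- c(mz, cand)
    }
    mz <- mz[seq_len(k)]
    list(mz = mz, intensity = stats::runif(k, 10, 1000))
  }
  out <- list()
  for (i in seq_len(nrow(library))) for (r in seq_len(n_replicates)) {
    jit <- stats::runif(1, -mz_jitter_ppm, mz_jitter_ppm) * 1e-6
    pmz <- library$mz[i] * (1 + jit)
    rt <- library$rt_min[i] + stats::rnorm(1, 0, rt_jitter)
    fp <- filler()
    rep_jit <- stats::runif(1, -mz_jitter_ppm, mz_jitter_ppm) * 1e-6
    rep_mz <- reporter * (1 + rep_jit)
    rep_int <- reporter_rel_intensity * max(fp$intensity)
    out[[length(out) + 1L]] <- ms2_spectrum(
      spectrum_id = sprintf("lib%03d_rep%d", library$index[i], r),
      precursor_mz = pmz, retention_time = rt,
      mz = c(fp$mz, rep_mz), intensity = c(fp$intensity, rep_int))
  }
  for (d in seq_len(n_decoys)) {
    fp <- filler()
    out[[length(out) + 1L]] <- ms2_spectrum(
      spectrum_id = sprintf("decoy%03d", d),
      precursor_mz = stats::runif(1, 100, 900),
      retention_time = stats::runif(1, 0, 10),
      mz = fp$mz, intensity = fp$intensity)
  }
  out
}

#' Reported cohort fold changes and baselines
#'
#' Loads the packaged per-matrix parameter file: for each targeted thiol
#' the printed two-group ratio, the group it favours, and the endogenous
#' baseline used as the control geometric mean.
#'
#' @param matrix `"serum"` or `"csf"`.
#' @return data.frame: analyte, fold (printed ratio), higher_in,
#'   control_gm_pmol, case_over_control (ratio on the case/control scale).
#' @export
fig_cohort_params <- function(matrix = c("serum", "csf")) {
  matrix <- match.arg(matrix)
  y <- yaml::read_yaml(system.file("extdata", "fig7_foldchanges.yaml",
                                   package = "thioltrace"))[[matrix]]
  data.frame(analyte = names(y),
             fold = vapply(y, function(e) e$fold, numeric(1)),
             higher_in = vapply(y, function(e) e$higher_in, character(1)),
             control_gm_pmol = vapply(y, function(e) e$control_gm_pmol,
                                      numeric(1)),
             case_over_control = vapply(y, function(e)
               if (e$higher_in == "PCNSL") e$fold else 1 / e$fold, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a synthetic two-group cohort table
#'
#' Per-analyte log-normal concentrations: the control group has geometric
#' mean `control_gm`, the case group `control_gm * fold`; `cv` is the
#' coefficient of variation on the natural scale (sdlog =
#' sqrt(log(1 + cv^2))), identical in both groups, so the ratio of
#' arithmetic group means equals `fold` in expectation.
#'
#' @param params data.frame with columns `analyte`, `control_gm_pmol` and
#'   `case_over_control` (e.g. from [fig_cohort_params()]).
#' @param n_per_group Samples per group (default 30).
#' @param cv Natural-scale coefficient of variation (default 0.15).
#' @param seed Integer seed.
#' @param matrix Matrix label carried in the table.
#' @param case,control Group labels.
#' @return Cohort data.frame: sample_id, group, matrix, one column per
#'   analyte.
#' @export
gen_cohort <- function(params = fig_cohort_params("serum"),
                       n_per_group = 30L, cv = 0.15, seed = 1L,
                       matrix = "serum", case = "PCNSL", control = "HV") {
  stopifnot(all(params$case_over_control > 0), n_per_group >= 2, cv >= 0)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  n <- 2L * n_per_group
  grp <- rep(c(case, control), each = n_per_group)
  out <- data.frame(
    sample_id = sprintf("%s_%02d", grp, c(seq_len(n_per_group),
                                          seq_len(n_per_group))),
    group = grp, matrix = matrix, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(params))) {
    gm <- params$control_gm_pmol[i] *
      ifelse(grp == case, params$case_over_control[i], 1)
    out[[params$analyte[i]]] <- if (sdlog == 0) gm else
      stats::rlnorm(n, meanlog = log(gm), sdlog = sdlog)
  }
  out
}

#' Generate calibration series from known linear equations
#'
#' `ratio = slope * amount + intercept + N(0, noise_sd)`, with `reps`
#' replicates per level (triplicates by default, mirroring triplicate
#' calibration measurements).
#'
#' @param curves data.frame with columns `analyte`, `slope`, `intercept`
#'   and optionally `range_min_pmol` / `range_max_pmol` (e.g.
#'   [table2_curves()]).
#' @param amounts Amounts in pmol; by default 7 levels geometrically spaced
#'   over each analyte's calibrated range.
#' @param noise_sd Gaussian noise SD in ratio units (0 for exact data).
#' @param reps Replicates per level.
#' @param seed Integer seed.
#' @return data.frame: analyte, amount_pmol, replicate, ratio.
#' @export
gen_calibration_series <- function(curves, amounts = NULL, noise_sd = 0,
                                   reps = 3L, seed = 1L) {
  stopifnot(noise_sd >= 0, reps >= 1)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(curves))) {
    amt <- amounts
    if (is.null(amt)) {
      lo <- curves$range_min_pmol[i]; hi <- curves$range_max_pmol[i]
      amt <- exp(seq(log(lo), log(hi), length.out = 7))
    }
    if (length(unique(amt)) < 3L) stop("need >= 3 levels", call. = FALSE)
    for (a in amt) for (r in seq_len(reps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = curves$analyte[i], amount_pmol = a, replicate = r,
        ratio = curves$slope[i] * a + curves$intercept[i] +
          if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a protein-abundance table with planted effects
#'
#' Background abundances are Gaussian (mean `baseline`, SD 1) in both
#' groups; `n_planted` randomly chosen features are shifted by
#' `effect_size` SDs in the case group. The planted feature names are
#' attached as attribute `"planted"` for truth-aware tests.
#'
#' @param n_features Total features (default 340).
#' @param n_planted Number of shifted features (default 12).
#' @param effect_size Shift in SD units (default 3).
#' @param n_per_group Samples per group (default 10).
#' @param seed Integer seed.
#' @param baseline Background mean (keeps abundances positive).
#' @param case,control Group labels.
#' @return Cohort data.frame with attribute `planted`.
#' @export
gen_protein_table <- function(n_features = 340L, n_planted = 12L,
                              effect_size = 3, n_per_group = 10L,
                              seed = 1L, baseline = 10,
                              case = "PCNSL", control = "HV") {
  stopifnot(n_planted <= n_features, n_per_group >= 2)
  set.seed(seed)
  n <- 2L * n_per_group
  grp <- rep(c(case, control), each = n_per_group)
  feats <- sprintf("prot%03d", seq_len(n_features))
  x <- matrix(stats::rnorm(n * n_features, baseline, 1), n, n_features,
              dimnames = list(NULL, feats))
  planted <- sort(sample(n_features, n_planted))
  x[grp == case, planted] <- x[grp == case, planted] + effect_size
  out <- cbind(data.frame(sample_id = sprintf("%s_%02d", grp,
                                              c(seq_len(n_per_group),
                                                seq_len(n_per_group))),
                          group = grp, matrix = "serum",
                          stringsAsFactors = FALSE),
               as.data.frame(x))
  attr(out, "planted") <- feats[planted]
  out
}
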
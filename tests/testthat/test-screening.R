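# Diagnostic-fragment screening, annotation and deduplication.

test_that("find_diagnostic picks the reporter peak and applies the floor", {
  s <- ms2_spectrum("a", 500, 1, mz = c(100, 406.1753), int = c(50, 1000))
  hit <- find_diagnostic(s, 406.1753, tol_ppm = 10)
  expect_equal(hit$matched_peak_mz, 406.1753)
  expect_equal(hit$relative_intensity, 1)
  # nothing within tolerance
  expect_null(find_diagnostic(ms2_spectrum("b", 500, 1, mz = c(100, 200),
                                           int = c(1, 2)), 406.1753, 10))
  # reporter present but under the relative-intensity floor
  s2 <- ms2_spectrum("c", 500, 1, mz = c(100, 406.1753), int = c(1000, 10))
  expect_null(find_diagnostic(s2, 406.1753, 10, min_rel_intensity = 0.05))
  expect_null(find_diagnostic(ms2_spectrum("d", 500, 1), 406.1753, 10))
})

test_that("find_diagnostic equals an exhaustive linear scan on 1000 spectra", {
  rep_mz <- probe_spec()$diagnostic_fragment_mz
  fx <- make_random_spectra(1000, 300, rep_mz, jitter_ppm = 5, seed = 42)
  got <- logical(1000)
  for (i in seq_along(fx$spectra)) {
    hit <- find_diagnostic(fx$spectra[[i]], rep_mz, 10, 0.05)
    ref <- brute_find_diagnostic(fx$spectra[[i]], rep_mz, 10, 0.05)
    expect_equal(is.null(hit), is.null(ref))
    if (!is.null(hit)) expect_equal(hit$matched_peak_mz, ref$mz)
    got[i] <- !is.null(hit)
  }
  # exactly the 300 planted reporters recovered
  expect_identical(got, fx$truth)
})

test_that("infer_native_mass inverts the derivative model", {
  pr <- probe_spec()
  expect_equal(infer_native_mass(493.2074, pr), 121.0197, tolerance = 1e-3)
  for (f in thiol_targets()$formula)
    expect_equal(infer_native_mass(derivative_mz(f, pr), pr),
                 monoisotopic_mass(f), tolerance = 1e-6)
  expect_error(infer_native_mass(300, pr), "lighter than the probe")
})

test_that("best-mode annotation agrees with exhaustive candidate search", {
  lib <- load_library()
  set.seed(7)
  # random hits near random library records, plus far-off ones
  idx <- sample(nrow(lib), 40, replace = TRUE)
  hits <- data.frame(
    spectrum_id = paste0("h", seq_along(idx)),
    matched_peak_mz = 406.1753, ppm_to_reporter = 0, relative_intensity = 1,
    precursor_mz = lib$mz[idx] * (1 + runif(40, -8e-6, 8e-6)),
    retention_time = lib$rt_min[idx] + runif(40, -0.3, 0.3))
  ann <- annotate_hits(hits, lib, mz_tol_ppm = 5, rt_tol = 0.5, mode = "best")
  expect_equal(nrow(ann), 40)
  for (h in seq_len(nrow(hits))) {
    # brute force over every record
    ppm <- (hits$precursor_mz[h] - lib$mz) / lib$mz * 1e6
    drt <- abs(hits$retention_time[h] - lib$rt_min)
    ok <- which(abs(ppm) <= 5 & drt <= 0.5)
    if (!length(ok)) {
      expect_true(is.na(ann$record_index[h]))
    } else {
      o <- ok[order(abs(ppm[ok]), drt[ok], lib$index[ok])][1]
      expect_equal(ann$record_index[h], lib$index[o])
    }
  }
})

test_that("all-mode annotation emits one row per candidate identity", {
  lib <- load_library()
  # precursor at the co-eluting 209.0596 / RT 6.27 feature: four candidate
  # identities share it in the packaged library
  hits <- data.frame(spectrum_id = "h1", matched_peak_mz = 406.1753,
                     ppm_to_reporter = 0, relative_intensity = 1,
                     precursor_mz = 209.0596, retention_time = 6.27)
  ann <- annotate_hits(hits, lib, mode = "all")
  expect_equal(sort(ann$record_index), c(3L, 14L, 15L, 16L))
  # unmatched hit is kept with an empty record
  far <- transform(hits, precursor_mz = 777.777)
  ann2 <- annotate_hits(far, lib, mode = "all")
  expect_equal(nrow(ann2), 1)
  expect_true(is.na(ann2$record_index))
})

test_that("deduplication merges proximal annotations per record", {
  lib <- load_library()
  hits <- data.frame(
    spectrum_id = c("a", "b"), matched_peak_mz = 406.1753,
    ppm_to_reporter = 0, relative_intensity = c(0.9, 0.5),
    precursor_mz = c(148.0425, 148.0425 * (1 + 2e-6)),
    retention_time = c(0.75, 0.76))
  ann <- annotate_hits(hits, lib, mode = "all")
  dd <- deduplicate_annotations(ann)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$spectrum_id, "a")  # highest relative intensity wins
  expect_equal(dd$n_spectra, 2L)
})

test_that("dedup cluster count equals proximity-graph components", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    rt <- runif(n, 0, 2)
    mz <- 400 * (1 + runif(n, -3e-5, 3e-5))
    ann <- data.frame(spectrum_id = paste0("s", 1:n), retention_time = rt,
                      precursor_mz = mz, relative_intensity = runif(n),
                      record_index = 1L, record_rt = NA_real_,
                      record_mz = NA_real_, formula = "C", matched_adduct = "M+H",
                      ppm_error = 0, description = "x", in_serum = TRUE,
                      in_csf = FALSE, native_thiol_mass = 1)
    dd <- deduplicate_annotations(ann, rt_window = 0.3, mz_window_ppm = 10)
    ref <- brute_components(rt, mz, 0.3, 10)
    expect_equal(nrow(dd), length(unique(ref)))
  }
})

test_that("screening a synthetic run recovers the library and no decoys", {
  lib <- load_library()
  spectra <- gen_ms2_run(lib, seed = 1, mz_jitter_ppm = 3, n_decoys = 20)
  expect_length(spectra, 117)
  ann <- screen_run(spectra, lib)
  expect_equal(sum(!is.na(ann$record_index)), 97)
  expect_equal(sum(is.na(ann$record_index)), 0)
  expect_false(any(grepl("decoy", ann$spectrum_id)))
  # replicate spectra still collapse to one row per metabolite
  spectra3 <- gen_ms2_run(lib, seed = 5, mz_jitter_ppm = 2, n_replicates = 3)
  ann3 <- screen_run(spectra3, lib)
  expect_equal(sum(!is.na(ann3$record_index)), 97)
  expect_true(all(ann3$n_spectra >= 1))
})

test_that("screen_run is order-invariant and handles empty runs", {
  lib <- load_library()
  spectra <- gen_ms2_run(lib[1:10, ], seed = 3, n_decoys = 5)
  ann1 <- screen_run(spectra, lib)
  set.seed(123)
  ann2 <- screen_run(sample(spectra), lib)
  expect_equal(ann1$record_index, ann2$record_index)
  expect_equal(ann1$precursor_mz, ann2$precursor_mz)
  empty <- screen_run(list(), lib)
  expect_equal(nrow(empty), 0)
})
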
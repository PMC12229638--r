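# Diagnostic-fragment screening of MS2 spectra and library annotation.

#' Construct an MS2 spectrum
#'
#' Peaks are sorted ascending by m/z; negative intensities and non-positive
#' precursors are rejected.
#'
#' @param spectrum_id Identifier.
#' @param precursor_mz Precursor m/z in Th (> 0).
#' @param retention_time Retention time in minutes.
#' @param mz,intensity Peak list vectors of equal length.
#' @param precursor_charge Integer charge (default 1).
#' @return An `ms2_spectrum` list.
#' @export
ms2_spectrum <- function(spectrum_id, precursor_mz, retention_time,
                         mz = numeric(0), intensity = numeric(0),
                         precursor_charge = 1L) {
  if (!is.numeric(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be positive", call. = FALSE)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 retention_time = retention_time,
                 mz = mz[o], intensity = intensity[o]),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s  precursor %.4f (z=%d)  RT %.2f min  %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$precursor_charge,
              x$retention_time, length(x$mz)))
  invisible(x)
}

#' Screening configuration
#'
#' Tolerances and windows for [screen_run()]. Defaults: 10 ppm reporter
#' match, 5 ppm library annotation, 0.5 min retention-time window, 5%
#' minimum reporter relative intensity, and a 10 ppm / 0.5 min
#' deduplication window (twice the annotation tolerance, so two observed
#' features of one library compound always collapse to one row).
#'
#' @param reporter_mz Diagnostic-fragment m/z.
#' @param reporter_tol_ppm Reporter match tolerance (ppm).
#' @param annot_tol_ppm Library annotation tolerance (ppm).
#' @param rt_tol Library retention-time tolerance (min).
#' @param min_rel_intensity Minimum reporter intensity as fraction of base peak.
#' @param dedup_rt,dedup_ppm Deduplication proximity windows.
#' @param probe A [probe_spec()].
#' @return A `screen_config` list.
#' @export
screen_config <- function(reporter_mz = NULL, reporter_tol_ppm = 10,
                          annot_tol_ppm = 5, rt_tol = 0.5,
                          min_rel_intensity = 0.05,
                          dedup_rt = 0.5, dedup_ppm = 10,
                          probe = probe_spec()) {
  if (is.null(reporter_mz)) reporter_mz <- probe$diagnostic_fragment_mz
  stopifnot(reporter_tol_ppm > 0, annot_tol_ppm > 0, rt_tol > 0,
            min_rel_intensity >= 0, min_rel_intensity < 1,
            dedup_rt > 0, dedup_ppm > 0)
  structure(list(reporter_mz = reporter_mz,
                 reporter_tol_ppm = reporter_tol_ppm,
                 annot_tol_ppm = annot_tol_ppm, rt_tol = rt_tol,
                 min_rel_intensity = min_rel_intensity,
                 dedup_rt = dedup_rt, dedup_ppm = dedup_ppm,
                 probe = probe),
            class = "screen_config")
}

#' Find the diagnostic reporter peak in one spectrum
#'
#' Returns the most intense peak within `tol_ppm` of the reporter m/z,
#' provided its intensity is at least `min_rel_intensity` of the base peak;
#' `NULL` otherwise (an empty peak list is not an error).
#'
#' @param s An [ms2_spectrum()].
#' @param reporter_mz Reporter m/z in Th.
#' @param tol_ppm Match tolerance in ppm (> 0).
#' @param min_rel_intensity Fraction of base-peak intensity in [0, 1).
#' @return A one-row data.frame (spectrum_id, matched_peak_mz,
#'   ppm_to_reporter, relative_intensity, precursor_mz, retention_time) or
#'   `NULL`.
#' @export
find_diagnostic <- function(s, reporter_mz, tol_ppm = 10,
                            min_rel_intensity = 0.05) {
  stopifnot(tol_ppm > 0, min_rel_intensity >= 0, min_rel_intensity < 1)
  if (!length(s$mz)) return(NULL)
  ppm <- 1e6 * (s$mz - reporter_mz) / reporter_mz
  cand <- which(abs(ppm) <= tol_ppm)
  if (!length(cand)) return(NULL)
  base <- max(s$intensity)
  i <- cand[which.max(s$intensity[cand])]
  if (s$intensity[i] < min_rel_intensity * base) return(NULL)
  data.frame(spectrum_id = s$spectrum_id,
             matched_peak_mz = s$mz[i],
             ppm_to_reporter = ppm[i],
             relative_intensity = s$intensity[i] / base,
             precursor_mz = s$precursor_mz,
             retention_time = s$retention_time,
             stringsAsFactors = FALSE)
}

#' Neutral thiol mass from a derivative precursor
#'
#' Inverse of the derivative-mass model for a singly charged derivative:
#' `mass = precursor_mz + electron mass - mass(probe cation) +
#' mass(leaving group)`. Composing with [derivative_mz()] is the identity
#' within 1e-6 Da.
#'
#' @param precursor_mz Observed precursor m/z (singly charged derivative).
#' @param probe A [probe_spec()].
#' @return Neutral thiol monoisotopic mass in Da.
#' @export
infer_native_mass <- function(precursor_mz, probe = probe_spec()) {
  m <- precursor_mz + ELECTRON_MASS -
    monoisotopic_mass(probe$cation_formula) +
    monoisotopic_mass(probe$leaving_group)
  if (any(m <= 0))
    stop("precursor lighter than the probe tag: inferred native mass <= 0",
         call. = FALSE)
  m
}

#' Annotate diagnostic hits against a compound library
#'
#' Candidates are library records whose listed m/z lies within
#' `mz_tol_ppm` of the hit precursor and (when the record carries a
#' retention time) within `rt_tol` minutes. Two modes:
#'
#' * `mode = "best"`: one annotation per hit, the candidate minimizing
#'   absolute ppm; ties broken by smaller retention-time difference, then
#'   lower record index. Unmatched hits are kept with `record_index = NA`.
#' * `mode = "all"`: one annotation per (hit, candidate record). Co-eluting
#'   features with several indistinguishable library identities yield one
#'   row per candidate identity, which is how the screening table lists one
#'   row per catalogued metabolite.
#'
#' The matched adduct is the declared adduct of the record whose computed
#' m/z is closest to the observation (metadata only; matching itself uses
#' the record's listed m/z, which is an observed, adducted value).
#'
#' @param hits data.frame of hits from [find_diagnostic()] (row-bound).
#' @param library Compound library from [load_library()].
#' @param mz_tol_ppm Annotation tolerance (ppm).
#' @param rt_tol Retention-time tolerance (min).
#' @param mode `"best"` or `"all"`.
#' @param probe A [probe_spec()] used to infer native thiol masses.
#' @return data.frame of annotations.
#' @export
annotate_hits <- function(hits, library, mz_tol_ppm = 5, rt_tol = 0.5,
                          mode = c("best", "all"), probe = probe_spec()) {
  mode <- match.arg(mode)
  if (is.null(library) || !nrow(library))
    stop("library must be non-empty", call. = FALSE)
  out <- list()
  if (is.null(hits) || !nrow(hits)) return(.empty_annotations())
  for (h in seq_len(nrow(hits))) {
    pmz <- hits$precursor_mz[h]
    prt <- hits$retention_time[h]
    ppm <- 1e6 * (pmz - library$mz) / library$mz
    drt <- abs(prt - library$rt_min)
    ok <- abs(ppm) <= mz_tol_ppm & (is.na(library$rt_min) | drt <= rt_tol)
    native <- tryCatch(infer_native_mass(pmz, probe), error = function(e) NA_real_)
    if (!any(ok)) {
      out[[length(out) + 1L]] <- .annotation_row(hits[h, ], NA_integer_,
                                                NA_character_, NA_real_,
                                                native, library)
      next
    }
    idx <- which(ok)
    if (mode == "best") {
      o <- order(abs(ppm[idx]), drt[idx], library$index[idx])
      idx <- idx[o[1L]]
    }
    for (i in idx)
      out[[length(out) + 1L]] <- .annotation_row(hits[h, ], i,
                                                .best_adduct(library, i, pmz),
                                                ppm[i], native, library)
  }
  do.call(rbind, out)
}

.best_adduct <- function(library, i, observed_mz) {
  adds <- strsplit(library$adducts[i], ";", fixed = TRUE)[[1]]
  if (length(adds) == 1L) return(adds)
  theo <- vapply(adds, function(a)
    tryCatch(adduct_mz(library$formula[i], a), error = function(e) NA_real_),
    numeric(1))
  if (all(is.na(theo))) return(adds[1L])
  adds[which.min(abs(theo - observed_mz))]
}

.annotation_row <- function(hit, lib_i, adduct, ppm, native, library) {
  rec <- if (!is.na(lib_i)) library[lib_i, ] else NULL
  data.frame(spectrum_id = hit$spectrum_id,
             retention_time = hit$retention_time,
             precursor_mz = hit$precursor_mz,
             relative_intensity = hit$relative_intensity,
             record_index = if (!is.na(lib_i)) rec$index else NA_integer_,
             record_rt = if (!is.na(lib_i)) rec$rt_min else NA_real_,
             record_mz = if (!is.na(lib_i)) rec$mz else NA_real_,
             formula = if (!is.na(lib_i)) rec$formula else NA_character_,
             matched_adduct = adduct,
             ppm_error = ppm,
             description = if (!is.na(lib_i)) rec$description else NA_character_,
             in_serum = if (!is.na(lib_i)) rec$in_serum else NA,
             in_csf = if (!is.na(lib_i)) rec$in_csf else NA,
             native_thiol_mass = native,
             stringsAsFactors = FALSE)
}

.empty_annotations <- function() {
  data.frame(spectrum_id = character(0), retention_time = numeric(0),
             precursor_mz = numeric(0), relative_intensity = numeric(0),
             record_index = integer(0), record_rt = numeric(0),
             record_mz = numeric(0), formula = character(0),
             matched_adduct = character(0), ppm_error = numeric(0),
             description = character(0), in_serum = logical(0),
             in_csf = logical(0), native_thiol_mass = numeric(0))
}

#' Deduplicate annotations into one row per metabolite feature
#'
#' Annotations are grouped by annotated library record (unannotated hits
#' form their own group) and clustered within a group by (retention time,
#' m/z) proximity: two annotations belong to the same cluster when they are
#' linked by a chain of pairs within `rt_window` minutes and
#' `mz_window_ppm` ppm (connected components of the proximity graph).
#' Each cluster is represented by its highest-relative-intensity member and
#' the output is sorted by retention time.
#'
#' @param annos Annotation data.frame from [annotate_hits()].
#' @param rt_window,mz_window_ppm Proximity windows (> 0).
#' @return Deduplicated annotation data.frame with an `n_spectra` column.
#' @export
deduplicate_annotations <- function(annos, rt_window = 0.5,
                                    mz_window_ppm = 10) {
  stopifnot(rt_window > 0, mz_window_ppm > 0)
  if (is.null(annos) || !nrow(annos)) {
    out <- .empty_annotations(); out$n_spectra <- integer(0); return(out)
  }
  key <- ifelse(is.na(annos$record_index), "unmatched",
                paste0("rec", annos$record_index))
  reps <- list()
  for (k in unique(key)) {
    g <- annos[key == k, , drop = FALSE]
    comp <- .proximity_components(g$retention_time, g$precursor_mz,
                                  rt_window, mz_window_ppm)
    for (cl in unique(comp)) {
      m <- g[comp == cl, , drop = FALSE]
      rep_row <- m[which.max(m$relative_intensity), , drop = FALSE]
      rep_row$n_spectra <- length(unique(m$spectrum_id))
      reps[[length(reps) + 1L]] <- rep_row
    }
  }
  out <- do.call(rbind, reps)
  out <- out[order(out$retention_time, out$precursor_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Connected components of the (RT, m/z) proximity graph via union-find.
.proximity_components <- function(rt, mz, rt_window, mz_window_ppm) {
  n <- length(rt)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (abs(rt[i] - rt[j]) <= rt_window &&
        abs(mz[i] - mz[j]) / ((mz[i] + mz[j]) / 2) * 1e6 <= mz_window_ppm) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Screen an MS2 run for labeled thiols
#'
#' Composition of [find_diagnostic()] over all spectra,
#' [infer_native_mass()], [annotate_hits()] (mode `"all"`, one row per
#' candidate library identity) and [deduplicate_annotations()]. The result
#' is one row per catalogued metabolite feature, in the layout of the
#' packaged compound library plus provenance columns.
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param library Compound library from [load_library()].
#' @param config A [screen_config()].
#' @return Annotation data.frame sorted by retention time.
#' @export
screen_run <- function(spectra, library, config = screen_config()) {
  hits <- lapply(spectra, find_diagnostic,
                 reporter_mz = config$reporter_mz,
                 tol_ppm = config$reporter_tol_ppm,
                 min_rel_intensity = config$min_rel_intensity)
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits) || !nrow(hits)) {
    out <- .empty_annotations(); out$n_spectra <- integer(0); return(out)
  }
  annos <- annotate_hits(hits, library,
                         mz_tol_ppm = config$annot_tol_ppm,
                         rt_tol = config$rt_tol,
                         mode = "all", probe = config$probe)
  deduplicate_annotations(annos, rt_window = config$dedup_rt,
                          mz_window_ppm = config$dedup_ppm)
}
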
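# Readers and writers: MGF, mzML (via mzR), compound-library CSV, YAML
# run configuration. Retention times are minutes internally; mzML and MGF
# store seconds and are converted on read/write. m/z are written with 6
# decimals, intensities at full float precision.

#' Write spectra to an MGF file
#'
#' One `BEGIN IONS`/`END IONS` block per spectrum with TITLE, PEPMASS,
#' CHARGE and RTINSECONDS headers. Writing the same spectra twice produces
#' byte-identical files.
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$precursor_charge),
                 sprintf("RTINSECONDS=%.4f", s$retention_time * 60),
                 sprintf("%.6f %.9g", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read an MGF file
#'
#' @param path MGF file path.
#' @return List of [ms2_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  i <- 1L; n <- length(lines); spec_idx <- 0L
  while (i <= n) {
    if (lines[i] != "BEGIN IONS")
      stop("malformed MGF '", path, "': expected BEGIN IONS at entry ",
           spec_idx + 1L, call. = FALSE)
    spec_idx <- spec_idx + 1L
    title <- paste0("spectrum", spec_idx)
    pepmass <- NA_real_; rt <- NA_real_; charge <- 1L
    mz <- numeric(0); int <- numeric(0)
    i <- i + 1L; ended <- FALSE
    while (i <= n) {
      ln <- lines[i]
      if (ln == "END IONS") { ended <- TRUE; i <- i + 1L; break }
      if (grepl("=", ln, fixed = TRUE)) {
        key <- sub("=.*$", "", ln); val <- sub("^[^=]*=", "", ln)
        if (key == "TITLE") title <- val
        else if (key == "PEPMASS") pepmass <- as.numeric(strsplit(val, " ")[[1]][1])
        else if (key == "RTINSECONDS") rt <- as.numeric(val) / 60
        else if (key == "CHARGE") charge <- as.integer(sub("[+-]$", "", val))
      } else {
        parts <- strsplit(ln, "[ \t]+")[[1]]
        if (length(parts) < 2L || anyNA(suppressWarnings(as.numeric(parts[1:2]))))
          stop("malformed MGF '", path, "': bad peak line in spectrum ",
               spec_idx, call. = FALSE)
        mz <- c(mz, as.numeric(parts[1])); int <- c(int, as.numeric(parts[2]))
      }
      i <- i + 1L
    }
    if (!ended)
      stop("malformed MGF '", path, "': spectrum ", spec_idx,
           " is truncated (missing END IONS)", call. = FALSE)
    if (is.na(pepmass))
      stop("malformed MGF '", path, "': spectrum ", spec_idx,
           " has no PEPMASS", call. = FALSE)
    out[[length(out) + 1L]] <- ms2_spectrum(title, pepmass, rt, mz, int, charge)
  }
  out
}

#' Read MS2 spectra from mzML or MGF
#'
#' mzML is read through Bioconductor's mzR; MS1 scans are skipped, MS2
#' scans without a precursor m/z are skipped with a message, retention
#' times are converted from seconds to minutes, peaks are sorted. The
#' format is inferred from the file extension unless given.
#'
#' @param path Input file.
#' @param format `"auto"`, `"mzml"` or `"mgf"`.
#' @return List of [ms2_spectrum()] objects (possibly empty, with a
#'   warning for a run containing no MS2 scans).
#' @export
read_ms2 <- function(path, format = c("auto", "mzml", "mgf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mgf") "mgf" else "mzml"
  }
  spectra <- if (format == "mgf") read_mgf(path) else .read_mzml(path)
  if (!length(spectra))
    warning("empty run: no MS2 spectra with precursors in '", path, "'")
  spectra
}

.read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  keep <- which(hdr$msLevel == 2L)
  skipped <- sum(is.na(hdr$precursorMZ[keep]) | hdr$precursorMZ[keep] <= 0)
  if (skipped > 0)
    message(skipped, " MS2 scan(s) without precursor m/z skipped in '",
            path, "'")
  keep <- keep[!is.na(hdr$precursorMZ[keep]) & hdr$precursorMZ[keep] > 0]
  lapply(keep, function(i) {
    pk <- mzR::peaks(handle, i)
    z <- hdr$precursorCharge[i]
    ms2_spectrum(spectrum_id = as.character(hdr$seqNum[i]),
                 precursor_mz = hdr$precursorMZ[i],
                 retention_time = hdr$retentionTime[i] / 60,
                 mz = pk[, 1], intensity = pk[, 2],
                 precursor_charge = if (is.na(z) || z == 0) 1L else z)
  })
}

#' Load a compound library CSV
#'
#' Required columns: index, rt_min, charge, mz, formula, adducts,
#' description (plus optional mass_error_ppm, in_serum, in_csf). Formulas
#' must be plain Hill notation; duplicate indices are rejected. The
#' packaged library loads to exactly 97 records.
#'
#' @param path CSV path; default the packaged library of catalogued thiol
#'   metabolites.
#' @return data.frame of validated records, class `compound_library`.
#' @export
load_library <- function(path = system.file("extdata", "table4_library.csv",
                                            package = "thioltrace")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("index", "rt_min", "charge", "mz", "formula", "adducts",
                "description")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("library '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(tab)) {
    class(tab) <- c("compound_library", class(tab))
    return(tab)
  }
  if (anyDuplicated(tab$index))
    stop("duplicate record indices in library: ",
         paste(unique(tab$index[duplicated(tab$index)]), collapse = ", "),
         call. = FALSE)
  if (any(tab$mz <= 0)) stop("library m/z must be positive", call. = FALSE)
  if (any(!nzchar(tab$adducts)))
    stop("every library record needs at least one adduct", call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({ parse_formula(tab$formula[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop("library row ", i, ": ", conditionMessage(ok), call. = FALSE)
  }
  if (!"in_serum" %in% names(tab)) tab$in_serum <- NA
  if (!"in_csf" %in% names(tab)) tab$in_csf <- NA
  tab$in_serum <- as.logical(tab$in_serum)
  tab$in_csf <- as.logical(tab$in_csf)
  class(tab) <- c("compound_library", class(tab))
  tab
}

#' Default run configuration
#'
#' Every tunable of the pipeline with its documented default; values loaded
#' from a YAML file override these, and command-line flags override both.
#'
#' @return Nested list: probe, screening, quant, stats, classify, seed,
#'   log_level.
#' @export
default_config <- function() {
  list(probe = list(cation_formula = "C25H28BrNP", leaving_group = "HBr",
                    diagnostic_fragment_formula = "C25H29NPS"),
       screening = list(reporter_tol_ppm = 10, annot_tol_ppm = 5,
                        rt_tol = 0.5, min_rel_intensity = 0.05,
                        dedup_rt = 0.5, dedup_ppm = 10),
       quant = list(weighting = "none"),
       stats = list(variant = "student", n_components = 3,
                    p_adjust = "none"),
       classify = list(model = "rf", n_trials = 200, n_train = 14,
                       n_test = 6, rf_trees = 500, lr_lambda = 1),
       seed = 1L,
       log_level = "info")
}

#' Load a YAML run configuration
#'
#' Fields present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

.screen_config_from <- function(cfg) {
  pr <- do.call(probe_spec, cfg$probe)
  screen_config(reporter_tol_ppm = cfg$screening$reporter_tol_ppm,
                annot_tol_ppm = cfg$screening$annot_tol_ppm,
                rt_tol = cfg$screening$rt_tol,
                min_rel_intensity = cfg$screening$min_rel_intensity,
                dedup_rt = cfg$screening$dedup_rt,
                dedup_ppm = cfg$screening$dedup_ppm,
                probe = pr)
}

#' Write an annotation table to CSV
#'
#' @param annotations data.frame from [screen_run()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
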
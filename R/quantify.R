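# Internal-standard calibration and method-validation arithmetic.

#' Fit an internal-standard calibration curve
#'
#' Ordinary least squares of the peak-area ratio (analyte area / internal
#' standard area) on amount, optionally 1/x-weighted. R^2 is
#' `1 - SS_res / SS_tot`.
#'
#' @param points data.frame with columns `amount_pmol` and either `ratio` or
#'   both `analyte_area` and `is_area` (ratio computed as their quotient).
#' @param weighting `"none"` (default; the printed calibration equations are
#'   simple linear fits) or `"1/x"` (weights `1/amount`; zero-amount points
#'   are dropped from a weighted fit).
#' @param analyte Optional analyte name carried in the result.
#' @return A `calibration_curve` with `coef()`, `predict()` and `print()`
#'   methods; fields slope, intercept, r_squared, range (pmol), and `lod`/
#'   `loq` (fmol, `NA` until [lod_loq()] is applied).
#' @export
fit_calibration <- function(points, weighting = c("none", "1/x"),
                            analyte = NA_character_) {
  weighting <- match.arg(weighting)
  if (!"ratio" %in% names(points)) {
    if (!all(c("analyte_area", "is_area") %in% names(points)))
      stop("points need a 'ratio' column or 'analyte_area' + 'is_area'",
           call. = FALSE)
    if (any(points$is_area <= 0))
      stop("internal-standard areas must be positive", call. = FALSE)
    points$ratio <- points$analyte_area / points$is_area
  }
  if (any(points$amount_pmol < 0))
    stop("amounts must be >= 0", call. = FALSE)
  if (length(unique(points$amount_pmol)) < 3L)
    stop("calibration requires at least 3 distinct amounts", call. = FALSE)
  if (weighting == "1/x") {
    pts <- points[points$amount_pmol > 0, , drop = FALSE]
    fit <- stats::lm(ratio ~ amount_pmol, data = pts,
                     weights = 1 / pts$amount_pmol)
  } else {
    fit <- stats::lm(ratio ~ amount_pmol, data = points)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$ratio - mean(points$ratio))^2)
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = 1 - ss_res / ss_tot,
                 range = range(points$amount_pmol),
                 weighting = weighting,
                 n = nrow(points),
                 lod = NA_real_, loq = NA_real_,
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, digits = 6, ...) {
  cat(sprintf("<calibration_curve>%s y = %sx %s %s  (R2 = %.4f, n = %d, %s)\n",
              if (is.na(x$analyte)) "" else paste0(" ", x$analyte, ":"),
              signif(x$slope, digits),
              if (x$intercept < 0) "-" else "+",
              signif(abs(x$intercept), digits),
              x$r_squared, x$n,
              if (x$weighting == "none") "unweighted" else "1/x-weighted"))
  cat(sprintf("  range %g-%g pmol", x$range[1], x$range[2]))
  if (!is.na(x$lod)) cat(sprintf("  LOD %.3g fmol  LOQ %.3g fmol", x$lod, x$loq))
  cat("\n")
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_curve <- function(object, amount_pmol, ...) {
  object$intercept + object$slope * amount_pmol
}

#' Invert a calibration curve
#'
#' `amount = (ratio - intercept) / slope`. Amounts outside the calibrated
#' range are returned unchanged but flagged (never clipped).
#'
#' @param curve A [fit_calibration()] result.
#' @param ratio Measured area ratio(s).
#' @return data.frame with columns `amount_pmol` and `flag`
#'   (`"ok"`, `"below-range"` or `"above-range"`).
#' @export
apply_calibration <- function(curve, ratio) {
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  amount <- (ratio - curve$intercept) / curve$slope
  flag <- ifelse(amount < curve$range[1], "below-range",
                 ifelse(amount > curve$range[2], "above-range", "ok"))
  data.frame(amount_pmol = amount, flag = flag, stringsAsFactors = FALSE)
}

#' Limits of detection and quantification
#'
#' Signal-to-noise definitions 3:1 and 10:1 applied to the calibration
#' slope: `LOD = 3 sigma / slope`, `LOQ = 10 sigma / slope`, with sigma the
#' blank-ratio noise SD in ratio units. Results are reported in fmol
#' (amounts are pmol throughout; x1000 for display). `LOQ / LOD = 10/3` by
#' construction.
#'
#' @param curve A [fit_calibration()] result (slope > 0).
#' @param noise_sd Blank-ratio standard deviation (> 0), ratio units.
#' @return The curve with `lod` and `loq` filled in (fmol).
#' @export
lod_loq <- function(curve, noise_sd) {
  if (curve$slope <= 0) stop("slope must be positive", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  curve$lod <- 3 * noise_sd / curve$slope * 1000
  curve$loq <- 10 * noise_sd / curve$slope * 1000
  curve
}

#' Coefficient of variation of replicate measurements
#'
#' Sample standard deviation (n-1 denominator) over mean, x100.
#'
#' @param replicates Numeric vector of measured amounts (n >= 2).
#' @param analyte,level,grouping Metadata carried into the result.
#' @return A one-row data.frame (analyte, level, grouping, n, cv_pct);
#'   `cv_pct` is `NA` when the mean is zero (not computable).
#' @export
precision_cv <- function(replicates, analyte = NA_character_,
                         level = NA_real_, grouping = c("intra", "inter")) {
  grouping <- match.arg(grouping)
  if (length(replicates) < 2L)
    stop("precision requires at least 2 replicates", call. = FALSE)
  m <- mean(replicates)
  cv <- if (m == 0) NA_real_ else stats::sd(replicates) / m * 100
  data.frame(analyte = analyte, level = level, grouping = grouping,
             n = length(replicates), cv_pct = cv, stringsAsFactors = FALSE)
}

#' Spike recovery
#'
#' `(spiked_mean - unspiked_mean) / spike x 100`; invariant under common
#' scaling of all three inputs.
#'
#' @param unspiked_mean Mean endogenous amount (pmol).
#' @param spiked_mean Mean measured amount after spiking (pmol).
#' @param spike Spiked amount (pmol, > 0).
#' @return Recovery in percent.
#' @export
recovery <- function(unspiked_mean, spiked_mean, spike) {
  if (any(spike <= 0)) stop("spike must be positive", call. = FALSE)
  (spiked_mean - unspiked_mean) / spike * 100
}

#' Packaged validation fixtures
#'
#' `table2_curves()` returns the packaged per-analyte calibration equations
#' (slope, intercept, R^2, range, printed LOD/LOQ); `table3_recovery()` the
#' packaged spike-recovery panel (per-matrix unspiked and spiked means,
#' CVs, per-level and mean recoveries).
#'
#' @return data.frame.
#' @export
table2_curves <- function() {
  utils::read.csv(system.file("extdata", "table2_calibration.csv",
                              package = "thioltrace"),
                  stringsAsFactors = FALSE)
}

#' @rdname table2_curves
#' @export
table3_recovery <- function() {
  utils::read.csv(system.file("extdata", "table3_recovery.csv",
                              package = "thioltrace"),
                  stringsAsFactors = FALSE)
}

#' Assemble a method-validation report
#'
#' Per analyte: fitted calibration curve (when calibration data are given),
#' precision CVs, and per-level plus mean spike recoveries per matrix. Mean
#' recovery is the arithmetic mean of per-level recoveries. Missing
#' analytes in any input yield `NA` cells, never an error.
#'
#' @param calibration data.frame (analyte, amount_pmol, ratio or areas), or
#'   NULL.
#' @param recovery_data data.frame in the layout of [table3_recovery()]
#'   (analyte, matrix, spike_pmol, measured_mean_pmol); the unspiked row
#'   has `spike_pmol = 0`. Or NULL.
#' @param precision data.frame (analyte, level, grouping, measured_pmol)
#'   of replicate measurements, or NULL.
#' @param weighting Calibration weighting, see [fit_calibration()].
#' @return A `validation_report` list: `curves` (named list of
#'   `calibration_curve`), `precision` (CV table), `recovery` (per-level
#'   table with a `recovery_pct` column), `mean_recovery` (analyte x matrix
#'   means).
#' @export
validation_report <- function(calibration = NULL, recovery_data = NULL,
                              precision = NULL,
                              weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  curves <- list()
  if (!is.null(calibration)) {
    for (a in unique(calibration$analyte)) {
      pts <- calibration[calibration$analyte == a, , drop = FALSE]
      curves[[a]] <- tryCatch(fit_calibration(pts, weighting, analyte = a),
                              error = function(e) NULL)
    }
  }
  prec <- NULL
  if (!is.null(precision)) {
    keys <- unique(precision[c("analyte", "level", "grouping")])
    prec <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sel <- precision$analyte == keys$analyte[i] &
        precision$level == keys$level[i] &
        precision$grouping == keys$grouping[i]
      precision_cv(precision$measured_pmol[sel], keys$analyte[i],
                   keys$level[i], keys$grouping[i])
    }))
  }
  rec <- NULL; mean_rec <- NULL
  if (!is.null(recovery_data)) {
    rec_rows <- list()
    keys <- unique(recovery_data[c("analyte", "matrix")])
    for (i in seq_len(nrow(keys))) {
      g <- recovery_data[recovery_data$analyte == keys$analyte[i] &
                           recovery_data$matrix == keys$matrix[i], ,
                         drop = FALSE]
      base <- g$measured_mean_pmol[g$spike_pmol == 0]
      base <- if (length(base)) base[1L] else NA_real_
      sp <- g[g$spike_pmol > 0, , drop = FALSE]
      rpct <- if (is.na(base) || !nrow(sp)) numeric(0) else
        recovery(base, sp$measured_mean_pmol, sp$spike_pmol)
      if (nrow(sp))
        rec_rows[[length(rec_rows) + 1L]] <-
          data.frame(analyte = keys$analyte[i], matrix = keys$matrix[i],
                     spike_pmol = sp$spike_pmol,
                     unspiked_mean = base,
                     spiked_mean = sp$measured_mean_pmol,
                     recovery_pct = if (length(rpct)) rpct else NA_real_,
                     stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rec_rows)
    if (!is.null(rec)) {
      agg <- stats::aggregate(recovery_pct ~ analyte + matrix, data = rec,
                              FUN = mean)
      names(agg)[3L] <- "mean_recovery_pct"
      mean_rec <- agg
    }
  }
  structure(list(curves = curves, precision = prec, recovery = rec,
                 mean_recovery = mean_rec),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (length(x$curves)) {
    cat(sprintf("  %d calibration curve(s):\n", length(x$curves)))
    for (cv in x$curves) if (!is.null(cv)) { cat("  "); print(cv) }
  }
  if (!is.null(x$mean_recovery)) {
    cat("  mean recoveries (%):\n")
    print(x$mean_recovery, row.names = FALSE)
  }
  if (!is.null(x$precision))
    cat(sprintf("  precision: %d CV cells, range %.2f-%.2f%%\n",
                nrow(x$precision), min(x$precision$cv_pct, na.rm = TRUE),
                max(x$precision$cv_pct, na.rm = TRUE)))
  invisible(x)
}
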
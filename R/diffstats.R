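# Cohort-level differential statistics: fold changes, two-sample tests,
# NIPALS PLS-DA with S-plot, z-scored heatmap clustering, volcano stage.

.cohort_features <- function(table) {
  setdiff(names(table), c("sample_id", "group", "matrix"))
}

.check_cohort <- function(table, feature = NULL) {
  stopifnot(is.data.frame(table), all(c("sample_id", "group") %in% names(table)))
  if (!is.null(feature) && !feature %in% names(table))
    stop("feature '", feature, "' not in cohort table", call. = FALSE)
  invisible(TRUE)
}

#' Group-mean fold change for one feature
#'
#' Ratio of arithmetic group means, case over control. The direction is
#' explicit in the result so "x times higher than" is well defined for
#' either group.
#'
#' @param table Cohort data.frame: `sample_id`, `group`, optional `matrix`,
#'   then one numeric column per feature.
#' @param feature Feature column name.
#' @param case,control Group labels (default `"PCNSL"` vs `"HV"`).
#' @return List with `fold_change` (case/control), `case_mean`,
#'   `control_mean`, `higher_in`. A zero control mean gives `NA` with a
#'   warning, not an error.
#' @export
fold_change <- function(table, feature, case = "PCNSL", control = "HV") {
  .check_cohort(table, feature)
  mc <- mean(table[[feature]][table$group == case])
  m0 <- mean(table[[feature]][table$group == control])
  if (is.na(m0) || m0 == 0) {
    warning("control mean is zero for '", feature, "'; fold change undefined")
    fc <- NA_real_
  } else fc <- mc / m0
  list(feature = feature, fold_change = fc, case_mean = mc, control_mean = m0,
       higher_in = if (is.na(fc) || fc == 1) NA_character_ else
         if (fc > 1) case else control)
}

#' Significance stars for a p-value
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, `""` otherwise.
#' @param p p-value(s).
#' @return Character vector.
#' @export
signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Two-sample t-test for one feature
#'
#' Two-sided. The default `"student"` variant uses the pooled-variance
#' Student's t (the test named for the cohort comparisons); `"welch"` is
#' available by flag. Degenerate input with zero variance in both groups
#' and equal means yields p = 1; with unequal means the p-value underflows
#' toward the double floor (~1e-300) rather than erroring.
#'
#' @inheritParams fold_change
#' @param variant `"student"` or `"welch"`.
#' @return List: feature, fold_change, t_stat, df, p_value, stars.
#' @export
two_sample_t <- function(table, feature, case = "PCNSL", control = "HV",
                         variant = c("student", "welch")) {
  variant <- match.arg(variant)
  .check_cohort(table, feature)
  x <- table[[feature]][table$group == case]
  y <- table[[feature]][table$group == control]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    tt <- list(statistic = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
               parameter = length(x) + length(y) - 2,
               p.value = if (eq) 1 else .Machine$double.xmin)
  } else {
    tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  }
  fc <- fold_change(table, feature, case, control)$fold_change
  list(feature = feature, fold_change = fc,
       t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, stars = signif_stars(tt$p.value))
}

#' Compare all features between two groups
#'
#' @inheritParams two_sample_t
#' @param p_adjust `"none"` (default; raw p < 0.05 is the reported
#'   criterion) or `"BH"` for Benjamini-Hochberg, added as `p_adj`.
#' @return data.frame, one row per feature.
#' @export
group_compare <- function(table, case = "PCNSL", control = "HV",
                          variant = c("student", "welch"),
                          p_adjust = c("none", "BH")) {
  variant <- match.arg(variant); p_adjust <- match.arg(p_adjust)
  feats <- .cohort_features(table)
  rows <- lapply(feats, function(f) {
    r <- two_sample_t(table, f, case, control, variant)
    data.frame(feature = f, fold_change = r$fold_change, t_stat = r$t_stat,
               p_value = r$p_value, stars = r$stars, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out
}

# Autoscale a matrix; constant columns are dropped with a warning.
.autoscale <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep))
    warning("dropping constant feature(s) from autoscaling: ",
            paste(colnames(x)[!keep], collapse = ", "))
  xs <- scale(x[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  list(x = xs, mean = mu[keep], sd = sdv[keep], kept = colnames(x)[keep])
}

#' Partial least squares discriminant analysis (NIPALS)
#'
#' Two-group PLS-DA on autoscaled (unit-variance) features with the class
#' coded as a +/-1 dummy. Components are extracted by the NIPALS algorithm
#' with deflation of X and y after each component; for a univariate
#' response the inner loop converges immediately, but iteration up to
#' `max_iter` with weight-change tolerance `tol` is retained for
#' generality. Initialization is from y, so the fit is deterministic. The
#' sign of each component is fixed by making its largest-magnitude weight
#' positive.
#'
#' @param table Cohort data.frame (see [fold_change()]).
#' @param n_components Number of latent components (default 3, for the 3-D
#'   score plot); must be <= min(samples - 1, features).
#' @param case,control Group labels; `case` is coded +1.
#' @param max_iter,tol NIPALS inner-loop controls.
#' @return A `plsda` object: `scores` (samples x components), `weights`,
#'   `loadings`, `y_loadings`, `x_mean`, `x_sd`, `explained` (fraction of
#'   autoscaled X variance per component), `groups`.
#' @export
plsda_fit <- function(table, n_components = 3, case = "PCNSL",
                      control = "HV", max_iter = 500, tol = 1e-10) {
  .check_cohort(table)
  feats <- .cohort_features(table)
  x <- as.matrix(table[, feats, drop = FALSE])
  grp <- table$group
  if (!all(grp %in% c(case, control)))
    stop("groups other than case/control present", call. = FALSE)
  sc <- .autoscale(x)
  xs <- sc$x
  y <- ifelse(grp == case, 1, -1)
  y <- y - mean(y)
  n <- nrow(xs); p <- ncol(xs)
  if (n_components > min(n - 1, p))
    stop("n_components must be <= min(samples - 1, features)", call. = FALSE)
  ssx_total <- sum(xs^2)
  Tm <- matrix(0, n, n_components)
  W <- P <- matrix(0, p, n_components)
  cvec <- numeric(n_components)
  Xd <- xs; yd <- y
  for (a in seq_len(n_components)) {
    u <- yd
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tvec <- Xd %*% w
      cc <- sum(yd * tvec) / sum(tvec^2)
      u_new <- yd * cc  # univariate y: u proportional to y, converges at once
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w; u <- u_new
    }
    # sign convention: largest-|weight| element positive
    s <- sign(w[which.max(abs(w))]); if (s == 0) s <- 1
    w <- w * s; tvec <- tvec * s; cc <- cc * s
    pvec <- crossprod(Xd, tvec)[, 1] / sum(tvec^2)
    Xd <- Xd - tcrossprod(tvec, pvec)
    yd <- yd - tvec[, 1] * cc
    Tm[, a] <- tvec; W[, a] <- w; P[, a] <- pvec; cvec[a] <- cc
  }
  dimnames(Tm) <- list(table$sample_id, paste0("t", seq_len(n_components)))
  dimnames(W) <- dimnames(P) <-
    list(sc$kept, paste0("comp", seq_len(n_components)))
  structure(list(scores = Tm, weights = W, loadings = P, y_loadings = cvec,
                 x_mean = sc$mean, x_sd = sc$sd, features = sc$kept,
                 groups = grp, case = case, control = control,
                 explained = vapply(seq_len(n_components), function(a)
                   sum(Tm[, a]^2) * sum(P[, a]^2) / ssx_total, numeric(1))),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d samples (%s vs %s), %d features, %d components\n",
              nrow(x$scores), x$case, x$control, length(x$features),
              ncol(x$scores)))
  cat("  X-variance explained per component:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.plsda <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- scale(x, center = object$x_mean, scale = object$x_sd)
  R <- object$weights %*% solve(crossprod(object$loadings, object$weights))
  scores <- xs %*% R
  yhat <- scores %*% object$y_loadings
  list(scores = scores,
       class = ifelse(yhat[, 1] > 0, object$case, object$control))
}

#' S-plot coordinates from a fitted PLS-DA model
#'
#' For each feature: `p1`, the covariance of the autoscaled feature with
#' the first score vector (modeled magnitude), and `pcorr1`, its
#' correlation with the first score vector (reliability, in [-1, 1]).
#' Zero-variance features are emitted with `NA`.
#'
#' @param model A [plsda_fit()] result.
#' @param table The cohort table the model was fitted to.
#' @return data.frame: feature, p1, pcorr1.
#' @export
splot <- function(model, table) {
  x <- as.matrix(table[, model$features, drop = FALSE])
  xs <- scale(x, center = model$x_mean, scale = model$x_sd)
  t1 <- model$scores[, 1]
  p1 <- apply(xs, 2, function(col) stats::cov(col, t1))
  pcorr1 <- apply(xs, 2, function(col)
    if (stats::sd(col) == 0) NA_real_ else stats::cor(col, t1))
  data.frame(feature = model$features, p1 = p1, pcorr1 = pcorr1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Z-scored heatmap with agglomerative clustering
#'
#' Features are z-scored across samples ((x - mean) / SD, exactly mean 0 /
#' SD 1 per feature), then features and samples are clustered by average-
#' linkage agglomeration on Euclidean distances; leaf orders are the
#' deterministic `stats::hclust` orders.
#'
#' @param table Cohort data.frame with >= 2 features and >= 2 samples.
#' @return List: `z` (features x samples z-score matrix), `feature_order`,
#'   `sample_order`, `feature_hclust`, `sample_hclust`.
#' @export
heatmap_cluster <- function(table) {
  .check_cohort(table)
  feats <- .cohort_features(table)
  if (length(feats) < 2L) stop("need >= 2 features", call. = FALSE)
  x <- t(as.matrix(table[, feats, drop = FALSE]))  # features x samples
  colnames(x) <- table$sample_id
  if (ncol(x) < 2L)
    stop("z-scores undefined for a single sample", call. = FALSE)
  z <- t(scale(t(x)))
  z[is.nan(z)] <- 0  # constant feature: zero row rather than NaN
  hc_f <- stats::hclust(stats::dist(z), method = "average")
  hc_s <- stats::hclust(stats::dist(t(z)), method = "average")
  list(z = z, feature_order = hc_f$order, sample_order = hc_s$order,
       feature_hclust = hc_f, sample_hclust = hc_s)
}

#' Volcano-stage differential analysis for a protein table
#'
#' Per-protein two-sample t-test and log2 fold change (case over control);
#' down-regulation is a negative log2 fold change. The output supports the
#' usual volcano plot of log2 FC against -log10 p.
#'
#' @inheritParams group_compare
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return data.frame: feature, log2_fc, p_value, neg_log10_p, significant,
#'   direction.
#' @export
volcano <- function(table, case = "PCNSL", control = "HV",
                    variant = c("student", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  cmp <- group_compare(table, case, control, variant)
  data.frame(feature = cmp$feature,
             log2_fc = log2(cmp$fold_change),
             p_value = cmp$p_value,
             neg_log10_p = -log10(cmp$p_value),
             significant = cmp$p_value < alpha,
             direction = ifelse(cmp$fold_change >= 1, "up", "down"),
             stringsAsFactors = FALSE)
}
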
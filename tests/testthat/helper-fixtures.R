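# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

# Random MS2 spectra, `n_with_reporter` of which carry a jittered reporter
# peak. Returns list(spectra, truth) with truth a logical vector.
make_random_spectra <- function(n, n_with_reporter, reporter_mz,
                                jitter_ppm = 5, seed = 42) {
  set.seed(seed)
  truth <- rep(FALSE, n)
  truth[sample(n, n_with_reporter)] <- TRUE
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(5:15, 1)
    mz <- runif(k, 50, 1000)
    # keep random fillers out of a generous reporter neighbourhood
    off <- abs(mz - reporter_mz) / reporter_mz * 1e6 < 40
    mz[off] <- mz[off] + 5
    int <- runif(k, 10, 500)
    if (truth[i]) {
      mz <- c(mz, reporter_mz * (1 + runif(1, -jitter_ppm, jitter_ppm) * 1e-6))
      int <- c(int, max(int) * runif(1, 0.5, 1))
    }
    spectra[[i]] <- ms2_spectrum(paste0("s", i), runif(1, 100, 900),
                                 runif(1, 0, 10), mz, int)
  }
  list(spectra = spectra, truth = truth)
}

# Exhaustive linear-scan reference for the diagnostic-peak search: walks
# every peak, keeps those within tolerance, applies the intensity floor.
brute_find_diagnostic <- function(s, reporter_mz, tol_ppm, min_rel) {
  if (!length(s$mz)) return(NULL)
  best <- NULL
  base <- max(s$intensity)
  for (j in seq_along(s$mz)) {
    ppm <- (s$mz[j] - reporter_mz) / reporter_mz * 1e6
    if (abs(ppm) <= tol_ppm &&
        (is.null(best) || s$intensity[j] > best$int)) {
      best <- list(mz = s$mz[j], int = s$intensity[j], ppm = ppm)
    }
  }
  if (is.null(best) || best$int < min_rel * base) return(NULL)
  best
}

# Brute-force connected components of the (RT, m/z) proximity graph by
# repeated breadth-first search (independent of the union-find in the
# package).
brute_components <- function(rt, mz, rt_window, ppm_window) {
  n <- length(rt)
  linked <- function(i, j)
    abs(rt[i] - rt[j]) <= rt_window &&
    abs(mz[i] - mz[j]) / ((mz[i] + mz[j]) / 2) * 1e6 <= ppm_window
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      for (u in seq_len(n))
        if (is.na(comp[u]) && linked(v, u)) queue <- c(queue, u)
    }
  }
  comp
}

# Eigen/SVD-based PLS1 reference: weight = leading left singular vector of
# X'y, explicit deflation; written with different linear algebra than the
# NIPALS loop in the package.
svd_pls1 <- function(x, y, ncomp) {
  xs <- scale(x)
  ys <- y - mean(y)
  Tm <- matrix(0, nrow(xs), ncomp)
  W <- matrix(0, ncol(xs), ncomp)
  for (a in seq_len(ncomp)) {
    s <- svd(crossprod(xs, matrix(ys, ncol = 1)))
    w <- s$u[, 1]
    w <- w * sign(w[which.max(abs(w))])
    tv <- xs %*% w
    p <- crossprod(xs, tv) / sum(tv^2)
    cc <- sum(ys * tv) / sum(tv^2)
    xs <- xs - tcrossprod(tv, p)
    ys <- ys - tv[, 1] * cc
    Tm[, a] <- tv; W[, a] <- w
  }
  list(scores = Tm, weights = W)
}

# Tiny two-group cohort with named analytes, log-normal as in the generator.
tiny_cohort <- function(n = 10, seed = 99) {
  params <- data.frame(analyte = c("A", "B", "C"),
                       control_gm_pmol = c(1, 10, 5),
                       case_over_control = c(2, 1, 0.5))
  gen_cohort(params, n_per_group = n, cv = 0.1, seed = seed)
}
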
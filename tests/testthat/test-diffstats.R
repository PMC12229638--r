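# Fold changes, t-tests, PLS-DA, S-plot, heatmap clustering, volcano.

make_table <- function(case_vals, control_vals, feature = "f1") {
  n1 <- length(case_vals); n2 <- length(control_vals)
  out <- data.frame(sample_id = paste0("s", seq_len(n1 + n2)),
                    group = rep(c("PCNSL", "HV"), c(n1, n2)))
  out[[feature]] <- c(case_vals, control_vals)
  out
}

test_that("fold change is the ratio of group means with direction", {
  tab <- make_table(c(2, 2), c(1, 1))
  fc <- fold_change(tab, "f1")
  expect_equal(fc$fold_change, 2)
  expect_equal(fc$higher_in, "PCNSL")
  same <- make_table(c(3, 5), c(3, 5))
  expect_equal(fold_change(same, "f1")$fold_change, 1)
  zero <- make_table(c(1, 2), c(0, 0))
  expect_warning(fc0 <- fold_change(zero, "f1"), "undefined")
  expect_true(is.na(fc0$fold_change))
})

test_that("pooled t-test matches the closed-form hand computation", {
  tab <- make_table(c(1, 2, 3), c(4, 5, 6))
  r <- two_sample_t(tab, "f1")
  expect_equal(r$t_stat, -3.6742, tolerance = 1e-4)
  expect_equal(r$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(r$stars, "*")
  ident <- make_table(c(5, 5, 5), c(5, 5, 5))
  ri <- two_sample_t(ident, "f1")
  expect_equal(ri$t_stat, 0)
  expect_equal(ri$p_value, 1)
  # degenerate, unequal constant groups: p floors instead of erroring
  deg <- make_table(c(1, 1), c(2, 2))
  expect_lt(two_sample_t(deg, "f1")$p_value, 1e-100)
  # welch variant uses unpooled df
  w <- two_sample_t(make_table(c(1, 2, 3, 9), c(4, 5, 6)), "f1", variant = "welch")
  expect_lt(w$df, 5)
})

test_that("significance stars map the conventional thresholds", {
  expect_equal(signif_stars(c(0.2, 0.04, 0.004, 0.0004)),
               c("", "*", "**", "***"))
})

test_that("NIPALS PLS-DA matches an SVD-based PLS1 oracle on a tiny matrix", {
  set.seed(21)
  x <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  tab <- cbind(data.frame(sample_id = paste0("s", 1:6),
                          group = rep(c("PCNSL", "HV"), each = 3)),
               as.data.frame(x))
  m <- plsda_fit(tab, n_components = 2)
  ref <- svd_pls1(x, ifelse(tab$group == "PCNSL", 1, -1), 2)
  for (a in 1:2) {
    # same subspace up to sign; signs fixed identically by both conventions
    expect_equal(abs(m$scores[, a]), abs(ref$scores[, a]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(m$weights[, a]), abs(ref$weights[, a]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PLS-DA agrees with mixOmics scores up to sign", {
  set.seed(22)
  co <- tiny_cohort(8, seed = 5)
  m <- plsda_fit(co, n_components = 2)
  x <- as.matrix(co[, c("A", "B", "C")])
  ref <- mixOmics::pls(x, ifelse(co$group == "PCNSL", 1, -1), ncomp = 2,
                       scale = TRUE, mode = "regression")
  for (a in 1:2) {
    r <- abs(cor(m$scores[, a], ref$variates$X[, a]))
    expect_gt(r, 0.999)
  }
})

test_that("PLS-DA scores are orthogonal and separate separable groups", {
  co <- tiny_cohort(10, seed = 17)
  m <- plsda_fit(co, n_components = 3)
  G <- crossprod(m$scores)
  nrm <- sqrt(diag(G))
  off <- abs(G - diag(diag(G))) / outer(nrm, nrm)
  expect_lt(max(off), 1e-6)
  # component-1 scores separate the groups (feature A has a 2x shift)
  t1 <- m$scores[, 1]
  expect_true(max(t1[co$group == "HV"]) < min(t1[co$group == "PCNSL"]) ||
              min(t1[co$group == "HV"]) > max(t1[co$group == "PCNSL"]))
  # constant features are dropped with a warning
  co$const <- 5
  expect_warning(plsda_fit(co, 2), "constant")
  expect_error(plsda_fit(tiny_cohort(2, seed = 1), n_components = 5),
               "n_components")
})

test_that("S-plot separates engineered markers from noise", {
  set.seed(33)
  n <- 40
  grp <- rep(c("PCNSL", "HV"), each = n / 2)
  tab <- data.frame(sample_id = paste0("s", 1:n), group = grp)
  tab$marker <- rnorm(n) + ifelse(grp == "PCNSL", 3, 0)
  for (j in 1:5) tab[[paste0("noise", j)]] <- rnorm(n)
  m <- plsda_fit(tab, n_components = 2)
  sp <- splot(m, tab)
  expect_true(all(abs(sp$pcorr1) <= 1 + 1e-12))
  mk <- sp[sp$feature == "marker", ]
  nz <- sp[sp$feature != "marker", ]
  expect_gt(abs(mk$pcorr1), 0.9)
  expect_lt(max(abs(nz$pcorr1)), abs(mk$pcorr1))
  # sign coherence between covariance and correlation arms
  expect_true(all(sign(sp$p1) == sign(sp$pcorr1) | sp$p1 == 0))
})

test_that("pcorr1 stays within [-1, 1] on random data", {
  set.seed(44)
  for (k in 1:25) {
    n <- sample(6:16, 1)
    tab <- data.frame(sample_id = paste0("s", 1:n),
                      group = rep(c("PCNSL", "HV"), length.out = n))
    for (j in 1:4) tab[[paste0("v", j)]] <- rnorm(n)
    m <- plsda_fit(tab, n_components = 1)
    expect_true(all(abs(splot(m, tab)$pcorr1) <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("heatmap z-scores are exact and clustering matches a naive oracle", {
  co <- tiny_cohort(5, seed = 8)
  hm <- heatmap_cluster(co)
  expect_equal(unname(rowMeans(hm$z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(hm$z, 1, sd)), rep(1, 3), tolerance = 1e-12)
  # duplicated feature rows sit on adjacent leaves
  co2 <- co
  co2$A2 <- co2$A
  hm2 <- heatmap_cluster(co2)
  ord <- hm2$feature_hclust$order
  pos <- match(c("A", "A2"), rownames(hm2$z)[ord])
  expect_equal(abs(diff(pos)), 1)
  # merge heights equal brute-force average-linkage agglomeration on 5x4
  set.seed(9)
  zm <- matrix(rnorm(20), 5, 4)
  d <- as.matrix(dist(zm))
  clusters <- as.list(1:5)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  hc <- hclust(dist(zm), method = "average")
  expect_equal(hc$height, heights, tolerance = 1e-12)
  expect_error(heatmap_cluster(co[, c("sample_id", "group", "A")]),
               ">= 2 features")
})

test_that("volcano flags planted proteins with the right direction", {
  tab <- gen_protein_table(n_features = 60, n_planted = 6, effect_size = 3,
                           n_per_group = 10, seed = 13)
  planted <- attr(tab, "planted")
  v <- volcano(tab)
  expect_true(all(v$significant[v$feature %in% planted]))
  expect_true(all(v$log2_fc[v$feature %in% planted] > 0))
  # null table: about the nominal fraction of flags
  null <- gen_protein_table(n_features = 300, n_planted = 0, n_per_group = 10,
                            seed = 14)
  frac <- mean(volcano(null)$significant)
  expect_gt(frac, 0.01); expect_lt(frac, 0.11)
  expect_equal(v$neg_log10_p, -log10(v$p_value))
})
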
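test_that("the feature matrix standardizes, encodes and guards degeneracy", {
  cat0 <- load_reference_catalog()
  sv <- sample_feature_vectors(cat0, 15, 0.05, seed = 8)
  fm <- build_feature_matrix(sv)
  expect_equal(dim(fm$x), c(135, 12))
  expect_true(all(abs(colMeans(fm$x)) < 1e-9))
  expect_true(all(abs(apply(fm$x, 2, sd) - 1) < 1e-9))
  # absent sideband encoded as 0 before standardization
  expect_equal(fm$center[["sideband_spacing"]],
               mean(ifelse(is.na(sv$sideband_spacing), 0, sv$sideband_spacing)))
  expect_identical(fm$labels, sv$group)

  expect_error(build_feature_matrix(sv[1, ]), "at least two")
  two_same <- sv[c(1, 1), ]
  expect_warning(build_feature_matrix(two_same), "constant")
})

test_that("k-means partitions the textbook 1-D instance", {
  x <- matrix(c(0, 0.1, 10, 10.1))
  fit <- cluster_calls(x, 2, seed = 1)
  expect_setequal(as.numeric(fit$centroids), c(0.05, 10.05))
  a <- fit$assignments
  expect_equal(a[1], a[2])
  expect_equal(a[3], a[4])
  expect_false(a[1] == a[3])
  expect_error(cluster_calls(x, 5, seed = 1), "exceed")
})

test_that("within-SS matches the exhaustive bipartition minimum on small instances", {
  fails <- 0
  for (rep in 1:100) {
    x <- withr::with_seed(1000 + rep, {
      n <- sample(4:8, 1)
      matrix(stats::rnorm(n * 2), n)
    })
    fit <- cluster_calls(x, 2, seed = rep, restarts = 50)
    # Lloyd monotonicity along the winning restart
    expect_true(all(diff(fit$wss_history) <= 1e-9))
    if (abs(fit$within_ss - brute_force_wss2(x)) > 1e-8) fails <- fails + 1
  }
  expect_equal(fails, 0)
})

test_that("k-means agrees with an independent implementation on separated data", {
  x <- withr::with_seed(3, rbind(
    matrix(stats::rnorm(40, 0), ncol = 2),
    matrix(stats::rnorm(40, 6), ncol = 2),
    matrix(stats::rnorm(40, -6), ncol = 2)
  ))
  fit <- cluster_calls(x, 3, seed = 1, restarts = 20)
  ref <- withr::with_seed(1, stats::kmeans(x, 3, nstart = 20))
  expect_equal(fit$within_ss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("assignments are invariant to input row order", {
  x <- withr::with_seed(5, matrix(stats::rnorm(60), ncol = 2))
  fit1 <- cluster_calls(x, 3, seed = 7)
  perm <- withr::with_seed(6, sample(nrow(x)))
  fit2 <- cluster_calls(x[perm, ], 3, seed = 7)
  # permuting rows permutes assignments identically (up to label identity)
  expect_identical(fit2$assignments, fit1$assignments[perm])
  expect_equal(fit2$within_ss, fit1$within_ss)
})

test_that("catalog-sampled vectors are recovered at k = 9 with ARI >= 0.9", {
  skip_if_not_installed("mclust")
  cat0 <- load_reference_catalog()
  sv <- sample_feature_vectors(cat0, 20, 0.05, seed = 12)
  fm <- build_feature_matrix(sv)
  fit <- cluster_calls(fm, 9, seed = 1, restarts = 50)
  expect_gte(mclust::adjustedRandIndex(fit$assignments, sv$group), 0.9)
})

test_that("silhouette selection finds the generating number of blobs", {
  x <- withr::with_seed(4, rbind(
    matrix(stats::rnorm(60, 0, 0.4), ncol = 2),
    matrix(stats::rnorm(60, 5, 0.4), ncol = 2),
    matrix(stats::rnorm(60, c(10, 0), 0.4), ncol = 2)
  ))
  expect_equal(as.integer(select_k(x, 2:6, seed = 2)), 3L)

  # 4-point 1-D instance where the silhouette is hand-checkable: {0, 1} vs
  # {10, 11} gives mean silhouette (1 - 1/10.5)/... > any 3-way split
  y <- matrix(c(0, 1, 10, 11))
  expect_equal(as.integer(select_k(y, 2:3, seed = 1)), 2L)
})

test_that("group summaries reproduce ranges, ordering and nesting", {
  m <- tibble::tibble(
    min_f = c(5, 5.5, 5.2), max_f = c(8, 8.5, 8.2), start_f = c(5, 5.5, 5.2),
    end_f = c(8, 8.5, 8.2), delta_f = c(3, 3, 3), duration = c(0.2, 0.5, 1.0),
    n_extrema = c(1L, 2L, 3L), n_inflections = c(0L, 1L, 2L),
    fm_rate = c(0, 2, 2), has_harmonics = TRUE,
    sideband_spacing = NA_real_, call_class = "whistle"
  )
  s <- summarize_groups(m, rep(1L, 3))
  expect_equal(nrow(s), 1)
  expect_equal(s$n, 3)
  expect_equal(c(s$duration_lo, s$duration_hi), c(0.2, 1.0))

  # catalog-sampled calls: every summary range nests within the printed range
  cat0 <- load_reference_catalog()
  sv <- sample_feature_vectors(cat0, 10, 0.05, seed = 3)
  s2 <- summarize_groups(sv, as.integer(factor(sv$group)))
  expect_equal(nrow(s2), 9)
  expect_equal(s2$n[1], 10)
  for (g in unique(sv$group)) {
    idx <- sv$group == g
    cg <- cat0[cat0$group_id == g, ]
    expect_gte(min(sv$duration[idx]), cg$duration_lo)
    expect_lte(max(sv$duration[idx]), cg$duration_hi)
  }
})

test_that("tidy, glance and augment expose the fit in broom shape", {
  x <- withr::with_seed(2, matrix(stats::rnorm(40), ncol = 2))
  fit <- cluster_calls(x, 2, seed = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$size), 20)
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$within_ss, fit$within_ss)
  au <- augment(fit, tibble::tibble(id = 1:20))
  expect_equal(levels(au$.cluster), c("1", "2"))
})
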
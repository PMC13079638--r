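test_that("population-divisor z-scores: hand value, idempotence, TSS = n p", {
  z <- standardize_scores(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(round(as.numeric(z), 4), c(-1.2247, 0, 1.2247))
  expect_equal(standardize_scores(z), z, tolerance = 1e-12)
  ds <- generate_survey(default_generator_config(seed = 42))
  zz <- standardize_scores(system_scores(ds$symptoms, default_codebook()))
  expect_equal(sum(zz^2), 62 * 10, tolerance = 1e-9)
  expect_error(standardize_scores(cbind(a = c(1, 2), b = c(4, 4))),
               "constant column.*b")
})

test_that("k-means at the extremes: k = 1 gives TSS, k = n gives zero", {
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  k1 <- kmeans_fit(x, 1)
  expect_equal(k1$centers[1, ], colMeans(x), ignore_attr = TRUE)
  expect_equal(k1$wcss, sum(sweep(x, 2, colMeans(x))^2))
  expect_equal(kmeans_fit(x, 20)$wcss, 0, tolerance = 1e-12)
})

test_that("k-means separates two distant clouds and matches stats::kmeans", {
  set.seed(42)
  x <- rbind(cbind(rnorm(30) + 10, rnorm(30)),
             cbind(rnorm(30) - 10, rnorm(30)))
  km <- kmeans_fit(x, 2, seed = 42, restarts = 10)
  # Perfect separation: labels constant within each cloud.
  expect_length(unique(km$labels[1:30]), 1)
  expect_length(unique(km$labels[31:60]), 1)
  expect_false(km$labels[1] == km$labels[31])
  # WCSS equals within-cloud scatter and the independent implementation.
  scatter <- sum(sweep(x[1:30, ], 2, colMeans(x[1:30, ]))^2) +
    sum(sweep(x[31:60, ], 2, colMeans(x[31:60, ]))^2)
  expect_equal(km$wcss, scatter, tolerance = 1e-9)
  ref <- kmeans(x, 2, algorithm = "Lloyd", nstart = 10)
  expect_equal(km$wcss, ref$tot.withinss, tolerance = 1e-9)
})

test_that("k-means is bitwise reproducible and WCSS decreases in k", {
  ds <- generate_survey(default_generator_config(seed = 3))
  z <- standardize_scores(system_scores(ds$symptoms, default_codebook()))
  a <- kmeans_fit(z, 3, seed = 42, restarts = 10)
  b <- kmeans_fit(z, 3, seed = 42, restarts = 10)
  expect_identical(a, b)
  wcss <- vapply(1:6, function(k) kmeans_fit(z, k, seed = 42)$wcss, numeric(1))
  expect_true(all(diff(wcss) <= 1e-9))
})

test_that("elbow selects the curvature maximum and flags weak structure", {
  # Three well-separated spherical clouds.
  set.seed(5)
  x <- rbind(cbind(rnorm(30, 0, 0.5), rnorm(30, 0, 0.5)),
             cbind(rnorm(30, 15, 0.5), rnorm(30, 0, 0.5)),
             cbind(rnorm(30, 0, 0.5), rnorm(30, 15, 0.5)))
  el <- elbow(x, k_max = 6, seed = 42)
  expect_identical(el$selected_k, 3L)
  expect_false(el$weak)
  # Single spherical cloud: smooth decay, weak curvature flagged.
  set.seed(6)
  x1 <- matrix(rnorm(400), ncol = 2)
  expect_warning(el1 <- elbow(x1, k_max = 6, seed = 42), "weak")
  expect_true(el1$weak)
  expect_error(elbow(x, k_max = 2), "k_max")
})

test_that("curvature of the published-and-interpolated WCSS curve peaks at k = 2", {
  # The automated criterion lands on k = 2 but flags the choice as weak,
  # i.e. one to confirm by inspection of the reported curvature table.
  expect_warning(cv <- wcss_curvature(c(620, 347.6, 279.78, 255, 240)),
                 "weak")
  expect_identical(cv$selected_k, 2L)
  expect_equal(cv$curvature$second_diff,
               c(620 - 2 * 347.6 + 279.78, 347.6 - 2 * 279.78 + 255,
                 279.78 - 2 * 255 + 240))
  expect_true(cv$weak)
})

test_that("cluster profiles report shares and renumber by descending burden", {
  labels <- rep(c(2L, 0L, 1L), c(13, 25, 24))
  tsb <- rep(c(32, 12, 3), c(13, 25, 24))
  sys <- matrix(tsb / 10, length(tsb), 10,
                dimnames = list(NULL, paste0("sys", 1:10)))
  prof <- cluster_profiles(labels, sys, tsb)
  # Highest-burden group becomes cluster 0 regardless of input labels.
  expect_equal(prof$profiles$cluster, 0:2)
  expect_equal(prof$profiles$size, c(13, 25, 24))
  expect_equal(round(100 * prof$profiles$share, 2), c(20.97, 40.32, 38.71))
  expect_equal(prof$profiles$mean_tsb, c(32, 12, 3))
  expect_equal(prof$labels[1], 0L)
  # All respondents in one cluster -> share 100%.
  one <- cluster_profiles(rep(0L, 10), sys[1:10, ], tsb[1:10])
  expect_equal(one$profiles$share, 1)
})

test_that("well-separated latent classes are recovered by clustering", {
  cb <- default_codebook()
  hits <- 0; ari <- numeric(100)
  for (seed in 1:100) {
    ds <- generate_survey(separated_config(seed = seed))
    sys <- system_scores(ds$symptoms, cb)
    z <- standardize_scores(sys)
    km <- kmeans_fit(z, 3, seed = 42, restarts = 10)
    prof <- cluster_profiles(km$labels, sys, total_symptom_burden(ds$symptoms))
    sizes <- sort(prof$profiles$size)
    if (all(abs(sizes - sort(c(13, 25, 24))) <= 2)) hits <- hits + 1
    ari[seed] <- mclust::adjustedRandIndex(prof$labels, ds$latent_class)
  }
  expect_gte(hits, 80)
  expect_gte(mean(ari), 0.9)
})
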
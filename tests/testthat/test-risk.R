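test_that("exposure prevalence is the column mean of the binary matrix", {
  m <- cbind(a = rep(0L, 62), b = c(rep(1L, 37), rep(0L, 25)), c = rep(1L, 62))
  ep <- exposure_prevalence(m)
  expect_equal(ep$ep, c(0, 37 / 62, 1))
  expect_equal(round(ep$ep[2], 4), 0.5968)
  expect_error(exposure_prevalence(cbind(a = c(0, 2))), "binary")
})

test_that("Cohen's d uses the (n1-1, n2-1) pooled standard deviation", {
  expect_equal(effect_size(c(3, 5, 7, 2, 4), c(1, 1, 1, 0, 0)),
               2 / sqrt(10 / 3), tolerance = 1e-12)
  expect_equal(effect_size(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 0)
  # Scale invariance.
  expect_equal(effect_size(10 * c(3, 5, 7, 2, 4), c(1, 1, 1, 0, 0)),
               effect_size(c(3, 5, 7, 2, 4), c(1, 1, 1, 0, 0)))
  expect_warning(d <- effect_size(c(1, 2, 3), c(1, 1, 1)), "fewer than 2")
  expect_true(is.na(d))
  expect_warning(d0 <- effect_size(rep(5, 6), c(1, 1, 1, 0, 0, 0)),
                 "pooled standard deviation is zero")
  expect_true(is.na(d0))
})

test_that("Cohen's d matches a brute-force oracle on random small vectors", {
  set.seed(101)
  for (i in 1:1000) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    # Oracle: definition computed from first principles.
    sp <- sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2))
    expect_equal(effect_size(c(x, y), rep(c(1, 0), c(n1, n2))),
                 (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney matches enumeration and wilcox.test", {
  # Frozen hand-enumerated case: maximal separation of 3 vs 3.
  r <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$U, 9)
  expect_equal(r$p, 0.1)
  expect_identical(r$method, "exact")
  # Identical tied samples: every arrangement is as extreme.
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # Tie-free random cases against the exact wilcox.test oracle.
  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1); y <- sample(setdiff(seq_len(50), x), n2)
    ours <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal form", {
  set.seed(8)
  x <- sample(0:5, 30, replace = TRUE)
  y <- sample(0:5, 25, replace = TRUE) + 1
  ours <- mann_whitney_u(x, y)
  expect_identical(ours$method, "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("breadth counts systems with significant burden differences", {
  set.seed(21)
  # Strong shift in all 10 systems, n = 31 + 31.
  expo <- rep(c(1, 0), each = 31)
  scores <- matrix(rnorm(62 * 10), 62, 10,
                   dimnames = list(NULL, paste0("sys", 1:10)))
  scores[expo == 1, ] <- scores[expo == 1, ] + 3
  b <- baps(scores, expo)
  expect_identical(b$baps, 10L)
  # Identical exact distributions are never counted.
  sc1 <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), 6, 2)
  b1 <- baps(sc1, c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(b1$p_values), c(1, 1))
  expect_identical(b1$baps, 0L)
  expect_warning(b2 <- baps(sc1, rep(1, 6)), "empty")
  expect_true(is.na(b2$baps))
})

test_that("breadth type-I rate is near 10 x alpha under the null", {
  ds <- generate_survey(default_generator_config(seed = 2))
  sys <- system_scores(ds$symptoms, default_codebook())
  set.seed(33)
  nulls <- replicate(1000, {
    expo <- rbinom(62, 1, 0.5)
    if (all(expo == 1) || all(expo == 0)) NA_integer_
    else baps(sys, expo)$baps
  })
  # Expected BAPS = 10 * 0.05 = 0.5; tolerance +/- 50% relative.
  expect_gt(mean(nulls, na.rm = TRUE), 0.25)
  expect_lt(mean(nulls, na.rm = TRUE), 0.75)
})

test_that("composite risk score is the declared weighted aggregate", {
  # ES_norm, BAPS_norm, EP all at the ceiling.
  expect_equal(composite_risk_score(ep = 1, es = 2, baps = 10, es_max = 2), 1)
  expect_equal(composite_risk_score(ep = 0.4, es = 0.8, baps = 6, es_max = 1),
               0.5 * 0.8 + 0.3 * 0.6 + 0.2 * 0.4)
  expect_equal(composite_risk_score(ep = 0, es = 0, baps = 0), 0)
  expect_error(composite_risk_score(1, 1, 1, weights = c(es = 0.5, baps = 0.3,
                                                         ep = 0.3)),
               "sum to 1")
  # Monotone nondecreasing in each component.
  base <- composite_risk_score(ep = 0.3, es = 0.5, baps = 4, es_max = 1)
  expect_gte(composite_risk_score(ep = 0.4, es = 0.5, baps = 4, es_max = 1), base)
  expect_gte(composite_risk_score(ep = 0.3, es = 0.7, baps = 4, es_max = 1), base)
  expect_gte(composite_risk_score(ep = 0.3, es = 0.5, baps = 5, es_max = 1), base)
})

test_that("risk ranking: dominance wins, absent factors flagged NA", {
  cb <- default_codebook()
  cfg <- default_generator_config(seed = 13)
  ds <- generate_survey(cfg)
  # Plant a dominant factor: exposure strongly tied to burden.
  tsb <- total_symptom_burden(ds$symptoms)
  ds$risks[, 1] <- as.integer(tsb > median(tsb))
  ds$risks[, 2] <- 0L  # never-present factor
  tab <- rank_risk_factors(ds, cb)
  expect_identical(tab$item[1], colnames(ds$risks)[1])
  row2 <- tab[tab$item == colnames(ds$risks)[2], ]
  expect_equal(row2$ep, 0)
  expect_true(is.na(row2$es) && is.na(row2$crs))
  expect_identical(row2$rank, nrow(tab))
  # Per-system p-values come along in long format.
  sp <- attr(tab, "system_p")
  expect_identical(nrow(sp), 47L * 10L)
})
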
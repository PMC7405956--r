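test_that("Bland-Altman reproduces hand-computed bias and limits", {
  ba0 <- bland_altman(c(5, 7, 9), c(5, 7, 9))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_upper - ba0$loa_lower, 0)
  ba1 <- bland_altman(c(2, 3, 4), c(1, 2, 3))  # differences all 1
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$sd_diff, 0)
  expect_equal(c(ba1$loa_lower, ba1$loa_upper), c(1, 1))
  ba2 <- bland_altman(c(1, 4), c(1, 2))        # differences 0, 2
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$loa_lower, 1 - 1.96 * sqrt(2))
  expect_equal(ba2$loa_upper, 1 + 1.96 * sqrt(2))
  # CI widths follow the SD/sqrt(n) and sqrt(3) SD/sqrt(n) standard errors
  n <- 2
  tq <- qt(0.975, n - 1)
  expect_equal(diff(ba2$bias_ci), 2 * tq * sqrt(2) / sqrt(2))
  expect_equal(diff(ba2$loa_lower_ci), 2 * tq * sqrt(3) * sqrt(2) / sqrt(2))
  expect_error(bland_altman(1, 1), "2 complete pairs")
  expect_error(bland_altman(1:3, 1:4), "length")
  td <- tidy(ba2)
  expect_equal(td$estimate[td$term == "bias"], 1)
})

test_that("Bland-Altman bias is antisymmetric under argument swap", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(10, 50, 5)
    b <- a + rnorm(10, 0.5, 1)
    f <- bland_altman(a, b)
    r <- bland_altman(b, a)
    expect_equal(f$bias, -r$bias)
    expect_equal(f$loa_lower, -r$loa_upper)
    expect_equal(f$sd_diff, r$sd_diff)
  }
})

test_that("Mann-Whitney U matches brute-force pairwise counting and enumeration", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 3))$U, 1.5)  # midrank tie
  expect_equal(mann_whitney_u(1:4, 1:4)$U, 16 / 2)       # identical -> n^2/2
  # exhaustive: all 2-vs-2 samples over values 1..4 and 3-vs-3 over 1..3
  vals2 <- expand.grid(a1 = 1:4, a2 = 1:4, b1 = 1:4, b2 = 1:4)
  for (i in seq_len(nrow(vals2))) {
    a <- as.numeric(vals2[i, 1:2]); b <- as.numeric(vals2[i, 3:4])
    res <- mann_whitney_u(a, b, method = "exact")
    expect_equal(res$U, brute_u(a, b))
    expect_equal(res$p, brute_mw_p(a, b))
  }
  vals3 <- expand.grid(a1 = 1:3, a2 = 1:3, a3 = 1:3,
                       b1 = 1:3, b2 = 1:3, b3 = 1:3)
  idx <- seq(1, nrow(vals3), by = 7)  # systematic subsample of the 729 grids
  for (i in idx) {
    a <- as.numeric(vals3[i, 1:3]); b <- as.numeric(vals3[i, 4:6])
    res <- mann_whitney_u(a, b, method = "exact")
    expect_equal(res$U, brute_u(a, b))
    expect_equal(res$p, brute_mw_p(a, b))
  }
})

test_that("Mann-Whitney agrees with wilcox.test and is monotone-invariant", {
  set.seed(9)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  res <- mann_whitney_u(a, b)
  w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(res$U, min(unname(w$statistic),
                          length(a) * length(b) - unname(w$statistic)))
  expect_equal(res$p, w$p.value, tolerance = 1e-10)
  # invariance under a monotone transform of the pooled data
  res2 <- mann_whitney_u(exp(a), exp(b))
  expect_equal(res2$U, res$U)
  expect_equal(res2$p, res$p)
  expect_error(mann_whitney_u(numeric(), 1:3), "nonempty")
})

test_that("t statistics match the from-scratch formula oracle", {
  # frozen: a = 1:3 vs b = 2:4, pooled t = -1.2247448714, p = 0.2878641347
  tt <- unpaired_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.2247448714, tolerance = 1e-9)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878641347, tolerance = 1e-9)
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  pt0 <- paired_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(pt0$t, 0)
  expect_equal(pt0$p, 1)
  expect_equal(pt0$flag, "zero_variance_zero_diff")
  pt1 <- paired_t(c(5, 6, 7), c(4, 5, 6))
  expect_equal(pt1$p, 0)
  expect_equal(pt1$flag, "zero_variance_nonzero_diff")
  ht <- t.test(c(1, 5, 3, 4) - c(2, 2, 2, 5))
  pt2 <- paired_t(c(1, 5, 3, 4), c(2, 2, 2, 5))
  expect_equal(pt2$t, unname(ht$statistic))
  expect_equal(pt2$p, ht$p.value)
})

test_that("Yates chi-square reproduces the study's sex-distribution bound", {
  res <- chi_square_2x2(matrix(c(12, 13, 14, 16), 2, byrow = TRUE))
  expect_gt(res$p, 0.99)
  expect_equal(res$df, 1)
  # identical proportions: statistic 0 after correction clamp
  expect_equal(chi_square_2x2(matrix(c(10, 10, 20, 20), 2))$statistic, 0)
  expect_lt(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$p, 0.001)
  expect_error(chi_square_2x2(matrix(c(1, 2, 3), 1)), "2x2")
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margins")
})

test_that("D'Agostino-Pearson matches frozen reference values", {
  x <- c(2.3, 1.8, 4.1, 0.5, 3.3, 2.9, 1.1, 5.2, 2.0, 3.7,
         0.9, 2.6, 4.4, 1.5, 3.0, 2.2, 1.9, 3.9, 0.2, 2.8)
  res <- dagostino_pearson(x)
  expect_equal(res$K2, 0.2493586541, tolerance = 1e-8)
  expect_equal(res$p, 0.8827799409, tolerance = 1e-8)
  y <- c(0.1, 0.2, 0.3, 0.5, 0.8, 1.3, 2.1, 3.4, 5.5, 8.9, 14.4, 23.3)
  resy <- dagostino_pearson(y)
  expect_equal(resy$K2, 11.2464772557, tolerance = 1e-8)
  expect_equal(resy$p, 0.0036129212, tolerance = 1e-8)
  expect_error(dagostino_pearson(rep(1, 10)), "Constant")
  expect_error(dagostino_pearson(1:5), "n >= 8")
})

test_that("D'Agostino-Pearson separates normal from skewed samples", {
  normal_ok <- 0
  expo_flag <- 0
  nseed <- 60
  for (s in seq_len(nseed)) {
    set.seed(1000 + s)
    if (dagostino_pearson(rnorm(500))$p > 0.05) normal_ok <- normal_ok + 1
    if (dagostino_pearson(rexp(500))$p < 0.05) expo_flag <- expo_flag + 1
  }
  expect_gte(normal_ok / nseed, 0.90)
  expect_gte(expo_flag / nseed, 0.90)
})

test_that("the normality gate routes to t or Mann-Whitney as prescribed", {
  set.seed(21)
  a <- rnorm(30, 10, 2)
  b <- rnorm(30, 12, 2)
  res <- compare_groups(a, b)
  expect_equal(res$test, "t")
  expect_equal(res$gate$reason, "normal_equal_variance")
  skew <- rexp(30)
  res2 <- compare_groups(a, skew)
  expect_equal(res2$test, "mann_whitney")
  expect_equal(res2$gate$reason, "non_normal")
  res3 <- compare_groups(rnorm(30, 10, 1), rnorm(30, 10, 6))
  expect_equal(res3$test, "mann_whitney")
  expect_equal(res3$gate$reason, "unequal_variance")
  res4 <- compare_groups(rnorm(5), rnorm(30))
  expect_equal(res4$test, "mann_whitney")
  expect_equal(res4$gate$reason, "group_too_small_for_normality_test")
  expect_true(all(c(res$p, res2$p, res3$p, res4$p) >= 0 &
                    c(res$p, res2$p, res3$p, res4$p) <= 1))
})

test_that("random eye selection is seeded, uniform, and respects availability", {
  co <- tibble::tibble(participant = sprintf("P%02d", 1:6),
                       has_od = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                       has_os = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  s1 <- select_random_eye(co, seed = 3)
  expect_identical(s1, select_random_eye(co, seed = 3))
  expect_equal(s1$eye[3], "OD")  # single-eye participants keep their eye
  expect_equal(s1$eye[4], "OS")
  both <- tibble::tibble(participant = "X", has_od = TRUE, has_os = TRUE)
  picks <- vapply(1:2000, function(s) select_random_eye(both, seed = s)$eye, "")
  expect_equal(mean(picks == "OD"), 0.5, tolerance = 0.05)
  expect_error(select_random_eye(tibble::tibble(participant = "Y",
                                                has_od = FALSE,
                                                has_os = FALSE), seed = 1),
               "at least one eye")
})
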
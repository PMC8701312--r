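test_that("Welch t reproduces the printed demographic statistics", {
  # full-scale IQ row
  expect_equal(round(welch_t_from_summary(101.38, 13.19, 33,
                                          107.07, 11.52, 37)$statistic, 2),
               -1.91)
  # interscan interval row
  expect_equal(round(welch_t_from_summary(2.07, 0.28, 33,
                                          2.06, 0.20, 37)$statistic, 2), 0.17)
  # repetitive-behavior totals and subscales at T1
  expect_equal(round(welch_t_from_summary(25.18, 18.80, 33,
                                          2.11, 3.67, 37)$statistic, 1), 6.9)
  expect_equal(round(welch_t_from_summary(16.88, 11.26, 33,
                                          1.59, 2.85, 37)$statistic, 2), 7.59)
  expect_equal(round(welch_t_from_summary(4.36, 5.17, 33,
                                          0.16, 0.60, 37)$statistic, 2), 4.64)
})

test_that("Welch t agrees with the direct-formula oracle on random summaries", {
  set.seed(21)
  for (i in 1:50) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.5, 4); s2 <- runif(1, 0.5, 4)
    n1 <- sample(3:80, 1); n2 <- sample(3:80, 1)
    gt <- welch_t_from_summary(m1, s1, n1, m2, s2, n2)
    t_oracle <- (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
    df_oracle <- (s1^2 / n1 + s2^2 / n2)^2 /
      ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    expect_equal(gt$statistic, t_oracle, tolerance = 1e-12)
    expect_equal(gt$df, df_oracle, tolerance = 1e-12)
    expect_equal(gt$p, 2 * pt(-abs(t_oracle), df_oracle), tolerance = 1e-12)
  }
})

test_that("identical summaries give t = 0, p = 1; degenerate variances error", {
  gt <- welch_t_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p, 1)
  expect_error(welch_t_from_summary(1, 0, 5, 2, 0, 5), "degenerate")
})

test_that("Yates chi-squared reproduces the printed handedness and sex rows", {
  expect_equal(round(chi2_2x2(29, 4, 34, 3)$statistic, 3), 0.025)
  expect_lt(chi2_2x2(27, 6, 30, 7)$statistic, 0.001)
})

test_that("proportional tables give zero; Yates never exceeds plain chi-squared", {
  expect_equal(chi2_2x2(10, 20, 5, 10, continuity = FALSE)$statistic, 0)
  set.seed(31)
  for (i in 1:30) {
    x <- sample(1:30, 4, replace = TRUE)
    y <- chi2_2x2(x[1], x[2], x[3], x[4], continuity = TRUE)$statistic
    p <- chi2_2x2(x[1], x[2], x[3], x[4], continuity = FALSE)$statistic
    expect_lte(y, p + 1e-12)
  }
  expect_error(chi2_2x2(0, 0, 3, 4), "margin")
})

test_that("complete matrices pass through imputation unchanged", {
  m <- fixture_item_matrix(10, 6)
  expect_identical(pmm_impute(m, seed = 1), m)
})

test_that("single-donor imputation picks the nearest-prediction donor (toy oracle)", {
  # 4 subjects x 3 items; subject 4 missing item 3. Complete cases 1-3.
  # OLS of item3 on items 1-2 over rows 1-3, prediction for each row,
  # donor = complete case with nearest prediction to subject 4's.
  m <- rbind(c(0, 1, 1),
             c(1, 2, 2),
             c(3, 3, 3),
             c(1, 2, NA))
  X <- cbind(1, m[1:3, 1:2])
  beta <- qr.solve(X, m[1:3, 3])
  pred <- drop(X %*% beta)
  pred4 <- sum(c(1, 1, 2) * beta)
  donor <- which.min(abs(pred - pred4))
  out <- pmm_impute(m, k_donors = 1, seed = 5)
  expect_equal(out[4, 3], m[donor, 3])
  expect_identical(out[1:3, ], m[1:3, ])
})

test_that("imputed values stay in the observed support; randomness is local to imputed cells", {
  set.seed(9)
  m <- fixture_item_matrix(30, 8, seed = 12)
  miss <- m
  holes <- cbind(sample(1:30, 12), sample(1:8, 12, replace = TRUE))
  miss[holes] <- NA
  out1 <- pmm_impute(miss, seed = 3)
  out2 <- pmm_impute(miss, seed = 3)
  out3 <- pmm_impute(miss, seed = 4)
  expect_identical(out1, out2)
  expect_false(anyNA(out1))
  for (j in 1:8) {
    obs <- miss[!is.na(miss[, j]), j]
    expect_true(all(out1[, j] %in% obs | !is.na(miss[, j])))
    expect_true(all(out1[, j] >= min(obs) & out1[, j] <= max(obs)))
  }
  changed <- which(out1 != out3)
  expect_true(all(changed %in% which(is.na(miss))))
})

test_that("insufficient donors is an informative error", {
  m <- rbind(c(1, 2, NA), c(2, 1, 3))
  expect_error(pmm_impute(m, k_donors = 5, seed = 1), "insufficient donors")
})

test_that("scoring sums items into totals and factors; deltas are antisymmetric", {
  fm <- list(F1 = 1:2, F2 = 3, F3 = 4, F4 = 5)
  t1 <- matrix(c(1, 2, 0, 3, 1), 1)
  t2 <- matrix(c(2, 2, 1, 0, 1), 1)
  sc <- score_rbsr(t1, t2, fm)
  expect_equal(sc$total_t1, 7)
  expect_equal(sc$F1_t1, 3)
  expect_equal(sc$F2_t1, 0)
  expect_equal(sc$F3_t1, 3)
  expect_equal(sc$F4_t1, 1)
  swapped <- score_rbsr(t2, t1, fm)
  expect_equal(sc$delta_total, -swapped$delta_total)
  z <- matrix(0, 2, 5)
  expect_true(all(as.matrix(score_rbsr(z, z, fm)) == 0))
  expect_equal(score_rbsr(t1, t1, fm)$delta_total, 0)
})

test_that("factor maps must assign every item to exactly one factor", {
  expect_error(score_rbsr(matrix(0, 1, 5), matrix(0, 1, 5),
                          list(F1 = 1:3, F2 = 3:5)), "more than one factor")
  expect_error(score_rbsr(matrix(0, 1, 5), matrix(0, 1, 5),
                          list(F1 = 1:4)), "every item")
  fm43 <- default_rbsr_factor_map()
  expect_equal(sort(unlist(fm43, use.names = FALSE)), 1:43)
})

test_that("change-score distribution fractions and extrema", {
  s <- change_distribution_summary(c(-3, 0, 2))
  expect_equal(s$decreased, 1 / 3)
  expect_equal(s$increased, 1 / 3)
  expect_equal(s$unchanged, 1 / 3)
  expect_equal(s$max_decrease, -3)
  expect_equal(s$max_increase, 2)
  z <- change_distribution_summary(rep(0, 5))
  expect_equal(z$unchanged, 1)
  p1 <- change_distribution_summary(c(5, -2, 0, 1))
  p2 <- change_distribution_summary(c(0, 1, 5, -2))
  expect_equal(p1, p2)
  expect_error(change_distribution_summary(numeric(0)), "empty")
})

test_that("cohort comparison table has the demographic and behavioral layers", {
  m <- fixture_mesh(0)
  sc <- simulate_cohort(sim_config(seed = 6, mesh_subdivisions = 0), mesh = m)
  tab <- cohort_comparison_table(sc$cohort, seed = 2)
  expect_true(all(c("fsiq", "sex", "handedness", "rbsr_total_t1") %in% tab$measure))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_lt(tab$p[tab$measure == "rbsr_total_t1"], 0.001)
})
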
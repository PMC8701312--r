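test_that("identical seed gives bit-identical cohorts", {
  m <- fixture_mesh(1)
  cfg <- sim_config(seed = 5, mesh_subdivisions = 1)
  a <- simulate_cohort(cfg, mesh = m)
  b <- simulate_cohort(cfg, mesh = m)
  expect_identical(a$ct_t1, b$ct_t1)
  expect_identical(a$ct_t2, b$ct_t2)
  expect_identical(a$cohort$rbsr_t1, b$cohort$rbsr_t1)
  expect_identical(a$cohort$subjects, b$cohort$subjects)
})

test_that("seed sub-streams are independent across components", {
  m <- fixture_mesh(1)
  cfg1 <- sim_config(seed = 5, mesh_subdivisions = 1)
  cfg2 <- sim_config(seed = 5, mesh_subdivisions = 1,
                     rbsr = list(missing_rate = 0.3))
  a <- simulate_cohort(cfg1, mesh = m)
  b <- simulate_cohort(cfg2, mesh = m)
  # changing the behavioral component must not perturb the thickness draws
  expect_identical(a$ct_t1, b$ct_t1)
})

test_that("deterministic limit: zero noise recovers the thinning rate exactly", {
  m <- fixture_mesh(1)
  cfg <- sim_config(seed = 2, mesh_subdivisions = 1, subject_sd = 0,
                    noise_sd = 0, age_slope = 0)
  sc <- simulate_cohort(cfg, mesh = m)
  rate <- (sc$ct_t2 - sc$ct_t1) / sc$cohort$subjects$isi
  expect_equal(as.numeric(rate), rep(cfg$thinning_rate_td, length(rate)),
               tolerance = 1e-12)
})

test_that("planted patch shifts the cluster-mean CT_spc difference as generated", {
  m <- fixture_mesh(2)
  delta <- 0.02
  diffs <- vapply(1:25, function(s) {
    cfg <- sim_config(seed = s, mesh_subdivisions = 2, group_rate_delta = delta,
                      planted_clusters = list(list(seed_vertex = 7L,
                                                   radius = 18, sign = 1)))
    sc <- simulate_cohort(cfg, mesh = m)
    patch <- which(sc$truth$cluster_labels == 1)
    ct <- cohort_ctspc(sc)
    g <- sc$cohort$subjects$group
    mean(ct[g == "ASD", patch]) - mean(ct[g == "TD", patch])
  }, 0)
  # analytic value implied by the generative slopes
  b <- 2.7; r <- -0.03; isi <- 2.06
  expected <- 100 * (r + delta) / (b + (r + delta) * isi / 2) -
    100 * r / (b + r * isi / 2)
  expect_gt(mean(diffs), 0)
  expect_lt(abs(mean(diffs) - expected),
            2.5 * stats::sd(diffs) / sqrt(length(diffs)) + 0.02 * abs(expected))
})

test_that("null exchangeability: no planted effect gives a centered group t-map", {
  m <- fixture_mesh(2)
  tbars <- vapply(1:20, function(s) {
    sc <- simulate_cohort(sim_config(seed = s, mesh_subdivisions = 2), mesh = m)
    fit <- fit_vertex_glm(cohort_ctspc(sc),
                          build_design(sc$cohort$subjects, "group_model"),
                          "group")
    mean(fit$tmap)
  }, 0)
  expect_lt(abs(mean(tbars)), 3 * stats::sd(tbars) / sqrt(length(tbars)) + 0.02)
})

test_that("ASD item totals stochastically dominate TD totals", {
  m <- fixture_mesh(0)
  sc <- simulate_cohort(sim_config(seed = 3, mesh_subdivisions = 0), mesh = m)
  t1 <- pmm_impute(sc$cohort$rbsr_t1, seed = 1)
  tot <- rowSums(t1)
  g <- sc$cohort$subjects$group
  wt <- stats::wilcox.test(tot[g == "ASD"], tot[g == "TD"],
                           alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 1e-4)
})

test_that("planted cluster radius beyond the mesh diameter is a config error", {
  expect_error(sim_config(planted_clusters = list(
    list(seed_vertex = 1L, radius = 1000))), "exceeds the mesh diameter")
})

test_that("expression generator plants genes at the configured correlation", {
  m <- fixture_mesh(2)
  eff <- rnorm(n_vertices(m))
  ex <- simulate_expression(m, eff, list(n_genes = 50, n_samples = 60,
                                         n_planted = 5,
                                         planted_correlation = 1), seed = 4)
  sv <- eff[ex$samples$vertex]
  for (g in ex$planted) {
    expect_equal(abs(cor(ex$expr[g, ], sv)), 1, tolerance = 1e-10)
  }
  ex2 <- simulate_expression(m, eff, list(n_genes = 50, n_samples = 60,
                                          n_planted = 5,
                                          planted_correlation = 1), seed = 4)
  expect_identical(ex$expr, ex2$expr)
  expect_error(
    simulate_expression(m, eff, list(n_genes = 10, n_samples = 2,
                                     n_planted = 0,
                                     planted_correlation = 0), seed = 1),
    "3 samples")
})

test_that("null expression decodes at the nominal false-positive rate", {
  m <- fixture_mesh(2)
  eff <- rnorm(n_vertices(m))
  frac <- vapply(1:40, function(s) {
    ex <- simulate_expression(m, eff, list(n_genes = 200, n_samples = 40,
                                           n_planted = 0,
                                           planted_correlation = 0), seed = s)
    d <- decode(eff, ex$expr, ex$samples, alpha = 0.05)
    length(d$candidates) / nrow(ex$expr)
  }, 0)
  # candidates require r > 0 as well as two-sided p < alpha: alpha/2 expected
  expect_equal(mean(frac), 0.025, tolerance = 0.35)
})
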
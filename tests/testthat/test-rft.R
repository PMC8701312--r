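test_that("smoothness estimate recovers the applied kernel width", {
  m <- fixture_mesh(4)
  set.seed(51)
  n <- 30
  R <- matrix(rnorm(n * n_vertices(m)), n)
  Rs <- smooth_vertex_map(R, m, 10)
  sm <- estimate_smoothness(Rs, m)
  expect_lt(abs(sm$fwhm_median - 10) / 10, 0.2)
  expect_true(all(sm$fwhm > 0))
  expect_true(sm$total_resels > 0)
})

test_that("doubling the mesh scale doubles the FWHM estimate (units mm)", {
  m1 <- fixture_mesh(2, 40)
  m2 <- fixture_mesh(2, 80)
  set.seed(52)
  R <- matrix(rnorm(20 * n_vertices(m1)), 20)
  f1 <- estimate_smoothness(R, m1)$fwhm_median
  f2 <- estimate_smoothness(R, m2)$fwhm_median
  expect_equal(f2, 2 * f1, tolerance = 1e-10)
})

test_that("rougher residuals give fewer mm of FWHM and more resels", {
  m <- fixture_mesh(3)
  set.seed(53)
  R <- matrix(rnorm(25 * n_vertices(m)), 25)
  sm_rough <- estimate_smoothness(smooth_vertex_map(R, m, 6), m)
  sm_smooth <- estimate_smoothness(smooth_vertex_map(R, m, 14), m)
  expect_lt(sm_rough$fwhm_median, sm_smooth$fwhm_median)
  expect_gt(sm_rough$total_resels, sm_smooth$total_resels)
})

test_that("degenerate residuals are rejected", {
  m <- fixture_mesh(1)
  R <- matrix(rep(rnorm(n_vertices(m)), each = 5), 5)
  expect_error(estimate_smoothness(R * 0, m), "zero-variance")
  expect_error(estimate_smoothness(matrix(rnorm(2 * 42), 2), m), "3 subjects")
})

test_that("cluster finding labels a hand-built patch on the icosahedron", {
  m <- fixture_mesh(0)  # 12 vertices
  t <- numeric(12)
  patch <- c(1L, 2L)    # adjacent on the icosahedron
  expect_true(2L %in% m$adjacency[[1L]])
  t[patch] <- 5
  cs <- find_clusters(t, dof = 30, p_form = 0.05, m, tails = 2)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(sort(cs$members[[1]]), patch)
  expect_equal(cs$clusters$sign, "positive")
  expect_equal(cs$clusters$peak_t, 5)
  expect_equal(sum(cs$labels > 0), 2)
})

test_that("an all-zero map has no clusters; negation mirrors the cluster sets", {
  m <- fixture_mesh(2)
  expect_equal(nrow(find_clusters(numeric(n_vertices(m)), 30, 0.05, m)$clusters), 0)
  set.seed(54)
  t <- smooth_vertex_map(rnorm(n_vertices(m), 0, 2), m, 12)
  cs_pos <- find_clusters(t, 30, 0.05, m)
  cs_neg <- find_clusters(-t, 30, 0.05, m)
  expect_equal(nrow(cs_pos$clusters), nrow(cs_neg$clusters))
  pos_members <- cs_pos$members[cs_pos$clusters$sign == "positive"]
  neg_members <- cs_neg$members[cs_neg$clusters$sign == "negative"]
  expect_setequal(lapply(pos_members, sort), lapply(neg_members, sort))
})

test_that("corrected p is monotone in extent with the upper-bound limit at zero extent", {
  m <- fixture_mesh(2)
  set.seed(55)
  R <- smooth_vertex_map(matrix(rnorm(20 * n_vertices(m)), 20), m, 10)
  sm <- estimate_smoothness(R, m)
  cs <- list(u = qt(0.975, 16), dof = 16, tails = 2,
             members = list(1L, 1:7, 1:30),
             clusters = data.frame(id = 1:3, sign = "positive",
                                   n_vertices = c(1, 7, 30),
                                   area_mm2 = 1, peak_t = 3, peak_vertex = 1))
  class(cs) <- "cluster_set"
  out <- cluster_p_rft(cs, sm)
  p <- out$clusters$p_cluster
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  # zero-extent limit equals the probability of any cluster at all
  cs0 <- cs
  cs0$members <- list(integer(0))
  cs0$clusters <- cs0$clusters[1, ]
  p0 <- cluster_p_rft(cs0, sm)$clusters$p_cluster
  expect_equal(p0, 1 - exp(-2 * out$expected_clusters))
  bad <- cs; bad$u <- -1
  expect_error(cluster_p_rft(bad, sm), "positive")
})

test_that("negating the t-map leaves corrected cluster p-values unchanged", {
  m <- fixture_mesh(3)
  sc <- simulate_cohort(sim_config(seed = 60, mesh_subdivisions = 3), mesh = m)
  Y <- smooth_vertex_map(cohort_ctspc(sc), m, 10)
  fit <- fit_vertex_glm(Y, build_design(sc$cohort$subjects, "group_model"),
                        "group")
  sm <- estimate_smoothness(residuals(fit), m)
  a <- cluster_p_rft(find_clusters(fit$tmap, fit$dof, 0.05, m), sm)
  b <- cluster_p_rft(find_clusters(-fit$tmap, fit$dof, 0.05, m), sm)
  expect_equal(sort(a$clusters$p_cluster), sort(b$clusters$p_cluster),
               tolerance = 1e-12)
})

test_that("permutation test is seeded, floored at 1/(n+1), and flags strong effects", {
  m <- fixture_mesh(3)
  cfg <- sim_config(seed = 61, mesh_subdivisions = 3, group_rate_delta = 0.05,
                    planted_clusters = list(list(seed_vertex = 20L,
                                                 radius = 18, sign = 1)))
  sc <- simulate_cohort(cfg, mesh = m)
  Y <- smooth_vertex_map(cohort_ctspc(sc), m, 10)
  d <- build_design(sc$cohort$subjects, "group_model")
  pt1 <- permutation_cluster_test(Y, d, "group", m, 0.05, n_perm = 99, seed = 3)
  pt2 <- permutation_cluster_test(Y, d, "group", m, 0.05, n_perm = 99, seed = 3)
  expect_identical(pt1$clusters$p_perm, pt2$clusters$p_perm)
  expect_equal(min(pt1$clusters$p_perm), 1 / 100)
  expect_warning(
    permutation_cluster_test(Y, d, "group", m, 0.05, n_perm = 20, seed = 1),
    "n_perm")
})
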
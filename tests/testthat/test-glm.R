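test_that("design columns are centered over the declared population", {
  subj <- fixture_subjects(24)
  d <- build_design(subj, "group_model")
  for (col in c("age", "fsiq", "isi", "age2")) {
    expect_lt(abs(mean(d$X[, col])), 1e-10)
  }
  d_asd <- build_design(subj, "group_model", centering_population = "asd")
  asd <- subj$group == "ASD"
  expect_lt(abs(mean(d_asd$X[asd, "age"])), 1e-10)
  expect_gt(abs(mean(d_asd$X[, "age"])), 1e-10)
})

test_that("two subjects identical except group differ only in the group column", {
  subj <- fixture_subjects(24)
  subj2 <- subj
  subj2$group[1] <- if (subj$group[1] == "ASD") "TD" else "ASD"
  # keep the centering population comparable by flipping one of each
  X1 <- build_design(subj, "group_model")$X
  X2 <- build_design(subj2, "group_model")$X
  changed <- which(colSums(abs(X1 - X2)) > 1e-12)
  expect_equal(colnames(X1)[changed], "group")
})

test_that("duplicated covariates give a rank-deficiency error naming the column", {
  subj <- fixture_subjects(24)
  subj$isi <- subj$age_t1     # perfectly collinear with age
  expect_error(build_design(subj, "group_model"), "collinear.*isi")
})

test_that("fit recovers noiseless coefficients exactly and matches the normal-equations oracle", {
  subj <- fixture_subjects(30)
  d <- build_design(subj, "group_model")
  p <- ncol(d$X)
  set.seed(17)
  V <- 80
  beta_true <- matrix(rnorm(p * V), p, V)
  Y0 <- d$X %*% beta_true
  fit0 <- fit_vertex_glm(Y0, d, "group")
  expect_equal(unname(fit0$beta), unname(beta_true), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit0))), 1e-9)

  Y <- Y0 + matrix(rnorm(nrow(Y0) * V), nrow(Y0), V)
  fit <- fit_vertex_glm(Y, d, "group")
  X <- d$X
  xtxinv <- solve(t(X) %*% X)
  cvec <- as.numeric(colnames(X) == "group")
  picks <- sample(V, 50)
  for (v in picks) {
    b_or <- xtxinv %*% t(X) %*% Y[, v]
    expect_equal(unname(fit$beta[, v]), as.numeric(b_or), tolerance = 1e-8)
    res <- Y[, v] - X %*% b_or
    s2 <- sum(res^2) / (nrow(X) - ncol(X))
    t_or <- (t(cvec) %*% b_or) / sqrt(s2 * t(cvec) %*% xtxinv %*% cvec)
    expect_equal(fit$tmap[v], as.numeric(t_or), tolerance = 1e-8)
  }
})

test_that("permuting subjects consistently leaves beta and t unchanged", {
  subj <- fixture_subjects(25)
  d <- build_design(subj, "group_model")
  set.seed(5)
  Y <- matrix(rnorm(25 * 40), 25, 40)
  fit <- fit_vertex_glm(Y, d, "group")
  perm <- sample(25)
  fit_p <- fit_vertex_glm(Y[perm, ], d$X[perm, ], "group")
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-10)
  expect_equal(fit_p$tmap, fit$tmap, tolerance = 1e-10)
})

test_that("adding a constant to a covariate leaves the group t-map unchanged", {
  subj <- fixture_subjects(25)
  set.seed(6)
  Y <- matrix(rnorm(25 * 30), 25, 30)
  f1 <- fit_vertex_glm(Y, build_design(subj, "group_model"), "group")
  subj2 <- subj
  subj2$fsiq <- subj2$fsiq + 1000
  f2 <- fit_vertex_glm(Y, build_design(subj2, "group_model"), "group")
  expect_equal(f1$tmap, f2$tmap, tolerance = 1e-9)
})

test_that("null group t-map follows the Student t distribution (unsmoothed maps)", {
  m <- fixture_mesh(3)
  sc <- simulate_cohort(sim_config(seed = 77, mesh_subdivisions = 3), mesh = m)
  fit <- fit_vertex_glm(cohort_ctspc(sc),
                        build_design(sc$cohort$subjects, "group_model"),
                        "group")
  ks <- stats::ks.test(fit$tmap, stats::pt, df = fit$dof)
  expect_gt(ks$p.value, 0.01)
})

test_that("underdetermined fits and length mismatches are rejected", {
  subj <- fixture_subjects(7)   # exactly as many subjects as regressors
  d <- build_design(subj, "group_model")
  expect_error(fit_vertex_glm(matrix(0, 7, 4), d, "group"), "more subjects")
  expect_error(fit_vertex_glm(matrix(0, 9, 4), d, "group"), "do not match")
  expect_error(fit_vertex_glm(matrix(rnorm(60), 20, 3),
                              build_design(fixture_subjects(20), "group_model"),
                              "nope"), "unknown contrast")
})

test_that("step-up selection admits a planted main effect but not an absent interaction", {
  m <- fixture_mesh(1)
  n_admit_main <- 0
  n_admit_int <- 0
  for (s in 1:20) {
    sc <- simulate_cohort(sim_config(seed = s + 300, mesh_subdivisions = 1),
                          mesh = m)
    subj <- sc$cohort$subjects
    set.seed(s)
    subj$delta_rbsr <- rnorm(nrow(subj), 0, 8)
    Y <- cohort_ctspc(sc)
    # plant a strong global main effect of the change score, no interaction
    Y <- Y + 0.08 * matrix(subj$delta_rbsr, nrow(Y), ncol(Y))
    designs <- list(group = build_design(subj, "group_model"),
                    rbsr = build_design(subj, "rbsr_model"),
                    interaction = build_design(subj, "rbsr_interaction_model"))
    sel <- stepup_model_selection(Y, designs)
    if (sel$selected %in% c("rbsr", "interaction")) n_admit_main <- n_admit_main + 1
    if (sel$selected == "interaction") n_admit_int <- n_admit_int + 1
  }
  expect_gte(n_admit_main, 18)
  expect_lte(n_admit_int, 5)
})

test_that("step-up selection has approximately nominal type-I rate on null data", {
  m <- fixture_mesh(0)
  admitted <- vapply(1:200, function(s) {
    sc <- simulate_cohort(sim_config(seed = s + 900, mesh_subdivisions = 0),
                          mesh = m)
    subj <- sc$cohort$subjects
    set.seed(s)
    subj$delta_rbsr <- rnorm(nrow(subj), 0, 8)
    designs <- list(group = build_design(subj, "group_model"),
                    rbsr = build_design(subj, "rbsr_model"))
    sel <- stepup_model_selection(cohort_ctspc(sc), designs)
    sel$selected == "rbsr"
  }, NA)
  rate <- mean(admitted)
  # 95% binomial band around alpha = 0.05 at 200 replicates
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("non-nested or rank-degenerate model sequences are rejected", {
  subj <- fixture_subjects(20)
  Y <- matrix(rnorm(20 * 10), 20, 10)
  d1 <- build_design(subj, "group_model")
  d_dup <- d1
  d_dup$X <- cbind(d1$X, group2 = d1$X[, "group"])
  expect_error(stepup_model_selection(Y, list(a = d1, b = d_dup)),
               "no rank")
  d_small <- d1
  d_small$X <- d1$X[, 1:4]
  expect_error(stepup_model_selection(Y, list(a = d1, b = d_small)),
               "not strictly nested")
})
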
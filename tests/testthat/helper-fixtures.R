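# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture_mesh <- function(subdivisions, radius = 40) {
  key <- paste0("mesh", subdivisions, "_", radius)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_icosphere(subdivisions, radius)
  }
  .fixture_env[[key]]
}

# small cohort data.frame with covariates for design-matrix tests
fixture_subjects <- function(n = 20, seed = 42) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%02d", 1:n),
    group = factor(rep(c("ASD", "TD"), length.out = n),
                   levels = c("ASD", "TD")),
    sex = factor(sample(c("male", "female"), n, replace = TRUE),
                 levels = c("male", "female")),
    age_t1 = runif(n, 11, 18),
    isi = runif(n, 1.8, 2.4),
    fsiq = rnorm(n, 105, 12),
    handedness = factor(sample(c("right", "left"), n, replace = TRUE),
                        levels = c("right", "left")),
    stringsAsFactors = FALSE
  )
}

fixture_item_matrix <- function(n = 8, n_items = 5, seed = 7) {
  set.seed(seed)
  matrix(sample(0:3, n * n_items, replace = TRUE), n, n_items)
}
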
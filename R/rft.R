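#' Estimate local spatial smoothness from GLM residuals
#'
#' Local FWHM along mesh edges from normalized residuals: residual columns
#' are scaled to unit norm, and for each edge the mean squared difference
#' of the normalized residuals approximates twice (1 - correlation), giving
#' the squared derivative of the field per mm. Under a Gaussian
#' autocorrelation model, `FWHM = sqrt(4 log 2 * len^2 / ssq)`. Per-vertex
#' FWHM averages the squared-derivative estimate over incident edges, and
#' the resel (resolution element) density is vertex area / FWHM^2 - the
#' currency of nonisotropic cluster inference.
#'
#' @param residuals subjects x vertices residual matrix from a fitted GLM
#' @param mesh a `surface_mesh`
#' @return a `smoothness_estimate`: per-vertex `fwhm` (mm), `resel_density`
#'   (resels per vertex), `total_resels`, `fwhm_median`
#' @export
estimate_smoothness <- function(residuals, mesh) {
  R <- as.matrix(residuals)
  if (nrow(R) < 3L) stop("need at least 3 subjects of residuals")
  check_dim <- ncol(R) == n_vertices(mesh)
  if (!check_dim) stop("residual columns do not match mesh vertices")
  norms <- sqrt(colSums(R^2))
  if (any(norms == 0)) stop("degenerate: zero-variance residual column")
  Rn <- sweep(R, 2L, norms, "/")
  i <- mesh$edges[, 1L]
  j <- mesh$edges[, 2L]
  ssq <- colSums((Rn[, i, drop = FALSE] - Rn[, j, drop = FALSE])^2)
  if (all(ssq == 0)) stop("degenerate: residuals identical across vertices")
  lambda_edge <- ssq / mesh$edge_lengths^2   # squared derivative per mm^2
  nv <- n_vertices(mesh)
  lam_sum <- numeric(nv)
  lam_n <- numeric(nv)
  for (end in list(i, j)) {
    t1 <- tapply(lambda_edge, end, sum)
    lam_sum[as.integer(names(t1))] <- lam_sum[as.integer(names(t1))] + t1
    t2 <- tapply(rep(1, length(end)), end, sum)
    lam_n[as.integer(names(t2))] <- lam_n[as.integer(names(t2))] + t2
  }
  lambda_v <- lam_sum / pmax(lam_n, 1)
  fwhm <- sqrt(4 * log(2) / pmax(lambda_v, .Machine$double.eps))
  resel_density <- mesh$vertex_area / fwhm^2
  structure(list(fwhm = fwhm, resel_density = resel_density,
                 total_resels = sum(resel_density),
                 fwhm_median = stats::median(fwhm)),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("smoothness_estimate: median FWHM ", format(round(x$fwhm_median, 2)),
      " mm, total search region ", format(round(x$total_resels, 1)),
      " resels\n", sep = "")
  invisible(x)
}

#' Find supra-threshold clusters in a t-map
#'
#' The cluster-forming threshold is the Student-t quantile
#' `u = qt(1 - p_form / tails, dof)`. Vertices with `t >= u` and vertices
#' with `t <= -u` are labeled separately into connected components over
#' shared-edge vertex adjacency.
#'
#' @param tmap `vertex_map` or numeric t vector
#' @param dof degrees of freedom of the t-map
#' @param p_form cluster-forming p (default 0.05, the study's threshold)
#' @param mesh a `surface_mesh`
#' @param tails 2 (default) or 1
#' @return a `cluster_set`: list with `clusters` (data.frame: id, sign,
#'   n_vertices, area_mm2, peak_t, peak_vertex), `members` (list of vertex
#'   index vectors), `labels` (integer per-vertex label map, 0 = none),
#'   `u`, `dof`, `tails`
#' @export
find_clusters <- function(tmap, dof, p_form = 0.05, mesh, tails = 2) {
  if (p_form <= 0 || p_form >= 1) stop("p_form must be in (0, 1)")
  t <- map_values(tmap)
  u <- stats::qt(1 - p_form / tails, dof)
  labels <- integer(length(t))
  members <- list()
  rows <- list()
  g <- mesh_graph(mesh)
  next_id <- 0L
  for (sgn in if (tails == 2) c(1, -1) else 1) {
    supra <- which(!is.na(t) & sgn * t >= u)
    if (!length(supra)) next
    sub <- igraph::induced_subgraph(g, supra)
    comp <- igraph::components(sub)
    for (k in seq_len(comp$no)) {
      vs <- supra[comp$membership == k]
      next_id <- next_id + 1L
      labels[vs] <- next_id
      members[[next_id]] <- vs
      pk <- vs[which.max(sgn * t[vs])]
      rows[[next_id]] <- data.frame(
        id = next_id, sign = if (sgn > 0) "positive" else "negative",
        n_vertices = length(vs), area_mm2 = sum(mesh$vertex_area[vs]),
        peak_t = t[pk], peak_vertex = pk)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), sign = character(0), n_vertices = integer(0),
               area_mm2 = numeric(0), peak_t = numeric(0),
               peak_vertex = integer(0))
  structure(list(clusters = clusters, members = members, labels = labels,
                 u = u, dof = dof, tails = tails),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set: ", nrow(x$clusters), " cluster(s) at |t| >= ",
      format(round(x$u, 3)), " (dof ", x$dof, ", ", x$tails, "-tailed)\n",
      sep = "")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

# Euler-characteristic densities of a t-field (2-D search region)
ec_density_t <- function(u, dof, d) {
  f4 <- 4 * log(2)
  switch(as.character(d),
    "0" = stats::pt(u, dof, lower.tail = FALSE),
    "1" = sqrt(f4) / (2 * pi) * (1 + u^2 / dof)^(-(dof - 1) / 2),
    "2" = f4 / (2 * pi)^1.5 *
      exp(lgamma((dof + 1) / 2) - lgamma(dof / 2)) / sqrt(dof / 2) *
      u * (1 + u^2 / dof)^(-(dof - 1) / 2),
    stop("unsupported EC dimension"))
}

#' Random-field-theory corrected cluster p-values
#'
#' Expected-topology cluster inference on a closed 2-D search region
#' measured in resels. The expected number of clusters above the forming
#' threshold `u` is `E[m] = R0 * rho0(u) + R2 * rho2(u)` with `R0 = 2` (the
#' half Euler characteristic of a closed sphere-topology surface, boundary
#' term zero) and `R2` the total resel count. The cluster-extent tail
#' starts from the exponential approximation in resel units with rate
#' `beta = rho2 / rho0` (matching the expected extent per cluster) and
#' applies the t-field finite-df correction: a t-field cluster extent
#' behaves as a Gaussian-field extent rescaled by the local variance
#' estimate, and integrating the exponential tail over the chi-squared
#' distribution of that scaling gives
#' `P(S >= s) = (1 + 2 beta s / dof)^(-dof/2)`, heavier in the far tail
#' and reducing to `exp(-beta s)` as dof grows. The corrected p of a
#' cluster of `s` resels is `1 - exp(-tails * E[m] * P(S >= s))` (a
#' two-tailed search doubles the expected cluster count in the Poisson
#' clumping bound). Nonisotropy enters by measuring each cluster's extent
#' as the sum of its member vertices' local resel densities.
#'
#' @param cluster_set a `cluster_set` from [find_clusters()]
#' @param smoothness a `smoothness_estimate`
#' @return the `cluster_set` with columns `resels` and `p_cluster` added
#' @export
cluster_p_rft <- function(cluster_set, smoothness) {
  cs <- cluster_set
  if (cs$u <= 0) stop("cluster-forming threshold must be positive")
  R2 <- smoothness$total_resels
  rho0 <- ec_density_t(cs$u, cs$dof, 0)
  rho2 <- ec_density_t(cs$u, cs$dof, 2)
  Em <- 2 * ec_density_t(cs$u, cs$dof, 0) + R2 * rho2
  beta <- rho2 / rho0
  if (!nrow(cs$clusters)) {
    cs$clusters$resels <- numeric(0)
    cs$clusters$p_cluster <- numeric(0)
    return(cs)
  }
  resels <- vapply(cs$members, function(vs) sum(smoothness$resel_density[vs]), 0)
  # finite-df extent tail (chi-squared mixture of the exponential law);
  # the two-tailed search doubles the expected cluster count in the
  # Poisson clumping bound (monotone and tie-free near 1)
  pS <- (1 + 2 * beta * resels / cs$dof)^(-cs$dof / 2)
  p <- 1 - exp(-cs$tails * Em * pS)
  cs$clusters$resels <- resels
  cs$clusters$p_cluster <- p
  cs$expected_clusters <- Em
  cs
}

#' RFT cluster correction of a fitted vertex GLM
#'
#' Convenience wrapper: estimates residual smoothness, finds clusters in
#' the contrast t-map, and attaches corrected p-values.
#'
#' @param fit a `vertex_glm`
#' @param mesh a `surface_mesh`
#' @param p_form cluster-forming p (default 0.05)
#' @param tails 2 (default) or 1
#' @return a `cluster_set` with `p_cluster`, plus the smoothness estimate
#'   in `$smoothness`
#' @export
rft_cluster_correct <- function(fit, mesh, p_form = 0.05, tails = 2) {
  sm <- estimate_smoothness(residuals(fit), mesh)
  cs <- find_clusters(fit$tmap, fit$dof, p_form, mesh, tails)
  cs <- cluster_p_rft(cs, sm)
  cs$smoothness <- sm
  cs
}

#' Permutation cluster test (validation oracle)
#'
#' Freedman-Lane residual permutation: the nuisance-only model (the design
#' without the contrast columns) is fitted, its residuals are permuted over
#' subjects and added back to the nuisance fit, the full model is refitted,
#' and the maximum supra-threshold cluster resel extent is recorded per
#' permutation (positive and negative tails pooled for two-tailed tests).
#' Each observed cluster's p is
#' `(1 + #{max extent >= observed}) / (1 + n_perm)`.
#'
#' @param Y subjects x vertices response matrix
#' @param design a `design_matrix` (or matrix)
#' @param contrast contrast name or weight vector
#' @param mesh a `surface_mesh`
#' @param p_form cluster-forming p
#' @param n_perm number of permutations (a warning is issued below 99)
#' @param seed integer seed
#' @param tails 2 (default) or 1
#' @return a `cluster_set` for the observed data with `p_perm` attached,
#'   plus `max_null_extents` (the permutation distribution)
#' @export
permutation_cluster_test <- function(Y, design, contrast, mesh,
                                     p_form = 0.05, n_perm = 199L,
                                     seed = 1L, tails = 2) {
  if (n_perm < 99L) warning("n_perm < 99 gives a coarse p-value floor")
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  cvec <- contrast_vector(contrast, colnames(X))
  fit <- fit_vertex_glm(Y, X, cvec)
  sm <- estimate_smoothness(residuals(fit), mesh)
  obs <- find_clusters(fit$tmap, fit$dof, p_form, mesh, tails)
  obs <- cluster_p_rft(obs, sm)
  obs$smoothness <- sm
  obs_extents <- obs$clusters$resels

  Xz <- X[, cvec == 0, drop = FALSE]
  qz <- qr(Xz)
  fitted_z <- Xz %*% ifelse(is.na(qr.coef(qz, Y)), 0, qr.coef(qz, Y))
  res_z <- Y - fitted_z
  n <- nrow(Y)
  max_ext <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      fb <- fit_vertex_glm(fitted_z + res_z[perm, , drop = FALSE], X, cvec)
      cb <- find_clusters(fb$tmap, fb$dof, p_form, mesh, tails)
      if (!length(cb$members)) return(0)
      max(vapply(cb$members,
                 function(vs) sum(sm$resel_density[vs]), 0))
    }, 0)
  })
  if (length(obs_extents)) {
    obs$clusters$p_perm <- vapply(obs_extents, function(s) {
      (1 + sum(max_ext >= s)) / (1 + n_perm)
    }, 0)
  } else {
    obs$clusters$p_perm <- numeric(0)
  }
  obs$max_null_extents <- max_ext
  obs
}
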
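#' Build a design matrix for the vertex-wise GLM
#'
#' Constructs the fixed-effects design: intercept, diagnostic group
#' (TD = 0, ASD = 1), sex (male = 0, female = 1), and mean-centered
#' continuous covariates. The quadratic age term is built from centered age
#' and then itself centered, which keeps the design well conditioned over
#' an adolescent age range. With 0/1 group coding and centered covariates,
#' the group coefficient is the adjusted ASD - TD difference.
#'
#' Model presets: `"group_model"` (group + sex + age + age^2 + fsiq + isi),
#' `"rbsr_model"` (adds the behavioral change score) and
#' `"rbsr_interaction_model"` (adds its group interaction). The change
#' score is taken from `data$delta_rbsr`.
#'
#' @param data data.frame with columns `group`, `sex`, `age_t1`, `fsiq`,
#'   `isi` and, for the behavioral models, `delta_rbsr`
#' @param model preset name (see above)
#' @param centering_population `"all"` (default) or `"asd"`: the rows over
#'   which continuous covariates are mean centered (the within-ASD
#'   subanalysis centers across the ASD participants only)
#' @return a `design_matrix`: list with `X`, `centering` record, `model`
#' @export
build_design <- function(data,
                         model = c("group_model", "rbsr_model",
                                   "rbsr_interaction_model"),
                         centering_population = c("all", "asd")) {
  model <- match.arg(model)
  centering_population <- match.arg(centering_population)
  pop <- if (centering_population == "asd") data$group == "ASD" else
    rep(TRUE, nrow(data))
  if (!any(pop)) stop("empty centering population")
  center <- function(x) x - mean(x[pop])

  group01 <- as.numeric(data$group == "ASD")
  sex01 <- as.numeric(data$sex == "female")
  age_c <- center(data$age_t1)
  age2_c <- center(age_c^2)
  X <- cbind(intercept = 1, group = group01, sex = sex01,
             age = age_c, age2 = age2_c,
             fsiq = center(data$fsiq), isi = center(data$isi))
  centering <- list(population = centering_population,
                    age = mean(data$age_t1[pop]),
                    fsiq = mean(data$fsiq[pop]), isi = mean(data$isi[pop]))
  if (model %in% c("rbsr_model", "rbsr_interaction_model")) {
    if (is.null(data$delta_rbsr)) stop("data$delta_rbsr required for ", model)
    drb <- center(data$delta_rbsr)
    X <- cbind(X, delta_rbsr = drb)
    centering$delta_rbsr <- mean(data$delta_rbsr[pop])
    if (model == "rbsr_interaction_model") {
      X <- cbind(X, delta_rbsr_x_group = drb * group01)
    }
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, centering = centering, model = model),
            class = "design_matrix")
}

#' Fit the mass-univariate vertex-wise GLM
#'
#' Ordinary least squares fitted independently at every vertex with one
#' shared design matrix, plus the t-map of a single contrast:
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^{-1}c)` with `dof = n - rank(X)`.
#' Residuals are retained for spatial smoothness estimation.
#'
#' @param Y subjects x vertices response matrix (e.g. CT_spc, %/year)
#' @param design a `design_matrix` (or bare numeric matrix)
#' @param contrast contrast weights: a column name (weight 1 on that
#'   column) or a numeric vector of length `ncol(X)`
#' @return a `vertex_glm` object with elements `beta` (regressors x
#'   vertices), `sigma2`, `dof`, `tmap`, `se`, `residuals`, `design`,
#'   `contrast`
#' @export
fit_vertex_glm <- function(Y, design, contrast = "group") {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("rows of Y (", nrow(Y),
                               ") do not match rows of X (", nrow(X), ")")
  qrx <- qr(X)
  p <- qrx$rank
  n <- nrow(X)
  if (n <= p) stop("need more subjects (", n, ") than design rank (", p, ")")
  cvec <- contrast_vector(contrast, colnames(X))
  beta <- qr.coef(qrx, Y)
  beta[is.na(beta)] <- 0
  res <- Y - X %*% beta
  dof <- n - p
  sigma2 <- colSums(res^2) / dof
  xtxinv <- chol2inv(qr.R(qrx)[, order(qrx$pivot), drop = FALSE])
  cXXc <- drop(t(cvec) %*% xtxinv %*% cvec)
  se <- sqrt(sigma2 * cXXc)
  tmap <- ifelse(se > 0, drop(crossprod(cvec, beta)) / se, NA_real_)
  structure(list(beta = beta, sigma2 = sigma2, dof = dof, tmap = tmap,
                 se = se, residuals = res, design = design,
                 contrast = cvec, cXXc = cXXc, n = n),
            class = "vertex_glm")
}

contrast_vector <- function(contrast, cols) {
  if (is.character(contrast)) {
    if (!contrast %in% cols) stop("unknown contrast column: ", contrast)
    cvec <- as.numeric(cols == contrast)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != length(cols)) {
      stop("contrast length ", length(cvec), " != ", length(cols), " columns")
    }
  }
  cvec
}

#' @export
print.vertex_glm <- function(x, ...) {
  cat("vertex_glm: ", x$n, " subjects x ", ncol(x$beta), " vertices, dof = ",
      x$dof, "\n", sep = "")
  cols <- colnames(x$beta)
  if (is.null(cols)) cols <- rownames(x$beta)
  cat("  regressors:", paste(rownames(x$beta), collapse = ", "), "\n")
  cat("  contrast t-map: mean ", format(round(mean(x$tmap, na.rm = TRUE), 4)),
      ", range ", format(round(min(x$tmap, na.rm = TRUE), 2)), " .. ",
      format(round(max(x$tmap, na.rm = TRUE), 2)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.vertex_glm <- function(object, ...) {
  out <- list(
    n = object$n, dof = object$dof, n_vertices = ncol(object$beta),
    t_quantiles = stats::quantile(object$tmap,
                                  c(0.01, 0.25, 0.5, 0.75, 0.99),
                                  na.rm = TRUE),
    sigma2_median = stats::median(object$sigma2))
  class(out) <- "summary.vertex_glm"
  out
}

#' @export
print.summary.vertex_glm <- function(x, ...) {
  cat("vertex_glm fit: n =", x$n, ", dof =", x$dof,
      ", vertices =", x$n_vertices, "\n")
  cat("t-map quantiles:\n")
  print(round(x$t_quantiles, 3))
  cat("median residual variance:", format(x$sigma2_median), "\n")
  invisible(x)
}

#' @export
coef.vertex_glm <- function(object, ...) object$beta

#' @export
residuals.vertex_glm <- function(object, ...) object$residuals

#' Step-up nested model selection for the vertex-wise GLM
#'
#' Starting from the simplest model, each candidate term is admitted when
#' the extra-sum-of-squares test of the enriched against the current model
#' rejects at `alpha`; the procedure stops at the first non-admitted term.
#' Two cortex-wide aggregations of the per-vertex tests are available:
#' `"pooled"` (default) sums residual sums of squares over vertices and
#' performs a single nested F with vertex-scaled degrees of freedom (exact
#' when vertex noise is independent and homoscedastic), and `"mean_p"`
#' compares the cortex-average per-vertex p-value to its null expectation
#' of 1/2 by a normal approximation.
#'
#' @param Y subjects x vertices response matrix
#' @param designs named list of `design_matrix` objects, strictly nested,
#'   simplest first
#' @param alpha admission level (default 0.05)
#' @param method `"pooled"` or `"mean_p"`
#' @return a `model_selection`: list with `selected` (name), `path`
#'   (data.frame of per-step F / p / decision), `fit` of the selected model
#' @export
stepup_model_selection <- function(Y, designs, alpha = 0.05,
                                   method = c("pooled", "mean_p")) {
  method <- match.arg(method)
  if (length(designs) < 2L) stop("need at least two nested models")
  nm <- names(designs)
  if (is.null(nm)) nm <- paste0("model", seq_along(designs))
  Y <- as.matrix(Y)
  nv <- ncol(Y)
  n <- nrow(Y)
  rss <- function(X) {
    fit <- qr(X)
    colSums((Y - X %*% ifelse(is.na(qr.coef(fit, Y)), 0,
                              qr.coef(fit, Y)))^2)
  }
  get_X <- function(d) if (inherits(d, "design_matrix")) d$X else as.matrix(d)
  path <- list()
  cur <- 1L
  X0 <- get_X(designs[[1L]])
  rss0 <- rss(X0)
  p0 <- qr(X0)$rank
  for (k in 2L:length(designs)) {
    X1 <- get_X(designs[[k]])
    if (!all(colnames(X0) %in% colnames(X1)) || ncol(X1) <= ncol(X0)) {
      stop("models are not strictly nested at step ", k)
    }
    p1 <- qr(X1)$rank
    q <- p1 - p0
    if (q < 1L) stop("candidate term adds no rank at step ", k,
                     " (duplicate of an existing column)")
    rss1 <- rss(X1)
    if (method == "pooled") {
      num <- (sum(rss0) - sum(rss1)) / (q * nv)
      den <- sum(rss1) / ((n - p1) * nv)
      Fstat <- num / den
      pval <- stats::pf(Fstat, q * nv, (n - p1) * nv, lower.tail = FALSE)
    } else {
      Fv <- ((rss0 - rss1) / q) / (rss1 / (n - p1))
      pv <- stats::pf(Fv, q, n - p1, lower.tail = FALSE)
      Fstat <- mean(Fv)
      z <- (mean(pv) - 0.5) / sqrt(1 / (12 * nv))
      pval <- stats::pnorm(z)
    }
    admitted <- pval < alpha
    path[[length(path) + 1L]] <- data.frame(
      step = k - 1L, candidate = nm[k], F = Fstat, p = pval,
      admitted = admitted, stringsAsFactors = FALSE)
    if (!admitted) break
    cur <- k
    X0 <- X1
    rss0 <- rss1
    p0 <- p1
  }
  structure(list(selected = nm[cur],
                 path = do.call(rbind, path),
                 fit = designs[[cur]]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("step-up model selection: selected '", x$selected, "'\n", sep = "")
  print(x$path, row.names = FALSE)
  invisible(x)
}
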
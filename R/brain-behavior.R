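#' Cluster-wise mean CT_spc per subject
#'
#' Extracts, for each significant cluster, each subject's mean CT_spc over
#' the cluster's member vertices (unweighted by default; the area-weighted
#' option is recorded in the result's attributes for provenance).
#'
#' @param ctspc subjects x vertices matrix of CT_spc (%/year)
#' @param cluster_set a `cluster_set` (or an integer label map)
#' @param mesh optional `surface_mesh`, required for `area_weighted = TRUE`
#' @param area_weighted weight vertices by area within each cluster
#' @return subjects x clusters matrix (columns `cluster_<id>`)
#' @export
extract_cluster_means <- function(ctspc, cluster_set, mesh = NULL,
                                  area_weighted = FALSE) {
  Y <- as.matrix(ctspc)
  members <- if (inherits(cluster_set, "cluster_set")) cluster_set$members
  else split(seq_along(cluster_set), cluster_set)[-1]
  if (!length(members)) stop("no clusters to extract")
  out <- vapply(members, function(vs) {
    if (!length(vs)) stop("empty cluster")
    if (area_weighted) {
      w <- mesh$vertex_area[vs]
      as.numeric(Y[, vs, drop = FALSE] %*% (w / sum(w)))
    } else {
      rowMeans(Y[, vs, drop = FALSE])
    }
  }, numeric(nrow(Y)))
  out <- matrix(out, nrow = nrow(Y))
  colnames(out) <- paste0("cluster_", seq_along(members))
  attr(out, "area_weighted") <- area_weighted
  out
}

#' Cluster-by-measure Pearson correlations with FDR control
#'
#' Correlates each cluster's subject-level mean CT_spc with each behavioral
#' measure (Pearson, two-sided), then applies Benjamini-Hochberg adjustment
#' across the full cluster x measure family computed in the run (the widest
#' in-run family; recorded in the output attributes). Zero-variance columns
#' are flagged and excluded from testing.
#'
#' @param features subjects x clusters matrix (see
#'   [extract_cluster_means()])
#' @param scores data.frame or matrix of per-subject measures
#' @return long data.frame: cluster, measure, n, r, p, p_adj (NA rows for
#'   excluded zero-variance pairs)
#' @export
correlate_with_fdr <- function(features, scores) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("cluster_", seq_len(ncol(features)))
  }
  scores <- as.data.frame(scores)
  rows <- list()
  for (cl in colnames(features)) {
    for (ms in names(scores)) {
      x <- features[, cl]
      y <- scores[[ms]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 3L) stop("fewer than 3 complete pairs for ", cl, " x ", ms)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("zero variance in ", cl, " x ", ms, "; excluded")
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, measure = ms, n = n, r = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, measure = ms, n = n, r = unname(ct$estimate),
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "family") <- "all cluster x measure pairs in this run"
  out
}
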
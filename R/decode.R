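#' Sample a t-map at expression sample locations
#'
#' Each sample takes the t-value at its assigned vertex; samples assigned
#' to a parcel (a set of vertices) take the unweighted parcel mean.
#'
#' @param tmap `vertex_map` or numeric vector
#' @param samples data.frame with a `vertex` column (integer index) or a
#'   `parcel` list-column of vertex index vectors
#' @return numeric vector, one t value per sample
#' @export
sample_tmap <- function(tmap, samples) {
  t <- map_values(tmap)
  if (!is.null(samples$parcel)) {
    return(vapply(samples$parcel, function(vs) mean(t[vs]), 0))
  }
  if (is.null(samples$vertex)) stop("samples must carry a vertex or parcel binding")
  v <- samples$vertex
  if (any(is.na(v)) || any(v < 1L) || any(v > length(t))) {
    stop("unbound or out-of-range sample vertex")
  }
  t[v]
}

#' Gene-expression decoding of a statistical map
#'
#' Ranks genes by the Pearson correlation between their spatial expression
#' profile and the map sampled at the expression sample locations.
#' Candidate genes are those with a spatially *similar* pattern: positive
#' correlation at two-sided p below `alpha` (set `signed = TRUE` to also
#' return the dissimilar list). Constant-expression genes are flagged and
#' excluded. The result is invariant to affine rescaling of the map.
#'
#' @param tmap `vertex_map` or numeric vector
#' @param expr genes x samples expression matrix with gene rownames
#'   (duplicate symbols are collapsed by their mean with a warning)
#' @param samples data.frame binding samples to vertices/parcels (see
#'   [sample_tmap()])
#' @param alpha candidate threshold on the two-sided p (default 0.05)
#' @param signed also report the negatively correlated list
#' @return a `decoding_result`: `table` (gene, r, p, similar flag, ordered
#'   by decreasing r), `candidates`, optional `dissimilar`, `alpha`,
#'   `excluded` (constant genes)
#' @export
decode <- function(tmap, expr, samples, alpha = 0.05, signed = FALSE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(expr))) {
    warning(sum(duplicated(rownames(expr))),
            " duplicate gene symbol(s) collapsed by mean")
    expr <- rowsum(expr, rownames(expr)) /
      as.vector(table(rownames(expr))[unique(sort(rownames(expr)))])
    # rowsum orders by sorted unique names
  }
  y <- sample_tmap(tmap, samples)
  if (length(y) != ncol(expr)) stop("samples do not match expression columns")
  if (length(y) < 3L) stop("need at least 3 samples")
  sds <- apply(expr, 1L, stats::sd)
  excluded <- rownames(expr)[sds == 0]
  keep <- sds > 0
  if (!any(keep)) stop("all expression rows are constant")
  if (stats::sd(y) == 0) stop("sampled map is constant; correlation undefined")
  E <- expr[keep, , drop = FALSE]
  ns <- length(y)
  yc <- (y - mean(y)) / stats::sd(y)
  Ec <- sweep(E, 1L, rowMeans(E))
  r <- as.numeric(Ec %*% yc) / (sds[keep] * (ns - 1))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((ns - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), ns - 2)
  p[abs(r) == 1] <- 0
  tab <- data.frame(gene = rownames(E), r = r, p = p,
                    similar = r > 0 & p < alpha, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r), ]
  rownames(tab) <- NULL
  out <- list(table = tab, candidates = tab$gene[tab$similar],
              alpha = alpha, excluded = excluded, n_samples = ns)
  if (signed) out$dissimilar <- tab$gene[tab$r < 0 & tab$p < alpha]
  structure(out, class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("decoding_result:", nrow(x$table), "genes over", x$n_samples,
      "samples;", length(x$candidates), "candidates at p <", x$alpha, "\n")
  print(utils::head(x$table, 5), row.names = FALSE)
  invisible(x)
}

#' Hypergeometric gene-set enrichment of a candidate list
#'
#' For each gene set, the 2x2 table over the declared universe is
#' `a` = candidates in set, `b` = candidates not in set, `c` = set members
#' not in the candidate list, `d` = the rest; the enrichment p is the
#' hypergeometric upper tail `P(X >= a)` and the odds ratio is
#' `(a d)/(b c)` (with a Haldane-Anscombe 0.5 added to every cell for the
#' *reported* OR only when any cell is zero; the p-value is untouched).
#' Benjamini-Hochberg adjustment runs across all sets tested in one call.
#'
#' @param candidates character vector of candidate gene symbols
#' @param gene_sets a `gene_set` or (named) list of them
#' @param universe_size declared number of genes tested; defaults must be
#'   supplied by the caller (typically the number of genes in the
#'   expression matrix)
#' @return data.frame: set, annotation, set_size, n_candidates, overlap,
#'   odds_ratio, p, p_adj
#' @export
enrich <- function(candidates, gene_sets, universe_size) {
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  candidates <- unique(candidates)
  rows <- lapply(gene_sets, function(gs) {
    members <- unique(gs$members)
    union_n <- length(unique(c(candidates, members)))
    if (universe_size < union_n) {
      stop("universe (", universe_size, ") smaller than candidates union set (",
           union_n, ")")
    }
    a <- length(intersect(candidates, members))
    b <- length(candidates) - a
    c_ <- length(members) - a
    d <- universe_size - a - b - c_
    p <- stats::phyper(a - 1, length(members), universe_size - length(members),
                       length(candidates), lower.tail = FALSE)
    cells <- c(a, b, c_, d)
    or <- if (a == 0) 0 else {
      # Haldane-Anscombe correction keeps the *reported* OR finite when a
      # non-overlap cell is zero; the hypergeometric p is never corrected
      oc <- if (any(cells == 0)) cells + 0.5 else cells
      (oc[1] * oc[4]) / (oc[2] * oc[3])
    }
    data.frame(set = gs$name, annotation = gs$annotation,
               set_size = length(members), n_candidates = length(candidates),
               overlap = a, odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
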
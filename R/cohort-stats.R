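#' Two-sample t-test from printed summary statistics
#'
#' Computes the unequal-variance (Welch) t statistic with
#' Welch-Satterthwaite degrees of freedom from group means, SDs and sizes,
#' as needed to reproduce published demographic tables. A pooled-variance
#' variant is available.
#'
#' @param mean1,sd1,n1 summary statistics of group 1
#' @param mean2,sd2,n2 summary statistics of group 2
#' @param family `"welch-t"` (default) or `"pooled-t"`
#' @return a `group_test`: list with `statistic`, `df`, `p`, `family`
#' @examples
#' welch_t_from_summary(101.38, 13.19, 33, 107.07, 11.52, 37) # t = -1.91
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 family = c("welch-t", "pooled-t")) {
  family <- match.arg(family)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop("degenerate: both group variances are zero")
  if (family == "welch-t") {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  group_test(t, df, 2 * stats::pt(-abs(t), df), family)
}

group_test <- function(statistic, df, p, family) {
  structure(list(statistic = statistic, df = df, p = p, family = family),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  lab <- if (grepl("chi2", x$family)) "chi-squared" else "t"
  cat(x$family, ": ", lab, "(", format(round(x$df, 2)), ") = ",
      format(round(x$statistic, 4)), ", p = ", format.pval(x$p), "\n", sep = "")
  invisible(x)
}

#' Chi-squared test of a 2x2 contingency table
#'
#' Cell layout: rows are groups, columns are categories, i.e. the table is
#' `rbind(c(a, b), c(c, d))`. Defaults to the Yates continuity correction,
#' which is what reproduces published small-sample demographic chi-squared
#' statistics.
#'
#' @param a,b,c,d non-negative integer cell counts
#' @param continuity apply the Yates correction (default TRUE)
#' @return a `group_test`
#' @export
chi2_2x2 <- function(a, b, c, d, continuity = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  group_test(unname(res$statistic), unname(res$parameter), res$p.value,
             if (continuity) "chi2-yates" else "chi2-plain")
}

#' Predictive-mean-matching imputation of ordinal item responses
#'
#' Single imputation of missing cells in a subjects x items matrix. For
#' each item with missing values, a linear prediction is fitted on the
#' complete cases (predictors: all other items; a recipient's own missing
#' predictors are filled with complete-case column means for prediction
#' only). The donor pool is the `k_donors` complete cases whose predicted
#' values are nearest the recipient's prediction, and the imputed value is
#' drawn uniformly from the donors' observed values - so it always lies in
#' the item's observed support. Complete rows are returned untouched, and
#' randomness only enters at imputed cells.
#'
#' @param item_matrix subjects x items numeric matrix with NA = missing
#' @param k_donors size of the donor pool (default 5)
#' @param seed integer seed for the donor draws
#' @param max_missing per-row missingness cap (default 3)
#' @return completed matrix of the same dimensions
#' @export
pmm_impute <- function(item_matrix, k_donors = 5L, seed = 1L,
                       max_missing = 3L) {
  m <- as.matrix(item_matrix)
  if (!anyNA(m)) return(m)
  nmiss <- rowSums(is.na(m))
  if (any(nmiss > max_missing)) {
    stop("row(s) ", paste(which(nmiss > max_missing), collapse = ", "),
         " exceed the missingness cap of ", max_missing)
  }
  complete <- which(nmiss == 0L)
  col_means <- colMeans(m[complete, , drop = FALSE])
  out <- m
  with_seed(substream_seed(seed, "pmm"), {
    for (j in seq_len(ncol(m))) {
      recipients <- which(is.na(m[, j]))
      if (!length(recipients)) next
      if (length(complete) < k_donors) {
        stop("insufficient donors for item ", j, ": ", length(complete),
             " complete case(s), need ", k_donors)
      }
      X <- m[complete, -j, drop = FALSE]
      y <- m[complete, j]
      fit <- stats::lm.fit(cbind(1, X), y)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred_donor <- as.numeric(cbind(1, X) %*% beta)
      for (i in recipients) {
        xi <- m[i, -j]
        xi[is.na(xi)] <- col_means[-j][is.na(xi)]
        pred_i <- sum(c(1, xi) * beta)
        pool <- order(abs(pred_donor - pred_i))[seq_len(k_donors)]
        out[i, j] <- y[pool[sample.int(k_donors, 1L)]]
      }
    }
  })
  out
}

#' Default four-factor item map for the 43-item repetitive-behavior scale
#'
#' Items 1-6 stereotyped (F2), 7-14 self-injurious (F3), 15-22 compulsive
#' (F4), 23-43 persistent (F1: ritualistic, sameness and restricted
#' behaviors combined). This is the package's default configuration, not a
#' canonical published assignment; supply your own map to [score_rbsr()]
#' to match a specific factor solution.
#'
#' @return named list of item index vectors (`F1` .. `F4`)
#' @export
default_rbsr_factor_map <- function() {
  it <- rbsr_subscale_items()
  list(F1 = it$F1_persistent, F2 = it$F2_stereotyped,
       F3 = it$F3_self_injurious, F4 = it$F4_compulsive)
}

#' Score the repetitive-behavior instrument
#'
#' Totals and four factor scores at each timepoint plus change scores.
#' Items must be complete (impute first with [pmm_impute()]); every item
#' must be mapped to exactly one factor.
#'
#' @param items_t1,items_t2 subjects x 43 complete item matrices
#' @param factor_map named list of item index vectors (see
#'   [default_rbsr_factor_map()])
#' @return an `rbsr_scores` data.frame: total/factor scores per timepoint
#'   and deltas (`delta_total = total_t2 - total_t1`, etc.)
#' @export
score_rbsr <- function(items_t1, items_t2, factor_map = default_rbsr_factor_map()) {
  m1 <- as.matrix(items_t1)
  m2 <- as.matrix(items_t2)
  if (anyNA(m1) || anyNA(m2)) stop("items must be complete; impute first")
  if (!identical(dim(m1), dim(m2))) stop("timepoint matrices differ in shape")
  all_items <- as.integer(sort(unlist(factor_map, use.names = FALSE)))
  if (anyDuplicated(all_items)) {
    stop("config error: item(s) mapped to more than one factor: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "))
  }
  if (!identical(all_items, seq_len(ncol(m1)))) {
    stop("config error: factor map must assign every item exactly once")
  }
  scores <- data.frame(total_t1 = rowSums(m1), total_t2 = rowSums(m2))
  for (f in names(factor_map)) {
    idx <- factor_map[[f]]
    scores[[paste0(f, "_t1")]] <- rowSums(m1[, idx, drop = FALSE])
    scores[[paste0(f, "_t2")]] <- rowSums(m2[, idx, drop = FALSE])
    scores[[paste0("delta_", f)]] <- scores[[paste0(f, "_t2")]] -
      scores[[paste0(f, "_t1")]]
  }
  scores$delta_total <- scores$total_t2 - scores$total_t1
  class(scores) <- c("rbsr_scores", "data.frame")
  scores
}

#' Distribution of change scores within a group
#'
#' @param delta vector of change scores (T2 - T1)
#' @return list: fractions `decreased` / `increased` / `unchanged`
#'   (summing to 1), `max_decrease`, `max_increase` (NA when no such case)
#' @export
change_distribution_summary <- function(delta) {
  if (!length(delta)) stop("empty group")
  n <- length(delta)
  dec <- delta < 0
  inc <- delta > 0
  list(decreased = sum(dec) / n, increased = sum(inc) / n,
       unchanged = sum(delta == 0) / n,
       max_decrease = if (any(dec)) min(delta) else NA_real_,
       max_increase = if (any(inc)) max(delta) else NA_real_)
}

#' Group-comparison table for a cohort
#'
#' Welch t for continuous measures and Yates chi-squared for sex and
#' handedness, mirroring the layout of a demographic comparison table.
#' Behavioral totals are scored after predictive-mean-matching imputation.
#'
#' @param cohort a `cohort`
#' @param seed seed for the imputation draws
#' @return data.frame: measure, group means +/- SD, statistic, df, p, test
#' @export
cohort_comparison_table <- function(cohort, seed = 1L) {
  s <- cohort$subjects
  asd <- s$group == "ASD"
  rows <- list()
  add_t <- function(name, x) {
    gt <- welch_t_from_summary(mean(x[asd]), stats::sd(x[asd]), sum(asd),
                               mean(x[!asd]), stats::sd(x[!asd]), sum(!asd))
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = name,
      asd = sprintf("%.2f ± %.2f", mean(x[asd]), stats::sd(x[asd])),
      td = sprintf("%.2f ± %.2f", mean(x[!asd]), stats::sd(x[!asd])),
      statistic = gt$statistic, df = gt$df, p = gt$p, test = gt$family,
      stringsAsFactors = FALSE)
  }
  add_chi2 <- function(name, f) {
    tab <- table(s$group, f)
    gt <- chi2_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = name,
      asd = paste(tab[1, ], collapse = "/"), td = paste(tab[2, ], collapse = "/"),
      statistic = gt$statistic, df = gt$df, p = gt$p, test = gt$family,
      stringsAsFactors = FALSE)
  }
  add_t("age_t1", s$age_t1)
  add_t("isi", s$isi)
  add_t("fsiq", s$fsiq)
  add_chi2("sex", s$sex)
  add_chi2("handedness", s$handedness)
  if (!is.null(cohort$rbsr_t1)) {
    t1 <- pmm_impute(cohort$rbsr_t1, seed = seed)
    t2 <- pmm_impute(cohort$rbsr_t2, seed = seed + 1L)
    sc <- score_rbsr(t1, t2)
    add_t("rbsr_total_t1", sc$total_t1)
    add_t("rbsr_total_t2", sc$total_t2)
    add_t("rbsr_delta_total", sc$delta_total)
  }
  do.call(rbind, rows)
}
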
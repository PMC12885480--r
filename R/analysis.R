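#' Summarise a parameter map over a region
#'
#' Computes the unweighted mean, sample variance (denominator `n - 1`) and
#' adjusted Fisher-Pearson skewness of the non-missing in-mask voxels of a
#' parameter map. These per-region statistics are the raw material for
#' subject-level averaging and group tests; variance and skewness also
#' support checks that a group shift is a shift of the mean rather than a
#' change of distribution shape.
#'
#' @param param_map 3D numeric array (`NA` marks missing voxels).
#' @param mask 3D logical array selecting the region.
#' @param subject_id,region,hemisphere Optional identifiers carried through
#'   to the output row.
#' @return A one-row `data.frame` with columns `subject_id`, `region`,
#'   `hemisphere`, `mean`, `variance`, `skewness`, `n_voxels`, or `NULL`
#'   (with a warning) if no valid voxel falls in the mask.
#' @export
summarize_region <- function(param_map, mask, subject_id = NA_character_,
                             region = NA_character_,
                             hemisphere = NA_character_) {
  if (!identical(dim(param_map), dim(mask)))
    stopf("param_map and mask dimensions must match")
  vals <- param_map[mask]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    warnf("no valid voxels in region: summary is missing")
    return(NULL)
  }
  n <- length(vals)
  data.frame(subject_id = subject_id, region = region,
             hemisphere = hemisphere,
             mean = mean(vals),
             variance = if (n > 1) var(vals) else 0,
             skewness = if (n > 2 && sd(vals) > 0)
               e1071::skewness(vals, type = 2) else 0,
             n_voxels = n,
             stringsAsFactors = FALSE)
}

#' Pool hemisphere summaries into one value per subject
#'
#' The within-subject average uses both hemisphere images when available, or
#' the single available hemisphere otherwise. By default hemispheres are
#' averaged with equal weight; `voxel_weighted = TRUE` weights them by voxel
#' count instead.
#'
#' @param summaries A `data.frame` of region summaries (rows from
#'   [summarize_region()]) with columns `subject_id`, `mean` and `n_voxels`.
#' @param voxel_weighted Weight hemispheres by their voxel counts.
#' @return A `data.frame` with one row per subject: `subject_id`, `mean`,
#'   `n_hemispheres`, `n_voxels`. Subjects contributing no summary are absent.
#' @export
pool_hemispheres <- function(summaries, voxel_weighted = FALSE) {
  stopifnot(is.data.frame(summaries),
            all(c("subject_id", "mean", "n_voxels") %in% names(summaries)))
  split_rows <- split(summaries, summaries$subject_id)
  out <- lapply(split_rows, function(d) {
    w <- if (voxel_weighted) d$n_voxels else rep(1, nrow(d))
    data.frame(subject_id = d$subject_id[1],
               mean = sum(d$mean * w) / sum(w),
               n_hemispheres = nrow(d),
               n_voxels = sum(d$n_voxels),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Bonferroni adjustment: never decreases p, caps at 1.
bonferroni <- function(p, m) pmin(1, m * p)

.comparison <- function(test, statistic, df, p_value, adjustment = "none",
                        m = 1L) {
  adjusted <- if (identical(adjustment, "bonferroni")) bonferroni(p_value, m)
              else NULL
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, adjusted_p = adjusted,
                 adjustment = if (is.null(adjusted)) "none"
                              else sprintf("bonferroni(%d)", m)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  dfs <- paste(round(x$df, 2), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g%s\n", x$test,
              x$statistic, dfs, x$p_value,
              if (!is.null(x$adjusted_p))
                sprintf(", adjusted p = %.4g [%s]", x$adjusted_p, x$adjustment)
              else ""))
  invisible(x)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's two-tailed independent-samples t-test computed from `(n, mean,
#' SD)` triplets, as printed in figure captions. Identical to the raw-sample
#' pooled t for any samples having exactly those statistics.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group sizes, means and standard
#'   deviations.
#' @return A `group_comparison` with the t statistic on `n1 + n2 - 2` df.
#' @examples
#' t_test_summary(15, 0.715, 0.018, 15, 0.701, 0.022)
#' @export
t_test_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se > 0) (mean1 - mean2) / se else 0
  p <- if (se > 0) 2 * pt(-abs(t), df) else 1
  .comparison("pooled_t", t, df, p)
}

#' One-way ANOVA from summary statistics
#'
#' Between/within sums of squares reconstructed from per-group `(n, mean,
#' SD)`.
#'
#' @param n,means,sds Vectors of group sizes, means and standard deviations.
#' @return A `group_comparison` with the F statistic on
#'   `(k - 1, N - k)` df.
#' @export
oneway_anova_summary <- function(n, means, sds) {
  k <- length(n)
  stopifnot(k >= 2, length(means) == k, length(sds) == k)
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- k - 1; df2 <- N - k
  f <- if (ssw > 0) (ssb / df1) / (ssw / df2) else if (ssb > 0) Inf else 0
  p <- if (is.finite(f)) pf(f, df1, df2, lower.tail = FALSE) else 0
  .comparison("oneway_anova", f, c(df1, df2), p)
}

#' Compare independent groups of subject values
#'
#' Two groups: Student's pooled-variance two-tailed t-test on
#' `n1 + n2 - 2` df. Three or more: one-way ANOVA, optionally followed by
#' Bonferroni-adjusted pairwise pooled t-tests. Degenerate input with zero
#' variance everywhere and equal means yields a zero statistic with `p = 1`.
#'
#' Instead of raw values, a `data.frame` with columns `n`, `mean`, `sd` may
#' be supplied to run the same tests from printed summary statistics.
#'
#' @param groups List of numeric vectors (one per group, each `n >= 2`), or a
#'   summary `data.frame` as above.
#' @param adjustment `"none"` or `"bonferroni"` (applied to post-hoc pairs).
#' @param welch Use Welch's correction instead of the pooled variance
#'   (off by default).
#' @return A `group_comparison`; for `>= 3` groups with
#'   `adjustment = "bonferroni"`, the element `posthoc` lists the pairwise
#'   comparisons.
#' @export
compare_independent <- function(groups, adjustment = c("none", "bonferroni"),
                                welch = FALSE) {
  adjustment <- match.arg(adjustment)
  if (is.data.frame(groups)) {
    stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
    k <- nrow(groups)
    if (k < 2) stopf("need at least 2 groups")
    if (k == 2) {
      return(t_test_summary(groups$n[1], groups$mean[1], groups$sd[1],
                            groups$n[2], groups$mean[2], groups$sd[2]))
    }
    res <- oneway_anova_summary(groups$n, groups$mean, groups$sd)
    if (adjustment == "bonferroni") {
      pairs <- utils::combn(k, 2)
      m <- ncol(pairs)
      res$posthoc <- apply(pairs, 2, function(ij) {
        cmp <- t_test_summary(groups$n[ij[1]], groups$mean[ij[1]],
                              groups$sd[ij[1]], groups$n[ij[2]],
                              groups$mean[ij[2]], groups$sd[ij[2]])
        cmp$adjusted_p <- bonferroni(cmp$p_value, m)
        cmp$adjustment <- sprintf("bonferroni(%d)", m)
        cmp
      })
    }
    return(res)
  }
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) stopf("each group needs n >= 2")
  if (length(groups) == 2) {
    x <- groups[[1]]; y <- groups[[2]]
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
      return(.comparison("pooled_t", 0, length(x) + length(y) - 2, 1))
    tt <- t.test(x, y, var.equal = !welch)
    return(.comparison(if (welch) "welch_t" else "pooled_t",
                       unname(tt$statistic), unname(tt$parameter),
                       tt$p.value))
  }
  values <- unlist(groups)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (sd(values) == 0)
    return(.comparison("oneway_anova", 0,
                       c(length(groups) - 1, length(values) - length(groups)),
                       1))
  fit <- aov(values ~ grp)
  s <- summary(fit)[[1]]
  res <- .comparison("oneway_anova", s[["F value"]][1],
                     c(s[["Df"]][1], s[["Df"]][2]), s[["Pr(>F)"]][1])
  if (adjustment == "bonferroni") {
    pairs <- utils::combn(length(groups), 2)
    m <- ncol(pairs)
    res$posthoc <- apply(pairs, 2, function(ij) {
      cmp <- compare_independent(groups[ij], welch = welch)
      cmp$adjusted_p <- bonferroni(cmp$p_value, m)
      cmp$adjustment <- sprintf("bonferroni(%d)", m)
      cmp
    })
  }
  res
}

#' Paired comparison of matched subject values
#'
#' Two matched vectors: paired two-tailed Student's t-test on the
#' within-subject differences. A repeated-measures table (subjects in rows,
#' conditions in columns): repeated-measures ANOVA with subject as blocking
#' factor, `df = (k - 1, (k - 1)(n - 1))`. Zero-variance differences are
#' handled as a degenerate case: equal vectors give `t = 0, p = 1`; a
#' constant nonzero shift gives an infinite-t sentinel with `p = 0`.
#'
#' @param values_a,values_b Matched numeric vectors (paired t), or
#'   `values_a` alone as an `n x k` matrix/data.frame of repeated measures.
#' @return A `group_comparison`.
#' @export
compare_paired <- function(values_a, values_b = NULL) {
  if (is.null(values_b)) {
    tab <- as.matrix(values_a)
    n <- nrow(tab); k <- ncol(tab)
    if (n < 2 || k < 2) stopf("need >= 2 subjects and >= 2 conditions")
    df_long <- data.frame(
      y = as.numeric(tab),
      cond = factor(rep(seq_len(k), each = n)),
      subj = factor(rep(seq_len(n), k)))
    fit <- aov(y ~ cond + Error(subj), data = df_long)
    s <- summary(fit)[["Error: Within"]][[1]]
    return(.comparison("rm_anova", s[["F value"]][1],
                       c(s[["Df"]][1], s[["Df"]][2]), s[["Pr(>F)"]][1]))
  }
  if (length(values_a) != length(values_b))
    stopf("paired comparison requires matched observations of equal length")
  if (length(values_a) < 2) stopf("need n >= 2 subjects")
  d <- values_a - values_b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(.comparison("paired_t", 0, n - 1, 1))
    return(.comparison("paired_t", sign(mean(d)) * Inf, n - 1, 0))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  .comparison("paired_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value)
}

#' Voxelwise correlation between two parameter maps
#'
#' Pearson correlation between two parameter maps over the valid in-mask
#' voxels, with a Fisher-z 95% confidence interval. Used to quantify the
#' anticorrelation between the free fraction and the bound lifetime.
#'
#' @param map_a,map_b 3D numeric arrays (`NA` marks missing voxels).
#' @param mask 3D logical array.
#' @return List with `r`, `conf_int` (length 2) and `n`, or `NULL` (with a
#'   warning) when fewer than 3 valid pairs exist or a map is constant.
#' @export
param_correlation <- function(map_a, map_b, mask) {
  if (!identical(dim(map_a), dim(mask)) || !identical(dim(map_b), dim(mask)))
    stopf("map and mask dimensions must match")
  a <- map_a[mask]; b <- map_b[mask]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) {
    warnf("fewer than 3 paired valid voxels: correlation undefined")
    return(NULL)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    warnf("constant map: correlation undefined")
    return(NULL)
  }
  ct <- cor.test(a, b, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate),
       conf_int = if (!is.null(ct$conf.int)) as.numeric(ct$conf.int)
                  else c(NA_real_, NA_real_),
       n = length(a))
}
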
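#' Significance stars for a p-value
#'
#' Maps a p-value to the star annotation used in figure legends. Two
#' conventions are supported: the figure-legend thresholds
#' (0.05, 0.01, 0.001 — the default) and the methods-text thresholds
#' (0.05, 0.01, 0.005). Comparison is strict (`p < threshold`); values at
#' or above 0.05 give `"ns"`.
#'
#' @param p p-value.
#' @param convention `"legends"` (default; *** below 0.001) or
#'   `"methods"` (*** below 0.005).
#' @return one of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
significance_stars <- function(p, convention = c("legends", "methods")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(p), length(p) == 1L, !is.na(p))
  th3 <- if (convention == "legends") 0.001 else 0.005
  if (p < th3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

## exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
## group assignments of the pooled sample (tie-safe); two-sided p is the
## probability of a U at least as far from its null mean as observed
.mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)                    # midranks handle ties
  mu <- n1 * n2 / 2
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- sqrt(.Machine$double.eps)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
}

## normal approximation with tie correction and continuity correction
.mw_normal_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(pooled)
  tie_term <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
  v <- n1 * n2 / 12 * (n1 + n2 + 1 - tie_term)
  if (v <= 0) return(1)
  zstat <- (abs(u - mu) - 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-max(zstat, 0)))
}

#' Two-group comparison
#'
#' Two-tailed comparison of two samples, mirroring the decision rule used
#' for condition comparisons: Student's t test by default, the
#' Wilcoxon-Mann-Whitney rank-sum test where normal-theory assumptions
#' fail, or `"auto"`, which runs an F test for equal variances and falls
#' back to the rank-sum test when it fails (p < 0.05). The rank-sum p-value
#' is exact (full enumeration, tie-safe) when both groups have at most
#' `exact_max` observations, and uses the tie- and continuity-corrected
#' normal approximation otherwise.
#'
#' @param a,b numeric sample vectors.
#' @param test `"student_t"`, `"mann_whitney"`, or `"auto"`.
#' @param exact_max enumeration cutoff per group for the rank test
#'   (default 8).
#' @param convention star convention, see [significance_stars()].
#' @return `group_comparison` object: list with `test_name`, `statistic`,
#'   `p_value`, `n_per_group`, `significance_stars`.
#' @export
compare_groups <- function(a, b, test = c("student_t", "mann_whitney", "auto"),
                           exact_max = 8L, convention = "legends") {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample")

  if (test == "auto") {
    test <- if (length(a) >= 2L && length(b) >= 2L &&
                stats::sd(a) > 0 && stats::sd(b) > 0 &&
                stats::var.test(a, b)$p.value < 0.05) "mann_whitney"
    else "student_t"
  }

  if (test == "student_t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t test needs at least 2 observations per group")
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      ## degenerate: both groups constant
      statistic <- if (mean(a) == mean(b)) 0 else Inf
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    }
    name <- "student_t"
  } else {
    n1 <- length(a)
    rk <- rank(c(a, b))
    statistic <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2   # U for sample a
    p <- if (max(length(a), length(b)) <= exact_max) .mw_exact_p(a, b)
    else .mw_normal_p(a, b)
    name <- "mann_whitney"
  }

  out <- list(test_name = name, statistic = statistic, p_value = p,
              n_per_group = c(length(a), length(b)),
              significance_stars = significance_stars(p, convention))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s (n = %d, %d)\n",
              x$test_name, x$statistic, x$p_value, x$significance_stars,
              x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus one-way ANOVA over three or more groups followed by all
#' pairwise two-tailed t tests using the pooled within-group variance,
#' with each raw p multiplied by the number of pairs (capped at 1). With
#' every group a constant of the same value the omnibus F is reported as
#' 0 with p 1.
#'
#' @param groups list of numeric sample vectors (>= 3 groups, each with
#'   >= 2 observations).
#' @param labels optional group names.
#' @param convention star convention, see [significance_stars()].
#' @return `anova_result` object: list with `omnibus` (list: `f`, `df1`,
#'   `df2`, `p_value`) and `comparisons` (data frame: `group_a`,
#'   `group_b`, `statistic`, `p_value`, `p_adjusted`, `stars`).
#' @export
anova_bonferroni <- function(groups, labels = NULL, convention = "legends") {
  if (!is.list(groups) || length(groups) < 3L)
    stop("anova_bonferroni needs at least 3 groups; use compare_groups for 2")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 observations")
  g <- length(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(g))
  stopifnot(length(labels) == g)

  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  df1 <- g - 1L; df2 <- N - g
  if (ss_between == 0) {
    f <- 0; p_omni <- 1
  } else if (ss_within == 0) {
    f <- Inf; p_omni <- 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p_omni <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  mse <- if (df2 > 0) ss_within / df2 else NA_real_
  pairs <- utils::combn(g, 2L)
  k <- ncol(pairs)
  comparisons <- do.call(rbind, lapply(seq_len(k), function(i) {
    ia <- pairs[1L, i]; ib <- pairs[2L, i]
    se <- sqrt(mse * (1 / n[ia] + 1 / n[ib]))
    if (is.na(se) || se == 0) {
      tstat <- if (means[ia] == means[ib]) 0 else Inf
      p <- if (means[ia] == means[ib]) 1 else 0
    } else {
      tstat <- (means[ia] - means[ib]) / se
      p <- 2 * stats::pt(-abs(tstat), df2)
    }
    data.frame(group_a = labels[ia], group_b = labels[ib], statistic = tstat,
               p_value = p, stringsAsFactors = FALSE)
  }))
  comparisons$p_adjusted <- pmin(1, comparisons$p_value * k)
  comparisons$stars <- vapply(comparisons$p_adjusted, significance_stars, "",
                              convention = convention)

  out <- list(omnibus = list(f = f, df1 = df1, df2 = df2, p_value = p_omni),
              comparisons = comparisons)
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$f, x$omnibus$p_value))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
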
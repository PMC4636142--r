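#' Student's t test with the conventions used throughout the package
#'
#' Equal-variance (pooled) two-sample t test, or a paired t test on the
#' within-subject differences. All reported p values are two-tailed.
#' Degenerate zero-variance inputs do not error: when the pooled variance is
#' zero the p value is 1 if the group means agree and 0 otherwise, with a
#' warning, so batch pipelines complete on pathological inputs.
#'
#' @param x,y numeric vectors of measurements (finite values only).
#' @param paired if TRUE, a paired t test on \code{x - y} (equal lengths).
#' @param welch if TRUE, use the unequal-variance (Welch) form instead of the
#'   pooled form; ignored when \code{paired = TRUE}.
#' @return list with elements \code{t} (statistic), \code{p} (two-tailed),
#'   \code{df}, \code{mean_diff}.
#' @examples
#' student_t(c(1, 2, 3), c(11, 12, 13))$p
#' @export
student_t <- function(x, y, paired = FALSE, welch = FALSE) {
  check_sample(x, "x")
  check_sample(y, "y")
  if (paired) {
    if (length(x) != length(y))
      stop("paired test requires equal lengths")
    if (length(x) < 2L) stop("paired test requires n >= 2")
    d <- x - y
    if (stats::var(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      warning("zero variance of paired differences; p = ", p, " by convention")
      return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  p = p, df = length(d) - 1L, mean_diff = mean(d)))
    }
    ht <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (length(x) < 2L || length(y) < 2L)
      stop("two-sample test requires n >= 2 per group")
    pooled_var <- ((length(x) - 1) * stats::var(x) +
                   (length(y) - 1) * stats::var(y)) /
                  (length(x) + length(y) - 2)
    if (pooled_var == 0) {
      md <- mean(x) - mean(y)
      p <- if (md == 0) 1 else 0
      warning("zero pooled variance; p = ", p, " by convention")
      return(list(t = if (md == 0) 0 else sign(md) * Inf,
                  p = p, df = length(x) + length(y) - 2L, mean_diff = md))
    }
    ht <- stats::t.test(x, y, var.equal = !welch)
  }
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_diff = if (paired) mean(x - y) else mean(x) - mean(y))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p value by summing hypergeometric probabilities less than or
#' equal to that of the observed table, at fixed margins (the classical
#' definition, as implemented by \code{\link[stats]{fisher.test}}).
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = groups
#'   (e.g. genotypes), columns = outcome (e.g. abnormal/normal).
#' @return list with \code{odds_ratio} (conditional MLE) and \code{p}
#'   (two-sided).
#' @examples
#' fisher_exact(matrix(c(14, 1, 15, 24), nrow = 2))$p
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: empty margin")
  ht <- stats::fisher.test(tab)
  list(odds_ratio = unname(ht$estimate), p = ht$p.value)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return list with \code{F}, \code{p} (ANOVA), and \code{pairwise}, a
#'   data.frame of pair labels, mean differences and Tukey-adjusted p values.
#' @examples
#' g <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5) + 3)
#' anova_tukey(g)$pairwise
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  for (g in groups) check_sample(g, "group")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  if (all(vapply(groups, stats::var, 0) == 0) &&
      length(unique(vapply(groups, mean, 0))) == 1L) {
    warning("all groups constant and equal; F undefined, p = 1 by convention")
    pairs <- utils::combn(names(groups), 2)
    pw <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     diff = 0, p_adj = 1, stringsAsFactors = FALSE)
    return(list(F = NA_real_, p = 1, pairwise = pw))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       pairwise = data.frame(pair = rownames(tk),
                             diff = unname(tk[, "diff"]),
                             p_adj = unname(tk[, "p adj"]),
                             stringsAsFactors = FALSE))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 2; neither may be constant.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  check_sample(x, "x")
  check_sample(y, "y")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need n >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y, method = "pearson")
}

#' Mean and standard error of the mean
#'
#' @param x numeric vector (length >= 1).
#' @return list with \code{mean} and \code{se} (= sd / sqrt(n)); for a single
#'   value the SE is reported as 0 with a warning.
#' @export
mean_se <- function(x) {
  check_sample(x, "x")
  if (length(x) == 1L) {
    warning("single observation: SE undefined, reported as 0")
    return(list(mean = x, se = 0))
  }
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

# shared argument validation: finite numeric, length >= 1
check_sample <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L)
    stop(name, " must be a non-empty numeric vector")
  if (any(!is.finite(x)))
    stop(name, " contains non-finite values")
  invisible(x)
}
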
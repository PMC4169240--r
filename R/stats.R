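#' Pearson correlation with t-based p value
#'
#' Product-moment correlation `r` with the two-sided p value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (delegated to [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, non-zero variance.
#' @return List with `r`, `p.value`, `statistic` (t), `n`.
#' @examples
#' pearson(1:10, 2 * (1:10) + 1)
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p.value = ct$p.value,
       statistic = unname(ct$statistic), n = length(x))
}

#' Unpaired two-sample t test
#'
#' Student's pooled-variance t test by default (the study reports plain
#' "unpaired t-test"); set `pooled = FALSE` for Welch.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance (Student) form.
#' @return List with `statistic` (t), `p.value`, `df`, `means`.
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6))
#' @export
unpaired_t <- function(a, b, pooled = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p.value = 1,
                  df = length(a) + length(b) - 2L,
                  means = c(mean(a), mean(b))))
    stop("degenerate: zero variance in both groups with unequal means")
  }
  tt <- t.test(a, b, var.equal = pooled)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), means = unname(tt$estimate))
}

#' One-way ANOVA
#'
#' Standard between/within decomposition, `F = MS_between / MS_within`
#' (delegated to [stats::aov()]).  All-identical data return `F = 0`,
#' `p = 1`; groups with zero variance are tolerated.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `statistic` (F), `p.value`, `df`, `ss_between`,
#'   `ss_within`, and the fitted `aov` object (for [tukey_hsd()]).
#' @examples
#' one_way_anova(list(rnorm(5), rnorm(5), rnorm(5)))
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop("each group needs n >= 2")
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(seq_along(groups), vapply(groups, length, 0L))))
  fit <- aov(y ~ g, data = dat)
  # degenerate (all-identical) inputs are resolved below; silence the
  # perfect-fit warning anova() emits for them
  tab <- suppressWarnings(anova(fit))
  ssb <- tab$`Sum Sq`[1L]; ssw <- tab$`Sum Sq`[2L]
  if (ssb <= .Machine$double.eps * max(1, sum(dat$y^2))) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- tab$`F value`[1L]; p <- tab$`Pr(>F)`[1L]
  }
  list(statistic = f, p.value = p, df = tab$Df,
       ss_between = ssb, ss_within = ssw, fit = fit)
}

#' Tukey honest-significant-difference post-hoc comparison
#'
#' Pairwise group contrasts with studentized-range adjusted p values
#' (delegated to [stats::TukeyHSD()]).
#'
#' @inheritParams one_way_anova
#' @param labels Optional group labels.
#' @return `data.frame` with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, labels = NULL) {
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(labels, vapply(groups, length, 0L)), levels = labels))
  hsd <- TukeyHSD(aov(y ~ g, data = dat))$g
  data.frame(comparison = rownames(hsd), diff = hsd[, "diff"],
             lwr = hsd[, "lwr"], upr = hsd[, "upr"],
             p_adj = hsd[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Decade binning of subject ages
#'
#' The cohort's decade grouping: 17-26, 27-36, 37-46, 47-56, 57-66, 67-77
#' (inclusive).  Ages outside 17..77 are excluded with a message.
#'
#' @param ages Integer vector of ages.
#' @param values Optional numeric vector (e.g. per-subject mutation
#'   frequencies) split by bin; defaults to the ages themselves.
#' @return Named list of per-bin value vectors (empty bins kept).
#' @examples
#' bin_by_decade(c(17, 26, 27, 77))
#' @export
bin_by_decade <- function(ages, values = NULL) {
  if (is.null(values)) values <- ages
  if (length(values) != length(ages)) stop("values must match ages in length")
  labels <- c("17-26", "27-36", "37-46", "47-56", "57-66", "67-77")
  keep <- ages >= 17 & ages <= 77
  if (any(!keep))
    message(sum(!keep), " subject(s) outside ages 17-77 excluded from binning")
  bin <- cut(ages[keep], breaks = c(16, 26, 36, 46, 56, 66, 77),
             labels = labels)
  out <- split(values[keep], bin)
  out[labels]
}

#' Fold change between two groups
#'
#' Ratio of group means, `mean(a) / mean(b)`.
#'
#' @param a,b Numeric vectors (non-empty); `mean(b)` must be non-zero.
#' @return Numeric scalar.
#' @examples
#' fold_change(c(2, 2), c(1, 1))
#' @export
fold_change <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  if (mean(b) == 0) stop("fold change undefined: zero denominator mean")
  mean(a) / mean(b)
}

#' Two-group comparison summary
#'
#' Convenience wrapper tying [fold_change()] and [unpaired_t()] together for
#' the old-versus-young style contrasts.
#'
#' @param a,b Numeric vectors (e.g. per-subject mutation frequencies).
#' @param labels Length-2 character group labels.
#' @param pooled Passed to [unpaired_t()].
#' @return Object of class `"group_comparison"`.
#' @export
group_comparison <- function(a, b, labels = c("old", "young"), pooled = TRUE) {
  tt <- unpaired_t(a, b, pooled = pooled)
  out <- list(labels = labels, means = c(mean(a), mean(b)),
              fold_change = fold_change(a, b),
              statistic = tt$statistic, p.value = tt$p.value,
              test = if (pooled) "Student t" else "Welch t")
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: means %.4g / %.4g (%.2g-fold), %s: p = %.4g\n",
              x$labels[1], x$labels[2], x$means[1], x$means[2],
              x$fold_change, x$test, x$p.value))
  invisible(x)
}
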
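# Group comparisons for the per-flight kinematic variables: one-way
# ANOVA with Tukey HSD post hoc tests and the Kruskal-Wallis rank test.
# Statistics follow the textbook closed forms so that generic model
# fitters can serve as independent cross-checks.

check_groups <- function(groups, min_size = 1L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) < min_size)) {
    stop(sprintf("every group needs at least %d observation(s)", min_size),
         call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  groups
}

#' One-way analysis of variance
#'
#' F test of equal group means from the between/within sums of squares,
#' with flow velocity (or any other factor) defining the groups.
#'
#' @param groups named list of numeric vectors, each with >= 2 values.
#' @return a \code{"test_result"} with statistic \code{F} and degrees of
#'   freedom in \code{note}; the fitted decomposition is attached as
#'   attribute \code{"anova"}.
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups, min_size = 2L)
  k <- length(groups)
  ni <- vapply(groups, length, 1L)
  N <- sum(ni)
  means <- vapply(groups, mean, 1)
  grand <- sum(ni * means) / N
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    stop("no variance within or between groups: F undefined (0/0)",
         call. = FALSE)
  }
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  res <- new_test_result("One-way ANOVA", c(F = f), p, "two.sided",
                         exact = FALSE,
                         note = sprintf("df = (%d, %d)", df1, df2))
  attr(res, "anova") <- list(ssb = ssb, ssw = ssw, df1 = df1, df2 = df2,
                             msw = ssw / df2, group_n = ni,
                             group_means = means)
  res
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group differences with adjusted p-values from the
#' studentized-range distribution (Tukey-Kramer: the standard error of a
#' pair uses the harmonic mean of its two group sizes, so unbalanced
#' designs are handled).
#'
#' @inheritParams one_way_anova
#' @return data.frame with one row per pair: \code{pair, diff, q, p_adj}.
#' @export
tukey_hsd <- function(groups) {
  aov_res <- one_way_anova(groups)
  an <- attr(aov_res, "anova")
  k <- length(an$group_n)
  nms <- names(an$group_n)
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      diff <- an$group_means[j] - an$group_means[i]
      se <- sqrt(an$msw / 2 * (1 / an$group_n[i] + 1 / an$group_n[j]))
      q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
      p <- if (is.infinite(q)) 0 else
        ptukey(q, k, an$df2, lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        pair = paste(nms[j], nms[i], sep = "-"),
        diff = unname(diff), q = unname(q), p_adj = unname(p))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric analogue of the one-way ANOVA: tie-corrected H with a
#' chi-squared approximation on \code{k - 1} degrees of freedom. When
#' every observation is identical the test degenerates to H = 0, p = 1.
#'
#' @inheritParams one_way_anova
#' @return a \code{"test_result"} with statistic \code{H}.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups, min_size = 1L)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  rk <- rank(x)
  Ri <- tapply(rk, g, sum)
  ni <- tapply(rk, g, length)
  h <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  tie_tab <- table(x)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr <= 0) {
    # all observations identical
    return(new_test_result("Kruskal-Wallis", c(H = 0), 1, "two.sided",
                           exact = FALSE, note = "degenerate: all ties"))
  }
  h <- h / corr
  df <- length(groups) - 1L
  p <- pchisq(h, df, lower.tail = FALSE)
  new_test_result("Kruskal-Wallis", c(H = h), p, "two.sided",
                  exact = FALSE, note = sprintf("df = %d", df))
}
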
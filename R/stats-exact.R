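# Exact small-sample nonparametric tests. The null distributions are
# enumerated (sign assignments for the signed-rank test, rank subsets for
# the rank-sum test, the binomial pmf for the binomial test) so that
# small-sample p-values are exact rather than asymptotic.

new_test_result <- function(name, statistic, p, alternative, exact,
                            note = NULL) {
  structure(list(test = name, statistic = statistic,
                 p.value = min(max(p, 0), 1),
                 alternative = alternative, exact = exact, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test, "\n")
  cat(sprintf("  %s = %g, p = %.6g (%s, %s)\n",
              names(x$statistic)[1], x$statistic[1], x$p.value,
              x$alternative, if (x$exact) "exact" else "approximate"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Exact pmf of the signed-rank statistic for given (possibly tied,
# midrank) ranks: distribution of the sum of a uniformly random subset.
# Ranks are doubled so midranks (multiples of 0.5) become integers; the
# returned support is on the doubled scale.
signed_rank_null_pmf <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1L)  # index i holds P(V2 = i - 1)
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), p[seq_len(total + 1L - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' One-sample Wilcoxon signed-rank test with exact enumeration
#'
#' Tests whether values are symmetrically distributed about \code{mu}.
#' Values equal to \code{mu} are dropped before ranking; ties among the
#' absolute deviations receive midranks. \code{V} is the sum of the
#' ranks of the positive deviations. For \code{n <= exact_limit} the
#' p-value is exact: all \code{2^n} equally likely sign assignments are
#' enumerated (via the generating function of the rank sum, which handles
#' midranks). Beyond that a normal approximation with tie correction and
#' continuity correction is used. Two-sided p doubles the smaller tail,
#' capped at 1.
#'
#' @param values numeric sample (e.g. 12 daily proportions).
#' @param mu null centre of symmetry (0.5 for a choice proportion).
#' @param alternative \code{"greater"}, \code{"less"} or
#'   \code{"two.sided"}.
#' @param exact_limit maximum n for exact enumeration.
#' @return a \code{"test_result"} with statistic \code{V}.
#' @examples
#' # 12 daily proportions all above 0.5: V = 78, one-sided p = 1/4096
#' wilcoxon_signed_rank(seq(0.55, 0.77, 0.02), mu = 0.5, "greater")
#' @export
wilcoxon_signed_rank <- function(values, mu = 0.5,
                                 alternative = c("greater", "less",
                                                 "two.sided"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  d <- values - mu
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (!n) stop("all values equal `mu`: no data to test", call. = FALSE)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  ties <- any(duplicated(rk))
  if (n <= exact_limit) {
    pmf <- signed_rank_null_pmf(as.integer(round(2 * rk)))
    v2 <- as.integer(round(2 * V))
    p_ge <- sum(pmf[(v2 + 1L):length(pmf)])
    p_le <- sum(pmf[seq_len(v2 + 1L)])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(new_test_result("Wilcoxon signed-rank (one-sample)",
                           c(V = V), p, alternative, exact = TRUE,
                           note = if (ties) "midranks enumerated" else NULL))
  }
  mu_v <- n * (n + 1) / 4
  tie_tab <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  cc <- 0.5
  z_ge <- (V - mu_v - cc) / sqrt(sig2)
  z_le <- (V - mu_v + cc) / sqrt(sig2)
  p <- switch(alternative,
              greater = stats::pnorm(z_ge, lower.tail = FALSE),
              less = stats::pnorm(z_le),
              two.sided = min(1, 2 * min(stats::pnorm(z_ge,
                                                      lower.tail = FALSE),
                                         stats::pnorm(z_le))))
  new_test_result("Wilcoxon signed-rank (one-sample)", c(V = V), p,
                  alternative, exact = FALSE,
                  note = "normal approximation with tie correction")
}

#' Exact binomial test
#'
#' Exact test of \code{k} successes in \code{n} trials against success
#' probability \code{p0}. The two-sided p-value uses the small-P method:
#' the sum of probabilities of all outcomes no more likely than the
#' observed one (for \code{p0 = 0.5} this is the symmetric tail sum).
#'
#' @param k,n successes and trials.
#' @param p0 null success probability.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return a \code{"test_result"} with statistic \code{k}.
#' @export
binomial_test <- function(k, n, p0 = 0.5,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (k < 0L || k > n) stop("`k` must lie in 0..n", call. = FALSE)
  pmf <- dbinom(0:n, n, p0)
  p <- switch(alternative,
              greater = sum(pmf[(k + 1L):(n + 1L)]),
              less = sum(pmf[seq_len(k + 1L)]),
              two.sided = sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)]))
  new_test_result("Exact binomial test", c(k = k, n = n), p, alternative,
                  exact = TRUE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Compares two samples by the rank sum of the first. With
#' \code{m + n <= exact_limit} and no ties the p-value is exact, from
#' full enumeration of all \eqn{\binom{m+n}{m}} rank subsets; otherwise
#' a normal approximation with tie correction and continuity correction
#' is used. The reported statistic \code{W} is the Mann-Whitney form
#' (rank sum of \code{a} minus its minimum), matching common software.
#'
#' @param a,b numeric samples.
#' @param alternative \code{"two.sided"}, \code{"greater"} (a tends
#'   larger) or \code{"less"}.
#' @param exact_limit maximum m+n for exact enumeration.
#' @return a \code{"test_result"} with statistic \code{W}.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater",
                                              "less"),
                              exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(a); n <- length(b)
  rk <- rank(c(a, b))
  Ra <- sum(rk[seq_len(m)])
  W <- Ra - m * (m + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (m + n <= exact_limit && !ties) {
    combos <- utils::combn(m + n, m)
    sums <- colSums(matrix(seq_len(m + n)[combos], nrow = m))
    p_ge <- mean(sums >= Ra)
    p_le <- mean(sums <= Ra)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(new_test_result("Wilcoxon rank-sum (two-sample)", c(W = W), p,
                           alternative, exact = TRUE))
  }
  mu_w <- m * n / 2
  N <- m + n
  tie_tab <- table(rk)
  sig2 <- m * n / 12 * (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  cc <- 0.5
  z_ge <- (W - mu_w - cc) / sqrt(sig2)
  z_le <- (W - mu_w + cc) / sqrt(sig2)
  p <- switch(alternative,
              greater = stats::pnorm(z_ge, lower.tail = FALSE),
              less = stats::pnorm(z_le),
              two.sided = min(1, 2 * min(stats::pnorm(z_ge,
                                                      lower.tail = FALSE),
                                         stats::pnorm(z_le))))
  new_test_result("Wilcoxon rank-sum (two-sample)", c(W = W), p,
                  alternative, exact = FALSE,
                  note = "normal approximation with tie and continuity correction")
}
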
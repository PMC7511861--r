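# Shared statistical primitives.
#
# Every helper returns a one-row "test result" data.frame
# (statistic, df, p_value, estimate) so results from different tests can be
# stacked into a single TSV.

test_result <- function(statistic, df, p_value, estimate) {
  data.frame(statistic = statistic, df = df, p_value = p_value,
             estimate = estimate)
}

#' Pearson correlation with two-sided p-value
#'
#' p comes from the t transform r * sqrt((n-2)/(1-r^2)) on n-2 df.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance
#' @return one-row data.frame: statistic (t), df, p_value, estimate (r)
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
              unname(ct$estimate))
}

#' Critical Pearson correlation at a two-sided significance level
#'
#' Returns r* with p(r*, n) = alpha: r* = t* / sqrt(n - 2 + t*^2) where t*
#' is the (1 - alpha/2) Student-t quantile on n - 2 df. At alpha = 0.05 and
#' n = 52 this is the familiar |r| >= 0.27 cutoff.
#'
#' @param alpha two-sided significance level in (0, 1)
#' @param n sample size >= 3
#' @return the critical |r|
#' @export
critical_r <- function(alpha, n) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n < 3) stop("n must be >= 3")
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(n - 2 + tq^2)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Welch-Satterthwaite df, two-sided p. When both groups are constant and
#' equal the comparison is degenerate and p = 1 by convention (p = 0 when
#' constant but different). `paired_by` averages within its levels first
#' and runs a paired comparison across levels present in both groups
#' (strain-paired variant).
#'
#' @param a,b numeric vectors (each n >= 2)
#' @param paired_by optional factor pairs: list(a = keys_a, b = keys_b)
#' @return one-row data.frame: statistic (t), df, p_value,
#'   estimate (mean(a) - mean(b))
#' @export
welch_t <- function(a, b, paired_by = NULL) {
  if (!is.null(paired_by)) {
    ka <- tapply(a, paired_by$a, mean)
    kb <- tapply(b, paired_by$b, mean)
    shared <- intersect(names(ka), names(kb))
    if (length(shared) < 2) stop("need >= 2 shared pairing levels")
    d <- ka[shared] - kb[shared]
    if (stats::sd(d) == 0)
      return(test_result(if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                         length(d) - 1, as.numeric(mean(d) == 0), mean(d)))
    tt <- stats::t.test(d)
    return(test_result(unname(tt$statistic), unname(tt$parameter),
                       tt$p.value, mean(d)))
  }
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  est <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(test_result(if (est == 0) 0 else Inf * sign(est),
                       length(a) + length(b) - 2,
                       as.numeric(est == 0), est))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value, est)
}

#' Partial (Type-II-style) F-test for one term of a linear model
#'
#' Compares the full OLS fit against the fit with the named term removed.
#' For a single-column term the F statistic equals the square of the
#' coefficient's t statistic and the estimate is that coefficient; for a
#' categorical term with k levels the numerator df is k - 1 and the
#' estimate is NA.
#'
#' @param response numeric vector
#' @param design data.frame of covariate columns (numeric or factor)
#' @param term name of the column to test
#' @return one-row data.frame: statistic (F), df (numerator), df_denom,
#'   p_value, estimate
#' @export
ols_partial_f <- function(response, design, term) {
  if (!term %in% names(design)) stop("unknown term: ", term)
  dat <- cbind(.y = response, design)
  full <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(.y ~ ., data = dat[, setdiff(names(dat), term),
                                          drop = FALSE])
  an <- stats::anova(reduced, full)
  fstat <- an$F[2]
  df1 <- an$Df[2]
  df2 <- an$Res.Df[2]
  est <- NA_real_
  cf <- stats::coef(full)
  if (is.numeric(design[[term]]) && term %in% names(cf)) est <- cf[[term]]
  out <- test_result(fstat, df1, an$`Pr(>F)`[2], est)
  out$df_denom <- df2
  out[c("statistic", "df", "df_denom", "p_value", "estimate")]
}

#' Hypergeometric tail probabilities
#'
#' Upper tail P(X >= k) (enrichment) under sampling n draws without
#' replacement from a population of N with K successes. `lower = TRUE`
#' instead returns the depletion tail P(X <= k).
#'
#' @param N population size
#' @param K successes in the population
#' @param n number of draws
#' @param k observed successes among the draws
#' @param lower return P(X <= k) instead of P(X >= k)
#' @return tail probability
#' @export
hypergeometric_tail <- function(N, K, n, k, lower = FALSE) {
  if (any(c(N, K, n, k) < 0) || k > n || n > N || K > N || k > K)
    stop("incoherent hypergeometric counts")
  if (lower)
    stats::phyper(k, K, N - K, n)
  else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
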
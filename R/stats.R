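# Group-comparison and correlation statistics: Mann-Whitney U, pooled t-test
# (with summary-statistic input), 2x2 chi-square, Spearman rho, Kendall
# tau-b, Bonferroni control.

#' Mann-Whitney U test
#'
#' U statistic with midrank tie correction. p-value: exact enumeration (via
#' \code{stats::wilcox.test}) when the smaller sample has at most
#' \code{exact_max} observations and there are no ties, otherwise a two-sided
#' normal approximation with tie-corrected variance.
#'
#' @param x,y numeric samples.
#' @param exact_max largest min-group size for exact enumeration (default 8).
#' @return list with \code{U} (for the first sample), \code{p}, \code{n1},
#'   \code{n2}.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && min(n1, n2) <= exact_max) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # fully tie-degenerate data carry no ordering information
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = U, p = min(p, 1), n1 = n1, n2 = n2)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance, two-sided. Accepts either raw samples or
#' summary statistics \code{c(mean, sd, n)} for each group.
#'
#' @param x,y numeric samples, or length-3 vectors \code{c(mean, sd, n)} when
#'   \code{summary = TRUE}.
#' @param summary interpret inputs as summary statistics.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
t_test_pooled <- function(x, y, summary = FALSE) {
  if (summary) {
    m1 <- x[1]; s1 <- x[2]; n1 <- x[3]
    m2 <- y[1]; s2 <- y[2]; n2 <- y[3]
  } else {
    n1 <- length(x); n2 <- length(y)
    m1 <- mean(x); m2 <- mean(y)
    s1 <- stats::sd(x); s2 <- stats::sd(y)
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 <= 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = df))
    stop("degenerate variance")
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param a,b,c,d cell counts (first row a, b; second row c, d).
#' @return list with \code{chi2}, \code{p}.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in 2x2 table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; two-sided p-value from the t
#' approximation with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric samples (n >= 3).
#' @param alpha significance level before Bonferroni adjustment.
#' @param m number of comparisons for the Bonferroni flag (default 1).
#' @return object of class \code{correlation_result}: list(method,
#'   coefficient, p_value, n, significant_after_bonferroni, adjusted_alpha).
#' @export
spearman_corr <- function(x, y, alpha = 0.05, m = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined coefficient: constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  correlation_result("spearman", rho, p, n, alpha, m)
}

#' Kendall tau-b correlation
#'
#' tau-b with the standard tie terms (via \code{stats::cor}); two-sided
#' p-value from the normal approximation of \code{stats::cor.test}.
#'
#' @inheritParams spearman_corr
#' @return a \code{correlation_result}.
#' @export
kendall_tau_b <- function(x, y, alpha = 0.05, m = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined coefficient: all-tied input vector")
  tau <- stats::cor(x, y, method = "kendall")
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE)$p.value
  )
  correlation_result("kendall_tau_b", tau, p, n, alpha, m)
}

correlation_result <- function(method, coefficient, p_value, n, alpha, m) {
  adj <- bonferroni_alpha(alpha, m)
  structure(list(method = method, coefficient = coefficient,
                 p_value = p_value, n = n,
                 adjusted_alpha = adj,
                 significant_after_bonferroni = p_value < adj),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: coefficient %.3f, p = %.3g, n = %d%s\n", x$method,
              x$coefficient, x$p_value, x$n,
              if (x$significant_after_bonferroni)
                sprintf(" (significant at Bonferroni alpha %.3g)", x$adjusted_alpha)
              else ""))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return alpha / m.
#' @examples
#' bonferroni_alpha(0.05, 40)  # 0.00125
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / m
}
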
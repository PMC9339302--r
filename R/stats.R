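# Statistical readouts used by the assay: chi-square goodness of fit
# against wildtype-derived proportions, chi-square test of independence on
# a contingency table, and two-tailed two-sample t-tests on per-field
# percentages. Significance is conventionally read at alpha = 0.05.

test_result <- function(test_name, statistic, df, p_value, alpha = 0.05,
                        degenerate = FALSE) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, alpha = alpha, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, df = %g, p = %.4g%s\n", x$test_name,
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(test_name = x$test_name, statistic = x$statistic, df = x$df,
             p_value = x$p_value, alpha = x$alpha)
}

#' Chi-square goodness-of-fit test
#'
#' Compares observed category counts to expected counts
#' `E = N * proportion`; the statistic is `sum((O - E)^2 / E)` with
#' `categories - 1` degrees of freedom and the p-value from the upper
#' tail of the chi-square distribution (the regularized incomplete gamma
#' function).
#'
#' @param observed Integer vector of counts per category (>= 2
#'   categories).
#' @param expected_proportions Expected proportions summing to 1, all
#'   positive.
#' @param alpha Significance level recorded in the result.
#' @return A `test_result`.
#' @export
#' @examples
#' chi_square_gof(c(30, 70), c(0.5, 0.5))  # statistic 16, df 1
chi_square_gof <- function(observed, expected_proportions, alpha = 0.05) {
  if (length(observed) < 2) stop_usage("need >= 2 categories")
  if (length(observed) != length(expected_proportions)) {
    stop_usage("observed and expected_proportions differ in length")
  }
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop_usage("expected proportions must sum to 1")
  }
  expected <- sum(observed) * expected_proportions
  if (any(expected <= 0)) stop_usage("expected counts must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  test_result("chi_square_gof", stat, df,
              pchisq(stat, df, lower.tail = FALSE), alpha)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a 2-way contingency table with
#' `E_ij = row_i * col_j / N`, `df = (r - 1)(c - 1)` and no continuity
#' correction.
#'
#' @param table Numeric matrix of counts with all row and column sums
#'   positive.
#' @param alpha Significance level recorded in the result.
#' @return A `test_result`.
#' @export
chi_square_independence <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop_usage("contingency table must be at least 2x2")
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs <= 0) || any(cs <= 0)) {
    stop_usage("all row and column sums must be positive")
  }
  expected <- outer(rs, cs) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  test_result("chi_square_independence", stat, df,
              pchisq(stat, df, lower.tail = FALSE), alpha)
}

#' Two-tailed two-sample t-test
#'
#' Student's t (pooled variance, `df = n_a + n_b - 2`) by default; Welch
#' optional. Intended for per-field matched percentages. Degenerate
#' inputs (both samples zero-variance) yield p = 1 for equal means and a
#' flagged p = 0 otherwise.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param variant `"student"` or `"welch"`.
#' @param alpha Significance level recorded in the result.
#' @return A `test_result`.
#' @export
t_two_sample <- function(a, b, variant = c("student", "welch"),
                         alpha = 0.05) {
  variant <- match.arg(variant)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop_usage("each sample needs >= 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(test_result(paste0("t_", variant), 0, na + nb - 2, 1, alpha))
    }
    return(test_result(paste0("t_", variant), Inf, na + nb - 2, 0, alpha,
                       degenerate = TRUE))
  }
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  stat <- (mean(a) - mean(b)) / se
  test_result(paste0("t_", variant), stat, df, 2 * pt(-abs(stat), df), alpha)
}
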
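#' Methylation-positive rate
#'
#' @param calls Character vector of `"POSITIVE"`/`"NEGATIVE"` calls (or a
#'   logical vector, `TRUE` = positive).
#' @return Percentage of positive calls (full precision; round for
#'   presentation).
#' @export
#' @examples
#' positive_rate(rep(c("POSITIVE", "NEGATIVE"), c(90, 4)))  # 95.744...
positive_rate <- function(calls) {
  if (length(calls) == 0L) stop("positive rate undefined for an empty set")
  pos <- if (is.logical(calls)) calls else calls == "POSITIVE"
  100 * sum(pos) / length(pos)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Classical Pearson statistic `sum((O - E)^2 / E)` on 1 degree of freedom
#' with the upper-tail p value; Yates continuity correction is available
#' but off by default.  A zero expected count makes the statistic
#' undefined and raises an error suggesting an exact test.
#'
#' @param table 2x2 matrix of non-negative counts (rows = groups,
#'   columns = positive/negative).
#' @param continuity Apply the Yates correction (default `FALSE`).
#' @return List with `statistic`, `df` (1) and `p_value` (two-sided).
#' @export
#' @examples
#' chi_square_2x2(matrix(c(64, 16, 18, 18), nrow = 2))
chi_square_2x2 <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be non-negative counts")
  }
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected == 0)) {
    stop("a zero expected count makes the chi-square statistic undefined; ",
         "use an exact test")
  }
  dev <- abs(table - expected)
  if (continuity) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  list(statistic = statistic, df = 1L,
       p_value = pchisq(statistic, df = 1L, lower.tail = FALSE))
}

#' Mann-Whitney / t comparison of two Ct groups
#'
#' Compares the reference-gene Ct of two sample groups.  The U statistic is
#' computed by rank sums with midranks for ties and the two-sided p value
#' by the normal approximation with tie-corrected variance (appropriate at
#' cohort sizes; exact enumeration is used only as a test oracle).  An
#' unequal-variance (Welch) t test is reported alongside.  `delta_ct` is
#' `median(b) - median(a)`: positive when group b sits at higher Ct, i.e.
#' lower input template.
#'
#' @param group_a,group_b Numeric vectors of Ct values, each non-empty.
#' @return List of class `"group_comparison"`: `median_a`, `median_b`,
#'   `mean_a`, `mean_b`, `delta_ct`, `u_statistic`, `t_statistic`,
#'   `p_mw`, `p_t`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney(rnorm(20, 31), rnorm(20, 33))
mann_whitney <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("Ct groups must not contain NA")
  n_a <- length(a); n_b <- length(b)

  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks for ties
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  n <- n_a + n_b
  mu <- n_a * n_b / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    p_mw <- 1    # all values tied: no evidence of a shift
    z <- 0
  } else {
    z <- (u_a - mu) / sqrt(sigma2)
    p_mw <- min(1, 2 * pnorm(-abs(z)))
  }

  tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  structure(
    list(n_a = n_a, n_b = n_b,
         median_a = median(a), median_b = median(b),
         mean_a = mean(a), mean_b = mean(b),
         delta_ct = median(b) - median(a),
         u_statistic = u_a,
         t_statistic = unname(tt$statistic),
         p_mw = p_mw, p_t = tt$p.value),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (n = %d vs %d)\n", x$n_a, x$n_b))
  cat(sprintf("  median: %.2f vs %.2f  (delta Ct = %.2f)\n",
              x$median_a, x$median_b, x$delta_ct))
  cat(sprintf("  mean:   %.2f vs %.2f\n", x$mean_a, x$mean_b))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.4g\n", x$u_statistic, x$p_mw))
  if (!is.na(x$t_statistic)) {
    cat(sprintf("  Welch t = %.2f, p = %.4g\n", x$t_statistic, x$p_t))
  }
  invisible(x)
}
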
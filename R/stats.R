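## Statistical comparison of the two accuracy tables: column means,
## Shapiro-Wilk normality, QQ points and the two-tailed paired t-test.

#' Shapiro-Wilk normality test (Royston's approximation)
#'
#' Computes the W statistic from the Blom-scored order statistics with
#' Royston's polynomial weight corrections, and the p-value from his normal
#' approximation of log(1 - W) (exact arcsine form at n = 3). The null
#' hypothesis of normality is retained when p exceeds the chosen level.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List with `W`, `p_value` and `n`.
#' @references Royston, P. (1995). A remark on algorithm AS 181: the W-test
#'   for normality. Applied Statistics 44, 547-551.
#' @export
shapiro_wilk <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 3) stop("Shapiro-Wilk requires at least 3 observations")
  if (n > 5000) stop("Shapiro-Wilk supports at most 5000 observations")
  if (x[n] - x[1] == 0) stop("sample is constant; W is undefined")

  m <- qnorm((seq_len(n) - 0.375) / (n + 0.25))
  ssm <- sum(m^2)
  rsn <- 1 / sqrt(n)
  a <- m / sqrt(ssm)
  if (n > 3) {
    an <- -2.706056 * rsn^5 + 4.434685 * rsn^4 - 2.071190 * rsn^3 -
      0.147981 * rsn^2 + 0.221157 * rsn + a[n]
    if (n > 5) {
      an1 <- -3.582633 * rsn^5 + 5.682633 * rsn^4 - 1.752461 * rsn^3 -
        0.293762 * rsn^2 + 0.042981 * rsn + a[n - 1]
      phi <- (ssm - 2 * m[n]^2 - 2 * m[n - 1]^2) /
        (1 - 2 * an^2 - 2 * an1^2)
      a <- m / sqrt(phi)
      a[c(1, n)] <- c(-an, an)
      a[c(2, n - 1)] <- c(-an1, an1)
    } else {
      phi <- (ssm - 2 * m[n]^2) / (1 - 2 * an^2)
      a <- m / sqrt(phi)
      a[c(1, n)] <- c(-an, an)
    }
  }
  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  W <- min(W, 1)

  p <- if (n == 3) {
    pi6 <- 6 / pi
    min(max(pi6 * (asin(sqrt(W)) - asin(sqrt(0.75))), 0), 1)
  } else if (n <= 11) {
    g <- -2.273 + 0.459 * n
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    pnorm((-log(g - log1p(-W)) - mu) / sig, lower.tail = FALSE)
  } else {
    ln <- log(n)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sig <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    pnorm((log1p(-W) - mu) / sig, lower.tail = FALSE)
  }
  list(W = W, p_value = p, n = n)
}

#' Normal QQ points with Blom plotting positions
#'
#' Pairs the sample order statistics with standard-normal quantiles at
#' plotting positions `(i - 0.375) / (n + 0.25)`.
#'
#' @param x Numeric sample, n >= 2.
#' @return Data frame with `theoretical` and `sample` columns, ordered.
#' @export
qq_points <- function(x) {
  n <- length(x)
  if (n < 2) stop("QQ points require at least 2 observations")
  data.frame(theoretical = qnorm((seq_len(n) - 0.375) / (n + 0.25)),
             sample = sort(as.numeric(x)))
}

#' Two-tailed paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`
#' (sample sd, n - 1 denominator), with `df = n - 1` and the two-tailed
#' p-value from Student's t distribution. Identical samples give t = 0,
#' p = 1; a non-zero constant difference (zero variance) is degenerate and
#' rejected.
#'
#' @param x,y Paired numeric vectors of equal length n >= 2.
#' @return List with `t`, `df`, `p_value`, `mean_diff` and `n`.
#' @export
paired_t_two_tailed <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) stop("paired t-test requires at least 2 pairs")
  d <- as.numeric(x) - as.numeric(y)
  sdd <- sd(d)
  if (sdd == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1L, p_value = 1, mean_diff = 0, n = n))
    }
    stop("paired differences have zero variance; t is degenerate")
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1L,
       p_value = 2 * pt(-abs(t), df = n - 1),
       mean_diff = mean(d), n = n)
}

#' Full statistical comparison of two accuracy tables
#'
#' Reproduces the study's analysis: per-budget group means (reported at two
#' decimals), per-budget Shapiro-Wilk normality for both groups with the
#' retain/reject decision at `alpha`, the two-tailed paired t-test between
#' the groups at the chosen budget column (pairing subjects by row order,
#' on the unrounded cell values), the mean paired difference and the table
#' maxima.
#'
#' @param control,baseline [accuracy_table()]s with matching subject counts
#'   and budgets.
#' @param budget Budget column tested (default 60, the column that
#'   reproduces the published test statistic).
#' @param alpha Significance level.
#' @return A `stat_report` object.
#' @export
compare_groups <- function(control, baseline, budget = 60, alpha = 0.05) {
  stopifnot(inherits(control, "accuracy_table"),
            inherits(baseline, "accuracy_table"))
  if (nrow(control$values) != nrow(baseline$values)) {
    stop("groups have different subject counts; cannot pair rows")
  }
  if (!identical(control$budgets, baseline$budgets)) {
    stop("groups have different budget columns")
  }
  budget <- as.character(budget)
  if (!budget %in% colnames(control$values)) {
    stop("budget ", budget, " is not a column of the tables")
  }
  normality <- lapply(list(control = control, baseline = baseline),
                      function(tab) {
    if (nrow(tab$values) < 3) {
      # too few subjects for a normality test; report NA, do not guess
      return(data.frame(budget = tab$budgets, W = NA_real_,
                        p_value = NA_real_, normal = NA))
    }
    res <- lapply(as.data.frame(tab$values), shapiro_wilk)
    data.frame(budget = tab$budgets,
               W = vapply(res, `[[`, numeric(1), "W"),
               p_value = vapply(res, `[[`, numeric(1), "p_value"),
               normal = vapply(res, function(r) r$p_value > alpha,
                               logical(1)),
               row.names = NULL)
  })
  tt <- if (nrow(control$values) >= 2) {
    paired_t_two_tailed(control$values[, budget], baseline$values[, budget])
  } else {
    d <- control$values[, budget] - baseline$values[, budget]
    list(t = NA_real_, df = 0L, p_value = NA_real_,
         mean_diff = mean(d), n = length(d))
  }
  out <- list(
    means = list(control = column_means(control),
                 baseline = column_means(baseline)),
    normality = normality,
    test_budget = as.integer(budget),
    paired_t = tt,
    mean_diff = tt$mean_diff,
    max_cell = list(control = table_max(control),
                    baseline = table_max(baseline)),
    alpha = alpha
  )
  class(out) <- "stat_report"
  out
}

#' @export
print.stat_report <- function(x, ...) {
  cat("Group mean accuracies (%):\n")
  print(rbind(control = x$means$control, baseline = x$means$baseline))
  ok <- isTRUE(all(x$normality$control$normal)) &&
    isTRUE(all(x$normality$baseline$normal))
  cat(sprintf("\nShapiro-Wilk at alpha = %g: normality %s\n", x$alpha,
              if (ok) "retained in every budget column"
              else "rejected (or untestable) in at least one budget column"))
  cat(sprintf(
    "Paired t-test (budget %d): t = %.4f, df = %d, two-tailed p = %.4g\n",
    x$test_budget, x$paired_t$t, x$paired_t$df, x$paired_t$p_value))
  cat(sprintf("Mean paired difference: %.2f%%; table maxima: control %.2f%%, baseline %.2f%%\n",
              x$mean_diff, x$max_cell$control, x$max_cell$baseline))
  invisible(x)
}

#' Serialize a stat report to JSON
#'
#' @param report A [compare_groups()] report.
#' @param path Optional file path; when `NULL`, the JSON text is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "stat_report"))
  doc <- unclass(report)
  doc$means <- lapply(doc$means, as.list)  # keep budget names as JSON keys
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          dataframe = "columns")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
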
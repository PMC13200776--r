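# Agreement and reliability statistics used to validate the grading
# method: Spearman correlation, Bland-Altman limits of agreement, two-way
# mixed-model intraclass correlation, Cronbach alpha, the published
# classification bins, and the normality-gated paired-change test.

#' Construct a rater table
#'
#' A complete subjects x measurements matrix (raters, or repeated
#' measurements of one instrument) feeding the ICC / alpha / agreement
#' statistics.  Missing cells are not allowed; apply listwise deletion
#' upstream.
#'
#' @param x Numeric matrix or data frame, n subjects x k measurements,
#'   `n >= 2`, `k >= 2`.
#' @param subjects Optional subject ids (default rownames or 1..n).
#' @param measurements Optional measurement labels (default colnames).
#' @return A numeric matrix of class `rater_table`.
#' @export
rater_table <- function(x, subjects = NULL, measurements = NULL) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  class(m) <- setdiff(class(m), "rater_table")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("a rater table needs at least 2 subjects and 2 measurements",
         call. = FALSE)
  }
  if (anyNA(m) || !all(is.finite(m))) {
    stop("rater table must be complete and finite", call. = FALSE)
  }
  rownames(m) <- subjects %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  colnames(m) <- measurements %||% colnames(m) %||%
    paste0("m", seq_len(ncol(m)))
  class(m) <- c("rater_table", class(m))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero rank variance: a constant vector has no rank correlation",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Bland-Altman agreement analysis
#'
#' Differences are computed as `method_a - method_b`; the report carries
#' the bias (mean difference), the sample SD of the differences, the 95%
#' limits of agreement `bias +/- 1.96 * SD`, and the number of pairs
#' falling outside the limits.  Both methods must be on the same
#' standardized scale.
#'
#' @param method_a,method_b Paired numeric vectors of equal length `>= 2`.
#' @return A list of class `bland_altman` with `bias`, `sd_bias`,
#'   `loa_low`, `loa_high`, `n`, `n_outside`, `means`, `differences`.
#' @export
bland_altman <- function(method_a, method_b) {
  if (length(method_a) != length(method_b)) {
    stop("method_a and method_b must be paired (equal length)",
         call. = FALSE)
  }
  if (length(method_a) < 2L) {
    stop("at least 2 pairs are required", call. = FALSE)
  }
  d <- method_a - method_b
  bias <- mean(d)
  sd_bias <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_bias
  loa_high <- bias + 1.96 * sd_bias
  structure(list(
    bias = bias, sd_bias = sd_bias,
    loa_low = loa_low, loa_high = loa_high,
    n = length(d),
    n_outside = sum(d < loa_low | d > loa_high),
    means = (method_a + method_b) / 2,
    differences = d
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f (SD %.2f), 95%% LoA [%.2f, %.2f]\n",
              x$bias, x$sd_bias, x$loa_low, x$loa_high))
  cat(sprintf("  n = %d pairs, %d outside the limits\n", x$n, x$n_outside))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias and limits of agreement
#' as horizontal lines.
#'
#' @param x A `bland_altman` report.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$differences,
       xlab = "Mean of methods", ylab = "Difference (A - B)", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Two-way mixed-model intraclass correlation
#'
#' ICC from the two-way (subjects x measurements) ANOVA decomposition with
#' mean squares MSR (rows/subjects), MSC (columns/measurements), and MSE
#' (residual):
#'
#' * consistency, single:  `(MSR - MSE) / (MSR + (k-1) MSE)`
#' * consistency, average: `(MSR - MSE) / MSR`
#' * absolute, single:
#'   `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' * absolute, average:    `(MSR - MSE) / (MSR + (MSC - MSE) / n)`
#'
#' "Absolute agreement" penalizes systematic rater offsets; "consistency"
#' does not.  The significance test is the F-test `MSR / MSE` with
#' `(n-1, (n-1)(k-1))` degrees of freedom.  The consistency/average form
#' equals Cronbach alpha.  A table with (numerically) zero between-subject
#' variance is degenerate: the ICC is reported as 0 with a flag.
#'
#' @param table A `rater_table` (or coercible matrix).
#' @param type `"absolute_agreement"` or `"consistency"`.
#' @param unit `"single"` or `"average"`.
#' @return A list of class `icc_report` with `icc`, `model`, `type`,
#'   `unit`, `label` (Cicchetti bin), `cronbach_alpha`, `alpha_label`,
#'   `p_value`, `significant`, `degenerate`, `n`, `k`, and the mean
#'   squares.
#' @export
icc_two_way <- function(table, type = c("absolute_agreement", "consistency"),
                        unit = c("average", "single")) {
  type <- match.arg(type)
  unit <- match.arg(unit)
  m <- rater_table(table)
  n <- nrow(m)
  k <- ncol(m)
  g <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  SSR <- k * sum((row_means - g)^2)
  SSC <- n * sum((col_means - g)^2)
  SST <- sum((m - g)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  degenerate <- MSR <= .Machine$double.eps * max(1, abs(g))^2
  if (degenerate) {
    icc <- 0
    p <- 1
  } else {
    icc <- switch(paste(type, unit, sep = "."),
      consistency.single = (MSR - MSE) / (MSR + (k - 1) * MSE),
      consistency.average = (MSR - MSE) / MSR,
      absolute_agreement.single =
        (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
      absolute_agreement.average = (MSR - MSE) / (MSR + (MSC - MSE) / n)
    )
    Fv <- MSR / MSE
    p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }

  alpha <- if (degenerate) NA_real_ else (MSR - MSE) / MSR
  structure(list(
    icc = icc,
    model = "two-way mixed",
    type = type,
    unit = unit,
    label = classify_icc(icc),
    cronbach_alpha = alpha,
    alpha_label = if (is.na(alpha)) NA_character_ else classify_alpha(alpha),
    p_value = p,
    significant = p < 0.05,
    degenerate = degenerate,
    n = n, k = k,
    ms = c(MSR = MSR, MSC = MSC, MSE = MSE)
  ), class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("ICC (%s, %s, %s measures): %.3f [%s]\n",
              x$model, sub("_", " ", x$type), x$unit, x$icc, x$label))
  cat(sprintf("  F-test p = %.4g%s; n = %d subjects, k = %d measurements\n",
              x$p_value, if (x$significant) " *" else "", x$n, x$k))
  if (x$degenerate) cat("  (degenerate: zero between-subject variance)\n")
  invisible(x)
}

#' Cronbach alpha
#'
#' Internal consistency of k measurements:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`.
#' Algebraically identical to the consistency, average-measures two-way
#' ICC.
#'
#' @param table A `rater_table` (or coercible matrix).
#' @return Alpha, `<= 1`.
#' @export
cronbach_alpha <- function(table) {
  m <- rater_table(table)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps * max(1, mean(abs(m)))^2) {
    stop("zero total variance: alpha is undefined", call. = FALSE)
  }
  item_var <- apply(m, 2L, stats::var)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Classify an ICC value (Cicchetti bins)
#'
#' `< 0.4` unacceptable, `[0.4, 0.6)` fair, `[0.6, 0.75)` good,
#' `>= 0.75` excellent.
#'
#' @param icc Finite ICC value.
#' @return Label string.
#' @export
classify_icc <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.6) "good"
  else if (icc >= 0.4) "fair"
  else "unacceptable"
}

#' Classify a Cronbach alpha value
#'
#' `< 0.7` unacceptable, `[0.7, 0.8)` fair, `[0.8, 0.9)` good,
#' `>= 0.9` excellent.
#'
#' @param alpha Finite alpha value.
#' @return Label string.
#' @export
classify_alpha <- function(alpha) {
  stopifnot(is.finite(alpha))
  if (alpha >= 0.9) "excellent"
  else if (alpha >= 0.8) "good"
  else if (alpha >= 0.7) "fair"
  else "unacceptable"
}

#' Normality-gated paired-change test
#'
#' Compares paired pre/post values.  The Shapiro-Wilk test on the paired
#' differences (alpha = .05) gates the choice of test: approximately
#' normal differences use a paired t test, otherwise the Wilcoxon
#' matched-pairs signed-rank test is used.  The base tests are delegated
#' to [stats::t.test()] and [stats::wilcox.test()]; only the gate and the
#' report are implemented here.
#'
#' @param pre,post Paired numeric vectors, length `>= 3`.
#' @param alpha Gate significance level for the Shapiro-Wilk test.
#' @return A list of class `paired_change` with `test_used`, `statistic`,
#'   `p_value`, `shapiro_p`, `n`, `mean_change`.
#' @export
paired_change_test <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post) || length(pre) < 3L) {
    stop("pre and post must be paired with length >= 3", call. = FALSE)
  }
  d <- post - pre
  if (all(d == 0)) {
    stop("degenerate differences: all paired differences are zero",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    ht <- stats::t.test(post, pre, paired = TRUE)
    used <- "paired t test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
    used <- "Wilcoxon matched-pairs signed-rank test"
  }
  structure(list(
    test_used = used,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    shapiro_p = sw$p.value,
    n = length(d),
    mean_change = mean(d)
  ), class = "paired_change")
}

#' @export
print.paired_change <- function(x, ...) {
  cat(sprintf("%s (gate: Shapiro-Wilk p = %.3g)\n", x$test_used,
              x$shapiro_p))
  cat(sprintf("  statistic %.3f, p = %.4g, mean change %.2f, n = %d\n",
              x$statistic, x$p_value, x$mean_change, x$n))
  invisible(x)
}
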
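# Statistical battery for agreement and accuracy analyses of paired
# biometry measurements: normality screening, paired/one-sample t-tests,
# Friedman test with Bonferroni post-hoc, Bland-Altman agreement, and
# paired-design sample-size calculation on the noncentral t distribution.

.test_result <- function(statistic, p_value, df = NA_real_, method = "") {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), method = method),
            class = "protocol_test")
}

#' @export
print.protocol_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, ifelse(is.na(x$df), "-", format(x$df)), x$p_value))
  invisible(x)
}

#' Paired two-sided t-test
#'
#' @param x,y Equal-length paired samples, n >= 2.
#' @return A `protocol_test` with statistic, df = n - 1 and p-value.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (all(d == d[1])) {
    if (d[1] == 0) return(.test_result(0, 1, length(x) - 1, "paired t-test"))
    stop("paired differences are constant and non-zero; t undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  .test_result(tt$statistic, tt$p.value, tt$parameter, "paired t-test")
}

#' One-sample two-sided t-test
#'
#' @param x Sample, n >= 2 with non-zero variance (unless exactly at `mu`).
#' @param mu Null-hypothesis mean.
#' @return A `protocol_test`.
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0) {
    if (x[1] == mu) return(.test_result(0, 1, length(x) - 1,
                                        "one-sample t-test"))
    stop("zero variance; t statistic undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, mu = mu)
  .test_result(tt$statistic, tt$p.value, tt$parameter, "one-sample t-test")
}

#' Friedman test with Bonferroni-corrected pairwise comparisons
#'
#' Overall Friedman chi-square (average-rank tie handling) over an
#' n-subjects by k-conditions matrix of (absolute) errors, followed by
#' pairwise comparisons on the rank-sum difference statistic
#' z = |Ri - Rj| / sqrt(n k (k+1) / 6), each raw p multiplied by the
#' number of pairs and capped at 1.
#'
#' @param m Numeric matrix, rows = subjects, columns = conditions; no
#'   missing cells.
#' @return List with `overall` (a `protocol_test`) and `pairwise`
#'   (data.frame: condition pair, z, raw and Bonferroni-adjusted p).
#' @export
friedman_bonferroni <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions",
                           call. = FALSE)
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  if (max(rj) == min(rj)) {
    overall <- .test_result(0, 1, k - 1, "Friedman rank sum test")
  } else {
    ft <- stats::friedman.test(m)
    overall <- .test_result(ft$statistic, ft$p.value, ft$parameter,
                            "Friedman rank sum test")
  }
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  se <- sqrt(n * k * (k + 1) / 6)
  cn <- colnames(m); if (is.null(cn)) cn <- as.character(seq_len(k))
  pw <- data.frame(
    cond_a = cn[pairs[1, ]], cond_b = cn[pairs[2, ]],
    z = abs(rj[pairs[1, ]] - rj[pairs[2, ]]) / se,
    stringsAsFactors = FALSE)
  pw$p_raw <- 2 * stats::pnorm(-pw$z)
  pw$p_adj <- pmin(1, pw$p_raw * npairs)
  rownames(pw) <- NULL
  list(overall = overall, pairwise = pw)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of `x` against a normal with the sample mean and
#' SD, using the exact small-sample null distribution of D. Because the
#' reference parameters are estimated from the same sample, this nominal
#' test is conservative (the Lilliefors effect inflates p);
#' `lilliefors = TRUE` applies the Lilliefors-corrected null instead.
#'
#' @param x Sample, n >= 5.
#' @param lilliefors Use the Lilliefors correction for estimated
#'   parameters (requires the nortest package)?
#' @return A `protocol_test` with the D statistic and p-value.
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
  if (length(x) < 5) stop("need at least 5 observations", call. = FALSE)
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("the Lilliefors variant requires the nortest package",
           call. = FALSE)
    }
    lt <- nortest::lillie.test(x)
    return(.test_result(lt$statistic, lt$p.value, NA_real_,
                        "Lilliefors (KS) normality test"))
  }
  kt <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x), exact = TRUE))
  .test_result(kt$statistic, kt$p.value, NA_real_,
               "exact one-sample KS normality test")
}

#' Bland-Altman agreement analysis
#'
#' Differences x - y against means (x + y)/2; bias is the mean
#' difference, limits of agreement are bias +/- 1.96 SD of the
#' differences (normal quantile, standard Bland-Altman practice).
#'
#' @param x,y Equal-length paired measurements, n >= 2.
#' @return An object of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `means`/`diffs`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(x), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias = %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Sample size for a paired two-sided t-test
#'
#' Smallest number of pairs n such that the two-sided paired t-test at
#' level `alpha` attains the requested power against a mean difference
#' `delta` with within-subject SD `sigma`, using the noncentral t
#' distribution with noncentrality delta * sqrt(n) / sigma. The search
#' starts from the normal-approximation lower bound
#' ceil(((z_{1-alpha/2} + z_{power}) sigma / delta)^2) and increments n,
#' guaranteeing the minimal integer solution.
#'
#' @param delta Detectable mean difference (D), > 0.
#' @param sigma Within-subject SD of the differences (D), > 0.
#' @param alpha Two-sided significance level, default 0.05.
#' @param power Requested power, default 0.80.
#' @return Integer sample size (pairs).
#' @export
paired_t_sample_size <- function(delta, sigma, alpha = 0.05, power = 0.80) {
  if (delta <= 0 || sigma <= 0) stop("delta and sigma must be positive",
                                     call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  zbound <- ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
                       sigma / delta)^2)
  n <- max(2L, as.integer(zbound) - 5L)
  power_at <- function(n) {
    df <- n - 1
    ncp <- delta * sqrt(n) / sigma
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  limit <- 10000000L
  while (power_at(n) < power) {
    n <- n + 1L
    if (n > limit) stop("requested power unreachable below n = ", limit,
                        call. = FALSE)
  }
  n
}
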
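#' Kuder-Richardson formula 20 (KR-20)
#'
#' Internal-consistency reliability for dichotomous items, the binary
#' special case of Cronbach's alpha:
#' \deqn{KR_{20} = \frac{k}{k-1}\left(1 - \frac{\sum_i p_i(1-p_i)}{s^2_{total}}\right)}
#' with \eqn{k} items, \eqn{p_i} the endorsement proportion of item *i* and
#' \eqn{s^2_{total}} the variance of total scores. Item variances use the
#' same denominator convention as the total-score variance.
#'
#' @param responses binary subjects x items matrix, >= 2 items, >= 2 subjects.
#' @param variance `"sample"` (n-1 denominator, default) or `"population"`
#'   (n). The two differ in the third decimal at typical sample sizes; the
#'   choice is exposed because published reports rarely state it.
#' @return KR-20 coefficient (always <= 1; can be negative).
#' @export
kr20 <- function(responses, variance = c("sample", "population")) {
  variance <- match.arg(variance)
  responses <- as_item_matrix(responses)
  n <- nrow(responses); k <- ncol(responses)
  if (k < 2L) stop_validation("KR-20 needs at least 2 items, got %d", k)
  if (n < 2L) stop_validation("KR-20 needs at least 2 subjects, got %d", n)
  totals <- rowSums(responses)
  denom <- if (variance == "sample") n - 1 else n
  s2_total <- sum((totals - mean(totals))^2) / denom
  if (s2_total <= 0)
    stop_computation("total-score variance is zero: reliability is undefined")
  p <- colMeans(responses)
  item_var <- p * (1 - p) * n / denom
  (k / (k - 1)) * (1 - sum(item_var) / s2_total)
}

#' KR-20 per factor
#'
#' @param responses binary subjects x items matrix.
#' @param fmap a [factor_map()] covering the items.
#' @param ... passed to [kr20()].
#' @return named numeric vector, one KR-20 per factor (NA for factors
#'   where the coefficient is undefined, e.g. a single-item factor).
#' @export
kr20_by_factor <- function(responses, fmap, ...) {
  responses <- as_item_matrix(responses)
  if (!inherits(fmap, "factor_map")) stop_validation("`fmap` must be a `factor_map`")
  vapply(attr(fmap, "factor_names"), function(f) {
    its <- names(fmap)[unclass(fmap) == f]
    tryCatch(kr20(responses[, its, drop = FALSE], ...),
             screenval_error = function(e) NA_real_)
  }, numeric(1))
}

#' Test-retest intraclass correlation coefficient
#'
#' ICC between paired total scores at two occasions, from the two-occasion
#' ANOVA decomposition. Three single-measure variants are available:
#' \describe{
#'   \item{`twoway_agreement`}{ICC(A,1): two-way random effects, absolute
#'     agreement — the default; occasion-level shifts count against agreement.}
#'   \item{`twoway_consistency`}{ICC(C,1): two-way mixed, consistency —
#'     invariant to adding a constant to one occasion.}
#'   \item{`oneway`}{ICC(1): one-way random effects.}
#' }
#' The F statistic is the between-subjects mean square over the error
#' (residual) mean square of the two-way layout (between/within for the
#' one-way model), testing no subject-level variance.
#'
#' @param test_totals,retest_totals equal-length paired score vectors, n >= 3.
#' @param model ICC variant, see Details.
#' @return list: `icc`, `f`, `df1`, `df2`, `p`, `model`, `n`,
#'   `interpretation` (poor < 0.40 < moderate < 0.60 < good < 0.80 <
#'   excellent <= 1.00).
#' @export
icc_test_retest <- function(test_totals, retest_totals,
                            model = c("twoway_agreement", "twoway_consistency",
                                      "oneway")) {
  model <- match.arg(model)
  n <- check_paired_vectors(test_totals, retest_totals,
                            "test_totals", "retest_totals", min_n = 3L)
  x <- cbind(test_totals, retest_totals)
  k <- 2L
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)                       # between subjects
  msc <- ss_cols / (k - 1)                       # between occasions
  mse <- ss_err / ((n - 1) * (k - 1))            # residual
  msw <- (ss_cols + ss_err) / (n * (k - 1))      # within subjects (one-way)
  if (msr <= 0 && mse <= 0)
    stop_computation("scores are constant: ICC is undefined")
  icc <- switch(model,
    twoway_agreement = (msr - mse) /
      (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    twoway_consistency = (msr - mse) / (msr + (k - 1) * mse),
    oneway = (msr - msw) / (msr + (k - 1) * msw))
  if (model == "oneway") {
    f <- msr / msw; df1 <- n - 1; df2 <- n * (k - 1)
  } else {
    f <- msr / mse; df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  }
  list(icc = icc, f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       model = model, n = n, interpretation = interpretation_band(icc))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties — appropriate
#' for heavily tied integer scores). The p-value tests rho = 0: exact by
#' enumeration where feasible for small untied samples, otherwise the
#' t-approximation (as in [stats::cor.test()]).
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list: `rho`, `p`, `n`, `interpretation`.
#' @export
spearman_rho <- function(x, y) {
  n <- check_paired_vectors(x, y, "x", "y", min_n = 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_computation("constant vector: rank correlation is undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 10)$p.value)
  list(rho = rho, p = p, n = n, interpretation = interpretation_band(rho))
}

#' Sample size for detecting a correlation (Fisher z)
#'
#' Minimum group size for a two-sided test that a correlation equals zero,
#' via the Fisher z-transformation:
#' \deqn{n = \lceil \left(\frac{z_{1-\alpha/2} + z_{power}}{\mathrm{atanh}(\rho)}\right)^2 + 3 \rceil}
#' The ceiling is taken because a fractional subject cannot deliver the
#' stated power.
#'
#' @param rho expected correlation, in (0, 1).
#' @param alpha type I error probability.
#' @param power desired power (1 - type II error probability).
#' @return integer minimum subjects per group.
#' @examples
#' correlation_sample_size(0.60, 0.05, 0.90)  # 25
#' @export
correlation_sample_size <- function(rho, alpha = 0.05, power = 0.90) {
  check_scalar_number(rho, "rho", lower = 0, upper = 1,
                      open_lower = TRUE, open_upper = TRUE)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      open_lower = TRUE, open_upper = TRUE)
  check_scalar_number(power, "power", lower = 0, upper = 1,
                      open_lower = TRUE, open_upper = TRUE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling((z / atanh(rho))^2 + 3))
}
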
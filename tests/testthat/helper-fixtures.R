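# Shared fixture builders. Everything is generated in code, under explicit
# seeds, so the suite carries no data files.

random_binary_matrix <- function(n, k, p = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p)) p <- runif(k, 0.2, 0.8)
  m <- matrix(rbinom(n * k, 1L, rep(p, each = n)), nrow = n)
  dimnames(m) <- list(sprintf("S%04d", seq_len(n)), sprintf("it_%02d", seq_len(k)))
  m
}

# a score/diagnosis fixture with both classes present
random_score_fixture <- function(n, max_score = 26L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    theta <- rnorm(n)
    totals <- rbinom(n, max_score, plogis(theta))
    dx <- rbinom(n, 1L, plogis(1.5 * theta))
    if (sum(dx) > 0 && sum(dx) < n) return(list(totals = totals, diagnosis = dx))
  }
}

# Cronbach's alpha in its covariance form: independent oracle for KR-20
alpha_covariance_oracle <- function(m) {
  k <- ncol(m)
  v <- stats::cov(m)
  (k / (k - 1)) * (1 - sum(diag(v)) / sum(v))
}

# AUC by brute-force pair counting with half credit for ties
auc_pair_oracle <- function(totals, diagnosis) {
  pos <- totals[diagnosis == 1]; neg <- totals[diagnosis == 0]
  gt <- outer(pos, neg, ">"); eq <- outer(pos, neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# same statistic via the mid-rank Mann-Whitney identity; O(n log n), for
# oracle checks at Monte-Carlo sample sizes where pair enumeration is infeasible
auc_rank_oracle <- function(totals, diagnosis) {
  n1 <- as.numeric(sum(diagnosis == 1)); n0 <- as.numeric(sum(diagnosis == 0))
  w <- sum(rank(totals)[diagnosis == 1])
  (w - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# test item parameters with strong, flat signal for fast convergence
strong_params <- function(a = 2, K = 9L, thr = 5L) {
  irt_params(rep(a, 26), rep(0, 26), K, 2, 0, thr)
}
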
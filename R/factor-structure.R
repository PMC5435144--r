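#' Phi correlation matrix of binary items
#'
#' Pairwise Pearson correlations of the binary item columns (the phi
#' coefficient). Every item must show both responses; a constant item has
#' no defined correlation and is reported by name.
#'
#' @param responses binary subjects x items matrix.
#' @return symmetric correlation matrix with unit diagonal and a
#'   `kind = "phi"` attribute.
#' @export
phi_matrix <- function(responses) {
  responses <- as_item_matrix(responses)
  p <- colMeans(responses)
  const <- p %in% c(0, 1)
  if (any(const))
    stop_computation("constant item(s): %s",
                     paste(colnames(responses)[const], collapse = ", "))
  r <- stats::cor(responses)
  diag(r) <- 1
  attr(r, "kind") <- "phi"
  r
}

# P(X <= h, Y <= k) under the standard bivariate normal with correlation
# rho, by 1-D reduction: int_{-inf}^{h} phi(x) Phi((k - rho x)/s) dx.
pbvnorm <- function(h, k, rho) {
  if (abs(rho) >= 1) {
    return(if (rho > 0) stats::pnorm(min(h, k))
           else max(0, stats::pnorm(h) - stats::pnorm(-k)))
  }
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s),
                   -Inf, h, rel.tol = 1e-10)$value
}

# ML tetrachoric correlation from one 2x2 table, margins fixed at the
# observed thresholds; log-likelihood maximised over rho in (-0.999, 0.999).
tetrachoric_from_table <- function(n11, n10, n01, n00, smooth = TRUE) {
  cells <- c(n11, n10, n01, n00)
  if (any(cells == 0)) {
    if (!smooth)
      stop_computation("2x2 table has an empty cell; enable smoothing (0.5 continuity correction)")
    cells <- cells + 0.5
  }
  n <- sum(cells)
  p1 <- (cells[1] + cells[2]) / n  # P(row item = 1)
  p2 <- (cells[1] + cells[3]) / n  # P(col item = 1)
  h <- stats::qnorm(1 - p1)        # threshold: X > h  <=>  item 1 endorsed
  k <- stats::qnorm(1 - p2)
  negll <- function(rho) {
    p11 <- pbvnorm(-h, -k, rho)    # P(X > h, Y > k) by symmetry
    p10 <- (1 - stats::pnorm(h)) - p11
    p01 <- (1 - stats::pnorm(k)) - p11
    p00 <- 1 - p11 - p10 - p01
    pr <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(cells * log(pr))
  }
  stats::optimize(negll, c(-0.999, 0.999), tol = 1e-8)$minimum
}

#' Tetrachoric correlation matrix of binary items
#'
#' Latent bivariate-normal correlation estimated by maximum likelihood from
#' each pair's 2x2 table, with thresholds fixed at the observed margins.
#' When a table has an empty cell a 0.5 continuity correction is applied to
#' all four cells of that table (or an error is raised with
#' `smooth = FALSE`).
#'
#' @param responses binary subjects x items matrix.
#' @param smooth apply the 0.5 correction to tables with an empty cell.
#' @return symmetric matrix with unit diagonal, `kind = "tetrachoric"`.
#' @export
tetrachoric_matrix <- function(responses, smooth = TRUE) {
  responses <- as_item_matrix(responses)
  p <- colMeans(responses)
  const <- p %in% c(0, 1)
  if (any(const))
    stop_computation("constant item(s): %s",
                     paste(colnames(responses)[const], collapse = ", "))
  k <- ncol(responses)
  r <- diag(1, k)
  dimnames(r) <- list(colnames(responses), colnames(responses))
  for (i in seq_len(k - 1L)) {
    xi <- responses[, i]
    for (j in (i + 1L):k) {
      xj <- responses[, j]
      n11 <- sum(xi == 1 & xj == 1); n10 <- sum(xi == 1 & xj == 0)
      n01 <- sum(xi == 0 & xj == 1); n00 <- sum(xi == 0 & xj == 0)
      r[i, j] <- r[j, i] <- tetrachoric_from_table(n11, n10, n01, n00, smooth)
    }
  }
  attr(r, "kind") <- "tetrachoric"
  r
}

#' Clip a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue clipping at a small floor, then rescaling to a unit diagonal.
#' Tetrachoric matrices assembled pairwise need not be positive definite;
#' KMO and factor extraction require an invertible matrix.
#'
#' @param r symmetric matrix.
#' @param floor smallest permitted eigenvalue.
#' @return PSD correlation matrix; a warning is issued when clipping
#'   actually changed the matrix.
#' @export
nearest_psd <- function(r, floor = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= floor) return(r)
  warning("matrix is not positive definite; eigenvalues clipped", call. = FALSE)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(r)
  attr(out, "kind") <- attr(r, "kind")
  out
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' \deqn{KMO = \frac{\sum_{i \ne j} r_{ij}^2}{\sum_{i \ne j} r_{ij}^2 + \sum_{i \ne j} q_{ij}^2}}
#' where \eqn{q_{ij}} are the anti-image partial correlations obtained from
#' the inverse of the correlation matrix. Values near 1 indicate that
#' partial correlations are small relative to raw correlations, i.e. the
#' matrix is factorable; values around 0.5 (the no-structure boundary) or
#' below flag an unfactorable matrix. The `factorable` flag uses the
#' conventional 0.6 minimum-adequacy bar.
#'
#' @param r correlation matrix (invertible, >= 2 items).
#' @return list: `kmo` (overall), `msa` (per-item measures), `factorable`
#'   (logical, overall >= 0.6).
#' @export
kmo <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r) || nrow(r) < 2L)
    stop_validation("`r` must be a square correlation matrix with >= 2 items")
  inv <- tryCatch(solve(r), error = function(e)
    stop_computation("correlation matrix is singular; consider nearest_psd() smoothing"))
  d <- 1 / sqrt(diag(inv))
  q <- -inv * tcrossprod(d)      # anti-image partial correlations
  diag(q) <- 0
  r0 <- r; diag(r0) <- 0
  sum_r2 <- sum(r0^2); sum_q2 <- sum(q^2)
  overall <- sum_r2 / (sum_r2 + sum_q2)
  msa <- colSums(r0^2) / (colSums(r0^2) + colSums(q^2))
  names(msa) <- colnames(r)
  list(kmo = overall, msa = msa, factorable = overall >= 0.6)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity (no common
#' structure): \deqn{\chi^2 = -(n - 1 - (2k+5)/6)\,\ln\det R,\quad
#' df = k(k-1)/2.}
#'
#' @param r correlation matrix (positive definite).
#' @param n number of subjects behind `r` (must exceed the item count).
#' @return list: `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(r, n) {
  if (!is.matrix(r) || nrow(r) != ncol(r))
    stop_validation("`r` must be a square correlation matrix")
  k <- nrow(r)
  check_scalar_number(n, "n", lower = k + 1)
  det_r <- det(r)
  if (det_r <= 0)
    stop_computation("correlation matrix is not positive definite")
  chi2 <- -(n - 1 - (2 * k + 5) / 6) * log(det_r)
  df <- k * (k - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' One-factor loadings by iterated principal axis
#'
#' Exploratory single-factor solution: communalities are initialised from
#' squared multiple correlations, then the reduced matrix (communalities on
#' the diagonal) is decomposed and the leading eigenvector re-estimates the
#' loadings until the largest communality change falls below `tol`. The
#' loading sign is fixed so the loading sum is non-negative.
#'
#' @param r correlation matrix.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on communalities.
#' @return named loading vector. On non-convergence an error of class
#'   `screenval_computation_error` carries the last iterate in its
#'   `payload`.
#' @export
one_factor_loadings <- function(r, max_iter = 200L, tol = 1e-8) {
  if (!is.matrix(r) || nrow(r) != ncol(r) || nrow(r) < 2L)
    stop_validation("`r` must be a square correlation matrix with >= 2 items")
  inv <- tryCatch(solve(r), error = function(e)
    stop_computation("correlation matrix is singular; consider nearest_psd() smoothing"))
  h2 <- 1 - 1 / diag(inv)        # squared multiple correlations
  lambda <- rep(0, nrow(r))
  for (it in seq_len(max_iter)) {
    rh <- r; diag(rh) <- h2
    e <- eigen(rh, symmetric = TRUE)
    lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
    h2_new <- pmin(lambda^2, 1)
    if (max(abs(h2_new - h2)) < tol) {
      if (sum(lambda) < 0) lambda <- -lambda
      names(lambda) <- colnames(r)
      return(lambda)
    }
    h2 <- h2_new
  }
  stop_computation("one-factor extraction did not converge in %d iterations",
                   max_iter, payload = lambda)
}
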
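test_that("phi matrix: identity diagonal, complement items, closed-form value", {
  set.seed(61)
  m <- random_binary_matrix(80, 4)
  m[, 2] <- 1L - m[, 1]                   # item 2 is the complement of item 1
  r <- phi_matrix(m)
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(r, t(r), ignore_attr = TRUE)
  expect_equal(r[1, 2], -1)
  # 2x2 counts (a,b,c,d) = (40,10,10,40): phi = (ad-bc)/sqrt(products) = 0.6
  x <- c(rep(1L, 50), rep(0L, 50))
  y <- c(rep(1L, 40), rep(0L, 10), rep(1L, 10), rep(0L, 40))
  r2 <- phi_matrix(cbind(i1 = x, i2 = y))
  expect_equal(r2[1, 2], (40 * 40 - 10 * 10) / sqrt(50 * 50 * 50 * 50),
               tolerance = 1e-12)
  expect_equal(r2[1, 2], 0.6, tolerance = 1e-12)
})

test_that("constant items are reported by name", {
  m <- random_binary_matrix(30, 3, seed = 62)
  m[, 2] <- 1L
  colnames(m) <- c("a", "konst", "c")
  expect_error(phi_matrix(m), "konst", class = "screenval_computation_error")
  expect_error(tetrachoric_matrix(m), "konst", class = "screenval_computation_error")
})

test_that("tetrachoric estimate matches a likelihood grid-search oracle", {
  tet <- screenval:::tetrachoric_from_table
  pbv <- screenval:::pbvnorm
  loglik <- function(rho, cells, h, k) {
    p11 <- pbv(-h, -k, rho)
    p10 <- (1 - pnorm(h)) - p11
    p01 <- (1 - pnorm(k)) - p11
    p00 <- 1 - p11 - p10 - p01
    sum(cells * log(pmax(c(p11, p10, p01, p00), 1e-12)))
  }
  cells <- c(40, 10, 10, 40)
  h <- qnorm(1 - 0.5); k <- qnorm(1 - 0.5)
  grid <- seq(-0.998, 0.998, by = 1e-4)
  ll <- vapply(grid, loglik, numeric(1), cells = cells, h = h, k = k)
  expect_equal(tet(40, 10, 10, 40), grid[which.max(ll)], tolerance = 1e-4)
  # independence: odds ratio 1 -> rho 0
  expect_equal(tet(25, 25, 25, 25), 0, tolerance = 1e-6)
  # perfect concordance with smoothing -> approaches 1
  expect_gt(tet(50, 0, 0, 50, smooth = TRUE), 0.95)
  expect_error(tet(50, 0, 0, 50, smooth = FALSE), class = "screenval_computation_error")
})

test_that("tetrachoric magnitude dominates phi on random interior tables", {
  set.seed(63)
  wins <- 0L; total <- 0L
  for (i in 1:500) {
    cells <- rmultinom(1, 200, prob = runif(4, 0.05, 1))[, 1]
    if (any(cells + c(cells[2], cells[1], cells[4], cells[3]) == 0)) next
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    if ((a + b) * (c_ + d) * (a + c_) * (b + d) == 0) next
    phi <- (a * d - b * c_) / sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
    tet <- screenval:::tetrachoric_from_table(a, b, c_, d)
    total <- total + 1L
    if (abs(tet) >= abs(phi) - 1e-6) wins <- wins + 1L
  }
  expect_gt(wins / total, 0.98)   # attenuation property, statistical check
})

test_that("KMO matches a dense-inverse oracle on an equicorrelation matrix", {
  k <- 26; lam2 <- 0.49
  r <- matrix(lam2, k, k); diag(r) <- 1
  got <- kmo(r)
  inv <- solve(r)
  d <- 1 / sqrt(diag(inv))
  q <- -inv * tcrossprod(d); diag(q) <- 0
  r0 <- r; diag(r0) <- 0
  expect_equal(got$kmo, sum(r0^2) / (sum(r0^2) + sum(q^2)), tolerance = 1e-12)
  expect_true(got$factorable)
  # item reordering leaves KMO unchanged
  set.seed(64)
  m <- generate_cohort(default_irt_params(), 300, seed = 65)$responses
  rp <- phi_matrix(m)
  perm <- sample(26)
  expect_equal(kmo(rp[perm, perm])$kmo, kmo(rp)$kmo, tolerance = 1e-12)
})

test_that("near-identity correlation matrices are flagged unfactorable near 0.5", {
  k <- 8
  r <- matrix(1e-6, k, k); diag(r) <- 1
  got <- kmo(r)
  expect_equal(got$kmo, 0.5, tolerance = 1e-3)
  expect_false(got$factorable)
  expect_error(kmo(matrix(1, 1, 1)), class = "screenval_validation_error")
})

test_that("Bartlett chi-square follows the determinant closed form", {
  # 3-item equicorrelation 0.5, n = 100: det = (1-.5)^2 (1+2*.5) = 0.5
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  got <- bartlett_sphericity(r, 100)
  expect_equal(got$chi2, -(99 - 11 / 6) * log(0.5), tolerance = 1e-8)
  expect_equal(got$df, 3)
  # identity: chi2 = 0, p = 1
  id <- bartlett_sphericity(diag(5), 50)
  expect_equal(id$chi2, 0); expect_equal(id$p, 1)
  # df for the 26-item instrument
  expect_equal(bartlett_sphericity(diag(26), 415)$df, 325)
  # invariant to item reordering
  set.seed(66)
  m <- random_binary_matrix(120, 6)
  r6 <- phi_matrix(m); perm <- sample(6)
  expect_equal(bartlett_sphericity(r6[perm, perm], 120)$chi2,
               bartlett_sphericity(r6, 120)$chi2, tolerance = 1e-10)
  expect_error(bartlett_sphericity(r, 2), class = "screenval_validation_error")
})

test_that("one-factor extraction recovers constructed loadings", {
  lam <- rep(0.7, 10)
  r <- tcrossprod(lam) + diag(1 - lam^2)
  expect_equal(unname(one_factor_loadings(r)), lam, tolerance = 1e-6)
  # identity matrix: no common factor
  expect_lt(max(abs(one_factor_loadings(diag(6) + 1e-9))), 1e-3)
  # random loadings in [0.4, 0.8], noiseless matrix, recovery to 1e-3
  set.seed(67)
  for (i in 1:5) {
    l2 <- runif(6, 0.4, 0.8)
    r2 <- tcrossprod(l2) + diag(1 - l2^2)
    expect_equal(unname(one_factor_loadings(r2)), l2, tolerance = 1e-3)
  }
})

test_that("one-factor solution is a fixed point of its own implied matrix", {
  m <- generate_cohort(default_irt_params(), 400, seed = 68)$responses
  l1 <- one_factor_loadings(phi_matrix(m))
  r_implied <- tcrossprod(l1) + diag(1 - pmin(l1^2, 1))
  l2 <- one_factor_loadings(r_implied)
  expect_equal(unname(l2), unname(l1), tolerance = 1e-4)
})

test_that("PSD clipping repairs an indefinite matrix and warns", {
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.9; r[1, 3] <- r[3, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- -0.9          # violates PSD
  expect_warning(rp <- nearest_psd(r), "clipped")
  expect_gte(min(eigen(rp, symmetric = TRUE)$values), 0)
  expect_equal(diag(rp), rep(1, 3))
  expect_silent(nearest_psd(diag(3)))
})
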
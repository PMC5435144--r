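#' Two-parameter logistic generator parameters
#'
#' Bundle of parameters for the synthetic-cohort generator. Each of the 26
#' scale items follows a two-parameter logistic (2PL) item-response model:
#' given a subject's latent severity \eqn{\theta \sim N(0,1)}, item *i* is
#' endorsed with probability \eqn{\mathrm{logistic}(a_i(\theta - b_i))}.
#' The gold-standard criterion is a count of `criterion_items` endorsed
#' criteria, drawn Binomial with per-criterion probability
#' \eqn{\mathrm{logistic}(a_c(\theta - b_c))}; the diagnosis flag is 1 when
#' the count reaches `diagnosis_threshold`.
#'
#' @param discrimination numeric vector of 26 positive slopes \eqn{a_i}.
#' @param difficulty numeric vector of 26 locations \eqn{b_i} on the latent
#'   trait scale.
#' @param criterion_items number of gold-standard criterion items `K`.
#' @param criterion_discrimination positive slope \eqn{a_c} of the criterion.
#' @param criterion_difficulty location \eqn{b_c} of the criterion.
#' @param diagnosis_threshold integer in `[0, K]`; criterion counts at or
#'   above it are diagnosed.
#' @return An object of class `irt_params`.
#' @seealso [default_irt_params()] for the shipped configuration,
#'   [generate_cohort()] to draw a cohort.
#' @export
irt_params <- function(discrimination, difficulty,
                       criterion_items, criterion_discrimination,
                       criterion_difficulty, diagnosis_threshold) {
  if (!is.numeric(discrimination) || length(discrimination) != 26L)
    stop_validation("`discrimination` must be a numeric vector of length 26, got length %d",
                    length(discrimination))
  if (!is.numeric(difficulty) || length(difficulty) != 26L)
    stop_validation("`difficulty` must be a numeric vector of length 26, got length %d",
                    length(difficulty))
  if (anyNA(discrimination) || any(discrimination <= 0))
    stop_validation("`discrimination` must be strictly positive for every item")
  if (anyNA(difficulty) || any(!is.finite(difficulty)))
    stop_validation("`difficulty` must be finite for every item")
  check_scalar_number(criterion_items, "criterion_items", lower = 1)
  if (criterion_items != round(criterion_items))
    stop_validation("`criterion_items` must be a whole number")
  check_scalar_number(criterion_discrimination, "criterion_discrimination",
                      lower = 0, open_lower = TRUE)
  check_scalar_number(criterion_difficulty, "criterion_difficulty")
  check_scalar_number(diagnosis_threshold, "diagnosis_threshold",
                      lower = 0, upper = criterion_items)
  if (diagnosis_threshold != round(diagnosis_threshold))
    stop_validation("`diagnosis_threshold` must be a whole number")
  structure(list(discrimination = as.numeric(discrimination),
                 difficulty = as.numeric(difficulty),
                 criterion_items = as.integer(criterion_items),
                 criterion_discrimination = as.numeric(criterion_discrimination),
                 criterion_difficulty = as.numeric(criterion_difficulty),
                 diagnosis_threshold = as.integer(diagnosis_threshold)),
            class = "irt_params")
}

#' Default generator configuration
#'
#' Ships a fixed, documented parameter set: discriminations spread evenly
#' over `[0.8, 2.0]`, difficulties over `[-1.5, 1.5]`, a 9-item criterion
#' with diagnosis at 5+ endorsed criteria, and the criterion difficulty
#' solved numerically (via the latent-trait quadrature) so that the
#' population diagnosed prevalence equals `target_prevalence`. The default
#' target, 35.66%, is the prevalence the instrument's validation study
#' design assumes.
#'
#' @param target_prevalence population prevalence of the diagnosis in (0,1).
#' @return An `irt_params` object.
#' @export
default_irt_params <- function(target_prevalence = 0.3566) {
  check_scalar_number(target_prevalence, "target_prevalence",
                      lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  a <- seq(0.8, 2.0, length.out = 26)
  b <- seq(-1.5, 1.5, length.out = 26)
  K <- 9L; thr <- 5L; a_c <- 2.0
  prev_at <- function(b_c) {
    p <- irt_params(a, b, K, a_c, b_c, thr)
    latent_prevalence(p) - target_prevalence
  }
  b_c <- stats::uniroot(prev_at, c(-4, 4), tol = 1e-10)$root
  irt_params(a, b, K, a_c, b_c, thr)
}

logistic <- function(x) 1 / (1 + exp(-x))

# Gauss-type quadrature over the standard-normal latent trait: a fine
# trapezoid grid is accurate to ~1e-12 here and keeps dependencies nil.
theta_grid <- function(n = 2001L, lim = 8) {
  th <- seq(-lim, lim, length.out = n)
  w <- stats::dnorm(th)
  w <- w / sum(w)
  list(theta = th, weight = w)
}

#' Population prevalence of the diagnosis under the generator
#'
#' Computes \eqn{\Pr(\mathrm{criterion\ count} \ge \mathrm{threshold})} by
#' quadrature over the latent trait.
#'
#' @param params an [irt_params()] object.
#' @return prevalence in `[0, 1]`.
#' @export
latent_prevalence <- function(params) {
  if (!inherits(params, "irt_params")) stop_validation("`params` must be an `irt_params` object")
  g <- theta_grid()
  p_c <- logistic(params$criterion_discrimination * (g$theta - params$criterion_difficulty))
  pdx <- stats::pbinom(params$diagnosis_threshold - 1L, params$criterion_items,
                       p_c, lower.tail = FALSE)
  sum(g$weight * pdx)
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects: latent traits \eqn{\theta_j \sim N(0,1)}, 26 binary
#' item responses from the 2PL model, a Binomial criterion count and its
#' diagnosis flag. Fully reproducible: one master `seed` is split into
#' deterministic sub-streams (trait, items, criterion), and each subject
#' occupies a contiguous block of the item/criterion streams, so growing
#' `n` leaves earlier subjects' draws untouched.
#'
#' @param params an [irt_params()] object.
#' @param n number of subjects (>= 1).
#' @param seed integer master seed.
#' @return An object of class `synthetic_cohort`: list with `responses`
#'   (n x 26 binary matrix, rownames are subject IDs), `criterion_scores`,
#'   `diagnosis`, `latent_trait`, `seed`, `params`.
#' @examples
#' coh <- generate_cohort(default_irt_params(), n = 100, seed = 1)
#' mean(coh$diagnosis)
#' @export
generate_cohort <- function(params, n, seed) {
  if (!inherits(params, "irt_params")) stop_validation("`params` must be an `irt_params` object")
  check_scalar_number(n, "n", lower = 1)
  if (n != round(n)) stop_validation("`n` must be a whole number")
  check_scalar_number(seed, "seed")
  n <- as.integer(n)

  theta <- local({ set.seed(derive_seed(seed, 1L)); stats::rnorm(n) })
  responses <- draw_items(theta, params, derive_seed(seed, 2L))

  p_c <- logistic(params$criterion_discrimination *
                    (theta - params$criterion_difficulty))
  u_c <- local({
    set.seed(derive_seed(seed, 3L))
    matrix(stats::runif(params$criterion_items * n), nrow = params$criterion_items)
  })
  criterion_scores <- as.integer(colSums(u_c < rep(p_c, each = params$criterion_items)))
  diagnosis <- as.integer(criterion_scores >= params$diagnosis_threshold)

  structure(list(responses = responses,
                 criterion_scores = criterion_scores,
                 diagnosis = diagnosis,
                 latent_trait = theta,
                 seed = as.integer(seed),
                 params = params),
            class = "synthetic_cohort")
}

# n x 26 binary matrix from a trait vector; uniforms laid out one
# 26-value block per subject (column-major with items as rows).
draw_items <- function(theta, params, stream_seed) {
  n <- length(theta)
  k <- length(params$discrimination)
  p <- logistic(outer(params$discrimination, theta) -
                  params$discrimination * params$difficulty)  # k x n
  u <- local({ set.seed(stream_seed); matrix(stats::runif(k * n), nrow = k) })
  resp <- t((u < p) + 0L)
  dimnames(resp) <- list(sprintf("S%04d", seq_len(n)),
                         sprintf("spai_%02d", seq_len(k)))
  storage.mode(resp) <- "integer"
  resp
}

#' Regenerate item responses at a retest occasion
#'
#' The retest trait is \eqn{\theta' = s\,\theta + \sqrt{1-s^2}\,\epsilon}
#' with \eqn{\epsilon \sim N(0,1)}, so `stability` is the test-retest
#' correlation of the latent trait; items are redrawn from the same 2PL
#' parameters at \eqn{\theta'}. Correlation is induced through the trait,
#' not by copying responses, so item-level disagreement between occasions
#' occurs, as in real retests.
#'
#' @param cohort a [generate_cohort()] result.
#' @param stability latent-trait test-retest correlation in `[0, 1]`.
#' @param seed integer seed for the retest streams.
#' @return binary matrix with the same subject IDs and item labels as
#'   `cohort$responses`.
#' @export
generate_retest <- function(cohort, stability, seed) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop_validation("`cohort` must be a `synthetic_cohort`")
  if (length(cohort$latent_trait) < 1L)
    stop_validation("`cohort` is empty")
  check_scalar_number(stability, "stability", lower = 0, upper = 1)
  check_scalar_number(seed, "seed")
  eps <- local({
    set.seed(derive_seed(seed, 1L))
    stats::rnorm(length(cohort$latent_trait))
  })
  theta2 <- stability * cohort$latent_trait + sqrt(1 - stability^2) * eps
  m <- draw_items(theta2, cohort$params, derive_seed(seed, 2L))
  dimnames(m) <- dimnames(cohort$responses)
  m
}

# P(total score = s | theta) for every quadrature node: Poisson-binomial
# recursion over items, vectorised across nodes.
score_dist_given_theta <- function(theta, params) {
  k <- length(params$discrimination)
  P <- matrix(0, nrow = length(theta), ncol = k + 1L)
  P[, 1L] <- 1
  for (i in seq_len(k)) {
    p_i <- logistic(params$discrimination[i] * (theta - params$difficulty[i]))
    prev <- P
    P <- prev * (1 - p_i)
    P[, 2:(k + 1L)] <- P[, 2:(k + 1L)] + prev[, 1:k] * p_i
  }
  P
}

#' Theoretical AUC of the total score against the diagnosis
#'
#' Exact (to quadrature accuracy) area under the ROC curve of the 26-item
#' total score as a classifier of the generator's diagnosis: the
#' probability that a random diagnosed subject outscores a random
#' non-diagnosed one, with half credit for ties. Score distributions
#' conditional on diagnosis are obtained by Poisson-binomial recursion and
#' quadrature over the latent trait. Serves as the recovery oracle for
#' empirical ROC analysis of generated cohorts.
#'
#' @param params an [irt_params()] object.
#' @return AUC in `[0.5, 1]` for any positively discriminating parameter set.
#' @export
theoretical_auc <- function(params) {
  if (!inherits(params, "irt_params")) stop_validation("`params` must be an `irt_params` object")
  g <- theta_grid()
  p_c <- logistic(params$criterion_discrimination * (g$theta - params$criterion_difficulty))
  pdx <- stats::pbinom(params$diagnosis_threshold - 1L, params$criterion_items,
                       p_c, lower.tail = FALSE)
  S <- score_dist_given_theta(g$theta, params)      # nodes x 27
  f1 <- colSums(S * (g$weight * pdx))
  f0 <- colSums(S * (g$weight * (1 - pdx)))
  if (sum(f1) <= 0 || sum(f0) <= 0)
    stop_computation("diagnosis is degenerate under these parameters (prevalence 0 or 1)")
  f1 <- f1 / sum(f1); f0 <- f0 / sum(f0)
  F0 <- cumsum(f0)
  # P(S1 > S0) + 0.5 P(S1 = S0)
  sum(f1 * (c(0, F0[-length(F0)]) + 0.5 * f0))
}

#' @export
print.irt_params <- function(x, ...) {
  cat("2PL generator parameters: 26 items\n")
  cat(sprintf("  discrimination: [%.3g, %.3g]  difficulty: [%.3g, %.3g]\n",
              min(x$discrimination), max(x$discrimination),
              min(x$difficulty), max(x$difficulty)))
  cat(sprintf("  criterion: %d items, a=%.3g, b=%.3g, diagnosed at >= %d\n",
              x$criterion_items, x$criterion_discrimination,
              x$criterion_difficulty, x$diagnosis_threshold))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d items (seed %d)\n",
              nrow(x$responses), ncol(x$responses), x$seed))
  cat(sprintf("  diagnosed: %d (%.2f%%)\n", sum(x$diagnosis),
              100 * mean(x$diagnosis)))
  invisible(x)
}
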
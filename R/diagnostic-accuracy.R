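#' Relative misclassification cost weights
#'
#' The four relative medical-cost constants of the decision-theory
#' expected-cost formula. The defaults are the mental-health screening
#' cost proportions of Smits and colleagues: true positive 0.89, true
#' negative 0.001, false positive 0.03, false negative 1.0 (a missed case
#' is the costliest outcome; a correct reassurance is nearly free).
#'
#' @param c_tp,c_tn,c_fp,c_fn non-negative relative costs.
#' @return object of class `cost_weights`.
#' @export
cost_weights <- function(c_tp = 0.89, c_tn = 0.001, c_fp = 0.03, c_fn = 1.0) {
  for (nm in c("c_tp", "c_tn", "c_fp", "c_fn"))
    check_scalar_number(get(nm), nm, lower = 0)
  w <- list(c_tp = c_tp, c_tn = c_tn, c_fp = c_fp, c_fn = c_fn)
  if (all(unlist(w) == 0))
    warning("all cost weights are zero; every cut-off has zero cost", call. = FALSE)
  structure(w, class = "cost_weights")
}

#' Cross-tabulate a score cut-off against the diagnosis
#'
#' A subject screens positive when `total >= cutoff` (the screening
#' orientation: lower cut-offs catch more cases).
#'
#' @param totals numeric score vector.
#' @param diagnosis binary vector, same length.
#' @param cutoff integer cut-off.
#' @return object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `cutoff`.
#' @export
confusion_at_cutoff <- function(totals, diagnosis, cutoff) {
  check_paired_vectors(totals, diagnosis, "totals", "diagnosis")
  if (!all(diagnosis %in% c(0, 1)))
    stop_validation("`diagnosis` must be binary")
  check_scalar_number(cutoff, "cutoff")
  pos <- totals >= cutoff
  structure(list(tp = sum(pos & diagnosis == 1),
                 fp = sum(pos & diagnosis == 0),
                 tn = sum(!pos & diagnosis == 0),
                 fn = sum(!pos & diagnosis == 1),
                 cutoff = cutoff),
            class = "confusion_counts")
}

#' Empirical ROC curve with Hanley-McNeil standard error
#'
#' One operating point per integer cut-off `0 ... max_score + 1` (at 0
#' everyone screens positive; at `max_score + 1` nobody does). The AUC is
#' the trapezoidal integral over (1 - specificity, sensitivity), which for
#' integer scores equals the tie-corrected Mann-Whitney statistic
#' \eqn{P(S_1 > S_0) + \tfrac12 P(S_1 = S_0)}. The standard error is
#' Hanley-McNeil:
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_1-1)(Q_1 - A^2) + (n_0-1)(Q_2 - A^2)}{n_1 n_0}}}
#' with \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}.
#'
#' @param totals integer score vector.
#' @param diagnosis binary vector (both classes must be present).
#' @param max_score maximum attainable score (defaults to `max(totals)`);
#'   26 for the full instrument.
#' @return object of class `roc_curve`: `points` (data.frame of cutoff,
#'   sensitivity, specificity), `auc`, `auc_se`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(totals, diagnosis, max_score = NULL) {
  check_paired_vectors(totals, diagnosis, "totals", "diagnosis")
  if (!all(diagnosis %in% c(0, 1)))
    stop_validation("`diagnosis` must be binary")
  n1 <- sum(diagnosis == 1); n0 <- sum(diagnosis == 0)
  if (n1 == 0 || n0 == 0)
    stop_validation("both diagnosed and non-diagnosed subjects are required")
  if (is.null(max_score)) max_score <- max(totals)
  cutoffs <- 0:(max_score + 1L)
  sens <- vapply(cutoffs, function(cc) sum(totals >= cc & diagnosis == 1) / n1,
                 numeric(1))
  spec <- vapply(cutoffs, function(cc) sum(totals < cc & diagnosis == 0) / n0,
                 numeric(1))
  fpr <- 1 - spec
  # cutoffs ascend => fpr and sens descend; integrate left to right
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  structure(list(points = data.frame(cutoff = cutoffs, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, auc_se = se, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' Predictive values and accuracy at a given prevalence
#'
#' Bayes adjustment of a test's prevalence-free properties to a target
#' population:
#' \deqn{PPV = \frac{\pi\,se}{\pi\,se + (1-\pi)(1-sp)},\qquad
#'       NPV = \frac{(1-\pi)\,sp}{(1-\pi)\,sp + \pi(1-se)},\qquad
#'       acc = \pi\,se + (1-\pi)\,sp.}
#' A predictive value whose denominator is zero (no positive, or no
#' negative, screens occur at that prevalence) is returned as `NA`.
#'
#' @param sensitivity,specificity test properties in `[0, 1]`.
#' @param prevalence target prevalence in (0, 1).
#' @return list: `ppv`, `npv`, `accuracy`.
#' @examples
#' adjust_to_prevalence(0.9054, 0.5993, 0.3566)
#' @export
adjust_to_prevalence <- function(sensitivity, specificity, prevalence) {
  check_scalar_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  check_scalar_number(specificity, "specificity", lower = 0, upper = 1)
  check_scalar_number(prevalence, "prevalence", lower = 0, upper = 1,
                      open_lower = TRUE, open_upper = TRUE)
  p_pos <- prevalence * sensitivity + (1 - prevalence) * (1 - specificity)
  p_neg <- (1 - prevalence) * specificity + prevalence * (1 - sensitivity)
  list(ppv = if (p_pos > 0) prevalence * sensitivity / p_pos else NA_real_,
       npv = if (p_neg > 0) (1 - prevalence) * specificity / p_neg else NA_real_,
       accuracy = prevalence * sensitivity + (1 - prevalence) * specificity)
}

#' Expected relative cost of screening at a cut-off
#'
#' Decision-theoretic expected cost per screened subject:
#' \deqn{cost = C_{TP} P_{TP} + C_{TN} P_{TN} + C_{FP} P_{FP} + C_{FN} P_{FN}}
#' with outcome probabilities \eqn{P_{TP} = \pi\,se}, \eqn{P_{FN} =
#' \pi(1-se)}, \eqn{P_{TN} = (1-\pi)\,sp}, \eqn{P_{FP} = (1-\pi)(1-sp)}.
#'
#' @inheritParams adjust_to_prevalence
#' @param weights a [cost_weights()] object.
#' @return non-negative expected cost (in the weights' relative units).
#' @export
expected_cost <- function(sensitivity, specificity, prevalence,
                          weights = cost_weights()) {
  if (!inherits(weights, "cost_weights"))
    stop_validation("`weights` must be a `cost_weights` object")
  check_scalar_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  check_scalar_number(specificity, "specificity", lower = 0, upper = 1)
  check_scalar_number(prevalence, "prevalence", lower = 0, upper = 1,
                      open_lower = TRUE, open_upper = TRUE)
  weights$c_tp * prevalence * sensitivity +
    weights$c_fn * prevalence * (1 - sensitivity) +
    weights$c_tn * (1 - prevalence) * specificity +
    weights$c_fp * (1 - prevalence) * (1 - specificity)
}

metrics_at_point <- function(cutoff, sensitivity, specificity, prevalence,
                             weights) {
  adj <- adjust_to_prevalence(sensitivity, specificity, prevalence)
  data.frame(cutoff = cutoff, prevalence = prevalence,
             sensitivity = sensitivity, specificity = specificity,
             ppv = adj$ppv, npv = adj$npv, accuracy = adj$accuracy,
             expected_cost = expected_cost(sensitivity, specificity,
                                           prevalence, weights))
}

#' Cost-minimizing cut-off
#'
#' Scans every operating point of the ROC curve and returns the cut-off
#' with the lowest expected cost at the given prevalence. Ties are broken
#' toward the lower cut-off: a screening instrument favours sensitivity,
#' and lower cut-offs are the more sensitive ones (a message notes when a
#' tie occurred).
#'
#' @param roc a [roc_curve()] object.
#' @param prevalence target prevalence in (0, 1).
#' @param weights a [cost_weights()] object.
#' @return list: `cutoff` and `metrics` (one-row data.frame with
#'   sensitivity, specificity, ppv, npv, accuracy, expected_cost).
#' @export
optimal_cutoff <- function(roc, prevalence, weights = cost_weights()) {
  if (!inherits(roc, "roc_curve")) stop_validation("`roc` must be a `roc_curve`")
  pts <- roc$points
  costs <- mapply(expected_cost, pts$sensitivity, pts$specificity,
                  MoreArgs = list(prevalence = prevalence, weights = weights))
  best <- min(costs)
  ties <- which(costs <= best + 1e-12)
  if (length(ties) > 1L)
    message(sprintf("cost tie among cutoffs {%s}; choosing the lowest",
                    paste(pts$cutoff[ties], collapse = ", ")))
  i <- ties[1L]
  list(cutoff = pts$cutoff[i],
       metrics = metrics_at_point(pts$cutoff[i], pts$sensitivity[i],
                                  pts$specificity[i], prevalence, weights))
}

#' Cut-off by prevalence metrics table
#'
#' The full grid of cut-off x prevalence diagnostic metrics: sensitivity,
#' specificity, PPV, NPV, accuracy and expected cost for every integer
#' cut-off at each prevalence in the grid, with the per-prevalence
#' cost-optimal cut-off flagged. Sensitivity and specificity are
#' prevalence-free and so repeat across the grid; the predictive values,
#' accuracy and cost are recomputed for each prevalence.
#'
#' @inheritParams roc_curve
#' @param prevalence_grid prevalences in (0, 1).
#' @param weights a [cost_weights()] object.
#' @return data.frame with one row per (prevalence, cutoff) and a logical
#'   `optimal` column.
#' @export
metrics_table <- function(totals, diagnosis, prevalence_grid,
                          weights = cost_weights(), max_score = NULL) {
  if (!is.numeric(prevalence_grid) || !length(prevalence_grid) ||
      any(prevalence_grid <= 0 | prevalence_grid >= 1))
    stop_validation("`prevalence_grid` values must lie strictly in (0, 1)")
  roc <- roc_curve(totals, diagnosis, max_score)
  out <- do.call(rbind, lapply(prevalence_grid, function(prev) {
    rows <- do.call(rbind, lapply(seq_len(nrow(roc$points)), function(i) {
      metrics_at_point(roc$points$cutoff[i], roc$points$sensitivity[i],
                       roc$points$specificity[i], prev, weights)
    }))
    rows$optimal <- FALSE
    best <- suppressMessages(optimal_cutoff(roc, prev, weights))
    rows$optimal[rows$cutoff == best$cutoff] <- TRUE
    rows
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion at cutoff %s: TP %d  FP %d  TN %d  FN %d (n = %d)\n",
              format(x$cutoff), x$tp, x$fp, x$tn, x$fn,
              x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %d operating points, %d diagnosed / %d non-diagnosed\n",
              nrow(x$points), x$n_pos, x$n_neg))
  cat(sprintf("  AUC = %.4f (SE %.4f, Hanley-McNeil)\n", x$auc, x$auc_se))
  invisible(x)
}
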
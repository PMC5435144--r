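#' Validate and coerce a subjects-by-items binary response matrix
#'
#' The universal input of the pipeline: one row per subject, one column per
#' item, every value 0 ("no") or 1 ("yes"), unique subject IDs as rownames.
#'
#' @param x matrix or data.frame of responses.
#' @param what label used in error messages.
#' @return integer matrix with rownames (subject IDs) and colnames (items).
#' @export
as_item_matrix <- function(x, what = "responses") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) < 1L || nrow(x) < 1L)
    stop_validation("`%s` must be a non-empty subjects x items matrix", what)
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%04d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop_validation("`%s` has duplicated subject IDs (e.g. '%s')", what,
                    rownames(x)[anyDuplicated(rownames(x))])
  if (is.null(colnames(x))) colnames(x) <- sprintf("item_%02d", seq_len(ncol(x)))
  bad <- which(!(x %in% c(0, 1)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(x)) + 1L
    stop_validation("`%s` contains a non-binary value at subject '%s', item '%s'",
                    what, rownames(x)[i], colnames(x)[j])
  }
  storage.mode(x) <- "integer"
  x
}

#' Item-to-factor assignment
#'
#' A named partition of the item set into scale factors. Every item must be
#' assigned to exactly one factor.
#'
#' @param assignment named character vector: names are item labels, values
#'   are factor labels.
#' @return object of class `factor_map` (the assignment vector with a
#'   `factor_names` attribute preserving first-appearance order).
#' @export
factor_map <- function(assignment) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop_validation("`assignment` must be named by unique item labels")
  structure(as.character(stats::setNames(assignment, names(assignment))),
            names = names(assignment),
            factor_names = unique(unname(assignment)),
            class = "factor_map")
}

#' Default four-factor map for the 26-item scale
#'
#' Reconstructed assignment of the 26 items to the four classical factors
#' of the instrument family (compulsive behavior, functional impairment,
#' withdrawal, tolerance; the tolerance factor has only 3 items). The
#' source validation report does not print the assignment, so this map is
#' an editable default, not ground truth; supply your own [factor_map()]
#' where the true assignment is known.
#'
#' @return a `factor_map` over items `spai_01` ... `spai_26`.
#' @export
default_factor_map <- function() {
  items <- sprintf("spai_%02d", 1:26)
  fac <- c(rep("compulsive_behavior", 9),
           rep("functional_impairment", 7),
           rep("withdrawal", 7),
           rep("tolerance", 3))
  factor_map(stats::setNames(fac, items))
}

#' Score the scale: totals and per-factor totals
#'
#' The total score is the count of endorsed (1) items per subject; factor
#' scores count within each factor's items. Factor scores always sum to
#' the total.
#'
#' @param responses binary subjects x items matrix (see [as_item_matrix()]).
#' @param fmap optional [factor_map()] covering exactly the response items.
#' @param reverse optional character vector of item labels scored in
#'   reverse (0 counts as endorsement).
#' @return data.frame with `subject_id`, `total`, and one column per factor
#'   when `fmap` is supplied.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), nrow = 2, dimnames = list(c("a", "b"), c("i1", "i2")))
#' score_scale(m)
#' @export
score_scale <- function(responses, fmap = NULL, reverse = NULL) {
  responses <- as_item_matrix(responses)
  if (!is.null(reverse)) {
    unknown <- setdiff(reverse, colnames(responses))
    if (length(unknown))
      stop_validation("`reverse` names unknown items: %s",
                      paste(unknown, collapse = ", "))
    responses[, reverse] <- 1L - responses[, reverse]
  }
  out <- data.frame(subject_id = rownames(responses),
                    total = as.integer(rowSums(responses)),
                    stringsAsFactors = FALSE)
  if (!is.null(fmap)) {
    if (!inherits(fmap, "factor_map")) stop_validation("`fmap` must be a `factor_map`")
    if (!setequal(names(fmap), colnames(responses)))
      stop_validation("factor map items do not match response items (map has %d, data has %d)",
                      length(fmap), ncol(responses))
    for (f in attr(fmap, "factor_names")) {
      its <- names(fmap)[unclass(fmap) == f]
      out[[f]] <- as.integer(rowSums(responses[, its, drop = FALSE]))
    }
  }
  out
}

#' Score the gold-standard criterion
#'
#' Counts endorsed criterion items per subject and flags a diagnosis when
#' the count reaches `threshold`.
#'
#' @param criterion_responses binary subjects x criterion-items matrix.
#' @param threshold integer in `[0, number of criterion items]`.
#' @return data.frame with `subject_id`, `criterion_score`, `diagnosis`.
#' @export
score_criterion <- function(criterion_responses, threshold) {
  criterion_responses <- as_item_matrix(criterion_responses, "criterion_responses")
  check_scalar_number(threshold, "threshold", lower = 0,
                      upper = ncol(criterion_responses))
  data.frame(subject_id = rownames(criterion_responses),
             criterion_score = as.integer(rowSums(criterion_responses)),
             diagnosis = as.integer(rowSums(criterion_responses) >= threshold),
             stringsAsFactors = FALSE)
}

#' Score a synthetic cohort end to end
#'
#' Convenience wrapper combining [score_scale()] on the cohort's responses
#' with the generator's criterion count and diagnosis.
#'
#' @param cohort a [generate_cohort()] result.
#' @param fmap optional [factor_map()].
#' @return data.frame: `subject_id`, `total`, factor columns (if any),
#'   `criterion_score`, `diagnosis`.
#' @export
score_cohort <- function(cohort, fmap = NULL) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop_validation("`cohort` must be a `synthetic_cohort`")
  s <- score_scale(cohort$responses, fmap)
  s$criterion_score <- cohort$criterion_scores
  s$diagnosis <- cohort$diagnosis
  s
}

#' Read subject-level responses from CSV
#'
#' Strict reader for the pipeline's flat schema: a `subject_id` column,
#' scale item columns `spai_01` ... , and either criterion columns
#' `goodman_01` ... or a precomputed `diagnosis` column; optional
#' `retest_spai_*` columns for the retest subsample. Every item cell must
#' be 0 or 1; empty cells are rejected unless `allow_missing = "drop"`,
#' which drops incomplete subjects (a note is attached to the result).
#'
#' @param path CSV file path (header row required).
#' @param allow_missing `"error"` (default) or `"drop"`.
#' @return list with `responses`, and when present `criterion`, `diagnosis`
#'   (named integer vector), `retest` (matrix over the retest subsample),
#'   `demographics` (pass-through of unrecognised columns), `n_dropped`.
#' @export
read_responses <- function(path, allow_missing = c("error", "drop")) {
  allow_missing <- match.arg(allow_missing)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop_validation("CSV must have a `subject_id` column")
  item_cols <- grep("^spai_[0-9]+$", names(df), value = TRUE)
  if (!length(item_cols)) stop_validation("no `spai_*` item columns found")
  crit_cols <- grep("^goodman_[0-9]+$", names(df), value = TRUE)
  retest_cols <- grep("^retest_spai_[0-9]+$", names(df), value = TRUE)

  used <- c(item_cols, crit_cols, retest_cols, "diagnosis")
  n_dropped <- 0L
  core <- df[, c(item_cols, crit_cols, intersect("diagnosis", names(df)))]
  incomplete <- apply(core, 1L, function(r) any(is.na(r) | r == ""))
  if (any(incomplete)) {
    if (allow_missing == "error") {
      row <- which(incomplete)[1]
      col <- names(core)[which(is.na(core[row, ]) | core[row, ] == "")[1]]
      stop_validation("empty cell at row %d (subject '%s'), column '%s'; use allow_missing = \"drop\" to discard incomplete subjects",
                      row, df$subject_id[row], col)
    }
    n_dropped <- sum(incomplete)
    df <- df[!incomplete, , drop = FALSE]
  }

  mk <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    rownames(m) <- df$subject_id
    as_item_matrix(m, paste(cols[1], "block"))
  }
  out <- list(responses = mk(item_cols), n_dropped = n_dropped)
  if (length(crit_cols)) out$criterion <- mk(crit_cols)
  if ("diagnosis" %in% names(df)) {
    dx <- df$diagnosis
    if (!all(dx %in% c(0, 1)))
      stop_validation("`diagnosis` column must be binary")
    out$diagnosis <- stats::setNames(as.integer(dx), df$subject_id)
  }
  if (length(retest_cols)) {
    has_rt <- !apply(df[, retest_cols, drop = FALSE], 1L,
                     function(r) any(is.na(r) | r == ""))
    if (any(has_rt)) {
      m <- as.matrix(df[has_rt, retest_cols, drop = FALSE])
      rownames(m) <- df$subject_id[has_rt]
      out$retest <- as_item_matrix(m, "retest block")
    }
  }
  extras <- setdiff(names(df), c(used, "subject_id"))
  if (length(extras))
    out$demographics <- df[, c("subject_id", extras), drop = FALSE]
  out
}
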
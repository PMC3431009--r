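# Competition scoring, binary diagnostic metrics, and data splitting.

check_labels <- function(x, name) {
  x <- as.character(x)
  bad <- setdiff(unique(x), dx_levels())
  if (length(bad)) {
    stop(name, " contains labels outside the diagnosis set: ",
         paste(bad, collapse = ", "))
  }
  x
}

#' Hierarchical competition score
#'
#' One point for an exact label match (a correctly classified TD subject or
#' a correctly subtyped ADHD subject); half a point when a true ADHD subject
#' is called ADHD but with the wrong subtype; zero otherwise. The percent is
#' points over the maximum (one per subject).
#'
#' @param truth,pred label vectors of equal length in the four-level set.
#' @return List with `points` and `percent`.
#' @export
#' @examples
#' competition_score("INATTENTIVE", "COMBINED")$points  # 0.5
competition_score <- function(truth, pred) {
  truth <- check_labels(truth, "truth")
  pred <- check_labels(pred, "pred")
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths (", length(truth), " vs ",
         length(pred), ")")
  }
  pts <- ifelse(truth == pred, 1,
                ifelse(truth != "TD" & pred != "TD", 0.5, 0))
  list(points = sum(pts), percent = 100 * sum(pts) / length(pts))
}

#' Binary diagnostic metrics after collapsing subtypes
#'
#' Collapses the three ADHD subtypes to a single positive class:
#' sensitivity = detected ADHD / true ADHD, specificity = predicted TD /
#' true TD, Youden's J = sensitivity + specificity - 1, and the conditional
#' subtype accuracy = correct subtype among the ADHD subjects whose ADHD
#' status was correctly detected. Metrics whose denominator is empty are
#' returned as `NA` rather than raising an error.
#'
#' @param truth,pred label vectors of equal length.
#' @return List with `sensitivity`, `specificity`, `youden_j`,
#'   `conditional_subtype_accuracy`.
#' @export
binary_metrics <- function(truth, pred) {
  truth <- check_labels(truth, "truth")
  pred <- check_labels(pred, "pred")
  stopifnot(length(truth) == length(pred))
  t_adhd <- truth != "TD"
  p_adhd <- pred != "TD"
  sens <- if (any(t_adhd)) mean(p_adhd[t_adhd]) else NA_real_
  spec <- if (any(!t_adhd)) mean(!p_adhd[!t_adhd]) else NA_real_
  detected <- t_adhd & p_adhd
  cond <- if (any(detected)) mean(truth[detected] == pred[detected]) else NA_real_
  list(sensitivity = sens, specificity = spec, youden_j = sens + spec - 1,
       conditional_subtype_accuracy = cond)
}

#' Full score report
#'
#' @param truth,pred label vectors.
#' @return Object of class `score_report` combining [competition_score()]
#'   and [binary_metrics()] plus `n`.
#' @export
score_report <- function(truth, pred) {
  cs <- competition_score(truth, pred)
  bm <- binary_metrics(truth, pred)
  structure(c(cs, bm, list(n = length(truth))), class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("competition score: %.1f / %d points (%.1f%%)\n",
              x$points, x$n, x$percent))
  cat(sprintf("sensitivity %.3f  specificity %.3f  Youden's J %.3f\n",
              x$sensitivity, x$specificity, x$youden_j))
  cat(sprintf("conditional subtype accuracy %.3f\n",
              x$conditional_subtype_accuracy))
  invisible(x)
}

#' Random train/test split of a cohort
#'
#' Uniformly random disjoint split, reproducible by seed.
#'
#' @param cohort data.frame (or vector) to split.
#' @param n_test number of test rows; must be positive and smaller than the
#'   cohort size.
#' @param seed RNG seed.
#' @return List with `train` and `test` (same type as the input) and the
#'   `test_idx` indices.
#' @export
split_cohort <- function(cohort, n_test, seed = 1L) {
  n <- if (is.data.frame(cohort)) nrow(cohort) else length(cohort)
  if (n_test >= n || n_test < 1L) {
    stop("n_test must be in 1..", n - 1L, ", got ", n_test)
  }
  idx <- with_seed(seed, sort(sample.int(n, n_test)))
  if (is.data.frame(cohort)) {
    list(train = cohort[-idx, , drop = FALSE],
         test = cohort[idx, , drop = FALSE], test_idx = idx)
  } else {
    list(train = cohort[-idx], test = cohort[idx], test_idx = idx)
  }
}
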
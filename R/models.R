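# Classifier stages and ensembling: four-class random forest on motor-network
# correlations plus demographics, two-stage gradient boosting (TD-vs-ADHD
# then subtype), and plurality voting with a designated tie-breaker.

#' Construct a prediction set
#'
#' @param subject_id character vector.
#' @param label predicted labels in the four-level diagnosis set.
#' @param source model identifier.
#' @return data.frame of class `prediction_set`.
#' @export
prediction_set <- function(subject_id, label, source) {
  label <- as.character(label)
  bad <- setdiff(unique(label), dx_levels())
  if (length(bad)) stop("labels outside the diagnosis set: ", paste(bad, collapse = ", "))
  out <- data.frame(subject_id = as.character(subject_id),
                    label = factor(label, levels = dx_levels()),
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("prediction_set", "data.frame")
  out
}

rf_required_columns <- function() {
  c(m1_pair_labels(), "age", "gender", "site", "handedness", "iq_composite")
}

#' Random forest on motor-network correlations and demographics
#'
#' Four-class random forest using the 10 M1 inter-parcel correlations
#' together with age, gender, site, handedness, and composite IQ.
#'
#' @param features data.frame containing the required columns (extra columns
#'   are ignored).
#' @param labels factor of diagnosis labels.
#' @param ntree number of trees.
#' @param seed RNG seed for the fit.
#' @return Object of class `rf_pipeline`.
#' @export
fit_random_forest_pipeline <- function(features, labels, ntree = 500L, seed = 1L) {
  req <- rf_required_columns()
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stop("missing required feature columns: ", paste(missing_cols, collapse = ", "))
  }
  y <- droplevels(factor(labels, levels = dx_levels()))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  X <- features[req]
  fit <- with_seed(seed, randomForest::randomForest(x = X, y = y, ntree = ntree))
  structure(list(fit = fit, feature_names = req, ntree = ntree, seed = seed),
            class = "rf_pipeline")
}

#' @export
predict.rf_pipeline <- function(object, newdata, subject_id = newdata$subject_id, ...) {
  lab <- as.character(stats::predict(object$fit, newdata[object$feature_names]))
  prediction_set(subject_id, lab, source = "rf_parcel")
}

# one-hot design matrix with stored factor levels, reproducible at predict
build_design <- function(df, cols, levels = NULL) {
  mats <- list()
  lv <- list()
  for (cn in cols) {
    x <- df[[cn]]
    if (is.numeric(x)) {
      mats[[cn]] <- matrix(x, ncol = 1L, dimnames = list(NULL, cn))
    } else {
      lev <- if (!is.null(levels[[cn]])) levels[[cn]] else sort(unique(as.character(x)))
      lv[[cn]] <- lev
      M <- outer(as.character(x), lev, "==") * 1
      colnames(M) <- paste0(cn, "_", lev)
      mats[[cn]] <- M
    }
  }
  out <- do.call(cbind, mats)
  attr(out, "levels") <- lv
  out
}

default_gbm_params <- function() {
  list(nrounds = 150L, max_depth = 3L, eta = 0.1, subsample = 1,
       colsample_bytree = 1)
}

xgb_fit <- function(X, y, objective, num_class = NULL, params, seed) {
  p <- list(objective = objective, max_depth = params$max_depth,
            eta = params$eta, subsample = params$subsample,
            colsample_bytree = params$colsample_bytree, nthread = 1L)
  if (!is.null(num_class)) p$num_class <- num_class
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  with_seed(seed, xgboost::xgb.train(params = p, data = dtrain,
                                     nrounds = params$nrounds, verbose = 0))
}

#' Two-stage gradient boosting classifier
#'
#' Stage 1 is a binary gradient-boosted model for TD versus any ADHD,
#' trained on all subjects; stage 2 is a subtype model trained on the true
#' ADHD subjects only. At prediction time a subject called TD by stage 1 is
#' labelled TD regardless of stage 2; otherwise the stage-2 subtype is
#' assigned.
#'
#' @param features data.frame with `subject_id` and predictor columns.
#' @param labels factor of diagnosis labels (all four levels allowed).
#' @param feature_cols predictor column names (numeric or categorical;
#'   categoricals are one-hot encoded with stored levels).
#' @param params boosting hyperparameters (`nrounds`, `max_depth`, `eta`,
#'   `subsample`, `colsample_bytree`); unstated components take conventional
#'   defaults.
#' @param seed RNG seed for both fits.
#' @param source model identifier attached to predictions.
#' @return Object of class `two_stage_gbm`.
#' @export
fit_two_stage_gbm <- function(features, labels, feature_cols,
                              params = list(), seed = 1L, source = "gbm2") {
  params <- utils::modifyList(default_gbm_params(), params)
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols)) {
    stop("missing required feature columns: ", paste(missing_cols, collapse = ", "))
  }
  y <- factor(labels, levels = dx_levels())
  if (nlevels(droplevels(y)) < 2L) stop("training labels contain a single class")
  is_adhd <- y != "TD"
  if (!any(is_adhd)) stop("no ADHD subjects in training data")
  X <- build_design(features, feature_cols)
  lv <- attr(X, "levels")

  stage1 <- xgb_fit(X, as.numeric(is_adhd), "binary:logistic",
                    params = params, seed = seed)

  sub_levels <- intersect(c("COMBINED", "HYPERACTIVE", "INATTENTIVE"),
                          as.character(unique(y[is_adhd])))
  if (length(sub_levels) >= 2L) {
    y2 <- as.integer(factor(as.character(y[is_adhd]), levels = sub_levels)) - 1L
    stage2 <- xgb_fit(X[is_adhd, , drop = FALSE], y2, "multi:softprob",
                      num_class = length(sub_levels), params = params,
                      seed = derive_seed(seed, 2L))
  } else {
    stage2 <- NULL   # single observed subtype: predicted constantly
  }
  structure(
    list(stage1 = stage1, stage2 = stage2, sub_levels = sub_levels,
         feature_cols = feature_cols, levels = lv, params = params,
         seed = seed, source = source),
    class = "two_stage_gbm"
  )
}

#' @export
predict.two_stage_gbm <- function(object, newdata,
                                  subject_id = newdata$subject_id, ...) {
  X <- build_design(newdata, object$feature_cols, levels = object$levels)
  p1 <- stats::predict(object$stage1, X)
  lab <- rep("TD", nrow(X))
  adhd <- p1 >= 0.5
  if (any(adhd)) {
    if (is.null(object$stage2)) {
      lab[adhd] <- object$sub_levels
    } else {
      pr <- stats::predict(object$stage2, X[adhd, , drop = FALSE])
      if (is.null(dim(pr))) {
        pr <- matrix(pr, ncol = length(object$sub_levels), byrow = TRUE)
      }
      lab[adhd] <- object$sub_levels[max.col(pr, ties.method = "first")]
    }
  }
  prediction_set(subject_id, lab, source = object$source)
}

#' Combine prediction sets by plurality vote
#'
#' Per subject, the label with the most votes wins; any tie among the top
#' counts (including four-way ties) is resolved by the tie-breaker model's
#' label.
#'
#' @param predictions list of `prediction_set` objects over identical
#'   subjects.
#' @param tiebreak_source `source` identifier of the tie-breaking member.
#' @return A `prediction_set` with source `"ensemble"`.
#' @export
majority_vote <- function(predictions, tiebreak_source) {
  stopifnot(is.list(predictions), length(predictions) >= 1L)
  ids <- predictions[[1L]]$subject_id
  sources <- vapply(predictions, function(p) p$source[1L], character(1))
  if (!tiebreak_source %in% sources) {
    stop("tiebreak_source '", tiebreak_source, "' not among inputs: ",
         paste(sources, collapse = ", "))
  }
  aligned <- lapply(predictions, function(p) {
    if (!setequal(p$subject_id, ids) || length(p$subject_id) != length(ids)) {
      stop("prediction sets cover different subjects")
    }
    as.character(p$label)[match(ids, p$subject_id)]
  })
  votes <- do.call(cbind, aligned)
  tb <- aligned[[match(tiebreak_source, sources)]]
  lab <- vapply(seq_along(ids), function(i) {
    tab <- table(factor(votes[i, ], levels = dx_levels()))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else tb[i]
  }, character(1))
  prediction_set(ids, lab, source = "ensemble")
}
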
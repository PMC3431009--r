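# End-to-end driver: simulate -> preprocess -> features -> split -> train ->
# predict -> ensemble -> score -> associate, fully determined by one config.

#' Pipeline configuration
#'
#' @param generator a [generator_config()] describing the cohort.
#' @param detrend_order,band temporal preprocessing parameters.
#' @param cur_c,cur_rank CUR selection size and leverage rank.
#' @param k_pca number of principal components retained from the CUR
#'   covariance vectors and from the seed connectivity vectors (default 10).
#' @param seed_radius seed-sphere radius in voxels.
#' @param n_test internal test-set size; default one quarter of the cohort.
#' @param use_seed_model fit the seed-connectivity two-stage model (the
#'   slowest stage; disable for quick runs).
#' @param rf_ntree random-forest size.
#' @param gbm_params boosting hyperparameter overrides.
#' @param tiebreak source identifier of the ensemble tie-breaker (default
#'   `"gbm_cur"`, the CUR-based two-stage model, which had the best internal
#'   accuracy in the original study).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            detrend_order = 2L, band = c(0.01, 0.1),
                            cur_c = 20L, cur_rank = cur_c, k_pca = 10L,
                            seed_radius = 1, n_test = NULL,
                            use_seed_model = TRUE, rf_ntree = 500L,
                            gbm_params = list(), tiebreak = "gbm_cur") {
  stopifnot(inherits(generator, "generator_config"))
  structure(
    list(generator = generator, detrend_order = as.integer(detrend_order),
         band = band, cur_c = as.integer(cur_c), cur_rank = as.integer(cur_rank),
         k_pca = as.integer(k_pca), seed_radius = seed_radius, n_test = n_test,
         use_seed_model = isTRUE(use_seed_model), rf_ntree = as.integer(rf_ntree),
         gbm_params = gbm_params, tiebreak = tiebreak),
    class = "pipeline_config"
  )
}

# per-subject feature extraction across sessions, averaged within subject
extract_cohort_features <- function(cohort, template, config, verbose = FALSE) {
  gen <- config$generator
  sessions <- lapply(seq_len(gen$n_sessions), function(s) {
    rows_parcel <- matrix(NA_real_, nrow(cohort), 10L,
                          dimnames = list(NULL, m1_pair_labels()))
    rows_cur <- NULL
    rows_seed <- NULL
    periph <- numeric(nrow(cohort))
    motion <- matrix(NA_real_, nrow(cohort), gen$n_motion_params,
                     dimnames = list(NULL, paste0("mp", seq_len(gen$n_motion_params))))
    for (i in seq_len(nrow(cohort))) {
      scan <- simulate_scan(cohort[i, ], template, gen, session = s)
      pp <- preprocess_scan(scan, template, detrend_order = config$detrend_order,
                            band = config$band)
      rows_parcel[i, ] <- pairwise_correlations(parcel_mean_timecourses(pp, template))
      cf <- cur_covariance_vector(pp, template, c = config$cur_c,
                                  rank_k = config$cur_rank)
      if (is.null(rows_cur)) {
        rows_cur <- matrix(NA_real_, nrow(cohort), length(cf$values),
                           dimnames = list(NULL, names(cf$values)))
      }
      rows_cur[i, ] <- cf$values
      periph[i] <- peripheral_fraction(cf$selection, template)
      if (config$use_seed_model) {
        sv <- seed_connectivity_vector(pp, template, radius = config$seed_radius)
        if (is.null(rows_seed)) {
          rows_seed <- matrix(NA_real_, nrow(cohort), length(sv),
                              dimnames = list(NULL, names(sv)))
        }
        rows_seed[i, ] <- sv
      }
      motion[i, ] <- colMeans(abs(scan$motion_params))
      if (verbose && i %% 50L == 0L) {
        message("  session ", s, ": ", i, "/", nrow(cohort), " subjects")
      }
    }
    list(parcel = rows_parcel, cur = rows_cur, seed = rows_seed,
         periph = periph, motion = motion)
  })
  avg <- function(field) {
    if (is.null(sessions[[1L]][[field]])) return(NULL)
    Reduce(`+`, lapply(sessions, `[[`, field)) / length(sessions)
  }
  list(parcel = avg("parcel"), cur = avg("cur"), seed = avg("seed"),
       periph = avg("periph"), motion = avg("motion"))
}

#' Run the full ensemble pipeline on a synthetic cohort
#'
#' Simulates the cohort and scans, preprocesses them, extracts motor-parcel
#' correlations, CUR covariance vectors (PCA-reduced on the training split),
#' and optionally seed connectivity with motion summaries; splits off an
#' internal test set; fits the random-forest model and the two two-stage
#' gradient-boosting models on the training split; combines their test-set
#' predictions by majority vote with the configured tie-breaker; and scores
#' the ensemble with the hierarchical competition metric. Association
#' analyses (group summaries, nested multinomial models, per-pair logistic
#' models) are run on the full cohort. Two runs with the same configuration
#' produce identical results.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: phenotypes, features, predictions,
#'   score, association tables, and a checksum manifest are written there.
#' @param extra_predictions optional list of externally produced
#'   `prediction_set` objects over the test subjects, added to the ensemble
#'   vote (plug-in models).
#' @param verbose print stage progress.
#' @return Object of class `pipeline_result`: `score` (a `score_report`),
#'   `per_model_scores`, `baseline_percent` (majority-class competition
#'   score on the test set), `predictions`, `association`, `features`,
#'   `cohort`, `split`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         extra_predictions = list(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator
  say <- function(...) if (verbose) message(...)

  say("simulating cohort and template")
  template <- make_brain_template(gen)
  cohort <- simulate_cohort(gen)
  n <- nrow(cohort)
  n_test <- if (is.null(config$n_test)) max(1L, round(n / 4)) else config$n_test

  say("extracting features (", n, " subjects)")
  feats <- extract_cohort_features(cohort, template, config, verbose = verbose)
  pheno <- prepare_covariates(cohort)

  split <- split_cohort(seq_len(n), n_test = n_test,
                        seed = derive_seed(gen$rng_seed, 21L))
  tr_idx <- split$train
  te_idx <- split$test

  say("reducing CUR features to ", config$k_pca, " components")
  cur_pca <- pca_reduce(feats$cur[tr_idx, , drop = FALSE], k = config$k_pca)
  cur_pcs <- stats::predict(cur_pca, feats$cur)
  colnames(cur_pcs) <- paste0("cur_PC", seq_len(config$k_pca))

  covars <- pheno[, c("subject_id", "age", "gender", "site", "handedness",
                      "iq_composite")]
  frame_rf <- cbind(covars, as.data.frame(feats$parcel))
  frame_cur <- cbind(covars, as.data.frame(cur_pcs))

  labels <- cohort$dx
  say("fitting models")
  rf <- fit_random_forest_pipeline(frame_rf[tr_idx, ], labels[tr_idx],
                                   ntree = config$rf_ntree,
                                   seed = derive_seed(gen$rng_seed, 31L))
  gbm_feats_cur <- c(colnames(cur_pcs), "age", "gender", "site", "handedness",
                     "iq_composite")
  gbm_cur <- fit_two_stage_gbm(frame_cur[tr_idx, ], labels[tr_idx],
                               feature_cols = gbm_feats_cur,
                               params = config$gbm_params,
                               seed = derive_seed(gen$rng_seed, 32L),
                               source = "gbm_cur")
  preds <- list(stats::predict(rf, frame_rf[te_idx, ]),
                stats::predict(gbm_cur, frame_cur[te_idx, ]))

  if (config$use_seed_model) {
    say("reducing seed connectivity")
    seed_pca <- pca_reduce(feats$seed[tr_idx, , drop = FALSE], k = config$k_pca)
    seed_pcs <- stats::predict(seed_pca, feats$seed)
    colnames(seed_pcs) <- paste0("seed_PC", seq_len(config$k_pca))
    frame_seed <- cbind(covars, as.data.frame(seed_pcs),
                        as.data.frame(feats$motion))
    gbm_seed <- fit_two_stage_gbm(
      frame_seed[tr_idx, ], labels[tr_idx],
      feature_cols = c(colnames(seed_pcs), colnames(feats$motion), "age",
                       "gender", "site", "handedness", "iq_composite"),
      params = config$gbm_params, seed = derive_seed(gen$rng_seed, 33L),
      source = "gbm_seed")
    preds <- c(preds, list(stats::predict(gbm_seed, frame_seed[te_idx, ])))
  }
  preds <- c(preds, extra_predictions)

  say("ensembling and scoring")
  ens <- majority_vote(preds, tiebreak_source = config$tiebreak)
  truth_te <- as.character(labels[te_idx])
  score <- score_report(truth_te, as.character(ens$label))
  per_model <- vapply(preds, function(p) {
    competition_score(truth_te, as.character(p$label))$percent
  }, numeric(1))
  names(per_model) <- vapply(preds, function(p) p$source[1L], character(1))
  maj <- names(which.max(table(as.character(labels[tr_idx]))))
  baseline <- competition_score(truth_te, rep(maj, length(te_idx)))$percent

  say("association analyses")
  assoc <- list(
    summary = subtype_correlation_summary(feats$parcel, labels),
    multinomial = subtype_association_models(feats$parcel, pheno, labels),
    logistic = pairwise_logistic_models(feats$parcel, pheno, labels)
  )

  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_pipeline_artifacts(out_dir, cohort, pheno, feats,
                                         ens, score, assoc)
  }

  structure(
    list(score = score, per_model_scores = per_model,
         baseline_percent = baseline, predictions = ens,
         member_predictions = preds, association = assoc,
         features = feats, cohort = cohort, pheno = pheno,
         split = list(train = tr_idx, test = te_idx), manifest = manifest,
         config = config),
    class = "pipeline_result"
  )
}

write_pipeline_artifacts <- function(out_dir, cohort, pheno, feats, ens,
                                     score, assoc) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr(cohort[, setdiff(names(cohort), "scan_seed")], "phenotypes.csv")
  wr(data.frame(subject_id = cohort$subject_id, feats$parcel,
                peripheral_fraction = feats$periph, check.names = FALSE),
     "features_parcel.csv")
  wr(data.frame(subject_id = cohort$subject_id, feats$cur, check.names = FALSE),
     "features_cur.csv")
  wr(as.data.frame(ens), "predictions.csv")
  wr(assoc$summary, "association_summary.csv")
  wr(assoc$multinomial, "association_multinomial.csv")
  wr(assoc$logistic, "association_logistic.csv")
  sp <- file.path(out_dir, "score.json")
  jsonlite::write_json(unclass(score), sp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, sp)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result on", nrow(x$cohort), "subjects (",
      length(x$split$test), "test )\n")
  print(x$score)
  cat(sprintf("majority-class baseline: %.1f%%\n", x$baseline_percent))
  cat("member scores (%):",
      paste(sprintf("%s %.1f", names(x$per_model_scores), x$per_model_scores),
            collapse = ", "), "\n")
  invisible(x)
}
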
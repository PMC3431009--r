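# Classifiers and ensembling.

test_that("majority vote matches an exhaustive count-and-argmax oracle", {
  lv <- dx_levels()
  ids <- "s1"
  patterns <- expand.grid(v1 = lv, v2 = lv, v3 = lv, v4 = lv,
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patterns))) {
    votes <- unlist(patterns[i, ])
    sets <- lapply(1:4, function(j) {
      prediction_set(ids, votes[j], source = paste0("m", j))
    })
    got <- majority_vote(sets, tiebreak_source = "m2")
    counts <- table(factor(votes, levels = lv))
    top <- names(counts)[counts == max(counts)]
    want <- if (length(top) == 1L) top else votes[2]
    expect_equal(as.character(got$label), unname(want))
  }
})

test_that("majority vote reproduces the stated examples and degenerate rules", {
  mk <- function(labs) {
    lapply(seq_along(labs), function(j) {
      prediction_set("s1", labs[j], source = paste0("m", j))
    })
  }
  v <- majority_vote(mk(c("TD", "TD", "COMBINED", "INATTENTIVE")), "m3")
  expect_equal(as.character(v$label), "TD")
  v <- majority_vote(mk(c("TD", "COMBINED", "COMBINED", "TD")), "m2")
  expect_equal(as.character(v$label), "COMBINED")
  v <- majority_vote(mk(rep("INATTENTIVE", 4)), "m1")
  expect_equal(as.character(v$label), "INATTENTIVE")

  same <- prediction_set(c("a", "b"), c("TD", "COMBINED"), "m1")
  ens <- majority_vote(list(same, same, same), "m1")
  expect_equal(as.character(ens$label), c("TD", "COMBINED"))

  other <- prediction_set(c("a", "zz"), c("TD", "TD"), "m2")
  expect_error(majority_vote(list(same, other), "m1"), "different subjects")
  expect_error(majority_vote(list(same), "nope"), "tiebreak_source")
})

test_that("random forest pipeline validates inputs and learns planted signal", {
  set.seed(20)
  cfg <- tiny_config(design = data.frame(
    site = rep(c("SiteA", "SiteB"), each = 4),
    dx = rep(c("TD", "COMBINED", "HYPERACTIVE", "INATTENTIVE"), 2),
    n = c(150L, 60L, 15L, 75L, 150L, 60L, 15L, 75L)
  ), rng_seed = 41L)
  coh <- simulate_cohort(cfg)
  conn <- suppressMessages(simulate_connectivity_cohort(coh, cfg))
  pheno <- prepare_covariates(coh)
  frame <- cbind(pheno[c("subject_id", "age", "gender", "site", "handedness",
                         "iq_composite")], as.data.frame(conn))

  expect_error(fit_random_forest_pipeline(frame[-2], coh$dx), "age")
  expect_error(fit_random_forest_pipeline(frame[coh$dx == "TD", ],
                                          coh$dx[coh$dx == "TD"]),
               "single class")

  sp <- split_cohort(seq_len(nrow(frame)), n_test = 150, seed = 5)
  rf <- fit_random_forest_pipeline(frame[sp$train, ], coh$dx[sp$train], seed = 9)
  pred <- predict(rf, frame[sp$test, ])
  acc <- competition_score(as.character(coh$dx[sp$test]),
                           as.character(pred$label))$percent
  maj <- names(which.max(table(coh$dx[sp$train])))
  base <- competition_score(as.character(coh$dx[sp$test]),
                            rep(maj, 150))$percent
  expect_gt(acc, base)

  # null cohort: no signal anywhere; accuracy stays within noise of baseline
  ncfg <- null_generator_config(design = cfg$design, grid_dims = cfg$grid_dims,
                                n_seeds = cfg$n_seeds,
                                n_timepoints = cfg$n_timepoints, rng_seed = 42L)
  ncoh <- simulate_cohort(ncfg)
  nconn <- suppressMessages(simulate_connectivity_cohort(ncoh, ncfg))
  npheno <- prepare_covariates(ncoh)
  nframe <- cbind(npheno[c("subject_id", "age", "gender", "site", "handedness",
                           "iq_composite")], as.data.frame(nconn))
  nrf <- fit_random_forest_pipeline(nframe[sp$train, ], ncoh$dx[sp$train], seed = 9)
  npred <- predict(nrf, nframe[sp$test, ])
  nacc <- competition_score(as.character(ncoh$dx[sp$test]),
                            as.character(npred$label))$percent
  nbase <- competition_score(as.character(ncoh$dx[sp$test]),
                             rep(maj, 150))$percent
  band <- 196 * sqrt(0.62 * 0.38 / 150)   # ~2 SE of a percent on 150 subjects
  expect_lt(nacc - nbase, band)
})

test_that("two-stage model gates subtype predictions on the ADHD stage", {
  set.seed(21)
  n <- 240
  x <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  labels <- factor(c(rep("TD", n / 2),
                     sample(c("COMBINED", "INATTENTIVE", "HYPERACTIVE"),
                            n / 2, replace = TRUE)),
                   levels = dx_levels())
  feats <- data.frame(subject_id = paste0("s", 1:n), x = x,
                      y = rnorm(n) + as.integer(labels))
  fit <- fit_two_stage_gbm(feats, labels, feature_cols = c("x", "y"), seed = 2)
  pred <- predict(fit, feats)

  X <- adhdconn:::build_design(feats, fit$feature_cols, fit$levels)
  p1 <- predict(fit$stage1, X)
  expect_true(all(as.character(pred$label)[p1 < 0.5] == "TD"))
  expect_true(all(as.character(pred$label)[p1 >= 0.5] != "TD"))
  expect_true(all(as.character(pred$label)[p1 >= 0.5] %in%
                    c("COMBINED", "INATTENTIVE", "HYPERACTIVE")))

  expect_error(fit_two_stage_gbm(feats[labels == "TD", ],
                                 labels[labels == "TD"],
                                 feature_cols = c("x", "y")), "single class")
  expect_error(fit_two_stage_gbm(feats, labels, feature_cols = c("x", "nope")),
               "nope")
})

test_that("adding CUR features to the two-stage model improves specificity", {
  cfg <- tiny_config(design = data.frame(site = "SiteA",
                                         dx = c("TD", "COMBINED", "INATTENTIVE"),
                                         n = c(110L, 50L, 60L)),
                     grid_dims = c(12L, 12L, 8L), n_timepoints = 80L,
                     rng_seed = 77L)
  tpl <- make_brain_template(cfg)
  coh <- simulate_cohort(cfg)
  cur <- t(sapply(seq_len(nrow(coh)), function(i) {
    sc <- simulate_scan(coh[i, ], tpl, cfg)
    suppressMessages(cur_covariance_vector(preprocess_scan(sc, tpl), tpl))$values
  }))
  pheno <- prepare_covariates(coh)
  sp <- split_cohort(seq_len(nrow(coh)), n_test = 70, seed = 1)
  pcs <- pca_reduce(cur[sp$train, ], k = 10)
  scores <- predict(pcs, cur)
  colnames(scores) <- paste0("cur_PC", 1:10)
  base_cols <- c("age", "gender", "handedness", "iq_composite")
  frame <- cbind(pheno[c("subject_id", base_cols)], as.data.frame(scores))

  spec_of <- function(cols) {
    fit <- fit_two_stage_gbm(frame[sp$train, ], coh$dx[sp$train],
                             feature_cols = cols, seed = 4)
    pred <- predict(fit, frame[sp$test, ])
    binary_metrics(as.character(coh$dx[sp$test]),
                   as.character(pred$label))$specificity
  }
  expect_gt(spec_of(c(base_cols, colnames(scores))), spec_of(base_cols))
})
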
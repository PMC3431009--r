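# Synthetic-data generator: template geometry, cohort phenotypes, scans.

test_that("template satisfies its geometric invariants and is deterministic", {
  cfg <- tiny_config()
  tpl <- make_brain_template(cfg)

  # five parcels, disjoint by construction of the label image, each >= 8
  # voxels, all inside the mask
  counts <- table(tpl$parcel_labels[tpl$parcel_labels > 0])
  expect_equal(length(counts), 5L)
  expect_true(all(counts >= 8L))
  expect_true(all(tpl$brain_mask[tpl$parcel_labels > 0]))

  expect_true(all(tpl$brain_mask[tpl$csf_region]))
  expect_true(all(tpl$brain_mask[tpl$periphery]))
  expect_gt(sum(tpl$periphery), 0L)

  seed_lin <- coord_to_linear_test(tpl$seed_coords, tpl$grid_dims)
  expect_true(all(tpl$brain_mask[seed_lin]))
  expect_equal(nrow(tpl$seed_coords), cfg$n_seeds)

  expect_identical(tpl, make_brain_template(cfg))
  tpl2 <- make_brain_template(tiny_config(rng_seed = 99L))
  expect_false(identical(tpl$seed_coords, tpl2$seed_coords))
})

test_that("template construction fails on grids too small for its parts", {
  expect_error(make_brain_template(tiny_config(grid_dims = c(6L, 6L, 4L),
                                               n_seeds = 264L)),
               "too small")
  expect_error(make_brain_template(tiny_config(grid_dims = c(5L, 5L, 4L))),
               "too small")
})

test_that("cohort counts match the design exactly and missingness boundary holds", {
  cfg <- tiny_config(design = data.frame(site = "SiteA",
                                         dx = c("TD", "COMBINED"),
                                         n = c(50L, 50L)),
                     iq_missing_rate = 1)
  coh <- simulate_cohort(cfg)
  expect_equal(as.integer(table(coh$dx)[c("TD", "COMBINED")]), c(50L, 50L))
  expect_true(all(is.na(coh[c("iq_verbal", "iq_performance",
                              "iq_full2", "iq_full4")])))
  expect_identical(coh, simulate_cohort(cfg))
  expect_true(all(coh$age > 0))
})

test_that("cohort IQ means recover the configured group targets", {
  cfg <- tiny_config(design = data.frame(site = "SiteA",
                                         dx = c("TD", "COMBINED"),
                                         n = c(500L, 500L)),
                     iq_mean_td = 110, iq_mean_adhd = 100, iq_sd = 10,
                     iq_measure_sd = 0, iq_missing_rate = 0, site_iq_sd = 0,
                     rng_seed = 31L)
  coh <- simulate_cohort(cfg)
  se3 <- 3 * 10 / sqrt(500)
  expect_lt(abs(mean(coh$iq_verbal[coh$dx == "TD"]) - 110), se3)
  expect_lt(abs(mean(coh$iq_verbal[coh$dx == "COMBINED"]) - 100), se3)
})

test_that("parcel-mean correlations track a strong imposed target", {
  tgt <- diag(5)
  tgt[2, 5] <- tgt[5, 2] <- 0.9   # DM, DL
  dimnames(tgt) <- list(m1_parcels(), m1_parcels())
  cfg <- tiny_config(design = data.frame(site = "SiteA", dx = "TD", n = 3L),
                     subtype_corr = list(TD = tgt), corr_sd = 0,
                     n_timepoints = 500L, rng_seed = 11L)
  tpl <- make_brain_template(cfg)
  coh <- simulate_cohort(cfg)
  for (i in 1:3) {
    cc <- parcel_connectivity(simulate_scan(coh[i, ], tpl, cfg), tpl)
    expect_lt(abs(cc[["DM_DL"]] - 0.9), 0.1)
  }
})

test_that("without motion planting, periphery and interior variances match", {
  cfg <- tiny_config(motion = list(n_motion_voxels = 0L),
                     drift_linear = 0, drift_quadratic = 0)
  tpl <- make_brain_template(cfg)
  coh <- simulate_cohort(cfg)
  sc <- simulate_scan(coh[1, ], tpl, cfg)
  mat <- scan_matrix(sc, tpl)
  v <- apply(mat, 2, var)
  plab <- tpl$parcel_labels[attr(mat, "voxel_index")]
  periph <- tpl$periphery[attr(mat, "voxel_index")]
  ratio <- mean(v[periph & plab == 0]) / mean(v[!periph & plab == 0])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("planted motion voxels exceed the 95th variance percentile", {
  cfg <- tiny_config(motion = list(n_motion_voxels = 10L,
                                   variance_multiplier = 8))
  tpl <- make_brain_template(cfg)
  coh <- simulate_cohort(cfg)
  for (i in 1:5) {
    sc <- simulate_scan(coh[i, ], tpl, cfg)
    mat <- scan_matrix(sc, tpl)
    v <- apply(mat, 2, var)
    planted <- attr(mat, "voxel_index") %in% sc$motion_voxels
    expect_true(all(v[planted] > quantile(v[!planted], 0.95)))
  }
})

test_that("scans are bit-identical under identical config and seed", {
  cfg <- tiny_config()
  tpl <- make_brain_template(cfg)
  coh <- simulate_cohort(cfg)
  s1 <- simulate_scan(coh[2, ], tpl, cfg)
  s2 <- simulate_scan(coh[2, ], tpl, cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$motion_params, s2$motion_params)
  # different sessions of one subject differ but are reproducible
  s3 <- simulate_scan(coh[2, ], tpl, cfg, session = 2L)
  expect_false(identical(s1$data, s3$data))
  expect_identical(s3$data, simulate_scan(coh[2, ], tpl, cfg, session = 2L)$data)
})

test_that("fast connectivity generator recovers an arbitrary PSD target", {
  tgt <- matrix(0.3, 5, 5); diag(tgt) <- 1
  dimnames(tgt) <- list(m1_parcels(), m1_parcels())
  cfg <- tiny_config(design = data.frame(site = "SiteA", dx = "TD", n = 500L),
                     subtype_corr = list(TD = tgt), n_timepoints = 150L,
                     rng_seed = 23L)
  coh <- simulate_cohort(cfg)
  cc <- suppressMessages(simulate_connectivity_cohort(coh, cfg))
  expect_true(all(abs(colMeans(cc) - 0.3) < 0.03))
})

test_that("fast path matches full-scan connectivity in distribution", {
  cfg <- tiny_config(design = data.frame(site = "SiteA", dx = "TD", n = 60L),
                     n_timepoints = 100L, rng_seed = 17L)
  tpl <- make_brain_template(cfg)
  coh <- simulate_cohort(cfg)
  full <- cohort_parcel_connectivity(coh, tpl, cfg)
  fast <- suppressMessages(simulate_connectivity_cohort(coh, cfg))
  # identical latent draws: the paths differ per subject only through the
  # voxel-level noise and the detrend projection the fast path omits
  expect_lt(mean(abs(full - fast)), 0.02)
  expect_lt(max(abs(full - fast)), 0.15)
  expect_lt(max(abs(colMeans(full) - colMeans(fast))), 0.02)
})
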
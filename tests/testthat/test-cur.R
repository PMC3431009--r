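# CUR leverage scores, column selection, covariance features, and the
# peripheral-fraction motion diagnostic.

test_that("leverage scores match closed forms on structured matrices", {
  set.seed(10)
  s <- rnorm(12)
  X <- cbind(2 * s, s, 0)
  sc <- leverage_scores(X, rank_k = 1)
  expect_equal(unname(as.numeric(sc)), c(0.8, 0.2, 0), tolerance = 1e-10)

  # zero-mean orthonormal columns: every column carries unit leverage
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(12 * 5), 12, 5))))[, -1]
  scQ <- leverage_scores(Q, rank_k = 5)
  expect_equal(unname(as.numeric(scQ)), rep(1, 5), tolerance = 1e-8)

  R <- matrix(rnorm(15 * 8), 15, 8)
  for (k in c(1, 3, 8)) {
    expect_equal(sum(leverage_scores(R, k)), k, tolerance = 1e-8)
  }
  expect_true(all(leverage_scores(R, 4) >= 0))

  expect_warning(leverage_scores(X, rank_k = 2), "numerical rank")
  expect_error(leverage_scores(R, rank_k = 9), "rank_k")
})

test_that("top-c selection matches the exhaustive full-SVD oracle", {
  set.seed(11)
  for (case in 1:100) {
    T <- sample(3:12, 1)
    V <- sample(3:12, 1)
    X <- matrix(rnorm(T * V), T, V)
    k <- sample(seq_len(min(T, V) - 1L), 1)
    c <- sample(seq_len(V), 1)
    sc <- leverage_scores(X, rank_k = k)
    expect_equal(as.numeric(sc), leverage_oracle(X, k), tolerance = 1e-8)
    sel <- select_top_columns(sc, c = c)
    oracle_order <- order(-leverage_oracle(X, k), seq_len(V))
    expect_setequal(sel$columns, oracle_order[seq_len(c)])
  }
})

test_that("selection ties break toward the lower column index", {
  expect_equal(select_top_columns(c(0.8, 0.2, 0), c = 1)$columns, 1L)
  expect_equal(select_top_columns(rep(0.5, 6), c = 2)$columns, c(1L, 2L))
  expect_error(select_top_columns(rep(1, 3), c = 4), "exceeds")
})

test_that("leverage is invariant to mean-preserving orthogonal time transforms", {
  set.seed(12)
  X <- matrix(rnorm(20 * 6), 20, 6)
  base <- as.numeric(leverage_scores(X, 3))
  expect_equal(as.numeric(leverage_scores(X[sample(20), ], 3)), base,
               tolerance = 1e-8)
  v <- rnorm(20); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  H <- diag(20) - 2 * tcrossprod(v)   # Householder fixing the constant vector
  expect_equal(as.numeric(leverage_scores(H %*% X, 3)), base, tolerance = 1e-8)
})

test_that("planted high-variance voxels are recovered by top-20 leverage", {
  hits <- 0L; total <- 0L
  for (seed in 1:8) {
    cfg <- tiny_config(motion = list(n_motion_voxels = 20L,
                                     variance_multiplier = 10),
                       grid_dims = c(20L, 20L, 10L),
                       n_timepoints = 80L, rng_seed = seed)
    tpl <- make_brain_template(cfg)
    coh <- simulate_cohort(cfg)
    sc <- simulate_scan(coh[1, ], tpl, cfg)
    mat <- detrend_poly(scan_matrix(sc, tpl))
    sel <- select_top_columns(leverage_scores(mat, rank_k = 20L), c = 20L)
    hits <- hits + length(intersect(sel$grid_indices, sc$motion_voxels))
    total <- total + length(sc$motion_voxels)
  }
  expect_gte(hits / total, 0.95)
})

test_that("covariance vector has c(c+1)/2 entries in row-major upper-triangle order", {
  set.seed(13)
  X <- matrix(rnorm(60 * 100), 60, 100)
  cf <- cur_covariance_vector(X, c = 20L)
  expect_length(cf$values, 210L)
  expect_length(cur_covariance_vector(X, c = 2L)$values, 3L)

  # verify the layout against the selected columns' covariance matrix
  S <- X[, cf$selection$columns]
  Cv <- cov(S)
  k <- 1L
  for (i in 1:20) for (j in i:20) {
    expect_equal(unname(cf$values[k]), Cv[i, j], tolerance = 1e-12)
    k <- k + 1L
  }
  expect_true(all(cf$values[paste0("cov_", 1:20, "_", 1:20)] >= 0))

  # identical dominant series: every entry equals the shared variance
  s <- 10 * rnorm(40)
  Xd <- cbind(s, s, matrix(0.01 * rnorm(40 * 5), 40, 5))
  cfd <- cur_covariance_vector(Xd, c = 2L, rank_k = 1L)
  expect_equal(unname(cfd$values), rep(var(s), 3), tolerance = 1e-10)

  expect_error(cur_covariance_vector(matrix(1, 10, 30), c = 20L), "non-constant")
})

test_that("peripheral fraction flags boundary selections and motion cohorts", {
  cfg <- tiny_config()
  tpl <- make_brain_template(cfg)
  flagged <- which(tpl$periphery | tpl$csf_region)
  interior <- setdiff(which(tpl$brain_mask), flagged)

  mk_sel <- function(idx) {
    structure(list(columns = seq_along(idx), grid_indices = idx,
                   leverage_scores = rep(1, length(idx)),
                   c = length(idx), rank_k = 1L),
              class = "cur_selection")
  }
  expect_equal(peripheral_fraction(mk_sel(flagged[1:5]), tpl), 1.0)
  expect_equal(peripheral_fraction(mk_sel(interior[1:5]), tpl), 0.0)

  frac_for <- function(n_motion) {
    cfg <- tiny_config(design = data.frame(site = "SiteA", dx = "TD", n = 10L),
                       motion = list(n_motion_voxels = n_motion,
                                     variance_multiplier = 10),
                       n_timepoints = 80L, rng_seed = 3L)
    tpl <- make_brain_template(cfg)
    coh <- simulate_cohort(cfg)
    mean(sapply(seq_len(10), function(i) {
      sc <- simulate_scan(coh[i, ], tpl, cfg)
      cf <- cur_covariance_vector(preprocess_scan(sc, tpl), tpl, c = 20L)
      peripheral_fraction(cf$selection, tpl)
    }))
  }
  expect_gt(frac_for(20L), frac_for(0L))
})
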
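# Shared fixtures: small configurations and simulated objects rebuilt in
# code at test time.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    design = data.frame(site = "SiteA", dx = c("TD", "COMBINED"), n = c(4L, 4L)),
    grid_dims = c(12L, 12L, 8L),
    n_seeds = 20L,
    n_timepoints = 40L,
    rng_seed = 7L
  )
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  do.call(generator_config, defaults)
}

# full-scan parcel connectivity for every subject of a cohort
cohort_parcel_connectivity <- function(cohort, template, config) {
  suppressMessages(t(vapply(seq_len(nrow(cohort)), function(i) {
    parcel_connectivity(simulate_scan(cohort[i, ], template, config), template)
  }, numeric(10L))))
}

# independent leverage-score oracle: full SVD of the explicitly centered
# matrix, diagonal of the rank-k right-projection
leverage_oracle <- function(X, rank_k) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  v <- svd(Xc)$v[, seq_len(rank_k), drop = FALSE]
  diag(v %*% t(v))
}

# independent per-subject competition scoring table over all 16 label pairs
competition_rule_table <- function() {
  lv <- dx_levels()
  g <- expand.grid(truth = lv, pred = lv, stringsAsFactors = FALSE)
  g$points <- NA_real_
  for (i in seq_len(nrow(g))) {
    tr <- g$truth[i]; pr <- g$pred[i]
    g$points[i] <- if (tr == pr) 1 else if (tr != "TD" && pr != "TD") 0.5 else 0
  }
  g
}

# covariate frame with no diagnosis signal beyond what the caller injects
make_covariates <- function(n, seed = 1L, iq_shift = rep(0, n)) {
  set.seed(seed)
  data.frame(
    age = round(runif(n, 8, 16), 1),
    iq_composite = rnorm(n, 105, 12) + iq_shift,
    gender = factor(sample(c("F", "M"), n, replace = TRUE)),
    handedness = factor(sample(c("L", "R"), n, replace = TRUE, prob = c(0.1, 0.9))),
    site = factor(sample(c("SiteA", "SiteB"), n, replace = TRUE))
  )
}

coord_to_linear_test <- function(coords, dims) {
  (coords[, 3] - 1L) * dims[1] * dims[2] + (coords[, 2] - 1L) * dims[1] + coords[, 1]
}
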
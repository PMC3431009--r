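# Scan simulation: latent multivariate-normal parcel signals with
# subtype-dependent correlation targets, voxel-level white noise, per-voxel
# polynomial drift, planted heavy-tailed motion voxels, and emitted motion
# nuisance parameters.

# per-subject target correlation matrix: Fisher-z jitter around the group
# target, projected back to the PSD cone if the jitter breaks it
jitter_correlation <- function(R, corr_sd) {
  if (corr_sd <= 0) return(R)
  idx <- which(upper.tri(R))
  z <- atanh(pmin(pmax(R[idx], -0.999), 0.999))
  z <- z + stats::rnorm(length(idx), 0, corr_sd)
  Rj <- R
  Rj[idx] <- tanh(z)
  Rj[lower.tri(Rj)] <- t(Rj)[lower.tri(Rj)]
  ev <- eigen(Rj, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    message("jittered correlation matrix projected to nearest PSD")
    Rj <- project_to_psd(Rj)
  }
  Rj
}

# unit-variance scaled-t time course (heavy tails, df = 3)
scaled_t_course <- function(T, df = 3) {
  stats::rt(T, df = df) / sqrt(df / (df - 2))
}

#' Simulate one subject's 4D BOLD scan
#'
#' Every voxel of one of the five M1 parcels shares that parcel's latent
#' unit-SD signal; the five latent signals are drawn from a multivariate
#' normal whose correlation matrix is the subject's subtype target after
#' Fisher-z jitter (PSD-projected if needed). All mask voxels additionally
#' receive white noise, a random linear + quadratic drift, and non-parcel
#' voxels carry independent unit-SD background signal. `n_motion_voxels`
#' voxels drawn from the periphery/CSF compartments receive a shared
#' heavy-tailed (scaled-t, df 3) motion time course scaled so their variance
#' is approximately `variance_multiplier` times baseline (times
#' `adhd_factor` for ADHD subjects); when `shared_direction` is set the
#' loading signs come from the cohort-level template pattern. Motion
#' nuisance parameters (default 36 columns) are emitted as AR(1) series.
#' Deterministic given the subject's `scan_seed`.
#'
#' @param subject one row of a [simulate_cohort()] data.frame (or a list with
#'   fields `dx`, `site`, `scan_seed`, `subject_id`).
#' @param template a [make_brain_template()] result.
#' @param config the [generator_config()] used for the cohort.
#' @param session session number; shifts the seed so repeated sessions of one
#'   subject differ but remain reproducible.
#' @return An object of class `scan4d`: list with `data` (4D array,
#'   grid x T, zero outside the mask), `tr`, `motion_params` (T x
#'   `n_motion_params`), `motion_voxels` (linear indices of planted voxels),
#'   `subject_id`, `dx`.
#' @export
simulate_scan <- function(subject, template, config, session = 1L) {
  stopifnot(inherits(template, "brain_template"),
            inherits(config, "generator_config"))
  dx <- as.character(subject$dx)
  if (!dx %in% names(config$subtype_corr)) {
    stop("no subtype correlation target for diagnosis ", dx)
  }
  T <- config$n_timepoints
  dims <- template$grid_dims
  mlin <- which(template$brain_mask)
  V <- length(mlin)
  plab <- template$parcel_labels[mlin]           # 0 or 1..5 per masked voxel
  se <- site_effects(config)
  nmult <- se$noise_mult[match(as.character(subject$site), se$site)]
  if (is.na(nmult)) nmult <- 1

  seed <- derive_seed(subject$scan_seed, as.integer(session))
  with_seed(seed, {
    R0 <- config$subtype_corr[[dx]]
    Rj <- jitter_correlation(R0, config$corr_sd)
    L <- matrix(stats::rnorm(T * 5L), T, 5L) %*% chol(Rj)   # T x 5 latent

    # voxel x time matrix over the mask
    X <- matrix(stats::rnorm(V * T), V, T)
    in_parcel <- plab > 0L
    X[in_parcel, ] <- X[in_parcel, , drop = FALSE] * (config$voxel_noise_sd * nmult) +
      t(L)[plab[in_parcel], , drop = FALSE]
    X[!in_parcel, ] <- X[!in_parcel, , drop = FALSE] * nmult

    tl <- seq(-1, 1, length.out = T)
    tq <- tl^2 - mean(tl^2)
    a <- stats::rnorm(V, 0, config$drift_linear)
    b <- stats::rnorm(V, 0, config$drift_quadratic)
    X <- X + outer(a, tl) + outer(b, tq)

    chosen <- integer(0)
    mot <- config$motion
    if (mot$n_motion_voxels > 0L && mot$variance_multiplier > 1) {
      cand <- as.integer(names(template$motion_sign))
      k <- min(mot$n_motion_voxels, length(cand))
      pick <- sample.int(length(cand), k)
      chosen <- cand[pick]
      mult_eff <- mot$variance_multiplier * if (dx != "TD") mot$adhd_factor else 1
      sgn <- if (isTRUE(mot$shared_direction)) {
        template$motion_sign[pick]
      } else {
        sample(c(-1L, 1L), k, replace = TRUE)
      }
      m <- scaled_t_course(T)
      rows <- match(chosen, mlin)
      X[rows, ] <- X[rows, , drop = FALSE] +
        outer(as.numeric(sgn) * sqrt(mult_eff - 1), m)
    }

    motion_params <- sapply(seq_len(config$n_motion_params), function(j) {
      as.numeric(stats::filter(stats::rnorm(T, 0, 0.05), 0.95, "recursive"))
    })

    arr <- array(0, dim = c(dims, T))
    arr[rep(mlin, T) + rep.int((seq_len(T) - 1L) * prod(dims), rep.int(V, T))] <- X

    structure(
      list(data = arr, tr = config$tr, motion_params = motion_params,
           motion_voxels = chosen, subject_id = subject$subject_id, dx = dx),
      class = "scan4d"
    )
  })
}

#' Extract the time-by-voxel matrix of a scan over the brain mask
#'
#' @param scan a `scan4d`.
#' @param template the matching `brain_template`.
#' @return T x V numeric matrix with attribute `voxel_index` giving the
#'   1-based linear grid index of each column.
#' @export
scan_matrix <- function(scan, template) {
  stopifnot(inherits(scan, "scan4d"), inherits(template, "brain_template"))
  dims <- template$grid_dims
  T <- dim(scan$data)[4]
  mlin <- which(template$brain_mask)
  V <- length(mlin)
  idx <- rep(mlin, T) + rep.int((seq_len(T) - 1L) * prod(dims), rep.int(V, T))
  out <- t(matrix(scan$data[idx], V, T))
  attr(out, "voxel_index") <- mlin
  attr(out, "tr") <- scan$tr
  out
}

# rebuild a scan4d from a processed T x V masked matrix
matrix_to_scan <- function(mat, template, scan) {
  dims <- template$grid_dims
  T <- nrow(mat)
  mlin <- attr(mat, "voxel_index")
  V <- length(mlin)
  arr <- array(0, dim = c(dims, T))
  arr[rep(mlin, T) + rep.int((seq_len(T) - 1L) * prod(dims), rep.int(V, T))] <- t(mat)
  out <- scan
  out$data <- arr
  out
}

#' @export
print.scan4d <- function(x, ...) {
  d <- dim(x$data)
  cat("scan4d:", x$subject_id, paste(d[1:3], collapse = "x"), "grid,",
      d[4], "volumes, TR", x$tr, "s,", length(x$motion_voxels),
      "planted motion voxels\n")
  invisible(x)
}

#' Fast generator of per-subject parcel correlation vectors
#'
#' Draws each subject's 10 inter-parcel correlations from the same
#' statistical model as [simulate_scan()] — subtype target matrix, Fisher-z
#' jitter, T samples of the latent 5-signal process, sample Pearson
#' correlations — but skips the voxel stage (whose white noise perturbs
#' parcel means by under 1% with default settings). Useful for simulation
#' studies that need thousands of subjects, e.g. p-value calibration of the
#' association models.
#'
#' @param cohort a [simulate_cohort()] data.frame.
#' @param config the matching [generator_config()].
#' @return n x 10 matrix of sample correlations, columns in canonical pair
#'   order, rownames = subject ids.
#' @export
simulate_connectivity_cohort <- function(cohort, config) {
  stopifnot(inherits(config, "generator_config"))
  T <- config$n_timepoints
  out <- t(vapply(seq_len(nrow(cohort)), function(i) {
    dx <- as.character(cohort$dx[i])
    with_seed(derive_seed(cohort$scan_seed[i], 1L), {
      Rj <- jitter_correlation(config$subtype_corr[[dx]], config$corr_sd)
      L <- matrix(stats::rnorm(T * 5L), T, 5L) %*% chol(Rj)
      matrix_to_pair_vector(stats::cor(L))
    })
  }, numeric(10L)))
  rownames(out) <- cohort$subject_id
  colnames(out) <- m1_pair_labels()
  out
}
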
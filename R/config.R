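# Generator configuration: the single object that defines the statistical
# conditions of a simulated cohort.

#' Default site-by-subtype cohort design
#'
#' Emulates the site imbalance of the ADHD-200 training sample at a reduced
#' scale: one roughly balanced site, one ADHD-heavy site, and one
#' controls-only site (as Pittsburgh and Washington University contributed
#' only controls). The hyperactive/impulsive subtype is rare, as observed.
#'
#' @param scale positive multiplier applied to all counts (rounded).
#' @return data.frame with columns `site`, `dx`, `n`.
#' @export
default_cohort_design <- function(scale = 1) {
  d <- data.frame(
    site = rep(c("SiteA", "SiteB", "SiteC"), times = c(4L, 4L, 1L)),
    dx = c("TD", "COMBINED", "HYPERACTIVE", "INATTENTIVE",
           "TD", "COMBINED", "HYPERACTIVE", "INATTENTIVE",
           "TD"),
    n = c(25L, 10L, 2L, 8L,
          20L, 12L, 2L, 11L,
          30L),
    stringsAsFactors = FALSE
  )
  d$n <- as.integer(round(d$n * scale))
  d
}

#' Generator configuration for synthetic rs-fMRI cohorts
#'
#' Bundles every parameter of the synthetic-data model: the site-by-subtype
#' design, per-subtype inter-parcel correlation targets, between-subject
#' correlation jitter, scan geometry and length, noise and drift levels,
#' phenotype distributions with site-dependent IQ missingness, and the planted
#' motion-artifact model.
#'
#' @param design data.frame with columns `site`, `dx`, `n` (counts per cell).
#' @param grid_dims integer 3-vector of voxel grid dimensions.
#' @param n_seeds number of seed voxels placed in the brain mask (default 264,
#'   matching the whole-brain seed set used for the seed-connectivity model).
#' @param subtype_corr named list of 5x5 target correlation matrices, one per
#'   diagnosis level; defaults to the empirical group means
#'   ([default_subtype_targets()]).
#' @param corr_sd between-subject jitter SD applied on the Fisher-z scale to
#'   each subject's target correlations (default 0.2, matching the observed
#'   between-subject SDs of roughly 0.15-0.21).
#' @param n_timepoints scan length T (default 150 volumes).
#' @param tr repetition time in seconds (default 2).
#' @param voxel_noise_sd SD of voxel-level white noise added on top of the
#'   unit-SD latent parcel signals (default 0.2, kept low so the imposed
#'   parcel-level correlations survive spatial averaging).
#' @param drift_linear,drift_quadratic SDs of the per-voxel random linear and
#'   quadratic drift coefficients (signal-SD units over the scan).
#' @param iq_mean_td,iq_mean_adhd,iq_sd latent composite-IQ distribution by
#'   diagnosis (defaults 110 / 100 / 15: ADHD roughly two-thirds of a
#'   population SD below controls, as seen in the sample).
#' @param iq_measure_sd measurement SD of each individual IQ instrument around
#'   the subject's latent IQ.
#' @param iq_missing_rate probability that any single IQ measure is missing;
#'   scalar or named per-site vector (default 0.05 / 0.15 / 0.30 for the
#'   three default sites, emulating site-dependent missingness).
#' @param p_male_td,p_male_adhd probability of male gender by diagnosis
#'   (ADHD-heavy sites skew male in the real sample).
#' @param p_left_handed probability of left handedness.
#' @param age_mean,age_sd,age_range age distribution (years), truncated.
#' @param site_iq_sd SD of the additive per-site IQ offset.
#' @param site_noise_sd SD of the per-site log noise multiplier on scan noise.
#' @param n_sessions scanning sessions per subject (features are averaged
#'   across sessions downstream).
#' @param motion list with `n_motion_voxels` (planted high-variance voxels per
#'   scan), `variance_multiplier` (target variance ratio of planted voxels to
#'   baseline), `shared_direction` (logical; planted loadings share one
#'   cohort-level sign pattern), and `adhd_factor` (extra variance multiplier
#'   for ADHD subjects, so in-scanner motion differs by diagnostic group).
#' @param n_motion_params number of emitted motion nuisance parameters
#'   (default 36).
#' @param rng_seed integer seed governing every random draw in the generator.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(design = default_cohort_design(),
                             grid_dims = c(20L, 20L, 10L),
                             n_seeds = 264L,
                             subtype_corr = default_subtype_targets(),
                             corr_sd = 0.2,
                             n_timepoints = 150L,
                             tr = 2,
                             voxel_noise_sd = 0.2,
                             drift_linear = 1,
                             drift_quadratic = 0.5,
                             iq_mean_td = 110,
                             iq_mean_adhd = 100,
                             iq_sd = 15,
                             iq_measure_sd = 5,
                             iq_missing_rate = c(SiteA = 0.05, SiteB = 0.15, SiteC = 0.30),
                             p_male_td = 0.55,
                             p_male_adhd = 0.75,
                             p_left_handed = 0.1,
                             age_mean = 12,
                             age_sd = 3,
                             age_range = c(7, 20),
                             site_iq_sd = 2,
                             site_noise_sd = 0.05,
                             n_sessions = 1L,
                             motion = list(n_motion_voxels = 10L,
                                           variance_multiplier = 8,
                                           shared_direction = TRUE,
                                           adhd_factor = 2),
                             n_motion_params = 36L,
                             rng_seed = 1L) {
  stopifnot(is.data.frame(design), all(c("site", "dx", "n") %in% names(design)))
  if (!all(design$dx %in% dx_levels())) {
    stop("design$dx must be in {", paste(dx_levels(), collapse = ", "), "}")
  }
  if (any(design$n < 0)) stop("design counts must be >= 0")
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L))
  stopifnot(corr_sd >= 0, voxel_noise_sd >= 0, drift_linear >= 0,
            drift_quadratic >= 0, iq_sd >= 0, iq_measure_sd >= 0,
            site_iq_sd >= 0, site_noise_sd >= 0)
  stopifnot(all(iq_missing_rate >= 0), all(iq_missing_rate <= 1))
  stopifnot(p_male_td >= 0, p_male_td <= 1, p_male_adhd >= 0, p_male_adhd <= 1,
            p_left_handed >= 0, p_left_handed <= 1)
  stopifnot(n_timepoints >= 2L, tr > 0, n_sessions >= 1L)
  need <- unique(design$dx)
  if (!all(need %in% names(subtype_corr))) {
    stop("subtype_corr missing entries for: ",
         paste(setdiff(need, names(subtype_corr)), collapse = ", "))
  }
  for (g in names(subtype_corr)) {
    M <- subtype_corr[[g]]
    stopifnot(is.matrix(M), nrow(M) == 5L, ncol(M) == 5L)
    if (max(abs(M - t(M))) > 1e-10) stop("subtype_corr[[", g, "]] not symmetric")
    if (max(abs(diag(M) - 1)) > 1e-10) stop("subtype_corr[[", g, "]] diagonal != 1")
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("subtype_corr[[", g, "]] is not positive semi-definite")
    }
  }
  stopifnot(is.list(motion))
  motion <- utils::modifyList(
    list(n_motion_voxels = 10L, variance_multiplier = 8,
         shared_direction = TRUE, adhd_factor = 2),
    motion
  )
  stopifnot(motion$n_motion_voxels >= 0L, motion$variance_multiplier >= 0,
            motion$adhd_factor > 0)
  structure(
    list(design = design, grid_dims = grid_dims, n_seeds = as.integer(n_seeds),
         subtype_corr = subtype_corr, corr_sd = corr_sd,
         n_timepoints = as.integer(n_timepoints), tr = tr,
         voxel_noise_sd = voxel_noise_sd, drift_linear = drift_linear,
         drift_quadratic = drift_quadratic, iq_mean_td = iq_mean_td,
         iq_mean_adhd = iq_mean_adhd, iq_sd = iq_sd,
         iq_measure_sd = iq_measure_sd, iq_missing_rate = iq_missing_rate,
         p_male_td = p_male_td, p_male_adhd = p_male_adhd,
         p_left_handed = p_left_handed, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, site_iq_sd = site_iq_sd,
         site_noise_sd = site_noise_sd, n_sessions = as.integer(n_sessions),
         motion = motion, n_motion_params = as.integer(n_motion_params),
         rng_seed = as.integer(rng_seed)),
    class = "generator_config"
  )
}

#' Null-generator configuration
#'
#' Variant of [generator_config()] in which diagnosis carries no signal:
#' every subtype shares one correlation target (the TD matrix by default),
#' IQ, gender, and motion distributions are identical across groups. Used for
#' calibration checks (p-value uniformity, chance-level classification).
#'
#' @param ... arguments forwarded to [generator_config()].
#' @param corr_target single 5x5 correlation matrix shared by all subtypes.
#' @return A `generator_config`.
#' @export
null_generator_config <- function(..., corr_target = m1_correlation_targets("TD")) {
  cfg <- generator_config(...)
  shared <- lapply(dx_levels(), function(g) corr_target)
  names(shared) <- dx_levels()
  cfg$subtype_corr <- shared
  cfg$iq_mean_adhd <- cfg$iq_mean_td
  cfg$p_male_adhd <- cfg$p_male_td
  cfg$motion$adhd_factor <- 1
  cfg
}

# deterministic per-site effects (IQ offset, log noise multiplier)
site_effects <- function(config) {
  sites <- unique(config$design$site)
  with_seed(derive_seed(config$rng_seed, 7L), {
    data.frame(
      site = sites,
      iq_offset = stats::rnorm(length(sites), 0, config$site_iq_sd),
      noise_mult = exp(stats::rnorm(length(sites), 0, config$site_noise_sd)),
      stringsAsFactors = FALSE
    )
  })
}
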
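# Phenotype cohort simulation: site-structured subtype prevalence, age,
# gender, handedness, four IQ instruments with site-dependent missingness.

#' Simulate a phenotype cohort
#'
#' Draws one subject record per design cell count: diagnosis and site exactly
#' as specified in `config$design`, age truncated-normal, gender with a
#' diagnosis-dependent male fraction, handedness, and four IQ instruments
#' (verbal, performance, two full-scale variants) around a latent composite
#' IQ whose mean is lower for ADHD subjects. Each IQ entry is independently
#' missing at its site's configured rate. Every subject receives a
#' deterministic `scan_seed` so scan simulation is reproducible per subject.
#'
#' @param config a [generator_config()].
#' @return A data.frame of class `cohort` with columns `subject_id`, `site`,
#'   `dx` (factor with the four diagnosis levels), `age`, `gender`,
#'   `handedness`, `iq_verbal`, `iq_performance`, `iq_full2`, `iq_full4`,
#'   `n_sessions`, `scan_seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(generator_config())
#' table(coh$site, coh$dx)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  des <- config$design[config$design$n > 0, , drop = FALSE]
  n <- sum(des$n)
  site <- rep(des$site, des$n)
  dx <- rep(des$dx, des$n)
  se <- site_effects(config)
  rate <- config$iq_missing_rate
  if (is.null(names(rate))) {
    rate <- stats::setNames(rep_len(rate, length(unique(site))), unique(site))
  } else if (!all(unique(site) %in% names(rate))) {
    rate <- stats::setNames(rep_len(unname(rate)[1], length(unique(site))), unique(site))
  }

  with_seed(derive_seed(config$rng_seed, 1L), {
    is_adhd <- dx != "TD"
    age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                     config$age_range[1]), config$age_range[2])
    p_male <- ifelse(is_adhd, config$p_male_adhd, config$p_male_td)
    gender <- ifelse(stats::runif(n) < p_male, "M", "F")
    handedness <- ifelse(stats::runif(n) < config$p_left_handed, "L", "R")
    iq_lat <- stats::rnorm(
      n,
      ifelse(is_adhd, config$iq_mean_adhd, config$iq_mean_td) +
        se$iq_offset[match(site, se$site)],
      config$iq_sd
    )
    iq <- sapply(1:4, function(j) iq_lat + stats::rnorm(n, 0, config$iq_measure_sd))
    miss_p <- rate[site]
    for (j in 1:4) iq[stats::runif(n) < miss_p, j] <- NA_real_
    scan_seed <- sample.int(2147483646L, n)
    out <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      site = factor(site),
      dx = factor(dx, levels = dx_levels()),
      age = round(age, 2),
      gender = factor(gender, levels = c("F", "M")),
      handedness = factor(handedness, levels = c("L", "R")),
      iq_verbal = round(iq[, 1], 1),
      iq_performance = round(iq[, 2], 1),
      iq_full2 = round(iq[, 3], 1),
      iq_full4 = round(iq[, 4], 1),
      n_sessions = config$n_sessions,
      scan_seed = scan_seed,
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort", "data.frame")
    out
  })
}
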
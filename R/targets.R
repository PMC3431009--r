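# Canonical motor-network (M1) parcellation constants and the empirical
# group-mean inter-parcel correlation targets from the ADHD-200 training
# sample. The five M1 parcels follow the dorsomedial-to-ventrolateral
# organisation of the motor homunculus: ventrolateral (VL, oro-motor),
# dorsomedial (DM, trunk/lower limb), posterior lateral (PL), anterior
# lateral (AL), and dorsolateral (DL, upper limb).

#' Canonical M1 parcel names
#'
#' Fixed parcel order used everywhere a 5-region motor parcellation appears:
#' VL, DM, PL, AL, DL. All pairwise outputs follow the induced
#' `utils::combn()` pair order.
#'
#' @return Character vector of length 5.
#' @export
m1_parcels <- function() c("VL", "DM", "PL", "AL", "DL")

#' Canonical M1 parcel-pair labels
#'
#' The 10 unordered parcel pairs in canonical order:
#' VL_DM, VL_PL, VL_AL, VL_DL, DM_PL, DM_AL, DM_DL, PL_AL, PL_DL, AL_DL.
#'
#' @return Character vector of length 10.
#' @export
m1_pair_labels <- function() {
  p <- m1_parcels()
  idx <- utils::combn(5L, 2L)
  paste(p[idx[1L, ]], p[idx[2L, ]], sep = "_")
}

# pair-value vectors in canonical pair order, per diagnostic group
.m1_target_rows <- list(
  OVERALL     = c(0.115, 0.344, 0.183, 0.277, -0.002, 0.272, 0.146, 0.450, 0.229, 0.187),
  TD          = c(0.134, 0.349, 0.192, 0.284, -0.007, 0.279, 0.168, 0.456, 0.241, 0.179),
  COMBINED    = c(0.084, 0.349, 0.192, 0.281,  0.008, 0.289, 0.084, 0.469, 0.210, 0.171),
  INATTENTIVE = c(0.103, 0.317, 0.185, 0.249, -0.015, 0.266, 0.120, 0.449, 0.239, 0.175)
)

.m1_target_sds <- list(
  OVERALL     = c(0.206, 0.184, 0.204, 0.191, 0.189, 0.207, 0.201, 0.182, 0.205, 0.187),
  TD          = c(0.207, 0.182, 0.203, 0.188, 0.183, 0.205, 0.200, 0.174, 0.201, 0.189),
  COMBINED    = c(0.209, 0.173, 0.198, 0.185, 0.196, 0.201, 0.194, 0.174, 0.201, 0.198),
  INATTENTIVE = c(0.210, 0.183, 0.191, 0.203, 0.187, 0.213, 0.199, 0.201, 0.201, 0.148)
)

#' Build a 5x5 correlation matrix from a 10-vector of pair values
#'
#' @param values numeric vector of length 10 in canonical pair order.
#' @return A 5x5 correlation matrix with parcel dimnames.
#' @export
pair_vector_to_matrix <- function(values) {
  stopifnot(length(values) == 10L)
  p <- m1_parcels()
  idx <- utils::combn(5L, 2L)
  M <- diag(5)
  for (k in seq_len(10L)) {
    M[idx[1L, k], idx[2L, k]] <- values[k]
    M[idx[2L, k], idx[1L, k]] <- values[k]
  }
  dimnames(M) <- list(p, p)
  M
}

# inverse of pair_vector_to_matrix: extract canonical pair vector
matrix_to_pair_vector <- function(M) {
  idx <- utils::combn(5L, 2L)
  out <- M[cbind(idx[1L, ], idx[2L, ])]
  names(out) <- m1_pair_labels()
  out
}

#' Empirical M1 inter-parcel correlation targets by diagnostic group
#'
#' Group-mean resting-state correlations between the five M1 parcels observed
#' in the ADHD-200 training sample, as a correlation matrix. Groups are the
#' overall sample, typically developing controls (TD), ADHD combined type,
#' and ADHD inattentive type. These are the default generator targets.
#'
#' @param group one of `"OVERALL"`, `"TD"`, `"COMBINED"`, `"INATTENTIVE"`.
#' @param what `"mean"` for the correlation matrix of group means, `"sd"` for
#'   the 10-vector of between-subject standard deviations.
#' @return A 5x5 correlation matrix (`what = "mean"`) or named 10-vector.
#' @export
#' @examples
#' m1_correlation_targets("COMBINED")["DM", "DL"]  # 0.084
m1_correlation_targets <- function(group = c("OVERALL", "TD", "COMBINED", "INATTENTIVE"),
                                   what = c("mean", "sd")) {
  group <- match.arg(group)
  what <- match.arg(what)
  if (what == "sd") {
    out <- .m1_target_sds[[group]]
    names(out) <- m1_pair_labels()
    return(out)
  }
  pair_vector_to_matrix(.m1_target_rows[[group]])
}

#' Default per-subtype generator correlation targets
#'
#' One 5x5 target matrix per diagnosis level. The hyperactive/impulsive
#' subtype (about 1% of the ADHD-200 sample) has no published group row and
#' defaults to the overall-sample matrix.
#'
#' @return Named list of four correlation matrices
#'   (`TD`, `COMBINED`, `HYPERACTIVE`, `INATTENTIVE`).
#' @export
default_subtype_targets <- function() {
  list(
    TD          = m1_correlation_targets("TD"),
    COMBINED    = m1_correlation_targets("COMBINED"),
    HYPERACTIVE = m1_correlation_targets("OVERALL"),
    INATTENTIVE = m1_correlation_targets("INATTENTIVE")
  )
}

#' Diagnosis factor levels
#'
#' @return `c("TD", "COMBINED", "HYPERACTIVE", "INATTENTIVE")`.
#' @export
dx_levels <- function() c("TD", "COMBINED", "HYPERACTIVE", "INATTENTIVE")
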
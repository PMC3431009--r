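# Parcel-mean and seed-based connectivity features, PCA reduction, and
# within-subject session averaging.

#' Mean time course of each M1 parcel
#'
#' @param scan a `scan4d`.
#' @param template the matching `brain_template`.
#' @return T x 5 matrix, columns in canonical parcel order (VL, DM, PL, AL,
#'   DL).
#' @export
parcel_mean_timecourses <- function(scan, template) {
  mat <- scan_matrix(scan, template)
  plab <- template$parcel_labels[attr(mat, "voxel_index")]
  out <- sapply(seq_len(5L), function(p) {
    cols <- which(plab == p)
    if (length(cols) == 0L) {
      stop("parcel ", m1_parcels()[p], " is empty within the brain mask")
    }
    rowMeans(mat[, cols, drop = FALSE])
  })
  colnames(out) <- m1_parcels()
  attr(out, "tr") <- scan$tr
  out
}

#' Pairwise Pearson correlations of time-course columns
#'
#' All unordered column pairs in canonical (`utils::combn`) order. For a
#' 5-column M1 matrix this is the 10-vector in the canonical pair order.
#'
#' @param tcs T x p matrix of time courses (columns named).
#' @return Named numeric vector of length `p (p - 1) / 2` with values in
#'   `[-1, 1]`.
#' @export
pairwise_correlations <- function(tcs) {
  tcs <- as.matrix(tcs)
  p <- ncol(tcs)
  if (p < 2L) stop("need at least two columns")
  sds <- apply(tcs, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(tcs)[sds == 0], collapse = ", "))
  }
  C <- stats::cor(tcs)
  idx <- utils::combn(p, 2L)
  out <- C[cbind(idx[1L, ], idx[2L, ])]
  nm <- colnames(tcs)
  if (is.null(nm)) nm <- paste0("c", seq_len(p))
  names(out) <- paste(nm[idx[1L, ]], nm[idx[2L, ]], sep = "_")
  out
}

#' Seed-based connectivity vector
#'
#' For each seed voxel, averages the masked voxel time courses within
#' `radius` (Euclidean, voxel units; radius 0 keeps the seed's own series),
#' then returns the upper-triangle (diagonal excluded) Pearson correlations
#' of the seed-by-seed matrix.
#'
#' @param scan a `scan4d`.
#' @param template the matching `brain_template` (supplies `seed_coords`).
#' @param radius sphere radius in voxels (default 1).
#' @return Named numeric vector of length `s (s - 1) / 2` for `s` seeds.
#' @export
seed_connectivity_vector <- function(scan, template, radius = 1) {
  mat <- scan_matrix(scan, template)
  dims <- template$grid_dims
  vox <- linear_to_coord(attr(mat, "voxel_index"), dims)
  seeds <- template$seed_coords
  s <- nrow(seeds)
  courses <- sapply(seq_len(s), function(i) {
    d2 <- (vox[, 1] - seeds[i, 1])^2 + (vox[, 2] - seeds[i, 2])^2 +
      (vox[, 3] - seeds[i, 3])^2
    cols <- which(d2 <= radius^2 + 1e-9)
    if (length(cols) == 0L) stop("seed ", i, " has no masked voxels within radius")
    rowMeans(mat[, cols, drop = FALSE])
  })
  colnames(courses) <- sprintf("s%03d", seq_len(s))
  pairwise_correlations(courses)
}

#' PCA reduction by column-centered SVD
#'
#' Centers columns and takes the top-`k` singular triplets; scores are
#' `U_k d_k`, loadings the right singular vectors. Component signs are fixed
#' deterministically (largest-magnitude loading entry positive). When the
#' feature dimension greatly exceeds the sample count, the decomposition is
#' computed from the n x n Gram matrix for speed.
#'
#' @param features n x d numeric matrix (subjects in rows).
#' @param k number of components (default 10); `k <= min(n, d)`.
#' @return Object of class `pca_reduction`: `scores` (n x k), `loadings`
#'   (d x k, orthonormal), `center`, `sdev` (singular values scaled by
#'   `1/sqrt(n - 1)`), `k`.
#' @export
pca_reduce <- function(features, k = 10L) {
  X <- as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (k > min(n, d)) {
    stop("k = ", k, " exceeds min(n, d) = ", min(n, d))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (d > 4L * n) {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    dv <- sqrt(pmax(e$values[seq_len(k)], 0))
    U <- e$vectors[, seq_len(k), drop = FALSE]
    V <- crossprod(Xc, U)
    V <- sweep(V, 2L, ifelse(dv > 1e-12, dv, 1), "/")
    V[, dv <= 1e-12] <- 0
  } else {
    sv <- svd(Xc, nu = k, nv = k)
    dv <- sv$d[seq_len(k)]
    U <- sv$u
    V <- sv$v
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U * rep(dv, each = n)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(V) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, loadings = V, center = ctr,
         sdev = dv / sqrt(max(n - 1L, 1L)), k = k),
    class = "pca_reduction"
  )
}

#' Project new data onto a fitted PCA reduction
#'
#' @param object a `pca_reduction`.
#' @param newdata matrix with the same columns as the training features.
#' @param ... unused.
#' @return n_new x k score matrix.
#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  sweep(X, 2L, object$center) %*% object$loadings
}

#' Average feature rows within subject across sessions
#'
#' @param rows data.frame with a `subject_id` column and numeric feature
#'   columns, one row per session, or a list of such data.frames (one per
#'   session) with identical column sets.
#' @return data.frame with one row per subject (order of first appearance),
#'   features averaged arithmetically.
#' @export
average_sessions <- function(rows) {
  if (is.list(rows) && !is.data.frame(rows)) {
    nms <- lapply(rows, names)
    if (!all(vapply(nms, identical, logical(1), nms[[1]]))) {
      stop("session tables have mismatched feature sets")
    }
    rows <- do.call(rbind, rows)
  }
  stopifnot(is.data.frame(rows), "subject_id" %in% names(rows))
  feat_cols <- setdiff(names(rows), "subject_id")
  if (!all(vapply(rows[feat_cols], is.numeric, logical(1)))) {
    stop("all feature columns must be numeric")
  }
  ids <- unique(rows$subject_id)
  g <- factor(rows$subject_id, levels = ids)
  M <- rowsum(as.matrix(rows[feat_cols]), g) / as.vector(table(g))
  out <- data.frame(subject_id = ids, M, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Parcel connectivity vector of a scan
#'
#' Convenience extractor: parcel-mean time courses, polynomial detrend
#' (removing the generator's drift terms), then the canonical 10 pairwise
#' correlations.
#'
#' @param scan a `scan4d`.
#' @param template the matching `brain_template`.
#' @param detrend_order polynomial detrend order (default 2).
#' @return Named numeric vector of length 10.
#' @export
parcel_connectivity <- function(scan, template, detrend_order = 2L) {
  tcs <- parcel_mean_timecourses(scan, template)
  pairwise_correlations(detrend_poly(tcs, order = detrend_order))
}
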
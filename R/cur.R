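# CUR-decomposition feature extraction: statistical leverage scores over
# voxel columns, deterministic top-c column selection, the covariance
# feature vector of the selected time courses, and the peripheral-fraction
# motion diagnostic.

# right singular vectors of the column-centered matrix, via the smaller of
# the two Gram problems; returns list(v = V x r matrix, d = singular values)
centered_right_singular <- function(X) {
  Xc <- sweep(as.matrix(X), 2L, colMeans(X))
  T <- nrow(Xc); V <- ncol(Xc)
  if (V <= T) {
    sv <- svd(Xc, nu = 0)
    list(v = sv$v, d = sv$d)
  } else {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    keep <- seq_len(min(T, V))
    U <- e$vectors[, keep, drop = FALSE]
    d <- d[keep]
    Vm <- crossprod(Xc, U)
    Vm <- sweep(Vm, 2L, ifelse(d > 1e-12, d, 1), "/")
    Vm[, d <= 1e-12] <- 0
    list(v = Vm, d = d)
  }
}

#' Statistical leverage scores of time-course columns
#'
#' The leverage score of column `j` is the squared mass of its entries in
#' the top `rank_k` right singular vectors of the column-centered matrix:
#' `score_j = sum_{i <= rank_k} v_{ji}^2`. Scores are non-negative and sum
#' to `rank_k`. This is the column-importance measure of CUR decomposition.
#'
#' @param X T x V matrix (time in rows, voxels/series in columns).
#' @param rank_k subspace rank used for the scores; reduced to the numerical
#'   rank with a warning if it exceeds it.
#' @return Numeric vector of length V with attributes `rank_k` and (when `X`
#'   carries one) `voxel_index`.
#' @export
leverage_scores <- function(X, rank_k) {
  X <- as.matrix(X)
  if (rank_k < 1L || rank_k > min(dim(X))) {
    stop("rank_k must be in 1..min(T, V) = ", min(dim(X)))
  }
  rs <- centered_right_singular(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(rs$d, 0)
  num_rank <- sum(rs$d > tol)
  if (rank_k > num_rank) {
    warning("rank_k = ", rank_k, " exceeds numerical rank ", num_rank,
            "; using rank ", num_rank)
    rank_k <- num_rank
  }
  scores <- rowSums(rs$v[, seq_len(rank_k), drop = FALSE]^2)
  attr(scores, "rank_k") <- rank_k
  vi <- attr(X, "voxel_index")
  if (!is.null(vi)) attr(scores, "voxel_index") <- vi
  scores
}

#' Select the top-scoring columns
#'
#' Deterministic top-`c` selection by leverage score; ties are broken by the
#' lower column (voxel linear) index.
#'
#' @param scores output of [leverage_scores()] (or any per-column scores).
#' @param c number of columns to select (default 20).
#' @return Object of class `cur_selection`: `columns` (indices into the
#'   score vector), `grid_indices` (1-based linear voxel indices, when
#'   available), `leverage_scores`, `c`, `rank_k`.
#' @export
select_top_columns <- function(scores, c = 20L) {
  V <- length(scores)
  if (c > V) stop("c = ", c, " exceeds number of columns ", V)
  ord <- order(-as.numeric(scores), seq_len(V))
  cols <- sort(ord[seq_len(c)])
  vi <- attr(scores, "voxel_index")
  structure(
    list(columns = cols,
         grid_indices = if (!is.null(vi)) vi[cols] else cols,
         leverage_scores = as.numeric(scores), c = as.integer(c),
         rank_k = attr(scores, "rank_k")),
    class = "cur_selection"
  )
}

#' CUR covariance feature vector of a scan
#'
#' Selects the `c` masked voxel time courses with the highest leverage
#' scores (rank `rank_k`) and returns the row-major upper triangle,
#' including the diagonal, of their c x c covariance matrix: `c (c + 1) / 2`
#' values (210 for the default c = 20), the diagonal carrying the selected
#' voxels' variances.
#'
#' @param x a `scan4d` (requires `template`) or a T x V matrix.
#' @param template the matching `brain_template` when `x` is a scan.
#' @param c number of voxels to select (default 20).
#' @param rank_k leverage rank (default `c`).
#' @return List of class `cur_features`: `values` (named numeric,
#'   length `c (c + 1) / 2`), `selection` (a `cur_selection`),
#'   `subject_id`.
#' @export
cur_covariance_vector <- function(x, template = NULL, c = 20L, rank_k = c) {
  if (inherits(x, "scan4d")) {
    if (is.null(template)) stop("template required for a scan input")
    subject_id <- x$subject_id
    mat <- scan_matrix(x, template)
  } else {
    subject_id <- NA_character_
    mat <- as.matrix(x)
  }
  if (ncol(mat) < c) stop("fewer than c = ", c, " voxels available")
  sds <- sqrt(colMeans(mat^2) - colMeans(mat)^2)
  if (sum(sds > 0) < c) {
    stop("fewer than c = ", c, " non-constant voxel time courses")
  }
  scores <- leverage_scores(mat, rank_k = rank_k)
  sel <- select_top_columns(scores, c = c)
  S <- mat[, sel$columns, drop = FALSE]
  Cv <- stats::cov(S)
  vals <- Cv[lower.tri(Cv, diag = TRUE)]   # row-major upper triangle
  ij <- which(lower.tri(Cv, diag = TRUE), arr.ind = TRUE)
  names(vals) <- paste0("cov_", ij[, 2L], "_", ij[, 1L])
  structure(list(values = vals, selection = sel, subject_id = subject_id),
            class = "cur_features")
}

#' Fraction of selected voxels in peripheral or CSF compartments
#'
#' The motion diagnostic: selected high-leverage voxels concentrating at the
#' brain-mask edge or in CSF indicate residual in-scanner motion rather than
#' neural signal.
#'
#' @param selection a `cur_selection` carrying grid voxel indices.
#' @param template the matching `brain_template`.
#' @return Fraction in `[0, 1]`.
#' @export
peripheral_fraction <- function(selection, template) {
  stopifnot(inherits(selection, "cur_selection"),
            inherits(template, "brain_template"))
  idx <- selection$grid_indices
  flagged <- template$periphery | template$csf_region
  mean(flagged[idx])
}
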
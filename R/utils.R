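# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws inside the package do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}

#' Project a symmetric matrix to the nearest correlation matrix
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal; falls back on
#' [Matrix::nearPD()] for the strict nearest-correlation projection. Used when
#' per-subject Fisher-z jitter pushes a target correlation matrix outside the
#' positive semi-definite cone.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param tol smallest admissible eigenvalue before projection triggers.
#' @return A positive semi-definite correlation matrix.
#' @export
project_to_psd <- function(R, tol = 1e-8) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= tol) return(R)
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE, do2eigen = TRUE)$mat)
  dimnames(out) <- dimnames(R)
  out
}

# linear index <-> (i,j,k) coordinate helpers for a 3D grid
coord_to_linear <- function(coords, dims) {
  coords <- matrix(as.integer(coords), ncol = 3)
  (coords[, 3] - 1L) * dims[1] * dims[2] + (coords[, 2] - 1L) * dims[1] + coords[, 1]
}

linear_to_coord <- function(idx, dims) {
  idx0 <- as.integer(idx) - 1L
  k <- idx0 %/% (dims[1] * dims[2])
  r <- idx0 %% (dims[1] * dims[2])
  cbind(r %% dims[1] + 1L, r %/% dims[1] + 1L, k + 1L)
}

# statistical mode with deterministic lexicographic tie-break
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(as.character(x))
  lv <- sort(names(tab)[tab == max(tab)])
  lv[1L]
}
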
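# Synthetic brain template: mask, M1 parcels, seed voxels, CSF and
# periphery compartments shared by a simulated cohort.

# 2x2x2 parcel blocks at fixed fractional positions of the grid; order
# follows m1_parcels(): VL, DM, PL, AL, DL.
.parcel_positions <- rbind(
  VL = c(0.30, 0.50, 0.40),
  DM = c(0.50, 0.50, 0.75),
  PL = c(0.50, 0.70, 0.55),
  AL = c(0.50, 0.30, 0.55),
  DL = c(0.70, 0.50, 0.40)
)

block_voxels <- function(center, dims) {
  lo <- pmax(1L, pmin(dims - 1L, as.integer(round(center))))
  as.matrix(expand.grid(lo[1]:(lo[1] + 1L), lo[2]:(lo[2] + 1L), lo[3]:(lo[3] + 1L)))
}

#' Build a synthetic brain template
#'
#' Constructs the spatial scaffolding shared by all scans of a cohort: an
#' ellipsoidal brain mask inscribed in the voxel grid, five disjoint 8-voxel
#' M1 parcels at fixed anatomically-inspired positions, a central CSF
#' compartment, the one-voxel-deep peripheral shell of the mask, a set of
#' seed voxels sampled uniformly inside the mask, and a fixed cohort-level
#' sign pattern over periphery/CSF voxels used for planted motion artifacts.
#'
#' @param config a [generator_config()]; uses `grid_dims`, `n_seeds`,
#'   `rng_seed`.
#' @return An object of class `brain_template` with elements `grid_dims`,
#'   `brain_mask`, `parcel_labels` (integer array, 0 = unlabelled, 1-5 in
#'   canonical parcel order), `seed_coords` (n_seeds x 3 integer matrix of
#'   1-based voxel coordinates), `csf_region`, `periphery` (logical arrays),
#'   and `motion_sign`.
#' @export
#' @examples
#' tpl <- make_brain_template(generator_config(n_seeds = 50))
#' table(tpl$parcel_labels[tpl$parcel_labels > 0])
make_brain_template <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  dims <- config$grid_dims
  ctr <- (dims + 1) / 2
  ax <- dims / 2

  g <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])))
  r2 <- ((g[, 1] - ctr[1]) / ax[1])^2 + ((g[, 2] - ctr[2]) / ax[2])^2 +
    ((g[, 3] - ctr[3]) / ax[3])^2
  mask <- array(r2 <= 1, dim = dims)

  parcel_labels <- array(0L, dim = dims)
  for (p in seq_len(5L)) {
    vox <- block_voxels(.parcel_positions[p, ] * dims, dims)
    lin <- coord_to_linear(vox, dims)
    if (!all(mask[lin])) {
      stop("grid too small: parcel ", m1_parcels()[p], " falls outside the brain mask")
    }
    if (any(parcel_labels[lin] != 0L)) {
      stop("grid too small: parcel ", m1_parcels()[p], " overlaps another parcel")
    }
    parcel_labels[lin] <- p
  }

  csf <- array(FALSE, dim = dims)
  cc <- block_voxels(ctr, dims)
  csf_lin <- coord_to_linear(cc, dims)
  if (!all(mask[csf_lin])) stop("grid too small: CSF region outside mask")
  if (any(parcel_labels[csf_lin] != 0L)) {
    stop("grid too small: CSF region overlaps a parcel")
  }
  csf[csf_lin] <- TRUE

  # periphery: mask voxels with a 6-neighbour outside the mask or on the edge
  periphery <- array(FALSE, dim = dims)
  mlin <- which(mask)
  mc <- linear_to_coord(mlin, dims)
  on_edge <- rep(FALSE, length(mlin))
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- mc
      nb[, d] <- nb[, d] + s
      out <- nb[, d] < 1L | nb[, d] > dims[d]
      inside <- !out
      nb_lin <- coord_to_linear(nb[inside, , drop = FALSE], dims)
      hit <- rep(TRUE, length(mlin))
      hit[inside] <- !mask[nb_lin]
      on_edge <- on_edge | out | hit
    }
  }
  periphery[mlin[on_edge]] <- TRUE

  if (length(mlin) < config$n_seeds) {
    stop("grid too small: mask has ", length(mlin), " voxels but ",
         config$n_seeds, " seeds requested")
  }
  seed_lin <- with_seed(derive_seed(config$rng_seed, 11L),
                        sort(sample(mlin, config$n_seeds)))
  seed_coords <- linear_to_coord(seed_lin, dims)
  colnames(seed_coords) <- c("x", "y", "z")

  cand <- which(periphery | csf)
  motion_sign <- with_seed(derive_seed(config$rng_seed, 13L),
                           sample(c(-1L, 1L), length(cand), replace = TRUE))
  names(motion_sign) <- cand

  structure(
    list(grid_dims = dims, brain_mask = mask, parcel_labels = parcel_labels,
         seed_coords = seed_coords, csf_region = csf, periphery = periphery,
         motion_sign = motion_sign),
    class = "brain_template"
  )
}

#' @export
print.brain_template <- function(x, ...) {
  cat("brain_template:", paste(x$grid_dims, collapse = "x"), "grid,",
      sum(x$brain_mask), "mask voxels,", nrow(x$seed_coords), "seeds,",
      sum(x$periphery), "periphery,", sum(x$csf_region), "CSF voxels\n")
  invisible(x)
}
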
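# File interchange: NIfTI volumes (RAS+, unit voxels), phenotype CSVs with
# explicit NA encoding, seed-coordinate and motion-parameter TSVs.

#' Write a scan as 4D NIfTI
#'
#' RAS+ orientation with an identity-scaled affine; the repetition time is
#' stored in the fourth pixdim slot.
#'
#' @param scan a `scan4d`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_scan_nifti <- function(scan, path) {
  img <- RNifti::asNifti(scan$data)
  RNifti::pixdim(img) <- c(1, 1, 1, scan$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI into a `scan4d`
#'
#' @param path NIfTI file.
#' @param subject_id identifier to attach.
#' @param motion_params optional T x C matrix (e.g. from
#'   [read_motion_tsv()]).
#' @return A `scan4d`.
#' @export
read_scan_nifti <- function(path, subject_id = NA_character_, motion_params = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  structure(
    list(data = arr, tr = tr, motion_params = motion_params,
         motion_voxels = integer(0), subject_id = subject_id, dx = NA_character_),
    class = "scan4d"
  )
}

#' Write template volumes and seed coordinates
#'
#' Writes `mask.nii.gz`, `parcels.nii.gz`, `csf.nii.gz`, `periphery.nii.gz`
#' (3D label images) and `seeds.tsv` (columns x, y, z, 1-based voxel
#' coordinates) into a directory.
#'
#' @param template a `brain_template`.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_template_nifti <- function(template, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- list(mask = template$brain_mask * 1L,
               parcels = template$parcel_labels,
               csf = template$csf_region * 1L,
               periphery = template$periphery * 1L)
  for (nm in names(vols)) {
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(vols[[nm]]),
                                             dim = template$grid_dims)),
                       file.path(dir, paste0(nm, ".nii.gz")))
  }
  utils::write.table(as.data.frame(template$seed_coords),
                     file.path(dir, "seeds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read seed coordinates from TSV
#'
#' @param path TSV with columns x, y, z.
#' @return Integer matrix with one row per seed.
#' @export
read_seeds_tsv <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("x", "y", "z") %in% names(d)))
  as.matrix(d[, c("x", "y", "z")])
}

#' Write / read a phenotype table as CSV
#'
#' Missing values are written as empty fields and read back as `NA`.
#'
#' @param pheno phenotype data.frame.
#' @param path CSV path.
#' @return The path (write) or the data.frame with factor columns restored
#'   (read).
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  d <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if ("dx" %in% names(d)) d$dx <- factor(d$dx, levels = dx_levels())
  for (cn in intersect(c("site", "gender", "handedness"), names(d))) {
    d[[cn]] <- factor(d[[cn]])
  }
  d
}

#' Write / read motion parameters as TSV (T rows)
#'
#' @param motion_params T x C numeric matrix.
#' @param path TSV path.
#' @return The path (write) or a numeric matrix (read).
#' @export
write_motion_tsv <- function(motion_params, path) {
  utils::write.table(motion_params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = paste0("mp", seq_len(ncol(motion_params))))
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(utils::read.delim(path))
}
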
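# NIfTI and TSV input/output with schema validation. Volumes round-trip
# bit-exact for integer labels and to single-float precision for
# statistical maps (maps are written as float64 to keep them exact).

#' Write a 3D/4D volume to NIfTI-1
#'
#' @param values Numeric or integer array.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size Isotropic voxel edge in mm.
#' @param integer Store as 32-bit integer labels (bit-exact round trip).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, path, voxel_size = 3, integer = FALSE) {
  img <- RNifti::asNifti(if (integer) array(as.integer(values), dim(values))
                         else array(as.double(values), dim(values)))
  RNifti::pixdim(img) <- rep(voxel_size, length(dim(values)))
  RNifti::writeNifti(img, path,
                     datatype = if (integer) "int32" else "double")
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#' @param path NIfTI path.
#' @return Numeric array.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Check that volumes share a spatial grid
#' @param ... Arrays (3D/4D) whose first three dimensions must agree.
#' @return TRUE, invisibly; errors on mismatch.
#' @export
check_grid_alignment <- function(...) {
  dims <- lapply(list(...), function(a) dim(a)[1:3])
  for (i in seq_along(dims)[-1])
    if (!identical(dims[[1]], dims[[i]]))
      imgtx_stop(sprintf("grid shape mismatch: %s vs %s",
                         paste(dims[[1]], collapse = "x"),
                         paste(dims[[i]], collapse = "x")))
  invisible(TRUE)
}

manifest_columns <- c("subject_id", "site", "sex", "group", "age")

#' Write / read a subject manifest TSV
#'
#' @param manifest Data.frame with at least subject_id, site, sex, group,
#'   age.
#' @param path TSV path.
#' @return The path (write) or the validated data.frame (read).
#' @export
write_manifest <- function(manifest, path) {
  miss <- setdiff(manifest_columns, names(manifest))
  if (length(miss))
    imgtx_stop(paste("manifest is missing column(s):", paste(miss, collapse = ", ")))
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(manifest_columns, names(m))
  if (length(miss))
    imgtx_stop(paste("manifest is missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(m$subject_id))
    imgtx_stop("manifest contains duplicate subject_id values")
  if (!is.numeric(m$age) || any(!is.finite(m$age)))
    imgtx_stop("manifest column 'age' must be numeric and finite")
  m
}

#' Write a motion trace TSV (3 translations mm, 3 rotations radians)
#' @param motion t x 6 matrix.
#' @param path TSV path.
#' @export
write_motion <- function(motion, path) {
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Write a generated cohort bundle to disk
#'
#' One 4D NIfTI and one motion TSV per subject, plus the manifest TSV,
#' the integer parcellation NIfTI and the ground-truth JSON.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @param voxel_size Voxel edge in mm.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, voxel_size = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (run in bundle$runs) {
    write_volume(run$data, file.path(dir, paste0(run$subject_id, "_bold.nii.gz")),
                 voxel_size)
    write_motion(run$motion, file.path(dir, paste0(run$subject_id, "_motion.tsv")))
  }
  write_manifest(bundle$manifest, file.path(dir, "manifest.tsv"))
  write_volume(bundle$parcellation$labels, file.path(dir, "parcellation.nii.gz"),
               voxel_size, integer = TRUE)
  truth <- bundle$truth
  jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
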
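# NIfTI affine for the package axis convention. Patient x is positive to the
# LEFT internally, while NIfTI RAS has x positive to the RIGHT, so the first
# axis gets a negative spacing; offsets place the grid center at the world
# origin.
grid_affine <- function(grid) {
  n <- grid$shape; h <- grid$spacing_mm
  aff <- diag(4)
  aff[1, 1] <- -h[1]; aff[1, 4] <- (n[1] - 1) / 2 * h[1]
  aff[2, 2] <- h[2]; aff[2, 4] <- -(n[2] - 1) / 2 * h[2]
  aff[3, 3] <- h[3]; aff[3, 4] <- -(n[3] - 1) / 2 * h[3]
  aff
}

#' Write a volume as NIfTI-1
#'
#' @param vol 3D array.
#' @param grid the [voxel_grid()] it lives on.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype "uint8" for label maps, "float" for scalar volumes.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, grid, path, datatype = "float") {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- grid$spacing_mm  # scale must precede the xform
  aff <- structure(grid_affine(grid), code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume together with its grid
#' @param path NIfTI file path.
#' @return list with `vol` (plain array) and `grid` (a [voxel_grid()]).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  h <- abs(RNifti::pixdim(img))[1:3]
  list(vol = array(as.numeric(img), dim = dim(img)),
       grid = voxel_grid(dim(img), h))
}

#' Write all phantom volumes as NIfTI files
#'
#' Writes `<prefix>_labels.nii.gz` (unsigned 8-bit), `<prefix>_hu.nii.gz`,
#' `<prefix>_activity_v.nii.gz` and `<prefix>_activity_q.nii.gz` (32-bit
#' float).
#'
#' @param phantom a phantom.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return named character vector of paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    labels = file.path(dir, paste0(prefix, "_labels.nii.gz")),
    hu = file.path(dir, paste0(prefix, "_hu.nii.gz")),
    activity_v = file.path(dir, paste0(prefix, "_activity_v.nii.gz")),
    activity_q = file.path(dir, paste0(prefix, "_activity_q.nii.gz")))
  write_volume_nifti(phantom$labels, phantom$grid, paths["labels"], "uint8")
  write_volume_nifti(phantom$hu, phantom$grid, paths["hu"], "float")
  write_volume_nifti(phantom$activity$V, phantom$grid, paths["activity_v"], "float")
  write_volume_nifti(phantom$activity$Q, phantom$grid, paths["activity_q"], "float")
  invisible(paths)
}

#' Serialize a phantom spec to JSON
#' @param spec a [phantom_spec()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass_recursive(spec), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a phantom spec from JSON
#' @param path JSON file written by [write_phantom_spec()] (or hand-written
#'   with the same fields; missing fields take the package defaults).
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(phantom_spec)))]
  if (!is.null(args$fissures)) args$fissures <- do.call(fissure_params, as.list(args$fissures))
  if (!is.null(args$hotspots)) args$hotspots <- lapply(args$hotspots, as.list)
  do.call(phantom_spec, args)
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}
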
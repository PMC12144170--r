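## Volume I/O via NIfTI: greyscale volumes and label maps share the
## grid conventions of the rest of the pipeline.

#' Write a volume or label map as NIfTI
#'
#' @param x a \linkS4class{VoxelVolume} or \linkS4class{LabelMap}.
#' @param file output path (\code{.nii} or \code{.nii.gz}).
#' @return the file path, invisibly.
#' @export
writeVolumeNifti <- function(x, file) {
  arr <- if (is(x, "VoxelVolume")) x@values else x@labels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x@spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI file as a VoxelVolume
#'
#' @param file path to a NIfTI file.
#' @param origin grid origin to attach (mm); NIfTI orientation metadata
#'   is not interpreted beyond the voxel spacing.
#' @return a \linkS4class{VoxelVolume}.
#' @export
readVolumeNifti <- function(file, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(file)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  new("VoxelVolume", dims = as.integer(dim(arr)),
      spacing = as.numeric(sp[1:3]), origin = as.numeric(origin),
      values = arr)
}
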
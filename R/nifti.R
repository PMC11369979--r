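# Thin NIfTI wrappers around RNifti keeping the package's voxel-grid
# convention (caudal = increasing slice index along the slice axis).

#' Write a volume to NIfTI
#'
#' @param values 3-D numeric or logical array.
#' @param path output path (.nii or .nii.gz).
#' @param grid a \code{\link{voxel_grid}} supplying the voxel size.
#' @return the path, invisibly.
#' @export
write_volume <- function(values, path, grid) {
  if (is.logical(values)) values <- values * 1L
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param slice_axis slice axis to record on the returned grid.
#' @return list with \code{values} (array) and \code{grid}.
#' @export
read_volume <- function(path, slice_axis = 3L) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  values <- array(as.numeric(img), dim(img))
  list(values = values, grid = voxel_grid(dim(img), vs, slice_axis))
}

#' Write the cohort table as CSV
#'
#' @param cohort a \code{nigra_cohort}.
#' @param path output CSV path.
#' @param with_latent also append the latent degeneration columns.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, with_latent = FALSE) {
  df <- cohort$subjects
  if (with_latent) {
    df <- cbind(df, cohort$latent[, setdiff(names(cohort$latent),
                                            c("id", "group"))])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
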
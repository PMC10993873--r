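#' Write a 3D map or mask to NIfTI
#'
#' @param vol 3D array (logical masks are stored as 0/1 integers)
#' @param path output path (`.nii` or `.nii.gz`)
#' @param voxel_size voxel dimensions in mm
#' @return the path, invisibly
#' @export
write_volume <- function(vol, path, voxel_size = c(0.45, 0.45, 1.2)) {
  if (is.logical(vol)) vol <- array(as.integer(vol), dim = dim(vol))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D/4D NIfTI volume as a plain array
#'
#' @param path NIfTI file
#' @return array with attribute `voxel_size`
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)
  out
}

#' Write a DSC series (4D) to NIfTI with a JSON timing sidecar
#'
#' @param series a `dsc_series`
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   `.json`
#' @param voxel_size spatial voxel dimensions in mm
#' @return the path, invisibly
#' @export
write_dsc <- function(series, path, voxel_size = c(0.45, 0.45, 1.2)) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(voxel_size, series$frame_interval)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(tr_ms = series$tr, te_ms = series$te,
                            bolus_image_index = series$bolus_image_index,
                            truncation_index = series$truncation_index),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DSC series written by [write_dsc()]
#'
#' @param path NIfTI path (sidecar expected alongside)
#' @return a `dsc_series`
#' @export
read_dsc <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::fromJSON(side)
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 tr = meta$tr_ms, te = meta$te_ms,
                 frame_interval = meta$tr_ms / 1000,
                 bolus_image_index = meta$bolus_image_index,
                 truncation_index = meta$truncation_index),
            class = "dsc_series")
}

#' Write a cohort or profile table to CSV with a provenance sidecar
#'
#' @param table data.frame
#' @param path CSV path
#' @param config optional [pipeline_config()] recorded in `<path>.json`
#' @return the path, invisibly
#' @export
write_cohort_csv <- function(table, path, config = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(list(config = unclass(config),
                              package_version =
                                as.character(utils::packageVersion("strokefate")),
                              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write phantom ground truth (maps, masks and a JSON sidecar)
#'
#' @param phantom a `stroke_phantom`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$voxel_size
  write_volume(phantom$labels, file.path(dir, "atlas_labels.nii.gz"), vs)
  for (nm in names(phantom$truth))
    write_volume(phantom$truth[[nm]], file.path(dir, paste0("truth_", nm, ".nii.gz")), vs)
  for (nm in names(phantom$lesion_truth))
    write_volume(phantom$lesion_truth[[nm]],
                 file.path(dir, paste0("lesion_", nm, ".nii.gz")), vs)
  jsonlite::write_json(list(voxel_size = vs, midline_axis = phantom$midline_axis,
                            voxel_volume_ul = phantom$voxel_volume_ul),
                       file.path(dir, "phantom.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
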
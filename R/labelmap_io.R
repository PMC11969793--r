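#' Read and write segmented label maps as NIfTI-1
#'
#' Label maps are stored as integer NIfTI volumes (.nii / .nii.gz) with
#' voxel spacing in the header and the world origin in the qform offset.
#' Tissue names are not representable in a NIfTI header, so they travel
#' in a JSON sidecar (`<path minus extension>.labels.json`) written
#' alongside the volume and read back automatically.
#'
#' @param grid a [tissue_grid()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `write_labelmap` returns `path` invisibly; `read_labelmap`
#'   returns a [tissue_grid()].
#' @export
write_labelmap <- function(grid, path) {
  stopifnot(inherits(grid, "tissue_grid"))
  hdr <- list(pixdim = c(1, grid$spacing, 0, 0, 0, 0),
              qform_code = 2L,
              quatern_b = 0, quatern_c = 0, quatern_d = 0,
              qoffset_x = grid$origin[1], qoffset_y = grid$origin[2],
              qoffset_z = grid$origin[3])
  img <- RNifti::asNifti(grid$labels, reference = hdr, datatype = "int16")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(grid$label_names), sidecar_path(path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
}

#' @rdname write_labelmap
#' @param label_names optional named character vector overriding the JSON
#'   sidecar.
#' @export
read_labelmap <- function(path, label_names = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3)
    stop("label map must be a 3-D volume, got ", length(dim(arr)), "-D")
  if (any(arr != round(arr)))
    stop("label map contains non-integer voxel values")
  if (is.null(label_names)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop("no label-name sidecar found at ", sc,
           "; pass label_names explicitly")
    label_names <- unlist(jsonlite::read_json(sc))
  }
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- RNifti::xform(img)[1:3, 4]
  tissue_grid(arr, spacing, origin, label_names)
}

#' Write a field-magnitude map as a float NIfTI volume
#'
#' @param field 3-D numeric array (V/cm).
#' @param grid the [tissue_grid()] providing spacing/origin.
#' @param path output path.
#' @export
write_fieldmap <- function(field, grid, path) {
  stopifnot(identical(dim(field), dim(grid$labels)))
  hdr <- list(pixdim = c(1, grid$spacing, 0, 0, 0, 0),
              qform_code = 2L,
              quatern_b = 0, quatern_c = 0, quatern_d = 0,
              qoffset_x = grid$origin[1], qoffset_y = grid$origin[2],
              qoffset_z = grid$origin[3])
  img <- RNifti::asNifti(field, reference = hdr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}
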
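# Volume I/O: NIfTI for quantitative exchange, multi-page TIFF + JSON sidecar
# for tools that expect section stacks.

#' Write a volume or mask to NIfTI
#'
#' Projection volumes are written as float32, masks as uint8; the voxel size is
#' carried in the header pixdim.
#'
#' @param x a `projection_volume`, `binary_mask`, `atlas_partition`,
#'   `density_class_map` or `confidence_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  v <- x$values %||% x$labels %||% x$classes
  dtype <- if (inherits(x, "projection_volume")) "float" else "uint8"
  storage.mode(v) <- if (dtype == "float") "double" else "integer"
  attr(v, "pixdim") <- x$voxel_size_um / 1000  # header in mm
  RNifti::writeNifti(v, path, datatype = dtype)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param as `"volume"` for a `projection_volume`, `"mask"` for a
#'   `binary_mask`, `"atlas"` for raw integer labels + names supplied later.
#' @return The requested object (for `"atlas"`, a plain integer array with a
#'   `voxel_size_um` attribute, to be wrapped with [atlas_partition()]).
#' @export
read_volume_nifti <- function(path, as = c("volume", "mask", "atlas")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3] * 1000
  v <- array(as.vector(img), dim = dim(img))
  switch(as,
    volume = projection_volume(v, vs, origin_label = path),
    mask = binary_mask(v > 0.5, vs),
    atlas = {
      storage.mode(v) <- "integer"
      attr(v, "voxel_size_um") <- vs
      v
    }
  )
}

#' Write a volume as a multi-page TIFF stack with a JSON sidecar
#'
#' One TIFF page per anterior-posterior section; the sidecar records voxel
#' size and the axis convention so the stack can be reconstituted losslessly.
#'
#' @param x a `projection_volume` or `binary_mask`.
#' @param path output `.tif` path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path) {
  v <- x$values
  storage.mode(v) <- "double"
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    voxel_size_um = x$voxel_size_um,
    axis_order = c("anterior-posterior", "dorsal-ventral", "medial-lateral"),
    kind = if (inherits(x, "binary_mask")) "mask" else "volume",
    n_sections = dim(v)[1]
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_volume_tiff()]
#'
#' @param path `.tif` path with a `<path>.json` sidecar.
#' @return A `projection_volume` or `binary_mask` per the sidecar's `kind`.
#' @export
read_volume_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d2 <- dim(pages[[1]])
  v <- array(0, dim = c(length(pages), d2))
  for (i in seq_along(pages)) v[i, , ] <- pages[[i]]
  if (identical(sidecar$kind, "mask")) {
    binary_mask(v > 0.5, sidecar$voxel_size_um)
  } else {
    projection_volume(v, sidecar$voxel_size_um)
  }
}
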
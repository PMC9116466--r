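#' Write a trabecular volume as a multipage TIFF
#'
#' One 8-bit grayscale page per z slice; 0 = marrow, 255 = bone. TIFF
#' carries no voxel-size metadata here, so the physical voxel size must be
#' supplied again when reading.
#'
#' @param vol a \code{trabecular_volume}.
#' @param path output file path (.tif).
#' @return \code{path}, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "trabecular_volume"))
  d <- dim(vol)
  pages <- lapply(seq_len(d[3]), function(k) {
    # tiff expects row-major images: rows = y, cols = x
    t(matrix(as.numeric(vol[, , k]), nrow = d[1]))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a trabecular volume from a multipage TIFF
#'
#' Inverse of [write_volume_tiff()]: pages become z slices, pixel values
#' >= 0.5 become bone.
#'
#' @param path TIFF file path.
#' @param voxel_size voxel edge length in mm (default: the reference
#'   24.5 um).
#' @return A \code{trabecular_volume}.
#' @export
read_volume_tiff <- function(path, voxel_size = 0.0245) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])[1:2]
  mask <- array(FALSE, dim = c(d2[2], d2[1], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    mask[, , k] <- t(pg) >= 0.5
  }
  trabecular_volume(mask, voxel_size)
}
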
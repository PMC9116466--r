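#' Bone volume fraction of a trabecular volume
#'
#' BV/TV: the fraction of voxels that are bone matrix.
#'
#' @param vol a \code{trabecular_volume} (or any logical 3D array).
#' @return A fraction in \[0, 1\].
#' @export
measure_bvtv <- function(vol) {
  stopifnot(length(vol) > 0)
  mean(vol)
}

#' Plate-model trabecular histomorphometry
#'
#' Standard indirect (plate-model) measures derived from the bone volume
#' and surface:
#' \itemize{
#'   \item BS: bone surface, estimated by counting exposed voxel faces
#'     (bone voxel adjacent to marrow in the 6-neighborhood) times the face
#'     area, multiplied by a stereological correction
#'     (\code{surface_correction}, default 2/3, which compensates the
#'     overestimate of a staircase voxel surface for randomly oriented
#'     interfaces; use 1 for axis-aligned plates).
#'   \item Tb.Th = 2 BV/BS, Tb.N = (BV/TV)/Tb.Th, Tb.Sp = 1/Tb.N - Tb.Th.
#'   \item Tb.Sp SD: SD of twice the Euclidean distance from marrow voxels
#'     to the nearest bone voxel (a local-separation proxy).
#' }
#' Faces on the array boundary are not counted as exposed.
#'
#' @param vol a \code{trabecular_volume}.
#' @param surface_correction multiplier applied to the voxel-face surface
#'   area estimate.
#' @return A list of class \code{morphometry_report} with \code{bvtv}
#'   (fraction), \code{bs_bv} (mm^-1), \code{tb_th} (um), \code{tb_n}
#'   (mm^-1), \code{tb_sp} (um), \code{tb_sp_sd} (um).
#' @export
measure_plate_model <- function(vol, surface_correction = 2 / 3) {
  stopifnot(inherits(vol, "trabecular_volume"))
  lv <- attr(vol, "voxel_size")
  mask <- unclass(vol); attributes(mask) <- list(dim = dim(vol))
  nb <- sum(mask)
  if (nb == 0L) stop("degenerate volume: no bone voxels")
  n_faces <- count_exposed_faces(mask)
  if (n_faces == 0L) stop("degenerate volume: zero bone surface area")
  bvtv <- mean(mask)
  bv <- nb * lv^3                                   # mm^3
  bs <- surface_correction * n_faces * lv^2         # mm^2
  tb_th <- 2 * bv / bs                              # mm
  tb_n <- bvtv / tb_th                              # mm^-1
  tb_sp <- 1 / tb_n - tb_th                         # mm
  edt <- edt3d(!mask, lv)                           # distance marrow -> bone
  tb_sp_sd <- stats::sd(2 * edt[!mask])
  structure(list(bvtv = bvtv, bs_bv = bs / bv,
                 tb_th = tb_th * 1000, tb_n = tb_n,
                 tb_sp = tb_sp * 1000, tb_sp_sd = tb_sp_sd * 1000),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("BV/TV %.1f%%  BS/BV %.2f mm^-1  Tb.Th %.0f um  Tb.N %.2f mm^-1  Tb.Sp %.0f um (SD %.0f)\n",
              100 * x$bvtv, x$bs_bv, x$tb_th, x$tb_n, x$tb_sp, x$tb_sp_sd))
  invisible(x)
}

# number of bone/marrow interface faces (6-neighborhood, non-periodic;
# faces on the array boundary are not exposed)
count_exposed_faces <- function(mask) {
  d <- dim(mask)
  sum(mask[-d[1], , ] != mask[-1, , ]) +
    sum(mask[, -d[2], ] != mask[, -1, ]) +
    sum(mask[, , -d[3]] != mask[, , -1])
}

#' Euclidean distance transform of a 3D mask
#'
#' Exact Euclidean distance (in mm) from every TRUE voxel to the nearest
#' FALSE voxel, computed with the separable lower-envelope algorithm.
#' Voxels in the FALSE phase get distance 0.
#'
#' @param mask logical 3D array; distances are computed inside TRUE.
#' @param voxel_size voxel edge length in mm.
#' @return A numeric 3D array of distances.
#' @export
edt3d <- function(mask, voxel_size = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- cpp_edt3d(as.integer(mask), dim(mask))
  dim(d) <- dim(mask)
  sqrt(d) * voxel_size
}
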
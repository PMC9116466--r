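#' Stage-specific structural population parameters
#'
#' Means and SDs of cortical thickness (mm) and trabecular bone volume
#' fraction (%) for the three osteoporosis stages of the ultradistal-radius
#' population model, plus their Pearson correlation.
#'
#' @return A list with per-stage \code{c_th} and \code{bvtv_pct}
#'   (mean, sd) and the correlation \code{r}.
#' @export
structure_population <- function() {
  list(
    normal       = list(c_th = c(mean = 0.804, sd = 0.149),
                        bvtv_pct = c(mean = 13.4, sd = 2.8)),
    osteopenia   = list(c_th = c(mean = 0.571, sd = 0.173),
                        bvtv_pct = c(mean = 10.3, sd = 3.0)),
    osteoporosis = list(c_th = c(mean = 0.487, sd = 0.138),
                        bvtv_pct = c(mean = 8.5,  sd = 2.2)),
    r = 0.54
  )
}

#' Sample the structural parameters of one tissue model
#'
#' Dermis and subcutaneous thicknesses are uniform on \[1, 2\] mm and
#' \[1, 6\] mm. Cortical thickness and BV/TV are drawn from a bivariate
#' normal with the stage's marginals and correlation r = 0.54
#' (Gaussian copula on the stated normal marginals), rejection-resampled
#' until the cortical thickness is positive, BV/TV lies in (0, 1) and the
#' cortical shell fits inside the outer bone surface.
#'
#' @param stage one of \code{"normal"}, \code{"osteopenia"},
#'   \code{"osteoporosis"}.
#' @param correlation Pearson correlation between cortical thickness and
#'   BV/TV (default from [structure_population()]).
#' @param l_obs outer-bone-surface side length, mm.
#' @param y_extent axial (y) extent of the bone, mm.
#' @param mbmd bone-matrix mineral density, g/cm^3.
#' @param max_attempts resampling bound.
#' @return A list of class \code{structural_params}: \code{t_dermis},
#'   \code{t_subcut}, \code{c_th} (mm), \code{bvtv} (fraction),
#'   \code{stage}, \code{l_obs}, \code{y_extent}, \code{mbmd}.
#' @export
sample_structure <- function(stage = c("normal", "osteopenia", "osteoporosis"),
                             correlation = NULL, l_obs = 17.15,
                             y_extent = 35.28, mbmd = 1.2,
                             max_attempts = 1000L) {
  stage <- match.arg(stage)
  pop <- structure_population()
  r <- if (is.null(correlation)) pop$r else correlation
  st <- pop[[stage]]
  t_dermis <- runif(1, 1, 2)
  t_subcut <- runif(1, 1, 6)
  for (i in seq_len(max_attempts)) {
    z1 <- rnorm(1); z2 <- rnorm(1)
    c_th <- st$c_th["mean"] + st$c_th["sd"] * z1
    bvtv <- (st$bvtv_pct["mean"] +
               st$bvtv_pct["sd"] * (r * z1 + sqrt(1 - r^2) * z2)) / 100
    if (c_th > 0 && bvtv > 0 && bvtv < 1 && 2 * c_th < l_obs) {
      return(structure(list(t_dermis = t_dermis, t_subcut = t_subcut,
                            c_th = unname(c_th), bvtv = unname(bvtv),
                            stage = stage, l_obs = l_obs,
                            y_extent = y_extent, mbmd = mbmd),
                       class = "structural_params"))
    }
  }
  stop("sample_structure: resampling bound exceeded")
}

#' Optical properties of one tissue
#'
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s scattering coefficient, mm^-1 (>= 0).
#' @param g scattering anisotropy factor, in (-1, 1).
#' @param n refractive index (>= 1).
#' @return A list of class \code{optical_props}.
#' @export
optical_props <- function(mu_a, mu_s, g, n) {
  stopifnot(mu_a >= 0, mu_s >= 0, g > -1, g < 1, n >= 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_props")
}

#' Bone scattering coefficient from matrix mineral density
#'
#' Linear wet-density relation \eqn{\mu_s = 17.77\, mBMD - 0.74} (mm^-1,
#' mBMD in g/cm^3) at 850 nm.
#'
#' @param mbmd bone-matrix mineral density, g/cm^3.
#' @return Scattering coefficient in mm^-1.
#' @export
#' @examples
#' mu_s_from_mbmd(1.2)  # 20.584
mu_s_from_mbmd <- function(mbmd) {
  mus <- 17.77 * mbmd - 0.74
  if (any(mus < 0))
    stop("mu_s_from_mbmd: negative scattering coefficient (mbmd < 0.74/17.77)")
  mus
}

#' Sample per-tissue optical properties
#'
#' Soft-tissue coefficients are uniform over the literature ranges at
#' 850 nm; bone properties are fixed; marrow shares the drawn subcutaneous
#' properties (radial marrow is predominantly adipose).
#'
#' \tabular{lllll}{
#'  tissue \tab mu_a (mm^-1) \tab mu_s (mm^-1) \tab g \tab n \cr
#'  dermis \tab U(0.0063, 0.0856) \tab U(14.20, 25.06) \tab 0.9 \tab 1.4 \cr
#'  subcutaneous \tab U(0.0049, 0.0124) \tab U(8.30, 13.96) \tab 0.9 \tab 1.4 \cr
#'  bone (cortical & trabecular) \tab 0.0237 \tab [mu_s_from_mbmd()] \tab 0.9 \tab 1.55 \cr
#'  marrow \tab = subcutaneous draw \tab = subcutaneous draw \tab 0.9 \tab 1.4
#' }
#'
#' @param mbmd bone-matrix mineral density, g/cm^3.
#' @return A named list of [optical_props()] for \code{dermis},
#'   \code{subcutaneous}, \code{cortical}, \code{trabecular}, \code{marrow}.
#' @export
sample_optics <- function(mbmd = 1.2) {
  dermis <- optical_props(runif(1, 0.0063, 0.0856), runif(1, 14.20, 25.06),
                          0.9, 1.4)
  subcut <- optical_props(runif(1, 0.0049, 0.0124), runif(1, 8.30, 13.96),
                          0.9, 1.4)
  bone <- optical_props(0.0237, mu_s_from_mbmd(mbmd), 0.9, 1.55)
  list(dermis = dermis, subcutaneous = subcut, cortical = bone,
       trabecular = bone, marrow = subcut)
}

#' Areal bone mineral density of the bone tissue
#'
#' Converts the volumetric description (matrix density, cortical shell,
#' trabecular volume fraction) into the areal BMD label:
#' \deqn{aBMD = mBMD\left[1 - (1 - BV/TV)\left(1 - \frac{2\,C.Th}{l_{obs}}\right)^2\right]}
#' The thickness ratio is dimensionless, so cortical thickness and outer
#' bone surface side may be given in any common unit; the result carries
#' the conventional g/cm^2 label.
#'
#' @param p a \code{structural_params} list (or any list with \code{c_th},
#'   \code{bvtv}, \code{l_obs}, \code{mbmd}).
#' @return aBMD in g/cm^2.
#' @export
#' @examples
#' compute_abmd(list(bvtv = 0.134, c_th = 0.804, l_obs = 17.15, mbmd = 1.2))
compute_abmd <- function(p) {
  stopifnot(p$bvtv >= 0, p$bvtv <= 1, p$c_th >= 0)
  if (2 * p$c_th >= p$l_obs)
    stop("compute_abmd: cortical shells overlap (2*C.Th >= l_obs)")
  p$mbmd * (1 - (1 - p$bvtv) * (1 - 2 * p$c_th / p$l_obs)^2)
}

#' Assemble a layered voxel tissue model
#'
#' Builds the simulation geometry: nested rectangular shells in the x-z
#' plane (dermis outside subcutaneous outside cortical), extruded along the
#' bone (y) axis, with the trabecular compartment filled by periodic tiling
#' of the binary trabecular pattern. The y faces are bare bone-tissue
#' boundaries (no soft-tissue cap). Shell thicknesses are rounded to whole
#' voxels. Marrow optics must equal subcutaneous optics and cortical optics
#' must equal trabecular (bone) optics.
#'
#' @param p a \code{structural_params} from [sample_structure()].
#' @param optics named list from [sample_optics()].
#' @param trabecular a \code{trabecular_volume}; its voxel size sets the
#'   simulation voxel size.
#' @param seed provenance seed recorded on the model.
#' @return A list of class \code{tissue_model}: voxel size \code{lv} (mm),
#'   grid dims \code{dims}, per-axis shell voxel counts \code{n_dermis},
#'   \code{n_subcut}, \code{n_cortical}, the trabecular \code{mask},
#'   optics matrix (5 tissues x mu_a, mu_s, g, n), \code{structure},
#'   \code{abmd} and extents in mm.
#' @export
assemble <- function(p, optics, trabecular, seed = NA_integer_) {
  stopifnot(inherits(p, "structural_params"),
            inherits(trabecular, "trabecular_volume"))
  lab <- c("dermis", "subcutaneous", "cortical", "trabecular", "marrow")
  stopifnot(all(lab %in% names(optics)))
  if (!identical(unclass(optics$marrow), unclass(optics$subcutaneous)))
    stop("marrow optics must equal subcutaneous optics")
  if (!identical(unclass(optics$cortical), unclass(optics$trabecular)))
    stop("cortical and trabecular must share bone optics")
  lv <- attr(trabecular, "voxel_size")
  n_obs <- round(p$l_obs / lv)
  n_c <- max(1L, round(p$c_th / lv))
  n_d <- max(1L, round(p$t_dermis / lv))
  n_s <- max(1L, round(p$t_subcut / lv))
  n_inner <- n_obs - 2L * n_c
  if (n_inner < 1L) stop("cortical shell leaves no trabecular interior")
  if (any(dim(trabecular) < 1L)) stop("empty trabecular volume")
  nx <- n_obs + 2L * (n_d + n_s)
  ny <- round(p$y_extent / lv)
  nz <- nx
  om <- t(vapply(optics[lab],
                 function(o) c(o$mu_a, o$mu_s, o$g, o$n), numeric(4)))
  dimnames(om) <- list(lab, c("mu_a", "mu_s", "g", "n"))
  structure(list(type = "radius", lv = lv, dims = c(nx, ny, nz),
                 n_dermis = n_d, n_subcut = n_s, n_cortical = n_c,
                 mask = trabecular, optics = om, structure = p,
                 abmd = compute_abmd(p), seed = seed,
                 extent = c(nx, ny, nz) * lv),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("Tissue model (%s): %dx%dx%d voxels at %.4g mm (%.1f x %.1f x %.1f mm)\n",
              x$type, x$dims[1], x$dims[2], x$dims[3], x$lv,
              x$extent[1], x$extent[2], x$extent[3]))
  if (!is.null(x$abmd)) cat(sprintf("  aBMD label %.4f g/cm^2\n", x$abmd))
  invisible(x)
}

#' Tissue label at a point inside a model
#'
#' Pure-R reference of the label rule used by the transport engine:
#' the point is voxelized and classified by its ring depth in the x-z
#' plane; interior voxels look up the periodically tiled trabecular mask.
#'
#' @param model a \code{tissue_model}.
#' @param point numeric xyz in mm, inside the model extent.
#' @return One of "dermis", "subcutaneous", "cortical", "trabecular",
#'   "marrow" (for a z-slab model, the layer's label).
#' @export
model_label_at <- function(model, point) {
  stopifnot(all(point >= 0), all(point <= model$extent + 1e-12))
  iv <- pmin(pmax(floor(point / model$lv), 0), model$dims - 1L)
  if (model$type == "zslab") {
    layer <- findInterval(iv[3], cumsum(model$z_bands), left.open = FALSE) + 1L
    return(rownames(model$optics)[min(layer, nrow(model$optics))])
  }
  fx <- min(iv[1], model$dims[1] - 1L - iv[1])
  fz <- min(iv[3], model$dims[3] - 1L - iv[3])
  ring <- min(fx, fz)
  n_d <- model$n_dermis; n_s <- model$n_subcut; n_c <- model$n_cortical
  if (ring < n_d) return("dermis")
  if (ring < n_d + n_s) return("subcutaneous")
  if (ring < n_d + n_s + n_c) return("cortical")
  md <- dim(model$mask)
  off <- n_d + n_s  # mask indexed from the inner box origin, tiled periodically
  ix <- (iv[1] - off) %% md[1] + 1L
  iy <- iv[2] %% md[2] + 1L
  iz <- (iv[3] - off) %% md[3] + 1L
  if (model$mask[ix, iy, iz]) "trabecular" else "marrow"
}
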
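#' Monte Carlo simulation configuration
#'
#' @param n_photons number of photon packets to launch (reference 1e7).
#' @param seed integer RNG seed; every photon gets its own counter-based
#'   stream derived from it, so results do not depend on execution order.
#' @param ambient_n refractive index of the surrounding medium (air).
#' @param roulette_threshold weight below which Russian roulette is played.
#' @param roulette_chance survival probability; survivors are reweighted by
#'   1/chance (unbiased termination).
#' @param mode \code{"region"} (default) accelerates propagation through the
#'   homogeneous soft-tissue shells by stepping region-boundary to
#'   region-boundary; \code{"voxel"} is the naive voxel-by-voxel traversal.
#'   Both modes implement identical physics.
#' @param record_escapes keep the per-packet escape table (needed for
#'   feature extraction).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_photons = 1e5, seed = 1L, ambient_n = 1.0,
                       roulette_threshold = 1e-4, roulette_chance = 0.1,
                       mode = c("region", "voxel"), record_escapes = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_photons >= 1, roulette_chance > 0, roulette_chance <= 1,
            roulette_threshold >= 0, ambient_n >= 1)
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 ambient_n = ambient_n,
                 roulette_threshold = roulette_threshold,
                 roulette_chance = roulette_chance, mode = mode,
                 record_escapes = record_escapes),
            class = "sim_config")
}

#' Run the voxel Monte Carlo photon transport
#'
#' Launches \code{config$n_photons} photon packets orthogonally onto the
#' center of the entry (z = 0) face of the model as a collimated,
#' infinitely narrow beam. Each packet starts with weight
#' \eqn{1 - R_{sp}} after the specular reflection
#' \eqn{R_{sp} = ((n_{amb} - n_1)/(n_{amb} + n_1))^2}, then undergoes
#' hop-drop-spin propagation: exponential steps
#' \eqn{s = -\ln\xi/(\mu_a + \mu_s)}, voxel-boundary handling with Fresnel
#' reflection/refraction at refractive-index mismatches, absorption deposits
#' \eqn{w\,\mu_a/\mu_t} at every scattering site, Henyey-Greenstein
#' direction updates and Russian roulette termination. Packets that leave
#' the model are recorded with exit position, direction, weight and face.
#'
#' @param model a \code{tissue_model} from [assemble()] or [slab_model()].
#' @param config a [sim_config()].
#' @return A list of class \code{run_result}: \code{escapes} (data.frame
#'   x, y, z, ux, uy, uz, w, face), \code{absorbed}, \code{specular},
#'   \code{escaped_weight}, \code{n_launched}, \code{launch} (x, y of the
#'   beam axis, mm). Energy bookkeeping satisfies
#'   specular + absorbed + escaped_weight = n_launched up to float
#'   round-off (roulette-corrected accounting).
#' @export
run_transport <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "tissue_model"), inherits(config, "sim_config"))
  m <- model
  if (m$type == "radius") {
    mask <- m$mask
    m$mask_data <- as.logical(mask)
    m$mask_dims <- dim(mask)
  }
  res <- cpp_run_transport(m, config$n_photons, config$seed,
                           config$roulette_threshold, config$roulette_chance,
                           config$mode, config$ambient_n,
                           config$record_escapes)
  faces <- c("z_min", "z_max", "x_max", "x_min", "y_min", "y_max")
  esc <- NULL
  if (config$record_escapes) {
    esc <- as.data.frame(res$escapes)
    esc$face <- factor(faces[esc$face], levels = faces)
  }
  structure(list(escapes = esc, absorbed = res$absorbed,
                 specular = res$specular,
                 escaped_weight = res$escaped_weight,
                 n_launched = res$n_launched,
                 launch = c(x = model$extent[1] / 2,
                            y = model$extent[2] / 2),
                 config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Monte Carlo run: N = %g, specular %.4g, absorbed %.4g, escaped %.4g\n",
              x$n_launched, x$specular, x$absorbed, x$escaped_weight))
  if (!is.null(x$escapes))
    print(table(x$escapes$face))
  invisible(x)
}

#' Layered slab tissue model
#'
#' A stack of homogeneous layers along z with finite lateral extent, used
#' for physics fixtures and for validating the voxel engine against a
#' layered Monte Carlo reference.
#'
#' @param layers data.frame with columns \code{thickness} (mm),
#'   \code{mu_a}, \code{mu_s} (mm^-1), \code{g}, \code{n}; one row per
#'   layer, first row is the entry layer.
#' @param lv voxel edge length, mm.
#' @param lateral lateral (x and y) extent, mm.
#' @return A \code{tissue_model} of type \code{"zslab"}.
#' @export
slab_model <- function(layers, lv = 0.05, lateral = 40) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1,
            all(c("thickness", "mu_a", "mu_s", "g", "n") %in% names(layers)))
  z_bands <- pmax(1L, as.integer(round(layers$thickness / lv)))
  nl <- as.integer(round(lateral / lv))
  nz <- sum(z_bands)
  om <- as.matrix(layers[, c("mu_a", "mu_s", "g", "n")])
  rownames(om) <- paste0("layer", seq_len(nrow(layers)))
  structure(list(type = "zslab", lv = lv, dims = c(nl, nl, nz),
                 z_bands = z_bands, optics = om,
                 extent = c(nl, nl, nz) * lv),
            class = "tissue_model")
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized reflectances; beyond the critical
#' angle the reflectance is 1 (total internal reflection).
#'
#' @param n_i,n_t refractive indices of the incident and transmitting media.
#' @param cos_i cosine of the incidence angle, in \[0, 1\].
#' @return list with \code{R} (reflectance) and \code{cos_t} (refracted
#'   cosine; 0 under total internal reflection).
#' @export
#' @examples
#' fresnel_unpolarized(1, 1.4, 1)$R  # 0.027778
fresnel_unpolarized <- function(n_i, n_t, cos_i) {
  stopifnot(n_i > 0, n_t > 0, cos_i >= 0, cos_i <= 1)
  cpp_fresnel(n_i, n_t, cos_i)
}

#' Specular reflectance of the entry beam
#'
#' Normal-incidence Fresnel reflectance at the ambient/first-tissue
#' interface; the launched packet weight is 1 minus this.
#'
#' @param n_ambient,n_tissue refractive indices.
#' @return Reflectance in \[0, 1).
#' @export
specular_reflectance <- function(n_ambient, n_tissue) {
  ((n_ambient - n_tissue) / (n_ambient + n_tissue))^2
}

#' Photon step length
#'
#' \eqn{s = -\ln(\xi)/(\mu_a + \mu_s)} with \eqn{\xi \sim U(0, 1]}.
#'
#' @param mu_a,mu_s absorption and scattering coefficients, mm^-1.
#' @param xi uniform random deviate(s) in (0, 1\]; defaults to fresh draws.
#' @return Step length(s) in mm.
#' @export
step_size <- function(mu_a, mu_s, xi = runif(1)) {
  mut <- mu_a + mu_s
  if (any(mut <= 0))
    stop("step_size: mu_a + mu_s must be positive (vacuum voxels unsupported)")
  -log(xi) / mut
}

#' Distance from a point inside a voxel to the voxel boundary
#'
#' For a cubic voxel of edge \code{lv} centered at the origin, the distance
#' along direction \code{mu} from local position \code{p} to the first face
#' hit: the minimum over axes of
#' \eqn{(l_v/2 - p_k\,\mathrm{sign}(\mu_k))/|\mu_k|} (axes with
#' \eqn{\mu_k = 0} excluded). Exact ties are broken toward the lower axis
#' index.
#'
#' @param p numeric length-3 local position, each component in
#'   \[-lv/2, lv/2\].
#' @param mu unit direction vector.
#' @param lv voxel edge length.
#' @return list with \code{db} (distance), \code{axis} (1 = x, 2 = y,
#'   3 = z) and \code{dir} (+1/-1, the travel sign on that axis).
#' @export
distance_to_boundary <- function(p, mu, lv) {
  if (all(mu == 0)) stop("direction vector is zero")
  stopifnot(length(p) == 3, length(mu) == 3,
            abs(sqrt(sum(mu^2)) - 1) < 1e-6,
            all(abs(p) <= lv / 2 + 1e-12))
  d <- rep(Inf, 3)
  for (k in 1:3) {
    if (mu[k] != 0)
      d[k] <- (lv / 2 - p[k] * sign(mu[k])) / abs(mu[k])
  }
  axis <- which.min(d)  # ties go to the lowest axis index
  list(db = d[axis], axis = axis, dir = sign(mu[axis]))
}

#' Henyey-Greenstein scattering-angle quantile
#'
#' Closed-form inverse CDF of the HG phase function:
#' \deqn{\cos\theta = \frac{1}{2g}\left[1 + g^2 -
#'   \left(\frac{1 - g^2}{1 - g + 2 g \xi}\right)^2\right]}
#' reducing to \eqn{\cos\theta = 2\xi - 1} (isotropic) as g approaches 0.
#'
#' @param g anisotropy factor, in (-1, 1).
#' @param xi uniform deviate(s) in \[0, 1\].
#' @return Scattering-angle cosine(s).
#' @export
#' @examples
#' hg_cosine(0.9, 0.5)  # 0.98550
hg_cosine <- function(g, xi) {
  stopifnot(g > -1, g < 1, all(xi >= 0), all(xi <= 1))
  if (abs(g) < 1e-12) return(2 * xi - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * xi)
  (1 + g^2 - t^2) / (2 * g)
}

#' Draw Henyey-Greenstein cosines with the engine's sampler
#'
#' Uses the same RNG and inversion as the C++ transport engine; intended
#' for statistical checks of the phase-function sampling.
#'
#' @param n number of draws.
#' @param g anisotropy factor.
#' @param seed integer seed.
#' @return numeric vector of cosines.
#' @export
sample_hg <- function(n, g, seed = 1L) {
  cpp_sample_hg(as.integer(n), g, as.integer(seed))
}
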
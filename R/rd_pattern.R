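#' Parameters of the activator-inhibitor reaction-diffusion model
#'
#' Bundles the coefficients, diffusion constants and grid description of the
#' two-species Turing system used to grow synthetic trabecular bone:
#' \deqn{\partial u/\partial t = f(u,v) + d_u \Delta u, \qquad
#'       \partial v/\partial t = g(u,v) + d_v \Delta v}
#' with cubic activator kinetics \eqn{f(u,v) = a_1 u + a_2 v + a_3 u^3}
#' (defaults 0.6, -1, -1) and linear inhibitor kinetics
#' \eqn{g(u,v) = b_1 u + b_2 v} (defaults 1.5, -2). With the default
#' diffusion contrast (\code{du = 2e-4}, \code{dv = 0.01}) the homogeneous
#' state is Turing-unstable and the activator settles into a labyrinthine
#' pattern whose thresholded super-level set resembles trabecular struts.
#'
#' @param shape integer vector of length 3, grid nodes per axis (all >= 8;
#'   even sizes recommended for spectral symmetry). The reference
#'   configuration is 720^3; 128^3 is the routine working size.
#' @param f_coeffs numeric length 3: coefficients of u, v and u^3 in f.
#' @param g_coeffs numeric length 2: coefficients of u and v in g.
#' @param du,dv diffusion coefficients of activator and inhibitor.
#' @param dt time step of the semi-implicit update.
#' @param n_steps number of update steps (fixed-count convergence).
#' @param spacing grid spacing in model units.
#' @param init_amplitude half-width of the uniform initial noise; u and v
#'   start as independent Uniform(-init_amplitude, +init_amplitude) fields.
#' @param seed integer RNG seed for the initial noise.
#'
#' @return An object of class \code{rd_params} (a validated list).
#' @seealso [solve_rd()], [calibrate_threshold()]
#' @export
#' @examples
#' p <- rd_params(shape = c(32, 32, 32), seed = 1)
rd_params <- function(shape = c(128L, 128L, 128L),
                      f_coeffs = c(0.6, -1, -1),
                      g_coeffs = c(1.5, -2),
                      du = 2e-4, dv = 0.01,
                      dt = 1, n_steps = 100L,
                      spacing = 0.025,
                      init_amplitude = 0.5,
                      seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(f_coeffs) == 3L, length(g_coeffs) == 2L,
            du > 0, dv > 0, dt > 0, spacing > 0,
            n_steps >= 1L, init_amplitude >= 0)
  structure(list(shape = shape, f_coeffs = as.numeric(f_coeffs),
                 g_coeffs = as.numeric(g_coeffs), du = du, dv = dv,
                 dt = dt, n_steps = as.integer(n_steps), spacing = spacing,
                 init_amplitude = init_amplitude, seed = as.integer(seed)),
            class = "rd_params")
}

#' @export
print.rd_params <- function(x, ...) {
  cat(sprintf("Reaction-diffusion parameters: %dx%dx%d grid, spacing %g\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing))
  cat(sprintf("  f = %.3g u %+.3g v %+.3g u^3 ; g = %.3g u %+.3g v\n",
              x$f_coeffs[1], x$f_coeffs[2], x$f_coeffs[3],
              x$g_coeffs[1], x$g_coeffs[2]))
  cat(sprintf("  du = %g, dv = %g, dt = %g, %d steps, seed %d\n",
              x$du, x$dv, x$dt, x$n_steps, x$seed))
  invisible(x)
}

# Squared magnitude of the continuous Laplacian symbol on the periodic grid:
# k^2 summed over the three axes, one value per grid node.
rd_laplacian_symbol <- function(shape, spacing) {
  k2_axis <- function(n) {
    m <- c(0:(n %/% 2), if (n > 2) -(((n - n %/% 2) - 1):1)) / (n * spacing)
    (2 * pi * m)^2
  }
  kx <- k2_axis(shape[1]); ky <- k2_axis(shape[2]); kz <- k2_axis(shape[3])
  outer(outer(kx, ky, "+"), kz, "+")
}

#' Solve the activator-inhibitor system on a periodic 3D grid
#'
#' Advances the reaction-diffusion system with a semi-implicit Fourier
#' spectral scheme: the stiff diffusion term is treated implicitly in
#' Fourier space, the reaction term explicitly, i.e.
#' \deqn{u_{t+1} = \mathcal{F}^{-1}\!\left[\frac{\mathcal{F}(u_t + dt\, f(u_t,v_t))}{1 + dt\, d_u k^2}\right]}
#' and analogously for v. The scheme is unconditionally stable for the
#' diffusion part; both real fields are packed into one complex FFT per
#' direction so each step costs two 3D transforms.
#'
#' @param params an [rd_params()] object.
#' @param init optional list with elements \code{u} and \code{v}, arrays of
#'   dimension \code{params$shape}, overriding the seeded uniform noise
#'   (used for deterministic tests and restarts).
#' @param return_v if TRUE, return both fields as a list.
#'
#' @return The converged activator field u as a 3D array with attributes
#'   \code{spacing} and \code{params} (class \code{scalar_field3d}), or
#'   \code{list(u, v)} when \code{return_v} is TRUE.
#' @export
#' @examples
#' u <- solve_rd(rd_params(shape = c(16, 16, 16), n_steps = 5, seed = 3))
#' range(u)
solve_rd <- function(params, init = NULL, return_v = FALSE) {
  stopifnot(inherits(params, "rd_params"))
  n <- params$shape
  if (is.null(init)) {
    set.seed(params$seed)
    a <- params$init_amplitude
    u <- array(runif(prod(n), -a, a), dim = n)
    v <- array(runif(prod(n), -a, a), dim = n)
  } else {
    u <- init$u; v <- init$v
    stopifnot(all(dim(u) == n), all(dim(v) == n))
  }
  k2 <- rd_laplacian_symbol(n, params$spacing)
  den_u <- 1 + params$dt * params$du * k2
  den_v <- 1 + params$dt * params$dv * k2
  rm(k2)
  # index-reversal permutation per axis: frequency negation k -> -k
  rx <- c(1L, n[1]:2L); ry <- c(1L, n[2]:2L); rz <- c(1L, n[3]:2L)
  fc <- params$f_coeffs; gc <- params$g_coeffs; dt <- params$dt
  nvox <- prod(n)
  for (it in seq_len(params$n_steps)) {
    fu <- fc[1] * u + fc[2] * v + fc[3] * u^3
    gv <- gc[1] * u + gc[2] * v
    # pack the two real reaction-updated fields into one complex transform
    FT <- fft(u + dt * fu + 1i * (v + dt * gv))
    FTc <- Conj(FT[rx, ry, rz])
    uh <- (FT + FTc) / 2
    vh <- (FT - FTc) / 2i
    z <- fft(uh / den_u + 1i * (vh / den_v), inverse = TRUE)
    u <- Re(z); v <- Im(z)
    u <- u / nvox; v <- v / nvox
    dim(u) <- n; dim(v) <- n
    if (!all(is.finite(range(u))) || !all(is.finite(range(v))))
      stop(sprintf("solver diverged at step %d (non-finite field values)", it))
  }
  attr(u, "spacing") <- params$spacing
  attr(u, "params") <- params
  class(u) <- c("scalar_field3d", class(u))
  if (return_v) list(u = u, v = v) else u
}

#' Activator threshold for a target bone volume fraction
#'
#' Evaluates the calibration polynomial that maps a target trabecular bone
#' volume fraction BV/TV to the activator threshold at which the binarized
#' pattern attains that fraction:
#' \deqn{u_{th} = -7.662\,x^3 + 1.645\,x^2 - 0.452\,x + 0.604}
#' with x = BV/TV as a fraction. The cubic is calibrated for the reference
#' solver configuration (default [rd_params()]); re-run
#' [calibrate_threshold()] if solver parameters change.
#'
#' @param bvtv target bone volume fraction, in (0, 1); the calibrated range
#'   is about 0.03 to 0.25.
#' @param coeffs polynomial coefficients in decreasing degree
#'   (cubic, quadratic, linear, constant), e.g. from [calibrate_threshold()].
#' @return The threshold value(s), vectorized over \code{bvtv}.
#' @export
#' @examples
#' uth_from_bvtv(0.134)
uth_from_bvtv <- function(bvtv, coeffs = c(-7.662, 1.645, -0.452, 0.604)) {
  if (any(!is.finite(bvtv)) || any(bvtv <= 0) || any(bvtv >= 1))
    stop("bvtv must lie strictly in (0, 1)")
  stopifnot(length(coeffs) == 4L)
  ((coeffs[1] * bvtv + coeffs[2]) * bvtv + coeffs[3]) * bvtv + coeffs[4]
}

#' Binarize an activator field into a trabecular volume
#'
#' Voxels with activator value \code{u >= uth} become bone matrix, the rest
#' marrow space.
#'
#' @param u a 3D numeric array (e.g. from [solve_rd()]).
#' @param uth finite threshold.
#' @param voxel_size physical edge length assigned to one grid voxel, in mm
#'   (reference 24.5 um = 0.0245 mm).
#' @return A \code{trabecular_volume}: logical 3D array (TRUE = bone) with a
#'   \code{voxel_size} attribute.
#' @export
binarize <- function(u, uth, voxel_size = 0.0245) {
  stopifnot(is.finite(uth), voxel_size > 0, length(dim(u)) == 3L)
  mask <- u >= uth
  attributes(mask) <- list(dim = dim(u))
  trabecular_volume(mask, voxel_size)
}

#' Construct a trabecular volume from a logical mask
#'
#' @param mask logical 3D array, TRUE = bone matrix, FALSE = marrow.
#' @param voxel_size voxel edge length in mm.
#' @return Object of class \code{trabecular_volume}.
#' @export
trabecular_volume <- function(mask, voxel_size = 0.0245) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, voxel_size > 0)
  structure(mask, voxel_size = voxel_size, class = "trabecular_volume")
}

#' @export
print.trabecular_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "Trabecular volume %dx%dx%d voxels, voxel %.4g mm, BV/TV = %.3f\n",
    d[1], d[2], d[3], attr(x, "voxel_size"), mean(x)))
  invisible(x)
}

#' Calibrate the threshold-to-BV/TV polynomial
#'
#' Re-derives the cubic mapping BV/TV -> threshold for a given solver
#' configuration: solves the reaction-diffusion system for
#' \code{n_patterns} independent seeds, binarizes every field at each
#' candidate threshold, averages the resulting bone volume fractions, and
#' fits a degree-3 least-squares polynomial threshold ~ BV/TV.
#'
#' @param params an [rd_params()] object (its \code{seed} seeds pattern 1;
#'   pattern k uses \code{seed + k - 1}).
#' @param thresholds candidate thresholds (>= 4 distinct values; the
#'   reference calibration used 13).
#' @param n_patterns number of independent patterns (>= 1; reference 10).
#' @return A list of class \code{uth_calibration} with \code{coeffs}
#'   (decreasing degree, usable as the \code{coeffs} argument of
#'   [uth_from_bvtv()]), \code{bvtv} (mean fraction per threshold),
#'   \code{thresholds}, and \code{residuals} of the fit.
#' @export
calibrate_threshold <- function(params, thresholds = default_calibration_thresholds(),
                                n_patterns = 10L) {
  stopifnot(inherits(params, "rd_params"),
            length(unique(thresholds)) >= 4L, n_patterns >= 1L)
  bv <- matrix(NA_real_, nrow = n_patterns, ncol = length(thresholds))
  for (k in seq_len(n_patterns)) {
    pk <- params
    pk$seed <- params$seed + k - 1L
    u <- solve_rd(pk)
    for (j in seq_along(thresholds)) bv[k, j] <- mean(u >= thresholds[j])
  }
  mbv <- colMeans(bv)
  if (length(unique(round(mbv, 12))) < 4L)
    stop("degenerate calibration design: thresholds give too few distinct BV/TV values")
  fit <- lm(thresholds ~ poly(mbv, 3, raw = TRUE))
  co <- rev(unname(coef(fit)))          # decreasing degree
  structure(list(coeffs = co, bvtv = mbv, thresholds = thresholds,
                 residuals = unname(fit$residuals),
                 n_patterns = n_patterns, params = params),
            class = "uth_calibration")
}

#' Default calibration thresholds
#'
#' 13 threshold values spanning the useful pattern range (bone volume
#' fractions of roughly 3 to 25 percent for the reference configuration).
#' @return numeric vector of length 13.
#' @export
default_calibration_thresholds <- function() seq(0.52, 0.64, by = 0.01)

#' Tile a trabecular volume along the bone axis
#'
#' Replicates the (periodic) pattern along the y axis to reach the axial
#' extent of the bone model; the bone volume fraction is unchanged.
#'
#' @param vol a \code{trabecular_volume}.
#' @param copies integer >= 1.
#' @return A \code{trabecular_volume} with \code{copies} times the y extent.
#' @export
tile_y <- function(vol, copies) {
  stopifnot(inherits(vol, "trabecular_volume"), copies >= 1)
  copies <- as.integer(copies)
  if (copies == 1L) return(vol)
  d <- dim(vol)
  out <- array(FALSE, dim = c(d[1], d[2] * copies, d[3]))
  m <- unclass(vol); attributes(m) <- list(dim = d)
  for (k in seq_len(copies))
    out[, ((k - 1L) * d[2] + 1L):(k * d[2]), ] <- m
  trabecular_volume(out, attr(vol, "voxel_size"))
}
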
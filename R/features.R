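#' Detection geometry and feature-pipeline settings
#'
#' Binning of the escaped-photon records into spatially resolved intensity
#' profiles, and the smoothing/downsampling applied to the lateral profile.
#'
#' @param dr radial bin width for backward/forward profiles, mm.
#' @param r_max maximum radius scored, mm.
#' @param r0_backward first scored radius of the backward profile, mm (the
#'   region under the source is excluded as unmeasurable).
#' @param dz lateral bin width along z, mm.
#' @param z_max maximum lateral distance scored, mm.
#' @param dy_half effective half-width of the lateral detector along y, mm.
#' @param smooth_window moving-average window for the lateral profile, mm.
#' @param downsample block-mean interval for the lateral profile, mm.
#' @param ln_eps_rel zero values are floored at this fraction of the
#'   block's maximum positive value before taking logs.
#' @return A list of class \code{profile_spec}.
#' @export
profile_spec <- function(dr = 0.4, r_max = 10, r0_backward = 0.5,
                         dz = 0.1, z_max = 20, dy_half = 5,
                         smooth_window = 1, downsample = 2,
                         ln_eps_rel = 1e-12) {
  stopifnot(dr > 0, r_max > 0, r0_backward > 0, r0_backward < r_max,
            dz > 0, z_max > 0, dy_half > 0, smooth_window > 0,
            downsample > 0, ln_eps_rel > 0)
  structure(list(dr = dr, r_max = r_max, r0_backward = r0_backward,
                 dz = dz, z_max = z_max, dy_half = dy_half,
                 smooth_window = smooth_window, downsample = downsample,
                 ln_eps_rel = ln_eps_rel),
            class = "profile_spec")
}

# bin edges of the backward profile: full-width bins from r0, the last one
# truncated at r_max
backward_edges <- function(spec) {
  e <- seq(spec$r0_backward, spec$r_max, by = spec$dr)
  if (e[length(e)] < spec$r_max) e <- c(e, spec$r_max)
  e
}

forward_edges <- function(spec) seq(0, spec$r_max, by = spec$dr)

lateral_edges <- function(spec) seq(0, spec$z_max, by = spec$dz)

bin_weights <- function(x, w, edges) {
  keep <- x >= edges[1] & x < edges[length(edges)]
  idx <- findInterval(x[keep], edges, rightmost.closed = FALSE)
  out <- numeric(length(edges) - 1L)
  if (any(keep)) {
    sums <- tapply(w[keep], idx, sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

#' Score the backward (reflected) radial intensity profile
#'
#' Packets leaving through the entry face are binned by radial distance
#' from the beam axis into annuli of width \code{dr} starting at
#' \code{r0_backward}; each bin's summed weight is divided by N and the
#' exact annulus area \eqn{\pi(r_{i+1}^2 - r_i^2)}, giving an intensity per
#' launched photon per mm^2.
#'
#' @param escapes escape data.frame (columns x, y, z, w, face).
#' @param spec a [profile_spec()].
#' @param N number of launched photons.
#' @param launch xy position of the beam axis, mm (named or positional).
#' @return Numeric vector of bin intensities with attribute \code{edges}.
#' @export
score_backward <- function(escapes, spec, N, launch) {
  edges <- backward_edges(spec)
  e <- escapes[escapes$face == "z_min", , drop = FALSE]
  r <- sqrt((e$x - launch[[1]])^2 + (e$y - launch[[2]])^2)
  iw <- bin_weights(r, e$w, edges)
  area <- pi * diff(edges^2)
  structure(iw / (N * area), edges = edges)
}

#' Score the forward (transmitted) radial intensity profile
#'
#' As [score_backward()] but for packets leaving through the far (+z)
#' face, with annular bins starting at r = 0, i.e. areas
#' \eqn{\Delta A_i = 2\pi (i + 1/2)\Delta r^2}.
#'
#' @inheritParams score_backward
#' @return Numeric vector of bin intensities with attribute \code{edges}.
#' @export
score_forward <- function(escapes, spec, N, launch) {
  edges <- forward_edges(spec)
  e <- escapes[escapes$face == "z_max", , drop = FALSE]
  r <- sqrt((e$x - launch[[1]])^2 + (e$y - launch[[2]])^2)
  iw <- bin_weights(r, e$w, edges)
  area <- pi * diff(edges^2)   # equals 2*pi*(i + 1/2)*dr^2
  structure(iw / (N * area), edges = edges)
}

#' Score the lateral axial intensity profile
#'
#' Packets leaving through the +x face within \code{dy_half} of the beam
#' axis in y are binned by their z distance from the irradiated surface;
#' each bin is divided by N and the detector area
#' \eqn{\Delta A_z = 2\,\Delta y\,\Delta z}.
#'
#' @inheritParams score_backward
#' @return Numeric vector of bin intensities with attribute \code{edges}.
#' @export
score_lateral <- function(escapes, spec, N, launch) {
  edges <- lateral_edges(spec)
  e <- escapes[escapes$face == "x_max", , drop = FALSE]
  e <- e[abs(e$y - launch[[2]]) <= spec$dy_half, , drop = FALSE]
  iw <- bin_weights(e$z, e$w, edges)
  area <- 2 * spec$dy_half * spec$dz
  structure(iw / (N * area), edges = edges)
}

#' Intensity profiles of one Monte Carlo run
#'
#' @param run a \code{run_result} from [run_transport()] with recorded
#'   escapes.
#' @param spec a [profile_spec()].
#' @return List of class \code{intensity_profiles} with \code{Br},
#'   \code{Fr}, \code{Lz} and \code{N}.
#' @export
score_profiles <- function(run, spec = profile_spec()) {
  stopifnot(inherits(run, "run_result"), !is.null(run$escapes))
  structure(list(Br = score_backward(run$escapes, spec, run$n_launched, run$launch),
                 Fr = score_forward(run$escapes, spec, run$n_launched, run$launch),
                 Lz = score_lateral(run$escapes, spec, run$n_launched, run$launch),
                 N = run$n_launched),
            class = "intensity_profiles")
}

pop_var <- function(x) mean((x - mean(x))^2)

safe_ln <- function(x, eps_rel) {
  mx <- max(x[x > 0], 0)
  if (mx == 0) return(rep(NA_real_, length(x)))
  log(pmax(x, eps_rel * mx))
}

#' Build the diffuse-light feature vector
#'
#' Assembles the three feature blocks from the intensity profiles:
#' \itemize{
#'   \item \code{Bf}: the raw backward bins plus log mean and log variance,
#'   \item \code{Ff}: log mean and log variance of the forward profile (the
#'     raw forward bins do not form a usable distribution),
#'   \item \code{Lf}: the lateral profile after a centered moving average
#'     over \code{smooth_window} and block means over \code{downsample}
#'     (10 values for the default geometry), each log-transformed, plus log
#'     mean and log variance of the raw lateral profile.
#' }
#' Zeros are floored at \code{ln_eps_rel} times the block maximum before
#' logs; a block with no signal at all yields NA features and the
#' \code{flagged} attribute names it.
#'
#' @param profiles an [score_profiles()] result.
#' @param spec the matching [profile_spec()].
#' @return Named numeric feature vector (length 40 for the default
#'   geometry) with attributes \code{blocks} (index ranges) and
#'   \code{flagged} (character vector of empty blocks, possibly empty).
#' @export
build_features <- function(profiles, spec = profile_spec()) {
  Br <- as.numeric(profiles$Br)
  Fr <- as.numeric(profiles$Fr)
  Lz <- as.numeric(profiles$Lz)
  eps <- spec$ln_eps_rel
  flagged <- character(0)

  if (all(Br <= 0)) flagged <- c(flagged, "Bf")
  mBr <- mean(Br); vBr <- pop_var(Br)
  Bf <- c(Br, safe_ln(c(mBr, vBr), eps))

  if (all(Fr <= 0)) flagged <- c(flagged, "Ff")
  Ff <- safe_ln(c(mean(Fr), pop_var(Fr)), eps)

  if (all(Lz <= 0)) flagged <- c(flagged, "Lf")
  win <- 2L * (round(spec$smooth_window / spec$dz) %/% 2L) + 1L  # centered, odd
  halfw <- win %/% 2L
  nL <- length(Lz)
  cs <- cumsum(c(0, Lz))
  lo <- pmax(seq_len(nL) - halfw, 1L)
  hi <- pmin(seq_len(nL) + halfw, nL)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)   # edge-truncated window
  blk <- round(spec$downsample / spec$dz)
  nblk <- floor(length(sm) / blk)
  dsm <- vapply(seq_len(nblk),
                function(i) mean(sm[((i - 1L) * blk + 1L):(i * blk)]),
                numeric(1))
  Lf <- c(safe_ln(dsm, eps), safe_ln(c(mean(Lz), pop_var(Lz)), eps))

  fv <- c(Bf, Ff, Lf)
  names(fv) <- c(sprintf("Bf_%02d", seq_along(Br) - 1L), "Bf_lnm", "Bf_lnv",
                 "Ff_lnm", "Ff_lnv",
                 sprintf("Lf_%02d", seq_len(nblk) - 1L), "Lf_lnm", "Lf_lnv")
  blocks <- list(Bf = seq_len(length(Br) + 2L),
                 Ff = length(Br) + 2L + 1:2,
                 Lf = length(Br) + 4L + seq_len(nblk + 2L))
  structure(fv, blocks = blocks, flagged = flagged)
}

#' Fit a feature standardizer
#'
#' Per-column mean-0/SD-1 scaling (population SD). Constant columns are
#' dropped and recorded. The \code{fitted_on} provenance string records
#' whether the scaler saw only training folds (\code{"train-folds"}, the
#' leakage-free default) or the whole dataset (\code{"full-dataset"}).
#'
#' @param X numeric matrix, rows = models, columns = features.
#' @param fitted_on provenance label.
#' @return A list of class \code{standardizer} with \code{mu},
#'   \code{sigma}, \code{keep} (retained column indices), \code{dropped}
#'   (names of constant columns) and \code{fitted_on}.
#' @export
fit_standardizer <- function(X, fitted_on = c("train-folds", "full-dataset")) {
  fitted_on <- match.arg(fitted_on)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- which(sigma > 0)
  dropped <- colnames(X)[sigma == 0]
  if (length(dropped))
    warning(sprintf("dropping %d constant feature(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  structure(list(mu = mu, sigma = sigma, keep = keep, dropped = dropped,
                 fitted_on = fitted_on),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param s a [fit_standardizer()] result.
#' @param X matrix (or single feature vector) to transform with the stored
#'   means and SDs; constant columns identified at fit time are removed.
#' @return Transformed matrix with the retained columns.
#' @export
apply_standardizer <- function(s, X) {
  stopifnot(inherits(s, "standardizer"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, s$mu), 2, pmax(s$sigma, .Machine$double.xmin), "/")
  Z[, s$keep, drop = FALSE]
}
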